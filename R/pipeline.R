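#' @title Pipeline runners: calibrate, extract, guilds
#'
#' @description
#' Three runners wire the modules into the genome-to-guilds pipeline
#' and write their outputs to disk: [run_calibrate()] turns labelled
#' score files into a cutoff manifest, [run_extract()] turns genome or
#' proteome FASTA files into count, assertion and trait matrices, and
#' [run_guilds()] turns a trait matrix into distances, a dendrogram, a
#' variance curve, guild assignments and guild profiles. A thin
#' command-line script over these functions ships in
#' `inst/cli/traitguilds.R`.
#'
#' Genomes are processed independently, so extraction parallelises by
#' mapping genomes to workers; results are independent of the worker
#' count and scheduling, and reruns on identical inputs are
#' byte-identical.
#'
#' @name pipeline
NULL

#' Build and validate a run configuration
#'
#' @param genomes Directory of nucleotide FASTA files (`.fa`, `.fna`,
#'   `.fasta`), or `NULL` for proteome input.
#' @param proteins Directory of amino-acid FASTA files (`.faa`), or
#'   `NULL`.
#' @param hmm_library Path to the HMMER3 profile library.
#' @param manifest_file,rules_file,hierarchy_file Schema file paths
#'   (default: the packaged example schema).
#' @param score_dir Directory of labelled score files (calibration
#'   runs).
#' @param trait_matrix_file Trait matrix path (guild runs).
#' @param out Output directory (created if absent).
#' @param threads Worker count for per-genome parallelism.
#' @param seed Integer seed for all randomness.
#' @param missing_cutoff,min_ribosomal,min_guild_size Policy flags.
#' @param k,variance_target Guild resolution (exactly one for guild
#'   runs).
#' @param growth_model_file,ogt_model_file Life-history model files
#'   (`NULL` disables life-history prediction).
#' @return A validated `"run_config"` list.
#' @export
run_config <- function(genomes = NULL, proteins = NULL,
                       hmm_library = NULL, manifest_file = NULL,
                       rules_file = NULL, hierarchy_file = NULL,
                       score_dir = NULL, trait_matrix_file = NULL,
                       out = "traitguilds_out", threads = 1L, seed = 1L,
                       missing_cutoff = "reject", min_ribosomal = 10L,
                       min_guild_size = 1L, k = NULL,
                       variance_target = NULL,
                       growth_model_file = NULL, ogt_model_file = NULL) {
  schema_dir <- system.file("extdata", "schema", package = "traitguilds")
  if (is.null(manifest_file)) manifest_file <- file.path(schema_dir, "manifest.tsv")
  if (is.null(rules_file)) rules_file <- file.path(schema_dir, "rules.tsv")
  if (is.null(hierarchy_file)) hierarchy_file <- file.path(schema_dir, "hierarchy.tsv")
  cfg <- list(genomes = genomes, proteins = proteins,
              hmm_library = hmm_library, manifest_file = manifest_file,
              rules_file = rules_file, hierarchy_file = hierarchy_file,
              score_dir = score_dir,
              trait_matrix_file = trait_matrix_file, out = out,
              threads = as.integer(threads), seed = as.integer(seed),
              missing_cutoff = missing_cutoff,
              min_ribosomal = as.integer(min_ribosomal),
              min_guild_size = as.integer(min_guild_size), k = k,
              variance_target = variance_target,
              growth_model_file = growth_model_file,
              ogt_model_file = ogt_model_file)
  for (field in c("genomes", "proteins", "hmm_library", "manifest_file",
                  "rules_file", "hierarchy_file", "score_dir",
                  "trait_matrix_file", "growth_model_file",
                  "ogt_model_file")) {
    p <- cfg[[field]]
    if (!is.null(p) && !file.exists(p)) {
      stop("config path does not exist: ", field, " = ", p,
           call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

write_run_manifest <- function(config, out_dir, extra = list()) {
  meta <- list(
    package_version = as.character(utils::packageVersion("traitguilds")),
    r_version = R.version.string,
    seed = config$seed,
    engines = list(
      prodigal = unname(Sys.which("prodigal")),
      hmmsearch = unname(Sys.which("hmmsearch"))
    )
  )
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1L))]
  yaml::write_yaml(c(list(config = cfg), meta, extra),
                   file.path(out_dir, "run_manifest.yaml"))
}

list_fasta <- function(dir, exts) {
  files <- sort(list.files(dir, full.names = TRUE))
  files[tools::file_ext(files) %in% exts]
}

#' Run trusted-cutoff calibration over a directory of score files
#'
#' @param config A `"run_config"` with `score_dir` set.
#' @return Invisibly, the [summarize_performance()] summary; writes
#'   `cutoffs.tsv`, `performance.tsv` and `run_manifest.yaml` into the
#'   output directory. Uncalibratable models are listed in the summary
#'   and left without a cutoff.
#' @export
run_calibrate <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$score_dir)) {
    stop("calibration needs score_dir", call. = FALSE)
  }
  files <- sort(list.files(config$score_dir, pattern = "\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0L) {
    stop("no score files in ", config$score_dir, call. = FALSE)
  }
  cutoffs <- lapply(files, function(f) {
    select_trusted_cutoff(threshold_metrics(read_score_set(f)))
  })
  summary <- summarize_performance(cutoffs)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_cutoff_table(summary, file.path(config$out, "cutoffs.tsv"))
  utils::write.table(summary$table, file.path(config$out, "performance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(config, config$out,
                     list(n_models = summary$aggregate$n_models,
                          n_uncalibratable =
                            summary$aggregate$n_models -
                            summary$aggregate$n_calibratable))
  invisible(summary)
}

extract_one_genome <- function(path, config, schema, is_proteome) {
  if (is_proteome) {
    proteins <- read_proteome_fasta(path)
    genome <- genome_record(proteins$genome_id, sequence = NULL)
  } else {
    genome <- read_genome_fasta(path)
    proteins <- predict_orfs(genome)
  }
  hits <- scan_proteins(proteins, config$hmm_library)
  kept <- filter_hits(hits, schema$manifest,
                      missing_cutoff = config$missing_cutoff)
  list(genome = genome, proteins = proteins, hits = kept)
}

#' Run trait extraction over a directory of genomes or proteomes
#'
#' @param config A `"run_config"` with `genomes` or `proteins` and
#'   `hmm_library` set.
#' @return Invisibly, a list with the count table, assertion matrix and
#'   the trait matrices at granularities 3, 2 and 1; all are also
#'   written to the output directory together with a run manifest.
#'   Genomes that fail are skipped with a warning and listed in the
#'   manifest.
#' @export
run_extract <- function(config) {
  stopifnot(inherits(config, "run_config"))
  is_proteome <- is.null(config$genomes)
  dir <- if (is_proteome) config$proteins else config$genomes
  if (is.null(dir)) stop("extract needs genomes or proteins", call. = FALSE)
  if (is.null(config$hmm_library)) {
    stop("extract needs hmm_library", call. = FALSE)
  }
  files <- list_fasta(dir, if (is_proteome) "faa" else
    c("fa", "fna", "fasta"))
  if (length(files) == 0L) stop("no FASTA files in ", dir, call. = FALSE)

  manifest <- read_hmm_manifest(config$manifest_file)
  rules <- read_rules(config$rules_file)
  hierarchy <- read_trait_hierarchy(config$hierarchy_file)
  compiled <- compile_ruleset(rules, manifest)
  schema <- list(manifest = manifest, rules = rules,
                 hierarchy = hierarchy, compiled = compiled)

  worker <- function(path) {
    tryCatch(extract_one_genome(path, config, schema, is_proteome),
             error = function(e) structure(list(path = path,
                                                message = conditionMessage(e)),
                                           class = "extract_failure"))
  }
  results <- if (config$threads > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(files, worker, mc.cores = config$threads,
                       mc.preschedule = FALSE)
  } else {
    lapply(files, worker)
  }

  failed <- Filter(function(r) inherits(r, "extract_failure"), results)
  results <- Filter(function(r) !inherits(r, "extract_failure"), results)
  for (f in failed) {
    warning("genome skipped: ", f$path, " (", f$message, ")",
            call. = FALSE)
  }
  if (length(results) == 0L) stop("all genomes failed", call. = FALSE)

  genomes <- lapply(results, `[[`, "genome")
  hits <- do.call(rbind, lapply(results, `[[`, "hits"))
  # deterministic ordering regardless of worker scheduling
  hits <- hits[order(hits$genome_id, hits$hmm_name, hits$protein_id,
                     -hits$bitscore), , drop = FALSE]
  table <- count_table(hits, genomes, models = manifest$hmm_name)
  assertions <- suppressWarnings(assert_matrix(compiled, table))
  tm3 <- build_trait_matrix(assertions, table, schema,
                            unknown_size = if (is_proteome) "raw" else
                              "error")
  tm2 <- rollup(tm3, 2L)
  tm1 <- rollup(tm3, 1L)

  life <- NULL
  if (!is.null(config$growth_model_file) &&
      !is.null(config$ogt_model_file) && !is_proteome) {
    rows <- lapply(results, function(r) {
      tryCatch(life_history_traits(r$genome, r$proteins, r$hits,
                                   manifest,
                                   config$growth_model_file,
                                   config$ogt_model_file,
                                   min_ribosomal = config$min_ribosomal),
               error = function(e) c(doubling_time_h = NA_real_,
                                     ogt_celsius = NA_real_))
    })
    life <- do.call(rbind, rows)
    rownames(life) <- vapply(genomes, `[[`, "", "genome_id")
  }

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  write_count_table(table, file.path(config$out, "gene_counts.tsv"))
  write_assertion_matrix(assertions,
                         file.path(config$out, "rule_assertions.tsv"))
  write_trait_matrix(tm3, file.path(config$out, "traits_granularity3.tsv"))
  write_trait_matrix(tm2, file.path(config$out, "traits_granularity2.tsv"))
  write_trait_matrix(tm1, file.path(config$out, "traits_granularity1.tsv"))
  utils::write.table(hits, file.path(config$out, "filtered_hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(life)) {
    utils::write.table(data.frame(genome_id = rownames(life), life),
                       file.path(config$out, "life_history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_run_manifest(config, config$out, list(
    n_genomes = length(genomes),
    n_failed = length(failed),
    failed = vapply(failed, `[[`, "", "path"),
    cutoff_table_hash = unname(tools::md5sum(config$manifest_file))))
  invisible(list(count_table = table, assertions = assertions,
                 traits3 = tm3, traits2 = tm2, traits1 = tm1,
                 life_history = life, n_failed = length(failed)))
}

#' Read a trait matrix written by [write_trait_matrix()]
#'
#' @param path Trait matrix path.
#' @return A `"trait_matrix"` (value types inferred: columns with only
#'   0/1 values are binary).
#' @export
read_trait_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- strsplit(lines[[1L]], "\t")[[1L]][-1L]
  strategy <- strsplit(lines[[2L]], "\t")[[1L]][-1L]
  df <- utils::read.delim(text = lines[-(1:2)], header = FALSE)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  colnames(values) <- header
  vt <- ifelse(apply(values, 2L, function(col) all(col %in% c(0, 1))),
               "binary", "count")
  new_trait_matrix(values, vt, strategy, 3L)
}

#' Run guild discovery on a trait matrix
#'
#' @param config A `"run_config"` with `trait_matrix_file` and one of
#'   `k` / `variance_target` set.
#' @return Invisibly, a list with the fitted `"guild_model"`, the
#'   `"guild_assignment"` and the `"guild_profile"`; writes the
#'   distance matrix, Newick dendrogram, variance curve, assignments
#'   and profiles into the output directory.
#' @export
run_guilds <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$trait_matrix_file)) {
    stop("guild run needs trait_matrix_file", call. = FALSE)
  }
  matrix <- read_trait_matrix(config$trait_matrix_file)
  if (nrow(matrix) < 2L) stop("need at least 2 genomes", call. = FALSE)
  model <- guild_model(matrix)
  assignment <- define_guilds(model, k = config$k,
                              variance_target = config$variance_target,
                              min_size = config$min_guild_size)
  profile <- guild_profiles(assignment, matrix)

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  dm <- as.matrix(model$distance)
  utils::write.table(data.frame(genome_id = rownames(dm), dm,
                                check.names = FALSE),
                     file.path(config$out, "distance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_dendrogram_newick(model$tree,
                           file.path(config$out, "dendrogram.nwk"))
  utils::write.table(model$curve,
                     file.path(config$out, "variance_curve.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(genome_id = names(assignment$assignment),
               guild = assignment$assignment,
               flagged = assignment$assignment %in% assignment$flagged),
    file.path(config$out, "guild_assignments.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(guild = rownames(profile$means), profile$means,
               check.names = FALSE),
    file.path(config$out, "guild_profiles.tsv"), sep = "\t",
    quote = FALSE, row.names = FALSE)
  utils::write.table(profile$tests,
                     file.path(config$out, "trait_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_manifest(config, config$out,
                     list(k = assignment$k,
                          r_squared = assignment$r_squared))
  invisible(list(model = model, assignment = assignment,
                 profile = profile))
}
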