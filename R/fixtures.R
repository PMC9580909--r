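#' @title Synthetic data generators
#'
#' @description
#' Every stage of the pipeline can be exercised without external
#' downloads: labelled bit-score sets stand in for database benchmark
#' scans, planted-guild trait matrices stand in for genome compendia,
#' and toy genomes with planted ORFs stand in for real assemblies. All
#' generators are driven by a single Mersenne-Twister seed; per-purpose
#' sub-seeds are derived by stable hashing of `(seed, purpose)` so that
#' adding one stage never perturbs another.
#'
#' @name fixtures
NULL

# stable 31-bit sub-seed from (seed, purpose)
derive_seed <- function(seed, purpose) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(purpose)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Generate a labelled bit-score set
#'
#' Positive scores are drawn from `Normal(mu_pos, sd)` and negatives
#' from `Normal(mu_neg, sd)`; `mu_pos > mu_neg` is required unless
#' `allow_overlap` (for deliberately inseparable fixtures).
#'
#' @param model Model name.
#' @param n_pos,n_neg Numbers of positive / reported negative scores.
#' @param mu_pos,mu_neg,sd Score distribution parameters (bits).
#' @param n_unreported_neg Extra negatives scanned but never reported
#'   (below the engine floor).
#' @param seed Integer seed.
#' @param allow_overlap Permit `mu_pos <= mu_neg`.
#' @return A `"labeled_score_set"`.
#' @export
make_score_set <- function(model = "toy", n_pos = 50L, n_neg = 50L,
                           mu_pos = 100, mu_neg = 30, sd = 5,
                           n_unreported_neg = 0L, seed = 1L,
                           allow_overlap = FALSE) {
  if (mu_pos <= mu_neg && !allow_overlap) {
    stop("mu_pos must exceed mu_neg (set allow_overlap = TRUE to force)",
         call. = FALSE)
  }
  with_seed(derive_seed(seed, paste0("score_set/", model)), {
    labeled_score_set(
      model,
      positive_scores = stats::rnorm(n_pos, mu_pos, sd),
      negative_scores = stats::rnorm(n_neg, mu_neg, sd),
      n_negatives_total = n_neg + n_unreported_neg)
  })
}

#' Generate a planted-guild trait matrix
#'
#' Binary traits are drawn per guild from Bernoulli profiles, count
#' traits per guild from Poisson rates, and counts are normalised by
#' genome sizes drawn uniformly from `size_range`. With the default
#' parameters the guild profiles diverge strongly (between-guild
#' Bernoulli probability divergence 0.9, within-guild noise 0.05), the
#' regime in which complete-linkage clustering of the Wishart distance
#' recovers the planted labels.
#'
#' @param n_genomes Total genomes (split as evenly as possible across
#'   guilds).
#' @param n_binary,n_count Numbers of binary / count traits.
#' @param n_guilds Number of planted guilds.
#' @param divergence Between-guild profile divergence in (0, 1]: guild
#'   profiles use Bernoulli probabilities `0.5 +/- divergence/2`.
#' @param noise Probability of flipping each binary value after
#'   drawing.
#' @param rate_low,rate_high Poisson rates (counts per genome) for
#'   count traits in low/high guilds.
#' @param size_range Genome size range in bp.
#' @param seed Integer seed.
#' @return List with `matrix` (a `"trait_matrix"` at granularity 3),
#'   `labels` (planted guild of each genome) and `size_bp`.
#' @export
make_planted_guild_matrix <- function(n_genomes = 60L, n_binary = 20L,
                                      n_count = 5L, n_guilds = 3L,
                                      divergence = 0.9, noise = 0.05,
                                      rate_low = 2, rate_high = 20,
                                      size_range = c(2e6, 6e6),
                                      seed = 1L) {
  stopifnot(divergence > 0, divergence <= 1, noise >= 0, noise <= 0.5)
  with_seed(derive_seed(seed, "planted_guilds"), {
    labels <- rep(seq_len(n_guilds), length.out = n_genomes)
    labels <- sort(labels)
    p_hi <- 0.5 + divergence / 2
    p_lo <- 0.5 - divergence / 2
    # per-guild Bernoulli profile: every trait gets a high/low pattern
    # that is non-constant across guilds (constant traits carry no
    # guild signal and would only dilute the planted structure)
    non_constant_pattern <- function(levels) {
      repeat {
        pat <- sample(levels, n_guilds, replace = TRUE)
        if (length(unique(pat)) > 1L) return(pat)
      }
    }
    bin_profile <- if (n_guilds > 1L) {
      vapply(seq_len(n_binary), function(t) {
        non_constant_pattern(c(p_lo, p_hi))
      }, numeric(n_guilds))
    } else {
      matrix(sample(c(p_lo, p_hi), n_binary, replace = TRUE), nrow = 1L)
    }
    bin_profile <- matrix(bin_profile, nrow = n_guilds)
    cnt_profile <- if (n_guilds > 1L && n_count > 0L) {
      matrix(vapply(seq_len(n_count), function(t) {
        non_constant_pattern(c(rate_low, rate_high))
      }, numeric(n_guilds)), nrow = n_guilds)
    } else {
      matrix(sample(c(rate_low, rate_high), n_count, replace = TRUE),
             nrow = 1L)
    }
    size_bp <- round(stats::runif(n_genomes, size_range[[1L]],
                                  size_range[[2L]]))
    bin <- matrix(0, n_genomes, n_binary)
    for (i in seq_len(n_genomes)) {
      p <- bin_profile[labels[[i]], ]
      draw <- stats::rbinom(n_binary, 1L, p)
      flip <- stats::rbinom(n_binary, 1L, noise) == 1L
      draw[flip] <- 1L - draw[flip]
      bin[i, ] <- draw
    }
    cnt <- matrix(0, n_genomes, n_count)
    if (n_count > 0L) {
      # rates are per Mb: the per-bp genomic investment is the
      # guild-conserved quantity, so expected counts scale with the
      # drawn genome size
      for (i in seq_len(n_genomes)) {
        lambda <- cnt_profile[labels[[i]], ] * size_bp[[i]] / 1e6
        cnt[i, ] <- stats::rpois(n_count, lambda) / size_bp[[i]]
      }
    }
    values <- cbind(bin, cnt)
    rownames(values) <- sprintf("genome%03d", seq_len(n_genomes))
    colnames(values) <- c(sprintf("btrait%02d", seq_len(n_binary)),
                          if (n_count > 0L)
                            sprintf("ctrait%02d", seq_len(n_count)))
    mat <- new_trait_matrix(
      values,
      value_type = c(rep("binary", n_binary), rep("count", n_count)),
      strategy = rep("resource use", n_binary + n_count),
      granularity = 3L)
    names(size_bp) <- rownames(values)
    list(matrix = mat, labels = labels, size_bp = size_bp)
  })
}

# longest stop-free stretch (bp) over the off frames of a CDS: the two
# shifted forward frames and all three reverse frames
max_open_offframe_run <- function(cds) {
  stops <- c("TAA", "TAG", "TGA")
  runs <- numeric(0L)
  rev_comp <- chartr("ACGT", "TGCA",
                     paste(rev(strsplit(cds, "")[[1L]]), collapse = ""))
  for (seqs in list(c(substring(cds, 2L), substring(cds, 3L)),
                    c(rev_comp, substring(rev_comp, 2L),
                      substring(rev_comp, 3L)))) {
    for (s in seqs) {
      n <- nchar(s) %/% 3L
      if (n == 0L) next
      cods <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
      stop_at <- c(0L, which(cods %in% stops), n + 1L)
      runs <- c(runs, 3L * max(diff(stop_at) - 1L))
    }
  }
  max(runs)
}

# deterministic back-translation: synonymous codons sampled per
# position, resampled until every off frame (shifted or reverse) is
# interrupted by stop codons often enough that gene callers see a
# single unambiguous ORF
back_translate <- function(protein, max_open_bp = 150L, attempts = 50L) {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), gc)
  aa <- strsplit(toupper(protein), "")[[1L]]
  best <- NULL
  best_run <- Inf
  for (try in seq_len(attempts)) {
    codons <- vapply(aa, function(a) {
      fam <- fams[[a]]
      if (is.null(fam)) stop("invalid amino acid: ", a, call. = FALSE)
      fam[[sample.int(length(fam), 1L)]]
    }, "")
    cds <- paste(codons, collapse = "")
    run <- max_open_offframe_run(paste0("ATG", cds, "TAA"))
    if (run < best_run) {
      best <- cds
      best_run <- run
    }
    if (best_run <= max_open_bp) break
  }
  best
}

random_spacer <- function(len) {
  # flank with a motif carrying stop codons in every frame on both
  # strands, so planted ORFs are cleanly delimited for gene callers
  stops <- "TTAATTAATTAA"
  core <- max(0L, len - 2L * nchar(stops))
  paste0(stops,
         paste(sample(c("A", "C", "G", "T"), core, replace = TRUE),
               collapse = ""),
         stops)
}

#' Generate a toy genome with planted ORFs
#'
#' Back-translates the given protein sequences (start codon ATG, stop
#' codon TAA, random synonymous codons elsewhere), separates them with
#' random intergenic spacers and records the expected proteins, so a
#' prokaryotic gene caller can be checked for recovering the planted
#' genes by subsequence match.
#'
#' @param orfs Named character vector of amino-acid sequences to plant
#'   (without initial Met or stop).
#' @param genome_id Genome id.
#' @param spacer_bp Intergenic spacer length.
#' @param seed Integer seed.
#' @return List with `genome` (a `"genome_record"`) and `expected` (a
#'   `"protein_set"` of the planted proteins, Met-prefixed).
#' @export
make_toy_genome <- function(orfs, genome_id = "toy", spacer_bp = 150L,
                            seed = 1L) {
  stopifnot(length(names(orfs)) == length(orfs))
  with_seed(derive_seed(seed, paste0("toy_genome/", genome_id)), {
    pieces <- character(0L)
    expected <- character(0L)
    pieces <- random_spacer(spacer_bp)
    for (i in seq_along(orfs)) {
      aa <- toupper(orfs[[i]])
      cds <- paste0("ATG", back_translate(aa), "TAA")
      pieces <- c(pieces, cds, random_spacer(spacer_bp))
      expected[[names(orfs)[[i]]]] <- paste0("M", aa)
    }
    sequence <- paste(pieces, collapse = "")
    list(genome = genome_record(genome_id, c(contig1 = sequence)),
         expected = protein_set(genome_id, expected))
  })
}

#' Generate a random protein sequence
#'
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return Amino-acid string (no Met start, no stop).
#' @export
random_protein <- function(length = 150L, seed = 1L) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  with_seed(derive_seed(seed, paste0("protein/", length)), {
    paste(sample(aa, length, replace = TRUE), collapse = "")
  })
}

#' Build a toy profile-HMM library from mutated seed proteins
#'
#' For each requested model a family of point-mutated copies of a
#' random seed protein is generated (point mutations only, so the
#' copies are already aligned) and turned into a profile with
#' [build_hmm_from_seed_alignment()]. The true family members score
#' far above unrelated sequences, giving cleanly separated score
#' distributions.
#'
#' @param model_names Character vector of model names.
#' @param protein_length Seed protein length.
#' @param n_seed_seqs Family members per model.
#' @param mutation_rate Per-residue substitution probability.
#' @param seed Integer seed.
#' @param out Output library path.
#' @return List with `library` (path), `seeds` (named character vector
#'   of the seed proteins, one per model).
#' @export
make_toy_hmm_library <- function(model_names, protein_length = 120L,
                                 n_seed_seqs = 6L, mutation_rate = 0.1,
                                 seed = 1L,
                                 out = tempfile(fileext = ".hmm")) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  seeds <- character(0L)
  profiles <- character(0L)
  for (m in model_names) {
    fam <- with_seed(derive_seed(seed, paste0("hmm/", m)), {
      base <- sample(aa, protein_length, replace = TRUE)
      vapply(seq_len(n_seed_seqs), function(i) {
        mut <- stats::rbinom(protein_length, 1L, mutation_rate) == 1L
        copy <- base
        copy[mut] <- sample(aa, sum(mut), replace = TRUE)
        paste(copy, collapse = "")
      }, "")
    })
    names(fam) <- sprintf("%s_seed%d", m, seq_along(fam))
    seeds[[m]] <- fam[[1L]]
    profiles <- c(profiles, build_hmm_from_seed_alignment(fam, m))
  }
  concat_hmm_library(profiles, out)
  unlink(setdiff(profiles, out))
  list(library = out, seeds = seeds)
}
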