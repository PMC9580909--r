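# Shared end-to-end fixture: a toy HMM library for a subset of the
# packaged schema's gene families, plus small genomes with planted
# (mutated) family members. Built once per test run; everything is
# generated from code under a fixed seed.

pipeline_fixture_env <- new.env(parent = emptyenv())

# gene families of the packaged schema that get a toy profile HMM
fixture_families <- c("narG", "narH", "narI", "napA", "napB", "nirS",
                      "nirK", "norB", "norC", "norV", "norW", "nosZ",
                      "ptsG", "xylF", "xylG", "xylH", "amtB")

# which families each toy genome carries (name = copies planted)
fixture_gene_plan <- list(
  g01 = c(narG = 1L, narH = 1L, narI = 1L, napA = 1L, napB = 1L,
          nirS = 1L, norB = 1L, norC = 1L, nosZ = 1L, ptsG = 2L),
  g02 = c(nirK = 1L, norB = 1L, norC = 1L, nosZ = 1L),
  g03 = c(narG = 1L, narH = 1L, narI = 1L, xylF = 1L, xylG = 1L,
          xylH = 1L),
  g04 = integer(0L),
  g05 = c(nosZ = 3L, amtB = 1L)
)

mutate_protein <- function(protein, rate) {
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  chars <- strsplit(protein, "")[[1L]]
  mut <- stats::rbinom(length(chars), 1L, rate) == 1L
  chars[mut] <- sample(aa, sum(mut), replace = TRUE)
  paste(chars, collapse = "")
}

# Returns list(genome_dir, hmm_library, manifest_file, seeds, plan)
pipeline_fixture <- function(seed = 42L) {
  key <- as.character(seed)
  hit <- pipeline_fixture_env[[key]]
  if (!is.null(hit)) return(hit)

  root <- file.path(tempdir(), sprintf("tg_fixture_%d", seed))
  genome_dir <- file.path(root, "genomes")
  dir.create(genome_dir, showWarnings = FALSE, recursive = TRUE)

  lib <- make_toy_hmm_library(fixture_families, protein_length = 150L,
                              n_seed_seqs = 5L, mutation_rate = 0.08,
                              seed = seed,
                              out = file.path(root, "toy.hmm"))

  set.seed(seed + 1L)
  for (gid in names(fixture_gene_plan)) {
    plan <- fixture_gene_plan[[gid]]
    orfs <- character(0L)
    for (fam in names(plan)) {
      for (copy in seq_len(plan[[fam]])) {
        orfs[[sprintf("%s_%s_%d", gid, fam, copy)]] <-
          mutate_protein(lib$seeds[[fam]], 0.05)
      }
    }
    # every genome also carries unrelated filler genes (incl. g04,
    # which has no planted families at all)
    for (i in 1:2) {
      orfs[[sprintf("%s_filler%d", gid, i)]] <-
        random_protein(100L, seed = seed * 100L + i +
                         match(gid, names(fixture_gene_plan)) * 10L)
    }
    tg <- make_toy_genome(orfs, gid, spacer_bp = 120L,
                          seed = seed + match(gid, names(fixture_gene_plan)))
    writeLines(paste0(">", names(tg$genome$sequence), "\n",
                      tg$genome$sequence),
               file.path(genome_dir, paste0(gid, ".fa")))
  }

  # manifest: packaged annotations, uniform permissive cutoff of 50
  # bits (planted-family hits score in the hundreds; decoys never
  # reach the reporting floor)
  schema_dir <- system.file("extdata", "schema", package = "traitguilds")
  manifest <- read_hmm_manifest(file.path(schema_dir, "manifest.tsv"))
  manifest$trusted_cutoff <- rep(50, nrow(manifest))
  manifest_file <- file.path(root, "manifest.tsv")
  write_hmm_manifest(manifest, manifest_file)

  out <- list(genome_dir = genome_dir, hmm_library = lib$library,
              manifest_file = manifest_file, seeds = lib$seeds,
              plan = fixture_gene_plan, root = root)
  pipeline_fixture_env[[key]] <- out
  out
}
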