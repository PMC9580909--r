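#' @title Gene-family detection: genomes to gene-count tables
#'
#' @description
#' A genome (nucleotide FASTA) or proteome (amino-acid FASTA) is turned
#' into a per-genome gene-family count table in three steps: open
#' reading frames are predicted with Prodigal (skipped for proteome
#' input), the proteins are scanned against a profile-HMM library with
#' HMMER/`hmmsearch`, and the hits are filtered at each model's trusted
#' bit-score cutoff. Both external engines run behind small interfaces
#' so that the rest of the pipeline only sees plain data frames.
#'
#' @name gene_detection
NULL

# ---- genome and protein containers -----------------------------------------

#' Genome and protein-set records
#'
#' @param genome_id Unique genome identifier.
#' @param sequence Named character vector of contig nucleotide sequences
#'   (may be `NULL` for proteome-only input).
#' @param size_bp Genome length in base pairs; derived from `sequence`
#'   when present.
#' @return `genome_record()` returns a `"genome_record"`;
#'   `protein_set()` a `"protein_set"`.
#' @export
genome_record <- function(genome_id, sequence = NULL, size_bp = NULL) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (length(sequence) == 0L || !any(nzchar(sequence))) {
      stop("empty genome sequence for ", genome_id, call. = FALSE)
    }
    if (any(grepl("[^ACGTNRYSWKMBDHV]", sequence))) {
      stop("non-nucleotide characters in sequence of ", genome_id,
           call. = FALSE)
    }
    if (is.null(names(sequence))) {
      names(sequence) <- sprintf("%s_contig%d", genome_id,
                                 seq_along(sequence))
    }
    total <- sum(nchar(sequence))
    if (!is.null(size_bp) && size_bp != total) {
      stop("size_bp disagrees with sequence length for ", genome_id,
           call. = FALSE)
    }
    size_bp <- total
  }
  structure(list(genome_id = genome_id, sequence = sequence,
                 size_bp = size_bp), class = "genome_record")
}

#' @rdname genome_record
#' @param proteins Named character vector of amino-acid sequences;
#'   names are protein ids, unique within the genome.
#' @param cds Optional named character vector of the corresponding
#'   nucleotide coding sequences (same names as `proteins`), kept for
#'   codon-usage analyses.
#' @export
protein_set <- function(genome_id, proteins, cds = NULL) {
  proteins <- stats::setNames(as.character(proteins), names(proteins))
  stopifnot(!is.null(names(proteins)))
  if (anyDuplicated(names(proteins))) {
    stop("duplicate protein ids in genome ", genome_id, call. = FALSE)
  }
  structure(list(genome_id = genome_id, proteins = proteins, cds = cds),
            class = "protein_set")
}

#' Read a genome or proteome FASTA file
#'
#' One file is one genome; multiple records are treated as contigs.
#'
#' @param path FASTA path.
#' @param genome_id Genome id; defaults to the file name without
#'   extension.
#' @return A `"genome_record"` (nucleotide) or `"protein_set"`
#'   (amino acid).
#' @export
read_genome_fasta <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(fa|fna|fasta)$", "", basename(path))
  }
  seqs <- Biostrings::readDNAStringSet(path)
  sequence <- as.character(seqs)
  names(sequence) <- sub("\\s.*$", "", names(seqs))
  genome_record(genome_id, sequence)
}

#' @rdname read_genome_fasta
#' @export
read_proteome_fasta <- function(path, genome_id = NULL) {
  if (is.null(genome_id)) {
    genome_id <- sub("\\.(faa|fasta)$", "", basename(path))
  }
  seqs <- Biostrings::readAAStringSet(path)
  proteins <- sub("\\*+$", "", as.character(seqs))
  names(proteins) <- sub("\\s.*$", "", names(seqs))
  protein_set(genome_id, proteins)
}

write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(seqs) else
    Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

require_tool <- function(tool) {
  path <- Sys.which(tool)
  if (!nzchar(path)) {
    stop(sprintf("external tool '%s' not found on PATH", tool),
         call. = FALSE)
  }
  unname(path)
}

# ---- ORF prediction (Prodigal) ---------------------------------------------

orf_cache <- new.env(parent = emptyenv())

#' Predict open reading frames with Prodigal
#'
#' Runs Prodigal on the genome's contigs and returns the predicted
#' proteome with stable, deterministic protein ids
#' (`<contig>_<orf index>`). Results are cached per genome id and
#' sequence fingerprint within the session. `mode = "auto"` selects
#' Prodigal's metagenome mode for genomes shorter than 100 kb (single
#' mode needs enough sequence to train on).
#'
#' @param genome A `"genome_record"` with nucleotide sequence.
#' @param mode `"auto"`, `"single"` or `"meta"`.
#' @return A `"protein_set"`.
#' @export
predict_orfs <- function(genome, mode = c("auto", "single", "meta")) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "genome_record"))
  if (is.null(genome$sequence)) {
    stop("genome ", genome$genome_id,
         " has no nucleotide sequence; ORF prediction needs one",
         call. = FALSE)
  }
  if (mode == "auto") {
    mode <- if (genome$size_bp < 100000L) "meta" else "single"
  }
  fp <- paste(genome$genome_id, mode, genome$size_bp,
              substr(genome$sequence[[1L]], 1L, 80L), sep = "\r")
  hit <- orf_cache[[genome$genome_id]]
  if (!is.null(hit) && identical(hit$fingerprint, fp)) {
    return(hit$proteins)
  }

  require_tool("prodigal")
  tmp_fa <- tempfile(fileext = ".fa")
  tmp_faa <- tempfile(fileext = ".faa")
  tmp_fna <- tempfile(fileext = ".fna")
  on.exit(unlink(c(tmp_fa, tmp_faa, tmp_fna)))
  write_fasta(genome$sequence, tmp_fa, "DNA")
  status <- system2("prodigal",
                    c("-i", tmp_fa, "-a", tmp_faa, "-d", tmp_fna,
                      "-p", mode, "-q"),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tmp_faa)) {
    stop("prodigal failed on genome ", genome$genome_id, call. = FALSE)
  }
  seqs <- Biostrings::readAAStringSet(tmp_faa)
  proteins <- sub("\\*+$", "", as.character(seqs))
  names(proteins) <- sub("\\s.*$", "", names(seqs))
  cds_seqs <- Biostrings::readDNAStringSet(tmp_fna)
  cds <- as.character(cds_seqs)
  names(cds) <- sub("\\s.*$", "", names(cds_seqs))
  out <- protein_set(genome$genome_id, proteins, cds = cds[names(proteins)])
  orf_cache[[genome$genome_id]] <- list(fingerprint = fp, proteins = out)
  out
}

# ---- profile-HMM search (HMMER) --------------------------------------------

#' Scan proteins against a profile-HMM library with hmmsearch
#'
#' All hits above HMMER's reporting floor are returned with the
#' full-sequence bit score and E-value. Filtering at trusted cutoffs is
#' a separate step ([filter_hits()]).
#'
#' @param proteins A `"protein_set"` (or a list of them).
#' @param hmm_library Path to an HMMER3 ASCII profile library.
#' @return Data frame with columns `genome_id`, `protein_id`,
#'   `hmm_name`, `bitscore`, `evalue`, ordered by genome, model,
#'   descending score.
#' @export
scan_proteins <- function(proteins, hmm_library) {
  if (inherits(proteins, "protein_set")) proteins <- list(proteins)
  stopifnot(all(vapply(proteins, inherits, logical(1L), "protein_set")))
  if (!file.exists(hmm_library)) {
    stop("profile library not found: ", hmm_library, call. = FALSE)
  }
  if (sum(vapply(proteins, function(p) length(p$proteins), integer(1L))) == 0L) {
    stop("empty protein set", call. = FALSE)
  }
  first <- readLines(hmm_library, n = 1L)
  if (!grepl("^HMMER3", first)) {
    stop("malformed profile library (not HMMER3 ASCII): ", hmm_library,
         call. = FALSE)
  }
  require_tool("hmmsearch")

  # one search over all genomes; protein ids are namespaced by genome
  tmp_faa <- tempfile(fileext = ".faa")
  tmp_tbl <- tempfile(fileext = ".tbl")
  on.exit(unlink(c(tmp_faa, tmp_tbl)))
  seqs <- unlist(lapply(proteins, function(p) {
    stats::setNames(p$proteins,
                    paste(p$genome_id, names(p$proteins), sep = "\x01"))
  }))
  names(seqs) <- gsub("\x01", "|:|", names(seqs), fixed = TRUE)
  write_fasta(seqs, tmp_faa, "AA")
  status <- system2("hmmsearch",
                    c("--noali", "--cpu", "1", "--tblout", tmp_tbl,
                      "-o", if (.Platform$OS.type == "unix") "/dev/null" else "NUL",
                      hmm_library, tmp_faa),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(tmp_tbl)) {
    stop("hmmsearch failed", call. = FALSE)
  }
  parse_hmmsearch_tblout(tmp_tbl)
}

# Parse HMMER3 --tblout per-target output (full-sequence score columns)
parse_hmmsearch_tblout <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  empty <- data.frame(genome_id = character(0L), protein_id = character(0L),
                      hmm_name = character(0L), bitscore = numeric(0L),
                      evalue = numeric(0L))
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  target <- vapply(fields, `[`, "", 1L)
  query <- vapply(fields, `[`, "", 3L)
  evalue <- as.numeric(vapply(fields, `[`, "", 5L))
  score <- as.numeric(vapply(fields, `[`, "", 6L))
  parts <- strsplit(target, "|:|", fixed = TRUE)
  out <- data.frame(
    genome_id = vapply(parts, `[`, "", 1L),
    protein_id = vapply(parts, function(p) paste(p[-1L], collapse = "|:|"), ""),
    hmm_name = query, bitscore = score, evalue = evalue,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$genome_id, out$hmm_name, -out$bitscore,
                   out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- trusted-cutoff filtering and counting ---------------------------------

#' Filter HMM hits at trusted cutoffs
#'
#' Keeps hits whose full-sequence bit score is at or above the trusted
#' cutoff of their model (a score equal to the cutoff passes), and for
#' every (genome, protein, model) triple keeps only the best-scoring
#' hit.
#'
#' @param hits Hit data frame from [scan_proteins()].
#' @param manifest An `"hmm_manifest"` supplying per-model cutoffs.
#' @param missing_cutoff Policy for models without a cutoff: `"reject"`
#'   (default, error) or `"pass"` (hits kept unfiltered, with a
#'   warning).
#' @return Filtered hit data frame.
#' @export
filter_hits <- function(hits, manifest,
                        missing_cutoff = c("reject", "pass")) {
  missing_cutoff <- match.arg(missing_cutoff)
  stopifnot(inherits(manifest, "hmm_manifest"))
  unknown <- setdiff(unique(hits$hmm_name), manifest$hmm_name)
  if (length(unknown) > 0L) {
    stop("hits reference models absent from the manifest: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(hits) == 0L) return(hits)
  cutoff <- manifest$trusted_cutoff[match(hits$hmm_name, manifest$hmm_name)]
  if (anyNA(cutoff)) {
    bad <- unique(hits$hmm_name[is.na(cutoff)])
    if (missing_cutoff == "reject") {
      stop("models without a trusted cutoff: ",
           paste(bad, collapse = ", "),
           " (set missing_cutoff = \"pass\" to keep their hits)",
           call. = FALSE)
    }
    warning("models without a trusted cutoff pass unfiltered: ",
            paste(bad, collapse = ", "), call. = FALSE)
    cutoff[is.na(cutoff)] <- -Inf
  }
  kept <- hits[hits$bitscore >= cutoff, , drop = FALSE]
  if (nrow(kept) > 1L) {
    kept <- kept[order(kept$genome_id, kept$hmm_name, kept$protein_id,
                       -kept$bitscore, kept$evalue), , drop = FALSE]
    key <- paste(kept$genome_id, kept$hmm_name, kept$protein_id,
                 sep = "\r")
    kept <- kept[!duplicated(key), , drop = FALSE]
  }
  rownames(kept) <- NULL
  kept
}

#' Build a gene-family count table
#'
#' `count(genome, model)` is the number of distinct proteins of that
#' genome with a retained hit to that model. A protein may count toward
#' several models (family overlap is resolved downstream by the rules).
#' Genomes without hits appear as all-zero rows.
#'
#' @param filtered Filtered hit data frame from [filter_hits()].
#' @param genomes Character vector of genome ids, or a list of
#'   `"genome_record"` objects (their sizes are attached for later
#'   normalisation).
#' @param models Column set; defaults to the models observed in
#'   `filtered`. Pass `manifest$hmm_name` for a full-width table.
#' @return Integer matrix of class `"gene_count_table"` (genomes x
#'   models) with attribute `size_bp` when genome records were given.
#' @export
count_table <- function(filtered, genomes, models = NULL) {
  size_bp <- NULL
  if (is.list(genomes) && all(vapply(genomes, inherits, logical(1L),
                                     "genome_record"))) {
    size_bp <- vapply(genomes, function(g) {
      if (is.null(g$size_bp)) NA_real_ else as.numeric(g$size_bp)
    }, numeric(1L))
    genomes <- vapply(genomes, `[[`, "", "genome_id")
    names(size_bp) <- genomes
  }
  genomes <- as.character(genomes)
  if (anyDuplicated(genomes)) stop("duplicate genome ids", call. = FALSE)
  if (is.null(models)) models <- sort(unique(filtered$hmm_name))
  mat <- matrix(0L, nrow = length(genomes), ncol = length(models),
                dimnames = list(genomes, models))
  if (nrow(filtered) > 0L) {
    f <- filtered[filtered$genome_id %in% genomes &
                    filtered$hmm_name %in% models, , drop = FALSE]
    if (nrow(f) > 0L) {
      key <- paste(f$genome_id, f$hmm_name, f$protein_id, sep = "\r")
      f <- f[!duplicated(key), , drop = FALSE]
      tab <- table(factor(f$genome_id, levels = genomes),
                   factor(f$hmm_name, levels = models))
      mat[] <- as.integer(tab)
    }
  }
  structure(mat, size_bp = size_bp, class = c("gene_count_table", "matrix"))
}

#' @rdname count_table
#' @param table A `"gene_count_table"`.
#' @return `presence_matrix()` returns the companion logical matrix
#'   `count > 0`.
#' @export
presence_matrix <- function(table) {
  unclass(table) > 0L
}

#' Write a count table as tab-separated text
#'
#' @param table A `"gene_count_table"` (or any matrix).
#' @param path Output path. Rows are genomes, columns models.
#' @export
write_count_table <- function(table, path) {
  df <- data.frame(genome_id = rownames(table),
                   as.data.frame(unclass(table), check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
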