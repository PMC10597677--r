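# Global pairwise identity for homologous gene sets.

#' Global percent identity of two nucleotide sequences
#'
#' End-to-end (Needleman-Wunsch) alignment with match +1, mismatch -1,
#' linear gap -2, terminal gaps penalized. Identity is
#' `100 * identical columns / alignment length` (terminal gaps included in
#' the length). The dynamic-programming traceback uses a fixed preference
#' (diagonal, then gap in the second sequence, then gap in the first) so
#' results are reproducible. Comparison is case-insensitive and `N` never
#' counts as a match.
#'
#' @param a,b non-empty nucleotide sequences (character or `DNAString`).
#' @param match,mismatch,gap scoring parameters.
#' @return Percent identity in `[0, 100]`; symmetric in its arguments.
#' @examples
#' global_percent_identity("ACGTACGT", "ACGTACGT") # 100
#' @export
global_percent_identity <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  nw_alignment(a, b, match = match, mismatch = mismatch, gap = gap)$identity
}

#' Global alignment details
#'
#' The full result backing [global_percent_identity()]: score, aligned
#' strings, column and match counts.
#'
#' @inheritParams global_percent_identity
#' @return List with `score`, `aligned_a`, `aligned_b`, `columns`,
#'   `matches`, `identity`.
#' @export
nw_alignment <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  if (methods::is(a, "DNAString")) a <- as.character(a)
  if (methods::is(b, "DNAString")) b <- as.character(b)
  stopifnot(is.character(a), length(a) == 1, is.character(b), length(b) == 1)
  if (!nzchar(a) || !nzchar(b)) {
    abort("sequences must be non-empty", "pufa_input_error")
  }
  nw_align_cpp(toupper(a), toupper(b), match, mismatch, gap)
}

#' Construct a gene set for identity comparison
#'
#' A gene set is one sample's collection of homologous gene sequences keyed
#' by gene name (e.g. `elovl2/5`, `fed1`..`fed4`, `wx1`, `wx2`).
#'
#' @param sample_id sample identifier.
#' @param sequences named character vector or list, gene name to nucleotide
#'   sequence; names must be unique and sequences non-empty.
#' @param species,site optional metadata.
#' @return An object of class `gene_set`.
#' @export
gene_set <- function(sample_id, sequences, species = NA_character_,
                     site = NA_character_) {
  sequences <- unlist(as.list(sequences))
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))) ||
      anyDuplicated(names(sequences))) {
    abort("sequences must have unique, non-empty gene names", "pufa_input_error")
  }
  if (any(!nzchar(sequences))) {
    abort("sequences must be non-empty", "pufa_input_error")
  }
  structure(list(sample_id = sample_id, species = species, site = site,
                 sequences = toupper(sequences)),
            class = "gene_set")
}

#' Read a gene set from FASTA
#'
#' FASTA headers are taken as gene names.
#'
#' @param path FASTA path.
#' @inheritParams gene_set
#' @return A [gene_set()].
#' @export
read_gene_set <- function(path, sample_id = basename(path),
                          species = NA_character_, site = NA_character_) {
  dna <- Biostrings::readDNAStringSet(path)
  gene_set(sample_id, stats::setNames(as.character(dna), names(dna)),
           species = species, site = site)
}

#' Pairwise identity table for gene sets
#'
#' For each requested pair of samples, computes [global_percent_identity()]
#' per shared gene. Genes missing from either set are reported as `NA`
#' (rendered `*` in the TSV output), never as 0. Pairs sharing no gene are
#' skipped with a warning.
#'
#' @param sets list of [gene_set()] objects.
#' @param pairs list of length-2 character vectors of sample ids; default
#'   all unordered pairs.
#' @return A data frame of class `pufa_identity_table`: one row per pair,
#'   one column per gene occurring in any requested pair, plus `pair`.
#' @export
identity_table <- function(sets, pairs = NULL) {
  stopifnot(all(vapply(sets, inherits, TRUE, "gene_set")))
  ids <- vapply(sets, function(s) s$sample_id, "")
  if (anyDuplicated(ids)) abort("duplicate sample ids", "pufa_input_error")
  names(sets) <- ids
  if (is.null(pairs)) {
    if (length(ids) < 2) abort("need at least two sets", "pufa_input_error")
    idx <- utils::combn(ids, 2, simplify = FALSE)
    pairs <- idx
  }
  genes <- character(0)
  rows <- list()
  for (p in pairs) {
    if (!all(p %in% ids)) {
      abort(sprintf("unknown sample id in pair (%s)", paste(p, collapse = ",")),
            "pufa_input_error")
    }
    a <- sets[[p[1]]]; b <- sets[[p[2]]]
    shared <- intersect(names(a$sequences), names(b$sequences))
    if (length(shared) == 0) {
      warning(sprintf("pair %s,%s shares no gene; skipped", p[1], p[2]))
      next
    }
    union_genes <- union(names(a$sequences), names(b$sequences))
    genes <- union(genes, union_genes)
    vals <- stats::setNames(rep(NA_real_, length(union_genes)), union_genes)
    for (g in shared) {
      vals[[g]] <- global_percent_identity(a$sequences[[g]], b$sequences[[g]])
    }
    rows[[length(rows) + 1L]] <-
      list(pair = paste(p, collapse = " vs "), vals = vals)
  }
  genes <- sort(genes)
  df <- data.frame(pair = vapply(rows, function(r) r$pair, ""),
                   stringsAsFactors = FALSE)
  for (g in genes) {
    df[[g]] <- vapply(rows, function(r) {
      if (g %in% names(r$vals)) r$vals[[g]] else NA_real_
    }, 1)
  }
  class(df) <- c("pufa_identity_table", "data.frame")
  df
}

#' Write an identity table as TSV
#'
#' Identities are printed to one decimal; absent genes are rendered `*`
#' (the "no gene found" convention).
#'
#' @param tab a [identity_table()] result.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_identity_table <- function(tab, path) {
  out <- as.data.frame(tab)
  for (col in setdiff(names(out), "pair")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "*", sprintf("%.1f", out[[col]]))
  }
  write_tsv(out, path)
}
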