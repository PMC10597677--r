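# cox1 DNA-barcode contamination screening.
#
# Contigs are scored against a cox1 reference panel by local pairwise
# alignment (blastn-like scoring) and a sample is called positive when any
# contig exceeds the identity positivity threshold (strictly greater than
# 75% by default) over a minimal aligned length.

#' Recruit reads sharing k-mers with a reference panel
#'
#' A lightweight stand-in for read mapping: a read is recruited when it
#' shares at least one canonical k-mer (the lexicographic minimum of the
#' k-mer and its reverse complement) with any panel sequence, so
#' recruitment is strand-invariant. Reads shorter than `k` are never
#' recruited; k-mers containing `N` are ignored.
#'
#' @param reads FASTA/FASTQ path, `DNAStringSet`, or named character vector.
#' @param panel reference panel (same accepted forms); must be non-empty.
#' @param k odd k-mer size, default 31.
#' @return The recruited subset of `reads` as a `DNAStringSet`.
#' @export
recruit_reads <- function(reads, panel, k = 31) {
  k <- as.integer(k)
  if (k < 1 || k %% 2 == 0) abort("k must be odd and positive", "pufa_input_error")
  reads <- as_dna_set(reads)
  panel <- as_dna_set(panel)
  if (length(panel) == 0) abort("reference panel is empty", "pufa_config_error")

  panel_kmers <- new.env(parent = emptyenv())
  for (i in seq_along(panel)) {
    for (km in canonical_kmers(as.character(panel[[i]]), k)) {
      assign(km, TRUE, envir = panel_kmers)
    }
  }
  keep <- vapply(seq_along(reads), function(i) {
    kms <- canonical_kmers(as.character(reads[[i]]), k)
    any(vapply(kms, exists, TRUE, envir = panel_kmers, inherits = FALSE))
  }, TRUE)
  reads[keep]
}

canonical_kmers <- function(seq, k) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  fwd <- substring(seq, starts, starts + k - 1L)
  fwd <- fwd[!grepl("N", fwd, fixed = TRUE)]
  if (length(fwd) == 0) return(character(0))
  rc <- vapply(fwd, revcomp_chr, "", USE.NAMES = FALSE)
  unique(pmin(fwd, rc))
}

#' Default local-alignment scoring for the cox1 screen
#'
#' blastn-like defaults: match +1, mismatch -2, gap opening -5, gap
#' extension -2. Identity is computed over all alignment columns of the
#' best local alignment, internal gaps included (the stricter reading).
#'
#' @return Named list of scoring parameters.
#' @export
cox1_scoring <- function() {
  list(match = 1, mismatch = -2, gap_opening = 5, gap_extension = 2)
}

local_align_identity <- function(contig, ref, scoring = cox1_scoring()) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(contig), Biostrings::DNAString(ref),
    type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_opening, gapExtension = scoring$gap_extension)
  p <- as.character(Biostrings::pattern(aln))
  s <- as.character(Biostrings::subject(aln))
  cols <- nchar(p)
  if (cols == 0) return(list(identity = 0, aligned_length = 0L, score = -Inf))
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  matches <- sum(pc == sc & pc != "-" & pc != "N")
  list(identity = 100 * matches / cols, aligned_length = cols,
       score = Biostrings::score(aln))
}

#' Best-identity cox1 hit for one contig
#'
#' Locally aligns the contig (both strands) against every panel sequence
#' and reports the panel member maximizing percent identity among
#' alignments of at least `min_aligned_length` columns. Ties are broken by
#' longer aligned length, then lexicographic reference id. Identity is
#' `100 * matches / alignment columns`, internal gaps included.
#'
#' @param contig nucleotide sequence (character or `DNAString`).
#' @param panel cox1 reference panel (FASTA path, `DNAStringSet`, or named
#'   character vector); must be non-empty.
#' @param min_aligned_length minimal alignment length in columns
#'   (default 100 nt) below which a hit is not reported.
#' @param threshold positivity threshold in percent (exclusive; the rule is
#'   identity strictly greater than 75).
#' @param scoring scoring parameters, see [cox1_scoring()].
#' @return One-row data frame (`contig_id`, `reference_id`,
#'   `percent_identity`, `aligned_length`, `positive`); zero rows when no
#'   alignment reaches `min_aligned_length`.
#' @export
best_identity <- function(contig, panel, min_aligned_length = 100,
                          threshold = 75, scoring = cox1_scoring(),
                          contig_id = "contig") {
  if (methods::is(contig, "DNAString")) contig <- as.character(contig)
  stopifnot(is.character(contig), length(contig) == 1)
  contig <- toupper(contig)
  panel <- as_dna_set(panel)
  if (length(panel) == 0) abort("reference panel is empty", "pufa_config_error")

  best <- NULL
  for (i in seq_along(panel)) {
    ref <- as.character(panel[[i]])
    ref_id <- names(panel)[i]
    for (seq in c(contig, revcomp_chr(contig))) {
      hit <- local_align_identity(seq, ref, scoring)
      if (hit$aligned_length < min_aligned_length) next
      cand <- list(reference_id = ref_id, identity = hit$identity,
                   aligned_length = hit$aligned_length)
      if (is.null(best) ||
          cand$identity > best$identity ||
          (cand$identity == best$identity &&
             cand$aligned_length > best$aligned_length) ||
          (cand$identity == best$identity &&
             cand$aligned_length == best$aligned_length &&
             cand$reference_id < best$reference_id)) {
        best <- cand
      }
    }
  }
  if (is.null(best)) {
    return(data.frame(contig_id = character(0), reference_id = character(0),
                      percent_identity = numeric(0), aligned_length = integer(0),
                      positive = logical(0), stringsAsFactors = FALSE))
  }
  data.frame(contig_id = contig_id, reference_id = best$reference_id,
             percent_identity = best$identity,
             aligned_length = best$aligned_length,
             positive = best$identity > threshold &&
               best$aligned_length >= min_aligned_length,
             stringsAsFactors = FALSE)
}

#' Screen contigs for cox1 contamination
#'
#' Runs [best_identity()] on every contig and summarizes the sample with
#' [flag_contamination()].
#'
#' @param contigs FASTA path, `DNAStringSet`, or named character vector.
#' @inheritParams best_identity
#' @return A `pufa_cox1_report`, see [flag_contamination()].
#' @export
screen_cox1 <- function(contigs, panel, threshold = 75,
                        min_aligned_length = 100, scoring = cox1_scoring()) {
  dna <- as_dna_set(contigs)
  hits <- lapply(seq_along(dna), function(i) {
    seq <- as.character(dna[[i]])
    if (nchar(seq) < min_aligned_length) return(NULL)
    best_identity(seq, panel, min_aligned_length = min_aligned_length,
                  threshold = threshold, scoring = scoring,
                  contig_id = names(dna)[i])
  })
  hits <- do.call(rbind, c(hits, list(
    data.frame(contig_id = character(0), reference_id = character(0),
               percent_identity = numeric(0), aligned_length = integer(0),
               positive = logical(0), stringsAsFactors = FALSE))))
  flag_contamination(hits, threshold = threshold)
}

#' Summarize cox1 hits into a contamination verdict
#'
#' A hit is positive when its identity is strictly greater than `threshold`
#' ("higher than 75%": identity exactly 75.0 is negative); a sample is
#' positive when any hit is. Positive contigs are listed sorted by identity
#' descending.
#'
#' @param hits data frame of hits as returned by [best_identity()].
#' @param threshold positivity threshold in percent, default 75.
#' @return An object of class `pufa_cox1_report` with elements `positive`
#'   (sample verdict), `hits` (all hits, positivity recomputed at
#'   `threshold`) and `positives` (positive hits, identity-descending).
#' @export
flag_contamination <- function(hits, threshold = 75) {
  stopifnot(is.data.frame(hits))
  if (nrow(hits) > 0) {
    hits$positive <- hits$percent_identity > threshold
  }
  pos <- hits[hits$positive %in% TRUE, , drop = FALSE]
  pos <- pos[order(-pos$percent_identity, pos$contig_id), , drop = FALSE]
  rownames(pos) <- NULL
  structure(list(positive = nrow(pos) > 0, threshold = threshold,
                 hits = hits, positives = pos),
            class = "pufa_cox1_report")
}

#' @export
print.pufa_cox1_report <- function(x, ...) {
  cat(sprintf("<pufa_cox1_report: sample %s (%d/%d hits positive at >%g%%)>\n",
              if (x$positive) "POSITIVE" else "negative",
              nrow(x$positives), nrow(x$hits), x$threshold))
  invisible(x)
}

#' Bundled synthetic cox1 reference panel
#'
#' Returns the path of the synthetic rotifer-like cox1 panel shipped with
#' the package (file `cox1_panel_synthetic.fasta`). The sequences are
#' randomly generated stand-ins with rotifer-style taxon labels, bundled so
#' that no download is ever required; real Rotifera panels are
#' user-supplied.
#'
#' @return Path to the bundled FASTA.
#' @export
bundled_cox1_panel <- function() {
  system.file("extdata", "cox1_panel_synthetic.fasta",
              package = "pufascreen", mustWork = TRUE)
}
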