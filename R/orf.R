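# Six-frame ORF extraction from assembly contigs.

GENETIC_CODE_TABLE <- NULL

genetic_code <- function() {
  # cached copy of the standard code, names = codons
  if (is.null(GENETIC_CODE_TABLE)) {
    utils::assignInMyNamespace("GENETIC_CODE_TABLE", Biostrings::GENETIC_CODE)
  }
  GENETIC_CODE_TABLE
}

#' Find full-length open reading frames in a contig
#'
#' Scans all six frames for ATG-to-stop ORFs under the standard genetic
#' code. Each reported ORF runs from the first ATG after the previous
#' in-frame stop to the stop codon (so nested shorter ORFs sharing a stop
#' are suppressed in favour of the longest) and must span at least
#' `min_codons` codons, the stop codon included. ORFs whose span contains
#' an `N` are skipped. Coordinates are 0-based half-open on the forward
#' strand regardless of the ORF's strand; `frame` is the 0/1/2 offset on
#' the ORF's own strand.
#'
#' @param contig nucleotide sequence (character, `DNAString`, or a
#'   length-one `DNAStringSet`) over the alphabet A, C, G, T, N.
#' @param min_codons minimal ORF length in codons (stop included); the
#'   default 100 reflects the shortest plausible full-length enzyme of the
#'   screened families (elongases are about 270 aa, desaturases about 350).
#' @param contig_id identifier carried into the output.
#' @return Data frame with columns `contig_id`, `strand`, `frame`,
#'   `nt_start`, `nt_end`, `protein`, sorted by forward-strand position.
#'   The protein excludes the stop and always begins with `M`.
#' @export
find_orfs <- function(contig, min_codons = 100, contig_id = "contig") {
  if (methods::is(contig, "DNAStringSet")) contig <- contig[[1]]
  if (methods::is(contig, "DNAString")) contig <- as.character(contig)
  stopifnot(is.character(contig), length(contig) == 1)
  if (min_codons < 1) abort("min_codons must be >= 1", "pufa_input_error")
  contig <- toupper(contig)
  check_dna_alphabet(contig, "contig")
  L <- nchar(contig)

  scan_strand <- function(seq_chr, strand) {
    out <- list()
    for (frame in 0:2) {
      n_codons <- (nchar(seq_chr) - frame) %/% 3
      if (n_codons < 1) next
      starts <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
      codons <- substring(seq_chr, starts, starts + 2L)
      is_stop <- codons %in% c("TAA", "TAG", "TGA")
      is_atg <- codons == "ATG"
      pending <- NA_integer_
      for (i in seq_len(n_codons)) {
        if (is.na(pending) && is_atg[i]) pending <- i
        if (is_stop[i]) {
          if (!is.na(pending) && (i - pending + 1L) >= min_codons) {
            s0 <- frame + 3L * (pending - 1L) # 0-based on this strand
            e0 <- frame + 3L * i
            span <- substr(seq_chr, s0 + 1L, e0)
            if (!grepl("N", span, fixed = TRUE)) {
              aa <- paste(genetic_code()[codons[pending:(i - 1L)]],
                          collapse = "")
              fwd <- if (strand == "+") c(s0, e0) else c(L - e0, L - s0)
              out[[length(out) + 1L]] <- data.frame(
                contig_id = contig_id, strand = strand, frame = frame,
                nt_start = fwd[1], nt_end = fwd[2], protein = aa,
                stringsAsFactors = FALSE)
            }
          }
          pending <- NA_integer_
        }
      }
    }
    out
  }

  recs <- c(scan_strand(contig, "+"),
            scan_strand(revcomp_chr(contig), "-"))
  if (length(recs) == 0) {
    return(data.frame(contig_id = character(0), strand = character(0),
                      frame = integer(0), nt_start = integer(0),
                      nt_end = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, recs)
  df <- df[order(df$nt_start, df$nt_end, df$strand), ]
  rownames(df) <- NULL
  df
}
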