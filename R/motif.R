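# Diagnostic-motif scanning and enzyme-family classification.
#
# Family rules (X = any residue), applied to the translated ORF:
#   ELOVL            KXXEXXDT, then NXXXHXXMYXYY, then HXXHH, then TXXQXXQ,
#                    each strictly after the previous hit's end.
#   FED              HPGG (heme-binding motif of the cytochrome b5 domain),
#                    then H-boxes HXXXH, HXXXHH-or-HXXHH, QXXHH in order.
#   DESATURASE_OTHER as FED but the third box resolves as HXXHH, not QXXHH
#                    (such desaturases are not regarded as front-end).
#   OMEGA_X          no HPGG anywhere; H-boxes HXXXH, HXXHH, HXXHH in order.

MOTIFS <- list(
  HPGG  = "HPGG",
  HB1   = "HXXXH",
  HB2L  = "HXXXHH",
  HB2S  = "HXXHH",
  QBOX  = "QXXHH",
  ELO1  = "KXXEXXDT",
  ELO2  = "NXXXHXXMYXYY",
  ELO3  = "HXXHH",
  ELO4  = "TXXQXXQ")

#' Scan a protein for an X-wildcard motif
#'
#' Reports every (possibly overlapping) occurrence of `pattern` in
#' `protein`, where `X` matches any residue and all other characters match
#' literally.
#'
#' @param protein amino-acid string.
#' @param pattern motif over the 20 amino-acid letters plus `X`.
#' @param pattern_id identifier carried into the output (defaults to the
#'   pattern itself).
#' @return Data frame with columns `pattern_id`, `pattern`, `start`
#'   (0-based position in the protein) and `matched`, in ascending start
#'   order.
#' @examples
#' scan_motif("AAHPGGAA", "HPGG")   # one hit at start 2
#' scan_motif("HAAHH", "HXXHH")     # one hit at start 0
#' @export
scan_motif <- function(protein, pattern, pattern_id = pattern) {
  stopifnot(is.character(protein), length(protein) == 1,
            is.character(pattern), length(pattern) == 1, nzchar(pattern))
  if (grepl("[^A-Z]", pattern)) {
    abort("pattern must use upper-case amino-acid letters and X",
          "pufa_input_error")
  }
  rx <- paste0("(?=", gsub("X", ".", pattern, fixed = TRUE), ")")
  m <- gregexpr(rx, protein, perl = TRUE)[[1]]
  starts <- if (m[1] == -1) integer(0) else as.integer(m) - 1L
  if (length(starts) == 0) return(empty_evidence())
  data.frame(pattern_id = rep(pattern_id, length(starts)),
             pattern = rep(pattern, length(starts)),
             start = starts,
             matched = substring(protein, starts + 1L,
                                 starts + nchar(pattern)),
             stringsAsFactors = FALSE)
}

# First occurrence of `pattern` starting at 0-based position >= from;
# NULL if none.
first_hit_after <- function(protein, pattern, from, pattern_id = pattern) {
  hits <- scan_motif(protein, pattern, pattern_id)
  hits <- hits[hits$start >= from, , drop = FALSE]
  if (nrow(hits) == 0) NULL else hits[1, , drop = FALSE]
}

empty_evidence <- function() {
  data.frame(pattern_id = character(0), pattern = character(0),
             start = integer(0), matched = character(0),
             stringsAsFactors = FALSE)
}

# Greedy, leftmost chain of motifs, each strictly after the previous end.
# Returns the evidence data frame, or NULL if the chain does not resolve.
chain_motifs <- function(protein, patterns, ids, from = 0L) {
  ev <- list()
  pos <- from
  for (k in seq_along(patterns)) {
    h <- first_hit_after(protein, patterns[[k]], pos, ids[[k]])
    if (is.null(h)) return(NULL)
    ev[[k]] <- h
    pos <- h$start + nchar(h$pattern)
  }
  do.call(rbind, ev)
}

#' Classify a protein into an LC-PUFA enzyme family
#'
#' Applies the diagnostic-motif decision procedure, in order: elongase
#' (ELOVL), front-end desaturase (FED), other desaturase
#' (DESATURASE_OTHER: the ordered H-box triple resolves but the third box
#' is HXXHH rather than QXXHH), methyl-end desaturase (OMEGA_X: the H-box
#' triple without any HPGG), else UNCLASSIFIED. Box assignment is
#' leftmost-greedy; when both HXXXHH and HXXHH match at the second-box
#' search position the longer HXXXHH is preferred.
#'
#' @param protein amino-acid string.
#' @return A list of class `pufa_classification` with elements `family`
#'   (one of `"ELOVL"`, `"FED"`, `"DESATURASE_OTHER"`, `"OMEGA_X"`,
#'   `"UNCLASSIFIED"`), `evidence` (accepted hits, see [scan_motif()]) and
#'   `has_cytb5` (HPGG present anywhere).
#' @export
classify_protein <- function(protein) {
  stopifnot(is.character(protein), length(protein) == 1, nzchar(protein))
  has_hpgg <- nrow(scan_motif(protein, MOTIFS$HPGG, "HPGG")) > 0

  result <- function(family, evidence) {
    structure(list(family = family,
                   evidence = evidence %||% empty_evidence(),
                   has_cytb5 = has_hpgg),
              class = "pufa_classification")
  }

  # (1) elongase
  ev <- chain_motifs(protein,
                     c(MOTIFS$ELO1, MOTIFS$ELO2, MOTIFS$ELO3, MOTIFS$ELO4),
                     c("ELO1", "ELO2", "HBOX", "ELO4"))
  if (!is.null(ev)) return(result("ELOVL", ev))

  # (2)/(3) desaturases with a cytochrome b5 domain
  hp <- first_hit_after(protein, MOTIFS$HPGG, 0L, "HPGG")
  if (!is.null(hp)) {
    pos <- hp$start + nchar(hp$pattern)
    b1 <- first_hit_after(protein, MOTIFS$HB1, pos, "HBOX1")
    if (!is.null(b1)) {
      pos <- b1$start + nchar(b1$pattern)
      bL <- first_hit_after(protein, MOTIFS$HB2L, pos, "HBOX2")
      bS <- first_hit_after(protein, MOTIFS$HB2S, pos, "HBOX2")
      b2 <- if (is.null(bL)) bS
            else if (is.null(bS)) bL
            else if (bS$start < bL$start) bS else bL # tie -> longer HXXXHH
      if (!is.null(b2)) {
        pos <- b2$start + nchar(b2$pattern)
        b3 <- first_hit_after(protein, MOTIFS$QBOX, pos, "QBOX")
        if (!is.null(b3)) {
          return(result("FED", rbind(hp, b1, b2, b3)))
        }
        b3h <- first_hit_after(protein, MOTIFS$HB2S, pos, "HBOX3")
        if (!is.null(b3h)) {
          return(result("DESATURASE_OTHER", rbind(hp, b1, b2, b3h)))
        }
      }
    }
  }

  # (4) methyl-end desaturase: H-box triple, no cytochrome b5 domain
  if (!has_hpgg) {
    ev <- chain_motifs(protein,
                       c(MOTIFS$HB1, MOTIFS$HB2S, MOTIFS$HB2S),
                       c("HBOX1", "HBOX2", "HBOX3"))
    if (!is.null(ev)) return(result("OMEGA_X", ev))
  }

  result("UNCLASSIFIED", NULL)
}

#' @export
print.pufa_classification <- function(x, ...) {
  cat(sprintf("<pufa_classification %s; cytb5=%s; %d motif hits>\n",
              x$family, x$has_cytb5, nrow(x$evidence)))
  invisible(x)
}

FAMILY_LEVELS <- c("ELOVL", "FED", "OMEGA_X", "DESATURASE_OTHER")

#' Screen an assembly for LC-PUFA enzyme-family candidates
#'
#' Extracts full-length ORFs from every contig ([find_orfs()]), classifies
#' each translation ([classify_protein()]), deduplicates candidates with
#' identical protein sequences, and tallies an occurrence summary per
#' family (the freshwater samples of the study typically show one elovl2/5,
#' four fed and two omega-x).
#'
#' @param contigs multi-FASTA path, `DNAStringSet`, or named character
#'   vector of contig sequences. An empty input yields an empty result.
#' @param min_codons passed to [find_orfs()].
#' @return An object of class `pufa_screen`: list with `candidates`
#'   (classified, deduplicated ORFs; data frame with an `evidence`
#'   list-column), `summary` (named integer vector over the four
#'   families), `n_orfs`, and `params`.
#' @export
screen_assembly <- function(contigs, min_codons = 100) {
  dna <- as_dna_set(contigs)
  if (anyDuplicated(names(dna))) {
    abort("duplicate contig ids in input", "pufa_input_error")
  }

  all_orfs <- list()
  for (i in seq_along(dna)) {
    orfs <- find_orfs(as.character(dna[[i]]), min_codons = min_codons,
                      contig_id = names(dna)[i])
    if (nrow(orfs) > 0) all_orfs[[length(all_orfs) + 1L]] <- orfs
  }
  orfs <- if (length(all_orfs)) do.call(rbind, all_orfs) else
    data.frame(contig_id = character(0), strand = character(0),
               frame = integer(0), nt_start = integer(0),
               nt_end = integer(0), protein = character(0),
               stringsAsFactors = FALSE)

  cls <- lapply(orfs$protein, classify_protein)
  orfs$family <- vapply(cls, function(x) x$family, "")
  orfs$has_cytb5 <- vapply(cls, function(x) x$has_cytb5, TRUE)

  cand <- orfs[orfs$family != "UNCLASSIFIED", , drop = FALSE]
  cand_ev <- cls[orfs$family != "UNCLASSIFIED"]
  ord <- order(cand$contig_id, cand$nt_start, cand$nt_end)
  cand <- cand[ord, , drop = FALSE]
  cand_ev <- cand_ev[ord]

  # deduplicate on exact protein identity: first occurrence kept
  dup <- duplicated(cand$protein)
  cand$duplicate <- dup
  uniq <- cand[!dup, , drop = FALSE]
  summary <- vapply(FAMILY_LEVELS, function(f) sum(uniq$family == f), 1L)

  cand$evidence <- I(lapply(cand_ev, function(x) x$evidence))
  rownames(cand) <- NULL

  structure(list(candidates = cand, summary = summary,
                 n_orfs = nrow(orfs), n_contigs = length(dna),
                 params = list(min_codons = min_codons)),
            class = "pufa_screen")
}

#' @export
print.pufa_screen <- function(x, ...) {
  cat(sprintf("<pufa_screen: %d contigs, %d ORFs, %d candidates>\n",
              x$n_contigs, x$n_orfs, sum(!x$candidates$duplicate)))
  print(x$summary)
  invisible(x)
}

#' Write screen outputs
#'
#' Emits candidate proteins as FASTA (headers `contig|strand|start-end|family`),
#' the evidence and summary as TSV, and a machine-readable JSON report.
#'
#' @param screen a `pufa_screen` object.
#' @param out_prefix path prefix for `_candidates.fasta`, `_candidates.tsv`,
#'   `_summary.tsv` and `_report.json`.
#' @return Invisibly, the written paths.
#' @export
write_screen <- function(screen, out_prefix) {
  stopifnot(inherits(screen, "pufa_screen"))
  cand <- screen$candidates
  fa_path <- paste0(out_prefix, "_candidates.fasta")
  headers <- sprintf("%s|%s|%d-%d|%s", cand$contig_id, cand$strand,
                     cand$nt_start, cand$nt_end, cand$family)
  writeLines(as.vector(rbind(paste0(">", headers), cand$protein)), fa_path)

  tsv_path <- paste0(out_prefix, "_candidates.tsv")
  write_tsv(cand[, c("contig_id", "strand", "frame", "nt_start", "nt_end",
                     "family", "has_cytb5", "duplicate")], tsv_path)

  sum_path <- paste0(out_prefix, "_summary.tsv")
  write_tsv(data.frame(family = names(screen$summary),
                       n = unname(screen$summary)), sum_path)

  json_path <- paste0(out_prefix, "_report.json")
  jsonlite::write_json(
    list(n_contigs = screen$n_contigs, n_orfs = screen$n_orfs,
         summary = as.list(screen$summary),
         candidates = cand[, c("contig_id", "strand", "nt_start", "nt_end",
                               "family", "protein")]),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(fa_path, tsv_path, sum_path, json_path))
}
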