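# Exon-intron organization and introner-like element classification.
#
# Internal coordinates are 0-based half-open on the forward strand; GFF3
# input (1-based inclusive) is converted at the boundary.

#' Gene structure on a genomic scaffold
#'
#' @param gene_id gene identifier.
#' @param scaffold_id scaffold the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix (or data frame) of 0-based half-open
#'   `(start, end)` exon coordinates on the forward strand; must be
#'   non-overlapping and is stored sorted ascending.
#' @return An object of class `gene_structure`.
#' @export
gene_structure <- function(gene_id, scaffold_id, strand, exons) {
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  colnames(exons) <- c("start", "end")
  if (nrow(exons) < 1) abort("need at least one exon", "pufa_input_error")
  if (!(strand %in% c("+", "-"))) abort("strand must be + or -", "pufa_input_error")
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (any(exons[, "end"] <= exons[, "start"])) {
    abort("exon end must exceed start", "pufa_input_error")
  }
  if (nrow(exons) > 1 &&
      any(exons[-1, "start"] < exons[-nrow(exons), "end"])) {
    abort("exons overlap", "pufa_input_error")
  }
  structure(list(gene_id = gene_id, scaffold_id = scaffold_id,
                 strand = strand, exons = exons),
            class = "gene_structure")
}

#' @export
print.gene_structure <- function(x, ...) {
  cat(sprintf("<gene_structure %s on %s(%s): %d exon(s)>\n",
              x$gene_id, x$scaffold_id, x$strand, nrow(x$exons)))
  invisible(x)
}

#' Is a gene intronless?
#'
#' @param g a [gene_structure()].
#' @return `TRUE` when the gene has a single exon.
#' @export
is_intronless <- function(g) {
  stopifnot(inherits(g, "gene_structure"))
  nrow(g$exons) == 1
}

#' Extract introns from a gene structure
#'
#' Introns are the gaps between consecutive exons, numbered in
#' transcription order: for minus-strand genes the order is reversed and
#' each intron sequence is reverse-complemented, so intron 1 is always the
#' gap nearest the transcription start and splice sites read 5' to 3'.
#'
#' @param g a [gene_structure()].
#' @param scaffold scaffold nucleotide sequence (character, `DNAString`,
#'   or named `DNAStringSet` containing `g$scaffold_id`).
#' @return List of `intron` objects (fields `index`, `start`, `end` on the
#'   forward strand, `sequence` in transcription orientation, `length`);
#'   empty for single-exon genes.
#' @export
introns_from_structure <- function(g, scaffold) {
  stopifnot(inherits(g, "gene_structure"))
  if (methods::is(scaffold, "DNAStringSet")) {
    if (!(g$scaffold_id %in% names(scaffold))) {
      abort(sprintf("scaffold %s not found", g$scaffold_id), "pufa_input_error")
    }
    scaffold <- as.character(scaffold[[g$scaffold_id]])
  }
  if (methods::is(scaffold, "DNAString")) scaffold <- as.character(scaffold)
  scaffold <- toupper(scaffold)
  L <- nchar(scaffold)
  if (any(g$exons < 0) || any(g$exons > L)) {
    abort("exon coordinates outside scaffold bounds", "pufa_input_error")
  }
  n <- nrow(g$exons)
  if (n < 2) return(list())
  gaps <- cbind(start = g$exons[-n, "end"], end = g$exons[-1, "start"])
  if (g$strand == "-") gaps <- gaps[rev(seq_len(n - 1)), , drop = FALSE]
  lapply(seq_len(n - 1), function(i) {
    s <- gaps[i, "start"]; e <- gaps[i, "end"]
    seq <- substr(scaffold, s + 1L, e)
    if (g$strand == "-") seq <- revcomp_chr(seq)
    new_intron(index = i, start = s, end = e, sequence = seq)
  })
}

new_intron <- function(index, start, end, sequence) {
  len <- end - start
  if (len < 4L) abort("intron shorter than 4 bp", "pufa_input_error")
  stopifnot(nchar(sequence) == len)
  structure(list(index = as.integer(index), start = as.integer(start),
                 end = as.integer(end), sequence = sequence,
                 length = as.integer(len)),
            class = "intron")
}

#' Construct an intron directly from its sequence
#'
#' Convenience constructor for testing intron features without a full gene
#' structure; coordinates default to `[0, length)`.
#'
#' @param sequence intron sequence in transcription orientation.
#' @param index 1-based ordinal, default 1.
#' @return An `intron` object.
#' @export
intron_from_sequence <- function(sequence, index = 1) {
  sequence <- toupper(sequence)
  new_intron(index, 0L, nchar(sequence), sequence)
}

#' @export
print.intron <- function(x, ...) {
  cat(sprintf("<intron %d: %d bp [%d,%d) %s..%s>\n", x$index, x$length,
              x$start, x$end, substr(x$sequence, 1, 2),
              substr(x$sequence, x$length - 1, x$length)))
  invisible(x)
}

#' Check intron splice sites
#'
#' Canonical spliceosomal introns start `GT` (donor) and end `AG`
#' (acceptor) in transcription orientation.
#'
#' @param i an `intron`.
#' @return `"canonical"` or `"non_canonical"`.
#' @export
check_splice_sites <- function(i) {
  stopifnot(inherits(i, "intron"))
  donor <- substr(i$sequence, 1, 2)
  acceptor <- substr(i$sequence, i$length - 1, i$length)
  if (donor == "GT" && acceptor == "AG") "canonical" else "non_canonical"
}

#' Find a polypyrimidine tract near an intron's 3' end
#'
#' Searches the 3'-terminal `window` nucleotides of the intron (excluding
#' the final AG dinucleotide) for the longest contiguous run of at least
#' `min_len` nucleotides whose pyrimidine (C/T) fraction is at least
#' `min_frac`; leftmost on ties. Parameter defaults (40 nt window, 8 nt
#' minimum, 0.8 fraction) follow canonical spliceosomal intron
#' descriptions.
#'
#' @param i an `intron`.
#' @param window length of the 3' search window in nt.
#' @param min_len minimal tract length in nt.
#' @param min_frac minimal pyrimidine fraction, in (0.5, 1].
#' @return List with 1-based `start`/`end` positions within the intron
#'   sequence, `length` and `pyrimidine_fraction`; `NULL` when no tract
#'   qualifies.
#' @export
find_polypyrimidine_tract <- function(i, window = 40, min_len = 8,
                                      min_frac = 0.8) {
  stopifnot(inherits(i, "intron"))
  if (window < 1 || min_len < 1) abort("parameters must be positive",
                                       "pufa_input_error")
  if (min_frac <= 0.5 || min_frac > 1) {
    abort("min_frac must be in (0.5, 1]", "pufa_input_error")
  }
  stop_at <- i$length - 2L           # exclude the terminal AG
  if (stop_at < min_len) return(NULL)
  from <- max(1L, stop_at - as.integer(window) + 1L)
  region <- substr(i$sequence, from, stop_at)
  is_pyr <- strsplit(region, "")[[1]] %in% c("C", "T")
  n <- length(is_pyr)
  if (n < min_len) return(NULL)
  cum <- c(0, cumsum(is_pyr))
  best <- NULL
  for (len in seq(n, as.integer(min_len))) { # longest first
    for (s in seq_len(n - len + 1L)) {       # leftmost first
      frac <- (cum[s + len] - cum[s]) / len
      if (frac >= min_frac) { best <- c(s, len, frac); break }
    }
    if (!is.null(best)) break
  }
  if (is.null(best)) return(NULL)
  s <- from + best[1] - 1L
  list(start = s, end = s + best[2] - 1L, length = as.integer(best[2]),
       pyrimidine_fraction = best[3])
}

#' Classify an intron as introner-like
#'
#' An intron is flagged introner-like when it has canonical GT/AG splice
#' sites, a polypyrimidine tract near its 3' end, and is relatively long
#' (at least `min_length`; the motivating genomic example is a 940-bp third
#' intron).
#'
#' @inheritParams find_polypyrimidine_tract
#' @param min_length minimal intron length in bp, default 100.
#' @return List with `introner_like` (logical) and a `criteria` list giving
#'   each criterion's outcome (`canonical_splice_sites`, `tract_found`,
#'   `long_enough`) plus the tract span when found.
#' @export
classify_introner_like <- function(i, min_length = 100, window = 40,
                                   min_len = 8, min_frac = 0.8) {
  stopifnot(inherits(i, "intron"))
  canon <- check_splice_sites(i) == "canonical"
  tract <- find_polypyrimidine_tract(i, window = window, min_len = min_len,
                                     min_frac = min_frac)
  long_enough <- i$length >= min_length
  list(introner_like = canon && !is.null(tract) && long_enough,
       criteria = list(canonical_splice_sites = canon,
                       tract_found = !is.null(tract),
                       long_enough = long_enough),
       tract = tract, length = i$length)
}

#' Read gene structures from a GFF3 annotation
#'
#' Exon features are grouped by their `Parent` attribute (one structure per
#' transcript); GFF3 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention.
#'
#' @param gff GFF3 path or a `GRanges` as returned by
#'   [rtracklayer::import()].
#' @return Named list of [gene_structure()] objects.
#' @export
structures_from_gff <- function(gff) {
  gr <- if (methods::is(gff, "GRanges")) gff else rtracklayer::import(gff)
  exons <- gr[gr$type == "exon"]
  if (length(exons) == 0) return(list())
  parents <- vapply(S4Vectors::mcols(exons)$Parent, function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, "")
  out <- list()
  for (pid in unique(parents)) {
    ex <- exons[parents == pid]
    strand <- as.character(GenomicRanges::strand(ex))[1]
    if (strand == "*") strand <- "+"
    coords <- cbind(start = GenomicRanges::start(ex) - 1L,
                    end = GenomicRanges::end(ex))
    out[[pid]] <- gene_structure(
      gene_id = pid,
      scaffold_id = as.character(GenomicRanges::seqnames(ex))[1],
      strand = strand, exons = coords)
  }
  out[order(names(out))]
}

#' Analyse exon-intron organization of annotated genes
#'
#' Combines [structures_from_gff()], [introns_from_structure()] and
#' [classify_introner_like()] over a genome.
#'
#' @param genome genome FASTA path or named `DNAStringSet`.
#' @param gff GFF3 path or `GRanges`.
#' @param ... introner parameters passed to [classify_introner_like()].
#' @return List with `genes` (per-gene data frame: exon count, genomic
#'   span, intronless flag) and `introns` (per-intron data frame: length,
#'   splice-site class, tract presence, introner-like flag).
#' @export
analyze_gene_structures <- function(genome, gff, ...) {
  dna <- as_dna_set(genome)
  structs <- structures_from_gff(gff)
  gene_rows <- list(); intron_rows <- list()
  for (g in structs) {
    ints <- introns_from_structure(g, dna)
    gene_rows[[g$gene_id]] <- data.frame(
      gene_id = g$gene_id, scaffold_id = g$scaffold_id, strand = g$strand,
      n_exons = nrow(g$exons),
      exon_bp = sum(g$exons[, "end"] - g$exons[, "start"]),
      intron_bp = sum(vapply(ints, function(i) i$length, 1L), 0L),
      span = max(g$exons[, "end"]) - min(g$exons[, "start"]),
      intronless = is_intronless(g), stringsAsFactors = FALSE)
    for (i in ints) {
      cl <- classify_introner_like(i, ...)
      intron_rows[[paste(g$gene_id, i$index)]] <- data.frame(
        gene_id = g$gene_id, index = i$index, start = i$start, end = i$end,
        length = i$length, splice_sites = check_splice_sites(i),
        tract_found = cl$criteria$tract_found,
        introner_like = cl$introner_like, stringsAsFactors = FALSE)
    }
  }
  genes <- do.call(rbind, c(gene_rows, list(NULL)))
  introns <- do.call(rbind, c(intron_rows, list(NULL)))
  if (!is.null(genes)) rownames(genes) <- NULL
  if (!is.null(introns)) rownames(introns) <- NULL
  list(genes = genes, introns = introns)
}
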