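# Orchestration: full screen over one or more samples, paper-shaped reports.

# Assign field-style gene labels (elovl2/5, fed1..fedN, wx1..wxN, other1..)
# to the deduplicated candidates of one screen, ordered by contig position.
label_candidates <- function(screen) {
  cand <- screen$candidates[!screen$candidates$duplicate, , drop = FALSE]
  if (nrow(cand) == 0) {
    cand$label <- character(0)
    return(cand)
  }
  cand <- cand[order(cand$contig_id, cand$nt_start), , drop = FALSE]
  prefix <- c(ELOVL = "elovl2/5", FED = "fed", OMEGA_X = "wx",
              DESATURASE_OTHER = "other")
  cand$label <- NA_character_
  for (fam in unique(cand$family)) {
    idx <- which(cand$family == fam)
    cand$label[idx] <- if (fam == "ELOVL" && length(idx) == 1) "elovl2/5"
                       else paste0(prefix[[fam]], seq_along(idx))
  }
  cand
}

# Pair the gene candidates of two samples within each family by greedy
# best mutual identity, so homologous copies line up even though contig
# ids differ between assemblies.
pair_gene_sets <- function(cand_a, cand_b) {
  pairs <- list()
  for (fam in intersect(cand_a$family, cand_b$family)) {
    ia <- which(cand_a$family == fam)
    ib <- which(cand_b$family == fam)
    scores <- outer(ia, ib, Vectorize(function(i, j) {
      global_percent_identity(cand_a$cds[i], cand_b$cds[j])
    }))
    while (length(ia) > 0 && length(ib) > 0) {
      best <- which(scores == max(scores), arr.ind = TRUE)[1, ]
      pairs[[length(pairs) + 1L]] <- data.frame(
        label = cand_a$label[ia[best[1]]],
        identity = scores[best[1], best[2]], stringsAsFactors = FALSE)
      ia <- ia[-best[1]]; ib <- ib[-best[2]]
      scores <- scores[-best[1], -best[2], drop = FALSE]
    }
  }
  if (length(pairs)) do.call(rbind, pairs)
  else data.frame(label = character(0), identity = numeric(0))
}

#' Run the full screening workflow over samples
#'
#' For each sample: motif-based gene screen ([screen_assembly()]) and cox1
#' contamination screen ([screen_cox1()]). Across samples: a cross-sample
#' identity table for shared gene families, with homologous copies paired
#' within each family by greedy best mutual coding-sequence identity. The
#' result bundles an occurrence matrix (one row per sample, one column per
#' family), per-sample contamination verdicts and the identity table;
#' every number is the direct output of a module operation.
#'
#' @param samples named list of sample inputs (FASTA paths,
#'   `DNAStringSet`s, or named character vectors); at least one.
#' @param panel cox1 reference panel (default: the bundled synthetic one).
#' @param config a [default_config()].
#' @return An object of class `pufa_report`: list with `occurrence`
#'   (data frame), `verdicts` (named logical), `cox1` (per-sample
#'   `pufa_cox1_report`s), `screens`, `identity` (data frame or NULL) and
#'   `config`. Written to `config$out_dir` when set.
#' @export
run_full_screen <- function(samples, panel = bundled_cox1_panel(),
                            config = default_config()) {
  if (length(samples) == 0) {
    abort("need at least one sample", "pufa_usage_error")
  }
  if (is.null(names(samples)) || any(!nzchar(names(samples)))) {
    names(samples) <- paste0("sample", seq_along(samples))
  }

  screens <- list(); cox1 <- list(); labelled <- list()
  for (nm in names(samples)) {
    dna <- as_dna_set(samples[[nm]])
    log_msg("info", sprintf("screening %s (%d contigs)", nm, length(dna)),
            min_level = config$log_level)
    scr <- screen_assembly(dna, min_codons = config$min_codons)
    screens[[nm]] <- scr
    cand <- label_candidates(scr)
    cand$cds <- vapply(seq_len(nrow(cand)), function(i) {
      seq <- as.character(dna[[cand$contig_id[i]]])
      cds <- substr(seq, cand$nt_start[i] + 1L, cand$nt_end[i])
      if (cand$strand[i] == "-") revcomp_chr(cds) else cds
    }, "")
    labelled[[nm]] <- cand
    cox1[[nm]] <- screen_cox1(dna, panel,
                              threshold = config$cox1_threshold,
                              min_aligned_length = config$cox1_min_aligned_length)
  }

  occurrence <- data.frame(
    sample = names(samples),
    t(vapply(screens, function(s) s$summary, setNames(integer(4), FAMILY_LEVELS))),
    check.names = FALSE, stringsAsFactors = FALSE)
  rownames(occurrence) <- NULL
  verdicts <- vapply(cox1, function(x) x$positive, TRUE)

  identity <- NULL
  if (length(samples) >= 2) {
    combos <- utils::combn(names(samples), 2, simplify = FALSE)
    rows <- list()
    for (p in combos) {
      m <- pair_gene_sets(labelled[[p[1]]], labelled[[p[2]]])
      if (nrow(m) == 0) next
      row <- stats::setNames(as.list(m$identity), m$label)
      row <- c(list(pair = paste(p, collapse = " vs ")), row)
      rows[[length(rows) + 1L]] <- row
    }
    if (length(rows)) {
      labels <- sort(unique(unlist(lapply(rows, function(r) setdiff(names(r), "pair")))))
      identity <- data.frame(pair = vapply(rows, function(r) r$pair, ""),
                             stringsAsFactors = FALSE)
      for (lb in labels) {
        identity[[lb]] <- vapply(rows, function(r) r[[lb]] %||% NA_real_, 1)
      }
    }
  }

  report <- structure(list(occurrence = occurrence, verdicts = verdicts,
                           cox1 = cox1, screens = screens,
                           identity = identity, config = config),
                      class = "pufa_report")
  if (!is.na(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pufa_report <- function(x, ...) {
  cat("<pufa_report>\noccurrence:\n")
  print(x$occurrence)
  cat("cox1 verdicts:\n")
  print(x$verdicts)
  invisible(x)
}

#' Write a report bundle to a directory
#'
#' Emits `occurrence.tsv`, `cox1_hits.tsv`, `verdicts.json`,
#' `identity.tsv` (when present) and `report.json`. Outputs are
#' byte-identical across reruns with the same inputs and configuration.
#'
#' @param report a `pufa_report`.
#' @param out_dir output directory.
#' @return Invisibly, the directory.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pufa_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(report$occurrence, file.path(out_dir, "occurrence.tsv"))

  hits <- do.call(rbind, lapply(names(report$cox1), function(nm) {
    h <- report$cox1[[nm]]$hits
    if (nrow(h) == 0) return(NULL)
    cbind(sample = nm, h)
  }))
  if (is.null(hits)) {
    hits <- data.frame(sample = character(0), contig_id = character(0),
                       reference_id = character(0),
                       percent_identity = numeric(0),
                       aligned_length = integer(0), positive = logical(0))
  }
  write_tsv(hits, file.path(out_dir, "cox1_hits.tsv"))

  jsonlite::write_json(as.list(report$verdicts),
                       file.path(out_dir, "verdicts.json"),
                       auto_unbox = TRUE)
  if (!is.null(report$identity)) {
    out <- report$identity
    for (col in setdiff(names(out), "pair")) {
      out[[col]] <- ifelse(is.na(out[[col]]), "*", sprintf("%.1f", out[[col]]))
    }
    write_tsv(out, file.path(out_dir, "identity.tsv"))
  }
  cfg <- unclass(report$config)
  cfg$out_dir <- NULL # path varies between runs; keep reports byte-stable
  jsonlite::write_json(
    list(occurrence = report$occurrence,
         verdicts = as.list(report$verdicts),
         identity = report$identity,
         config = cfg),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(out_dir)
}
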