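# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored on exit. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

abort <- function(message, class) {
  stop(structure(class = c(class, "pufascreen_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Coerce a path / character vector / XStringSet to a named DNAStringSet.
as_dna_set <- function(x, format = "fasta") {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    fmt <- format
    if (grepl("\\.(fq|fastq)(\\.gz)?$", x, ignore.case = TRUE)) fmt <- "fastq"
    dna <- Biostrings::readDNAStringSet(x, format = fmt)
    names(dna) <- sub("\\s.*$", "", names(dna)) # id = first header token
    return(dna)
  }
  if (is.character(x)) {
    nm <- names(x) %||% paste0("seq", seq_along(x))
    return(stats::setNames(Biostrings::DNAStringSet(toupper(x)), nm))
  }
  abort("cannot interpret input as DNA sequences", "pufa_input_error")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

check_dna_alphabet <- function(seq, where = "sequence") {
  if (grepl("[^ACGTN]", seq)) {
    abort(sprintf("%s contains characters outside {A,C,G,T,N}", where),
          "pufa_input_error")
  }
  invisible(seq)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

log_msg <- function(level, ..., min_level = getOption("pufascreen.log_level", "info")) {
  levels <- c(debug = 1L, info = 2L, warn = 3L, error = 4L)
  if (levels[[level]] >= levels[[min_level]]) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    toupper(level), paste0(..., collapse = "")))
  }
  invisible(NULL)
}
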