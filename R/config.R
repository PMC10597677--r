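# Run configuration shared by the orchestrated pipeline and the CLI.

#' Default run configuration
#'
#' Flat list of the documented thresholds: cox1 positivity threshold
#' (75%, exclusive), minimal aligned length for cox1 hits (100 nt),
#' minimal ORF length (100 codons), k-mer size for read recruitment (31),
#' polypyrimidine-tract parameters (window 40 nt, minimal length 8 nt,
#' pyrimidine fraction 0.8), introner minimal length (100 bp), the
#' activity preset name, seed, output directory and log level. The
#' configuration round-trips through JSON serialization.
#'
#' @param ... overrides for individual keys.
#' @return A validated named list of class `pufa_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    cox1_threshold = 75,
    cox1_min_aligned_length = 100,
    kmer_k = 31,
    min_codons = 100,
    pp_window = 40,
    pp_min_len = 8,
    pp_min_frac = 0.8,
    introner_min_length = 100,
    activity_preset = "bdelloid_characterized",
    seed = 1,
    out_dir = NA_character_,
    log_level = "info")
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          "pufa_config_error")
  }
  validate_config(structure(utils::modifyList(cfg, overrides),
                            class = "pufa_config"))
}

validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) abort(msg, "pufa_config_error")
  chk(cfg$cox1_threshold >= 0 && cfg$cox1_threshold <= 100,
      "cox1_threshold must be in [0, 100]")
  chk(cfg$cox1_min_aligned_length >= 1, "cox1_min_aligned_length must be >= 1")
  chk(cfg$kmer_k >= 1 && cfg$kmer_k %% 2 == 1, "kmer_k must be odd")
  chk(cfg$min_codons >= 1, "min_codons must be >= 1")
  chk(cfg$pp_min_frac > 0.5 && cfg$pp_min_frac <= 1,
      "pp_min_frac must be in (0.5, 1]")
  chk(cfg$pp_window >= 1 && cfg$pp_min_len >= 1,
      "polypyrimidine parameters must be positive")
  chk(cfg$introner_min_length >= 1, "introner_min_length must be >= 1")
  chk(cfg$log_level %in% c("debug", "info", "warn", "error"),
      "log_level must be one of debug/info/warn/error")
  cfg
}

#' Read / write a configuration as JSON
#'
#' CLI flags override file values; see [run_cli()].
#'
#' @param path JSON path.
#' @return [read_config()] returns a validated `pufa_config`.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- Filter(Negate(is.null), raw) # JSON null -> package default
  do.call(default_config, raw)
}

#' @rdname read_config
#' @param cfg a `pufa_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pufa_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
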