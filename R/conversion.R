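# Yeast-assay conversion arithmetic from GC-FID peak areas.
#
# Conversion of an enzyme towards an exogenously supplied substrate is
#   100 * sum(product areas) / (sum(product areas) + substrate area),
# with the expected products enumerated as the closure of the substrate
# under the single introduced enzyme's activities (the yeast re-uses the
# enzyme iteratively, e.g. C18 -> C20 -> C22 elongation).

#' Expected products of a single enzyme on a substrate
#'
#' Enumerates, in breadth-first order, every acid producible from
#' `substrate` by iterated application of the enzyme's activities within
#' their substrate ranges. The substrate itself is never included.
#'
#' @param substrate [fatty_acid()] or shorthand string.
#' @param activities list of [enzyme_activity()] objects or a preset name
#'   (e.g. `"elovl25"`, `"fed_d5"`, `"fed_d6"`, `"wx"`).
#' @param max_carbons chain-length bound, default 24.
#' @return Character vector of product acids in shorthand, production order.
#' @examples
#' expected_products("18:3n-3", "elovl25") # "20:3n-3" "22:3n-3"
#' expected_products("18:3n-3", "fed_d5")  # none: no bond at Delta-8
#' @export
expected_products <- function(substrate, activities, max_carbons = 24) {
  if (inherits(substrate, "fatty_acid")) substrate <- format(substrate)
  r <- reachable_set(activities, list(substrate), max_carbons = max_carbons)
  df <- r$acids[order(r$acids$step, r$acids$carbons, r$acids$double_bonds), ]
  setdiff(df$acid, format(parse_fatty_acid(substrate)))
}

#' Conversion percentage from peak areas
#'
#' `100 * sum(products) / (sum(products) + substrate)`. All-zero input is
#' an undefined conversion and raises an error.
#'
#' @param substrate_area non-negative substrate peak area.
#' @param product_areas numeric vector of non-negative product peak areas
#'   (may be empty).
#' @return Conversion percentage in `[0, 100]`.
#' @examples
#' conversion_percent(50, c(25, 25)) # 50
#' conversion_percent(100, numeric(0)) # 0
#' @export
conversion_percent <- function(substrate_area, product_areas = numeric(0)) {
  stopifnot(is.numeric(substrate_area), length(substrate_area) == 1,
            is.numeric(product_areas))
  if (substrate_area < 0 || any(product_areas < 0)) {
    abort("areas must be non-negative", "pufa_input_error")
  }
  tot <- sum(product_areas) + substrate_area
  if (tot == 0) {
    abort("all areas are zero: conversion undefined", "pufa_undefined_conversion")
  }
  100 * sum(product_areas) / tot
}

#' Read a GC-FID peak-area table
#'
#' TSV with columns `fatty_acid` (shorthand notation) and `area`
#' (non-negative, arbitrary but uniform units). Fatty-acid keys are
#' canonicalized and must be unique.
#'
#' @param path TSV path.
#' @return Data frame with canonical `fatty_acid` keys and `area`.
#' @export
read_area_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("fatty_acid", "area") %in% names(df))) {
    abort("area table needs columns fatty_acid, area", "pufa_input_error")
  }
  validate_area_table(df)
}

validate_area_table <- function(df) {
  df$fatty_acid <- vapply(df$fatty_acid,
                          function(x) format(parse_fatty_acid(x)), "")
  if (anyDuplicated(df$fatty_acid)) {
    abort("duplicate fatty-acid keys in area table", "pufa_input_error")
  }
  if (any(df$area < 0)) abort("areas must be non-negative", "pufa_input_error")
  df
}

#' Summarize a yeast functional assay
#'
#' For each assayed substrate, resolves the expected products of the
#' enzyme ([expected_products()]), looks their areas up in the table
#' (missing product rows count as area 0) and reports one conversion per
#' substrate. A substrate absent from the table yields a per-substrate
#' error entry rather than a global failure. Endogenous-substrate
#' methyl-end assays are represented as `18:1n-9` rows in the same format.
#'
#' @param table area table (data frame as from [read_area_table()], or a
#'   path).
#' @param activities enzyme activities or preset name.
#' @param substrates character vector of assayed substrates in shorthand.
#' @return Data frame with columns `substrate`, `products`
#'   (comma-separated), `conversion_percent` and `error` (NA on success).
#' @examples
#' tab <- data.frame(fatty_acid = c("18:3n-3", "20:3n-3", "22:3n-3"),
#'                   area = c(80, 15, 5))
#' summarize_assay(tab, "elovl25", "18:3n-3") # conversion 20
#' @export
summarize_assay <- function(table, activities, substrates) {
  if (is.character(table) && length(table) == 1) table <- read_area_table(table)
  table <- validate_area_table(table)
  areas <- stats::setNames(table$area, table$fatty_acid)
  rows <- lapply(substrates, function(s) {
    key <- format(parse_fatty_acid(s))
    prods <- expected_products(key, activities)
    if (!(key %in% names(areas))) {
      return(data.frame(substrate = key,
                        products = paste(prods, collapse = ","),
                        conversion_percent = NA_real_,
                        error = "substrate absent from area table",
                        stringsAsFactors = FALSE))
    }
    parea <- areas[intersect(prods, names(areas))]
    conv <- tryCatch(
      conversion_percent(areas[[key]], unname(parea)),
      pufa_undefined_conversion = function(e) NA_real_)
    data.frame(substrate = key, products = paste(prods, collapse = ","),
               conversion_percent = conv,
               error = if (is.na(conv)) "all areas zero" else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
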