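#' Enzyme activities of the LC-PUFA biosynthesis network
#'
#' An enzyme activity is one edge type of the desaturation-elongation
#' reaction network: a front-end desaturation at a fixed Delta position, a
#' methyl-end desaturation at a fixed Delta position, a two-carbon
#' elongation restricted to a set of substrate chain lengths, or the
#' beta-oxidative chain shortening of the Sprecher route.
#'
#' @param kind one of `"front_end_desaturation"`, `"methyl_end_desaturation"`,
#'   `"elongation"`, `"beta_oxidation_shortening"`.
#' @param delta Delta position (desaturations only). Front-end activities
#'   require `delta >= 4`.
#' @param substrate_carbons admissible substrate chain lengths
#'   (elongation only); must be non-empty.
#' @return An object of class `enzyme_activity`.
#' @examples
#' enzyme_activity("front_end_desaturation", delta = 6)
#' enzyme_activity("elongation", substrate_carbons = c(18, 20))
#' @export
enzyme_activity <- function(kind, delta = NULL, substrate_carbons = NULL) {
  kinds <- c("front_end_desaturation", "methyl_end_desaturation",
             "elongation", "beta_oxidation_shortening")
  if (!(is.character(kind) && length(kind) == 1 && kind %in% kinds)) {
    abort(paste("kind must be one of:", paste(kinds, collapse = ", ")),
          "pufa_validation_error")
  }
  if (kind %in% c("front_end_desaturation", "methyl_end_desaturation")) {
    if (is.null(delta)) abort("desaturation activities need delta",
                              "pufa_validation_error")
    delta <- as.integer(delta)
    if (kind == "front_end_desaturation" && delta < 4L) {
      abort("front-end desaturation requires delta >= 4", "pufa_validation_error")
    }
  } else {
    delta <- NULL
  }
  if (kind == "elongation") {
    if (is.null(substrate_carbons) || length(substrate_carbons) == 0) {
      abort("elongation needs a non-empty substrate_carbons set",
            "pufa_validation_error")
    }
    substrate_carbons <- sort(unique(as.integer(substrate_carbons)))
  } else {
    substrate_carbons <- NULL
  }
  structure(list(kind = kind, delta = delta,
                 substrate_carbons = substrate_carbons),
            class = "enzyme_activity")
}

#' @export
format.enzyme_activity <- function(x, ...) {
  switch(x$kind,
    front_end_desaturation = sprintf("Fed d%d", x$delta),
    methyl_end_desaturation = sprintf("wx d%d", x$delta),
    elongation = sprintf("Elo C%s", paste(x$substrate_carbons, collapse = "+C")),
    beta_oxidation_shortening = "beta-ox shortening")
}

#' @export
print.enzyme_activity <- function(x, ...) {
  cat(sprintf("<enzyme_activity %s>\n", format(x))); invisible(x)
}

# Apply one activity to one acid; NULL if the reaction is inapplicable.
activity_product <- function(act, fa) {
  res <- tryCatch(
    switch(act$kind,
      front_end_desaturation = apply_front_end_desaturation(fa, act$delta),
      methyl_end_desaturation = apply_methyl_end_desaturation(fa, act$delta),
      elongation = {
        if (!(fa$carbons %in% act$substrate_carbons)) NULL
        else apply_elongation(fa)
      },
      beta_oxidation_shortening = apply_beta_oxidation_shortening(fa)),
    pufa_inapplicable_reaction = function(e) NULL,
    pufa_validation_error = function(e) NULL)
  res
}

#' Load enzyme-activity presets
#'
#' Presets bundle the activity sets used throughout the package as JSON
#' (`inst/extdata/activity_presets.json`). The preset
#' `"bdelloid_characterized"` encodes the activities demonstrated for the
#' bdelloid rotifer enzymes in yeast assays: dual Delta-12/Delta-15
#' methyl-end desaturation, Delta-6 and Delta-5 front-end desaturation, and
#' elongation of C18 and C20 (but not C22) substrates. Single-enzyme presets
#' (`"elovl25"`, `"fed_d5"`, `"fed_d6"`, `"fed_d8"`, `"fed_d4"`, `"wx"`)
#' back the yeast-assay conversion calculations.
#'
#' @param name preset name; see [list_activity_presets()].
#' @return A list of [enzyme_activity()] objects.
#' @export
activity_preset <- function(name) {
  presets <- load_presets()
  if (!(name %in% names(presets))) {
    abort(sprintf("unknown activity preset '%s' (available: %s)", name,
                  paste(names(presets), collapse = ", ")),
          "pufa_config_error")
  }
  activities_from_list(presets[[name]])
}

#' @rdname activity_preset
#' @export
list_activity_presets <- function() names(load_presets())

load_presets <- function() {
  path <- system.file("extdata", "activity_presets.json",
                      package = "pufascreen", mustWork = TRUE)
  jsonlite::read_json(path)
}

activities_from_list <- function(lst) {
  lapply(lst, function(a) {
    enzyme_activity(a$kind,
                    delta = a$delta %||% NULL,
                    substrate_carbons = unlist(a$substrate_carbons %||% NULL))
  })
}

#' Read an activity set from a JSON file
#'
#' The file holds a JSON array of objects with fields `kind`, optional
#' `delta`, and optional `substrate_carbons`, mirroring [enzyme_activity()].
#'
#' @param path path to the JSON file.
#' @return A list of [enzyme_activity()] objects.
#' @export
read_activities <- function(path) {
  activities_from_list(jsonlite::read_json(path))
}

#' Reachable fatty acids under an enzyme activity set
#'
#' Computes the breadth-first closure of a set of precursor acids under all
#' applicable activities, bounded by a maximal chain length. The traversal
#' is deterministic: at each level, frontier acids are expanded in
#' lexicographic order of (carbons, double_bonds, omega) and each product
#' records the first (predecessor, activity) pair that produced it, so
#' every member of the closure carries a reconstructible reaction path.
#'
#' @param activities list of [enzyme_activity()] objects (or a preset name).
#' @param precursors list of [fatty_acid()] objects or shorthand strings.
#' @param max_carbons chain-length bound for the search; the default 24
#'   covers the C24 intermediates of the Sprecher route to DHA.
#' @return An object of class `pufa_reachability`: a list with `acids`
#'   (data frame of reachable acids with predecessor links) and the call
#'   parameters. Use [is_reachable()] and [reaction_path()] to query it.
#' @examples
#' r <- reachable_set("bdelloid_characterized", list("18:1n-9"))
#' is_reachable(r, "20:5n-3") # EPA: TRUE
#' is_reachable(r, "22:6n-3") # DHA: FALSE
#' @export
reachable_set <- function(activities, precursors, max_carbons = 24) {
  if (is.character(activities) && length(activities) == 1) {
    activities <- activity_preset(activities)
  }
  stopifnot(all(vapply(activities, inherits, TRUE, "enzyme_activity")))
  precursors <- lapply(precursors, function(p) {
    if (inherits(p, "fatty_acid")) p else parse_fatty_acid(p)
  })
  max_carbons <- as.integer(max_carbons)

  acts <- activities
  act_labels <- vapply(acts, format, "")

  nodes <- new.env(parent = emptyenv())
  order_key <- function(fa) {
    sprintf("%03d|%03d|%03d", fa$carbons, fa$double_bonds,
            if (is.na(fa$omega)) 0L else fa$omega)
  }
  add_node <- function(fa, pred, act_idx, step) {
    key <- format(fa)
    if (!is.null(nodes[[key]])) return(FALSE)
    nodes[[key]] <- list(fa = fa, predecessor = pred, activity = act_idx,
                         step = step)
    TRUE
  }

  frontier <- list()
  for (p in precursors) {
    if (p$carbons <= max_carbons && add_node(p, NA_character_, NA_integer_, 0L)) {
      frontier <- c(frontier, list(p))
    }
  }
  step <- 0L
  while (length(frontier) > 0) {
    step <- step + 1L
    frontier <- frontier[order(vapply(frontier, order_key, ""))]
    nxt <- list()
    for (fa in frontier) {
      for (i in seq_along(acts)) {
        prod <- activity_product(acts[[i]], fa)
        if (is.null(prod) || prod$carbons > max_carbons) next
        if (add_node(prod, format(fa), i, step)) nxt <- c(nxt, list(prod))
      }
    }
    frontier <- nxt
  }

  keys <- ls(nodes)
  info <- lapply(keys, function(k) nodes[[k]])
  df <- data.frame(
    acid = keys,
    carbons = vapply(info, function(x) x$fa$carbons, 1L),
    double_bonds = vapply(info, function(x) x$fa$double_bonds, 1L),
    omega = vapply(info, function(x) x$fa$omega, 1L),
    predecessor = vapply(info, function(x) x$predecessor, ""),
    activity = vapply(info, function(x) {
      if (is.na(x$activity)) NA_character_ else act_labels[[x$activity]]
    }, ""),
    step = vapply(info, function(x) x$step, 1L),
    stringsAsFactors = FALSE)
  df <- df[order(df$carbons, df$double_bonds, df$omega, df$acid), ]
  rownames(df) <- NULL

  structure(list(acids = df, activities = acts,
                 precursors = vapply(precursors, format, ""),
                 max_carbons = max_carbons),
            class = "pufa_reachability")
}

#' @export
print.pufa_reachability <- function(x, ...) {
  cat(sprintf("<pufa_reachability: %d acids reachable from {%s} under %d activities>\n",
              nrow(x$acids), paste(x$precursors, collapse = ", "),
              length(x$activities)))
  invisible(x)
}

#' @rdname reachable_set
#' @param r a `pufa_reachability` object.
#' @param target a [fatty_acid()] or shorthand string.
#' @export
is_reachable <- function(r, target) {
  stopifnot(inherits(r, "pufa_reachability"))
  key <- if (inherits(target, "fatty_acid")) format(target)
         else format(parse_fatty_acid(target))
  key %in% r$acids$acid
}

#' Reconstruct one reaction path to a reachable acid
#'
#' Follows the stored predecessor links from `target` back to a precursor.
#'
#' @inheritParams is_reachable
#' @return Data frame with columns `step`, `substrate`, `activity`,
#'   `product`; zero rows if the target is itself a precursor.
#' @export
reaction_path <- function(r, target) {
  stopifnot(inherits(r, "pufa_reachability"))
  key <- if (inherits(target, "fatty_acid")) format(target)
         else format(parse_fatty_acid(target))
  if (!(key %in% r$acids$acid)) {
    abort(sprintf("%s is not reachable", key), "pufa_input_error")
  }
  rows <- list()
  cur <- key
  repeat {
    rec <- r$acids[r$acids$acid == cur, ]
    if (is.na(rec$activity)) break
    rows <- c(list(data.frame(substrate = rec$predecessor,
                              activity = rec$activity,
                              product = cur, stringsAsFactors = FALSE)), rows)
    cur <- rec$predecessor
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(substrate = character(0), activity = character(0),
                         product = character(0), stringsAsFactors = FALSE)
  out$step <- seq_len(nrow(out))
  out[, c("step", "substrate", "activity", "product")]
}
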