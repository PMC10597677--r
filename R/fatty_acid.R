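#' Fatty acids in shorthand notation
#'
#' A fatty acid is represented canonically by its chain length (`carbons`),
#' number of double bonds (`double_bonds`) and, for unsaturated acids, the
#' omega class (`omega`): the position of the terminal double bond counted
#' from the methyl end. All acids handled by the reaction network are
#' even-chain and methylene-interrupted, so the full set of double-bond
#' positions is derivable from these three numbers and is never stored
#' (see [delta_positions()]).
#'
#' Shorthand notation is the field standard `C:Dn-W`, e.g. `"20:5n-3"` for
#' eicosapentaenoic acid (EPA) and `"18:0"` for stearic acid.
#'
#' @param carbons even integer chain length, at least 4.
#' @param double_bonds non-negative integer count of double bonds.
#' @param omega omega class (3, 6 or 9); must be `NA` for saturated acids.
#' @return An object of class `fatty_acid`.
#' @examples
#' fatty_acid(20, 5, 3)          # EPA
#' parse_fatty_acid("18 : 3n-3") # ALA, whitespace tolerated
#' @export
fatty_acid <- function(carbons, double_bonds, omega = NA) {
  fa <- structure(
    list(carbons = as.integer(carbons),
         double_bonds = as.integer(double_bonds),
         omega = if (is.na(omega)) NA_integer_ else as.integer(omega)),
    class = "fatty_acid")
  validate_fatty_acid(fa)
}

validate_fatty_acid <- function(fa) {
  c_ <- fa$carbons; d <- fa$double_bonds; w <- fa$omega
  if (is.na(c_) || c_ < 4 || c_ %% 2 != 0) {
    abort("carbons must be an even integer >= 4", "pufa_validation_error")
  }
  if (is.na(d) || d < 0) {
    abort("double_bonds must be a non-negative integer", "pufa_validation_error")
  }
  if (d == 0 && !is.na(w)) {
    abort("saturated acids carry no omega class", "pufa_validation_error")
  }
  if (d > 0) {
    if (is.na(w) || !(w %in% c(3L, 6L, 9L))) {
      abort("unsaturated acids need omega in {3, 6, 9}", "pufa_validation_error")
    }
    # methylene-interruption feasibility: the proximal double bond must sit
    # at position >= 2 from the carboxyl terminus
    if (c_ - w - 3L * (d - 1L) < 2L) {
      abort(sprintf("%d:%dn-%d is not a feasible methylene-interrupted acid",
                    c_, d, w), "pufa_validation_error")
    }
  }
  fa
}

#' Parse fatty-acid shorthand notation
#'
#' Accepts `"C:D"` for saturated acids and `"C:Dn-W"` for unsaturated ones,
#' tolerating whitespace around the separators (as commonly typeset, e.g.
#' `"20 : 5n-3"`). The result round-trips through [format()] to the
#' canonical `"C:Dn-W"` form.
#'
#' @param x a single shorthand string.
#' @return A [fatty_acid()] object.
#' @export
parse_fatty_acid <- function(x) {
  if (!is.character(x) || length(x) != 1 || is.na(x)) {
    abort("notation must be a single string", "pufa_parse_error")
  }
  m <- regmatches(x, regexec(
    "^\\s*([0-9]+)\\s*:\\s*([0-9]+)\\s*(?:n\\s*-\\s*([0-9]+)\\s*)?$", x))[[1]]
  if (length(m) == 0) {
    abort(sprintf("cannot parse fatty-acid notation '%s'", x), "pufa_parse_error")
  }
  omega <- if (m[4] == "") NA else as.integer(m[4])
  fatty_acid(as.integer(m[2]), as.integer(m[3]), omega)
}

#' @export
format.fatty_acid <- function(x, ...) {
  if (x$double_bonds == 0) sprintf("%d:%d", x$carbons, x$double_bonds)
  else sprintf("%d:%dn-%d", x$carbons, x$double_bonds, x$omega)
}

#' @export
print.fatty_acid <- function(x, ...) {
  dp <- delta_positions(x)
  cat(sprintf("<fatty_acid %s>%s\n", format(x),
              if (length(dp)) paste0(" delta positions: ",
                                     paste(dp, collapse = ",")) else ""))
  invisible(x)
}

#' @export
`==.fatty_acid` <- function(e1, e2) {
  identical(format(e1), format(e2))
}

#' Double-bond positions from the carboxyl terminus
#'
#' Derives the ordered Delta positions of a methylene-interrupted acid.
#' The distal bond sits at `carbons - omega` (the omega anchor) and each
#' further bond lies three carbons closer to the carboxyl terminus, so the
#' positions are `(carbons - omega) - 3k` for `k = 0 .. double_bonds - 1`,
#' returned ascending. Saturated acids yield an empty vector.
#'
#' @param fa a [fatty_acid()].
#' @return Integer vector of Delta positions, ascending.
#' @examples
#' delta_positions(parse_fatty_acid("18:3n-3")) # 9 12 15
#' @export
delta_positions <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  if (fa$double_bonds == 0) return(integer(0))
  sort((fa$carbons - fa$omega) - 3L * (seq_len(fa$double_bonds) - 1L))
}

#' Apply a front-end desaturation
#'
#' Front-end desaturases (Fed) insert a double bond between an existing bond
#' and the carboxyl terminus. The new bond at `delta` must be methylene-
#' interrupted with the current proximal bond, i.e. the substrate must carry
#' a bond at `delta + 3` and none at `delta`.
#'
#' @param fa substrate [fatty_acid()].
#' @param delta position of the inserted bond, counted from the carboxyl end.
#' @return The product fatty acid (`double_bonds + 1`, omega unchanged).
#' @examples
#' apply_front_end_desaturation(parse_fatty_acid("18:3n-3"), 6) # 18:4n-3
#' @export
apply_front_end_desaturation <- function(fa, delta) {
  stopifnot(inherits(fa, "fatty_acid"))
  delta <- as.integer(delta)
  dp <- delta_positions(fa)
  if (!((delta + 3L) %in% dp) || delta %in% dp) {
    abort(sprintf("front-end desaturation at delta %d inapplicable to %s",
                  delta, format(fa)), "pufa_inapplicable_reaction")
  }
  # with methylene interruption, a bond at delta+3 that is not the proximal
  # bond implies a bond at delta, caught above; so delta is the new minimum
  out <- tryCatch(fatty_acid(fa$carbons, fa$double_bonds + 1L, fa$omega),
                  pufa_validation_error = function(e) {
                    abort(conditionMessage(e), "pufa_inapplicable_reaction")
                  })
  out
}

#' Apply a methyl-end desaturation
#'
#' Methyl-end desaturases (omega-x) insert a double bond distal to the
#' existing distal-most bond, moving the omega class closer to the methyl
#' end (9 to 6 for a Delta-12 activity on C18 substrates; 6 to 3 for
#' Delta-15). The substrate's distal bond must sit at `delta - 3` and the
#' product omega (`carbons - delta`) must be 3 or 6.
#'
#' @inheritParams apply_front_end_desaturation
#' @return The product fatty acid with decreased omega.
#' @examples
#' apply_methyl_end_desaturation(parse_fatty_acid("18:1n-9"), 12) # 18:2n-6
#' @export
apply_methyl_end_desaturation <- function(fa, delta) {
  stopifnot(inherits(fa, "fatty_acid"))
  delta <- as.integer(delta)
  dp <- delta_positions(fa)
  new_omega <- fa$carbons - delta
  if (length(dp) == 0 || max(dp) != delta - 3L || !(new_omega %in% c(3L, 6L))) {
    abort(sprintf("methyl-end desaturation at delta %d inapplicable to %s",
                  delta, format(fa)), "pufa_inapplicable_reaction")
  }
  fatty_acid(fa$carbons, fa$double_bonds + 1L, new_omega)
}

#' Apply a two-carbon elongation
#'
#' Elongases (Elovl) extend the chain by two carbons at the carboxyl end;
#' the omega class is unchanged and every Delta position shifts by +2.
#'
#' @param fa substrate [fatty_acid()].
#' @return The elongated fatty acid.
#' @examples
#' apply_elongation(parse_fatty_acid("18:3n-3")) # 20:3n-3
#' @export
apply_elongation <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  fatty_acid(fa$carbons + 2L, fa$double_bonds, fa$omega)
}

#' Apply one round of beta-oxidative chain shortening
#'
#' The partial beta-oxidation step of the Sprecher route removes two carbons
#' from the carboxyl end, shifting every Delta position by -2. It requires
#' the proximal bond to sit at position 6 or higher so the product remains a
#' valid front-end acid (proximal bond at >= 4).
#'
#' @param fa substrate [fatty_acid()].
#' @return The shortened fatty acid.
#' @examples
#' apply_beta_oxidation_shortening(parse_fatty_acid("24:6n-3")) # 22:6n-3
#' @export
apply_beta_oxidation_shortening <- function(fa) {
  stopifnot(inherits(fa, "fatty_acid"))
  dp <- delta_positions(fa)
  if (length(dp) == 0 || min(dp) < 6L) {
    abort(sprintf("beta-oxidation shortening inapplicable to %s (proximal bond < 6)",
                  format(fa)), "pufa_inapplicable_reaction")
  }
  fatty_acid(fa$carbons - 2L, fa$double_bonds, fa$omega)
}
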