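# Fatty-acid notation, Delta-position derivation and reaction operators.

all_valid_acids <- function(max_carbons = 24) {
  out <- list()
  for (c_ in seq(4, max_carbons, by = 2)) {
    out[[length(out) + 1L]] <- fatty_acid(c_, 0)
    for (w in c(3, 6, 9)) {
      d <- 1
      while (c_ - w - 3 * (d - 1) >= 2) {
        out[[length(out) + 1L]] <- fatty_acid(c_, d, w)
        d <- d + 1
      }
    }
  }
  out
}

test_that("parsing accepts shorthand with whitespace and round-trips", {
  fa <- parse_fatty_acid("20 : 5n-3")
  expect_equal(fa$carbons, 20L)
  expect_equal(fa$double_bonds, 5L)
  expect_equal(fa$omega, 3L)
  expect_equal(format(fa), "20:5n-3")

  sat <- parse_fatty_acid("18:0")
  expect_equal(sat$carbons, 18L)
  expect_true(is.na(sat$omega))
  expect_equal(format(sat), "18:0")

  for (fa in all_valid_acids()) {
    expect_true(parse_fatty_acid(format(fa)) == fa)
  }
})

test_that("malformed or infeasible notation is rejected", {
  expect_error(parse_fatty_acid("foo"), class = "pufa_parse_error")
  expect_error(parse_fatty_acid("18-3n:3"), class = "pufa_parse_error")
  expect_error(parse_fatty_acid("18:7n-3"), class = "pufa_validation_error")
  expect_error(parse_fatty_acid("17:0"), class = "pufa_validation_error")
  expect_error(parse_fatty_acid("18:1n-5"), class = "pufa_validation_error")
  expect_error(fatty_acid(18, 0, 3), class = "pufa_validation_error")
})

test_that("delta positions match the brute-force placement oracle", {
  expect_equal(delta_positions(parse_fatty_acid("18:1n-9")), 9L)
  expect_equal(delta_positions(parse_fatty_acid("18:3n-3")), c(9L, 12L, 15L))
  expect_equal(delta_positions(parse_fatty_acid("22:6n-3")),
               c(4L, 7L, 10L, 13L, 16L, 19L))
  expect_equal(delta_positions(parse_fatty_acid("18:0")), integer(0))
  for (fa in all_valid_acids()) {
    expect_equal(delta_positions(fa),
                 ora_delta_positions(fa$carbons, fa$double_bonds, fa$omega),
                 info = format(fa))
  }
})

test_that("front-end desaturation follows the proximal-bond rule", {
  expect_equal(format(apply_front_end_desaturation(
    parse_fatty_acid("18:3n-3"), 6)), "18:4n-3")
  expect_equal(format(apply_front_end_desaturation(
    parse_fatty_acid("18:2n-6"), 6)), "18:3n-6")
  expect_equal(format(apply_front_end_desaturation(
    parse_fatty_acid("20:4n-3"), 5)), "20:5n-3")
  expect_equal(format(apply_front_end_desaturation(
    parse_fatty_acid("20:3n-6"), 5)), "20:4n-6")
  expect_error(apply_front_end_desaturation(parse_fatty_acid("18:0"), 6),
               class = "pufa_inapplicable_reaction")
  expect_error(apply_front_end_desaturation(parse_fatty_acid("18:3n-3"), 9),
               class = "pufa_inapplicable_reaction") # bond already at 9
})

test_that("methyl-end desaturation moves the omega class inward", {
  expect_equal(format(apply_methyl_end_desaturation(
    parse_fatty_acid("18:1n-9"), 12)), "18:2n-6")
  expect_equal(format(apply_methyl_end_desaturation(
    parse_fatty_acid("18:2n-6"), 15)), "18:3n-3")
  expect_equal(format(apply_methyl_end_desaturation(
    parse_fatty_acid("18:3n-6"), 15)), "18:4n-3")
  expect_error(apply_methyl_end_desaturation(parse_fatty_acid("18:1n-9"), 15),
               class = "pufa_inapplicable_reaction") # distal bond at 9, not 12
  expect_error(apply_methyl_end_desaturation(parse_fatty_acid("18:0"), 12),
               class = "pufa_inapplicable_reaction")
})

test_that("elongation and shortening shift positions by two carbons", {
  expect_equal(format(apply_elongation(parse_fatty_acid("18:3n-3"))), "20:3n-3")
  expect_equal(format(apply_elongation(parse_fatty_acid("20:5n-3"))), "22:5n-3")
  expect_equal(format(apply_elongation(parse_fatty_acid("18:0"))), "20:0")

  expect_equal(format(apply_beta_oxidation_shortening(
    parse_fatty_acid("24:6n-3"))), "22:6n-3")
  sh <- apply_beta_oxidation_shortening(parse_fatty_acid("24:5n-3"))
  expect_equal(format(sh), "22:5n-3")
  expect_equal(delta_positions(sh),
               delta_positions(parse_fatty_acid("24:5n-3")) - 2L)
  # min Delta 9 >= 6: allowed
  expect_equal(format(apply_beta_oxidation_shortening(
    parse_fatty_acid("18:3n-3"))), "16:3n-3")
  # DHA has proximal bond at 4: shortening would break front-end validity
  expect_error(apply_beta_oxidation_shortening(parse_fatty_acid("22:6n-3")),
               class = "pufa_inapplicable_reaction")
})

test_that("operators preserve invariants; elongate-then-shorten is identity", {
  for (fa in all_valid_acids(22)) {
    el <- apply_elongation(fa)
    expect_equal(delta_positions(el), delta_positions(fa) + 2L)
    if (fa$double_bonds > 0 && min(delta_positions(el)) >= 6) {
      back <- apply_beta_oxidation_shortening(el)
      expect_true(back == fa, info = format(fa))
    }
  }
})
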