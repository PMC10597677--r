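# Reaction-network reachability and activity presets.

test_that("the characterized preset reaches EPA and ARA but not DHA", {
  r <- reachable_set("bdelloid_characterized", list("18:1n-9"))
  expect_true(is_reachable(r, "20:5n-3")) # EPA
  expect_true(is_reachable(r, "20:4n-6")) # ARA
  expect_false(is_reachable(r, "22:6n-3")) # DHA
  # every reachable acid has a reconstructible path ending at itself
  for (acid in r$acids$acid) {
    path <- reaction_path(r, acid)
    if (nrow(path) > 0) {
      expect_equal(path$product[nrow(path)], acid)
      expect_true(path$substrate[1] %in% r$precursors)
      # replay the path step by step through the operators
      cur <- parse_fatty_acid(path$substrate[1])
      for (k in seq_len(nrow(path))) {
        expect_equal(format(cur), path$substrate[k])
        cur <- parse_fatty_acid(path$product[k])
      }
    }
  }
})

test_that("both DHA routes open it up: Delta-4, and Sprecher", {
  base <- activity_preset("bdelloid_characterized")
  # Delta-4 route requires C20 elongation for the 22:5n-3 substrate
  with_d4 <- c(base, list(enzyme_activity("front_end_desaturation", delta = 4)))
  r1 <- reachable_set(with_d4, list("18:1n-9"))
  expect_true(is_reachable(r1, "22:6n-3"))

  # without C20 elongation, Delta-4 alone cannot reach DHA
  no_c20 <- list(
    enzyme_activity("methyl_end_desaturation", delta = 12),
    enzyme_activity("methyl_end_desaturation", delta = 15),
    enzyme_activity("front_end_desaturation", delta = 6),
    enzyme_activity("front_end_desaturation", delta = 5),
    enzyme_activity("elongation", substrate_carbons = 18),
    enzyme_activity("front_end_desaturation", delta = 4))
  expect_false(is_reachable(reachable_set(no_c20, list("18:1n-9")), "22:6n-3"))

  # Sprecher route: C22 elongation + Delta-6 + beta-oxidation shortening
  sprecher <- c(base, list(
    enzyme_activity("elongation", substrate_carbons = 22),
    enzyme_activity("beta_oxidation_shortening")))
  r2 <- reachable_set(sprecher, list("18:1n-9"))
  expect_true(is_reachable(r2, "22:6n-3"))
  path <- reaction_path(r2, "22:6n-3")
  expect_true("24:6n-3" %in% path$substrate) # via the C24 intermediate
})

test_that("closure is monotone in the activity set and idempotent", {
  base <- activity_preset("bdelloid_characterized")
  precursors <- list("18:1n-9")
  r_base <- reachable_set(base, precursors)
  for (k in seq_along(base)) {
    r_sub <- reachable_set(base[-k], precursors)
    expect_true(all(r_sub$acids$acid %in% r_base$acids$acid),
                info = sprintf("dropping activity %d", k))
  }
  # closure of the closure is itself
  r_again <- reachable_set(base, as.list(r_base$acids$acid))
  expect_setequal(r_again$acids$acid, r_base$acids$acid)
})

test_that("empty activity list yields exactly the precursors", {
  r <- reachable_set(list(), list("18:1n-9", "18:0"))
  expect_setequal(r$acids$acid, c("18:1n-9", "18:0"))
})

test_that("max_carbons bounds the search", {
  elo <- list(enzyme_activity("elongation", substrate_carbons = seq(4, 30, 2)))
  r <- reachable_set(elo, list("18:0"), max_carbons = 24)
  expect_setequal(r$acids$acid, c("18:0", "20:0", "22:0", "24:0"))
})

test_that("presets load from JSON and reject unknown names", {
  expect_true("bdelloid_characterized" %in% list_activity_presets())
  acts <- activity_preset("elovl25")
  expect_length(acts, 1)
  expect_equal(acts[[1]]$substrate_carbons, c(18L, 20L))
  expect_error(activity_preset("nope"), class = "pufa_config_error")

  # a user file round-trips through read_activities
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(list(
    list(kind = "front_end_desaturation", delta = 8),
    list(kind = "elongation", substrate_carbons = c(20, 22))),
    tmp, auto_unbox = TRUE)
  acts <- read_activities(tmp)
  expect_equal(acts[[1]]$delta, 8L)
  expect_equal(acts[[2]]$substrate_carbons, c(20L, 22L))
})

test_that("activity construction validates its arguments", {
  expect_error(enzyme_activity("front_end_desaturation", delta = 3),
               class = "pufa_validation_error")
  expect_error(enzyme_activity("elongation"), class = "pufa_validation_error")
  expect_error(enzyme_activity("desaturation"), class = "pufa_validation_error")
})
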