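test_that("charge-pair classification covers all four categories", {
  p <- data.frame(
    n_position = c(6L, 6L, NA, 6L, NA),
    n_residue = c("D", "D", NA, "D", NA),
    c_position = c(7L, 7L, NA, NA, 7L),
    c_residue = c("R", "E", NA, NA, "K"),
    stringsAsFactors = FALSE
  )
  expect_identical(classify_charge_pair(p),
                   c("opposite", "like", "none", "single", "single"))
})

test_that("opposite/like/none are symmetric under side swap", {
  pairs <- enumerate_pairs()
  swapped <- pairs
  swapped[c("n_position", "n_residue", "c_position", "c_residue")] <-
    pairs[c("c_position", "c_residue", "n_position", "n_residue")]
  expect_identical(classify_charge_pair(pairs), classify_charge_pair(swapped))
  expect_identical(residue_spacing(pairs), residue_spacing(swapped))
})

test_that("residue spacing requires two charged residues", {
  p <- make_isolates(c(6, 2, 6), c("D", "D", "D"),
                     c(7, 11, NA), c("R", "K", NA), c(90, 60, 30))
  expect_identical(residue_spacing(p), c(1L, 9L, NA))
})

test_that("within_spacing fractions are inclusive and per class", {
  iso <- make_isolates(
    n_pos = c(2, 2, 6, 2, 6), n_res = c("D", "D", "D", "D", "D"),
    c_pos = c(3, 11, 11, 11, 7), c_res = c("R", "R", "R", "R", "R"),
    percent = c(90, 90, 60, 60, 30))
  fr <- within_spacing(iso, threshold = 5)
  expect_equal(fr[["high"]], 0.5)   # spacings {1, 9}
  expect_equal(fr[["medium"]], 0.5) # spacings {5 (inclusive), 9}
  expect_equal(fr[["low"]], 1.0)
  # spacing exactly at the threshold counts as within
  at5 <- make_isolates(2, "D", 7, "K", 90)
  expect_equal(within_spacing(at5, 5)[["high"]], 1.0)
  expect_equal(within_spacing(at5, 4)[["high"]], 0.0)
  # class with no both-charged pairs reports NA, not 0
  none <- make_isolates(6, "D", NA, NA_character_, 90)
  expect_true(is.na(within_spacing(none)[["high"]]))
})

test_that("positional distribution counts per class, side and position", {
  one <- make_isolates(6, "D", 7, "R", 95)
  tab <- positional_distribution(one)
  expect_identical(tab$count[tab$side == "N" & tab$position == 6], 1)
  expect_identical(tab$count[tab$side == "C" & tab$position == 7], 1)
  expect_identical(sum(tab$count), 2)
  # empty input gives an empty (all-zero) table
  empty <- make_isolates(integer(0), character(0), integer(0),
                         character(0), numeric(0))
  expect_equal(sum(positional_distribution(empty)$count), 0)
  # conservation: per class and side, counts sum to charged TMDs there
  iso <- simulate_selection(config = screen_config(seed = 11))
  tab <- positional_distribution(iso, "observed_count")
  for (cl in unique(iso$affinity_class)) {
    sel <- iso$affinity_class == cl
    n_charged <- sum(iso$observed_count[sel & residue_charge(iso$n_residue) != 0])
    expect_equal(sum(tab$count[tab$affinity_class == cl & tab$side == "N"]),
                 n_charged)
  }
})

test_that("count_matching agrees with combinatorial closed forms", {
  pairs <- enumerate_pairs()
  # opposite charges, one residue at 6 and the other at 7: 2neg x 2pos x
  # 2 sign arrangements x 2 position orders = 16
  expect_identical(count_matching(pattern_predicate("opposite", c(6, 7)),
                                  pairs), 16L)
  expect_identical(count_matching(pattern_predicate("any"), pairs), 1089L)
  expect_identical(count_matching(pattern_predicate("none"), pairs), 1L)
  # N-side charged at one given position: 4 residues x 33 partners
  expect_identical(
    count_matching(pattern_predicate("any", n_side = list(positions = 6)),
                   pairs), 4L * 33L)
  # all opposite pairs: 16 charged options per side, half the sign
  # combinations are opposite: 16 * 16 * 2 / 2... = 512
  qn <- residue_charge(pairs$n_residue)
  qc <- residue_charge(pairs$c_residue)
  expect_identical(count_matching(pattern_predicate("opposite"), pairs),
                   sum(qn * qc == -1L))
  expect_identical(count_matching(pattern_predicate("opposite"), pairs), 512L)
  # single-position set means both residues at that position
  expect_identical(count_matching(pattern_predicate("opposite", 6), pairs),
                   8L)
})

test_that("overrepresentation reproduces the printed worked example", {
  res <- overrepresentation(pattern_predicate("opposite", c(6, 7)),
                            n_isolates = 71, observed = 8)
  expect_identical(res$matching_pairs, 16L)
  expect_equal(round(res$p_prior, 4), 0.0147)
  expect_equal(round(res$expected, 2), 1.04)
  expect_identical(res$factor_rounded, 8L)
  expect_equal(res$factor_raw, 8 / (16 / 1089 * 71))
})

test_that("overrepresentation handles edge cases", {
  pred <- pattern_predicate("opposite", c(6, 7))
  expect_equal(overrepresentation(pred, 71, 0)$factor_raw, 0)
  # p_prior = 1 predicate: expected = n, factor = observed / n
  all_pred <- pattern_predicate("any")
  res <- overrepresentation(all_pred, 50, 10)
  expect_equal(res$expected, 50)
  expect_equal(res$factor_raw, 0.2)
  # empty pattern with observations is flagged undefined
  impossible <- pattern_predicate("opposite", c(6, 7),
                                  n_side = list(residues = "E",
                                                positions = 2))
  res0 <- overrepresentation(impossible, 71, 3)
  expect_true(res0$undefined)
  expect_true(is.na(res0$factor_raw))
  expect_error(overrepresentation(pred, 5, 6), "n_isolates >= observed")
})

test_that("class summaries count categories with unit fractions", {
  iso <- make_isolates(
    n_pos = c(6, 2, 6), n_res = c("D", "E", "D"),
    c_pos = c(7, 3, 7), c_res = c("R", "D", "K"),
    percent = c(95, 95, 95))
  sm <- summarize_by_class(iso)
  high <- sm[sm$affinity_class == "high", ]
  expect_equal(high$fraction[high$category == "opposite"], 2 / 3)
  expect_equal(high$fraction[high$category == "like"], 1 / 3)
  expect_equal(sum(high$fraction), 1)
  # multiplicities respected via count_col
  sm2 <- summarize_by_class(transform(iso, observed_count = c(4L, 1L, 1L)),
                            "observed_count")
  high2 <- sm2[sm2$affinity_class == "high", ]
  expect_equal(high2$count[high2$category == "opposite"], 5)
  # fractions sum to 1 in every non-empty class of a simulated screen
  sim <- simulate_selection(config = screen_config(seed = 3))
  sm3 <- summarize_by_class(sim, "observed_count")
  sums <- tapply(sm3$fraction, sm3$affinity_class, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
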