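test_that("dose_series enforces its invariants", {
  xs <- standard_doses()
  expect_error(dose_series("p", xs[-1], rep(1, 6)), "zero")
  expect_error(dose_series("p", c(0, 1, 2, 3), rep(1, 4)), "5 distinct")
  expect_error(dose_series("p", xs, rep(1, 6)), "equal length")
  expect_error(dose_series("p", xs, c(-0.1, rep(1, 6))), ">= 0")
  s <- dose_series("p", rev(xs), rev(1 / (1 + (rev(xs) / 50)^3)))
  expect_equal(s$concentrations, xs)  # sorted by dose
})

test_that("noiseless curves are recovered to 1e-6 and y(k) = c/2", {
  cases <- list(c(1, 50, 3), c(0.8, 120, 1.5), c(2.5, 15, 8), c(1.2, 300, 2))
  for (p in cases) {
    x <- sort(unique(c(standard_doses(), p[2] * c(0.5, 1, 2, 4))))
    fit <- fit_hill(make_hill_series(p[1], p[2], p[3], x = x))
    expect_true(fit$diagnostics$accepted)
    expect_lt(abs(fit$params$c - p[1]) / p[1], 1e-6)
    expect_lt(abs(fit$params$k - p[2]) / p[2], 1e-6)
    expect_lt(abs(fit$params$g - p[3]) / p[3], 1e-6)
    # half-maximum identity of the LD50 under the fitted model
    expect_lt(abs(predict(fit$params, fit$params$k) - fit$params$c / 2),
              1e-9)
  }
})

test_that("degenerate series are rejected with diagnostics, not errors", {
  xs <- standard_doses()
  flat <- fit_hill(dose_series("flat", xs, rep(0.7, 7)))
  expect_false(flat$diagnostics$converged)
  expect_false(flat$diagnostics$accepted)
  expect_match(flat$diagnostics$reason, "equal")

  up <- fit_hill(dose_series("up", xs, seq(0.1, 0.7, length.out = 7)))
  expect_false(up$diagnostics$accepted)
  expect_match(up$diagnostics$reason, "never decrease")

  expect_true(is.na(flat$params$k))
})

test_that("noisy fit matches the brute-force grid oracle", {
  xs <- standard_doses()
  set.seed(42)
  y <- pmax(1 / (1 + (xs / 50)^3) + rnorm(7, sd = 0.05), 0)
  fit <- fit_hill(dose_series("noisy", xs, y))
  oracle <- grid_hill_oracle(xs, y)
  # the optimizer must never do worse than the dense grid
  expect_lte(fit$diagnostics$rss, oracle$sse + 1e-9)
  # and must agree with the grid argmin within the grid resolution
  expect_lt(abs(fit$params$c - oracle$c), diff(range(y)) / 59 * 1.5)
  expect_lt(abs(fit$params$k - oracle$k), 400 / 79 * 1.5)
  expect_lt(abs(fit$params$g - oracle$g), 9.5 / 59 * 1.5)
})

test_that("fitted SSE beats the grid oracle on varied seeded curves", {
  xs <- standard_doses()
  for (seed in 1:5) {
    set.seed(seed)
    y <- pmax(1 / (1 + (xs / 80)^2) + rnorm(7, sd = 0.05), 0)
    fit <- fit_hill(dose_series("s", xs, y))
    oracle <- grid_hill_oracle(xs, y)
    expect_lte(fit$diagnostics$rss, oracle$sse + 1e-9)
  }
})

test_that("fitting is scale-equivariant in the dose axis", {
  base <- fit_hill(make_hill_series(1, 50, 3))
  for (s in c(0.1, 10)) {
    xs <- standard_doses() * s
    scaled <- fit_hill(dose_series("s", xs, 1 / (1 + (xs / (50 * s))^3)))
    expect_lt(abs(scaled$params$k - base$params$k * s) / (base$params$k * s),
              1e-6)
    expect_lt(abs(scaled$params$c - base$params$c), 1e-6)
    expect_lt(abs(scaled$params$g - base$params$g), 1e-6)
  }
})

test_that("fit_hill is deterministic", {
  set.seed(99)
  y <- pmax(1 / (1 + (standard_doses() / 60)^4) + rnorm(7, 0, 0.03), 0)
  s <- dose_series("d", standard_doses(), y)
  f1 <- fit_hill(s)
  f2 <- fit_hill(s)
  expect_identical(f1, f2)
})

test_that("aggregate_ld50 reproduces mean/SEM arithmetic", {
  fit_with_k <- function(k) {
    fit_hill(make_hill_series(1, k, 3, x = c(0, 10, 25, 50, 100, 200, 400,
                                             2 * k)))
  }
  agg <- aggregate_ld50(lapply(c(40, 60), fit_with_k), "p")
  expect_equal(agg$ld50_mean, 50, tolerance = 1e-6)
  expect_equal(agg$ld50_sem, 10, tolerance = 1e-6)

  one <- aggregate_ld50(list(fit_with_k(30)), "p")
  expect_equal(one$ld50_mean, 30, tolerance = 1e-6)
  expect_true(is.na(one$ld50_sem))
  expect_identical(one$n, 1L)

  same <- aggregate_ld50(lapply(rep(50, 4), fit_with_k), "p")
  expect_equal(same$ld50_sem, 0, tolerance = 1e-9)
})

test_that("aggregate_ld50 matches direct formulas on random inputs", {
  set.seed(7)
  for (i in 1:10) {
    ks <- runif(sample(2:6, 1), 20, 200)
    fits <- lapply(ks, function(k)
      fit_hill(make_hill_series(1, k, 3,
                                x = sort(unique(c(0, k * c(0.2, 0.5, 1, 2, 4),
                                                  300))))))
    agg <- aggregate_ld50(fits, "p")
    expect_equal(agg$ld50_mean, mean(ks), tolerance = 1e-5)
    expect_equal(agg$ld50_sem, sd(ks) / sqrt(length(ks)), tolerance = 1e-4)
  }
})

test_that("zero accepted fits is an explicit named error", {
  bad <- fit_hill(dose_series("hopeless", standard_doses(), rep(0.5, 7)))
  expect_error(aggregate_ld50(list(bad)), "hopeless")
  # rejected fits are excluded but counted
  good <- fit_hill(make_hill_series())
  agg <- aggregate_ld50(list(good, bad))
  expect_identical(agg$n, 1L)
  expect_identical(agg$n_rejected, 1L)
})

test_that("normalization and affinity classes follow the stated rules", {
  mk <- function(mean) structure(list(pair_id = "x", ld50_mean = mean,
                                      ld50_sem = NA_real_, n = 1L,
                                      n_rejected = 0L),
                                 class = "ld50_result")
  expect_equal(normalize_affinity(mk(80), mk(80))$percent_of_reference, 100)
  expect_equal(normalize_affinity(mk(40), mk(80))$percent_of_reference, 50)
  expect_error(normalize_affinity(mk(40), mk(0)), "> 0")

  expect_identical(classify_affinity(29), "low")
  expect_identical(classify_affinity(37), "low")
  expect_identical(classify_affinity(c(50, 80, 80.01, 49.99)),
                   c("medium", "medium", "high", "low"))
  expect_error(classify_affinity(-1), ">= 0")
})

test_that("expression normalization is background-subtracted per density", {
  expect_equal(normalize_expression(100, 100, 0.4)$normalized, 0)
  expect_equal(normalize_expression(200, 100, 0.5)$normalized, 200)
  ref <- normalize_expression(200, 100, 0.5)$normalized
  self <- normalize_expression(200, 100, 0.5, reference_normalized = ref)
  expect_equal(self$percent_of_reference, 100)
  expect_error(normalize_expression(200, 100, 0), "> 0")
})
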