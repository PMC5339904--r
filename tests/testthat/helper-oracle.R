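# Independent brute-force oracle for the Hill fit: dense grid search over
# (c, k, g) minimizing the residual sum of squares. Deliberately knows
# nothing about the package's optimizer.
grid_hill_oracle <- function(x, y,
                             c_grid = seq(0.5 * max(y), 1.5 * max(y),
                                          length.out = 60),
                             k_grid = seq(max(min(x[x > 0]) / 2, 1e-3),
                                          max(x), length.out = 80),
                             g_grid = seq(0.5, 10, length.out = 60)) {
  best <- list(sse = Inf)
  for (cc in c_grid) for (kk in k_grid) for (gg in g_grid) {
    sse <- sum((y - cc / (1 + (x / kk)^gg))^2)
    if (sse < best$sse) best <- list(c = cc, k = kk, g = gg, sse = sse)
  }
  best
}

standard_doses <- function() c(0, 10, 25, 50, 100, 200, 400)

# noiseless kill curve from known parameters
make_hill_series <- function(c = 1, k = 50, g = 3, x = standard_doses(),
                             pair_id = "truth") {
  dose_series(pair_id, x, c / (1 + (x / k)^g))
}

# small in-memory isolate table builder
make_isolates <- function(n_pos, n_res, c_pos, c_res, percent,
                          count = rep(1L, length(percent))) {
  data.frame(
    n_position = as.integer(n_pos), n_residue = n_res,
    c_position = as.integer(c_pos), c_residue = c_res,
    observed_count = as.integer(count),
    percent_of_reference = percent,
    affinity_class = classify_affinity(percent),
    stringsAsFactors = FALSE
  )
}
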