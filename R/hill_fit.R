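#' Decreasing Hill model parameters
#'
#' The dose-response model used throughout the package is the decreasing
#' Hill curve
#' \deqn{y(x) = c / (1 + (x/k)^g)}
#' where `c` is the curve maximum (cell density without ampicillin), `k`
#' is the LD50 in ug/mL (the dose at which density drops to half its
#' maximum) and `g > 0` is the Hill coefficient controlling steepness.
#' By construction `y(0) = c` and `y(k) = c/2`.
#'
#' @param c Curve maximum in absorbance units, > 0.
#' @param k LD50 in ug/mL, > 0.
#' @param g Hill coefficient, > 0.
#' @return An object of class `hill_params`.
#' @export
#' @examples
#' p <- hill_params(1, 50, 3)
#' predict(p, c(0, 50))  # c and c/2
hill_params <- function(c, k, g) {
  stopifnot(is.numeric(c), is.numeric(k), is.numeric(g),
            length(c) == 1L, length(k) == 1L, length(g) == 1L)
  if (!is.na(c) && c <= 0) stop("`c` must be > 0")
  if (!is.na(k) && k <= 0) stop("`k` must be > 0")
  if (!is.na(g) && g <= 0) stop("`g` must be > 0")
  structure(list(c = c, k = k, g = g), class = "hill_params")
}

#' @param object A `hill_params` object.
#' @param x Numeric vector of doses.
#' @param ... Unused.
#' @rdname hill_params
#' @export
predict.hill_params <- function(object, x, ...) {
  hill_curve(x, object$c, object$k, object$g)
}

#' @export
print.hill_params <- function(x, ...) {
  cat(sprintf("<hill_params> c = %.6g, LD50 k = %.6g ug/mL, g = %.6g\n",
              x$c, x$k, x$g))
  invisible(x)
}

# model kernel; x = 0 maps to y = c for any g > 0
hill_curve <- function(x, c, k, g) {
  c / (1 + (x / k)^g)
}

#' Fit control settings for [fit_hill()]
#'
#' @param r_squared_min Minimum coefficient of determination for a fit to
#'   be accepted by QC (default 0.85).
#' @param g_starts Multi-start grid of initial Hill coefficients; the fit
#'   with the lowest residual sum of squares wins, ties going to the
#'   smallest start.
#' @param max_iter Iteration cap per start.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(r_squared_min = 0.85, g_starts = c(1, 3, 8),
                        max_iter = 200L) {
  stopifnot(r_squared_min <= 1, length(g_starts) >= 1L, all(g_starts > 0))
  structure(list(r_squared_min = r_squared_min,
                 g_starts = as.numeric(g_starts),
                 max_iter = as.integer(max_iter)),
            class = "fit_control")
}

#' Fit the decreasing Hill equation to an ampicillin dose-response series
#'
#' Bounded nonlinear least squares of \eqn{y = c / (1 + (x/k)^g)} against
#' one replicate's kill curve. The starting value for `c` is the maximum
#' response, for `k` the linearly interpolated dose at half-maximum, and
#' the Hill coefficient is multi-started over `config$g_starts`; the
#' lowest-SSE solution is kept. Doses are fitted on their natural scale
#' (the model is defined at x = 0, which is retained).
#'
#' Degenerate inputs — all responses equal, or responses that never
#' decrease with dose (no kill signal) — are rejected without fitting,
#' with `converged = FALSE` and a reason in the diagnostics. QC acceptance
#' additionally requires `r_squared >= config$r_squared_min`.
#'
#' @param series A [dose_series()].
#' @param config A [fit_control()] object.
#' @return A list of class `hill_fit` with elements
#'   `params` ([hill_params()]; parameters are `NA` when no fit was
#'   attempted), `diagnostics` (list: `r_squared`, `rss`, `n_points`,
#'   `converged`, `accepted`, `reason`), `pair_id` and `replicate_id`.
#' @export
#' @examples
#' xs <- c(0, 10, 25, 50, 100, 200, 400)
#' s <- dose_series("demo", xs, 1 / (1 + (xs / 50)^3))
#' fit <- fit_hill(s)
#' fit$params$k  # recovers 50
fit_hill <- function(series, config = fit_control()) {
  stopifnot(inherits(series, "dose_series"), inherits(config, "fit_control"))
  x <- series$concentrations
  y <- series$responses
  n <- length(x)

  bail <- function(reason) {
    structure(list(
      params = structure(list(c = NA_real_, k = NA_real_, g = NA_real_),
                         class = "hill_params"),
      diagnostics = list(r_squared = NA_real_, rss = NA_real_,
                         n_points = n, converged = FALSE,
                         accepted = FALSE, reason = reason),
      pair_id = series$pair_id, replicate_id = series$replicate_id
    ), class = "hill_fit")
  }

  if (diff(range(y)) == 0) return(bail("all responses equal"))
  if (all(diff(y) >= 0)) return(bail("responses never decrease with dose"))

  cmax0 <- max(y)
  k0 <- half_max_dose(x, y, cmax0)
  lower <- c(c = 1e-8, k = max(min(x[x > 0]) / 100, 1e-8), g = 0.05)
  upper <- c(c = 10 * cmax0, k = max(x) * 100, g = 64)
  k0 <- min(max(k0, lower[["k"]]), upper[["k"]])

  sse <- function(p) sum((y - hill_curve(x, p[1], p[2], p[3]))^2)

  best <- NULL
  for (g0 in config$g_starts) {
    cand <- fit_one_start(x, y, start = c(c = cmax0, k = k0, g = g0),
                          lower = lower, upper = upper,
                          max_iter = config$max_iter, sse = sse)
    if (is.null(cand)) next
    if (is.null(best) || cand$rss < best$rss - 1e-12 * (1 + best$rss)) {
      best <- cand
    }
  }
  if (is.null(best)) return(bail("no start converged"))

  tss <- sum((y - mean(y))^2)
  r2 <- 1 - best$rss / tss
  accepted <- best$converged && r2 >= config$r_squared_min
  structure(list(
    params = hill_params(best$par[["c"]], best$par[["k"]], best$par[["g"]]),
    diagnostics = list(
      r_squared = r2, rss = best$rss, n_points = n,
      converged = best$converged, accepted = accepted,
      reason = if (accepted) NA_character_ else if (!best$converged)
        "did not converge" else "r_squared below threshold"
    ),
    pair_id = series$pair_id, replicate_id = series$replicate_id
  ), class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(
    "<hill_fit> %s/%s: LD50 = %.4g ug/mL (c = %.4g, g = %.3g), R2 = %.4f, %s\n",
    x$pair_id, x$replicate_id, x$params$k, x$params$c, x$params$g,
    d$r_squared, if (isTRUE(d$accepted)) "accepted" else
      paste0("rejected (", d$reason, ")")
  ))
  invisible(x)
}

# dose at which the curve first crosses half its maximum, by linear
# interpolation along the dose-ordered series; falls back to the median
# positive dose when the curve never crosses
half_max_dose <- function(x, y, cmax) {
  half <- cmax / 2
  below <- which(y <= half)
  if (length(below) == 0L) return(median(x[x > 0]))
  i <- below[1L]
  if (i == 1L) return(max(x[1L], min(x[x > 0]) / 2))
  x0 <- x[i - 1L]; x1 <- x[i]; y0 <- y[i - 1L]; y1 <- y[i]
  if (y0 == y1) return((x0 + x1) / 2)
  x0 + (half - y0) * (x1 - x0) / (y1 - y0)
}

# one bounded least-squares solve: nls(port) polished by L-BFGS-B, with
# L-BFGS-B alone as fallback when nls cannot evaluate the model
fit_one_start <- function(x, y, start, lower, upper, max_iter, sse) {
  par <- NULL
  converged <- FALSE
  fit <- tryCatch(
    suppressWarnings(nls(
      y ~ cc / (1 + (x / kk)^gg),
      start = list(cc = start[["c"]], kk = start[["k"]], gg = start[["g"]]),
      lower = c(lower[["c"]], lower[["k"]], lower[["g"]]),
      upper = c(upper[["c"]], upper[["k"]], upper[["g"]]),
      algorithm = "port",
      control = stats::nls.control(maxiter = max_iter, warnOnly = TRUE)
    )),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    cf <- coef(fit)
    par <- c(c = unname(cf[["cc"]]), k = unname(cf[["kk"]]),
             g = unname(cf[["gg"]]))
    converged <- isTRUE(fit$convInfo$isConv)
  }
  if (is.null(par)) par <- start
  pol <- tryCatch(
    optim(par, sse, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = max_iter * 5L, factr = 10)),
    error = function(e) NULL
  )
  if (is.null(pol) && is.null(fit)) return(NULL)
  if (!is.null(pol) && pol$value <= sse(par)) {
    par <- setNames(pol$par, c("c", "k", "g"))
    converged <- converged || pol$convergence == 0L
  }
  list(par = par, rss = sse(par), converged = converged)
}
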