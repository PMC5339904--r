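#' Aggregate replicate Hill fits into a per-pair LD50 estimate
#'
#' Replicates are fitted individually (one curve per transformation /
#' culture) and the accepted LD50 values are averaged; the spread is
#' reported as the standard error of the mean, SEM = sample SD / sqrt(n).
#' Rejected fits are excluded from the estimate but counted.
#'
#' @param fits List of `hill_fit` objects for one construct pair.
#' @param pair_id Optional pair label; defaults to the label of the first
#'   fit.
#' @return A list of class `ld50_result` with `pair_id`, `ld50_mean`,
#'   `ld50_sem` (`NA` when `n = 1`), `n` (accepted fits) and `n_rejected`.
#' @export
#' @examples
#' xs <- c(0, 10, 25, 50, 100, 200, 400)
#' fits <- lapply(c(40, 60), function(k)
#'   fit_hill(dose_series("p", xs, 1 / (1 + (xs / k)^3))))
#' aggregate_ld50(fits)  # mean 50, SEM 10
aggregate_ld50 <- function(fits, pair_id = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "hill_fit")))
  if (is.null(pair_id)) pair_id <- fits[[1L]]$pair_id
  acc <- vapply(fits, function(f) isTRUE(f$diagnostics$accepted), logical(1))
  if (!any(acc)) {
    stop(sprintf("no accepted replicate fits for pair '%s' (%d rejected)",
                 pair_id, sum(!acc)))
  }
  ks <- vapply(fits[acc], function(f) f$params$k, numeric(1))
  n <- length(ks)
  structure(list(
    pair_id = pair_id,
    ld50_mean = mean(ks),
    ld50_sem = if (n > 1L) sd(ks) / sqrt(n) else NA_real_,
    n = n,
    n_rejected = sum(!acc)
  ), class = "ld50_result")
}

#' @export
print.ld50_result <- function(x, ...) {
  cat(sprintf("<ld50_result> %s: LD50 = %.4g +/- %.3g ug/mL (n = %d)\n",
              x$pair_id, x$ld50_mean, x$ld50_sem, x$n))
  invisible(x)
}

#' Normalize an LD50 estimate to a reference construct
#'
#' Expresses a pair's mean LD50 as a percentage of a reference homodimer
#' (the reference itself maps to 100) and attaches the affinity class
#' from [classify_affinity()].
#'
#' @param result,reference `ld50_result` objects; the reference mean must
#'   be positive.
#' @return A list of class `relative_affinity` with `pair_id`,
#'   `percent_of_reference` and `affinity_class`.
#' @export
normalize_affinity <- function(result, reference) {
  stopifnot(inherits(result, "ld50_result"),
            inherits(reference, "ld50_result"))
  if (is.na(reference$ld50_mean) || reference$ld50_mean <= 0) {
    stop("reference LD50 mean must be > 0")
  }
  pct <- 100 * result$ld50_mean / reference$ld50_mean
  structure(list(
    pair_id = result$pair_id,
    percent_of_reference = pct,
    affinity_class = classify_affinity(pct)
  ), class = "relative_affinity")
}

#' Affinity class from a reference-normalized LD50
#'
#' Pairs are binned relative to the reference homodimer:
#' `"high"` above 80%, `"medium"` from 50% to 80% (both ends inclusive),
#' `"low"` below 50%.
#'
#' @param percent Numeric vector of percent-of-reference values, >= 0.
#' @param boundaries Length-2 numeric `c(low, high)` class boundaries
#'   (default `c(50, 80)`).
#' @return Character vector in `{"low", "medium", "high"}`.
#' @export
#' @examples
#' classify_affinity(c(29, 37, 80, 80.01))
classify_affinity <- function(percent, boundaries = c(50, 80)) {
  stopifnot(is.numeric(percent), length(boundaries) == 2L,
            boundaries[1] < boundaries[2])
  if (anyNA(percent)) stop("`percent` must not contain NA")
  if (any(percent < 0)) stop("`percent` must be >= 0")
  ifelse(percent > boundaries[2], "high",
         ifelse(percent >= boundaries[1], "medium", "low"))
}

#' Cell-density-normalized GFP expression
#'
#' Background-subtracts raw GFP fluorescence and divides by the culture's
#' absorbance at 544 nm, so that expression is reported per unit cell
#' density; optionally rescales so that a reference construct reads 100%.
#'
#' @param gfp_raw Raw fluorescence reading(s).
#' @param background Blank-medium fluorescence to subtract.
#' @param a544 Absorbance at 544 nm; must be > 0.
#' @param reference_normalized Optional normalized value of the reference
#'   construct; when given, `percent_of_reference` is added.
#' @param pair_id Optional label(s).
#' @return A data.frame of class `expression_record` with columns
#'   `pair_id`, `gfp_raw`, `background`, `a544`, `normalized` and (when a
#'   reference is supplied) `percent_of_reference`.
#' @export
#' @examples
#' normalize_expression(200, 100, 0.5)$normalized  # 200
normalize_expression <- function(gfp_raw, background, a544,
                                 reference_normalized = NULL,
                                 pair_id = NA_character_) {
  stopifnot(is.numeric(gfp_raw), is.numeric(background), is.numeric(a544))
  if (any(a544 <= 0)) stop("`a544` must be > 0 for normalization")
  out <- data.frame(
    pair_id = pair_id, gfp_raw = gfp_raw, background = background,
    a544 = a544, normalized = (gfp_raw - background) / a544,
    stringsAsFactors = FALSE
  )
  if (!is.null(reference_normalized)) {
    stopifnot(is.numeric(reference_normalized),
              length(reference_normalized) == 1L)
    if (reference_normalized == 0) stop("reference normalized value is 0")
    out$percent_of_reference <- 100 * out$normalized / reference_normalized
  }
  class(out) <- c("expression_record", class(out))
  out
}
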