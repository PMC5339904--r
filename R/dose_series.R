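#' Dose-response series for one construct pair
#'
#' Container for a single replicate's ampicillin kill curve: cell density
#' (absorbance at 544 nm) measured across a ladder of ampicillin
#' concentrations for one (N-BLa, C-BLa) construct pair.
#'
#' @param pair_id Character label of the construct pair.
#' @param concentrations Numeric vector of ampicillin doses in ug/mL.
#'   Must be non-negative and contain at least 5 distinct values
#'   including 0.
#' @param responses Numeric vector of A544 readings (dimensionless,
#'   non-negative), same length as `concentrations`.
#' @param replicate_id Character label of the replicate (default `"r1"`).
#' @param condition Optional free-text metadata (e.g. inducer levels);
#'   carried through unchanged.
#'
#' @return An object of class `dose_series`.
#' @seealso [fit_hill()]
#' @export
#' @examples
#' xs <- c(0, 10, 25, 50, 100, 200, 400)
#' dose_series("GpA+1", xs, 1 / (1 + (xs / 50)^3))
dose_series <- function(pair_id, concentrations, responses,
                        replicate_id = "r1", condition = NULL) {
  stopifnot(is.character(pair_id), length(pair_id) == 1L)
  concentrations <- as.numeric(concentrations)
  responses <- as.numeric(responses)
  if (length(concentrations) != length(responses)) {
    stop("`concentrations` and `responses` must have equal length")
  }
  if (anyNA(concentrations) || anyNA(responses)) {
    stop("dose series must not contain missing values")
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0")
  if (any(responses < 0)) stop("responses must be >= 0")
  if (length(unique(concentrations)) < 5L) {
    stop("need at least 5 distinct concentration values")
  }
  if (!any(concentrations == 0)) {
    stop("the zero-ampicillin dose must be included")
  }
  ord <- order(concentrations)
  structure(
    list(
      pair_id = pair_id,
      replicate_id = as.character(replicate_id),
      condition = condition,
      concentrations = concentrations[ord],
      responses = responses[ord]
    ),
    class = "dose_series"
  )
}

#' @export
print.dose_series <- function(x, ...) {
  cat(sprintf(
    "<dose_series> pair %s / replicate %s: %d doses, %g-%g ug/mL\n",
    x$pair_id, x$replicate_id, length(x$concentrations),
    min(x$concentrations), max(x$concentrations)
  ))
  invisible(x)
}

#' @export
as.data.frame.dose_series <- function(x, ...) {
  data.frame(
    pair_id = x$pair_id,
    replicate = x$replicate_id,
    ampicillin_ug_ml = x$concentrations,
    a544 = x$responses,
    stringsAsFactors = FALSE
  )
}
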