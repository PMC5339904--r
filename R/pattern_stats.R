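#' Charge sign of an ionizable residue
#'
#' Asp and Glu count as negative, Lys and Arg as positive; anything else
#' (including the uncharged wild-type, `NA`) as 0. Protonation state is
#' not modeled.
#'
#' @param residue Character vector of single-letter residues (or `NA`).
#' @return Integer vector in `{-1, 0, +1}`.
#' @export
residue_charge <- function(residue) {
  out <- integer(length(residue))
  out[residue %in% c("D", "E")] <- -1L
  out[residue %in% c("K", "R")] <- 1L
  out
}

#' Charge relationship of TMD pairs
#'
#' Classifies each (N-BLa, C-BLa) pair by the charges its two TMDs
#' carry: `"opposite"` (one positive, one negative), `"like"` (both the
#' same sign), `"single"` (exactly one TMD charged) or `"none"`.
#'
#' @param pairs A data.frame with columns `n_residue` and `c_residue`
#'   (e.g. from [enumerate_pairs()] or [read_isolate_table()]).
#' @return Character vector, one class per row.
#' @export
#' @examples
#' p <- data.frame(n_residue = c("D", "D", "D", NA),
#'                 c_residue = c("R", "E", NA, NA))
#' classify_charge_pair(p)
classify_charge_pair <- function(pairs) {
  qn <- residue_charge(pairs$n_residue)
  qc <- residue_charge(pairs$c_residue)
  out <- rep("none", nrow(pairs))
  both <- qn != 0L & qc != 0L
  out[both & qn == -qc] <- "opposite"
  out[both & qn == qc] <- "like"
  out[xor(qn != 0L, qc != 0L)] <- "single"
  out
}

#' Position spacing of a pair's ionizable residues
#'
#' Absolute difference between the two charged positions; `NA` unless
#' both TMDs carry an ionizable residue. Symmetric in the two sides.
#'
#' @inheritParams classify_charge_pair
#' @return Integer vector (`NA` where fewer than two residues are
#'   charged).
#' @export
residue_spacing <- function(pairs) {
  sp <- abs(pairs$n_position - pairs$c_position)
  sp[residue_charge(pairs$n_residue) == 0L |
       residue_charge(pairs$c_residue) == 0L] <- NA_integer_
  as.integer(sp)
}

#' Fraction of closely spaced charge pairs per affinity class
#'
#' Among pairs where both TMDs are charged, the fraction whose
#' ionizable residues sit within `threshold` positions of each other
#' (inclusive), reported separately for each affinity class. Classes
#' with no eligible (both-charged) pairs report `NA`, not 0.
#'
#' @param pairs Data.frame with `n_position`, `n_residue`, `c_position`,
#'   `c_residue` and `affinity_class` columns.
#' @param threshold Spacing cutoff in residue positions (default 5).
#' @return Named numeric vector of fractions, one per class present
#'   (ordered high, medium, low where applicable).
#' @export
within_spacing <- function(pairs, threshold = 5L) {
  stopifnot(threshold >= 0, "affinity_class" %in% names(pairs))
  sp <- residue_spacing(pairs)
  classes <- intersect(c("high", "medium", "low"),
                       unique(pairs$affinity_class))
  classes <- c(classes, setdiff(unique(pairs$affinity_class), classes))
  vapply(setNames(classes, classes), function(cl) {
    s <- sp[pairs$affinity_class == cl]
    s <- s[!is.na(s)]
    if (length(s) == 0L) NA_real_ else mean(s <= threshold)
  }, numeric(1))
}

#' Positional distribution of ionizable residues among isolates
#'
#' Counts charged residues at each randomized position, separately for
#' the N-BLa and C-BLa sides and for each affinity class. Rows can be
#' weighted by an isolate-count column to count repeated isolations.
#'
#' @inheritParams within_spacing
#' @param count_col Optional name of a column of per-row multiplicities
#'   (e.g. `"observed_count"`); default counts each row once.
#' @return A data.frame with columns `affinity_class`, `side` (`"N"` or
#'   `"C"`), `position` and `count`, covering every randomized position
#'   (zero counts included).
#' @export
positional_distribution <- function(pairs, count_col = NULL) {
  stopifnot("affinity_class" %in% names(pairs))
  w <- if (is.null(count_col)) rep(1, nrow(pairs)) else pairs[[count_col]]
  classes <- unique(pairs$affinity_class)
  if (length(classes) == 0L) classes <- character(0)
  grid <- expand.grid(position = randomized_positions(),
                      side = c("N", "C"), affinity_class = classes,
                      stringsAsFactors = FALSE)
  grid <- grid[, c("affinity_class", "side", "position")]
  if (nrow(grid) == 0L) {
    grid$count <- numeric(0)
    return(grid)
  }
  grid$count <- mapply(function(cl, side, pos) {
    p <- if (side == "N") pairs$n_position else pairs$c_position
    r <- if (side == "N") pairs$n_residue else pairs$c_residue
    sel <- pairs$affinity_class == cl & !is.na(p) & p == pos &
      residue_charge(r) != 0L
    sum(w[sel])
  }, grid$affinity_class, grid$side, grid$position)
  rownames(grid) <- NULL
  grid
}

#' Sequence-pattern predicate over the pair library
#'
#' Describes a class of (N-BLa, C-BLa) pairs by their charge relation
#' and, optionally, the positions of the charged residues. When
#' `position_set` is given, both TMDs must be charged and the unordered
#' pair of their positions must equal the set (a length-1 set means both
#' residues at that position). Per-side constraints restrict one side's
#' position and/or residue.
#'
#' @param relation One of `"any"`, `"opposite"`, `"like"`, `"single"`,
#'   `"none"`.
#' @param position_set Integer vector of 1 or 2 randomized positions, or
#'   `NULL` for any.
#' @param n_side,c_side Optional lists with elements `positions` and/or
#'   `residues` constraining that side (a constrained side must be
#'   charged).
#' @return An object of class `pattern_predicate`.
#' @export
#' @examples
#' opp67 <- pattern_predicate("opposite", position_set = c(6, 7))
#' count_matching(opp67)  # 16 of 1089
pattern_predicate <- function(relation = c("any", "opposite", "like",
                                           "single", "none"),
                              position_set = NULL,
                              n_side = NULL, c_side = NULL) {
  relation <- match.arg(relation)
  if (!is.null(position_set)) {
    position_set <- as.integer(position_set)
    if (!length(position_set) %in% 1:2 ||
        !all(position_set %in% randomized_positions())) {
      stop("`position_set` must be 1 or 2 randomized positions")
    }
  }
  structure(list(relation = relation, position_set = position_set,
                 n_side = n_side, c_side = c_side),
            class = "pattern_predicate")
}

#' Evaluate a predicate over a table of pairs
#'
#' @param predicate A [pattern_predicate()].
#' @param pairs A pair table (default the fully enumerated library).
#' @return Logical vector, one element per pair.
#' @export
matches_predicate <- function(predicate, pairs = enumerate_pairs()) {
  stopifnot(inherits(predicate, "pattern_predicate"))
  ok <- rep(TRUE, nrow(pairs))
  if (predicate$relation != "any") {
    ok <- ok & classify_charge_pair(pairs) == predicate$relation
  }
  if (!is.null(predicate$position_set)) {
    ps <- sort(predicate$position_set)
    if (length(ps) == 1L) ps <- c(ps, ps)
    both <- residue_charge(pairs$n_residue) != 0L &
      residue_charge(pairs$c_residue) != 0L
    ok <- ok & both & !is.na(pairs$n_position) & !is.na(pairs$c_position) &
      pmin(pairs$n_position, pairs$c_position) == ps[1L] &
      pmax(pairs$n_position, pairs$c_position) == ps[2L]
  }
  side_ok <- function(pos, res, side) {
    keep <- rep(TRUE, nrow(pairs))
    if (is.null(side)) return(keep)
    keep <- residue_charge(res) != 0L
    if (!is.null(side$positions)) keep <- keep & pos %in% side$positions
    if (!is.null(side$residues)) keep <- keep & res %in% side$residues
    keep & !is.na(keep)
  }
  ok & side_ok(pairs$n_position, pairs$n_residue, predicate$n_side) &
    side_ok(pairs$c_position, pairs$c_residue, predicate$c_side)
}

#' Exhaustive pattern count over the enumerated library
#'
#' Brute-force count of ordered library pairs satisfying a predicate.
#' This exhaustive count is the authoritative prior for
#' [overrepresentation()]; closed-form combinatorics serve only as
#' cross-checks.
#'
#' @inheritParams matches_predicate
#' @return Integer count.
#' @export
count_matching <- function(predicate, pairs = enumerate_pairs()) {
  sum(matches_predicate(predicate, pairs))
}

#' Observed-vs-expected overrepresentation of a sequence pattern
#'
#' Under uniform sampling of the library, the prior probability of a
#' pattern is its exhaustive pair count divided by the library size
#' (1089 for the default library). The expected number among
#' `n_isolates` sequenced isolates is `p_prior * n_isolates`, and the
#' overrepresentation factor is `observed / expected`. For the
#' opposite-charge pattern at positions 6 and 7 the default library
#' gives 16/1089 = 0.0147, hence 1.04 expected among 71 isolates;
#' 8 observed is an overrepresentation factor of 8 (nearest integer).
#'
#' @inheritParams matches_predicate
#' @param n_isolates Total isolates sequenced (duplicates included).
#' @param observed Observed isolates matching the pattern.
#' @return A list of class `overrep_result`: `matching_pairs`,
#'   `total_pairs`, `p_prior`, `n_isolates`, `expected`, `observed`,
#'   `factor_raw`, `factor_rounded` and `undefined` (TRUE when
#'   `expected = 0` with `observed > 0`).
#' @export
#' @examples
#' overrepresentation(pattern_predicate("opposite", c(6, 7)),
#'                    n_isolates = 71, observed = 8)
overrepresentation <- function(predicate, n_isolates, observed,
                               pairs = enumerate_pairs()) {
  stopifnot(n_isolates >= observed, observed >= 0)
  m <- count_matching(predicate, pairs)
  total <- nrow(pairs)
  p <- m / total
  expected <- p * n_isolates
  undefined <- expected == 0 && observed > 0
  factor_raw <- if (undefined) NA_real_ else if (observed == 0) 0
    else observed / expected
  structure(list(
    matching_pairs = m, total_pairs = total, p_prior = p,
    n_isolates = n_isolates, expected = expected, observed = observed,
    factor_raw = factor_raw,
    factor_rounded = if (is.na(factor_raw)) NA_integer_
      else as.integer(round(factor_raw)),
    undefined = undefined
  ), class = "overrep_result")
}

#' @export
print.overrep_result <- function(x, ...) {
  cat(sprintf(
    paste0("<overrep_result> %d/%d matching pairs (p = %.4f); expected ",
           "%.2f of %d isolates, observed %d -> factor %s\n"),
    x$matching_pairs, x$total_pairs, x$p_prior, x$expected, x$n_isolates,
    x$observed,
    if (x$undefined) "undefined (expected = 0)"
      else sprintf("%.2f (~%d)", x$factor_raw, x$factor_rounded)
  ))
  invisible(x)
}

#' Charge-pair category counts per affinity class
#'
#' Cross-tabulates isolated pairs by affinity class and charge-pair
#' category (opposite / like / single / none), with within-class
#' fractions.
#'
#' @inheritParams within_spacing
#' @param count_col Optional multiplicity column name.
#' @return Data.frame with columns `affinity_class`, `category`,
#'   `count`, `fraction`; fractions sum to 1 within each non-empty
#'   class.
#' @export
summarize_by_class <- function(pairs, count_col = NULL) {
  stopifnot("affinity_class" %in% names(pairs))
  w <- if (is.null(count_col)) rep(1, nrow(pairs)) else pairs[[count_col]]
  cat_levels <- c("opposite", "like", "single", "none")
  category <- factor(classify_charge_pair(pairs), levels = cat_levels)
  classes <- intersect(c("high", "medium", "low"),
                       unique(pairs$affinity_class))
  classes <- c(classes, setdiff(unique(pairs$affinity_class), classes))
  out <- do.call(rbind, lapply(classes, function(cl) {
    sel <- pairs$affinity_class == cl
    counts <- tapply(w[sel], category[sel], sum, default = 0)
    data.frame(affinity_class = cl, category = cat_levels,
               count = as.numeric(counts),
               fraction = as.numeric(counts) / sum(counts),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
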