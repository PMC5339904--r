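#' Ground-truth affinity model for the selection simulator
#'
#' Encodes, as a multiplicative model on the true LD50, the qualitative
#' drivers of heterotypic TMD-TMD affinity that the screen is built to
#' detect: oppositely charged pairs interact more strongly than
#' like-charged ones, positions 6/7 (about two helical turns upstream of
#' the GxxxG glycines) are the best location, and affinity decays as the
#' two charged positions move apart. This is a stated ground truth for
#' testing the analysis pipeline, not an inference from data.
#'
#' The default anchors the uncharged backbone homodimer at 37% of the
#' reference homodimer's LD50, the reference-normalized affinity of the
#' plain poly-Leu template.
#'
#' @param base_ld50 True LD50 (ug/mL) of an uncharged pair.
#' @param reference_ld50 True LD50 of the synthetic reference homodimer
#'   (the 100% anchor); must exceed `base_ld50`.
#' @param bonus_opposite Multiplier for oppositely charged pairs.
#' @param bonus_positions_67 Extra multiplier when the opposite charges
#'   sit exactly at positions 6 and 7.
#' @param penalty_like Multiplier for like-charged pairs (weakly above 1:
#'   hydrogen bonding contributes less than a salt bridge).
#' @param spacing_decay Per-residue decay factor applied for each residue
#'   of charge spacing beyond 1.
#' @param noise_cv Clone-to-clone coefficient of variation of the true
#'   LD50 (log-normal).
#' @return A list of class `affinity_model`.
#' @export
affinity_model <- function(base_ld50 = 37, reference_ld50 = 100,
                           bonus_opposite = 2.0, bonus_positions_67 = 1.35,
                           penalty_like = 1.25, spacing_decay = 0.92,
                           noise_cv = 0.15) {
  stopifnot(base_ld50 > 0, reference_ld50 > base_ld50,
            bonus_opposite > 0, bonus_positions_67 > 0, penalty_like > 0,
            spacing_decay > 0, noise_cv >= 0)
  structure(list(base_ld50 = base_ld50, reference_ld50 = reference_ld50,
                 bonus_opposite = bonus_opposite,
                 bonus_positions_67 = bonus_positions_67,
                 penalty_like = penalty_like, spacing_decay = spacing_decay,
                 noise_cv = noise_cv),
            class = "affinity_model")
}

#' Deterministic mean true LD50 of each pair under a ground-truth model
#'
#' @param pairs A pair table (see [enumerate_pairs()]).
#' @param model An [affinity_model()].
#' @return Numeric vector of mean LD50s in ug/mL, one per pair.
#' @export
mean_true_ld50 <- function(pairs, model = affinity_model()) {
  stopifnot(inherits(model, "affinity_model"))
  cls <- classify_charge_pair(pairs)
  sp <- residue_spacing(pairs)
  f <- rep(1, nrow(pairs))
  f[cls == "opposite"] <- model$bonus_opposite
  f[cls == "like"] <- model$penalty_like
  at67 <- cls == "opposite" & !is.na(sp) &
    pmin(pairs$n_position, pairs$c_position) == 6L &
    pmax(pairs$n_position, pairs$c_position) == 7L
  f[at67] <- f[at67] * model$bonus_positions_67
  decay <- !is.na(sp) & sp > 1L
  f[decay] <- f[decay] * model$spacing_decay^(sp[decay] - 1L)
  model$base_ld50 * f
}

#' Draw per-clone true LD50s
#'
#' Multiplies [mean_true_ld50()] by a mean-1 log-normal clone factor
#' with coefficient of variation `model$noise_cv`, standing in for
#' clonal variation between transformations.
#'
#' @inheritParams mean_true_ld50
#' @param seed Optional integer seed; when given, draws are made in a
#'   local RNG scope and are reproducible.
#' @return Numeric vector of LD50s in ug/mL.
#' @export
assign_true_ld50 <- function(pairs, model = affinity_model(), seed = NULL) {
  mu <- mean_true_ld50(pairs, model)
  if (model$noise_cv == 0) return(mu)
  draw <- function() {
    sdlog <- sqrt(log1p(model$noise_cv^2))
    mu * rlnorm(length(mu), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Per-cell survival probability under ampicillin
#'
#' The simulator's survival model uses the same decreasing Hill family
#' as the dose-response fits: a cell with true LD50 `ld50` survives dose
#' `dose` with probability \eqn{S = 1 / (1 + (dose/ld50)^g)}. `S(0) = 1`
#' and `S` is increasing in `ld50` and decreasing in dose.
#'
#' @param dose Ampicillin dose(s), ug/mL.
#' @param ld50 True LD50(s), ug/mL.
#' @param g Steepness of the survival curve.
#' @return Survival probabilities in (0, 1].
#' @export
survival_prob <- function(dose, ld50, g) {
  stopifnot(all(dose >= 0), all(ld50 > 0), g > 0)
  1 / (1 + (dose / ld50)^g)
}

#' Configuration of the two-step ampicillin selection
#'
#' Defaults mirror the screen protocol: plating on agar at 5 ug/mL
#' ampicillin followed by liquid selection at 30 ug/mL, with a 10-fold
#' excess of transformants over library size for coverage.
#'
#' @param plate_amp Ampicillin in the plate (step 1), ug/mL.
#' @param liquid_amp Ampicillin in liquid medium (step 2), ug/mL.
#' @param transformant_excess Plated cells as a multiple of library size
#'   (used when `cells_plated` is `NULL`).
#' @param cells_plated Explicit number of plated cells, overriding
#'   `transformant_excess`.
#' @param survival_g Steepness of the per-cell survival model (a free
#'   calibration parameter; see [simulate_control_discrimination()]).
#' @param n_sequenced Number of passing colonies to sequence (`NULL` =
#'   all of them).
#' @param seed Integer RNG seed; `NULL` uses the caller's RNG state.
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(plate_amp = 5, liquid_amp = 30,
                          transformant_excess = 10, cells_plated = NULL,
                          survival_g = 4, n_sequenced = NULL, seed = NULL) {
  stopifnot(plate_amp >= 0, liquid_amp >= 0, transformant_excess > 0,
            survival_g > 0,
            is.null(cells_plated) || cells_plated > 0,
            is.null(n_sequenced) || n_sequenced > 0)
  structure(list(plate_amp = plate_amp, liquid_amp = liquid_amp,
                 transformant_excess = transformant_excess,
                 cells_plated = cells_plated, survival_g = survival_g,
                 n_sequenced = n_sequenced, seed = seed),
            class = "screen_config")
}

#' Simulate the two-step ampicillin selection over a pair library
#'
#' Step 1: each plated cell carries a pair drawn from `frequencies`
#' (uniform by default) and survives the plate dose with probability
#' [survival_prob()] at its clone's true LD50. Step 2: each surviving
#' colony independently passes the liquid dose the same way. The
#' "sequencing" output lists every pair among the passing colonies with
#' its multiplicity (optionally subsampled to `config$n_sequenced`
#' colonies).
#'
#' @param pairs Pair library (default [enumerate_pairs()]).
#' @param model An [affinity_model()] ground truth.
#' @param config A [screen_config()].
#' @param frequencies Optional plating frequencies per pair (recycled to
#'   sum 1); default uniform.
#' @return The `pairs` rows with `observed_count > 0`, augmented with
#'   `true_ld50`, `percent_of_reference` and `affinity_class` columns.
#'   Attributes `n_plated`, `n_survivors_plate` and `n_isolates` carry
#'   the step totals. An empty data.frame (zero survivors) is a valid
#'   outcome.
#' @export
#' @examples
#' isolates <- simulate_selection(config = screen_config(seed = 1))
#' sum(isolates$observed_count) == attr(isolates, "n_isolates")
simulate_selection <- function(pairs = enumerate_pairs(),
                               model = affinity_model(),
                               config = screen_config(),
                               frequencies = NULL) {
  stopifnot(nrow(pairs) >= 1L, inherits(config, "screen_config"))
  n_pairs <- nrow(pairs)
  n_cells <- if (is.null(config$cells_plated)) {
    as.integer(round(config$transformant_excess * n_pairs))
  } else as.integer(config$cells_plated)
  freq <- if (is.null(frequencies)) rep(1 / n_pairs, n_pairs) else {
    stopifnot(length(frequencies) == n_pairs, all(frequencies >= 0),
              sum(frequencies) > 0)
    frequencies / sum(frequencies)
  }

  run <- function() {
    plated <- as.integer(rmultinom(1L, n_cells, freq))
    ld50 <- assign_true_ld50(pairs, model)
    s1 <- rbinom(n_pairs, plated,
                 survival_prob(config$plate_amp, ld50, config$survival_g))
    s2 <- rbinom(n_pairs, s1,
                 survival_prob(config$liquid_amp, ld50, config$survival_g))
    list(plated = plated, ld50 = ld50, s1 = s1, s2 = s2)
  }
  res <- if (is.null(config$seed)) run() else
    withr::with_seed(config$seed, run())

  counts <- res$s2
  if (!is.null(config$n_sequenced) && sum(counts) > config$n_sequenced) {
    colony_pair <- rep.int(seq_len(n_pairs), counts)
    pick <- if (is.null(config$seed)) {
      sample(colony_pair, config$n_sequenced)
    } else {
      withr::with_seed(config$seed + 1L,
                       sample(colony_pair, config$n_sequenced))
    }
    counts <- tabulate(pick, nbins = n_pairs)
  }

  out <- pairs[counts > 0L, , drop = FALSE]
  out$observed_count <- counts[counts > 0L]
  out$true_ld50 <- res$ld50[counts > 0L]
  out$percent_of_reference <- 100 * out$true_ld50 / model$reference_ld50
  out$affinity_class <- if (nrow(out)) {
    classify_affinity(out$percent_of_reference)
  } else character(0)
  rownames(out) <- NULL
  attr(out, "n_plated") <- n_cells
  attr(out, "n_survivors_plate") <- sum(res$s1)
  attr(out, "n_isolates") <- sum(counts)
  out
}

#' Simulate noisy dose-response curves from known Hill parameters
#'
#' Forward model of the LD50 workflow: evaluates a true decreasing Hill
#' curve on a dose ladder and adds i.i.d. Gaussian read noise, truncated
#' at zero (absorbance cannot be negative).
#'
#' @param true A [hill_params()] ground truth.
#' @param concentrations Dose ladder including 0, ug/mL.
#' @param noise_sd Read noise standard deviation, absorbance units.
#' @param replicates Number of replicate series to generate.
#' @param pair_id Label for the generated series.
#' @param seed Optional integer seed (local RNG scope, reproducible).
#' @return A list of [dose_series()], replicates named `r1`, `r2`, ...
#' @export
#' @examples
#' s <- simulate_dose_response(hill_params(1, 50, 3),
#'                             c(0, 10, 25, 50, 100, 200, 400),
#'                             noise_sd = 0, replicates = 1)
#' fit_hill(s[[1]])$params$k  # 50
simulate_dose_response <- function(true, concentrations, noise_sd = 0.05,
                                   replicates = 4L, pair_id = "sim",
                                   seed = NULL) {
  stopifnot(inherits(true, "hill_params"), replicates >= 1L,
            noise_sd >= 0, any(concentrations == 0))
  clean <- predict(true, concentrations)
  draw <- function() {
    lapply(seq_len(replicates), function(i) {
      y <- pmax(clean + rnorm(length(clean), sd = noise_sd), 0)
      dose_series(pair_id, concentrations, y,
                  replicate_id = sprintf("r%d", i))
    })
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Expected wild-type vs mutant discrimination of the selection
#'
#' For two single-pair "libraries" plated identically, returns the
#' ratio of expected survivor counts after the plate step and after
#' both steps. Because expectations are analytic under the binomial
#' survival model, this is deterministic; it is the tool used to
#' calibrate `survival_g` (and, if needed, the dose pair) against a
#' known wild-type/mutant discrimination ratio.
#'
#' @param wt_ld50,mut_ld50 True LD50s of the two constructs, > 0.
#' @param config A [screen_config()].
#' @return A list with `plate_ratio`, `two_step_ratio` and `infinite`
#'   (TRUE when the mutant's expected survival is zero).
#' @export
simulate_control_discrimination <- function(wt_ld50, mut_ld50,
                                            config = screen_config()) {
  stopifnot(wt_ld50 > 0, mut_ld50 > 0, inherits(config, "screen_config"))
  g <- config$survival_g
  s_wt <- survival_prob(config$plate_amp, wt_ld50, g)
  s_mut <- survival_prob(config$plate_amp, mut_ld50, g)
  l_wt <- survival_prob(config$liquid_amp, wt_ld50, g)
  l_mut <- survival_prob(config$liquid_amp, mut_ld50, g)
  inf <- s_mut == 0 || s_mut * l_mut == 0
  list(
    plate_ratio = if (s_mut == 0) Inf else s_wt / s_mut,
    two_step_ratio = if (inf) Inf else (s_wt * l_wt) / (s_mut * l_mut),
    infinite = inf
  )
}
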