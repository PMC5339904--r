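#' End-to-end screen analysis
#'
#' Orchestrates the full analysis of a selection screen: read the plate
#' table, fit every replicate's Hill curve, aggregate accepted LD50s per
#' pair, normalize to the reference homodimer and classify affinities;
#' then, when an isolate table is supplied, compute the charge-pair
#' class summary, positional distribution, spacing fractions and the
#' overrepresentation report for the configured predicate. All outputs
#' are plain TSV/JSON plus a JSON run manifest (inputs, configuration,
#' package version) from which the run can be reproduced; re-running
#' with the same config yields byte-identical outputs.
#'
#' Configuration keys (list or DCF file via [read_run_config()]):
#' `plate_table` (path, required), `reference_pair` (pair_id of the
#' 100% construct, required), `isolate_table` (path, optional),
#' `out_dir` (default `"tmdscreen_out"`), `r_squared_min` (default
#' 0.85), `boundaries` (two values, default 50,80),
#' `predicate_relation` / `predicate_positions` (default opposite at
#' 6,7), `spacing_threshold` (default 5).
#'
#' @param config Named list or path to a DCF config file.
#' @return Invisibly, a list with `ld50` (per-pair data.frame), `fits`,
#'   `class_summary`, `positional`, `spacing`, `overrep`, `manifest`
#'   and `out_dir`.
#' @export
run_screen_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  defaults <- list(out_dir = "tmdscreen_out", r_squared_min = 0.85,
                   boundaries = c(50, 80),
                   predicate_relation = "opposite",
                   predicate_positions = c(6, 7),
                   spacing_threshold = 5)
  config <- modifyList(defaults, config)
  for (key in c("plate_table", "reference_pair")) {
    if (is.null(config[[key]])) stop("config is missing `", key, "`")
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  series <- stage("read", read_plate_table(config$plate_table))
  ctrl <- fit_control(r_squared_min = config$r_squared_min)
  fits <- stage("fit", lapply(series, fit_hill, config = ctrl))

  by_pair <- split(fits, vapply(fits, `[[`, character(1), "pair_id"))
  results <- stage("aggregate", lapply(by_pair, aggregate_ld50))

  if (!config$reference_pair %in% names(results)) {
    stop(sprintf("stage 'normalize' failed: reference pair '%s' absent",
                 config$reference_pair), call. = FALSE)
  }
  reference <- results[[config$reference_pair]]
  ld50 <- stage("normalize", do.call(rbind, lapply(results, function(r) {
    rel <- normalize_affinity(r, reference)
    data.frame(pair_id = r$pair_id, ld50_mean = r$ld50_mean,
               ld50_sem = r$ld50_sem, n = r$n, n_rejected = r$n_rejected,
               percent_of_reference = rel$percent_of_reference,
               affinity_class = classify_affinity(
                 rel$percent_of_reference, boundaries = config$boundaries),
               stringsAsFactors = FALSE)
  })))
  rownames(ld50) <- NULL

  class_summary <- positional <- spacing <- overrep <- NULL
  if (!is.null(config$isolate_table)) {
    isolates <- stage("isolates", read_isolate_table(config$isolate_table))
    if (!"affinity_class" %in% names(isolates)) {
      stop("stage 'isolates' failed: isolate table lacks ",
           "percent_of_reference", call. = FALSE)
    }
    class_summary <- stage("patterns",
                           summarize_by_class(isolates, "observed_count"))
    positional <- stage("patterns",
                        positional_distribution(isolates, "observed_count"))
    spacing <- stage("patterns",
                     within_spacing(isolates, config$spacing_threshold))
    pred <- pattern_predicate(config$predicate_relation,
                              position_set = config$predicate_positions)
    n_iso <- sum(isolates$observed_count)
    obs <- sum(isolates$observed_count[matches_predicate(pred, isolates)])
    overrep <- stage("overrep", overrepresentation(pred, n_iso, obs))
  }

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  tsv(ld50, "ld50_results.tsv")
  fit_report <- lapply(fits, function(f) {
    list(pair_id = f$pair_id, replicate_id = f$replicate_id,
         params = unclass(f$params), diagnostics = f$diagnostics)
  })
  jsonlite::write_json(unname(fit_report),
                       file.path(out_dir, "fit_report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  if (!is.null(class_summary)) {
    tsv(class_summary, "class_summary.tsv")
    tsv(positional, "positional_distribution.tsv")
    tsv(data.frame(affinity_class = names(spacing),
                   fraction_within = as.numeric(spacing)), "spacing.tsv")
    jsonlite::write_json(unclass(overrep),
                         file.path(out_dir, "overrep.json"),
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
  }
  manifest <- list(
    package = "tmdscreen",
    version = as.character(packageVersion("tmdscreen")),
    config = config,
    inputs = list(plate_table = unname(tools::md5sum(config$plate_table)),
                  isolate_table = if (!is.null(config$isolate_table))
                    unname(tools::md5sum(config$isolate_table))),
    n_series = length(series),
    n_pairs = nrow(ld50)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  invisible(list(ld50 = ld50, fits = fits, class_summary = class_summary,
                 positional = positional, spacing = spacing,
                 overrep = overrep, manifest = manifest,
                 out_dir = out_dir))
}
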