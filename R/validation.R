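# Bioanalytical validation battery: linearity, carryover, intraday
# precision, matrix effect, selectivity and limit of detection, with
# pass/fail against the assay's acceptance thresholds (carryover < 5%,
# %CV < 15%, S/N > 3 with reference > 5).

#' Fit calibration linearity
#'
#' Ordinary least squares of mean peak area against nominal concentration
#' (one mean per level). Weighted fits (1/x, 1/x^2) are available for
#' heteroscedastic series.
#'
#' @param concentration Numeric vector of nominal concentrations (ng/mL).
#' @param area Numeric vector of peak areas, same length.
#' @param weighting `"none"` (default), `"1/x"` or `"1/x2"`; weights apply
#'   to the per-level means (zero-concentration levels get the smallest
#'   positive weight present).
#' @return List with `slope`, `intercept`, `r2`, `n_levels`, `fit` (the
#'   `lm` object on level means).
#' @export
fit_linearity <- function(concentration, area,
                          weighting = c("none", "1/x", "1/x2")) {
  weighting <- match.arg(weighting)
  stopifnot(length(concentration) == length(area))
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  levels <- sort(unique(concentration))
  if (length(levels) < 2L)
    stop("at least 2 distinct concentration levels are required")
  mean_area <- vapply(levels, function(l) mean(area[concentration == l]),
                      numeric(1))
  w <- switch(weighting,
              "none" = rep(1, length(levels)),
              "1/x" = 1 / levels,
              "1/x2" = 1 / levels^2)
  if (any(!is.finite(w)))
    w[!is.finite(w)] <- max(w[is.finite(w)])
  fit <- stats::lm(mean_area ~ levels, weights = w)
  ss_res <- sum(w * stats::residuals(fit)^2)
  ss_tot <- sum(w * (mean_area - stats::weighted.mean(mean_area, w))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = max(0, r2), n_levels = length(levels), fit = fit)
}

#' Back-calculate concentrations from a linearity fit
#'
#' Inverts the calibration line: `(area - intercept) / slope`.
#'
#' @param area Numeric vector of areas.
#' @param fit Result of [fit_linearity()].
#' @return Numeric vector of back-calculated concentrations.
#' @export
back_calculate <- function(area, fit) {
  if (fit$slope == 0) stop("cannot back-calculate with zero slope")
  (area - fit$intercept) / fit$slope
}

#' Carryover ratio
#'
#' Residual signal in blanks following high-concentration injections:
#' `mean(blank areas) / mean(high areas) * 100`. The assay passes when the
#' ratio is below 5%.
#'
#' @param high_areas Areas of the high-concentration runs.
#' @param blank_areas Areas of the alternating blank runs.
#' @param threshold Pass threshold in percent (default 5).
#' @return List with `ratio_pct`, `pass`, `flag` (set when the high mean is
#'   zero).
#' @export
carryover_ratio <- function(high_areas, blank_areas, threshold = 5) {
  stopifnot(length(high_areas) >= 1L, length(blank_areas) >= 1L)
  mh <- mean(high_areas)
  if (mh == 0)
    return(list(ratio_pct = NA_real_, pass = NA,
                flag = "zero high-concentration area"))
  ratio <- mean(blank_areas) / mh * 100
  list(ratio_pct = ratio, pass = ratio < threshold, flag = NULL)
}

#' Intraday precision (%CV per level)
#'
#' Coefficient of variation `100 * sd / mean` of back-calculated
#' concentrations per nominal level; each level passes when %CV < 15.
#'
#' @param nominal Numeric vector of nominal concentrations.
#' @param backcalc Numeric vector of back-calculated concentrations.
#' @param threshold Pass threshold in percent (default 15).
#' @return `data.frame` with `nominal`, `n`, `mean`, `cv_pct`, `pass` (one
#'   row per level); %CV is `NA`-flagged when a level mean is zero.
#' @export
intraday_precision <- function(nominal, backcalc, threshold = 15) {
  stopifnot(length(nominal) == length(backcalc))
  levels <- sort(unique(nominal))
  rows <- lapply(levels, function(l) {
    x <- backcalc[nominal == l]
    if (length(x) < 2L)
      stop("at least 2 replicates required at level ", l)
    m <- mean(x)
    cv <- if (m == 0) NA_real_ else 100 * stats::sd(x) / m
    data.frame(nominal = l, n = length(x), mean = m, cv_pct = cv,
               pass = if (is.na(cv)) NA else cv < threshold)
  })
  do.call(rbind, rows)
}

#' Matrix effect ratio
#'
#' Ratio of the mean response in fortified matrix (urine) to the mean
#' response in fortified neat solution, in percent. 100% means no matrix
#' effect; below 100% indicates ion suppression.
#'
#' @param urine_areas Areas of fortified-urine runs.
#' @param neat_areas Areas of fortified-neat runs.
#' @return List with `ratio_pct` and `flag` (set when the neat mean is
#'   zero).
#' @export
matrix_effect <- function(urine_areas, neat_areas) {
  stopifnot(length(urine_areas) >= 1L, length(neat_areas) >= 1L)
  mn <- mean(neat_areas)
  if (mn == 0)
    return(list(ratio_pct = NA_real_, flag = "zero neat-solution area"))
  list(ratio_pct = mean(urine_areas) / mn * 100, flag = NULL)
}

#' Estimate the limit of detection from a dilution ladder
#'
#' The LOD is the lowest concentration at which the detection criterion
#' holds across replicates: in `"all"` mode (default) every replicate must
#' have S/N above the threshold; in `"mean"` mode the replicate mean S/N
#' must. The concentration meeting the stricter reference S/N is reported
#' alongside.
#'
#' @param concentration Numeric vector, one entry per replicate injection.
#' @param snr Numeric vector of measured S/N values, same length.
#' @param threshold Detection S/N threshold (default 3).
#' @param reference Reference S/N (default 5).
#' @param mode `"all"` or `"mean"`.
#' @return List with `lod` (numeric, or `Inf` when no level passes, i.e.
#'   above the maximum tested), `lod_reference`, `above_max` (logical),
#'   `per_level` (`data.frame`: `concentration`, `n`, `min_snr`,
#'   `mean_snr`, `pass`, `pass_reference`).
#' @export
estimate_lod <- function(concentration, snr, threshold = 3, reference = 5,
                         mode = c("all", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(concentration) == length(snr))
  levels <- sort(unique(concentration))
  if (length(levels) < 2L)
    stop("a dilution ladder needs at least 2 concentrations")
  per <- do.call(rbind, lapply(levels, function(l) {
    x <- snr[concentration == l]
    stat <- if (mode == "all") min(x) else mean(x)
    data.frame(concentration = l, n = length(x), min_snr = min(x),
               mean_snr = mean(x), pass = stat > threshold,
               pass_reference = stat > reference)
  }))
  pick <- function(flag) {
    ok <- per$concentration[flag]
    if (!length(ok)) Inf else min(ok)
  }
  lod <- pick(per$pass)
  list(lod = lod, lod_reference = pick(per$pass_reference),
       above_max = !is.finite(lod), per_level = per)
}

#' Selectivity assessment
#'
#' Passes iff every spiked sample is detected and no negative sample is.
#' Failing sample identifiers are reported.
#'
#' @param spiked_detected Logical vector (or list of `detection_result`)
#'   for spiked samples.
#' @param negative_detected Same for negative samples.
#' @param spiked_ids,negative_ids Optional sample identifiers.
#' @return List with `pass`, `missed_spiked`, `false_positive_negatives`.
#' @export
selectivity <- function(spiked_detected, negative_detected,
                        spiked_ids = seq_along(spiked_detected),
                        negative_ids = seq_along(negative_detected)) {
  as_flag <- function(x) vapply(x, function(e)
    if (inherits(e, "detection_result")) e$detected else isTRUE(e),
    logical(1))
  sp <- as_flag(spiked_detected); ng <- as_flag(negative_detected)
  if (!length(sp) || !length(ng))
    stop("both spiked and negative results are required")
  list(pass = all(sp) && !any(ng),
       missed_spiked = spiked_ids[!sp],
       false_positive_negatives = negative_ids[ng])
}

# ---------------------------------------------------------------------------
# Whole-study evaluation
# ---------------------------------------------------------------------------

#' Evaluate a validation study from measured areas and detections
#'
#' Takes the per-run area table of a validation study (columns `run_id`,
#' `arm`, `role`, `nominal_conc`, `area`, and optionally `detected` for the
#' selectivity arm) and computes the full validation report.
#'
#' @param study `data.frame` as above, e.g. from [measure_study()] or a
#'   study CSV.
#' @param weighting Calibration weighting passed to [fit_linearity()] for
#'   the reported linearity figures.
#' @param backcalc_weighting Weighting of the calibration fit used to
#'   back-calculate precision-arm concentrations (default `"1/x2"`:
#'   over a wide calibration range with proportional error, an unweighted
#'   fit leaves the intercept too loosely determined for back-calculation
#'   at the lowest levels).
#' @return Object of class `validation_report`: list with components
#'   `linearity`, `carryover`, `precision`, `matrix_effect`, `selectivity`
#'   (each `NULL` when its arm is absent) and `thresholds`.
#' @export
validate_study <- function(study, weighting = "none",
                           backcalc_weighting = "1/x2") {
  need <- c("run_id", "arm", "role", "nominal_conc", "area")
  if (!all(need %in% names(study)))
    stop("study table must have columns: ", paste(need, collapse = ", "))
  rep_out <- list(thresholds = c(carryover_pct = 5, cv_pct = 15,
                                 snr_threshold = 3, snr_reference = 5))

  lin <- study[study$arm == "linearity", ]
  fit <- NULL
  if (nrow(lin)) {
    fit <- fit_linearity(lin$nominal_conc, lin$area, weighting = weighting)
    rep_out$linearity <- fit[c("slope", "intercept", "r2", "n_levels")]
  }

  co <- study[study$arm == "carryover", ]
  if (nrow(co))
    rep_out$carryover <- carryover_ratio(co$area[co$role == "high"],
                                         co$area[co$role == "blank"])

  pr <- study[study$arm == "precision", ]
  if (nrow(pr)) {
    if (is.null(fit))
      stop("precision evaluation requires a linearity arm for back-calculation")
    bc_fit <- if (identical(backcalc_weighting, weighting)) fit else
      fit_linearity(lin$nominal_conc, lin$area,
                    weighting = backcalc_weighting)
    bc <- back_calculate(pr$area, bc_fit)
    rep_out$precision <- intraday_precision(pr$nominal_conc, bc)
  }

  mx <- study[study$arm == "matrix", ]
  if (nrow(mx))
    rep_out$matrix_effect <- matrix_effect(mx$area[mx$role == "urine"],
                                           mx$area[mx$role == "neat"])

  sel <- study[study$arm == "selectivity", ]
  if (nrow(sel) && "detected" %in% names(study)) {
    sp <- sel[sel$role == "spiked", ]; ng <- sel[sel$role == "negative", ]
    rep_out$selectivity <- selectivity(sp$detected, ng$detected,
                                       sp$run_id, ng$run_id)
  }
  structure(rep_out, class = "validation_report")
}

#' Measure a simulated validation study
#'
#' Runs the detection module over every run of a
#' [simulate_validation_study()] result and returns the study area table
#' expected by [validate_study()] (areas for all arms; detection calls for
#' the selectivity arm).
#'
#' @param sim Result of [simulate_validation_study()].
#' @param transition The monitored [transition_entry()] (default
#'   [target_transition()]).
#' @param policy A [detection_policy()].
#' @return `data.frame`: `run_id`, `arm`, `role`, `nominal_conc`, `area`,
#'   `snr`, `detected`.
#' @export
measure_study <- function(sim, transition = target_transition(),
                          policy = detection_policy()) {
  mani <- sim$manifest
  rows <- lapply(seq_len(nrow(mani)), function(i) {
    run <- sim$runs[[mani$run_id[i]]]
    need_det <- mani$arm[i] == "selectivity"
    if (need_det) {
      det <- detect_target(run, transition, policy)
      area <- measure_peak_area(run, transition, policy)
      data.frame(mani[i, ], area = area, snr = det$snr,
                 detected = det$detected, stringsAsFactors = FALSE)
    } else {
      data.frame(mani[i, ],
                 area = measure_peak_area(run, transition, policy),
                 snr = NA_real_, detected = NA, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>\n")
  if (!is.null(x$linearity))
    cat(sprintf("  linearity: slope %.4g, intercept %.4g, r2 %.4f (%d levels)\n",
                x$linearity$slope, x$linearity$intercept, x$linearity$r2,
                x$linearity$n_levels))
  if (!is.null(x$carryover))
    cat(sprintf("  carryover: %.2f%% (pass: %s)\n",
                x$carryover$ratio_pct, x$carryover$pass))
  if (!is.null(x$precision)) {
    cat("  intraday precision:\n")
    for (i in seq_len(nrow(x$precision)))
      cat(sprintf("    %g ng/mL: %%CV %.2f (pass: %s)\n",
                  x$precision$nominal[i], x$precision$cv_pct[i],
                  x$precision$pass[i]))
  }
  if (!is.null(x$matrix_effect))
    cat(sprintf("  matrix effect: %.1f%%\n", x$matrix_effect$ratio_pct))
  if (!is.null(x$selectivity))
    cat(sprintf("  selectivity: pass %s\n", x$selectivity$pass))
  invisible(x)
}

#' Serialise a validation report to JSON
#'
#' @param report A `validation_report`.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_validation_report <- function(report, path = NULL) {
  obj <- unclass(report)
  obj$precision <- if (!is.null(obj$precision)) obj$precision else NULL
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                            na = "null", force = TRUE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", force = TRUE)
  invisible(path)
}
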