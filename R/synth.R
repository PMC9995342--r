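# Synthetic centroided SIM/MS2 run generation with known ground truth,
# emulating the signal structure of the targeted glycopeptide assay:
# a precursor isotopologue cluster eluting as a Gaussian peak in narrow-window
# MS1 scans, plus oxonium-bearing MS2 scans inside the elution window.

#' Configuration for a synthetic run
#'
#' Defaults emulate the targeted assay's acquisition: a 2-minute SIM
#' acquisition window centred on a 15-minute elution apex inside a 35-minute
#' gradient, one MS1 scan every 0.03 min with an MS2 scan after every third
#' MS1 scan, Gaussian elution of 0.2 min full width at half maximum, and a
#' chemical background at the target mass (positive baseline + Gaussian
#' fluctuation + sparse exponential spikes) chosen so that blank runs sit
#' well below the S/N detection threshold.
#'
#' The quantitative convention: the full-window XIC area of the monitored
#' isotopologue equals `concentration * response_factor` (before noise), so
#' `response_factor` has units of area per ng/mL.
#'
#' @param transition A [transition_entry()] (default [target_transition()]).
#' @param concentration Analyte concentration in ng/mL (>= 0).
#' @param response_factor XIC area per ng/mL (default 100).
#' @param rt_peak Elution apex in minutes (default 15).
#' @param peak_fwhm Chromatographic full width at half maximum in minutes
#'   (default 0.2).
#' @param acq_window Acquisition window in minutes (default apex +/- 1).
#' @param scan_interval MS1 scan spacing in minutes (default 0.03).
#' @param ms2_every One MS2 scan after every this many MS1 scans
#'   (default 3).
#' @param n_isotopologues Isotopologues simulated for the precursor cluster
#'   (default 5).
#' @param product_rel Relative MS2 product intensities (fraction of the
#'   precursor apex height), recycled over the transition's products.
#' @param baseline,noise_sd Background level and Gaussian fluctuation sd at
#'   the target mass (defaults 20 and 4 counts).
#' @param spike_rate Probability per MS1 scan of an extra noise spike
#'   (default 0.01).
#' @param spike_mean Mean of the exponential spike intensity (default 15).
#' @param mz_jitter_ppm Mass-accuracy jitter sd applied to every centroid
#'   (default 2 ppm).
#' @param carryover_signal Extra signal area injected independently of
#'   `concentration` (used for carryover blanks; default 0).
#' @param seed Integer seed; a fixed seed makes the run bitwise
#'   reproducible.
#' @return Object of class `synthetic_run_config`.
#' @export
synthetic_run_config <- function(transition = target_transition(),
                                 concentration = 100,
                                 response_factor = 100,
                                 rt_peak = 15, peak_fwhm = 0.2,
                                 acq_window = rt_peak + c(-1, 1),
                                 scan_interval = 0.03, ms2_every = 3L,
                                 n_isotopologues = 5L,
                                 product_rel = c(0.5, 0.2, 0.4, 0.3, 0.25),
                                 baseline = 20, noise_sd = 4,
                                 spike_rate = 0.01, spike_mean = 15,
                                 mz_jitter_ppm = 2,
                                 carryover_signal = 0,
                                 seed = 1L) {
  if (concentration < 0) stop("concentration must be non-negative")
  structure(as.list(environment()), class = "synthetic_run_config")
}

#' Simulate a centroided targeted run
#'
#' MS1 scans carry the precursor isotopologue cluster with Gaussian elution
#' scaled by `concentration * response_factor`, on top of a chemical
#' background at the target mass; MS2 scans inside the elution window carry
#' the transition's product ions plus random background peaks. The output
#' is deterministic under the config seed.
#'
#' @param config A [synthetic_run_config()].
#' @return An [ms_run()] with the config stored in `metadata$config`.
#' @export
simulate_run <- function(config) {
  stopifnot(inherits(config, "synthetic_run_config"))
  cf <- config
  if (cf$concentration < 0) stop("concentration must be non-negative")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(cf$seed)

  tr <- cf$transition
  sd_rt <- cf$peak_fwhm / (2 * sqrt(2 * log(2)))
  # neutral mass back from the monitored precursor
  neutral <- tr$precursor_mz * tr$charge -
    tr$charge * mass_constants[["proton"]] -
    tr$isotopologue * mass_constants[["c13_minus_c12"]]
  cluster <- isotope_cluster(neutral, tr$charge, cf$n_isotopologues)
  # scale cluster so the monitored isotopologue has relative intensity 1
  mon <- cluster$relative_intensity[cluster$isotopologue == tr$isotopologue]
  if (!length(mon) || mon == 0) mon <- max(cluster$relative_intensity)
  cluster$relative_intensity <- cluster$relative_intensity / mon

  signal_area <- cf$concentration * cf$response_factor + cf$carryover_signal
  apex_height <- signal_area / (sd_rt * sqrt(2 * pi))

  rts <- seq(cf$acq_window[1], cf$acq_window[2], by = cf$scan_interval)
  jitter <- function(mz) mz * (1 + stats::rnorm(length(mz)) *
                                 cf$mz_jitter_ppm * 1e-6)
  sim_window <- tr$precursor_mz + c(-5, 5)

  ms1 <- vector("list", length(rts))
  for (i in seq_along(rts)) {
    rt <- rts[i]
    h <- apex_height * exp(-(rt - cf$rt_peak)^2 / (2 * sd_rt^2))
    mz <- numeric(); inten <- numeric()
    if (h > 0) {
      mz <- c(mz, jitter(cluster$mz))
      inten <- c(inten, h * cluster$relative_intensity)
    }
    # chemical background centroid at the target mass, always present
    mz <- c(mz, jitter(tr$precursor_mz))
    inten <- c(inten, max(0, cf$baseline + stats::rnorm(1, 0, cf$noise_sd)))
    # diffuse background elsewhere in the SIM window
    n_bg <- stats::rpois(1, 5)
    if (n_bg > 0) {
      mz <- c(mz, stats::runif(n_bg, sim_window[1], sim_window[2]))
      inten <- c(inten, abs(stats::rnorm(n_bg, cf$baseline / 2, cf$noise_sd)))
    }
    if (stats::runif(1) < cf$spike_rate) {
      mz <- c(mz, jitter(tr$precursor_mz))
      inten <- c(inten, stats::rexp(1, 1 / cf$spike_mean))
    }
    keep <- inten > 0
    mz <- mz[keep]; inten <- inten[keep]
    o <- order(mz)
    ms1[[i]] <- list(rt = rt, mz = mz[o], intensity = inten[o])
  }

  ms2 <- list()
  prod_rel <- rep_len(cf$product_rel, nrow(tr$products))
  ms2_rts <- rts[seq_along(rts) %% cf$ms2_every == 0]
  for (rt in ms2_rts) {
    h <- apex_height * exp(-(rt - cf$rt_peak)^2 / (2 * sd_rt^2))
    mz <- numeric(); inten <- numeric()
    if (h > 0) {
      keep <- h * prod_rel >= 1  # centroids below 1 count are not recorded
      if (any(keep)) {
        mz <- c(mz, jitter(tr$products$mz[keep]))
        inten <- c(inten, h * prod_rel[keep])
      }
    }
    n_bg <- stats::rpois(1, 15)
    if (n_bg > 0) {
      mz <- c(mz, stats::runif(n_bg, 150, 1500))
      inten <- c(inten, abs(stats::rnorm(n_bg, cf$baseline / 2, cf$noise_sd)))
    }
    if (!length(mz)) next
    o <- order(mz)
    ms2[[length(ms2) + 1L]] <- list(
      rt = rt, precursor_mz = tr$precursor_mz, isolation_width = 2,
      mz = mz[o], intensity = pmax(inten[o], 0))
  }

  ms_run(ms1, ms2, metadata = list(config = cf))
}

# ---------------------------------------------------------------------------
# Full validation-study simulation
# ---------------------------------------------------------------------------

#' Design of a synthetic validation study
#'
#' The default design mirrors a full bioanalytical validation battery for
#' the assay: an 8-level calibration series (0, 25, 50, 100, 200, 400, 600,
#' 800 ng/mL) with 7 replicates per level; 5 high-concentration
#' (1000 ng/mL) injections alternated with 5 blanks for carryover; 3
#' precision levels (0.5, 50, 200 ng/mL) with 5 replicates; 5 spiked
#' (10 ng/mL) and 5 negative samples for selectivity; and 5 fortified-urine
#' / 5 fortified-neat pairs for the matrix effect.
#'
#' Injected truths: per-run proportional response noise (`cv_linearity`,
#' default 5%), a larger replicate CV for the precision arm
#' (`cv_precision`, default 8%), a carryover fraction of the preceding high
#' run's signal in each carryover blank (`carryover_fraction`, default 2%),
#' and a urine suppression factor for the matrix arm (`suppression`,
#' default 0.9).
#'
#' @param linearity_levels,linearity_reps Calibration concentrations and
#'   replicate count.
#' @param carryover_conc,carryover_pairs High concentration and number of
#'   high/blank pairs.
#' @param precision_levels,precision_reps Precision concentrations and
#'   replicates.
#' @param selectivity_conc,selectivity_pairs Spiked concentration and
#'   number of spiked/negative pairs.
#' @param matrix_conc,matrix_pairs Fortified concentration and number of
#'   urine/neat pairs.
#' @param cv_linearity,cv_precision,carryover_fraction,suppression Injected
#'   truths (see above).
#' @param response_factor Area per ng/mL (default 100).
#' @param seed Integer seed for the whole study.
#' @param run_args Extra arguments passed to every
#'   [synthetic_run_config()].
#' @return Object of class `validation_design`.
#' @export
validation_study_design <- function(
    linearity_levels = c(0, 25, 50, 100, 200, 400, 600, 800),
    linearity_reps = 7L,
    carryover_conc = 1000, carryover_pairs = 5L,
    precision_levels = c(0.5, 50, 200), precision_reps = 5L,
    selectivity_conc = 10, selectivity_pairs = 5L,
    matrix_conc = 10, matrix_pairs = 5L,
    cv_linearity = 0.05, cv_precision = 0.08,
    carryover_fraction = 0.02, suppression = 0.9,
    response_factor = 100, seed = 1L, run_args = list()) {
  structure(as.list(environment()), class = "validation_design")
}

#' Simulate a complete validation study
#'
#' Generates one synthetic run per injection of the design and a manifest
#' labelling each run with its role (`level`, `high`, `blank`, `spiked`,
#' `negative`, `urine`, `neat`) and nominal concentration, plus a truth
#' ledger of every injected parameter for recovery testing.
#'
#' @param design A [validation_study_design()].
#' @return List with `runs` (named list of [ms_run()]), `manifest`
#'   (`data.frame`: `run_id`, `arm`, `role`, `nominal_conc`), and `truth`
#'   (list of injected parameters).
#' @export
simulate_validation_study <- function(design = validation_study_design()) {
  stopifnot(inherits(design, "validation_design"))
  d <- design
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()), add = TRUE)
  set.seed(d$seed)

  runs <- list()
  manifest <- list()
  next_seed <- function() sample.int(.Machine$integer.max, 1)
  make_run <- function(id, arm, role, conc, response, carry_signal = 0) {
    cfg <- do.call(synthetic_run_config, c(
      list(concentration = conc, response_factor = response,
           carryover_signal = carry_signal, seed = next_seed()),
      d$run_args))
    runs[[id]] <<- simulate_run(cfg)
    manifest[[length(manifest) + 1L]] <<- data.frame(
      run_id = id, arm = arm, role = role, nominal_conc = conc,
      stringsAsFactors = FALSE)
  }
  noisy <- function(cv) d$response_factor * (1 + stats::rnorm(1, 0, cv))

  for (lev in d$linearity_levels)
    for (r in seq_len(d$linearity_reps))
      make_run(sprintf("lin_%g_%d", lev, r), "linearity", "level", lev,
               noisy(d$cv_linearity))

  for (k in seq_len(d$carryover_pairs)) {
    high_resp <- noisy(d$cv_linearity)
    make_run(sprintf("carry_high_%d", k), "carryover", "high",
             d$carryover_conc, high_resp)
    make_run(sprintf("carry_blank_%d", k), "carryover", "blank", 0,
             d$response_factor,
             carry_signal = d$carryover_fraction * d$carryover_conc *
               high_resp)
  }

  for (lev in d$precision_levels)
    for (r in seq_len(d$precision_reps))
      make_run(sprintf("prec_%g_%d", lev, r), "precision", "level", lev,
               noisy(d$cv_precision))

  for (k in seq_len(d$selectivity_pairs)) {
    make_run(sprintf("sel_spiked_%d", k), "selectivity", "spiked",
             d$selectivity_conc, noisy(d$cv_linearity))
    make_run(sprintf("sel_negative_%d", k), "selectivity", "negative", 0,
             d$response_factor)
  }

  for (k in seq_len(d$matrix_pairs)) {
    make_run(sprintf("mx_urine_%d", k), "matrix", "urine", d$matrix_conc,
             noisy(d$cv_linearity) * d$suppression)
    make_run(sprintf("mx_neat_%d", k), "matrix", "neat", d$matrix_conc,
             noisy(d$cv_linearity))
  }

  list(runs = runs,
       manifest = do.call(rbind, manifest),
       truth = list(response_factor = d$response_factor,
                    cv_linearity = d$cv_linearity,
                    cv_precision = d$cv_precision,
                    carryover_fraction = d$carryover_fraction,
                    suppression = d$suppression,
                    seed = d$seed))
}
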