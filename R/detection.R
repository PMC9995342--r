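# Targeted detection: XIC extraction, robust S/N estimation, MS2 product
# matching, and the detection call for a transition entry.

#' Extract an ion chromatogram
#'
#' Per-MS1-scan summed intensity of centroids within `+/- ppm_tol` of `mz`,
#' restricted to a retention-time window.
#'
#' @param run An [ms_run()].
#' @param mz Target m/z.
#' @param ppm_tol Tolerance in parts per million (default 10, matching the
#'   assay's precursor mass tolerance).
#' @param rt_window Numeric length-2 window in minutes (default all scans).
#' @return Object of class `chromatogram`: `data.frame` with strictly
#'   increasing `rt` and `intensity`.
#' @export
extract_xic <- function(run, mz, ppm_tol = 10, rt_window = c(-Inf, Inf)) {
  stopifnot(inherits(run, "ms_run"))
  if (!is.numeric(ppm_tol) || ppm_tol <= 0) stop("ppm_tol must be > 0")
  half <- mz * ppm_tol * 1e-6
  rows <- lapply(run$ms1, function(s) {
    if (s$rt < rt_window[1] || s$rt > rt_window[2]) return(NULL)
    sel <- abs(s$mz - mz) <= half
    data.frame(rt = s$rt, intensity = sum(s$intensity[sel]))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(rt = numeric(), intensity = numeric())
  class(out) <- c("chromatogram", "data.frame")
  out
}

#' Robust signal-to-noise of a chromatographic peak
#'
#' S/N is the apex intensity inside `peak_region` divided by a robust noise
#' level estimated from the points outside it: `median + 1.4826 * MAD`.
#' The robust estimator tolerates sparse spikes in the background. When the
#' background is entirely zero (or empty) the ratio is infinite and the
#' result carries the attribute `flag = "zero-background"`.
#'
#' @param chrom A `chromatogram` (or data.frame with `rt`, `intensity`).
#' @param peak_region Numeric length-2 retention-time interval containing
#'   the peak.
#' @return Single numeric S/N value (0 for an all-zero chromatogram,
#'   `Inf` with a flag for zero background noise).
#' @export
estimate_snr <- function(chrom, peak_region) {
  if (!nrow(chrom)) stop("chromatogram is empty")
  inside <- chrom$rt >= peak_region[1] & chrom$rt <= peak_region[2]
  apex <- if (any(inside)) max(chrom$intensity[inside]) else 0
  bg <- chrom$intensity[!inside]
  if (apex == 0) return(0)
  noise <- if (length(bg)) stats::median(bg) + stats::mad(bg) else 0
  if (noise <= 0)
    return(structure(Inf, flag = "zero-background"))
  unname(apex / noise)
}

#' Match expected product ions against an MS2 spectrum
#'
#' One-to-one nearest-centroid assignment, closest absolute m/z error
#' first; when two candidate pairs have equal error the lower expected m/z
#' wins. Tolerance is absolute m/z by default or ppm.
#'
#' @param spectrum List with `mz` and `intensity` (an MS2 scan of an
#'   [ms_run()]).
#' @param expected `data.frame` of fragment ions (columns `label`, `mz`).
#' @param tol Tolerance value (default 0.01 m/z, the printed precision of
#'   published transition tables).
#' @param tol_unit `"mz"` (absolute) or `"ppm"`.
#' @return `data.frame` with one row per expected ion: `label`,
#'   `expected_mz`, `matched_mz`, `intensity`, `error_mz`, `error_ppm`,
#'   `matched` (logical).
#' @export
match_products <- function(spectrum, expected, tol = 0.01,
                           tol_unit = c("mz", "ppm")) {
  tol_unit <- match.arg(tol_unit)
  ne <- nrow(expected)
  out <- data.frame(label = expected$label, expected_mz = expected$mz,
                    matched_mz = NA_real_, intensity = NA_real_,
                    error_mz = NA_real_, error_ppm = NA_real_,
                    matched = FALSE, stringsAsFactors = FALSE)
  if (!ne || !length(spectrum$mz)) return(out)
  tol_abs <- if (tol_unit == "ppm") expected$mz * tol * 1e-6 else rep(tol, ne)
  # all candidate pairs within tolerance
  pairs <- do.call(rbind, lapply(seq_len(ne), function(i) {
    err <- abs(spectrum$mz - expected$mz[i])
    j <- which(err <= tol_abs[i])
    if (!length(j)) return(NULL)
    data.frame(i = i, j = j, err = err[j])
  }))
  if (is.null(pairs)) return(out)
  pairs <- pairs[order(pairs$err, expected$mz[pairs$i]), , drop = FALSE]
  used_e <- logical(ne); used_c <- logical(length(spectrum$mz))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs$i[r]; j <- pairs$j[r]
    if (used_e[i] || used_c[j]) next
    used_e[i] <- TRUE; used_c[j] <- TRUE
    out$matched_mz[i] <- spectrum$mz[j]
    out$intensity[i] <- spectrum$intensity[j]
    out$error_mz[i] <- spectrum$mz[j] - expected$mz[i]
    out$error_ppm[i] <- out$error_mz[i] / expected$mz[i] * 1e6
    out$matched[i] <- TRUE
  }
  out
}

#' Detection policy
#'
#' Bundles the thresholds of the targeted detection call: the S/N
#' detection threshold (3) with its stricter reference value (5), the
#' minimum number of matched composition-derived product ions (4 of the 5
#' oxonium/di-/tri-saccharide ions; ions labelled `"extra"` in a transition
#' never count), and the mass tolerances.
#'
#' @param snr_threshold S/N required for detection (default 3).
#' @param snr_reference Stricter reference S/N reported alongside
#'   (default 5).
#' @param min_products Minimum matched non-extra product ions (default 4).
#' @param ppm_tol Precursor XIC tolerance in ppm (default 10).
#' @param product_tol Product-ion tolerance, absolute m/z (default 0.01).
#' @param peak_halfwidth_scans Half-width of the peak region around the
#'   XIC apex, in scan widths (default 3).
#' @return Object of class `detection_policy`.
#' @export
detection_policy <- function(snr_threshold = 3, snr_reference = 5,
                             min_products = 4L, ppm_tol = 10,
                             product_tol = 0.01, peak_halfwidth_scans = 3) {
  structure(list(snr_threshold = snr_threshold,
                 snr_reference = snr_reference,
                 min_products = as.integer(min_products),
                 ppm_tol = ppm_tol, product_tol = product_tol,
                 peak_halfwidth_scans = peak_halfwidth_scans),
            class = "detection_policy")
}

# trapezoidal integral of a chromatogram over [lo, hi] (minutes * counts)
.trapezoid_area <- function(chrom, lo = -Inf, hi = Inf) {
  sel <- chrom$rt >= lo & chrom$rt <= hi
  rt <- chrom$rt[sel]; y <- chrom$intensity[sel]
  if (length(rt) < 2L) return(0)
  sum(diff(rt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Measure the XIC peak area of a transition
#'
#' Baseline-corrected trapezoidal integral of the precursor XIC over the
#' transition's retention-time window: the median XIC intensity of the
#' window (the chemical background at the target mass) is subtracted
#' before integration, as in standard chromatographic peak integration.
#' Used by the validation battery as the quantitative response; blank
#' injections therefore integrate to approximately zero.
#'
#' @param run An [ms_run()].
#' @param transition A [transition_entry()].
#' @param policy A [detection_policy()].
#' @return Peak area (intensity x minutes); may be slightly negative for
#'   pure-noise windows.
#' @export
measure_peak_area <- function(run, transition,
                              policy = detection_policy()) {
  chrom <- extract_xic(run, transition$precursor_mz, policy$ppm_tol,
                       transition$rt_window)
  if (!nrow(chrom)) return(0)
  chrom$intensity <- chrom$intensity - stats::median(chrom$intensity)
  .trapezoid_area(chrom)
}

#' Targeted detection of one transition in a run
#'
#' Extracts the precursor XIC in the transition's retention-time window,
#' locates the apex, estimates S/N against the background outside
#' `apex +/- peak_halfwidth_scans` scan widths, and confirms identity by
#' matching the transition's product ions in MS2 scans whose isolation
#' window covers the precursor. The call is positive iff
#' `S/N > snr_threshold` *and* at least `min_products` non-extra product
#' ions are matched in some covering MS2 scan.
#'
#' @param run An [ms_run()].
#' @param transition A [transition_entry()].
#' @param policy A [detection_policy()].
#' @return Object of class `detection_result`: list with `detected`,
#'   `peak_rt`, `peak_area`, `snr`, `meets_reference`, `n_matched`,
#'   `matches` (best MS2 match table), `diagnostics` (character vector).
#' @export
detect_target <- function(run, transition, policy = detection_policy()) {
  stopifnot(inherits(run, "ms_run"), inherits(transition, "transition_entry"))
  diagnostics <- character()
  chrom <- extract_xic(run, transition$precursor_mz, policy$ppm_tol,
                       transition$rt_window)
  result <- function(detected, peak_rt = NA_real_, area = NA_real_,
                     snr = NA_real_, n_matched = 0L, matches = NULL) {
    structure(list(transition = transition, detected = detected,
                   peak_rt = peak_rt, peak_area = area, snr = snr,
                   meets_reference = isTRUE(snr > policy$snr_reference),
                   n_matched = n_matched, matches = matches,
                   diagnostics = diagnostics),
              class = "detection_result")
  }
  if (!nrow(chrom) || all(chrom$intensity == 0)) {
    diagnostics <- c(diagnostics, "empty or all-zero XIC")
    return(result(FALSE))
  }
  apex_i <- which.max(chrom$intensity)
  apex_rt <- chrom$rt[apex_i]
  scan_w <- if (nrow(chrom) > 1L) stats::median(diff(chrom$rt)) else 0.01
  region <- apex_rt + c(-1, 1) * policy$peak_halfwidth_scans * scan_w
  snr <- estimate_snr(chrom, region)
  if (!is.null(attr(snr, "flag")))
    diagnostics <- c(diagnostics, attr(snr, "flag"))
  area <- .trapezoid_area(chrom, region[1], region[2])

  # MS2 confirmation on non-extra products
  expected <- transition$products[transition$products$kind != "extra", ,
                                  drop = FALSE]
  covering <- Filter(function(s)
    abs(s$precursor_mz - transition$precursor_mz) <= s$isolation_width / 2 &&
      s$rt >= transition$rt_window[1] && s$rt <= transition$rt_window[2],
    run$ms2)
  best <- NULL; n_matched <- 0L
  if (!length(covering)) {
    diagnostics <- c(diagnostics, "no MS2 coverage")
  } else {
    for (s in covering) {
      m <- match_products(s, expected, tol = policy$product_tol)
      if (sum(m$matched) > n_matched || is.null(best)) {
        n_matched <- sum(m$matched)
        best <- m
      }
    }
  }
  detected <- isTRUE(as.numeric(snr) > policy$snr_threshold) &&
    n_matched >= policy$min_products
  result(detected, apex_rt, area, as.numeric(snr), n_matched, best)
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection> %s  detected=%s  S/N=%.2f  rt=%.2f  area=%.1f  products=%d\n",
    x$transition$glycopeptide$peptide$sequence,
    x$detected, x$snr, x$peak_rt, x$peak_area, x$n_matched))
  if (length(x$diagnostics))
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  invisible(x)
}
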