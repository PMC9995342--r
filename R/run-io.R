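# The in-memory run container and mzML input/output via the proteowizard
# backend of mzR.

#' Construct an in-memory MS run
#'
#' A run holds centroided MS1 (SIM) scans and MS2 scans with retention
#' times. Scans are sorted by retention time; every scan's m/z and
#' intensity arrays have equal length and non-negative intensities.
#'
#' @param ms1 List of MS1 scans, each `list(rt =, mz =, intensity =)` with
#'   `rt` in minutes.
#' @param ms2 List of MS2 scans, each
#'   `list(rt =, precursor_mz =, isolation_width =, mz =, intensity =)`.
#' @param metadata Arbitrary provenance list (source path or synthetic
#'   config).
#' @return Object of class `ms_run`.
#' @export
ms_run <- function(ms1 = list(), ms2 = list(), metadata = list()) {
  check_scan <- function(s, lvl) {
    stopifnot(is.numeric(s$rt), length(s$mz) == length(s$intensity))
    if (any(s$intensity < 0)) stop("negative intensity in ", lvl, " scan")
    if (lvl == "MS2" && (is.null(s$precursor_mz) || is.null(s$isolation_width)))
      stop("MS2 scan lacks precursor_mz / isolation_width")
    s
  }
  ms1 <- lapply(ms1, check_scan, "MS1")
  ms2 <- lapply(ms2, check_scan, "MS2")
  if (length(ms1) > 1L)
    ms1 <- ms1[order(vapply(ms1, `[[`, numeric(1), "rt"))]
  if (length(ms2) > 1L)
    ms2 <- ms2[order(vapply(ms2, `[[`, numeric(1), "rt"))]
  structure(list(ms1 = ms1, ms2 = ms2, metadata = metadata),
            class = "ms_run")
}

#' @export
print.ms_run <- function(x, ...) {
  rng <- range(c(vapply(x$ms1, `[[`, numeric(1), "rt"),
                 vapply(x$ms2, `[[`, numeric(1), "rt")), na.rm = TRUE)
  cat(sprintf("<ms_run> %d MS1 scans, %d MS2 scans, rt %.2f-%.2f min\n",
              length(x$ms1), length(x$ms2),
              if (is.finite(rng[1])) rng[1] else NA,
              if (is.finite(rng[2])) rng[2] else NA))
  invisible(x)
}

#' Read a centroided mzML file
#'
#' Loads a (centroided) mzML file into an [ms_run()]. Profile-mode spectra
#' are rejected with guidance, since the targeted detection logic assumes
#' centroided peak lists.
#'
#' @param path Path to an mzML file.
#' @return An [ms_run()]; empty files give an empty run with a warning.
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hdr <- mzR::header(fh)
  if (!nrow(hdr)) {
    warning("no spectra in ", path)
    return(ms_run(metadata = list(source = path)))
  }
  if (any(!is.na(hdr$centroided) & !hdr$centroided))
    stop("profile-mode spectra found in ", path,
         "; centroid the data (e.g. msconvert peakPicking) before reading")
  ms1 <- list(); ms2 <- list()
  for (i in seq_len(nrow(hdr))) {
    pk <- mzR::peaks(fh, i)
    scan <- list(rt = hdr$retentionTime[i] / 60,
                 mz = as.numeric(pk[, 1]), intensity = as.numeric(pk[, 2]))
    if (hdr$msLevel[i] == 1L) {
      ms1[[length(ms1) + 1L]] <- scan
    } else {
      scan$precursor_mz <- hdr$precursorMZ[i]
      iso <- hdr$isolationWindowLowerOffset[i] +
        hdr$isolationWindowUpperOffset[i]
      scan$isolation_width <- if (is.na(iso) || iso <= 0) 2 else iso
      ms2[[length(ms2) + 1L]] <- scan
    }
  }
  ms_run(ms1, ms2, metadata = list(source = path))
}

#' Write a run to mzML
#'
#' Writes centroided spectra through mzR's proteowizard backend; the
#' written file round-trips through [read_run()] within floating-point
#' tolerance.
#'
#' @param run An [ms_run()].
#' @param path Output mzML path.
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  stopifnot(inherits(run, "ms_run"))
  scans <- c(lapply(run$ms1, function(s) c(s, list(level = 1L))),
             lapply(run$ms2, function(s) c(s, list(level = 2L))))
  if (!length(scans)) stop("cannot write an empty run")
  scans <- scans[order(vapply(scans, `[[`, numeric(1), "rt"))]
  n <- length(scans)
  pks <- lapply(scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  na_r <- rep(NA_real_, n); na_i <- rep(NA_integer_, n)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = vapply(scans, `[[`, integer(1), "level"),
    polarity = rep(1L, n),
    peaksCount = vapply(pks, nrow, integer(1)),
    totIonCurrent = vapply(scans, function(s) sum(s$intensity), numeric(1)),
    retentionTime = vapply(scans, `[[`, numeric(1), "rt") * 60,
    basePeakMZ = vapply(scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, numeric(1)),
    collisionEnergy = na_r, ionisationEnergy = rep(0, n),
    lowMZ = vapply(scans, function(s)
      if (length(s$mz)) min(s$mz) else 0, numeric(1)),
    highMZ = vapply(scans, function(s)
      if (length(s$mz)) max(s$mz) else 0, numeric(1)),
    precursorScanNum = na_i,
    precursorMZ = vapply(scans, function(s)
      if (s$level == 2L) s$precursor_mz else NA_real_, numeric(1)),
    precursorCharge = na_i, precursorIntensity = na_r,
    mergedScan = na_i, mergedResultScanNum = na_i,
    mergedResultStartScanNum = na_i, mergedResultEndScanNum = na_i,
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = na_r,
    isolationWindowTargetMZ = vapply(scans, function(s)
      if (s$level == 2L) s$precursor_mz else NA_real_, numeric(1)),
    isolationWindowLowerOffset = vapply(scans, function(s)
      if (s$level == 2L) s$isolation_width / 2 else NA_real_, numeric(1)),
    isolationWindowUpperOffset = vapply(scans, function(s)
      if (s$level == 2L) s$isolation_width / 2 else NA_real_, numeric(1)),
    scanWindowLowerLimit = na_r, scanWindowUpperLimit = na_r,
    stringsAsFactors = FALSE)
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
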