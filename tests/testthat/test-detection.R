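# XIC extraction, S/N estimation, product matching and the detection call.

# a minimal run built by hand: single centroid per MS1 scan at the target
# m/z, plus one MS2 scan carrying chosen product peaks
handmade_run <- function(intensities, mz0, rt0 = 10, dt = 0.02,
                         ms2_mz = numeric(), ms2_int = NULL) {
  rts <- rt0 + (seq_along(intensities) - 1) * dt
  ms1 <- Map(function(rt, y) list(rt = rt, mz = mz0, intensity = y),
             rts, intensities)
  ms2 <- list()
  if (length(ms2_mz))
    ms2 <- list(list(rt = mean(rts), precursor_mz = mz0,
                     isolation_width = 2, mz = sort(ms2_mz),
                     intensity = if (is.null(ms2_int))
                       rep(100, length(ms2_mz)) else
                       ms2_int[order(ms2_mz)]))
  ms_run(ms1, ms2)
}

test_that("XIC extraction agrees with a brute-force per-scan filter", {
  cfg <- synthetic_run_config(concentration = 50, seed = 3)
  run <- simulate_run(cfg)
  mz0 <- cfg$transition$precursor_mz
  for (ppm in c(5, 10, 50)) {
    chrom <- extract_xic(run, mz0, ppm_tol = ppm)
    half <- mz0 * ppm * 1e-6
    want <- vapply(run$ms1, function(s)
      sum(s$intensity[abs(s$mz - mz0) <= half]), numeric(1))
    expect_identical(chrom$intensity, unname(want))
    expect_identical(chrom$rt, vapply(run$ms1, `[[`, numeric(1), "rt"))
  }
  expect_error(extract_xic(run, mz0, ppm_tol = 0), "ppm_tol")
})

test_that("XIC respects the rt window, tolerance and linearity", {
  cfg <- synthetic_run_config(concentration = 100, seed = 5)
  run <- simulate_run(cfg)
  mz0 <- cfg$transition$precursor_mz
  chrom <- extract_xic(run, mz0, 10, rt_window = c(14.5, 15.5))
  expect_true(all(chrom$rt >= 14.5 & chrom$rt <= 15.5))
  # apex at the injected elution time
  expect_equal(chrom$rt[which.max(chrom$intensity)], cfg$rt_peak,
               tolerance = 0.05)
  # 50 ppm off at 10 ppm tolerance: no signal
  off <- extract_xic(run, mz0 * (1 + 50e-6), 10)
  expect_true(all(off$intensity[abs(off$rt - cfg$rt_peak) < 0.2] <
                    max(chrom$intensity) / 100))
  # doubling all intensities doubles the XIC everywhere
  run2 <- run
  run2$ms1 <- lapply(run$ms1, function(s) {
    s$intensity <- 2 * s$intensity; s
  })
  expect_equal(extract_xic(run2, mz0, 10)$intensity,
               2 * extract_xic(run, mz0, 10)$intensity)
  # empty window gives an empty chromatogram
  expect_identical(nrow(extract_xic(run, mz0, 10, c(99, 100))), 0L)
})

test_that("S/N estimation is robust, scale-invariant and flags edge cases", {
  # flat zero chromatogram
  flat <- handmade_run(rep(0, 50), 500)
  expect_equal(estimate_snr(extract_xic(flat, 500, 10), c(10.4, 10.6)), 0)
  # known background: median + 1.4826 * MAD
  set.seed(42)
  bg <- abs(rnorm(200, 20, 4))
  y <- c(bg[1:100], 300, bg[101:200])
  chrom <- data.frame(rt = seq_along(y) * 0.01, intensity = y)
  region <- c(100.5, 101.5) * 0.01
  got <- estimate_snr(chrom, region)
  want <- 300 / (median(bg) + mad(bg))
  expect_equal(got, want, tolerance = 1e-9)
  # scale invariance
  chrom2 <- chrom; chrom2$intensity <- 7 * chrom2$intensity
  expect_equal(estimate_snr(chrom2, region), got, tolerance = 1e-9)
  # all-zero background is flagged infinite
  spike <- handmade_run(c(rep(0, 20), 100, rep(0, 20)), 500)
  s <- estimate_snr(extract_xic(spike, 500, 10), c(10.39, 10.41))
  expect_identical(as.numeric(s), Inf)
  expect_identical(attr(s, "flag"), "zero-background")
  expect_error(estimate_snr(data.frame(rt = numeric(),
                                       intensity = numeric()), c(0, 1)),
               "empty")
})

test_that("S/N estimator recovers the injected ratio over 100 simulations", {
  # apex height 300 over a background of median 20 and robust spread 4:
  # truth = (300 + 20) / (20 + 4)
  cfg0 <- synthetic_run_config(seed = 1)
  sd_rt <- cfg0$peak_fwhm / (2 * sqrt(2 * log(2)))
  conc <- 300 * sd_rt * sqrt(2 * pi) / cfg0$response_factor
  truth <- (300 + cfg0$baseline) / (cfg0$baseline + cfg0$noise_sd)
  region <- cfg0$rt_peak + c(-3.5, 3.5) * sd_rt
  ratios <- vapply(1:100, function(s) {
    cfg <- synthetic_run_config(concentration = conc, seed = s)
    run <- simulate_run(cfg)
    chrom <- extract_xic(run, cfg$transition$precursor_mz, 10)
    as.numeric(estimate_snr(chrom, region)) / truth
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.25)
  expect_gt(mean(abs(ratios - 1) < 0.25), 0.9)
})

test_that("product matching is one-to-one, closest-first", {
  expected <- oxonium_ions("_6_7_1_4")
  expected <- expected[expected$label %in%
                         c("HexNAc", "NeuAc", "NeuAc-H2O", "HexNAc+Hex",
                           "HexNAc+Hex+NeuAc"), ]
  # all five present
  sp <- list(mz = sort(expected$mz + 0.002),
             intensity = rep(50, 5))
  m <- match_products(sp, expected, tol = 0.01)
  expect_identical(sum(m$matched), 5L)
  expect_true(all(abs(m$error_mz - 0.002) < 1e-9))
  # empty spectrum
  m0 <- match_products(list(mz = numeric(), intensity = numeric()),
                       expected)
  expect_identical(sum(m0$matched), 0L)
  # two expected ions near one centroid: single assignment to the closer
  exp2 <- data.frame(kind = "oxonium", label = c("a", "b"),
                     mz = c(100.000, 100.006), charge = 1L, index = NA)
  sp2 <- list(mz = 100.004, intensity = 10)
  m2 <- match_products(sp2, exp2, tol = 0.01)
  expect_identical(m2$matched, c(FALSE, TRUE))
  # exact tie (errors exactly representable) broken by lower expected m/z
  exp3 <- data.frame(kind = "oxonium", label = c("lo", "hi"),
                     mz = c(99.5, 100.5), charge = 1L, index = NA)
  sp3 <- list(mz = 100, intensity = 10)
  m3 <- match_products(sp3, exp3, tol = 1)
  expect_identical(m3$matched, c(TRUE, FALSE))
  # ppm tolerance mode
  m4 <- match_products(sp, expected, tol = 5, tol_unit = "ppm")
  expect_identical(sum(m4$matched), 1L)  # 0.002 is within 5 ppm only >400 m/z
})

test_that("detection calls combine S/N and MS2 confirmation", {
  tr <- target_transition()
  # high-abundance synthetic positive
  pos <- simulate_run(synthetic_run_config(concentration = 100, seed = 9))
  d <- detect_target(pos, tr)
  expect_true(d$detected)
  expect_gte(d$n_matched, 4L)
  expect_true(d$meets_reference)
  expect_equal(d$peak_rt, 15, tolerance = 0.05)
  # synthetic blank
  blank <- simulate_run(synthetic_run_config(concentration = 0, seed = 9))
  db <- detect_target(blank, tr)
  expect_false(db$detected)
  # positive with MS2 removed: policy consequence, diagnostic set
  noms2 <- pos; noms2$ms2 <- list()
  dn <- detect_target(noms2, tr)
  expect_false(dn$detected)
  expect_true("no MS2 coverage" %in% dn$diagnostics)
})

test_that("detection is monotone in concentration under shared noise", {
  tr <- target_transition()
  concs <- c(0, 0.02, 0.1, 0.5, 2, 20)
  det <- vapply(concs, function(cc) {
    run <- simulate_run(synthetic_run_config(concentration = cc, seed = 77))
    detect_target(run, tr)$detected
  }, logical(1))
  # once detected, detected at every higher concentration
  expect_true(all(diff(as.integer(det)) >= 0))
  expect_false(det[1])
  expect_true(det[length(det)])
})
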