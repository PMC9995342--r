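# Validation battery computations and their pass/fail thresholds.

test_that("linearity fit recovers a noiseless line exactly", {
  conc <- rep(c(0, 25, 50, 100, 200, 400, 600, 800), each = 7)
  area <- 100 * conc
  fit <- fit_linearity(conc, area)
  expect_equal(fit$slope, 100)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  # constant areas: zero slope, r2 0
  flat <- fit_linearity(conc, rep(5, length(conc)))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0)
  expect_error(fit_linearity(rep(1, 5), 1:5), "2 distinct")
})

test_that("linearity with 5% proportional noise recovers the slope", {
  set.seed(6)
  conc <- rep(c(0, 25, 50, 100, 200, 400, 600, 800), each = 7)
  area <- 100 * conc * (1 + rnorm(length(conc), 0, 0.05))
  fit <- fit_linearity(conc, area)
  expect_lt(abs(fit$slope - 100) / 100, 0.02)
  expect_gt(fit$r2, 0.99)
  # weighted variants run and stay near the truth
  for (w in c("1/x", "1/x2"))
    expect_lt(abs(fit_linearity(conc, area, w)$slope - 100) / 100, 0.05)
})

test_that("back-calculation inverts the calibration line", {
  fit <- list(slope = 100, intercept = 40)
  expect_equal(back_calculate(100 * 7 + 40, fit), 7)
  expect_error(back_calculate(1, list(slope = 0, intercept = 0)), "slope")
})

test_that("carryover ratio thresholds behave exactly as specified", {
  # blanks all zero
  expect_equal(carryover_ratio(c(100, 110), c(0, 0))$ratio_pct, 0)
  expect_true(carryover_ratio(c(100, 110), c(0, 0))$pass)
  # 4% passes, 6% fails (pass iff strictly < 5%)
  expect_true(carryover_ratio(100, 4)$pass)
  expect_false(carryover_ratio(100, 6)$pass)
  expect_false(carryover_ratio(100, 5)$pass)   # boundary is a fail
  expect_true(carryover_ratio(100, 4.999)$pass)
  z <- carryover_ratio(c(0, 0), c(0, 0))
  expect_true(is.na(z$ratio_pct))
  expect_identical(z$flag, "zero high-concentration area")
})

test_that("intraday %CV is computed per level and is scale-invariant", {
  # identical replicates
  expect_equal(intraday_precision(rep(1, 3), c(5, 5, 5))$cv_pct, 0)
  # hand-computed: sd(9,10,11)/mean = 1/10
  p <- intraday_precision(rep(50, 3), c(9, 10, 11))
  expect_equal(p$cv_pct, 10.0)
  expect_true(p$pass)
  # scale invariance
  set.seed(3)
  x <- rnorm(10, 100, 12)
  cv1 <- intraday_precision(rep(1, 10), x)$cv_pct
  cv2 <- intraday_precision(rep(1, 10), 13 * x)$cv_pct
  expect_equal(cv1, cv2)
  # threshold straddling: pass iff strictly < 15%
  make <- function(cv) c(100 - cv, 100 + cv) # sd = cv*sqrt(2), mean = 100
  cv_of <- function(v) intraday_precision(rep(1, 2), v)$cv_pct
  lo <- make(14.5 / sqrt(2)); hi <- make(15.5 / sqrt(2))
  expect_lt(cv_of(lo), 15); expect_true(intraday_precision(rep(1, 2), lo)$pass)
  expect_gt(cv_of(hi), 15); expect_false(intraday_precision(rep(1, 2), hi)$pass)
  # zero mean flagged
  expect_true(is.na(intraday_precision(rep(1, 2), c(-1, 1))$cv_pct))
  expect_error(intraday_precision(1, 5), "2 replicates")
})

test_that("matrix effect is the urine:neat mean ratio in percent", {
  expect_equal(matrix_effect(c(10, 10), c(10, 10))$ratio_pct, 100)
  expect_equal(matrix_effect(8, 10)$ratio_pct, 80)
  expect_identical(matrix_effect(1, 0)$flag, "zero neat-solution area")
})

test_that("LOD picks the lowest level passing the replicate criterion", {
  conc <- rep(c(1, 2, 4, 8), each = 3)
  # S/N crosses 3 between levels 2 and 4: level-2 replicates straddle 3
  snr <- c(1, 1.2, 0.9,  2.5, 3.4, 2.8,  5.5, 6, 5.8,  11, 12, 10)
  r <- estimate_lod(conc, snr)
  expect_equal(r$lod, 4)           # "all replicates" mode skips level 2
  expect_equal(r$lod_reference, 4) # min S/N 5.5 > 5 at level 4
  expect_false(r$above_max)
  # mean mode admits level 2 (mean 2.9 < 3? no: mean = 2.9 -> still level 4)
  expect_equal(estimate_lod(conc, snr, mode = "mean")$lod, 4)
  # all levels pass
  expect_equal(estimate_lod(conc, snr + 10)$lod, 1)
  # none pass: above the maximum tested
  none <- estimate_lod(conc, snr * 0)
  expect_identical(none$lod, Inf)
  expect_true(none$above_max)
  # boundary: S/N exactly 3 is not a detection
  expect_equal(estimate_lod(rep(c(1, 2), each = 2), c(3, 3, 4, 4))$lod, 2)
  expect_error(estimate_lod(rep(1, 3), 1:3), "2 concentrations")
})

test_that("selectivity requires all spiked detected and no negatives", {
  expect_true(selectivity(rep(TRUE, 5), rep(FALSE, 5))$pass)
  s <- selectivity(c(TRUE, FALSE, TRUE), rep(FALSE, 3),
                   spiked_ids = c("s1", "s2", "s3"))
  expect_false(s$pass)
  expect_identical(s$missed_spiked, "s2")
  s2 <- selectivity(rep(TRUE, 3), c(FALSE, TRUE, FALSE),
                    negative_ids = c("n1", "n2", "n3"))
  expect_false(s2$pass)
  expect_identical(s2$false_positive_negatives, "n2")
  expect_error(selectivity(logical(), logical()), "required")
})

test_that("validate_study assembles a coherent report from a study table", {
  set.seed(21)
  conc <- rep(c(0, 25, 50, 100, 200, 400, 600, 800), each = 7)
  study <- rbind(
    data.frame(run_id = paste0("lin", seq_along(conc)), arm = "linearity",
               role = "level", nominal_conc = conc,
               area = 100 * conc * (1 + rnorm(length(conc), 0, 0.05)) + 40),
    data.frame(run_id = paste0("c", 1:10), arm = "carryover",
               role = rep(c("high", "blank"), 5), nominal_conc = c(1000, 0),
               area = rep(c(100040, 2040), 5)),
    data.frame(run_id = paste0("p", 1:6), arm = "precision", role = "level",
               nominal_conc = rep(c(50, 200), each = 3),
               area = c(100 * 50 * c(0.95, 1, 1.05),
                        100 * 200 * c(0.92, 1, 1.08)) + 40),
    data.frame(run_id = paste0("m", 1:4), arm = "matrix",
               role = rep(c("urine", "neat"), 2), nominal_conc = 10,
               area = rep(c(900, 1000), 2)))
  study$detected <- NA
  rep_out <- validate_study(study)
  expect_s3_class(rep_out, "validation_report")
  expect_lt(abs(rep_out$linearity$slope - 100) / 100, 0.02)
  expect_gt(rep_out$linearity$r2, 0.99)
  expect_equal(rep_out$carryover$ratio_pct, 2040 / 100040 * 100)
  expect_true(rep_out$carryover$pass)
  expect_true(all(rep_out$precision$pass))
  expect_equal(rep_out$matrix_effect$ratio_pct, 90, tolerance = 0.001)
  # pass flags recomputable from reported numbers and thresholds
  expect_identical(rep_out$carryover$pass,
                   rep_out$carryover$ratio_pct <
                     rep_out$thresholds[["carryover_pct"]])
  expect_identical(rep_out$precision$pass,
                   rep_out$precision$cv_pct <
                     rep_out$thresholds[["cv_pct"]])
  # JSON serialisation round-trips the headline numbers
  tf <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep_out, tf)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$linearity$slope, rep_out$linearity$slope)
  expect_equal(back$carryover$ratio_pct, rep_out$carryover$ratio_pct)
})
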