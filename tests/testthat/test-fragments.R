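# Oxonium ions, backbone series, Y-ladders, isotopologue clusters and
# transition lists.

test_that("oxonium ions reproduce the diagnostic sialoglycopeptide masses", {
  ox <- oxonium_ions(glycan_composition(NeuAc = 1))
  expect_equal(ox$mz[ox$label == "NeuAc"], 292.1027, tolerance = 1e-3)
  expect_equal(ox$mz[ox$label == "NeuAc-H2O"], 274.0921, tolerance = 1e-3)
  ox <- oxonium_ions(glycan_composition(HexNAc = 1, Hex = 1))
  expect_equal(ox$mz[ox$label == "HexNAc+Hex"], 366.1395, tolerance = 1e-3)
  # the full target composition carries all five diagnostics
  ox <- oxonium_ions("_6_7_1_4")
  expect_true(all(c("HexNAc", "Hex", "Fuc", "NeuAc", "NeuAc-H2O",
                    "HexNAc+Hex", "HexNAc+Hex+NeuAc") %in% ox$label))
  # each m/z recomputable from composition within 1e-4
  expect_equal(ox$mz[ox$label == "HexNAc"],
               formula_mass("C8H13NO5") + 1.007276, tolerance = 1e-4)
  expect_equal(ox$mz[ox$label == "HexNAc+Hex+NeuAc"],
               formula_mass("C8H13NO5") + formula_mass("C6H10O5") +
                 formula_mass("C11H17NO8") + 1.007276, tolerance = 1e-4)
  expect_identical(nrow(oxonium_ions(glycan_composition())), 0L)
})

test_that("backbone b/y ladders are complete and complementary", {
  # y1 of a C-terminal K peptide: K + water + proton
  y <- backbone_ions("HCSLNENITVPDTK", "y")
  expect_equal(y$mz[y$index == 1], 147.1128, tolerance = 1e-4)
  # y6 (TVPDTK) from residue-table arithmetic
  expect_equal(y$mz[y$index == 6], 660.3563, tolerance = 1e-4)
  # b_i + y_(n-i) = M + 2 protons at z = 1, for every peptide
  set.seed(23)
  for (i in 1:10) {
    s <- random_protein(sample(3:20, 1))
    b <- backbone_ions(s, "b"); yy <- backbone_ions(s, "y")
    n <- nchar(s)
    m <- peptide_mass(s)
    for (k in seq_len(n - 1))
      expect_equal(b$mz[b$index == k] + yy$mz[yy$index == n - k],
                   m + 2 * 1.007276, tolerance = 1e-9)
  }
  expect_error(backbone_ions("PEPTIDE", "c"), "arg")
  expect_error(backbone_ions("PEPTIDE", "y", charge = 0), "charge")
})

test_that("Y-ladder runs from bare peptide to the full glycan", {
  gp <- target_gp()
  lad <- y_ladder(gp)
  # one step per residue
  expect_identical(nrow(lad), sum(gp$glycan) + 1L)
  # head: [peptide + H]+; first step adds a HexNAc (core-first order)
  expect_equal(lad$mz[1], 1627.7745, tolerance = 1e-3)
  expect_equal(lad$mz[2] - lad$mz[1], 203.0794, tolerance = 1e-3)
  # tail equals the full glycopeptide [M+H]+
  expect_equal(lad$mz[nrow(lad)], glycopeptide_mz(gp, 1), tolerance = 1e-9)
  # monotone increasing
  expect_true(all(diff(lad$mz) > 0))
})

test_that("isotope clusters have exact spacing and a mass-dependent mode", {
  cl <- isotope_cluster(5290.0527, charge = 4, n_peaks = 5)
  expect_equal(cl$mz[1], 1323.5205, tolerance = 1e-3)
  expect_equal(unique(round(diff(cl$mz), 6)), round(1.003355 / 4, 6))
  expect_true(all(cl$relative_intensity >= 0))
  expect_equal(max(cl$relative_intensity), 1)
  # envelope maximum moves up with mass: glycine at index 0, 5 kDa at >= 2
  small <- isotope_cluster(75.032, charge = 1, n_peaks = 5)
  expect_identical(which.max(small$relative_intensity), 1L)   # index 0
  expect_gte(which.max(cl$relative_intensity) - 1L, 2L)
  # binomial-model oracle: intensities proportional to dbinom over carbons
  n_c <- round(5290.0527 / 111.1254 * 4.9384)
  want <- dbinom(0:4, n_c, 0.0107); want <- want / max(want)
  expect_equal(cl$relative_intensity, want, tolerance = 1e-12)
  expect_equal(isotope_cluster(1000, 1, 2)$mz[2] -
                 isotope_cluster(1000, 1, 2)$mz[1], 1.003355)
})

test_that("the default target transition reproduces the printed assay row", {
  tr <- target_transition()
  expect_equal(tr$precursor_mz, 1324.02, tolerance = 0.01)
  expect_identical(tr$charge, 4L)
  expect_identical(tr$isotopologue, 2L)
  got <- sort(round(tr$products$mz, 2))
  expect_true(all(c(204.09, 274.09, 292.10, 366.14, 657.23) %in% got))
  # optional extra monitored mass is carried verbatim and labelled extra
  tr2 <- target_transition(extra_product_mz = 658.23)
  expect_true(any(tr2$products$kind == "extra" &
                    abs(tr2$products$mz - 658.23) < 1e-9))
})

test_that("transition lists build per candidate x charge and deduplicate", {
  gp <- target_gp()
  trs <- build_transition_list(list(gp), charges = c(3L, 4L))
  expect_length(trs, 2L)
  expect_warning(build_transition_list(list(gp, gp), charges = 4L),
                 "duplicate")
  expect_error(build_transition_list(list()), "non-empty")
  # precursor m/z consistent with glycopeptide_mz for every entry
  for (tr in trs)
    expect_equal(tr$precursor_mz,
                 glycopeptide_mz(gp, tr$charge, tr$isotopologue))
})

test_that("transition CSV round-trips exactly", {
  trs <- list(target_transition(rt_window = c(14, 16),
                                extra_product_mz = 658.23),
              transition_entry(target_gp(), charge = 3L, isotopologue = 1L,
                               rt_window = c(10.5, 12.25)))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(trs, tf)
  back <- read_transition_csv(tf)
  expect_length(back, 2L)
  for (k in seq_along(trs)) {
    expect_identical(back[[k]]$precursor_mz, trs[[k]]$precursor_mz)
    expect_identical(back[[k]]$products$mz, trs[[k]]$products$mz)
    expect_identical(back[[k]]$products$label, trs[[k]]$products$label)
    expect_identical(back[[k]]$rt_window, trs[[k]]$rt_window)
    expect_identical(back[[k]]$charge, trs[[k]]$charge)
    expect_identical(back[[k]]$glycopeptide$peptide$sequence,
                     trs[[k]]$glycopeptide$peptide$sequence)
    expect_identical(unclass(back[[k]]$glycopeptide$glycan),
                     unclass(trs[[k]]$glycopeptide$glycan))
  }
})
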