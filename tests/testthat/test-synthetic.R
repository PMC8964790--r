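test_that("band signal generator hits its target correlations", {
  # a band-limited series of T seconds carries roughly 2 * bandwidth * T
  # effective samples, so per-seed sampling error scales with
  # 1/sqrt(2 * BW * T): tight in the wide band V, broad in band II.
  bII <- default_bands()$II
  bV <- default_bands()$V
  # identity target: off-diagonal sample correlations stay near zero
  s0 <- generate_band_signals(diag(4), bV, 16000, 16, seed = 1)
  r0 <- stats::cor(s0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.1)

  # r = 0.8 target: per-seed recovery within +-0.05 in band V, and an
  # unbiased mean across seeds in the much narrower band II
  R <- matrix(c(1, 0.8, 0.8, 1), 2, 2)
  errsV <- sapply(1:20, function(s)
    stats::cor(generate_band_signals(R, bV, 16000, 16, seed = s))[1, 2] - 0.8)
  expect_lt(max(abs(errsV)), 0.05)
  errsII <- sapply(1:20, function(s)
    stats::cor(generate_band_signals(R, bII, 16000, 16, seed = s))[1, 2] - 0.8)
  expect_lt(abs(mean(errsII)), 0.05)

  # determinism and PSD validation
  expect_identical(generate_band_signals(R, bII, 2048, 16, seed = 9),
                   generate_band_signals(R, bII, 2048, 16, seed = 9))
  bad <- matrix(c(1, 2, 2, 1), 2, 2)
  expect_error(generate_band_signals(bad, bII, 1024, 16, seed = 1),
               "positive semidefinite")
})

test_that("sessions obey the construction identities", {
  d <- tiny_design(duration = 60)
  s <- generate_session(d, "p1", "PVT", "L2")
  expect_identical(s$recordings$HbT$samples,
                   s$recordings$HbO$samples + s$recordings$HbR$samples)
  expect_equal(s$fatigue_level, "L2")
  expect_length(s$mfi_items, 20)
  expect_error(generate_session(d, "p1", "PVT", "L9"), "unknown fatigue level")

  # degenerate case: no channel noise, no HbO/HbR coupling -> every channel
  # inside an ROI is an exact copy of its ROI latent
  cs <- default_coupling_spec()
  cs$noise_sd <- 0
  cs$kappa <- 0
  d0 <- tiny_design(duration = 60, coupling = cs)
  s0 <- generate_session(d0, "p1", "PVT", "L1")
  hbo <- s0$recordings$HbO$samples
  expect_equal(hbo[, "1"], hbo[, "4"], tolerance = 1e-12)   # both L-PFC
  expect_equal(hbo[, "13"], hbo[, "14"], tolerance = 1e-12) # both R-FEF
  expect_false(isTRUE(all.equal(hbo[, "1"], hbo[, "13"])))
})

test_that("MFI item scores separate L1 from the L2 center", {
  d <- tiny_design()
  below <- sapply(1:100, function(i) {
    s <- generate_session(d, paste0("p", i), "PVT", "L1", species = NULL)
    mean(s$mfi_items) < d$mfi$center[["L2"]]
  })
  expect_gte(mean(below), 0.95)
})

test_that("study generation is deterministic and extension-stable", {
  d <- tiny_design(n_per_cell = 2)
  sess <- generate_study(d, species = NULL)
  expect_length(sess, 18)   # 2 x 3 tasks x 3 levels

  # same master seed: byte-identical written output
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  d1 <- tiny_design(n_per_cell = 1, duration = 40)
  generate_study(d1, out_dir = dir1)
  generate_study(d1, out_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)), label = f)
  }

  # doubling the cell count leaves the original sessions untouched
  big <- generate_study(tiny_design(n_per_cell = 4), species = NULL)
  small <- generate_study(tiny_design(n_per_cell = 2), species = NULL)
  for (id in names(small)) {
    expect_identical(small[[id]]$mfi_items, big[[id]]$mfi_items, label = id)
    expect_identical(small[[id]]$nback, big[[id]]$nback, label = id)
  }
  # and a species-subset run reproduces the full run's HbO signals
  full <- generate_session(d1, "PVT-L1-01", "PVT", "L1")
  sub <- generate_session(d1, "PVT-L1-01", "PVT", "L1", species = "HbO")
  expect_identical(sub$recordings$HbO$samples, full$recordings$HbO$samples)
})

test_that("level modifiers propagate to downstream band-III clustering", {
  # raising the band-III coupling multiplier raises the band-III clustering
  # coefficient computed through the analysis path (rank correlation > 0)
  grid <- c(0.6, 0.8, 1.0, 1.2, 1.4)
  mean_C <- sapply(grid, function(m) {
    effects <- default_level_effects()
    effects$L1$band_mult <- c(III = m)
    d <- study_design(n_per_cell = 1, duration = 120, seed = 303,
                      level_effects = effects)
    mean(sapply(1:10, function(i) {
      s <- generate_session(d, paste0("g", m, "-", i), "PVT", "L1",
                            species = "HbO")
      ser <- roi_aggregate(s$recordings$HbO, bands = default_bands()["III"])
      clustering_coefficient(fc_matrix(ser$III)$w)
    }))
  })
  expect_gt(stats::cor(grid, mean_C, method = "spearman"), 0)
})

test_that("coupling specs validate their invariants", {
  expect_error(coupling_spec(list(I = matrix(c(1, 0.5, 0.4, 1), 2, 2)),
                             c(I = 1)), "symmetric")
  R <- diag(2); R[1, 2] <- R[2, 1] <- 0.5
  expect_error(coupling_spec(list(I = R), c(II = 1)), "amplitudes missing")
  expect_error(coupling_spec(list(I = R), c(I = 1), kappa = 2), "kappa")
  d <- R; diag(d) <- 2
  expect_error(coupling_spec(list(I = d), c(I = 1)), "unit diagonal")
  expect_error(study_design(duration = 10, fs = 16), "512")
})
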