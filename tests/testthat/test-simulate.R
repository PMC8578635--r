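test_that("every generator is deterministic under a fixed seed", {
  expect_identical(simulate_screen(seed = 9), simulate_screen(seed = 9))
  expect_identical(simulate_combination_plate(seed = 9),
                   simulate_combination_plate(seed = 9))
  expect_identical(simulate_expression_chain(seed = 9),
                   simulate_expression_chain(seed = 9))
  expect_identical(simulate_decatenation(seed = 9),
                   simulate_decatenation(seed = 9))
  expect_identical(simulate_pk(seed = 9), simulate_pk(seed = 9))
  # and different seeds change the data
  expect_false(identical(simulate_screen(seed = 9)$screen,
                         simulate_screen(seed = 10)$screen))
})

test_that("zero-noise limits reproduce the model means exactly", {
  # screen: log10 IC50 is exactly base + shift + genotype effects
  sim <- simulate_screen(n_lines = 20, n_drugs = 3, target_fraction = 0.5,
                         selective_shift = c(drug002 = -1), noise_sd = 0,
                         seed = 2)
  ann <- sim$annotations
  lg <- log10(sim$screen$ic50)
  expect_equal(
    lg,
    sim$truth$base[sim$screen$drug] +
      sim$truth$shifts[sim$screen$drug] *
        (ann$lineage[match(sim$screen$cell_line, ann$cell_line)] ==
           "neuroblastoma") +
      sim$truth$tp53_effect *
        ann$tp53_mutant[match(sim$screen$cell_line, ann$cell_line)] +
      sim$truth$mycn_effect *
        ann$mycn_amplified[match(sim$screen$cell_line, ann$cell_line)],
    tolerance = 1e-12, ignore_attr = TRUE)

  # plate: normalization inverts the raw-signal map exactly
  simp <- simulate_combination_plate(noise_sd = 0, control_sd = 0, seed = 2)
  dm <- normalize_plate(simp$plate)
  for (r in 1:dim(dm$death)[3]) {
    expect_equal(dm$death[, , r], simp$truth$death, tolerance = 1e-9)
  }
  expect_equal(rowMeans(dm$mono1), simp$truth$y1, tolerance = 1e-9)

  # decatenation: truth curves recovered
  simd <- simulate_decatenation(ic25_A = 30, ic25_B = 10, noise_sd = 0,
                                seed = 2)
  pref <- preference_ratio(simd$decat)
  expect_equal(pref$fold_preference, 3, tolerance = 1e-4)

  # pk: cv = 0 gives the exponential exactly
  simk <- simulate_pk(cv = 0, seed = 2)
  p <- simk$profiles[simk$profiles$subject == "M01", ]
  expect_equal(p$conc_ugL,
               simk$truth$c0_ugL * exp(-simk$truth$k * p$time_h),
               tolerance = 1e-12)
})

test_that("noiseless planted selective drug has the minimum score", {
  sim <- simulate_screen(n_lines = 30, n_drugs = 6, target_fraction = 0.3,
                         selective_shift = c(drug004 = -1), noise_sd = 0,
                         tp53_effect = 0, mycn_effect = 0, seed = 3)
  rk <- rank_drugs(sim$screen, sim$annotations, "neuroblastoma")
  expect_equal(rk$results$drug[1], "drug004")
  expect_lt(rk$results$score[1], min(rk$results$score[-1]))
})

test_that("generated CSV schemas round-trip through the readers", {
  tmp <- withr::local_tempdir()
  sim <- simulate_screen(n_lines = 10, n_drugs = 2, target_fraction = 0.4,
                         seed = 4)
  write.csv(data.frame(cell_line = sim$screen$cell_line,
                       drug = sim$screen$drug, ic50_uM = sim$screen$ic50),
            file.path(tmp, "screen.csv"), row.names = FALSE)
  write.csv(data.frame(cell_line = sim$annotations$cell_line,
                       lineage = sim$annotations$lineage,
                       mycn_amplified = as.integer(sim$annotations$mycn_amplified),
                       tp53_mutant = as.integer(sim$annotations$tp53_mutant)),
            file.path(tmp, "annotations.csv"), row.names = FALSE)
  sc <- read_screen_csv(file.path(tmp, "screen.csv"))
  an <- read_annotations_csv(file.path(tmp, "annotations.csv"))
  expect_equal(sc$ic50, sim$screen$ic50)
  expect_identical(an$mycn_amplified, sim$annotations$mycn_amplified)

  simd <- simulate_decatenation(seed = 4)
  write.csv(simd$decat, file.path(tmp, "decat.csv"), row.names = FALSE)
  expect_equal(read_decat_csv(file.path(tmp, "decat.csv")),
               simd$decat, tolerance = 1e-12)
})
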