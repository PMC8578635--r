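test_that("plate normalization maps controls to 0/100 and is affine-invariant", {
  sim <- simulate_combination_plate(noise_sd = 0, control_sd = 0, seed = 1)
  p <- sim$plate
  v <- mean(p$vehicle); k <- mean(p$maxkill)
  # control identities and linearity through a hand-built plate
  p$raw[1, 1, 1] <- v;            p$raw[1, 2, 1] <- k
  p$raw[1, 3, 1] <- (v + k) / 2
  dm <- normalize_plate(p)
  expect_equal(dm$death[1, 1, 1], 0)
  expect_equal(dm$death[1, 2, 1], 100)
  expect_equal(dm$death[1, 3, 1], 50)
  # adding a constant to every raw signal (controls included) changes nothing
  p2 <- p
  p2$raw <- p$raw + 5e3; p2$mono1_raw <- p$mono1_raw + 5e3
  p2$mono2_raw <- p$mono2_raw + 5e3
  p2$vehicle <- p$vehicle + 5e3; p2$maxkill <- p$maxkill + 5e3
  dm2 <- normalize_plate(p2)
  expect_equal(dm2$death, dm$death, tolerance = 1e-12)
  # inverted controls error
  p3 <- p; p3$vehicle <- p$maxkill; p3$maxkill <- p$vehicle
  expect_error(normalize_plate(p3), "invalid controls")
})

test_that("ZIP expectation obeys its arithmetic identities", {
  expect_equal(zip_expectation(0, 37), 37)
  expect_equal(zip_expectation(100, 100), 100)
  expect_equal(zip_expectation(50, 50), 75)
  # clamping happens inside the formula only
  expect_equal(zip_expectation(-10, 40), 40)
  expect_equal(zip_expectation(120, 40), 100)
})

test_that("zero-interaction surfaces give near-zero delta; transpose symmetry", {
  sim <- simulate_combination_plate(noise_sd = 0, control_sd = 0, seed = 2)
  dm <- normalize_plate(sim$plate)
  surf <- zip_delta_surface(dm)
  expect_lt(max(abs(surf$delta)), 1)
  # swapping the two drugs transposes the delta surface
  dmT <- dm
  dmT$death <- aperm(dm$death, c(2, 1, 3))
  dmT$mono1 <- dm$mono2; dmT$mono2 <- dm$mono1
  dmT$doses1 <- dm$doses2; dmT$doses2 <- dm$doses1
  surfT <- zip_delta_surface(dmT)
  expect_equal(surfT$delta, t(surf$delta), tolerance = 0.1)
})

test_that("a planted synergy block is recovered near its amplitude", {
  sim <- simulate_combination_plate(
    delta_spec = list(type = "block", rows = 5:8, cols = 5:8, eps = 10),
    noise_sd = 2, seed = 3)
  dm <- normalize_plate(sim$plate)
  surf <- zip_delta_surface(dm)
  expect_gt(mean(surf$delta[5:8, 5:8]), 7)
  expect_lt(mean(surf$delta[5:8, 5:8]), 13)
  # oracle: observed-minus-expectation on the noiseless truth
  direct <- sim$truth$death - outer(sim$truth$y1, sim$truth$y2,
                                    zip_expectation)
  expect_equal(mean(direct[5:8, 5:8]), 10, tolerance = 1e-10)
  # naive mode agrees with the oracle on noiseless data
  sim0 <- simulate_combination_plate(
    delta_spec = list(type = "block", rows = 5:8, cols = 5:8, eps = 10),
    noise_sd = 0, control_sd = 0, seed = 4)
  surf0 <- zip_delta_surface(normalize_plate(sim0$plate), mode = "naive")
  truth_delta0 <- sim0$truth$delta
  expect_equal(mean(surf0$delta[5:8, 5:8]), mean(truth_delta0[5:8, 5:8]),
               tolerance = 0.5)
})

test_that("combination calls follow the fold-change and p thresholds", {
  sim <- simulate_combination_plate(noise_sd = 1, seed = 5)
  dm <- normalize_plate(sim$plate)
  surf <- zip_delta_surface(dm)
  # hand-build replicate observations at the argmax pair: observed = 3 * E
  ij <- surf$argmax_index
  E <- zip_expectation(surf$y1hat[ij[1]], surf$y2hat[ij[2]])
  dm2 <- dm
  set.seed(6)
  dm2$death[ij[1], ij[2], ] <- 3 * E * exp(rnorm(dim(dm$death)[3], 0, 0.01))
  cl <- call_combination(dm2, surf)
  # argmax of the *surface* still points at the same pair; per-replicate
  # log2 FC there is ~log2(3) = 1.585 >= 1.5
  if (all(cl$max_pair_index == ij)) {
    expect_equal(cl$log2_fc_at_max, log2(3), tolerance = 0.05)
    expect_equal(cl$classification,
                 if (cl$p_max <= 0.01) "synergy" else "none")
  }
  # observed == E exactly -> log2 FC 0, classification none
  dm3 <- dm
  for (r in seq_len(dim(dm$death)[3])) {
    dm3$death[, , r] <- outer(surf$y1hat, surf$y2hat, zip_expectation)
  }
  surf3 <- zip_delta_surface(dm3)
  cl3 <- call_combination(dm3, surf3)
  expect_equal(cl3$log2_fc_at_max, 0, tolerance = 0.2)
  expect_equal(cl3$classification, "none")
})

test_that("classification is monotone in the planted boost", {
  classes <- sapply(c(0, 30, 60), function(eps) {
    sim <- simulate_combination_plate(
      mono1 = list(upper = 40, hill = 1.3, ec50 = 0.12),
      mono2 = list(upper = 35, hill = 1.1, ec50 = 1.5),
      delta_spec = list(type = "block", rows = 9:12, cols = 9:12, eps = eps),
      noise_sd = 1, seed = 7)
    dm <- normalize_plate(sim$plate)
    cl <- call_combination(dm, zip_delta_surface(dm))
    cl$classification == "synergy"
  })
  # once synergy appears it persists for larger boosts
  expect_true(all(diff(as.integer(classes)) >= 0))
})
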