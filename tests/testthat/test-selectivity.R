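make_ann <- function(lines, target) {
  data.frame(cell_line = lines,
             lineage = ifelse(lines %in% target, "neuroblastoma", "other"),
             mycn_amplified = FALSE, tp53_mutant = FALSE)
}

test_that("selectivity score matches rank arithmetic on known layouts", {
  # 100 lines, 5 target lines at ranks 1-5 -> median rank 3, score 0.03
  lines <- sprintf("L%03d", 1:100)
  ic50 <- setNames(seq(0.01, 1, length.out = 100), lines)
  ann <- make_ann(lines, lines[1:5])
  r <- selectivity_score(ic50, ann, "neuroblastoma")
  expect_equal(r$median_target_rank, 3)
  expect_equal(r$score, 0.03)

  # single target line with the largest IC50 among 10 -> score 1
  lines <- sprintf("L%02d", 1:10)
  ic50 <- setNames(1:10, lines)
  r <- selectivity_score(ic50, make_ann(lines, "L10"), "neuroblastoma")
  expect_equal(r$score, 1)

  # 12 lines, targets at ranks {2, 5, 9} -> score 5/12
  lines <- sprintf("L%02d", 1:12)
  ic50 <- setNames(1:12, lines)
  ann <- make_ann(lines, lines[c(2, 5, 9)])
  r <- selectivity_score(ic50, ann, "neuroblastoma")
  expect_equal(r$score, 5 / 12)
  o <- oracle_selectivity(ic50, ann$lineage == "neuroblastoma")
  expect_identical(r$score, o$score)

  # all-tied IC50s: every rank (N+1)/2, score (N+1)/(2N)
  ic50 <- setNames(rep(2, 12), lines)
  r <- selectivity_score(ic50, ann, "neuroblastoma")
  expect_equal(r$score, 13 / 24)
})

test_that("selectivity score equals brute-force oracle on random tables", {
  set.seed(42)
  for (i in 1:300) {
    n <- sample(5:20, 1)
    lines <- sprintf("L%02d", seq_len(n))
    # grid of values forces ties; some lines missing a record
    ic50 <- setNames(sample(c(0.1, 0.5, 1, 2, 5, 10), n, replace = TRUE),
                     lines)
    present <- runif(n) > 0.2
    present[sample(n, 2)] <- TRUE  # keep >= 2 records
    ic50 <- ic50[present]
    n_t <- sample(seq_len(max(1, length(ic50) - 1)), 1)
    targets <- sample(names(ic50), n_t)
    if (length(setdiff(names(ic50), targets)) == 0) next
    ann <- make_ann(lines, targets)
    r <- selectivity_score(ic50, ann, "neuroblastoma")
    o <- oracle_selectivity(ic50, names(ic50) %in% targets)
    expect_identical(r$score, o$score)
    expect_identical(r$median_target_rank, o$median_rank)
    expect_true(r$score > 0 && r$score <= 1)
  }
})

test_that("score is rank-based and monotone in target sensitivity", {
  lines <- sprintf("L%02d", 1:15)
  set.seed(7)
  ic50 <- setNames(rlnorm(15), lines)
  ann <- make_ann(lines, lines[c(3, 8, 12)])
  r1 <- selectivity_score(ic50, ann, "neuroblastoma")
  # invariance under a strictly increasing transform
  r2 <- selectivity_score(ic50^3 * 2, ann, "neuroblastoma")
  expect_identical(r1$score, r2$score)
  # moving a target line to a lower IC50 never increases the score
  ic50b <- ic50
  ic50b["L12"] <- min(ic50) / 2
  r3 <- selectivity_score(ic50b, ann, "neuroblastoma")
  expect_lte(r3$score, r1$score)
})

test_that("selectivity errors on bad input", {
  lines <- sprintf("L%02d", 1:6)
  ic50 <- setNames(1:6, lines)
  ann <- make_ann(lines, character(0))
  expect_error(selectivity_score(ic50, ann, "neuroblastoma"),
               "empty target group")
  ann2 <- make_ann(lines, "L01")
  bad <- ic50; bad["L02"] <- -1
  expect_error(selectivity_score(bad, ann2, "neuroblastoma"),
               "invalid concentration")
})

test_that("rank_drugs sorts by score, honors min_target and subgroup filter", {
  sim <- simulate_screen(n_lines = 40, n_drugs = 8, target_fraction = 0.3,
                         selective_shift = c(drug003 = -1.5), noise_sd = 0.2,
                         tp53_effect = 0, mycn_effect = 0, seed = 11)
  rk <- rank_drugs(sim$screen, sim$annotations, "neuroblastoma")
  expect_equal(rk$results$drug[1], "drug003")
  expect_true(all(diff(rk$results$score) >= 0))
  # subgroup filter narrows the median set but keeps the denominator
  sub <- rank_drugs(sim$screen, sim$annotations, "neuroblastoma",
                    subgroup_filter = function(a) a$mycn_amplified,
                    min_target = 1)
  expect_true(all(sub$results$n_screened ==
                    rk$results$n_screened[match(sub$results$drug,
                                                rk$results$drug)]))
  expect_true(all(sub$results$n_target <=
                    rk$results$n_target[match(sub$results$drug,
                                              rk$results$drug)]))
  # an impossible min_target reports drugs as skipped, not an error
  none <- rank_drugs(sim$screen, sim$annotations, "neuroblastoma",
                     min_target = 1000)
  expect_equal(nrow(none$results), 0)
  expect_equal(nrow(none$skipped), 8)
})

test_that("lineage t-test matches the Welch formula and is symmetric", {
  a <- c(-2, -2.1, -1.9); b <- c(0, 0.1, -0.1)
  r <- lineage_t_test(a, b)
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  expect_equal(r$t_statistic, t_hand, tolerance = 1e-12)
  expect_lt(r$p_value, 0.01)
  # group swap flips the sign, p unchanged
  r2 <- lineage_t_test(b, a)
  expect_equal(r2$t_statistic, -r$t_statistic)
  expect_equal(r2$p_value, r$p_value)
  # equal means -> t = 0, p = 1
  r3 <- lineage_t_test(c(1, 2, 3), c(0, 2, 4))
  expect_equal(r3$t_statistic, 0)
  expect_equal(r3$p_value, 1)
  expect_error(lineage_t_test(1, c(1, 2)), "insufficient observations")
})

test_that("rescreen concordance matches the covariance formula", {
  expect_equal(rescreen_concordance(1:4, 1:4)$pearson_r, 1)
  expect_equal(rescreen_concordance(1:4, 4:1)$pearson_r, -1)
  a <- c(0, 1, 2); b <- c(0, 1, 4)
  r <- rescreen_concordance(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(r$pearson_r, r_hand, tolerance = 1e-12)
  expect_error(rescreen_concordance(c(1, 1, 1), 1:3), "degenerate")
})
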