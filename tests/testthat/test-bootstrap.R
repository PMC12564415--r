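test_that("a cohort of identical individuals bootstraps to zero standard errors", {
  ind <- data.frame(id = c("a", "b", "c"), group = "ID", sex = "F",
                    dur_egg = 2L, dur_larva = 2L, dur_adult = 2L,
                    death_stage = "adult", stringsAsFactors = FALSE)
  fec <- data.frame(id = rep(c("a", "b", "c"), each = 2),
                    adult_day = rep(1:2, 3), eggs = rep(c(3L, 1L), 3))
  coh <- cohort("ID", toy_schema(), ind, fec)
  b <- bootstrap_parameters(coh, B = 50, seed = 1)
  expect_true(all(b$se == 0))
  expect_equal(unname(b$mean["R0"]), 4)
  expect_equal(unname(b$n_excluded), rep(0L, 6), ignore_attr = TRUE)
})

test_that("the bootstrap mean matches the exhaustive resampling oracle", {
  toy <- toy2_cohort()
  # exact enumeration over the 4 equally likely resamples: {AA: 6, AB: 3, BA: 3, BB: 0}
  exact <- enum_bootstrap_mean_R0(toy)
  expect_equal(exact, 3.0)
  B <- 2000
  b <- bootstrap_parameters(toy, B = B, seed = 42)
  mc_se <- sqrt(mean(c(6, 3, 3, 0)^2) - 9) / sqrt(B)  # sd over the 4 outcomes
  expect_lt(abs(b$mean["R0"] - exact), 3 * mc_se)

  # a 3-individual cohort against its 27-resample enumeration
  coh3 <- random_cohort(7, n = 3)
  exact3 <- enum_bootstrap_mean_R0(coh3)
  b3 <- bootstrap_parameters(coh3, B = 2000, seed = 9)
  eggs_each <- vapply(coh3$individuals$id, function(id)
    sum(coh3$fecundity$eggs[coh3$fecundity$id == id]), numeric(1))
  grid <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  outcomes <- apply(grid, 1, function(ix) mean(eggs_each[ix]))
  mc_se3 <- stats::sd(outcomes) / sqrt(2000)
  expect_lt(abs(b3$mean["R0"] - exact3), 4 * max(mc_se3, 1e-3))
})

test_that("bootstrap results are a pure function of cohort, B and seed", {
  toy <- toy2_cohort()
  b1 <- bootstrap_parameters(toy, B = 200, seed = 5)
  b2 <- bootstrap_parameters(toy, B = 200, seed = 5)
  expect_identical(b1$replicates, b2$replicates)
  # replicate-indexed substreams: growing B extends the series in place
  b3 <- bootstrap_parameters(toy, B = 400, seed = 5)
  expect_identical(b3$replicates[1:200, ], b1$replicates)
  b4 <- bootstrap_parameters(toy, B = 200, seed = 6)
  expect_false(identical(b4$replicates, b1$replicates))
})

test_that("zero-reproduction replicates keep R0 = F = 0 but are excluded for r, lambda, T", {
  toy <- toy2_cohort()
  b <- bootstrap_parameters(toy, B = 400, seed = 11)
  expect_equal(unname(b$n_excluded["R0"]), 0L)
  expect_equal(unname(b$n_excluded["F"]), 0L)
  n_zero <- sum(b$replicates[, "R0"] == 0)
  expect_gt(n_zero, 0)                     # the BB resample occurs w.p. 1/4
  expect_equal(unname(b$n_excluded["r"]), n_zero)
  expect_equal(sum(!is.na(b$replicates[, "r"])) + b$n_excluded[["r"]], 400L)
  # excluded replicates are exactly those with no offspring
  expect_true(all(is.na(b$replicates[b$replicates[, "R0"] == 0, "r"])))
})

test_that("the paired bootstrap separates clearly different cohorts and not identical ones", {
  toy <- toy2_cohort()
  same <- paired_bootstrap_test(toy, toy, B = 400, seed = 2)
  expect_gt(same$p["R0"], 0.5)
  expect_lt(abs(same$mean_diff["R0"]), 0.5)

  # two copies of the reproducing female vs two sterile individuals:
  # every difference replicate equals 6, so p attains its floor 1/B
  ind_f <- data.frame(id = c("f1", "f2"), group = "A", sex = "F",
                      dur_egg = 2L, dur_larva = 2L, dur_adult = 2L,
                      death_stage = "adult", stringsAsFactors = FALSE)
  fec_f <- data.frame(id = rep(c("f1", "f2"), each = 2), adult_day = rep(1:2, 2),
                      eggs = rep(c(4L, 2L), 2))
  fertile <- cohort("A", toy_schema(), ind_f, fec_f)
  ind_m <- data.frame(id = c("m1", "m2"), group = "B", sex = "M",
                      dur_egg = 2L, dur_larva = 2L, dur_adult = 2L,
                      death_stage = "adult", stringsAsFactors = FALSE)
  sterile <- cohort("B", toy_schema(), ind_m)
  cmp <- paired_bootstrap_test(fertile, sterile, B = 250, seed = 3)
  expect_true(all(cmp$diff[, "R0"] == 6))
  expect_equal(unname(cmp$p["R0"]), 1 / 250)
})

test_that("swapping the groups negates differences and preserves p", {
  a <- random_cohort(21)
  b <- random_cohort(22)
  ab <- paired_bootstrap_test(a, b, B = 300, seed = 4)
  # the p rule is exactly symmetric in the sign of the differences
  p_of <- function(d) {
    d <- d[!is.na(d)]
    min(max(2 * min(sum(d <= 0), sum(d >= 0)) / length(d), 1 / length(d)), 1)
  }
  for (par in colnames(ab$diff)) {
    expect_equal(p_of(ab$diff[, par]), p_of(-ab$diff[, par]))
  }
  # and the full swapped comparison agrees up to Monte-Carlo error
  ba <- paired_bootstrap_test(b, a, B = 300, seed = 4)
  expect_lt(abs(ba$mean_diff["R0"] + ab$mean_diff["R0"]), 1.0)
})

test_that("the percentile interval for R0 covers the generator's analytic value", {
  # calibration check over 100 simulation rounds: the 95% percentile interval
  # should cover the analytic R0 in at least 90% of rounds. Cohorts of n = 80
  # are used: percentile intervals are an asymptotic device and are known to
  # undercover for much smaller cohorts.
  cfg <- toy_config(n = 80)
  target <- analytic_R0(cfg)
  hits <- 0L
  rounds <- 100L
  for (k in seq_len(rounds)) {
    coh <- generate_cohort(cfg, seed = 7000 + k)
    b <- bootstrap_parameters(coh, B = 400, seed = k)
    hits <- hits + (b$ci[1, "R0"] <= target && target <= b$ci[2, "R0"])
  }
  expect_gte(hits / rounds, 0.9)
})
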