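test_that("degenerate configurations generate identical records", {
  cfg <- cohort_config(
    label = "D", schema = toy_schema(), n = 8, female_fraction = 0,
    stage_means = c(egg = 3, larva = 4), stage_sds = c(egg = 0, larva = 0),
    stage_survival = c(egg = 1, larva = 1),
    fecundity_mean = 10, fecundity_sd = 0,
    adult_longevity_mean = 5, adult_longevity_sd = 0
  )
  coh <- generate_cohort(cfg, seed = 1)
  expect_equal(unique(coh$individuals$dur_egg), 3L)
  expect_equal(unique(coh$individuals$dur_larva), 4L)
  expect_equal(unique(coh$individuals$dur_adult), 5L)
  expect_true(all(coh$individuals$sex == "M"))
})

test_that("generation is reproducible from the seed", {
  cfg <- toy_config()
  c1 <- generate_cohort(cfg, seed = 9)
  c2 <- generate_cohort(cfg, seed = 9)
  expect_identical(c1$individuals, c2$individuals)
  expect_identical(c1$fecundity, c2$fecundity)
  c3 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(c1$individuals, c3$individuals))
})

test_that("the control configuration reproduces the published stage means", {
  cfg <- config_control(n = 500)
  coh <- generate_cohort(cfg, seed = 2024)
  ind <- coh$individuals
  done <- ind$death_stage %in% c("pupa", "adult")   # completed the larval period
  larval <- rowSums(ind[done, paste0("dur_", c("L1", "L2", "L3", "L4", "L5"))])
  # published mean 31.37 with SD 0.76 over 30 individuals
  expect_lt(abs(mean(larval) - 31.37), 3 * 0.76 / sqrt(30))
  # egg duration is degenerate at 13 d in the control group
  expect_equal(unique(ind$dur_egg), 13L)
})

test_that("starvation effects modify exactly the configured knobs", {
  cfg <- config_control(n = 60)
  id_eff <- starvation_effect("L3")
  expect_equal(apply_starvation(cfg, id_eff)$stage_means, cfg$stage_means)

  eff <- starvation_effect("L3", duration_multiplier = 11.60 / 5.69,
                           pupal_offset = -5.06,
                           pupal_survival_multiplier = 0.5,
                           fecundity_multiplier = 19 / 40.6)
  mod <- apply_starvation(cfg, eff)
  expect_equal(mod$stage_means[["L3"]], 11.60, tolerance = 1e-12)
  expect_equal(mod$stage_means[["pupa"]], cfg$stage_means[["pupa"]] - 5.06)
  expect_equal(mod$stage_survival[["pupa"]], cfg$stage_survival[["pupa"]] * 0.5)
  expect_equal(mod$fecundity_mean, 19, tolerance = 1e-12)
  expect_equal(mod$stage_means[["L4"]], cfg$stage_means[["L4"]])

  # generated starved-instar mean tracks the multiplier
  coh <- generate_cohort(apply_starvation(config_control(n = 400), eff), seed = 5)
  l3 <- coh$individuals$dur_L3
  l3 <- l3[coh$individuals$death_stage %in% c("L4", "L5", "pupa", "adult")]
  expect_lt(abs(mean(l3) - 11.60), 0.5)

  # generated mean total fecundity tracks the fecundity multiplier
  nf <- sum(coh$individuals$sex == "F")
  expect_gt(nf, 10)
  expect_lt(abs(sum(coh$fecundity$eggs) / nf - 19), 3 * 8.92 / sqrt(nf))

  expect_error(apply_starvation(cfg, starvation_effect("imago")), "not a pre-adult")
  expect_error(apply_starvation(cfg, starvation_effect("L3", pupal_survival_multiplier = 5)),
               "leaves \\[0, 1\\]")
})

test_that("calibration reaches its targets and reports unreachable ones", {
  base <- config_control(n = 30)
  # already-met targets return an equivalent configuration
  ap0 <- analytic_parameters(base)
  same <- calibrate_to_targets(base, list(R0 = ap0$R0, T = ap0$T))
  expect_equal(same$stage_survival, base$stage_survival, tolerance = 1e-9)
  expect_equal(same$stage_means, base$stage_means, tolerance = 1e-9)

  cal <- calibrate_to_targets(base, list(R0 = 6.77, T = 357.87))
  ach <- attr(cal, "calibration")$achieved
  expect_equal(ach$R0, 6.77, tolerance = 1e-9)
  expect_lt(abs(ach$T - 357.87) / 357.87, 0.002)
  expect_equal(ach$R0, analytic_R0(cal), tolerance = 1e-9)

  # raising fecundity raises the achieved R0 monotonically
  hi <- cal
  hi$fecundity_mean <- hi$fecundity_mean * 1.5
  expect_gt(analytic_R0(hi), analytic_R0(cal))

  expect_error(calibrate_to_targets(base, list(R0 = 100, T = 357)), "unreachable")
})

test_that("life-table estimates recover the generator's analytic R0", {
  # parameter recovery: over many seeds the estimated R0 stays within
  # 3 Monte-Carlo SEs of the analytic value
  cfg <- toy_config(n = 500, fecundity_mean = 12, fecundity_sd = 4)
  target <- analytic_R0(cfg)
  ests <- vapply(1:60, function(s)
    sum(build_life_table(generate_cohort(cfg, seed = 3000 + s))$lxmx), numeric(1))
  mc_se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - target), 3 * mc_se)
})

test_that("starvation-configured cohorts grow slower than control cohorts", {
  # effect-direction recovery at the published effect sizes, n = 90
  wins <- 0L
  n_pairs <- 40L
  for (s in seq_len(n_pairs)) {
    cg <- generate_cohort(config_control(n = 90), seed = 5000 + s)
    st <- generate_cohort(config_starvation(n = 90), seed = 6000 + s)
    r_cg <- tryCatch(intrinsic_rate(build_life_table(cg)), error = function(e) NA)
    r_st <- tryCatch(intrinsic_rate(build_life_table(st)), error = function(e) NA)
    if (!is.na(r_cg) && !is.na(r_st) && r_cg > r_st) wins <- wins + 1L
  }
  expect_gte(wins / n_pairs, 0.99)
})
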