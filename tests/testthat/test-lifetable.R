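test_that("the worked two-individual example reproduces the hand-computed life table", {
  lt <- build_life_table(toy2_cohort())
  expect_equal(lt$lx, c(1, 1, 0.5, 0.5, 0.5, 0.5))
  expect_equal(lt$s_xj[3, "larva"], 0.5)
  expect_equal(lt$s_xj[5, "adult_F"], 0.5)
  expect_equal(lt$mx, c(0, 0, 0, 0, 4, 2))
  expect_equal(sum(lt$lxmx), 3.0)
  expect_equal(lt$f_xj[5, "adult_F"], 4)
})

test_that("the Euler-Lotka solver finds verified roots", {
  lt <- build_life_table(toy2_cohort())
  r <- intrinsic_rate(lt)
  expect_equal(r, TOY2_R, tolerance = 1e-8)
  x <- seq_along(lt$lxmx) - 1
  expect_lt(abs(sum(exp(-r * (x + 1)) * lt$lxmx) - 1), 1e-10)

  # point schedule: all net maternity at age 3 -> closed form r = ln(8)/4
  point <- structure(list(lxmx = c(0, 0, 0, 8)), class = "life_table")
  expect_equal(intrinsic_rate(point), log(8) / 4, tolerance = 1e-8)

  # replacement-level schedule: r = 0 exactly
  flat <- structure(list(lxmx = c(0, 0.5, 0.5)), class = "life_table")
  expect_equal(intrinsic_rate(flat), 0, tolerance = 1e-8)

  # shrinking schedule: negative rate, sign follows ln(R0)
  shrink <- structure(list(lxmx = c(0, 0.2, 0.3)), class = "life_table")
  expect_lt(intrinsic_rate(shrink), 0)

  none <- structure(list(lxmx = c(0, 0, 0)), class = "life_table")
  expect_error(intrinsic_rate(none), class = "agestage_degenerate")
})

test_that("population parameters satisfy their identities on the worked example", {
  toy <- toy2_cohort()
  p <- population_parameters(build_life_table(toy))
  expect_equal(p$R0, 3.0)
  expect_equal(p$GRR, 6.0)
  expect_equal(p$F, 6.0)
  expect_equal(p$N_f, 1L)
  expect_equal(p$R0, p$F * p$N_f / p$N, tolerance = 1e-12)
  expect_equal(p$lambda, exp(p$r), tolerance = 1e-12)
  expect_equal(p$T, log(3) / TOY2_R, tolerance = 1e-6)
})

test_that("a cohort with no reproduction yields survival but undefined rates", {
  ind <- data.frame(id = "m", group = "M", sex = "M", dur_egg = 3L,
                    dur_larva = 3L, dur_adult = 4L, death_stage = "adult",
                    stringsAsFactors = FALSE)
  coh <- cohort("M", toy_schema(), ind)
  lt <- build_life_table(coh)
  expect_equal(lt$lx, rep(1, 10))
  expect_true(all(lt$mx == 0))
  expect_error(population_parameters(lt), class = "agestage_degenerate")
  p <- population_parameters(lt, on_degenerate = "na")
  expect_true(p$degenerate)
  expect_true(is.na(p$r) && is.na(p$lambda) && is.na(p$T))
  expect_equal(p$R0, 0)
})

test_that("conservation and parameter identities hold over random cohorts", {
  for (seed in c(2, 11, 31, 57, 83)) {
    coh <- random_cohort(seed)
    lt <- build_life_table(coh)
    expect_equal(lt$n * sum(lt$lxmx), sum(coh$fecundity$eggs), tolerance = 1e-12)
    expect_equal(lt$lx[1], 1)
    expect_true(all(diff(lt$lx) <= 1e-12))
    expect_true(all(lt$s_xj >= 0 & lt$s_xj <= 1))
    p <- population_parameters(lt)
    expect_equal(p$lambda, exp(p$r), tolerance = 1e-12)
    if (p$t_defined) expect_equal(p$T, log(p$R0) / p$r, tolerance = 1e-12)
    expect_equal(p$R0, p$F * p$N_f / p$N, tolerance = 1e-12)
  }
})

test_that("scaling all fecundities up strictly increases R0, r and lambda", {
  for (seed in c(3, 19)) {
    coh <- random_cohort(seed)
    boosted <- coh
    boosted$fecundity$eggs <- boosted$fecundity$eggs * 3L
    p1 <- population_parameters(build_life_table(coh))
    p2 <- population_parameters(build_life_table(boosted))
    expect_gt(p2$R0, p1$R0)
    expect_gt(p2$r, p1$r)
    expect_gt(p2$lambda, p1$lambda)
  }
})

test_that("life expectancy matches hand values and the propagation oracle on the worked example", {
  toy <- toy2_cohort()
  e <- life_expectancy(toy)
  expect_equal(e[1, "egg"], 4)            # lifespans 6 and 2
  expect_equal(e[5, "adult_F"], 2)
  lt <- build_life_table(toy)
  expect_equal(e[1, "egg"], sum(lt$lx))   # e_0 equals total expected lifespan
  prop <- propagation_expectancy(toy)
  occ <- !is.na(e)
  expect_equal(e[occ], prop[occ], tolerance = 1e-12)

  ind <- data.frame(id = "s", group = "S", sex = "M", dur_egg = 4L,
                    dur_larva = 3L, dur_adult = 3L, death_stage = "adult",
                    stringsAsFactors = FALSE)
  single <- cohort("S", toy_schema(), ind)
  expect_equal(life_expectancy(single)[1, "egg"], 10)
})

test_that("newborn life expectancy equals the propagated value on random cohorts", {
  # propagation from age 0 reproduces the cohort's occupancy exactly, so the
  # path-based and transition-propagated estimators must agree there
  for (seed in c(5, 13, 29, 47)) {
    coh <- random_cohort(seed)
    e <- life_expectancy(coh)
    prop <- propagation_expectancy(coh)
    expect_equal(e[1, "egg"], prop[1, "egg"], tolerance = 1e-12)
    expect_equal(e[1, "egg"], sum(build_life_table(coh)$lx), tolerance = 1e-12)
  }
})

test_that("reproductive value discounts future eggs and anchors at lambda", {
  toy <- toy2_cohort()
  r <- intrinsic_rate(build_life_table(toy))
  v <- reproductive_value(toy, r)
  expect_equal(v[1, "egg"], exp(r), tolerance = 1e-9)
  expect_equal(v[5, "adult_F"], 4 + 2 * exp(-r), tolerance = 1e-8)
  # discount-free limit: mean undiscounted future eggs
  v0 <- reproductive_value(toy, 0)
  expect_equal(v0[1, "egg"], 3)           # (6 + 0) / 2
  expect_equal(v0[5, "adult_F"], 6)
})

test_that("the newborn reproductive value equals lambda on random synthetic cohorts", {
  for (seed in c(101, 202, 303, 404, 505, 606)) {
    coh <- generate_cohort(toy_config(n = 30), seed = seed)
    lt <- build_life_table(coh)
    if (sum(lt$lxmx) == 0) next
    r <- intrinsic_rate(lt)
    v <- reproductive_value(coh, r)
    expect_equal(v[1, "egg"], exp(r), tolerance = 1e-9)
  }
})
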