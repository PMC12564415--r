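# Shared fixtures and independent oracles, all built in code.

toy_schema <- function() stage_schema(c("egg", "larva", "adult"))

# Two-individual worked example used throughout: A is a female living
# 2 d egg + 2 d larva + 2 d adult laying (4, 2) eggs; B dies upon entering
# the larval stage at age 2.
toy2_cohort <- function() {
  ind <- data.frame(
    id = c("A", "B"), group = "TOY", sex = c("F", "U"),
    dur_egg = c(2L, 2L), dur_larva = c(2L, NA), dur_adult = c(2L, NA),
    death_stage = c("adult", "larva"), stringsAsFactors = FALSE
  )
  fec <- data.frame(id = c("A", "A"), adult_day = 1:2, eggs = c(4L, 2L))
  cohort("TOY", toy_schema(), ind, fec)
}

# independently verified Euler-Lotka root of 2 e^{-5r} + e^{-6r} = 1
# (uniroot at tol 1e-14, frozen)
TOY2_R <- 0.2068598071

# random small valid cohorts for property tests; the first individual is
# always a reproducing female so rates are defined
random_cohort <- function(seed, n = 6) {
  set.seed(seed)
  sch <- toy_schema()
  ids <- sprintf("i%02d", seq_len(n))
  sex <- character(n); death <- character(n)
  d_egg <- integer(n); d_lar <- rep(NA_integer_, n); d_ad <- rep(NA_integer_, n)
  fec <- list()
  for (i in seq_len(n)) {
    d_egg[i] <- sample(1:3, 1)
    fate <- if (i == 1L) "adult" else
      sample(c("egg", "larva_entry", "larva", "adult"), 1, prob = c(.15, .15, .2, .5))
    if (fate == "egg") { sex[i] <- "U"; death[i] <- "egg"; next }
    if (fate == "larva_entry") { sex[i] <- "U"; death[i] <- "larva"; next }
    d_lar[i] <- sample(1:4, 1)
    if (fate == "larva") { sex[i] <- "U"; death[i] <- "larva"; next }
    d_ad[i] <- sample(1:3, 1)
    sex[i] <- if (i == 1L) "F" else sample(c("F", "M"), 1)
    death[i] <- "adult"
    if (sex[i] == "F") {
      eggs <- stats::rpois(d_ad[i], 3)
      if (i == 1L && sum(eggs) == 0) eggs[1L] <- 2L
      fec[[length(fec) + 1L]] <- data.frame(id = ids[i], adult_day = seq_len(d_ad[i]),
                                            eggs = eggs)
    }
  }
  ind <- data.frame(id = ids, group = "RND", sex = sex,
                    dur_egg = d_egg, dur_larva = d_lar, dur_adult = d_ad,
                    death_stage = death, stringsAsFactors = FALSE)
  cohort("RND", sch, ind, if (length(fec)) do.call(rbind, fec) else NULL)
}

# transition-propagation oracle for life expectancy: expected remaining days
# from (x, j) obtained by backward induction over the empirical transition
# schedule (counts day x itself)
propagation_expectancy <- function(cohort) {
  sched <- derive_schedule(cohort)
  A <- sched$n_ages
  nst <- length(sched$stages)
  e <- matrix(0, A + 1L, nst)          # boundary: beyond last age, 0
  for (x in A:1) {
    nxt <- sched$stay[x, ] * e[x + 1L, ]
    nxt[-nst] <- nxt[-nst] + sched$advance[x, -nst] * e[x + 1L, -1L]
    nxt <- nxt + sched$advance2[x, ] * e[x + 1L, nst]
    e[x, ] <- 1 + nxt
  }
  structure(e[seq_len(A), , drop = FALSE], dimnames = list(seq_len(A) - 1L, sched$stages))
}

# exhaustive bootstrap oracle: exact mean resampled R0 over all n^n equally
# likely with-replacement resamples, from egg totals alone
enum_bootstrap_mean_R0 <- function(cohort) {
  ind <- cohort$individuals
  eggs_by_id <- vapply(ind$id, function(id)
    sum(cohort$fecundity$eggs[cohort$fecundity$id == id]), numeric(1))
  n <- length(eggs_by_id)
  grid <- expand.grid(rep(list(seq_len(n)), n))
  mean(apply(grid, 1L, function(ix) sum(eggs_by_id[ix]) / n))
}

# toy generator configuration (fast, short generations) for synthetic-module
# property tests
toy_config <- function(n = 40, fecundity_mean = 12, fecundity_sd = 4,
                       survival = c(egg = 0.9, larva = 0.8)) {
  cohort_config(
    label = "SIM", schema = toy_schema(), n = n, female_fraction = 0.5,
    stage_means = c(egg = 3, larva = 4), stage_sds = c(egg = 1, larva = 1),
    stage_survival = survival,
    fecundity_mean = fecundity_mean, fecundity_sd = fecundity_sd,
    adult_longevity_mean = 5, adult_longevity_sd = 1
  )
}
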