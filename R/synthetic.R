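#' Configuration of a synthetic cohort generator
#'
#' Describes the generative model used to emulate a reared cohort: per-stage
#' duration distributions (normal, discretized to integer days by mean-
#' preserving stochastic rounding, truncated at 1 day), per-stage Bernoulli
#' survival (probability of completing the
#' stage), sex assigned at adult emergence, adult longevity, and a total
#' fecundity per female (normal truncated at 0) spread over the adult days
#' by an oviposition schedule (front-loaded geometric by default, uniform as
#' an alternative).
#'
#' @param label Cohort label.
#' @param schema A \code{\link{stage_schema}}.
#' @param n Number of individuals.
#' @param female_fraction Probability an emerging adult is female.
#' @param stage_means,stage_sds Named numeric vectors over the pre-adult
#'   stages: duration mean and SD in days.
#' @param stage_survival Named numeric vector over the pre-adult stages:
#'   probability of completing each stage (entering the next).
#' @param fecundity_mean,fecundity_sd Total eggs per female: the mean is the
#'   mean of the truncated distribution (the underlying normal location is
#'   solved internally so truncation does not inflate it).
#' @param adult_longevity_mean,adult_longevity_sd Adult lifespan in days.
#' @param oviposition \code{"geometric"} (daily share proportional to
#'   \code{(1 - oviposition_q)^(day - 1)}) or \code{"uniform"}.
#' @param oviposition_q Decay parameter of the geometric schedule.
#' @return Object of class \code{cohort_config}.
#' @export
cohort_config <- function(label, schema, n, female_fraction,
                          stage_means, stage_sds, stage_survival,
                          fecundity_mean, fecundity_sd,
                          adult_longevity_mean = 20, adult_longevity_sd = 5,
                          oviposition = c("geometric", "uniform"),
                          oviposition_q = 0.3) {
  oviposition <- match.arg(oviposition)
  pre <- schema$pre_adult
  stage_means <- stage_means[pre]
  stage_sds <- stage_sds[pre]
  stage_survival <- stage_survival[pre]
  stopifnot(
    inherits(schema, "stage_schema"), n >= 1,
    !anyNA(stage_means), !anyNA(stage_sds), !anyNA(stage_survival),
    all(stage_means > 0), all(stage_sds >= 0),
    all(stage_survival >= 0), all(stage_survival <= 1),
    female_fraction >= 0, female_fraction <= 1,
    fecundity_mean > 0, fecundity_sd >= 0,
    adult_longevity_mean > 0, adult_longevity_sd >= 0,
    oviposition_q > 0, oviposition_q < 1
  )
  structure(
    list(label = label, schema = schema, n = as.integer(n),
         female_fraction = female_fraction,
         stage_means = stage_means, stage_sds = stage_sds,
         stage_survival = stage_survival,
         fecundity_mean = fecundity_mean, fecundity_sd = fecundity_sd,
         adult_longevity_mean = adult_longevity_mean,
         adult_longevity_sd = adult_longevity_sd,
         oviposition = oviposition, oviposition_q = oviposition_q),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$label, ": n = ", x$n,
      ", survival to adult = ", format(prod(x$stage_survival), digits = 3),
      ", female fraction = ", format(x$female_fraction, digits = 3),
      ", F = ", format(x$fecundity_mean, digits = 4), "\n", sep = "")
  invisible(x)
}

# integer duration draw: normal discretized by stochastic rounding
# (floor(x) + Bernoulli(frac(x)), which keeps the mean unbiased where plain
# rounding would shift it by up to half a day), truncated so the result is
# >= min (rejection sampling)
rtrunc_round <- function(n, mean, sd, min = 1L) {
  # degenerate configuration: essentially all mass below the floor
  if (stats::pnorm(min - 0.5, mean, max(sd, 1e-12)) > 0.999) {
    return(rep.int(as.integer(min), n))
  }
  out <- integer(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mean, sd)
    d <- floor(x) + (stats::runif(length(todo)) < x - floor(x))
    ok <- d >= min
    out[todo[ok]] <- as.integer(d[ok])
    todo <- todo[!ok]
  }
  out
}

# location of the underlying normal such that the 0-truncated distribution
# has the requested mean
trunc_normal_location <- function(target_mean, sd, lower = 0) {
  if (sd == 0) return(target_mean)
  trunc_mean <- function(mu) {
    a <- (lower - mu) / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  }
  stats::uniroot(function(mu) trunc_mean(mu) - target_mean,
                 lower = target_mean - 8 * sd, upper = target_mean,
                 extendInt = "upX", tol = 1e-9)$root
}

rtrunc0 <- function(n, target_mean, sd) {
  if (sd == 0) return(rep.int(target_mean, n))
  mu <- trunc_normal_location(target_mean, sd)
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    x <- stats::rnorm(length(todo), mu, sd)
    ok <- x >= 0
    out[todo[ok]] <- x[ok]
    todo <- todo[!ok]
  }
  out
}

oviposition_weights <- function(config, days) {
  w <- switch(config$oviposition,
              geometric = (1 - config$oviposition_q)^(seq_len(days) - 1L),
              uniform = rep(1, days))
  w / sum(w)
}

#' Generate a synthetic cohort
#'
#' Draws \code{config$n} independent individual life histories: integer stage
#' durations from the configured truncated-normal distributions, stage-wise
#' Bernoulli survival (an individual failing a stage dies after a uniformly
#' chosen 0..d-1 occupied days of it, except in the first stage, which is
#' always occupied at least one day), sex assigned at adult emergence, and
#' for females a total fecundity spread multinomially over the adult days by
#' the oviposition schedule.
#'
#' @param config A \code{\link{cohort_config}}.
#' @param seed Integer seed; the same (config, seed) always yields the
#'   identical cohort.
#' @return A valid \code{\link{cohort}}.
#' @export
generate_cohort <- function(config, seed) {
  set.seed(seed)
  sch <- config$schema
  pre <- sch$pre_adult
  K <- length(pre)
  n <- config$n
  # draw per-stage intended durations and survival outcomes for everyone,
  # then resolve each individual's fate
  dmat <- vapply(seq_len(K), function(k)
    rtrunc_round(n, config$stage_means[[k]], config$stage_sds[[k]]), integer(n))
  dmat <- matrix(dmat, nrow = n)
  smat <- matrix(stats::runif(n * K), n, K) <=
    matrix(config$stage_survival, n, K, byrow = TRUE)
  dur <- matrix(NA_integer_, n, K + 1L,
                dimnames = list(NULL, paste0("dur_", sch$stages)))
  sex <- rep("U", n)
  death <- character(n)
  fail_at <- apply(smat, 1L, function(s) if (all(s)) K + 1L else which.min(s))
  for (i in seq_len(n)) {
    fk <- fail_at[i]
    if (fk <= K) {
      if (fk > 1L) dur[i, seq_len(fk - 1L)] <- dmat[i, seq_len(fk - 1L)]
      u <- sample.int(dmat[i, fk], 1L) - 1L   # days occupied before dying
      if (fk == 1L && u == 0L) u <- 1L        # a laid egg occupies at least one day
      if (u >= 1L) dur[i, fk] <- u
      death[i] <- pre[fk]
    } else {
      dur[i, seq_len(K)] <- dmat[i, ]
      death[i] <- sch$adult
    }
  }
  adult <- fail_at > K
  n_ad <- sum(adult)
  if (n_ad) {
    dur[adult, K + 1L] <- rtrunc_round(n_ad, config$adult_longevity_mean,
                                       config$adult_longevity_sd)
    sex[adult] <- ifelse(stats::runif(n_ad) <= config$female_fraction, "F", "M")
  }
  ids <- paste0(config$label, "_", seq_len(n))
  fem <- which(sex == "F")
  fec <- NULL
  if (length(fem)) {
    totals <- round(rtrunc0(length(fem), config$fecundity_mean, config$fecundity_sd))
    Ls <- dur[fem, K + 1L]
    eggs <- lapply(seq_along(fem), function(j)
      as.vector(stats::rmultinom(1L, totals[j], oviposition_weights(config, Ls[j]))))
    fec <- data.frame(
      id = rep(ids[fem], Ls),
      adult_day = unlist(lapply(Ls, seq_len), use.names = FALSE),
      eggs = unlist(eggs, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  ind <- data.frame(id = ids, group = config$label, sex = sex,
                    stringsAsFactors = FALSE)
  ind <- cbind(ind, as.data.frame(dur))
  ind$death_stage <- death
  cohort(config$label, sch, ind, fec, check = TRUE)
}

#' Phenomenological effect of a three-day larval starvation pulse
#'
#' Multiplicative and additive modifiers summarizing how starving one instar
#' alters the generative parameters: the starved instar's duration is
#' extended (compensatory feeding), the pupal duration shifts (earlier
#' emergence), pupal survival drops, and female total fecundity is reduced.
#'
#' @param instar Name of the starved larval stage (must be a pre-adult stage
#'   of the schema the effect is applied to).
#' @param duration_multiplier Multiplier on the starved instar's mean
#'   duration (> 0).
#' @param pupal_offset Additive shift of the pupal mean duration in days
#'   (negative = shortened).
#' @param pupal_survival_multiplier Multiplier on pupal-stage survival (> 0).
#' @param fecundity_multiplier Multiplier on mean total fecundity (> 0).
#' @return Object of class \code{starvation_effect}.
#' @export
starvation_effect <- function(instar, duration_multiplier = 1,
                              pupal_offset = 0,
                              pupal_survival_multiplier = 1,
                              fecundity_multiplier = 1) {
  stopifnot(duration_multiplier > 0, pupal_survival_multiplier > 0,
            fecundity_multiplier > 0)
  structure(
    list(instar = instar, duration_multiplier = duration_multiplier,
         pupal_offset = pupal_offset,
         pupal_survival_multiplier = pupal_survival_multiplier,
         fecundity_multiplier = fecundity_multiplier),
    class = "starvation_effect"
  )
}

#' Apply a starvation effect to a cohort configuration
#'
#' @param config A \code{\link{cohort_config}}.
#' @param effect A \code{\link{starvation_effect}}; the starved instar must
#'   exist in the config's schema, and the pupal stage is taken to be the
#'   last pre-adult stage.
#' @return A modified \code{cohort_config}; everything not named by the
#'   effect is unchanged. Errors if a modified survival leaves [0, 1] or a
#'   duration becomes non-positive.
#' @export
apply_starvation <- function(config, effect) {
  stopifnot(inherits(effect, "starvation_effect"))
  pre <- config$schema$pre_adult
  if (!effect$instar %in% pre) stop("starved instar '", effect$instar, "' is not a pre-adult stage")
  pupa <- pre[length(pre)]
  cfg <- config
  cfg$stage_means[[effect$instar]] <- cfg$stage_means[[effect$instar]] * effect$duration_multiplier
  cfg$stage_means[[pupa]] <- cfg$stage_means[[pupa]] + effect$pupal_offset
  cfg$stage_survival[[pupa]] <- cfg$stage_survival[[pupa]] * effect$pupal_survival_multiplier
  cfg$fecundity_mean <- cfg$fecundity_mean * effect$fecundity_multiplier
  if (cfg$stage_means[[pupa]] <= 0) stop("pupal offset drives the pupal duration non-positive")
  if (cfg$stage_survival[[pupa]] > 1 || cfg$stage_survival[[pupa]] < 0)
    stop("pupal survival multiplier leaves [0, 1]")
  cfg
}

#' Analytic expectations of a cohort configuration
#'
#' \code{analytic_R0} is the expected net reproductive rate
#' \eqn{R_0 = p_{adult} \cdot f_{female} \cdot E[F]} (survival to adulthood
#' times female fraction times mean total fecundity). \code{analytic_parameters}
#' additionally solves the Euler-Lotka equation on the expected net-maternity
#' schedule (durations at their rounded means, eggs spread by the oviposition
#' weights over the mean adult lifespan) for r, and reports
#' \eqn{T = \ln(R_0)/r}.
#'
#' @param config A \code{\link{cohort_config}}.
#' @return \code{analytic_R0}: a number. \code{analytic_parameters}: list
#'   with \code{R0}, \code{r}, \code{T} and the expected \code{lxmx} vector.
#' @export
analytic_R0 <- function(config) {
  prod(config$stage_survival) * config$female_fraction * config$fecundity_mean
}

#' @rdname analytic_R0
#' @export
analytic_parameters <- function(config) {
  R0 <- analytic_R0(config)
  # expected adult entry age; stochastic rounding keeps per-stage expected
  # durations at their configured means (those below the 1-day floor clamp)
  a <- round(sum(pmax(config$stage_means, 1)))
  L <- max(round(config$adult_longevity_mean), 1)
  w <- oviposition_weights(config, L)
  lxmx <- numeric(a + L)
  lxmx[a + seq_len(L)] <- R0 * w             # reproduction at ages a..a+L-1
  r <- euler_lotka_rate(lxmx)
  list(R0 = R0, r = r, T = log(R0) / r, lxmx = lxmx)
}

#' Calibrate a configuration to target net reproductive rate and generation time
#'
#' Two-knob search: (1) all pre-adult survival probabilities are scaled by a
#' common factor so the analytic \eqn{R_0} matches \code{targets$R0} exactly
#' (stages capped at probability 1, the remainder redistributed); (2) the
#' pre-adult duration means are shifted uniformly until the analytic
#' generation time \eqn{T = \ln(R_0)/r} of the expected schedule matches
#' \code{targets$T} within \code{tol} (relative), iterating because ages are
#' integer-quantized.
#'
#' @param base A \code{\link{cohort_config}}.
#' @param targets List with positive elements \code{R0} and \code{T}.
#' @param tol Relative tolerance on the achieved T (default 0.002, about the
#'   1-day quantization limit of integer-day schedules near T = 360); R0 is
#'   matched exactly by construction.
#' @return The calibrated \code{cohort_config}, with attribute
#'   \code{calibration} recording the achieved (R0, r, T). Errors if the
#'   target R0 exceeds the maximum attainable
#'   \code{female_fraction * fecundity_mean}.
#' @export
calibrate_to_targets <- function(base, targets, tol = 0.002) {
  stopifnot(targets$R0 > 0, targets$T > 0)
  cfg <- base
  max_R0 <- cfg$female_fraction * cfg$fecundity_mean
  if (targets$R0 > max_R0) {
    stop("target R0 = ", targets$R0, " is unreachable: even with full survival the ",
         "configuration yields at most ", format(max_R0, digits = 4))
  }
  # knob 1: common survival scaling
  K <- length(cfg$stage_survival)
  scale_needed <- targets$R0 / analytic_R0(cfg)
  surv <- cfg$stage_survival
  for (it in seq_len(20L)) {
    free <- if (scale_needed < 1) rep(TRUE, K) else surv < 1
    if (!any(free)) break
    mult <- scale_needed^(1 / sum(free))
    surv[free] <- surv[free] * mult
    over <- surv > 1
    if (!any(over)) break
    surv[over] <- 1
    scale_needed <- targets$R0 / (prod(surv) * cfg$female_fraction * cfg$fecundity_mean)
    if (abs(scale_needed - 1) < 1e-12) break
  }
  cfg$stage_survival <- surv
  # knob 2: shift of the pre-adult duration means. The whole shift goes to
  # the last pre-adult stage (for the butterfly schema, the long
  # overwintering pupal stage): shifting every stage by the same amount
  # aliases all means to the same rounding phase, so the integer-day
  # pre-adult duration would jump in steps of the stage count instead of 1.
  last_pre <- K
  for (it in seq_len(40L)) {
    ap <- analytic_parameters(cfg)
    delta <- targets$T - ap$T
    if (abs(delta) <= tol * targets$T) break
    cfg$stage_means[[last_pre]] <- max(cfg$stage_means[[last_pre]] + delta, 1)
  }
  ap <- analytic_parameters(cfg)
  attr(cfg, "calibration") <- list(target = targets,
                                   achieved = ap[c("R0", "r", "T")])
  cfg
}
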