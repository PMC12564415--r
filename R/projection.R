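#' Derive an empirical age-stage transition schedule from a cohort
#'
#' For each occupied (age x, stage j) cell the schedule holds the empirical
#' fractions of occupants that, at age x + 1, stayed in j, advanced to the
#' next stage, or died. Advancement out of the last pre-adult stage is split
#' into the female-adult and male-adult columns using the observed sexes of
#' the individuals that emerged at that age, so that projecting one newborn
#' through the schedule reproduces the cohort's age-stage survival matrix
#' exactly. Per-capita daily fecundity of female adults is taken from the
#' life table's \eqn{f_{xj}}.
#'
#' @param cohort A valid \code{\link{cohort}}.
#' @return Object of class \code{transition_schedule}: matrices \code{stay},
#'   \code{advance} (into the primary successor: j + 1, which for the last
#'   pre-adult stage is the female-adult column) and \code{advance2} (into
#'   the male-adult column, nonzero only for the last pre-adult stage), the
#'   female-adult fecundity vector \code{fec} by age, stage axis, and the
#'   cohort's female fraction among emerged adults.
#' @export
derive_schedule <- function(cohort) {
  lt <- build_life_table(cohort)
  tab <- cohort_tableau(cohort)
  A <- max(tab$lifespan)
  S <- tab$S
  nst <- S + 1L
  occ <- matrix(0, A, nst)       # occupants of (x, j)
  stay_n <- matrix(0, A, nst)
  adv_n <- matrix(0, A, nst)     # advance into primary successor
  adv2_n <- matrix(0, A, nst)    # advance into male-adult (last pre-adult only)
  for (i in seq_len(tab$n)) {
    for (j in seq_len(S)) {
      d <- tab$dur[i, j]
      if (d == 0L) next
      a <- tab$entry[i, j]
      col <- if (j < S) j else if (tab$sex[i] == "F") S else S + 1L
      if (d > 1L) {
        occ[a + seq_len(d), col] <- occ[a + seq_len(d), col] + 1
        stay_n[a + seq_len(d - 1L), col] <- stay_n[a + seq_len(d - 1L), col] + 1
      } else {
        occ[a + 1L, col] <- occ[a + 1L, col] + 1
      }
      last <- a + d - 1L         # last occupied age in stage j
      if (j < S) {
        # advanced iff any later stage was actually occupied (dying upon entry
        # to the next stage counts as death, not advancement)
        advanced <- any(tab$dur[i, (j + 1L):S] > 0L)
        if (advanced) {
          if (j + 1L < S) {
            adv_n[last + 1L, col] <- adv_n[last + 1L, col] + 1
          } else if (tab$sex[i] == "F") {
            adv_n[last + 1L, col] <- adv_n[last + 1L, col] + 1
          } else {
            adv2_n[last + 1L, col] <- adv2_n[last + 1L, col] + 1
          }
        }
      }
    }
  }
  stages <- lt$stages
  safe_div <- function(num) {
    m <- ifelse(occ > 0, num / occ, 0)
    dimnames(m) <- list(seq_len(A) - 1L, stages)
    m
  }
  structure(
    list(stay = safe_div(stay_n), advance = safe_div(adv_n),
         advance2 = safe_div(adv2_n),
         fec = lt$f_xj[, S], stages = stages, n_ages = A,
         female_fraction = if (lt$n_female + lt$n_male > 0)
           lt$n_female / (lt$n_female + lt$n_male) else NA_real_,
         schema = cohort$schema),
    class = "transition_schedule"
  )
}

#' @export
print.transition_schedule <- function(x, ...) {
  cat("<transition_schedule> ", x$n_ages, " ages x ", length(x$stages),
      " stages; female fraction ", format(x$female_fraction, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Deterministic daily age-stage population projection
#'
#' Propagates a real-valued age-stage population vector day by day through an
#' empirical \code{\link{derive_schedule}}. Eggs laid by female adults on day
#' t enter the population as age-0 individuals of the first stage on day
#' t + 1 (consistent with the age-0-indexed Euler-Lotka discounting, so the
#' realized long-run growth rate converges to the cohort's intrinsic rate).
#' Individuals older than the schedule's last observed age die.
#'
#' @param schedule A \code{\link{transition_schedule}}.
#' @param initial Either a single number (that many age-0 individuals of the
#'   first stage) or a matrix (ages x stages, on the schedule's stage axis).
#' @param horizon Number of daily steps (>= 1); day 0 is the initial state.
#' @return Object of class \code{trajectory}: \code{stage_n} matrix
#'   ((horizon + 1) days x stages), \code{total} per-day totals,
#'   \code{newborns} per-day eggs laid.
#' @export
project <- function(schedule, initial, horizon) {
  stopifnot(horizon >= 1)
  A <- schedule$n_ages
  nst <- length(schedule$stages)
  if (is.matrix(initial)) {
    if (nrow(initial) > A || ncol(initial) != nst) stop("initial matrix must be (<= n_ages) x stages")
    state <- matrix(0, A, nst)
    state[seq_len(nrow(initial)), ] <- initial
  } else {
    stopifnot(length(initial) == 1L, initial >= 0)
    state <- matrix(0, A, nst)
    state[1L, 1L] <- initial
  }
  if (any(state < 0)) stop("initial abundances must be nonnegative")
  S <- nst - 1L                   # column index of the last pre-adult stage + 1 = female adult
  days <- horizon + 1L
  stage_n <- matrix(0, days, nst, dimnames = list(NULL, schedule$stages))
  newborns <- numeric(days)
  for (t in seq_len(days)) {
    stage_n[t, ] <- colSums(state)
    births <- sum(state[, S] * schedule$fec)
    newborns[t] <- births
    if (t == days) break
    nxt <- matrix(0, A, nst)
    surv_stay <- state * schedule$stay
    surv_adv <- state * schedule$advance
    surv_adv2 <- state * schedule$advance2
    if (A > 1L) {
      nxt[2:A, ] <- surv_stay[1:(A - 1L), ]
      nxt[2:A, 2:nst] <- nxt[2:A, 2:nst] + surv_adv[1:(A - 1L), 1:(nst - 1L)]
      nxt[2:A, nst] <- nxt[2:A, nst] + surv_adv2[1:(A - 1L), nst - 1L]
    }
    nxt[1L, 1L] <- nxt[1L, 1L] + births
    state <- nxt
  }
  structure(
    list(stage_n = stage_n, total = rowSums(stage_n), newborns = newborns,
         stages = schedule$stages, horizon = horizon),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", x$horizon, " days; total N: ",
      format(x$total[1L], digits = 4), " -> ",
      format(x$total[length(x$total)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' Zero-safe log10 stage size
#'
#' \eqn{\log_{10}(N + 1)}, the stage-size statistic used to plot projected
#' stage abundances without undefined values at zero individuals.
#'
#' @param N Nonnegative abundance(s).
#' @return \code{log10(N + 1)}.
#' @export
stage_size <- function(N) {
  if (any(N < 0)) stop("stage size is undefined for negative abundances")
  log10(N + 1)
}

#' Zero-safe daily growth rate
#'
#' \eqn{\varphi = \ln(N_{t+1} + 1) - \ln(N_t + 1)}; equals 0 when both
#' abundances are 0, avoiding undefined values.
#'
#' @param N_t,N_t1 Nonnegative abundances on consecutive days.
#' @return The daily log growth rate.
#' @export
growth_rate <- function(N_t, N_t1) {
  if (any(N_t < 0) || any(N_t1 < 0)) stop("growth rate is undefined for negative abundances")
  log(N_t1 + 1) - log(N_t + 1)
}

#' Percent decline of one projected population relative to another
#'
#' @param traj_control,traj_treatment \code{\link{project}} trajectories
#'   covering day \code{t}.
#' @param t Day at which to compare total population sizes.
#' @return \code{100 * (1 - total_treatment(t) / total_control(t))}, in
#'   percent. Errors if the control total at \code{t} is zero.
#' @export
decline_percent <- function(traj_control, traj_treatment, t) {
  stopifnot(t >= 0, t <= traj_control$horizon, t <= traj_treatment$horizon)
  nc <- traj_control$total[t + 1L]
  nt <- traj_treatment$total[t + 1L]
  if (nc <= 0) stop("decline is undefined: control population is zero at day ", t)
  100 * (1 - nt / nc)
}

#' Export a trajectory to CSV files
#'
#' Writes \code{<label>_trajectory.csv} (long: t, stage, N, stage_size, phi)
#' and \code{<label>_totals.csv} (t, total, newborns).
#'
#' @param traj A \code{\link{project}} trajectory.
#' @param dir Output directory.
#' @param label File-name stem.
#' @return Invisibly, the file paths.
#' @export
export_trajectory <- function(traj, dir, label = "trajectory") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  days <- nrow(traj$stage_n)
  phi <- rbind(traj$stage_n[-1L, , drop = FALSE], NA)  # phi_t uses t and t+1
  phi <- log(phi + 1) - log(traj$stage_n + 1)
  long <- data.frame(
    t = rep(seq_len(days) - 1L, times = length(traj$stages)),
    stage = rep(traj$stages, each = days),
    N = as.vector(traj$stage_n),
    stage_size = as.vector(stage_size(traj$stage_n)),
    phi = as.vector(phi)
  )
  p1 <- file.path(dir, paste0(label, "_trajectory.csv"))
  p2 <- file.path(dir, paste0(label, "_totals.csv"))
  utils::write.csv(long, p1, row.names = FALSE)
  utils::write.csv(data.frame(t = seq_len(days) - 1L, total = traj$total,
                              newborns = traj$newborns), p2, row.names = FALSE)
  invisible(c(p1, p2))
}
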