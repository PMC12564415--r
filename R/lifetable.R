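#' Build the age-stage two-sex life table of a cohort
#'
#' Computes the age-stage survival matrix \eqn{s_{xj}} (probability that a
#' newborn is alive and in stage j at age x), the age-stage daily fecundity
#' \eqn{f_{xj}} (eggs per living female adult per day), and the age vectors
#' \eqn{l_x = \sum_j s_{xj}} (age-specific survival),
#' \eqn{m_x} (age-specific fecundity, the \eqn{s_{xj}}-weighted mixture of
#' \eqn{f_{xj}}) and the net maternity \eqn{l_x m_x}. The adult stage is
#' split into female and male adult columns so that
#' \eqn{\sum_x l_x m_x} equals total eggs laid divided by cohort size.
#'
#' Census convention: an individual entering stage j at age a with duration d
#' occupies (x, j) for x = a, ..., a + d - 1; an individual dying upon stage
#' entry occupies no day of that stage.
#'
#' @param cohort A valid \code{\link{cohort}}.
#' @return An object of class \code{life_table}: list with \code{x} (ages,
#'   from 0), \code{stages} (pre-adult stages plus \code{<adult>_F},
#'   \code{<adult>_M}), matrices \code{s_xj} and \code{f_xj}, vectors
#'   \code{lx}, \code{mx}, \code{lxmx}, and counts \code{n}, \code{n_female},
#'   \code{n_male}, \code{total_eggs}.
#' @export
build_life_table <- function(cohort) {
  assert_valid_cohort(cohort)
  tab <- cohort_tableau(cohort)
  lt <- life_table_from_tableau(tab, seq_len(tab$n))
  lt$schema <- cohort$schema
  lt
}

# core life-table computation on a tableau and a resample index vector
life_table_from_tableau <- function(tab, idx) {
  n <- length(idx)
  lifespan <- tab$lifespan[idx]
  A <- max(lifespan)
  S <- tab$S
  stages <- c(tab$stages[-S], paste0(tab$stages[S], "_F"), paste0(tab$stages[S], "_M"))
  s_xj <- matrix(0, A, S + 1L, dimnames = list(seq_len(A) - 1L, stages))
  for (j in seq_len(S - 1L)) {
    s_xj[, j] <- interval_counts(tab$entry[idx, j], tab$dur[idx, j], A)
  }
  sex <- tab$sex[idx]
  fem <- sex == "F"
  s_xj[, S] <- interval_counts(tab$entry[idx[fem], S], tab$dur[idx[fem], S], A)
  s_xj[, S + 1L] <- interval_counts(tab$entry[idx[!fem], S], tab$dur[idx[!fem], S], A)
  eggs_x <- colSums(tab$eggs[idx, , drop = FALSE])[seq_len(A)]
  n_fad <- s_xj[, S]                          # female-adult counts by age
  f_xj <- matrix(0, A, S + 1L, dimnames = list(seq_len(A) - 1L, stages))
  f_xj[, S] <- ifelse(n_fad > 0, eggs_x / n_fad, 0)
  s_xj <- s_xj / n
  lx <- as.vector(rowSums(s_xj))
  lxmx <- eggs_x / n                          # = sum_j s_xj f_xj, conserved
  mx <- ifelse(lx > 0, lxmx / lx, 0)
  n_female <- sum(fem & tab$dur[idx, S] > 0L)
  n_male <- sum(sex == "M" & tab$dur[idx, S] > 0L)
  structure(
    list(x = seq_len(A) - 1L, stages = stages, s_xj = s_xj, f_xj = f_xj,
         lx = lx, mx = mx, lxmx = lxmx, n = n,
         n_female = n_female, n_male = n_male, total_eggs = sum(eggs_x)),
    class = "life_table"
  )
}

#' @export
print.life_table <- function(x, ...) {
  cat("<life_table> n = ", x$n, ", ages 0..", max(x$x),
      ", R0 = ", format(sum(x$lxmx), digits = 4),
      ", GRR = ", format(sum(x$mx), digits = 4), "\n", sep = "")
  invisible(x)
}

# Euler-Lotka residual sum_x exp(-r (x+1)) lxmx - 1, age indexed from 0.
# Monotone decreasing in r.
euler_lotka_residual <- function(r, lxmx) {
  x <- seq_along(lxmx) - 1
  sum(exp(-r * (x + 1)) * lxmx) - 1
}

# bracketed bisection for the Euler-Lotka root on a raw net-maternity vector
euler_lotka_rate <- function(lxmx, tol = 1e-10) {
  R0 <- sum(lxmx)
  if (R0 <= 0) {
    stop(errorCondition("intrinsic rate undefined: the cohort produced no offspring (R0 = 0)",
                        class = c("agestage_degenerate", "error", "condition")))
  }
  g <- function(r) euler_lotka_residual(r, lxmx)
  lo <- -1; hi <- 1
  while (g(lo) < 0) lo <- lo * 2
  while (g(hi) > 0) hi <- hi * 2
  mid <- (lo + hi) / 2
  for (i in seq_len(400L)) {
    gm <- g(mid)
    if (is.finite(gm) && abs(gm) < tol) break
    if (gm > 0) lo <- mid else hi <- mid
    mid <- (lo + hi) / 2
  }
  mid
}

#' Intrinsic rate of increase from the Euler-Lotka equation
#'
#' Solves \eqn{\sum_x e^{-r(x+1)} l_x m_x = 1} (ages indexed from 0) for r by
#' bracketed bisection on an initial bracket [-1, 1] per day, doubled until
#' the residual changes sign. The residual is monotone decreasing in r, so
#' bisection is unconditionally convergent; iteration stops when the residual
#' magnitude falls below \code{tol}.
#'
#' @param lt A \code{\link{life_table}}.
#' @param tol Residual tolerance (default 1e-10).
#' @return The intrinsic rate r (per day). Errors (condition class
#'   \code{agestage_degenerate}) if the cohort produced no offspring.
#' @export
intrinsic_rate <- function(lt, tol = 1e-10) {
  euler_lotka_rate(lt$lxmx, tol = tol)
}

#' Population parameters of a cohort life table
#'
#' Returns the demographic parameters of the age-stage two-sex analysis:
#' intrinsic rate of increase r (Euler-Lotka root), finite rate
#' \eqn{\lambda = e^r}, net reproductive rate \eqn{R_0 = \sum l_x m_x},
#' gross reproductive rate \eqn{GRR = \sum m_x}, mean generation time
#' \eqn{T = \ln(R_0)/r}, and mean total fecundity per female
#' \eqn{F = } total eggs / number of adult females. The point-estimate
#' identity \eqn{R_0 = F N_f / N} holds exactly.
#'
#' @param lt A \code{\link{life_table}}.
#' @param tol Tolerance passed to \code{\link{intrinsic_rate}}.
#' @param on_degenerate \code{"error"} (default) to propagate the
#'   undefined-rate error when \eqn{R_0 = 0}; \code{"na"} to return r,
#'   lambda and T as \code{NA} (used by the bootstrap).
#' @return Object of class \code{population_parameters}: list with r, lambda,
#'   R0, GRR, T (NA with attribute-free flag \code{t_defined = FALSE} when r
#'   = 0), F, N_f, N, and logical flags \code{degenerate}, \code{t_defined}.
#' @export
population_parameters <- function(lt, tol = 1e-10, on_degenerate = c("error", "na")) {
  on_degenerate <- match.arg(on_degenerate)
  R0 <- sum(lt$lxmx)
  GRR <- sum(lt$mx)
  Fm <- if (lt$n_female > 0) lt$total_eggs / lt$n_female else 0
  if (R0 <= 0) {
    if (on_degenerate == "error") {
      stop(errorCondition("population parameters undefined: R0 = 0",
                          class = c("agestage_degenerate", "error", "condition")))
    }
    return(structure(list(r = NA_real_, lambda = NA_real_, R0 = 0, GRR = GRR,
                          T = NA_real_, F = Fm, N_f = lt$n_female, N = lt$n,
                          degenerate = TRUE, t_defined = FALSE),
                     class = "population_parameters"))
  }
  r <- intrinsic_rate(lt, tol = tol)
  t_def <- abs(r) > .Machine$double.eps^0.5
  structure(
    list(r = r, lambda = exp(r), R0 = R0, GRR = GRR,
         T = if (t_def) log(R0) / r else NA_real_,
         F = Fm, N_f = lt$n_female, N = lt$n,
         degenerate = FALSE, t_defined = t_def),
    class = "population_parameters"
  )
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("<population_parameters>\n")
  cat(sprintf("  r      = %.6f /day\n", x$r))
  cat(sprintf("  lambda = %.6f /day\n", x$lambda))
  cat(sprintf("  R0     = %.4f offspring/individual\n", x$R0))
  cat(sprintf("  GRR    = %.4f\n", x$GRR))
  cat(sprintf("  T      = %s days\n", if (x$t_defined) sprintf("%.3f", x$T) else "undefined (r = 0)"))
  cat(sprintf("  F      = %.4f eggs/female (N_f = %d of N = %d)\n", x$F, x$N_f, x$N))
  invisible(x)
}

#' Age-stage life expectancy matrix
#'
#' \eqn{e_{xj}}: expected remaining days alive (counting day x itself) of an
#' individual occupying stage j at age x, estimated as the mean over the
#' cohort members observed in (x, j) of their remaining recorded lifespan.
#' Cells no individual occupied are \code{NA} (empty, not zero).
#'
#' @param cohort A valid \code{\link{cohort}}.
#' @return Matrix of class \code{expectancy_matrix} (ages 0.. by life-table
#'   stage axis).
#' @export
life_expectancy <- function(cohort) {
  assert_valid_cohort(cohort)
  tab <- cohort_tableau(cohort)
  acc <- occupancy_accumulate(tab, function(i, ages) tab$lifespan[i] - ages)
  structure(acc$sum / acc$count, class = "expectancy_matrix")
}

#' Age-stage reproductive value matrix
#'
#' \eqn{v_{xj}}: expected future offspring of an individual in (x, j),
#' discounted at the intrinsic rate r with the same age-0-indexed convention
#' as the Euler-Lotka equation, estimated over occupants of (x, j) as the
#' mean of \eqn{\sum_{i \ge x} e^{-r(i - x)} eggs(i)}. Under this convention
#' the value of a newborn is exactly the finite rate:
#' \eqn{v_{0,first} = \lambda}.
#'
#' @param cohort A valid \code{\link{cohort}}.
#' @param r Discount rate (per day), usually \code{\link{intrinsic_rate}} of
#'   the same cohort; r = 0 gives undiscounted mean future fecundity.
#' @return Matrix of class \code{reproductive_value_matrix}; unoccupied cells
#'   are \code{NA}.
#' @export
reproductive_value <- function(cohort, r) {
  assert_valid_cohort(cohort)
  stopifnot(is.finite(r))
  tab <- cohort_tableau(cohort)
  A <- max(tab$lifespan)
  # backward discounted future-egg sums per individual: D(x) = eggs(x) + e^-r D(x+1)
  disc <- matrix(0, tab$n, A)
  er <- exp(-r)
  disc[, A] <- tab$eggs[, A]
  if (A > 1L) for (x in (A - 1L):1L) disc[, x] <- tab$eggs[, x] + er * disc[, x + 1L]
  acc <- occupancy_accumulate(tab, function(i, ages) disc[i, ages + 1L])
  structure(acc$sum / acc$count, class = "reproductive_value_matrix")
}

# accumulate, over every occupied (x, j) cell, a per-individual age-indexed
# quantity f(i, ages); returns per-cell sums and occupant counts
occupancy_accumulate <- function(tab, value_fun) {
  A <- max(tab$lifespan)
  S <- tab$S
  stages <- c(tab$stages[-S], paste0(tab$stages[S], "_F"), paste0(tab$stages[S], "_M"))
  sm <- matrix(0, A, S + 1L, dimnames = list(seq_len(A) - 1L, stages))
  ct <- matrix(0, A, S + 1L, dimnames = list(seq_len(A) - 1L, stages))
  for (i in seq_len(tab$n)) {
    for (j in seq_len(S)) {
      d <- tab$dur[i, j]
      if (d == 0L) next
      ages <- tab$entry[i, j] + 0:(d - 1L)
      col <- if (j < S) j else if (tab$sex[i] == "F") S else S + 1L
      sm[ages + 1L, col] <- sm[ages + 1L, col] + value_fun(i, ages)
      ct[ages + 1L, col] <- ct[ages + 1L, col] + 1
    }
  }
  ct0 <- ct
  ct0[ct0 == 0] <- NA
  list(sum = sm, count = ct0)
}

#' Export a life table and its parameters to CSV files
#'
#' Writes three files into \code{dir}: \code{<label>_age_stage.csv} (long
#' format: x, stage, s_xj, f_xj), \code{<label>_age_vectors.csv}
#' (x, lx, mx, lxmx) and \code{<label>_parameters.csv}.
#'
#' @param lt A \code{\link{life_table}}.
#' @param params A \code{\link{population_parameters}} object.
#' @param dir Output directory (created if needed).
#' @param label File-name stem.
#' @return Invisibly, the file paths.
#' @export
export_life_table <- function(lt, params, dir, label = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- data.frame(
    x = rep(lt$x, times = length(lt$stages)),
    stage = rep(lt$stages, each = length(lt$x)),
    s_xj = as.vector(lt$s_xj),
    f_xj = as.vector(lt$f_xj)
  )
  p1 <- file.path(dir, paste0(label, "_age_stage.csv"))
  p2 <- file.path(dir, paste0(label, "_age_vectors.csv"))
  p3 <- file.path(dir, paste0(label, "_parameters.csv"))
  utils::write.csv(long, p1, row.names = FALSE)
  utils::write.csv(data.frame(x = lt$x, lx = lt$lx, mx = lt$mx, lxmx = lt$lxmx),
                   p2, row.names = FALSE)
  utils::write.csv(data.frame(
    parameter = c("Intrinsic rate of increase (r)", "Net reproductive rate (R0)",
                  "Finite rate of increase (lambda)", "Gross reproductive rate (GRR)",
                  "Total fecundity (F)", "Mean generation time (T)"),
    value = c(params$r, params$R0, params$lambda, params$GRR, params$F, params$T)
  ), p3, row.names = FALSE)
  invisible(c(p1, p2, p3))
}
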