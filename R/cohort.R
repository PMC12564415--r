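#' Construct a cohort of individual life-history records
#'
#' A cohort holds one row per individual (stage durations in days, stage of
#' death, sex) plus a long-format table of daily egg counts for females.
#' Durations are integer days under a daily-census convention: an individual
#' entering stage j at age a with duration d occupies stage j at integer ages
#' a, ..., a + d - 1. An individual that dies upon entering a stage (occupying
#' no census day of it) is recorded with that stage as \code{death_stage} and
#' an empty duration.
#'
#' @param label Cohort label (e.g. treatment group name).
#' @param schema A \code{\link{stage_schema}}.
#' @param individuals Data frame with columns \code{id}, \code{group},
#'   \code{sex} (one of \code{"F"}, \code{"M"}, \code{"U"}), one
#'   \code{dur_<stage>} column per schema stage (integer days, \code{NA} when
#'   the stage was not occupied), and \code{death_stage}.
#' @param fecundity Data frame with columns \code{id}, \code{adult_day}
#'   (1-based day of adult life) and \code{eggs}. Only female adults may have
#'   rows, one per adult day.
#' @param check If \code{TRUE} (default), stop on any invariant violation.
#' @return An object of class \code{cohort}.
#' @seealso \code{\link{validate_cohort}}, \code{\link{read_cohort}}
#' @export
cohort <- function(label, schema, individuals, fecundity = NULL, check = TRUE) {
  stopifnot(inherits(schema, "stage_schema"))
  if (is.null(fecundity)) {
    fecundity <- data.frame(id = character(), adult_day = integer(), eggs = integer(),
                            stringsAsFactors = FALSE)
  }
  individuals <- as.data.frame(individuals, stringsAsFactors = FALSE)
  fecundity <- as.data.frame(fecundity, stringsAsFactors = FALSE)
  dur_cols <- paste0("dur_", schema$stages)
  need <- c("id", "group", "sex", dur_cols, "death_stage")
  miss <- setdiff(need, names(individuals))
  if (length(miss)) stop("individuals table is missing columns: ", paste(miss, collapse = ", "))
  individuals$id <- as.character(individuals$id)
  fecundity$id <- as.character(fecundity$id)
  obj <- structure(
    list(label = as.character(label), schema = schema,
         individuals = individuals[, need], fecundity = fecundity),
    class = "cohort"
  )
  if (check) assert_valid_cohort(obj)
  obj
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$individuals)
  nf <- sum(x$individuals$sex == "F" & !is.na(x$individuals[[paste0("dur_", x$schema$adult)]]))
  cat("<cohort> ", x$label, ": n = ", n, " (", nf, " adult females), stages ",
      paste(x$schema$stages, collapse = "/"), ", total eggs = ",
      sum(x$fecundity$eggs), "\n", sep = "")
  invisible(x)
}

#' Number of individuals in a cohort
#' @param cohort A \code{\link{cohort}}.
#' @return Integer count.
#' @export
cohort_size <- function(cohort) nrow(cohort$individuals)

#' Validate a cohort against its schema invariants
#'
#' Validation is total: malformed data yields a table of violations, never an
#' error. Rules checked per individual: durations are integers >= 1; occupied
#' stages form a gap-free prefix of the schema; \code{death_stage} is either
#' the last occupied stage or the one after it (death upon entry); the first
#' stage is occupied; sex \code{U} only for individuals that never occupied an
#' adult day; fecundity rows only for adult females, one row per adult day
#' \code{1..dur_adult} with non-negative integer eggs and no duplicates.
#'
#' @param cohort A \code{\link{cohort}} (possibly invalid).
#' @return Data frame with columns \code{id}, \code{rule}, \code{detail};
#'   zero rows iff the cohort is valid.
#' @export
validate_cohort <- function(cohort) {
  sch <- cohort$schema
  ind <- cohort$individuals
  fec <- cohort$fecundity
  v <- list()
  bad <- function(id, rule, detail) {
    v[[length(v) + 1L]] <<- data.frame(id = id, rule = rule, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  if (anyDuplicated(ind$id)) {
    for (d in unique(ind$id[duplicated(ind$id)])) bad(d, "unique_id", "duplicate individual id")
  }
  dur_cols <- paste0("dur_", sch$stages)
  S <- length(sch$stages)
  dur_all <- suppressWarnings(
    matrix(as.numeric(as.matrix(ind[dur_cols])), nrow = nrow(ind)))
  fec_idx <- split(seq_len(nrow(fec)), fec$id)
  for (i in seq_len(nrow(ind))) {
    id <- ind$id[i]
    durs <- dur_all[i, ]
    raw <- ind[i, dur_cols]
    nonint <- which(!is.na(durs) & durs != round(durs))
    for (k in nonint) bad(id, "integer_duration",
                          paste0("dur_", sch$stages[k], " = ", raw[[k]], " is not an integer"))
    zero <- which(!is.na(durs) & durs < 1)
    for (k in zero) bad(id, "positive_duration",
                        paste0("dur_", sch$stages[k], " = ", durs[k], " but durations must be >= 1"))
    filled <- !is.na(durs)
    if (!filled[1L]) bad(id, "first_stage_occupied", "the first stage must be occupied at least one day")
    k_last <- if (any(filled)) max(which(filled)) else 0L
    if (k_last >= 1L && any(!filled[seq_len(k_last)])) {
      bad(id, "stage_gap", "occupied stages must form a gap-free prefix of the schema")
      next
    }
    ds <- ind$death_stage[i]
    if (!ds %in% sch$stages) {
      bad(id, "death_stage_known", paste0("unknown death_stage '", ds, "'"))
      next
    }
    k_death <- match(ds, sch$stages)
    if (k_last >= 1L && !(k_death == k_last || k_death == k_last + 1L)) {
      bad(id, "death_stage_position",
          "death_stage must be the last occupied stage or the stage entered at death")
    }
    adult_days <- durs[S]
    is_adult <- !is.na(adult_days)
    if (!ind$sex[i] %in% c("F", "M", "U")) bad(id, "sex_code", paste0("sex '", ind$sex[i], "'"))
    if (ind$sex[i] == "U" && is_adult) bad(id, "sex_unknown_preadult",
                                           "sex U is only permitted for individuals dying before adulthood")
    rows <- fec[fec_idx[[id]], , drop = FALSE]
    if (nrow(rows)) {
      if (ind$sex[i] != "F") bad(id, "fecundity_female_only",
                                 "daily fecundity recorded for a non-female individual")
      else if (!is_adult) bad(id, "fecundity_adult_only",
                              "daily fecundity recorded but the adult stage was never occupied")
      else {
        if (anyDuplicated(rows$adult_day)) bad(id, "fecundity_day_unique", "duplicate (id, adult_day)")
        if (any(rows$eggs < 0 | rows$eggs != round(rows$eggs), na.rm = TRUE))
          bad(id, "fecundity_nonnegative_integer", "egg counts must be non-negative integers")
        if (!setequal(rows$adult_day, seq_len(adult_days)))
          bad(id, "fecundity_covers_adult_life",
              paste0("fecundity days must be exactly 1..", adult_days))
      }
    } else if (ind$sex[i] == "F" && is_adult) {
      bad(id, "fecundity_covers_adult_life",
          paste0("adult female has no fecundity rows; expected days 1..", adult_days))
    }
  }
  orphans <- setdiff(unique(fec$id), ind$id)
  for (o in orphans) bad(o, "fecundity_known_id", "fecundity row for an id not in the cohort")
  if (length(v)) do.call(rbind, v)
  else data.frame(id = character(), rule = character(), detail = character(),
                  stringsAsFactors = FALSE)
}

assert_valid_cohort <- function(cohort) {
  v <- validate_cohort(cohort)
  if (nrow(v)) {
    msg <- paste0("  [", v$id, "] ", v$rule, ": ", v$detail, collapse = "\n")
    stop("invalid cohort '", cohort$label, "':\n", msg, call. = FALSE)
  }
  invisible(cohort)
}

#' Read a cohort from a pair of CSV files
#'
#' @param individuals_path CSV with columns \code{id}, \code{group},
#'   \code{sex}, \code{dur_<stage>} for each schema stage, \code{death_stage}.
#'   Empty cells mean the stage was never occupied.
#' @param fecundity_path CSV with columns \code{id}, \code{adult_day},
#'   \code{eggs}.
#' @param schema A \code{\link{stage_schema}}.
#' @param label Cohort label; defaults to the first \code{group} value.
#' @return A validated \code{\link{cohort}}.
#' @examples
#' ind <- system.file("extdata", "toy_individuals.csv", package = "agestage")
#' fec <- system.file("extdata", "toy_fecundity.csv", package = "agestage")
#' read_cohort(ind, fec, stage_schema(c("egg", "larva", "adult")))
#' @export
read_cohort <- function(individuals_path, fecundity_path, schema, label = NULL) {
  ind <- utils::read.csv(individuals_path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  fec <- utils::read.csv(fecundity_path, stringsAsFactors = FALSE, check.names = FALSE)
  dur_cols <- grep("^dur_", names(ind), value = TRUE)
  known <- paste0("dur_", schema$stages)
  unknown <- setdiff(dur_cols, known)
  if (length(unknown)) stop("unknown stage column(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(known, dur_cols)
  if (length(miss)) stop("missing stage column(s): ", paste(miss, collapse = ", "))
  for (cc in known) {
    val <- ind[[cc]]
    val[!nzchar(trimws(val))] <- NA
    num <- suppressWarnings(as.numeric(val))
    if (any(!is.na(val) & is.na(num))) stop("non-numeric duration in column ", cc)
    if (any(!is.na(num) & num != round(num))) stop("non-integer duration in column ", cc)
    ind[[cc]] <- as.integer(num)
  }
  if (!nrow(fec)) {
    fec <- data.frame(id = character(), adult_day = integer(), eggs = integer(),
                      stringsAsFactors = FALSE)
  }
  need_f <- c("id", "adult_day", "eggs")
  if (!all(need_f %in% names(fec))) stop("fecundity file must have columns id, adult_day, eggs")
  if (is.null(label)) label <- if (nrow(ind)) ind$group[1L] else "cohort"
  cohort(label, schema, ind, fec[need_f], check = TRUE)
}

#' Write a cohort to a pair of CSV files
#'
#' Inverse of \code{\link{read_cohort}}: writing then reading reproduces the
#' cohort field for field. Unoccupied stages are written as empty cells.
#'
#' @param cohort A valid \code{\link{cohort}}.
#' @param individuals_path,fecundity_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, individuals_path, fecundity_path) {
  utils::write.csv(cohort$individuals, individuals_path, row.names = FALSE, na = "")
  utils::write.csv(cohort$fecundity, fecundity_path, row.names = FALSE, na = "")
  invisible(c(individuals_path, fecundity_path))
}

# --- internal tableau: compact numeric view of a cohort used by the life
# table, bootstrap and projection code. One pass over the data frames, then
# everything downstream is matrix indexing (fast enough to rebuild thousands
# of bootstrap life tables).
#   entry  n x S matrix of stage entry ages (NA if never occupied)
#   dur    n x S matrix of days occupied (0 if never occupied)
#   lifespan  total days alive per individual
#   sex    factor-coded sex per individual
#   eggs   n x A matrix, eggs laid at age x (column x+1)
cohort_tableau <- function(cohort) {
  sch <- cohort$schema
  ind <- cohort$individuals
  n <- nrow(ind)
  S <- length(sch$stages)
  dur <- as.matrix(ind[, paste0("dur_", sch$stages)])
  storage.mode(dur) <- "integer"
  dur[is.na(dur)] <- 0L
  entry <- cbind(0L, t(apply(dur, 1L, cumsum))[, -S, drop = FALSE])
  lifespan <- as.integer(rowSums(dur))
  A <- max(lifespan)
  eggs <- matrix(0, n, A)
  if (nrow(cohort$fecundity)) {
    fi <- match(cohort$fecundity$id, ind$id)
    age <- entry[fi, S] + cohort$fecundity$adult_day - 1L  # age at laying
    eggs[cbind(fi, age + 1L)] <- cohort$fecundity$eggs
  }
  list(n = n, S = S, stages = sch$stages, adult = S,
       entry = entry, dur = dur, lifespan = lifespan,
       sex = ind$sex, eggs = eggs, schema = sch)
}

# occupancy counts per age for one stage, given entries/durations of the
# sampled individuals: interval accumulation via a difference vector
interval_counts <- function(starts, durs, A) {
  keep <- durs > 0L
  if (!any(keep)) return(numeric(A))
  s <- starts[keep] + 1L            # first occupied 1-based age column
  e <- s + durs[keep]               # first column past the interval
  cumsum(tabulate(s, A) - tabulate(e[e <= A], A))
}
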