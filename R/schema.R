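#' Define an ordered developmental stage schema
#'
#' A stage schema is the ordered list of developmental stages an individual
#' can pass through, ending in the adult stage. Durations are recorded per
#' stage in whole days (daily census). Reduced schemas (e.g.
#' \code{c("egg", "larva", "adult")}) are supported for small worked examples.
#'
#' @param stages Character vector of unique, non-empty stage names in
#'   developmental order. The last element is the adult stage.
#' @return An object of class \code{stage_schema} with elements
#'   \code{stages}, \code{adult} (name of the adult stage) and
#'   \code{pre_adult} (all earlier stages).
#' @examples
#' stage_schema(c("egg", "larva", "adult"))
#' stage_schema(c("egg", "L1", "L2", "L3", "L4", "L5", "pupa", "adult"))
#' @export
stage_schema <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) < 2L) stop("a schema needs at least one pre-adult stage and the adult stage")
  if (anyDuplicated(stages)) stop("stage names must be unique")
  if (any(!nzchar(stages))) stop("stage names must be non-empty")
  structure(
    list(
      stages = stages,
      adult = stages[length(stages)],
      pre_adult = stages[-length(stages)]
    ),
    class = "stage_schema"
  )
}

#' @export
print.stage_schema <- function(x, ...) {
  cat("<stage_schema> ", paste(x$stages, collapse = " -> "),
      "  (adult: ", x$adult, ")\n", sep = "")
  invisible(x)
}

# Stage axis used by life tables and projections: the adult stage is split by
# sex so that fecundity attaches to female adults only and sums such as
# sum_j s_xj f_xj conserve total eggs.
lt_stages <- function(schema) {
  c(schema$pre_adult, paste0(schema$adult, "_F"), paste0(schema$adult, "_M"))
}

#' The default eight-stage butterfly schema
#'
#' Egg, five larval instars, pupa and adult: the developmental sequence of
#' \emph{Luehdorfia chinensis} and most papilionid butterflies.
#'
#' @return A \code{\link{stage_schema}}.
#' @export
butterfly_schema <- function() {
  stage_schema(c("egg", "L1", "L2", "L3", "L4", "L5", "pupa", "adult"))
}
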