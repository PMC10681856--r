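#' Mean distance to the nearest target region
#'
#' The arithmetic mean of [nearest_distance()] over the regions of `a`;
#' zero iff every `a` region overlaps some `b` region. Query regions on
#' chromosomes with no target region are excluded with a warning.
#'
#' @param a,b Region-set tibbles on the same genome; `b` non-empty.
#' @inheritParams count_overlaps
#' @return A non-negative number.
#' @export
mean_distance <- function(a, b, genome = NULL) {
  d <- nearest_distance(a, b, genome = genome)
  if (anyNA(d)) {
    warn(paste0(sum(is.na(d)), " query region(s) lie on chromosomes with no ",
                "target region and were excluded from the mean distance."))
  }
  mean(d, na.rm = TRUE)
}

#' Evaluate an association statistic between two region sets
#'
#' Dispatches to a registered evaluation function by name. Built-ins:
#' `num_overlaps` (count-once overlaps, the default statistic),
#' `num_overlaps_pairs` (all overlapping pairs) and `mean_distance`.
#'
#' @param name Registered evaluation-function name.
#' @param a,b Region-set tibbles.
#' @param ... Passed to the evaluation function.
#' @return A finite number (possibly `NaN` for degenerate input).
#' @export
evaluate_association <- function(name, a, b, ...) {
  get_evaluation(name)$fn(a, b, ...)
}

#' Register a custom evaluation function
#'
#' @param name New evaluation name; existing names cannot be overwritten.
#' @param fn `function(a, b)` returning a single number.
#' @param higher_is_associated Direction flag: `TRUE` if larger values mean
#'   stronger association (like overlap counts), `FALSE` if smaller values do
#'   (like distances). Permutation tests use it to report normalized Z-scores
#'   whose positive sign always means "more associated than expected".
#' @return `name`, invisibly.
#' @export
register_evaluation <- function(name, fn, higher_is_associated = TRUE) {
  if (name %in% names(.cw_registry$eval)) {
    abort(paste0("Evaluation function '", name, "' is already registered."))
  }
  stopifnot(is.function(fn))
  .cw_registry$eval[[name]] <- list(fn = fn,
                                    higher_is_associated = higher_is_associated)
  invisible(name)
}

#' @rdname list_randomizations
#' @export
list_evaluations <- function() names(.cw_registry$eval)

get_evaluation <- function(name) {
  ev <- .cw_registry$eval[[name]]
  if (is.null(ev)) {
    abort(paste0("Unknown evaluation function '", name, "'. Available: ",
                 paste(list_evaluations(), collapse = ", "), "."))
  }
  ev
}
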