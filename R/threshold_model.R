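#' Classify detection outcomes from the fold-change test
#'
#' A gene is a failure (F) when the fold-change test reported zero for it,
#' and a success (S) otherwise. The fluorescence attached to each outcome
#' is the gene's mean intensity in the condition under analysis; it is the
#' variable the threshold interval is estimated on.
#'
#' @param fold_changes data.frame with columns `gene_id`, `fc` (e.g. from
#'   [fold_change()]).
#' @param signals Per-gene signals for the condition under analysis
#'   ([aggregate_replicates()] output); every gene in `fold_changes` must
#'   be present.
#' @return data.frame with columns `gene_id`, `outcome` (`"S"`/`"F"`),
#'   `fluorescence`.
#' @export
classify_outcomes <- function(fold_changes, signals) {
  m <- match(fold_changes$gene_id, signals$gene_id)
  if (anyNA(m)) {
    stop("no signal for gene(s): ",
         paste(fold_changes$gene_id[is.na(m)], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    gene_id = fold_changes$gene_id,
    outcome = ifelse(fold_changes$fc == 0, "F", "S"),
    fluorescence = signals$mean_intensity[m],
    stringsAsFactors = FALSE
  )
}

#' Estimate the threshold interval for a condition
#'
#' The operative fluorescence threshold theta separating failures from
#' successes is bracketed by the interval (max fluorescence among failures,
#' min fluorescence among successes). The classes are perfectly separated
#' exactly when the lower endpoint is strictly below the upper endpoint;
#' in that case every cutpoint in the interval classifies the data without
#' error under the rule "success iff X > theta".
#'
#' @param outcomes Output of [classify_outcomes()]; must contain at least
#'   one success and one failure.
#' @param condition_id Identifier recorded in the result.
#' @return data.frame (one row) with columns `condition_id`, `lower`,
#'   `upper`, `separated`.
#' @export
estimate_threshold <- function(outcomes, condition_id = "condition") {
  f <- outcomes$fluorescence[outcomes$outcome == "F"]
  s <- outcomes$fluorescence[outcomes$outcome == "S"]
  if (length(f) == 0L || length(s) == 0L) {
    stop("threshold undefined: single-class data", call. = FALSE)
  }
  lower <- max(f)
  upper <- min(s)
  data.frame(condition_id = condition_id, lower = lower, upper = upper,
             separated = lower < upper, stringsAsFactors = FALSE)
}

#' Apply a threshold interval to new fluorescence values
#'
#' Classifies fluorescence by the rule "success iff X > theta", with theta
#' taken as the midpoint of a separated threshold interval. The interval
#' endpoints themselves are always reported alongside; the midpoint is one
#' deterministic representative of the admissible cutpoints.
#'
#' @param x Numeric vector of fluorescence values.
#' @param interval One-row result of [estimate_threshold()] with
#'   `separated = TRUE`.
#' @return Character vector of `"S"`/`"F"`, same length as `x`.
#' @export
apply_threshold <- function(x, interval) {
  if (!isTRUE(interval$separated[1L])) {
    stop("threshold interval is not separated; no admissible cutpoint",
         call. = FALSE)
  }
  theta <- (interval$lower[1L] + interval$upper[1L]) / 2
  ifelse(x > theta, "S", "F")
}
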