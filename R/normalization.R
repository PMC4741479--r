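#' Aggregate triplicate spots into per-gene signals
#'
#' Collapses the replicate spots of each gene to its arithmetic mean and
#' sample standard deviation (n - 1 denominator; 0 when a gene has a single
#' spot) in the selected fluorescence channel. A gene is flagged `detected`
#' when its mean exceeds the detection floor; [qc_negative_controls()] can
#' additionally clear the flag for genes at or below the array background.
#'
#' @param condition An [array_condition()].
#' @param channel `"F635"` (default) or `"F532"`.
#' @param detection_floor Absolute intensity floor (a.u.); a gene whose mean
#'   does not exceed it is marked undetected. Default 0.
#' @return data.frame with columns `gene_id`, `control_class`,
#'   `mean_intensity`, `sd_intensity`, `n_replicates`, `detected`.
#' @export
aggregate_replicates <- function(condition, channel = c("F635", "F532"),
                                 detection_floor = 0) {
  stopifnot(inherits(condition, "array_condition"))
  channel <- match.arg(channel)
  s <- condition$spots
  if (nrow(s) == 0L) stop("condition has no spots", call. = FALSE)
  x <- if (channel == "F635") s$signal_f635 else s$signal_f532
  ids <- unique(s$gene_id)
  idx <- split(seq_len(nrow(s)), factor(s$gene_id, levels = ids))
  mu <- vapply(idx, function(i) mean(x[i]), numeric(1))
  sdv <- vapply(idx, function(i) if (length(i) > 1L) stats::sd(x[i]) else 0,
                numeric(1))
  n <- vapply(idx, length, integer(1))
  cc <- vapply(idx, function(i) s$control_class[i[1L]], character(1))
  data.frame(
    gene_id = ids, control_class = cc,
    mean_intensity = unname(mu), sd_intensity = unname(sdv),
    n_replicates = unname(n),
    detected = unname(mu > detection_floor),
    stringsAsFactors = FALSE
  )
}

#' QC against negative-control probes
#'
#' The array background is estimated as the mean of the negative-control
#' gene means (bacterial spike sequences such as gnd and fixB). Probe genes
#' whose mean intensity does not exceed the background are flagged and
#' marked undetected in the returned signal table.
#'
#' @param signals Output of [aggregate_replicates()].
#' @return list with `background` (a.u.; `NA` when no negative controls are
#'   present, with a warning), `flagged` (character vector of probe gene
#'   ids at or below background) and `signals` (the input with `detected`
#'   cleared for flagged genes).
#' @export
qc_negative_controls <- function(signals) {
  neg <- signals$control_class == "negative_control"
  if (!any(neg)) {
    warning("no negative controls present; background QC skipped",
            call. = FALSE)
    return(list(background = NA_real_, flagged = character(0),
                signals = signals))
  }
  background <- mean(signals$mean_intensity[neg])
  flag <- signals$control_class == "probe" &
    signals$mean_intensity <= background
  signals$detected[flag] <- FALSE
  list(background = background,
       flagged = signals$gene_id[flag],
       signals = signals)
}

#' Positive-control ratio normalization
#'
#' Each gene's normalized expression is its mean intensity divided by the
#' mean of the positive-control (housekeeping, e.g. U6 and 5S rRNA) gene
#' means on the same array. Normalization is per condition; no cross-array
#' adjustment is applied.
#'
#' @param signals Output of [aggregate_replicates()] (optionally passed
#'   through [qc_negative_controls()]).
#' @param condition_ref Identifier recorded in the output, e.g.
#'   `"GM0536_IR"`.
#' @return data.frame with columns `gene_id`, `control_class`, `value`
#'   (the normalized ratio), `mean_intensity`, `sd_intensity`, `detected`,
#'   `condition_ref`.
#' @export
normalize_signals <- function(signals, condition_ref = "condition") {
  pos <- signals$control_class == "positive_control"
  if (!any(pos)) {
    stop("no positive-control genes: normalization undefined", call. = FALSE)
  }
  denom <- mean(signals$mean_intensity[pos])
  if (!is.finite(denom) || denom <= 0) {
    stop("positive-control mean intensity is zero: normalization undefined",
         call. = FALSE)
  }
  data.frame(
    gene_id = signals$gene_id, control_class = signals$control_class,
    value = signals$mean_intensity / denom,
    mean_intensity = signals$mean_intensity,
    sd_intensity = signals$sd_intensity,
    detected = signals$detected,
    condition_ref = condition_ref,
    stringsAsFactors = FALSE
  )
}

#' Per-gene fold change between two normalized conditions
#'
#' The fold change of a gene is the ratio of its normalized expression in
#' the treated condition to the control condition. When the gene is
#' undetected on either array the fold change and its SD are reported as 0,
#' the convention used for absent signal in screen tables. The fold-change
#' SD is first-order (delta-method) propagation of the replicate-level SDs:
#' `sd_fc = fc * sqrt((sd_t/mean_t)^2 + (sd_c/mean_c)^2)`.
#'
#' @param treated,control Outputs of [normalize_signals()] over the same
#'   gene universe.
#' @return data.frame with columns `gene_id`, `control_class`, `fc`, `sd`,
#'   `detected_treated`, `detected_control`.
#' @export
fold_change <- function(treated, control) {
  only_t <- setdiff(treated$gene_id, control$gene_id)
  only_c <- setdiff(control$gene_id, treated$gene_id)
  if (length(only_t) + length(only_c) > 0L) {
    stop("gene universe mismatch between conditions; asymmetric genes: ",
         paste(c(only_t, only_c), collapse = ", "), call. = FALSE)
  }
  ctrl <- control[match(treated$gene_id, control$gene_id), ]
  both <- treated$detected & ctrl$detected
  fc <- ifelse(both, treated$value / ctrl$value, 0)
  rel_t <- ifelse(both, treated$sd_intensity / treated$mean_intensity, 0)
  rel_c <- ifelse(both, ctrl$sd_intensity / ctrl$mean_intensity, 0)
  sd_fc <- ifelse(both, fc * sqrt(rel_t^2 + rel_c^2), 0)
  data.frame(
    gene_id = treated$gene_id, control_class = treated$control_class,
    fc = fc, sd = sd_fc,
    detected_treated = treated$detected, detected_control = ctrl$detected,
    stringsAsFactors = FALSE
  )
}
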