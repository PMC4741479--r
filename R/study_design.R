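#' Correlation-based sample size via the Fisher z-transform
#'
#' Number of subjects per condition needed to detect an expected
#' correlation `r`: `n = z_sum_sq / C(r)^2 + 3`, where
#' `C(r) = atanh(r) = 1/2 * ln((1 + r) / (1 - r))` is the Fisher
#' z-transform and `z_sum_sq` is the squared sum of the standard-normal
#' quantiles for the chosen error rates (`(z_alpha + z_beta)^2`; default
#' 8.52, i.e. about 2.92 squared). The raw result is monotone decreasing
#' in `r` and tends to 3 as `r` approaches 1.
#'
#' @param r Expected correlation, strictly between 0 and 1.
#' @param z_sum_sq Squared quantile sum (default 8.52).
#' @param rounding `"ceil"` (default; conservative) or `"nearest"` for the
#'   integer requirement.
#' @return list with `r`, `z_sum_sq`, `fisher_z`, `n_raw`, `n_required`.
#' @export
sample_size <- function(r, z_sum_sq = 8.52, rounding = c("ceil", "nearest")) {
  rounding <- match.arg(rounding)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r >= 1) {
    stop("correlation must be in (0,1) exclusive", call. = FALSE)
  }
  stopifnot(z_sum_sq > 0)
  cz <- atanh(r)
  n_raw <- z_sum_sq / cz^2 + 3
  n_required <- if (rounding == "ceil") ceiling(n_raw) else round(n_raw)
  list(r = r, z_sum_sq = z_sum_sq, fisher_z = cz,
       n_raw = n_raw, n_required = as.integer(n_required))
}
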