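#' Call one miRNA's radiation response from fold change and SD
#'
#' Formalizes the two-standard-deviation significance rule on the linear
#' fold-change scale: a miRNA is `up` when `fc - 1 >= sd_multiplier * sd`
#' (and `fc > 1`), `down` when `1 - fc >= sd_multiplier * sd` (and
#' `fc < 1`), `undetected` when both fold change and SD are exactly zero
#' (the screen-table convention for absent signal), and `unchanged`
#' otherwise. Ties with the band edge count as significant. A zero SD with
#' a nonzero effect is called significant: any effect exceeds a zero-width
#' noise band.
#'
#' @param fc Non-negative fold change(s).
#' @param sd Non-negative fold-change SD(s).
#' @param sd_multiplier Width of the significance band in SD units
#'   (default 2).
#' @return data.frame with columns `call`
#'   (`up`/`down`/`unchanged`/`undetected`), `effect` (`fc - 1`; `NA` for
#'   undetected) and `threshold_used` (`sd_multiplier * sd`).
#' @export
call_hit <- function(fc, sd, sd_multiplier = 2) {
  if (any(fc < 0) || any(sd < 0) || sd_multiplier <= 0) {
    stop("fc and sd must be non-negative and sd_multiplier positive",
         call. = FALSE)
  }
  stopifnot(length(fc) == length(sd))
  undet <- fc == 0 & sd == 0
  band <- sd_multiplier * sd
  up <- !undet & fc > 1 & (fc - 1) >= band
  down <- !undet & fc < 1 & (1 - fc) >= band
  call <- rep("unchanged", length(fc))
  call[up] <- "up"
  call[down] <- "down"
  call[undet] <- "undetected"
  data.frame(call = call,
             effect = ifelse(undet, NA_real_, fc - 1),
             threshold_used = band)
}

#' Screen a fold-change table for significantly altered miRNAs
#'
#' Applies [call_hit()] to every record of a screen table for one genotype
#' and tallies the calls. The tally is deterministic given the table and
#' the multiplier.
#'
#' @param records Screen table in [read_screen_table()] layout.
#' @param genotype `"ATM_null"` or `"ATM_wt"`: which fold-change/SD column
#'   pair to screen.
#' @param sd_multiplier Significance band width in SD units (default 2).
#' @return list with `calls` (data.frame: `mirna_id`, `genotype`, `fc`,
#'   `sd`, `call`, `effect`, `threshold_used`) and `summary` (named vector
#'   `n_up`, `n_down`, `n_altered`, `n_unchanged`, `n_undetected`).
#' @export
screen_hits <- function(records, genotype = c("ATM_null", "ATM_wt"),
                        sd_multiplier = 2) {
  genotype <- match.arg(genotype)
  if (nrow(records) == 0L) stop("empty screen table", call. = FALSE)
  fc <- if (genotype == "ATM_wt") records$fc_wt else records$fc_null
  sd <- if (genotype == "ATM_wt") records$sd_wt else records$sd_null
  h <- call_hit(fc, sd, sd_multiplier)
  calls <- data.frame(mirna_id = records$mirna_id, genotype = genotype,
                      fc = fc, sd = sd, h, stringsAsFactors = FALSE)
  n_up <- sum(calls$call == "up")
  n_down <- sum(calls$call == "down")
  list(
    calls = calls,
    summary = c(n_up = n_up, n_down = n_down, n_altered = n_up + n_down,
                n_unchanged = sum(calls$call == "unchanged"),
                n_undetected = sum(calls$call == "undetected"))
  )
}

#' Write a hit-call table
#'
#' Serializes the `calls` component of [screen_hits()] as TSV with a
#' trailing `# summary:` comment line.
#'
#' @param hits Result of [screen_hits()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  out <- hits$calls
  for (cn in c("fc", "sd", "effect", "threshold_used")) {
    out[[cn]] <- .fmt_num(out[[cn]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("# summary: ",
                    paste(names(hits$summary), hits$summary,
                          sep = "=", collapse = " ")), con)
  invisible(path)
}
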