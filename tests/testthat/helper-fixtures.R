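# build an array_condition from a named list of per-gene replicate
# intensities; control class is inferred from the gene name prefix
make_condition <- function(genes, cell_line = "GM0536", genotype = "ATM_wt",
                           treatment = "mock", dose = 0) {
  rows <- list()
  pos <- 0L
  for (g in names(genes)) {
    x <- genes[[g]]
    cc <- if (startsWith(g, "pos")) "positive_control"
          else if (startsWith(g, "neg")) "negative_control" else "probe"
    for (i in seq_along(x)) {
      pos <- pos + 1L
      rows[[pos]] <- data.frame(
        gene_id = g, block = 1L, row = pos, col = 1L, replicate_index = i,
        signal_f635 = x[i], signal_f532 = x[i], control_class = cc,
        stringsAsFactors = FALSE)
    }
  }
  array_condition(cell_line, genotype, treatment, dose, do.call(rbind, rows))
}

# minimal three-group cohort from per-group expression lists:
# values[[group]][[mirna]] is a numeric vector (one entry per patient)
make_cohort <- function(values, atm = NULL) {
  rows <- list()
  k <- 0L
  for (grp in names(values)) {
    v <- values[[grp]]
    n <- length(v[[1L]])
    for (i in seq_len(n)) {
      k <- k + 1L
      row <- data.frame(patient_id = sprintf("%s_%d", grp, i), group = grp,
                        stringsAsFactors = FALSE, check.names = FALSE)
      if (!is.null(atm)) row$atm_protein <- atm[[grp]][i]
      for (m in names(v)) row[[m]] <- v[[m]][i]
      rows[[k]] <- row
    }
  }
  do.call(rbind, rows)
}

# closed-form Welch two-sided t-test p-value (independent oracle)
welch_p_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a); vb <- var(b)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * pt(-abs(t), df)
}
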