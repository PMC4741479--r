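.cohort_mirnas <- function(cohort) {
  setdiff(names(cohort), c("patient_id", "group", "atm_protein"))
}

.check_groups <- function(cohort, needed = PATIENT_GROUPS) {
  missing_grp <- setdiff(needed, unique(cohort$group))
  if (length(missing_grp) > 0L) {
    stop("cohort is missing patient group(s): ",
         paste(missing_grp, collapse = ", "), call. = FALSE)
  }
}

# Welch (or pooled) two-sided t-test p-value that degrades gracefully on
# zero-variance input instead of erroring like stats::t.test
.safe_t_p <- function(a, b, var_equal = FALSE) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  }
  stats::t.test(a, b, var.equal = var_equal)$p.value
}

#' Per-miRNA group means, ratios vs untreated, and responder/progressor test
#'
#' For each miRNA the arithmetic mean expression is computed per patient
#' group, and the responder and progressor means are expressed as ratios to
#' the untreated mean (a pseudocount is added to both numerator and
#' denominator means, so ratios stay defined at zero expression).
#' Responders and progressors are compared with a two-sided Welch t-test,
#' by default on `log2(x + pseudo)`-transformed expression.
#'
#' @param cohort Cohort data.frame ([read_cohort_table()] layout) with all
#'   three groups present.
#' @param pseudo Pseudocount added to group means before forming ratios and
#'   to expression before the log transform (default 0.5).
#' @param log_transform Test on `log2(x + pseudo)` scale (default `TRUE`)
#'   or on the raw scale.
#' @param var_equal Use the pooled-variance Student t-test instead of
#'   Welch (default `FALSE`).
#' @return data.frame with one row per miRNA: `mirna_id`,
#'   `ratio_responder`, `ratio_progressor`, `p_value`, `n_responder`,
#'   `n_progressor`, `n_untreated`, `undefined_ratio` (flags a zero
#'   untreated mean at `pseudo = 0`).
#' @export
group_ratios <- function(cohort, pseudo = 0.5, log_transform = TRUE,
                         var_equal = FALSE) {
  stopifnot(pseudo >= 0)
  .check_groups(cohort)
  mirnas <- .cohort_mirnas(cohort)
  if (length(mirnas) == 0L) stop("cohort has no miRNA columns", call. = FALSE)
  is_r <- cohort$group == "responder"
  is_p <- cohort$group == "progressor"
  is_u <- cohort$group == "untreated"
  res <- lapply(mirnas, function(m) {
    x <- cohort[[m]]
    m_r <- mean(x[is_r]); m_p <- mean(x[is_p]); m_u <- mean(x[is_u])
    denom <- m_u + pseudo
    undef <- denom == 0
    a <- x[is_r]; b <- x[is_p]
    if (log_transform) { a <- log2(a + pseudo); b <- log2(b + pseudo) }
    data.frame(
      mirna_id = m,
      ratio_responder = if (undef) NA_real_ else (m_r + pseudo) / denom,
      ratio_progressor = if (undef) NA_real_ else (m_p + pseudo) / denom,
      p_value = .safe_t_p(a, b, var_equal),
      n_responder = sum(is_r), n_progressor = sum(is_p),
      n_untreated = sum(is_u),
      undefined_ratio = undef,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, res)
}

.invitro_directions <- function(ratios, screen, reference) {
  if (is.data.frame(reference)) {
    stopifnot(all(c("mirna_id", "direction") %in% names(reference)))
    bad <- setdiff(unique(reference$direction), c("up", "down"))
    if (length(bad) > 0L) {
      stop("direction table contains invalid direction(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    dir <- reference$direction[match(ratios$mirna_id, reference$mirna_id)]
    dir[is.na(dir)] <- "unchanged"
    return(dir)
  }
  if (!reference %in% GENOTYPES) {
    stop("unknown reference genotype '", reference,
         "'; use ATM_wt, ATM_null or an explicit direction table",
         call. = FALSE)
  }
  h <- screen_hits(screen, genotype = reference)$calls
  dir <- h$call[match(ratios$mirna_id, h$mirna_id)]
  dir
}

#' Directional-concordance screen against the in vitro reference
#'
#' A miRNA joins the signature when three clauses hold together: (i) its
#' responder and progressor expression move in opposite, non-flat
#' directions relative to the untreated group (the inverse-pattern
#' requirement), (ii) the responder direction matches the in vitro
#' post-irradiation direction of the reference, and (iii) the
#' responder-vs-progressor test is significant at `alpha`. Direction is
#' derived from the log2 ratio with a dead band of `epsilon` around zero.
#'
#' @param ratios Output of [group_ratios()].
#' @param screen Screen table ([read_screen_table()] layout); every ratio
#'   miRNA must appear in it, others are dropped with a warning.
#' @param reference `"ATM_wt"`, `"ATM_null"` (directions derived from the
#'   screen's hit calls for that genotype), or an explicit direction table
#'   (data.frame `mirna_id`, `direction` in up/down), e.g.
#'   [signature_directions()]. miRNAs absent from an explicit table are
#'   treated as having no reference direction and cannot be concordant.
#' @param epsilon Minimum `|log2 ratio|` for a non-flat direction
#'   (default 0.25, about a 1.19-fold change).
#' @param alpha Significance level for the responder-vs-progressor p-value
#'   (default 0.05).
#' @param p_adjust Multiple-testing adjustment applied to the p-values
#'   before the `alpha` cut: `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return data.frame with one row per screened miRNA: `mirna_id`,
#'   `ratio_responder`, `ratio_progressor`, `direction_responder`,
#'   `direction_progressor`, `invitro_direction`, `p_value`, `concordant`.
#'   The signature is the `concordant` subset.
#' @export
concordance_screen <- function(ratios, screen, reference = "ATM_null",
                               epsilon = 0.25, alpha = 0.05,
                               p_adjust = c("none", "bonferroni", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(epsilon >= 0, alpha >= 0, alpha <= 1)
  unknown <- setdiff(ratios$mirna_id, screen$mirna_id)
  if (length(unknown) > 0L) {
    warning("miRNA(s) absent from the screen table ignored: ",
            paste(unknown, collapse = ", "), call. = FALSE)
    ratios <- ratios[!ratios$mirna_id %in% unknown, , drop = FALSE]
  }
  if (nrow(ratios) == 0L) stop("no screened miRNAs to assess", call. = FALSE)
  direction_of <- function(r) {
    ifelse(is.na(r), "flat",
           ifelse(log2(r) > epsilon, "up",
                  ifelse(log2(r) < -epsilon, "down", "flat")))
  }
  dir_r <- direction_of(ratios$ratio_responder)
  dir_p <- direction_of(ratios$ratio_progressor)
  invitro <- .invitro_directions(ratios, screen, reference)
  p <- stats::p.adjust(ratios$p_value, method = p_adjust)
  opposite <- (dir_r == "up" & dir_p == "down") |
    (dir_r == "down" & dir_p == "up")
  concordant <- opposite & invitro %in% c("up", "down") &
    dir_r == invitro & p <= alpha
  data.frame(
    mirna_id = ratios$mirna_id,
    ratio_responder = ratios$ratio_responder,
    ratio_progressor = ratios$ratio_progressor,
    direction_responder = dir_r,
    direction_progressor = dir_p,
    invitro_direction = invitro,
    p_value = p,
    concordant = concordant,
    stringsAsFactors = FALSE
  )
}

#' Compare ATM protein (RPPA) levels between response groups
#'
#' Two-sided Welch t-test of the RPPA-normalized ATM level between
#' responders (radiosensitive) and progressors (radioresistant), with the
#' direction of the difference.
#'
#' @param cohort Cohort data.frame with an `atm_protein` column; at least
#'   two non-missing values per compared group.
#' @return list with `mean_responder`, `mean_progressor`, `p_value`,
#'   `direction` (sign of responder minus progressor mean), `n_responder`,
#'   `n_progressor`.
#' @export
atm_group_comparison <- function(cohort) {
  if (!"atm_protein" %in% names(cohort)) {
    stop("cohort has no atm_protein column", call. = FALSE)
  }
  a <- cohort$atm_protein[cohort$group == "responder"]
  b <- cohort$atm_protein[cohort$group == "progressor"]
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least 2 ATM protein values per compared group",
         call. = FALSE)
  }
  list(mean_responder = mean(a), mean_progressor = mean(b),
       p_value = .safe_t_p(a, b),
       direction = sign(mean(a) - mean(b)),
       n_responder = length(a), n_progressor = length(b))
}

#' Relative-expression matrix for heatmap-style display
#'
#' Per-patient expression of the irradiated groups relative to the
#' untreated group mean of the same miRNA (a pseudocount stabilizes zero
#' means), the matrix behind a responder/progressor heatmap.
#'
#' @param cohort Cohort data.frame.
#' @param mirnas miRNA ids to include (default: all cohort miRNAs).
#' @param pseudo Pseudocount (default 0.5).
#' @return Numeric matrix, rows = miRNAs, columns = responder and
#'   progressor patient ids.
#' @export
relative_expression_matrix <- function(cohort, mirnas = NULL, pseudo = 0.5) {
  .check_groups(cohort)
  if (is.null(mirnas)) mirnas <- .cohort_mirnas(cohort)
  treated <- cohort[cohort$group %in% c("responder", "progressor"), ,
                    drop = FALSE]
  is_u <- cohort$group == "untreated"
  mat <- sapply(mirnas, function(m) {
    (treated[[m]] + pseudo) / (mean(cohort[[m]][is_u]) + pseudo)
  })
  mat <- matrix(mat, nrow = nrow(treated),
                dimnames = list(treated$patient_id, mirnas))
  t(mat)
}
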