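# run expr under a local RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards so generators never perturb user RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# multiplicative lognormal noise with unit mean and coefficient of
# variation cv; degenerates to exactly 1 at cv = 0
.lnorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for a synthetic array experiment
#'
#' Defines a two-cell-line (ATM-proficient GM0536-like and ATM-deficient
#' GM1526-like), mock-vs-6-Gy miRNA array simulation: lognormal true gene
#' abundances, triplicate spots with multiplicative lognormal spot noise,
#' housekeeping positive controls and bacterial-sequence negative controls
#' at fixed levels, and planted multiplicative irradiation effects per
#' genotype (an effect of 0 encodes irradiation-induced dropout).
#'
#' @param seed Integer RNG seed.
#' @param mirnas Character vector of miRNA ids (default 24 synthetic ids).
#' @param n_positive_controls Number of housekeeping control genes (>= 2).
#' @param n_negative_controls Number of background control genes.
#' @param baseline_log_mean,baseline_log_sd Natural-log parameters of the
#'   lognormal true abundance of a gene (a.u.).
#' @param spot_cv Coefficient of variation of replicate-spot noise.
#' @param control_level Positive-control true intensity (a.u.).
#' @param background_level Negative-control true intensity (a.u.).
#' @param effects Named list per genotype (`ATM_wt`, `ATM_null`) of named
#'   numeric vectors: multiplicative IR effect per miRNA (default none).
#' @param dropout_rate Probability that a gene is absent (true level 0) in
#'   a given condition, independent per gene and condition.
#' @return list of class `array_sim_config`.
#' @export
array_sim_config <- function(seed = 1L,
                             mirnas = sprintf("hsa-mir-sim-%03d", 1:24),
                             n_positive_controls = 4L,
                             n_negative_controls = 8L,
                             baseline_log_mean = log(800),
                             baseline_log_sd = 0.6,
                             spot_cv = 0.08,
                             control_level = 1500,
                             background_level = 40,
                             effects = list(),
                             dropout_rate = 0) {
  stopifnot(length(mirnas) >= 1L, n_positive_controls >= 2L,
            n_negative_controls >= 0L, spot_cv >= 0,
            control_level > 0, background_level > 0,
            dropout_rate >= 0, dropout_rate <= 1)
  bad_gt <- setdiff(names(effects), GENOTYPES)
  if (length(bad_gt) > 0L) {
    stop("effects keyed by unknown genotype(s): ",
         paste(bad_gt, collapse = ", "), call. = FALSE)
  }
  for (gt in names(effects)) {
    e <- effects[[gt]]
    if (any(e < 0) || is.null(names(e)) ||
        !all(names(e) %in% mirnas)) {
      stop("effects must be named non-negative multipliers over the ",
           "configured miRNAs", call. = FALSE)
    }
  }
  structure(
    list(seed = seed, mirnas = mirnas,
         n_positive_controls = as.integer(n_positive_controls),
         n_negative_controls = as.integer(n_negative_controls),
         baseline_log_mean = baseline_log_mean,
         baseline_log_sd = baseline_log_sd, spot_cv = spot_cv,
         control_level = control_level, background_level = background_level,
         effects = effects, dropout_rate = dropout_rate),
    class = "array_sim_config")
}

.spot_grid <- function(n_spots, per_row = 12L) {
  i <- seq_len(n_spots) - 1L
  data.frame(block = 1L, row = i %/% per_row + 1L, col = i %% per_row + 1L)
}

.one_array <- function(cfg, cell_line, genotype, treatment, dose,
                       true_levels) {
  genes <- c(cfg$mirnas,
             sprintf("pos-ctrl-%02d", seq_len(cfg$n_positive_controls)),
             if (cfg$n_negative_controls > 0L)
               sprintf("neg-ctrl-%02d", seq_len(cfg$n_negative_controls)))
  cc <- c(rep("probe", length(cfg$mirnas)),
          rep("positive_control", cfg$n_positive_controls),
          rep("negative_control", cfg$n_negative_controls))
  levels <- c(true_levels,
              rep(cfg$control_level, cfg$n_positive_controls),
              rep(cfg$background_level, cfg$n_negative_controls))
  n_spots <- 3L * length(genes)
  grid <- .spot_grid(n_spots)
  spots <- data.frame(
    gene_id = rep(genes, each = 3L),
    grid,
    replicate_index = rep(1:3, times = length(genes)),
    stringsAsFactors = FALSE
  )
  lev <- rep(levels, each = 3L)
  spots$signal_f635 <- lev * .lnorm_noise(n_spots, cfg$spot_cv)
  spots$signal_f532 <- lev * .lnorm_noise(n_spots, cfg$spot_cv)
  spots$control_class <- rep(cc, each = 3L)
  array_condition(cell_line, genotype, treatment, dose, spots)
}

#' Simulate a four-condition miRNA array experiment
#'
#' Generates the two cell lines (ATM_wt "GM0536", ATM_null "GM1526"), each
#' mock-treated (0 Gy) and irradiated (6 Gy), with triplicate spots and a
#' ground-truth table of the planted multiplicative effects. Deterministic
#' under the configured seed.
#'
#' @param config An [array_sim_config()].
#' @return list with `conditions` (named list of four [array_condition()]:
#'   `GM0536_mock`, `GM0536_IR`, `GM1526_mock`, `GM1526_IR`) and `truth`
#'   (data.frame `genotype`, `mirna_id`, `effect`, `dropped_mock`,
#'   `dropped_ir`).
#' @export
simulate_array <- function(config) {
  stopifnot(inherits(config, "array_sim_config"))
  .with_seed(config$seed, {
    lines <- data.frame(cell_line = c("GM0536", "GM1526"),
                        genotype = GENOTYPES, stringsAsFactors = FALSE)
    conditions <- list()
    truth <- list()
    for (i in 1:2) {
      gt <- lines$genotype[i]
      base <- stats::rlnorm(length(config$mirnas),
                            meanlog = config$baseline_log_mean,
                            sdlog = config$baseline_log_sd)
      eff <- rep(1, length(config$mirnas))
      names(eff) <- config$mirnas
      planted <- config$effects[[gt]]
      if (!is.null(planted)) eff[names(planted)] <- planted
      drop_mock <- stats::runif(length(base)) < config$dropout_rate
      drop_ir <- stats::runif(length(base)) < config$dropout_rate
      mock_levels <- ifelse(drop_mock, 0, base)
      ir_levels <- ifelse(drop_ir, 0, base * eff)
      conditions[[paste0(lines$cell_line[i], "_mock")]] <-
        .one_array(config, lines$cell_line[i], gt, "mock", 0, mock_levels)
      conditions[[paste0(lines$cell_line[i], "_IR")]] <-
        .one_array(config, lines$cell_line[i], gt, "IR", 6, ir_levels)
      truth[[i]] <- data.frame(genotype = gt, mirna_id = config$mirnas,
                               effect = unname(eff),
                               dropped_mock = drop_mock,
                               dropped_ir = drop_ir,
                               stringsAsFactors = FALSE)
    }
    list(conditions = conditions, truth = do.call(rbind, truth))
  })
}

#' Configuration for a synthetic three-arm patient cohort
#'
#' Emulates the clinical validation cohort: three patient groups
#' (responder = irradiated with complete response, progressor = irradiated
#' with additional tumor event, untreated), per-miRNA lognormal baseline
#' abundance shared across groups, multiplicative planted group effects on
#' chosen miRNAs, patient-level lognormal biological noise, and an
#' RPPA-scale ATM protein level that is shifted in progressors with
#' Gaussian noise.
#'
#' @param seed Integer RNG seed.
#' @param n_per_group Patients per group (default 10, the validation
#'   cohort's group size).
#' @param mirnas Character vector of miRNA ids (default: the packaged
#'   28-miRNA screen fixture's ids).
#' @param baseline_log2_mean,baseline_log2_sd log2-scale parameters of the
#'   per-miRNA baseline abundance (normalized-count scale).
#' @param noise_cv Patient-level lognormal noise CV (default 0.3).
#' @param planted Named list: per miRNA a numeric vector
#'   `c(responder = , progressor = )` of multiplicative effects relative
#'   to the untreated baseline (default none; unlisted miRNAs are null).
#' @param atm_baseline RPPA-normalized ATM baseline (default 0).
#' @param atm_progressor_shift Additive ATM shift in progressors
#'   (default 0.5).
#' @param atm_noise_sd Gaussian SD of patient ATM levels (default 0.2).
#' @return list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(seed = 1L,
                              n_per_group = 10L,
                              mirnas = invitro_screen()$mirna_id,
                              baseline_log2_mean = 8,
                              baseline_log2_sd = 2,
                              noise_cv = 0.3,
                              planted = list(),
                              atm_baseline = 0,
                              atm_progressor_shift = 0.5,
                              atm_noise_sd = 0.2) {
  stopifnot(n_per_group >= 2L, length(mirnas) >= 1L, noise_cv >= 0,
            atm_noise_sd >= 0)
  bad <- setdiff(names(planted), mirnas)
  if (length(bad) > 0L) {
    stop("planted effects for miRNA(s) not in the cohort: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  for (p in planted) {
    if (!all(c("responder", "progressor") %in% names(p)) || any(p <= 0)) {
      stop("each planted entry needs positive 'responder' and 'progressor' ",
           "multipliers", call. = FALSE)
    }
  }
  structure(
    list(seed = seed, n_per_group = as.integer(n_per_group),
         mirnas = mirnas, baseline_log2_mean = baseline_log2_mean,
         baseline_log2_sd = baseline_log2_sd, noise_cv = noise_cv,
         planted = planted, atm_baseline = atm_baseline,
         atm_progressor_shift = atm_progressor_shift,
         atm_noise_sd = atm_noise_sd),
    class = "cohort_sim_config")
}

#' Simulate a three-arm patient cohort with known ground truth
#'
#' Untreated expression is the lognormal per-miRNA baseline times
#' patient-level lognormal noise; responder and progressor expression
#' additionally carry the planted multiplicative group effect. ATM protein
#' is Gaussian around the baseline, shifted in progressors. Deterministic
#' under the configured seed.
#'
#' @param config A [cohort_sim_config()].
#' @return list with `cohort` (data.frame in [read_cohort_table()] layout,
#'   including `atm_protein`) and `truth` (data.frame `mirna_id`,
#'   `mult_responder`, `mult_progressor`, `planted`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  .with_seed(config$seed, {
    n <- config$n_per_group
    groups <- rep(c("responder", "progressor", "untreated"), each = n)
    n_pat <- length(groups)
    cohort <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n_pat)),
      group = groups,
      atm_protein = config$atm_baseline +
        ifelse(groups == "progressor", config$atm_progressor_shift, 0) +
        stats::rnorm(n_pat, 0, config$atm_noise_sd),
      stringsAsFactors = FALSE, check.names = FALSE
    )
    mult_r <- mult_p <- rep(1, length(config$mirnas))
    names(mult_r) <- names(mult_p) <- config$mirnas
    for (m in names(config$planted)) {
      mult_r[m] <- config$planted[[m]]["responder"]
      mult_p[m] <- config$planted[[m]]["progressor"]
    }
    baselines <- 2^stats::rnorm(length(config$mirnas),
                                config$baseline_log2_mean,
                                config$baseline_log2_sd)
    for (j in seq_along(config$mirnas)) {
      m <- config$mirnas[j]
      mult <- ifelse(groups == "responder", mult_r[j],
                     ifelse(groups == "progressor", mult_p[j], 1))
      cohort[[m]] <- baselines[j] * mult * .lnorm_noise(n_pat, config$noise_cv)
    }
    truth <- data.frame(mirna_id = config$mirnas,
                        mult_responder = unname(mult_r),
                        mult_progressor = unname(mult_p),
                        planted = config$mirnas %in% names(config$planted),
                        stringsAsFactors = FALSE)
    list(cohort = cohort, truth = truth)
  })
}

#' Cohort configuration planting the five-miRNA signature pattern
#'
#' Convenience wrapper around [cohort_sim_config()] that plants the
#' signature expression pattern over the packaged 28-miRNA screen:
#' direction-table "up" members get a 2-fold increase in responders and a
#' 2-fold decrease in progressors, "down" members the inverse, and all
#' other screen miRNAs stay null.
#'
#' @param seed Integer RNG seed.
#' @param effect Fold effect planted in the concordant direction
#'   (default 2).
#' @param ... Further arguments passed to [cohort_sim_config()].
#' @return list of class `cohort_sim_config`.
#' @export
signature_pattern_config <- function(seed = 1L, effect = 2, ...) {
  stopifnot(effect > 0)
  dirs <- signature_directions()
  planted <- lapply(seq_len(nrow(dirs)), function(i) {
    if (dirs$direction[i] == "up") {
      c(responder = effect, progressor = 1 / effect)
    } else {
      c(responder = 1 / effect, progressor = effect)
    }
  })
  names(planted) <- dirs$mirna_id
  cohort_sim_config(seed = seed, planted = planted, ...)
}
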