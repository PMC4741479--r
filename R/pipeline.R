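#' Pipeline configuration with documented defaults
#'
#' Collects every tunable of the screen and signature stages in one place.
#' Defaults: channel F635, detection floor 0 a.u. (the negative-control
#' background still applies), significance band 2 SD, packaged explicit
#' direction table as the in vitro reference, alpha 0.05, epsilon 0.25
#' (log2 dead band), pseudocount 0.5, log2-scale Welch t-test,
#' conservative `ceil` rounding for sample sizes.
#'
#' @param channel Fluorescence channel analysed, `"F635"` or `"F532"`.
#' @param detection_floor Absolute detection floor (a.u.).
#' @param sd_multiplier Hit-calling band width in SD units.
#' @param reference In vitro reference for [concordance_screen()]:
#'   `"direction_table"` (packaged table), `"ATM_null"` or `"ATM_wt"`.
#' @param alpha Significance level.
#' @param epsilon Minimum `|log2 ratio|` for a non-flat direction.
#' @param pseudo Pseudocount for ratios and log transforms.
#' @param log_transform Test expression on the log2 scale.
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param p_adjust Multiple-testing adjustment (`"none"`, `"bonferroni"`,
#'   `"BH"`).
#' @param rounding Sample-size rounding rule.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(channel = "F635", detection_floor = 0,
                            sd_multiplier = 2,
                            reference = "direction_table",
                            alpha = 0.05, epsilon = 0.25, pseudo = 0.5,
                            log_transform = TRUE, var_equal = FALSE,
                            p_adjust = "none", rounding = "ceil") {
  structure(
    list(channel = match.arg(channel, c("F635", "F532")),
         detection_floor = detection_floor,
         sd_multiplier = sd_multiplier, reference = reference,
         alpha = alpha, epsilon = epsilon, pseudo = pseudo,
         log_transform = log_transform, var_equal = var_equal,
         p_adjust = p_adjust,
         rounding = match.arg(rounding, c("ceil", "nearest"))),
    class = "pipeline_config")
}

.resolve_reference <- function(reference) {
  if (is.data.frame(reference)) return(reference)
  if (identical(reference, "direction_table")) return(signature_directions())
  reference
}

# all outputs of a stage are staged in a temporary sibling directory and
# renamed into place, so a failed run leaves no partial output tree
.write_atomically <- function(out_dir, writer) {
  parent <- dirname(normalizePath(out_dir, mustWork = FALSE))
  if (!dir.exists(parent)) dir.create(parent, recursive = TRUE)
  tmp <- tempfile("radiomir-stage-", tmpdir = parent)
  dir.create(tmp)
  ok <- FALSE
  on.exit(if (!ok) unlink(tmp, recursive = TRUE))
  writer(tmp)
  if (dir.exists(out_dir)) {
    stop("output directory already exists: ", out_dir, call. = FALSE)
  }
  if (!file.rename(tmp, out_dir)) {
    stop("could not move staged outputs to ", out_dir, call. = FALSE)
  }
  ok <- TRUE
  invisible(out_dir)
}

# screen one cell line pair (mock, IR): aggregate -> QC -> normalize -> fc
.screen_pair <- function(mock, ir, config) {
  agg_mock <- aggregate_replicates(mock, config$channel,
                                   config$detection_floor)
  agg_ir <- aggregate_replicates(ir, config$channel, config$detection_floor)
  qc_mock <- qc_negative_controls(agg_mock)
  qc_ir <- qc_negative_controls(agg_ir)
  nm <- normalize_signals(qc_mock$signals,
                          paste(mock$cell_line, mock$treatment, sep = "_"))
  ni <- normalize_signals(qc_ir$signals,
                          paste(ir$cell_line, ir$treatment, sep = "_"))
  fc <- fold_change(ni, nm)
  list(fc = fc, agg_mock = agg_mock, agg_ir = agg_ir,
       qc = list(mock = qc_mock[c("background", "flagged")],
                 ir = qc_ir[c("background", "flagged")]))
}

.threshold_row <- function(fc, signals, condition_id) {
  probes <- fc[fc$control_class == "probe", ]
  out <- classify_outcomes(probes[c("gene_id", "fc")], signals)
  tryCatch(estimate_threshold(out, condition_id),
           error = function(e) {
             data.frame(condition_id = condition_id, lower = NA_real_,
                        upper = NA_real_, separated = NA,
                        stringsAsFactors = FALSE)
           })
}

#' Run the in vitro screen end to end
#'
#' Composes the array stages over the four experimental conditions:
#' replicate aggregation, negative-control QC, positive-control ratio
#' normalization, IR-vs-mock fold changes per cell line, threshold-interval
#' estimation per condition, and two-SD hit calling per genotype. When
#' `out_dir` is given, writes `screen.tsv` (fold-change table),
#' `thresholds.tsv`, `hits_ATM_wt.tsv` and `hits_ATM_null.tsv` atomically.
#'
#' @param conditions Either a named list of four [array_condition()]
#'   objects (`GM0536_mock`, `GM0536_IR`, `GM1526_mock`, `GM1526_IR`,
#'   as produced by [simulate_array()]) or a directory containing the four
#'   correspondingly named `.tsv` probe tables.
#' @param out_dir Optional output directory (must not yet exist).
#' @param config A [pipeline_config()].
#' @return list with `screen` (fold-change table), `thresholds`, `hits`
#'   (per genotype, see [screen_hits()]) and `qc`.
#' @export
run_screen <- function(conditions, out_dir = NULL,
                       config = pipeline_config()) {
  wanted <- c("GM0536_mock", "GM0536_IR", "GM1526_mock", "GM1526_IR")
  if (is.character(conditions) && length(conditions) == 1L) {
    dir <- conditions
    paths <- file.path(dir, paste0(wanted, ".tsv"))
    if (!all(file.exists(paths))) {
      stop("expected condition file(s) missing: ",
           paste(paths[!file.exists(paths)], collapse = ", "), call. = FALSE)
    }
    meta <- data.frame(
      cell_line = c("GM0536", "GM0536", "GM1526", "GM1526"),
      genotype = c("ATM_wt", "ATM_wt", "ATM_null", "ATM_null"),
      treatment = c("mock", "IR", "mock", "IR"),
      dose = c(0, 6, 0, 6), stringsAsFactors = FALSE)
    conditions <- Map(read_array_table, paths, meta$cell_line,
                      meta$genotype, meta$treatment, meta$dose)
    names(conditions) <- wanted
  }
  miss <- setdiff(wanted, names(conditions))
  if (length(miss) > 0L) {
    stop("missing condition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  wt <- .screen_pair(conditions$GM0536_mock, conditions$GM0536_IR, config)
  nl <- .screen_pair(conditions$GM1526_mock, conditions$GM1526_IR, config)
  probes_wt <- wt$fc[wt$fc$control_class == "probe", ]
  probes_nl <- nl$fc[nl$fc$control_class == "probe", ]
  if (!identical(sort(probes_wt$gene_id), sort(probes_nl$gene_id))) {
    stop("the two cell lines carry different probe sets", call. = FALSE)
  }
  m <- match(probes_wt$gene_id, probes_nl$gene_id)
  screen <- data.frame(mirna_id = probes_wt$gene_id,
                       fc_wt = probes_wt$fc, sd_wt = probes_wt$sd,
                       fc_null = probes_nl$fc[m], sd_null = probes_nl$sd[m],
                       stringsAsFactors = FALSE)
  thresholds <- rbind(
    .threshold_row(wt$fc, wt$agg_mock, "GM0536_mock"),
    .threshold_row(wt$fc, wt$agg_ir, "GM0536_IR"),
    .threshold_row(nl$fc, nl$agg_mock, "GM1526_mock"),
    .threshold_row(nl$fc, nl$agg_ir, "GM1526_IR"))
  hits <- list(ATM_wt = screen_hits(screen, "ATM_wt", config$sd_multiplier),
               ATM_null = screen_hits(screen, "ATM_null",
                                      config$sd_multiplier))
  result <- list(screen = screen, thresholds = thresholds, hits = hits,
                 qc = list(ATM_wt = wt$qc, ATM_null = nl$qc))
  if (!is.null(out_dir)) {
    .write_atomically(out_dir, function(tmp) {
      write_screen_table(screen, file.path(tmp, "screen.tsv"))
      utils::write.table(thresholds, file.path(tmp, "thresholds.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_hit_table(hits$ATM_wt, file.path(tmp, "hits_ATM_wt.tsv"))
      write_hit_table(hits$ATM_null, file.path(tmp, "hits_ATM_null.tsv"))
    })
  }
  result
}

#' Run the cohort signature stage end to end
#'
#' Computes per-miRNA group ratios and responder-vs-progressor tests,
#' screens them for directional concordance with the in vitro reference,
#' compares ATM protein levels between response groups (when RPPA data are
#' present), and assembles the relative-expression matrix. When `out_dir`
#' is given, writes `signature.tsv`, `atm_comparison.tsv` and
#' `relative_expression.tsv` atomically.
#'
#' @param screen Screen table ([read_screen_table()] layout) or a path to
#'   one.
#' @param cohort Cohort data.frame ([read_cohort_table()] layout) or a
#'   path to one.
#' @param out_dir Optional output directory (must not yet exist).
#' @param config A [pipeline_config()].
#' @return list with `entries` (full [concordance_screen()] table),
#'   `signature` (concordant miRNA ids), `atm` ([atm_group_comparison()]
#'   result or `NULL`), `relative_expression` (matrix) and `ratios`.
#' @export
run_signature <- function(screen, cohort, out_dir = NULL,
                          config = pipeline_config()) {
  if (is.character(screen)) screen <- read_screen_table(screen)
  if (is.character(cohort)) cohort <- read_cohort_table(cohort)
  .check_groups(cohort)
  ratios <- group_ratios(cohort, pseudo = config$pseudo,
                         log_transform = config$log_transform,
                         var_equal = config$var_equal)
  entries <- concordance_screen(ratios, screen,
                                reference = .resolve_reference(config$reference),
                                epsilon = config$epsilon,
                                alpha = config$alpha,
                                p_adjust = config$p_adjust)
  atm <- if ("atm_protein" %in% names(cohort) &&
             sum(!is.na(cohort$atm_protein[cohort$group == "responder"])) >= 2 &&
             sum(!is.na(cohort$atm_protein[cohort$group == "progressor"])) >= 2) {
    atm_group_comparison(cohort)
  }
  relmat <- relative_expression_matrix(cohort, mirnas = entries$mirna_id,
                                       pseudo = config$pseudo)
  result <- list(entries = entries,
                 signature = entries$mirna_id[entries$concordant],
                 atm = atm, relative_expression = relmat, ratios = ratios)
  if (!is.null(out_dir)) {
    .write_atomically(out_dir, function(tmp) {
      utils::write.table(entries, file.path(tmp, "signature.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(atm)) {
        utils::write.table(as.data.frame(atm),
                           file.path(tmp, "atm_comparison.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      rm_out <- data.frame(mirna_id = rownames(relmat), relmat,
                           check.names = FALSE, stringsAsFactors = FALSE)
      utils::write.table(rm_out, file.path(tmp, "relative_expression.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }
  result
}
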