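#' @keywords internal
"_PACKAGE"

CONTROL_CLASSES <- c("probe", "positive_control", "negative_control")
GENOTYPES <- c("ATM_wt", "ATM_null")
TREATMENTS <- c("mock", "IR")
PATIENT_GROUPS <- c("responder", "progressor", "untreated")

# numeric columns are serialized with full double precision so that a
# write/read cycle is the identity on the binary values
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

.read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "NA",
                    colClasses = "character", comment.char = "")
}

.as_num <- function(x, what, path) {
  suppressWarnings(v <- as.numeric(x))
  bad <- which(is.na(v) & !is.na(x) & x != "NA")
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric value %s in column '%s' of '%s' (data row %d)",
                 dQuote(x[bad[1L]]), what, path, bad[1L]), call. = FALSE)
  }
  v
}

#' Construct an array condition
#'
#' Container for one microarray hybridization: the cell line, its ATM
#' genotype, the treatment (mock or ionizing radiation) with dose in Gray,
#' and the probe-level spot table. Spots carry both fluorescence channels
#' (F635 and F532) and a control class; probes are spotted in triplicate.
#'
#' @param cell_line Cell line label, e.g. `"GM0536"`.
#' @param genotype `"ATM_wt"` or `"ATM_null"`.
#' @param treatment `"mock"` or `"IR"`.
#' @param dose Radiation dose in Gy; must be 0 for mock.
#' @param spots data.frame with columns `gene_id`, `block`, `row`, `col`,
#'   `replicate_index`, `signal_f635`, `signal_f532`, `control_class`.
#' @return An object of class `array_condition`.
#' @export
array_condition <- function(cell_line, genotype, treatment, dose, spots) {
  genotype <- match.arg(genotype, GENOTYPES)
  treatment <- match.arg(treatment, TREATMENTS)
  stopifnot(is.numeric(dose), length(dose) == 1L, dose >= 0)
  if (treatment == "mock" && dose != 0) {
    stop("mock treatment requires dose = 0", call. = FALSE)
  }
  req <- c("gene_id", "block", "row", "col", "replicate_index",
           "signal_f635", "signal_f532", "control_class")
  miss <- setdiff(req, names(spots))
  if (length(miss) > 0L) {
    stop("spot table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  bad_cc <- setdiff(unique(spots$control_class), CONTROL_CLASSES)
  if (length(bad_cc) > 0L) {
    stop("unknown control_class value(s): ", paste(bad_cc, collapse = ", "),
         "; allowed: ", paste(CONTROL_CLASSES, collapse = ", "), call. = FALSE)
  }
  if (any(spots$signal_f635 < 0, na.rm = TRUE) ||
      any(spots$signal_f532 < 0, na.rm = TRUE)) {
    stop("negative fluorescence intensity in spot table", call. = FALSE)
  }
  key <- paste(spots$block, spots$row, spots$col)
  if (anyDuplicated(key)) {
    stop("duplicate (block, row, col) position in spot table", call. = FALSE)
  }
  structure(
    list(cell_line = cell_line, genotype = genotype, treatment = treatment,
         dose = dose, spots = spots[req]),
    class = "array_condition"
  )
}

#' @export
print.array_condition <- function(x, ...) {
  cat(sprintf("array_condition: %s [%s], %s %g Gy, %d spots / %d genes\n",
              x$cell_line, x$genotype, x$treatment, x$dose,
              nrow(x$spots), length(unique(x$spots$gene_id))))
  invisible(x)
}

#' Read a probe-level array table
#'
#' Parses a tab-separated probe table in a GenePix-results-like dialect:
#' one row per spot with grid position (`block`, `row`, `col`), both
#' fluorescence channels (`F635`, `F532`) and a `control_class`. Replicate
#' indices are assigned per gene by order of appearance.
#'
#' @param path Path to the TSV file.
#' @inheritParams array_condition
#' @return An [array_condition()].
#' @export
read_array_table <- function(path, cell_line, genotype, treatment, dose) {
  tab <- .read_tsv(path)
  req <- c("gene_id", "block", "row", "col", "F635", "F532", "control_class")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("'%s' is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  f635 <- .as_num(tab$F635, "F635", path)
  f532 <- .as_num(tab$F532, "F532", path)
  neg <- which(f635 < 0 | f532 < 0)
  if (length(neg) > 0L) {
    stop(sprintf("negative intensity in '%s' at data row %d (file line %d)",
                 path, neg[1L], neg[1L] + 1L), call. = FALSE)
  }
  spots <- data.frame(
    gene_id = tab$gene_id,
    block = as.integer(tab$block),
    row = as.integer(tab$row),
    col = as.integer(tab$col),
    replicate_index = stats::ave(seq_along(tab$gene_id), tab$gene_id,
                                 FUN = seq_along),
    signal_f635 = f635,
    signal_f532 = f532,
    control_class = tab$control_class,
    stringsAsFactors = FALSE
  )
  array_condition(cell_line, genotype, treatment, dose, spots)
}

#' Write a probe-level array table
#'
#' Inverse of [read_array_table()]: intensities are serialized at full
#' double precision, so a write/read round trip reproduces the spot table
#' exactly.
#'
#' @param condition An [array_condition()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_array_table <- function(condition, path) {
  stopifnot(inherits(condition, "array_condition"))
  s <- condition$spots
  out <- data.frame(
    gene_id = s$gene_id, block = s$block, row = s$row, col = s$col,
    F635 = .fmt_num(s$signal_f635), F532 = .fmt_num(s$signal_f532),
    control_class = s$control_class, stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a fold-change screen table
#'
#' Five tab-separated columns: miRNA id, then fold change and standard
#' deviation after irradiation for the ATM-proficient and ATM-deficient
#' cell line. A fold change of 0 with SD 0 encodes non-detection.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `mirna_id`, `fc_wt`, `sd_wt`, `fc_null`,
#'   `sd_null`, one row per miRNA, input order preserved.
#' @export
read_screen_table <- function(path) {
  tab <- .read_tsv(path)
  req <- c("mirna_id", "fc_wt", "sd_wt", "fc_null", "sd_null")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("'%s' is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  if (anyDuplicated(tab$mirna_id)) {
    dup <- unique(tab$mirna_id[duplicated(tab$mirna_id)])
    stop("duplicate miRNA id(s) in screen table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    mirna_id = tab$mirna_id,
    fc_wt = .as_num(tab$fc_wt, "fc_wt", path),
    sd_wt = .as_num(tab$sd_wt, "sd_wt", path),
    fc_null = .as_num(tab$fc_null, "fc_null", path),
    sd_null = .as_num(tab$sd_null, "sd_null", path),
    stringsAsFactors = FALSE
  )
  if (any(unlist(out[-1]) < 0, na.rm = TRUE)) {
    stop("fold changes and SDs must be non-negative in '", path, "'",
         call. = FALSE)
  }
  out
}

#' Write a fold-change screen table
#'
#' @param screen data.frame in [read_screen_table()] layout.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_table <- function(screen, path) {
  out <- data.frame(
    mirna_id = screen$mirna_id,
    fc_wt = .fmt_num(screen$fc_wt), sd_wt = .fmt_num(screen$sd_wt),
    fc_null = .fmt_num(screen$fc_null), sd_null = .fmt_num(screen$sd_null),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient cohort table
#'
#' Wide tab-separated layout: `patient_id`, `group` (one of responder,
#' progressor, untreated), optionally `atm_protein` (RPPA-normalized ATM
#' level), and one non-negative expression column per miRNA.
#'
#' @param path Path to the TSV file.
#' @param strict If `TRUE` (default), a missing expression cell is an
#'   error; if `FALSE` it is kept as `NA`.
#' @return data.frame, one row per patient.
#' @export
read_cohort_table <- function(path, strict = TRUE) {
  tab <- .read_tsv(path)
  req <- c("patient_id", "group")
  miss <- setdiff(req, names(tab))
  if (length(miss) > 0L) {
    stop(sprintf("'%s' is missing mandatory column(s): %s",
                 path, paste(miss, collapse = ", ")), call. = FALSE)
  }
  bad_grp <- setdiff(unique(tab$group), PATIENT_GROUPS)
  if (length(bad_grp) > 0L) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "),
         "; allowed: ", paste(PATIENT_GROUPS, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tab$patient_id)) {
    stop("duplicate patient_id in '", path, "'", call. = FALSE)
  }
  num_cols <- setdiff(names(tab), req)
  out <- data.frame(patient_id = tab$patient_id, group = tab$group,
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (cn in num_cols) {
    v <- .as_num(tab[[cn]], cn, path)
    if (cn != "atm_protein") {
      if (strict && anyNA(v)) {
        stop(sprintf("missing expression value for '%s' in '%s' (strict mode)",
                     cn, path), call. = FALSE)
      }
      if (any(v < 0, na.rm = TRUE)) {
        stop(sprintf("negative expression value for '%s' in '%s'", cn, path),
             call. = FALSE)
      }
    }
    out[[cn]] <- v
  }
  out
}

#' Write a patient cohort table
#'
#' @param cohort data.frame in [read_cohort_table()] layout.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  out <- cohort
  for (cn in setdiff(names(out), c("patient_id", "group"))) {
    out[[cn]] <- .fmt_num(out[[cn]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged fold-change screen fixture
#'
#' The 28-miRNA in vitro screen result shipped with the package: per miRNA,
#' the post-irradiation fold change and SD in the ATM-proficient (GM0536)
#' and ATM-deficient (GM1526) lymphoblastoid lines. Rows with fold change 0
#' and SD 0 encode miRNAs undetected after irradiation.
#'
#' @return data.frame in [read_screen_table()] layout (28 rows).
#' @export
invitro_screen <- function() {
  read_screen_table(system.file("extdata", "invitro_screen.tsv",
                                package = "radiomir", mustWork = TRUE))
}

#' Packaged in vitro reference direction table
#'
#' Explicit post-irradiation expression directions for the five signature
#' miRNAs (miR-016, miR-029b, miR-150, miR-1254 up; let-7e down) used as
#' the in vitro reference in [concordance_screen()].
#'
#' @return data.frame with columns `mirna_id`, `direction`.
#' @export
signature_directions <- function() {
  tab <- .read_tsv(system.file("extdata", "signature_directions.tsv",
                               package = "radiomir", mustWork = TRUE))
  stopifnot(all(tab$direction %in% c("up", "down")))
  tab
}
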