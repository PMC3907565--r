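#' Construct a perimetry cohort
#'
#' A cohort bundles the 24-2 layout with one record per tested eye.  Each
#' record holds the 52 threshold sensitivities (dB, right-eye frame), age
#' (years), the three reliability indices as fractions in \[0, 1\], and the
#' instrument's normal/abnormal label.  Ground-truth archetype and severity
#' columns may be present on synthetic cohorts.
#'
#' @param records A data.frame with columns `subject_id`, `eye`
#'   (`"left"`/`"right"`), `p01`..`p52` (thresholds, dB, non-negative),
#'   `age`, `fp_rate`, `fl_rate`, `fn_rate` (fractions in \[0, 1\]) and
#'   `fdt_label` (`"normal"`/`"abnormal"`); optionally `archetype` and
#'   `severity`.
#' @param provenance `"clinical"` or `"synthetic"`.
#' @param layout Layout the threshold columns refer to (right-eye frame).
#' @return An object of class `fdt_cohort`.
#' @export
fdt_cohort <- function(records, provenance = c("synthetic", "clinical"),
                       layout = layout_242()) {
  provenance <- match.arg(provenance)
  validate_records(records)
  structure(
    list(layout = layout, records = records, provenance = provenance),
    class = "fdt_cohort"
  )
}

threshold_cols <- function() sprintf("p%02d", seq_len(n_points_242()))

validate_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("cohort records must be a non-empty data.frame")
  needed <- c("subject_id", "eye", threshold_cols(), "age",
              "fp_rate", "fl_rate", "fn_rate", "fdt_label")
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("cohort is missing required column(s): ",
         paste(missing, collapse = ", "))
  th <- as.matrix(records[threshold_cols()])
  if (!is.numeric(th)) stop("threshold columns must be numeric")
  bad <- which(!stats::complete.cases(th))
  if (length(bad)) stop("non-numeric or missing threshold in row ", bad[1L])
  if (any(th < 0)) stop("thresholds must be non-negative dB")
  for (rc in c("fp_rate", "fl_rate", "fn_rate")) {
    v <- records[[rc]]
    if (any(!is.finite(v)) || any(v < 0 | v > 1))
      stop("reliability column '", rc, "' must lie in [0, 1]")
  }
  if (!all(records$fdt_label %in% c("normal", "abnormal")))
    stop("fdt_label must be 'normal' or 'abnormal'")
  if (!all(records$eye %in% c("left", "right")))
    stop("eye must be 'left' or 'right'")
  invisible(records)
}

#' @export
print.fdt_cohort <- function(x, ...) {
  n <- nrow(x$records)
  tab <- table(x$records$fdt_label)
  cat(sprintf(
    "<fdt_cohort> %d fields (%s), %d normal / %d abnormal by FDT label\n",
    n, x$provenance,
    if ("normal" %in% names(tab)) tab[["normal"]] else 0L,
    if ("abnormal" %in% names(tab)) tab[["abnormal"]] else 0L))
  invisible(x)
}

#' Number of records in a cohort
#' @param cohort An `fdt_cohort`.
#' @return Integer count.
#' @export
cohort_size <- function(cohort) nrow(cohort$records)

#' Threshold matrix of a cohort
#' @param cohort An `fdt_cohort`.
#' @return N x 52 numeric matrix of threshold sensitivities (dB).
#' @export
cohort_thresholds <- function(cohort)
  as.matrix(cohort$records[threshold_cols()])

#' Model input matrix: 52 thresholds plus age
#'
#' Builds the N x 53 matrix analysed by the mixture model (thresholds in
#' layout order, then age).  Labels and reliability indices are never part
#' of the model input.
#'
#' @param cohort An `fdt_cohort`.
#' @param include_age Drop the age column when `FALSE` (used by the age
#'   ablation).
#' @return Numeric matrix with named columns.
#' @export
cohort_matrix <- function(cohort, include_age = TRUE) {
  m <- cohort_thresholds(cohort)
  if (include_age) m <- cbind(m, age = cohort$records$age)
  m
}

#' Read a cohort from a delimited file
#'
#' One row per eye, threshold columns `p01`..`p52` indexed by the canonical
#' right-eye layout.  Files written by [save_cohort()] carry a `frame`
#' column set to `"right"`; files without it (or with `frame == "native"`)
#' are taken to hold left-eye fields in the left eye's own mirrored grid,
#' and those rows are remapped onto the right-eye frame on load so a single
#' layout serves every record.
#'
#' @param path File path.
#' @param dialect `"csv"` or `"tsv"`.
#' @param provenance Provenance tag for the resulting cohort.
#' @return An `fdt_cohort` in the right-eye frame.
#' @export
load_cohort <- function(path, dialect = c("csv", "tsv"),
                        provenance = c("synthetic", "clinical")) {
  dialect <- match.arg(dialect)
  provenance <- match.arg(provenance)
  if (!file.exists(path)) stop("cohort file not found: ", path)
  sep <- if (dialect == "csv") "," else "\t"
  records <- utils::read.table(path, header = TRUE, sep = sep,
                               stringsAsFactors = FALSE,
                               colClasses = c(subject_id = "character"))
  extra <- grep("^p[0-9]+$", names(records), value = TRUE)
  wrong <- setdiff(extra, threshold_cols())
  if (length(wrong))
    stop("unexpected threshold column(s): ", paste(wrong, collapse = ", "))
  missing <- setdiff(threshold_cols(), names(records))
  if (length(missing))
    stop("missing threshold column(s): ", paste(missing, collapse = ", "))
  th <- records[threshold_cols()]
  for (j in seq_along(th)) {
    v <- th[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric threshold in column ", names(th)[j],
           " at data row ", if (length(bad)) bad[1L] else NA_integer_)
    }
  }
  native <- is.null(records$frame) | records$frame == "native"
  if (is.null(records$frame)) native <- rep(TRUE, nrow(records))
  flip <- native & records$eye == "left"
  if (any(flip)) {
    perm <- mirror_permutation_242()
    block <- as.matrix(records[flip, threshold_cols()])
    records[flip, threshold_cols()] <- block[, perm, drop = FALSE]
  }
  records$frame <- "right"
  fdt_cohort(records, provenance = provenance)
}

#' Write a cohort to a delimited file
#'
#' Values are written in the right-eye frame with `frame = "right"`, so
#' `load_cohort(save_cohort(x))` is the identity at stored precision.
#'
#' @param cohort An `fdt_cohort`.
#' @param path Output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
save_cohort <- function(cohort, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "csv") "," else "\t"
  rec <- cohort$records
  rec$frame <- "right"
  utils::write.table(rec, path, sep = sep, row.names = FALSE,
                     quote = TRUE)
  invisible(path)
}

#' Filter a cohort on test reliability
#'
#' Retains records whose false-positive, fixation-loss and false-negative
#' rates are all at or below `max_rate` (boundary inclusive, matching the
#' conventional 33% reliability cut-off for perimetry).  Order is
#' preserved and the number of removed records is reported via a message.
#'
#' @param cohort An `fdt_cohort`.
#' @param max_rate Maximum admissible rate (fraction), default 0.33.
#' @return Filtered `fdt_cohort` (warning, not error, if empty).
#' @export
apply_reliability_filter <- function(cohort, max_rate = 0.33) {
  r <- cohort$records
  keep <- r$fp_rate <= max_rate & r$fl_rate <= max_rate & r$fn_rate <= max_rate
  removed <- sum(!keep)
  if (removed > 0)
    message(sprintf("reliability filter removed %d of %d records",
                    removed, nrow(r)))
  if (!any(keep)) {
    warning("reliability filter removed every record")
    cohort$records <- r[keep, , drop = FALSE]
    return(cohort)
  }
  cohort$records <- r[keep, , drop = FALSE]
  cohort
}

#' Mean deviation of a field
#'
#' Unweighted mean over the 52 analysed points of (threshold - normative
#' mean), in dB.  The instrument's proprietary eccentricity weighting is
#' not reproduced; for synthetic cohorts the reference is the generator's
#' own normal-field mean surface, which keeps calibration targets
#' self-consistent.
#'
#' @param thresholds Numeric 52-vector of sensitivities (dB), or a row of
#'   an `fdt_cohort`'s threshold matrix.
#' @param normative_means Numeric 52-vector of reference sensitivities.
#' @return Mean deviation in dB (negative = loss).
#' @export
mean_deviation <- function(thresholds, normative_means) {
  if (length(thresholds) != length(normative_means))
    stop("thresholds and normative_means differ in length")
  mean(thresholds - normative_means)
}

#' Mean deviation of every field in a cohort
#' @param cohort An `fdt_cohort`.
#' @param normative_means Numeric 52-vector of reference sensitivities.
#' @return Numeric vector of per-field MD values (dB).
#' @export
cohort_md <- function(cohort, normative_means) {
  th <- cohort_thresholds(cohort)
  if (ncol(th) != length(normative_means))
    stop("normative_means must have length ", ncol(th))
  rowMeans(sweep(th, 2, normative_means))
}
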