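#' @importFrom stats median sd cor complete.cases rnorm rlnorm quantile
#' @importFrom utils read.table write.table head packageVersion
NULL

# Internal constructor: conc is a 3-d array [subject, timepoint, metabolite]
# with complete dimnames; the first timepoint is the baseline.
new_cohort <- function(conc, truth = NULL, report = NULL) {
  stopifnot(is.array(conc), length(dim(conc)) == 3L,
            !is.null(dimnames(conc)))
  structure(list(
    concentrations = conc,
    subjects = dimnames(conc)[[1]],
    timepoints = dimnames(conc)[[2]],
    baseline = dimnames(conc)[[2]][1],
    metabolites = dimnames(conc)[[3]],
    truth = truth,
    report = report
  ), class = "pbi_cohort")
}

#' Validate a cohort table into a cohort object
#'
#' Accepts a long table (columns \code{subject_id}, \code{timepoint},
#' \code{metabolite}, \code{concentration}), a wide table
#' (\code{subject_id}, \code{timepoint}, one column per metabolite), or an
#' already-validated cohort (returned unchanged, so validation is
#' idempotent). Concentrations are in micromol/L by convention but units
#' are not enforced.
#'
#' The first timepoint is the baseline (t0, "at rest"). By default
#' timepoints are ordered by first appearance in the table; pass
#' \code{timepoint_order} to override (e.g. when labels do not sort
#' naturally).
#'
#' Validation enforces: unique (subject, timepoint, metabolite) records,
#' non-negative concentrations, and a baseline record for every subject.
#' Missing cells are allowed and counted in the attached report.
#'
#' @param x data.frame (long or wide) or a \code{pbi_cohort}.
#' @param timepoint_order optional character vector giving the full
#'   timepoint order, first element = baseline.
#' @return object of class \code{pbi_cohort} with fields
#'   \code{concentrations} (subject x timepoint x metabolite array,
#'   \code{NA} = missing), \code{subjects}, \code{timepoints},
#'   \code{baseline}, \code{metabolites}, and a validation \code{report}
#'   (missing-value counts per metabolite).
#' @examples
#' tab <- expand.grid(subject_id = c("s1", "s2"),
#'                    timepoint = c("t0", "t1"),
#'                    metabolite = c("Lac", "Ala"),
#'                    stringsAsFactors = FALSE)
#' tab$concentration <- 10
#' ds <- validate_cohort(tab)
#' ds$metabolites
#' @export
validate_cohort <- function(x, timepoint_order = NULL) {
  if (inherits(x, "pbi_cohort")) {
    check_cohort_invariants(x)
    return(x)
  }
  if (!is.data.frame(x)) {
    stop("validate_cohort() expects a data.frame or a pbi_cohort", call. = FALSE)
  }
  long <- as_long_table(x)

  if (any(is.na(long$subject_id)) || any(is.na(long$timepoint)) ||
      any(is.na(long$metabolite))) {
    stop("missing subject/timepoint/metabolite identifiers in input table",
         call. = FALSE)
  }
  neg <- which(!is.na(long$concentration) & long$concentration < 0)
  if (length(neg) > 0) {
    i <- neg[1]
    stop(sprintf(
      "negative concentration (%g) for subject '%s', timepoint '%s', metabolite '%s'; concentrations must be >= 0",
      long$concentration[i], long$subject_id[i], long$timepoint[i],
      long$metabolite[i]), call. = FALSE)
  }
  key <- paste(long$subject_id, long$timepoint, long$metabolite, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf(
      "duplicate record for subject '%s', timepoint '%s', metabolite '%s'",
      long$subject_id[i], long$timepoint[i], long$metabolite[i]),
      call. = FALSE)
  }

  subjects <- unique(long$subject_id)
  tps <- if (!is.null(timepoint_order)) {
    if (!setequal(timepoint_order, unique(long$timepoint))) {
      stop("timepoint_order must contain exactly the timepoints present in the data",
           call. = FALSE)
    }
    as.character(timepoint_order)
  } else {
    unique(long$timepoint)
  }
  mets <- unique(long$metabolite)
  if (length(tps) < 2) {
    stop("cohort needs at least two timepoints (baseline plus one follow-up)",
         call. = FALSE)
  }

  baseline <- tps[1]
  has_t0 <- unique(long$subject_id[long$timepoint == baseline &
                                     !is.na(long$concentration)])
  missing_t0 <- setdiff(subjects, has_t0)
  if (length(missing_t0) > 0) {
    stop("subject(s) without any baseline ('", baseline, "') record: ",
         paste(missing_t0, collapse = ", "), call. = FALSE)
  }

  conc <- array(NA_real_, dim = c(length(subjects), length(tps), length(mets)),
                dimnames = list(subjects, tps, mets))
  conc[cbind(match(long$subject_id, subjects),
             match(long$timepoint, tps),
             match(long$metabolite, mets))] <- long$concentration

  report <- list(
    n_cells = length(conc),
    n_missing = sum(is.na(conc)),
    missing_per_metabolite = apply(conc, 3, function(m) sum(is.na(m)))
  )
  ds <- new_cohort(conc, report = report)
  check_cohort_invariants(ds)
  ds
}

# Re-check structural invariants of an existing cohort object.
check_cohort_invariants <- function(ds) {
  conc <- ds$concentrations
  stopifnot(identical(dimnames(conc)[[1]], ds$subjects),
            identical(dimnames(conc)[[2]], ds$timepoints),
            identical(dimnames(conc)[[3]], ds$metabolites),
            identical(ds$baseline, ds$timepoints[1]))
  if (anyDuplicated(ds$subjects) || anyDuplicated(ds$metabolites) ||
      anyDuplicated(ds$timepoints)) {
    stop("subject, timepoint and metabolite identifiers must be unique",
         call. = FALSE)
  }
  if (any(conc < 0, na.rm = TRUE)) {
    stop("negative concentrations present; concentrations must be >= 0",
         call. = FALSE)
  }
  base_ok <- if (length(ds$metabolites) == 0) rep(TRUE, length(ds$subjects))
             else apply(!is.na(conc[, 1, , drop = FALSE]), 1, any)
  if (!all(base_ok)) {
    stop("subject(s) without any baseline record: ",
         paste(ds$subjects[!base_ok], collapse = ", "), call. = FALSE)
  }
  invisible(ds)
}

# Normalize a long or wide data.frame to the canonical long columns.
# Identifier columns are matched case-insensitively (with a few
# synonyms); all other column names (metabolites) are left untouched.
as_long_table <- function(x) {
  canon <- c(subject_id = "subject_id", subject = "subject_id",
             timepoint = "timepoint", metabolite = "metabolite",
             analyte = "metabolite", concentration = "concentration",
             value = "concentration")
  lower <- tolower(names(x))
  for (k in seq_along(canon)) {
    hit <- which(lower == names(canon)[k] & !(names(x) %in% canon))
    if (length(hit)) names(x)[hit[1]] <- canon[[k]]
  }
  long_cols <- c("subject_id", "timepoint", "metabolite", "concentration")
  if (all(long_cols %in% names(x))) {
    out <- x[long_cols]
  } else if (all(c("subject_id", "timepoint") %in% names(x))) {
    mets <- setdiff(names(x), c("subject_id", "timepoint"))
    if (length(mets) == 0) stop("wide table has no metabolite columns", call. = FALSE)
    out <- data.frame(
      subject_id = rep(x$subject_id, times = length(mets)),
      timepoint = rep(x$timepoint, times = length(mets)),
      metabolite = rep(mets, each = nrow(x)),
      concentration = unlist(x[mets], use.names = FALSE),
      stringsAsFactors = FALSE
    )
    out <- out[!is.na(out$concentration), , drop = FALSE]
  } else {
    stop("table must have columns subject_id, timepoint, metabolite, concentration (long) or subject_id, timepoint plus metabolite columns (wide)",
         call. = FALSE)
  }
  out$subject_id <- as.character(out$subject_id)
  if (is.factor(out$timepoint)) {
    out$timepoint <- as.character(out$timepoint)
  } else {
    out$timepoint <- as.character(out$timepoint)
  }
  out$metabolite <- as.character(out$metabolite)
  out$concentration <- as.numeric(out$concentration)
  out
}

#' @export
print.pbi_cohort <- function(x, ...) {
  cat(sprintf("pbinet cohort: %d subjects x %d timepoints x %d metabolites\n",
              length(x$subjects), length(x$timepoints), length(x$metabolites)))
  cat("  timepoints:", paste(x$timepoints, collapse = ", "),
      sprintf("(baseline: %s)\n", x$baseline))
  if (!is.null(x$report)) {
    cat(sprintf("  missing cells: %d of %d\n",
                x$report$n_missing, x$report$n_cells))
  }
  if (!is.null(x$truth)) {
    cat(sprintf("  planted truth: %d responder metabolite(s)\n",
                nrow(x$truth$planted)))
  }
  invisible(x)
}

# Internal paired-sample constructor from aligned vectors; drops
# incomplete pairs and enforces the minimum sample size.
new_paired_sample <- function(baseline, followup, subjects, label,
                              min_pairs = 3) {
  stopifnot(length(baseline) == length(followup),
            length(subjects) == length(baseline))
  keep <- !is.na(baseline) & !is.na(followup)
  n_excluded <- sum(!keep)
  if (sum(keep) < min_pairs) {
    stop(sprintf(
      "'%s': only %d complete baseline/follow-up pair(s) (minimum %d)",
      label, sum(keep), min_pairs), call. = FALSE)
  }
  structure(list(
    baseline = unname(baseline[keep]),
    followup = unname(followup[keep]),
    subjects = subjects[keep],
    label = label,
    n_excluded = n_excluded
  ), class = "pbi_paired")
}

#' Extract the paired baseline/follow-up view of one metabolite
#'
#' Returns the aligned per-subject concentration vectors at the baseline
#' and at one follow-up timepoint for a single metabolite. Subjects with
#' a missing value at either timepoint are excluded; the exclusion count
#' is kept in the result (\code{n_excluded}) so effective sample sizes
#' remain auditable. Row order of the original input never affects the
#' pairing: alignment is by subject identifier.
#'
#' @param ds a \code{pbi_cohort}.
#' @param metabolite metabolite label in \code{ds$metabolites}.
#' @param t_x a non-baseline timepoint of \code{ds}.
#' @param min_pairs minimum number of complete pairs (default 3; the
#'   median and CV of fewer pairs are degenerate).
#' @return object of class \code{pbi_paired} with fields
#'   \code{baseline}, \code{followup}, \code{subjects}, \code{label},
#'   \code{n_excluded}.
#' @export
paired_view <- function(ds, metabolite, t_x, min_pairs = 3) {
  ds <- validate_cohort(ds)
  if (!metabolite %in% ds$metabolites) {
    stop("unknown metabolite '", metabolite, "'", call. = FALSE)
  }
  if (!t_x %in% ds$timepoints) {
    stop("unknown timepoint '", t_x, "'", call. = FALSE)
  }
  if (identical(t_x, ds$baseline)) {
    stop("t_x must be a non-baseline timepoint", call. = FALSE)
  }
  new_paired_sample(
    baseline = ds$concentrations[, ds$baseline, metabolite],
    followup = ds$concentrations[, t_x, metabolite],
    subjects = ds$subjects,
    label = metabolite,
    min_pairs = min_pairs
  )
}

#' @export
print.pbi_paired <- function(x, ...) {
  cat(sprintf("paired sample '%s': %d subjects (%d excluded)\n",
              x$label, length(x$baseline), x$n_excluded))
  invisible(x)
}
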