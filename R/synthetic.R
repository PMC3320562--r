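#' Simulation specification for synthetic cohorts
#'
#' Describes a longitudinal cohort with a null backbone of independent
#' Normal(null_mean, null_sd) concentrations (truncated at 0) and an
#' optional set of planted responder metabolites with directionally
#' consistent fold changes at the follow-up timepoints. The defaults
#' (30 subjects, 60 metabolites, N(10, 1) null) match the controlled
#' simulated data used to calibrate the network threshold and the scale
#' of the bicycle stress-test cohort the method was developed on.
#'
#' @param n_subjects number of subjects (default 30).
#' @param n_metabolites number of metabolites (default 60).
#' @param timepoints ordered timepoint labels, first = baseline
#'   (default \code{c("t0", "tmax")}).
#' @param null_mean,null_sd parameters of the null concentration
#'   distribution (defaults 10 and 1).
#' @param planted \code{NULL} or a data.frame with one row per planted
#'   metabolite and columns \code{metabolite} (index into
#'   \code{1:n_metabolites}), \code{fold} (> 0), \code{direction}
#'   (\code{"up"} or \code{"down"}), \code{responder_fraction} in (0, 1],
#'   \code{fold_jitter_sd} (sd of the multiplicative lognormal jitter on
#'   the fold), and optionally \code{timepoints} (comma-separated
#'   follow-up labels the effect applies to; empty/NA = all follow-ups).
#' @param seed integer seed; all randomness of generation and planting
#'   derives from it.
#' @return object of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_subjects = 30, n_metabolites = 60,
                            timepoints = c("t0", "tmax"),
                            null_mean = 10, null_sd = 1,
                            planted = NULL, seed = 1L) {
  stopifnot(n_subjects >= 1, n_metabolites >= 1, length(timepoints) >= 2,
            null_sd > 0)
  if (!is.null(planted)) {
    planted <- as.data.frame(planted)
    req <- c("metabolite", "fold", "direction", "responder_fraction",
             "fold_jitter_sd")
    if (!all(req %in% names(planted))) {
      stop("planted needs columns: ", paste(req, collapse = ", "),
           call. = FALSE)
    }
    if (!"timepoints" %in% names(planted)) planted$timepoints <- NA_character_
    stopifnot(
      "planted folds must be > 0" = all(planted$fold > 0),
      "responder_fraction must be in (0, 1]" =
        all(planted$responder_fraction > 0 & planted$responder_fraction <= 1),
      "direction must be 'up' or 'down'" =
        all(planted$direction %in% c("up", "down")),
      "fold_jitter_sd must be >= 0" = all(planted$fold_jitter_sd >= 0)
    )
    idx <- planted$metabolite
    if (anyDuplicated(idx) || any(idx < 1) || any(idx > n_metabolites)) {
      stop("planted metabolite indices must be distinct and within 1..n_metabolites",
           call. = FALSE)
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    n_metabolites = as.integer(n_metabolites),
    timepoints = as.character(timepoints),
    null_mean = as.numeric(null_mean),
    null_sd = as.numeric(null_sd),
    planted = planted,
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

# Normal draws truncated below at 0 by resampling (no point mass at 0;
# negligible at mean 10, sd 1 but honors non-negative concentrations).
rnorm_nonneg <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  bad <- x < 0
  while (any(bad)) {
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
    bad <- x < 0
  }
  x
}

#' Generate a pure-null synthetic cohort
#'
#' Every concentration is drawn independently from
#' Normal(\code{null_mean}, \code{null_sd}) truncated below at 0.
#' Reproducible: the same spec (including seed) yields an identical
#' cohort.
#'
#' @param spec a [simulation_spec()].
#' @return a validated \code{pbi_cohort}.
#' @export
generate_null <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  subjects <- sprintf("S%02d", seq_len(spec$n_subjects))
  mets <- sprintf("M%02d", seq_len(spec$n_metabolites))
  conc <- withr::with_seed(spec$seed, {
    array(rnorm_nonneg(spec$n_subjects * length(spec$timepoints) *
                         spec$n_metabolites, spec$null_mean, spec$null_sd),
          dim = c(spec$n_subjects, length(spec$timepoints),
                  spec$n_metabolites),
          dimnames = list(subjects, spec$timepoints, mets))
  })
  ds <- new_cohort(conc, report = list(n_cells = length(conc),
                                       n_missing = 0L,
                                       missing_per_metabolite =
                                         stats::setNames(rep(0L, length(mets)), mets)))
  check_cohort_invariants(ds)
  ds
}

#' Plant responder effects into a cohort
#'
#' For each planted metabolite, a seeded \code{responder_fraction}
#' subset of subjects has its follow-up concentrations multiplied
#' (direction \code{"up"}) or divided (\code{"down"}) by
#' \code{fold} times a multiplicative lognormal jitter
#' (\code{exp(N(0, fold_jitter_sd))}, drawn per subject and timepoint).
#' Non-responders and the baseline are untouched. The realized truth
#' (responder subjects, affected timepoints) is recorded in
#' \code{ds$truth} so recovery experiments can check against what was
#' actually modified.
#'
#' Planting randomness derives deterministically from \code{spec$seed}
#' (offset from the stream used by [generate_null()], so concentrations
#' and responder choices are independent).
#'
#' @param ds a \code{pbi_cohort} (typically from [generate_null()]).
#' @param spec a [simulation_spec()] with a non-NULL \code{planted}
#'   table.
#' @return the modified cohort with \code{truth} metadata.
#' @export
plant_effects <- function(ds, spec) {
  ds <- validate_cohort(ds)
  stopifnot(inherits(spec, "simulation_spec"))
  if (is.null(spec$planted) || nrow(spec$planted) == 0) return(ds)
  if (any(spec$planted$metabolite > length(ds$metabolites))) {
    stop("planted metabolite index out of range for this cohort",
         call. = FALSE)
  }
  followups <- setdiff(ds$timepoints, ds$baseline)
  conc <- ds$concentrations
  truth_rows <- list()
  responders <- list()
  withr::with_seed(spec$seed + 101L, {
    for (r in seq_len(nrow(spec$planted))) {
      p <- spec$planted[r, ]
      met <- ds$metabolites[p$metabolite]
      tps <- if (is.na(p$timepoints) || !nzchar(p$timepoints)) followups else
        strsplit(p$timepoints, ",", fixed = TRUE)[[1]]
      if (!all(tps %in% followups)) {
        stop("planted timepoint(s) not among the follow-up timepoints: ",
             paste(setdiff(tps, followups), collapse = ", "), call. = FALSE)
      }
      n_resp <- max(1L, round(p$responder_fraction * length(ds$subjects)))
      resp <- sort(sample(length(ds$subjects), n_resp))
      for (tp in tps) {
        jitter <- stats::rlnorm(n_resp, 0, p$fold_jitter_sd)
        factor <- p$fold * jitter
        if (p$direction == "up") {
          conc[resp, tp, met] <- conc[resp, tp, met] * factor
        } else {
          conc[resp, tp, met] <- conc[resp, tp, met] / factor
        }
      }
      truth_rows[[r]] <- data.frame(
        metabolite = met, fold = p$fold, direction = p$direction,
        responder_fraction = p$responder_fraction,
        fold_jitter_sd = p$fold_jitter_sd,
        n_responders = n_resp,
        timepoints = paste(tps, collapse = ","),
        stringsAsFactors = FALSE)
      responders[[met]] <- ds$subjects[resp]
    }
  })
  out <- new_cohort(conc,
                    truth = list(planted = do.call(rbind, truth_rows),
                                 responders = responders),
                    report = ds$report)
  check_cohort_invariants(out)
  out
}

#' Generate a synthetic cohort (null backbone + planted effects)
#'
#' Convenience wrapper: [generate_null()] followed by
#' [plant_effects()].
#'
#' @param spec a [simulation_spec()].
#' @return a \code{pbi_cohort}.
#' @export
generate_cohort <- function(spec) {
  plant_effects(generate_null(spec), spec)
}

#' Preset: synthetic bicycle stress-test cohort
#'
#' Emulates the design of an incremental bicycle stress test panel:
#' 30 subjects, 60 metabolites, timepoints \code{t0} (at rest) and
#' \code{tmax} (individual maximum workload), with 5 planted
#' up-responder metabolites (folds 2 to 4 in even steps, responder
#' fraction 0.9, lognormal fold jitter sd 0.1) on a N(10, 1) null
#' backbone. The planted metabolite indices are drawn from the seed, so
#' signal position carries no information. Two pairs of planted
#' responders with the largest fold separation are recorded in the truth
#' metadata as expected interacting pairs (their concentration ratio
#' shifts by the fold quotient, producing network edges).
#'
#' @param seed integer seed.
#' @return a \code{pbi_cohort} with \code{truth} metadata (fields
#'   \code{planted}, \code{responders}, \code{interacting_pairs}).
#' @export
generate_stress_cohort <- function(seed = 1L) {
  idx <- withr::with_seed(seed + 7L, sample(60, 5))
  planted <- data.frame(
    metabolite = idx,
    fold = seq(2, 4, length.out = 5),
    direction = "up",
    responder_fraction = 0.9,
    fold_jitter_sd = 0.1,
    stringsAsFactors = FALSE
  )
  spec <- simulation_spec(n_subjects = 30, n_metabolites = 60,
                          timepoints = c("t0", "tmax"),
                          null_mean = 10, null_sd = 1,
                          planted = planted, seed = seed)
  ds <- generate_cohort(spec)
  p <- ds$truth$planted[order(ds$truth$planted$fold), ]
  ds$truth$interacting_pairs <- data.frame(
    metabolite_i = c(p$metabolite[1], p$metabolite[2]),
    metabolite_j = c(p$metabolite[5], p$metabolite[4]),
    fold_ratio = c(p$fold[5] / p$fold[1], p$fold[4] / p$fold[2]),
    stringsAsFactors = FALSE
  )
  ds
}
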