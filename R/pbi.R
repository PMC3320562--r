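#' Per-subject fold changes of a paired sample
#'
#' Element i is \code{followup[i] / baseline[i]}. Zero baselines are
#' handled by the configured policy: \code{"exclude-subject"} drops the
#' subject (with a warning), \code{"epsilon"} substitutes \code{epsilon}
#' for the zero baseline.
#'
#' @param pair a \code{pbi_paired} sample.
#' @param zero_policy \code{"exclude-subject"} or \code{"epsilon"}.
#' @param epsilon replacement value under the epsilon policy.
#' @param min_pairs minimum subjects that must remain after exclusions.
#' @return numeric vector of fold changes, one per retained subject.
#' @export
fold_changes <- function(pair, zero_policy = c("exclude-subject", "epsilon"),
                         epsilon = 1e-6, min_pairs = 3) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(pair, "pbi_paired"))
  b <- pair$baseline
  f <- pair$followup
  zero <- b == 0
  if (any(zero)) {
    if (zero_policy == "exclude-subject") {
      warning(sprintf("'%s': excluding %d subject(s) with zero baseline",
                      pair$label, sum(zero)), call. = FALSE)
      b <- b[!zero]
      f <- f[!zero]
    } else {
      b[zero] <- epsilon
    }
  }
  if (length(b) < min_pairs) {
    stop(sprintf("'%s': fewer than %d subjects remain after zero-baseline exclusions",
                 pair$label, min_pairs), call. = FALSE)
  }
  f / b
}

#' Symmetric fold-change transform
#'
#' Maps a (median) fold change \eqn{\Delta > 0} onto a scale symmetric
#' about no change: \eqn{\Delta} itself when \eqn{\Delta \ge 1}, and
#' \eqn{-1/\Delta} otherwise. A halving and a doubling thus get the same
#' magnitude 2 with opposite signs, and \eqn{|\Delta_{change}| \ge 1}
#' always.
#'
#' @param delta positive fold change(s).
#' @return signed transformed value(s).
#' @examples
#' delta_change(c(2, 0.5, 1)) # 2, -2, 1
#' @export
delta_change <- function(delta) {
  if (any(!is.finite(delta)) || any(delta <= 0)) {
    stop("delta must be a positive finite fold change", call. = FALSE)
  }
  ifelse(delta >= 1, delta, -1 / delta)
}

#' Discriminance of a fold-change vector
#'
#' Fraction of subjects changing in the dominant direction:
#' \code{max(#fold > 1, #fold < 1) / n}. Subjects with fold exactly 1
#' (no change) count toward neither direction but stay in the
#' denominator, so unchanged subjects are evidence against either
#' direction. The result lies in \[0, 1\]; 1 means a perfectly
#' consistent directional response.
#'
#' @param folds numeric vector of per-subject fold changes.
#' @return discriminance value in \[0, 1\].
#' @export
discriminance <- function(folds) {
  if (length(folds) == 0) stop("empty fold-change vector", call. = FALSE)
  max(sum(folds > 1), sum(folds < 1)) / length(folds)
}

#' Capped coefficient of variation of fold changes
#'
#' Sample standard deviation divided by the mean of the fold-change
#' vector, then clipped to \code{[cv_floor, cv_cap]}. The cap (default 1)
#' makes the score consider only distributions with smaller variance:
#' high-variance responses cannot be penalized past the cap. The floor
#' keeps scores finite when all subjects change by an identical factor.
#'
#' @param folds numeric vector of per-subject fold changes (length >= 3).
#' @param cv_cap upper clip value (default 1).
#' @param cv_floor lower clip value (default 1e-6).
#' @return clipped CV.
#' @export
coefficient_of_variation <- function(folds, cv_cap = 1, cv_floor = 1e-6) {
  if (length(folds) < 3) {
    stop("need at least 3 fold changes for a coefficient of variation",
         call. = FALSE)
  }
  cv <- stats::sd(folds) / mean(folds)
  min(max(cv, cv_floor), cv_cap)
}

# Fast internal core: score a fold-change vector, returning all
# components. Used by pbi_score() and by the ratio-matrix loop.
pbi_core <- function(folds, config) {
  delta <- stats::median(folds)
  dc <- delta_change(delta)
  da <- discriminance(folds)
  cv <- coefficient_of_variation(folds, config$cv_cap, config$cv_floor)
  score <- config$lambda_scale * da * abs(dc) / cv * sign(dc)
  list(score = score, delta = delta, delta_change = dc,
       da_star = da, cv = cv)
}

#' Paired Biomarker Identifier (pBI) score
#'
#' Scores one paired sample (a metabolite, or a metabolite ratio treated
#' as an analyte) by
#' \deqn{pBI = \lambda \cdot DA^* \cdot |\Delta_{change} / CV| \cdot
#'   sign(\Delta_{change})}
#' where \eqn{\Delta} is the median per-subject fold change
#' (follow-up / baseline), \eqn{\Delta_{change}} its symmetric transform
#' (see [delta_change()]), \eqn{DA^*} the directional consistency (see
#' [discriminance()]) and CV the capped coefficient of variation of the
#' fold changes. Positive scores indicate increased levels at the
#' follow-up, negative decreased; the magnitude is a signal-to-noise
#' style measure of discriminatory ability.
#'
#' @param pair a \code{pbi_paired} sample.
#' @param config an [analysis_config()].
#' @return object of class \code{pbi_result}: list with \code{score},
#'   \code{delta}, \code{delta_change}, \code{da_star}, \code{cv},
#'   \code{n_pairs}, \code{n_excluded}, \code{label},
#'   \code{predictor_class}.
#' @examples
#' tab <- data.frame(
#'   subject_id = rep(paste0("s", 1:4), 2),
#'   timepoint = rep(c("t0", "tmax"), each = 4),
#'   metabolite = "Lac",
#'   concentration = c(10, 10, 10, 10, 20, 18, 22, 40))
#' pbi_score(paired_view(validate_cohort(tab), "Lac", "tmax"))$score # ~518.1
#' @export
pbi_score <- function(pair, config = analysis_config()) {
  stopifnot(inherits(pair, "pbi_paired"))
  folds <- fold_changes(pair, zero_policy = config$zero_policy,
                        epsilon = config$epsilon,
                        min_pairs = config$min_pairs)
  comp <- pbi_core(folds, config)
  res <- c(comp, list(
    n_pairs = length(folds),
    n_excluded = pair$n_excluded + (length(pair$baseline) - length(folds)),
    label = pair$label,
    predictor_class = classify_predictor(comp$score, config)
  ))
  class(res) <- "pbi_result"
  res
}

#' @export
print.pbi_result <- function(x, ...) {
  cat(sprintf("pBI '%s': score %.6g (%s)\n", x$label, x$score,
              x$predictor_class))
  cat(sprintf("  delta %.6g  delta_change %.6g  DA* %.4g  CV %.6g  n %d\n",
              x$delta, x$delta_change, x$da_star, x$cv, x$n_pairs))
  invisible(x)
}

#' Classify scores into weak/moderate/strong predictor classes
#'
#' Strong iff \code{|score| > strong_cutoff} (strict, mirroring the
#' strict edge-inclusion rule of the network step), moderate iff
#' \code{moderate_cutoff < |score| <= strong_cutoff}, weak otherwise.
#'
#' @param score numeric vector of pBI scores (NA allowed, stays NA).
#' @param config an [analysis_config()].
#' @return character vector of \code{"weak"}, \code{"moderate"},
#'   \code{"strong"}.
#' @export
classify_predictor <- function(score, config = analysis_config()) {
  out <- ifelse(abs(score) > config$strong_cutoff, "strong",
                ifelse(abs(score) > config$moderate_cutoff, "moderate",
                       "weak"))
  out[is.na(score)] <- NA_character_
  out
}

#' Rank all metabolites of a cohort by |pBI|
#'
#' Scores every metabolite at the contrast baseline vs. \code{t_x} and
#' returns the table sorted by absolute score (descending; ties broken
#' alphabetically by metabolite name). Metabolites that cannot be scored
#' (fewer complete pairs than the minimum) are retained at the bottom of
#' the table with \code{NA} score and the failure reason, never silently
#' dropped.
#'
#' @param ds a \code{pbi_cohort}.
#' @param t_x non-baseline timepoint to contrast against the baseline.
#' @param config an [analysis_config()].
#' @return data.frame with columns \code{metabolite}, \code{score},
#'   \code{delta}, \code{delta_change}, \code{da_star}, \code{cv},
#'   \code{n_pairs}, \code{predictor_class}, \code{note}.
#' @export
rank_metabolites <- function(ds, t_x, config = analysis_config()) {
  ds <- validate_cohort(ds)
  rows <- lapply(ds$metabolites, function(m) {
    res <- tryCatch(
      pbi_score(paired_view(ds, m, t_x, min_pairs = config$min_pairs),
                config),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      data.frame(metabolite = m, score = NA_real_, delta = NA_real_,
                 delta_change = NA_real_, da_star = NA_real_,
                 cv = NA_real_, n_pairs = NA_integer_,
                 predictor_class = NA_character_,
                 note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(metabolite = m, score = res$score, delta = res$delta,
                 delta_change = res$delta_change, da_star = res$da_star,
                 cv = res$cv, n_pairs = res$n_pairs,
                 predictor_class = res$predictor_class, note = "",
                 stringsAsFactors = FALSE)
    }
  })
  tbl <- do.call(rbind, rows)
  if (is.null(tbl)) {
    tbl <- data.frame(metabolite = character(), score = numeric(),
                      delta = numeric(), delta_change = numeric(),
                      da_star = numeric(), cv = numeric(),
                      n_pairs = integer(), predictor_class = character(),
                      note = character(), stringsAsFactors = FALSE)
  }
  scored <- !is.na(tbl$score)
  ord <- order(!scored, -abs(tbl$score), tbl$metabolite)
  tbl <- tbl[ord, , drop = FALSE]
  rownames(tbl) <- NULL
  attr(tbl, "contrast") <- c(ds$baseline, t_x)
  attr(tbl, "moderate_cutoff") <- config$moderate_cutoff
  attr(tbl, "strong_cutoff") <- config$strong_cutoff
  tbl
}
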