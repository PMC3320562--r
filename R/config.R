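#' Analysis configuration
#'
#' Collects every tunable parameter of the scoring and network-inference
#' pipeline in one validated object. All user-facing functions accept a
#' config; defaults reproduce the standard analysis (score scale 100,
#' strong-predictor cutoff 73, network threshold 73, 3-nearest-neighbor
#' classifier with 10-fold cross-validation).
#'
#' @param lambda_scale positive scaling factor \eqn{\lambda} of the pBI
#'   score. With the discriminance on a 0-1 scale, 100 puts scores on the
#'   scale on which 73 is the strong-predictor cutoff.
#' @param cv_cap upper cap for the coefficient of variation of the
#'   fold-change vector; CV values above the cap are set to the cap so
#'   that only low-variance responses can boost a score.
#' @param cv_floor small positive lower bound for the CV, keeping scores
#'   finite when all subjects change by an identical factor.
#' @param strong_cutoff scores with \eqn{|pBI| >} \code{strong_cutoff}
#'   (strict) are classified strong.
#' @param moderate_cutoff lower bound (strict) of the moderate class.
#' @param tau default network edge-inclusion threshold on \eqn{|s_{ij}|}.
#' @param knn_k number of neighbors for the KNN classifier.
#' @param cv_folds number of cross-validation folds.
#' @param seed integer seed driving fold assignment and any other
#'   randomness inside the pipeline.
#' @param zero_policy how zero baseline values are handled when forming
#'   fold changes: \code{"exclude-subject"} drops the subject (with a
#'   warning), \code{"epsilon"} replaces the zero by \code{epsilon}.
#' @param epsilon small positive value used by the epsilon policy and as
#'   the floor for absolute log2 ratios (which are zero for equal
#'   concentrations).
#' @param ratio_type ratio variable scored in network inference:
#'   \code{"absolute"} uses \eqn{|log2(m_i/m_j)|} (symmetric in i,j, the
#'   default); \code{"signed"} scores the raw ratio \eqn{m_i/m_j} for
#'   \eqn{i > j}, retaining the direction of the pair.
#' @param grouped_folds if TRUE (default) cross-validation folds are
#'   grouped by subject so a subject's baseline and follow-up samples
#'   never straddle the train/test split; FALSE uses naive per-sample
#'   folds.
#' @param hub_k default number of top-degree vertices reported as hubs.
#' @param min_pairs minimum number of complete baseline/follow-up pairs
#'   required to compute any score.
#'
#' @return an object of class \code{pbi_config} (a named list).
#' @examples
#' cfg <- analysis_config(tau = 50)
#' cfg$tau
#' @export
analysis_config <- function(lambda_scale = 100,
                            cv_cap = 1,
                            cv_floor = 1e-6,
                            strong_cutoff = 73,
                            moderate_cutoff = 40,
                            tau = 73,
                            knn_k = 3,
                            cv_folds = 10,
                            seed = 1L,
                            zero_policy = c("exclude-subject", "epsilon"),
                            epsilon = 1e-6,
                            ratio_type = c("absolute", "signed"),
                            grouped_folds = TRUE,
                            hub_k = 4,
                            min_pairs = 3) {
  zero_policy <- match.arg(zero_policy)
  ratio_type <- match.arg(ratio_type)
  stopifnot(
    "lambda_scale must be > 0" = is.numeric(lambda_scale) && lambda_scale > 0,
    "need 0 < cv_floor < cv_cap" = is.numeric(cv_floor) && is.numeric(cv_cap) &&
      cv_floor > 0 && cv_floor < cv_cap,
    "need 0 < moderate_cutoff < strong_cutoff" =
      moderate_cutoff > 0 && moderate_cutoff < strong_cutoff,
    "tau must be >= 0" = is.numeric(tau) && tau >= 0,
    "knn_k must be >= 1" = knn_k >= 1,
    "cv_folds must be >= 2" = cv_folds >= 2,
    "epsilon must be > 0" = is.numeric(epsilon) && epsilon > 0,
    "min_pairs must be >= 2" = min_pairs >= 2
  )
  structure(list(
    lambda_scale = as.numeric(lambda_scale),
    cv_cap = as.numeric(cv_cap),
    cv_floor = as.numeric(cv_floor),
    strong_cutoff = as.numeric(strong_cutoff),
    moderate_cutoff = as.numeric(moderate_cutoff),
    tau = as.numeric(tau),
    knn_k = as.integer(knn_k),
    cv_folds = as.integer(cv_folds),
    seed = as.integer(seed),
    zero_policy = zero_policy,
    epsilon = as.numeric(epsilon),
    ratio_type = ratio_type,
    grouped_folds = isTRUE(grouped_folds),
    hub_k = as.integer(hub_k),
    min_pairs = as.integer(min_pairs)
  ), class = "pbi_config")
}

#' @export
print.pbi_config <- function(x, ...) {
  cat("pbinet analysis configuration\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Merge a named list (e.g. parsed from a YAML config file) over defaults;
# unknown keys are an error so typos do not pass silently.
config_from_list <- function(values) {
  if (is.null(values)) return(analysis_config())
  known <- names(formals(analysis_config))
  bad <- setdiff(names(values), known)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(analysis_config, values)
}
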