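#' Metabolites connected in the network at a given threshold
#'
#' Feature-selection step of threshold evaluation: the metabolites with
#' at least one edge (degree > 0) in the network inferred at \code{tau}.
#'
#' @param ds a \code{pbi_cohort}.
#' @param t_x non-baseline timepoint.
#' @param tau edge threshold.
#' @param config an [analysis_config()].
#' @param sm optional precomputed [ratio_score_matrix()] for \code{ds}
#'   and \code{t_x} (avoids recomputation along a threshold grid).
#' @return character vector of metabolite names (possibly empty).
#' @export
features_by_network <- function(ds, t_x, tau, config = analysis_config(),
                                sm = NULL) {
  if (is.null(sm)) sm <- ratio_score_matrix(ds, t_x, config)
  net <- infer_network(sm, tau)
  d <- igraph::degree(net)
  names(d)[d > 0]
}

#' Cross-validated KNN accuracy of a feature subset
#'
#' Evaluates how well the selected metabolites separate baseline from
#' follow-up samples. Every subject contributes two samples (its
#' concentration vector at the baseline, labelled \code{t0}, and at
#' \code{t_x}, labelled \code{t_x}); a k-nearest-neighbor classifier is
#' scored by cross-validation. By default folds are grouped by subject,
#' so the two samples of one subject are always in the same fold and a
#' subject never appears in both train and test (paired samples would
#' otherwise leak). Features are standardized with training-fold means
#' and standard deviations only.
#'
#' An empty feature set returns the two-class chance level 0.5 with
#' attribute \code{flagged = TRUE} instead of failing, so that grid
#' evaluation over thresholds never aborts.
#'
#' @param ds a \code{pbi_cohort}.
#' @param features character vector of metabolite names.
#' @param t_x non-baseline timepoint.
#' @param config an [analysis_config()]; uses \code{knn_k},
#'   \code{cv_folds}, \code{seed}, \code{grouped_folds}.
#' @return mean accuracy over folds (numeric in \[0, 1\]) with
#'   attributes \code{n_subjects}, \code{n_features}, \code{flagged}.
#' @export
knn_cv_accuracy <- function(ds, features, t_x, config = analysis_config()) {
  ds <- validate_cohort(ds)
  if (length(features) == 0) {
    return(structure(0.5, n_subjects = length(ds$subjects),
                     n_features = 0L, flagged = TRUE))
  }
  if (!all(features %in% ds$metabolites)) {
    stop("unknown feature metabolite(s): ",
         paste(setdiff(features, ds$metabolites), collapse = ", "),
         call. = FALSE)
  }
  x0 <- ds$concentrations[, ds$baseline, features, drop = FALSE][, 1, , drop = FALSE]
  x1 <- ds$concentrations[, t_x, features, drop = FALSE][, 1, , drop = FALSE]
  x0 <- matrix(x0, nrow = length(ds$subjects),
               dimnames = list(ds$subjects, features))
  x1 <- matrix(x1, nrow = length(ds$subjects),
               dimnames = list(ds$subjects, features))
  complete <- stats::complete.cases(x0) & stats::complete.cases(x1)
  x0 <- x0[complete, , drop = FALSE]
  x1 <- x1[complete, , drop = FALSE]
  n <- nrow(x0)
  if (n < 2) stop("need at least 2 complete subjects for cross-validation",
                  call. = FALSE)

  X <- rbind(x0, x1)
  y <- factor(rep(c("t0", "tx"), each = n))
  subj <- rep(seq_len(n), 2)

  k_folds <- min(config$cv_folds, n)
  acc <- withr::with_seed(config$seed, {
    if (config$grouped_folds) {
      fold_of_subject <- sample(rep_len(seq_len(k_folds), n))
      fold <- fold_of_subject[subj]
    } else {
      fold <- sample(rep_len(seq_len(k_folds), 2 * n))
    }
    vapply(seq_len(k_folds), function(f) {
      tr <- fold != f
      te <- !tr
      mu <- colMeans(X[tr, , drop = FALSE])
      sdev <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sdev[sdev == 0 | is.na(sdev)] <- 1
      Xtr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sdev, "/")
      Xte <- sweep(sweep(X[te, , drop = FALSE], 2, mu), 2, sdev, "/")
      k_use <- min(config$knn_k, nrow(Xtr))
      pred <- class::knn(Xtr, Xte, y[tr], k = k_use)
      mean(pred == y[te])
    }, numeric(1))
  })
  structure(mean(acc), n_subjects = n, n_features = length(features),
            flagged = FALSE)
}

#' Select the network threshold by classifier accuracy
#'
#' Grid evaluation of the edge threshold: for every candidate \eqn{\tau}
#' the network is inferred, the degree > 0 metabolites become classifier
#' features, and the mean cross-validated KNN accuracy is computed
#' ([knn_cv_accuracy()]). The selected \eqn{\tau} is the accuracy
#' argmax; ties are broken toward the smallest candidate (denser
#' networks retain more interpretable pair reactions at equal accuracy).
#'
#' The default grid spans 0 to the maximum observed \eqn{|s_{ij}|} in 40
#' even steps, with the configured default threshold (73) injected.
#'
#' @param ds a \code{pbi_cohort}.
#' @param t_x non-baseline timepoint.
#' @param tau_grid optional numeric vector of candidate thresholds.
#' @param config an [analysis_config()].
#' @return object of class \code{threshold_evaluation}: list with
#'   \code{curve} (data.frame \code{tau}, \code{mean_accuracy},
#'   \code{n_features}, \code{flagged}), \code{selected_tau},
#'   \code{seed}, \code{contrast}.
#' @export
select_tau <- function(ds, t_x, tau_grid = NULL,
                       config = analysis_config()) {
  ds <- validate_cohort(ds)
  sm <- ratio_score_matrix(ds, t_x, config)
  if (is.null(tau_grid)) {
    smax <- max(abs(sm$scores), na.rm = TRUE)
    tau_grid <- unique(sort(c(seq(0, smax, length.out = 40), config$tau)))
  }
  if (length(tau_grid) == 0) stop("empty tau grid", call. = FALSE)
  tau_grid <- sort(unique(as.numeric(tau_grid)))

  rows <- lapply(tau_grid, function(tau) {
    feats <- features_by_network(ds, t_x, tau, config, sm = sm)
    a <- knn_cv_accuracy(ds, feats, t_x, config)
    data.frame(tau = tau, mean_accuracy = as.numeric(a),
               n_features = length(feats),
               flagged = isTRUE(attr(a, "flagged")))
  })
  curve <- do.call(rbind, rows)
  # grid is ascending, so which.max's first-match rule = smallest tau
  selected <- curve$tau[which.max(curve$mean_accuracy)]
  structure(list(
    curve = curve,
    selected_tau = selected,
    seed = config$seed,
    contrast = c(ds$baseline, t_x)
  ), class = "threshold_evaluation")
}

#' @export
print.threshold_evaluation <- function(x, ...) {
  cat(sprintf("pbinet threshold evaluation (%s vs %s): %d candidates\n",
              x$contrast[2], x$contrast[1], nrow(x$curve)))
  best <- x$curve[x$curve$tau == x$selected_tau, ]
  cat(sprintf("  selected tau = %g (mean accuracy %.4f, %d features)\n",
              x$selected_tau, best$mean_accuracy, best$n_features))
  invisible(x)
}

#' @export
plot.threshold_evaluation <- function(x, ...) {
  graphics::plot(x$curve$tau, x$curve$mean_accuracy, type = "b", pch = 16,
                 xlab = expression(tau), ylab = "mean CV accuracy",
                 ylim = c(0, 1), ...)
  graphics::abline(v = x$selected_tau, lty = 2)
  invisible(x)
}
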