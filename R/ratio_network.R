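#' Absolute log2 ratio of two concentrations
#'
#' \code{|log2(m_i / m_j)|}, the symmetric dissimilarity of two analyte
#' levels: the absolute value makes the ratio and its reciprocal
#' equivalent, so the quantity does not depend on which analyte is the
#' numerator. Zeros are replaced by \code{epsilon} before taking the
#' logarithm.
#'
#' @param m_i,m_j non-negative concentration vectors.
#' @param epsilon replacement for zero concentrations.
#' @return non-negative vector of absolute log2 ratios.
#' @examples
#' log_ratio(4, 2) # 1
#' log_ratio(2, 4) # 1 as well
#' @export
log_ratio <- function(m_i, m_j, epsilon = 1e-6) {
  stopifnot(all(m_i >= 0, na.rm = TRUE), all(m_j >= 0, na.rm = TRUE))
  m_i[!is.na(m_i) & m_i == 0] <- epsilon
  m_j[!is.na(m_j) & m_j == 0] <- epsilon
  abs(log2(m_i / m_j))
}

#' Pairwise pBI scores on metabolite ratios
#'
#' For every unordered metabolite pair (i, j) the per-subject absolute
#' log2 ratio \eqn{r_{ij} = |log2(m_i/m_j)|} is treated as an analyte: a
#' paired sample of its baseline and follow-up values is built and
#' scored with [pbi_score()]'s arithmetic, giving \eqn{s_{ij}}. A large
#' \eqn{|s_{ij}|} means the balance between the two metabolites shifts
#' consistently across subjects between the two timepoints — the basis
#' for calling the pair a putative interaction.
#'
#' Baseline ratio values below \code{epsilon} (equal concentrations give
#' r = 0) are floored at \code{epsilon} so fold changes of the ratio are
#' defined. Under \code{zero_policy = "exclude-subject"} a subject with a
#' zero concentration is dropped for the pairs involving it. With
#' \code{ratio_type = "signed"} the raw ratio \eqn{m_i/m_j} (i > j) is
#' scored instead of its absolute log.
#'
#' @param ds a \code{pbi_cohort}.
#' @param t_x non-baseline timepoint.
#' @param config an [analysis_config()].
#' @return object of class \code{pbi_score_matrix}: list with the
#'   symmetric \code{scores} matrix (NA diagonal and NA for unscored
#'   pairs), matching \code{n_pairs} matrix, \code{metabolites},
#'   \code{contrast} and an \code{unscored} data.frame.
#' @export
ratio_score_matrix <- function(ds, t_x, config = analysis_config()) {
  ds <- validate_cohort(ds)
  if (!t_x %in% ds$timepoints || identical(t_x, ds$baseline)) {
    stop("t_x must be a non-baseline timepoint of the cohort", call. = FALSE)
  }
  mets <- ds$metabolites
  m <- length(mets)
  c0 <- ds$concentrations[, ds$baseline, , drop = TRUE]
  c1 <- ds$concentrations[, t_x, , drop = TRUE]
  if (length(ds$subjects) == 1L) {
    c0 <- matrix(c0, nrow = 1, dimnames = list(ds$subjects, mets))
    c1 <- matrix(c1, nrow = 1, dimnames = list(ds$subjects, mets))
  }
  zero0 <- !is.na(c0) & c0 == 0
  zero1 <- !is.na(c1) & c1 == 0
  if (config$zero_policy == "epsilon") {
    c0[zero0] <- config$epsilon
    c1[zero1] <- config$epsilon
  } else {
    c0[zero0] <- NA_real_
    c1[zero1] <- NA_real_
  }
  l0 <- log2(c0)
  l1 <- log2(c1)

  scores <- matrix(NA_real_, m, m, dimnames = list(mets, mets))
  n_pairs <- matrix(NA_integer_, m, m, dimnames = list(mets, mets))
  unscored <- list()

  for (i in seq_len(m)) {
    if (i == 1L) next
    for (j in seq_len(i - 1L)) {
      if (config$ratio_type == "absolute") {
        r0 <- pmax(abs(l0[, i] - l0[, j]), config$epsilon)
        r1 <- pmax(abs(l1[, i] - l1[, j]), config$epsilon)
      } else {
        r0 <- 2^(l0[, i] - l0[, j])
        r1 <- 2^(l1[, i] - l1[, j])
      }
      keep <- !is.na(r0) & !is.na(r1)
      if (sum(keep) < config$min_pairs) {
        unscored[[length(unscored) + 1L]] <- data.frame(
          metabolite_i = mets[i], metabolite_j = mets[j],
          n_complete = sum(keep), stringsAsFactors = FALSE)
        next
      }
      comp <- pbi_core(r1[keep] / r0[keep], config)
      scores[i, j] <- scores[j, i] <- comp$score
      n_pairs[i, j] <- n_pairs[j, i] <- sum(keep)
    }
  }
  if (m >= 2 && all(is.na(scores[lower.tri(scores)]))) {
    stop("no metabolite pair could be scored (all below the minimum pair count)",
         call. = FALSE)
  }
  structure(list(
    scores = scores,
    n_pairs = n_pairs,
    metabolites = mets,
    contrast = c(ds$baseline, t_x),
    unscored = if (length(unscored)) do.call(rbind, unscored) else
      data.frame(metabolite_i = character(), metabolite_j = character(),
                 n_complete = integer(), stringsAsFactors = FALSE)
  ), class = "pbi_score_matrix")
}

#' @export
print.pbi_score_matrix <- function(x, ...) {
  m <- length(x$metabolites)
  scored <- sum(!is.na(x$scores[lower.tri(x$scores)]))
  cat(sprintf("pbinet ratio score matrix: %d metabolites, %d/%d pairs scored (%s vs %s)\n",
              m, scored, m * (m - 1) / 2, x$contrast[2], x$contrast[1]))
  invisible(x)
}

#' Threshold a score matrix into a metabolite network
#'
#' Builds the undirected graph with an edge between metabolites i and j
#' iff \eqn{|s_{ij}| > \tau} (strict). All metabolites are kept as
#' vertices, including isolated ones. Edges carry the signed score and
#' its absolute value; vertices carry their degree and, when an analyte
#' ranking is supplied, the single-analyte pBI score and predictor
#' class.
#'
#' @param sm a \code{pbi_score_matrix}.
#' @param tau non-negative edge-inclusion threshold.
#' @param analyte_table optional output of [rank_metabolites()] used to
#'   annotate vertices.
#' @return object of class \code{pbi_network} (an igraph graph with
#'   graph attributes \code{tau} and \code{contrast}).
#' @export
infer_network <- function(sm, tau, analyte_table = NULL) {
  stopifnot(inherits(sm, "pbi_score_matrix"), is.numeric(tau), tau >= 0)
  adj <- !is.na(sm$scores) & abs(sm$scores) > tau
  mode(adj) <- "numeric"
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    s <- sm$scores[cbind(el[, 1], el[, 2])]
    igraph::E(g)$score <- s
    igraph::E(g)$abs_score <- abs(s)
  } else {
    g <- igraph::set_edge_attr(g, "score", value = numeric(0))
    g <- igraph::set_edge_attr(g, "abs_score", value = numeric(0))
  }
  igraph::V(g)$degree <- igraph::degree(g)
  if (!is.null(analyte_table)) {
    idx <- match(igraph::V(g)$name, analyte_table$metabolite)
    igraph::V(g)$pbi_score <- analyte_table$score[idx]
    igraph::V(g)$predictor_class <- analyte_table$predictor_class[idx]
  }
  g <- igraph::set_graph_attr(g, "tau", as.numeric(tau))
  g <- igraph::set_graph_attr(g, "contrast",
                              paste(sm$contrast, collapse = " vs "))
  class(g) <- c("pbi_network", class(g))
  g
}

#' @export
print.pbi_network <- function(x, ...) {
  cat(sprintf("pbinet network (%s, tau = %g): %d vertices, %d edges\n",
              igraph::graph_attr(x, "contrast"),
              igraph::graph_attr(x, "tau"),
              igraph::vcount(x), igraph::ecount(x)))
  invisible(x)
}

#' Kinetic networks: one network per follow-up timepoint
#'
#' Infers one network per non-baseline timepoint, each contrasting that
#' timepoint against the baseline. Comparing the resulting series shows
#' when metabolite-pair interactions appear or disappear along the time
#' course (e.g. along increasing workload in a stress test).
#'
#' @param ds a \code{pbi_cohort} (ideally with >= 2 follow-up
#'   timepoints).
#' @param tau edge threshold (defaults to \code{config$tau}).
#' @param config an [analysis_config()].
#' @param annotate if TRUE (default) vertices are annotated with the
#'   single-analyte pBI of the matching contrast.
#' @return named list of \code{pbi_network} objects in timepoint order.
#' @export
kinetic_networks <- function(ds, tau = NULL, config = analysis_config(),
                             annotate = TRUE) {
  ds <- validate_cohort(ds)
  if (is.null(tau)) tau <- config$tau
  followups <- setdiff(ds$timepoints, ds$baseline)
  nets <- lapply(followups, function(tp) {
    sm <- ratio_score_matrix(ds, tp, config)
    tab <- if (annotate) rank_metabolites(ds, tp, config) else NULL
    infer_network(sm, tau, tab)
  })
  names(nets) <- followups
  nets
}

#' Vertex degrees of a network
#'
#' @param net a \code{pbi_network}.
#' @return data.frame (\code{metabolite}, \code{degree}) sorted by
#'   degree descending, ties broken alphabetically.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "pbi_network"))
  d <- igraph::degree(net)
  out <- data.frame(metabolite = names(d), degree = as.integer(d),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$degree, out$metabolite), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-degree vertices (hubs)
#'
#' Highly connected vertices are the network's hubs; under ratio-score
#' inference a high degree is a proxy for a high discriminatory value of
#' the metabolite and for its centrality in the perturbed metabolism.
#'
#' @param net a \code{pbi_network}.
#' @param top_k number of hubs to return (default 4).
#' @return head of [degree_table()]; if \code{top_k} exceeds the vertex
#'   count, all vertices are returned with a message.
#' @export
hubs <- function(net, top_k = 4) {
  dt <- degree_table(net)
  if (top_k > nrow(dt)) {
    message("top_k (", top_k, ") exceeds vertex count (", nrow(dt),
            "); returning all vertices")
    top_k <- nrow(dt)
  }
  utils::head(dt, top_k)
}

#' Correlation network baseline
#'
#' Comparison baseline for benchmarks: connects metabolites i and j iff
#' the absolute Pearson correlation of their per-subject log2 fold
#' changes (t_x vs. baseline) exceeds \code{r_threshold} (strict).
#' Metabolites with constant fold changes have undefined correlations
#' and contribute no edges (with a warning).
#'
#' @param ds a \code{pbi_cohort}.
#' @param t_x non-baseline timepoint.
#' @param r_threshold correlation threshold in \[0, 1\].
#' @param config an [analysis_config()].
#' @return a \code{pbi_network} whose edges carry the correlation in
#'   \code{score}.
#' @export
correlation_baseline <- function(ds, t_x, r_threshold = 0.9,
                                 config = analysis_config()) {
  ds <- validate_cohort(ds)
  if (!t_x %in% ds$timepoints || identical(t_x, ds$baseline)) {
    stop("t_x must be a non-baseline timepoint of the cohort", call. = FALSE)
  }
  c0 <- ds$concentrations[, ds$baseline, , drop = TRUE]
  c1 <- ds$concentrations[, t_x, , drop = TRUE]
  c0[!is.na(c0) & c0 == 0] <- config$epsilon
  c1[!is.na(c1) & c1 == 0] <- config$epsilon
  lfc <- log2(c1 / c0)
  suppressWarnings(cmat <- stats::cor(lfc, use = "pairwise.complete.obs"))
  if (any(is.na(cmat[upper.tri(cmat)]))) {
    warning("correlation undefined for some metabolite pair(s) (constant fold changes); no edge drawn",
            call. = FALSE)
  }
  adj <- !is.na(cmat) & abs(cmat) > r_threshold
  diag(adj) <- FALSE
  mode(adj) <- "numeric"
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) > 0) {
    r <- cmat[cbind(el[, 1], el[, 2])]
    igraph::E(g)$score <- r
    igraph::E(g)$abs_score <- abs(r)
  }
  igraph::V(g)$degree <- igraph::degree(g)
  g <- igraph::set_graph_attr(g, "tau", as.numeric(r_threshold))
  g <- igraph::set_graph_attr(g, "contrast",
                              paste(c(ds$baseline, t_x), collapse = " vs "))
  g <- igraph::set_graph_attr(g, "method", "correlation")
  class(g) <- c("pbi_network", class(g))
  g
}
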