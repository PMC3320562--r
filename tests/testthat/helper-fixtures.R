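# Fixture builders and the independent scoring oracle shared across tests.

# Long-format table for n subjects, one metabolite, two timepoints.
pair_table <- function(baseline, followup, label = "X",
                       tps = c("t0", "t1")) {
  n <- length(baseline)
  data.frame(
    subject_id = rep(sprintf("s%03d", seq_len(n)), 2),
    timepoint = rep(tps, each = n),
    metabolite = label,
    concentration = c(baseline, followup),
    stringsAsFactors = FALSE
  )
}

# Paired sample straight from two vectors.
make_pair <- function(baseline, followup, label = "X") {
  ds <- validate_cohort(pair_table(baseline, followup, label))
  paired_view(ds, label, "t1")
}

# Cohort from per-timepoint subject x metabolite matrices.
make_cohort <- function(..., tps = NULL) {
  mats <- list(...)
  if (is.null(tps)) tps <- c("t0", paste0("t", seq_len(length(mats) - 1)))
  n <- nrow(mats[[1]])
  m <- ncol(mats[[1]])
  mets <- colnames(mats[[1]])
  if (is.null(mets)) mets <- sprintf("M%02d", seq_len(m))
  rows <- lapply(seq_along(mats), function(k) {
    data.frame(
      subject_id = rep(sprintf("s%03d", seq_len(n)), m),
      timepoint = tps[k],
      metabolite = rep(mets, each = n),
      concentration = as.vector(mats[[k]]),
      stringsAsFactors = FALSE
    )
  })
  validate_cohort(do.call(rbind, rows), timepoint_order = tps)
}

# Score-matrix object with prescribed symmetric scores, for tests that
# need exact score values (threshold boundaries, degree structure).
make_score_matrix <- function(scores, contrast = c("t0", "t1")) {
  stopifnot(is.matrix(scores), nrow(scores) == ncol(scores))
  mets <- rownames(scores)
  if (is.null(mets)) {
    mets <- sprintf("M%02d", seq_len(nrow(scores)))
    dimnames(scores) <- list(mets, mets)
  }
  diag(scores) <- NA_real_
  np <- matrix(10L, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  structure(list(scores = scores, n_pairs = np, metabolites = mets,
                 contrast = contrast,
                 unscored = data.frame(metabolite_i = character(),
                                       metabolite_j = character(),
                                       n_complete = integer())),
            class = "pbi_score_matrix")
}

# Independent oracle: a literal, loop-based transcription of the score
# definition, kept deliberately separate from the package's code path.
pbi_oracle <- function(baseline, followup, lambda = 100, cv_cap = 1,
                       cv_floor = 1e-6) {
  n <- length(baseline)
  folds <- numeric(n)
  for (i in seq_len(n)) folds[i] <- followup[i] / baseline[i]
  srt <- sort(folds)
  delta <- if (n %% 2 == 1) srt[(n + 1) / 2] else
    (srt[n / 2] + srt[n / 2 + 1]) / 2
  dch <- if (delta >= 1) delta else -1 / delta
  up <- 0; down <- 0
  for (f in folds) {
    if (f > 1) up <- up + 1 else if (f < 1) down <- down + 1
  }
  da <- max(up, down) / n
  mu <- sum(folds) / n
  ssq <- 0
  for (f in folds) ssq <- ssq + (f - mu)^2
  cv <- sqrt(ssq / (n - 1)) / mu
  if (cv > cv_cap) cv <- cv_cap
  if (cv < cv_floor) cv <- cv_floor
  sgn <- if (dch >= 0) 1 else -1
  lambda * da * abs(dch) / cv * sgn
}
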