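test_that("log_ratio is the symmetric absolute log2 ratio", {
  expect_equal(log_ratio(4, 2), 1)
  expect_equal(log_ratio(2, 4), 1)
  expect_equal(log_ratio(7, 7), 0)
  expect_equal(log_ratio(c(4, 2), c(2, 4)), c(1, 1))
  # zeros are substituted, not -Inf
  expect_true(is.finite(log_ratio(0, 2)))
  expect_error(log_ratio(-1, 2))
})

test_that("a time-constant cohort yields all-zero ratio scores", {
  t0 <- matrix(rlnorm(12, log(10), 0.2), 4, 3)
  ds <- make_cohort(t0, t0)
  sm <- ratio_score_matrix(ds, "t1")
  off <- sm$scores[lower.tri(sm$scores)]
  expect_equal(off, rep(0, 3))
})

test_that("three metabolites give exactly three scored pairs and a symmetric matrix", {
  set.seed(5)
  t0 <- matrix(rlnorm(15, log(10), 0.1), 5, 3)
  t1 <- matrix(rlnorm(15, log(10), 0.1), 5, 3)
  sm <- ratio_score_matrix(make_cohort(t0, t1), "t1")
  expect_equal(sum(!is.na(sm$scores[lower.tri(sm$scores)])), 3)
  expect_true(all(is.na(diag(sm$scores))))
  expect_equal(sm$scores, t(sm$scores))
})

test_that("a doubling metabolite against a stable partner scores beyond 73", {
  # noise-free 4-subject fixture: A doubles in every subject, B constant
  A0 <- c(8, 9, 11, 12)
  B0 <- rep(10, 4)
  ds <- make_cohort(cbind(A = A0, B = B0), cbind(A = 2 * A0, B = B0))
  sm <- ratio_score_matrix(ds, "t1")
  s_ab <- sm$scores["A", "B"]
  # independent check of the ratio fold changes feeding the score
  r0 <- abs(log2(A0 / B0))
  r1 <- abs(log2(2 * A0 / B0))
  expect_equal(s_ab, pbi_oracle(r0, r1), tolerance = 1e-12)
  expect_gt(abs(s_ab), 73)
})

test_that("edges obey the strict |s| > tau rule and keep all vertices", {
  sm <- make_score_matrix(matrix(c(0, 74, 74, 0), 2, 2))
  expect_equal(igraph::ecount(infer_network(sm, 73)), 1)
  sm73 <- make_score_matrix(matrix(c(0, 73, 73, 0), 2, 2))
  net0 <- infer_network(sm73, 73)
  expect_equal(igraph::ecount(net0), 0)
  expect_equal(igraph::vcount(net0), 2)
  # negative scores count by magnitude
  smn <- make_score_matrix(matrix(c(0, -90, -90, 0), 2, 2))
  expect_equal(igraph::ecount(infer_network(smn, 73)), 1)
  expect_equal(igraph::E(infer_network(smn, 73))$score, -90)
})

test_that("raising tau only removes edges", {
  set.seed(31)
  m <- 8
  s <- matrix(0, m, m)
  s[lower.tri(s)] <- runif(m * (m - 1) / 2, -150, 150)
  s <- s + t(s)
  sm <- make_score_matrix(s)
  taus <- c(0, 25, 73, 120)
  nets <- lapply(taus, function(tau) infer_network(sm, tau))
  for (k in 2:length(nets)) {
    e_hi <- igraph::as_edgelist(nets[[k]])
    e_lo <- igraph::as_edgelist(nets[[k - 1]])
    key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    expect_true(all(key(e_hi) %in% key(e_lo)))
  }
})

test_that("relabeling metabolites yields an isomorphic network", {
  set.seed(13)
  t0 <- matrix(rlnorm(40, log(10), 0.15), 8, 5)
  t1 <- matrix(rlnorm(40, log(10), 0.15), 8, 5)
  t1[, 2] <- t0[, 2] * 2.5
  ds <- make_cohort(t0, t1)
  perm <- c(4, 1, 5, 3, 2)
  dsp <- make_cohort(t0[, perm], t1[, perm])
  n1 <- infer_network(ratio_score_matrix(ds, "t1"), 40)
  n2 <- infer_network(ratio_score_matrix(dsp, "t1"), 40)
  expect_equal(sort(igraph::degree(n1)), sort(igraph::degree(n2)),
               ignore_attr = TRUE)
  expect_equal(igraph::ecount(n1), igraph::ecount(n2))
})

test_that("a global unit change leaves the ratio network unchanged", {
  # converting every concentration to another unit (e.g. nmol/L) cancels
  # in all ratios, so the score matrix is exactly preserved
  set.seed(17)
  t0 <- matrix(rlnorm(30, log(10), 0.15), 6, 5)
  t1 <- matrix(rlnorm(30, log(10), 0.15), 6, 5)
  sm1 <- ratio_score_matrix(make_cohort(t0, t1), "t1")
  sm2 <- ratio_score_matrix(make_cohort(t0 * 1000, t1 * 1000), "t1")
  expect_equal(sm2$scores, sm1$scores, tolerance = 1e-9)
})

test_that("the signed ratio variant is invariant to rescaling a single metabolite", {
  # scoring the raw ratio m_i/m_j makes per-metabolite scale factors
  # cancel between the two timepoints (the absolute-log form does not
  # have this property: it compares ratio magnitudes to parity)
  set.seed(18)
  t0 <- matrix(rlnorm(30, log(10), 0.15), 6, 5)
  t1 <- matrix(rlnorm(30, log(10), 0.15), 6, 5)
  cfg <- analysis_config(ratio_type = "signed")
  sm1 <- ratio_score_matrix(make_cohort(t0, t1), "t1", cfg)
  t0[, 3] <- t0[, 3] * 50
  t1[, 3] <- t1[, 3] * 50
  sm2 <- ratio_score_matrix(make_cohort(t0, t1), "t1", cfg)
  expect_equal(sm2$scores, sm1$scores, tolerance = 1e-9)
})

test_that("kinetic networks produce one network per follow-up, in order", {
  set.seed(19)
  mats <- replicate(3, matrix(rlnorm(40, log(10), 0.1), 8, 5),
                    simplify = FALSE)
  ds <- make_cohort(mats[[1]], mats[[2]], mats[[3]])
  nets <- kinetic_networks(ds, tau = 73)
  expect_named(nets, c("t1", "t2"))

  # planted effect at t2 only: edge appears only in the t2 network
  spec <- simulation_spec(
    n_subjects = 12, n_metabolites = 6, timepoints = c("t0", "t1", "t2"),
    planted = data.frame(metabolite = 2, fold = 4, direction = "up",
                         responder_fraction = 1, fold_jitter_sd = 0,
                         timepoints = "t2"),
    seed = 4)
  dsp <- generate_cohort(spec)
  netsp <- kinetic_networks(dsp, tau = 73)
  met <- dsp$truth$planted$metabolite
  deg_t1 <- igraph::degree(netsp$t1)[met]
  deg_t2 <- igraph::degree(netsp$t2)[met]
  expect_gt(deg_t2, deg_t1)
  expect_gt(deg_t2, 0)

  # single follow-up: consistent with direct inference
  ds2 <- make_cohort(mats[[1]], mats[[2]])
  single <- kinetic_networks(ds2, tau = 50)
  direct <- infer_network(ratio_score_matrix(ds2, "t1"), 50)
  expect_length(single, 1)
  expect_equal(igraph::as_edgelist(single$t1), igraph::as_edgelist(direct))
})

test_that("degree_table and hubs rank a star correctly", {
  m <- 5
  s <- matrix(0, m, m)
  s[1, 2:5] <- s[2:5, 1] <- 100 # star centered on M01
  net <- infer_network(make_score_matrix(s), 73)
  dt <- degree_table(net)
  expect_equal(dt$metabolite[1], "M01")
  expect_equal(dt$degree, c(4, 1, 1, 1, 1))
  expect_equal(hubs(net, 1)$metabolite, "M01")
  expect_message(all5 <- hubs(net, 99), "exceeds vertex count")
  expect_equal(nrow(all5), 5)

  empty <- infer_network(make_score_matrix(matrix(0, 3, 3)), 73)
  expect_equal(degree_table(empty)$degree, c(0, 0, 0))
  # alphabetical tie-break on equal degrees
  expect_equal(degree_table(empty)$metabolite, c("M01", "M02", "M03"))
})

test_that("correlation baseline connects identical responses and warns on constants", {
  set.seed(29)
  t0 <- matrix(rlnorm(30, log(10), 0.1), 10, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  fold <- rlnorm(10, 0.5, 0.4)
  t1 <- t0
  t1[, "A"] <- t0[, "A"] * fold
  t1[, "B"] <- t0[, "B"] * fold # identical fold-change vector as A
  t1[, "C"] <- t0[, "C"] * rlnorm(10, 0, 0.3)
  ds <- make_cohort(t0, t1)
  net <- correlation_baseline(ds, "t1", r_threshold = 0.99)
  el <- igraph::as_edgelist(net)
  expect_true(any(el[, 1] == "A" & el[, 2] == "B" |
                    el[, 1] == "B" & el[, 2] == "A"))

  # threshold 1 excludes even perfect correlation (strict inequality)
  expect_equal(igraph::ecount(
    correlation_baseline(ds, "t1", r_threshold = 1)), 0)

  t1c <- t1
  t1c[, "C"] <- t0[, "C"] # constant fold change -> undefined correlation
  expect_warning(netc <- correlation_baseline(make_cohort(t0, t1c), "t1",
                                              r_threshold = 0.99),
                 "undefined")
  expect_equal(igraph::degree(netc)[["C"]], 0)
})

test_that("network exports round-trip and follow their formats", {
  set.seed(37)
  ds <- generate_stress_cohort(2)
  tab <- rank_metabolites(ds, "tmax")
  net <- infer_network(ratio_score_matrix(ds, "tmax"), 73, tab)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(back), igraph::ecount(net))
  expect_equal(sort(igraph::V(back)$name), sort(igraph::V(net)$name))
  key <- function(g) {
    e <- igraph::as_edgelist(g)
    o <- order(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    data.frame(a = pmin(e[, 1], e[, 2])[o], b = pmax(e[, 1], e[, 2])[o],
               s = round(igraph::E(g)$score[o], 6))
  }
  expect_equal(key(back), key(net))
  expect_true("pbi_score" %in% igraph::vertex_attr_names(back))

  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(net, sif)
  lines <- readLines(sif)
  edge_lines <- grep("\t", lines, value = TRUE)
  expect_equal(length(edge_lines), igraph::ecount(net))
  expect_true(all(grepl("^[^\t]+\tratio\t[^\t]+$", edge_lines)))

  el <- withr::local_tempfile(fileext = ".tsv")
  write_edgelist(net, el)
  df <- utils::read.table(el, sep = "\t", header = TRUE)
  expect_equal(names(df), c("source", "target", "score"))
  expect_equal(nrow(df), igraph::ecount(net))

  # isolated vertices can be dropped on export
  s <- matrix(0, 4, 4); s[1, 2] <- s[2, 1] <- 100
  iso_net <- infer_network(make_score_matrix(s), 73)
  write_sif(iso_net, sif, drop_isolated = TRUE)
  expect_equal(length(readLines(sif)), 1)
  write_sif(iso_net, sif, drop_isolated = FALSE)
  expect_equal(length(readLines(sif)), 3) # 1 edge + 2 isolated vertices
})
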