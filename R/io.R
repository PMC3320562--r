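# Delimiter auto-detection among tab and comma, based on the header line.
detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (length(hdr) == 0) stop("empty input file: ", path, call. = FALSE)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr, fixed = TRUE))) > 0) "\t"
  else ","
}

#' Read a cohort from a delimited text file
#'
#' Reads long (\code{subject_id}, \code{timepoint}, \code{metabolite},
#' \code{concentration}) or wide (\code{subject_id}, \code{timepoint},
#' one column per metabolite) layouts; the delimiter is auto-detected
#' among tab and comma. The decimal separator is the point.
#'
#' @param path file path.
#' @param timepoint_order optional explicit timepoint order (first =
#'   baseline); default is order of first appearance.
#' @return a validated \code{pbi_cohort}.
#' @export
read_cohort <- function(path, timepoint_order = NULL) {
  sep <- detect_sep(path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  validate_cohort(tab, timepoint_order = timepoint_order)
}

#' Write a cohort to a delimited text file
#'
#' @param ds a \code{pbi_cohort}.
#' @param path output file path.
#' @param layout \code{"long"} (default) or \code{"wide"}.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_cohort <- function(ds, path, layout = c("long", "wide"), sep = "\t") {
  ds <- validate_cohort(ds)
  layout <- match.arg(layout)
  conc <- ds$concentrations
  long <- expand.grid(subject_id = ds$subjects, timepoint = ds$timepoints,
                      metabolite = ds$metabolites, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  long$concentration <- as.vector(conc)
  long <- long[!is.na(long$concentration), , drop = FALSE]
  if (layout == "wide") {
    wide <- expand.grid(subject_id = ds$subjects, timepoint = ds$timepoints,
                        stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    for (m in ds$metabolites) wide[[m]] <- as.vector(conc[, , m])
    out <- wide
  } else {
    out <- long
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write planted-truth metadata as a sidecar table
#'
#' @param ds a \code{pbi_cohort} carrying \code{truth} metadata.
#' @param path output file path (tab-separated).
#' @return \code{path}, invisibly.
#' @export
write_truth <- function(ds, path) {
  if (is.null(ds$truth)) stop("cohort has no planted-truth metadata",
                              call. = FALSE)
  tr <- ds$truth$planted
  tr$responders <- vapply(tr$metabolite, function(m)
    paste(ds$truth$responders[[m]], collapse = ","), character(1))
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a ranked score table as tab-separated text
#'
#' Floating-point columns are printed with 6 significant digits;
#' ordering is the deterministic ordering of [rank_metabolites()].
#'
#' @param tbl output of [rank_metabolites()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_ranked_table <- function(tbl, path) {
  out <- tbl
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], signif, digits = 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a threshold-evaluation curve as tab-separated text
#'
#' @param ev a \code{threshold_evaluation}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_evaluation <- function(ev, path) {
  stopifnot(inherits(ev, "threshold_evaluation"))
  out <- ev$curve
  out$tau <- signif(out$tau, 6)
  out$mean_accuracy <- signif(out$mean_accuracy, 6)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Optionally drop isolated vertices before export (mirrors figures that
# display only connected metabolites).
maybe_drop_isolated <- function(net, drop_isolated) {
  if (!drop_isolated) return(net)
  keep <- igraph::V(net)[igraph::degree(net) > 0]
  sub <- igraph::induced_subgraph(net, keep)
  class(sub) <- class(net)
  sub
}

#' Export a network as GraphML
#'
#' Node attributes: metabolite name, degree and (when present)
#' single-analyte pBI score and predictor class. Edge attributes: the
#' signed ratio score and its absolute value. The file loads in
#' Cytoscape and round-trips through \code{igraph::read_graph()}.
#'
#' @param net a \code{pbi_network}.
#' @param path output file path.
#' @param drop_isolated drop degree-0 vertices (default FALSE).
#' @return \code{path}, invisibly.
#' @export
write_graphml <- function(net, path, drop_isolated = FALSE) {
  stopifnot(inherits(net, "pbi_network"))
  g <- maybe_drop_isolated(net, drop_isolated)
  class(g) <- "igraph"
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network in simple interaction format (SIF)
#'
#' One line per edge: \code{metabolite_i<TAB>ratio<TAB>metabolite_j}.
#' Isolated vertices are written as bare single-column lines unless
#' dropped.
#'
#' @inheritParams write_graphml
#' @return \code{path}, invisibly.
#' @export
write_sif <- function(net, path, drop_isolated = FALSE) {
  stopifnot(inherits(net, "pbi_network"))
  g <- maybe_drop_isolated(net, drop_isolated)
  el <- igraph::as_edgelist(g, names = TRUE)
  lines <- if (nrow(el) > 0) paste(el[, 1], "ratio", el[, 2], sep = "\t")
           else character(0)
  iso <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, iso), path)
  invisible(path)
}

#' Export a network as a tab-separated edge list
#'
#' Header \code{source<TAB>target<TAB>score}; scores printed with 6
#' significant digits.
#'
#' @inheritParams write_graphml
#' @return \code{path}, invisibly.
#' @export
write_edgelist <- function(net, path, drop_isolated = FALSE) {
  stopifnot(inherits(net, "pbi_network"))
  g <- maybe_drop_isolated(net, drop_isolated)
  el <- igraph::as_edgelist(g, names = TRUE)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   score = signif(igraph::E(g)$score, 6),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, input file checksums, seed,
#' tool version and per-stage warnings in YAML, so a run can be audited
#' and reproduced. Identical inputs and configuration produce an
#' identical manifest (no timestamps).
#'
#' @param out_dir output directory (created if needed).
#' @param config the resolved [analysis_config()].
#' @param inputs character vector of input file paths (hashed with MD5).
#' @param warnings character vector of warnings emitted during the run.
#' @param extra optional named list of additional fields (e.g. selected
#'   tau).
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(out_dir, config, inputs = character(0),
                           warnings = character(0), extra = list()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hashes <- if (length(inputs)) {
    as.list(stats::setNames(unname(tools::md5sum(inputs)), basename(inputs)))
  } else list()
  manifest <- c(list(
    tool = "pbinet",
    version = as.character(utils::packageVersion("pbinet")),
    seed = config$seed,
    config = unclass(config),
    inputs = hashes,
    warnings = as.list(warnings)
  ), extra)
  path <- file.path(out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}
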