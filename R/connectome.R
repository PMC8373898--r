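# Region-mean time-series correlation network and seed-edge extraction.

#' Region-mean time series per group
#'
#' Per region: the voxel mean of each subject's time series, averaged across
#' the subjects of each group (all task time points, regardless of stimulus).
#'
#' @param ds A `timepoint_dataset`.
#' @param by_group Average within each group (default) or across all
#'   subjects.
#' @return With `by_group = TRUE`, a named list of R x T matrices (rownames =
#'   region ids), one per group; otherwise a single R x T matrix.
#' @export
region_mean_series <- function(ds, by_group = TRUE) {
  region_ids <- names(ds$region_index)
  per_subject <- lapply(ds$features, function(f) {
    m <- t(vapply(region_ids, function(r) {
      cols <- ds$region_index[[r]]
      if (length(cols) == 0) stop("empty region: ", r, call. = FALSE)
      rowMeans(f[, cols, drop = FALSE])
    }, numeric(ds$T)))
    rownames(m) <- region_ids
    m
  })
  if (!by_group)
    return(Reduce(`+`, per_subject) / length(per_subject))
  groups <- sort(unique(as.character(ds$group_labels)))
  out <- lapply(groups, function(g) {
    subs <- ds$subject_ids[ds$group_labels[ds$subject_ids] == g]
    Reduce(`+`, per_subject[subs]) / length(subs)
  })
  names(out) <- groups
  out
}

#' Absolute-correlation region network
#'
#' Absolute Pearson correlations between all region-mean time series. Edges
#' are retained where `|r| >= threshold` (absolute mode) or where `|r|` falls
#' in the top fraction of off-diagonal values (percentile mode, e.g.
#' `percentile = 0.3` keeps the top 30%). Zero-variance series give undefined
#' correlations; their edges are dropped with a warning.
#'
#' @param series R x T matrix of region-mean series (rownames = region ids).
#' @param threshold Absolute threshold in `[0, 1]` (study value 0.6).
#' @param mode `"absolute"` or `"percentile"`.
#' @param percentile Top fraction retained in percentile mode.
#' @return An object of class `region_graph`: the `|r|` matrix, the effective
#'   threshold, and the retained edge list.
#' @export
correlation_network <- function(series, threshold = 0.6,
                                mode = c("absolute", "percentile"),
                                percentile = 0.3) {
  mode <- match.arg(mode)
  series <- as.matrix(series)
  if (nrow(series) < 2) stop("need >= 2 regions", call. = FALSE)
  if (ncol(series) < 3) stop("need >= 3 time points", call. = FALSE)
  ids <- rownames(series) %||% as.character(seq_len(nrow(series)))
  sds <- apply(series, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance region series (", paste(ids[sds == 0], collapse = ", "),
            "); their edges are dropped", call. = FALSE)
  cc <- suppressWarnings(abs(stats::cor(t(series))))
  diag(cc) <- 1
  dimnames(cc) <- list(ids, ids)
  off <- cc[upper.tri(cc)]
  cut <- if (mode == "absolute") {
    if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]", call. = FALSE)
    threshold
  } else {
    stats::quantile(off[is.finite(off)], 1 - percentile, names = FALSE)
  }
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  keep <- is.finite(cc[ut]) & cc[ut] >= cut
  edges <- data.frame(region_i = ids[ut[keep, 1]],
                      region_j = ids[ut[keep, 2]],
                      abs_r = cc[ut][keep],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$abs_r), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(cor = cc, threshold = cut, mode = mode, edges = edges),
            class = "region_graph")
}

#' @export
print.region_graph <- function(x, ...) {
  cat(sprintf("<region_graph> %d regions, %s threshold %.3g, %d edges retained\n",
              nrow(x$cor), x$mode, x$threshold, nrow(x$edges)))
  invisible(x)
}

#' Suprathreshold neighbours of a seed region
#'
#' @param graph A [correlation_network()] result.
#' @param seed_region Region id (matched against the graph's region names).
#' @return Data frame of neighbours `(region, abs_r)` sorted by `|r|`
#'   descending; the count is `nrow()` of the result.
#' @export
seed_edges <- function(graph, seed_region) {
  ids <- rownames(graph$cor)
  seed <- as.character(seed_region)
  if (!(seed %in% ids)) stop("unknown seed region: ", seed, call. = FALSE)
  r <- graph$cor[seed, ]
  keep <- ids != seed & is.finite(r) & r >= graph$threshold
  out <- data.frame(region = ids[keep], abs_r = unname(r[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$abs_r), , drop = FALSE]
  rownames(out) <- NULL
  out
}
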