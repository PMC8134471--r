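# Anatomical localization of a consensus predictive network: node degree,
# hemisphere and distance partitions, and within/between-network edge
# counts.

check_mask <- function(mask, atlas) {
  K <- nrow(atlas)
  if (length(mask) != n_edges(K)) {
    stop(sprintf("mask length %d does not match K = %d nodes (%d edges)",
                 length(mask), K, n_edges(K)))
  }
  as.logical(mask)
}

#' Node degree within a predictive network
#'
#' The degree of a node is the number of selected edges incident to it; the
#' degrees sum to twice the edge count.
#'
#' @param mask Logical edge mask in canonical order (length K(K-1)/2).
#' @param atlas A `cpm_atlas`.
#' @return Integer vector of length K, one degree per node.
#' @export
node_degree <- function(mask, atlas) {
  mask <- check_mask(mask, atlas)
  ep <- edge_pairs(nrow(atlas))
  tabulate(c(ep$i[mask], ep$j[mask]), nbins = nrow(atlas))
}

#' Hemisphere partition of a predictive network
#'
#' Classifies each selected edge as ipsilateral-right, ipsilateral-left, or
#' interhemispheric by its endpoint hemisphere labels.
#'
#' @inheritParams node_degree
#' @return Named integer vector `c(ipsi_R, ipsi_L, inter)` summing to the
#'   number of selected edges.
#' @export
hemisphere_partition <- function(mask, atlas) {
  mask <- check_mask(mask, atlas)
  if (anyNA(atlas$hemisphere)) stop("hemisphere_partition: missing hemisphere label")
  ep <- edge_pairs(nrow(atlas))
  hi <- atlas$hemisphere[ep$i[mask]]
  hj <- atlas$hemisphere[ep$j[mask]]
  c(ipsi_R = sum(hi == "R" & hj == "R"),
    ipsi_L = sum(hi == "L" & hj == "L"),
    inter  = sum(hi != hj))
}

#' Long- vs short-range partition with a goodness-of-fit test
#'
#' An edge is long-range when the Euclidean distance between its endpoint
#' centroids is at least `threshold_mm` (default 60 mm, a conventional cut;
#' always report the threshold used).  The observed long/short split is
#' tested against `expected` proportions with a one-degree-of-freedom
#' chi-squared goodness-of-fit test; by default the expected proportions
#' are those of all atlas edges, i.e. the null that the predictive network
#' draws edges without regard to length.
#'
#' @inheritParams node_degree
#' @param threshold_mm Long-range distance cut in mm (> 0).
#' @param expected Expected `c(long, short)` proportions; `NULL` (default)
#'   uses the atlas-wide proportions; both must be positive and sum to 1.
#' @return List: `counts` (named long/short), `proportions`, `threshold_mm`,
#'   `expected`, `chi2`, `p`.
#' @export
range_partition <- function(mask, atlas, threshold_mm = 60, expected = NULL) {
  mask <- check_mask(mask, atlas)
  if (threshold_mm <= 0) stop("range_partition: threshold_mm must be > 0")
  ep <- edge_pairs(nrow(atlas))
  cent <- as.matrix(atlas[, c("x", "y", "z")])
  d <- sqrt(rowSums((cent[ep$i, , drop = FALSE] -
                     cent[ep$j, , drop = FALSE])^2))
  is_long <- d >= threshold_mm
  if (is.null(expected)) {
    expected <- c(long = mean(is_long), short = mean(!is_long))
  } else {
    expected <- stats::setNames(as.numeric(expected), c("long", "short"))
  }
  if (abs(sum(expected) - 1) > 1e-8) {
    stop("range_partition: expected proportions must sum to 1")
  }
  counts <- c(long = sum(is_long & mask), short = sum(!is_long & mask))
  total <- sum(counts)
  chi2 <- p <- NA_real_
  if (total > 0L && all(expected > 0)) {
    gof <- suppressWarnings(stats::chisq.test(counts, p = expected))
    chi2 <- unname(gof$statistic)
    p <- gof$p.value
  }
  list(counts = counts,
       proportions = if (total > 0L) counts / total else counts * NA_real_,
       threshold_mm = threshold_mm, expected = expected,
       chi2 = chi2, p = p)
}

count_matrix_by_label <- function(mask, atlas, labels, levels) {
  ep <- edge_pairs(nrow(atlas))
  li <- match(labels[ep$i[mask]], levels)
  lj <- match(labels[ep$j[mask]], levels)
  if (anyNA(li) || anyNA(lj)) {
    stop("unknown label(s): ",
         paste(unique(c(labels[ep$i[mask]], labels[ep$j[mask]])
                      [is.na(c(li, lj))]), collapse = ", "))
  }
  lo <- pmin(li, lj)
  hi <- pmax(li, lj)
  tab <- table(factor(lo, seq_along(levels)), factor(hi, seq_along(levels)))
  M <- unclass(tab) + t(unclass(tab))
  diag(M) <- diag(unclass(tab))
  dimnames(M) <- list(levels, levels)
  M
}

#' Within/between network edge counts
#'
#' Cell (a, b) is the number of selected edges whose endpoints lie in
#' canonical networks a and b; the matrix is symmetric and its upper
#' triangle plus diagonal sums to the number of selected edges.
#'
#' @inheritParams node_degree
#' @return 10 x 10 symmetric integer matrix over [CANONICAL_NETWORKS].
#' @export
network_matrix <- function(mask, atlas) {
  mask <- check_mask(mask, atlas)
  count_matrix_by_label(mask, atlas, atlas$network, CANONICAL_NETWORKS)
}

#' Within/between macroscale-region edge counts
#'
#' Like [network_matrix()] but over the free-form `region` labels of the
#' atlas (ordered by first appearance).
#'
#' @inheritParams node_degree
#' @return Symmetric integer matrix over the atlas's region labels.
#' @export
region_matrix <- function(mask, atlas) {
  mask <- check_mask(mask, atlas)
  count_matrix_by_label(mask, atlas, atlas$region, unique(atlas$region))
}

#' Export a predictive network as an annotated edge list
#'
#' One TSV row per selected edge: node ids, hemispheres, networks, and the
#' centroid distance in mm.  This is the portable localization output (in
#' place of an interactive brain viewer) and round-trips: the mask can be
#' reconstructed from the node-id columns.
#'
#' @inheritParams node_degree
#' @param path Output file path.
#' @return The exported data.frame, invisibly.
#' @export
export_edge_list <- function(mask, atlas, path) {
  mask <- check_mask(mask, atlas)
  ep <- edge_pairs(nrow(atlas))
  cent <- as.matrix(atlas[, c("x", "y", "z")])
  i <- ep$i[mask]
  j <- ep$j[mask]
  out <- data.frame(
    node_i = i, node_j = j,
    hemisphere_i = atlas$hemisphere[i], hemisphere_j = atlas$hemisphere[j],
    network_i = atlas$network[i], network_j = atlas$network[j],
    distance_mm = sqrt(rowSums((cent[i, , drop = FALSE] -
                                cent[j, , drop = FALSE])^2))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}

#' Read an exported edge list back into a mask
#' @param path Edge-list TSV written by [export_edge_list()].
#' @param atlas The `cpm_atlas` the list was exported against.
#' @return Logical edge mask in canonical order.
#' @export
read_edge_list_mask <- function(path, atlas) {
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  K <- nrow(atlas)
  ep <- edge_pairs(K)
  idx <- matrix(0L, K, K)
  idx[cbind(ep$i, ep$j)] <- seq_len(ep$n_edges)
  mask <- logical(ep$n_edges)
  if (nrow(el)) {
    pos <- idx[cbind(pmin(el$node_i, el$node_j), pmax(el$node_i, el$node_j))]
    if (any(pos == 0L)) stop("edge list contains invalid node pairs")
    mask[pos] <- TRUE
  }
  mask
}

#' Full localization summary of a predictive network
#'
#' Bundles [node_degree()], [hemisphere_partition()], [range_partition()],
#' [network_matrix()] and [region_matrix()] for one edge mask.
#'
#' @inheritParams range_partition
#' @return List of class `cpm_network_summary` with elements `total_edges`,
#'   `degree`, `hemisphere_counts`, `range`, `network_matrix`,
#'   `region_matrix`, `n_nodes_involved`.
#' @export
summarize_network <- function(mask, atlas, threshold_mm = 60,
                              expected = NULL) {
  mask <- check_mask(mask, atlas)
  deg <- node_degree(mask, atlas)
  structure(list(
    total_edges = sum(mask),
    degree = deg,
    n_nodes_involved = sum(deg > 0),
    hemisphere_counts = hemisphere_partition(mask, atlas),
    range = range_partition(mask, atlas, threshold_mm, expected),
    network_matrix = network_matrix(mask, atlas),
    region_matrix = region_matrix(mask, atlas)
  ), class = "cpm_network_summary")
}

#' @export
print.cpm_network_summary <- function(x, ...) {
  cat(sprintf("<cpm_network_summary> %d edges over %d nodes\n",
              x$total_edges, x$n_nodes_involved))
  h <- x$hemisphere_counts
  cat(sprintf("  hemispheres: %d ipsi-R, %d ipsi-L, %d interhemispheric\n",
              h[["ipsi_R"]], h[["ipsi_L"]], h[["inter"]]))
  r <- x$range
  if (x$total_edges > 0) {
    cat(sprintf("  range (>= %g mm): %d long (%.0f%%), %d short (%.0f%%), chi2 = %.2f, p = %.2g\n",
                r$threshold_mm, r$counts[["long"]],
                100 * r$proportions[["long"]], r$counts[["short"]],
                100 * r$proportions[["short"]], r$chi2, r$p))
  }
  invisible(x)
}
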