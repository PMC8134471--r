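# Atlas, phenotype, time-series and matrix I/O.  All files are plain
# delimited text; objects are validated on load so downstream code can
# assume the invariants.

#' The ten canonical functional network labels
#'
#' Medial frontal (MF), frontoparietal (FP), default mode (DMN),
#' motor/sensory (Mot), visual A (VI), visual B (VII), visual association
#' (VAs), salience (SAL), subcortical (SC), and cerebellum (CBL).
#' @export
CANONICAL_NETWORKS <- c("MF", "FP", "DMN", "Mot", "VI", "VII", "VAs",
                        "SAL", "SC", "CBL")

#' Construct and validate a node atlas
#'
#' An atlas maps node ids to hemisphere, canonical network, macroscale
#' region and an MNI-space centroid.  Node ids must be contiguous 1..K and
#' rows must be in node order; the canonical full-brain parcellation has
#' K = 268 nodes, but any K works (synthetic atlases are typically smaller).
#'
#' @param nodes data.frame with columns `node_id`, `hemisphere` ("L"/"R"),
#'   `network` (one of [CANONICAL_NETWORKS]), `region` (free-form macroscale
#'   label), and centroid coordinates `x`, `y`, `z` in mm.
#' @return The validated data.frame with class `cpm_atlas`.
#' @export
as_atlas <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  need <- c("node_id", "hemisphere", "network", "region", "x", "y", "z")
  miss <- setdiff(need, names(nodes))
  if (length(miss)) {
    stop("atlas: missing column(s): ", paste(miss, collapse = ", "))
  }
  K <- nrow(nodes)
  if (K < 2L) stop("atlas: need at least 2 nodes")
  ids <- nodes$node_id
  if (anyDuplicated(ids)) {
    stop("atlas: duplicate node_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!identical(as.integer(ids), seq_len(K))) {
    stop("atlas: node_id must be contiguous 1..K in row order")
  }
  bad_h <- !nodes$hemisphere %in% c("L", "R")
  if (any(bad_h)) {
    stop("atlas: invalid hemisphere at node(s) ",
         paste(ids[bad_h], collapse = ", "), " (must be L or R)")
  }
  bad_n <- !nodes$network %in% CANONICAL_NETWORKS
  if (any(bad_n)) {
    stop("atlas: unknown network label(s): ",
         paste(unique(nodes$network[bad_n]), collapse = ", "),
         " (expected one of ", paste(CANONICAL_NETWORKS, collapse = ", "), ")")
  }
  cent <- as.matrix(nodes[, c("x", "y", "z")])
  if (!is.numeric(cent) || any(!is.finite(cent))) {
    stop("atlas: centroid coordinates must be finite numbers")
  }
  nodes$node_id <- as.integer(ids)
  class(nodes) <- c("cpm_atlas", "data.frame")
  nodes
}

#' @export
print.cpm_atlas <- function(x, ...) {
  cat(sprintf("<cpm_atlas> %d nodes (%d L / %d R), %d networks, %d regions\n",
              nrow(x), sum(x$hemisphere == "L"), sum(x$hemisphere == "R"),
              length(unique(x$network)), length(unique(x$region))))
  invisible(x)
}

#' Read / write an atlas table
#'
#' Tab-separated, header `node_id hemisphere network region x y z`.
#' @param path File path.
#' @return `read_atlas()` a validated `cpm_atlas`; `write_atlas()` the path,
#'   invisibly.
#' @export
read_atlas <- function(path) {
  as_atlas(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_atlas
#' @param atlas A `cpm_atlas`.
#' @export
write_atlas <- function(atlas, path) {
  utils::write.table(as.data.frame(atlas), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a phenotype table
#'
#' Comma-separated with header; required columns `subject_id` and
#' `child_ari`; conventional extras are `parent_ari`, `age`, `sex`,
#' `motion`, `adhd`, `anxiety`, `med_*` flags and `state_frustration`.
#' Empty cells are missing values.  ARI totals (six items scored 0-2) must
#' lie in 0-12; missingness is preserved, never imputed.
#'
#' @param path File path.
#' @return A data.frame, one row per subject.
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotypes(ph)
}

#' @rdname read_phenotypes
#' @param phenotypes Phenotype data.frame.
#' @export
write_phenotypes <- function(phenotypes, path) {
  utils::write.csv(phenotypes, path, row.names = FALSE, na = "")
  invisible(path)
}

validate_phenotypes <- function(ph) {
  if (!"subject_id" %in% names(ph)) stop("phenotypes: missing subject_id column")
  ph$subject_id <- as.character(ph$subject_id)
  if (anyDuplicated(ph$subject_id)) {
    stop("phenotypes: duplicate subject_id: ",
         paste(unique(ph$subject_id[duplicated(ph$subject_id)]), collapse = ", "))
  }
  for (col in intersect(c("child_ari", "parent_ari"), names(ph))) {
    v <- ph[[col]]
    if (!is.numeric(v)) stop("phenotypes: column ", col, " must be numeric")
    bad <- which(!is.na(v) & (v < 0 | v > 12))
    if (length(bad)) {
      stop(sprintf("phenotypes: %s out of range [0, 12] at row(s) %s",
                   col, paste(bad, collapse = ", ")))
    }
  }
  ph
}

#' Read a node-time-series table
#'
#' Tab-separated, one file per subject and condition: first column
#' `node_id`, remaining columns the time points `t1..tT`.  Rows must cover
#' the atlas nodes; they are matched by id (and reordered if needed), not
#' by position.
#'
#' @param path File path.
#' @param atlas Optional `cpm_atlas`; when given, ids are checked against it.
#' @return K x T numeric matrix in atlas node order.
#' @export
read_time_series <- function(path, atlas = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (names(tab)[1L] != "node_id") {
    stop("time series: first column must be node_id (got ", names(tab)[1L], ")")
  }
  ids <- as.integer(tab$node_id)
  X <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(X)) stop("time series: non-numeric cells in ", path)
  K <- if (is.null(atlas)) length(ids) else nrow(atlas)
  if (anyDuplicated(ids) || !setequal(ids, seq_len(K))) {
    stop("time series: node_id must be exactly 1..", K, " in ", path)
  }
  X <- X[order(ids), , drop = FALSE]
  rownames(X) <- seq_len(K)
  X
}

#' Compute a Fisher z connectome from node time series
#'
#' Pairwise Pearson correlations between all node time courses, clipped to
#' `|r| <= 1 - 1e-7` and Fisher z-transformed (`atanh`), giving a symmetric
#' K x K matrix with zero diagonal.  The clip keeps degenerate perfect
#' correlations finite (z ~ 8.4) so edge-wise statistics stay defined.
#'
#' @param ts K x T numeric matrix of node time courses (rows = nodes in
#'   atlas order, columns = time points; T >= 3).
#' @return Symmetric K x K Fisher z matrix, diagonal 0.
#' @export
compute_connectivity <- function(ts) {
  if (!is.matrix(ts) || !is.numeric(ts)) {
    stop("compute_connectivity: ts must be a numeric matrix (nodes x time)")
  }
  if (any(!is.finite(ts))) stop("compute_connectivity: non-finite values in time series")
  if (ncol(ts) < 3L) {
    stop("compute_connectivity: need at least 3 time points, got ", ncol(ts))
  }
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    stop("compute_connectivity: zero-variance node(s): ",
         paste(which(sds == 0), collapse = ", "))
  }
  r <- stats::cor(t(ts))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  z
}

#' Read / write a connectivity matrix
#'
#' Whitespace- or comma-delimited K x K numeric text, no header.  On read
#' the matrix is checked for symmetry (1e-8) and finite off-diagonal
#' entries, and the diagonal is reset to 0.
#'
#' @param path File path.
#' @return `read_connectivity_matrix()`: a symmetric K x K matrix.
#' @export
read_connectivity_matrix <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
  M <- as.matrix(utils::read.table(path, sep = sep, header = FALSE))
  dimnames(M) <- NULL
  if (nrow(M) != ncol(M)) {
    stop(sprintf("connectivity matrix %s is %d x %d, not square",
                 path, nrow(M), ncol(M)))
  }
  if (!is.numeric(M)) stop("connectivity matrix ", path, ": non-numeric cells")
  diag(M) <- 0
  if (any(!is.finite(M))) stop("connectivity matrix ", path, ": non-finite edges")
  if (max(abs(M - t(M))) > 1e-8) {
    stop("connectivity matrix ", path, " is asymmetric beyond 1e-8")
  }
  M
}

#' @rdname read_connectivity_matrix
#' @param M Symmetric K x K matrix.
#' @export
write_connectivity_matrix <- function(M, path) {
  utils::write.table(format(M, digits = 17, trim = TRUE, scientific = TRUE),
                     path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a manifest of per-subject connectivity matrices
#'
#' The manifest is a TSV with header `subject_id condition path`; paths are
#' resolved relative to the manifest's directory.
#'
#' @param path Manifest file path.
#' @param condition Optional filter ("frustration" / "nonfrustration").
#' @return Named list of matrices (names = subject ids, in manifest order),
#'   with the manifest rows attached as attribute `"manifest"`.
#' @export
read_matrix_manifest <- function(path, condition = NULL) {
  man <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "condition", "path")
  if (!all(need %in% names(man))) {
    stop("manifest: header must contain ", paste(need, collapse = ", "))
  }
  if (!is.null(condition)) man <- man[man$condition == condition, , drop = FALSE]
  if (!nrow(man)) stop("manifest: no rows", if (!is.null(condition))
    paste0(" for condition '", condition, "'") else "")
  base <- dirname(path)
  mats <- lapply(man$path, function(p) {
    read_connectivity_matrix(if (startsWith(p, "/")) p else file.path(base, p))
  })
  names(mats) <- man$subject_id
  attr(mats, "manifest") <- man
  mats
}
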