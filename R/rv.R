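#' Escoufier Rv coefficient between two landmark coordinate blocks
#'
#' The Rv coefficient is a matrix-level generalization of the squared
#' Pearson correlation between two sets of variables — here the x/y
#' coordinate block of one landmark against another, across specimens. With
#' column-centered `N x 2` blocks `X` and `Y` and cross-product matrices
#' `S_xy = X'Y`,
#'
#' \deqn{Rv = tr(S_{xy} S_{yx}) / \sqrt{tr(S_{xx}^2)\, tr(S_{yy}^2)}}
#'
#' i.e. a squared cosine between positive semi-definite matrices. It lies in
#' \[0, 1\], equals 1 for a block against itself, equals 0 for uncorrelated
#' blocks, and is invariant to rotation and positive scaling of either block
#' (translation is absorbed by the centering) — which is what makes it
#' suitable for Procrustes-aligned shape data.
#'
#' @param x,y numeric `N x 2` matrices (same `N >= 3`): one landmark's
#'   coordinates across `N` specimens.
#' @return scalar in \[0, 1\].
#' @export
rv_coefficient <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != 2L || ncol(y) != 2L)
    stop("shape error: blocks must be N x 2 matrices", call. = FALSE)
  if (nrow(x) != nrow(y))
    stop("shape error: blocks must share the same number of specimens",
         call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  sxx <- crossprod(x); syy <- crossprod(y); sxy <- crossprod(x, y)
  den <- sqrt(sum(sxx * sxx) * sum(syy * syy))
  if (den == 0)
    stop("undefined correlation: zero-variance block", call. = FALSE)
  # tr(S_xy S_yx) = ||S_xy||_F^2 since S_yx = S_xy'
  val <- sum(sxy * sxy) / den
  min(max(val, 0), 1)
}

#' Rv matrix container
#'
#' @param values symmetric numeric matrix of Rv coefficients in \[0, 1\]
#'   with unit diagonal.
#' @param labels landmark labels (row/column names).
#' @param n_specimens number of specimens the coefficients were estimated
#'   from (`NA` if unknown, e.g. matrices read from file).
#' @return object of class `rv_matrix`.
#' @export
rv_matrix_obj <- function(values, labels = rownames(values),
                          n_specimens = NA_integer_) {
  values <- as.matrix(values)
  k <- nrow(values)
  if (is.null(labels)) labels <- paste0("MP", seq_len(k))
  if (ncol(values) != k) stop("Rv matrix must be square", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-8)
    stop("Rv matrix must be symmetric", call. = FALSE)
  if (any(values < -1e-12 | values > 1 + 1e-12))
    stop("value error: Rv entries must lie in [0, 1]", call. = FALSE)
  values <- pmin(pmax((values + t(values)) / 2, 0), 1)
  diag(values) <- 1
  dimnames(values) <- list(labels, labels)
  structure(list(values = values, labels = labels,
                 n_specimens = as.integer(n_specimens)),
            class = "rv_matrix")
}

#' @export
print.rv_matrix <- function(x, ...) {
  k <- length(x$labels)
  off <- x$values[upper.tri(x$values)]
  cat("Rv matrix: ", k, " landmarks (", k * (k - 1) / 2, " pairs), ",
      "n = ", x$n_specimens, "\n", sep = "")
  cat("  off-diagonal range: [", signif(min(off), 3), ", ",
      signif(max(off), 3), "]\n", sep = "")
  invisible(x)
}

#' All-pairs Rv matrix over aligned measurement points
#'
#' Computes [rv_coefficient()] for every pair of measurement points in an
#' aligned dataset. When replicate digitizations are present the default is
#' to average them per specimen first (`use = "specimen_means"`):
#' digitization error is certified negligible by the Procrustes ANOVA, and
#' the correlations target between-individual variation.
#'
#' @param aligned an [transfer()] result.
#' @param use `"specimen_means"` (default) or `"all_replicates"`.
#' @return an `rv_matrix`.
#' @export
rv_matrix <- function(aligned, use = c("specimen_means", "all_replicates")) {
  stopifnot(inherits(aligned, "aligned_dataset"))
  use <- match.arg(use)
  coords <- aligned$coords
  if (use == "specimen_means") {
    spec <- aligned$specimen
    ids <- unique(spec)
    k <- dim(coords)[1]
    mcoords <- array(NA_real_, c(k, 2, length(ids)))
    for (s in seq_along(ids)) {
      sel <- which(spec == ids[s])
      mcoords[, , s] <- apply(coords[, , sel, drop = FALSE], c(1, 2), mean)
    }
    coords <- mcoords
  }
  n <- dim(coords)[3]
  if (n < 3L) stop("need >= 3 effective observations", call. = FALSE)
  k <- dim(coords)[1]
  vals <- diag(k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    v <- tryCatch(
      rv_coefficient(t(coords[i, , ]), t(coords[j, , ])),
      error = function(e)
        stop("Rv failed for pair (", aligned$labels[i], ", ",
             aligned$labels[j], "): ", conditionMessage(e), call. = FALSE))
    vals[i, j] <- vals[j, i] <- v
  }
  rv_matrix_obj(vals, aligned$labels, n_specimens = n)
}

#' Correlation network container
#'
#' A weighted undirected graph over landmark labels: `weights[i, j]` holds
#' the retained Rv coefficient (0 where the edge was cut), zero diagonal.
#'
#' @param weights symmetric numeric matrix with zero diagonal.
#' @param labels node labels.
#' @param tau the threshold used to build the network (`NULL` = none).
#' @return object of class `corr_network`.
#' @export
corr_network <- function(weights, labels = rownames(weights), tau = NULL) {
  weights <- as.matrix(weights)
  k <- nrow(weights)
  if (is.null(labels)) labels <- paste0("MP", seq_len(k))
  if (ncol(weights) != k) stop("weight matrix must be square", call. = FALSE)
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("weight matrix must be symmetric", call. = FALSE)
  diag(weights) <- 0
  dimnames(weights) <- list(labels, labels)
  structure(list(labels = labels, weights = weights, tau = tau),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  k <- length(x$labels)
  ne <- sum(x$weights[upper.tri(x$weights)] > 0)
  cat("Correlation network: ", k, " nodes, ", ne, " edges",
      if (!is.null(x$tau)) paste0(" (tau = ", x$tau, ")"), "\n", sep = "")
  invisible(x)
}

#' Number of edges in a correlation network
#' @param net a `corr_network`.
#' @return integer edge count.
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  sum(net$weights[upper.tri(net$weights)] > 0)
}

#' Convert a correlation network to an igraph graph
#' @param net a `corr_network`.
#' @return an igraph object with `name` vertex and `weight` edge attributes
#'   (and a `tau` graph attribute when thresholded).
#' @export
as_igraph_network <- function(net) {
  stopifnot(inherits(net, "corr_network"))
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::graph_attr(g, "tau") <- if (is.null(net$tau)) NA_real_ else net$tau
  g
}

#' Threshold an Rv matrix into a correlation network
#'
#' Converts the correlation matrix into a weighted adjacency matrix: the
#' edge (i, j) is retained with weight `Rv_ij` iff `Rv_ij > tau` (strictly
#' above the threshold), otherwise the weight is 0. With `tau = NULL` no
#' threshold is applied and the result is the complete weighted graph. The
#' node set always equals the full label set; isolated nodes are permitted.
#' Thresholding by a significance level is deliberately not the default:
#' with hundreds of simultaneous tests the familywise type-I error is
#' uncontrolled, so a fixed Rv level is used instead.
#'
#' @param rv an `rv_matrix`.
#' @param tau numeric threshold in \[0, 1), or `NULL` for no threshold.
#'   `tau >= 1` yields an edgeless network, with a warning.
#' @return a [corr_network()].
#' @export
threshold_network <- function(rv, tau = 0.2) {
  stopifnot(inherits(rv, "rv_matrix"))
  w <- rv$values
  diag(w) <- 0
  if (!is.null(tau)) {
    if (!is.numeric(tau) || length(tau) != 1L || tau < 0)
      stop("tau must be a single number in [0, 1), or NULL", call. = FALSE)
    if (tau >= 1)
      warning("tau >= 1 retains no edges", call. = FALSE)
    w[w <= tau] <- 0
  }
  corr_network(w, rv$labels, tau)
}
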