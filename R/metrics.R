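## Clustering agreement metrics and Moran's I spatial autocorrelation.

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same spots,
#' computed from the contingency table:
#' `ARI = (sum_ij C(n_ij,2) - E) / (0.5 (sum_i C(a_i,2) + sum_j C(b_j,2)) - E)`
#' with `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`. Symmetric in its
#' arguments and invariant to relabeling either partition.
#'
#' @param predicted,truth label vectors of equal length (any alphabets).
#' @return Scalar in `[-1, 1]`; 1 for identical partitions, ~0 at chance.
#' @export
ari <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("label vectors differ in length: ", length(predicted), " vs ",
         length(truth))
  n <- length(predicted)
  if (n < 2) stop("need at least 2 observations")
  tab <- table(predicted, truth)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  maxi <- 0.5 * (sum_a + sum_b)
  if (maxi == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maxi - expected)
}

#' Normalized mutual information
#'
#' `NMI = 2 [H(Y) - H(Y|C)] / [H(Y) + H(C)]` (arithmetic-mean
#' normalization), with entropies in nats from the empirical joint
#' distribution. When both partitions are a single cluster the agreement
#' is total and the value is defined as 1 (with a warning).
#'
#' @inheritParams ari
#' @return Scalar in `[0, 1]`.
#' @export
nmi <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("label vectors differ in length: ", length(predicted), " vs ",
         length(truth))
  n <- length(predicted)
  if (n < 2) stop("need at least 2 observations")
  tab <- table(predicted, truth) / n
  px <- rowSums(tab)
  py <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- ent(px); hy <- ent(py)
  if (hx == 0 && hy == 0) {
    warning("both partitions have a single cluster; NMI defined as 1")
    return(1)
  }
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / (px[row(tab)[nz]] * py[col(tab)[nz]])))
  2 * mi / (hx + hy)
}

#' Spatial weights from a spatial view graph
#'
#' Binary adjacency weights (optionally row-standardized) with zero
#' diagonal, for use in [morans_i()].
#'
#' @param g a spatial `view_graph` from [build_spatial_graph()].
#' @param row_standardize divide each row by its sum (default `FALSE`,
#'   i.e. binary weights).
#' @return A `spatial_weights` object: list with `w` (sparse N x N) and
#'   `W_total`.
#' @export
spatial_weights <- function(g, row_standardize = FALSE) {
  stopifnot(inherits(g, "view_graph"))
  w <- g$adj
  if (row_standardize) {
    rs <- Matrix::rowSums(w)
    rs[rs == 0] <- 1
    w <- w / rs
  }
  wt <- sum(w)
  if (wt <= 0) stop("graph has no edges: total weight is 0")
  structure(list(w = w, W_total = wt), class = "spatial_weights")
}

#' Moran's I spatial autocorrelation
#'
#' `I = (N / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Positive values indicate spatially clustered expression, negative
#' values dispersion. Undefined (hard error) for constant `x`.
#'
#' @param x numeric vector of per-spot expression values.
#' @param sw a [spatial_weights] object (or a spatial `view_graph`).
#' @return Scalar Moran's I.
#' @export
morans_i <- function(x, sw) {
  if (inherits(sw, "view_graph")) sw <- spatial_weights(sw)
  stopifnot(inherits(sw, "spatial_weights"))
  n <- length(x)
  if (n != nrow(sw$w))
    stop("x has length ", n, " but weights are ", nrow(sw$w), " x ", ncol(sw$w))
  xc <- x - mean(x)
  ss <- sum(xc^2)
  if (ss == 0) stop("zero variance: Moran's I is undefined for constant x")
  num <- sum(xc * as.vector(sw$w %*% xc))
  (n / sw$W_total) * num / ss
}

#' Moran's I for every gene of a dataset
#'
#' Vectorized evaluation of [morans_i()] across genes using the spatial
#' view graph's binary weights. Constant genes are reported as `NA`.
#'
#' @param ds an [st_dataset].
#' @param graph a spatial `view_graph` over the same spots.
#' @param row_standardize passed to [spatial_weights()].
#' @return data frame `(gene_id, morans_i)` sorted by decreasing statistic
#'   (`NA` last).
#' @export
morans_i_per_gene <- function(ds, graph, row_standardize = FALSE) {
  stopifnot(inherits(ds, "st_dataset"), inherits(graph, "view_graph"))
  if (graph$kind != "spatial")
    stop("graph must be the spatial view (kind 'spatial', got '",
         graph$kind, "')")
  x <- as_dense(ds$expr)
  if (ncol(x) == 0)
    return(data.frame(gene_id = character(0), morans_i = numeric(0)))
  sw <- spatial_weights(graph, row_standardize = row_standardize)
  n <- nrow(x)
  xc <- sweep(x, 2, colMeans(x))
  ss <- colSums(xc^2)
  num <- colSums(xc * as.matrix(sw$w %*% xc))
  i_val <- ifelse(ss > 0, (n / sw$W_total) * num / ss, NA_real_)
  out <- data.frame(gene_id = ds$gene_ids, morans_i = i_val)
  out[order(-out$morans_i, na.last = TRUE), , drop = FALSE]
}
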