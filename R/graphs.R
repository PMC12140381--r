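#' View graphs over spots
#'
#' A `view_graph` holds a binary symmetric adjacency over the N spots of a
#' section, its construction provenance (`kind`, `params`), and — after
#' [normalize_adjacency()] — the symmetric-normalized operator used by the
#' graph convolutions.
#'
#' @name view_graph
#' @keywords internal
NULL

new_view_graph <- function(adj, kind, params) {
  structure(list(adj = adj, kind = kind, params = params,
                 norm_adj = NULL, norm_with_self_loops = NA),
            class = "view_graph")
}

#' @exportS3Method base::print
print.view_graph <- function(x, ...) {
  n <- nrow(x$adj)
  ne <- Matrix::nnzero(x$adj) / 2
  cat("view_graph (", x$kind, "): ", n, " spots, ", ne, " edges",
      if (!is.null(x$norm_adj)) ", normalized", "\n", sep = "")
  invisible(x)
}

#' Build the spatial-proximity view graph
#'
#' Spots `i` and `j` (i != j) are connected iff their Euclidean distance is
#' strictly below the radius `r`. The inequality is strict: spots at
#' distance exactly `r` are not neighbours. `r` is in the coordinate units
#' of the input (for Visium pixel coordinates the conventional default is
#' 700); no unit conversion is performed.
#'
#' @param coords N x 2 matrix of finite spot coordinates.
#' @param r neighbourhood radius (> 0).
#' @return A `view_graph` of kind `"spatial"`.
#' @examples
#' g <- build_spatial_graph(cbind(c(0, 500, 1000), 0), r = 700)
#' as.matrix(g$adj)  # edges 1-2 and 2-3 only
#' @export
build_spatial_graph <- function(coords, r = 700) {
  coords <- as.matrix(coords)
  if (r <= 0) stop("r must be > 0")
  if (nrow(coords) < 1) stop("need at least one spot")
  if (any(!is.finite(coords))) stop("coords must be finite")
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  a <- (d < r)
  diag(a) <- FALSE
  adj <- methods::as(Matrix::Matrix(a * 1, sparse = TRUE), "generalMatrix")
  new_view_graph(adj, "spatial", list(r = r))
}

#' Build the expression-similarity view graph
#'
#' Connects each spot to its `k` most cosine-similar other spots; the
#' directed k-nearest-neighbour lists are then symmetrized (by default by
#' union: an edge exists if either spot lists the other; `"mutual"`
#' requires both). Ties at equal similarity are broken toward the lower
#' spot index. All-zero expression rows have undefined cosine similarity;
#' it is taken as 0 against every other spot (with a warning), so such
#' spots receive neighbours purely by tie-break.
#'
#' @param expr N x G expression matrix (rows are spots).
#' @param k neighbours per spot (0 < k < N).
#' @param symmetrize `"union"` (default) or `"mutual"`.
#' @return A `view_graph` of kind `"feature"`.
#' @export
build_feature_graph <- function(expr, k = 20, symmetrize = c("union", "mutual")) {
  symmetrize <- match.arg(symmetrize)
  x <- as_dense(expr)
  n <- nrow(x)
  if (k <= 0 || k >= n) stop("k must satisfy 0 < k < N (k=", k, ", N=", n, ")")
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) {
    warning(sum(nrm == 0), " all-zero expression row(s); cosine similarity ",
            "taken as 0 for them")
    nrm[nrm == 0] <- 1
  }
  xn <- x / nrm
  sim <- tcrossprod(xn)
  diag(sim) <- -Inf
  # per-row top-k, ties toward the lower index
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    o <- order(-sim[i, ], seq_len(n))
    nb[i, ] <- o[seq_len(k)]
  }
  ii <- rep(seq_len(n), each = k)
  jj <- as.vector(t(nb))
  a <- Matrix::sparseMatrix(i = ii, j = jj, x = 1, dims = c(n, n))
  adj <- if (symmetrize == "union") {
    methods::as((a + Matrix::t(a)) > 0, "dMatrix") * 1
  } else {
    methods::as((a * Matrix::t(a)) > 0, "dMatrix") * 1
  }
  adj <- methods::as(adj, "generalMatrix")
  dimnames(adj) <- list(rownames(x), rownames(x))
  new_view_graph(adj, "feature", list(k = k, symmetrize = symmetrize))
}

#' Symmetric normalization of a view-graph adjacency
#'
#' Computes `D^{-1/2} A D^{-1/2}`. With `add_self_loops` (the convention
#' used by the graph convolutions here) the operator is built on
#' `A + I` with degrees taken from it, so a spot's own features always
#' propagate and isolated spots get an identity row. Without self-loops an
#' isolated spot's row is all zero (never NaN).
#'
#' @param g a `view_graph`.
#' @param add_self_loops add `I` before normalizing (default `TRUE`).
#' @return The graph with `norm_adj` filled in.
#' @export
normalize_adjacency <- function(g, add_self_loops = TRUE) {
  stopifnot(inherits(g, "view_graph"))
  a <- g$adj
  if (add_self_loops) a <- a + Matrix::Diagonal(nrow(a))
  deg <- Matrix::rowSums(a)
  dinv <- ifelse(deg > 0, 1 / sqrt(deg), 0)
  na <- Matrix::Diagonal(x = dinv) %*% a %*% Matrix::Diagonal(x = dinv)
  g$norm_adj <- methods::as(na, "generalMatrix")
  g$norm_with_self_loops <- add_self_loops
  g
}

#' Export a view graph as an edge list
#'
#' @param g a `view_graph`.
#' @param path optional TSV path; when given, writes columns `i, j, weight`
#'   (1-based upper-triangle edges of the binary adjacency).
#' @return The edge-list data frame, invisibly when written.
#' @export
graph_edges <- function(g, path = NULL) {
  stopifnot(inherits(g, "view_graph"))
  tm <- methods::as(methods::as(g$adj, "TsparseMatrix"), "generalMatrix")
  keep <- tm@i < tm@j
  df <- data.frame(i = tm@i[keep] + 1L, j = tm@j[keep] + 1L,
                   weight = tm@x[keep])
  df <- df[order(df$i, df$j), ]
  rownames(df) <- NULL
  if (!is.null(path)) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  }
  df
}
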