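#' Construct a spatial transcriptomics dataset
#'
#' The single container that flows through the pipeline: a spot-by-gene
#' expression matrix (raw counts or transformed values), 2-D spot
#' coordinates in platform units, and optional ground-truth domain labels
#' and an in-tissue mask.
#'
#' @param expr numeric matrix or `dgCMatrix`, N spots x G genes. Row/column
#'   names, when present, must agree with `spot_ids`/`gene_ids`.
#' @param coords numeric matrix or data frame with N rows and 2 columns
#'   (x, y) in the platform's coordinate units (e.g. Visium pixels).
#' @param spot_ids character vector of N unique spot identifiers. Defaults
#'   to `rownames(expr)`, or `spot_1..spot_N` when absent.
#' @param gene_ids character vector of G unique gene identifiers. Defaults
#'   to `colnames(expr)`, or `gene_1..gene_G`.
#' @param labels optional integer-like vector of N domain labels.
#' @param in_tissue optional logical vector of N; spots flagged `FALSE` are
#'   removed by [preprocess_st()]. Absent means all spots are in tissue.
#'
#' @return An object of class `st_dataset`: a list with elements `expr`,
#'   `coords`, `spot_ids`, `gene_ids`, `labels`, `in_tissue`.
#' @examples
#' ds <- st_dataset(matrix(rpois(6, 5), 3, 2), cbind(x = c(0, 1, 2), y = 0))
#' ds
#' @export
st_dataset <- function(expr, coords, spot_ids = NULL, gene_ids = NULL,
                       labels = NULL, in_tissue = NULL) {
  if (is.data.frame(expr)) expr <- as.matrix(expr)
  if (!(is.matrix(expr) || inherits(expr, "sparseMatrix")))
    stop("`expr` must be a matrix or sparse Matrix")
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("`coords` must have exactly 2 columns, got ", ncol(coords))
  storage.mode(coords) <- "double"
  n <- nrow(expr)
  g <- ncol(expr)
  if (nrow(coords) != n)
    stop("expr has ", n, " spots but coords has ", nrow(coords), " rows")
  if (is.null(spot_ids)) spot_ids <- rownames(expr)
  if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  if (is.null(gene_ids)) gene_ids <- colnames(expr)
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(g))
  spot_ids <- as.character(spot_ids)
  gene_ids <- as.character(gene_ids)
  if (length(spot_ids) != n)
    stop("length(spot_ids) (", length(spot_ids), ") != number of spots (", n, ")")
  if (length(gene_ids) != g)
    stop("length(gene_ids) (", length(gene_ids), ") != number of genes (", g, ")")
  if (anyDuplicated(spot_ids)) stop("duplicated spot_ids")
  if (anyDuplicated(gene_ids)) stop("duplicated gene_ids")
  rownames(expr) <- spot_ids
  colnames(expr) <- gene_ids
  rownames(coords) <- spot_ids
  colnames(coords) <- c("x", "y")
  if (!is.null(labels)) {
    if (length(labels) != n)
      stop("length(labels) != number of spots")
    labels <- as.integer(as.factor(labels))
  }
  if (!is.null(in_tissue)) {
    in_tissue <- as.logical(in_tissue)
    if (length(in_tissue) != n) stop("length(in_tissue) != number of spots")
  }
  structure(
    list(expr = expr, coords = coords, spot_ids = spot_ids,
         gene_ids = gene_ids, labels = labels, in_tissue = in_tissue),
    class = "st_dataset"
  )
}

#' @exportS3Method base::print
print.st_dataset <- function(x, ...) {
  cat("st_dataset: ", nrow(x$expr), " spots x ", ncol(x$expr), " genes",
      if (inherits(x$expr, "sparseMatrix")) " (sparse)", "\n", sep = "")
  cat("  coords range: x [", paste(signif(range(x$coords[, 1]), 4), collapse = ", "),
      "], y [", paste(signif(range(x$coords[, 2]), 4), collapse = ", "), "]\n", sep = "")
  if (!is.null(x$labels))
    cat("  labels: ", length(unique(x$labels)), " domains\n", sep = "")
  if (!is.null(x$in_tissue))
    cat("  in_tissue: ", sum(x$in_tissue), "/", length(x$in_tissue), "\n", sep = "")
  invisible(x)
}

#' @export
dim.st_dataset <- function(x) dim(x$expr)

# Internal: validate invariants that preprocessing must preserve.
validate_st <- function(ds, finite = TRUE) {
  stopifnot(inherits(ds, "st_dataset"))
  v <- as_dense(ds$expr)
  if (finite && any(!is.finite(v)))
    stop("expr contains non-finite values")
  if (finite && any(v < 0))
    stop("expr contains negative values")
  invisible(ds)
}

# Internal: dense numeric matrix view of expr.
as_dense <- function(x) {
  if (inherits(x, "sparseMatrix")) as.matrix(x) else x
}

# Internal: subset an st_dataset by spot and/or gene index.
subset_st <- function(ds, spots = NULL, genes = NULL) {
  if (is.null(spots)) spots <- seq_along(ds$spot_ids)
  if (is.null(genes)) genes <- seq_along(ds$gene_ids)
  st_dataset(
    expr = ds$expr[spots, genes, drop = FALSE],
    coords = ds$coords[spots, , drop = FALSE],
    spot_ids = ds$spot_ids[spots],
    gene_ids = ds$gene_ids[genes],
    labels = if (!is.null(ds$labels)) ds$labels[spots],
    in_tissue = if (!is.null(ds$in_tissue)) ds$in_tissue[spots]
  )
}
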