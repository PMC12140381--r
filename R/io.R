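#' Read a spatial transcriptomics dataset from disk
#'
#' Supported on-disk layouts (each a directory):
#' \describe{
#'   \item{`mtx-triplet`}{10x-style triplet: `matrix.mtx` (genes x spots,
#'     MatrixMarket), `features.tsv` (gene ids, first column), `barcodes.tsv`
#'     (spot ids), and `positions.csv` in the Visium dialect
#'     `barcode,in_tissue,array_row,array_col,pxl_row,pxl_col` (no header).
#'     Coordinates are taken from the pixel columns (`x = pxl_col`,
#'     `y = pxl_row`). An optional `labels.tsv` (barcode, label) attaches
#'     ground-truth domains.}
#'   \item{`tsv-dense`}{`expr.tsv`, a dense spots x genes table with spot ids
#'     as row names and gene ids as header, plus `coords.tsv` with columns
#'     `spot_id, x, y` and optional `in_tissue`, `label`.}
#'   \item{`h5-annotated`}{not available in this installation (no HDF5
#'     reader); convert to `mtx-triplet` first. Raises an error.}
#' }
#' Coordinates are joined to the expression matrix by spot id; a spot with no
#' coordinate row is a hard error naming the offending barcode.
#'
#' @param path directory containing the files above.
#' @param format one of `"mtx-triplet"`, `"tsv-dense"`, `"h5-annotated"`.
#' @return An [st_dataset]. The expression matrix is kept sparse for
#'   `mtx-triplet` input.
#' @seealso [write_st()]
#' @export
read_st <- function(path, format = c("mtx-triplet", "tsv-dense", "h5-annotated")) {
  format <- match.arg(format)
  if (!dir.exists(path)) stop("path does not exist: ", path)
  switch(format,
    "mtx-triplet" = read_st_mtx(path),
    "tsv-dense" = read_st_tsv(path),
    "h5-annotated" = stop(
      "format 'h5-annotated' is not supported by this installation ",
      "(no HDF5 reader available); convert to 'mtx-triplet' first"
    )
  )
}

read_st_mtx <- function(path) {
  fp <- function(f) file.path(path, f)
  for (f in c("matrix.mtx", "features.tsv", "barcodes.tsv", "positions.csv"))
    if (!file.exists(fp(f))) stop("missing file: ", fp(f))
  m <- Matrix::readMM(fp("matrix.mtx"))          # genes x spots, 10x layout
  genes <- read.table(fp("features.tsv"), sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)[[1]]
  barcodes <- read.table(fp("barcodes.tsv"), sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)[[1]]
  if (nrow(m) != length(genes))
    stop("matrix.mtx has ", nrow(m), " rows but features.tsv lists ",
         length(genes), " genes")
  if (ncol(m) != length(barcodes))
    stop("matrix.mtx has ", ncol(m), " columns but barcodes.tsv lists ",
         length(barcodes), " barcodes")
  pos <- read.table(fp("positions.csv"), sep = ",", header = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(pos) < 6)
    stop("positions.csv must have 6 columns ",
         "(barcode,in_tissue,array_row,array_col,pxl_row,pxl_col)")
  names(pos) <- c("barcode", "in_tissue", "array_row", "array_col",
                  "pxl_row", "pxl_col")
  idx <- match(barcodes, pos$barcode)
  if (anyNA(idx))
    stop("no coordinates for barcode(s): ",
         paste(utils::head(barcodes[is.na(idx)], 5), collapse = ", "))
  pos <- pos[idx, ]
  labels <- NULL
  if (file.exists(fp("labels.tsv"))) {
    lab <- read.table(fp("labels.tsv"), sep = "\t", header = FALSE,
                      stringsAsFactors = FALSE)
    li <- match(barcodes, lab[[1]])
    if (anyNA(li))
      stop("labels.tsv missing barcode(s): ",
           paste(utils::head(barcodes[is.na(li)], 5), collapse = ", "))
    labels <- lab[[2]][li]
  }
  expr <- methods::as(Matrix::t(m), "CsparseMatrix")  # spots x genes
  st_dataset(
    expr = expr,
    coords = cbind(x = pos$pxl_col, y = pos$pxl_row),
    spot_ids = barcodes, gene_ids = genes,
    labels = labels,
    in_tissue = as.logical(pos$in_tissue)
  )
}

read_st_tsv <- function(path) {
  fe <- file.path(path, "expr.tsv")
  fc <- file.path(path, "coords.tsv")
  for (f in c(fe, fc)) if (!file.exists(f)) stop("missing file: ", f)
  expr <- as.matrix(read.table(fe, sep = "\t", header = TRUE, row.names = 1,
                               check.names = FALSE))
  co <- read.table(fc, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  idx <- match(rownames(expr), co$spot_id)
  if (anyNA(idx))
    stop("no coordinates for spot(s): ",
         paste(utils::head(rownames(expr)[is.na(idx)], 5), collapse = ", "))
  co <- co[idx, ]
  st_dataset(
    expr = expr,
    coords = cbind(x = co$x, y = co$y),
    spot_ids = rownames(expr),
    labels = if ("label" %in% names(co)) co$label,
    in_tissue = if ("in_tissue" %in% names(co)) as.logical(co$in_tissue)
  )
}

#' Write a spatial transcriptomics dataset to disk
#'
#' Inverse of [read_st()]: integer count matrices survive a
#' write-then-read round trip exactly. Refuses to write non-finite
#' expression values.
#'
#' @param ds an [st_dataset].
#' @param path output directory (created if needed).
#' @param format `"mtx-triplet"` or `"tsv-dense"` (see [read_st()]).
#' @return `path`, invisibly.
#' @export
write_st <- function(ds, path, format = c("mtx-triplet", "tsv-dense")) {
  format <- match.arg(format)
  validate_st(ds)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path)) stop("cannot create directory: ", path)
  fp <- function(f) file.path(path, f)
  if (format == "mtx-triplet") {
    m <- methods::as(Matrix::t(methods::as(ds$expr, "CsparseMatrix")),
                     "generalMatrix")
    Matrix::writeMM(m, fp("matrix.mtx"))
    writeLines(ds$gene_ids, fp("features.tsv"))
    writeLines(ds$spot_ids, fp("barcodes.tsv"))
    it <- if (is.null(ds$in_tissue)) rep(1L, length(ds$spot_ids))
          else as.integer(ds$in_tissue)
    pos <- data.frame(
      barcode = ds$spot_ids, in_tissue = it,
      array_row = 0L, array_col = 0L,
      pxl_row = ds$coords[, "y"], pxl_col = ds$coords[, "x"]
    )
    write.table(pos, fp("positions.csv"), sep = ",", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    if (!is.null(ds$labels))
      write.table(data.frame(ds$spot_ids, ds$labels), fp("labels.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
  } else {
    expr <- as_dense(ds$expr)
    write.table(expr, fp("expr.tsv"), sep = "\t", quote = FALSE,
                col.names = NA)
    co <- data.frame(spot_id = ds$spot_ids,
                     x = ds$coords[, "x"], y = ds$coords[, "y"])
    if (!is.null(ds$in_tissue)) co$in_tissue <- as.integer(ds$in_tissue)
    if (!is.null(ds$labels)) co$label <- ds$labels
    write.table(co, fp("coords.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
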