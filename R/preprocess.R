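#' Preprocess a spatial transcriptomics dataset
#'
#' Applies the standard preprocessing chain for spot-level count data, in
#' this order:
#' \enumerate{
#'   \item remove spots flagged not-in-tissue (when an `in_tissue` mask is
#'     present; absent means every spot is kept);
#'   \item remove genes expressed (count > 0) in fewer than
#'     `min_spots_per_gene` spots;
#'   \item `log1p` transform (when `do_log`);
#'   \item library-size normalization to `target_sum` per spot (when
#'     `do_libsize_norm`);
#'   \item keep the `n_hvg` most highly variable genes by Seurat-style
#'     binned normalized dispersion.
#' }
#' The default order applies the log transform *before* library-size
#' normalization; set `normalize_first = TRUE` for the more conventional
#' normalize-then-log order.
#'
#' @param ds an [st_dataset] holding raw non-negative counts.
#' @param min_spots_per_gene genes expressed in fewer spots are dropped
#'   (default 3).
#' @param n_hvg number of highly variable genes to retain (default 3000).
#'   When `n_hvg` is `NULL` or at least the number of remaining genes, all
#'   are kept (with a warning in the latter case).
#' @param do_log apply `log1p`.
#' @param do_libsize_norm scale each spot to a common library size.
#' @param normalize_first normalize before the log transform instead of
#'   after.
#' @param target_sum per-spot sum after normalization (default `1e4`).
#' @return A list with `dataset` (the filtered, transformed [st_dataset])
#'   and `report`, a `preprocess_report` recording `n_spots_removed`,
#'   `n_genes_removed`, `n_hvg_kept` and `steps_applied`.
#' @examples
#' ds <- simulate_st(sim_spec(n_rows = 6, n_cols = 6, C = 2, G = 40, seed = 1))
#' pp <- preprocess_st(ds, n_hvg = 20)
#' pp$report
#' @export
preprocess_st <- function(ds, min_spots_per_gene = 3, n_hvg = 3000,
                          do_log = TRUE, do_libsize_norm = TRUE,
                          normalize_first = FALSE, target_sum = 1e4) {
  stopifnot(inherits(ds, "st_dataset"))
  validate_st(ds)
  steps <- character(0)

  n0 <- nrow(ds$expr)
  if (!is.null(ds$in_tissue)) {
    keep <- which(ds$in_tissue)
    if (length(keep) == 0L) stop("no in-tissue spots remain")
    if (length(keep) < n0) {
      ds <- subset_st(ds, spots = keep)
      steps <- c(steps, "filter_spots")
    }
  }
  n_spots_removed <- n0 - nrow(ds$expr)

  g0 <- ncol(ds$expr)
  n_expressing <- if (inherits(ds$expr, "sparseMatrix")) {
    Matrix::colSums(ds$expr > 0)
  } else {
    colSums(ds$expr > 0)
  }
  keep_g <- which(n_expressing >= min_spots_per_gene)
  if (length(keep_g) == 0L)
    stop("all genes removed: no gene is expressed in at least ",
         min_spots_per_gene, " spots")
  if (length(keep_g) < g0) {
    ds <- subset_st(ds, genes = keep_g)
    steps <- c(steps, "filter_genes")
  }
  n_genes_removed <- g0 - ncol(ds$expr)

  x <- as_dense(ds$expr)
  libnorm <- function(m) {
    ls <- rowSums(m)
    ls[ls == 0] <- 1
    m * (target_sum / ls)
  }
  if (normalize_first) {
    if (do_libsize_norm) { x <- libnorm(x); steps <- c(steps, "libsize_norm") }
    if (do_log)          { x <- log1p(x);  steps <- c(steps, "log1p") }
  } else {
    if (do_log)          { x <- log1p(x);  steps <- c(steps, "log1p") }
    if (do_libsize_norm) { x <- libnorm(x); steps <- c(steps, "libsize_norm") }
  }

  n_hvg_kept <- ncol(x)
  if (!is.null(n_hvg)) {
    if (n_hvg >= ncol(x)) {
      if (n_hvg > ncol(x))
        warning("n_hvg (", n_hvg, ") >= remaining genes (", ncol(x),
                "); keeping all")
    } else {
      disp <- normalized_dispersion(x)
      ord <- order(-disp, ds$gene_ids)  # ties: gene-id lexicographic
      keep_h <- sort(ord[seq_len(n_hvg)])
      x <- x[, keep_h, drop = FALSE]
      ds <- subset_st(ds, genes = keep_h)
      n_hvg_kept <- n_hvg
      steps <- c(steps, "hvg")
    }
  }
  ds$expr <- x
  rownames(ds$expr) <- ds$spot_ids
  colnames(ds$expr) <- ds$gene_ids
  validate_st(ds)

  report <- structure(
    list(n_spots_removed = n_spots_removed,
         n_genes_removed = n_genes_removed,
         n_hvg_kept = n_hvg_kept,
         steps_applied = steps),
    class = "preprocess_report"
  )
  list(dataset = ds, report = report)
}

#' @exportS3Method base::print
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report:\n")
  cat("  spots removed:", x$n_spots_removed, "\n")
  cat("  genes removed:", x$n_genes_removed, "\n")
  cat("  HVGs kept:    ", x$n_hvg_kept, "\n")
  cat("  steps:        ", paste(x$steps_applied, collapse = " -> "), "\n")
  invisible(x)
}

#' Normalized dispersion of each gene
#'
#' Seurat-style highly-variable-gene statistic: per-gene dispersion
#' (variance / mean) z-scored within `nbins` equal-frequency bins of the
#' gene mean, so that variability is judged relative to genes of similar
#' abundance.
#'
#' @param x spots x genes numeric matrix (typically log-transformed).
#' @param nbins number of mean-abundance bins (default 20).
#' @return Numeric vector of length `ncol(x)`; genes with zero mean or a
#'   single-gene bin get dispersion 0.
#' @export
normalized_dispersion <- function(x, nbins = 20) {
  mu <- colMeans(x)
  v <- apply(x, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  nb <- max(1L, min(nbins, length(unique(mu))))
  bins <- cut(mu, breaks = unique(stats::quantile(mu, probs = seq(0, 1, length.out = nb + 1))),
              include.lowest = TRUE)
  out <- numeric(length(disp))
  for (b in levels(bins)) {
    i <- which(bins == b)
    m <- mean(disp[i])
    s <- stats::sd(disp[i])
    out[i] <- if (length(i) < 2 || !is.finite(s) || s == 0) 0 else (disp[i] - m) / s
  }
  names(out) <- colnames(x)
  out
}
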