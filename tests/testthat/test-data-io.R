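test_that("tsv-dense round trip preserves a small dataset exactly", {
  expr <- matrix(c(1, 0, 3, 2, 5, 4), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("gA", "gB")))
  ds <- st_dataset(expr, cbind(x = c(0, 1, 2), y = c(0, 0, 1)),
                   labels = c(1, 1, 2))
  expect_equal(dim(ds), c(3L, 2L))
  dir <- withr::local_tempdir()
  write_st(ds, dir, format = "tsv-dense")
  ds2 <- read_st(dir, format = "tsv-dense")
  expect_equal(unname(as.matrix(ds2$expr)), unname(expr),
               ignore_attr = TRUE)
  expect_equal(unname(ds2$coords), unname(ds$coords))
  expect_equal(ds2$labels, ds$labels)
  expect_identical(ds2$spot_ids, ds$spot_ids)
})

test_that("mtx-triplet round trip is lossless for integer counts and stays sparse", {
  set.seed(1)
  n <- 40; g <- 60
  m <- matrix(rbinom(n * g, 1, 0.1) * rpois(n * g, 8), n, g)
  ds <- st_dataset(Matrix::Matrix(m, sparse = TRUE),
                   cbind(x = runif(n) * 100, y = runif(n) * 100))
  dir <- withr::local_tempdir()
  write_st(ds, dir, format = "mtx-triplet")
  ds2 <- read_st(dir, format = "mtx-triplet")
  expect_s4_class(ds2$expr, "sparseMatrix")
  expect_equal(unname(as.matrix(ds2$expr)), m, ignore_attr = TRUE)
  expect_equal(unname(ds2$coords), unname(ds$coords))
  expect_null(ds2$labels)

  # sparse storage is far smaller than the dense table for the same data
  dir2 <- withr::local_tempdir()
  big <- Matrix::rsparsematrix(500, 2000, density = 0.01)
  big@x <- abs(round(big@x * 10))
  dsb <- st_dataset(big, cbind(runif(500), runif(500)))
  write_st(dsb, dir2, format = "mtx-triplet")
  sz_mtx <- file.size(file.path(dir2, "matrix.mtx"))
  expect_lt(sz_mtx, 500 * 2000)   # a dense TSV would need >= 2 bytes/cell
})

test_that("a spot without coordinates is a hard error naming the barcode", {
  expr <- matrix(1:10, nrow = 5,
                 dimnames = list(paste0("bc", 1:5), c("g1", "g2")))
  ds <- st_dataset(expr, cbind(x = 1:5, y = 1:5))
  dir <- withr::local_tempdir()
  write_st(ds, dir, format = "mtx-triplet")
  pos <- readLines(file.path(dir, "positions.csv"))
  writeLines(pos[-3], file.path(dir, "positions.csv"))  # drop bc3
  expect_error(read_st(dir, format = "mtx-triplet"), "bc3")
})

test_that("dimension mismatches between matrix and id lists are hard errors", {
  ds <- st_dataset(matrix(1:10, nrow = 5), cbind(1:5, 1:5))
  dir <- withr::local_tempdir()
  write_st(ds, dir, format = "mtx-triplet")
  writeLines(c(readLines(file.path(dir, "barcodes.tsv")), "extra_bc"),
             file.path(dir, "barcodes.tsv"))
  expect_error(read_st(dir, format = "mtx-triplet"), "6 barcodes")
})

test_that("write_st refuses non-finite values and h5 input is rejected clearly", {
  expr <- matrix(c(1, NaN, 3, 4), 2, 2)
  ds <- st_dataset(expr, cbind(1:2, 1:2))
  expect_error(write_st(ds, withr::local_tempdir()), "non-finite")
  expect_error(read_st(withr::local_tempdir(), format = "h5-annotated"),
               "not supported")
})

test_that("dataset invariants are enforced at construction", {
  expect_error(st_dataset(matrix(1:4, 2), cbind(1:3, 1:3)), "2 spots")
  expect_error(st_dataset(matrix(1:4, 2, dimnames = list(c("a", "a"), NULL)),
                          cbind(1:2, 1:2)), "duplicated")
  expect_error(st_dataset(matrix(1:4, 2), cbind(1:2, 1:2),
                          gene_ids = c("g", "g")), "duplicated")
})

test_that("gene filtering removes genes expressed in fewer than min spots", {
  # gene 2 is nonzero in exactly 2 of 4 spots -> dropped at threshold 3
  expr <- cbind(g1 = c(1, 2, 3, 4), g2 = c(5, 0, 0, 6), g3 = c(1, 1, 1, 0))
  ds <- st_dataset(expr, cbind(1:4, 1:4))
  pp <- preprocess_st(ds, min_spots_per_gene = 3, n_hvg = NULL,
                      do_log = FALSE, do_libsize_norm = FALSE)
  expect_equal(pp$report$n_genes_removed, 1)
  expect_identical(pp$dataset$gene_ids, c("g1", "g3"))

  expect_error(
    preprocess_st(st_dataset(matrix(0, 4, 3), cbind(1:4, 1:4))),
    "all genes removed")
})

test_that("not-in-tissue spots are removed before anything else", {
  ds <- st_dataset(matrix(1:12, 4, 3), cbind(1:4, 1:4),
                   in_tissue = c(TRUE, FALSE, TRUE, TRUE))
  pp <- preprocess_st(ds, min_spots_per_gene = 1, n_hvg = NULL,
                      do_log = FALSE, do_libsize_norm = FALSE)
  expect_equal(pp$report$n_spots_removed, 1)
  expect_equal(nrow(pp$dataset$expr), 3)
  expect_true("filter_spots" %in% pp$report$steps_applied)
})

test_that("HVG selection matches a brute-force dispersion ranking", {
  set.seed(11)
  expr <- matrix(rpois(100 * 50, lambda = rep(exp(rnorm(50, 1, 1)), each = 100)),
                 100, 50)
  ds <- st_dataset(expr, cbind(runif(100), runif(100)))
  pp <- preprocess_st(ds, min_spots_per_gene = 0, n_hvg = 10,
                      do_log = TRUE, do_libsize_norm = TRUE)
  expect_equal(ncol(pp$dataset$expr), 10)
  expect_equal(pp$report$n_hvg_kept, 10)

  # independent ranking: recompute binned dispersion z-scores with loops
  x <- ds$expr
  x <- log1p(x)
  x <- x * (1e4 / rowSums(x))
  mu <- colMeans(x)
  disp <- apply(x, 2, var) / mu
  nb <- min(20, length(unique(mu)))
  brk <- unique(quantile(mu, seq(0, 1, length.out = nb + 1)))
  bin <- cut(mu, brk, include.lowest = TRUE)
  z <- numeric(50)
  for (b in levels(bin)) {
    i <- which(bin == b)
    z[i] <- if (length(i) < 2 || sd(disp[i]) == 0) 0
            else (disp[i] - mean(disp[i])) / sd(disp[i])
  }
  want <- sort(ds$gene_ids[order(-z, ds$gene_ids)][1:10])
  expect_identical(sort(pp$dataset$gene_ids), want)
})

test_that("filtering is idempotent and independent of gene order", {
  set.seed(5)
  expr <- matrix(rbinom(20 * 15, 3, 0.3), 20, 15)
  ds <- st_dataset(expr, cbind(1:20, 1:20))
  p1 <- preprocess_st(ds, min_spots_per_gene = 3, n_hvg = NULL,
                      do_log = FALSE, do_libsize_norm = FALSE)
  p2 <- preprocess_st(p1$dataset, min_spots_per_gene = 3, n_hvg = NULL,
                      do_log = FALSE, do_libsize_norm = FALSE)
  expect_equal(p2$report$n_genes_removed, 0)
  expect_equal(p2$report$n_spots_removed, 0)
  expect_identical(p2$dataset$expr, p1$dataset$expr)

  # permuting gene columns then preprocessing == preprocessing then permuting
  perm <- sample(15)
  dsp <- st_dataset(expr[, perm], cbind(1:20, 1:20),
                    gene_ids = ds$gene_ids[perm])
  pp <- preprocess_st(dsp, min_spots_per_gene = 3, n_hvg = NULL,
                      do_log = FALSE, do_libsize_norm = FALSE)
  common <- intersect(pp$dataset$gene_ids, p1$dataset$gene_ids)
  expect_setequal(pp$dataset$gene_ids, p1$dataset$gene_ids)
  expect_equal(pp$dataset$expr[, common], p1$dataset$expr[, common])
})

test_that("n_hvg >= remaining genes keeps all genes with a warning", {
  ds <- st_dataset(matrix(rpois(40, 5), 10, 4), cbind(1:10, 1:10))
  expect_warning(
    pp <- preprocess_st(ds, min_spots_per_gene = 1, n_hvg = 10),
    "keeping all")
  expect_equal(ncol(pp$dataset$expr), 4)
})

test_that("preprocessing order follows the log-then-normalize default", {
  expr <- matrix(c(1, 3, 9, 27), 2, 2,
                 dimnames = list(c("s1", "s2"), c("g1", "g2")))
  ds <- st_dataset(expr, cbind(1:2, 1:2))
  pp <- preprocess_st(ds, min_spots_per_gene = 0, n_hvg = NULL,
                      target_sum = 10)
  expect_identical(pp$report$steps_applied, c("log1p", "libsize_norm"))
  manual <- log1p(expr)
  manual <- manual * (10 / rowSums(manual))
  expect_equal(unname(as.matrix(pp$dataset$expr)), unname(manual))

  pp2 <- preprocess_st(ds, min_spots_per_gene = 0, n_hvg = NULL,
                       target_sum = 10, normalize_first = TRUE)
  expect_identical(pp2$report$steps_applied, c("libsize_norm", "log1p"))
})
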