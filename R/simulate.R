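#' Specification for a synthetic layered tissue section
#'
#' Describes a regular grid of spots partitioned into `C` spatial domains,
#' each with its own program of marker genes, from which overdispersed
#' (negative-binomial) counts are drawn. The defaults emulate the laminar
#' organisation of cortical tissue at Visium-like geometry: spots spaced
#' 100 coordinate units apart so that the default spatial-graph radius of
#' 700 spans a realistic neighbourhood.
#'
#' @param n_rows,n_cols grid dimensions (spots = `n_rows * n_cols`).
#' @param layout `"laminar"` (C horizontal bands), `"blocks"` (rectangular
#'   tiles), or `"shuffled"` (laminar labels randomly permuted across spots,
#'   destroying spatial coherence while keeping the expression-label joint
#'   distribution identical to `"laminar"`).
#' @param C number of domains (>= 2).
#' @param G number of genes.
#' @param n_program_genes marker genes per domain (`n_program_genes * C`
#'   must not exceed `G`).
#' @param effect_size mean log-scale shift of a marker gene in its own
#'   domain (default 1.5).
#' @param dispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2; default 0.3, typical of UMI counts).
#' @param mix_noise upper bound of the per-spot contamination fraction:
#'   each spot's expected profile is `(1 - w) * own-domain + w * adjacent-domain`
#'   with `w ~ Uniform(0, mix_noise)` and a random other domain as the
#'   contaminant, emulating within-domain cell-composition heterogeneity
#'   (spots capture mixtures of cell types).
#'   Default 0.4, calibrated so that expression alone separates domains
#'   only partially and spatial context carries real information.
#' @param libsize_range per-spot library-size bounds (uniform draw).
#'   The default 200-600 matches Visium-like depth scaled to `G` genes
#'   (a few thousand UMIs over ~3000 genes).
#' @param spacing inter-spot distance in coordinate units (default 100).
#' @param seed RNG seed for [simulate_st()].
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_rows = 40, n_cols = 50, layout = c("laminar", "blocks", "shuffled"),
                     C = 6, G = 200, n_program_genes = 10, effect_size = 1.5,
                     dispersion = 0.3, mix_noise = 0.4,
                     libsize_range = c(200, 600),
                     spacing = 100, seed = 1) {
  layout <- match.arg(layout)
  spec <- list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
               layout = layout, C = as.integer(C), G = as.integer(G),
               n_program_genes = as.integer(n_program_genes),
               effect_size = effect_size, dispersion = dispersion,
               mix_noise = mix_noise,
               libsize_range = libsize_range, spacing = spacing,
               seed = as.integer(seed))
  if (spec$C < 2) stop("C must be >= 2")
  if (spec$n_program_genes * spec$C > spec$G)
    stop("n_program_genes * C exceeds G")
  if (spec$effect_size <= 0) stop("effect_size must be > 0")
  if (spec$dispersion < 0) stop("dispersion must be >= 0")
  if (spec$mix_noise < 0 || spec$mix_noise >= 1)
    stop("mix_noise must be in [0, 1)")
  if (spec$n_rows < 1 || spec$n_cols < 1) stop("grid dimensions must be >= 1")
  structure(spec, class = "sim_spec")
}

#' Simulate a spatial transcriptomics section with known domains
#'
#' Spots sit on a regular `n_rows x n_cols` grid with coordinates spaced
#' `spacing` units apart. Domains are assigned by the layout (`laminar`:
#' horizontal bands; `blocks`: rectangular tiles; `shuffled`: laminar
#' labels permuted across spots). Gene `g` of domain `c`'s marker program
#' has its negative-binomial log-mean raised by `effect_size` in that
#' domain; all counts share a per-spot library-size factor and the common
#' overdispersion. The planted labels are attached to the returned dataset.
#'
#' @param spec a [sim_spec()].
#' @return An [st_dataset] with integer counts and `labels`.
#' @examples
#' ds <- simulate_st(sim_spec(n_rows = 10, n_cols = 10, C = 2, G = 50, seed = 7))
#' table(ds$labels)
#' @export
simulate_st <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_rows * spec$n_cols
  grid <- expand.grid(col = seq_len(spec$n_cols), row = seq_len(spec$n_rows))
  coords <- cbind(x = (grid$col - 1) * spec$spacing,
                  y = (grid$row - 1) * spec$spacing)

  # domain labels by layout; bands split rows as evenly as possible
  band_of_row <- rep(seq_len(spec$C), length.out = 0)
  band_sizes <- diff(round(seq(0, spec$n_rows, length.out = spec$C + 1)))
  band_of_row <- rep(seq_len(spec$C), times = band_sizes)
  labels <- band_of_row[grid$row]
  if (spec$layout == "blocks") {
    kr <- max(1L, round(sqrt(spec$C)))
    kc <- ceiling(spec$C / kr)
    rb <- pmin(kr, 1L + (grid$row - 1L) %/% ceiling(spec$n_rows / kr))
    cb <- pmin(kc, 1L + (grid$col - 1L) %/% ceiling(spec$n_cols / kc))
    labels <- 1L + ((rb - 1L) * kc + (cb - 1L)) %% spec$C
  } else if (spec$layout == "shuffled") {
    labels <- labels[sample.int(n)]
  }

  # per-gene baseline relative abundance; markers shifted in their domain
  base <- stats::rgamma(spec$G, shape = 0.6, rate = 0.6)   # skewed, CV ~ 1.3
  logmu <- matrix(log(base), nrow = spec$C, ncol = spec$G, byrow = TRUE)
  marker_domain <- rep(NA_integer_, spec$G)
  for (c in seq_len(spec$C)) {
    idx <- ((c - 1) * spec$n_program_genes + 1):(c * spec$n_program_genes)
    logmu[c, idx] <- logmu[c, idx] + spec$effect_size
    marker_domain[idx] <- c
  }
  rel <- exp(logmu)
  rel <- rel / rowSums(rel)                                # domain profiles

  lib <- stats::runif(n, spec$libsize_range[1], spec$libsize_range[2])
  prof <- rel[labels, , drop = FALSE]
  if (spec$mix_noise > 0) {
    w <- stats::runif(n, 0, spec$mix_noise)
    other <- 1L + (labels - 1L + sample.int(spec$C - 1L, n, replace = TRUE)) %% spec$C
    prof <- (1 - w) * prof + w * rel[other, , drop = FALSE]
  }
  mu <- prof * lib
  size <- if (spec$dispersion > 0) 1 / spec$dispersion else Inf
  counts <- if (is.finite(size)) {
    matrix(stats::rnbinom(n * spec$G, mu = mu, size = size), nrow = n)
  } else {
    matrix(stats::rpois(n * spec$G, lambda = mu), nrow = n)
  }
  storage.mode(counts) <- "double"

  ds <- st_dataset(
    expr = counts, coords = coords,
    spot_ids = sprintf("spot_%04d", seq_len(n)),
    gene_ids = sprintf("gene_%04d", seq_len(spec$G)),
    labels = labels
  )
  attr(ds, "sim_spec") <- spec
  attr(ds, "marker_domain") <- marker_domain
  ds
}

#' Plant a spatially variable gene into a simulated dataset
#'
#' Appends one gene whose negative-binomial mean follows a spatial pattern:
#' `"band"` raises the rate by `exp(amplitude)` inside the middle horizontal
#' third of the section; `"hotspot"` applies a Gaussian bump centred on the
#' section (sd = 1/4 of the section extent). `amplitude = 0` yields a
#' spatially unstructured control gene.
#'
#' @param ds an [st_dataset] produced by [simulate_st()].
#' @param pattern `"band"` or `"hotspot"`.
#' @param amplitude log-scale amplitude of the pattern (>= 0).
#' @param base_rate baseline mean count of the planted gene (default 5).
#' @param gene_id name of the appended gene (default `"svg_planted"`).
#' @param seed RNG seed for the count draw.
#' @return The dataset with one extra gene column.
#' @export
plant_svg <- function(ds, pattern = c("band", "hotspot"), amplitude = 2,
                      base_rate = 5, gene_id = "svg_planted", seed = 1) {
  pattern <- match.arg(pattern)
  stopifnot(inherits(ds, "st_dataset"), amplitude >= 0)
  spec <- attr(ds, "sim_spec")
  disp <- if (!is.null(spec)) spec$dispersion else 0.3
  set.seed(seed)
  x <- ds$coords[, "x"]; y <- ds$coords[, "y"]
  bump <- switch(pattern,
    band = as.numeric(y >= stats::quantile(y, 1 / 3) & y <= stats::quantile(y, 2 / 3)),
    hotspot = {
      s <- max(diff(range(x)), diff(range(y))) / 4
      exp(-((x - mean(range(x)))^2 + (y - mean(range(y)))^2) / (2 * s^2))
    })
  mu <- base_rate * exp(amplitude * bump)
  g <- if (disp > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / disp)
  } else {
    stats::rpois(length(mu), lambda = mu)
  }
  expr <- cbind(as_dense(ds$expr), g)
  out <- st_dataset(expr = expr, coords = ds$coords, spot_ids = ds$spot_ids,
                    gene_ids = c(ds$gene_ids, gene_id), labels = ds$labels,
                    in_tissue = ds$in_tissue)
  attr(out, "sim_spec") <- spec
  out
}
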