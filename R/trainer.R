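#' Training configuration
#'
#' Collects every hyperparameter of the training schedule. Defaults follow
#' the method's reference settings where stated (radius 700, k = 20, a
#' single graph-convolution layer per view, Adam with learning rate 0.003
#' and weight decay 0.001); the remaining values are package defaults
#' documented in the methods vignette.
#'
#' @param r spatial-graph radius in coordinate units.
#' @param k expression-graph neighbour count.
#' @param gcn_dim per-view embedding dimension d.
#' @param vgae_hidden VGAE shared hidden width.
#' @param vgae_latent VGAE posterior dimension (must equal `gcn_dim`: the
#'   contrastive score is an inner product between the two spaces).
#' @param tau InfoNCE temperature (> 0).
#' @param M augmentations per anchor.
#' @param b contrastive batch size (capped at N).
#' @param alpha,beta weights of the clustering (KL) and contrastive terms
#'   in the joint objective `L = alpha * L_KL + beta * L_CL`.
#' @param lr Adam learning rate.
#' @param weight_decay Adam weight decay (applied to weight matrices only).
#' @param max_iter iteration cap.
#' @param T target-distribution refresh interval (iterations).
#' @param delta stopping threshold on the fraction of labels changed
#'   between consecutive refresh checkpoints.
#' @param seed global seed; all component streams (initialization, k-means,
#'   posterior draws, batch sampling) derive from it.
#' @param ablation `"full"`, `"wo_F"` (drop feature view), `"wo_S"` (drop
#'   spatial view), or `"wo_A"` (mean fusion instead of attention).
#' @param gcn_final_relu rectify the GCN output layer (default `FALSE`;
#'   a linear output suits the Euclidean geometry of the clustering stage).
#' @param vgae_relu_out rectify the VGAE outputs (default `FALSE`; see
#'   [vgae_init()]).
#' @param scale_input column-standardize the expression matrix before the
#'   encoders (graph construction always uses the unscaled matrix).
#' @param feature_graph `"union"` or `"mutual"` kNN symmetrization.
#' @return A `spafuse_config` list.
#' @export
st_config <- function(r = 700, k = 20, gcn_dim = 32, vgae_hidden = 64,
                      vgae_latent = gcn_dim, tau = 0.5, M = 5, b = 512,
                      alpha = 1, beta = 1, lr = 0.003, weight_decay = 0.001,
                      max_iter = 1000, T = 50, delta = 0.001, seed = 0,
                      ablation = c("full", "wo_F", "wo_S", "wo_A"),
                      gcn_final_relu = FALSE, vgae_relu_out = FALSE,
                      scale_input = TRUE,
                      feature_graph = c("union", "mutual")) {
  ablation <- match.arg(ablation)
  feature_graph <- match.arg(feature_graph)
  if (tau <= 0) stop("tau must be > 0")
  if (M < 1) stop("M must be >= 1")
  if (delta < 0 || delta > 1) stop("delta must be in [0, 1]")
  if (vgae_latent != gcn_dim)
    stop("vgae_latent must equal gcn_dim (contrastive score is an inner ",
         "product between anchor and augmentation)")
  structure(list(
    r = r, k = k, gcn_dim = gcn_dim, vgae_hidden = vgae_hidden,
    vgae_latent = vgae_latent, tau = tau, M = as.integer(M),
    b = as.integer(b), alpha = alpha, beta = beta, lr = lr,
    weight_decay = weight_decay, max_iter = as.integer(max_iter),
    T = as.integer(T), delta = delta, seed = as.integer(seed),
    ablation = ablation, gcn_final_relu = gcn_final_relu,
    vgae_relu_out = vgae_relu_out, scale_input = scale_input,
    feature_graph = feature_graph
  ), class = "spafuse_config")
}

#' Fit the multi-view graph contrastive clustering model
#'
#' Runs the full training schedule on a preprocessed dataset:
#' \enumerate{
#'   \item build the spatial and expression view graphs (one is skipped
#'     under the `wo_F` / `wo_S` ablations) and their normalized
#'     self-looped operators;
#'   \item initialize centroids by k-means on a first fused forward pass;
#'   \item per iteration: update each view's VGAE by its negative ELBO;
#'     run each view's GCN; draw a batch and `M` implicit augmentations
#'     per anchor from the VGAE posterior and accumulate the per-view
#'     InfoNCE losses; fuse the views by attention (mean under `wo_A`);
#'     every `T` iterations refresh the target distribution and stop when
#'     fewer than a `delta` fraction of labels changed since the previous
#'     checkpoint; update the backbone (GCN weights, attention vector,
#'     centroids) by `alpha * L_KL + beta * L_CL` with Adam.
#' }
#' VGAE parameters receive no gradient from the joint objective and the
#' backbone receives none from the VGAE loss; augmentations are constants
#' with respect to the backbone.
#'
#' @param ds a preprocessed [st_dataset].
#' @param C number of spatial domains (defaults to the number of distinct
#'   ground-truth labels when the dataset carries them).
#' @param cfg an [st_config()].
#' @return A `spafuse_fit`: list with `labels`, `Z` (fused embedding),
#'   `view_embeddings`, `attention` (per-spot view coefficients, when
#'   applicable), `cluster` (centroids, `Q`, `P`), `log` (per-iteration
#'   losses and label-change fractions), `stopped_iter`, `config`.
#' @examples
#' ds <- simulate_st(sim_spec(n_rows = 8, n_cols = 8, C = 2, G = 40, seed = 3))
#' pp <- preprocess_st(ds, n_hvg = NULL)
#' fit <- fit_spafuse(pp$dataset, C = 2,
#'                    cfg = st_config(max_iter = 5, T = 2, b = 32, seed = 1))
#' table(fit$labels, ds$labels)
#' @export
fit_spafuse <- function(ds, C = NULL, cfg = st_config()) {
  stopifnot(inherits(ds, "st_dataset"), inherits(cfg, "spafuse_config"))
  X_raw <- as_dense(ds$expr)
  n <- nrow(X_raw)
  if (is.null(C)) {
    if (is.null(ds$labels))
      stop("C not given and dataset has no labels to infer it from")
    C <- length(unique(ds$labels))
  }
  if (C > n) stop("C (", C, ") exceeds number of spots (", n, ")")

  set.seed(cfg$seed)
  sub_seed <- sample.int(.Machine$integer.max - 1, 8)

  # --- views -------------------------------------------------------------
  kinds <- switch(cfg$ablation,
                  full = c("spatial", "feature"),
                  wo_A = c("spatial", "feature"),
                  wo_F = "spatial",
                  wo_S = "feature")
  graphs <- lapply(kinds, function(kind) {
    g <- if (kind == "spatial") {
      build_spatial_graph(ds$coords, r = cfg$r)
    } else {
      build_feature_graph(X_raw, k = cfg$k, symmetrize = cfg$feature_graph)
    }
    normalize_adjacency(g, add_self_loops = TRUE)
  })
  names(graphs) <- kinds
  nview <- length(graphs)
  a_tildes <- lapply(graphs, function(g)
    methods::as(g$adj + Matrix::Diagonal(n), "CsparseMatrix"))

  X <- X_raw
  if (cfg$scale_input) {
    sdv <- apply(X, 2, stats::sd)
    sdv[sdv == 0] <- 1
    X <- sweep(sweep(X, 2, colMeans(X)), 2, sdv, "/")
  }
  AX <- lapply(graphs, function(g) as.matrix(g$norm_adj %*% X))

  # --- parameters --------------------------------------------------------
  g_dim <- cfg$gcn_dim
  encs <- lapply(seq_len(nview), function(v)
    gcn_init(ncol(X), g_dim, final_relu = cfg$gcn_final_relu,
             seed = sub_seed[v]))
  vgaes <- lapply(seq_len(nview), function(v)
    vgae_init(ncol(X), cfg$vgae_hidden, cfg$vgae_latent,
              relu_out = cfg$vgae_relu_out, seed = sub_seed[2 + v]))
  set.seed(sub_seed[5])
  q_att <- stats::rnorm(g_dim) / sqrt(g_dim)

  forward_fuse <- function(caches) {
    Zs <- lapply(caches, `[[`, "Z")
    if (nview == 1L) {
      list(Z = Zs[[1]], fused = NULL)
    } else if (cfg$ablation == "wo_A") {
      list(Z = (Zs[[1]] + Zs[[2]]) / 2, fused = NULL)
    } else {
      f <- fuse_views(q_att, Zs[[1]], Zs[[2]])
      list(Z = f$Z, fused = f)
    }
  }

  # --- initialization (k-means on the initial fused embedding) -----------
  caches <- lapply(seq_len(nview), function(v)
    gcn_forward_cache(encs[[v]], graphs[[v]]$norm_adj, X, AX = AX[[v]]))
  ff <- forward_fuse(caches)
  centroids <- init_centroids(ff$Z, C, seed = sub_seed[6])
  Q <- soft_assign(ff$Z, centroids)
  labels <- hard_labels(Q)
  P <- target_distribution(Q)
  s_prev <- NULL                       # labels at the previous checkpoint

  # --- optimizers --------------------------------------------------------
  theta <- c(
    setNames(lapply(encs, function(e) e$layer_weights[[1]]),
             paste0("W", seq_len(nview))),
    list(q = q_att, MU = centroids)
  )
  opt_theta <- adam_new(theta)
  opt_vgae <- lapply(vgaes, function(v) adam_new(v[c("W0", "Wmu", "Wsig")]))

  set.seed(sub_seed[7])
  b_eff <- min(cfg$b, n)
  log_rows <- vector("list", cfg$max_iter)
  stopped_iter <- NA_integer_

  iter <- 0L
  while (iter < cfg$max_iter) {
    # (1) VGAE update per view (parameters Phi, loss L_VGAE only)
    l_vgae <- numeric(nview)
    posts <- vector("list", nview)
    for (v in seq_len(nview)) {
      eps <- matrix(stats::rnorm(n * cfg$vgae_latent), n, cfg$vgae_latent)
      vg <- vgae_loss_grads(vgaes[[v]], graphs[[v]]$norm_adj, X,
                            a_tildes[[v]], eps, AX = AX[[v]])
      if (!is.finite(vg$loss))
        stop("VGAE loss diverged (view ", kinds[v], ", iteration ", iter, ")")
      l_vgae[v] <- vg$loss
      posts[[v]] <- list(mu = vg$mu, logvar = vg$logvar)
      upd <- adam_step(opt_vgae[[v]], vgaes[[v]][c("W0", "Wmu", "Wsig")],
                       vg$grads, cfg$lr, cfg$weight_decay)
      opt_vgae[[v]] <- upd$state
      vgaes[[v]][c("W0", "Wmu", "Wsig")] <- upd$params
    }

    # (2) GCN forward per view
    caches <- lapply(seq_len(nview), function(v)
      gcn_forward_cache(encs[[v]], graphs[[v]]$norm_adj, X, AX = AX[[v]]))

    # (3) contrastive loss per view on a sampled batch
    idx <- sample.int(n, b_eff)
    l_cl <- 0
    dZ_cl <- vector("list", nview)
    if (cfg$beta != 0) {
      for (v in seq_len(nview)) {
        sd_v <- exp(0.5 * posts[[v]]$logvar[idx, , drop = FALSE])
        mu_v <- posts[[v]]$mu[idx, , drop = FALSE]
        aug <- array(0, c(b_eff, cfg$vgae_latent, cfg$M))
        for (m in seq_len(cfg$M)) {
          aug[, , m] <- mu_v + sd_v *
            matrix(stats::rnorm(b_eff * cfg$vgae_latent), b_eff)
        }
        cg <- contrastive_loss_grad(caches[[v]]$Z[idx, , drop = FALSE],
                                    aug, cfg$tau)
        l_cl <- l_cl + cg$loss
        dZ_cl[[v]] <- cg$dZ
      }
    }

    # (4) fuse views
    ff <- forward_fuse(caches)

    # (5) checkpoint: refresh P, check stopping
    label_change <- NA_real_
    if (iter %% cfg$T == 0L) {
      Qc <- soft_assign(ff$Z, centroids)
      s <- hard_labels(Qc)
      if (!is.null(s_prev)) {
        label_change <- mean(s != s_prev)
        if (label_change < cfg$delta) {
          stopped_iter <- iter
          log_rows[[iter + 1L]] <- data.frame(
            iter = iter, l_vgae_1 = l_vgae[1],
            l_vgae_2 = if (nview > 1) l_vgae[2] else NA_real_,
            l_cl = l_cl, l_kl = NA_real_, l_total = NA_real_,
            label_change = label_change,
            alpha1_mean = if (!is.null(ff$fused)) mean(ff$fused$alpha1) else NA_real_)
          break
        }
      }
      P <- target_distribution(Qc)
      s_prev <- s
    }

    # (6) joint objective for the backbone Theta
    dec <- dec_kl_grads(ff$Z, centroids, P)
    l_kl <- kl_loss(P, dec$Q)
    dZ_fused <- cfg$alpha * dec$dZ
    if (nview == 1L) {
      dZs <- list(dZ_fused)
      dq <- NULL
    } else if (cfg$ablation == "wo_A") {
      dZs <- list(dZ_fused / 2, dZ_fused / 2)
      dq <- NULL
    } else {
      fg <- fuse_views_grad(q_att, caches[[1]]$Z, caches[[2]]$Z, ff$fused,
                            dZ_fused)
      dZs <- list(fg$dZ1, fg$dZ2)
      dq <- cfg$alpha * fg$dq
    }
    grads <- list()
    for (v in seq_len(nview)) {
      dZ_v <- dZs[[v]]
      if (cfg$beta != 0)
        dZ_v[idx, ] <- dZ_v[idx, ] + cfg$beta * dZ_cl[[v]]
      gw <- gcn_backward(encs[[v]], graphs[[v]]$norm_adj, caches[[v]], dZ_v)
      grads[[paste0("W", v)]] <- gw[[1]]
    }
    grads$q <- dq
    grads$MU <- cfg$alpha * dec$dMU

    l_total <- cfg$alpha * l_kl + cfg$beta * l_cl
    if (!is.finite(l_total))
      stop("joint loss diverged at iteration ", iter,
           " (L_KL = ", l_kl, ", L_CL = ", l_cl, ")")

    theta <- c(
      setNames(lapply(encs, function(e) e$layer_weights[[1]]),
               paste0("W", seq_len(nview))),
      list(q = q_att, MU = centroids)
    )
    upd <- adam_step(opt_theta, theta, grads, cfg$lr, cfg$weight_decay,
                     decay_mask = paste0("W", seq_len(nview)))
    opt_theta <- upd$state
    for (v in seq_len(nview))
      encs[[v]]$layer_weights[[1]] <- upd$params[[paste0("W", v)]]
    q_att <- upd$params$q
    centroids <- upd$params$MU

    log_rows[[iter + 1L]] <- data.frame(
      iter = iter, l_vgae_1 = l_vgae[1],
      l_vgae_2 = if (nview > 1) l_vgae[2] else NA_real_,
      l_cl = l_cl, l_kl = l_kl, l_total = l_total,
      label_change = label_change,
      alpha1_mean = if (!is.null(ff$fused)) mean(ff$fused$alpha1) else NA_real_)
    iter <- iter + 1L
  }

  # final forward with the trained parameters
  caches <- lapply(seq_len(nview), function(v)
    gcn_forward_cache(encs[[v]], graphs[[v]]$norm_adj, X, AX = AX[[v]]))
  ff <- forward_fuse(caches)
  Q <- soft_assign(ff$Z, centroids)
  labels <- hard_labels(Q)

  kept <- log_rows[!vapply(log_rows, is.null, logical(1))]
  log_df <- if (length(kept)) do.call(rbind, kept) else
    data.frame(iter = integer(0), l_vgae_1 = numeric(0),
               l_vgae_2 = numeric(0), l_cl = numeric(0), l_kl = numeric(0),
               l_total = numeric(0), label_change = numeric(0),
               alpha1_mean = numeric(0))
  structure(list(
    labels = labels,
    Z = ff$Z,
    view_embeddings = setNames(lapply(caches, `[[`, "Z"), kinds),
    attention = if (!is.null(ff$fused))
      data.frame(spot_id = ds$spot_ids, alpha_spatial = ff$fused$alpha1,
                 alpha_feature = ff$fused$alpha2),
    cluster = list(centroids = centroids, Q = Q, P = P),
    graphs = graphs,
    models = list(gcn = encs, vgae = vgaes, q = q_att),
    log = log_df,
    stopped_iter = stopped_iter,
    config = cfg,
    spot_ids = ds$spot_ids
  ), class = "spafuse_fit")
}

#' @exportS3Method base::print
print.spafuse_fit <- function(x, ...) {
  cat("spafuse_fit: ", length(x$labels), " spots, ",
      nrow(x$cluster$centroids), " domains (ablation: ",
      x$config$ablation, ")\n", sep = "")
  if (!is.na(x$stopped_iter)) {
    cat("  converged at iteration", x$stopped_iter, "\n")
  } else {
    cat("  ran to max_iter =", x$config$max_iter, "\n")
  }
  cat("  domain sizes:", paste(tabulate(x$labels), collapse = " "), "\n")
  invisible(x)
}

#' Write fitted labels (and optionally attention) as TSV
#'
#' @param fit a `spafuse_fit`.
#' @param path output TSV path for `(spot_id, domain)`.
#' @param attention_path optional TSV path for per-spot attention
#'   coefficients.
#' @return `path`, invisibly.
#' @export
write_labels <- function(fit, path, attention_path = NULL) {
  stopifnot(inherits(fit, "spafuse_fit"))
  write.table(data.frame(spot_id = fit$spot_ids, domain = fit$labels),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(attention_path) && !is.null(fit$attention))
    write.table(fit$attention, attention_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

#' Run view/attention ablation variants
#'
#' Fits each requested variant with a shared seed and scores it against
#' the dataset's ground-truth labels.
#'
#' @param ds a preprocessed [st_dataset] carrying `labels`.
#' @param C number of domains (defaults to the distinct label count).
#' @param variants subset of `c("full", "wo_F", "wo_S", "wo_A")`.
#' @param cfg base [st_config()]; each variant overrides only `ablation`.
#' @return data frame `(variant, ari, nmi)`.
#' @export
run_ablation <- function(ds, C = NULL, variants = c("full", "wo_F", "wo_S", "wo_A"),
                         cfg = st_config()) {
  if (is.null(ds$labels)) stop("ablation scoring needs ground-truth labels")
  bad <- setdiff(variants, c("full", "wo_F", "wo_S", "wo_A"))
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  rows <- lapply(variants, function(vn) {
    cfg_v <- cfg
    cfg_v$ablation <- vn
    fit <- fit_spafuse(ds, C = C, cfg = cfg_v)
    data.frame(variant = vn,
               ari = ari(fit$labels, ds$labels),
               nmi = nmi(fit$labels, ds$labels))
  })
  do.call(rbind, rows)
}
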