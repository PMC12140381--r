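## Per-view encoders and the implicit contrastive objective.
##
## All forward passes and gradients are written out analytically (no
## autodiff framework); every gradient is checked against central finite
## differences in the test suite.

relu <- function(x) (x > 0) * x

glorot_uniform <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

#' Create a GCN encoder
#'
#' A stack of graph-convolution layers `Z_l = ReLU(A_hat Z_{l-1} W_l)`
#' with `Z_0 = X`. The default is a single layer. The rectifier on the
#' final layer can be disabled (`final_relu = FALSE`) to give a linear
#' embedding.
#'
#' @param in_dim input feature dimension (number of genes).
#' @param out_dim embedding dimension of the last layer.
#' @param hidden_dims integer vector of intermediate layer sizes (empty for
#'   a single layer).
#' @param final_relu apply ReLU on the last layer (default `TRUE`).
#' @param seed RNG seed for the Glorot-uniform initialization.
#' @return A `gcn_encoder` with `layer_weights`.
#' @export
gcn_init <- function(in_dim, out_dim, hidden_dims = integer(0),
                     final_relu = TRUE, seed = 1) {
  set.seed(seed)
  dims <- c(in_dim, hidden_dims, out_dim)
  w <- lapply(seq_len(length(dims) - 1),
              function(l) glorot_uniform(dims[l], dims[l + 1]))
  structure(list(layer_weights = w, final_relu = final_relu),
            class = "gcn_encoder")
}

#' GCN forward pass
#'
#' @param enc a [gcn_init()] encoder.
#' @param norm_adj N x N normalized adjacency operator (from
#'   [normalize_adjacency()]).
#' @param X N x in_dim feature matrix.
#' @return N x out_dim embedding.
#' @export
gcn_forward <- function(enc, norm_adj, X) {
  stopifnot(inherits(enc, "gcn_encoder"))
  if (ncol(X) != nrow(enc$layer_weights[[1]]))
    stop("X has ", ncol(X), " features but layer 1 expects ",
         nrow(enc$layer_weights[[1]]))
  if (nrow(X) != nrow(norm_adj))
    stop("X has ", nrow(X), " rows but norm_adj is ", nrow(norm_adj), " x ",
         ncol(norm_adj))
  z <- X
  nl <- length(enc$layer_weights)
  for (l in seq_len(nl)) {
    z <- as.matrix(norm_adj %*% z) %*% enc$layer_weights[[l]]
    if (l < nl || enc$final_relu) z <- relu(z)
  }
  z
}

# Forward keeping pre-activations, for backprop. `AX` optionally carries a
# precomputed norm_adj %*% X (it is loop-invariant during training).
gcn_forward_cache <- function(enc, norm_adj, X, AX = NULL) {
  nl <- length(enc$layer_weights)
  prop <- vector("list", nl)   # A z_{l-1}
  acts <- vector("list", nl)   # z_l
  z <- X
  for (l in seq_len(nl)) {
    p <- if (l == 1 && !is.null(AX)) AX else as.matrix(norm_adj %*% z)
    z <- p %*% enc$layer_weights[[l]]
    if (l < nl || enc$final_relu) z <- relu(z)
    prop[[l]] <- p
    acts[[l]] <- z
  }
  list(Z = z, prop = prop, acts = acts)
}

# Backprop dL/dZ through the encoder; returns per-layer weight gradients.
gcn_backward <- function(enc, norm_adj, cache, dZ) {
  nl <- length(enc$layer_weights)
  grads <- vector("list", nl)
  g <- dZ
  for (l in rev(seq_len(nl))) {
    if (l < nl || enc$final_relu) g <- g * (cache$acts[[l]] > 0)
    grads[[l]] <- crossprod(cache$prop[[l]], g)
    if (l > 1) g <- as.matrix(norm_adj %*% (g %*% t(enc$layer_weights[[l]])))
  }
  grads
}

#' Create a variational graph autoencoder
#'
#' Two-layer GCN encoder producing a per-spot Gaussian posterior
#' `N(mu_n, diag(sigma_n^2))`. The mean and log-variance branches share the
#' first-layer weights (the same matrix object); their output layers are
#' linear by default. `relu_out = TRUE` instead applies the rectifier to
#' both outputs (which constrains `mu >= 0` and `log sigma^2 >= 0`).
#'
#' @param in_dim input feature dimension.
#' @param hidden_dim shared hidden layer width (default 64).
#' @param latent_dim posterior dimension D (default 32).
#' @param relu_out rectify the mu / log-variance outputs (default `FALSE`).
#' @param seed RNG seed for initialization.
#' @return A `vgae_model` with `W0`, `Wmu`, `Wsig`.
#' @export
vgae_init <- function(in_dim, hidden_dim = 64, latent_dim = 32,
                      relu_out = FALSE, seed = 1) {
  set.seed(seed)
  structure(list(
    W0 = glorot_uniform(in_dim, hidden_dim),
    Wmu = glorot_uniform(hidden_dim, latent_dim),
    Wsig = glorot_uniform(hidden_dim, latent_dim),
    relu_out = relu_out
  ), class = "vgae_model")
}

LOGVAR_CLAMP <- 10

# Class-balance factors for the decoder BCE. On a complete target graph
# there is no negative class and reweighting is meaningless; fall back to
# the plain unweighted mean.
bce_weights <- function(n, e) {
  if (e >= n^2) list(pw = 1, norm = 1)
  else list(pw = (n^2 - e) / e, norm = n^2 / (2 * (n^2 - e)))
}

#' VGAE encoding pass
#'
#' `H1 = ReLU(A_hat X W0)`, then `mu = A_hat H1 Wmu` and
#' `log sigma^2 = A_hat H1 Wsig` (shared `W0`; outputs rectified when the
#' model was built with `relu_out`). The log-variance is clamped to
#' `[-10, 10]` for numerical stability.
#'
#' @param v a [vgae_init()] model.
#' @param norm_adj normalized self-looped adjacency operator.
#' @param X N x in_dim features.
#' @return list with `mu` and `logvar`, each N x latent_dim.
#' @export
vgae_encode <- function(v, norm_adj, X) {
  vgae_encode_cache(v, norm_adj, X)[c("mu", "logvar")]
}

vgae_encode_cache <- function(v, norm_adj, X, AX = NULL) {
  stopifnot(inherits(v, "vgae_model"))
  if (ncol(X) != nrow(v$W0))
    stop("X has ", ncol(X), " features but W0 expects ", nrow(v$W0))
  p1 <- if (is.null(AX)) as.matrix(norm_adj %*% X) else AX
  h1 <- relu(p1 %*% v$W0)
  q1 <- as.matrix(norm_adj %*% h1)
  mu_raw <- q1 %*% v$Wmu
  lv_raw <- q1 %*% v$Wsig
  mu <- if (v$relu_out) relu(mu_raw) else mu_raw
  lv <- if (v$relu_out) relu(lv_raw) else lv_raw
  lv_c <- pmin(pmax(lv, -LOGVAR_CLAMP), LOGVAR_CLAMP)
  list(mu = mu, logvar = lv_c, h1 = h1, q1 = q1, p1 = p1,
       mu_raw = mu_raw, lv_raw = lv_raw, lv = lv)
}

#' Per-node Gaussian KL divergence against the standard-normal prior
#'
#' `KL[N(mu_n, diag(sigma_n^2)) || N(0, I)] =
#'  0.5 * sum_d (mu^2 + sigma^2 - 1 - log sigma^2)`.
#'
#' @param mu,logvar N x D posterior parameters.
#' @return Numeric vector of N per-node divergences (each >= 0).
#' @export
gaussian_kl <- function(mu, logvar) {
  0.5 * rowSums(mu^2 + exp(logvar) - 1 - logvar)
}

#' VGAE loss (negative ELBO)
#'
#' Weighted binary cross-entropy between the inner-product decoder
#' `sigmoid(H H^T)` and the self-looped adjacency, plus the Gaussian KL
#' term. Positive pairs are reweighted by `(N^2 - E)/E` (E = number of
#' ones in the target) and the cross-entropy is scaled by
#' `N^2 / (2 (N^2 - E))`, the standard class-balance treatment for sparse
#' graphs; on a complete target graph (no negative class) the plain
#' unweighted mean is used instead. The KL term is averaged over nodes.
#'
#' @param mu,logvar posterior parameters from [vgae_encode()].
#' @param sampled_H N x D latent sample drawn by reparameterization
#'   (`H = mu + sigma * eps`).
#' @param adj_with_self_loops binary N x N target adjacency including the
#'   diagonal.
#' @return Scalar loss with attributes `recon` and `kl`.
#' @export
vgae_loss <- function(mu, logvar, sampled_H, adj_with_self_loops) {
  a <- methods::as(methods::as(adj_with_self_loops, "CsparseMatrix"), "dMatrix")
  n <- nrow(sampled_H)
  e <- Matrix::nnzero(a)
  w <- bce_weights(n, e)
  rec <- vgae_recon_loss_grad(sampled_H, a, w$pw, w$norm, want_grad = FALSE)$loss
  kl <- sum(gaussian_kl(mu, logvar)) / n
  if (!is.finite(rec)) stop("non-finite VGAE reconstruction loss")
  if (!is.finite(kl)) stop("non-finite VGAE KL term")
  structure(rec + kl, recon = rec, kl = kl)
}

# Full VGAE training step gradient: forward (reparameterized), loss, and
# gradients for W0, Wmu, Wsig. `eps` is the N x D standard-normal draw.
vgae_loss_grads <- function(v, norm_adj, X, a_tilde, eps, AX = NULL) {
  cc <- vgae_encode_cache(v, norm_adj, X, AX = AX)
  n <- nrow(cc$mu)
  sd_ <- exp(0.5 * cc$logvar)
  H <- cc$mu + sd_ * eps
  w <- bce_weights(n, Matrix::nnzero(a_tilde))
  rec <- vgae_recon_loss_grad(H, a_tilde, w$pw, w$norm, want_grad = TRUE)
  kl <- sum(gaussian_kl(cc$mu, cc$logvar)) / n

  dH <- rec$grad
  dmu <- dH + cc$mu / n
  dlv <- dH * eps * 0.5 * sd_ + 0.5 * (exp(cc$logvar) - 1) / n
  # clamp: zero gradient where the raw log-variance was clipped
  dlv <- dlv * (abs(cc$lv) < LOGVAR_CLAMP)
  if (v$relu_out) {
    dmu <- dmu * (cc$mu_raw > 0)
    dlv <- dlv * (cc$lv_raw > 0)
  }
  dWmu <- crossprod(cc$q1, dmu)
  dWsig <- crossprod(cc$q1, dlv)
  dq1 <- dmu %*% t(v$Wmu) + dlv %*% t(v$Wsig)
  dh1 <- as.matrix(norm_adj %*% dq1) * (cc$h1 > 0)
  dW0 <- crossprod(cc$p1, dh1)
  list(loss = rec$loss + kl, recon = rec$loss, kl = kl,
       grads = list(W0 = dW0, Wmu = dWmu, Wsig = dWsig),
       mu = cc$mu, logvar = cc$logvar)
}

#' Draw implicit augmentations from the VGAE posterior
#'
#' Samples `a_n^m = mu_n + sigma_n * eps_{n,m}` with
#' `eps ~ N(0, I)`, `m = 1..M`. Reproducible under a fixed seed.
#'
#' @param mu,logvar N x D posterior parameters.
#' @param M number of augmentations per spot (>= 1).
#' @param seed RNG seed.
#' @return N x D x M array of augmentations.
#' @export
draw_augmentations <- function(mu, logvar, M, seed = 1) {
  stopifnot(M >= 1)
  set.seed(seed)
  n <- nrow(mu); d <- ncol(mu)
  sd_ <- exp(0.5 * logvar)
  out <- array(0, c(n, d, M))
  for (m in seq_len(M)) {
    out[, , m] <- mu + sd_ * matrix(stats::rnorm(n * d), n, d)
  }
  out
}

#' InfoNCE contrastive loss with implicit augmentations
#'
#' For each anchor embedding `z_n` and each of its `M` posterior samples
#' `a_n^m`, the pair `(z_n, a_n^m)` is positive and the remaining anchors
#' in the batch act as negatives:
#' `L = -(1/NM) sum_{n,m} log[ exp(z_n . a_n^m / tau) /
#'                             sum_{n'} exp(z_{n'} . a_n^m / tau) ]`.
#' Computed with a numerically stabilized log-sum-exp.
#'
#' @param Z b x d anchor embeddings (the batch).
#' @param augmentations b x d x M array from [draw_augmentations()] (or a
#'   b x d matrix for M = 1).
#' @param tau temperature (> 0).
#' @return Scalar loss.
#' @export
contrastive_loss <- function(Z, augmentations, tau = 0.5) {
  contrastive_loss_grad(Z, augmentations, tau, want_grad = FALSE)$loss
}

contrastive_loss_grad <- function(Z, augmentations, tau, want_grad = TRUE) {
  if (tau <= 0) stop("tau must be > 0")
  if (is.matrix(augmentations))
    augmentations <- array(augmentations, c(dim(augmentations), 1L))
  b <- nrow(Z); d <- ncol(Z); M <- dim(augmentations)[3]
  stopifnot(dim(augmentations)[1] == b, dim(augmentations)[2] == d)
  # stack augmentations: row c = (m-1)*b + n holds a_n^m
  Aall <- matrix(aperm(augmentations, c(1, 3, 2)), b * M, d)
  S <- tcrossprod(Z, Aall) / tau              # b x (b*M); S[k, c] = z_k . a_c
  nc <- b * M
  tS <- t(S)
  cmax <- tS[cbind(seq_len(nc), max.col(tS, ties.method = "first"))]
  E <- exp(S - rep(cmax, each = b))
  colsum <- .colSums(E, b, nc)
  lse <- cmax + log(colsum)
  pos_idx <- cbind(rep(seq_len(b), times = M), seq_len(nc))
  loss <- mean(lse - S[pos_idx])
  if (!is.finite(loss)) stop("non-finite contrastive loss")
  if (!want_grad) return(list(loss = loss))
  dS <- E * rep(1 / colsum, each = b)         # softmax over anchors, per column
  dS[pos_idx] <- dS[pos_idx] - 1
  dZ <- (dS %*% Aall) / (tau * nc)
  list(loss = loss, dZ = dZ)
}

## ---- Adam ------------------------------------------------------------

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# One Adam step. `decay_mask` names the parameters subject to weight decay
# (added to the gradient, as in the coupled-L2 convention).
adam_step <- function(state, params, grads, lr, weight_decay = 0,
                      decay_mask = names(params),
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    if (is.null(g)) next
    if (weight_decay > 0 && k %in% decay_mask) g <- g + weight_decay * params[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    mhat <- state$m[[k]] / bc1
    vhat <- state$v[[k]] / bc2
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(state = state, params = params)
}
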