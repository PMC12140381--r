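# Independent brute-force oracles and small fixture builders. Every oracle
# here is written as plainly as possible (scalar loops, dense algebra) so
# that it shares no code path with the package implementation it checks.

# central finite-difference gradient of f at x (matrix or vector)
num_grad <- function(f, x, h = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# dense symmetric normalization with self-loops, straight from the formula
oracle_norm_adj <- function(A, self_loops = TRUE) {
  if (self_loops) A <- A + diag(nrow(A))
  d <- rowSums(A)
  di <- ifelse(d > 0, 1 / sqrt(d), 0)
  diag(di) %*% A %*% diag(di)
}

# scalar-loop InfoNCE: anchors Z (b x d), augs array (b x d x M)
oracle_contrastive <- function(Z, aug, tau) {
  b <- nrow(Z); M <- dim(aug)[3]
  total <- 0
  for (n in seq_len(b)) {
    for (m in seq_len(M)) {
      a <- aug[n, , m]
      num <- exp(sum(Z[n, ] * a) / tau)
      den <- 0
      for (np in seq_len(b)) den <- den + exp(sum(Z[np, ] * a) / tau)
      total <- total - log(num / den)
    }
  }
  total / (b * M)
}

# scalar-loop VGAE loss mirroring the documented scaling: weighted BCE over
# all N^2 decoder entries (positives reweighted, norm factor) + KL / N
oracle_vgae_loss <- function(mu, logvar, H, A_tilde) {
  n <- nrow(H)
  Ad <- as.matrix(A_tilde)
  e <- sum(Ad != 0)
  if (e >= n^2) { pw <- 1; norm <- 1 } else {
    pw <- (n^2 - e) / e
    norm <- n^2 / (2 * (n^2 - e))
  }
  bce <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      x <- sum(H[i, ] * H[j, ])
      p <- 1 / (1 + exp(-x))
      bce <- bce + if (Ad[i, j] != 0) -pw * log(p) else -log(1 - p)
    }
  }
  kl <- 0
  for (i in seq_len(nrow(mu))) {
    for (d in seq_len(ncol(mu))) {
      kl <- kl + 0.5 * (mu[i, d]^2 + exp(logvar[i, d]) - 1 - logvar[i, d])
    }
  }
  norm * bce / n^2 + kl / n
}

# element-loop DEC quantities
oracle_soft_assign <- function(Z, MU) {
  n <- nrow(Z); C <- nrow(MU)
  Q <- matrix(0, n, C)
  for (i in seq_len(n)) {
    for (j in seq_len(C)) Q[i, j] <- 1 / (1 + sum((Z[i, ] - MU[j, ])^2))
    Q[i, ] <- Q[i, ] / sum(Q[i, ])
  }
  Q
}

oracle_target_dist <- function(Q) {
  n <- nrow(Q); C <- ncol(Q)
  f <- colSums(Q)
  P <- matrix(0, n, C)
  for (i in seq_len(n)) {
    for (j in seq_len(C)) P[i, j] <- Q[i, j]^2 / f[j]
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  P
}

oracle_kl <- function(P, Q) {
  s <- 0
  for (i in seq_len(nrow(P))) {
    for (j in seq_len(ncol(P))) {
      if (P[i, j] > 0) s <- s + P[i, j] * log(P[i, j] / Q[i, j])
    }
  }
  s
}

# contingency-table ARI straight from the pair-counting formula
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  ex <- ai * bj / choose(length(a), 2)
  (nij - ex) / (0.5 * (ai + bj) - ex)
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  hx <- H(rowSums(tab) / n)
  hy <- H(colSums(tab) / n)
  mi <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      pij <- tab[i, j] / n
      if (pij > 0) mi <- mi + pij * log(pij / ((sum(tab[i, ]) / n) * (sum(tab[, j]) / n)))
    }
  }
  2 * mi / (hx + hy)
}

oracle_moran <- function(x, W) {
  n <- length(x)
  xb <- mean(x)
  num <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) num <- num + W[i, j] * (x[i] - xb) * (x[j] - xb)
  (n / sum(W)) * num / sum((x - xb)^2)
}

# wrap a dense 0/1 adjacency as a view_graph
new_graph_for_test <- function(a, kind = "spatial") {
  spaFuse:::new_view_graph(
    methods::as(Matrix::Matrix(a, sparse = TRUE), "generalMatrix"),
    kind, list())
}

# small random preprocessed-like dataset for trainer tests
tiny_dataset <- function(n_rows = 8, n_cols = 8, C = 2, G = 30, seed = 42) {
  ds <- simulate_st(sim_spec(n_rows = n_rows, n_cols = n_cols, C = C, G = G,
                             n_program_genes = max(3, G %/% (4 * C)),
                             seed = seed))
  preprocess_st(ds, n_hvg = NULL)$dataset
}

tiny_config <- function(...) {
  defaults <- list(max_iter = 10, T = 5, b = 32, gcn_dim = 8,
                   vgae_hidden = 16, vgae_latent = 8, M = 2, seed = 7)
  do.call(st_config, utils::modifyList(defaults, list(...)))
}
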