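test_that("GCN forward matches the dense formula and its degenerate cases", {
  set.seed(2)
  n <- 5; f <- 4; d <- 3
  a <- matrix(0, n, n); a[cbind(1:4, 2:5)] <- 1; a <- a + t(a)  # path graph
  g <- normalize_adjacency(new_graph_for_test(a), TRUE)
  X <- matrix(rnorm(n * f), n, f)

  enc <- gcn_init(f, d, seed = 3)
  # zero weights -> zero output
  enc0 <- enc; enc0$layer_weights[[1]][] <- 0
  expect_equal(gcn_forward(enc0, g$norm_adj, X), matrix(0, n, d))

  # identity propagation: A = I, W = I, X >= 0 -> Z = X
  gi <- normalize_adjacency(new_graph_for_test(matrix(0, f, f)), TRUE)
  enci <- gcn_init(f, f, seed = 1); enci$layer_weights[[1]] <- diag(f)
  Xp <- abs(matrix(rnorm(f * f), f, f))
  expect_equal(gcn_forward(enci, gi$norm_adj, Xp), Xp)

  # dense oracle: ReLU(A X W) computed step by step
  z <- gcn_forward(enc, g$norm_adj, X)
  ref <- pmax(as.matrix(g$norm_adj) %*% X %*% enc$layer_weights[[1]], 0)
  expect_equal(z, ref, tolerance = 1e-6)

  expect_error(gcn_forward(enc, g$norm_adj, X[, 1:2]), "features")
})

test_that("VGAE encoder shares the first layer and matches a dense oracle", {
  set.seed(4)
  n <- 6; f <- 5
  a <- matrix(rbinom(n * n, 1, 0.4), n, n); a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
  g <- normalize_adjacency(new_graph_for_test(a), TRUE)
  X <- matrix(rnorm(n * f), n, f)
  v <- vgae_init(f, hidden_dim = 4, latent_dim = 3, seed = 5)

  # all weights zero -> standard-normal posterior
  v0 <- v; v0$W0[] <- 0; v0$Wmu[] <- 0; v0$Wsig[] <- 0
  enc0 <- vgae_encode(v0, g$norm_adj, X)
  expect_equal(enc0$mu, matrix(0, n, 3))
  expect_equal(enc0$logvar, matrix(0, n, 3))
  expect_equal(sum(gaussian_kl(enc0$mu, enc0$logvar)), 0)

  # perturbing the mu head leaves the variance branch unchanged
  e1 <- vgae_encode(v, g$norm_adj, X)
  v2 <- v; v2$Wmu <- v2$Wmu + 1
  e2 <- vgae_encode(v2, g$norm_adj, X)
  expect_equal(e2$logvar, e1$logvar)
  expect_false(isTRUE(all.equal(e2$mu, e1$mu)))

  # dense two-layer oracle
  An <- as.matrix(g$norm_adj)
  h1 <- pmax(An %*% X %*% v$W0, 0)
  expect_equal(e1$mu, An %*% h1 %*% v$Wmu, tolerance = 1e-6)
  expect_equal(e1$logvar, An %*% h1 %*% v$Wsig, tolerance = 1e-6)
})

test_that("VGAE loss equals a scalar-loop oracle and its KL anchors hold", {
  # KL anchors, per node
  expect_equal(gaussian_kl(matrix(0, 1, 3), matrix(0, 1, 3)), 0)
  expect_equal(gaussian_kl(matrix(c(1, 0, 0), 1, 3), matrix(0, 1, 3)), 0.5)
  set.seed(6)
  for (rep in 1:20) {
    mu <- matrix(rnorm(6), 2, 3)
    lv <- matrix(rnorm(6, 0, 0.5), 2, 3)
    expect_true(all(gaussian_kl(mu, lv) >= 0))
  }

  set.seed(7)
  n <- 8; dd <- 3
  a <- matrix(rbinom(n * n, 1, 0.3), n, n); a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
  at <- Matrix::Matrix(a + diag(n), sparse = TRUE)
  for (rep in 1:10) {
    mu <- matrix(rnorm(n * dd), n, dd)
    lv <- matrix(rnorm(n * dd, 0, 0.5), n, dd)
    H <- matrix(rnorm(n * dd), n, dd)
    got <- vgae_loss(mu, lv, H, at)
    expect_equal(as.numeric(got), oracle_vgae_loss(mu, lv, H, at),
                 tolerance = 1e-6)
  }
})

test_that("VGAE gradients match finite differences", {
  set.seed(8)
  n <- 6; f <- 4
  a <- matrix(rbinom(n * n, 1, 0.4), n, n); a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
  g <- normalize_adjacency(new_graph_for_test(a), TRUE)
  at <- methods::as(Matrix::Matrix(a + diag(n), sparse = TRUE), "CsparseMatrix")
  X <- matrix(rnorm(n * f), n, f)
  v <- vgae_init(f, hidden_dim = 3, latent_dim = 2, seed = 9)
  eps <- matrix(rnorm(n * 2), n, 2)

  got <- spaFuse:::vgae_loss_grads(v, g$norm_adj, X, at, eps)
  loss_at <- function(vmod) spaFuse:::vgae_loss_grads(vmod, g$norm_adj, X, at, eps)$loss
  for (w in c("W0", "Wmu", "Wsig")) {
    ng <- num_grad(function(wv) {
      v2 <- v; v2[[w]][] <- wv; loss_at(v2)
    }, v[[w]])
    expect_equal(got$grads[[w]], ng, tolerance = 1e-4)
  }
})

test_that("posterior draws are reproducible, unbiased, and collapse as sigma -> 0", {
  mu <- matrix(c(0.5, -1, 2, 0), 2, 2)
  lv <- matrix(-1e9, 2, 2)          # clamped to -10: sd ~ 6.7e-3
  a <- draw_augmentations(mu, lv, M = 3, seed = 42)
  expect_equal(dim(a), c(2, 2, 3))
  for (m in 1:3) expect_equal(a[, , m], mu, tolerance = 0.05)

  a1 <- draw_augmentations(mu, matrix(0, 2, 2), M = 5, seed = 1)
  a2 <- draw_augmentations(mu, matrix(0, 2, 2), M = 5, seed = 1)
  expect_identical(a1, a2)

  # Monte-Carlo mean within 3 standard errors
  M <- 1e4
  lv2 <- matrix(log(0.25), 1, 2)    # sd = 0.5
  aa <- draw_augmentations(matrix(c(1, -2), 1, 2), lv2, M = M, seed = 3)
  se <- 0.5 / sqrt(M)
  expect_lt(abs(mean(aa[1, 1, ]) - 1), 3 * se)
  expect_lt(abs(mean(aa[1, 2, ]) + 2), 3 * se)
})

test_that("contrastive loss matches closed forms and a double-loop oracle", {
  # identical embeddings and augmentations: softmax is uniform -> log N
  N <- 7; d <- 3
  z <- matrix(rep(c(1, 2, 3), each = N), N, d)
  aug <- array(z, c(N, d, 1))
  expect_equal(contrastive_loss(z, aug, tau = 0.5), log(N), tolerance = 1e-10)

  # two orthonormal anchors, tau = 1: loss = -log(e / (e + 1))
  z2 <- diag(2)
  expect_equal(contrastive_loss(z2, array(z2, c(2, 2, 1)), tau = 1),
               -log(exp(1) / (exp(1) + 1)), tolerance = 1e-10)

  set.seed(10)
  for (rep in 1:10) {
    b <- 16; d <- 4; M <- 3
    z <- matrix(rnorm(b * d), b, d)
    aug <- array(rnorm(b * d * M), c(b, d, M))
    expect_equal(contrastive_loss(z, aug, tau = 0.7),
                 oracle_contrastive(z, aug, 0.7), tolerance = 1e-6)
  }
  expect_error(contrastive_loss(z2, array(z2, c(2, 2, 1)), tau = 0),
               "tau")
})

test_that("contrastive loss decreases as positive-pair similarity grows", {
  set.seed(12)
  b <- 10; d <- 4
  z <- matrix(rnorm(b * d), b, d)
  noise <- matrix(rnorm(b * d), b, d)
  losses <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(w) {
    aug <- array(w * z + (1 - w) * noise, c(b, d, 1))
    contrastive_loss(z, aug, tau = 0.5)
  })
  expect_true(all(diff(losses) < 0))
})

test_that("contrastive gradient matches finite differences", {
  set.seed(14)
  b <- 6; d <- 3; M <- 2
  z <- matrix(rnorm(b * d), b, d)
  aug <- array(rnorm(b * d * M), c(b, d, M))
  got <- spaFuse:::contrastive_loss_grad(z, aug, tau = 0.5)
  ng <- num_grad(function(zz) contrastive_loss(matrix(zz, b, d), aug, 0.5), z)
  expect_equal(got$dZ, ng, tolerance = 1e-5)
})

test_that("GCN backward pass matches finite differences", {
  set.seed(15)
  n <- 6; f <- 4; d <- 3
  a <- matrix(rbinom(n * n, 1, 0.4), n, n); a <- 1 * ((a + t(a)) > 0); diag(a) <- 0
  g <- normalize_adjacency(new_graph_for_test(a), TRUE)
  X <- matrix(rnorm(n * f), n, f)
  enc <- gcn_init(f, d, seed = 16)
  targ <- matrix(rnorm(n * d), n, d)
  lossf <- function(w) {
    e2 <- enc; e2$layer_weights[[1]][] <- w
    sum((gcn_forward(e2, g$norm_adj, X) - targ)^2)
  }
  cache <- spaFuse:::gcn_forward_cache(enc, g$norm_adj, X)
  dZ <- 2 * (cache$Z - targ)
  got <- spaFuse:::gcn_backward(enc, g$norm_adj, cache, dZ)[[1]]
  expect_equal(got, num_grad(lossf, enc$layer_weights[[1]]), tolerance = 1e-4)
})
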