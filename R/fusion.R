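## Attention fusion of view embeddings and deep embedded clustering.

#' Attention-based fusion of two view embeddings
#'
#' Each spot `i` scores each view embedding against a shared attention
#' vector, `v_i^(j) = q . z_i^(j)`; a softmax over the two views yields
#' per-spot coefficients `alpha_i^(1) + alpha_i^(2) = 1`, and the fused
#' embedding is the per-spot convex combination
#' `z_i = alpha_i^(1) z_i^(1) + alpha_i^(2) z_i^(2)`.
#'
#' @param q attention vector of length `d` (shared across spots and views).
#' @param Z1,Z2 N x d view embeddings.
#' @return list with `Z` (fused N x d), `alpha1`, `alpha2` (length-N
#'   coefficient vectors).
#' @examples
#' Z <- matrix(rnorm(8), 4, 2)
#' fuse_views(c(1, -1), Z, Z)$alpha1  # identical views: all 0.5
#' @export
fuse_views <- function(q, Z1, Z2) {
  if (!all(dim(Z1) == dim(Z2)))
    stop("Z1 is ", nrow(Z1), "x", ncol(Z1), " but Z2 is ",
         nrow(Z2), "x", ncol(Z2))
  if (length(q) != ncol(Z1))
    stop("attention vector length ", length(q), " != embedding dim ", ncol(Z1))
  v1 <- drop(Z1 %*% q)
  v2 <- drop(Z2 %*% q)
  mx <- pmax(v1, v2)
  e1 <- exp(v1 - mx); e2 <- exp(v2 - mx)
  a1 <- e1 / (e1 + e2)
  a2 <- 1 - a1
  list(Z = a1 * Z1 + a2 * Z2, alpha1 = a1, alpha2 = a2)
}

# Backward pass of fuse_views: given dL/dZ, return gradients for the two
# view embeddings and the attention vector.
fuse_views_grad <- function(q, Z1, Z2, fused, dZ) {
  a1 <- fused$alpha1; a2 <- fused$alpha2
  g1 <- rowSums(dZ * Z1)          # dL/d alpha1 per spot
  g2 <- rowSums(dZ * Z2)
  dv1 <- a1 * a2 * (g1 - g2)      # softmax Jacobian over the two views
  dv2 <- -dv1
  dZ1 <- a1 * dZ + outer(dv1, q)
  dZ2 <- a2 * dZ + outer(dv2, q)
  dq <- drop(crossprod(Z1, dv1) + crossprod(Z2, dv2))
  list(dZ1 = dZ1, dZ2 = dZ2, dq = dq)
}

#' Initialize cluster centroids by k-means
#'
#' Runs `stats::kmeans` with 20 restarts under a fixed seed on the fused
#' embedding.
#'
#' @param Z N x d embedding.
#' @param C number of clusters (1 <= C <= N).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 20).
#' @return C x d centroid matrix.
#' @export
init_centroids <- function(Z, C, seed = 1, nstart = 20) {
  if (C < 1) stop("C must be >= 1")
  if (C > nrow(Z)) stop("C (", C, ") exceeds number of spots (", nrow(Z), ")")
  set.seed(seed)
  if (C == nrow(Z)) return(Z)
  km <- stats::kmeans(Z, centers = C, nstart = nstart, iter.max = 100)
  km$centers
}

#' Student's-t soft cluster assignment
#'
#' `q_ij = (1 + ||z_i - mu_j||^2)^{-1} / sum_j' (1 + ||z_i - mu_j'||^2)^{-1}`
#' (Student's t with one degree of freedom); rows sum to 1.
#'
#' @param Z N x d embedding.
#' @param centroids C x d centroid matrix.
#' @return N x C soft assignment matrix Q.
#' @export
soft_assign <- function(Z, centroids) {
  d2 <- sq_dists(Z, centroids)
  u <- 1 / (1 + d2)
  u / rowSums(u)
}

# Pairwise squared Euclidean distances between rows of Z and rows of M.
sq_dists <- function(Z, M) {
  zz <- rowSums(Z^2)
  mm <- rowSums(M^2)
  d2 <- outer(zz, mm, "+") - 2 * tcrossprod(Z, M)
  pmax(d2, 0)
}

#' DEC target distribution
#'
#' Sharpens a soft assignment:
#' `p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')` with cluster
#' frequency `f_j = sum_i q_ij`. Empty-cluster columns are guarded with
#' `f_j >= 1e-12` (they cannot arise from the Student's-t kernel on
#' finite data).
#'
#' @param Q N x C soft assignment with rows summing to 1.
#' @return N x C target distribution P, rows summing to 1.
#' @export
target_distribution <- function(Q) {
  f <- pmax(colSums(Q), 1e-12)
  w <- sweep(Q^2, 2, f, "/")
  w / rowSums(w)
}

#' KL divergence between target and soft assignment
#'
#' `sum_i sum_j p_ij log(p_ij / q_ij)`, with `0 log 0 = 0`. A `q_ij = 0`
#' where `p_ij > 0` is a hard error (infinite divergence).
#'
#' @param P,Q N x C row-stochastic matrices.
#' @return Scalar divergence (>= 0).
#' @export
kl_loss <- function(P, Q) {
  stopifnot(all(dim(P) == dim(Q)))
  pos <- P > 0
  if (any(Q[pos] == 0)) stop("q_ij = 0 where p_ij > 0: infinite divergence")
  sum(P[pos] * log(P[pos] / Q[pos]))
}

# Gradients of kl_loss(P, Q(Z, centroids)) wrt Z and the centroids, with P
# held constant (the canonical DEC treatment):
#   dL/dz_i   =  2 sum_j (q_ij - p_ij) u_ij (z_i - mu_j) * (-1) ... see below
# with u_ij = (1 + ||z_i - mu_j||^2)^{-1}:
#   dL/dz_i   =  2 sum_j (p_ij - q_ij) u_ij (z_i - mu_j)
#   dL/dmu_j  = -2 sum_i (p_ij - q_ij) u_ij (z_i - mu_j)
dec_kl_grads <- function(Z, centroids, P) {
  d2 <- sq_dists(Z, centroids)
  u <- 1 / (1 + d2)
  Q <- u / rowSums(u)
  W <- (P - Q) * u
  rw <- rowSums(W)
  dZ <- 2 * (rw * Z - W %*% centroids)
  dMU <- -2 * (crossprod(W, Z) - colSums(W) * centroids)
  list(dZ = dZ, dMU = dMU, Q = Q)
}

#' Hard labels from a soft assignment
#'
#' `labels[i] = argmax_j q_ij`; ties resolve to the lowest cluster index.
#'
#' @param Q N x C soft assignment.
#' @return Integer vector of cluster labels in `1..C`.
#' @export
hard_labels <- function(Q) {
  apply(Q, 1, which.max)
}
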