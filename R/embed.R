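#' Low-dimensional data representations
#'
#' Computes one of the six representations used throughout the pipeline:
#'
#' * `zscore` - the standardized data itself (no reduction).
#' * `pca` - principal component scores, keeping the components whose
#'   eigenvalues exceed the mean eigenvalue. This is the point where the
#'   normalized cumulative-eigenvalue curve's slope falls below 1 (the
#'   "unit slope" elbow rule).
#' * `dm` - diffusion map: eigen-decomposition of the row-normalized
#'   Gaussian-kernel Markov matrix, with kernel scale eps set to the cube of
#'   the mean off-diagonal pairwise Euclidean distance. Euclidean distance
#'   between embedded points equals the one-step diffusion distance.
#' * `midm` - isometric approximate diffusion map: a mu-selected landmark
#'   subset (pivoted-QR pivots of the kernel) defines a Nystrom low-rank
#'   approximation of the kernel, whose diffusion map extends the landmark
#'   eigenvectors to all points.
#' * `icpqr` / `icpqrd` - incomplete pivoted QR of the diffusion kernel
#'   (`icpqr`) or of the centered data matrix (`icpqrd`): columns are added
#'   greedily by largest remaining norm until the next pivot falls below
#'   `mu` times the first, and points are projected onto the retained
#'   orthonormal basis, approximately preserving pairwise distances.
#'
#' Input columns are assumed already standardized (see [zscore_columns()]);
#' the function does not standardize for you.
#'
#' @param x A [feature_table] or numeric matrix (subjects x features).
#' @param method One of `"zscore"`, `"pca"`, `"dm"`, `"midm"`, `"icpqr"`,
#'   `"icpqrd"`.
#' @param mu Pivoted-QR truncation tolerance in (0, 1) (used by `midm`,
#'   `icpqr`, `icpqrd`).
#' @param m Embedding dimension for `dm`/`midm`; default keeps the
#'   non-trivial eigenvalues at least 5 percent of the leading non-trivial
#'   one, capped at 94.
#' @return An object of class `embedding`: list with `coords` (subjects x
#'   m), `method`, `m`, `params`, and `eigenvalues` where applicable.
#' @examples
#' x <- gen_population(population_spec(n_per_category = 30, n_features = 6,
#'                                     d_vector = 0.4))
#' e <- embed_features(zscore_columns(x), "pca")
#' e
#' @export
embed_features <- function(x, method = c("zscore", "pca", "dm", "midm",
                                         "icpqr", "icpqrd"),
                           mu = 1e-4, m = NULL) {
  method <- match.arg(method)
  mat <- if (inherits(x, "feature_table")) x$features else as.matrix(x)
  switch(method,
         zscore = new_embedding(mat, "zscore", params = list()),
         pca = pca_embed(mat),
         dm = diffusion_map(mat, m = m),
         midm = midm_embed(mat, mu = mu, m = m),
         icpqr = icpqr_embed(mat, mu = mu, kernelized = TRUE),
         icpqrd = icpqr_embed(mat, mu = mu, kernelized = FALSE))
}

new_embedding <- function(coords, method, params, eigenvalues = NULL) {
  coords <- as.matrix(coords)
  structure(list(coords = coords, method = method, m = ncol(coords),
                 params = params, eigenvalues = eigenvalues),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> method=%s, %d subjects x %d dims\n",
              x$method, nrow(x$coords), x$m))
  if (length(x$params))
    cat("  params:", paste(names(x$params), format(unlist(x$params), digits = 4),
                           sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Principal component embedding with the mean-eigenvalue elbow
#'
#' @param mat Numeric matrix, subjects x features (columns standardized).
#' @return An `embedding`; `m` is the number of eigenvalues strictly above
#'   the mean eigenvalue.
#' @export
pca_embed <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("PCA needs at least 2 subjects and 2 features", call. = FALSE)
  pc <- stats::prcomp(mat, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  if (max(ev) == 0) stop("rank-0 matrix", call. = FALSE)
  m <- max(1L, sum(ev > mean(ev)))
  new_embedding(pc$x[, seq_len(m), drop = FALSE], "pca",
                params = list(), eigenvalues = ev)
}

# Gaussian kernel with the package's epsilon rule: eps = (mean off-diagonal
# pairwise Euclidean distance)^3. Returns the kernel and eps.
dm_kernel <- function(mat, eps = NULL) {
  d <- as.matrix(stats::dist(mat))
  if (is.null(eps)) eps <- mean(d[upper.tri(d)])^3
  if (!is.finite(eps) || eps <= 0)
    stop("degenerate kernel: non-positive epsilon (identical points?)",
         call. = FALSE)
  list(w = exp(-d^2 / eps), eps = eps)
}

# Spectral core shared by dm and midm: row-normalize a symmetric affinity,
# return the non-trivial eigenpairs via the symmetric conjugation
# A = D^-1/2 W D^-1/2, psi = D^-1/2 phi (normalized so sum_i d_i psi^2 = 1).
dm_spectral <- function(w, m) {
  d <- rowSums(w)
  if (any(d <= 0)) stop("degenerate kernel row", call. = FALSE)
  isq <- 1 / sqrt(d)
  a <- w * (isq %o% isq)
  es <- eigen((a + t(a)) / 2, symmetric = TRUE)
  lam <- es$values[-1L]
  psi <- es$vectors[, -1L, drop = FALSE] * isq
  if (is.null(m)) m <- min(max(1L, sum(lam >= 0.05 * lam[1L])), 94L)
  m <- min(m, length(lam))
  coords <- sweep(psi[, seq_len(m), drop = FALSE], 2L, lam[seq_len(m)], `*`)
  list(coords = coords, lam = lam[seq_len(m)])
}

#' Diffusion map embedding
#'
#' @param mat Numeric matrix, subjects x features.
#' @param m Embedding dimension (default: eigenvalue-ratio rule, see
#'   [embed_features()]).
#' @param eps Kernel scale; default is the cube of the mean off-diagonal
#'   pairwise distance.
#' @return An `embedding` whose coordinates are lambda_l psi_l(i) for the
#'   non-trivial eigenpairs of the Markov matrix; Euclidean distances in
#'   the full embedding equal one-step diffusion distances.
#' @export
diffusion_map <- function(mat, m = NULL, eps = NULL) {
  k <- dm_kernel(as.matrix(mat), eps)
  sp <- dm_spectral(k$w, m)
  new_embedding(sp$coords, "dm", params = list(eps = k$eps),
                eigenvalues = sp$lam)
}

#' Incomplete pivoted QR embedding
#'
#' Greedy column-pivoted QR of the diffusion kernel (`kernelized = TRUE`)
#' or of the centered data matrix (`kernelized = FALSE`), truncated when
#' the next pivot norm drops below `mu` times the first. Subjects are
#' projected onto the retained orthonormal basis.
#'
#' @param mat Numeric matrix, subjects x features.
#' @param mu Truncation tolerance in (0, 1).
#' @param kernelized Decompose the Gaussian kernel rather than the data.
#' @return An `embedding` with `m` = number of retained pivots.
#' @export
icpqr_embed <- function(mat, mu = 1e-4, kernelized = TRUE) {
  if (mu >= 1) stop("'mu' must be < 1 (nothing would be retained)",
                    call. = FALSE)
  if (mu <= 0) stop("'mu' must be positive", call. = FALSE)
  mat <- as.matrix(mat)
  params <- list(mu = mu)
  if (kernelized) {
    k <- dm_kernel(mat)
    cols <- k$w                       # n x n, column j = subject j
    params$eps <- k$eps
  } else {
    cols <- t(scale(mat, center = TRUE, scale = FALSE))  # p x n
  }
  qrx <- qr(cols, LAPACK = TRUE)
  rdiag <- abs(diag(qr.R(qrx)))
  m <- max(1L, sum(rdiag >= mu * rdiag[1L]))
  q <- qr.Q(qrx)[, seq_len(m), drop = FALSE]
  coords <- t(crossprod(q, cols))     # n x m projections
  new_embedding(coords, if (kernelized) "icpqr" else "icpqrd",
                params = params)
}

#' Isometric approximate diffusion map
#'
#' Selects landmark subjects as the pivots of an incomplete pivoted QR of
#' the diffusion kernel (retained at tolerance `mu`), builds the Nystrom
#' low-rank approximation of the kernel from those landmarks, and computes
#' the diffusion map of the approximated kernel. As `mu` decreases the
#' landmark set grows and the embedding converges to the dense diffusion
#' map, so landmark pairwise distances match dense diffusion distances.
#'
#' @inheritParams icpqr_embed
#' @param m Embedding dimension (default as in [diffusion_map()]).
#' @return An `embedding`; attribute `"landmarks"` holds the landmark
#'   indices.
#' @export
midm_embed <- function(mat, mu = 1e-4, m = NULL) {
  if (mu >= 1) stop("'mu' must be < 1 (nothing would be retained)",
                    call. = FALSE)
  mat <- as.matrix(mat)
  k <- dm_kernel(mat)
  qrx <- qr(k$w, LAPACK = TRUE)
  rdiag <- abs(diag(qr.R(qrx)))
  nl <- max(1L, sum(rdiag >= mu * rdiag[1L]))
  landmarks <- sort(qrx$pivot[seq_len(nl)])
  if (!is.null(m) && nl < m)
    stop(sprintf("only %d landmarks retained, fewer than m = %d", nl, m),
         call. = FALSE)
  wl <- k$w[, landmarks, drop = FALSE]
  wll <- k$w[landmarks, landmarks, drop = FALSE]
  what <- wl %*% pseudo_inverse(wll) %*% t(wl)
  what <- (what + t(what)) / 2
  sp <- dm_spectral(pmax(what, 0), m)
  out <- new_embedding(sp$coords, "midm",
                       params = list(eps = k$eps, mu = mu),
                       eigenvalues = sp$lam)
  attr(out, "landmarks") <- landmarks
  out
}

pseudo_inverse <- function(a, tol = 1e-12) {
  sv <- svd(a)
  keep <- sv$d > tol * sv$d[1L]
  sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
}
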