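#' @name spd-geometry
#' @title Geometry of symmetric positive-definite matrices
#'
#' @description
#' EEG epochs are summarized by their spatial covariance matrices, which live
#' on the manifold of symmetric positive-definite (SPD) matrices. Under the
#' affine-invariant Riemannian metric (AIRM), the distance between two SPD
#' matrices A and B is `sqrt(sum(log(lambda_i)^2))` over the eigenvalues
#' `lambda_i` of `solve(A) %*% B`; it is invariant to any common invertible
#' congruence (re-referencing, linear mixing), which is what makes covariance
#' classification robust without baseline correction.
NULL

# symmetric eigen helpers ----------------------------------------------------

sym_eig_fun <- function(m, f) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_sqrtm <- function(m) sym_eig_fun(m, sqrt)
spd_invsqrtm <- function(m) sym_eig_fun(m, function(v) 1 / sqrt(v))
spd_logm <- function(m) sym_eig_fun(m, log)
spd_expm <- function(m) sym_eig_fun(m, exp)

assert_spd <- function(m, arg = "matrix", tol = 0) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    abort(paste0(arg, " must be a square matrix."))
  if (max(abs(m - t(m))) > 1e-8 * max(1, max(abs(m))))
    abort(paste0(arg, " must be symmetric."))
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol)
    abort(paste0(arg, " must be positive definite (min eigenvalue ",
                 format(min(ev)), ")."))
  invisible(ev)
}

#' Affine-invariant Riemannian distance between SPD matrices
#'
#' @param a,b SPD matrices of equal dimension.
#' @return Non-negative scalar distance.
#' @rdname spd-geometry
#' @export
airm_distance <- function(a, b) {
  assert_spd(a, "a"); assert_spd(b, "b")
  if (!all(dim(a) == dim(b)))
    abort("a and b must have the same dimension.")
  # eigenvalues of solve(a) %*% b via the symmetric whitened form
  w <- spd_invsqrtm(a)
  lam <- eigen(w %*% b %*% w, symmetric = TRUE, only.values = TRUE)$values
  sqrt(sum(log(lam)^2))
}

#' Geodesic mean (Karcher/Frechet mean) of SPD matrices
#'
#' Fixed-point iteration: at the current estimate M, average the logarithmic
#' maps of all matrices in the tangent space at M and move along the
#' exponential map, until the gradient norm falls below `tol`.
#'
#' @param mats List of SPD matrices.
#' @param tol Gradient-norm (Frobenius) convergence tolerance.
#' @param max_iter Maximum iterations; non-convergence is an error carrying
#'   the last iterate in its `data` field.
#' @return The SPD mean.
#' @rdname spd-geometry
#' @export
riemann_mean <- function(mats, tol = 1e-8, max_iter = 50L) {
  if (!length(mats)) abort("Need at least one matrix.")
  for (m in mats) assert_spd(m)
  if (length(mats) == 1L) return(mats[[1]])
  m <- Reduce(`+`, mats) / length(mats)  # arithmetic mean as starting point
  for (it in seq_len(max_iter)) {
    s <- spd_sqrtm(m)
    si <- spd_invsqrtm(m)
    tang <- Reduce(`+`, lapply(mats, function(c) spd_logm(si %*% c %*% si))) /
      length(mats)
    m <- s %*% spd_expm(tang) %*% s
    m <- (m + t(m)) / 2
    if (norm(tang, "F") < tol) return(m)
  }
  abort("Riemannian mean did not converge.",
        class = "turnintent_convergence_error", data = m)
}

#' Geodesic between two SPD matrices
#'
#' `spd_geodesic(a, b, 0.5)` is the geodesic midpoint
#' `a^(1/2) (a^(-1/2) b a^(-1/2))^(1/2) a^(1/2)`.
#'
#' @param a,b SPD matrices.
#' @param t Position along the geodesic in `[0, 1]`.
#' @rdname spd-geometry
#' @export
spd_geodesic <- function(a, b, t = 0.5) {
  s <- spd_sqrtm(a); si <- spd_invsqrtm(a)
  s %*% sym_eig_fun(si %*% b %*% si, function(v) v^t) %*% s
}

# tangent space --------------------------------------------------------------

# Project SPD matrices to the tangent space at `ref`: vectorized upper
# triangle of log(ref^-1/2 C ref^-1/2) with off-diagonals scaled by sqrt(2)
# so Euclidean distance in the vector space matches the Frobenius norm.
tangent_project <- function(mats, ref) {
  si <- spd_invsqrtm(ref)
  n <- nrow(ref)
  ut <- upper.tri(ref, diag = TRUE)
  w <- ifelse(row(ref) == col(ref), 1, sqrt(2))[ut]
  t(vapply(mats, function(c) {
    l <- spd_logm(si %*% c %*% si)
    l[ut] * w
  }, numeric(sum(ut))))
}

# Inverse of tangent_project for a single tangent vector.
tangent_back <- function(vec, ref) {
  n <- nrow(ref)
  m <- matrix(0, n, n)
  ut <- upper.tri(m, diag = TRUE)
  w <- ifelse(row(m) == col(m), 1, sqrt(2))[ut]
  m[ut] <- vec / w
  m <- m + t(m) - diag(diag(m))
  s <- spd_sqrtm(ref)
  s %*% spd_expm(m) %*% s
}
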