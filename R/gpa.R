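#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared deviations of the landmarks from their
#' centroid — the scale measure removed by Procrustes superimposition.
#'
#' @param coords numeric p x 3 (or p x k) matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  ctr <- colMeans(coords)
  cs <- sqrt(sum(sweep(coords, 2, ctr)^2))
  if (!isTRUE(cs > 0))
    stop("degenerate configuration: all points identical (centroid size 0)")
  cs
}

center_config <- function(coords) {
  sweep(coords, 2, colMeans(coords))
}

#' Optimal rotation between two centered configurations
#'
#' Kabsch solution of the orthogonal Procrustes problem: the proper rotation
#' R (det = +1) minimizing ||A R - B||^2. Reflections are never returned, so
#' reflected copies in a symmetry analysis are not silently un-reflected.
#'
#' @param A,B centered numeric n x 3 matrices.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
optimal_rotation <- function(A, B) {
  stopifnot(nrow(A) == nrow(B), ncol(A) == 3, ncol(B) == 3)
  M <- crossprod(A, B)           # 3x3 cross-covariance
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1             # rank-deficient tie: continuous with identity
  D <- diag(c(1, 1, d))
  sv$u %*% D %*% t(sv$v)
}

#' Generalized Procrustes analysis
#'
#' Iterative superimposition removing translation (centering), scale
#' (all configurations scaled to centroid size one) and rotation (Kabsch,
#' proper rotations only), with recursive consensus updates until the
#' consensus stabilizes. Optionally interleaves bending-energy sliding of
#' semilandmarks against the current consensus.
#'
#' @param dataset a \code{landmark_dataset}.
#' @param slide \code{NULL} (no sliding) or a list from \code{slide_opts()}
#'   carrying the geometry to slide on.
#' @param tol convergence tolerance on the root-mean-square change of the
#'   consensus between iterations.
#' @param max_iter maximum outer iterations.
#' @return An object of class \code{procrustes_fit}: \code{aligned}
#'   (p x 3 x n array of Procrustes shape coordinates), \code{consensus},
#'   \code{centroid_sizes} (mm), \code{n_iterations}, \code{converged},
#'   \code{info} (metadata carried over), \code{schema}.
#' @export
gpa <- function(dataset, slide = NULL, tol = 1e-10, max_iter = 100) {
  coords <- dataset$coords
  n <- dim(coords)[3]
  if (n < 2) stop("GPA needs at least 2 configurations")
  p <- dim(coords)[1]

  cs <- numeric(n)
  aligned <- array(0, dim(coords), dimnames = dimnames(coords))
  for (i in seq_len(n)) {
    x <- center_config(coords[, , i])
    cs[i] <- sqrt(sum(x^2))
    if (!isTRUE(cs[i] > 0)) stop("degenerate configuration at index ", i)
    aligned[, , i] <- x / cs[i]
  }

  consensus <- aligned[, , 1]
  converged <- FALSE
  it <- 0
  ss_prev <- Inf
  while (it < max_iter) {
    it <- it + 1
    for (i in seq_len(n)) {
      R <- optimal_rotation(aligned[, , i], consensus)
      aligned[, , i] <- aligned[, , i] %*% R
    }
    new_cons <- apply(aligned, c(1, 2), mean)
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
    if (!is.null(slide)) {
      aligned <- slide_all(aligned, consensus, dataset$schema, slide)
      # re-center/scale slid configurations
      for (i in seq_len(n)) {
        x <- center_config(aligned[, , i])
        aligned[, , i] <- x / sqrt(sum(x^2))
      }
    }
    if (delta < tol && it > 1) { converged <- TRUE; break }
  }

  # fix the consensus frame deterministically: principal axes of the
  # consensus, signs chosen by coordinate skewness. This makes the output
  # independent of the inputs' original orientations.
  R0 <- consensus_frame(consensus)
  for (i in seq_len(n)) aligned[, , i] <- aligned[, , i] %*% R0
  consensus <- consensus %*% R0

  structure(list(
    aligned = aligned, consensus = consensus, centroid_sizes = cs,
    n_iterations = it, converged = converged,
    info = dataset$info, schema = dataset$schema
  ), class = "procrustes_fit")
}

# principal-axis rotation of a centered configuration with deterministic
# axis signs (third-moment rule; third axis fixed by right-handedness)
consensus_frame <- function(consensus) {
  V <- svd(consensus)$v
  for (j in 1:2) {
    s <- sum((consensus %*% V[, j])^3)
    if (s < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  V
}

# slide every configuration's semilandmarks against the current consensus
slide_all <- function(aligned, consensus, schema, slide) {
  n <- dim(aligned)[3]
  geoms <- slide$geometry
  shared <- !is.null(geoms) && !is.null(geoms$surface)  # single bundle
  for (i in seq_len(n)) {
    geom <- if (shared) geoms else geoms[[i]]
    res <- slide_semilandmarks(aligned[, , i], consensus, schema, geom,
                               opts = slide)
    aligned[, , i] <- res$positions
  }
  aligned
}

#' Sliding options for \code{gpa()}
#'
#' @param geometry a geometry bundle (shared frame) or a list of one bundle
#'   per configuration, used to project slid semilandmarks back onto their
#'   curve/surface. \code{NULL} slides along tangents without re-projection.
#' @param max_iter inner sliding iterations per outer GPA iteration.
#' @param tol relative bending-energy decrease below which sliding stops.
#' @export
slide_opts <- function(geometry = NULL, max_iter = 5, tol = 1e-8) {
  list(geometry = geometry, max_iter = max_iter, tol = tol)
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Procrustes fit: %d configurations, %d landmarks\n",
              dim(x$aligned)[3], dim(x$aligned)[1]))
  cat(sprintf("  iterations: %d (converged: %s)\n", x$n_iterations,
              x$converged))
  cat(sprintf("  centroid size range: %.3f - %.3f\n",
              min(x$centroid_sizes), max(x$centroid_sizes)))
  invisible(x)
}

#' Procrustes distance between two superimposed configurations
#'
#' Euclidean norm of the coordinate-wise difference between two
#' configurations already in the common shape space (partial Procrustes
#' distance in tangent coordinates).
#'
#' @param a,b numeric p x 3 matrices of Procrustes shape coordinates.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("configurations must have matching shape")
  sqrt(sum((a - b)^2))
}

#' Pairwise Procrustes distance matrix of a fit
#'
#' @param fit a \code{procrustes_fit}.
#' @return symmetric n x n matrix with zero diagonal.
#' @export
distance_matrix <- function(fit) {
  n <- dim(fit$aligned)[3]
  flat <- t(apply(fit$aligned, 3, identity))  # n x (p*3)
  D <- as.matrix(stats::dist(flat))
  dimnames(D) <- list(dimnames(fit$aligned)[[3]], dimnames(fit$aligned)[[3]])
  D
}
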