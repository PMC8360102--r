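# Thin-plate spline machinery in 3D.
#
# Kernel U(r) = -r (fundamental-solution sign convention), which makes the
# bending-energy quadratic form positive semidefinite on the non-affine
# subspace; the interpolant is identical to the |r| convention up to the sign
# bookkeeping inside the linear system.

tps_kernel_matrix <- function(X, Y = X) {
  d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  -sqrt(pmax(d2, 0))   # clamp the tiny negatives of exact self-distances
}

tps_system <- function(reference) {
  n <- nrow(reference)
  if (n < 5) stop("TPS in 3D needs at least 5 reference points")
  dd <- as.matrix(stats::dist(reference))
  if (any(dd[upper.tri(dd)] < 1e-12)) {
    idx <- which(dd < 1e-12 & upper.tri(dd), arr.ind = TRUE)
    stop("duplicated reference points: ",
         paste(apply(idx, 1, paste, collapse = "/"), collapse = ", "))
  }
  K <- -dd
  Q <- cbind(1, reference)                    # n x 4
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 4, 4)))
  L
}

#' Bending-energy matrix of a reference configuration
#'
#' The upper-left n x n block of the inverted thin-plate-spline system matrix.
#' It is symmetric positive semidefinite with a 4-dimensional null space
#' spanned by the affine functions (1, x, y, z) of the reference, so affine
#' deformations cost zero energy.
#'
#' @param reference numeric n x 3 matrix, n >= 5, points not coplanar.
#' @return symmetric n x n matrix.
#' @export
bending_energy_matrix <- function(reference) {
  L <- tps_system(reference)
  n <- nrow(reference)
  Li <- tryCatch(solve(L), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  B <- Li[1:n, 1:n, drop = FALSE]
  (B + t(B)) / 2
}

#' Fit a thin-plate-spline interpolant
#'
#' Exact 3D TPS interpolation mapping \code{reference} onto \code{target},
#' decomposed into an affine part and non-affine warp weights; the bending
#' energy is the quadratic form of the target in the reference's
#' bending-energy matrix.
#'
#' @param reference,target numeric n x 3 matrices.
#' @return An object of class \code{tps_transform} with elements
#'   \code{reference}, \code{affine} (4 x 3: intercept row + linear map),
#'   \code{weights} (n x 3 warp weights), \code{bending_energy}.
#' @export
tps_fit <- function(reference, target) {
  stopifnot(all(dim(reference) == dim(target)))
  n <- nrow(reference)
  L <- tps_system(reference)
  rhs <- rbind(target, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs), error = function(e)
    stop("singular TPS system: ", conditionMessage(e)))
  W <- sol[1:n, , drop = FALSE]
  A <- sol[(n + 1):(n + 4), , drop = FALSE]
  K <- tps_kernel_matrix(reference)
  be <- sum(diag(crossprod(W, K %*% W)))
  structure(list(reference = reference, affine = A, weights = W,
                 bending_energy = max(0, be)),
            class = "tps_transform")
}

#' Evaluate a TPS transform at new points
#'
#' @param transform a \code{tps_transform}.
#' @param points numeric m x 3 matrix.
#' @return m x 3 matrix of warped points.
#' @export
tps_predict <- function(transform, points) {
  points <- as.matrix(points)
  U <- tps_kernel_matrix(points, transform$reference)
  cbind(1, points) %*% transform$affine + U %*% transform$weights
}

#' @export
print.tps_transform <- function(x, ...) {
  cat(sprintf("TPS transform on %d points; bending energy %.6g\n",
              nrow(x$reference), x$bending_energy))
  invisible(x)
}
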