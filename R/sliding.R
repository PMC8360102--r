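# Bending-energy sliding of semilandmarks.
#
# Each outer iteration linearizes the geometry at the current positions:
# curve semilandmarks may move along the local polyline tangent (1 dof),
# surface semilandmarks in the local tangent plane of the mesh (2 dof).
# The tangential displacements minimizing the TPS bending energy relative to
# the reference are solved in closed form, then the slid points are projected
# back onto their curve/surface.

#' Slide semilandmarks to minimize bending energy
#'
#' @param current numeric p x 3 matrix: the configuration whose semilandmarks
#'   are slid (fixed landmarks never move).
#' @param reference numeric p x 3 matrix: the configuration (template or
#'   Procrustes consensus) whose bending-energy matrix defines the criterion.
#' @param schema an \code{asym_schema}.
#' @param geometry a \code{geometry_bundle} in the same frame as
#'   \code{current}, providing the curves and surface to slide on.
#' @param opts list from \code{slide_opts()} (\code{max_iter}, \code{tol}).
#' @return An object of class \code{sliding_result}: \code{positions}
#'   (p x 3), \code{bending_energy_trace} (energy at start and after each
#'   iteration, non-increasing), \code{n_iterations}.
#' @export
slide_semilandmarks <- function(current, reference, schema = palate_schema(),
                                geometry = NULL, opts = slide_opts()) {
  if (is.null(geometry))
    stop("sliding requires a geometry_bundle (curves and/or surface)")
  p <- nrow(schema)
  stopifnot(nrow(current) == p, nrow(reference) == p)
  B <- bending_energy_matrix(reference)
  bb <- geometry_bbox(geometry)

  energy <- function(Y) sum(Y * (B %*% Y))
  Y <- current
  trace <- energy(Y)
  max_iter <- if (is.null(opts$max_iter)) 5 else opts$max_iter
  tol <- if (is.null(opts$tol)) 1e-8 else opts$tol

  curve_pts <- which(schema$role == "curve")
  surf_pts <- which(schema$role == "surface")
  if (!is.null(geometry$surface) && length(surf_pts) == 0 &&
      length(curve_pts) == 0)
    stop("schema has no semilandmarks to slide")

  it <- 0
  while (it < max_iter) {
    it <- it + 1
    dirs <- list(); owner <- integer(0)
    for (l in curve_pts) {
      cid <- schema$curve_id[l]
      if (is.na(cid) || is.null(geometry$curves[[cid]])) next
      pr <- project_to_polyline(Y[l, ], geometry$curves[[cid]])
      dirs[[length(dirs) + 1]] <- pr$tangent
      owner <- c(owner, l)
    }
    if (!is.null(geometry$surface)) {
      for (l in surf_pts) {
        pr <- project_to_mesh(Y[l, ], geometry$surface)
        basis <- tangent_plane_basis(pr$normal)
        dirs[[length(dirs) + 1]] <- basis[, 1]
        owner <- c(owner, l)
        dirs[[length(dirs) + 1]] <- basis[, 2]
        owner <- c(owner, l)
      }
    }
    m <- length(dirs)
    if (m == 0) break
    # stacked coordinates y = [x; y; z] (3p), energy = y' (I3 (x) B) y
    y0 <- as.vector(Y)
    Tm <- matrix(0, 3 * p, m)
    for (k in seq_len(m)) {
      l <- owner[k]; u <- dirs[[k]]
      Tm[l, k] <- u[1]; Tm[p + l, k] <- u[2]; Tm[2 * p + l, k] <- u[3]
    }
    BT <- rbind(B %*% Tm[1:p, , drop = FALSE],
                B %*% Tm[(p + 1):(2 * p), , drop = FALSE],
                B %*% Tm[(2 * p + 1):(3 * p), , drop = FALSE])
    G <- crossprod(Tm, BT)
    g <- crossprod(BT, y0)
    G <- G + diag(1e-12 * max(diag(G), 1), m)   # guard near-singular solves
    s <- tryCatch(-solve(G, g), error = function(e)
      stop("singular sliding system: ", conditionMessage(e)))
    if (any(!is.finite(s))) stop("non-finite sliding solve")
    Ynew <- Y + matrix(Tm %*% s, p, 3)
    # project back onto geometry
    for (l in curve_pts) {
      cid <- schema$curve_id[l]
      if (is.na(cid) || is.null(geometry$curves[[cid]])) next
      check_bbox(Ynew[l, ], bb, l)
      Ynew[l, ] <- project_to_polyline(Ynew[l, ],
                                       geometry$curves[[cid]])$point
    }
    if (!is.null(geometry$surface)) {
      for (l in surf_pts) {
        check_bbox(Ynew[l, ], bb, l)
        Ynew[l, ] <- project_to_mesh(Ynew[l, ], geometry$surface)$point
      }
    }
    e_new <- energy(Ynew)
    e_old <- trace[length(trace)]
    if (e_new > e_old) break                    # projection undid the gain
    Y <- Ynew
    trace <- c(trace, e_new)
    if ((e_old - e_new) <= tol * max(e_old, .Machine$double.eps)) break
  }
  structure(list(positions = Y, bending_energy_trace = trace,
                 n_iterations = length(trace) - 1L),
            class = "sliding_result")
}

geometry_bbox <- function(geometry) {
  pts <- NULL
  if (!is.null(geometry$surface)) pts <- geometry$surface$vertices
  for (cv in geometry$curves) pts <- rbind(pts, cv)
  r <- apply(pts, 2, range)
  pad <- 0.25 * max(r[2, ] - r[1, ])
  rbind(r[1, ] - pad, r[2, ] + pad)
}

check_bbox <- function(p, bb, l) {
  if (any(p < bb[1, ]) || any(p > bb[2, ]))
    stop("projection failure: landmark ", l, " left the geometry bounding box")
  invisible(TRUE)
}

#' @export
print.sliding_result <- function(x, ...) {
  tr <- x$bending_energy_trace
  cat(sprintf("Sliding: %d iterations, bending energy %.6g -> %.6g\n",
              x$n_iterations, tr[1], tr[length(tr)]))
  invisible(x)
}
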