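# Geometry primitives: triangle meshes and polylines, nearest-point
# projection, tangent estimation. A geometry bundle is
#   list(surface = list(vertices = n x 3, faces = m x 3 integer),
#        curves  = list(curve_id = p x 3 ordered polyline))

#' Construct and validate a geometry bundle
#'
#' @param surface list with \code{vertices} (n x 3) and \code{faces}
#'   (m x 3, 1-based integer indices), or \code{NULL}.
#' @param curves named list of ordered polyline matrices (>= 2 points each).
#' @return validated geometry bundle (class \code{geometry_bundle}).
#' @export
geometry_bundle <- function(surface = NULL, curves = list()) {
  if (!is.null(surface)) {
    v <- as.matrix(surface$vertices); f <- as.matrix(surface$faces)
    storage.mode(f) <- "integer"
    if (ncol(v) != 3) stop("mesh vertices must be n x 3")
    if (ncol(f) != 3) stop("mesh must be triangulated (m x 3 faces)")
    if (min(f) < 1 || max(f) > nrow(v))
      stop("faces index vertices outside 1..", nrow(v))
    a <- triangle_areas(v, f)
    keep <- a > 1e-12 * max(a)   # degenerate faces are never projected onto
    f <- f[keep, , drop = FALSE]; a <- a[keep]
    if (nrow(f) == 0) stop("mesh has no non-degenerate faces")
    surface <- list(vertices = v, faces = f, areas = a)
  }
  curves <- lapply(curves, function(cv) {
    cv <- as.matrix(cv)
    if (nrow(cv) < 2) stop("polyline must have >= 2 points")
    if (ncol(cv) != 3) stop("polyline must be p x 3")
    cv
  })
  structure(list(surface = surface, curves = curves),
            class = "geometry_bundle")
}

triangle_areas <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# nearest point on segment ab to p
closest_on_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
  t <- min(1, max(0, t))
  a + t * ab
}

#' Project a point onto a polyline
#'
#' @param p length-3 point.
#' @param polyline ordered p x 3 matrix.
#' @return list(point, segment, tangent) — nearest point, index of the
#'   segment it lies on, and the unit tangent of the polyline there
#'   (central difference in the interior, one-sided at the ends).
#' @export
project_to_polyline <- function(p, polyline) {
  ns <- nrow(polyline) - 1
  best <- NULL; bd <- Inf; bs <- 1L
  for (s in seq_len(ns)) {
    q <- closest_on_segment(p, polyline[s, ], polyline[s + 1, ])
    d <- sum((p - q)^2)
    if (d < bd) { bd <- d; best <- q; bs <- s }
  }
  # tangent from neighbouring vertices around the segment
  i0 <- max(1, bs); i1 <- min(nrow(polyline), bs + 1)
  tang <- polyline[i1, ] - polyline[i0, ]
  if (bs > 1 && bs < ns) # central difference across adjacent vertices
    tang <- polyline[min(nrow(polyline), bs + 2), ] - polyline[max(1, bs - 1), ]
  tang <- tang / sqrt(sum(tang^2))
  list(point = best, segment = bs, tangent = tang)
}

# nearest point on triangle (a,b,c) to p (Ericson, Real-Time Collision
# Detection, 5.1.5)
closest_on_triangle <- function(p, a, b, c) {
  ab <- b - a; ac <- c - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + (d1 / (d1 - d3)) * ab)
  cp <- p - c
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + (d2 / (d2 - d6)) * ac)
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + ((d4 - d3) / ((d4 - d3) + (d5 - d6))) * (c - b))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

#' Project a point onto a triangle mesh
#'
#' @param p length-3 point.
#' @param surface mesh list (vertices, faces) from a geometry bundle.
#' @return list(point, face, normal) — nearest surface point, face index and
#'   unit face normal there.
#' @export
project_to_mesh <- function(p, surface) {
  v <- surface$vertices; f <- surface$faces
  # prune: only consider faces whose nearest vertex is among the closest
  d2v <- rowSums(sweep(v, 2, p)^2)
  ord <- order(d2v)[seq_len(min(30L, nrow(v)))]
  cand <- which(rowSums(matrix(f %in% ord, nrow(f))) > 0)
  if (length(cand) == 0) cand <- seq_len(nrow(f))
  bd <- Inf; bq <- NULL; bf <- NA_integer_
  for (j in cand) {
    tri <- f[j, ]
    q <- closest_on_triangle(p, v[tri[1], ], v[tri[2], ], v[tri[3], ])
    d <- sum((p - q)^2)
    if (d < bd) { bd <- d; bq <- q; bf <- j }
  }
  tri <- f[bf, ]
  e1 <- v[tri[2], ] - v[tri[1], ]; e2 <- v[tri[3], ] - v[tri[1], ]
  nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
           e1[3] * e2[1] - e1[1] * e2[3],
           e1[1] * e2[2] - e1[2] * e2[1])
  nrm <- nrm / sqrt(sum(nrm^2))
  list(point = bq, face = bf, normal = nrm)
}

# orthonormal basis of the plane orthogonal to unit vector n
tangent_plane_basis <- function(n) {
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  t1 <- a - sum(a * n) * n
  t1 <- t1 / sqrt(sum(t1^2))
  t2 <- c(n[2] * t1[3] - n[3] * t1[2],
          n[3] * t1[1] - n[1] * t1[3],
          n[1] * t1[2] - n[2] * t1[1])
  cbind(t1, t2)
}

polyline_length <- function(polyline) {
  sum(sqrt(rowSums(diff(polyline)^2)))
}

# point at arc-length fraction t in [0,1] along a polyline
polyline_point_at <- function(polyline, t) {
  seg <- sqrt(rowSums(diff(polyline)^2))
  cum <- c(0, cumsum(seg))
  target <- t * cum[length(cum)]
  s <- findInterval(target, cum, rightmost.closed = TRUE)
  s <- min(max(s, 1L), length(seg))
  frac <- (target - cum[s]) / seg[s]
  polyline[s, ] + frac * (polyline[s + 1, ] - polyline[s, ])
}
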