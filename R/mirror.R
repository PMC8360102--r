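#' Reflect and relabel a configuration
#'
#' The object-symmetry operation: negate the x coordinate (reflection in the
#' midsagittal plane x = 0) and permute landmark labels by the schema's
#' bilateral pairing so left/right landmarks swap identities. Applying it
#' twice returns the input.
#'
#' @param coords numeric p x 3 matrix in a frame where the midsagittal plane
#'   is x = 0 (raw coordinates after \code{midsagittal_align()}, or
#'   Procrustes coordinates).
#' @param schema an \code{asym_schema}.
#' @return p x 3 matrix of the reflected, relabelled configuration.
#' @export
reflect_relabel <- function(coords, schema = palate_schema()) {
  stopifnot(nrow(coords) == nrow(schema))
  perm <- match(schema$pair_id, schema$id)
  out <- coords[perm, , drop = FALSE]
  out[, 1] <- -out[, 1]
  dimnames(out) <- dimnames(coords)
  out
}

#' Mirror a landmark configuration
#'
#' Wraps \code{reflect_relabel()} for a \code{landmark_config}, toggling its
#' reflected-copy flag.
#'
#' @param config a \code{landmark_config} in the midsagittal frame.
#' @param schema an \code{asym_schema}.
#' @return a new \code{landmark_config}.
#' @export
mirror_configuration <- function(config, schema = palate_schema()) {
  landmark_config(
    reflect_relabel(config$coordinates, schema),
    individual_id = config$individual_id,
    age_group = config$age_group, sex = config$sex,
    collection = config$collection,
    is_reflected_copy = !config$is_reflected_copy
  )
}

#' Rotate a configuration into the midsagittal frame
#'
#' Defines the midsagittal plane operationally as the best-fit plane through
#' the midline landmark set (ids 1, 4, 5, 38-41 in the canonical schema) and
#' returns the configuration in a frame where that plane is x = 0, with the
#' left side at negative x.
#'
#' @param coords numeric p x 3 matrix (mm).
#' @param schema an \code{asym_schema}.
#' @return list(coords, rotation, center): transformed coordinates plus the
#'   rotation matrix and plane point used (new = (old - center) \%*\% rotation).
#' @export
midsagittal_align <- function(coords, schema = palate_schema()) {
  mid_ids <- attr(schema, "midplane_ids")
  idx <- match(mid_ids, schema$id)
  M <- coords[idx, , drop = FALSE]
  ctr <- colMeans(M)
  sv <- svd(sweep(M, 2, ctr))
  nrm <- sv$v[, 3]                       # least-variance direction
  basis <- tangent_plane_basis(nrm)
  R <- cbind(nrm, basis)
  out <- sweep(coords, 2, ctr) %*% R
  # orient: left landmarks at negative x
  left <- which(schema$side == "left")
  if (length(left) && mean(out[left, 1]) > 0) {
    out[, 1] <- -out[, 1]
    R[, 1] <- -R[, 1]
  }
  # keep the frame right-handed
  if (det(R) < 0) {
    out[, 3] <- -out[, 3]
    R[, 3] <- -R[, 3]
  }
  list(coords = out, rotation = R, center = ctr)
}

#' Complete a half-digitized template by mirroring
#'
#' Surface semilandmarks are digitized on the right hemi-palate only; their
#' left-side counterparts are created by mirroring across the midsagittal
#' plane and projecting onto the actual (possibly asymmetric) surface.
#'
#' @param half_template numeric 41 x 3 matrix in the midsagittal frame with
#'   rows of left-side surface semilandmarks set to \code{NA}.
#' @param schema an \code{asym_schema}.
#' @param geometry a \code{geometry_bundle} whose surface the mirrored points
#'   are projected onto (in the same frame).
#' @return complete 41 x 3 matrix conforming to the schema.
#' @export
complete_template_by_mirroring <- function(half_template,
                                           schema = palate_schema(),
                                           geometry = NULL) {
  out <- half_template
  fill <- which(schema$role == "surface" & schema$side == "left")
  missing_rows <- which(apply(is.na(half_template), 1, any))
  if (!all(missing_rows %in% fill))
    stop("only left-side surface semilandmarks may be missing")
  for (l in fill) {
    src <- match(schema$pair_id[l], schema$id)
    p <- half_template[src, ]
    if (any(is.na(p))) stop("right-side source landmark ", src, " is missing")
    p[1] <- -p[1]
    if (!is.null(geometry) && !is.null(geometry$surface)) {
      bb <- apply(geometry$surface$vertices, 2, range)
      diam <- sqrt(sum((bb[2, ] - bb[1, ])^2))
      pr <- project_to_mesh(p, geometry$surface)
      if (sqrt(sum((pr$point - p)^2)) > 0.5 * diam)
        stop("projection failure: mirrored point far outside the surface")
      p <- pr$point
    }
    out[l, ] <- p
  }
  if (any(is.na(out))) stop("template completion left missing coordinates")
  out
}
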