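# Object-symmetry decomposition: originals vs reflected/relabelled copies,
# directional asymmetry (DA) per group and fluctuating asymmetry (FA) per
# individual, at whole-configuration and per-landmark resolution.
#
# Convention: the individual asymmetry vector is a_i = O_i - RR_i and the
# group DA vector is d_k = mean_i(a_i), so FA deviations a_i - d_k are
# exactly centred within each group. The scalar DA equals the Procrustes
# distance between the group mean original and mean reflected configuration
# either way round (it is a norm).

#' Double a dataset with reflected/relabelled copies
#'
#' For each original configuration, appends its mirror image (x negated,
#' labels permuted by the bilateral pairing), ready for a joint Procrustes
#' superimposition of originals and copies.
#'
#' @param dataset a \code{landmark_dataset} of originals only.
#' @return a \code{landmark_dataset} with 2n configurations; reflected copies
#'   carry \code{is_reflected_copy = TRUE} and the same individual_id.
#' @export
build_symmetry_dataset <- function(dataset) {
  info <- dataset$info
  if (any(info$is_reflected_copy))
    stop("dataset already contains reflected copies")
  if (anyDuplicated(info$individual_id))
    stop("duplicate individual ids")
  n <- n_configs(dataset)
  p <- dim(dataset$coords)[1]
  coords <- array(NA_real_, c(p, 3, 2 * n))
  coords[, , seq_len(n)] <- dataset$coords
  for (i in seq_len(n))
    coords[, , n + i] <- reflect_relabel(dataset$coords[, , i],
                                         dataset$schema)
  info2 <- rbind(info, info)
  info2$is_reflected_copy <- rep(c(FALSE, TRUE), each = n)
  dataset_from_array(coords, info2, dataset$schema,
                     provenance = c(dataset$provenance,
                                    list(doubled = TRUE)))
}

#' Rotate a Procrustes fit into the symmetry frame
#'
#' After a joint GPA of originals and reflected copies the consensus is a
#' symmetric shape, but its symmetry plane sits at an arbitrary orientation
#' in the consensus frame. This rotates the whole fit so that the plane is
#' x = 0 (with the left side at negative x), which makes the reflection
#' operation \code{reflect_relabel()} act literally on the aligned
#' coordinates and the symmetric component reflection-invariant.
#'
#' @param fit a \code{procrustes_fit} on doubled data.
#' @return the fit, rotated.
#' @export
symmetry_frame <- function(fit) {
  schema <- fit$schema
  C <- fit$consensus
  perm <- match(schema$pair_id, schema$id)
  B <- C[perm, , drop = FALSE]          # relabelled (not reflected) consensus
  # improper orthogonal transform best mapping C onto B: C O ~ B, det(O) = -1
  M <- crossprod(C, B)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- if (d < 0) diag(3) else diag(c(1, 1, -1))
  O <- sv$u %*% D %*% t(sv$v)
  # plane normal: eigenvector of the (symmetrized) reflection with
  # eigenvalue -1
  ev <- eigen((O + t(O)) / 2, symmetric = TRUE)
  nrm <- ev$vectors[, which.min(ev$values)]
  Q <- cbind(nrm, tangent_plane_basis(nrm))
  rot <- function(X) X %*% Q
  aligned <- fit$aligned
  for (i in seq_len(dim(aligned)[3])) aligned[, , i] <- rot(aligned[, , i])
  C2 <- rot(C)
  left <- which(schema$side == "left")
  if (length(left) && mean(C2[left, 1]) > 0) {
    flip <- diag(c(-1, 1, -1))          # proper rotation flipping x (and z)
    for (i in seq_len(dim(aligned)[3]))
      aligned[, , i] <- aligned[, , i] %*% flip
    C2 <- C2 %*% flip
  }
  fit$aligned <- aligned
  fit$consensus <- C2
  fit
}

#' Decompose a doubled Procrustes fit into symmetric and asymmetric parts
#'
#' @param fit a \code{procrustes_fit} on a doubled dataset (every original
#'   paired with its reflected copy by individual_id).
#' @param groups grouping factor for the originals, or the name of a metadata
#'   column (default \code{"age_group"}).
#' @return list with elements \code{individual} (asymmetry vectors p x 3 x n,
#'   \code{fa_scalar}, \code{fa_per_landmark} n x p, ids, group),
#'   \code{group} (\code{da_vector} p x 3 x k, \code{da_scalar},
#'   \code{da_unbiased}, \code{da_per_landmark} k x p, \code{n}), and
#'   \code{symmetric} (per-individual symmetric shapes and group means).
#' @export
asym_decompose <- function(fit, groups = "age_group") {
  fit <- symmetry_frame(fit)
  info <- fit$info
  orig <- which(!info$is_reflected_copy)
  refl <- which(info$is_reflected_copy)
  ids <- info$individual_id[orig]
  partner <- refl[match(ids, info$individual_id[refl])]
  if (anyNA(partner))
    stop("unpaired configuration(s): ",
         paste(ids[is.na(partner)], collapse = ", "))
  if (is.character(groups) && length(groups) == 1)
    groups <- info[[groups]][orig]
  groups <- factor(groups)
  n <- length(orig)
  p <- dim(fit$aligned)[1]

  avec <- array(NA_real_, c(p, 3, n), dimnames = list(NULL, NULL, ids))
  sym <- array(NA_real_, c(p, 3, n), dimnames = list(NULL, NULL, ids))
  for (i in seq_len(n)) {
    O <- fit$aligned[, , orig[i]]
    RR <- fit$aligned[, , partner[i]]
    avec[, , i] <- O - RR
    sym[, , i] <- (O + RR) / 2
  }

  lev <- levels(groups)
  k <- length(lev)
  da_vec <- array(NA_real_, c(p, 3, k), dimnames = list(NULL, NULL, lev))
  da_scalar <- stats::setNames(numeric(k), lev)
  da_unbiased <- stats::setNames(numeric(k), lev)
  da_lm <- matrix(NA_real_, k, p, dimnames = list(lev, NULL))
  gn <- stats::setNames(integer(k), lev)
  fa_scalar <- stats::setNames(numeric(n), ids)
  fa_lm <- matrix(NA_real_, n, p, dimnames = list(ids, NULL))
  sym_group <- array(NA_real_, c(p, 3, k), dimnames = list(NULL, NULL, lev))

  for (g in seq_len(k)) {
    sel <- which(groups == lev[g])
    gn[g] <- length(sel)
    d <- apply(avec[, , sel, drop = FALSE], c(1, 2), mean)
    da_vec[, , g] <- d
    da_scalar[g] <- sqrt(sum(d^2))
    da_lm[g, ] <- sqrt(rowSums(d^2))
    sym_group[, , g] <- apply(sym[, , sel, drop = FALSE], c(1, 2), mean)
    for (i in sel) {
      dev <- avec[, , i] - d
      fa_scalar[i] <- sqrt(sum(dev^2))
      fa_lm[i, ] <- sqrt(rowSums(dev^2))
    }
    # unbiased squared-norm estimate of the true DA:
    # E||mean(a)||^2 = ||d_true||^2 + tr(Sigma)/n, with
    # tr(Sigma)/n estimated by sum(FA_i^2) / (n (n-1))
    if (gn[g] > 1) {
      corr <- sum(fa_scalar[sel]^2) / (gn[g] * (gn[g] - 1))
      da_unbiased[g] <- sqrt(max(0, da_scalar[g]^2 - corr))
    } else da_unbiased[g] <- da_scalar[g]
  }

  list(
    individual = list(asym_vector = avec, fa_scalar = fa_scalar,
                      fa_per_landmark = fa_lm, individual_id = ids,
                      group = groups),
    group = list(da_vector = da_vec, da_scalar = da_scalar,
                 da_unbiased = da_unbiased, da_per_landmark = da_lm,
                 n = gn),
    symmetric = list(individual = sym, group_mean = sym_group)
  )
}

#' Per-landmark DA and FA tables
#'
#' @param decomposition result of \code{asym_decompose()}.
#' @return list with \code{da} (k groups x p landmarks matrix) and \code{fa}
#'   (n individuals x p landmarks matrix).
#' @export
per_landmark_tables <- function(decomposition) {
  list(da = decomposition$group$da_per_landmark,
       fa = decomposition$individual$fa_per_landmark)
}

#' Fit the object-symmetry asymmetry model
#'
#' The package's central fitting function. Takes a dataset of original
#' configurations, appends reflected/relabelled copies, superimposes all of
#' them jointly by generalized Procrustes analysis (optionally with
#' semilandmark sliding), and decomposes each individual's shape into a
#' symmetric component and an asymmetry vector, summarized as group-level
#' directional asymmetry (DA) and individual fluctuating asymmetry (FA).
#'
#' @param dataset a \code{landmark_dataset} of originals.
#' @param groups grouping factor or metadata column name (default
#'   \code{"age_group"}).
#' @param slide \code{NULL} or \code{slide_opts()} for sliding during GPA.
#' @param gpa_mode \code{"pooled"} (one joint superimposition across all
#'   groups; default, required for between-group comparisons) or
#'   \code{"per_group"} (a separate superimposition per group).
#' @return An object of class \code{asymfit}.
#' @export
#' @examples
#' spec <- simulation_spec(n_per_group = c(A = 8, B = 8), seed = 7)
#' pop <- simulate_population(spec)
#' fit <- fit_asymmetry(pop$dataset)
#' fit
#' coef(fit)
fit_asymmetry <- function(dataset, groups = "age_group", slide = NULL,
                          gpa_mode = c("pooled", "per_group")) {
  gpa_mode <- match.arg(gpa_mode)
  doubled <- build_symmetry_dataset(dataset)
  if (is.character(groups) && length(groups) == 1) {
    gvec <- dataset$info[[groups]]
  } else {
    gvec <- groups
  }
  gvec <- factor(gvec)

  if (gpa_mode == "pooled") {
    fit <- symmetry_frame(gpa(doubled, slide = slide))
    dec <- asym_decompose(fit, groups = gvec)
    fits <- list(pooled = fit)
  } else {
    # independent shape space per group
    lev <- levels(gvec)
    fits <- list()
    parts <- list()
    for (g in lev) {
      sel <- which(c(gvec, gvec) == g)  # doubled info repeats the originals
      sub <- dataset_from_array(doubled$coords[, , sel, drop = FALSE],
                                doubled$info[sel, , drop = FALSE],
                                doubled$schema)
      fg <- symmetry_frame(gpa(sub, slide = slide))
      fits[[g]] <- fg
      parts[[g]] <- asym_decompose(fg, groups = rep(g, sum(gvec == g)))
    }
    dec <- merge_decompositions(parts, lev)
    fit <- fits[[1]]
  }

  structure(list(
    gpa = fit, gpa_mode = gpa_mode, fits = fits,
    decomposition = dec, groups = dec$individual$group,
    schema = dataset$schema, info = dataset$info,
    call = match.call()
  ), class = "asymfit")
}

merge_decompositions <- function(parts, lev) {
  ind <- list(
    asym_vector = do.call(function(...) {
      arrs <- list(...)
      array(unlist(arrs), c(dim(arrs[[1]])[1:2],
                            sum(vapply(arrs, function(a) dim(a)[3], 1L))))
    }, lapply(parts, function(p) p$individual$asym_vector)),
    fa_scalar = unlist(lapply(parts, function(p) p$individual$fa_scalar)),
    fa_per_landmark = do.call(rbind, lapply(parts, function(p)
      p$individual$fa_per_landmark)),
    individual_id = unlist(lapply(parts, function(p)
      p$individual$individual_id)),
    group = factor(unlist(lapply(parts, function(p)
      as.character(p$individual$group))), levels = lev)
  )
  grp <- list(
    da_vector = array(unlist(lapply(parts, function(p) p$group$da_vector)),
                      c(dim(parts[[1]]$group$da_vector)[1:2], length(lev)),
                      dimnames = list(NULL, NULL, lev)),
    da_scalar = stats::setNames(vapply(parts, function(p)
      p$group$da_scalar[[1]], 1), lev),
    da_unbiased = stats::setNames(vapply(parts, function(p)
      p$group$da_unbiased[[1]], 1), lev),
    da_per_landmark = do.call(rbind, lapply(parts, function(p)
      p$group$da_per_landmark)),
    n = stats::setNames(vapply(parts, function(p) p$group$n[[1]], 1L), lev)
  )
  list(individual = ind, group = grp,
       symmetric = parts[[1]]$symmetric)
}

#' @export
print.asymfit <- function(x, ...) {
  g <- x$decomposition$group
  cat("Object-symmetry asymmetry fit\n")
  cat(sprintf("  %d individuals in %d group(s); %d landmarks; GPA mode: %s\n",
              length(x$decomposition$individual$individual_id),
              length(g$n), dim(x$gpa$aligned)[1], x$gpa_mode))
  cat("  directional asymmetry (Procrustes units):\n")
  print(round(g$da_scalar, 6))
  invisible(x)
}

#' @export
summary.asymfit <- function(object, ...) {
  g <- object$decomposition$group
  ind <- object$decomposition$individual
  fa_mean <- tapply(ind$fa_scalar, ind$group, mean)
  out <- data.frame(
    group = names(g$da_scalar), n = as.integer(g$n),
    DA = as.numeric(g$da_scalar),
    DA_unbiased = as.numeric(g$da_unbiased),
    FA_mean = as.numeric(fa_mean[names(g$da_scalar)]),
    row.names = NULL
  )
  structure(list(table = out, gpa_mode = object$gpa_mode,
                 converged = object$gpa$converged,
                 n_iterations = object$gpa$n_iterations),
            class = "summary.asymfit")
}

#' @export
print.summary.asymfit <- function(x, ...) {
  cat("Object-symmetry asymmetry fit\n")
  cat(sprintf("  GPA: %d iterations (converged: %s), mode %s\n",
              x$n_iterations, x$converged, x$gpa_mode))
  cat("  per-group asymmetry (Procrustes units):\n")
  print(x$table, digits = 5)
  invisible(x)
}

#' @export
coef.asymfit <- function(object, type = c("da", "da_per_landmark"), ...) {
  type <- match.arg(type)
  g <- object$decomposition$group
  if (type == "da") g$da_scalar else g$da_per_landmark
}

#' @export
residuals.asymfit <- function(object, ...) {
  # FA deviation vectors: a_i - d_k(i), a p x 3 x n array
  dec <- object$decomposition
  avec <- dec$individual$asym_vector
  out <- avec
  for (i in seq_along(dec$individual$individual_id)) {
    gi <- as.character(dec$individual$group[i])
    out[, , i] <- avec[, , i] - dec$group$da_vector[, , gi]
  }
  out
}

#' @export
fitted.asymfit <- function(object, ...) {
  # per-individual symmetric shape plus half its group DA (model part of O_i)
  dec <- object$decomposition
  sym <- dec$symmetric$individual
  out <- sym
  for (i in seq_along(dec$individual$individual_id)) {
    gi <- as.character(dec$individual$group[i])
    out[, , i] <- sym[, , i] + dec$group$da_vector[, , gi] / 2
  }
  out
}

#' @export
plot.asymfit <- function(x, which = c("da", "fa"), ...) {
  which <- match.arg(which)
  dec <- x$decomposition
  p <- ncol(dec$group$da_per_landmark)
  if (which == "da") {
    tab <- dec$group$da_per_landmark
    graphics::matplot(seq_len(p), t(tab), type = "l", lty = 1,
                      xlab = "landmark", ylab = "DA (Procrustes units)",
                      main = "Directional asymmetry per landmark", ...)
    graphics::legend("topright", legend = rownames(tab), lty = 1,
                     col = seq_len(nrow(tab)), cex = 0.8, bty = "n")
  } else {
    fa <- dec$individual$fa_per_landmark
    grp <- dec$individual$group
    lev <- levels(grp)
    mu <- t(vapply(lev, function(g)
      colMeans(fa[grp == g, , drop = FALSE]), numeric(p)))
    graphics::matplot(seq_len(p), t(mu), type = "l", lty = 1,
                      xlab = "landmark", ylab = "mean FA (Procrustes units)",
                      main = "Fluctuating asymmetry per landmark", ...)
    graphics::legend("topright", legend = lev, lty = 1,
                     col = seq_along(lev), cex = 0.8, bty = "n")
  }
  invisible(x)
}
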