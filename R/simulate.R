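# Synthetic bilateral palate-like populations with known asymmetry ground
# truth. The template is a triangulated half-ellipsoid dome (palatal vault)
# with two lateral alveolar curves and a median-suture curve; individuals are
# drawn as template x growth scale + symmetric individual variation +
# antisymmetric directional field + antisymmetric fluctuating noise +
# isotropic measurement error, then moved by a random similarity jitter so
# superimposition is actually exercised.

#' Specification of a synthetic population
#'
#' @param n_per_group named integer vector of group sizes.
#' @param semi_axes dome semi-axes (half-width, half-length, depth) in mm.
#'   The default 25/25/12 gives a 50 mm dome.
#' @param growth_scale isotropic scale factor per group (same length/names as
#'   \code{n_per_group}); emulates palate growth across age groups.
#' @param da_magnitude per-group magnitude (mm) of the directional asymmetry
#'   field, measured as the Frobenius norm of its antisymmetric part.
#' @param da_landmarks landmark ids carrying the DA displacement (anterior
#'   surface semilandmarks by default, where the study localizes DA).
#' @param sigma_fa per-coordinate SD (mm) of the random asymmetric
#'   (fluctuating) field.
#' @param sigma_sym per-coordinate SD (mm) of symmetric individual variation.
#' @param sigma_noise isotropic landmark measurement error SD (mm); default
#'   0.05, the accuracy of the structured-light scanner emulated.
#' @param sex_effect optional 41 x 3 displacement (mm) added to males.
#' @param jitter apply a random rigid motion + scale jitter per individual.
#' @param seed integer seed.
#' @return list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_per_group = c(I = 5, II = 14, III = 11,
                                            IV = 26, V = 82, VI = 45),
                            semi_axes = c(25, 25, 12),
                            growth_scale = NULL,
                            da_magnitude = NULL,
                            da_landmarks = c(14, 15, 16, 2, 3),
                            sigma_fa = 0.1,
                            sigma_sym = 0.5,
                            sigma_noise = 0.05,
                            sex_effect = NULL,
                            jitter = TRUE,
                            seed = 1L) {
  k <- length(n_per_group)
  if (is.null(names(n_per_group)))
    names(n_per_group) <- paste0("G", seq_len(k))
  if (is.null(growth_scale)) {
    growth_scale <- if (k == 6) c(0.55, 0.7, 0.85, 0.95, 1, 1)
                    else rep(1, k)
    names(growth_scale) <- names(n_per_group)
  }
  if (is.null(da_magnitude)) {
    da_magnitude <- if (k == 6) c(0.3, 0.5, 0.35, 0.25, 0.25, 0.45)
                    else rep(0.5, k)
  }
  if (length(growth_scale) == 1) growth_scale <- rep(growth_scale, k)
  if (length(da_magnitude) == 1) da_magnitude <- rep(da_magnitude, k)
  names(growth_scale) <- names(n_per_group)
  names(da_magnitude) <- names(n_per_group)
  stopifnot(all(c(sigma_fa, sigma_sym, sigma_noise) >= 0),
            all(semi_axes > 0),
            length(growth_scale) == k, length(da_magnitude) == k)
  structure(list(
    n_per_group = n_per_group, semi_axes = semi_axes,
    growth_scale = growth_scale, da_magnitude = da_magnitude,
    da_landmarks = da_landmarks, sigma_fa = sigma_fa,
    sigma_sym = sigma_sym, sigma_noise = sigma_noise,
    sex_effect = sex_effect, jitter = jitter, seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Preset matching the growth-study design
#'
#' The six age groups with their published sizes (5, 14, 11, 26, 82, 45;
#' 183 individuals in total), male/female/indeterminate splits and the two
#' collection provenances.
#'
#' @param ... overrides passed to \code{simulation_spec()}.
#' @return a \code{simulation_spec} with attribute \code{design} holding the
#'   per-group sex and collection counts.
#' @export
study_preset <- function(...) {
  spec <- simulation_spec(
    n_per_group = c(I = 5, II = 14, III = 11, IV = 26, V = 82, VI = 45),
    ...)
  attr(spec, "design") <- list(
    # counts: Bologna M/F, Florence M/F/ND
    sex = list(I = c(M = 3, F = 2), II = c(M = 8, F = 6),
               III = c(M = 8, F = 3), IV = c(M = 11, F = 14, ND = 1),
               V = c(M = 42, F = 40), VI = c(M = 19, F = 26)),
    collection = list(I = c(Bologna = 4, Florence = 1),
                      II = c(Bologna = 11, Florence = 3),
                      III = c(Bologna = 6, Florence = 5),
                      IV = c(Bologna = 11, Florence = 15),
                      V = c(Bologna = 26, Florence = 56),
                      VI = c(Bologna = 29, Florence = 16))
  )
  spec
}

#' Build the dome geometry and template configuration
#'
#' @param spec a \code{simulation_spec}.
#' @param n_rings,n_sectors mesh resolution of the dome.
#' @return list(geometry, template, schema): a \code{geometry_bundle} (dome
#'   mesh + three curves), the 41 x 3 template coordinates placed on it, and
#'   the schema.
#' @export
make_palate_geometry <- function(spec = simulation_spec(), n_rings = 14,
                                 n_sectors = 40) {
  a <- spec$semi_axes[1]; b <- spec$semi_axes[2]; cc <- spec$semi_axes[3]
  if (any(spec$semi_axes <= 0)) stop("degenerate dome semi-axes")
  dome_z <- function(x, y) {
    r2 <- pmin(1, (x / a)^2 + (y / b)^2)
    -cc * sqrt(pmax(0, 1 - r2))
  }
  # triangulated dome: concentric rings (symmetric sector angles)
  vs <- matrix(c(0, 0, -cc), 1, 3)
  ring_of <- list()
  for (r in seq_len(n_rings)) {
    f <- r / n_rings
    th <- 2 * pi * (seq_len(n_sectors) - 1) / n_sectors
    x <- f * a * sin(th); y <- f * b * cos(th)
    ring_of[[r]] <- nrow(vs) + seq_len(n_sectors)
    vs <- rbind(vs, cbind(x, y, dome_z(x, y)))
  }
  fs <- NULL
  for (j in seq_len(n_sectors)) {     # fan around apex
    jn <- if (j == n_sectors) 1L else j + 1L
    fs <- rbind(fs, c(1L, ring_of[[1]][j], ring_of[[1]][jn]))
  }
  for (r in seq_len(n_rings - 1)) {
    for (j in seq_len(n_sectors)) {
      jn <- if (j == n_sectors) 1L else j + 1L
      v00 <- ring_of[[r]][j]; v01 <- ring_of[[r]][jn]
      v10 <- ring_of[[r + 1]][j]; v11 <- ring_of[[r + 1]][jn]
      fs <- rbind(fs, c(v00, v10, v11), c(v00, v11, v01))
    }
  }
  surface <- list(vertices = vs, faces = fs)

  path_on_dome <- function(xf, yf, tseq) {
    x <- xf * a * sin(tseq); y <- yf * b * cos(tseq)
    cbind(x, y, dome_z(x, y))
  }
  tmax <- 2.6
  tt <- seq(0, tmax, length.out = 80)
  curve_right <- path_on_dome(0.85, 0.9, tt)
  curve_left <- curve_right
  curve_left[, 1] <- -curve_left[, 1]
  ym <- seq(0.7 * b, -0.3 * b, length.out = 60)
  curve_middle <- cbind(0, ym, dome_z(0, ym))
  geometry <- geometry_bundle(surface = surface,
                              curves = list(curve_left = curve_left,
                                            curve_right = curve_right,
                                            curve_middle = curve_middle))

  schema <- palate_schema()
  tpl <- matrix(NA_real_, 41, 3)
  tpl[1, ] <- curve_right[1, ]                        # Incisor (midline, x=0)
  tpl[3, ] <- curve_right[nrow(curve_right), ]        # Ento-right
  tpl[2, ] <- tpl[3, ] * c(-1, 1, 1)                  # Ento-left
  tpl[4, ] <- curve_middle[1, ]                       # Post-foramen
  tpl[5, ] <- curve_middle[nrow(curve_middle), ]      # Middle
  for (j in 1:4) {                                    # 20% arc spacing
    tpl[5 + j, ] <- polyline_point_at(curve_left, j / 5)   # 6-9 left
    tpl[9 + j, ] <- polyline_point_at(curve_right, j / 5)  # 10-13 right
    tpl[37 + j, ] <- polyline_point_at(curve_middle, j / 5) # 38-41 middle
  }
  xf <- c(0.2, 0.45, 0.65); yf <- c(0.55, 0.2, -0.15, -0.5)
  grid <- expand.grid(x = xf, y = yf)
  for (j in seq_len(12)) {
    p0 <- c(grid$x[j] * a, grid$y[j] * b, 0)
    p0[3] <- dome_z(p0[1], p0[2])
    tpl[13 + j, ] <- project_to_mesh(p0, surface)$point     # 14-25 right
    tpl[25 + j, ] <- tpl[13 + j, ] * c(-1, 1, 1)            # 26-37 left
  }
  list(geometry = geometry, template = tpl, schema = schema)
}

# purely antisymmetric part of a displacement field
antisymmetrize <- function(v, schema) {
  (v - reflect_relabel(v, schema)) / 2
}

# DA displacement field: antisymmetric, of given Frobenius norm, localized
# at the given landmarks (x/z push on one member; antisymmetrization spreads
# it to the pair). Net translation and infinitesimal-rotation components are
# projected out so the injected magnitude survives Procrustes
# superimposition (a similarity transform cannot absorb any of it).
build_da_field <- function(magnitude, landmark_ids, schema, template) {
  p <- nrow(schema)
  v <- matrix(0, p, 3)
  if (magnitude == 0) return(v)
  v[landmark_ids, 1] <- 1
  v[landmark_ids, 3] <- 0.4          # mild vertical component
  av <- antisymmetrize(v, schema)
  # antisymmetric similarity generators at the (centred) template:
  # x-translation and infinitesimal rotations about the y and z axes
  tc <- sweep(template, 2, colMeans(template))
  gen <- list(
    cbind(1, 0, 0)[rep(1, p), , drop = FALSE],
    cbind(tc[, 3], 0, -tc[, 1]),     # e_y x t
    cbind(-tc[, 2], tc[, 1], 0)      # e_z x t
  )
  G <- vapply(gen, function(g)
    as.vector(antisymmetrize(g, schema)), numeric(3 * p))
  Q <- qr.Q(qr(G))
  x <- as.vector(av)
  x <- x - Q %*% crossprod(Q, x)
  av <- matrix(x, p, 3)
  nrm <- sqrt(sum(av^2))
  if (nrm < 1e-12)
    stop("DA field vanishes after removing similarity components")
  av * (magnitude / nrm)
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Simulate a bilateral population with known asymmetry
#'
#' @param spec a \code{simulation_spec}.
#' @return list with \code{dataset} (a \code{landmark_dataset}; the ground
#'   truth is also stored in its provenance), \code{ground_truth} (true
#'   per-group DA vectors and magnitudes in mm and expected Procrustes-unit
#'   DA, plus per-individual true asymmetry vectors), \code{geometry},
#'   \code{template}.
#' @export
simulate_population <- function(spec = simulation_spec()) {
  set.seed(spec$seed)
  geo <- make_palate_geometry(spec)
  schema <- geo$schema
  tpl <- geo$template
  design <- attr(spec, "design")

  groups <- names(spec$n_per_group)
  configs <- list()
  truth_ind <- list()
  truth_grp <- list()
  idx <- 0
  for (g in groups) {
    ng <- spec$n_per_group[[g]]
    base <- tpl * spec$growth_scale[[g]]
    da_field <- build_da_field(spec$da_magnitude[[g]], spec$da_landmarks,
                               schema, base)
    da_anti <- antisymmetrize(da_field, schema)
    cs_base <- centroid_size(base)
    truth_grp[[g]] <- list(
      da_vector_mm = da_anti,
      da_mm = sqrt(sum(da_anti^2)),
      expected_da_procrustes = sqrt(sum(da_anti^2)) / cs_base,
      n = ng
    )
    sexes <- if (!is.null(design)) {
      rep(names(design$sex[[g]]), design$sex[[g]])
    } else rep(c("M", "F"), length.out = ng)
    colls <- if (!is.null(design)) {
      rep(names(design$collection[[g]]), design$collection[[g]])
    } else rep(c("siteA", "siteB"), length.out = ng)
    for (i in seq_len(ng)) {
      idx <- idx + 1
      G <- matrix(stats::rnorm(123, sd = spec$sigma_sym), 41, 3)
      symdev <- (G + reflect_relabel(G, schema)) / 2
      Ff <- matrix(stats::rnorm(123, sd = spec$sigma_fa), 41, 3)
      fa_anti <- antisymmetrize(Ff, schema)
      noise <- matrix(stats::rnorm(123, sd = spec$sigma_noise), 41, 3)
      X <- base + symdev + 0.5 * da_anti + 0.5 * fa_anti + noise
      sx <- sexes[i]
      if (!is.null(spec$sex_effect) && identical(sx, "M"))
        X <- X + spec$sex_effect
      truth_ind[[idx]] <- da_anti + fa_anti
      if (isTRUE(spec$jitter)) {
        R <- random_rotation()
        s <- stats::runif(1, 0.97, 1.03)
        tr <- stats::rnorm(3, sd = 5)
        X <- s * X %*% R + matrix(tr, 41, 3, byrow = TRUE)
      }
      configs[[idx]] <- landmark_config(
        X, sprintf("%s_%02d", g, i), age_group = g, sex = sx,
        collection = colls[i])
    }
  }
  ground_truth <- list(spec = unclass(spec), group = truth_grp,
                       individual_asym_mm = truth_ind)
  dataset <- landmark_dataset(configs, schema,
                              provenance = list(source = "simulation",
                                                ground_truth = ground_truth))
  list(dataset = dataset, ground_truth = ground_truth,
       geometry = geo$geometry, template = tpl)
}
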