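test_that("TPS interpolates exactly and assigns zero energy to affine maps", {
  set.seed(13)
  ref <- matrix(rnorm(36), 12, 3)
  A <- matrix(rnorm(12), 4, 3)
  affine_target <- cbind(1, ref) %*% A
  ft <- tps_fit(ref, affine_target)
  expect_lt(ft$bending_energy, 1e-10)
  ft_id <- tps_fit(ref, ref)
  expect_lt(ft_id$bending_energy, 1e-12)
  expect_lt(max(abs(tps_predict(ft_id, ref) - ref)), 1e-8)
  target <- ref + matrix(rnorm(36, sd = 0.05), 12, 3)
  ft2 <- tps_fit(ref, target)
  expect_lt(max(abs(tps_predict(ft2, ref) - target)), 1e-8)
  # energy equals the quadratic form in the bending-energy matrix
  B <- bending_energy_matrix(ref)
  expect_lt(abs(ft2$bending_energy -
                  sum(diag(t(target) %*% B %*% target))), 1e-9)
})

test_that("bending-energy matrix is PSD with the affine null space", {
  set.seed(14)
  ref <- matrix(rnorm(30), 10, 3)
  B <- bending_energy_matrix(ref)
  expect_equal(B, t(B), tolerance = 1e-12)
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
  expect_lt(max(abs(B %*% rep(1, 10))), 1e-10)
  for (j in 1:3) expect_lt(max(abs(B %*% ref[, j])), 1e-9)
  # exactly 4 (near-)zero eigenvalues: 1, x, y, z
  expect_equal(sum(abs(ev) < 1e-10), 4)
})

test_that("degenerate references are rejected with named duplicates", {
  ref <- matrix(rnorm(30), 10, 3)
  ref[7, ] <- ref[2, ]
  expect_error(tps_fit(ref, ref), "duplicated")
  expect_error(bending_energy_matrix(matrix(rnorm(12), 4, 3)), "at least 5")
})

test_that("sliding decreases bending energy monotonically and leaves fixed landmarks", {
  geo <- make_palate_geometry(simulation_spec(n_per_group = c(A = 2)))
  tpl <- geo$template
  sch <- geo$schema
  cur <- tpl
  # push semilandmarks along their geometry
  set.seed(15)
  for (l in which(sch$role == "curve")) {
    cv <- geo$geometry$curves[[sch$curve_id[l]]]
    cur[l, ] <- palatasym:::polyline_point_at(
      cv, stats::runif(1, 0.1, 0.9))
  }
  res <- slide_semilandmarks(cur, tpl, sch, geo$geometry,
                             slide_opts(max_iter = 8))
  tr <- res$bending_energy_trace
  expect_true(all(diff(tr) <= 1e-12))
  expect_equal(res$positions[sch$role == "fixed", ],
               cur[sch$role == "fixed", ])
  # already-minimal input does not move
  res0 <- slide_semilandmarks(tpl, tpl, sch, geo$geometry, slide_opts())
  expect_lt(max(abs(res0$positions - tpl)), 1e-6)
  # slid points stay on their geometry
  for (l in which(sch$role == "surface")) {
    pr <- project_to_mesh(res$positions[l, ], geo$geometry$surface)
    expect_lt(sqrt(sum((pr$point - res$positions[l, ])^2)), 1e-6 * 50)
  }
})

test_that("line-constrained sliding matches direct quadratic minimization", {
  geo <- make_palate_geometry(simulation_spec(n_per_group = c(A = 2)))
  tpl <- geo$template
  sch <- geo$schema
  # replace the median-suture curve with a straight line through its ends
  ends <- geo$geometry$curves$curve_middle[c(1, 60), ]
  line <- cbind(seq(ends[1, 1], ends[2, 1], length.out = 50),
                seq(ends[1, 2], ends[2, 2], length.out = 50),
                seq(ends[1, 3], ends[2, 3], length.out = 50))
  geom <- geometry_bundle(curves = list(curve_middle = line))
  cur <- tpl
  for (j in 1:4)
    cur[37 + j, ] <- palatasym:::polyline_point_at(line, j / 5)
  # perturb along the line
  cur[38, ] <- palatasym:::polyline_point_at(line, 0.1)
  cur[40, ] <- palatasym:::polyline_point_at(line, 0.77)
  res <- slide_semilandmarks(cur, tpl, sch, geom,
                             slide_opts(max_iter = 20, tol = 1e-14))
  # independent oracle: optimize the 4 positions along the line numerically
  B <- bending_energy_matrix(tpl)
  u <- (ends[2, ] - ends[1, ])
  u <- u / sqrt(sum(u^2))
  energy_of <- function(s) {
    Y <- cur
    for (j in 1:4) Y[37 + j, ] <- cur[37 + j, ] + s[j] * u
    sum(Y * (B %*% Y))
  }
  opt <- stats::optim(rep(0, 4), energy_of, method = "BFGS",
                      control = list(reltol = 1e-14, maxit = 500))
  Yopt <- cur
  for (j in 1:4) Yopt[37 + j, ] <- cur[37 + j, ] + opt$par[j] * u
  expect_lt(max(abs(res$positions[38:41, ] - Yopt[38:41, ])), 1e-6)
  expect_equal(res$bending_energy_trace[length(res$bending_energy_trace)],
               opt$value, tolerance = 1e-6)
})

test_that("reflect/relabel is an involution fixing symmetric shapes", {
  sch <- palate_schema()
  x <- asym_test_config(seed = 16)
  expect_equal(reflect_relabel(reflect_relabel(x, sch), sch), x)
  tpl <- make_palate_geometry(simulation_spec(n_per_group = c(A = 2)))$template
  expect_lt(max(abs(reflect_relabel(tpl, sch) - tpl)), 1e-12)
  # displacing landmark 2 by (0,0,eps) moves landmark 3 in the output
  y <- tpl
  y[2, 3] <- y[2, 3] + 0.5
  ry <- reflect_relabel(y, sch)
  expect_equal(ry[3, 3] - tpl[3, 3], 0.5)
  expect_equal(ry[2, ], tpl[2, ])       # landmark 2 untouched in the image
})

test_that("mirroring a configuration toggles the copy flag", {
  sch <- palate_schema()
  cfg <- landmark_config(asym_test_config(seed = 17), "m1")
  m <- mirror_configuration(cfg, sch)
  expect_true(m$is_reflected_copy)
  mm <- mirror_configuration(m, sch)
  expect_false(mm$is_reflected_copy)
  expect_equal(mm$coordinates, cfg$coordinates)
})

test_that("midsagittal alignment brings the midline set to x = 0", {
  sch <- palate_schema()
  tpl <- make_palate_geometry(simulation_spec(n_per_group = c(A = 2)))$template
  moved <- rigid_motion(tpl, angle = 0.8, axis = c(2, 1, 1),
                        translation = c(12, 3, -9))
  al <- midsagittal_align(moved, sch)
  mid <- match(attr(sch, "midplane_ids"), sch$id)
  expect_lt(max(abs(al$coords[mid, 1])), 1e-8)
  left <- sch$side == "left"
  expect_lt(mean(al$coords[left, 1]), 0)
  expect_equal(det(al$rotation), 1, tolerance = 1e-10)
})

test_that("template completion mirrors onto the actual surface", {
  sp <- simulation_spec(n_per_group = c(A = 2))
  geo <- make_palate_geometry(sp)
  sch <- geo$schema
  half <- geo$template
  left_surf <- which(sch$role == "surface" & sch$side == "left")
  half[left_surf, ] <- NA
  done <- complete_template_by_mirroring(half, sch, geo$geometry)
  expect_false(any(is.na(done)))
  expect_equal(as.integer(table(sch$role)[c("fixed", "curve", "surface")]),
               c(5L, 12L, 24L))
  # symmetric dome: completed points at the exact mirror positions
  expect_lt(max(abs(done - reflect_relabel(done, sch))), 1e-8)
  # asymmetric dome: completed points lie ON the surface, not at mirrors
  warp <- geo$geometry$surface
  lx <- warp$vertices[, 1] < 0
  warp$vertices[lx, 3] <- warp$vertices[lx, 3] * 1.15   # deepen left side
  geom2 <- geometry_bundle(surface = warp, curves = geo$geometry$curves)
  done2 <- complete_template_by_mirroring(half, sch, geom2)
  for (l in left_surf) {
    pr <- project_to_mesh(done2[l, ], geom2$surface)
    expect_lt(sqrt(sum((pr$point - done2[l, ])^2)), 1e-6 * 50)
  }
  expect_gt(max(abs(done2 - reflect_relabel(done2, sch))), 0.01)
})
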