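test_that("doubling appends flagged reflected copies", {
  pop <- small_population(n = 3, seed = 81)
  db <- build_symmetry_dataset(pop$dataset)
  expect_equal(dim(db$coords)[3], 6)
  expect_equal(db$info$is_reflected_copy, rep(c(FALSE, TRUE), each = 3))
  expect_error(build_symmetry_dataset(db), "reflected")
  one <- landmark_dataset(list(landmark_config(asym_test_config(1), "solo")))
  expect_equal(dim(build_symmetry_dataset(one)$coords)[3], 2)
})

test_that("perfectly symmetric noise-free data yields zero DA and FA", {
  spec <- simulation_spec(n_per_group = c(A = 4, B = 4), da_magnitude = 0,
                          sigma_fa = 0, sigma_noise = 0, seed = 91)
  pop <- simulate_population(spec)
  fit <- fit_asymmetry(pop$dataset)
  expect_lt(max(fit$decomposition$group$da_scalar), 1e-9)
  expect_lt(max(fit$decomposition$individual$fa_scalar), 1e-9)
})

test_that("a single-individual group has FA exactly zero", {
  spec <- simulation_spec(n_per_group = c(A = 1, B = 3), seed = 92)
  pop <- simulate_population(spec)
  fit <- fit_asymmetry(pop$dataset)
  dec <- fit$decomposition
  solo <- which(dec$individual$group == "A")
  expect_equal(unname(dec$individual$fa_scalar[solo]), 0)
})

test_that("decomposition identities hold exactly", {
  pop <- small_population(n = 6, groups = 2, seed = 93)
  doubled <- build_symmetry_dataset(pop$dataset)
  fit <- symmetry_frame(gpa(doubled))
  dec <- asym_decompose(fit)
  n <- length(dec$individual$individual_id)
  # orthogonality: sym +/- a/2 reproduces O and RR
  for (i in c(1, n)) {
    O <- fit$aligned[, , i]
    RR <- fit$aligned[, , n + i]
    expect_equal(dec$symmetric$individual[, , i] +
                   dec$individual$asym_vector[, , i] / 2, O,
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(dec$symmetric$individual[, , i] -
                   dec$individual$asym_vector[, , i] / 2, RR,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # symmetric component is its own reflection
  sym1 <- dec$symmetric$individual[, , 1]
  expect_lt(max(abs(reflect_relabel(sym1) - sym1)), 1e-10)
  # group mean of FA deviations is exactly zero
  for (g in levels(dec$individual$group)) {
    sel <- which(dec$individual$group == g)
    dev <- dec$individual$asym_vector[, , sel, drop = FALSE]
    for (i in sel) dev[, , match(i, sel)] <-
        dec$individual$asym_vector[, , i] - dec$group$da_vector[, , g]
    expect_lt(max(abs(apply(dev, c(1, 2), mean))), 1e-12)
  }
  # scalar consistency: DA and FA are the norms of their per-landmark rows
  expect_equal(unname(dec$group$da_scalar),
               unname(sqrt(rowSums(dec$group$da_per_landmark^2))),
               tolerance = 1e-12)
  expect_equal(unname(dec$individual$fa_scalar),
               unname(sqrt(rowSums(dec$individual$fa_per_landmark^2))),
               tolerance = 1e-12)
  # DA is symmetric in the sign convention (norm of either difference)
  g1 <- levels(dec$individual$group)[1]
  sel <- which(dec$individual$group == g1)
  mO <- apply(fit$aligned[, , sel, drop = FALSE], c(1, 2), mean)
  mR <- apply(fit$aligned[, , n + sel, drop = FALSE], c(1, 2), mean)
  expect_equal(unname(dec$group$da_scalar[g1]), sqrt(sum((mR - mO)^2)),
               tolerance = 1e-12)
})

test_that("unpaired configurations are refused", {
  pop <- small_population(n = 3, seed = 94)
  db <- build_symmetry_dataset(pop$dataset)
  broken <- palatasym:::dataset_from_array(
    db$coords[, , -4, drop = FALSE], db$info[-4, , drop = FALSE], db$schema)
  fit <- gpa(broken)
  expect_error(asym_decompose(fit), "unpaired")
})

test_that("injected DA is recovered within 2% without FA noise", {
  spec <- simulation_spec(n_per_group = c(A = 12), da_magnitude = 0.5,
                          sigma_fa = 0, sigma_sym = 0.3, sigma_noise = 0,
                          seed = 95)
  pop <- simulate_population(spec)
  fit <- fit_asymmetry(pop$dataset)
  est <- unname(fit$decomposition$group$da_scalar["A"])
  truth <- pop$ground_truth$group$A$expected_da_procrustes
  expect_lt(abs(est - truth) / truth, 0.02)
})

test_that("DA scales linearly with injected asymmetry in the small regime", {
  est <- vapply(c(0.5, 1), function(m) {
    spec <- simulation_spec(n_per_group = c(A = 10), da_magnitude = m,
                            sigma_fa = 0, sigma_sym = 0, sigma_noise = 0,
                            seed = 96)
    pop <- simulate_population(spec)
    fit <- fit_asymmetry(pop$dataset)
    unname(fit$decomposition$group$da_scalar["A"])
  }, 1)
  expect_equal(est[2] / est[1], 2, tolerance = 0.01)
})

test_that("DA/FA scalars are invariant to the consensus frame", {
  pop <- small_population(n = 5, seed = 97)
  db <- build_symmetry_dataset(pop$dataset)
  fit <- gpa(db)
  dec <- asym_decompose(fit)
  # rotate the whole shape space
  set.seed(97)
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  fit2 <- fit
  for (i in seq_len(dim(fit$aligned)[3]))
    fit2$aligned[, , i] <- fit$aligned[, , i] %*% Q
  dec2 <- asym_decompose(fit2)
  expect_equal(dec2$group$da_scalar, dec$group$da_scalar, tolerance = 1e-10)
  expect_equal(dec2$individual$fa_scalar, dec$individual$fa_scalar,
               tolerance = 1e-10)
})

test_that("per-landmark tables have one row per unit and 41 columns", {
  pop <- small_population(n = 4, groups = 3, seed = 98)
  fit <- fit_asymmetry(pop$dataset)
  tabs <- per_landmark_tables(fit$decomposition)
  expect_equal(dim(tabs$da), c(3, 41))
  expect_equal(dim(tabs$fa), c(12, 41))
  # symmetric data: all zero
  spec0 <- simulation_spec(n_per_group = c(A = 3), da_magnitude = 0,
                           sigma_fa = 0, sigma_noise = 0, seed = 99)
  fit0 <- fit_asymmetry(simulate_population(spec0)$dataset)
  tabs0 <- per_landmark_tables(fit0$decomposition)
  expect_lt(max(abs(tabs0$da)), 1e-9)
  expect_lt(max(abs(tabs0$fa)), 1e-9)
})

test_that("model methods expose the decomposition coherently", {
  pop <- small_population(n = 5, groups = 2, seed = 100)
  fit <- fit_asymmetry(pop$dataset)
  expect_equal(coef(fit), fit$decomposition$group$da_scalar)
  expect_equal(dim(coef(fit, "da_per_landmark")), c(2, 41))
  res <- residuals(fit)
  # residual of the first individual reconstructs its asymmetry vector
  g1 <- as.character(fit$decomposition$individual$group[1])
  expect_equal(res[, , 1] + fit$decomposition$group$da_vector[, , g1],
               fit$decomposition$individual$asym_vector[, , 1],
               tolerance = 1e-12)
  s <- summary(fit)
  expect_s3_class(s, "summary.asymfit")
  expect_equal(nrow(s$table), 2)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  plot(fit, "da"); plot(fit, "fa")
  grDevices::dev.off()
  expect_true(file.exists(f))
})

test_that("per-group superimposition mode produces the same structure", {
  pop <- small_population(n = 5, groups = 2, seed = 101)
  fit <- fit_asymmetry(pop$dataset, gpa_mode = "per_group")
  expect_equal(length(fit$fits), 2)
  expect_equal(dim(fit$decomposition$group$da_per_landmark), c(2, 41))
  expect_equal(length(fit$decomposition$individual$fa_scalar), 10)
})
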