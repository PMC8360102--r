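doubled_fit <- function(n, seed, ...) {
  spec <- simulation_spec(n_per_group = stats::setNames(n, "A"),
                          seed = seed, ...)
  pop <- simulate_population(spec)
  gpa(build_symmetry_dataset(pop$dataset))
}

test_that("Procrustes ANOVA has the published df structure", {
  fit5 <- doubled_fit(5, seed = 111)
  tab <- procrustes_anova_symmetry(fit5, n_perm = 99, seed = 1)
  expect_equal(tab$df, c(4L, 1L, 4L))
  expect_equal(tab$effect,
               c("Ind", "Reflections", "Ind x Reflections"))
  expect_equal(tab$MS, tab$SS / tab$df, tolerance = 1e-12)
  expect_equal(sum(tab$Rsq), 1, tolerance = 1e-12)
  expect_error(procrustes_anova_symmetry(doubled_fit(1, seed = 112)),
               ">= 2")
})

test_that("Procrustes ANOVA SS match a brute-force decomposition", {
  fit <- doubled_fit(4, seed = 113)
  tab <- procrustes_anova_symmetry(fit, n_perm = 0)
  # brute force: loop over individuals, sides, landmarks, coordinates
  n <- 4
  X <- array(NA_real_, c(n, 2, 41, 3))
  info <- fit$info
  orig <- which(!info$is_reflected_copy)
  refl <- which(info$is_reflected_copy)
  for (i in seq_len(n)) {
    X[i, 1, , ] <- fit$aligned[, , orig[i]]
    j <- refl[match(info$individual_id[orig[i]],
                    info$individual_id[refl])]
    X[i, 2, , ] <- fit$aligned[, , j]
  }
  grand <- apply(X, c(3, 4), mean)
  ss_ind <- 0; ss_refl <- 0; ss_int <- 0
  for (i in seq_len(n)) for (s in 1:2) {
    mi <- apply(X[i, , , ], c(2, 3), mean)
    ms <- apply(X[, s, , ], c(2, 3), mean)
    ss_int <- ss_int + sum((X[i, s, , ] - mi - ms + grand)^2)
  }
  for (i in seq_len(n))
    ss_ind <- ss_ind + 2 * sum((apply(X[i, , , ], c(2, 3), mean) - grand)^2)
  for (s in 1:2)
    ss_refl <- ss_refl + n * sum((apply(X[, s, , ], c(2, 3), mean) - grand)^2)
  expect_equal(tab$SS, c(ss_ind, ss_refl, ss_int), tolerance = 1e-10)
})

test_that("symmetric data put all variation in the individual effect", {
  fitsym <- doubled_fit(4, seed = 114, da_magnitude = 0, sigma_fa = 0,
                        sigma_noise = 0)
  tab <- procrustes_anova_symmetry(fitsym, n_perm = 0)
  expect_lt(tab$SS[2], 1e-18)
  expect_lt(tab$SS[3], 1e-18)
  expect_gt(tab$SS[1], 0)
})

test_that("permutation p-values are reproducible and floored at 1/(B+1)", {
  fit <- doubled_fit(12, seed = 115, da_magnitude = 2)
  t1 <- procrustes_anova_symmetry(fit, n_perm = 199, seed = 9)
  t2 <- procrustes_anova_symmetry(fit, n_perm = 199, seed = 9)
  expect_identical(t1$p, t2$p)
  expect_gte(min(t1$p, na.rm = TRUE), 1 / 200)
  # strong injected DA: reflection effect at (or within a tie of) the
  # attainable permutation floor
  expect_lte(t1$p[2], 2 / 200)
})

test_that("one-way ANOVA matches lm/anova and the published df", {
  set.seed(116)
  vals <- rnorm(246)
  labs <- factor(rep(paste0("g", 1:6), each = 41))
  tab <- oneway_anova(vals, labs)
  expect_equal(tab$df, c(5, 240))
  ref <- stats::anova(stats::lm(vals ~ labs))
  expect_equal(tab$SS, ref$`Sum Sq`, tolerance = 1e-9)
  expect_equal(tab$F[1], ref$`F value`[1], tolerance = 1e-9)
  expect_equal(tab$p[1], ref$`Pr(>F)`[1], tolerance = 1e-12)
  # all equal values: zero between-group SS and F
  tab0 <- oneway_anova(rep(1, 12), factor(rep(1:3, 4)))
  expect_equal(tab0$SS[1], 0)
  expect_equal(tab0$F[1], 0)
  expect_error(oneway_anova(1:3, factor(c("a", "a", "a"))), "2 groups")
})

test_that("hand-worked three-group ANOVA F is reproduced", {
  # classic textbook layout: 3 balanced groups of 4
  vals <- c(6, 8, 4, 5, 3, 4, 1, 2, 8, 12, 9, 11)
  labs <- factor(rep(c("a", "b", "c"), each = 4))
  # hand computation: means 5.75, 2.5, 10; grand 6.083333...
  ss_b <- 4 * ((5.75 - 73 / 12)^2 + (2.5 - 73 / 12)^2 + (10 - 73 / 12)^2)
  ss_w <- sum((vals - rep(c(5.75, 2.5, 10), each = 4))^2)
  f_hand <- (ss_b / 2) / (ss_w / 9)
  tab <- oneway_anova(vals, labs)
  expect_equal(tab$F[1], f_hand, tolerance = 1e-9)
})

test_that("Tukey HSD produces all pairs with valid intervals", {
  set.seed(117)
  vals <- rnorm(246)
  labs <- factor(rep(paste0("g", 1:6), each = 41))
  tk <- tukey_hsd(vals, labs)
  expect_equal(nrow(tk), 15)
  expect_true(all(tk$lwr <= tk$diff & tk$diff <= tk$upr))
  expect_true(all(tk$p_adj >= 0 & tk$p_adj <= 1))
  # identical groups: tiny diff, p ~ 1
  v2 <- rep(c(1, 2, 3), 2)
  tk2 <- tukey_hsd(c(v2, v2), factor(rep(c("x", "y"), each = 6)))
  expect_equal(tk2$diff, 0)
  expect_gt(tk2$p_adj, 0.99)
  # balanced case agrees with the studentized-range construction
  set.seed(118)
  v3 <- rnorm(30); l3 <- factor(rep(1:3, each = 10))
  tk3 <- tukey_hsd(v3, l3)
  ms_w <- stats::anova(stats::lm(v3 ~ l3))$`Mean Sq`[2]
  hw <- stats::qtukey(0.95, 3, 27) * sqrt(ms_w / 10)
  gm <- tapply(v3, l3, mean)
  expect_equal(tk3$diff[1], unname(gm[2] - gm[1]), tolerance = 1e-10)
  expect_equal(tk3$upr[1] - tk3$diff[1], hw, tolerance = 1e-9)
  p_hand <- stats::ptukey(abs(gm[2] - gm[1]) / sqrt(ms_w / 10), 3, 27,
                          lower.tail = FALSE)
  expect_equal(tk3$p_adj[1], unname(p_hand), tolerance = 1e-9)
  # the stacked-correction audit flag only inflates p
  tk3b <- tukey_hsd(v3, l3, stack_bonferroni = TRUE)
  expect_true(all(tk3b$p_adj >= tk3$p_adj - 1e-12))
})

test_that("PERMANOVA pseudo-F equals classical F on univariate data", {
  set.seed(119)
  vals <- rnorm(30)
  labs <- factor(rep(1:3, each = 10))
  D <- as.matrix(stats::dist(vals))
  pm <- permanova(D, labs, n_perm = 99, seed = 3)
  f_classic <- stats::anova(stats::lm(vals ~ labs))$`F value`[1]
  expect_equal(pm$F, f_classic, tolerance = 1e-10)
  expect_error(permanova(D, labs[1:10]), "length")
})

test_that("PERMANOVA separates distinct clusters at the permutation floor", {
  set.seed(120)
  a <- matrix(rnorm(60), 20, 3)
  b <- matrix(rnorm(60), 20, 3) + 50
  D <- as.matrix(stats::dist(rbind(a, b)))
  pm <- permanova(D, factor(rep(1:2, each = 20)), n_perm = 199, seed = 4)
  expect_equal(pm$p, 1 / 200)
})

test_that("dispersion homogeneity behaves on matched and scaled groups", {
  set.seed(121)
  a <- matrix(rnorm(90), 30, 3)
  b <- matrix(rnorm(90), 30, 3)
  D <- as.matrix(stats::dist(rbind(a, b)))
  dh <- dispersion_homogeneity(D, factor(rep(1:2, each = 30)),
                               n_perm = 199, seed = 5)
  expect_gt(dh$p, 0.05)
  b3 <- b * 3
  D3 <- as.matrix(stats::dist(rbind(a, b3)))
  dh3 <- dispersion_homogeneity(D3, factor(rep(1:2, each = 30)),
                                n_perm = 199, seed = 6)
  expect_lt(dh3$p, 0.05)
  # Euclidean input: embedding distances to centroid match direct ones
  grp <- factor(rep(1:2, each = 30))
  bd <- dh$model
  direct <- numeric(60)
  pts <- rbind(a, b)
  for (g in 1:2) {
    sel <- grp == g
    ctr <- colMeans(pts[sel, ])
    direct[sel] <- sqrt(rowSums(sweep(pts[sel, ], 2, ctr)^2))
  }
  expect_equal(unname(bd$distances), direct, tolerance = 1e-8)
})

test_that("Kruskal-Wallis H matches the hand formula and ties are handled", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  labs <- factor(rep(c("a", "b", "c"), each = 3))
  kw <- kruskal_wallis(vals, labs)
  r <- rank(vals)
  rs <- tapply(r, labs, sum)
  h_hand <- 12 / (9 * 10) * sum(rs^2 / 3) - 3 * 10
  expect_equal(kw$H, h_hand, tolerance = 1e-9)
  expect_equal(kw$df, 2)
  expect_warning(kw0 <- kruskal_wallis(rep(1, 6), factor(rep(1:2, 3))),
                 "tied")
  expect_equal(kw0$H, 0)
  # two groups: H equals the squared tie-corrected Dunn Z
  set.seed(122)
  v <- rnorm(14)
  l2 <- factor(rep(1:2, 7))
  kw2 <- kruskal_wallis(v, l2)
  z <- dunn_posthoc(v, l2)$Z
  expect_equal(kw2$H, z^2, tolerance = 1e-9)
})

test_that("Dunn post-hoc matches a hand-worked untied example", {
  vals <- 1:9
  labs <- factor(rep(c("a", "b", "c"), each = 3))
  dn <- dunn_posthoc(vals, labs)
  expect_equal(nrow(dn), 3)
  # mean ranks 2, 5, 8; SE = sqrt((9*10/12)*(2/3)) = sqrt(5)
  expect_equal(dn$Z[dn$comparison == "a-b"], -3 / sqrt(5), tolerance = 1e-9)
  expect_equal(dn$Z[dn$comparison == "a-c"], -6 / sqrt(5), tolerance = 1e-9)
  expect_equal(dn$p_adj, pmin(1, dn$p_unadj * 3), tolerance = 1e-12)
  # 41 landmark labels -> 820 pairs
  set.seed(123)
  v41 <- rnorm(41 * 6)
  l41 <- factor(rep(1:41, each = 6))
  expect_equal(nrow(dunn_posthoc(v41, l41)), 820)
  # identical groups: small |Z|, adjusted p ~ 1
  dn0 <- dunn_posthoc(rep(c(1.0, 2.0, 3.0, 4.0), 3),
                      factor(rep(c("x", "y", "z"), each = 4)))
  expect_true(all(dn0$p_adj > 0.9))
})

test_that("Spearman matrix equals Pearson on midranks", {
  set.seed(124)
  da <- matrix(rnorm(4 * 41), 4, 41,
               dimnames = list(paste0("g", 1:4), NULL))
  sp <- spearman_matrix(da)
  expect_equal(diag(sp), rep(1, 4), ignore_attr = TRUE)
  ranks <- t(apply(da, 1, rank))
  expect_equal(sp, stats::cor(t(ranks)), tolerance = 1e-12,
               ignore_attr = TRUE)
  rev2 <- rbind(a = 1:10, b = 10:1)
  expect_equal(spearman_matrix(rev2)[1, 2], -1)
  expect_warning(spearman_matrix(rbind(a = rep(1, 5), b = 1:5)), "constant")
})

test_that("Mann-Whitney switches correctly between exact and approximate", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_true(mw$exact)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)   # 2 extreme of 20 arrangements
  tied <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_false(tied$exact)
  expect_true(tied$ties)
  expect_equal(tied$p, 1, tolerance = 1e-9)
  # large-sample: matches the tie-corrected normal approximation
  set.seed(125)
  x <- round(rnorm(30), 1); y <- round(rnorm(35, 0.3), 1)
  mw2 <- mann_whitney(x, y)
  expect_false(mw2$exact)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(mw2$p, ref$p.value, tolerance = 1e-12)
})

test_that("Bonferroni correction caps at one and validates input", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 3), 1)
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_error(bonferroni(1.2), "must lie")
})
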