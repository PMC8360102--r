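# Simulation-based validation experiments: DA recovery across injected
# magnitudes, and type-I error calibration of the permutation tests under
# null data. Used by the test suite and the acceptance script.

#' Directional-asymmetry recovery experiment
#'
#' Simulates replicate populations with known injected DA magnitudes on the
#' default 50 mm dome, runs the full fit on each, and summarizes how well the
#' estimated group DA scales with the injected magnitude. The estimator is
#' the unbiased-norm DA (see \code{asym_decompose}), pooled across replicates
#' on the squared scale. At the largest magnitude the reflection effect of
#' the Procrustes ANOVA is also tested per replicate.
#'
#' @param magnitudes injected DA magnitudes in mm.
#' @param n individuals per simulated group.
#' @param n_rep replicates per magnitude.
#' @param sigma_fa fluctuating-asymmetry noise SD (mm).
#' @param n_perm permutations for the significance check.
#' @param alpha significance threshold for the power count.
#' @param seed integer seed.
#' @return list with \code{da} (n_rep x length(magnitudes) matrix of
#'   unbiased DA estimates, Procrustes units), \code{expected} (per-magnitude
#'   truth), \code{ratios} (successive ratios of pooled estimates),
#'   \code{ratio_error_pct} (worst relative deviation from the injected
#'   ratios, percent), \code{power} (fraction of replicates with reflection
#'   p <= alpha at the largest magnitude), \code{p_values}.
#' @export
da_recovery_experiment <- function(magnitudes = c(0.25, 0.5, 1.0), n = 30,
                                   n_rep = 20, sigma_fa = 0.1,
                                   n_perm = 499, alpha = 0.01, seed = 1L) {
  nm <- length(magnitudes)
  da <- matrix(NA_real_, n_rep, nm)
  expected <- numeric(nm)
  pvals <- numeric(n_rep)
  for (j in seq_len(nm)) {
    for (r in seq_len(n_rep)) {
      spec <- simulation_spec(
        n_per_group = c(A = n), da_magnitude = magnitudes[j],
        sigma_fa = sigma_fa, sigma_noise = 0,
        seed = (seed + 7919L * r + 104729L * j) %% .Machine$integer.max)
      pop <- simulate_population(spec)
      fit <- fit_asymmetry(pop$dataset)
      da[r, j] <- unname(fit$decomposition$group$da_unbiased["A"])
      expected[j] <- pop$ground_truth$group$A$expected_da_procrustes
      if (j == nm) {
        tab <- procrustes_anova_symmetry(fit$gpa, n_perm = n_perm,
                                         seed = seed + 13L * r)
        pvals[r] <- tab$p[tab$effect == "Reflections"]
      }
    }
  }
  pooled <- sqrt(colMeans(da^2))
  ratios <- pooled[-1] / pooled[-nm]
  target <- magnitudes[-1] / magnitudes[-nm]
  list(da = da, expected = expected, pooled = pooled, ratios = ratios,
       ratio_error_pct = 100 * max(abs(ratios / target - 1)),
       power = mean(pvals <= alpha), p_values = pvals)
}

#' Type-I error calibration of the permutation tests
#'
#' Repeatedly simulates null data (no directional asymmetry, exchangeable
#' group labels) and records the rejection rate at the given level for the
#' reflection effect of the Procrustes ANOVA, PERMANOVA, dispersion
#' homogeneity and Kruskal-Wallis.
#'
#' @param n_sims simulations per test.
#' @param alpha nominal level.
#' @param n_perm permutations per simulation.
#' @param n individuals per simulated group (Procrustes ANOVA null).
#' @param seed integer seed.
#' @return named list of rejection rates.
#' @export
type1_calibration <- function(n_sims = 200, alpha = 0.05, n_perm = 199,
                              n = 10, seed = 1L) {
  rej <- c(reflection = 0, permanova = 0, dispersion = 0,
           kruskal_wallis = 0)
  for (s in seq_len(n_sims)) {
    base_seed <- (seed + 6151L * s) %% .Machine$integer.max
    # reflection effect under zero DA
    spec <- simulation_spec(n_per_group = c(A = n), da_magnitude = 0,
                            sigma_fa = 0.1, sigma_noise = 0,
                            seed = base_seed)
    pop <- simulate_population(spec)
    fit <- gpa(build_symmetry_dataset(pop$dataset))
    tab <- procrustes_anova_symmetry(fit, n_perm = n_perm,
                                     seed = base_seed + 1L)
    if (tab$p[tab$effect == "Reflections"] <= alpha)
      rej["reflection"] <- rej["reflection"] + 1
    # multivariate nulls: one gaussian cloud, arbitrary labels
    set.seed(base_seed + 2L)
    pts <- matrix(stats::rnorm(30 * 3), 30, 3)
    labs <- factor(rep(1:2, each = 15))
    D <- as.matrix(stats::dist(pts))
    pm <- permanova(D, labs, n_perm = n_perm, seed = base_seed + 3L)
    if (pm$p <= alpha) rej["permanova"] <- rej["permanova"] + 1
    dh <- dispersion_homogeneity(D, labs, n_perm = n_perm,
                                 seed = base_seed + 4L)
    if (dh$p <= alpha) rej["dispersion"] <- rej["dispersion"] + 1
    set.seed(base_seed + 5L)
    kw <- kruskal_wallis(stats::rnorm(30), factor(rep(1:3, each = 10)))
    if (kw$p <= alpha) rej["kruskal_wallis"] <- rej["kruskal_wallis"] + 1
  }
  as.list(rej / n_sims)
}
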