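# The statistical battery: Procrustes ANOVA with residual-randomization
# permutation for the symmetry decomposition, and the between-group tests
# (one-way ANOVA + Tukey HSD, PERMANOVA, dispersion homogeneity,
# Kruskal-Wallis + Dunn, Spearman, Mann-Whitney, Bonferroni). Standard tests
# delegate to stats/vegan; the Procrustes ANOVA and Dunn post-hoc are
# implemented here.

#' Procrustes ANOVA of object symmetry within one group
#'
#' Decomposes shape variation of originals + reflected/relabelled copies
#' into individual variation, reflection (directional asymmetry) and the
#' individual-by-reflection interaction (fluctuating asymmetry), with sums
#' of squares accumulated over all landmark coordinates. F ratios use the
#' interaction as error term; p-values come from residual randomization
#' under the respective reduced model (RRPP).
#'
#' Permutation schemes respect the object-symmetry structure: the reflection
#' effect is tested by randomly swapping the two sides within each individual
#' (sign flips of the asymmetry vectors — the exchangeable units under the
#' no-DA null), the individual effect by residual randomization under the
#' side-means-only reduced model.
#'
#' @param fit a \code{procrustes_fit} on doubled data (one group, or use
#'   \code{subset}).
#' @param n_perm number of permutations (999 default; the minimum attainable
#'   p is 1/(n_perm+1)).
#' @param seed integer seed for the permutations.
#' @param subset optional logical/integer selector of configurations (e.g.
#'   one age group out of a pooled fit).
#' @return data frame of class \code{anova_table} with rows Individual,
#'   Reflection, Individual x Reflection and columns effect, df, SS, MS,
#'   Rsq, F, p.
#' @export
procrustes_anova_symmetry <- function(fit, n_perm = 999, seed = NULL,
                                      subset = NULL) {
  info <- fit$info
  aligned <- fit$aligned
  if (!is.null(subset)) {
    info <- info[subset, , drop = FALSE]
    aligned <- aligned[, , subset, drop = FALSE]
  }
  orig <- which(!info$is_reflected_copy)
  refl <- which(info$is_reflected_copy)
  n <- length(orig)
  if (n < 2) stop("Procrustes ANOVA of symmetry needs >= 2 individuals")
  partner <- refl[match(info$individual_id[orig], info$individual_id[refl])]
  if (anyNA(partner)) stop("unpaired configuration(s)")

  # observations: rows = 2n flattened configurations
  flat <- function(i) as.vector(aligned[, , i])
  X <- t(vapply(c(orig, partner), flat, numeric(prod(dim(aligned)[1:2]))))
  ind <- factor(rep(seq_len(n), 2))
  side <- factor(rep(c("O", "RR"), each = n))

  ss_decomp <- function(X) {
    grand <- colMeans(X)
    Mi <- rowsum(X, ind) / 2                 # n x q individual means
    Ms <- rowsum(X, side) / n                # 2 x q side means
    ss_ind <- 2 * sum(sweep(Mi, 2, grand)^2)
    ss_refl <- n * sum(sweep(Ms, 2, grand)^2)
    resid <- X - Mi[ind, , drop = FALSE] - Ms[side, , drop = FALSE] +
      matrix(grand, nrow(X), ncol(X), byrow = TRUE)
    ss_int <- sum(resid^2)
    c(ind = ss_ind, refl = ss_refl, int = ss_int)
  }

  obs <- ss_decomp(X)
  df <- c(ind = n - 1, refl = 1, int = n - 1)
  ms <- obs / df
  f_ind <- ms[["ind"]] / ms[["int"]]
  f_refl <- ms[["refl"]] / ms[["int"]]

  if (!is.null(seed)) set.seed(seed)
  count_ind <- 0L; count_refl <- 0L
  if (n_perm > 0) {
    # Reflection: swap sides within individuals. With the asymmetry vectors
    # a_i (rows of A), SS_refl = n/2 ||mean(s_i a_i)||^2 and
    # SS_int = sum_i ||s_i a_i - mean(s a)||^2 / 2 for signs s_i = +/-1.
    A <- X[seq_len(n), , drop = FALSE] - X[n + seq_len(n), , drop = FALSE]
    for (b in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      As <- A * s
      abar <- colMeans(As)
      ss_r <- n / 2 * sum(abar^2)
      ss_i <- sum(sweep(As, 2, abar)^2) / 2
      fb <- (ss_r / df[["refl"]]) / (ss_i / df[["int"]])
      if (fb >= f_refl - 1e-12) count_refl <- count_refl + 1L
    }
    # Individual: residual randomization under the side-means-only model
    Ms <- rowsum(X, side) / n
    fit_ind_red <- Ms[side, , drop = FALSE]
    res_ind <- X - fit_ind_red
    for (b in seq_len(n_perm)) {
      pi2 <- sample.int(2 * n)
      Xi <- fit_ind_red + res_ind[pi2, , drop = FALSE]
      s2 <- ss_decomp(Xi)
      if ((s2[["ind"]] / df[["ind"]]) / (s2[["int"]] / df[["int"]]) >=
          f_ind - 1e-12) count_ind <- count_ind + 1L
    }
  }
  p_ind <- if (n_perm > 0) (count_ind + 1) / (n_perm + 1) else NA_real_
  p_refl <- if (n_perm > 0) (count_refl + 1) / (n_perm + 1) else NA_real_

  tot <- sum(obs)
  out <- data.frame(
    effect = c("Ind", "Reflections", "Ind x Reflections"),
    df = as.integer(df),
    SS = as.numeric(obs),
    MS = as.numeric(ms),
    Rsq = as.numeric(obs) / tot,
    F = c(f_ind, f_refl, NA_real_),
    p = c(p_ind, p_refl, NA_real_),
    stringsAsFactors = FALSE
  )
  class(out) <- c("anova_table", "data.frame")
  out
}

#' One-way ANOVA on scalar values
#'
#' Classical one-way decomposition with parametric F p-value, returned in
#' the df/SS/MS/Rsq/F/p layout used for the between-group DA and FA tables.
#'
#' @param values numeric vector.
#' @param labels grouping factor.
#' @param n_perm if > 0, an additional permutation p-value (label shuffling)
#'   is reported in column \code{p_perm}.
#' @param seed seed for the permutation option.
#' @return data frame of class \code{anova_table}.
#' @export
oneway_anova <- function(values, labels, n_perm = 0, seed = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (any(table(labels) == 0)) stop("empty group level")
  if (length(values) - nlevels(labels) < 1) stop("no residual df")
  grand <- mean(values)
  gm <- tapply(values, labels, mean)
  gn <- tapply(values, labels, length)
  ss_b <- sum(gn * (gm - grand)^2)
  ss_w <- sum((values - gm[labels])^2)
  df_b <- nlevels(labels) - 1
  df_w <- length(values) - nlevels(labels)
  ms_b <- ss_b / df_b; ms_w <- ss_w / df_w
  if (ms_w == 0) {
    f <- if (ms_b == 0) 0 else Inf
  } else f <- ms_b / ms_w
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  out <- data.frame(
    effect = c("group", "Residuals"),
    df = c(df_b, df_w),
    SS = c(ss_b, ss_w),
    MS = c(ms_b, ms_w),
    Rsq = c(ss_b, ss_w) / (ss_b + ss_w),
    F = c(f, NA_real_),
    p = c(p, NA_real_),
    stringsAsFactors = FALSE
  )
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      vb <- values[sample.int(length(values))]
      gmb <- tapply(vb, labels, mean)
      fb <- (sum(gn * (gmb - grand)^2) / df_b) /
        (sum((vb - gmb[labels])^2) / df_w)
      if (fb >= f - 1e-12) cnt <- cnt + 1L
    }
    out$p_perm <- c((cnt + 1) / (n_perm + 1), NA_real_)
  }
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Tukey HSD post-hoc test
#'
#' Tukey-Kramer all-pairs comparisons via \code{stats::TukeyHSD}.
#'
#' @param values numeric vector.
#' @param labels grouping factor.
#' @param conf.level confidence level of the intervals.
#' @param stack_bonferroni compatibility flag: additionally multiply the
#'   Tukey-adjusted p-values by the number of pairs (statistically
#'   redundant; off by default).
#' @return data frame with columns pair, diff, lwr, upr, p_adj.
#' @export
tukey_hsd <- function(values, labels, conf.level = 0.95,
                      stack_bonferroni = FALSE) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  fit <- stats::aov(values ~ labels)
  tk <- stats::TukeyHSD(fit, conf.level = conf.level)$labels
  out <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL,
                    stringsAsFactors = FALSE)
  if (stack_bonferroni)
    out$p_adj <- pmin(1, out$p_adj * nrow(out))
  out
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (pseudo-F from the
#' Gower-centered distance decomposition), delegated to
#' \code{vegan::adonis2}.
#'
#' @param dist square symmetric distance matrix (or \code{dist}).
#' @param labels grouping factor.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return list(F, Rsq, p, table).
#' @export
permanova <- function(dist, labels, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(dist)
  labels <- factor(labels)
  if (length(labels) != attr(d, "Size"))
    stop("labels length does not match distance matrix")
  if (!is.null(seed)) set.seed(seed)
  df <- data.frame(g = labels)
  tab <- vegan::adonis2(d ~ g, data = df, permutations = n_perm)
  list(F = tab$F[1], Rsq = tab$R2[1], p = tab$`Pr(>F)`[1], table = tab)
}

#' Homogeneity of multivariate dispersion
#'
#' Principal-coordinate embedding of the distance matrix, per-point distance
#' to the group centroid, and a permutation test of equal dispersion
#' (\code{vegan::betadisper} + \code{vegan::permutest}).
#'
#' @param dist square symmetric distance matrix (or \code{dist}).
#' @param labels grouping factor.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param type \code{"centroid"} (default) or \code{"median"}.
#' @return list(F, p, model).
#' @export
dispersion_homogeneity <- function(dist, labels, n_perm = 999, seed = NULL,
                                   type = c("centroid", "median")) {
  type <- match.arg(type)
  d <- stats::as.dist(dist)
  labels <- factor(labels)
  if (length(labels) != attr(d, "Size"))
    stop("labels length does not match distance matrix")
  bd <- vegan::betadisper(d, labels, type = type)
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm)
  list(F = pt$tab$F[1], p = pt$tab$`Pr(>F)`[1], model = bd)
}

#' Kruskal-Wallis rank sum test
#'
#' Midrank-based H with tie correction and chi-square p (df = k - 1),
#' via \code{stats::kruskal.test}.
#'
#' @param values numeric vector.
#' @param labels grouping factor.
#' @return list(H, df, p).
#' @export
kruskal_wallis <- function(values, labels) {
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need >= 2 groups")
  if (length(unique(values)) == 1) {
    warning("all values tied; H = 0")
    return(list(H = 0, df = nlevels(labels) - 1, p = 1))
  }
  kt <- stats::kruskal.test(values, labels)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Dunn's post-hoc test
#'
#' All-pairs z tests on mean midranks with tie-corrected variance, following
#' a Kruskal-Wallis test; p-values Bonferroni-adjusted over the number of
#' pairs.
#'
#' @param values numeric vector.
#' @param labels grouping factor.
#' @param adjust adjustment method (\code{"bonferroni"} or \code{"none"}).
#' @return data frame with columns comparison, Z, p_unadj, p_adj.
#' @export
dunn_posthoc <- function(values, labels, adjust = c("bonferroni", "none")) {
  adjust <- match.arg(adjust)
  labels <- factor(labels)
  k <- nlevels(labels)
  if (k < 2) stop("need >= 2 groups")
  N <- length(values)
  r <- rank(values)                 # midranks
  rb <- tapply(r, labels, mean)
  nn <- tapply(r, labels, length)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  pairs <- utils::combn(levels(labels), 2)
  m <- ncol(pairs)
  Z <- numeric(m); lab <- character(m)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / nn[[a]] + 1 / nn[[b]]))
    Z[j] <- (rb[[a]] - rb[[b]]) / se
    lab[j] <- paste0(a, "-", b)
  }
  p_un <- 2 * stats::pnorm(-abs(Z))
  p_adj <- if (adjust == "bonferroni") pmin(1, p_un * m) else p_un
  data.frame(comparison = lab, Z = Z, p_unadj = p_un, p_adj = p_adj,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation matrix of per-landmark DA profiles
#'
#' Rank correlation (midranks for ties) of the per-landmark DA vectors
#' between each pair of groups.
#'
#' @param da_table k x p matrix (rows = groups, columns = landmarks).
#' @return k x k correlation matrix.
#' @export
spearman_matrix <- function(da_table) {
  if (any(apply(da_table, 1, function(r) length(unique(r)) == 1)))
    warning("constant DA profile: correlation undefined for that group")
  suppressWarnings(stats::cor(t(da_table), method = "spearman"))
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact two-sided p by enumeration when both samples are small and untied;
#' otherwise the normal approximation with tie-corrected variance and
#' continuity correction (\code{stats::wilcox.test}).
#'
#' @param x,y numeric samples.
#' @param exact_threshold use the exact distribution when both sample sizes
#'   are <= this and there are no ties.
#' @return list(U, p, exact, ties).
#' @export
mann_whitney <- function(x, y, exact_threshold = 8) {
  if (length(x) == 0 || length(y) == 0) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- !ties && length(x) <= exact_threshold &&
    length(y) <= exact_threshold
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact, ties = ties)
}

#' Bonferroni correction
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param m family size (defaults to \code{length(p_values)}).
#' @return adjusted p-values, \code{min(1, p * m)}.
#' @export
bonferroni <- function(p_values, m = NULL) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (is.null(m)) m <- length(p_values)
  pmin(1, p_values * m)
}
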