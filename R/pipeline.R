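# Config-driven end-to-end analysis: load or simulate a population, double it
# with reflected/relabelled copies, superimpose, run the dispersion/PERMANOVA
# pooling gate, decompose asymmetry, and emit the full table battery plus a
# machine-readable run log.

#' Build a pipeline configuration
#'
#' Exactly one of \code{input} (path + format to a landmark file) or
#' \code{simulation} (a \code{simulation_spec}) must be given.
#'
#' @param simulation a \code{simulation_spec}, or \code{NULL}.
#' @param input list(path, format), or \code{NULL}.
#' @param out_dir output directory for tables and the run log.
#' @param gpa_mode \code{"pooled"} or \code{"per_group"}.
#' @param n_perm permutation count for all permutation tests.
#' @param seed master seed; every stochastic stage derives its own seed from
#'   it.
#' @param slide \code{NULL} or \code{slide_opts()}.
#' @param groups metadata column used as grouping factor.
#' @param alpha significance level used by the pooling gate.
#' @return list of class \code{asym_config}.
#' @export
asym_config <- function(simulation = NULL, input = NULL,
                        out_dir = tempfile("asym_run_"),
                        gpa_mode = "pooled", n_perm = 999, seed = 1L,
                        slide = NULL, groups = "age_group", alpha = 0.05) {
  if (is.null(simulation) == is.null(input))
    stop("exactly one of 'simulation' or 'input' must be given")
  stopifnot(n_perm >= 0, seed == as.integer(seed))
  structure(list(simulation = simulation, input = input, out_dir = out_dir,
                 gpa_mode = gpa_mode, n_perm = n_perm,
                 seed = as.integer(seed), slide = slide, groups = groups,
                 alpha = alpha),
            class = "asym_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of \code{asym_config()}; the
#'   \code{simulation} block holds \code{simulation_spec()} arguments.
#' @return an \code{asym_config}.
#' @export
read_asym_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    args <- y$simulation
    if (!is.null(args$n_per_group)) args$n_per_group <-
        unlist(args$n_per_group)
    preset <- isTRUE(args$preset == "study") || isTRUE(args$preset)
    args$preset <- NULL
    sim <- if (preset) do.call(study_preset,
                               args[setdiff(names(args), "n_per_group")])
           else do.call(simulation_spec, args)
  }
  asym_config(simulation = sim, input = y$input,
              out_dir = y$out_dir %||% tempfile("asym_run_"),
              gpa_mode = y$gpa_mode %||% "pooled",
              n_perm = y$n_perm %||% 999, seed = y$seed %||% 1L,
              groups = y$groups %||% "age_group",
              alpha = y$alpha %||% 0.05)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full asymmetry pipeline
#'
#' Executes, in order: load/simulate; double with reflected copies; GPA
#' (optionally with sliding); Procrustes distance matrix; dispersion
#' homogeneity and PERMANOVA on collection within each group (the pooling
#' gate); symmetry decomposition; per-group Procrustes ANOVA; per-landmark
#' DA/FA tables; between-group ANOVAs with Tukey HSD; Spearman matrix of DA
#' profiles; Kruskal-Wallis + Dunn across landmarks; per-landmark FA
#' Kruskal-Wallis with Bonferroni correction; Mann-Whitney sex comparisons
#' for adult groups. All tables are written as TSV into the run directory
#' together with a JSON run log.
#'
#' @param config an \code{asym_config} or path to a YAML config file.
#' @return the run directory path, invisibly; the fitted \code{asymfit} is
#'   attached as attribute \code{fit}.
#' @export
run_asym_pipeline <- function(config) {
  if (is.character(config)) config <- read_asym_config(config)
  stopifnot(inherits(config, "asym_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- list(config = serialize_config(config),
              package_version = as.character(
                utils::packageVersion("palatasym")),
              r_version = paste(R.version$major, R.version$minor, sep = "."),
              stages = character(0), warnings = character(0),
              notices = character(0))
  note <- function(msg) log$notices <<- c(log$notices, msg)
  stage <- function(name) log$stages <<- c(log$stages, name)

  run_stage <- function(name, expr) {
    stage(name)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  # 1. load or simulate ------------------------------------------------
  dataset <- run_stage("load", {
    if (!is.null(config$simulation)) {
      sim <- simulate_population(config$simulation)
      sim$dataset
    } else {
      read_landmarks(config$input$path, config$input$format)
    }
  })
  groups <- factor(dataset$info[[config$groups]])
  lev <- levels(groups)

  # 2-3. double + GPA ---------------------------------------------------
  fit <- run_stage("fit", fit_asymmetry(dataset, groups = config$groups,
                                        slide = config$slide,
                                        gpa_mode = config$gpa_mode))
  dec <- fit$decomposition

  # 4. distance matrix --------------------------------------------------
  D <- run_stage("distances", distance_matrix(fit$gpa))

  # 5-6. pooling gate: collection differences within each group ---------
  pool <- run_stage("pooling_gate", {
    orig <- which(!fit$gpa$info$is_reflected_copy)
    res <- list()
    for (g in lev) {
      sel <- orig[groups == g]
      coll <- factor(dataset$info$collection[groups == g])
      if (nlevels(coll) < 2 || min(table(coll)) < 3) {
        res[[g]] <- list(permanova_p = NA_real_, dispersion_p = NA_real_,
                         note = "collection comparison not estimable")
        next
      }
      Dg <- D[sel, sel]
      pm <- permanova(Dg, coll, n_perm = config$n_perm,
                      seed = config$seed + 101 + match(g, lev))
      dh <- dispersion_homogeneity(Dg, coll, n_perm = config$n_perm,
                                   seed = config$seed + 201 + match(g, lev))
      res[[g]] <- list(permanova_p = pm$p, dispersion_p = dh$p)
    }
    res
  })
  pool_p <- vapply(pool, function(x) x$permanova_p %||% NA_real_, 1)
  pooled_ok <- all(is.na(pool_p) | pool_p > config$alpha)
  note(if (pooled_ok)
    "Because of the absence of significant collection differences, the sample was put together (pooling rule fired)."
    else
    "Significant collection differences detected; pooling rule did NOT fire.")
  write_table(data.frame(group = names(pool),
                         permanova_p = vapply(pool, function(x)
                           x$permanova_p %||% NA_real_, 1),
                         dispersion_p = vapply(pool, function(x)
                           x$dispersion_p %||% NA_real_, 1)),
              file.path(out, "pooling_gate.tsv"))

  # 8. per-group Procrustes ANOVA (within-group table) -------------------
  t3 <- run_stage("procrustes_anova", {
    rows <- list()
    for (g in lev) {
      sel <- which(c(groups, groups) == g)
      tab <- procrustes_anova_symmetry(fit$gpa, n_perm = config$n_perm,
                                       seed = config$seed + 301 +
                                         match(g, lev),
                                       subset = sel)
      tab <- cbind(group = g, tab)
      rows[[g]] <- tab
    }
    do.call(rbind, rows)
  })
  write_table(t3, file.path(out, "table3_procrustes_anova_within.tsv"))

  # 9. per-landmark DA/FA tables -----------------------------------------
  tabs <- per_landmark_tables(dec)
  da_long <- data.frame(
    unit_id = rep(rownames(tabs$da), ncol(tabs$da)),
    landmark_id = rep(seq_len(ncol(tabs$da)), each = nrow(tabs$da)),
    value = as.vector(tabs$da))
  da_long <- da_long[order(da_long$unit_id, da_long$landmark_id), ]
  write_table(da_long, file.path(out, "da_per_landmark.tsv"))
  fa_long <- data.frame(
    unit_id = rep(rownames(tabs$fa), ncol(tabs$fa)),
    group = rep(as.character(dec$individual$group), ncol(tabs$fa)),
    landmark_id = rep(seq_len(ncol(tabs$fa)), each = nrow(tabs$fa)),
    value = as.vector(tabs$fa))
  fa_long <- fa_long[order(fa_long$unit_id, fa_long$landmark_id), ]
  write_table(fa_long, file.path(out, "fa_per_landmark.tsv"))

  # 10. between-group ANOVAs + Tukey -------------------------------------
  da_vals <- as.vector(tabs$da)
  da_grp <- factor(rep(rownames(tabs$da), ncol(tabs$da)), levels = lev)
  t4 <- run_stage("da_between", oneway_anova(da_vals, da_grp))
  write_table(t4, file.path(out, "table4_da_anova_between.tsv"))
  write_table(tukey_hsd(da_vals, da_grp),
              file.path(out, "table5_da_tukey.tsv"))
  fa_vals <- as.vector(tabs$fa)
  fa_grp <- factor(rep(as.character(dec$individual$group), ncol(tabs$fa)),
                   levels = lev)
  t8 <- run_stage("fa_between", oneway_anova(fa_vals, fa_grp))
  write_table(t8, file.path(out, "table8_fa_anova_between.tsv"))
  write_table(tukey_hsd(fa_vals, fa_grp),
              file.path(out, "table9_fa_tukey.tsv"))

  # 11. Spearman matrix of DA profiles -----------------------------------
  sp <- run_stage("spearman", spearman_matrix(tabs$da))
  sp_df <- data.frame(group = rownames(sp), as.data.frame(sp))
  write_table(sp_df, file.path(out, "table6_da_spearman.tsv"))

  # 12. KW + Dunn across landmarks; per-landmark FA KW --------------------
  lm_lab <- factor(rep(seq_len(ncol(tabs$da)), each = nrow(tabs$da)))
  kw_da <- run_stage("kw_da", kruskal_wallis(as.vector(t(tabs$da)), lm_lab))
  dunn <- dunn_posthoc(as.vector(t(tabs$da)), lm_lab)
  write_table(data.frame(H = kw_da$H, df = kw_da$df, p = kw_da$p),
              file.path(out, "kw_da_across_landmarks.tsv"))
  write_table(dunn, file.path(out, "table7_da_dunn.tsv"))
  kw_fa <- run_stage("kw_fa", {
    ps <- vapply(seq_len(ncol(tabs$fa)), function(l)
      kruskal_wallis(tabs$fa[, l], dec$individual$group)$p, 1)
    data.frame(landmark_id = seq_len(ncol(tabs$fa)), p = ps,
               p_bonferroni = bonferroni(ps))
  })
  write_table(kw_fa, file.path(out, "fa_kw_per_landmark.tsv"))

  # 13. sex comparisons (adult groups only) -------------------------------
  sex_rows <- run_stage("sex_tests", {
    rows <- list()
    adult <- setdiff(lev, c("I", "II", "III"))  # no reliable sexual traits
    skipped <- setdiff(lev, adult)
    if (length(skipped))
      note(paste("sex comparison skipped for groups:",
                 paste(skipped, collapse = ", ")))
    for (g in adult) {
      selg <- groups == g
      sex <- dataset$info$sex[selg]
      ok <- sex %in% c("M", "F")
      if (sum(sex[ok] == "M") < 2 || sum(sex[ok] == "F") < 2) {
        note(paste("sex comparison not estimable for group", g))
        next
      }
      # per-landmark DA computed separately by sex
      idx <- which(selg)[ok]
      for (what in c("DA", "FA")) {
        if (what == "DA") {
          av <- dec$individual$asym_vector[, , idx, drop = FALSE]
          m_val <- per_landmark_norm(apply(
            av[, , sex[ok] == "M", drop = FALSE], c(1, 2), mean))
          f_val <- per_landmark_norm(apply(
            av[, , sex[ok] == "F", drop = FALSE], c(1, 2), mean))
        } else {
          fa <- dec$individual$fa_per_landmark[idx, , drop = FALSE]
          m_val <- colMeans(fa[sex[ok] == "M", , drop = FALSE])
          f_val <- colMeans(fa[sex[ok] == "F", , drop = FALSE])
        }
        mw <- mann_whitney(m_val, f_val)
        rows[[paste(g, what)]] <- data.frame(
          group = g, measure = what, U = mw$U, p = mw$p, exact = mw$exact)
      }
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(group = character(0), measure = character(0),
                 U = numeric(0), p = numeric(0), exact = logical(0))
  })
  write_table(sex_rows, file.path(out, "sex_mann_whitney.tsv"))

  # run log ---------------------------------------------------------------
  log$pooling <- list(fired = pooled_ok, per_group_p = as.list(pool_p))
  log$converged <- fit$gpa$converged
  log$n_individuals <- length(dec$individual$individual_id)
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(structure(out, fit = fit))
}

per_landmark_norm <- function(v) sqrt(rowSums(v^2))

serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$simulation <- if (!is.null(cfg$simulation)) unclass(cfg$simulation)
  cfg$slide <- if (!is.null(cfg$slide)) {
    s <- cfg$slide; s$geometry <- NULL; s
  }
  cfg
}

#' Render summary figures from a run directory
#'
#' Reads the per-landmark TSV tables written by \code{run_asym_pipeline()}
#' and renders the standard figures: per-group DA profiles, mean FA with a
#' 95\% envelope, and the sex-split comparisons. Missing tables are listed,
#' not fatal.
#'
#' @param run_dir run directory.
#' @param format \code{"png"} or \code{"pdf"}.
#' @return character vector of figure paths (possibly empty), invisibly;
#'   attribute \code{missing} lists absent tables.
#' @export
report_asym_pipeline <- function(run_dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  figdir <- file.path(run_dir, "figures")
  dir.create(figdir, showWarnings = FALSE)
  made <- character(0); missing <- character(0)
  open_dev <- function(path) {
    if (format == "png") grDevices::png(path, width = 900, height = 600)
    else grDevices::pdf(path, width = 9, height = 6)
  }
  da_path <- file.path(run_dir, "da_per_landmark.tsv")
  if (file.exists(da_path)) {
    da <- utils::read.delim(da_path)
    wide <- stats::xtabs(value ~ unit_id + landmark_id, data = da)
    f <- file.path(figdir, paste0("da_profiles.", format))
    open_dev(f)
    graphics::matplot(as.integer(colnames(wide)), t(wide), type = "l",
                      lty = 1, xlab = "landmark",
                      ylab = "DA (Procrustes units)",
                      main = "Directional asymmetry per landmark")
    graphics::legend("topright", legend = rownames(wide), lty = 1,
                     col = seq_len(nrow(wide)), bty = "n")
    grDevices::dev.off()
    made <- c(made, f)
  } else missing <- c(missing, da_path)
  fa_path <- file.path(run_dir, "fa_per_landmark.tsv")
  if (file.exists(fa_path)) {
    fa <- utils::read.delim(fa_path)
    mu <- stats::aggregate(value ~ group + landmark_id, data = fa, mean)
    se <- stats::aggregate(value ~ group + landmark_id, data = fa,
                           function(v) stats::sd(v) / sqrt(length(v)))
    f <- file.path(figdir, paste0("fa_profiles.", format))
    open_dev(f)
    glev <- unique(mu$group)
    lm_ids <- sort(unique(mu$landmark_id))
    ylim <- range(mu$value + 2 * se$value, mu$value - 2 * se$value, 0)
    graphics::plot(NULL, xlim = range(lm_ids), ylim = ylim,
                   xlab = "landmark", ylab = "mean FA (Procrustes units)",
                   main = "Fluctuating asymmetry per landmark (95% envelope)")
    for (i in seq_along(glev)) {
      m <- mu$value[mu$group == glev[i]]
      s <- se$value[se$group == glev[i]]
      graphics::polygon(c(lm_ids, rev(lm_ids)),
                        c(m + 1.96 * s, rev(m - 1.96 * s)),
                        col = grDevices::adjustcolor(i, alpha.f = 0.15),
                        border = NA)
      graphics::lines(lm_ids, m, col = i)
    }
    graphics::legend("topright", legend = glev, lty = 1,
                     col = seq_along(glev), bty = "n")
    grDevices::dev.off()
    made <- c(made, f)
  } else missing <- c(missing, fa_path)
  sex_path <- file.path(run_dir, "sex_mann_whitney.tsv")
  if (file.exists(sex_path)) {
    sx <- utils::read.delim(sex_path)
    if (nrow(sx) > 0) {
      f <- file.path(figdir, paste0("sex_tests.", format))
      open_dev(f)
      graphics::barplot(sx$p, names.arg = paste(sx$group, sx$measure),
                        ylab = "Mann-Whitney p", ylim = c(0, 1),
                        main = "Sex comparisons (DA/FA)")
      graphics::abline(h = 0.05, lty = 2)
      grDevices::dev.off()
      made <- c(made, f)
    }
  } else missing <- c(missing, sex_path)
  structure(invisible(made), missing = missing)
}
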