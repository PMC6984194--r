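# Bootstrap statistical machinery: classical mixed two-way ANOVA F
# statistics, bootstrap null distributions (mixed ANOVA, two-sided t,
# Pearson correlation), and Bonferroni-Holm correction.

#' Assemble mixed-design data
#'
#' @param subject Subject identifiers.
#' @param group Between-subject factor (2 levels); constant within subject.
#' @param condition Within-subject factor (2 levels); each subject
#'   contributes one value per level.
#' @param value Measurements.
#' @return A validated tibble with those four columns.
#' @export
mixed_design <- function(subject, group, condition, value) {
  d <- tibble(subject = as.character(subject), group = as.character(group),
              condition = as.character(condition), value = as.numeric(value))
  if (length(unique(d$group)) != 2 || length(unique(d$condition)) != 2) {
    abort_validation("`group` and `condition` must each have exactly 2 levels")
  }
  tab <- table(d$subject, d$condition)
  if (any(tab != 1)) {
    abort_validation("every subject needs exactly one value per condition")
  }
  gtab <- table(d$subject, d$group)
  if (any(rowSums(gtab > 0) != 1)) {
    abort_validation("every subject must belong to exactly one group")
  }
  d
}

# Internal fast path: y is an N x 2 matrix (subjects x conditions), g a
# logical vector (TRUE = group 1). Returns the three F statistics of the
# balanced 2 (between) x 2 (within) mixed decomposition, dfs (1, N-2).
mixed_anova_f_mat <- function(y, g) {
  n <- nrow(y)
  n1 <- sum(g); n2 <- n - n1
  subj_mean <- rowMeans(y)
  grand <- mean(y)
  m_g1 <- mean(subj_mean[g]); m_g2 <- mean(subj_mean[!g])
  m_c <- colMeans(y)
  # cell means group x condition
  mc_g1 <- colMeans(y[g, , drop = FALSE])
  mc_g2 <- colMeans(y[!g, , drop = FALSE])
  ss_group <- 2 * (n1 * (m_g1 - grand)^2 + n2 * (m_g2 - grand)^2)
  ss_subj <- 2 * (sum((subj_mean[g] - m_g1)^2) + sum((subj_mean[!g] - m_g2)^2))
  ss_cond <- n * sum((m_c - grand)^2)
  ss_int <- n1 * sum((mc_g1 - m_g1 - m_c + grand)^2) +
    n2 * sum((mc_g2 - m_g2 - m_c + grand)^2)
  cell_mean <- matrix(0, n, 2)
  cell_mean[g, ] <- matrix(mc_g1, n1, 2, byrow = TRUE)
  cell_mean[!g, ] <- matrix(mc_g2, n2, 2, byrow = TRUE)
  grp_mean <- ifelse(g, m_g1, m_g2)
  resid <- y - subj_mean - cell_mean + grp_mean
  ss_err <- sum(resid^2)
  df_s <- n - 2
  # a numerator SS of exactly zero is a zero effect even when the error
  # stratum is also degenerate (0/0 would otherwise give NaN)
  safe_f <- function(num, den) if (num < 1e-24) 0 else num / (den / df_s)
  c(group = safe_f(ss_group, ss_subj),
    within = safe_f(ss_cond, ss_err),
    interaction = safe_f(ss_int, ss_err))
}

design_to_mat <- function(data) {
  conds <- sort(unique(data$condition))
  groups <- sort(unique(data$group))
  wide <- tidyr::pivot_wider(data, id_cols = c("subject", "group"),
                             names_from = "condition",
                             values_from = "value")
  wide <- wide[order(wide$subject), , drop = FALSE]   # canonical order
  if (anyNA(wide)) abort_validation("missing cell in the mixed design")
  y <- as.matrix(wide[, conds])
  list(y = y, g = wide$group == groups[1], subjects = wide$subject,
       groups = groups, conds = conds)
}

#' Mixed two-way ANOVA F statistics
#'
#' Classical sums-of-squares decomposition of a balanced 2 (between-subject
#' group) x 2 (within-subject condition) design: the group effect is tested
#' against between-subject variation, the condition and interaction effects
#' against the condition-by-subject residual. All three F statistics have
#' (1, N - 2) degrees of freedom.
#'
#' @param data A [mixed_design()] tibble.
#' @return Named numeric vector `F_group`, `F_within`, `F_interaction`,
#'   with the dfs as attribute `df`.
#' @export
mixed_anova_f <- function(data) {
  d <- mixed_design(data$subject, data$group, data$condition, data$value)
  m <- design_to_mat(d)
  if (min(sum(m$g), sum(!m$g)) < 2) {
    abort_validation("each group needs at least 2 subjects")
  }
  f <- mixed_anova_f_mat(m$y, m$g)
  out <- setNames(as.numeric(f), c("F_group", "F_within", "F_interaction"))
  attr(out, "df") <- c(1, nrow(m$y) - 2)
  out
}

new_bootstrap_result <- function(observed, null_dist, p, ci = NULL, B, seed,
                                 statistic, extra = list()) {
  structure(c(list(observed = observed, null_distribution = null_dist,
                   p = p, ci = ci, B = B, seed = seed,
                   statistic = statistic), extra),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s = %.4g, p = %.4g (B = %d)\n",
              x$statistic, x$observed, x$p, x$B))
  if (!is.null(x$ci)) {
    cat(sprintf("  null 95%% CI: (%.3g, %.3g)\n", x$ci[1], x$ci[2]))
  }
  invisible(x)
}

boot_p <- function(null_exceeds, B) (1 + null_exceeds) / (B + 1)

#' Bootstrap mixed two-way ANOVA
#'
#' Builds the null by (i) centering the within-subject factor (subtracting
#' each condition's grand mean, so the condition effect is nulled while
#' each subject's condition deviations are preserved), (ii) resampling the
#' N subjects with replacement as whole cases, and (iii) randomly
#' reassigning the between-factor labels while preserving the group sizes.
#' The three F statistics are recomputed per replicate; `p` is the
#' proportion of null F values at or above the observed one, computed as
#' `(1 + #exceed) / (B + 1)` to avoid zero p-values.
#'
#' @param data A [mixed_design()] tibble.
#' @param B Number of bootstrap replicates (default 3000; a warning is
#'   issued below 100).
#' @param seed Integer seed.
#' @return A list of three `bootstrap_result` objects (`group`, `within`,
#'   `interaction`).
#' @export
bootstrap_mixed_anova <- function(data, B = 3000, seed = NULL) {
  check_scalar(B, "B", lower = 1, integerish = TRUE)
  if (B < 100) warn("B < 100 gives unstable bootstrap p-values")
  d <- mixed_design(data$subject, data$group, data$condition, data$value)
  m <- design_to_mat(d)
  obs <- mixed_anova_f_mat(m$y, m$g)
  n <- nrow(m$y)
  n1 <- sum(m$g)
  centered <- sweep(m$y, 2, colMeans(m$y))
  null_f <- with_rng_seed(seed, {
    out <- matrix(0, B, 3)
    for (b in seq_len(B)) {
      idx <- sample.int(n, n, replace = TRUE)
      g_b <- logical(n)
      g_b[sample.int(n, n1)] <- TRUE
      out[b, ] <- mixed_anova_f_mat(centered[idx, , drop = FALSE], g_b)
    }
    out
  })
  effects <- c("group", "within", "interaction")
  res <- lapply(seq_along(effects), function(k) {
    new_bootstrap_result(
      observed = unname(obs[k]),
      null_dist = null_f[, k],
      p = boot_p(sum(null_f[, k] >= obs[k]), B),
      B = B, seed = seed,
      statistic = paste0("F_", effects[k]))
  })
  setNames(res, effects)
}

two_sample_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Bootstrap two-sided independent-samples t-test
#'
#' Observed pooled-variance two-sample t; the null t distribution is built
#' by pooling both samples and repeatedly drawing two samples of the
#' original sizes with replacement. Two-sided p is the proportion of null
#' |t| at or above the observed |t|; `ci` holds the 2.5/97.5 percentiles of
#' the null t distribution.
#'
#' @param x,y Numeric samples (>= 2 values each).
#' @param B Replicates (default 3000).
#' @param seed Integer seed.
#' @return A `bootstrap_result`.
#' @export
bootstrap_ttest <- function(x, y, B = 3000, seed = NULL) {
  if (length(x) < 2 || length(y) < 2) {
    abort_validation("each sample needs at least 2 values")
  }
  check_scalar(B, "B", lower = 1, integerish = TRUE)
  if (B < 100) warn("B < 100 gives unstable bootstrap p-values")
  pool <- sort(c(x, y))   # canonical order: p invariant to input row order
  if (var(pool) < 1e-24) abort_validation("zero pooled variance")
  t_obs <- two_sample_t(x, y)
  n1 <- length(x); n2 <- length(y)
  null_t <- with_rng_seed(seed, {
    draws <- matrix(sample(pool, (n1 + n2) * B, replace = TRUE),
                    nrow = n1 + n2)
    apply(draws, 2, function(col) two_sample_t(col[seq_len(n1)],
                                               col[-seq_len(n1)]))
  })
  null_t <- null_t[is.finite(null_t)]
  new_bootstrap_result(
    observed = t_obs, null_dist = null_t,
    p = boot_p(sum(abs(null_t) >= abs(t_obs)), length(null_t)),
    ci = unname(quantile(null_t, c(0.025, 0.975))),
    B = B, seed = seed, statistic = "t")
}

#' Bootstrap Pearson correlation
#'
#' Observed Pearson r (with R^2 reported); the null distribution shuffles
#' one variable while keeping the other fixed. Two-sided p compares |r|.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param B Replicates (default 3000).
#' @param seed Integer seed.
#' @return A `bootstrap_result` with extra field `r_squared`.
#' @export
bootstrap_correlation <- function(x, y, B = 3000, seed = NULL) {
  if (length(x) != length(y) || length(x) < 3) {
    abort_validation("`x` and `y` must be paired with n >= 3")
  }
  check_scalar(B, "B", lower = 1, integerish = TRUE)
  if (B < 100) warn("B < 100 gives unstable bootstrap p-values")
  if (sd(x) < 1e-12 || sd(y) < 1e-12) {
    abort_validation("constant variable; correlation undefined")
  }
  r_obs <- cor(x, y)
  n <- length(x)
  ord <- order(x, y)      # canonical order: p invariant to input row order
  x <- x[ord]; y <- y[ord]
  xc <- (x - mean(x)) / (sd(x) * sqrt(n - 1))
  yc <- (y - mean(y)) / (sd(y) * sqrt(n - 1))
  null_r <- with_rng_seed(seed, {
    vapply(seq_len(B), function(b) sum(xc * yc[sample.int(n)]), numeric(1))
  })
  new_bootstrap_result(
    observed = r_obs, null_dist = null_r,
    p = boot_p(sum(abs(null_r) >= abs(r_obs)), B),
    B = B, seed = seed, statistic = "r",
    extra = list(r_squared = r_obs^2))
}

#' Bonferroni-Holm correction
#'
#' Step-down Holm procedure: p-values sorted ascending are compared with
#' `alpha / (m - i + 1)` and testing stops at the first failure. Adjusted
#' p-values come from [stats::p.adjust()] and are monotone non-decreasing
#' in the raw p ordering.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return A tibble `p`, `p_adjusted`, `reject`, in input order.
#' @export
holm_correction <- function(p, alpha = 0.05) {
  if (length(p) == 0) abort_validation("`p` must be non-empty")
  check_probability(p, "p")
  m <- length(p)
  ord <- order(p)
  reject <- logical(m)
  for (i in seq_len(m)) {
    if (p[ord[i]] <= alpha / (m - i + 1)) reject[ord[i]] <- TRUE else break
  }
  tibble(p = p, p_adjusted = p.adjust(p, method = "holm"), reject = reject)
}
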