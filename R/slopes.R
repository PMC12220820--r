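#' Group-contrast score slope per cell type
#'
#' Ordinary least squares of the per-cell score on a 0/1 group indicator
#' (0 = baseline, typically sham; 1 = pooled contrast, typically all
#' post-injury time points), fitted separately per cell type. With a binary
#' covariate the OLS slope equals the difference of group means exactly; the
#' regression framing supplies the 95% confidence interval and p-value from
#' the t-distribution on n - 2 degrees of freedom. The slope is the
#' per-cell-type pan-PCD sensitivity metric: how much the activity score
#' rises from baseline to injury.
#'
#' @param scores A score table with columns `auc_score` (or `score_col`),
#'   a group column and a cell-type column.
#' @param baseline_group Label of the baseline group (indicator 0).
#' @param contrast_groups Character vector of labels pooled as indicator 1.
#' @param by Name of the cell-type column (default `"cell_type"`); use a
#'   constant column for a single pooled fit.
#' @param score_col,group_col Column names (defaults `"auc_score"`,
#'   `"group"`).
#' @param conf_level Confidence level (default 0.95).
#' @return A tibble of class `pcd_slopes` with columns `cell_type`, `slope`,
#'   `ci_low`, `ci_high`, `p`, `n_baseline`, `n_contrast`. Cell types
#'   missing either group (or with < 2 cells in one) are omitted with a
#'   warning.
#' @export
group_slope <- function(scores, baseline_group, contrast_groups,
                        by = "cell_type", score_col = "auc_score",
                        group_col = "group", conf_level = 0.95) {
  stopifnot(is.data.frame(scores))
  for (col in c(by, score_col, group_col)) {
    if (!col %in% names(scores)) abort(sprintf("Column `%s` not found in `scores`.", col))
  }
  dat <- tibble(
    cell_type = as.character(scores[[by]]),
    score = as.numeric(scores[[score_col]]),
    grp = as.character(scores[[group_col]])
  ) |>
    filter(.data$grp %in% c(baseline_group, contrast_groups)) |>
    mutate(z = as.integer(.data$grp %in% contrast_groups))

  rows <- purrr::map(sort(unique(dat$cell_type)), function(ct) {
    sub <- filter(dat, .data$cell_type == ct)
    n0 <- sum(sub$z == 0); n1 <- sum(sub$z == 1)
    if (n0 < 2 || n1 < 2) {
      warn(sprintf("Cell type '%s' skipped: needs >= 2 cells in both groups (baseline %d, contrast %d).",
                   ct, n0, n1))
      return(NULL)
    }
    if (all(sub$score == sub$score[1])) {
      # degenerate zero-variance input: no evidence either way
      return(tibble(cell_type = ct, slope = 0, ci_low = 0, ci_high = 0, p = 1,
                    n_baseline = n0, n_contrast = n1))
    }
    if (var(sub$score[sub$z == 0]) == 0 && var(sub$score[sub$z == 1]) == 0) {
      # perfect separation: zero residual variance, exact slope
      slope <- mean(sub$score[sub$z == 1]) - mean(sub$score[sub$z == 0])
      return(tibble(cell_type = ct, slope = slope, ci_low = slope,
                    ci_high = slope, p = 0, n_baseline = n0, n_contrast = n1))
    }
    fit <- lm(score ~ z, data = sub)
    slope <- unname(coef(fit)[2])
    ci <- confint(fit, "z", level = conf_level)
    p <- summary(fit)$coefficients["z", "Pr(>|t|)"]
    if (is.nan(p)) p <- if (slope == 0) 1 else 0
    tibble(cell_type = ct, slope = slope, ci_low = ci[1], ci_high = ci[2],
           p = p, n_baseline = n0, n_contrast = n1)
  })
  out <- bind_rows(rows)
  attr(out, "baseline_group") <- baseline_group
  attr(out, "contrast_groups") <- contrast_groups
  class(out) <- c("pcd_slopes", class(out))
  out
}

#' Ratio of two group slopes with bootstrap confidence interval
#'
#' Compares pan-PCD sensitivity between two populations (e.g. adult vs
#' neonatal microglia) as the ratio of their group-contrast slopes. The
#' uncertainty comes from a percentile bootstrap over cells, resampled with
#' replacement within each (population x group) stratum — the score
#' distributions are bimodal, so a cell-level bootstrap is preferred to a
#' delta-method normal approximation. If the denominator slope's confidence
#' interval spans zero the ratio is numerically unstable and is flagged.
#'
#' @param scores_num,scores_den Score tables for the numerator and
#'   denominator populations (columns `auc_score`, `group`).
#' @param baseline_group,contrast_groups Group coding as in [group_slope()].
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Bootstrap seed.
#' @param score_col,group_col Column names.
#' @return A one-row tibble: `ratio`, `ci_low`, `ci_high`, `slope_num`,
#'   `slope_den`, `unstable`, `n_boot`.
#' @export
slope_ratio <- function(scores_num, scores_den, baseline_group, contrast_groups,
                        n_boot = 1000, seed = 1L,
                        score_col = "auc_score", group_col = "group") {
  pull_arms <- function(scores) {
    s <- as.numeric(scores[[score_col]])
    g <- as.character(scores[[group_col]])
    list(base = s[g %in% baseline_group], contr = s[g %in% contrast_groups])
  }
  a <- pull_arms(scores_num)
  b <- pull_arms(scores_den)
  if (any(lengths(a) < 2) || any(lengths(b) < 2)) {
    abort("Each population needs >= 2 cells in both baseline and contrast groups.")
  }
  slope_of <- function(arms) mean(arms$contr) - mean(arms$base)
  s_num <- slope_of(a)
  s_den <- slope_of(b)
  if (s_den == 0) abort("Denominator slope is exactly 0; the ratio is undefined.")

  # is the denominator distinguishable from 0?
  den_se <- sqrt(var(b$contr) / length(b$contr) + var(b$base) / length(b$base))
  unstable <- abs(s_den) < 1.96 * den_se

  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      rs <- function(x) x[sample.int(length(x), replace = TRUE)]
      num_b <- mean(rs(a$contr)) - mean(rs(a$base))
      den_b <- mean(rs(b$contr)) - mean(rs(b$base))
      num_b / den_b
    }, numeric(1))
  })
  boots <- boots[is.finite(boots)]
  ci <- unname(quantile(boots, c(0.025, 0.975)))
  if (unstable) {
    warn("Denominator slope CI spans 0; the slope ratio is unstable.")
  }
  tibble(ratio = s_num / s_den, ci_low = ci[1], ci_high = ci[2],
         slope_num = s_num, slope_den = s_den,
         unstable = unstable, n_boot = n_boot)
}

#' @export
tidy.pcd_slopes <- function(x, ...) {
  tibble(term = x$cell_type, estimate = x$slope, conf.low = x$ci_low,
         conf.high = x$ci_high, p.value = x$p)
}

#' @export
glance.pcd_slopes <- function(x, ...) {
  tibble(n_cell_types = nrow(x),
         max_slope = if (nrow(x)) max(x$slope) else NA_real_,
         steepest = if (nrow(x)) x$cell_type[which.max(x$slope)] else NA_character_)
}
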