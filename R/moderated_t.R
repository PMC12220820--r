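#' Empirical-Bayes moderated two-group t-test
#'
#' Differential expression between two sample groups on a log2-scale
#' expression matrix, with gene-wise variances shrunk toward a common prior
#' by empirical Bayes. For gene g with pooled residual variance `s2_g` on
#' `d_g = n_A + n_B - 2` degrees of freedom, the posterior variance is
#' `(d0*s0^2 + d_g*s2_g) / (d0 + d_g)` and the moderated statistic
#' `t = logFC / (s_tilde * sqrt(1/n_A + 1/n_B))` is referred to a
#' t-distribution on `d0 + d_g` degrees of freedom. When `prior_df` is
#' `NULL`, the prior `(d0, s0^2)` is estimated by moment matching on
#' `log(s2_g)` (digamma/trigamma moment equations, Newton iteration). With
#' `prior_df = 0` the statistic reduces exactly to the ordinary pooled
#' two-sample t-test; with `prior_df = Inf` every gene is tested against the
#' common variance.
#'
#' `logFC` is `mean(group_b) - mean(group_a)` on the log2 scale, so
#' `group_a` is the reference (e.g. sham) and `group_b` the condition.
#'
#' @param expr Numeric genes-by-samples matrix (log2 scale, no missing
#'   values) with gene row names, or a data frame whose first column is the
#'   gene id.
#' @param group_a,group_b Character vectors of column (sample) names, or
#'   logical/integer column selectors. Must be disjoint, each of size >= 2.
#' @param prior_df Prior degrees of freedom `d0`; `NULL` (default) estimates
#'   it from the data, `0` gives the ordinary pooled t-test, `Inf` full
#'   shrinkage.
#' @param fc_threshold,p_threshold Thresholds used for the convenience
#'   `is_deg` flag (strict inequalities): `|logFC| > fc_threshold` and
#'   `p < p_threshold`.
#' @return A tibble with columns `gene`, `log_fc`, `t`, `df`, `p`, `is_deg`,
#'   with the estimated `prior_df` and `s0_sq` as attributes.
#' @examples
#' m <- matrix(rnorm(60, 5), nrow = 10,
#'             dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
#' moderated_t_test(m, paste0("s", 1:3), paste0("s", 4:6))
#' @export
moderated_t_test <- function(expr, group_a, group_b, prior_df = NULL,
                             fc_threshold = 1.5, p_threshold = 0.05) {
  expr <- check_expr_matrix(expr)
  a <- resolve_samples(expr, group_a, "group_a")
  b <- resolve_samples(expr, group_b, "group_b")
  if (length(intersect(a, b)) > 0) abort("`group_a` and `group_b` must be disjoint.")
  n_a <- length(a); n_b <- length(b)
  if (n_a < 2 || n_b < 2) abort("Each group needs at least 2 samples.")

  xa <- expr[, a, drop = FALSE]
  xb <- expr[, b, drop = FALSE]
  mean_a <- rowMeans(xa)
  mean_b <- rowMeans(xb)
  log_fc <- mean_b - mean_a
  d_g <- n_a + n_b - 2
  ss <- rowSums((xa - mean_a)^2) + rowSums((xb - mean_b)^2)
  s2 <- ss / d_g

  if (is.null(prior_df)) {
    prior <- fit_variance_prior(s2, d_g)
  } else {
    stopifnot(is.numeric(prior_df), length(prior_df) == 1, prior_df >= 0)
    prior <- fit_variance_prior(s2, d_g, d0 = prior_df)
  }
  d0 <- prior$d0
  s0_sq <- prior$s0_sq

  if (d0 == 0) {
    s2_post <- s2
  } else if (is.infinite(d0)) {
    s2_post <- rep(s0_sq, length(s2))
  } else {
    s2_post <- (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  }
  df_total <- d0 + d_g
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  t_stat <- ifelse(se > 0, log_fc / se, ifelse(log_fc == 0, 0, sign(log_fc) * Inf))
  p <- 2 * pt(abs(t_stat), df = df_total, lower.tail = FALSE)
  # zero-variance, zero-effect genes carry no evidence
  p[se == 0 & log_fc == 0] <- 1

  out <- tibble(
    gene = rownames(expr),
    log_fc = unname(log_fc),
    t = unname(t_stat),
    df = df_total,
    p = unname(p),
    is_deg = abs(log_fc) > fc_threshold & p < p_threshold
  )
  attr(out, "prior_df") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

resolve_samples <- function(expr, sel, arg) {
  if (is.character(sel)) {
    missing <- setdiff(sel, colnames(expr))
    if (length(missing) > 0) {
      abort(sprintf("`%s`: samples not in `expr`: %s", arg, paste(missing, collapse = ", ")))
    }
    sel
  } else {
    colnames(expr)[sel]
  }
}

# Moment-matching estimate of the variance prior (d0, s0^2) from gene-wise
# sample variances s2 on d degrees of freedom, via the log-F representation:
#   E[log s2]  = log s0^2 + digamma(d/2) - log(d/2) - digamma(d0/2) + log(d0/2)
#   Var[log s2] = trigamma(d/2) + trigamma(d0/2)
# trigamma is inverted by Newton iteration. When d0 is supplied it is held
# fixed and only s0^2 is solved from the mean equation.
fit_variance_prior <- function(s2, d, d0 = NULL) {
  if (!is.null(d0) && d0 == 0) return(list(d0 = 0, s0_sq = NA_real_))
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) return(list(d0 = d0 %||% 0, s0_sq = 0))
  e <- log(s2[ok])
  emean <- mean(e)
  if (is.null(d0)) {
    evar <- var(e) - trigamma(d / 2)
    if (!is.finite(evar) || evar <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * trigamma_inverse(evar)
    }
  }
  if (is.infinite(d0)) {
    # no detectable gene-to-gene variance heterogeneity: the common variance
    # is just the average sample variance
    s0_sq <- mean(s2[ok])
  } else {
    offset <- digamma(d0 / 2) - log(d0 / 2)
    s0_sq <- exp(emean - digamma(d / 2) + log(d / 2) + offset)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

# Solve trigamma(y) = x for y > 0 by Newton iteration on the monotone
# decreasing trigamma function (worked in log space for stability).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Call differentially expressed genes from a moderated-t table
#'
#' Applies the strict thresholds `|logFC| > fc_threshold` and
#' `p < p_threshold` (a gene at exactly the fold-change cut is excluded).
#'
#' @param deg A tibble from [moderated_t_test()] (columns `gene`, `log_fc`,
#'   `p`).
#' @param fc_threshold Absolute log2 fold-change threshold (default 1.5).
#' @param p_threshold p-value threshold (default 0.05).
#' @return The subset tibble of genes passing both thresholds.
#' @export
call_degs <- function(deg, fc_threshold = 1.5, p_threshold = 0.05) {
  stopifnot(is.data.frame(deg), all(c("gene", "log_fc", "p") %in% names(deg)))
  filter(deg, abs(.data$log_fc) > fc_threshold, .data$p < p_threshold)
}
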