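#' Preranked running-sum enrichment of a panel
#'
#' Tests whether panel genes concentrate at either end of a ranked
#' differential profile. Genes are sorted by statistic descending (ties
#' broken by a seeded shuffle) and a running sum is accumulated:
#' `P_hit` advances by `|r|^weight` (normalized over panel hits) at each
#' panel gene, `P_miss` by `1/(n - m)` elsewhere. The enrichment score `es`
#' is the signed maximum deviation of `P_hit - P_miss`, in \[-1, 1\]. The
#' null is built by permuting gene labels `n_perm` times; `nes` divides `es`
#' by the mean magnitude of same-sign permutation scores, and the p-value
#' uses the add-one estimator `(1 + #{same-sign |es_pi| >= |es|}) /
#' (1 + #same-sign)` so it is never exactly zero.
#'
#' @param profile A tibble with columns `gene` and `stat` (e.g. log
#'   fold-changes), or a named numeric vector.
#' @param panel Panel tibble or gene vector.
#' @param weight Exponent on `|stat|` in the hit increments (default 1;
#'   0 gives the unweighted Kolmogorov-Smirnov-like statistic).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Seed for tie-breaking and permutations.
#' @return An object of class `pcd_enrichment`: list with `es`, `nes`, `p`,
#'   `n_perm`, `leading_edge`, `m`, `n`.
#' @export
preranked_enrichment <- function(profile, panel, weight = 1, n_perm = 1000, seed = 1L) {
  prof <- as_profile(profile)
  hit <- prof$gene %in% match_genes(panel_genes(panel), prof$gene)
  m <- sum(hit)
  n <- nrow(prof)
  if (m == 0 || m == n) {
    abort("Panel must overlap the profile partially (0 < m < n).")
  }
  with_seed(seed, {
    ord <- order(-prof$stat, runif(n))
    stat <- prof$stat[ord]
    gene_sorted <- prof$gene[ord]
    hit_sorted <- hit[ord]
    w <- abs(stat)^weight

    es_of <- function(hit_idx_logical) {
      wh <- w * hit_idx_logical
      denom_hit <- sum(wh)
      if (denom_hit == 0) wh <- as.numeric(hit_idx_logical) / sum(hit_idx_logical)
      else wh <- wh / denom_hit
      dev <- cumsum(wh - (!hit_idx_logical) / (n - m))
      dev[which.max(abs(dev))]
    }

    es <- es_of(hit_sorted)
    perm <- vapply(seq_len(n_perm), function(i) {
      idx <- logical(n)
      idx[sample.int(n, m)] <- TRUE
      es_of(idx)
    }, numeric(1))
  })
  same_sign <- perm[sign(perm) == sign(es)]
  nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(same_sign) >= abs(es))) / (1 + length(same_sign))

  dev <- {
    wh <- abs(stat)^weight * hit_sorted
    wh <- if (sum(wh) == 0) as.numeric(hit_sorted) / m else wh / sum(wh)
    cumsum(wh - (!hit_sorted) / (n - m))
  }
  peak <- which.max(abs(dev))
  leading <- if (es >= 0) gene_sorted[seq_len(peak)][hit_sorted[seq_len(peak)]]
             else gene_sorted[peak:n][hit_sorted[peak:n]]

  out <- list(es = es, nes = nes, p = p, n_perm = n_perm,
              leading_edge = leading, m = m, n = n, weight = weight)
  class(out) <- "pcd_enrichment"
  out
}

as_profile <- function(profile) {
  if (is.numeric(profile) && !is.null(names(profile))) {
    profile <- tibble(gene = names(profile), stat = unname(profile))
  }
  stopifnot(is.data.frame(profile), all(c("gene", "stat") %in% names(profile)))
  if (anyDuplicated(profile$gene)) abort("Profile genes must be unique.")
  if (!all(is.finite(profile$stat))) abort("Profile statistics must be finite.")
  as_tibble(profile[, c("gene", "stat")])
}

#' @export
print.pcd_enrichment <- function(x, ...) {
  cat(sprintf("<pcd_enrichment> es = %.3f, nes = %.3f, p = %.4g (%d/%d genes, %d permutations)\n",
              x$es, x$nes, x$p, x$m, x$n, x$n_perm))
  invisible(x)
}

#' @export
tidy.pcd_enrichment <- function(x, ...) {
  tibble(term = x$leading_edge)
}

#' @export
glance.pcd_enrichment <- function(x, ...) {
  tibble(es = x$es, nes = x$nes, p.value = x$p, n_perm = x$n_perm,
         n_panel = x$m, n_genes = x$n, n_leading_edge = length(x$leading_edge))
}
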