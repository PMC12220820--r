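#' Build an up/down query signature from a differential table
#'
#' Splits the panel genes of a contrast (e.g. adult vs neonatal microglia
#' post-injury) by the sign of their log fold-change: `up` genes rise in the
#' contrast, `down` genes fall, zeros are excluded. The full logFC vector is
#' retained for the correlation screening mode.
#'
#' @param deg A tibble with columns `gene` and `log_fc` (e.g. from
#'   [moderated_t_test()]).
#' @param panel Panel tibble or gene vector restricting the signature.
#' @return An object of class `pcd_signature`: list with `up`, `down`
#'   (character vectors) and `log_fc` (named numeric vector).
#' @export
build_query_signature <- function(deg, panel) {
  stopifnot(is.data.frame(deg), all(c("gene", "log_fc") %in% names(deg)))
  sub <- filter(deg, .data$gene %in% match_genes(panel_genes(panel), .data$gene))
  query_signature(setNames(sub$log_fc, sub$gene))
}

#' Construct a query signature from a named logFC vector
#'
#' @param log_fc Named numeric vector (gene -> log fold-change).
#' @return A `pcd_signature` object (see [build_query_signature()]).
#' @export
query_signature <- function(log_fc) {
  stopifnot(is.numeric(log_fc), !is.null(names(log_fc)))
  log_fc <- log_fc[is.finite(log_fc)]
  up <- names(log_fc)[log_fc > 0]
  down <- names(log_fc)[log_fc < 0]
  if (length(up) == 0 || length(down) == 0) {
    abort(paste("A KS query signature needs both up- and down-regulated genes;",
                "use correlation_connectivity() for one-sided signatures."))
  }
  out <- list(up = up, down = down, log_fc = log_fc)
  class(out) <- "pcd_signature"
  out
}

#' @export
print.pcd_signature <- function(x, ...) {
  cat(sprintf("<pcd_signature> %d up / %d down genes\n", length(x$up), length(x$down)))
  invisible(x)
}

# Classic tag-set KS statistic: for t tag ranks V (ascending) among n genes,
#   a = max_j [ j/t - V(j)/n ],  b = max_j [ V(j)/n - (j-1)/t ]
# return a if a > b else -b.
ks_tag <- function(ranks, n) {
  t <- length(ranks)
  v <- sort(ranks)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' KS connectivity of a query signature to one perturbation profile
#'
#' The classic connectivity-mapping statistic: the up and down arms of the
#' query are located in the compound's ranked perturbation profile
#' (statistic descending) and each arm gets a signed Kolmogorov-Smirnov
#' tag-set score. When the arms disagree in sign — the informative case —
#' the raw connectivity is `s = (ks(up) - ks(down)) / 2`, in \[-1, 1\];
#' when they agree the compound is called null (`s = 0`) by convention.
#' Negative `s` means the compound's profile opposes the query signature
#' (signature reversal).
#'
#' @param signature A `pcd_signature` ([build_query_signature()]).
#' @param profile Named numeric vector of per-gene perturbation statistics,
#'   or a tibble with `gene` and `stat`.
#' @return Raw connectivity score in \[-1, 1\]. Query genes missing from the
#'   profile are dropped with a warning; a fully missing arm is an error.
#' @export
ks_connectivity <- function(signature, profile) {
  stopifnot(inherits(signature, "pcd_signature"))
  prof <- as_profile(profile)
  rank_map <- setNames(rank(-prof$stat, ties.method = "first"), prof$gene)
  arm_ranks <- function(arm, label) {
    present <- intersect(arm, prof$gene)
    missing <- setdiff(arm, prof$gene)
    if (length(missing) > 0) {
      warn(sprintf("%d %s-arm gene(s) missing from the profile; dropped.",
                   length(missing), label))
    }
    if (length(present) == 0) abort(sprintf("The whole %s arm is missing from the profile.", label))
    unname(rank_map[present])
  }
  up <- arm_ranks(signature$up, "up")
  down <- arm_ranks(signature$down, "down")
  n <- nrow(prof)
  ks_up <- ks_tag(up, n)
  ks_down <- ks_tag(down, n)
  if (sign(ks_up) == sign(ks_down)) return(0)
  (ks_up - ks_down) / 2
}

#' Scale raw connectivity scores to the +/-100 convention
#'
#' Positive raw scores are divided by the maximum positive raw score,
#' negative by the magnitude of the most negative, then multiplied by 100:
#' within one library run the strongest mimic maps to +100 and the
#' strongest reverser to -100. Signs are never changed and zero stays zero.
#'
#' @param raw Numeric vector of raw connectivity scores for one library run.
#' @return Numeric vector of scaled scores in \[-100, 100\].
#' @export
scale_scores <- function(raw) {
  stopifnot(is.numeric(raw), length(raw) >= 1)
  out <- numeric(length(raw))
  pos <- raw > 0
  neg <- raw < 0
  if (any(pos)) out[pos] <- 100 * raw[pos] / max(raw[pos])
  if (any(neg)) out[neg] <- 100 * raw[neg] / abs(min(raw[neg]))
  names(out) <- names(raw)
  out
}

#' Permutation p-value for a KS connectivity score
#'
#' Null: random up/down tag sets of the observed sizes drawn from the
#' profile's gene universe. The two-sided p-value uses the add-one
#' estimator `(1 + #{|s_pi| >= |s_obs|}) / (1 + n_perm)`.
#'
#' @param signature A `pcd_signature`.
#' @param profile Named numeric vector or tibble (`gene`, `stat`).
#' @param s_obs Observed raw score; computed via [ks_connectivity()] when
#'   `NULL`.
#' @param n_perm Number of permutations (>= 100, default 1000).
#' @param seed Permutation seed.
#' @return A one-row tibble: `s_obs`, `p`, `n_perm`.
#' @export
connectivity_pvalue <- function(signature, profile, s_obs = NULL,
                                n_perm = 1000, seed = 1L) {
  if (n_perm < 100) abort("`n_perm` must be >= 100.")
  prof <- as_profile(profile)
  if (is.null(s_obs)) s_obs <- ks_connectivity(signature, profile)
  n <- nrow(prof)
  t_up <- length(intersect(signature$up, prof$gene))
  t_down <- length(intersect(signature$down, prof$gene))
  null <- with_seed(seed, ks_null_sample(n, t_up, t_down, n_perm))
  p <- (1 + sum(abs(null) >= abs(s_obs))) / (1 + n_perm)
  tibble(s_obs = s_obs, p = p, n_perm = n_perm)
}

# Sample the connectivity null: random tag ranks for both arms. Random tag
# sets drawn from the universe of a tie-free profile have uniformly random
# ranks, so sampling ranks directly is an exact shortcut.
ks_null_sample <- function(n, t_up, t_down, n_perm) {
  vapply(seq_len(n_perm), function(i) {
    ku <- ks_tag(sample.int(n, t_up), n)
    kd <- ks_tag(sample.int(n, t_down), n)
    if (sign(ku) == sign(kd)) 0 else (ku - kd) / 2
  }, numeric(1))
}

#' Spearman correlation connectivity
#'
#' Continuous alternative to the dichotomized KS mode: Spearman rank
#' correlation between the query's logFC vector and the compound's
#' perturbation statistics over their shared genes (>= 5 required), with a
#' permutation p-value obtained by shuffling the profile values among the
#' shared genes.
#'
#' @param signature A `pcd_signature` (its `log_fc` vector is used) or a
#'   named numeric logFC vector.
#' @param profile Named numeric vector or tibble (`gene`, `stat`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Permutation seed.
#' @return A one-row tibble: `rho`, `p`, `n_genes`, `n_perm`.
#' @export
correlation_connectivity <- function(signature, profile, n_perm = 1000, seed = 1L) {
  query <- if (inherits(signature, "pcd_signature")) signature$log_fc else signature
  stopifnot(is.numeric(query), !is.null(names(query)))
  prof <- as_profile(profile)
  stat <- setNames(prof$stat, prof$gene)
  shared <- intersect(names(query), names(stat))
  if (length(shared) < 5) abort("Need >= 5 shared genes for correlation connectivity.")
  q <- query[shared]
  s <- stat[shared]
  rho <- cor(q, s, method = "spearman")
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) cor(q, sample(s), method = "spearman"), numeric(1))
  })
  p <- (1 + sum(abs(null) >= abs(rho))) / (1 + n_perm)
  tibble(rho = rho, p = p, n_genes = length(shared), n_perm = n_perm)
}

#' Screen a perturbation library against a query signature
#'
#' Scores every compound of a library (compounds-by-genes matrix of
#' perturbation statistics) against the query: KS connectivity (default) or
#' Spearman correlation, library-wide +/-100 scaling of the raw scores, and
#' a permutation p-value per compound. In KS mode the permutation null
#' depends only on the arm sizes and universe size, so one null sample is
#' shared across compounds of a run.
#'
#' @param signature A `pcd_signature`.
#' @param library Numeric compounds-by-genes matrix with compound row names
#'   and gene column names, or a list with elements `profiles` (+ optional
#'   `compound_meta`) as returned by [simulate_perturbation_library()].
#' @param method `"ks"` (default) or `"correlation"`.
#' @param n_perm Permutations for the p-value (default 1000).
#' @param seed Seed.
#' @return A connectivity table: tibble with `compound`, `raw`, `scaled`,
#'   `p`.
#' @export
screen_library <- function(signature, library, method = c("ks", "correlation"),
                           n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  if (is.list(library) && !is.matrix(library)) library <- library$profiles
  stopifnot(is.matrix(library), !is.null(rownames(library)), !is.null(colnames(library)))
  if (anyDuplicated(rownames(library))) abort("Compound ids must be unique.")
  if (!all(is.finite(library))) abort("Perturbation statistics must be finite.")
  compounds <- rownames(library)
  if (method == "ks") {
    raw <- vapply(compounds, function(cp) {
      ks_connectivity(signature, setNames(library[cp, ], colnames(library)))
    }, numeric(1))
    n <- ncol(library)
    t_up <- length(intersect(signature$up, colnames(library)))
    t_down <- length(intersect(signature$down, colnames(library)))
    null <- with_seed(seed, ks_null_sample(n, t_up, t_down, n_perm))
    p <- vapply(raw, function(s) (1 + sum(abs(null) >= abs(s))) / (1 + n_perm), numeric(1))
  } else {
    res <- purrr::imap(compounds, function(cp, i) {
      correlation_connectivity(signature, setNames(library[cp, ], colnames(library)),
                               n_perm = n_perm, seed = child_seed(seed, i))
    })
    raw <- purrr::map_dbl(res, "rho")
    p <- purrr::map_dbl(res, "p")
  }
  tibble(compound = compounds, raw = unname(raw),
         scaled = unname(scale_scores(raw)), p = unname(p))
}

#' Consensus screen across datasets
#'
#' Applies the all-datasets reversal rule: a compound is retained when its
#' scaled connectivity score is negative AND its permutation p-value is
#' below `alpha` in EVERY dataset. Retained compounds are ranked by
#' ascending mean scaled score (strongest reversers first); per-dataset
#' evidence is kept in wide columns.
#'
#' @param tables Named list (>= 2) of connectivity tables from
#'   [screen_library()], one per dataset.
#' @param alpha Per-dataset significance threshold (default 0.05).
#' @return A tibble with `compound`, `mean_scaled`, `n_datasets_negative_significant`,
#'   `retained`, and per-dataset `scaled_*` / `p_*` columns, ranked with
#'   retained compounds first by ascending mean scaled score.
#' @export
consensus_screen <- function(tables, alpha = 0.05) {
  stopifnot(is.list(tables))
  if (length(tables) < 2) abort("Consensus screening needs >= 2 datasets.")
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  long <- purrr::imap(tables, function(tb, nm) {
    stopifnot(is.data.frame(tb), all(c("compound", "scaled", "p") %in% names(tb)))
    mutate(tb, dataset = nm)
  }) |> bind_rows()
  missing <- long |>
    count(.data$compound) |>
    filter(.data$n < length(tables))
  if (nrow(missing) > 0) {
    warn(sprintf("%d compound(s) absent from some datasets; they cannot be retained.",
                 nrow(missing)))
  }
  summary_tbl <- long |>
    group_by(.data$compound) |>
    summarise(
      mean_scaled = mean(.data$scaled),
      n_datasets = n(),
      n_datasets_negative_significant = sum(.data$scaled < 0 & .data$p < alpha),
      .groups = "drop"
    ) |>
    mutate(retained = .data$n_datasets == length(tables) &
             .data$n_datasets_negative_significant == length(tables))
  wide <- long |>
    select("compound", "dataset", "scaled", "p") |>
    tidyr::pivot_wider(names_from = "dataset", values_from = c("scaled", "p"))
  summary_tbl |>
    left_join(wide, by = "compound") |>
    arrange(dplyr::desc(.data$retained), .data$mean_scaled)
}
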