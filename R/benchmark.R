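#' End-to-end synthetic benchmark
#'
#' Runs the whole pipeline on synthetic data with planted ground truth:
#' simulate a multi-model bulk time course, derive the core panel
#' (moderated-t DEGs per acute time point, catalog intersection, cross-model
#' rank-sum refinement, multi-model intersection), simulate a single-cell
#' population carrying the derived panel, score cells (rank AUC), detect
#' the high/low threshold, stratify, fit group slopes, compute the planted
#' slope-ratio contrast, build a query signature, and screen three
#' independently seeded perturbation libraries with the consensus rule.
#' Every stage is seeded from `seed`, so the report is reproducible.
#'
#' @param seed Master integer seed.
#' @param n_perm Permutations for the connectivity p-values (default 1000).
#' @param n_boot Bootstrap replicates for the slope ratio (default 1000).
#' @return An object of class `pcd_benchmark`: list with `metrics` (tidy
#'   tibble of recovery metrics), `checks` (tibble of named pass/fail
#'   properties), `panel`, `threshold`, `slopes`, `consensus`, `seed`.
#' @export
run_benchmark <- function(seed = 1L, n_perm = 1000, n_boot = 1000) {
  ## 1. bulk simulation and panel derivation -------------------------------
  bulk <- simulate_bulk_timecourse(bulk_sim_config(seed = child_seed(seed, 1)))
  meta <- bulk$sample_meta
  crush <- bulk$expression$crush
  crush_meta <- filter(meta, .data$model == "crush")
  sham_ids <- filter(crush_meta, .data$timepoint == "sham")$sample
  degs <- purrr::map(c("1dpi", "3dpi", "7dpi"), function(tp) {
    moderated_t_test(crush, sham_ids, filter(crush_meta, .data$timepoint == tp)$sample)
  }) |> setNames(c("1dpi", "3dpi", "7dpi"))
  candidates <- injury_responsive_set(degs, bulk$catalog)

  refine <- purrr::map(c("contusion", "hemisection"), function(m) {
    mm <- filter(meta, .data$model == m)
    res <- ranksum_filter(candidates$gene, bulk$expression[[m]],
                          injured = filter(mm, .data$group == "injured")$sample,
                          sham = filter(mm, .data$group == "sham")$sample)
    filter(res, .data$retained)
  }) |> setNames(c("contusion", "hemisection"))

  panel <- derive_panel(c(list(crush = candidates), refine), bulk$catalog)
  core <- bulk$truth$core
  jaccard <- length(intersect(panel$gene, core)) / length(union(panel$gene, core))

  ## 2. single-cell scoring and stratification -----------------------------
  cells <- simulate_cell_population(cell_sim_config(panel = panel$gene,
                                                   seed = child_seed(seed, 2)))
  scores <- score_cells_auc(cells$counts, panel, cells$cell_meta,
                            seed = child_seed(seed, 3))
  thr <- detect_threshold(scores)
  strat <- stratify_cells(scores, thr) |> left_join(cells$truth, by = "cell")
  sens <- with(strat, mean(stratum[activity == "high"] == "high"))
  spec <- with(strat, mean(stratum[activity == "low"] == "low"))
  bal_acc <- (sens + spec) / 2
  hf <- high_fraction(strat, .data$group)
  slopes_cells <- group_slope(strat, "sham", "injured")

  ## 3. planted slope-ratio contrast ---------------------------------------
  adult <- simulate_score_shift(shift = 0.16, seed = child_seed(seed, 4))
  neonatal <- simulate_score_shift(shift = 0.02, seed = child_seed(seed, 5))
  slope_adult <- group_slope(adult, "sham", "injured")
  slope_neo <- group_slope(neonatal, "sham", "injured")
  ratio <- slope_ratio(adult, neonatal, "sham", "injured",
                       n_boot = n_boot, seed = child_seed(seed, 6))

  ## 4. signature-reversal screen ------------------------------------------
  sig_vec <- with_seed(child_seed(seed, 7),
                       setNames(rnorm(nrow(panel)), panel$gene))
  signature <- query_signature(sig_vec)
  tables <- purrr::map(1:3, function(i) {
    lib <- simulate_perturbation_library(
      library_sim_config(signature = sig_vec, seed = child_seed(seed, 10 + i)))
    screen_library(signature, lib, method = "ks", n_perm = n_perm,
                   seed = child_seed(seed, 20 + i))
  }) |> setNames(paste0("dataset", 1:3))
  consensus <- consensus_screen(tables, alpha = 0.05)
  retained_by_class <- consensus |>
    filter(.data$retained) |>
    mutate(class = dplyr::case_when(
      grepl("^cpd_reverser", .data$compound) ~ "reverser",
      grepl("^cpd_mimic", .data$compound) ~ "mimic",
      TRUE ~ "inert"
    )) |>
    count(.data$class)
  n_of <- function(cl) {
    r <- filter(retained_by_class, .data$class == cl)
    if (nrow(r) == 0) 0L else r$n[1]
  }

  metrics <- tibble(
    metric = c("panel_size", "panel_jaccard", "threshold", "balanced_accuracy",
               "frac_high_sham", "frac_high_injured", "slope_injured",
               "slope_adult", "slope_neonatal", "slope_ratio",
               "ratio_ci_low", "ratio_ci_high", "n_reversers_retained",
               "n_mimics_retained", "n_inert_retained"),
    value = c(nrow(panel), jaccard, thr$threshold, bal_acc,
              filter(hf, .data$group == "sham")$frac_high,
              filter(hf, .data$group == "injured")$frac_high,
              slopes_cells$slope[1],
              slope_adult$slope[1], slope_neo$slope[1], ratio$ratio,
              ratio$ci_low, ratio$ci_high, n_of("reverser"), n_of("mimic"),
              n_of("inert"))
  )
  checks <- tibble(
    check = c("panel_jaccard >= 0.9", "threshold method bimodal_minimum",
              "balanced_accuracy >= 0.9", "adult slope CI covers 0.16",
              "neonatal slope CI covers 0.02", "ratio CI covers 8",
              "all 5 reversers retained", "no mimics retained"),
    pass = c(jaccard >= 0.9, thr$method == "bimodal_minimum", bal_acc >= 0.9,
             slope_adult$ci_low[1] <= 0.16 & 0.16 <= slope_adult$ci_high[1],
             slope_neo$ci_low[1] <= 0.02 & 0.02 <= slope_neo$ci_high[1],
             ratio$ci_low <= 8 & 8 <= ratio$ci_high,
             n_of("reverser") == 5, n_of("mimic") == 0)
  )
  out <- list(metrics = metrics, checks = checks, panel = panel,
              threshold = thr, slopes = slopes_cells, high_fraction = hf,
              ratio = ratio, consensus = consensus, seed = seed)
  class(out) <- "pcd_benchmark"
  out
}

#' @export
print.pcd_benchmark <- function(x, ...) {
  cat(sprintf("<pcd_benchmark> seed %d\n", x$seed))
  m <- x$metrics
  cat(sprintf("  %-22s %s\n", m$metric, formatC(m$value, digits = 4, format = "fg")),
      sep = "")
  cat(sprintf("  checks passed: %d/%d\n", sum(x$checks$pass), nrow(x$checks)))
  invisible(x)
}

#' @export
tidy.pcd_benchmark <- function(x, ...) x$metrics

#' @export
glance.pcd_benchmark <- function(x, ...) {
  tibble(seed = x$seed, n_checks = nrow(x$checks), n_passed = sum(x$checks$pass))
}
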