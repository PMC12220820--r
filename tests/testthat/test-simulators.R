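test_that("generators are pure functions of their config (same seed, same bytes)", {
  b1 <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 200, n_catalog_genes = 60,
                                                 n_core_responders = 10, seed = 3))
  b2 <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 200, n_catalog_genes = 60,
                                                 n_core_responders = 10, seed = 3))
  expect_identical(b1$expression, b2$expression)
  c1 <- simulate_cell_population(cell_sim_config(n_cells = 100, n_genes = 400, seed = 4))
  c2 <- simulate_cell_population(cell_sim_config(n_cells = 100, n_genes = 400, seed = 4))
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$truth, c2$truth)
  l1 <- simulate_perturbation_library(library_sim_config(seed = 5))
  l2 <- simulate_perturbation_library(library_sim_config(seed = 5))
  expect_identical(l1$profiles, l2$profiles)
})

test_that("emitted matrices satisfy the consuming modules' invariants", {
  sim <- simulate_cell_population(cell_sim_config(n_cells = 150, n_genes = 500, seed = 6))
  expect_true(min(sim$counts) >= 0)
  expect_false(anyDuplicated(rownames(sim$counts)) > 0)
  expect_false(anyDuplicated(colnames(sim$counts)) > 0)
  expect_setequal(sim$truth$cell, colnames(sim$counts))
  bulk <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 150, n_catalog_genes = 50,
                                                   n_core_responders = 10, seed = 7))
  for (m in names(bulk$expression)) {
    expect_false(anyNA(bulk$expression[[m]]))
    expect_equal(nrow(bulk$expression[[m]]), 150)
  }
  expect_s3_class(bulk$catalog, "pcd_catalog")
})

test_that("truth labels have the exact cardinalities the config requests", {
  cfg <- cell_sim_config(n_cells = 200, high_fraction = c(sham = 0.2, injured = 0.6),
                         n_genes = 400, seed = 8)
  sim <- simulate_cell_population(cfg)
  counts <- sim$truth |>
    dplyr::left_join(sim$cell_meta, by = "cell") |>
    dplyr::count(group, activity)
  expect_equal(counts$n[counts$group == "sham" & counts$activity == "high"], 40)
  expect_equal(counts$n[counts$group == "injured" & counts$activity == "high"], 120)
  bulk <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 300, n_catalog_genes = 100,
                                                   n_core_responders = 25,
                                                   n_model_specific_responders = 5,
                                                   seed = 9))
  expect_length(bulk$truth$core, 25)
  expect_true(all(lengths(bulk$truth$model_specific) == 5))
})

test_that("a null bulk simulation (effect 0) yields no called responders", {
  sim <- simulate_bulk_timecourse(bulk_sim_config(n_genes = 300, n_catalog_genes = 100,
                                                  n_core_responders = 30,
                                                  models = "crush",
                                                  n_model_specific_responders = 0,
                                                  effect_size = 0, seed = 10))
  meta <- sim$sample_meta
  sham <- meta$sample[meta$timepoint == "sham"]
  degs <- lapply(c("1dpi", "3dpi", "7dpi"), function(tp) {
    moderated_t_test(sim$expression$crush, sham, meta$sample[meta$timepoint == tp])
  })
  res <- injury_responsive_set(degs, sim$catalog)
  # |logFC| > 1.5 is ~9 noise sds here; chance survivors are essentially impossible
  expect_equal(nrow(res), 0)
})

test_that("fold_elevation 1 leaves high and low cells indistinguishable (in aggregate)", {
  # the labels carry no signal, so the rank-sum p is U(0,1); assert in
  # aggregate over seeds rather than on a single draw
  ps <- vapply(1:5, function(s) {
    sim <- simulate_cell_population(cell_sim_config(
      n_cells = 200, groups = "sham", high_fraction = c(sham = 0.5),
      fold_elevation = 1, n_genes = 500, panel = sprintf("Gene%04d", 1:30),
      seed = 10 + s))
    scores <- score_cells_auc(sim$counts, sim$panel, seed = 1) |>
      dplyr::left_join(sim$truth, by = "cell")
    wilcox.test(scores$auc_score[scores$activity == "high"],
                scores$auc_score[scores$activity == "low"])$p.value
  }, numeric(1))
  expect_gte(sum(ps > 0.05), 3)
  expect_gt(median(ps), 0.05)
})

test_that("zero high-fraction in both groups gives a null slope with covering CI", {
  sim <- simulate_cell_population(cell_sim_config(
    n_cells = 250, high_fraction = c(sham = 0, injured = 0), n_genes = 600,
    panel = sprintf("Gene%04d", 1:30), seed = 12))
  scores <- score_cells_auc(sim$counts, sim$panel, sim$cell_meta, seed = 1)
  sl <- group_slope(scores, "sham", "injured")
  expect_true(sl$ci_low <= 0 && 0 <= sl$ci_high)
  expect_lt(abs(sl$slope), 0.02)
})

test_that("a noiseless reverser anti-correlates perfectly with the query", {
  lib <- simulate_perturbation_library(library_sim_config(
    n_reversers = 1, n_mimics = 0, n_inert = 0, noise_sd = 0, seed = 13))
  sig <- query_signature(lib$signature)
  res <- correlation_connectivity(sig, setNames(lib$profiles[1, ], colnames(lib$profiles)),
                                  n_perm = 100, seed = 1)
  expect_equal(res$rho, -1)
})

test_that("with no planted reversers the consensus retains almost nothing", {
  sig_vec <- withr::with_seed(14, setNames(rnorm(68), sprintf("Gene%04d", 1:68)))
  sig <- query_signature(sig_vec)
  tables <- lapply(1:3, function(i) {
    lib <- simulate_perturbation_library(library_sim_config(
      signature = sig_vec, n_reversers = 0, n_mimics = 0, n_inert = 30,
      seed = 300 + i))
    screen_library(sig, lib, n_perm = 300, seed = 400 + i)
  })
  cs <- consensus_screen(tables)
  expect_lte(sum(cs$retained), 2)
})

test_that("config invariants are enforced", {
  expect_error(bulk_sim_config(n_core_responders = 300, n_catalog_genes = 100),
               "n_core_responders")
  expect_error(bulk_sim_config(noise_sd = 0), "noise_sd")
  expect_error(cell_sim_config(high_fraction = c(sham = 1.2, injured = 0.5)),
               "high_fraction")
  expect_error(cell_sim_config(fold_elevation = 0.5), "fold_elevation")
  expect_error(library_sim_config(gain = 0), "gain")
  expect_error(library_sim_config(n_inert = -1), "counts")
})

test_that("cell matrices round-trip through Matrix Market + TSV files", {
  sim <- simulate_cell_population(cell_sim_config(n_cells = 40, n_genes = 120, seed = 15))
  dir <- withr::local_tempdir()
  write_cell_counts(sim$counts, dir)
  back <- read_cell_counts(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                           file.path(dir, "barcodes.tsv"))
  expect_equal(as.matrix(back), as.matrix(sim$counts), ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(sim$counts))
  expect_equal(colnames(back), colnames(sim$counts))
})
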