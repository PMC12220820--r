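test_that("per-cell ranking orders strictly expressed genes and rejects empty cells", {
  m <- matrix(c(5, 3, 1), ncol = 1, dimnames = list(c("g1", "g2", "g3"), "c1"))
  r <- rank_genes_per_cell(m, seed = 1)
  expect_equal(unname(r[, 1]), c(1L, 2L, 3L))
  m0 <- cbind(m, c2 = c(0, 0, 0))
  expect_error(rank_genes_per_cell(m0, seed = 1), "c2")
})

test_that("tie-breaking is seeded: reproducible per seed, variable across seeds", {
  m <- matrix(c(2, 2, 1), ncol = 1, dimnames = list(c("g1", "g2", "g3"), "c1"))
  r1 <- rank_genes_per_cell(m, seed = 5)
  r2 <- rank_genes_per_cell(m, seed = 5)
  expect_identical(r1, r2)
  orders <- vapply(1:20, function(s) rank_genes_per_cell(m, seed = s)["g1", 1],
                   integer(1))
  expect_setequal(unique(orders), c(1L, 2L))
})

test_that("ranking and AUC are invariant under strictly monotone transforms", {
  m <- toy_counts(n_genes = 40, n_cells = 8, seed = 3)
  m <- m[, colSums(m) > 0]
  r_raw <- rank_genes_per_cell(m, seed = 2)
  r_log <- rank_genes_per_cell(log1p(m), seed = 2)
  expect_identical(r_raw, r_log)
  panel <- rownames(m)[1:5]
  expect_equal(auc_score(r_raw, panel, 0.2), auc_score(r_log, panel, 0.2))
})

test_that("recovery-curve AUC hits its extremes and the worked example", {
  n <- 10
  mk_ranking <- function(perm) matrix(perm, ncol = 1,
                                      dimnames = list(sprintf("g%02d", 1:n), "c1"))
  # panel occupies top ranks -> 1.0
  r <- mk_ranking(1:10)
  expect_equal(unname(auc_score(r, c("g01", "g02"), top_fraction = 0.5)), 1.0)
  # no panel gene in top k -> 0.0
  expect_equal(unname(auc_score(r, c("g09", "g10"), top_fraction = 0.5)), 0.0)
  # n = 10, k = 5, panel at ranks 2 and 5 -> 5/9
  expect_equal(unname(auc_score(r, c("g02", "g05"), top_fraction = 0.5)), 5 / 9)
  expect_error(auc_score(r, "absent"), "No panel gene")
  expect_error(auc_score(r, "g01", top_fraction = 0), "top_fraction")
})

test_that("AUC equals the brute-force recovery-curve oracle on random instances", {
  withr::with_seed(17, {
    for (i in 1:100) {
      n <- sample(10:50, 1)
      m <- sample(1:10, 1)
      top_fraction <- runif(1, 0.05, 1)
      perm <- sample(n)
      ranking <- matrix(perm, ncol = 1,
                        dimnames = list(sprintf("g%03d", 1:n), "c1"))
      panel <- sprintf("g%03d", sample(n, m))
      got <- unname(auc_score(ranking, panel, top_fraction))
      want <- oracle_auc(perm[match(panel, sprintf("g%03d", 1:n))], n, top_fraction)
      expect_equal(got, want, tolerance = 1e-12)
      expect_gte(got, 0); expect_lte(got, 1)
    }
  })
})

test_that("score_cells_auc returns a tidy table joined with metadata", {
  m <- toy_counts(30, 6, seed = 4)
  meta <- tibble::tibble(cell = colnames(m), group = rep(c("sham", "injured"), 3))
  st <- score_cells_auc(m, rownames(m)[1:4], meta, seed = 1)
  expect_named(st, c("cell", "auc_score", "group"))
  expect_equal(nrow(st), 6)
  expect_true(all(st$auc_score >= 0 & st$auc_score <= 1))
})

test_that("module score centers on null panels and is shift-invariant per cell", {
  sim <- simulate_cell_population(cell_sim_config(
    n_cells = 300, groups = "sham", high_fraction = c(sham = 0.5),
    fold_elevation = 1, n_genes = 800, panel = sprintf("Gene%04d", 1:40), seed = 2))
  ln <- lognormalize_counts(sim$counts)
  # fold 1: the "panel" is background; score should hover near zero
  ms <- module_score(ln, sim$panel, seed = 1)
  expect_lt(abs(mean(ms)), 0.05)
  # per-cell shift invariance, exact: adding a constant to every gene of a
  # cell cancels in panel-minus-control (bins depend on gene averages, which
  # shift uniformly when every cell is offset)
  offsets <- withr::with_seed(8, runif(ncol(ln), -1, 3))
  shifted <- sweep(ln, 2, offsets, "+")
  ms2 <- module_score(shifted, sim$panel, seed = 1)
  expect_equal(ms2, ms, tolerance = 1e-12)
  expect_error(module_score(ln[1:10, ], sim$panel, n_bins = 24), "Fewer genes")
})

test_that("module score separates planted high-activity cells (2-fold elevation)", {
  sim <- simulate_cell_population(cell_sim_config(
    n_cells = 400, groups = "sham", high_fraction = c(sham = 0.5),
    fold_elevation = 2, seed = 1))
  ln <- lognormalize_counts(sim$counts)
  ms <- module_score(ln, sim$panel, seed = 1)
  truth <- sim$truth$activity[match(names(ms), sim$truth$cell)]
  p <- wilcox.test(ms[truth == "high"], ms[truth == "low"],
                   alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
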