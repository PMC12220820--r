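test_that("read_gmt parses sets, normalizes case, and collapses duplicates", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c(
    "pyroptosis\tsrc\tGsdmd\tCasp1",
    "dup_set\tsrc\tGsdmd\tGSDMD",
    "ferroptosis\tFerrdb\tGPX4\tacsl4\tGpx4"
  ), path)
  sets <- read_gmt(path)
  expect_s3_class(sets, "tbl_df")
  pyro <- dplyr::filter(sets, set == "pyroptosis")
  expect_setequal(pyro$gene, c("Gsdmd", "Casp1"))
  expect_equal(dplyr::filter(sets, set == "dup_set")$gene, "Gsdmd")
  expect_setequal(dplyr::filter(sets, set == "ferroptosis")$gene, c("Gpx4", "Acsl4"))
})

test_that("read_gmt rejects malformed and empty files with informative errors", {
  bad <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("ok\tsrc\tGsdmd", "broken\tonly_two_fields"), bad)
  expect_error(read_gmt(bad), "line 2")
  empty <- withr::local_tempfile(fileext = ".gmt")
  writeLines(character(), empty)
  expect_error(read_gmt(empty), "empty")
  expect_error(read_gmt(file.path(tempdir(), "nope.gmt")), "not found")
})

test_that("gmt round-trips through write_gmt", {
  sets <- tibble::tibble(set = c("a", "a", "b", "b", "b"), source = "s",
                         gene = c("G1", "G2", "G2", "G3", "G4"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_equal(nrow(back), 5)
  expect_setequal(dplyr::filter(back, set == "b")$gene, c("G2", "G3", "G4"))
})

test_that("build_catalog unions genes and records multi-membership", {
  sets <- tibble::tibble(set = c("A", "A", "B", "B"), source = "demo",
                         gene = c("g1", "g2", "g2", "g3"))
  cat1 <- build_catalog(sets)
  expect_equal(nrow(cat1), 3)
  expect_equal(cat1$n_types[cat1$gene == "G2"], 2L)
  # single set: catalog is that set
  one <- build_catalog(tibble::tibble(set = "A", source = "s", gene = c("g1", "g2")))
  expect_setequal(one$gene, c("G1", "G2"))
  expect_true(all(one$n_types == 1))
  expect_error(build_catalog(tibble::tibble(set = character(), gene = character())),
               "empty")
})

test_that("build_catalog is order-invariant and idempotent through catalog_as_sets", {
  withr::with_seed(42, {
    sets <- tibble::tibble(
      set = sample(LETTERS[1:4], 60, replace = TRUE),
      source = "s",
      gene = sample(sprintf("g%02d", 1:25), 60, replace = TRUE)
    )
  })
  cat1 <- build_catalog(sets)
  cat2 <- build_catalog(sets[sample(nrow(sets)), ])
  expect_equal(cat1$gene, cat2$gene)
  expect_equal(cat1$types, cat2$types)
  # idempotence: rebuilding from the long form reproduces the catalog
  cat3 <- build_catalog(catalog_as_sets(cat1))
  expect_equal(cat3$gene, cat1$gene)
  expect_equal(cat3$types, cat1$types)
  # union size <= sum of set sizes, equality iff pairwise disjoint
  per_set <- dplyr::n_distinct(paste(sets$set, normalize_symbols(sets$gene)))
  expect_lte(nrow(cat1), per_set)
})

test_that("catalog_summary counts types, union, and multi-membership genes", {
  cat1 <- build_catalog(tibble::tibble(
    set = c("A", "A", "B"), source = "s", gene = c("g1", "g2", "g2")))
  s <- catalog_summary(cat1)
  expect_equal(s$per_type$n_genes[s$per_type$type == "A"], 2)
  expect_equal(s$per_type$n_genes[s$per_type$type == "B"], 1)
  expect_equal(s$n_genes, 2)
  expect_equal(s$n_multi, 1)
  # two disjoint sets of 5
  disj <- build_catalog(tibble::tibble(
    set = rep(c("A", "B"), each = 5), source = "s", gene = sprintf("g%02d", 1:10)))
  sd <- catalog_summary(disj)
  expect_equal(sd$n_genes, 10)
  expect_equal(sd$n_multi, 0)
})

test_that("restrict_to_universe drops absent genes and guards empty overlap", {
  cat1 <- build_catalog(tibble::tibble(set = "A", source = "s", gene = c("g1", "g2")))
  r <- suppressWarnings(restrict_to_universe(cat1, c("g2", "g3")))
  expect_equal(r$gene, "G2")
  expect_equal(attr(r, "dropped"), "G1")
  # superset universe: identity, no drops
  r2 <- restrict_to_universe(cat1, c("g1", "g2", "g3"))
  expect_equal(r2$gene, cat1$gene)
  expect_length(attr(r2, "dropped"), 0)
  expect_error(restrict_to_universe(cat1, c("x1", "x2")), "No catalog gene")
  expect_warning(restrict_to_universe(cat1, "g1"), "absent")
  # summary after restriction never reports a gene outside the universe
  s <- catalog_summary(r)
  expect_true(all(r$gene %in% normalize_symbols(c("g2", "g3"))))
  expect_equal(s$n_genes, nrow(r))
})

test_that("catalog TSV export is readable and faithful", {
  cat1 <- build_catalog(tibble::tibble(
    set = c("A", "B", "B"), source = "s", gene = c("g1", "g1", "g2")))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog_tsv(cat1, path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$gene, c("G1", "G2"))
  expect_equal(back$types[1], "A;B")
})
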