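mk_profile <- function(stats, prefix = "g") {
  setNames(stats, sprintf("%s%03d", prefix, seq_along(stats)))
}

test_that("query signatures split panel genes by logFC sign and reject one-sided input", {
  deg <- tibble::tibble(gene = c("g1", "g2", "g3", "g4"),
                        log_fc = c(2, -1, 0, 3))
  sig <- build_query_signature(deg, c("g1", "g2", "g3"))
  expect_setequal(sig$up, "g1")
  expect_setequal(sig$down, "g2")
  expect_false("g3" %in% names(sig$log_fc)[sig$log_fc != 0])
  expect_error(query_signature(c(a = 1, b = 2)), "correlation")
})

test_that("extremal tag placements give near-maximal, antisymmetric connectivity", {
  n <- 100
  prof <- mk_profile(seq(n, 1))     # descending: g001 ranks first
  sig <- query_signature(setNames(c(1, 1, 1, -1, -1, -1),
                                  c("g001", "g002", "g003", "g098", "g099", "g100")))
  s_top <- ks_connectivity(sig, prof)
  expect_gt(s_top, 0.9)             # -> 1 as n grows; exactly 1 - (2t-1)/(2n)
  expect_equal(s_top, 1 - (2 * 3 - 1) / (2 * n), tolerance = 1e-12)
  s_rev <- ks_connectivity(sig, -prof)
  expect_equal(s_rev, -s_top, tolerance = 1e-12)
})

test_that("same-sign arm scores are nulled by convention", {
  prof <- mk_profile(seq(50, 1))
  # both arms near the top of the ranking
  sig <- query_signature(setNames(c(1, 1, -1, -1), c("g001", "g002", "g003", "g004")))
  expect_equal(ks_connectivity(sig, prof), 0)
})

test_that("KS connectivity equals the exhaustive a/b-loop oracle on random instances", {
  withr::with_seed(13, {
    for (i in 1:100) {
      n <- sample(20:100, 1)
      prof <- mk_profile(rnorm(n))
      t_up <- sample(2:10, 1); t_down <- sample(2:10, 1)
      picks <- sample(names(prof), t_up + t_down)
      sig <- query_signature(setNames(c(rep(1, t_up), rep(-1, t_down)), picks))
      got <- ks_connectivity(sig, prof)
      rk <- rank(-prof, ties.method = "first")
      want <- oracle_ks_connectivity(rk[sig$up], rk[sig$down], n)
      expect_equal(got, want, tolerance = 1e-12)
    }
  })
})

test_that("swapping the up and down arms negates every connectivity score", {
  withr::with_seed(29, {
    for (i in 1:30) {
      n <- sample(30:80, 1)
      prof <- mk_profile(rnorm(n))
      picks <- sample(names(prof), 8)
      sig <- query_signature(setNames(c(rep(1, 4), rep(-1, 4)), picks))
      swapped <- query_signature(setNames(c(rep(-1, 4), rep(1, 4)), picks))
      expect_equal(ks_connectivity(swapped, prof), -ks_connectivity(sig, prof),
                   tolerance = 1e-12)
    }
  })
})

test_that("missing tag genes are dropped with a warning; missing arms error", {
  prof <- mk_profile(seq(20, 1))
  sig <- query_signature(setNames(c(1, 1, -1), c("g001", "zzz", "g020")))
  expect_warning(s <- ks_connectivity(sig, prof), "dropped")
  expect_true(is.finite(s))
  sig2 <- query_signature(setNames(c(1, -1), c("ghostA", "g020")))
  expect_error(suppressWarnings(ks_connectivity(sig2, prof)), "up arm")
})

test_that("scale_scores maps per-sign extremes to +/-100 and preserves signs", {
  expect_equal(unname(scale_scores(c(0.5, -0.25, 0))), c(100, -100, 0))
  expect_equal(unname(scale_scores(c(0.5, 0.25))), c(100, 50))
  expect_equal(unname(scale_scores(-0.3)), -100)
  expect_equal(unname(scale_scores(c(0, 0))), c(0, 0))
  withr::with_seed(3, {
    for (i in 1:20) {
      raw <- rnorm(sample(2:30, 1))
      sc <- scale_scores(raw)
      expect_equal(sign(sc), sign(raw))
      expect_true(all(abs(sc) <= 100 + 1e-12))
      if (any(raw != 0)) expect_equal(max(abs(sc)), 100)
    }
  })
})

test_that("permutation p-values behave at the extremes", {
  prof <- mk_profile(seq(100, 1))
  sig <- query_signature(setNames(c(1, 1, -1, -1), c("g001", "g050", "g051", "g100")))
  # s_obs = 0 -> p = 1 (every |s_pi| >= 0)
  pv0 <- connectivity_pvalue(sig, prof, s_obs = 0, n_perm = 200, seed = 1)
  expect_equal(pv0$p, 1)
  # noiseless planted reverser -> minimum attainable p
  lib <- simulate_perturbation_library(library_sim_config(
    n_reversers = 1, n_mimics = 0, n_inert = 0, noise_sd = 0, seed = 3))
  rsig <- query_signature(lib$signature)
  pv <- connectivity_pvalue(rsig, setNames(lib$profiles[1, ], colnames(lib$profiles)),
                            n_perm = 200, seed = 4)
  expect_equal(pv$p, 1 / 201, tolerance = 1e-12)
  expect_lt(pv$s_obs, -0.9)
  expect_error(connectivity_pvalue(sig, prof, n_perm = 50), ">= 100")
})

test_that("correlation connectivity hits +/-1 on exact mimics and reversers", {
  q <- setNames(rnorm(20), sprintf("g%03d", 1:20))
  sig <- query_signature(q)
  expect_equal(correlation_connectivity(sig, -q, n_perm = 100, seed = 1)$rho, -1)
  expect_equal(correlation_connectivity(sig, q, n_perm = 100, seed = 1)$rho, 1)
  expect_error(correlation_connectivity(sig, q[1:4], n_perm = 100), ">= 5 shared")
})

test_that("consensus retains only compounds negative and significant everywhere", {
  tb <- function(scaled, p) tibble::tibble(compound = c("keep", "drop"),
                                           raw = scaled / 100, scaled = scaled, p = p)
  tables <- list(
    d1 = tb(c(-80, -80), c(0.01, 0.01)),
    d2 = tb(c(-50, 20), c(0.03, 0.40)),
    d3 = tb(c(-60, -60), c(0.02, 0.02))
  )
  cs <- consensus_screen(tables)
  expect_true(cs$retained[cs$compound == "keep"])
  expect_false(cs$retained[cs$compound == "drop"])
  expect_equal(cs$mean_scaled[cs$compound == "keep"], mean(c(-80, -50, -60)))
  expect_error(consensus_screen(tables[1]), ">= 2 datasets")
})

test_that("screening a simulated library recovers planted reversers and rejects mimics", {
  sig_vec <- withr::with_seed(21, setNames(rnorm(68), sprintf("Gene%04d", 1:68)))
  sig <- query_signature(sig_vec)
  tables <- lapply(1:3, function(i) {
    lib <- simulate_perturbation_library(
      library_sim_config(signature = sig_vec, seed = 100 + i))
    screen_library(sig, lib, n_perm = 500, seed = 200 + i)
  })
  names(tables) <- paste0("d", 1:3)
  cs <- consensus_screen(tables)
  retained <- cs$compound[cs$retained]
  expect_length(grep("^cpd_reverser", retained), 5)
  expect_length(grep("^cpd_mimic", retained), 0)
  expect_lte(length(grep("^cpd_inert", retained)), 1)
  # retained reversers rank ahead of everything else
  expect_true(all(cs$mean_scaled[cs$retained] < 0))
})
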