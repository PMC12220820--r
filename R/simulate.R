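# Synthetic-data generators with planted ground truth. Each generator is a
# pure function of its config: the same config (including seed) reproduces
# the output exactly, and the truth labels have the exact cardinalities the
# config requests.

#' Configuration for the bulk injury time-course simulator
#'
#' Defaults emulate a multi-model injury study: log2 expression with
#' baseline means Uniform(2, 10), an additive injury effect on responder
#' genes during the acute phase, a core responder set shared by all injury
#' models plus model-specific responders, and an age-dependent attenuation
#' profile (persistent in the adult-like arm, attenuating across 1/3/7 dpi
#' in the neonatal-like arm).
#'
#' @param n_genes Total genes.
#' @param n_catalog_genes Genes belonging to the simulated pan-PCD catalog
#'   (the first `n_catalog_genes` gene ids).
#' @param n_core_responders Catalog genes responding in every model.
#' @param n_model_specific_responders Catalog genes responding in exactly
#'   one model (per model).
#' @param n_noncatalog_responders Injury-responsive genes outside the
#'   catalog (distractors for the catalog intersection step).
#' @param models,timepoints Injury model and acute time-point labels.
#' @param n_reps Replicates per (model, time point) arm, sham included.
#' @param effect_size Injury effect in log2 units (default 2.0).
#' @param attenuation Named list age -> per-time-point multiplier on
#'   `effect_size` (defaults: adult persistent `c(1,1,1)`, neonatal
#'   attenuating `c(1, 0.4, 0.1)`).
#' @param ages Ages to simulate (subset of `names(attenuation)`).
#' @param noise_sd Gaussian noise sd in log2 units (default 0.2).
#' @param seed Integer seed.
#' @return A validated `bulk_sim_config` list.
#' @export
bulk_sim_config <- function(n_genes = 1000, n_catalog_genes = 200,
                            n_core_responders = 30,
                            n_model_specific_responders = 10,
                            n_noncatalog_responders = 0,
                            models = c("crush", "contusion", "hemisection"),
                            timepoints = c("1dpi", "3dpi", "7dpi"),
                            n_reps = 4, effect_size = 2.0,
                            attenuation = list(adult = c(1, 1, 1),
                                               neonatal = c(1, 0.4, 0.1)),
                            ages = "adult", noise_sd = 0.2, seed = 1L) {
  cfg <- list(n_genes = n_genes, n_catalog_genes = n_catalog_genes,
              n_core_responders = n_core_responders,
              n_model_specific_responders = n_model_specific_responders,
              n_noncatalog_responders = n_noncatalog_responders,
              models = models, timepoints = timepoints, n_reps = n_reps,
              effect_size = effect_size, attenuation = attenuation,
              ages = ages, noise_sd = noise_sd, seed = seed)
  if (!(n_core_responders <= n_catalog_genes && n_catalog_genes <= n_genes)) {
    abort("Need n_core_responders <= n_catalog_genes <= n_genes.")
  }
  needed <- n_core_responders + length(models) * n_model_specific_responders
  if (needed > n_catalog_genes) abort("Not enough catalog genes for the requested responders.")
  if (n_noncatalog_responders > n_genes - n_catalog_genes) {
    abort("Not enough non-catalog genes for `n_noncatalog_responders`.")
  }
  if (effect_size < 0) abort("`effect_size` must be >= 0.")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0.")
  if (!all(ages %in% names(attenuation))) abort("Every age needs an attenuation profile.")
  if (any(lengths(attenuation[ages]) != length(timepoints))) {
    abort("Each attenuation profile must have one multiplier per time point.")
  }
  structure(cfg, class = "bulk_sim_config")
}

#' Simulate a bulk injury time course across models
#'
#' @param config A [bulk_sim_config()].
#' @return A list with `expression` (named list model -> genes-by-samples
#'   log2 matrix covering all ages), `sample_meta` (tibble: `sample`,
#'   `model`, `timepoint`, `group`, `age`), `catalog` (a `pcd_catalog` over
#'   the simulated catalog genes), and `truth` (planted core,
#'   model-specific, non-catalog responder ids and the per-model responder
#'   sets).
#' @export
simulate_bulk_timecourse <- function(config = bulk_sim_config()) {
  stopifnot(inherits(config, "bulk_sim_config"))
  cfg <- config
  genes <- sprintf("Gene%04d", seq_len(cfg$n_genes))
  catalog_genes <- genes[seq_len(cfg$n_catalog_genes)]
  core <- catalog_genes[seq_len(cfg$n_core_responders)]
  specific <- list()
  offset <- cfg$n_core_responders
  for (m in cfg$models) {
    idx <- offset + seq_len(cfg$n_model_specific_responders)
    specific[[m]] <- if (cfg$n_model_specific_responders > 0) catalog_genes[idx] else character()
    offset <- offset + cfg$n_model_specific_responders
  }
  noncatalog <- if (cfg$n_noncatalog_responders > 0) {
    genes[cfg$n_catalog_genes + seq_len(cfg$n_noncatalog_responders)]
  } else character()

  with_seed(cfg$seed, {
    baseline <- runif(cfg$n_genes, 2, 10)
    names(baseline) <- genes
    expression <- list()
    meta <- list()
    for (m in cfg$models) {
      responders <- c(core, specific[[m]], noncatalog)
      mats <- list()
      for (age in cfg$ages) {
        attn <- setNames(cfg$attenuation[[age]], cfg$timepoints)
        for (tp in c("sham", cfg$timepoints)) {
          eff <- if (tp == "sham") 0 else cfg$effect_size * attn[[tp]]
          for (r in seq_len(cfg$n_reps)) {
            id <- sprintf("%s_%s_%s_r%d", m, age, tp, r)
            mu <- baseline
            mu[responders] <- mu[responders] + eff
            mats[[id]] <- mu + rnorm(cfg$n_genes, 0, cfg$noise_sd)
            meta[[id]] <- tibble(sample = id, model = m, timepoint = tp,
                                 group = if (tp == "sham") "sham" else "injured",
                                 age = age)
          }
        }
      }
      expression[[m]] <- do.call(cbind, mats)
      rownames(expression[[m]]) <- genes
    }
  })
  sets <- tibble(
    set = rep(paste0("pcd_type_", ((seq_along(catalog_genes) - 1) %% 3) + 1),
              times = 1),
    source = "simulated",
    gene = catalog_genes
  )
  list(
    expression = expression,
    sample_meta = bind_rows(meta),
    catalog = build_catalog(sets),
    truth = list(core = core, model_specific = specific, noncatalog = noncatalog,
                 responders_by_model = purrr::map(cfg$models, ~ c(core, specific[[.x]], noncatalog)) |>
                   setNames(cfg$models)),
    config = cfg
  )
}

#' Configuration for the single-cell population simulator
#'
#' Negative-binomial UMI counts with a latent high/low panel-activity label
#' per cell: panel-gene relative abundances are multiplied by
#' `fold_elevation` in high-activity cells, and the prevalence of high cells
#' differs by condition (defaults 0.2 sham vs 0.6 injured, echoing the
#' sham-to-injury shift in high-scoring cells seen in injured cord).
#'
#' @param n_cells Cells per (cell_type x group x age) arm (default 2000).
#' @param cell_types,groups,ages Arm labels.
#' @param n_genes Gene universe size (default 2000).
#' @param panel Character vector of panel gene ids (must be within the
#'   simulated universe); default `NULL` plants genes `Gene0001..Gene0068`.
#' @param high_fraction Named numeric vector (by group) or tibble with
#'   columns `group`, `age`, `high_fraction`.
#' @param fold_elevation Abundance multiplier of panel genes in high cells
#'   (default 3).
#' @param nb_dispersion Negative-binomial dispersion (1/size; default 0.5).
#' @param library_size_lognorm `c(meanlog, sdlog)` of the per-cell library
#'   size (default `c(log(5000), 0.3)`).
#' @param seed Integer seed.
#' @return A validated `cell_sim_config` list.
#' @export
cell_sim_config <- function(n_cells = 2000, cell_types = "microglia",
                            groups = c("sham", "injured"), ages = "adult",
                            n_genes = 2000, panel = NULL,
                            high_fraction = c(sham = 0.2, injured = 0.6),
                            fold_elevation = 3, nb_dispersion = 0.5,
                            library_size_lognorm = c(log(5000), 0.3),
                            seed = 1L) {
  if (is.null(panel)) panel <- sprintf("Gene%04d", 1:68)
  cfg <- list(n_cells = n_cells, cell_types = cell_types, groups = groups,
              ages = ages, n_genes = n_genes, panel = unique(panel),
              high_fraction = high_fraction, fold_elevation = fold_elevation,
              nb_dispersion = nb_dispersion,
              library_size_lognorm = library_size_lognorm, seed = seed)
  if (is.numeric(high_fraction)) {
    if (!all(groups %in% names(high_fraction))) {
      abort("`high_fraction` must name every group.")
    }
    hf <- high_fraction
  } else {
    stopifnot(is.data.frame(high_fraction),
              all(c("group", "age", "high_fraction") %in% names(high_fraction)))
    hf <- high_fraction$high_fraction
  }
  if (any(hf < 0 | hf > 1)) abort("`high_fraction` values must be in [0, 1].")
  if (fold_elevation < 1) abort("`fold_elevation` must be >= 1.")
  if (nb_dispersion <= 0) abort("`nb_dispersion` must be > 0.")
  if (n_cells < 1) abort("`n_cells` must be >= 1.")
  structure(cfg, class = "cell_sim_config")
}

lookup_high_fraction <- function(cfg, group, age) {
  hf <- cfg$high_fraction
  if (is.numeric(hf)) return(unname(hf[[group]]))
  row <- filter(hf, .data$group == !!group, .data$age == !!age)
  if (nrow(row) == 0) abort(sprintf("No high_fraction for group '%s', age '%s'.", group, age))
  row$high_fraction[1]
}

#' Simulate a single-cell population with planted activity labels
#'
#' Per cell: library size ~ LogNormal, gene relative abundances from a
#' fixed skewed baseline (log-normal abundance weights; panel genes are
#' assigned mid-to-upper abundance so that elevation is visible to a
#' rank-based scorer), panel abundances multiplied by `fold_elevation` in
#' high-activity cells, and counts drawn negative-binomially with shared
#' dispersion.
#'
#' @param config A [cell_sim_config()].
#' @return A list with `counts` (genes-by-cells integer matrix),
#'   `cell_meta` (tibble: `cell`, `cell_type`, `group`, `age`), `truth`
#'   (tibble: `cell`, `activity` in `"high"`/`"low"`), `panel`, `config`.
#' @export
simulate_cell_population <- function(config = cell_sim_config()) {
  stopifnot(inherits(config, "cell_sim_config"))
  cfg <- config
  genes <- sprintf("Gene%04d", seq_len(cfg$n_genes))
  missing_panel <- setdiff(cfg$panel, genes)
  if (length(missing_panel) > 0) {
    abort(sprintf("%d panel gene(s) outside the simulated universe.", length(missing_panel)))
  }
  with_seed(cfg$seed, {
    abundance <- rlnorm(cfg$n_genes, 0, 1.5)
    names(abundance) <- genes
    # plant panel genes at mid-to-upper abundance quantiles
    abundance[cfg$panel] <- quantile(abundance, runif(length(cfg$panel), 0.55, 0.90))
    p_low <- abundance / sum(abundance)
    ab_high <- abundance
    ab_high[cfg$panel] <- ab_high[cfg$panel] * cfg$fold_elevation
    p_high <- ab_high / sum(ab_high)

    arms <- tidyr::expand_grid(cell_type = cfg$cell_types, group = cfg$groups,
                               age = cfg$ages)
    counts_blocks <- list()
    meta_blocks <- list()
    truth_blocks <- list()
    for (i in seq_len(nrow(arms))) {
      ct <- arms$cell_type[i]; gr <- arms$group[i]; ag <- arms$age[i]
      hf <- lookup_high_fraction(cfg, gr, ag)
      n_high <- round(hf * cfg$n_cells)
      activity <- rep(c("high", "low"), c(n_high, cfg$n_cells - n_high))
      activity <- sample(activity)
      cells <- sprintf("%s_%s_%s_c%04d", ct, gr, ag, seq_len(cfg$n_cells))
      lib <- rlnorm(cfg$n_cells, cfg$library_size_lognorm[1], cfg$library_size_lognorm[2])
      block <- vapply(seq_len(cfg$n_cells), function(j) {
        p <- if (activity[j] == "high") p_high else p_low
        rnbinom(cfg$n_genes, mu = lib[j] * p, size = 1 / cfg$nb_dispersion)
      }, numeric(cfg$n_genes))
      dimnames(block) <- list(genes, cells)
      counts_blocks[[i]] <- block
      meta_blocks[[i]] <- tibble(cell = cells, cell_type = ct, group = gr, age = ag)
      truth_blocks[[i]] <- tibble(cell = cells, activity = activity)
    }
  })
  list(
    counts = do.call(cbind, counts_blocks),
    cell_meta = bind_rows(meta_blocks),
    truth = bind_rows(truth_blocks),
    panel = cfg$panel,
    config = cfg
  )
}

#' Simulate per-cell score tables with planted group shifts
#'
#' Direct generator of activity-score tables for exercising the slope
#' statistics: scores are Gaussian around `baseline`, with `shift` added in
#' the contrast group, truncated to \[0, 1\].
#'
#' @param n_per_arm Cells per group (default 2000).
#' @param shift Planted score shift of the contrast group vs baseline group.
#' @param baseline Baseline mean score (default 0.10).
#' @param sd Score noise sd (default 0.05).
#' @param groups Two labels: baseline then contrast.
#' @param cell_type Cell-type label for all cells.
#' @param seed Integer seed.
#' @return A score table tibble: `cell`, `cell_type`, `group`, `auc_score`.
#' @export
simulate_score_shift <- function(n_per_arm = 2000, shift = 0.16, baseline = 0.10,
                                 sd = 0.05, groups = c("sham", "injured"),
                                 cell_type = "microglia", seed = 1L) {
  stopifnot(length(groups) == 2, sd > 0, n_per_arm >= 2)
  with_seed(seed, {
    scores <- c(rnorm(n_per_arm, baseline, sd), rnorm(n_per_arm, baseline + shift, sd))
  })
  scores <- pmin(pmax(scores, 0), 1)
  tibble(
    cell = sprintf("%s_c%05d", rep(groups, each = n_per_arm), seq_along(scores)),
    cell_type = cell_type,
    group = rep(groups, each = n_per_arm),
    auc_score = scores
  )
}

#' Configuration for the perturbation-library simulator
#'
#' @param signature Named numeric query vector (gene -> logFC-like
#'   statistic); default `NULL` draws a standard-normal signature over 68
#'   genes `Gene0001..Gene0068`.
#' @param n_genes Total library gene universe (signature genes included;
#'   default 1000).
#' @param n_reversers,n_mimics,n_inert Compound class counts (defaults
#'   5/2/43).
#' @param gain Signature gain `gamma` (> 0, default 1): reversers carry
#'   `-gain * signature`, mimics `+gain * signature`.
#' @param noise_sd Gaussian noise sd on every entry (default 0.5).
#' @param seed Integer seed.
#' @return A validated `library_sim_config` list.
#' @export
library_sim_config <- function(signature = NULL, n_genes = 1000,
                               n_reversers = 5, n_mimics = 2, n_inert = 43,
                               gain = 1, noise_sd = 0.5, seed = 1L) {
  if (is.null(signature)) {
    signature <- with_seed(941, setNames(rnorm(68), sprintf("Gene%04d", 1:68)))
  }
  stopifnot(is.numeric(signature), !is.null(names(signature)))
  if (any(c(n_reversers, n_mimics, n_inert) < 0)) abort("Compound counts must be >= 0.")
  if (gain <= 0) abort("`gain` must be > 0.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (n_genes < length(signature)) abort("`n_genes` must cover the signature genes.")
  structure(list(signature = signature, n_genes = n_genes,
                 n_reversers = n_reversers, n_mimics = n_mimics,
                 n_inert = n_inert, gain = gain, noise_sd = noise_sd,
                 seed = seed),
            class = "library_sim_config")
}

#' Simulate a perturbation-profile library with planted reversers
#'
#' Reverser profiles equal `-gain * signature` plus noise on the signature
#' genes, mimics `+gain * signature` plus noise, inert compounds pure noise;
#' non-signature genes are noise everywhere.
#'
#' @param config A [library_sim_config()].
#' @return A list with `profiles` (compounds-by-genes matrix),
#'   `compound_meta` (tibble: `compound`, `class`), `signature` (the query
#'   vector), `config`.
#' @export
simulate_perturbation_library <- function(config = library_sim_config()) {
  stopifnot(inherits(config, "library_sim_config"))
  cfg <- config
  sig_genes <- names(cfg$signature)
  extra <- setdiff(sprintf("Gene%04d", seq_len(cfg$n_genes + length(sig_genes))), sig_genes)
  genes <- c(sig_genes, extra[seq_len(cfg$n_genes - length(sig_genes))])
  classes <- rep(c("reverser", "mimic", "inert"),
                 c(cfg$n_reversers, cfg$n_mimics, cfg$n_inert))
  compounds <- sprintf("cpd_%s_%02d", classes, unlist(lapply(
    c(cfg$n_reversers, cfg$n_mimics, cfg$n_inert), seq_len)))
  with_seed(cfg$seed, {
    profiles <- matrix(rnorm(length(compounds) * length(genes), 0, cfg$noise_sd),
                       nrow = length(compounds),
                       dimnames = list(compounds, genes))
    sign_mult <- c(reverser = -1, mimic = 1, inert = 0)
    for (i in seq_along(compounds)) {
      mult <- sign_mult[[classes[i]]]
      if (mult != 0) {
        profiles[i, sig_genes] <- profiles[i, sig_genes] + mult * cfg$gain * cfg$signature
      }
    }
  })
  list(
    profiles = profiles,
    compound_meta = tibble(compound = compounds, class = classes),
    signature = cfg$signature,
    config = cfg
  )
}
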