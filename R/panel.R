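#' Injury-responsive catalog genes across acute time points
#'
#' Takes per-time-point differential-expression tables for one injury model
#' (typically 1, 3 and 7 days post-injury vs sham), calls DEGs at the strict
#' thresholds, unions them across time points, and intersects the pooled DEG
#' set with the pan-PCD catalog. The union captures genes active at any
#' acute phase; each retained gene carries the time points at which it
#' passed as provenance.
#'
#' @param deg_by_timepoint Named list of DEG tibbles (one per time point)
#'   from [moderated_t_test()].
#' @param catalog A `pcd_catalog` tibble ([build_catalog()]).
#' @param fc_threshold,p_threshold Thresholds forwarded to [call_degs()].
#' @param combine `"union"` (default) pools DEGs across time points;
#'   `"intersection"` requires a gene at every time point.
#' @return A tibble with columns `gene`, `timepoints` (semicolon-joined
#'   provenance).
#' @export
injury_responsive_set <- function(deg_by_timepoint, catalog,
                                  fc_threshold = 1.5, p_threshold = 0.05,
                                  combine = c("union", "intersection")) {
  combine <- match.arg(combine)
  stopifnot(is.list(deg_by_timepoint), length(deg_by_timepoint) >= 1)
  if (is.null(names(deg_by_timepoint))) {
    names(deg_by_timepoint) <- paste0("t", seq_along(deg_by_timepoint))
  }
  check_catalog(catalog)
  tested <- unique(unlist(purrr::map(deg_by_timepoint, "gene")))
  if (length(intersect(tested, catalog$gene)) == 0) {
    abort("The DEG tables and the catalog share no genes; check symbol conventions.")
  }
  hits <- purrr::imap(deg_by_timepoint, function(deg, tp) {
    tibble(gene = call_degs(deg, fc_threshold, p_threshold)$gene, timepoint = tp)
  }) |> bind_rows()
  if (nrow(hits) == 0) {
    return(tibble(gene = character(), timepoints = character()))
  }
  prov <- hits |>
    group_by(.data$gene) |>
    summarise(timepoints = paste(unique(.data$timepoint), collapse = ";"),
              n_timepoints = dplyr::n_distinct(.data$timepoint), .groups = "drop")
  if (combine == "intersection") {
    prov <- filter(prov, .data$n_timepoints == length(deg_by_timepoint))
  }
  prov |>
    filter(.data$gene %in% catalog$gene) |>
    select("gene", "timepoints") |>
    arrange(.data$gene)
}

#' Cross-model Wilcoxon rank-sum refinement
#'
#' Refines a candidate gene set against an independent injury model: each
#' candidate present on the platform is tested with a two-sided Wilcoxon
#' rank-sum test of injured vs sham expression, and retained when
#' `p < alpha` (unadjusted, by design: this is a per-gene replication filter,
#' not a discovery scan). The exact null distribution is used when both
#' groups have at most 10 samples and the values are tie-free; otherwise the
#' normal approximation with continuity and tie correction applies.
#' Candidates missing from the matrix are reported as untested, not
#' retained.
#'
#' @param candidates Character vector of gene symbols to test.
#' @param expr Genes-by-samples log2 expression matrix for a single injury
#'   model (or data frame with gene column first).
#' @param injured,sham Column selectors for the two sample groups.
#' @param alpha Retention threshold on the two-sided p-value (default 0.05).
#' @return A tibble with columns `gene`, `p`, `retained`; genes absent from
#'   the platform are listed in the `"not_tested"` attribute.
#' @export
ranksum_filter <- function(candidates, expr, injured, sham, alpha = 0.05) {
  expr <- check_expr_matrix(expr)
  injured <- resolve_samples(expr, injured, "injured")
  sham <- resolve_samples(expr, sham, "sham")
  if (length(injured) < 2 || length(sham) < 2) {
    abort("Need at least 2 injured and 2 sham samples for the rank-sum test.")
  }
  candidates <- unique(normalize_symbols(as.character(candidates)))
  idx <- match(candidates, normalize_symbols(rownames(expr)))
  present <- candidates[!is.na(idx)]
  rows <- rownames(expr)[idx[!is.na(idx)]]
  not_tested <- candidates[is.na(idx)]
  p <- purrr::map_dbl(rows, function(g) {
    x <- expr[g, injured]
    y <- expr[g, sham]
    exact <- length(x) <= 10 && length(y) <= 10 && !anyDuplicated(c(x, y))
    suppressWarnings(wilcox.test(x, y, alternative = "two.sided", exact = exact)$p.value)
  })
  out <- tibble(gene = present, p = p, retained = p < alpha) |> arrange(.data$gene)
  attr(out, "not_tested") <- sort(not_tested)
  out
}

#' Derive the core injury-specific panel
#'
#' Intersects per-model retained gene sets: the core panel is the set of
#' catalog genes that replicate across every injury model considered, so
#' adding a model can only shrink it. PCD-type annotations are copied from
#' the catalog and gene order is alphabetical for determinism.
#'
#' @param per_model_sets Named list (>= 2 models) of character gene vectors,
#'   or of tibbles with a `gene` column (e.g. [injury_responsive_set()] /
#'   filtered [ranksum_filter()] output).
#' @param catalog A `pcd_catalog` tibble used for annotations.
#' @return A tibble of class `pcd_panel` with columns `gene`, `types`
#'   (list-column), `provenance` (semicolon-joined model names).
#' @export
derive_panel <- function(per_model_sets, catalog) {
  stopifnot(is.list(per_model_sets))
  if (length(per_model_sets) < 2) abort("Panel derivation needs at least 2 injury models.")
  if (is.null(names(per_model_sets))) {
    names(per_model_sets) <- paste0("model", seq_along(per_model_sets))
  }
  check_catalog(catalog)
  sets <- purrr::map(per_model_sets, function(s) {
    if (is.data.frame(s)) s <- s$gene
    unique(normalize_symbols(as.character(s)))
  })
  core <- Reduce(intersect, sets)
  if (length(core) == 0) {
    sizes <- paste(sprintf("%s=%d", names(sets), lengths(sets)), collapse = ", ")
    abort(sprintf("The per-model sets have an empty intersection (%s).", sizes))
  }
  core <- sort(core)
  ann <- setNames(catalog$types, catalog$gene)
  out <- tibble(
    gene = core,
    types = purrr::map(core, ~ ann[[.x]] %||% character()),
    provenance = paste(names(sets), collapse = ";")
  )
  class(out) <- c("pcd_panel", class(out))
  out
}

#' Write a panel to TSV
#'
#' Columns: `gene`, `types` (semicolon-joined), `provenance`.
#' @param panel A `pcd_panel` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(is.data.frame(panel), "gene" %in% names(panel))
  flat <- tibble(
    gene = panel$gene,
    types = purrr::map_chr(panel$types %||% rep(list(character()), nrow(panel)),
                           paste, collapse = ";"),
    provenance = panel$provenance %||% NA_character_
  )
  readr::write_tsv(flat, path)
  invisible(path)
}

# Accept a panel object, tibble with `gene`, or bare character vector.
panel_genes <- function(panel) {
  g <- if (is.data.frame(panel)) panel$gene else panel
  unique(normalize_symbols(as.character(g)))
}

# Case-insensitive match of panel genes against a measured universe; returns
# the universe's own spelling so downstream indexing works.
match_genes <- function(genes, universe) {
  universe[tolower(universe) %in% tolower(genes)]
}
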