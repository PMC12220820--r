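#' Build a pan-PCD catalog from gene sets
#'
#' Merges a collection of programmed-cell-death pathway gene sets into a
#' single catalog mapping each gene to the full set of PCD types it belongs
#' to. Pathway sets overlap (a caspase can sit in both apoptosis and
#' pyroptosis), so the catalog keeps complete multi-membership rather than a
#' primary type. The result is deterministic regardless of input row order:
#' genes are sorted alphabetically and type memberships follow the sorted
#' type names.
#'
#' @param sets A tibble with columns `set`, `gene` (and optionally `source`),
#'   e.g. from [read_gmt()].
#' @return A tibble of class `pcd_catalog` with columns `gene`, `types`
#'   (list-column of PCD-type names), `n_types`. The per-type source tags are
#'   stored in the `"type_sources"` attribute (named character vector).
#' @examples
#' sets <- tibble::tibble(
#'   set = c("A", "A", "B", "B"), source = "demo",
#'   gene = c("g1", "g2", "g2", "g3")
#' )
#' build_catalog(sets)
#' @export
build_catalog <- function(sets) {
  stopifnot(is.data.frame(sets))
  if (!all(c("set", "gene") %in% names(sets))) {
    abort("`sets` must have columns `set` and `gene`.")
  }
  sets <- filter(sets, nzchar(.data$gene))
  if (nrow(sets) == 0) abort("Cannot build a catalog from empty gene sets.")
  sets <- mutate(sets, gene = normalize_symbols(.data$gene))
  cat_tbl <- sets |>
    distinct(.data$gene, .data$set) |>
    arrange(.data$gene, .data$set) |>
    group_by(.data$gene) |>
    summarise(types = list(unique(.data$set)), .groups = "drop") |>
    mutate(n_types = lengths(.data$types)) |>
    arrange(.data$gene)
  if ("source" %in% names(sets)) {
    src <- sets |>
      distinct(.data$set, .data$source) |>
      group_by(.data$set) |>
      summarise(source = paste(unique(.data$source), collapse = ";"), .groups = "drop")
    sources <- setNames(src$source, src$set)
  } else {
    sources <- setNames(rep("unknown", length(unique(sets$set))), sort(unique(sets$set)))
  }
  attr(cat_tbl, "type_sources") <- sources[sort(names(sources))]
  class(cat_tbl) <- c("pcd_catalog", class(cat_tbl))
  cat_tbl
}

#' Convert a catalog back to long gene-set form
#'
#' @param catalog A `pcd_catalog` tibble.
#' @return A tibble with columns `set`, `source`, `gene` (one row per
#'   membership), suitable for [build_catalog()] or [write_gmt()].
#' @export
catalog_as_sets <- function(catalog) {
  check_catalog(catalog)
  sources <- attr(catalog, "type_sources") %||% character()
  out <- catalog |>
    select("gene", "types") |>
    tidyr::unnest_longer("types", values_to = "set") |>
    mutate(source = unname(sources[.data$set]) %||% NA_character_) |>
    select("set", "source", "gene") |>
    arrange(.data$set, .data$gene)
  out$source[is.na(out$source)] <- "unknown"
  out
}

#' Summarise a pan-PCD catalog
#'
#' @param catalog A `pcd_catalog` tibble.
#' @return A list with `per_type` (tibble: `type`, `n_genes`), `n_genes`
#'   (union size), `n_types`, and `n_multi` (genes belonging to more than one
#'   PCD type).
#' @export
catalog_summary <- function(catalog) {
  check_catalog(catalog)
  long <- catalog |>
    select("gene", "types") |>
    tidyr::unnest_longer("types", values_to = "type")
  per_type <- long |>
    count(.data$type, name = "n_genes") |>
    arrange(.data$type)
  list(
    per_type = per_type,
    n_genes = nrow(catalog),
    n_types = length(unique(long$type)),
    n_multi = sum(catalog$n_types > 1)
  )
}

#' Restrict a catalog to a measured gene universe
#'
#' Drops catalog genes absent from the expression platform at hand; scoring a
#' cell for genes that were never measured is undefined. A warning is raised
#' when more than 10% of the catalog is lost, and an error when nothing
#' remains.
#'
#' @param catalog A `pcd_catalog` tibble.
#' @param universe Character vector of measured gene symbols (matched after
#'   case normalization).
#' @return The restricted catalog, with the dropped symbols in the
#'   `"dropped"` attribute.
#' @export
restrict_to_universe <- function(catalog, universe) {
  check_catalog(catalog)
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  universe <- normalize_symbols(as.character(universe))
  keep <- catalog$gene %in% universe
  if (!any(keep)) {
    abort("No catalog gene is present in the universe; scoring would be undefined.")
  }
  dropped <- catalog$gene[!keep]
  if (length(dropped) > 0.10 * nrow(catalog)) {
    warn(sprintf("%d of %d catalog genes (%.1f%%) are absent from the universe.",
                 length(dropped), nrow(catalog), 100 * length(dropped) / nrow(catalog)))
  }
  out <- catalog[keep, , drop = FALSE]
  attr(out, "type_sources") <- attr(catalog, "type_sources")
  attr(out, "dropped") <- dropped
  class(out) <- c("pcd_catalog", setdiff(class(out), "pcd_catalog"))
  out
}

#' Write a catalog to TSV
#'
#' Columns: `gene`, `types` (semicolon-joined), `n_types`.
#' @param catalog A `pcd_catalog` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog_tsv <- function(catalog, path) {
  check_catalog(catalog)
  flat <- catalog |>
    mutate(types = purrr::map_chr(.data$types, paste, collapse = ";")) |>
    select("gene", "types", "n_types")
  readr::write_tsv(flat, path)
  invisible(path)
}

check_catalog <- function(catalog) {
  if (!is.data.frame(catalog) || !all(c("gene", "types") %in% names(catalog))) {
    abort("Expected a `pcd_catalog` tibble with columns `gene` and `types`.")
  }
  if (anyDuplicated(catalog$gene)) abort("Catalog gene ids must be unique.")
  invisible(catalog)
}

#' Packaged synthetic pan-PCD catalog
#'
#' Loads the catalog fixture shipped with the package: a constructed
#' stand-in, anchored on canonical programmed-cell-death genes and padded
#' with synthetic symbols, sized to the published pan-PCD curation (963
#' unique genes across 13 PCD pathway types). It is labelled synthetic
#' because the original supplementary membership table is not redistributed
#' here; use it for examples and pipeline tests, not biology.
#'
#' @return A `pcd_catalog` tibble (see [build_catalog()]).
#' @export
pcd_catalog_fixture <- function() {
  path <- system.file("extdata", "pan_pcd_catalog_synthetic.gmt", package = "panpcd")
  build_catalog(read_gmt(path))
}

#' Packaged synthetic core pan-PCD panel
#'
#' Loads the 68-gene core panel fixture (a synthetic stand-in for the
#' published injury-specific panel) with its PCD-type annotations drawn from
#' the packaged catalog. The panel spans 7 PCD types.
#'
#' @return A tibble with columns `gene`, `types` (list-column), of class
#'   `pcd_panel`.
#' @export
pcd_panel_fixture <- function() {
  path <- system.file("extdata", "pan_pcd_panel_synthetic.tsv", package = "panpcd")
  flat <- readr::read_tsv(path, show_col_types = FALSE)
  out <- flat |>
    mutate(types = strsplit(.data$types, ";", fixed = TRUE)) |>
    select("gene", "types")
  class(out) <- c("pcd_panel", class(out))
  out
}
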