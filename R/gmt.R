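#' Read a GMT gene-set collection
#'
#' Parses the tab-separated GMT format (one set per line: name, description,
#' then gene symbols) into a long tibble with one row per (set, gene) pair.
#' Gene symbols are normalized to mouse title-case and de-duplicated within
#' each set; the description field is kept as a source/provenance tag.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set`, `source`, `gene`, of class
#'   `pcd_gene_sets`.
#' @seealso [write_gmt()], [build_catalog()]
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("GMT file is empty: %s", path))
  rows <- purrr::imap(lines, function(line, i) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    if (length(fields) < 3) {
      abort(sprintf("Malformed GMT line %d in %s: expected >= 3 tab-separated fields, got %d.",
                    i, path, length(fields)))
    }
    name <- fields[1]
    if (!nzchar(name)) abort(sprintf("Malformed GMT line %d in %s: empty set name.", i, path))
    genes <- unique(normalize_symbols(fields[-(1:2)][nzchar(fields[-(1:2)])]))
    tibble(set = name, source = fields[2], gene = genes)
  })
  out <- bind_rows(rows)
  class(out) <- c("pcd_gene_sets", class(out))
  out
}

#' Write gene sets to a GMT file
#'
#' @param sets A tibble with columns `set`, `source` (optional), `gene`, as
#'   returned by [read_gmt()], or any data frame with those columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.data.frame(sets), all(c("set", "gene") %in% names(sets)))
  if (!"source" %in% names(sets)) sets$source <- "na"
  lines <- sets |>
    group_by(.data$set) |>
    summarise(source = .data$source[1],
              genes = paste(unique(.data$gene), collapse = "\t"),
              .groups = "drop") |>
    mutate(line = paste(.data$set, .data$source, .data$genes, sep = "\t")) |>
    pull(.data$line)
  writeLines(lines, path)
  invisible(path)
}
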