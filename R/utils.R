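# Internal helpers shared across the package.

#' Normalize gene symbols to mouse title-case
#'
#' Gene symbols are matched case-insensitively throughout the package and
#' stored in the mouse convention: first letter upper-case, remainder
#' lower-case (`GSDMD` and `gsdmd` both become `Gsdmd`). Source lists mix
#' human-style upper-case and mouse-style symbols; normalizing once at entry
#' makes every later set operation well-defined.
#'
#' @param x Character vector of gene symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_symbols(c("GSDMD", "casp1", "Ripk3"))
#' @export
normalize_symbols <- function(x) {
  stopifnot(is.character(x))
  out <- tolower(x)
  substr(out, 1, 1) <- toupper(substr(out, 1, 1))
  out
}

# Validate a genes-by-samples expression matrix (log2 scale, bulk).
check_expr_matrix <- function(expr, arg = "expr") {
  if (is.data.frame(expr)) {
    gene_col <- names(expr)[1]
    genes <- as.character(expr[[gene_col]])
    mat <- as.matrix(expr[, -1, drop = FALSE])
    rownames(mat) <- genes
    expr <- mat
  }
  if (!is.matrix(expr) || !is.numeric(expr)) {
    abort(sprintf("`%s` must be a numeric matrix or a data frame with a gene column first.", arg))
  }
  if (is.null(rownames(expr))) abort(sprintf("`%s` must have gene ids as row names.", arg))
  if (anyDuplicated(rownames(expr))) abort(sprintf("`%s` has duplicated gene ids.", arg))
  if (anyNA(expr)) abort(sprintf("`%s` contains missing values.", arg))
  expr
}

# Run code with a temporary RNG state derived from `seed`, leaving the
# caller's RNG untouched. All stochastic operations route through this.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream-specific child seed so that independent stages of a
# pipeline driven by one master seed do not share RNG streams. Kept within
# 32-bit integer range.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  ((as.double(seed) * 1103 + as.double(stream) * 12347) %% 2147483629) + 1
}
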