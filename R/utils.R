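#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map_int map_chr imap
NULL

# Deterministic ordering of genes within a cell: decreasing count, ties by
# lexicographic gene id. Used by both the adjCPM exclusion set and the
# top-k-union clustering genes so the two stages agree on tie handling.
order_genes_by_count <- function(counts, gene_ids) {
  order(-counts, gene_ids, method = "radix")
}

assert_count_matrix <- function(x, arg = "counts") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric genes x cells matrix", arg))
  }
  if (length(x) > 0 && (is.null(rownames(x)) || is.null(colnames(x)))) {
    abort(sprintf("`%s` must have gene rownames and cell colnames", arg))
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    abort(sprintf("`%s` has duplicated gene or cell ids", arg))
  }
  if (any(x < 0)) abort(sprintf("`%s` contains negative values", arg))
  invisible(x)
}

# Derive a stage seed from a base seed; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483587L)
}
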