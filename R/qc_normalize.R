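#' Quality-control filtering of cells and genes
#'
#' Applies the two UMI-based filters in sequence: cells with fewer than
#' `min_genes_per_cell` expressed genes are removed first, then genes
#' expressed in fewer than `min_cells_per_gene` of the retained cells are
#' removed. "Expressed" means UMI count strictly greater than 1. The
#' per-cell mitochondrial UMI fraction is reported but never used to filter
#' (high-mito cells are kept).
#'
#' @param counts integer genes x cells matrix.
#' @param min_genes_per_cell minimum number of expressed genes a cell must
#'   have to be retained (default 500); the threshold itself is retained
#'   ("fewer than" is strict).
#' @param min_cells_per_gene minimum number of retained cells a gene must be
#'   expressed in (default 5); a gene expressed in exactly the threshold
#'   number of cells is retained.
#' @param mito_genes character vector of mitochondrial gene ids; defaults to
#'   rownames starting with `"mt-"`.
#' @return list with `counts` (filtered matrix) and `report`, a list holding
#'   `removed_cells`, `removed_genes`, and a `cell_qc` tibble (per input
#'   cell: expressed genes, total UMI, mitochondrial fraction, retained
#'   flag).
#' @export
qc_filter <- function(counts, min_genes_per_cell = 500,
                      min_cells_per_gene = 5, mito_genes = NULL) {
  assert_count_matrix(counts)
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  if (is.null(mito_genes)) {
    mito_genes <- grep("^mt-", rownames(counts), value = TRUE)
  }
  expressed <- counts > 1
  genes_per_cell <- colSums(expressed)
  total_umi <- colSums(counts)
  mito_frac <- if (length(mito_genes)) {
    colSums(counts[rownames(counts) %in% mito_genes, , drop = FALSE]) /
      pmax(total_umi, 1)
  } else rep(0, ncol(counts))

  keep_cell <- genes_per_cell >= min_genes_per_cell
  if (!any(keep_cell)) abort("QC removed every cell; thresholds too strict?")
  kept <- counts[, keep_cell, drop = FALSE]
  cells_per_gene <- rowSums(kept > 1)
  keep_gene <- cells_per_gene >= min_cells_per_gene

  report <- list(
    removed_cells = colnames(counts)[!keep_cell],
    removed_genes = rownames(counts)[!keep_gene],
    cell_qc = tibble(
      cell_id = colnames(counts),
      expressed_genes = unname(genes_per_cell),
      total_umi = unname(total_umi),
      mito_fraction = unname(mito_frac),
      retained = unname(keep_cell)
    )
  )
  list(counts = kept[keep_gene, , drop = FALSE], report = report)
}

#' Dominant-gene exclusion set for adjCPM normalization
#'
#' For every cell whose top `k` genes (by that cell's UMI count) together
#' exceed `share_threshold` of the cell's total UMI, those `k` genes join
#' the exclusion set; the union over cells is returned. Ties on counts are
#' broken by lexicographic gene id so the set is deterministic.
#'
#' @param counts integer genes x cells matrix.
#' @param k number of top genes per cell (default 2).
#' @param share_threshold fraction of total UMI the top-k genes must
#'   strictly exceed for the cell to contribute (default 0.5).
#' @return character vector of gene ids (sorted).
#' @export
adjcpm_exclusion_set <- function(counts, k = 2, share_threshold = 0.5) {
  assert_count_matrix(counts)
  if (ncol(counts) == 0) abort("empty matrix")
  gene_ids <- rownames(counts)
  totals <- colSums(counts)
  if (any(totals == 0)) {
    warn(sprintf("%d cell(s) with zero total UMI skipped", sum(totals == 0)))
  }
  sets <- lapply(which(totals > 0), function(j) {
    v <- counts[, j]
    ord <- order_genes_by_count(v, gene_ids)[seq_len(min(k, length(v)))]
    if (sum(v[ord]) > share_threshold * totals[j]) gene_ids[ord]
    else character(0)
  })
  sort(unique(unlist(sets)))
}

#' Adjusted counts-per-million (adjCPM) normalization
#'
#' CPM normalization in which the per-cell size factor is the total UMI over
#' genes *not* in `exclusion_set`, so that a few dominant hormone genes do
#' not distort the size factors. Excluded genes are still normalized and
#' reported; they are only ignored when computing the factors. With an empty
#' exclusion set this reduces exactly to standard CPM.
#'
#' @param counts integer genes x cells matrix.
#' @param exclusion_set character vector of gene ids excluded from the size
#'   factors (typically [adjcpm_exclusion_set()]).
#' @param S scale constant (default 1e6, counts per million).
#' @param log2_transform if `TRUE`, values are `log2(value + pseudocount)`.
#' @param pseudocount added before the log (default 1).
#' @return an object of class `normalized_matrix`: list with `values`
#'   (genes x cells), `size_factor` (per cell), `exclusion_set`, `scale`,
#'   `log_transformed`, `pseudocount`, and the raw `counts`.
#' @export
normalize_adjcpm <- function(counts, exclusion_set = character(0), S = 1e6,
                             log2_transform = FALSE, pseudocount = 1) {
  assert_count_matrix(counts)
  if (!all(exclusion_set %in% rownames(counts))) {
    abort("exclusion_set contains genes absent from the matrix")
  }
  keep <- !(rownames(counts) %in% exclusion_set)
  factor <- colSums(counts[keep, , drop = FALSE])
  if (any(factor == 0)) {
    abort(sprintf("zero normalization factor for cell(s): %s",
                  paste(colnames(counts)[factor == 0], collapse = ", ")))
  }
  values <- sweep(counts, 2, factor / S, "/")
  if (log2_transform) values <- log2(values + pseudocount)
  structure(
    list(values = values, size_factor = stats::setNames(factor,
                                                        colnames(counts)),
         exclusion_set = sort(exclusion_set), scale = S,
         log_transformed = isTRUE(log2_transform), pseudocount = pseudocount,
         counts = counts),
    class = "normalized_matrix"
  )
}

#' @method print normalized_matrix
#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d genes x %d cells (S = %g, %s scale)\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (x$log_transformed) "log2" else "linear"))
  cat(sprintf("  %d gene(s) excluded from size factors\n",
              length(x$exclusion_set)))
  invisible(x)
}

# Linear-scale and log2-scale views of a normalized matrix, regardless of
# how it was constructed.
norm_linear <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (norm$log_transformed) 2^norm$values - norm$pseudocount else norm$values
}

norm_log2 <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (norm$log_transformed) norm$values
  else log2(norm$values + norm$pseudocount)
}
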