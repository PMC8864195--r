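#' Union of each cell's top-k expressed genes
#'
#' @param counts integer genes x cells matrix.
#' @param k number of top genes per cell (default 10). Ties on counts are
#'   broken by lexicographic gene id.
#' @return sorted character vector of gene ids.
#' @export
top_k_union <- function(counts, k = 10) {
  assert_count_matrix(counts)
  stopifnot(k >= 1)
  gene_ids <- rownames(counts)
  sets <- lapply(seq_len(ncol(counts)), function(j) {
    v <- counts[, j]
    gene_ids[order_genes_by_count(v, gene_ids)[seq_len(min(k, length(v)))]]
  })
  sort(unique(unlist(sets)))
}

#' Hierarchical clustering of cells on a gene subset
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances of
#' log2-normalized expression) restricted to `genes`. Cells whose first
#' merge into the dendrogram happens above the `outlier_quantile` of all
#' leaf merge heights are flagged as outliers and removed, the remaining
#' cells are re-clustered, and the tree is cut into `n_clusters`.
#'
#' @param norm a `normalized_matrix`.
#' @param genes character vector of gene ids to cluster on (typically
#'   [top_k_union()]).
#' @param n_clusters number of clusters to cut (default 4).
#' @param outlier_quantile quantile of leaf merge heights above which a
#'   cell is treated as an outlier (default 0.99).
#' @param linkage hclust linkage method (default `"ward.D2"`).
#' @return list with `labels` (named integer vector over retained cells)
#'   and `outliers` (character vector of removed cell ids).
#' @export
hierarchical_cluster_cells <- function(norm, genes, n_clusters = 4,
                                       outlier_quantile = 0.99,
                                       linkage = "ward.D2") {
  stopifnot(inherits(norm, "normalized_matrix"), n_clusters >= 2)
  if (!all(genes %in% rownames(norm$values))) {
    abort("some clustering genes are absent from the matrix")
  }
  X <- t(norm_log2(norm)[genes, , drop = FALSE])
  if (nrow(X) < n_clusters) abort("fewer cells than clusters")

  leaf_heights <- function(hc) {
    h <- numeric(nrow(hc$merge) + 1)
    for (s in seq_len(nrow(hc$merge))) {
      leaves <- -hc$merge[s, ][hc$merge[s, ] < 0]
      h[leaves] <- hc$height[s]
    }
    h
  }
  hc <- stats::hclust(stats::dist(X), method = linkage)
  lh <- leaf_heights(hc)
  thr <- stats::quantile(lh, outlier_quantile, names = FALSE)
  out_idx <- which(lh > thr)
  keep <- setdiff(seq_len(nrow(X)), out_idx)
  if (length(keep) < n_clusters) abort("outlier removal left too few cells")
  hc2 <- stats::hclust(stats::dist(X[keep, , drop = FALSE]), method = linkage)
  labels <- stats::cutree(hc2, k = n_clusters)
  names(labels) <- rownames(X)[keep]
  list(labels = labels, outliers = rownames(X)[out_idx])
}

#' Highly variable gene selection by lowess residual
#'
#' Fits a lowess regression of log2 coefficient of variation on log2 mean
#' of the (linear-scale) normalized values across genes, and ranks genes by
#' their positive residual; genes with zero mean are excluded.
#'
#' @param norm a `normalized_matrix`.
#' @param n number of genes to return.
#' @param span lowess smoother span (default 2/3).
#' @return character vector of the top-`n` gene ids by residual.
#' @export
select_hvgs <- function(norm, n = 3000, span = 2 / 3) {
  stopifnot(inherits(norm, "normalized_matrix"))
  vals <- norm_linear(norm)
  mu <- rowMeans(vals)
  sd_ <- apply(vals, 1, stats::sd)
  ok <- mu > 0 & sd_ > 0
  if (n > sum(ok)) abort("n exceeds the number of genes with a defined CV")
  lm_ <- log2(mu[ok])
  lcv <- log2(sd_[ok] / mu[ok])
  lo <- stats::lowess(lm_, lcv, f = span)
  fitted <- stats::approx(lo$x, lo$y, xout = lm_, rule = 2, ties = mean)$y
  resid <- lcv - fitted
  ids <- names(mu)[ok]
  ids[order(-resid, ids, method = "radix")[seq_len(n)]]
}

# Truncated SVD helper: exact base svd for small problems, irlba otherwise.
top_svd_d <- function(X, k) {
  if (min(dim(X)) < 150 || k >= min(dim(X)) - 5) {
    svd(X, nu = 0, nv = 0)$d[seq_len(k)]
  } else {
    irlba::irlba(X, nv = k, nu = 0, tol = 1e-4)$d
  }
}

#' Jackstraw-validated significant principal components
#'
#' PCA of the centered and scaled log2-normalized expression of the HVGs.
#' The null distribution of each PC's explained-variance fraction is built
#' by repeatedly permuting a random subset of the genes across cells and
#' recomputing the leading singular values; a PC is significant when its
#' observed explained-variance fraction exceeds the `(1 - alpha)` null
#' quantile, and the selected block stops at the first non-significant PC.
#'
#' @param norm a `normalized_matrix`.
#' @param hvgs character vector of genes to use.
#' @param max_pcs maximum number of PCs examined.
#' @param n_perm number of jackstraw permutations.
#' @param subset_frac fraction of genes permuted per permutation.
#' @param alpha significance level.
#' @param seed integer seed for the permutations.
#' @param n_pcs optional override: force this many PCs instead of the
#'   jackstraw-selected count.
#' @return list with `scores` (cells x selected PCs), `n_selected`,
#'   `explained` (observed explained-variance fractions), `null_quantiles`.
#' @export
significant_pcs <- function(norm, hvgs, max_pcs = 30, n_perm = 100,
                            subset_frac = 0.1, alpha = 0.05, seed = 1L,
                            n_pcs = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  X <- t(norm_log2(norm)[hvgs, , drop = FALSE])
  v <- apply(X, 2, stats::var)
  X <- X[, v > 0, drop = FALSE]
  X <- scale(X)
  if (max_pcs > min(dim(X))) abort("max_pcs exceeds the matrix dimensions")
  total_ss <- sum(X^2)

  sv <- withr::with_seed(derive_seed(seed, 999), {
    if (min(dim(X)) < 150 || max_pcs >= min(dim(X)) - 5) {
      s <- svd(X, nu = 0, nv = max_pcs)
      list(d = s$d[seq_len(max_pcs)], v = s$v)
    } else {
      s <- irlba::irlba(X, nv = max_pcs)
      list(d = s$d, v = s$v)
    }
  })
  # deterministic sign convention: the largest-|loading| entry is positive
  for (j in seq_len(ncol(sv$v))) {
    i <- which.max(abs(sv$v[, j]))
    if (sv$v[i, j] < 0) sv$v[, j] <- -sv$v[, j]
  }
  evf <- sv$d^2 / total_ss

  null_evf <- withr::with_seed(seed, {
    m <- max(1L, ceiling(subset_frac * ncol(X)))
    t(vapply(seq_len(n_perm), function(i) {
      Xp <- X
      cols <- sample.int(ncol(X), m)
      for (j in cols) Xp[, j] <- Xp[sample.int(nrow(X)), j]
      top_svd_d(Xp, max_pcs)^2 / total_ss
    }, numeric(max_pcs)))
  })
  null_q <- apply(null_evf, 2, stats::quantile, probs = 1 - alpha,
                  names = FALSE)
  sig <- evf > null_q
  n_sel <- if (all(sig)) max_pcs else (which(!sig)[1] - 1L)
  if (!is.null(n_pcs)) n_sel <- min(as.integer(n_pcs), max_pcs)

  scores <- if (n_sel > 0) {
    S <- X %*% sv$v[, seq_len(n_sel), drop = FALSE]
    rownames(S) <- rownames(X)
    colnames(S) <- sprintf("PC%d", seq_len(n_sel))
    S
  } else {
    matrix(0, nrow(X), 0, dimnames = list(rownames(X), NULL))
  }
  list(scores = scores, n_selected = n_sel, explained = evf,
       null_quantiles = null_q)
}

#' Two-dimensional t-SNE embedding
#'
#' t-distributed stochastic neighbor embedding of the PC scores with the
#' stated hyperparameters; identical seeds give identical coordinates.
#'
#' @param pc_scores cells x PCs numeric matrix with cell rownames.
#' @param perplexity t-SNE perplexity (default 15).
#' @param early_exaggeration exaggeration factor (default 12).
#' @param learning_rate gradient descent learning rate (default 500).
#' @param seed integer seed.
#' @return an `islet_embedding` tibble (`cell_id`, `tsne1`, `tsne2`) with
#'   the hyperparameters stored as attributes.
#' @export
embed_2d <- function(pc_scores, perplexity = 15, early_exaggeration = 12,
                     learning_rate = 500, seed = 1L) {
  stopifnot(is.matrix(pc_scores), !is.null(rownames(pc_scores)))
  if (nrow(pc_scores) < 3 * perplexity + 2) {
    abort("too few cells for this perplexity")
  }
  fit <- withr::with_seed(seed, {
    Rtsne::Rtsne(pc_scores, dims = 2, perplexity = perplexity,
                 exaggeration_factor = early_exaggeration,
                 eta = learning_rate, pca = FALSE, theta = 0.5,
                 check_duplicates = FALSE, num_threads = 1)
  })
  out <- tibble(cell_id = rownames(pc_scores),
                tsne1 = fit$Y[, 1], tsne2 = fit$Y[, 2])
  attr(out, "hyperparameters") <- list(
    perplexity = perplexity, early_exaggeration = early_exaggeration,
    learning_rate = learning_rate, seed = seed,
    n_pcs = ncol(pc_scores)
  )
  class(out) <- c("islet_embedding", class(out))
  out
}

#' Density-based cliques on a 2-D embedding (DBSCAN)
#'
#' Standard DBSCAN: points with at least `min_pts` neighbors (self
#' included) within `eps` are core points; density-connected core points
#' and their borders form cliques; remaining points are noise (label 0).
#'
#' @param embedding an `islet_embedding` tibble or a 2-column coordinate
#'   matrix with cell rownames.
#' @param eps neighborhood radius (default 5).
#' @param min_pts minimum neighborhood size for a core point (default 5).
#' @return named integer vector of clique labels (0 = noise/singleton).
#' @export
dbscan_cliques <- function(embedding, eps = 5, min_pts = 5) {
  if (inherits(embedding, "islet_embedding") || is.data.frame(embedding)) {
    coords <- as.matrix(embedding[, c("tsne1", "tsne2")])
    rownames(coords) <- embedding$cell_id
  } else {
    coords <- as.matrix(embedding)
  }
  stopifnot(ncol(coords) == 2, !is.null(rownames(coords)))
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      j <- queue[[1]]
      queue <- queue[-1]
      for (kk in nb[[j]]) {
        if (labels[kk] == 0L) {
          labels[kk] <- cl
          if (core[kk]) queue <- c(queue, kk)
        }
      }
    }
  }
  stats::setNames(labels, rownames(coords))
}

#' Retain cells with consistent cluster and clique labels
#'
#' Builds the best-overlap matching between hierarchical clusters and
#' DBSCAN cliques and keeps the cells on which the two labelings agree.
#' Cliques are examined in decreasing size order; a cell is retained when
#' its clique's majority cluster is its own cluster, or, symmetrically,
#' when its cluster's majority clique is its own clique. The symmetric
#' clause keeps a homogeneous clique whole when the hierarchical tree
#' splits one cell population across two clusters, while still dropping
#' cells whose two labels genuinely disagree. Noise cells (clique 0) and
#' cells absent from either labeling are dropped.
#'
#' @param hier_labels named vector of hierarchical cluster labels.
#' @param clique_labels named integer vector of DBSCAN clique labels
#'   (0 = noise).
#' @return character vector of retained cell ids.
#' @export
consistency_filter <- function(hier_labels, clique_labels) {
  cells <- intersect(names(hier_labels), names(clique_labels))
  if (length(cells) == 0) abort("the two labelings share no cells")
  h <- hier_labels[cells]
  q <- clique_labels[cells]
  cells <- cells[q != 0]
  h <- h[q != 0]
  q <- q[q != 0]
  if (length(cells) == 0) return(character(0))
  sizes <- sort(table(q), decreasing = TRUE)
  # majority cluster of each clique (visited in decreasing clique size)
  clique_to_cluster <- vapply(names(sizes), function(cl) {
    names(which.max(table(h[q == cl])))
  }, "")
  # majority clique of each cluster
  cluster_to_clique <- vapply(unique(as.character(h)), function(cc) {
    names(which.max(table(q[h == cc])))
  }, "")
  ok <- clique_to_cluster[as.character(q)] == as.character(h) |
    cluster_to_clique[as.character(h)] == as.character(q)
  cells[ok]
}

#' Exclude cliques dominated by cell-cycle genes
#'
#' For each clique, runs a hurdle differential-expression comparison of the
#' clique against all other cells, takes the top up-regulated genes, and
#' scores their enrichment for annotated cell-cycle genes with a
#' hypergeometric test. Cliques whose enrichment score `-log10(p)` exceeds
#' `score_threshold` are removed (their cells are relabeled noise).
#'
#' @param norm a `normalized_matrix`.
#' @param cliques named integer clique labels (0 = noise).
#' @param cycle_genes character vector of cell-cycle gene ids.
#' @param score_threshold removal threshold on `-log10(p)`; the default 2
#'   corresponds to hypergeometric p < 0.01.
#' @param top_n number of top up-regulated genes scored (default 50).
#' @param covariates covariates for the clique-vs-rest comparison.
#' @param max_cells_per_side cap on cells used on each side of the
#'   clique-vs-rest comparison; larger groups are thinned deterministically
#'   (evenly spaced by cell id). The comparison only ranks top up-regulated
#'   genes, for which a few hundred cells per side are ample.
#' @return list with `cliques` (labels with removed cliques set to 0),
#'   `removed` (integer clique ids), `scores` (tibble: clique, overlap,
#'   pvalue, score).
#' @export
exclude_cycle_clique <- function(norm, cliques, cycle_genes,
                                 score_threshold = 2, top_n = 50,
                                 covariates = "cdr",
                                 max_cells_per_side = 400) {
  stopifnot(inherits(norm, "normalized_matrix"))
  cycle_genes <- intersect(cycle_genes, rownames(norm$values))
  if (length(cycle_genes) == 0) {
    warn("no annotated cell-cycle genes; nothing excluded")
    return(list(cliques = cliques, removed = integer(0),
                scores = tibble(clique = integer(), overlap = integer(),
                                pvalue = numeric(), score = numeric())))
  }
  ids <- sort(unique(cliques[cliques > 0]))
  scores <- vector("list", length(ids))
  removed <- integer(0)
  for (i in seq_along(ids)) {
    cl <- ids[i]
    inside <- names(cliques)[cliques == cl]
    outside <- names(cliques)[cliques != cl & cliques > 0]
    if (length(outside) == 0) next
    thin <- function(x) {
      if (length(x) <= max_cells_per_side) return(x)
      sort(x)[round(seq(1, length(x), length.out = max_cells_per_side))]
    }
    inside <- thin(inside)
    outside <- thin(outside)
    de <- run_de(norm, inside, outside, covariates = covariates)
    up <- de %>%
      filter(!is.na(.data$pvalue), .data$log2fc > 0) %>%
      arrange(.data$pvalue) %>%
      slice_head(n = top_n)
    universe <- de$gene[!is.na(de$pvalue)]
    K <- sum(universe %in% cycle_genes)
    ov <- sum(up$gene %in% cycle_genes)
    p <- stats::phyper(ov - 1, K, length(universe) - K, nrow(up),
                       lower.tail = FALSE)
    sc <- -log10(max(p, .Machine$double.xmin))
    scores[[i]] <- tibble(clique = cl, overlap = ov, pvalue = p, score = sc)
    if (sc > score_threshold) removed <- c(removed, cl)
  }
  out <- cliques
  out[out %in% removed] <- 0L
  list(cliques = out, removed = removed, scores = bind_rows(scores))
}

#' Annotate cliques with cell types from marker genes
#'
#' Each clique is assigned the cell type whose marker genes have the
#' highest mean log2 expression z-score across cliques; cells inherit their
#' clique's label. Cliques with no marker expression at all are labeled
#' `"unknown"`; exact ties are broken by the declared marker order and
#' flagged ambiguous.
#'
#' @param norm a `normalized_matrix`.
#' @param cliques named integer clique labels (0 = noise; noise cells get
#'   `NA`).
#' @param marker_map named list mapping cell type to marker gene ids
#'   (default beta/alpha/delta/pp to Ins2/Gcg/Sst/Ppy).
#' @return list with `cliques` (tibble: clique, cell_type, ambiguous) and
#'   `cells` (named character vector of per-cell labels).
#' @export
annotate_cell_types <- function(norm, cliques,
                                marker_map = list(beta = "Ins2",
                                                  alpha = "Gcg",
                                                  delta = "Sst",
                                                  pp = "Ppy")) {
  stopifnot(inherits(norm, "normalized_matrix"))
  present <- vapply(marker_map,
                    function(g) all(g %in% rownames(norm$values)), TRUE)
  if (!all(present)) {
    warn(sprintf("markers absent from matrix; cell type(s) %s unassignable",
                 paste(names(marker_map)[!present], collapse = ", ")))
    marker_map <- marker_map[present]
  }
  if (length(marker_map) == 0) abort("no usable marker genes")
  ids <- sort(unique(cliques[cliques > 0]))
  logm <- norm_log2(norm)
  # mean marker expression per (cell type, clique)
  M <- vapply(ids, function(cl) {
    cells <- names(cliques)[cliques == cl]
    vapply(marker_map, function(g) {
      mean(logm[g, cells, drop = FALSE])
    }, 1)
  }, numeric(length(marker_map)))
  M <- matrix(M, nrow = length(marker_map),
              dimnames = list(names(marker_map), ids))
  Z <- if (length(ids) > 1) t(scale(t(M))) else M
  Z[is.na(Z)] <- 0
  assign <- vapply(seq_along(ids), function(j) {
    cl_cells <- names(cliques)[cliques == ids[j]]
    raw_max <- max(vapply(marker_map, function(g) {
      max(norm_linear(norm)[g, cl_cells, drop = FALSE])
    }, 1))
    if (raw_max == 0) return("unknown")
    names(marker_map)[which.max(Z[, j])]
  }, "")
  ambiguous <- vapply(seq_along(ids), function(j) {
    sum(Z[, j] == max(Z[, j])) > 1 && assign[j] != "unknown"
  }, TRUE)
  clique_tbl <- tibble(clique = ids, cell_type = assign,
                       ambiguous = ambiguous)
  cell_labels <- rep(NA_character_, length(cliques))
  names(cell_labels) <- names(cliques)
  for (j in seq_along(ids)) {
    cell_labels[cliques == ids[j]] <- assign[j]
  }
  list(cliques = clique_tbl, cells = cell_labels)
}

#' Infer cell sex from X/Y marker gene expression
#'
#' A cell is called female if the X-inactivation marker (Xist) is detected
#' and no Y-linked gene is; male if any Y-linked gene is detected and Xist
#' is not; ambiguous otherwise.
#'
#' @param counts integer genes x cells matrix.
#' @param annotation optional gene annotation tibble with `gene_id` and
#'   `chromosome`; used to locate the Y-linked genes.
#' @param xist_gene id of the X-inactivation marker (default "Xist").
#' @param y_genes ids of Y-linked genes; defaults to the annotation's Y
#'   chromosome genes, or `c("Eif2s3y", "Ddx3y", "Uty")`.
#' @param declared optional tibble with `cell_id` and `declared_sex` to
#'   report mismatches against.
#' @return tibble with `cell_id`, `inferred_sex` ("M"/"F"/"ambiguous"),
#'   `xist_detected`, `y_detected`, and (if `declared` given) `declared_sex`
#'   and `mismatch`.
#' @export
infer_sex <- function(counts, annotation = NULL, xist_gene = "Xist",
                      y_genes = NULL, declared = NULL) {
  assert_count_matrix(counts)
  if (is.null(y_genes)) {
    y_genes <- if (!is.null(annotation)) {
      annotation$gene_id[annotation$chromosome == "Y"]
    } else c("Eif2s3y", "Ddx3y", "Uty")
  }
  y_genes <- intersect(y_genes, rownames(counts))
  if (!xist_gene %in% rownames(counts) || length(y_genes) == 0) {
    abort("sex marker genes absent from the matrix")
  }
  xist <- counts[xist_gene, ] > 0
  ydet <- colSums(counts[y_genes, , drop = FALSE] > 0) > 0
  sex <- ifelse(xist & !ydet, "F", ifelse(ydet & !xist, "M", "ambiguous"))
  out <- tibble(cell_id = colnames(counts), inferred_sex = unname(sex),
                xist_detected = unname(xist), y_detected = unname(ydet))
  if (!is.null(declared)) {
    out$declared_sex <- declared$declared_sex[match(out$cell_id,
                                                    declared$cell_id)]
    out$mismatch <- out$inferred_sex != out$declared_sex
  }
  out
}
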