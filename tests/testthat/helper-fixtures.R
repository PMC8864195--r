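# Shared fixtures, built in code and cached per test session.

fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = fixture_env)) {
    assign(key, force(expr), envir = fixture_env)
  }
  get(key, envir = fixture_env)
}

# tiny hand-checkable count matrix
tiny_counts <- function() {
  m <- matrix(
    c(70, 20, 10,
      5,  3,  2,
      0,  4,  8),
    nrow = 3, byrow = FALSE,
    dimnames = list(c("gA", "gB", "gC"), c("c1", "c2", "c3"))
  )
  storage.mode(m) <- "integer"
  m
}

# beta-only two-condition simulation used by several DE tests
de_sim <- function(seed = 5, n_genes = 1200, n_per = 120, effects = 0,
                   lfc = 1, sexes = "M") {
  groups <- tidyr::expand_grid(sex = sexes, condition = c("HC", "T2D"))
  groups$batch <- "b"
  groups$n <- n_per
  cfg <- islet_sim_config(
    n_genes = n_genes,
    cells_per_group = groups,
    celltype_props = c(beta = 1, alpha = 0, delta = 0, pp = 0),
    program_genes_per_type = 30,
    n_cycle_cells = 0, n_sex_biased = 0, n_t2d_shared = effects,
    n_t2d_female = 0, n_t2d_male = 0, effect_log2fc = lfc, seed = seed
  )
  sim <- simulate_islet(cfg)
  qc <- qc_filter(sim$counts, mito_genes = sim$genes$gene_id[sim$genes$mito],
                  min_genes_per_cell = min(500, round(n_genes / 5)))
  norm <- normalize_adjcpm(qc$counts, adjcpm_exclusion_set(qc$counts))
  cells <- sim$cells[sim$cells$cell_id %in% colnames(qc$counts), ]
  list(sim = sim, norm = norm, cells = cells)
}

pick_cells <- function(cells, cond, sex = NULL) {
  x <- cells[cells$condition == cond, ]
  if (!is.null(sex)) x <- x[x$declared_sex == sex, ]
  x$cell_id
}

# fabricate a de_result tibble for classifier logic tests
fake_de <- function(gene, pvalue, fdr, log2fc, ci_low = log2fc - 0.2,
                    ci_high = log2fc + 0.2, covariates = "cdr") {
  out <- tibble::tibble(
    gene = gene, baseMean = 50, log2fc = log2fc, ci_low = ci_low,
    ci_high = ci_high, lr = 1, df = 2L, pvalue = pvalue, fdr = fdr,
    direction = ifelse(log2fc >= 0, "up", "down")
  )
  attr(out, "comparison") <- list(covariates = covariates)
  class(out) <- c("de_result", class(out))
  out
}

# Independent DBSCAN reference facts, computed from first principles with
# igraph: core flags, connected components of the core-core <=eps graph,
# and the set of core neighbors of every point. Used to check dbscan_cliques
# without re-running the same algorithm.
dbscan_reference_facts <- function(coords, eps, min_pts) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  nb <- lapply(seq_len(n), function(i) setdiff(which(d[i, ] <= eps), i))
  core <- vapply(nb, length, 1L) + 1L >= min_pts
  core_idx <- which(core)
  adj <- d[core_idx, core_idx, drop = FALSE] <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  component <- rep(NA_integer_, n)
  component[core_idx] <- comp
  core_neighbors <- lapply(seq_len(n), function(i) intersect(nb[[i]], core_idx))
  list(core = core, component = component, core_neighbors = core_neighbors)
}

# Assert that a DBSCAN labeling is consistent with the reference facts:
# core points labeled by component (bijectively), noise = points with no
# core neighbor and not core, borders carry the label of one core neighbor.
expect_dbscan_consistent <- function(labels, facts) {
  core <- facts$core
  comp <- facts$component
  # bijection between component ids and labels on core points
  tab <- table(comp[core], labels[core])
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  expect_true(all(labels[core] > 0))
  for (i in which(!core)) {
    cn <- facts$core_neighbors[[i]]
    if (length(cn) == 0) {
      expect_identical(unname(labels[i]), 0L)
    } else {
      expect_true(labels[i] %in% labels[cn])
    }
  }
}
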