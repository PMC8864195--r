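test_that("top_k_union equals a brute-force union and respects the tie rule", {
  set.seed(4)
  m <- matrix(rpois(300 * 200, 2), 300, 200,
              dimnames = list(sprintf("g%03d", 1:300), sprintf("c%03d", 1:200)))
  storage.mode(m) <- "integer"
  got <- top_k_union(m, k = 10)
  # independent recomputation with a different formulation
  want <- sort(unique(unlist(lapply(1:200, function(j) {
    v <- m[, j]
    names(head(v[order(v, rownames(m), decreasing = c(TRUE, FALSE),
                       method = "radix")], 10))
  }))))
  expect_identical(got, want)
  # one cell -> exactly its top k genes
  one <- m[, 1, drop = FALSE]
  expect_length(top_k_union(one, k = 7), 7)
  # identical profiles -> union size k
  same <- m[, rep(1, 5)]
  colnames(same) <- sprintf("s%d", 1:5)
  expect_length(top_k_union(same, k = 10), 10)
})

test_that("hierarchical clustering recovers separated blobs and flags far outliers", {
  set.seed(11)
  n <- 60
  # two populations with opposite expression programs (normalization
  # removes overall scale, so the blobs must differ in direction)
  blob1 <- cbind(matrix(rpois(n * 10, 100), n, 10),
                 matrix(rpois(n * 10, 2), n, 10))
  blob2 <- cbind(matrix(rpois(n * 10, 2), n, 10),
                 matrix(rpois(n * 10, 100), n, 10))
  outlier <- c(5000L, rep(0L, 19))  # all mass on one gene
  m <- t(rbind(blob1, blob2, outlier))
  dimnames(m) <- list(sprintf("g%02d", 1:20), sprintf("c%03d", 1:(2 * n + 1)))
  storage.mode(m) <- "integer"
  norm <- normalize_adjcpm(m + 1L, character(0), S = 1e4)
  res <- hierarchical_cluster_cells(norm, rownames(m), n_clusters = 2,
                                    outlier_quantile = 0.99)
  expect_true("c121" %in% res$outliers)
  lab <- res$labels
  truth <- rep(1:2, each = n)[match(names(lab), sprintf("c%03d", 1:(2 * n)))]
  expect_equal(mclust::adjustedRandIndex(lab, truth), 1)
  expect_error(hierarchical_cluster_cells(norm, rownames(m), n_clusters = 500),
               "fewer cells")
})

test_that("select_hvgs ranks a variance-inflated gene first and recovers planted HVGs", {
  set.seed(21)
  n_cells <- 150
  mu <- exp(seq(log(30), log(300), length.out = 40))
  m <- sapply(seq_len(n_cells), function(i) rpois(40, mu))
  # gene 20 (interior of the mean range): same mean, much larger dispersion
  m[20, ] <- rnbinom(n_cells, mu = mu[20], size = 0.5)
  dimnames(m) <- list(sprintf("g%02d", 1:40), sprintf("c%03d", 1:n_cells))
  storage.mode(m) <- "integer"
  norm <- normalize_adjcpm(m + 1L, character(0), S = 1e4)
  expect_identical(select_hvgs(norm, n = 1), "g20")

  # planted overdispersed genes among Poisson background
  set.seed(22)
  n_genes <- 500
  mu2 <- exp(runif(n_genes, 1, 5))
  m2 <- sapply(seq_len(n_cells), function(i) rpois(n_genes, mu2))
  hv <- sample.int(n_genes, 50)
  for (g in hv) m2[g, ] <- rnbinom(n_cells, mu = mu2[g], size = 0.7)
  dimnames(m2) <- list(sprintf("g%03d", 1:n_genes), sprintf("c%03d", 1:n_cells))
  storage.mode(m2) <- "integer"
  norm2 <- normalize_adjcpm(m2 + 1L, character(0), S = 1e4)
  top <- select_hvgs(norm2, n = 60)
  expect_gte(mean(sprintf("g%03d", hv) %in% top), 0.9)
})

test_that("jackstraw finds no PCs in noise and the planted rank in signal", {
  set.seed(31)
  n <- 120
  p <- 200
  noise <- matrix(rnorm(n * p), n, p)
  mk_norm <- function(X) {
    m <- t(pmax(round(2^(X + 5)), 0))
    dimnames(m) <- list(sprintf("g%03d", 1:p), sprintf("c%03d", 1:n))
    storage.mode(m) <- "integer"
    normalize_adjcpm(m + 1L, character(0), S = 1e4)
  }
  res0 <- significant_pcs(mk_norm(noise * 0.05), sprintf("g%03d", 1:p),
                          max_pcs = 10, n_perm = 40, seed = 3)
  expect_lte(res0$n_selected, 1)

  # rank-3 structure: 3 random gene programs; amplitudes chosen so the
  # log-count nonlinearity's harmonics stay below the noise floor
  grp <- matrix(rnorm(3 * p), 3, p)
  scores <- matrix(rnorm(n * 3), n, 3)
  signal <- scores %*% grp * 0.25
  res3 <- significant_pcs(mk_norm(noise * 0.25 + signal),
                          sprintf("g%03d", 1:p),
                          max_pcs = 10, n_perm = 40, alpha = 0.01, seed = 3)
  expect_identical(res3$n_selected, 3L)
  expect_identical(ncol(res3$scores), 3L)
  # forcing the PC count overrides the selection
  resf <- significant_pcs(mk_norm(noise * 0.25 + signal),
                          sprintf("g%03d", 1:p),
                          max_pcs = 10, n_perm = 5, seed = 3, n_pcs = 6)
  expect_identical(ncol(resf$scores), 6L)
})

test_that("embed_2d is seed-deterministic and separates well-separated blobs", {
  set.seed(41)
  centers <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0))
  X <- do.call(rbind, lapply(1:3, function(k) {
    sweep(matrix(rnorm(60 * 3), 60, 3), 2, centers[k, ], "+")
  }))
  rownames(X) <- sprintf("c%03d", 1:180)
  e1 <- embed_2d(X, seed = 5)
  e2 <- embed_2d(X, seed = 5)
  expect_identical(e1, e2)
  e3 <- embed_2d(X, seed = 6)
  expect_false(identical(e1$tsne1, e3$tsne1))
  # silhouette of the true blobs on the embedded coordinates
  coords <- as.matrix(e1[, c("tsne1", "tsne2")])
  sil <- cluster::silhouette(rep(1:3, each = 60), stats::dist(coords))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
  expect_error(embed_2d(X[1:10, ], perplexity = 15), "too few")
})

test_that("dbscan_cliques matches first-principles density clustering facts", {
  # two clusters far apart -> two cliques
  pts <- rbind(matrix(rnorm(40, 0, 1), 20, 2),
               matrix(rnorm(40, 100, 1), 20, 2))
  rownames(pts) <- sprintf("p%02d", 1:40)
  lab <- dbscan_cliques(pts, eps = 5, min_pts = 5)
  expect_identical(length(unique(lab[lab > 0])), 2L)
  expect_identical(unname(lab[1]), unname(lab[20]))
  expect_false(lab[1] == lab[21])
  # a chain within eps is one clique
  chain <- cbind(seq(0, 50, by = 2), 0)
  rownames(chain) <- sprintf("q%02d", 1:nrow(chain))
  labc <- dbscan_cliques(chain, eps = 5, min_pts = 3)
  expect_identical(length(unique(labc)), 1L)
  # random 200-point instances against independent reference facts
  set.seed(52)
  for (rep in 1:3) {
    xy <- matrix(rnorm(400, sd = 8), 200, 2)
    rownames(xy) <- sprintf("r%03d", 1:200)
    lab <- dbscan_cliques(xy, eps = 2.5, min_pts = 5)
    facts <- dbscan_reference_facts(xy, eps = 2.5, min_pts = 5)
    expect_dbscan_consistent(lab, facts)
  }
})

test_that("consistency filter retains agreement and drops swapped cells", {
  cells <- sprintf("c%02d", 1:40)
  h <- stats::setNames(rep(1:2, each = 20), cells)
  q <- stats::setNames(rep(1:2, each = 20), cells)
  expect_setequal(consistency_filter(h, q), cells)
  q2 <- q
  q2["c01"] <- 2L
  expect_setequal(consistency_filter(h, q2), setdiff(cells, "c01"))
  # random partitions: retained = majority agreement in either direction
  set.seed(61)
  h3 <- stats::setNames(sample(1:3, 200, TRUE), sprintf("x%03d", 1:200))
  q3 <- stats::setNames(sample(1:4, 200, TRUE), names(h3))
  got <- consistency_filter(h3, q3)
  maj <- function(v) names(which.max(table(v)))
  q_to_h <- vapply(as.character(1:4), function(cl) maj(h3[q3 == cl]), "")
  h_to_q <- vapply(as.character(1:3), function(cc) maj(q3[h3 == cc]), "")
  want <- names(h3)[q_to_h[as.character(q3)] == as.character(h3) |
                      h_to_q[as.character(h3)] == as.character(q3)]
  expect_setequal(got, want)
  # a clique split across two clusters is kept whole by the symmetric rule
  h4 <- stats::setNames(rep(c(1, 2), each = 25), sprintf("y%02d", 1:50))
  q4 <- stats::setNames(rep(1L, 50), names(h4))
  expect_setequal(consistency_filter(h4, q4), names(h4))
  expect_error(consistency_filter(h3[1:5], q3[6:10]), "share no cells")
})

test_that("marker annotation labels cliques, breaks ties, and flags empty cliques", {
  genes <- c("Ins2", "Gcg", "Sst", "Ppy", "other")
  m <- matrix(1L, 5, 30, dimnames = list(genes, sprintf("c%02d", 1:30)))
  cl <- stats::setNames(rep(1:3, each = 10), colnames(m))
  m["Ins2", cl == 1] <- 60L
  m["Gcg", cl == 2] <- 60L
  m[, cl == 3] <- 0L
  m["other", cl == 3] <- 5L
  norm <- normalize_adjcpm(m, character(0), S = 1e4)
  res <- annotate_cell_types(norm, cl)
  tab <- res$cliques
  expect_identical(tab$cell_type[tab$clique == 1], "beta")
  expect_identical(tab$cell_type[tab$clique == 2], "alpha")
  expect_identical(tab$cell_type[tab$clique == 3], "unknown")
  expect_identical(unname(res$cells[["c01"]]), "beta")
  # markers absent -> warn and drop the type
  expect_warning(
    annotate_cell_types(norm, cl, marker_map = list(beta = "Ins2",
                                                    zeta = "Nope1")),
    "unassignable")
})

test_that("sex inference follows the marker logic", {
  genes <- c("Xist", "Eif2s3y", "Ddx3y", "Uty", "g1")
  m <- matrix(0L, 5, 4, dimnames = list(genes, c("f1", "m1", "amb1", "amb2")))
  m["g1", ] <- 3L
  m["Xist", "f1"] <- 5L
  m["Ddx3y", "m1"] <- 2L
  m["Xist", "amb2"] <- 1L
  m["Uty", "amb2"] <- 1L
  res <- infer_sex(m)
  expect_identical(res$inferred_sex, c("F", "M", "ambiguous", "ambiguous"))
})

test_that("the planted cycle clique and only it is excluded", {
  ident <- memo("default_ident", {
    sim <- memo("default_sim", simulate_islet(islet_sim_config(seed = 7)))
    qc <- qc_filter(sim$counts, mito_genes = sim$genes$gene_id[sim$genes$mito])
    norm <- normalize_adjcpm(qc$counts, adjcpm_exclusion_set(qc$counts))
    identify_cell_types(norm, sim$genes,
                        params = utils::modifyList(
                          default_run_config()$identify,
                          list(jackstraw_n_perm = 25L)),
                        jackstraw_seed = 11, embedding_seed = 22)
  })
  sim <- memo("default_sim", simulate_islet(islet_sim_config(seed = 7)))
  removed_cells <- names(ident$cycle$cliques)[ident$cycle$cliques == 0]
  truth_cycle <- sim$cells$cell_id[sim$cells$is_cycle]
  retained <- ident$retained
  expect_gt(length(ident$cycle$removed), 0)
  # the cycle clique is removed; a handful of boundary cells may have been
  # embedded elsewhere, so require near-complete exclusion
  expect_lte(sum(truth_cycle %in% retained), 0.1 * length(truth_cycle))
  # no non-cycle clique removed
  expect_identical(length(ident$cycle$removed), 1L)
  # degenerate threshold: any clique whose top genes contain >= 1 cycle gene
  sc <- ident$cycle$scores
  expect_true(all((sc$score > 0) == (sc$overlap >= 1)))
})
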