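small_cfg <- function(seed = 1, ...) {
  args <- list(
    n_genes = 400,
    cells_per_group = tibble::tibble(
      sex = c("M", "F"), condition = "HC", batch = "b", n = c(60, 60)
    ),
    celltype_props = c(beta = 1, alpha = 0, delta = 0, pp = 0),
    program_genes_per_type = 30, n_cycle_cells = 0,
    n_sex_biased = 5, n_t2d_shared = 5, n_t2d_female = 3, n_t2d_male = 3,
    seed = seed
  )
  do.call(islet_sim_config, utils::modifyList(args, list(...)))
}

test_that("identical config and seed reproduce the dataset byte-identically", {
  s1 <- simulate_islet(small_cfg(seed = 3))
  s2 <- simulate_islet(small_cfg(seed = 3))
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$truth$t2d_shared, s2$truth$t2d_shared)
  s3 <- simulate_islet(small_cfg(seed = 4))
  expect_false(identical(s1$counts, s3$counts))
})

test_that("sex marker structure holds: no Y counts in females, no Xist in males", {
  sim <- simulate_islet(small_cfg(seed = 8))
  f <- sim$cells$cell_id[sim$cells$declared_sex == "F"]
  m <- sim$cells$cell_id[sim$cells$declared_sex == "M"]
  y_genes <- sim$genes$gene_id[sim$genes$chromosome == "Y"]
  expect_identical(sum(sim$counts[y_genes, f]), 0L)
  expect_identical(sum(sim$counts["Xist", m]), 0L)
  expect_gt(sum(sim$counts["Xist", f]), 0L)
  expect_gt(sum(sim$counts[y_genes, m]), 0L)
})

test_that("disabling dropout regenerates the identical pre-thinning matrix", {
  with_do <- simulate_islet(small_cfg(seed = 12))
  no_do <- simulate_islet(small_cfg(seed = 12, dropout = FALSE))
  # dropout only zeroes entries; everything else is identical
  expect_true(all(no_do$counts >= with_do$counts))
  changed <- no_do$counts != with_do$counts
  expect_true(all(with_do$counts[changed] == 0))
  expect_gt(sum(changed), 0)
  # per-cell totals: thinned matrix = pre-dropout minus the dropped mass
  expect_identical(colSums(with_do$counts),
                   colSums(no_do$counts) - colSums(no_do$counts * changed))
})

test_that("with no planted effects, male and female mean profiles differ only stochastically", {
  cfg <- small_cfg(seed = 21, n_sex_biased = 0, n_t2d_shared = 0,
                   n_t2d_female = 0, n_t2d_male = 0)
  sim <- simulate_islet(cfg)
  f <- sim$cells$cell_id[sim$cells$declared_sex == "F"]
  m <- sim$cells$cell_id[sim$cells$declared_sex == "M"]
  genes <- sim$genes$gene_id[sim$genes$chromosome %in% as.character(1:19) &
                              !sim$genes$cell_cycle]
  genes <- genes[rowMeans(sim$counts[genes, ]) > 0.5]
  p <- vapply(genes, function(g) {
    stats::t.test(sim$counts[g, m], sim$counts[g, f])$p.value
  }, 1)
  expect_gt(suppressWarnings(stats::ks.test(p, "punif")$p.value), 0.01)
})

test_that("a planted T2D log2FC of 1 doubles the empirical mean, confirmed at 10x cells", {
  base <- tibble::tibble(sex = "M", condition = c("HC", "T2D"),
                         batch = "b", n = 100L)
  mk <- function(n_mult, seed) {
    g <- base
    g$n <- g$n * n_mult
    islet_sim_config(
      n_genes = 400, cells_per_group = g,
      celltype_props = c(beta = 1, alpha = 0, delta = 0, pp = 0),
      program_genes_per_type = 30, n_cycle_cells = 0,
      n_sex_biased = 0, n_t2d_shared = 5, n_t2d_female = 0, n_t2d_male = 0,
      effect_log2fc = 1, dropout = FALSE, seed = seed
    )
  }
  sim <- simulate_islet(mk(1, 31))
  # Monte-Carlo reference at 10x the cells (brute-force large-n recomputation)
  big <- simulate_islet(mk(10, 32))
  ratio_of <- function(s) {
    # up-planted genes only (the class mixes signs by design)
    up <- s$truth$t2d_shared$gene[s$truth$t2d_shared$log2fc > 0]
    t2d <- s$cells$cell_id[s$cells$condition == "T2D"]
    hc <- s$cells$cell_id[s$cells$condition == "HC"]
    # library-size normalize before comparing means
    cpm <- sweep(s$counts, 2, colSums(s$counts), "/")
    rowMeans(cpm[up, t2d, drop = FALSE]) / rowMeans(cpm[up, hc, drop = FALSE])
  }
  r_small <- ratio_of(sim)
  r_big <- ratio_of(big)
  expect_true(all(abs(log2(r_big) - 1) < 0.15))
  expect_true(all(abs(log2(r_small) - log2(mean(r_big))) < 0.5))
})

test_that("planting a T2D effect on a Y-linked gene in females errors", {
  bad <- tibble::tibble(gene = "Eif2s3y", log2fc = 1)
  expect_error(
    simulate_islet(small_cfg(seed = 2, t2d_female_specific = bad)),
    "Y-linked"
  )
  # and overlapping effect classes are rejected
  tb <- tibble::tibble(gene = "Gene0001", log2fc = 1)
  expect_error(
    simulate_islet(small_cfg(seed = 2, t2d_shared = tb,
                             t2d_male_specific = tb)),
    "disjoint"
  )
})

test_that("empty groups are allowed with a warning", {
  expect_warning(
    islet_sim_config(cells_per_group = tibble::tibble(
      sex = c("M", "F"), condition = "HC", batch = "b", n = c(50L, 0L)
    )),
    "empty"
  )
})

test_that("truth_gene_sets returns one set per effect class plus reproducible decoys", {
  sim <- simulate_islet(small_cfg(seed = 13))
  sets0 <- truth_gene_sets(sim$truth, decoys = 0)
  expect_setequal(sets0$t2d_shared, sim$truth$t2d_shared$gene)
  expect_setequal(sets0$sex_biased, sim$truth$sex_biased$gene)
  s1 <- truth_gene_sets(sim$truth, decoys = 5, set_size = 20, seed = 7)
  s2 <- truth_gene_sets(sim$truth, decoys = 5, set_size = 20, seed = 7)
  expect_identical(s1, s2)
  expect_length(grep("^decoy_", names(s1)), 5)
  expect_true(all(lengths(s1[grep("^decoy_", names(s1))]) == 20))
  expect_error(truth_gene_sets(sim$truth, decoys = 1, set_size = 1e5),
               "set_size")
})

test_that("the default configuration produces the expected data regime", {
  sim <- memo("default_sim", simulate_islet(islet_sim_config(seed = 7)))
  med <- stats::median(sim$cells$detected_genes)
  expect_gt(med, 1300)
  expect_lt(med, 1700)
  # dominant hormone genes give some beta cells a top-2 UMI share > 50%
  beta <- sim$cells$cell_id[sim$cells$cell_type == "beta"][1:200]
  share <- vapply(beta, function(cc) {
    v <- sort(sim$counts[, cc], decreasing = TRUE)
    sum(v[1:2]) / sum(v)
  }, 1)
  expect_gt(mean(share > 0.5), 0.05)
})
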