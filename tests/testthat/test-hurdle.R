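test_that("CDR counts detected genes and degenerates safely", {
  m <- tiny_counts()
  cdr <- compute_cdr(m)
  expect_identical(cdr$cdr, c(3L, 3L, 2L))
  const <- matrix(1L, 3, 4, dimnames = list(c("a", "b", "c"),
                                            sprintf("c%d", 1:4)))
  expect_identical(compute_cdr(const)$cdr_scaled, rep(0, 4))
})

test_that("the continuous coefficient matches the closed-form group-mean difference", {
  set.seed(71)
  n <- 400
  grp <- rep(c(1, 0), each = n / 2)
  X <- cbind("(Intercept)" = 1, group = grp)
  y <- ifelse(rbinom(n, 1, 0.7) == 1,
              pmax(rnorm(n, 5 + 1.3 * grp, 1), 0.01), 0)
  fit <- fit_hurdle_gene(y, X)
  det <- y > 0
  closed <- mean(y[det & grp == 1]) - mean(y[det & grp == 0])
  expect_equal(unname(fit$continuous$coef["group"]), closed, tolerance = 1e-10)
  # logistic part recovers the detection logit difference within its CI
  y2 <- ifelse(rbinom(n, 1, stats::plogis(-1.4 + 2.8 * grp)) == 1, 3, 0)
  fit2 <- fit_hurdle_gene(y2, X)
  est <- fit2$discrete$coef["group"]
  se <- sqrt(diag(fit2$discrete$vcov))[2]
  expect_lt(abs(est - 2.8), 3 * se + 0.5)
  # tidiers
  td <- tidy(fit)
  expect_setequal(unique(td$component), c("discrete", "continuous"))
  expect_identical(glance(fit)$n, as.integer(n))
})

test_that("an all-zero gene yields p = 1 and empty-ish effect", {
  X <- cbind("(Intercept)" = 1, group = rep(c(1, 0), each = 10))
  st <- isletdimorph:::hurdle_gene_stats(rep(0, 20), X,
                                         X[, 1, drop = FALSE],
                                         c(1, 1), c(1, 0), zq = 1.96)
  # handled upstream in run_de; the gene-level fit treats it as no info
  fit <- fit_hurdle_gene(rep(0, 20), X)
  expect_false(isTRUE(fit$discrete$informative))
  expect_null(fit$continuous)
  lr <- lrt_contrast(fit, fit_hurdle_gene(rep(0, 20), X[, 1, drop = FALSE]))
  expect_identical(lr$pvalue, 1)
})

test_that("identical designs give LR 0 and non-nested designs error", {
  set.seed(72)
  X <- cbind("(Intercept)" = 1, group = rep(c(1, 0), each = 30))
  y <- ifelse(rbinom(60, 1, 0.6) == 1, pmax(rnorm(60, 4), 0.1), 0)
  f <- fit_hurdle_gene(y, X)
  lr <- lrt_contrast(f, f)
  expect_equal(lr$lr, 0)
  expect_equal(lr$pvalue, 1)
  X2 <- X
  colnames(X2) <- c("(Intercept)", "other")
  expect_error(lrt_contrast(f, fit_hurdle_gene(y, X2)), "nested")
})

test_that("LR, p and log2FC are invariant to shifting a covariate", {
  set.seed(73)
  n <- 200
  grp <- rep(c(1, 0), each = n / 2)
  cov <- rnorm(n)
  y <- ifelse(rbinom(n, 1, stats::plogis(0.5 + 0.8 * grp + 0.3 * cov)) == 1,
              pmax(rnorm(n, 4 + grp + 0.5 * cov, 1), 0.01), 0)
  stats_at <- function(shift) {
    X <- cbind("(Intercept)" = 1, group = grp, cv = cov + shift)
    X0 <- X[, c(1, 3)]
    isletdimorph:::hurdle_gene_stats(y, X, X0, c(1, 1, mean(cov + shift)),
                                     c(1, 0, mean(cov + shift)), zq = 1.96)
  }
  a <- stats_at(0)
  b <- stats_at(100)
  expect_equal(a, b, tolerance = 1e-6)
})

test_that("run_de rejects bad groupings and confounded covariates", {
  d <- de_sim(seed = 44, n_genes = 400, n_per = 40, sexes = c("M", "F"))
  cells <- d$cells
  f <- pick_cells(cells, "HC", "F")
  m <- pick_cells(cells, "HC", "M")
  cd <- dplyr::transmute(cells, cell_id, sex = declared_sex)
  expect_error(run_de(d$norm, f, f, covariates = NULL), "disjoint")
  expect_error(run_de(d$norm, character(0), m), "nonempty")
  expect_error(run_de(d$norm, f, m, covariates = c("cdr", "sex"),
                      cell_data = cd), "confounded")
})

test_that("run_de output respects its declared invariants", {
  d <- memo("de_effect_sim",
            de_sim(seed = 5, n_genes = 800, n_per = 100, effects = 40))
  de <- memo("de_effect_res", {
    run_de(d$norm, pick_cells(d$cells, "T2D"), pick_cells(d$cells, "HC"),
           covariates = "cdr")
  })
  ok <- !is.na(de$pvalue)
  expect_true(all(de$lr[ok] >= 0))
  expect_true(all(de$pvalue[ok] >= 0 & de$pvalue[ok] <= 1))
  expect_true(all(de$ci_low[ok] <= de$log2fc[ok] + 1e-12))
  expect_true(all(de$ci_high[ok] >= de$log2fc[ok] - 1e-12))
  # BH monotone in p-rank; 0.05 calls nested in 0.25 calls
  o <- order(de$pvalue[ok])
  expect_true(all(diff(de$fdr[ok][o]) >= -1e-12))
  expect_true(all(de$gene[ok][de$fdr[ok] < 0.05] %in%
                    de$gene[ok][de$fdr[ok] < 0.25]))
  expect_identical(unname(de$direction[ok]),
                   ifelse(de$log2fc[ok] >= 0, "up", "down"))
  # fold-change direction agrees with planted truth
  tr <- d$sim$truth$t2d_shared
  j <- dplyr::inner_join(de, tr, by = "gene")
  expect_gt(mean(sign(j$log2fc.x) == sign(j$log2fc.y)), 0.9)
  # continuous-only mode gives finite alternatives
  de2 <- run_de(d$norm, pick_cells(d$cells, "T2D"), pick_cells(d$cells, "HC"),
                covariates = "cdr", lfc_mode = "continuous",
                genes = de$gene[1:50])
  expect_true(all(is.finite(de2$log2fc[!is.na(de2$pvalue)])))
})

test_that("CDR correlates with library size in simulated data", {
  d <- memo("de_effect_sim",
            de_sim(seed = 5, n_genes = 800, n_per = 100, effects = 40))
  cdr <- compute_cdr(d$norm$counts)
  lib <- colSums(d$norm$counts)
  expect_gt(stats::cor(cdr$cdr, lib), 0.5)
})

test_that("ks_compare equals the brute-force sup-ECDF difference", {
  brute_D <- function(a, b) {
    pool <- sort(unique(c(a, b)))
    max(abs(vapply(pool, function(t) mean(a <= t) - mean(b <= t), 1)))
  }
  set.seed(81)
  for (i in 1:20) {
    a <- rnorm(sample(5:60, 1))
    b <- rnorm(sample(5:60, 1), mean = runif(1, -1, 1))
    res <- ks_compare(a, b)
    expect_equal(res$statistic, brute_D(a, b), tolerance = 1e-12)
  }
  same <- rnorm(30)
  res <- ks_compare(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$pvalue, 1)
  expect_equal(ks_compare(1:10, 101:110)$statistic, 1)
  expect_error(ks_compare(1, 1:5), "at least 2")
})

test_that("log2FC profile correlation returns r and spread ratio", {
  de_x <- fake_de(sprintf("g%02d", 1:30), pvalue = runif(30),
                  fdr = runif(30), log2fc = rnorm(30))
  expect_equal(logfc_profile_correlation(de_x, de_x)$r, 1)
  de_y <- de_x
  de_y$log2fc <- de_x$log2fc * 0.5
  res <- logfc_profile_correlation(de_x, de_y)
  expect_equal(res$r, 1)
  expect_equal(res$spread_ratio, 2)
  de_z <- de_x
  de_z$log2fc <- 0
  expect_error(logfc_profile_correlation(de_x, de_z), "zero variance")
  expect_error(logfc_profile_correlation(de_x[1:2, ], de_x[1:2, ]),
               "at least 3")
})

test_that("shrinking one comparison's effects halves its fold-change spread", {
  d <- memo("de_effect_sim",
            de_sim(seed = 5, n_genes = 800, n_per = 100, effects = 40))
  de <- memo("de_effect_res", {
    run_de(d$norm, pick_cells(d$cells, "T2D"), pick_cells(d$cells, "HC"),
           covariates = "cdr")
  })
  half <- de
  half$log2fc <- de$log2fc * 0.5
  res <- logfc_profile_correlation(de, half,
                                   genes = d$sim$truth$t2d_shared$gene)
  expect_equal(res$spread_ratio, 2, tolerance = 1e-9)
})
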