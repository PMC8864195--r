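#' Cellular detection rate (CDR)
#'
#' The number of genes detected (count > 0) in each cell. The scaled column
#' (centered, unit variance) is what enters hurdle-model design matrices as
#' a covariate absorbing technical depth variation.
#'
#' @param counts integer genes x cells matrix.
#' @return tibble with `cell_id`, `cdr` (raw count), `cdr_scaled`.
#' @export
compute_cdr <- function(counts) {
  assert_count_matrix(counts)
  cdr <- as.integer(colSums(counts > 0))
  s <- stats::sd(cdr)
  tibble(
    cell_id = colnames(counts),
    cdr = cdr,
    cdr_scaled = if (is.na(s) || s == 0) rep(0, length(cdr))
                 else unname((cdr - mean(cdr)) / s)
  )
}

# Ridge-stabilised IRLS logistic regression. The penalty is applied to
# non-intercept columns only, so location shifts of covariates (absorbed by
# the intercept) leave the fit invariant; the reported deviance is the
# unpenalised binomial deviance.
fit_logistic_ridge <- function(X, y, lambda = 1e-4, maxit = 25, tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(lambda, p)
  pen[colnames(X) == "(Intercept)"] <- 0
  beta <- numeric(p)
  m <- mean(y)
  beta[1] <- stats::qlogis(min(max((sum(y) + 0.5) / (length(y) + 1), 1e-6),
                               1 - 1e-6))
  dev_old <- Inf
  converged <- FALSE
  A <- NULL
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- stats::plogis(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    W <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / W
    A <- crossprod(X, X * W) + diag(pen, p)
    beta <- tryCatch(solve(A, crossprod(X, W * z)),
                     error = function(e) NULL)
    if (is.null(beta)) {
      return(list(coef = rep(NA_real_, p), vcov = NULL, deviance = NA_real_,
                  converged = FALSE))
    }
    beta <- drop(beta)
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    mu <- pmin(pmax(stats::plogis(eta), 1e-10), 1 - 1e-10)
    dev <- -2 * sum(y * log(mu) + (1 - y) * log1p(-mu))
    if (abs(dev_old - dev) < tol * (abs(dev) + 0.1)) {
      converged <- TRUE
      dev_old <- dev
      break
    }
    dev_old <- dev
  }
  names(beta) <- colnames(X)
  list(coef = beta, vcov = solve(A), deviance = dev_old,
       converged = converged)
}

# OLS continuous component on detected cells; deviance is the Gaussian
# -2 log-likelihood with ML variance, up to constants shared by nested
# models on the same cells.
fit_gaussian <- function(X, y, var_floor = 1e-6) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) return(NULL)
  coef <- qr.coef(qr_x, y)
  res <- y - drop(X %*% coef)
  rss <- sum(res^2)
  n <- length(y)
  sigma2 <- max(rss / max(n - ncol(X), 1), var_floor)
  XtX_inv <- chol2inv(qr.R(qr_x))
  list(coef = stats::setNames(coef, colnames(X)),
       vcov = sigma2 * XtX_inv,
       sigma2 = sigma2,
       deviance = n * log(max(rss, var_floor * n) / n),
       n = n)
}

#' Fit the two-part hurdle model for one gene
#'
#' Fits a logistic regression of the detection indicator `y > 0` on the
#' design, and a Gaussian linear regression of `y` on the design over the
#' detected cells. `y` is log2-normalized expression (non-negative, zero =
#' undetected). Separation in the logistic part is handled by a small ridge
#' penalty on non-intercept coefficients; with fewer than 3 detected cells
#' the continuous part is skipped and the fit flagged discrete-only.
#'
#' @param y numeric vector of per-cell log2-normalized expression.
#' @param design numeric design matrix (first column the intercept,
#'   named `"(Intercept)"`).
#' @param ridge logistic ridge penalty (default 1e-4).
#' @param var_floor lower bound on the continuous residual variance.
#' @return object of class `hurdle_fit` with elements `discrete`,
#'   `continuous` (NULL if skipped), `detected`, `n`, `design_cols`.
#' @export
fit_hurdle_gene <- function(y, design, ridge = 1e-4, var_floor = 1e-6) {
  stopifnot(is.matrix(design), nrow(design) == length(y), all(y >= 0))
  d <- as.numeric(y > 0)
  nd <- sum(d)
  discrete <- if (nd == 0 || nd == length(y)) {
    # no variation in detection: component carries no information
    list(coef = NULL, vcov = NULL, deviance = 0, converged = TRUE,
         informative = FALSE)
  } else {
    f <- c(fit_logistic_ridge(design, d, lambda = ridge), informative = TRUE)
    f$separation <- !anyNA(f$coef) &&
      max(abs(design %*% f$coef)) > 15
    if (isTRUE(f$separation)) {
      stab <- fit_logistic_ridge(design, d, lambda = 0.5)
      f$effect_coef <- stab$coef
      f$effect_vcov <- stab$vcov
    } else {
      f$effect_coef <- f$coef
      f$effect_vcov <- f$vcov
    }
    f
  }
  continuous <- if (nd >= 3) {
    fit_gaussian(design[d == 1, , drop = FALSE], y[d == 1],
                 var_floor = var_floor)
  } else NULL
  structure(
    list(discrete = discrete, continuous = continuous,
         detected = nd, n = length(y), design_cols = colnames(design)),
    class = "hurdle_fit"
  )
}

#' Likelihood-ratio contrast between nested hurdle fits
#'
#' The hurdle LR statistic is the sum of the discrete and continuous
#' component deviance differences; the degrees of freedom are the number of
#' dropped design columns times the number of components actually fitted in
#' both models.
#'
#' @param fit_full,fit_reduced [fit_hurdle_gene()] results on nested
#'   designs (reduced columns a subset of full columns).
#' @return tibble with `lr`, `df`, `pvalue`.
#' @export
lrt_contrast <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "hurdle_fit"), inherits(fit_reduced, "hurdle_fit"))
  if (!all(fit_reduced$design_cols %in% fit_full$design_cols)) {
    abort("designs are not nested")
  }
  dropped <- length(fit_full$design_cols) - length(fit_reduced$design_cols)
  lr <- 0
  k <- 0L
  if (isTRUE(fit_full$discrete$informative) &&
      isTRUE(fit_reduced$discrete$informative)) {
    lr <- lr + max(fit_reduced$discrete$deviance - fit_full$discrete$deviance, 0)
    k <- k + 1L
  }
  if (!is.null(fit_full$continuous) && !is.null(fit_reduced$continuous)) {
    lr <- lr + max(fit_reduced$continuous$deviance -
                     fit_full$continuous$deviance, 0)
    k <- k + 1L
  }
  df <- dropped * k
  p <- if (df == 0) 1 else stats::pchisq(lr, df, lower.tail = FALSE)
  tibble(lr = lr, df = df, pvalue = p)
}

# Combined-expectation log2 fold change with delta-method CI.
# E[Y] = P(detect) * mu_continuous evaluated at covariate means; the
# contrast is the difference of E[Y] between the two groups on the
# log2-normalized scale.
hurdle_lfc <- function(fit, xa, xb, conf = 0.95, mode = "combined") {
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  disc <- fit$discrete
  cont <- fit$continuous
  if (mode == "continuous" && !is.null(cont)) {
    grp <- which(xa != xb)[1]
    est <- sum(cont$coef * (xa - xb))
    se <- sqrt(drop(t(xa - xb) %*% cont$vcov %*% (xa - xb)))
    return(tibble(log2fc = est, ci_low = est - zq * se,
                  ci_high = est + zq * se))
  }
  if (isTRUE(disc$informative)) {
    dco <- disc$effect_coef %||% disc$coef
    pa <- stats::plogis(sum(dco * xa))
    pb <- stats::plogis(sum(dco * xb))
  } else {
    pa <- pb <- if (fit$detected == fit$n) 1 else 0
  }
  if (!is.null(cont)) {
    mua <- sum(cont$coef * xa)
    mub <- sum(cont$coef * xb)
  } else {
    mua <- mub <- NA_real_
  }
  if (is.na(mua)) {
    # continuous part unavailable: no estimable mean shift
    est <- 0
    var <- 0
  } else {
    est <- pa * mua - pb * mub
    var <- 0
    if (isTRUE(disc$informative) && !is.null(disc$vcov)) {
      gd <- pa * (1 - pa) * mua * xa - pb * (1 - pb) * mub * xb
      dvc <- disc$effect_vcov %||% disc$vcov
      var <- var + drop(t(gd) %*% dvc %*% gd)
    }
    gc_ <- pa * xa - pb * xb
    var <- var + drop(t(gc_) %*% cont$vcov %*% gc_)
  }
  se <- sqrt(max(var, 0))
  tibble(log2fc = est, ci_low = est - zq * se, ci_high = est + zq * se)
}

# Lean per-gene engine behind run_de: fits the full and reduced hurdle
# models and returns c(lfc, ci_low, ci_high, lr, df, p), or NULL on a
# failed fit. Exactly the statistic of fit_hurdle_gene + lrt_contrast +
# hurdle_lfc, without per-gene object construction.
hurdle_gene_stats <- function(y, X, X0, xa, xb, zq, lfc_mode = "combined",
                              ridge = 1e-4, var_floor = 1e-6) {
  d <- as.numeric(y > 0)
  nd <- sum(d)
  n <- length(y)
  informative <- nd > 0 && nd < n
  if (informative) {
    f1d <- fit_logistic_ridge(X, d, lambda = ridge)
    f0d <- fit_logistic_ridge(X0, d, lambda = ridge)
    if (!f1d$converged || anyNA(f1d$coef) || !f0d$converged) return(NULL)
    # (quasi-)separation: deviances remain valid for the LRT, but the
    # coefficients diverge; use a strongly ridged refit for the effect size
    if (max(abs(X %*% f1d$coef)) > 15) {
      f1d_eff <- fit_logistic_ridge(X, d, lambda = 0.5)
    } else {
      f1d_eff <- f1d
    }
  }
  f1c <- f0c <- NULL
  if (nd >= 3) {
    det <- d == 1
    f1c <- fit_gaussian(X[det, , drop = FALSE], y[det], var_floor = var_floor)
    if (!is.null(f1c)) {
      f0c <- fit_gaussian(X0[det, , drop = FALSE], y[det],
                          var_floor = var_floor)
    }
  }
  lr <- 0
  k <- 0L
  if (informative) {
    lr <- lr + max(f0d$deviance - f1d$deviance, 0)
    k <- k + 1L
  }
  if (!is.null(f1c) && !is.null(f0c)) {
    lr <- lr + max(f0c$deviance - f1c$deviance, 0)
    k <- k + 1L
  }
  dfree <- (ncol(X) - ncol(X0)) * k
  p <- if (dfree == 0) 1 else stats::pchisq(lr, dfree, lower.tail = FALSE)

  if (lfc_mode == "continuous" && !is.null(f1c)) {
    dx <- xa - xb
    est <- sum(f1c$coef * dx)
    se <- sqrt(max(drop(t(dx) %*% f1c$vcov %*% dx), 0))
    return(c(est, est - zq * se, est + zq * se, lr, dfree, p))
  }
  if (informative) {
    pa <- stats::plogis(sum(f1d_eff$coef * xa))
    pb <- stats::plogis(sum(f1d_eff$coef * xb))
  } else {
    pa <- pb <- if (nd == n) 1 else 0
  }
  if (is.null(f1c)) {
    est <- 0
    se <- 0
  } else {
    mua <- sum(f1c$coef * xa)
    mub <- sum(f1c$coef * xb)
    est <- pa * mua - pb * mub
    v <- 0
    if (informative) {
      gd <- pa * (1 - pa) * mua * xa - pb * (1 - pb) * mub * xb
      v <- v + drop(t(gd) %*% f1d_eff$vcov %*% gd)
    }
    gc_ <- pa * xa - pb * xb
    v <- v + drop(t(gc_) %*% f1c$vcov %*% gc_)
    se <- sqrt(max(v, 0))
  }
  c(est, est - zq * se, est + zq * se, lr, dfree, p)
}

#' Hurdle-model differential expression between two cell groups
#'
#' Per-gene two-part hurdle fit with a group indicator plus covariates, a
#' likelihood-ratio test on the group term, Benjamini-Hochberg FDR across
#' tested genes, and a log2 fold change with 95% confidence interval.
#' Positive `log2fc` means higher expression in `cells_a`.
#'
#' @param norm a `normalized_matrix` from [normalize_adjcpm()]; the model is
#'   fitted on `log2(adjCPM + 1)` values.
#' @param cells_a,cells_b disjoint character vectors of cell ids
#'   (e.g. T2D vs healthy). `cells_a` is the numerator of the fold change.
#' @param covariates subset of `c("cdr", "sex")`; `cdr` is computed from the
#'   raw counts, `sex` requires `cell_data`.
#' @param cell_data tibble with `cell_id` and any covariate columns
#'   (`sex` coded "M"/"F"), required when `covariates` includes `"sex"`.
#' @param lfc_mode `"combined"` (contrast on the combined expectation
#'   `P(detect) * mu`, delta-method CI) or `"continuous"` (continuous
#'   component coefficient only).
#' @param conf confidence level for the fold-change interval.
#' @param genes optional subset of genes to test.
#' @return a `de_result` tibble: `gene`, `baseMean` (mean linear-scale
#'   normalized value across the comparison cells), `log2fc`, `ci_low`,
#'   `ci_high`, `lr`, `df`, `pvalue`, `fdr`, `direction`. Genes whose fit
#'   failed carry `NA` and are excluded from the FDR ranking.
#' @export
run_de <- function(norm, cells_a, cells_b, covariates = "cdr",
                   cell_data = NULL, lfc_mode = c("combined", "continuous"),
                   conf = 0.95, genes = NULL) {
  stopifnot(inherits(norm, "normalized_matrix"))
  lfc_mode <- match.arg(lfc_mode)
  cells_a <- as.character(cells_a)
  cells_b <- as.character(cells_b)
  if (length(cells_a) == 0 || length(cells_b) == 0) {
    abort("both cell groups must be nonempty")
  }
  if (length(intersect(cells_a, cells_b)) > 0) {
    abort("cell groups must be disjoint")
  }
  all_cells <- c(cells_a, cells_b)
  if (!all(all_cells %in% colnames(norm$values))) {
    abort("some cells are absent from the matrix")
  }
  grp <- c(rep(1, length(cells_a)), rep(0, length(cells_b)))

  X <- cbind("(Intercept)" = 1, group = grp)
  for (cv in covariates) {
    if (cv == "cdr") {
      cdr <- colSums(norm$counts[, all_cells, drop = FALSE] > 0)
      s <- stats::sd(cdr)
      if (is.na(s) || s == 0) {
        warn("CDR is constant across cells; covariate dropped")
        next
      }
      X <- cbind(X, cdr = (cdr - mean(cdr)) / s)
    } else {
      if (is.null(cell_data) || !cv %in% names(cell_data)) {
        abort(sprintf("covariate '%s' requires a matching column in cell_data", cv))
      }
      v <- cell_data[[cv]][match(all_cells, cell_data$cell_id)]
      if (anyNA(v)) abort(sprintf("covariate '%s' missing for some cells", cv))
      if (is.character(v) || is.factor(v)) v <- as.numeric(factor(v)) - 1
      s <- stats::sd(v)
      if (is.na(s) || s == 0) {
        warn(sprintf("covariate '%s' is constant; dropped", cv))
        next
      }
      v <- (v - mean(v)) / s
      if (abs(stats::cor(v, grp)) > 0.999) {
        abort(sprintf(paste0("covariate '%s' is confounded with the group ",
                             "contrast; remove it from `covariates`"), cv))
      }
      X <- cbind(X, v)
      colnames(X)[ncol(X)] <- cv
    }
  }
  if (qr(X)$rank < ncol(X)) {
    abort("design matrix is rank deficient; remove collinear covariates")
  }
  X0 <- X[, colnames(X) != "group", drop = FALSE]
  # contrast rows: group toggled, covariates at their (centered) mean = 0
  xa <- c(1, 1, rep(0, ncol(X) - 2))
  xb <- c(1, 0, rep(0, ncol(X) - 2))

  logmat <- norm_log2(norm)[, all_cells, drop = FALSE]
  linmat <- norm_linear(norm)[, all_cells, drop = FALSE]
  if (is.null(genes)) genes <- rownames(logmat)

  ng <- length(genes)
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  lfc <- lo <- hi <- lr <- pv <- rep(NA_real_, ng)
  df <- rep(NA_integer_, ng)
  bm <- rowMeans(linmat[genes, , drop = FALSE])
  for (i in seq_len(ng)) {
    y <- logmat[genes[i], ]
    if (all(y == 0)) {
      lfc[i] <- lo[i] <- hi[i] <- lr[i] <- 0
      df[i] <- 0L
      pv[i] <- 1
      next
    }
    st <- hurdle_gene_stats(y, X, X0, xa, xb, zq = zq, lfc_mode = lfc_mode)
    if (is.null(st)) next
    lfc[i] <- st[1]; lo[i] <- st[2]; hi[i] <- st[3]
    lr[i] <- st[4]; df[i] <- as.integer(st[5]); pv[i] <- st[6]
  }
  out <- tibble(gene = genes, baseMean = unname(bm), log2fc = lfc,
                ci_low = lo, ci_high = hi, lr = lr, df = df, pvalue = pv)
  out$fdr <- NA_real_
  tested <- !is.na(out$pvalue)
  out$fdr[tested] <- stats::p.adjust(out$pvalue[tested], method = "BH")
  out$direction <- ifelse(is.na(out$log2fc), NA_character_,
                          ifelse(out$log2fc >= 0, "up", "down"))
  attr(out, "comparison") <- list(n_a = length(cells_a), n_b = length(cells_b),
                                  covariates = covariates, lfc_mode = lfc_mode)
  class(out) <- c("de_result", class(out))
  out
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' The two-sample KS statistic `D = sup |ECDF_A - ECDF_B|` with its
#' asymptotic p value, used e.g. to compare marker-gene expression
#' distributions between male and female beta cells.
#'
#' @param values_a,values_b numeric samples (each of length >= 2).
#' @return tibble with `statistic` (D) and `pvalue`.
#' @export
ks_compare <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each sample needs at least 2 values")
  }
  kt <- suppressWarnings(stats::ks.test(values_a, values_b, exact = FALSE))
  tibble(statistic = unname(kt$statistic), pvalue = unname(kt$p.value))
}

#' Correlation and spread ratio of two log2 fold-change profiles
#'
#' Compares the log2 fold-change profiles of two differential-expression
#' analyses over a shared gene set: the Pearson correlation, and the ratio
#' of the standard deviation of the first profile to the second (a spread
#' ratio > 1 means the first comparison produced wider fold changes).
#'
#' @param de_x,de_y `de_result` tibbles (or any tibbles with `gene` and
#'   `log2fc` columns).
#' @param genes optional gene subset; defaults to all shared genes.
#' @return tibble with `r`, `spread_ratio`, `n_genes`.
#' @export
logfc_profile_correlation <- function(de_x, de_y, genes = NULL) {
  j <- inner_join(
    tibble(gene = de_x$gene, x = de_x$log2fc),
    tibble(gene = de_y$gene, y = de_y$log2fc),
    by = "gene"
  )
  if (!is.null(genes)) j <- filter(j, .data$gene %in% genes)
  j <- filter(j, !is.na(.data$x), !is.na(.data$y))
  if (nrow(j) < 3) abort("need at least 3 shared genes")
  if (stats::sd(j$x) == 0 || stats::sd(j$y) == 0) {
    abort("zero variance in one of the fold-change profiles")
  }
  tibble(r = stats::cor(j$x, j$y),
         spread_ratio = stats::sd(j$x) / stats::sd(j$y),
         n_genes = nrow(j))
}
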