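#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a hurdle model fit
#'
#' One row per coefficient per component ("discrete" for the logistic
#' detection part, "continuous" for the Gaussian part on detected cells),
#' with standard errors from the component covariance matrices.
#'
#' @param x a `hurdle_fit` from [fit_hurdle_gene()].
#' @param ... unused.
#' @return tibble with `component`, `term`, `estimate`, `std.error`.
#' @export
tidy.hurdle_fit <- function(x, ...) {
  rows <- list()
  if (isTRUE(x$discrete$informative)) {
    rows$disc <- tibble(
      component = "discrete", term = names(x$discrete$coef),
      estimate = unname(x$discrete$coef),
      std.error = sqrt(pmax(diag(x$discrete$vcov), 0))
    )
  }
  if (!is.null(x$continuous)) {
    rows$cont <- tibble(
      component = "continuous", term = names(x$continuous$coef),
      estimate = unname(x$continuous$coef),
      std.error = sqrt(pmax(diag(x$continuous$vcov), 0))
    )
  }
  if (length(rows) == 0) {
    return(tibble(component = character(), term = character(),
                  estimate = numeric(), std.error = numeric()))
  }
  bind_rows(rows)
}

#' Glance at a hurdle model fit
#'
#' @param x a `hurdle_fit` from [fit_hurdle_gene()].
#' @param ... unused.
#' @return one-row tibble: `n`, `n_detected`, `deviance_discrete`,
#'   `deviance_continuous`, `sigma2`, `converged`.
#' @export
glance.hurdle_fit <- function(x, ...) {
  tibble(
    n = x$n,
    n_detected = x$detected,
    deviance_discrete = if (isTRUE(x$discrete$informative))
      x$discrete$deviance else NA_real_,
    deviance_continuous = x$continuous$deviance %||% NA_real_,
    sigma2 = x$continuous$sigma2 %||% NA_real_,
    converged = isTRUE(x$discrete$converged)
  )
}

#' Glance at a differential-expression result
#'
#' @param x a `de_result` tibble.
#' @param fdr_cut FDR cutoff used for the significant-gene count.
#' @param ... unused.
#' @return one-row tibble: `n_genes`, `n_tested`, `n_significant`,
#'   `n_up`, `n_down`.
#' @export
glance.de_result <- function(x, fdr_cut = 0.05, ...) {
  sig <- !is.na(x$fdr) & x$fdr < fdr_cut
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$pvalue)),
    n_significant = sum(sig),
    n_up = sum(sig & x$direction == "up"),
    n_down = sum(sig & x$direction == "down")
  )
}

#' Glance at a GSEA result
#'
#' @param x a `gsea_result` tibble.
#' @param fdr_cut FDR cutoff for the significant-set count (default 0.25).
#' @param ... unused.
#' @return one-row tibble: `n_sets`, `n_significant`, `n_enriched_up`,
#'   `n_enriched_down`.
#' @export
glance.gsea_result <- function(x, fdr_cut = 0.25, ...) {
  sig <- !is.na(x$fdr) & x$fdr < fdr_cut
  tibble(
    n_sets = nrow(x),
    n_significant = sum(sig),
    n_enriched_up = sum(sig & x$nes > 0),
    n_enriched_down = sum(sig & x$nes < 0)
  )
}
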