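#' Sex-independent T2D altered genes
#'
#' Genes significant in the pooled T2D-vs-healthy comparison (run with both
#' CDR and sex as covariates) at the FDR cutoff, split by direction.
#'
#' @param de_pooled a `de_result` from the pooled comparison; it must have
#'   been run with `sex` among its covariates.
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return tibble with `gene`, `direction`, `fdr`.
#' @export
call_sex_independent <- function(de_pooled, fdr_cut = 0.05) {
  cmp <- attr(de_pooled, "comparison")
  if (!is.null(cmp) && !"sex" %in% cmp$covariates) {
    abort("de_pooled must be computed with 'sex' as a covariate")
  }
  de_pooled %>%
    filter(!is.na(.data$fdr), .data$fdr < fdr_cut) %>%
    transmute(.data$gene, .data$direction, .data$fdr) %>%
    as_tibble()
}

#' Candidate sex-dependent T2D altered genes (Venn stage)
#'
#' Per-sex T2D-vs-healthy DEGs at the FDR cutoff, with the sex-independent
#' genes removed: the non-overlapping genes are the potential sex-dependent
#' T2D altered genes.
#'
#' @param de_female,de_male `de_result` tibbles from the within-sex
#'   comparisons (covariate CDR).
#' @param sex_independent tibble from [call_sex_independent()] (or a
#'   character vector of genes).
#' @param fdr_cut FDR cutoff (default 0.05).
#' @return list with tibbles `candidates_female`, `candidates_male`
#'   (columns `gene`, `direction`, `fdr`), and `degs_female`, `degs_male`
#'   (the per-sex significant sets before subtraction).
#' @export
candidate_sex_dependent <- function(de_female, de_male, sex_independent,
                                    fdr_cut = 0.05) {
  si_genes <- if (is.character(sex_independent)) sex_independent
              else sex_independent$gene
  degs <- function(de) {
    de %>%
      filter(!is.na(.data$fdr), .data$fdr < fdr_cut) %>%
      transmute(.data$gene, .data$direction, .data$fdr) %>%
      as_tibble()
  }
  df <- degs(de_female)
  dm <- degs(de_male)
  list(
    candidates_female = filter(df, !.data$gene %in% si_genes),
    candidates_male = filter(dm, !.data$gene %in% si_genes),
    degs_female = df,
    degs_male = dm
  )
}

ci_disjoint <- function(lo1, hi1, lo2, hi2) {
  # closed-interval rule: touching endpoints count as overlap
  hi1 < lo2 | lo1 > hi2
}

#' Refine candidates into final sex-dependent T2D altered genes
#'
#' A candidate of one sex is accepted iff (1) its log2 fold-change 95%
#' confidence interval from that sex's analysis does not overlap the
#' interval from the other sex (closed intervals: touching endpoints count
#' as overlapping), and (2) the unadjusted p value in the non-significant
#' sex exceeds `p_other_min`. Both filter flags are recorded per gene.
#'
#' @param candidates result of [candidate_sex_dependent()].
#' @param de_female,de_male the per-sex `de_result` tibbles (must carry
#'   `ci_low`, `ci_high`, `pvalue` for every candidate).
#' @param p_other_min minimum p value required in the other sex
#'   (default 0.2, strict inequality).
#' @param p_other_use `"pvalue"` (default) or `"fdr"`: which column of the
#'   other sex's table criterion 2 reads.
#' @return object of class `sex_dependent_calls`: list with
#'   `sex_independent` (carried through if supplied via attribute),
#'   `candidates_female`, `candidates_male`, `final_female`, `final_male`;
#'   the final tibbles carry `gene`, `direction`, `log2fc`, `ci_pass`,
#'   `p_other_pass`, `accepted`. Disjointness invariants are asserted.
#' @export
refine_sex_dependent <- function(candidates, de_female, de_male,
                                 p_other_min = 0.2,
                                 p_other_use = c("pvalue", "fdr")) {
  p_other_use <- match.arg(p_other_use)
  refine_one <- function(cand, de_self, de_other) {
    if (nrow(cand) == 0) {
      return(tibble(gene = character(), direction = character(),
                    log2fc = numeric(), ci_pass = logical(),
                    p_other_pass = logical(), accepted = logical()))
    }
    is_ <- match(cand$gene, de_self$gene)
    io <- match(cand$gene, de_other$gene)
    if (anyNA(is_) || anyNA(io)) {
      abort("candidate gene missing from a per-sex DE table")
    }
    ci_pass <- ci_disjoint(de_self$ci_low[is_], de_self$ci_high[is_],
                           de_other$ci_low[io], de_other$ci_high[io])
    p_other <- de_other[[p_other_use]][io]
    p_pass <- !is.na(p_other) & p_other > p_other_min
    tibble(
      gene = cand$gene,
      direction = ifelse(de_self$log2fc[is_] >= 0, "up", "down"),
      log2fc = de_self$log2fc[is_],
      ci_pass = ci_pass,
      p_other_pass = p_pass,
      accepted = ci_pass & p_pass
    )
  }
  flags_f <- refine_one(candidates$candidates_female, de_female, de_male)
  flags_m <- refine_one(candidates$candidates_male, de_male, de_female)
  out <- structure(
    list(
      candidates_female = flags_f,
      candidates_male = flags_m,
      final_female = filter(flags_f, .data$accepted),
      final_male = filter(flags_m, .data$accepted),
      p_other_min = p_other_min,
      p_other_use = p_other_use
    ),
    class = "sex_dependent_calls"
  )
  if (length(intersect(out$final_female$gene, out$final_male$gene)) > 0) {
    abort("internal invariant violated: a gene is in both final sets")
  }
  out
}

#' Run the full sex-dependent classification chain
#'
#' Convenience wrapper: [call_sex_independent()] on the pooled comparison,
#' [candidate_sex_dependent()] on the per-sex comparisons, then
#' [refine_sex_dependent()].
#'
#' @inheritParams call_sex_independent
#' @inheritParams candidate_sex_dependent
#' @inheritParams refine_sex_dependent
#' @return a `sex_dependent_calls` object that additionally carries the
#'   `sex_independent` tibble.
#' @export
classify_sex_dependent <- function(de_pooled, de_female, de_male,
                                   fdr_cut = 0.05, p_other_min = 0.2,
                                   p_other_use = "pvalue") {
  si <- call_sex_independent(de_pooled, fdr_cut = fdr_cut)
  cand <- candidate_sex_dependent(de_female, de_male, si, fdr_cut = fdr_cut)
  out <- refine_sex_dependent(cand, de_female, de_male,
                              p_other_min = p_other_min,
                              p_other_use = p_other_use)
  out$sex_independent <- si
  final <- c(out$final_female$gene, out$final_male$gene)
  if (length(intersect(si$gene, final)) > 0) {
    abort("internal invariant violated: final genes overlap sex-independent set")
  }
  out
}

#' @method print sex_dependent_calls
#' @export
print.sex_dependent_calls <- function(x, ...) {
  cat("<sex_dependent_calls>\n")
  if (!is.null(x$sex_independent)) {
    cat(sprintf("  sex-independent: %d genes\n", nrow(x$sex_independent)))
  }
  cat(sprintf("  candidates: %d female, %d male\n",
              nrow(x$candidates_female), nrow(x$candidates_male)))
  cat(sprintf("  final: %d female-specific, %d male-specific\n",
              nrow(x$final_female), nrow(x$final_male)))
  invisible(x)
}
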