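#' Rank genes by the signed normal quantile of their DE p values
#'
#' Builds the preranked GSEA input from a differential-expression table by
#' mapping each gene's p value to a standard-normal quantile and signing it
#' with the direction of its fold change.
#'
#' Two orientations are provided. `"paper_intent"` (default) computes
#' `z = -qnorm(p) * sign(lfc)` (equivalently `qnorm(1 - p) * sign(lfc)`), so
#' significant up-regulated genes get large positive z and rank at the top —
#' the orientation under which positively enriched sets are up-regulated
#' sets. `"literal"` computes `qnorm(p) * sign(lfc)`, the sign-flipped
#' variant; see the methods vignette for why both exist.
#'
#' @param de a `de_result` tibble (needs `gene`, `pvalue`, `log2fc`).
#' @param orientation `"paper_intent"` or `"literal"`.
#' @return a `ranked_genes` tibble (`gene`, `z`) sorted by decreasing z;
#'   ties are broken by decreasing |log2fc| then gene id.
#' @export
rank_genes_z <- function(de, orientation = c("paper_intent", "literal")) {
  orientation <- match.arg(orientation)
  d <- filter(de, !is.na(.data$pvalue), !is.na(.data$log2fc))
  if (nrow(d) == 0) abort("no genes with defined p values")
  p <- pmin(pmax(d$pvalue, 1e-300), 1 - 1e-16)
  z <- stats::qnorm(p) * sign(d$log2fc)
  if (orientation == "paper_intent") z <- -z
  out <- tibble(gene = d$gene, z = z)
  out <- out[order(-out$z, -abs(d$log2fc), out$gene, method = "radix"), ]
  attr(out, "orientation") <- orientation
  class(out) <- c("ranked_genes", class(out))
  out
}

#' Weighted running-sum enrichment score
#'
#' The classic GSEA statistic: walking down the ranked list, hits increment
#' the running sum by `|z|^weight` (normalized by the set's total hit
#' weight) and misses decrement it by `1/(N - Nh)`. The enrichment score is
#' the extremum of the running sum; the leading edge is the set members at
#' or before the extremum (at or after it, for negative scores).
#'
#' @param ranked a `ranked_genes` tibble (or any tibble with `gene`, `z`
#'   sorted by decreasing z).
#' @param gene_set character vector of gene ids.
#' @param weight exponent on |z| for hit increments (0 = unweighted KS,
#'   1 = classic GSEA default).
#' @return list with `es`, `running` (numeric vector over the ranking),
#'   `leading_edge` (character vector), `peak` (index of the extremum).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- ranked$gene
  N <- length(genes)
  hit <- genes %in% gene_set
  nh <- sum(hit)
  if (nh == 0) abort("gene set has empty intersection with the ranking")
  if (nh == N) abort("gene set covers the entire ranking")
  w <- abs(ranked$z)^weight
  nr <- sum(w[hit])
  inc <- numeric(N)
  inc[hit] <- if (nr > 0) w[hit] / nr else 1 / nh
  inc[!hit] <- -1 / (N - nh)
  running <- cumsum(inc)
  peak <- which.max(abs(running))
  es <- running[peak]
  le <- if (es >= 0) genes[seq_len(peak)][hit[seq_len(peak)]]
        else genes[peak:N][hit[peak:N]]
  list(es = es, running = running, leading_edge = le, peak = peak)
}

# Enrichment score from sorted hit positions only (same statistic as
# enrichment_score, O(set size)); used for the permutation null.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  wi <- w[pos]
  nr <- sum(wi)
  cw <- if (nr > 0) cumsum(wi) / nr else seq_len(k) / k
  miss <- 1 / (N - k)
  after <- cw - (pos - seq_len(k)) * miss
  before <- c(0, cw[-k]) - (pos - seq_len(k)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Preranked gene set enrichment analysis
#'
#' Computes enrichment scores for each gene set against the ranked list,
#' a gene-label permutation null (random sets of matching size drawn from
#' the ranked universe), sign-stratified normalized enrichment scores
#' (`NES = ES / mean |same-sign null ES|`), nominal permutation p values,
#' and the sign-stratified GSEA false discovery rate.
#'
#' @param ranked a `ranked_genes` tibble.
#' @param sets named list of character vectors.
#' @param n_perm number of permutations per set.
#' @param min_size,max_size set-size bounds applied after intersecting each
#'   set with the ranking.
#' @param weight hit-weight exponent (see [enrichment_score()]).
#' @param seed integer seed for the permutation draws.
#' @return a `gsea_result` tibble: `set`, `size`, `es`, `nes`, `pvalue`,
#'   `fdr`, `leading_edge` (list column).
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000, min_size = 15,
                           max_size = 500, weight = 1, seed = 1L) {
  genes <- ranked$gene
  N <- length(genes)
  sizes <- vapply(sets, function(s) sum(genes %in% s), 1L)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) abort("all gene sets were filtered out by the size bounds")
  sets <- sets[keep]
  sizes <- sizes[keep]
  w <- abs(ranked$z)^weight

  obs <- lapply(sets, function(s) enrichment_score(ranked, s, weight = weight))
  es_obs <- vapply(obs, `[[`, 1, "es")

  null_es <- withr::with_seed(seed, {
    lapply(sizes, function(k) {
      vapply(seq_len(n_perm), function(i) {
        es_from_positions(sort.int(sample.int(N, k)), w, N)
      }, 1)
    })
  })

  norm_one <- function(es, null) {
    pos <- null[null > 0]
    neg <- null[null < 0]
    mp <- if (length(pos)) mean(pos) else NA_real_
    mn <- if (length(neg)) mean(abs(neg)) else NA_real_
    nes_null <- ifelse(null > 0, null / mp,
                       ifelse(null < 0, null / mn, 0))
    if (es >= 0) {
      list(nes = if (is.na(mp)) NA_real_ else es / mp,
           p = if (length(pos)) mean(pos >= es) else 0,
           nes_null = nes_null)
    } else {
      list(nes = if (is.na(mn)) NA_real_ else es / mn,
           p = if (length(neg)) mean(neg <= es) else 0,
           nes_null = nes_null)
    }
  }
  normed <- mapply(norm_one, es_obs, null_es, SIMPLIFY = FALSE)
  nes <- vapply(normed, `[[`, 1, "nes")
  pval <- vapply(normed, `[[`, 1, "p")
  null_nes_pool <- unlist(lapply(normed, `[[`, "nes_null"))

  q_of <- function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num_d <- sum(null_nes_pool >= 0)
      num <- if (num_d) sum(null_nes_pool >= x) / num_d else 0
      den_d <- sum(nes >= 0, na.rm = TRUE)
      den <- sum(nes >= x, na.rm = TRUE) / den_d
    } else {
      num_d <- sum(null_nes_pool < 0)
      num <- if (num_d) sum(null_nes_pool <= x) / num_d else 0
      den_d <- sum(nes < 0, na.rm = TRUE)
      den <- sum(nes <= x, na.rm = TRUE) / den_d
    }
    min(num / max(den, .Machine$double.eps), 1)
  }
  fdr <- vapply(nes, q_of, 1)

  out <- tibble(
    set = names(sets), size = unname(sizes), es = unname(es_obs),
    nes = unname(nes), pvalue = unname(pval), fdr = unname(fdr),
    leading_edge = unname(lapply(obs, `[[`, "leading_edge"))
  )
  out <- out[order(-out$nes), ]
  attr(out, "n_perm") <- n_perm
  attr(out, "weight") <- weight
  class(out) <- c("gsea_result", class(out))
  out
}
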