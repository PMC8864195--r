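#' Configuration for the synthetic islet scRNA-seq generator
#'
#' Builds a validated configuration object for [simulate_islet()]. The
#' defaults emulate a desk-scale version of a FACS-sorted mouse islet
#' experiment: cells from healthy (8-week and 9-month) and high-fat-diet T2D
#' (9-month) mice of both sexes, dominated by insulin-expressing beta cells,
#' with a handful of hormone genes (Ins2, Ins1, Gcg, Sst, Ppy, ...) that can
#' take over half of a cell's UMI, X/Y-linked sex marker genes,
#' mitochondrial genes, a small cycling subpopulation, and planted
#' sex-biased, shared-T2D, and sex-specific-T2D expression effects whose
#' identities are recorded as ground truth.
#'
#' Counts are drawn as a Poisson mixture: per-gene relative abundances from a
#' gamma distribution, per-cell library sizes from a log-normal, an optional
#' per-entry gamma overdispersion multiplier (negative-binomial-like
#' marginal), followed by logistic dropout in log mean expression.
#'
#' @param n_genes total number of genes simulated.
#' @param cells_per_group tibble with columns `sex` ("M"/"F"), `condition`
#'   ("HC"/"T2D"), `batch` (free label, e.g. age), `n` (cell count). The
#'   default halves the study-style group sizes: 8W-HC 528M/384F,
#'   9M-T2D 288M/288F, 9M-HC 288M/240F.
#' @param celltype_props named proportions over cell types
#'   (`beta`, `alpha`, `delta`, `pp`); the default mirrors a beta-sorted
#'   islet preparation (90% beta).
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   the per-cell target UMI total. Defaults are calibrated so the median
#'   number of detected genes per cell is near 1500.
#' @param baseline_shape,baseline_rate gamma parameters for per-gene
#'   relative abundance.
#' @param dropout_midpoint,dropout_slope logistic dropout parameters on the
#'   log2 mean-expression scale: an entry with mean mu is kept with
#'   probability `plogis(dropout_slope * (log2(mu) - dropout_midpoint))`.
#'   `dropout_slope` must be > 0.
#' @param dropout logical; set `FALSE` to disable the dropout thinning step
#'   (the count-drawing phase is unchanged, so the same seed reproduces the
#'   identical pre-dropout matrix).
#' @param overdispersion extra-Poisson dispersion; 0 gives pure Poisson.
#' @param n_dominant_genes how many of the named hormone genes receive
#'   boosted cell-type-specific means (at most 8).
#' @param program_genes_per_type size of each cell type's identity program:
#'   a disjoint set of background genes up-regulated in that type, giving
#'   cell types the broad transcriptome differences real islet cell types
#'   have beyond their hormone genes.
#' @param program_log2fc log2 boost of program genes in their own type.
#' @param dominant_scale multiplier on all hormone-gene boosts.
#' @param frac_mito fraction of genes flagged mitochondrial.
#' @param n_cycle_cells number of beta cells converted into a cycling
#'   subpopulation with boosted cell-cycle gene expression.
#' @param n_cycle_genes,cycle_boost number of cell-cycle genes and their
#'   mean multiplier in cycling cells.
#' @param n_sex_biased,n_t2d_shared,n_t2d_female,n_t2d_male how many effects
#'   of each class to plant when explicit effect tables are not supplied.
#' @param effect_log2fc magnitude of planted log2 fold changes.
#' @param sex_biased optional explicit tibble (`gene`, `log2fc`,
#'   `sex_direction`): `gene` expressed `2^log2fc`-fold higher in cells of
#'   `sex_direction`.
#' @param t2d_shared,t2d_female_specific,t2d_male_specific optional explicit
#'   tibbles (`gene`, `log2fc`): `2^log2fc` multiplier in T2D cells (of the
#'   named sex for the sex-specific tables).
#' @param seed integer seed; identical configurations with identical seeds
#'   produce byte-identical datasets.
#' @return a `islet_sim_config` list.
#' @export
islet_sim_config <- function(n_genes = 2500,
                             cells_per_group = NULL,
                             celltype_props = c(beta = 0.90, alpha = 0.055,
                                                delta = 0.03, pp = 0.015),
                             library_size_log_mean = log(33000),
                             library_size_log_sd = 0.45,
                             baseline_shape = 0.4,
                             baseline_rate = 1,
                             dropout_midpoint = -4,
                             dropout_slope = 1,
                             dropout = TRUE,
                             overdispersion = 0.6,
                             n_dominant_genes = 8,
                             dominant_scale = 1,
                             program_genes_per_type = 250,
                             program_log2fc = 2,
                             frac_mito = 0.013,
                             n_cycle_cells = 60,
                             n_cycle_genes = 30,
                             cycle_boost = 16,
                             n_sex_biased = 30,
                             n_t2d_shared = 20,
                             n_t2d_female = 15,
                             n_t2d_male = 15,
                             effect_log2fc = 1,
                             sex_biased = NULL,
                             t2d_shared = NULL,
                             t2d_female_specific = NULL,
                             t2d_male_specific = NULL,
                             seed = 1L) {
  if (is.null(cells_per_group)) {
    cells_per_group <- tibble(
      sex       = c("M", "F", "M", "F", "M", "F"),
      condition = c("HC", "HC", "T2D", "T2D", "HC", "HC"),
      batch     = c("8W", "8W", "9M", "9M", "9M", "9M"),
      n         = c(528L, 384L, 288L, 288L, 288L, 240L)
    )
  }
  cells_per_group <- as_tibble(cells_per_group)
  stopifnot(all(c("sex", "condition", "n") %in% names(cells_per_group)))
  if (!"batch" %in% names(cells_per_group)) cells_per_group$batch <- "b1"
  if (any(cells_per_group$n < 0)) abort("group cell counts must be >= 0")
  if (any(cells_per_group$n == 0)) {
    warn("cells_per_group contains empty groups")
  }
  if (!all(cells_per_group$sex %in% c("M", "F"))) {
    abort("sex must be 'M' or 'F'")
  }
  if (!all(cells_per_group$condition %in% c("HC", "T2D"))) {
    abort("condition must be 'HC' or 'T2D'")
  }
  if (dropout_slope <= 0) abort("dropout_slope must be > 0")
  if (n_genes < 60) abort("n_genes too small for the structured gene layout")
  stopifnot(
    abs(sum(celltype_props) - 1) < 1e-8,
    all(celltype_props >= 0),
    overdispersion >= 0, frac_mito >= 0, frac_mito < 0.5,
    n_cycle_cells >= 0, effect_log2fc != 0
  )

  cfg <- list(
    n_genes = as.integer(n_genes),
    cells_per_group = cells_per_group,
    celltype_props = celltype_props,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    baseline_shape = baseline_shape,
    baseline_rate = baseline_rate,
    dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope,
    dropout = isTRUE(dropout),
    overdispersion = overdispersion,
    n_dominant_genes = min(as.integer(n_dominant_genes), 8L),
    dominant_scale = dominant_scale,
    program_genes_per_type = as.integer(program_genes_per_type),
    program_log2fc = program_log2fc,
    frac_mito = frac_mito,
    n_cycle_cells = as.integer(n_cycle_cells),
    n_cycle_genes = as.integer(n_cycle_genes),
    cycle_boost = cycle_boost,
    n_sex_biased = as.integer(n_sex_biased),
    n_t2d_shared = as.integer(n_t2d_shared),
    n_t2d_female = as.integer(n_t2d_female),
    n_t2d_male = as.integer(n_t2d_male),
    effect_log2fc = effect_log2fc,
    sex_biased = sex_biased,
    t2d_shared = t2d_shared,
    t2d_female_specific = t2d_female_specific,
    t2d_male_specific = t2d_male_specific,
    seed = as.integer(seed)
  )
  class(cfg) <- "islet_sim_config"
  cfg
}

# Named hormone genes and their cell-type-specific relative weights,
# expressed as fractions of the summed baseline abundance B. Tuned so that
# in beta cells Ins2+Ins1 routinely exceeds 50% of the cell's UMI.
dominant_weight_table <- function() {
  list(
    beta  = c(Ins2 = 0.90, Ins1 = 0.30, Gcg = 0.010, Sst = 0.004,
              Ppy = 0.003, Pyy = 0.010, Ttr = 0.080, Malat1 = 0.060),
    alpha = c(Ins2 = 0.02, Ins1 = 0.010, Gcg = 1.50, Sst = 0.004,
              Ppy = 0.004, Pyy = 0.020, Ttr = 0.150, Malat1 = 0.060),
    delta = c(Ins2 = 0.02, Ins1 = 0.005, Gcg = 0.010, Sst = 1.20,
              Ppy = 0.004, Pyy = 0.050, Ttr = 0.100, Malat1 = 0.060),
    pp    = c(Ins2 = 0.01, Ins1 = 0.004, Gcg = 0.010, Sst = 0.004,
              Ppy = 1.00, Pyy = 0.300, Ttr = 0.080, Malat1 = 0.060)
  )
}

build_gene_annotation <- function(config) {
  hormone <- c("Ins2", "Ins1", "Gcg", "Sst", "Ppy", "Pyy", "Ttr", "Malat1")
  hormone <- hormone[seq_len(config$n_dominant_genes)]
  sex_genes <- c("Xist", "Eif2s3y", "Ddx3y", "Uty")
  n_mito <- max(1L, round(config$frac_mito * config$n_genes))
  mito <- c("mt-Rnr2", sprintf("mt-Gene%02d", seq_len(max(0L, n_mito - 1L))))
  cyc_named <- c("Mki67", "Top2a", "Ccnb1", "Cdk1", "Birc5")
  n_cyc <- config$n_cycle_genes
  cycle <- c(cyc_named[seq_len(min(5L, n_cyc))],
             if (n_cyc > 5) sprintf("Ccyc%02d", seq_len(n_cyc - 5L)))
  n_special <- length(hormone) + length(sex_genes) + length(mito) + length(cycle)
  n_generic <- config$n_genes - n_special
  if (n_generic < 10) abort("n_genes too small for the structured gene layout")
  generic <- sprintf("Gene%04d", seq_len(n_generic))
  gene_id <- c(hormone, sex_genes, mito, cycle, generic)

  chrom <- rep(NA_character_, length(gene_id))
  chrom[gene_id == "Xist"] <- "X"
  chrom[gene_id %in% c("Eif2s3y", "Ddx3y", "Uty")] <- "Y"
  chrom[gene_id %in% mito] <- "MT"
  autosomes <- as.character(1:19)
  idx <- is.na(chrom)
  chrom[idx] <- autosomes[(seq_len(sum(idx)) - 1L) %% 19L + 1L]

  marker_map <- c(Ins2 = "beta", Gcg = "alpha", Sst = "delta", Ppy = "pp")
  tibble(
    gene_id = gene_id,
    chromosome = chrom,
    mito = gene_id %in% mito,
    cell_cycle = gene_id %in% cycle,
    marker_of = unname(marker_map[gene_id])
  )
}

expand_cells <- function(config) {
  groups <- config$cells_per_group
  props <- config$celltype_props
  rows <- list()
  for (i in seq_len(nrow(groups))) {
    n <- groups$n[i]
    if (n == 0) next
    # largest-remainder apportionment of n cells over cell types
    raw <- props * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
      extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
      base[extra] <- base[extra] + 1
    }
    for (ct in names(props)) {
      if (base[[ct]] == 0) next
      rows[[length(rows) + 1L]] <- tibble(
        declared_sex = groups$sex[i], condition = groups$condition[i],
        batch = groups$batch[i], cell_type = ct, nn = base[[ct]]
      )
    }
  }
  cells <- bind_rows(rows)
  cells <- cells[rep(seq_len(nrow(cells)), cells$nn), ]
  cells$nn <- NULL
  cells$cell_id <- sprintf("cell%05d", seq_len(nrow(cells)))
  cells$is_cycle <- FALSE
  # convert a spread of beta cells into the cycling subpopulation
  if (config$n_cycle_cells > 0) {
    beta_idx <- which(cells$cell_type == "beta")
    if (length(beta_idx) < config$n_cycle_cells) {
      abort("n_cycle_cells exceeds the number of beta cells")
    }
    pick <- beta_idx[round(seq(1, length(beta_idx),
                               length.out = config$n_cycle_cells))]
    cells$is_cycle[pick] <- TRUE
  }
  cells[, c("cell_id", "declared_sex", "condition", "batch",
            "cell_type", "is_cycle")]
}

validate_effect_tables <- function(truth, genes) {
  ann <- genes
  y_genes <- ann$gene_id[ann$chromosome == "Y"]
  all_ids <- ann$gene_id
  check <- function(tb, nm, cols) {
    if (is.null(tb)) return(invisible())
    if (!all(cols %in% names(tb))) {
      abort(sprintf("effect table '%s' must have columns %s",
                    nm, paste(cols, collapse = ", ")))
    }
    if (!all(tb$gene %in% all_ids)) {
      abort(sprintf("effect table '%s' references unknown genes", nm))
    }
    if (any(tb$log2fc == 0)) {
      abort(sprintf("effect table '%s' contains zero log2fc", nm))
    }
  }
  check(truth$sex_biased, "sex_biased", c("gene", "log2fc", "sex_direction"))
  check(truth$t2d_shared, "t2d_shared", c("gene", "log2fc"))
  check(truth$t2d_female_specific, "t2d_female_specific", c("gene", "log2fc"))
  check(truth$t2d_male_specific, "t2d_male_specific", c("gene", "log2fc"))
  if (!is.null(truth$t2d_female_specific) &&
      any(truth$t2d_female_specific$gene %in% y_genes)) {
    abort("cannot plant a T2D effect on a Y-linked gene in female cells")
  }
  if (!is.null(truth$sex_biased) &&
      any(truth$sex_biased$gene %in% y_genes &
          truth$sex_biased$sex_direction == "F")) {
    abort("cannot plant a female-up effect on a Y-linked gene")
  }
  ov <- list(truth$t2d_shared$gene, truth$t2d_female_specific$gene,
             truth$t2d_male_specific$gene)
  for (i in 1:2) for (j in (i + 1):3) {
    if (length(intersect(ov[[i]], ov[[j]])) > 0) {
      abort("T2D effect classes must be pairwise disjoint")
    }
  }
  invisible()
}

#' Simulate an islet-like UMI count dataset with planted ground truth
#'
#' Draws a genes x cells UMI count matrix under the configured group design,
#' plants the configured sex-biased and T2D effects, and returns the counts
#' together with per-cell metadata, per-gene annotation, and a full record
#' of every planted effect. Y-linked genes are structurally zero in female
#' cells and the Xist-like X marker is expressed only in female cells.
#'
#' @param config an [islet_sim_config()] object.
#' @return an object of class `islet_sim`: a list with elements `counts`
#'   (integer genes x cells matrix), `cells` (tibble of per-cell metadata),
#'   `genes` (tibble of per-gene annotation), `truth` (list of planted
#'   effect tables, marker assignment, sex markers, cycle genes), and
#'   `config`.
#' @export
simulate_islet <- function(config) {
  if (!inherits(config, "islet_sim_config")) {
    abort("`config` must be created by islet_sim_config()")
  }
  genes <- build_gene_annotation(config)
  cells <- expand_cells(config)
  n_g <- nrow(genes)
  n_c <- nrow(cells)
  hormone <- genes$gene_id[!is.na(match(genes$gene_id,
                                        names(dominant_weight_table()$beta)))]
  special <- genes$gene_id[genes$mito | genes$cell_cycle |
                             genes$chromosome %in% c("X", "Y") |
                             genes$gene_id %in% hormone]

  out <- withr::with_seed(config$seed, {
    ## -- baseline relative abundances ------------------------------------
    w_base <- stats::rgamma(n_g, shape = config$baseline_shape,
                            rate = config$baseline_rate)
    names(w_base) <- genes$gene_id
    B <- sum(w_base[setdiff(genes$gene_id, special)])
    # mitochondrial genes total ~3% of baseline mass
    mito_ids <- genes$gene_id[genes$mito]
    w_base[mito_ids] <- w_base[mito_ids] / sum(w_base[mito_ids]) * 0.03 * B
    # sex markers: detectable but small
    w_base["Xist"] <- 0.004 * B
    w_base[c("Eif2s3y", "Ddx3y", "Uty")] <- 0.0015 * B

    ## -- cell-type identity programs --------------------------------------
    generic_pool <- setdiff(genes$gene_id, special)
    types <- names(config$celltype_props)
    n_prog <- config$program_genes_per_type
    programs <- list()
    if (n_prog > 0) {
      if (n_prog * length(types) > length(generic_pool)) {
        abort("program_genes_per_type too large for n_genes")
      }
      prog_pick <- sample(generic_pool, n_prog * length(types))
      programs <- split(prog_pick, rep(types, each = n_prog))
    }

    ## -- planted effects --------------------------------------------------
    truth <- list(
      sex_biased = config$sex_biased,
      t2d_shared = config$t2d_shared,
      t2d_female_specific = config$t2d_female_specific,
      t2d_male_specific = config$t2d_male_specific
    )
    if (is.null(truth$sex_biased) || is.null(truth$t2d_shared) ||
        is.null(truth$t2d_female_specific) || is.null(truth$t2d_male_specific)) {
      generic <- setdiff(genes$gene_id, special)
      # plant on genes expressed well enough to be detectable
      eligible <- generic[w_base[generic] >
                            stats::quantile(w_base[generic], 0.4)]
      need <- config$n_sex_biased + config$n_t2d_shared +
        config$n_t2d_female + config$n_t2d_male
      if (need > length(eligible)) abort("not enough eligible genes for effects")
      pick <- sample(eligible, need)
      o <- 0L
      take <- function(k) {
        res <- pick[seq_len(k) + o]
        o <<- o + k
        res
      }
      lfc <- config$effect_log2fc
      if (is.null(truth$sex_biased)) {
        g <- take(config$n_sex_biased)
        truth$sex_biased <- tibble(
          gene = g, log2fc = abs(lfc),
          sex_direction = sample(c("M", "F"), length(g), replace = TRUE))
      } else o <- o  # explicit table supplied
      if (is.null(truth$t2d_shared)) {
        g <- take(config$n_t2d_shared)
        truth$t2d_shared <- tibble(
          gene = g, log2fc = lfc * sample(c(-1, 1), length(g), replace = TRUE))
      }
      if (is.null(truth$t2d_female_specific)) {
        g <- take(config$n_t2d_female)
        truth$t2d_female_specific <- tibble(
          gene = g, log2fc = lfc * sample(c(-1, 1), length(g), replace = TRUE))
      }
      if (is.null(truth$t2d_male_specific)) {
        g <- take(config$n_t2d_male)
        truth$t2d_male_specific <- tibble(
          gene = g, log2fc = lfc * sample(c(-1, 1), length(g), replace = TRUE))
      }
    }
    validate_effect_tables(truth, genes)

    ## -- per-cell library sizes -------------------------------------------
    lib <- stats::rlnorm(n_c, config$library_size_log_mean,
                         config$library_size_log_sd)

    ## -- per-group mean construction and count draws ----------------------
    dom <- dominant_weight_table()
    cyc_ids <- genes$gene_id[genes$cell_cycle]
    y_ids <- genes$gene_id[genes$chromosome == "Y"]
    counts <- matrix(0L, n_g, n_c, dimnames = list(genes$gene_id,
                                                   cells$cell_id))
    mu_mat <- matrix(0, n_g, n_c)
    grp_key <- paste(cells$declared_sex, cells$condition,
                     cells$cell_type, cells$is_cycle)
    for (key in sort(unique(grp_key))) {
      idx <- which(grp_key == key)
      cc <- cells[idx[1], ]
      w <- w_base
      dw <- dom[[cc$cell_type]][hormone] * config$dominant_scale * B
      w[hormone] <- dw
      pg <- programs[[cc$cell_type]]
      if (length(pg)) w[pg] <- w[pg] * 2^config$program_log2fc
      if (cc$declared_sex == "F") {
        w[y_ids] <- 0
      } else {
        w["Xist"] <- 0
      }
      sb <- truth$sex_biased
      if (nrow(sb)) {
        hit <- sb$sex_direction == cc$declared_sex
        w[sb$gene[hit]] <- w[sb$gene[hit]] * 2^sb$log2fc[hit]
      }
      if (cc$condition == "T2D") {
        ts <- truth$t2d_shared
        w[ts$gene] <- w[ts$gene] * 2^ts$log2fc
        spec <- if (cc$declared_sex == "F") truth$t2d_female_specific
                else truth$t2d_male_specific
        w[spec$gene] <- w[spec$gene] * 2^spec$log2fc
      }
      if (cc$is_cycle) w[cyc_ids] <- w[cyc_ids] * config$cycle_boost
      p <- w / sum(w)
      mu <- outer(p, lib[idx])
      if (config$overdispersion > 0) {
        sh <- 1 / config$overdispersion
        mu <- mu * matrix(stats::rgamma(length(mu), shape = sh, rate = sh),
                          nrow(mu))
      }
      counts[, idx] <- stats::rpois(length(mu), mu)
      mu_mat[, idx] <- mu
    }

    ## -- dropout thinning (after all count draws, so disabling dropout
    ##    regenerates the identical pre-dropout matrix) --------------------
    if (config$dropout) {
      nz <- which(counts > 0)
      keep_p <- stats::plogis(config$dropout_slope *
                                (log2(mu_mat[nz]) - config$dropout_midpoint))
      drop <- stats::runif(length(nz)) > keep_p
      counts[nz[drop]] <- 0L
    }
    list(counts = counts, truth = truth, lib = lib, programs = programs)
  })

  storage.mode(out$counts) <- "integer"
  cells$library_size <- out$lib
  cells$total_umi <- colSums(out$counts)
  cells$detected_genes <- colSums(out$counts > 0)
  truth <- out$truth
  truth$marker_assignment <- tibble(
    gene = c("Ins2", "Gcg", "Sst", "Ppy"),
    cell_type = c("beta", "alpha", "delta", "pp")
  )
  truth$sex_markers <- list(x_inactivation = "Xist",
                            y_linked = c("Eif2s3y", "Ddx3y", "Uty"))
  truth$cycle_genes <- genes$gene_id[genes$cell_cycle]
  truth$type_programs <- out$programs
  truth$dominant_genes <- hormone
  truth$gene_ids <- genes$gene_id

  structure(
    list(counts = out$counts, cells = cells, genes = genes,
         truth = truth, config = config),
    class = "islet_sim"
  )
}

#' @method print islet_sim
#' @export
print.islet_sim <- function(x, ...) {
  cat(sprintf("<islet_sim> %d genes x %d cells\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  median detected genes/cell: %d\n",
              as.integer(stats::median(x$cells$detected_genes))))
  cat(sprintf("  planted effects: %d sex-biased, %d shared-T2D, %d/%d sex-specific-T2D\n",
              nrow(x$truth$sex_biased), nrow(x$truth$t2d_shared),
              nrow(x$truth$t2d_female_specific),
              nrow(x$truth$t2d_male_specific)))
  invisible(x)
}

#' Gene sets derived from planted ground truth, plus random decoys
#'
#' Builds one gene set per planted effect class (sex-biased, shared T2D,
#' female-specific T2D, male-specific T2D) plus `decoys` random sets drawn
#' from the simulated gene universe, for exercising preranked GSEA.
#'
#' @param truth the `truth` element of an [simulate_islet()] result.
#' @param decoys number of random decoy sets.
#' @param set_size size of each decoy set.
#' @param seed integer seed for decoy sampling.
#' @return named list of character vectors (a gene set collection, writable
#'   with [write_gmt()]).
#' @export
truth_gene_sets <- function(truth, decoys = 0, set_size = 50, seed = 1L) {
  universe <- truth$gene_ids
  if (set_size > length(universe)) abort("set_size exceeds gene universe")
  sets <- list(
    sex_biased = truth$sex_biased$gene,
    t2d_shared = truth$t2d_shared$gene,
    t2d_female_specific = truth$t2d_female_specific$gene,
    t2d_male_specific = truth$t2d_male_specific$gene,
    # direction-split variants, for signed enrichment checks
    t2d_shared_up = truth$t2d_shared$gene[truth$t2d_shared$log2fc > 0],
    t2d_shared_down = truth$t2d_shared$gene[truth$t2d_shared$log2fc < 0]
  )
  sets <- sets[vapply(sets, length, 1L) > 0]
  if (decoys > 0) {
    dec <- withr::with_seed(seed, {
      lapply(seq_len(decoys), function(i) sample(universe, set_size))
    })
    names(dec) <- sprintf("decoy_%03d", seq_len(decoys))
    sets <- c(sets, dec)
  }
  sets
}
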