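#' Default pipeline configuration
#'
#' Returns the full nested configuration driving [run_pipeline()], with
#' every stage's tunables at the package defaults and explicit seeds for
#' each stochastic stage (simulation, jackstraw, embedding, GSEA).
#'
#' @return a `run_config` list.
#' @export
default_run_config <- function() {
  structure(list(
    simulate = list(
      n_genes = 2500L, n_cycle_cells = 60L, overdispersion = 0.6,
      n_sex_biased = 30L, n_t2d_shared = 20L, n_t2d_female = 15L,
      n_t2d_male = 15L, effect_log2fc = 1
    ),
    qc = list(min_genes_per_cell = 500L, min_cells_per_gene = 5L),
    normalize = list(k = 2L, share_threshold = 0.5, scale = 1e6),
    identify = list(
      top_k = 10L, n_clusters = 4L, outlier_quantile = 0.99,
      n_hvgs = 3000L, max_pcs = 30L, jackstraw_n_perm = 50L,
      jackstraw_subset_frac = 0.1, jackstraw_alpha = 0.05,
      n_pcs = NULL, perplexity = 15, early_exaggeration = 12,
      learning_rate = 500, eps = 5, min_pts = 5L,
      cycle_score_threshold = 2
    ),
    de = list(fdr_cut = 0.05, lfc_mode = "combined"),
    sexdep = list(p_other_min = 0.2, p_other_use = "pvalue"),
    gsea = list(n_perm = 1000L, min_size = 15L, max_size = 500L,
                weight = 1, orientation = "paper_intent",
                decoys = 10L, decoy_set_size = 50L),
    seeds = list(simulation = 101L, jackstraw = 202L,
                 embedding = 303L, gsea = 404L)
  ), class = "run_config")
}

check_keys <- function(user, ref, path = "") {
  for (k in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", k) else k
    if (!k %in% names(ref)) {
      abort(sprintf("unknown configuration key: '%s'", full))
    }
    if (is.list(ref[[k]]) && !is.null(user[[k]])) {
      if (!is.list(user[[k]])) {
        abort(sprintf("configuration key '%s' must be a mapping", full))
      }
      check_keys(user[[k]], ref[[k]], full)
    } else if (!is.null(user[[k]]) && !is.null(ref[[k]])) {
      if (is.numeric(ref[[k]]) && !is.numeric(user[[k]])) {
        abort(sprintf("configuration key '%s' must be numeric", full))
      }
      if (is.character(ref[[k]]) && !is.character(user[[k]])) {
        abort(sprintf("configuration key '%s' must be a string", full))
      }
    }
  }
}

merge_config <- function(user, ref) {
  for (k in names(user)) {
    ref[[k]] <- if (is.list(ref[[k]]) && is.list(user[[k]])) {
      merge_config(user[[k]], ref[[k]])
    } else if (is.integer(ref[[k]]) && is.numeric(user[[k]])) {
      as.integer(user[[k]])
    } else user[[k]]
  }
  ref
}

#' Validate a pipeline configuration
#'
#' Reads a YAML configuration (or takes a list), rejects unknown keys,
#' type-checks values against the defaults, and requires an explicit seed
#' for every stochastic stage. Missing non-seed keys fall back to
#' [default_run_config()].
#'
#' @param config path to a YAML file, or a list.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) abort("configuration must be a YAML mapping")
  ref <- default_run_config()
  check_keys(config, ref)
  need <- c("simulation", "jackstraw", "embedding", "gsea")
  have <- names(config$seeds %||% list())
  missing <- setdiff(need, have)
  if (length(missing)) {
    abort(sprintf("configuration must set seeds for every stochastic stage; missing: %s",
                  paste(missing, collapse = ", ")))
  }
  out <- merge_config(config, unclass(ref))
  structure(out, class = "run_config")
}

#' Composite two-stage cell-type identification
#'
#' Runs the full identification procedure: hierarchical clustering on the
#' union of each cell's top expressed genes (with dendrogram outlier
#' removal), HVG selection, jackstraw-validated PCA, t-SNE embedding,
#' DBSCAN cliques, the cluster/clique consistency filter, cell-cycle clique
#' exclusion, marker-based cell-type annotation, and sex inference.
#'
#' @param norm a `normalized_matrix`.
#' @param annotation gene annotation tibble (`gene_id`, `chromosome`,
#'   `cell_cycle`, ...).
#' @param params the `identify` block of a [default_run_config()].
#' @param jackstraw_seed,embedding_seed seeds for the stochastic steps.
#' @return list with elements `hier`, `hvgs`, `pcs`, `embedding`,
#'   `cliques` (post-exclusion labels), `cycle` (exclusion record),
#'   `retained` (cell ids), `types` (annotation result), `sex` (inferred
#'   sex tibble), and `cell_table` (one row per input cell: clique,
#'   cell type, retained flag, inferred sex).
#' @export
identify_cell_types <- function(norm, annotation,
                                params = default_run_config()$identify,
                                jackstraw_seed = 1L, embedding_seed = 2L) {
  stopifnot(inherits(norm, "normalized_matrix"))
  counts <- norm$counts
  tku <- top_k_union(counts, k = params$top_k)
  hier <- hierarchical_cluster_cells(norm, tku,
                                     n_clusters = params$n_clusters,
                                     outlier_quantile = params$outlier_quantile)
  n_hvg <- min(params$n_hvgs, sum(rowMeans(norm_linear(norm)) > 0) - 1)
  hvgs <- select_hvgs(norm, n = n_hvg)
  pcs <- significant_pcs(norm, hvgs, max_pcs = params$max_pcs,
                         n_perm = params$jackstraw_n_perm,
                         subset_frac = params$jackstraw_subset_frac,
                         alpha = params$jackstraw_alpha,
                         seed = jackstraw_seed, n_pcs = params$n_pcs)
  emb <- embed_2d(pcs$scores, perplexity = params$perplexity,
                  early_exaggeration = params$early_exaggeration,
                  learning_rate = params$learning_rate,
                  seed = embedding_seed)
  cliques <- dbscan_cliques(emb, eps = params$eps, min_pts = params$min_pts)
  retained <- consistency_filter(hier$labels, cliques)
  cl_ret <- cliques[retained]
  cycle_genes <- annotation$gene_id[annotation$cell_cycle]
  cyc <- exclude_cycle_clique(norm, cl_ret, cycle_genes,
                              score_threshold = params$cycle_score_threshold)
  cl_final <- cyc$cliques[cyc$cliques > 0]
  types <- annotate_cell_types(norm, cl_final)
  sex <- infer_sex(counts, annotation = annotation)

  all_cells <- colnames(counts)
  cell_table <- tibble(
    cell_id = all_cells,
    hier_cluster = unname(hier$labels[all_cells]),
    clique = unname(cliques[all_cells]),
    retained = all_cells %in% names(cl_final),
    cell_type = unname(types$cells[all_cells]),
    inferred_sex = sex$inferred_sex[match(all_cells, sex$cell_id)]
  )
  list(hier = hier, hvgs = hvgs, pcs = pcs, embedding = emb,
       cliques = cyc$cliques, cycle = cyc, retained = names(cl_final),
       types = types, sex = sex, cell_table = cell_table)
}

stage_run <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)))
  })
}

tsv_safe <- function(x) {
  if ("leading_edge" %in% names(x)) {
    x$leading_edge <- vapply(x$leading_edge, paste, "", collapse = ";")
  }
  x
}

#' Run the full analysis pipeline on a synthetic islet dataset
#'
#' Orchestrates simulate, QC, adjCPM normalization, cell-type
#' identification, the three hurdle differential-expression comparisons on
#' beta cells (pooled T2D vs healthy with CDR + sex covariates, and
#' within-sex with CDR), the sex-dependent gene classification, and
#' preranked GSEA against the ground-truth gene sets plus decoys. All
#' stage outputs are written as TSV under `outdir` together with a
#' machine-readable manifest (seeds, parameters, content hashes); rerunning
#' with the same configuration reproduces identical hashes.
#'
#' @param config a `run_config` (see [validate_config()] /
#'   [default_run_config()]).
#' @param outdir output directory (created if needed); `NULL` skips
#'   writing files.
#' @return (invisibly) list with all stage results and the `manifest`.
#' @export
run_pipeline <- function(config = default_run_config(), outdir = NULL) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  seeds <- config$seeds

  sim <- stage_run("simulate", {
    sc <- config$simulate
    cfg <- islet_sim_config(
      n_genes = sc$n_genes, n_cycle_cells = sc$n_cycle_cells,
      overdispersion = sc$overdispersion, n_sex_biased = sc$n_sex_biased,
      n_t2d_shared = sc$n_t2d_shared, n_t2d_female = sc$n_t2d_female,
      n_t2d_male = sc$n_t2d_male, effect_log2fc = sc$effect_log2fc,
      seed = seeds$simulation
    )
    simulate_islet(cfg)
  })

  qc <- stage_run("qc", {
    qc_filter(sim$counts,
              min_genes_per_cell = config$qc$min_genes_per_cell,
              min_cells_per_gene = config$qc$min_cells_per_gene,
              mito_genes = sim$genes$gene_id[sim$genes$mito])
  })

  norm <- stage_run("normalize", {
    excl <- adjcpm_exclusion_set(qc$counts, k = config$normalize$k,
                                 share_threshold = config$normalize$share_threshold)
    normalize_adjcpm(qc$counts, excl, S = config$normalize$scale)
  })

  ident <- stage_run("identify", {
    identify_cell_types(norm, sim$genes, params = config$identify,
                        jackstraw_seed = seeds$jackstraw,
                        embedding_seed = seeds$embedding)
  })

  de <- stage_run("de", {
    meta <- sim$cells
    tab <- ident$cell_table %>%
      filter(.data$retained, .data$cell_type == "beta") %>%
      left_join(meta, by = "cell_id")
    beta_cells <- tab$cell_id
    # T2D vs age-matched healthy: restrict to batches containing T2D cells
    t2d_batches <- unique(tab$batch[tab$condition == "T2D"])
    tab <- filter(tab, .data$batch %in% t2d_batches)
    pick <- function(cond, sex = NULL) {
      x <- tab %>% filter(.data$condition == cond)
      if (!is.null(sex)) x <- filter(x, .data$declared_sex == sex)
      x$cell_id
    }
    cd <- meta %>% transmute(.data$cell_id, sex = .data$declared_sex)
    list(
      pooled = run_de(norm, pick("T2D"), pick("HC"),
                      covariates = c("cdr", "sex"), cell_data = cd,
                      lfc_mode = config$de$lfc_mode),
      female = run_de(norm, pick("T2D", "F"), pick("HC", "F"),
                      covariates = "cdr", lfc_mode = config$de$lfc_mode),
      male = run_de(norm, pick("T2D", "M"), pick("HC", "M"),
                    covariates = "cdr", lfc_mode = config$de$lfc_mode),
      beta_cells = beta_cells
    )
  })

  calls <- stage_run("sexdep", {
    classify_sex_dependent(de$pooled, de$female, de$male,
                           fdr_cut = config$de$fdr_cut,
                           p_other_min = config$sexdep$p_other_min,
                           p_other_use = config$sexdep$p_other_use)
  })

  gsea <- stage_run("gsea", {
    sets <- truth_gene_sets(sim$truth, decoys = config$gsea$decoys,
                            set_size = config$gsea$decoy_set_size,
                            seed = seeds$gsea)
    run_one <- function(de_tab, off) {
      ranked <- rank_genes_z(de_tab, orientation = config$gsea$orientation)
      gsea_preranked(ranked, sets, n_perm = config$gsea$n_perm,
                     min_size = config$gsea$min_size,
                     max_size = config$gsea$max_size,
                     weight = config$gsea$weight,
                     seed = derive_seed(seeds$gsea, off))
    }
    list(pooled = run_one(de$pooled, 1L), female = run_one(de$female, 2L),
         male = run_one(de$male, 3L), sets = sets)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("isletdimorph")),
    seeds = seeds,
    parameters = unclass(config)[setdiff(names(config), "seeds")],
    n_cells_simulated = ncol(sim$counts),
    n_cells_qc = ncol(qc$counts),
    n_genes_qc = nrow(qc$counts),
    n_cells_retained = length(ident$retained),
    n_beta_cells = length(de$beta_cells),
    hashes = list(
      counts = digest::digest(sim$counts),
      exclusion_set = digest::digest(norm$exclusion_set),
      cell_table = digest::digest(ident$cell_table),
      de_pooled = digest::digest(as.data.frame(de$pooled)),
      de_female = digest::digest(as.data.frame(de$female)),
      de_male = digest::digest(as.data.frame(de$male)),
      sex_dependent = digest::digest(list(calls$sex_independent,
                                          calls$final_female,
                                          calls$final_male)),
      gsea = digest::digest(lapply(gsea[c("pooled", "female", "male")],
                                   as.data.frame))
    )
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_counts(sim$counts, file.path(outdir, "counts"), "mtx",
                 genes = sim$genes, cells = sim$cells)
    readr::write_tsv(qc$report$cell_qc, file.path(outdir, "qc_cells.tsv"))
    writeLines(norm$exclusion_set, file.path(outdir, "exclusion_set.txt"))
    readr::write_tsv(ident$cell_table, file.path(outdir, "cell_labels.tsv"))
    readr::write_tsv(ident$embedding, file.path(outdir, "embedding.tsv"))
    readr::write_tsv(as_tibble(de$pooled), file.path(outdir, "de_pooled.tsv"))
    readr::write_tsv(as_tibble(de$female), file.path(outdir, "de_female.tsv"))
    readr::write_tsv(as_tibble(de$male), file.path(outdir, "de_male.tsv"))
    readr::write_tsv(calls$sex_independent,
                     file.path(outdir, "sex_independent.tsv"))
    readr::write_tsv(bind_rows(female = calls$candidates_female,
                               male = calls$candidates_male, .id = "sex"),
                     file.path(outdir, "sex_dependent_calls.tsv"))
    for (nm in c("pooled", "female", "male")) {
      readr::write_tsv(tsv_safe(as_tibble(gsea[[nm]])),
                       file.path(outdir, sprintf("gsea_%s.tsv", nm)))
    }
    write_gmt(gsea$sets, file.path(outdir, "gene_sets.gmt"))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  invisible(list(sim = sim, qc = qc, norm = norm, ident = ident, de = de,
                 calls = calls, gsea = gsea, manifest = manifest))
}
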