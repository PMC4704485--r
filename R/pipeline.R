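#' Run the full association pipeline on a study
#'
#' Orchestrates the stages in order: preprocessing (gene filters, age
#' adjustment) -> co-expression network (soft power, adjacency, TOM,
#' module detection, eigengenes) -> module-trait association (per-group
#' correlations, q-values, permutation and group-difference tests) ->
#' gene metrics (GS, kWithin, GS-GC reorganization, top-k overlap) ->
#' subgroup relevance classification, with optional module preservation
#' against a second dataset and optional gene-set enrichment / PPI
#' mapping. Every output table is written as TSV under \code{out_dir}
#' and a JSON manifest records parameters, seeds and produced files.
#'
#' A single global \code{seed} fans out to per-stage seeds (seed + stage
#' counter), so a rerun with the same inputs and seed is byte-identical.
#'
#' @param expr genes x samples log-intensity matrix.
#' @param samples sample table (group, age_years, tbv_cc).
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @param powers candidate soft-threshold powers.
#' @param r2_target scale-free fit target.
#' @param min_module_size minimum module size.
#' @param n_perm permutation count for association tests.
#' @param n_boot bootstrap resamples for CIs.
#' @param top_k hub/top-GS list length.
#' @param variance_alpha gene variance filter level (NULL disables).
#' @param expr_test optional second dataset for preservation.
#' @param gene_sets optional named list of gene sets for enrichment.
#' @param enrichment_background background size for enrichment.
#' @param ppi_edges optional PPI edge list (data frame from
#'   [read_edge_list()]); when absent the PPI mapping is skipped with a
#'   logged notice.
#' @return invisibly, a manifest list (also written as
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(expr, samples, out_dir, seed = 1L,
                         powers = 1:20, r2_target = 0.9, min_module_size = 30L,
                         n_perm = 10000L, n_boot = 10000L, top_k = 30L,
                         variance_alpha = 0.05,
                         expr_test = NULL, gene_sets = NULL,
                         enrichment_background = 21405L, ppi_edges = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list()
  note <- function(...) message("[tbvnet] ", ...)
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
  }

  # --- preprocessing ------------------------------------------------------
  note("preprocessing: ", nrow(expr), " genes, ", ncol(expr), " samples")
  collapsed <- collapse_replicates(expr, samples)
  expr <- filter_genes(collapsed$expr, variance_alpha = variance_alpha)
  expr <- expr[stats::complete.cases(expr), , drop = FALSE]
  samples <- age_adjust_trait(collapsed$samples)
  note("retained ", nrow(expr), " genes after filtering")

  # --- co-expression network ---------------------------------------------
  sp <- select_soft_power(expr, powers = powers, r2_target = r2_target)
  note("soft power ", sp$power)
  adj <- build_adjacency(expr, sp$power)
  tom <- compute_tom(adj)
  partition <- detect_modules(tom, expr, min_module_size = min_module_size)
  me <- compute_module_eigengenes(expr, partition)
  save_tsv(sp$fit_table, "scale_free_fit.tsv")
  save_tsv(data.frame(gene_id = names(partition), module = unname(partition)),
           "module_partition.tsv")
  save_tsv(data.frame(module = rownames(me$eigengenes), me$eigengenes,
                      check.names = FALSE), "module_eigengenes.tsv")

  # --- module-trait association ------------------------------------------
  assoc <- do.call(rbind, lapply(c("all", "case", "control"), function(g) {
    a <- module_trait_correlation(me, samples, group = g)
    a$q <- storey_qvalues(a$p)
    for (i in seq_len(nrow(a))) {
      ci <- bootstrap_ci(me$eigengenes[a$module[i], ], samples,
                         n_boot = n_boot, seed = seed + 2L, group = g)
      a$ci_low[i] <- ci$ci_low
      a$ci_high[i] <- ci$ci_high
    }
    a
  }))
  perm <- permutation_module_pvalue(expr, partition, samples,
                                    n_perm = n_perm, seed = seed + 3L)
  assoc$perm_p <- perm$perm_p[match(assoc$module, perm$module)]
  gd <- do.call(rbind, lapply(rownames(me$eigengenes), function(m) {
    g <- group_difference_permutation(me$eigengenes[m, ], samples,
                                      n_perm = n_perm, seed = seed + 4L)
    data.frame(module = m, r_case = g$r_case, r_control = g$r_control,
               z_diff = g$z_diff, perm_p = g$perm_p)
  }))
  save_tsv(assoc, "module_trait_association.tsv")
  save_tsv(gd, "group_difference.tsv")

  # --- gene metrics -------------------------------------------------------
  gc <- intramodular_connectivity(adj, partition)
  metrics <- lapply(c(case = "case", control = "control"), function(g) {
    gs <- gene_significance(expr, samples, group = g)
    merge(gs, gc, by = "gene")
  })
  gsgc <- do.call(rbind, lapply(rownames(me$eigengenes), function(m) {
    a <- gs_gc_analysis(metrics$case[metrics$case$module == m, ],
                        metrics$control[metrics$control$module == m, ])
    ov <- tryCatch(
      rank_and_overlap(metrics$case[metrics$case$module == m, ],
                       metrics$control[metrics$control$module == m, ], k = top_k),
      error = function(e) list(n_common = NA_integer_, n_different = NA_integer_))
    data.frame(module = m, r_case = a$r_case, r_control = a$r_control,
               z_diff = a$z_diff, top_common = ov$n_common,
               top_different = ov$n_different)
  }))
  save_tsv(metrics$case, "gene_metrics_case.tsv")
  save_tsv(metrics$control, "gene_metrics_control.tsv")
  save_tsv(gsgc, "gs_gc_reorganization.tsv")

  # --- PPI mapping & subgroup classification -----------------------------
  main_mod <- rownames(me$eigengenes)[1]
  mm <- metrics$control[metrics$control$module == main_mod, ]
  hubs <- tryCatch(mm$gene[order(-mm$GC, mm$gene)][seq_len(min(top_k, nrow(mm)))],
                   error = function(e) character(0))
  if (!is.null(ppi_edges) && length(hubs)) {
    mapped <- map_hubs_to_ppi(hubs, ppi_edges)
    save_tsv(mapped, "ppi_mapped_hubs.tsv")
    hubs_used <- mapped$gene
  } else {
    note("no PPI edge list supplied; hub mapping skipped")
    hubs_used <- hubs
  }
  sub <- tryCatch({
    lapply(c(case = "case", control = "control"), function(g) {
      classify_gene_relevance(hubs_used, expr, samples, group = g)
    })
  }, error = function(e) {
    note("subgroup classification skipped: ", conditionMessage(e))
    NULL
  })
  if (!is.null(sub)) {
    save_tsv(rbind(cbind(group = "case", sub$case$records),
                   cbind(group = "control", sub$control$records)),
             "subgroup_relevance.tsv")
  }

  # --- optional preservation & enrichment --------------------------------
  if (!is.null(expr_test)) {
    pres <- module_preservation(expr, expr_test, partition, beta = sp$power,
                                seed = seed + 5L)
    save_tsv(pres, "module_preservation.tsv")
  }
  if (!is.null(gene_sets)) {
    enr <- do.call(rbind, lapply(rownames(me$eigengenes), function(m) {
      e <- hypergeometric_enrichment(names(partition)[partition == m], gene_sets,
                                     background = enrichment_background)
      cbind(module = m, e)
    }))
    save_tsv(enr, "enrichment.tsv")
  }

  manifest <- list(
    package = "tbvnet",
    version = as.character(utils::packageVersion("tbvnet")),
    seed = seed,
    parameters = list(power = sp$power, r2_target = r2_target,
                      min_module_size = min_module_size, n_perm = n_perm,
                      n_boot = n_boot, top_k = top_k),
    n_genes = nrow(expr), n_samples = ncol(expr),
    modules = rownames(me$eigengenes),
    outputs = paths
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
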