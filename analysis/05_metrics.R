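#!/usr/bin/env Rscript
# Stage 5: gene-level network metrics and reorganization.
#
# Computes per-group gene significance (GS, signed trait correlation) and
# intramodular connectivity (GC, kWithin), quantifies GS-GC reorganization
# per module with the Fisher-z difference statistic, compares top-30 GS and
# GC rankings between groups, and forms the hub/top-GS 2x2 table with its
# Haldane/Woolf odds ratio.

library(tbvnet)

study <- load_study("results/data/expression_filtered.tsv",
                    "results/data/samples_adjusted.csv")
expr <- study$expr
samples <- study$samples
partition <- with(read.delim("results/module_partition.tsv"),
                  setNames(module, gene_id))
power <- readRDS("scratch/network_params.rds")$power
adj <- build_adjacency(expr, power)
gc <- intramodular_connectivity(adj, partition)

metrics <- lapply(c(case = "case", control = "control"), function(g) {
  merge(gene_significance(expr, samples, group = g), gc, by = "gene")
})

mods <- setdiff(sort(unique(partition)), "unassigned")
rows <- list(); or_rows <- list()
for (m in mods) {
  mc <- metrics$case[metrics$case$module == m, ]
  mk <- metrics$control[metrics$control$module == m, ]
  a <- gs_gc_analysis(mc, mk)
  ov_gs <- rank_and_overlap(mc, mk, k = 30, on = "GS")
  ov_gc <- rank_and_overlap(mc, mk, k = 30, on = "GC")
  rows[[m]] <- data.frame(
    module = m, r_case = a$r_case, r_control = a$r_control, z_diff = a$z_diff,
    top30_gs_common = ov_gs$n_common, top30_gs_different = ov_gs$n_different,
    top30_gc_common = ov_gc$n_common
  )
  # are the hub genes (top-30 GC) also the top-GS genes, per group?
  in_top <- function(mm, ov_top) sum(ov_top %in% mm$gene[order(-abs(mm$GS), mm$gene)][1:30])
  k_ctrl <- in_top(mk, ov_gc$top_control)
  k_case <- in_top(mc, ov_gc$top_case)
  tab <- matrix(c(k_ctrl, 30 - k_ctrl, k_case, 30 - k_case), 2, byrow = TRUE)
  or <- contingency_odds_ratio(tab)
  or_rows[[m]] <- data.frame(
    module = m, hub_top_gs_control = k_ctrl, hub_top_gs_case = k_case,
    or_value = or$or_value, ci_low = or$ci_low, ci_high = or$ci_high,
    fisher_p = or$fisher_p, corrected = or$corrected
  )
}

gsgc <- do.call(rbind, rows)
ors <- do.call(rbind, or_rows)
write.table(metrics$case, "results/gene_metrics_case.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(metrics$control, "results/gene_metrics_control.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gsgc, "results/gs_gc_reorganization.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ors, "results/hub_top_gs_odds_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("GS-GC reorganization (|GS| vs GC correlation, control minus case in z):")
print(gsgc, digits = 3, row.names = FALSE)
message("hub/top-GS contingency odds ratios:")
print(ors, digits = 3, row.names = FALSE)
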