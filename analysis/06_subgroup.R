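#!/usr/bin/env Rscript
# Stage 6: smaller- versus bigger-brain relevance classification.
#
# Maps the cell-cycle-like module's hub genes onto the (synthetic) PPI edge
# list, recomputes gene significance in the smaller-brain (residual < 0 cc)
# and bigger-brain (residual > 0 cc) subgroups of each diagnostic group, and
# classifies each mapped hub as retaining or losing its brain-size relevance
# against the group's minimum |GS-ALL| threshold. The per-group retained/
# lost counts feed a 2x2 odds-ratio comparison.

library(tbvnet)

study <- load_study("results/data/expression_filtered.tsv",
                    "results/data/samples_adjusted.csv")
expr <- study$expr
samples <- study$samples
partition <- with(read.delim("results/module_partition.tsv"),
                  setNames(module, gene_id))
metrics_ctrl <- read.delim("results/gene_metrics_control.tsv")

# hub set: top-30 kWithin of the largest module, mapped into the PPI network
m1 <- metrics_ctrl[metrics_ctrl$module == "M1", ]
hubs <- m1$gene[order(-m1$GC, m1$gene)][1:30]
edges <- read_edge_list("results/data/ppi_edges_synthetic.tsv")
mapped <- map_hubs_to_ppi(hubs, edges)
message(nrow(mapped), " of 30 hub genes map into the PPI network")
if (nrow(mapped) < 2L) {
  message("too few mapped hubs; classifying the full hub list instead")
  mapped <- data.frame(gene = hubs)
}

cls <- lapply(c(case = "case", control = "control"), function(g) {
  classify_gene_relevance(mapped$gene, expr, samples, group = g)
})

records <- rbind(cbind(group = "case", cls$case$records),
                 cbind(group = "control", cls$control$records))
write.table(records, "results/subgroup_relevance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

summarize <- function(side) {
  tab <- matrix(c(cls$control$counts[[side]], cls$case$counts[[side]]),
                2, byrow = TRUE)
  or <- contingency_odds_ratio(tab)
  message(side, "-brain retention control ",
          tab[1, 1], "/", sum(tab[1, ]), " vs case ",
          tab[2, 1], "/", sum(tab[2, ]),
          ": OR = ", signif(or$or_value, 3),
          " [", signif(or$ci_low, 3), ", ", signif(or$ci_high, 3), "]",
          ", Fisher p = ", signif(or$fisher_p, 2))
  data.frame(side = side, control_retained = tab[1, 1], control_lost = tab[1, 2],
             case_retained = tab[2, 1], case_lost = tab[2, 2],
             or_value = or$or_value, ci_low = or$ci_low, ci_high = or$ci_high,
             fisher_p = or$fisher_p)
}
tabs <- rbind(summarize("small"), summarize("big"))
write.table(tabs, "results/subgroup_odds_ratios.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

gained <- unique(c(cls$case$gained$small, cls$case$gained$big))
message(length(gained), " non-hub genes gained relevance in a case subgroup")
jsonlite::write_json(
  list(threshold_case = cls$case$threshold_all,
       threshold_control = cls$control$threshold_all,
       gained_case = cls$case$gained, gained_control = cls$control$gained),
  "results/subgroup_summary.json", auto_unbox = TRUE, digits = NA)
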