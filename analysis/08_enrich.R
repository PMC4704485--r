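#!/usr/bin/env Rscript
# Stage 8: gene-set enrichment of the detected modules.
#
# Hypergeometric (upper-tail) enrichment of each detected module against
# the synthetic gene-set collection from stage 1, using the gene universe
# of the filtered study as the background. With planted truth as gene sets
# this doubles as an end-to-end check: each detected module should enrich
# its own planted set and nothing else.

library(tbvnet)

partition <- with(read.delim("results/module_partition.tsv"),
                  setNames(module, gene_id))
sets <- read_gmt("results/data/gene_sets_synthetic.gmt")
universe <- names(partition)

mods <- setdiff(sort(unique(partition)), "unassigned")
enr <- do.call(rbind, lapply(mods, function(m) {
  e <- hypergeometric_enrichment(names(partition)[partition == m], sets,
                                 background = universe)
  cbind(module = m, e)
}))
write.table(enr, "results/enrichment.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

message("module enrichment against the synthetic gene-set collection:")
print(enr[enr$q < 0.05, c("module", "set_name", "k", "K", "n", "p", "q")],
      digits = 3, row.names = FALSE)
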