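#!/usr/bin/env Rscript
# Stage 1: simulate the study.
#
# Builds a synthetic two-group blood-expression study with the structure the
# downstream analysis expects: block-correlated co-expression modules
# (including a 253-gene cell-cycle-like module), a normally distributed
# trait (total brain volume, cc) with a smooth age trend, coupling between
# chosen module eigengenes and the trait that differs between groups, and
# hub-routed coupling in controls versus peripherally routed coupling in
# cases. Gene count is scaled to 2,000 so the whole workflow runs at desk
# scale; group sizes match the cohort design (87 cases, 55 controls).

library(tbvnet)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synthetic_config(
  n_genes = 2000L,
  n_samples_per_group = c(case = 87L, control = 55L),
  module_specs = data.frame(
    size = c(253L, 150L, 100L, 60L),
    within_cor = c(0.7, 0.65, 0.6, 0.55)
  ),
  trait_coupling = matrix(
    c(0.15, 0.55,    # M1, cell-cycle-like: couples in controls
      0.15, 0.45,    # M2, protein-folding-like: couples in controls
      0.45, 0.00,    # M3, cell-adhesion-like: couples in cases
      0.00, 0.00),
    4, 2, byrow = TRUE, dimnames = list(NULL, c("case", "control"))
  ),
  hub_fraction_coupled = c(case = 0.2, control = 1),
  seed = 20L
)

st <- generate_two_group_study(cfg, dir = out)

# a synthetic gene-set collection (GMT) built from the planted truth plus
# random sets, for the enrichment stage; clearly synthetic stand-ins
part <- st$truth$planted_partition
sets <- c(
  list(planted_cell_cycle = names(part)[part == "M1"],
       planted_protein_folding = names(part)[part == "M2"],
       planted_cell_adhesion = names(part)[part == "M3"]),
  setNames(lapply(1:3, function(i) {
    set.seed(100 + i)
    sample(names(part), 80)
  }), paste0("random_set_", 1:3))
)
gmt <- vapply(names(sets), function(s) {
  paste(c(s, "synthetic", sets[[s]]), collapse = "\t")
}, character(1))
writeLines(gmt, file.path(out, "gene_sets_synthetic.gmt"))

# a synthetic PPI edge list among the cell-cycle-like module's genes:
# hubs (first genes of the module carry the largest loadings) are wired
# densely, the rest sparsely
set.seed(30)
m1 <- names(part)[part == "M1"]
hubs <- m1[order(-st$truth$loadings[m1])][1:40]
edges <- rbind(
  t(combn(hubs[1:15], 2))[sample(105, 60), ],
  cbind(sample(hubs, 120, replace = TRUE), sample(m1, 120, replace = TRUE))
)
edges <- edges[edges[, 1] != edges[, 2], ]
write.table(edges, file.path(out, "ppi_edges_synthetic.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)

message("simulated ", nrow(st$expr), " genes x ", ncol(st$expr), " samples; ",
        "planted modules: ",
        paste(names(table(part[part != "noise"])), collapse = ", "))
message("realized eigengene-trait couplings (rows = modules):")
print(round(st$truth$realized_couplings, 3))
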