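#!/usr/bin/env Rscript
# Stage 3: co-expression network and module detection.
#
# Selects the soft-threshold power by the scale-free fit criterion (target
# signed R^2 = 0.90; if the block-structured simulation never reaches the
# target the best-fitting power is used, which the function reports), builds
# the unsigned adjacency and TOM, detects modules on the TOM dissimilarity,
# and summarizes each module by its eigengene.

library(tbvnet)

study <- load_study("results/data/expression_filtered.tsv",
                    "results/data/samples_adjusted.csv")
expr <- study$expr

sp <- withCallingHandlers(
  select_soft_power(expr, powers = 1:12),
  warning = function(w) { message("note: ", conditionMessage(w))
                          invokeRestart("muffleWarning") }
)
message("soft-threshold power: ", sp$power)

adj <- build_adjacency(expr, sp$power)
tom <- compute_tom(adj)
partition <- detect_modules(tom, expr, min_module_size = 30L)
me <- compute_module_eigengenes(expr, partition)

sizes <- table(partition[partition != "unassigned"])
message("detected ", length(sizes), " modules (sizes ",
        paste(sizes, collapse = ", "), "); ",
        sum(partition == "unassigned"), " genes unassigned")
message("variance explained by eigengenes: ",
        paste(names(me$var_explained), round(me$var_explained, 2),
              sep = "=", collapse = ", "))

dir.create("results", showWarnings = FALSE)
write.table(sp$fit_table, "results/scale_free_fit.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(gene_id = names(partition), module = unname(partition)),
            "results/module_partition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(module = rownames(me$eigengenes), me$eigengenes,
                       check.names = FALSE),
            "results/module_eigengenes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
saveRDS(list(power = sp$power), "scratch/network_params.rds")
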