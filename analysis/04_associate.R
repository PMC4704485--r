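#!/usr/bin/env Rscript
# Stage 4: module-trait association.
#
# Correlates each module eigengene with age-adjusted TBV in all samples and
# per group, attaches Storey q-values, percentile-bootstrap 95% CIs, a
# module-label permutation p-value (are the associations specific to the
# detected gene sets?), and a Fisher-z permutation test for group
# differences in correlation strength.

library(tbvnet)

study <- load_study("results/data/expression_filtered.tsv",
                    "results/data/samples_adjusted.csv")
expr <- study$expr
samples <- study$samples

partition <- with(read.delim("results/module_partition.tsv"),
                  setNames(module, gene_id))
me <- compute_module_eigengenes(expr, partition)

n_perm <- 1000L
assoc <- do.call(rbind, lapply(c("all", "case", "control"), function(g) {
  a <- module_trait_correlation(me, samples, group = g)
  a$q <- storey_qvalues(a$p)
  for (i in seq_len(nrow(a))) {
    ci <- bootstrap_ci(me$eigengenes[a$module[i], ], samples,
                       n_boot = 1000L, seed = 41L, group = g)
    a$ci_low[i] <- ci$ci_low
    a$ci_high[i] <- ci$ci_high
  }
  a
}))
perm <- permutation_module_pvalue(expr, partition, samples,
                                  n_perm = n_perm, seed = 42L)
assoc$perm_p <- perm$perm_p[match(assoc$module, perm$module)]

gd <- do.call(rbind, lapply(rownames(me$eigengenes), function(m) {
  g <- group_difference_permutation(me$eigengenes[m, ], samples,
                                    n_perm = n_perm, seed = 43L)
  data.frame(module = m, r_case = g$r_case, r_control = g$r_control,
             z_diff = g$z_diff, perm_p = g$perm_p)
}))

write.table(assoc, "results/module_trait_association.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(gd, "results/group_difference.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sig <- assoc[assoc$group != "all" & assoc$q < 0.05 & abs(assoc$r) > 0.3, ]
message("group-specific associations at |r| > 0.3, q < 0.05:")
print(sig[, c("module", "group", "n", "r", "p", "q", "perm_p")], digits = 3)
message("group differences (Fisher z, permutation p):")
print(gd, digits = 3)
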