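# tbvnet

Weighted gene co-expression analysis linking a blood transcriptome to
total brain volume (TBV) in a two-group (case/control) cohort — the
systems-biology workflow used to ask whether leukocyte expression carries
signatures of early brain-size variation, and whether the *organization*
of trait-relevant gene networks differs between diagnostic groups.

The package is aimed at analysts who want the full statistical pipeline
as tested, deterministic functions:

* **Network construction** — unsigned weighted adjacency
  `a_ij = |cor(x_i, x_j)|^β`, soft power chosen by the scale-free fit
  criterion (signed R² ≥ 0.90), topological overlap
  `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`, and
  deterministic module detection on `1 − TOM` (static cut with recursive
  re-cutting of incoherent branches plus a |kME| membership pass).
* **Module eigengenes** — first principal component per module over
  samples, sign-aligned, with variance explained.
* **Trait association** — Pearson r of eigengenes (or gene-set average
  expression) with age-adjusted TBV; Student asymptotic p
  (`t = r√(n−2)/√(1−r²)`); Storey q-values (π₀ smoother); 10,000-iteration
  module-label permutation nulls with the count/(N+1) convention;
  percentile bootstrap CIs; Fisher-z group-difference permutation tests.
* **Network reorganization** — gene significance (GS, signed trait
  correlation) vs intramodular connectivity (GC, kWithin); the Fisher-z
  difference `z = (atanh r₁ − atanh r₂)/√(1/(n₁−3)+1/(n₂−3))`; top-30
  ranking overlap; 2×2 odds ratios with Haldane–Anscombe zero-cell
  correction and Woolf CIs; Fisher exact p.
* **Smaller/bigger-brain subgroups** — GS-threshold relevance
  classification at the residual-sign split, PPI hub mapping.
* **Module preservation** — permutation Zsummary (density +
  connectivity statistics) and medianRank between datasets, with the
  usual bands (< 2 none, 2–10 moderate, > 10 high).
* **Enrichment** — upper-tail hypergeometric tests against a fixed
  background (default 21,405), GMT input.
* **Synthetic studies** — a factor-model generator that plants known
  modules, hub structure, and group-specific eigengene–trait coupling so
  every stage above is testable against ground truth.

See `vignettes/methods.Rmd` for the models, assumptions, parameter
defaults, and design decisions.

## Worked example

Simulate a study with two planted modules — one coupled to brain size in
controls (r = 0.5), one in cases (r = 0.45) — then detect modules and
test their eigengene–trait associations:

```r
library(tbvnet)

cfg <- synthetic_config(
  n_genes = 500L, n_samples_per_group = c(case = 60L, control = 60L),
  module_specs = data.frame(size = c(80L, 60L), within_cor = c(0.7, 0.6)),
  trait_coupling = matrix(c(0.1, 0.5,    # module 1: control-coupled
                            0.45, 0),    # module 2: case-coupled
                          2, 2, byrow = TRUE,
                          dimnames = list(NULL, c("case", "control"))),
  hub_fraction_coupled = c(case = 1, control = 1),
  seed = 1L)
study   <- generate_two_group_study(cfg)
samples <- age_adjust_trait(study$samples)

adj       <- build_adjacency(study$expr, beta = 6)
partition <- detect_modules(compute_tom(adj), study$expr)
table(partition)
#> partition
#>         M1         M2 unassigned
#>         81         62        357

me    <- compute_module_eigengenes(study$expr, partition)
assoc <- rbind(module_trait_correlation(me, samples, "control"),
               module_trait_correlation(me, samples, "case"))
assoc$q <- storey_qvalues(assoc$p)
print(assoc, digits = 2)
#>   module   group  n     r       p       q
#> 1     M1 control 60  0.33 0.01072 0.00536
#> 2     M2 control 60 -0.27 0.03388 0.01129
#> 3     M1    case 60  0.24 0.06152 0.01538
#> 4     M2    case 60  0.42 0.00085 0.00085

gd <- group_difference_permutation(me$eigengenes["M2", ], samples,
                                   n_perm = 1000, seed = 2)
#> M2: r_case = 0.42, r_control = -0.27, zDiff = 0.73, perm p = 0.001
```

The two planted modules are recovered almost exactly (81 and 62 genes
against 80 and 60 planted; the rest stay unassigned). The
control-coupled module associates with TBV in controls (r = 0.33) and
the case-coupled module in cases (r = 0.42, q < 0.001), with a
significant group difference in correlation strength for the
case-coupled module (permutation p = 0.001).

Closed-form statistics work directly from printed tables; for a 2×2
hub/top-GS table:

```r
contingency_odds_ratio(matrix(c(16, 14, 5, 25), 2, byrow = TRUE))
#> OR = 5.71, CI = [1.72, 18.94], Fisher p = 0.006
```

## The analysis workflow

`analysis/01_simulate.R` … `analysis/08_enrich.R` run the whole study at
desk scale (2,000 genes × 142 samples): simulation, preprocessing and age
adjustment, network and module detection, module–trait association with
permutation/bootstrap inference, GS–GC reorganization and hub odds
ratios, smaller/bigger-brain relevance classification, module
preservation against a replicate and against noise, and gene-set
enrichment. Each stage prints what it found and writes its tables under
`results/`.

```sh
for s in analysis/0*.R; do Rscript "$s"; done
```

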