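test_that("the generator is deterministic under a fixed seed, including files", {
  cfg <- small_config(seed = 5L, n_genes = 120L, sizes = c(40L, 30L),
                      n_per_group = c(case = 25L, control = 25L))
  a <- generate_two_group_study(cfg)
  b <- generate_two_group_study(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth$realized_couplings, b$truth$realized_couplings)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_two_group_study(cfg, dir = d1)
  generate_two_group_study(cfg, dir = d2)
  for (f in c("expression.tsv", "samples.csv", "truth.json")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("factor-model calibration hits the requested within-module correlation", {
  # independence: within_cor = 0 behaves like noise
  cfg0 <- small_config(seed = 2L, sizes = 40L, within_cor = 0,
                       n_genes = 40L, n_per_group = c(case = 50L, control = 50L),
                       coupling = matrix(0, 1, 2, dimnames = list(NULL, c("case", "control"))))
  st0 <- generate_expression(cfg0)
  cc0 <- cor(t(st0$expr))
  expect_lte(mean(abs(cc0[lower.tri(cc0)])), 0.1)

  # within_cor = 0.7, size 50, n = 200: mean pairwise r in [0.6, 0.8] over 20 seeds
  mean_cor <- vapply(1:20, function(s) {
    cfg <- small_config(seed = s, sizes = 50L, within_cor = 0.7, n_genes = 50L,
                        n_per_group = c(case = 100L, control = 100L),
                        coupling = matrix(0, 1, 2, dimnames = list(NULL, c("case", "control"))))
    cc <- cor(t(generate_expression(cfg)$expr))
    mean(cc[lower.tri(cc)])
  }, numeric(1))
  expect_gte(mean(mean_cor), 0.6)
  expect_lte(mean(mean_cor), 0.8)

  # partition covers every gene exactly once
  cfg <- small_config(seed = 1L)
  st <- generate_expression(cfg)
  expect_setequal(names(st$truth$planted_partition), rownames(st$expr))
  expect_false(anyNA(st$truth$planted_partition))
})

test_that("trait coupling is realized at the configured strength", {
  # no coupling: factor-trait correlations follow the null distribution
  # (mean |r| ~ sqrt(2/(pi n)), mean signed r ~ 0 at n = 60 per group)
  r0 <- vapply(1:100, function(s) {
    cfg <- small_config(seed = s, sizes = 20L, n_genes = 30L,
                        n_per_group = c(case = 60L, control = 60L),
                        coupling = matrix(0, 1, 2, dimnames = list(NULL, c("case", "control"))))
    st <- generate_two_group_study(cfg)
    st$truth$realized_couplings[1, "control"]
  }, numeric(1))
  expect_lt(abs(mean(abs(r0)) - sqrt(2 / (pi * 60))), 0.03)
  expect_lt(abs(mean(r0)), 0.05)

  # coupling 0.5 in controls only, n = 60/group: r in [0.25, 0.75] >= 90/100
  rc <- vapply(1:100, function(s) {
    cfg <- small_config(seed = s, sizes = 50L, within_cor = 0.7, n_genes = 60L,
                        coupling = matrix(c(0, 0.5), 1, 2,
                                          dimnames = list(NULL, c("case", "control"))))
    st <- generate_two_group_study(cfg)
    samples <- age_adjust_trait(st$samples)
    me <- compute_module_eigengenes(st$expr, st$truth$planted_partition)
    module_trait_correlation(me, samples, "control")$r[1]
  }, numeric(1))
  expect_gte(sum(rc >= 0.25 & rc <= 0.75), 90)
})

test_that("hub-routed coupling yields stronger GS-GC correlation than peripheral routing", {
  # control couples through hubs (fraction 1), case through the periphery (0.2)
  diffs <- vapply(1:20, function(s) {
    cfg <- small_config(seed = s, sizes = 50L, within_cor = 0.7, n_genes = 70L,
                        coupling = matrix(c(0.5, 0.5), 1, 2,
                                          dimnames = list(NULL, c("case", "control"))),
                        hub_fraction = c(case = 0.2, control = 1))
    st <- generate_two_group_study(cfg)
    samples <- age_adjust_trait(st$samples)
    adj <- build_adjacency(st$expr, 6)
    gc <- intramodular_connectivity(adj, st$truth$planted_partition)
    mod <- gc$module == "M1"
    r_for <- function(g) {
      gs <- gene_significance(st$expr, samples, g)
      cor(abs(gs$GS[mod]), gc$GC[mod])
    }
    r_for("control") - r_for("case")
  }, numeric(1))
  expect_gt(median(diffs), 0)
  expect_gte(mean(diffs > 0), 0.8)
})

test_that("invalid configurations are rejected", {
  expect_error(small_config(sizes = c(200L, 200L), n_genes = 300L), "exceed")
  expect_error(small_config(coupling = matrix(c(0, 1), 1, 2,
                                              dimnames = list(NULL, c("case", "control"))),
                            sizes = 50L), "< 1")
  expect_error(synthetic_config(n_samples_per_group = c(case = 0L, control = 10L)),
               "at least one sample")
  expect_error(small_config(within_cor = 1.2, sizes = 30L), "within_cor")
})

test_that("written studies round-trip through load_study", {
  cfg <- small_config(seed = 9L, n_genes = 80L, sizes = c(30L, 30L),
                      n_per_group = c(case = 20L, control = 20L))
  d <- withr::local_tempdir()
  st <- generate_two_group_study(cfg, dir = d)
  back <- load_study(st$paths$expression, st$paths$samples)
  expect_equal(back$expr, st$expr, tolerance = 1e-12)
  expect_equal(back$samples$sample_id, st$samples$sample_id)
  expect_equal(back$samples$tbv_cc, st$samples$tbv_cc, tolerance = 1e-12)
})
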