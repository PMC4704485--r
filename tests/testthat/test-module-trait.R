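test_that("eigengene-trait correlation matches the Student asymptotic test", {
  # r = 0.74 at n = 25: the asymptotic p is ~2.4e-5, within 2x of the
  # 2.7e-5 convention some software prints for the same inputs
  p74 <- exact_cor_pair(0.74, 25, seed = 2)
  me <- matrix(p74$x, 1, dimnames = list("M1", sprintf("S%03d", 1:25)))
  s <- make_samples(25, p74$y + 1000, group = rep("control", 25))
  out <- module_trait_correlation(me, s, "control")
  expect_equal(out$r, 0.74, tolerance = 1e-10)
  expect_lt(out$p, 2 * 2.7e-5)
  expect_gt(out$p, 2.7e-5 / 2)
  expect_equal(out$p, cor.test(p74$x, p74$y)$p.value, tolerance = 1e-10)
  # identity and antisymmetry
  v <- rnorm(30)
  me2 <- rbind(M1 = v, M2 = -v)
  colnames(me2) <- sprintf("S%03d", 1:30)
  s2 <- make_samples(30, v * 50 + 1000)
  out2 <- module_trait_correlation(me2, s2, "all")
  expect_equal(out2$r, c(1, -1), tolerance = 1e-10)
  # oracle sweep: p agrees with cor.test over random draws
  for (s3 in 1:10) {
    set.seed(s3)
    a <- rnorm(20); b <- rnorm(20)
    me3 <- matrix(a, 1, dimnames = list("M1", sprintf("S%03d", 1:20)))
    st <- make_samples(20, b + 1000)
    expect_equal(module_trait_correlation(me3, st)$p,
                 cor.test(a, st$tbv_residual_cc)$p.value, tolerance = 1e-10)
  }
  # degenerate input is an error
  me4 <- matrix(1, 1, 25, dimnames = list("M1", sprintf("S%03d", 1:25)))
  expect_error(module_trait_correlation(me4, s, "control"), "constant")
})

test_that("Storey q-values behave: saturation, FDR control, monotonicity", {
  expect_equal(storey_qvalues(rep(1, 40)), rep(1, 40))
  expect_identical(storey_qvalues(numeric(0)), numeric(0))
  # a strong block among nulls is called at q < 0.05 and never exceeds BH
  p <- c(rep(0.001, 10), runif(90, 0.5, 1))
  q <- storey_qvalues(p)
  expect_true(all(q[1:10] < 0.05))
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
  expect_true(all(q <= 1))
  # monotone in sorted p for arbitrary inputs
  for (s in 1:5) {
    set.seed(s)
    pr <- runif(60)
    qr <- storey_qvalues(pr)
    expect_true(all(diff(qr[order(pr)]) >= -1e-12))
  }
  expect_equal(storey_qvalues(p, method = "bh"), p.adjust(p, "BH"))
  expect_error(storey_qvalues(c(0.5, 1.2)), "0, 1")
})

test_that("module-label permutation p-values are seeded, floored and calibrated", {
  # a tight module whose eigengene is the trait beats every scrambled
  # draw: p = 0/(N+1) exactly, flagged as a floor
  set.seed(4)
  n <- 40L
  f <- rnorm(n)
  x <- rbind(outer(rep(1, 10), f) + 0.1 * matrix(rnorm(10 * n), 10, n),
             matrix(rnorm(190 * n), 190, n))
  dimnames(x) <- list(sprintf("g%03d", 1:200), sprintf("S%03d", 1:n))
  part <- setNames(rep(c("M1", "noise"), c(10L, 190L)), rownames(x))
  samples <- make_samples(n, f + 1000)
  a <- permutation_module_pvalue(x, part, samples, n_perm = 200, seed = 3)
  b <- permutation_module_pvalue(x, part, samples, n_perm = 200, seed = 3)
  expect_identical(a, b)
  expect_gt(a$r_obs[a$module == "M1"], 0.99)
  expect_equal(a$perm_p[a$module == "M1"], 0)
  expect_match(a$floor_note[a$module == "M1"], "< 1/201")
  expect_error(permutation_module_pvalue(x, part, samples, n_perm = 0), "n_perm")
  # null calibration at modest size: false-positive rate near nominal
  hits <- vapply(1:50, function(s) {
    nz <- generate_two_group_study(noise_config(seed = s + 100L, n_genes = 40L,
                                                n_per_group = c(case = 20L, control = 20L)))
    part <- setNames(rep(c("A", "noise"), c(15L, 25L)), rownames(nz$expr))
    sa <- age_adjust_trait(nz$samples)
    permutation_module_pvalue(nz$expr, part, sa, n_perm = 99, seed = s)$perm_p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.0)
  expect_lte(mean(hits), 0.12)
})

test_that("group-difference permutation is antisymmetric and null at no difference", {
  set.seed(6)
  n <- 24L
  v <- rnorm(n)
  trait <- 0.5 * v + rnorm(n, sd = 0.8)
  # identical samples duplicated into both groups: zDiff exactly 0
  s <- make_samples(2 * n, rep(trait + 1000, 2),
                    group = rep(c("case", "control"), each = n))
  gd <- group_difference_permutation(rep(v, 2), s, n_perm = 200, seed = 1)
  expect_equal(gd$z_diff, 0, tolerance = 1e-12)
  expect_gt(gd$perm_p, 0.5)
  # swapping the labels flips the sign
  set.seed(7)
  trait2 <- c(0.7 * v + rnorm(n, sd = 0.5), rnorm(n))
  s2 <- make_samples(2 * n, trait2 + 1000,
                     group = rep(c("case", "control"), each = n))
  s3 <- s2
  s3$group <- ifelse(s2$group == "case", "control", "case")
  g1 <- group_difference_permutation(rep(v, 2), s2, n_perm = 50, seed = 2)
  g2 <- group_difference_permutation(rep(v, 2), s3, n_perm = 50, seed = 2)
  expect_equal(g1$z_diff, -g2$z_diff, tolerance = 1e-12)
  expect_error(group_difference_permutation(v[1:6], make_samples(6, rnorm(6, 1000)),
                                            n_perm = 10), "at least 4")
})

test_that("planted coupling difference is detected with high power", {
  hits <- vapply(1:25, function(s) {
    cfg <- small_config(seed = s + 300L, n_genes = 60L, sizes = 40L,
                        within_cor = 0.7,
                        n_per_group = c(case = 50L, control = 50L),
                        coupling = matrix(c(0, 0.6), 1, 2,
                                          dimnames = list(NULL, c("case", "control"))))
    st <- generate_two_group_study(cfg)
    sa <- age_adjust_trait(st$samples)
    me <- compute_module_eigengenes(st$expr, st$truth$planted_partition)
    gd <- group_difference_permutation(me$eigengenes["M1", ], sa,
                                       n_perm = 199, seed = s)
    gd$perm_p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("bootstrap CIs are seeded, degenerate correctly, and cover the truth", {
  v <- rnorm(30)
  s <- make_samples(30, v + 1000)
  s$tbv_residual_cc <- v          # duplicated vector: r = 1 exactly
  ci <- bootstrap_ci(v, s, n_boot = 100, seed = 1)
  expect_equal(ci$r, 1, tolerance = 1e-12)
  expect_equal(c(ci$ci_low, ci$ci_high), c(1, 1), tolerance = 1e-12)
  ci2 <- bootstrap_ci(v, s, n_boot = 100, seed = 1)
  expect_identical(ci, ci2)
  # coverage at r = 0.5, n = 100
  cover <- vapply(1:60, function(s2) {
    pr <- exact_cor_pair(0.5, 100, seed = s2 + 50)
    st <- make_samples(100, pr$y + 1000)
    ci3 <- bootstrap_ci(pr$x, st, n_boot = 400, seed = s2)
    ci3$ci_low <= 0.5 && 0.5 <= ci3$ci_high
  }, logical(1))
  expect_gte(mean(cover), 0.9)
  expect_error(bootstrap_ci(v[1:5], make_samples(5, rnorm(5, 1000))), "at least 8")
})

test_that("subnetwork averages behave like their module eigengene", {
  cfg <- small_config(seed = 12L, n_genes = 90L, sizes = 60L, within_cor = 0.7,
                      coupling = matrix(c(0, 0.5), 1, 2,
                                        dimnames = list(NULL, c("case", "control"))))
  st <- generate_two_group_study(cfg)
  sa <- age_adjust_trait(st$samples)
  mod_genes <- names(st$truth$planted_partition)[st$truth$planted_partition == "M1"]
  # singleton set reduces to that gene's GS
  g1 <- mod_genes[1]
  sng <- subnetwork_association(g1, st$expr, sa, n_perm = 50, seed = 1)
  gs <- gene_significance(st$expr, sa, "control")
  expect_equal(sng$association$r[sng$association$group == "control"],
               gs$GS[gs$gene == g1], tolerance = 1e-10)
  # whole-module average tracks the eigengene association
  dr <- vapply(1:10, function(s) {
    cfgs <- small_config(seed = s + 40L, n_genes = 90L, sizes = 60L,
                         within_cor = 0.7,
                         coupling = matrix(c(0, 0.5), 1, 2,
                                           dimnames = list(NULL, c("case", "control"))))
    sts <- generate_two_group_study(cfgs)
    sas <- age_adjust_trait(sts$samples)
    mg <- names(sts$truth$planted_partition)[sts$truth$planted_partition == "M1"]
    sa2 <- subnetwork_association(mg, sts$expr, sas, n_perm = 1, seed = 1)
    me <- compute_module_eigengenes(sts$expr, sts$truth$planted_partition)
    mt <- module_trait_correlation(me, sas, "control")
    abs(abs(sa2$association$r[sa2$association$group == "control"]) - abs(mt$r[1]))
  }, numeric(1))
  expect_lte(max(dr), 0.15)
  expect_error(subnetwork_association(c("nope1", "nope2"), st$expr, sa),
               "missing|no genes")
})
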