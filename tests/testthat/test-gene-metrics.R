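test_that("gene significance is a signed trait correlation with asymptotic p", {
  set.seed(2)
  n <- 40L
  trait <- rnorm(n)
  x <- rbind(same = trait, anti = -trait, noise = rnorm(n))
  colnames(x) <- sprintf("S%03d", 1:n)
  s <- make_samples(n, trait + 1000)
  gs <- gene_significance(x, s)
  expect_equal(gs$GS[gs$gene == "same"], 1, tolerance = 1e-10)
  expect_equal(gs$GS[gs$gene == "anti"], -1, tolerance = 1e-10)
  expect_lt(gs$GS_p[gs$gene == "same"], 1e-12)
  # GS(-x) = -GS(x)
  gs2 <- gene_significance(-x, s)
  expect_equal(gs2$GS, -gs$GS, tolerance = 1e-12)
  # null genes rarely reach |GS| 0.3 at n = 100
  big <- matrix(rnorm(200 * 100), 200, 100,
                dimnames = list(paste0("g", 1:200), sprintf("S%03d", 1:100)))
  sb <- make_samples(100, rnorm(100, 1000))
  gsn <- gene_significance(big, sb)
  expect_gte(mean(abs(gsn$GS) < 0.3), 0.95)
  # constant gene: NA with warning
  x2 <- rbind(x, flat = rep(3, n))
  expect_warning(gsf <- gene_significance(x2, s), "constant")
  expect_true(is.na(gsf$GS[gsf$gene == "flat"]))
})

test_that("intramodular connectivity sums within-module adjacency", {
  a <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("g1", "g2"), c("g1", "g2")))
  gc <- intramodular_connectivity(a, setNames(c("M1", "M1"), c("g1", "g2")))
  expect_equal(gc$GC, c(0.8, 0.8))
  # a constructed hub dominates
  n <- 6L
  ah <- matrix(0.3, n, n); ah[1, ] <- ah[, 1] <- 0.9; diag(ah) <- 1
  dimnames(ah) <- list(paste0("g", 1:n), paste0("g", 1:n))
  part <- setNames(rep("M1", n), paste0("g", 1:n))
  gch <- intramodular_connectivity(ah, part)
  expect_equal(which.max(gch$GC), 1L)
  expect_equal(gch$GC[1], 0.9 * (n - 1), tolerance = 1e-12)
  # invariant to gene ordering
  o <- sample(n)
  gco <- intramodular_connectivity(ah[o, o], part[o])
  expect_equal(gco$GC[match(gch$gene, gco$gene)], gch$GC, tolerance = 1e-12)
  # unassigned pool flagged non-comparable
  part2 <- setNames(c(rep("M1", 3), rep("unassigned", 3)), paste0("g", 1:n))
  gcu <- intramodular_connectivity(ah, part2)
  expect_false(any(gcu$comparable[4:6]))
})

test_that("the Fisher-z difference reproduces the published reorganization statistics", {
  expect_equal(round(fisher_z_diff(0.64, 253, 0.42, 253), 2), 3.47)
  expect_equal(round(fisher_z_diff(0.74, 25, -0.34, 25), 2), 4.33)
  expect_equal(fisher_z_diff(0.5, 100, 0.5, 80), 0)
  expect_error(fisher_z_diff(0.5, 3, 0.5, 100), "more than 3")
  # gs_gc_analysis wires |GS| vs GC into the same statistic
  set.seed(9)
  ng <- 50L
  gc <- runif(ng, 1, 10)
  mc <- data.frame(gene = paste0("g", 1:ng), GS = 0.05 * gc + rnorm(ng, sd = 0.3),
                   GC = gc)
  mk <- data.frame(gene = paste0("g", 1:ng), GS = rnorm(ng, sd = 0.3), GC = gc)
  res <- gs_gc_analysis(mc, mk)
  expect_equal(res$z_diff,
               fisher_z_diff(res$r_case, ng, res$r_control, ng), tolerance = 1e-12)
  expect_error(gs_gc_analysis(mc[1:3, ], mk), "3 or fewer")
})

test_that("top-k overlap counts match brute-force expectations", {
  ng <- 40L
  genes <- sprintf("g%02d", 1:ng)
  mc <- data.frame(gene = genes, GS = seq(1, 0.025, length.out = ng), GC = ng:1)
  # identical metrics: full overlap
  ov <- rank_and_overlap(mc, mc, k = 30)
  expect_equal(ov$n_common, 30L)
  expect_equal(ov$n_different, 0L)
  # disjoint constructed rankings
  mk <- mc; mk$GS <- rev(mc$GS)
  ov2 <- rank_and_overlap(mc, mk, k = 10)
  expect_equal(ov2$n_common, 0L)
  # hand-set values: overlap equals the hand-counted intersection
  set.seed(3)
  mcr <- data.frame(gene = genes, GS = rnorm(ng), GC = runif(ng))
  mkr <- data.frame(gene = genes, GS = rnorm(ng), GC = runif(ng))
  ov3 <- rank_and_overlap(mcr, mkr, k = 12)
  hand <- length(intersect(genes[order(-abs(mcr$GS), genes)][1:12],
                           genes[order(-abs(mkr$GS), genes)][1:12]))
  expect_equal(ov3$n_common, hand)
  expect_error(rank_and_overlap(mcr, mkr, k = 50), "exceeds")
})

test_that("odds ratios reproduce every published value under Haldane + Woolf", {
  r1 <- contingency_odds_ratio(matrix(c(16, 14, 5, 25), 2, byrow = TRUE))
  expect_equal(round(r1$or_value, 2), 5.71)
  expect_equal(round(r1$ci_low, 2), 1.72)
  expect_equal(round(r1$ci_high, 2), 18.94)
  expect_false(r1$corrected)

  r2 <- contingency_odds_ratio(matrix(c(19, 0, 14, 5), 2, byrow = TRUE))
  expect_equal(round(r2$or_value, 1), 14.8)
  expect_equal(round(r2$ci_low, 2), 0.76)
  expect_equal(round(r2$ci_high, 1), 289.4)
  expect_true(r2$corrected)

  r3 <- contingency_odds_ratio(matrix(c(19, 0, 1, 18), 2, byrow = TRUE))
  expect_equal(round(r3$or_value), 481)
  expect_equal(round(r3$ci_low, 1), 18.4)
  expect_equal(r3$ci_high, 12570, tolerance = 0.002)

  r4 <- contingency_odds_ratio(matrix(c(14, 9, 1, 18), 2, byrow = TRUE))
  expect_equal(round(r4$or_value), 28)
  expect_equal(round(r4$ci_low, 1), 3.2)
  expect_equal(round(r4$ci_high), 248)
})

test_that("odds-ratio algebra: symmetry, inversion, degeneracy", {
  r <- contingency_odds_ratio(matrix(1, 2, 2))
  expect_equal(r$or_value, 1)
  expect_equal(log(r$ci_low), -log(r$ci_high), tolerance = 1e-12)
  # OR(swapped rows) = 1/OR on uncorrected tables
  for (s in 1:5) {
    set.seed(s)
    t1 <- matrix(sample(1:30, 4), 2)
    a <- contingency_odds_ratio(t1, zero_cell = "none")
    b <- contingency_odds_ratio(t1[2:1, ], zero_cell = "none")
    expect_equal(a$or_value, 1 / b$or_value, tolerance = 1e-12)
  }
  expect_error(contingency_odds_ratio(matrix(c(5, 0, 3, 0), 2, byrow = TRUE)),
               "undefined")
  expect_error(contingency_odds_ratio(matrix(c(1, 2, -1, 3), 2)), "nonnegative")
})

test_that("Fisher exact p equals exhaustive enumeration and fisher.test", {
  enumerate_p <- function(tab) {
    # independent oracle: walk the whole support of tables with these margins
    r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- r1 + r2
    obs <- choose(r1, tab[1, 1]) * choose(r2, c1 - tab[1, 1]) / choose(N, c1)
    tot <- 0
    for (a in max(0, c1 - r2):min(r1, c1)) {
      pr <- choose(r1, a) * choose(r2, c1 - a) / choose(N, c1)
      if (pr <= obs * (1 + 1e-7)) tot <- tot + pr
    }
    min(1, tot)
  }
  set.seed(10)
  for (i in 1:30) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (sum(tab) == 0 || sum(tab) > 60) next
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_p(tab)
    expect_equal(p, enumerate_p(tab), tolerance = 1e-10)
    expect_equal(p, fisher.test(tab)$p.value, tolerance = 1e-7)
  }
})

test_that("hub genes map onto a PPI edge list with degrees", {
  # star graph: centre degree n - 1
  star <- data.frame(from = rep("hub", 5), to = paste0("n", 1:5))
  m <- map_hubs_to_ppi(c("hub", "n2", "absent"), star)
  expect_equal(m$degree[m$gene == "hub"], 5L)
  expect_equal(m$degree[m$gene == "n2"], 1L)
  expect_false("absent" %in% m$gene)
  # duplicate and reversed edges collapse
  dup <- data.frame(from = c("a", "b", "a", "a"), to = c("b", "a", "b", "c"))
  m2 <- map_hubs_to_ppi(c("a", "b", "c"), dup)
  expect_equal(m2$degree[m2$gene == "a"], 2L)
  expect_equal(m2$degree[m2$gene == "b"], 1L)
  # empty intersection warns and returns an empty frame
  expect_warning(m3 <- map_hubs_to_ppi(c("x", "y"), star), "no hub genes")
  expect_equal(nrow(m3), 0L)
})

test_that("differential expression: antisymmetry, power, determinism", {
  set.seed(5)
  n <- 30L
  x <- matrix(rnorm(50 * 2 * n), 50, 2 * n,
              dimnames = list(paste0("g", 1:50), sprintf("S%03d", 1:(2 * n))))
  x[1:20, 1:n] <- x[1:20, 1:n] + 2          # 2-sd shift in cases
  s <- make_samples(2 * n, rnorm(2 * n, 1000),
                    group = rep(c("case", "control"), each = n))
  de <- differential_expression(x, s, n_perm = 100, seed = 2)
  expect_gte(mean(de$p[1:20] < 0.01), 0.95)
  de2 <- differential_expression(x, s, n_perm = 100, seed = 2)
  expect_identical(de, de2)
  # swapping group labels negates t
  s2 <- s; s2$group <- ifelse(s$group == "case", "control", "case")
  de3 <- differential_expression(x, s2, n_perm = 1, seed = 1)
  expect_equal(de3$t, -de$t, tolerance = 1e-12)
  expect_error(differential_expression(x[, 1:3],
                                       s[1:3, ], n_perm = 10), "at least 2")
})
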