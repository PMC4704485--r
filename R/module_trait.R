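#' Correlate module eigengenes with the age-adjusted trait
#'
#' Pearson correlation of each module eigengene with the TBV residual in
#' the requested group, with the Student asymptotic two-sided p-value
#' \code{t = r sqrt(n - 2)/sqrt(1 - r^2)}, df = n - 2.
#'
#' @param me eigengene set from [compute_module_eigengenes()] or a
#'   modules x samples matrix.
#' @param samples sample table with \code{tbv_residual_cc} filled.
#' @param group \code{"all"}, \code{"case"} or \code{"control"}.
#' @return data frame (module, group, n, r, p).
#' @export
module_trait_correlation <- function(me, samples, group = "all") {
  if (is.list(me) && !is.null(me$eigengenes)) me <- me$eigengenes
  .require_residual(samples)
  sel <- .match_group(samples, group) & !is.na(samples$tbv_residual_cc)
  if (sum(sel) < 4L) stop("fewer than 4 samples in group '", group, "'")
  trait <- samples$tbv_residual_cc[sel]
  cols <- match(samples$sample_id[sel], colnames(me))
  if (anyNA(cols)) stop("samples missing from eigengene matrix: ",
                        paste(samples$sample_id[sel][is.na(cols)], collapse = ", "))
  out <- do.call(rbind, lapply(rownames(me), function(m) {
    ct <- .cor_test(me[m, cols], trait)
    data.frame(module = m, group = group, n = ct$n, r = ct$r, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Storey q-values with a smoothed pi0 estimate
#'
#' The proportion of true nulls is estimated on the lambda grid as
#' \code{pi0(lambda) = mean(p > lambda)/(1 - lambda)}, smoothed with a
#' cubic smoothing spline (df = 3) and evaluated at the largest lambda,
#' then clipped to \[1/m, 1\]. q-values are the usual step-up minimum of
#' \code{pi0 * m * p_(i) / i}, monotone nondecreasing in sorted p and
#' capped at 1. \code{method = "bh"} falls back to Benjamini-Hochberg.
#'
#' @param pvals p-values in \[0, 1\].
#' @param lambda grid for pi0 estimation.
#' @param method \code{"smoother"} or \code{"bh"}.
#' @return q-values in the input order.
#' @export
storey_qvalues <- function(pvals, lambda = seq(0, 0.9, by = 0.05),
                           method = c("smoother", "bh")) {
  method <- match.arg(method)
  m <- length(pvals)
  if (m == 0L) return(numeric(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  if (method == "bh" || m < 2L) {
    return(stats::p.adjust(pvals, method = "BH"))
  }
  pi0_l <- vapply(lambda, function(l) mean(pvals > l) / (1 - l), numeric(1))
  sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(sp, x = max(lambda))$y
  # floor at 1/m: stabilizes the smoother for small collections, where a
  # raw estimate of 0 would zero out every q-value
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(pvals)
  q <- pi0 * m * pvals[o] / seq_len(m)
  q <- rev(cummin(rev(pmin(q, 1))))
  out <- numeric(m)
  out[o] <- q
  out
}

#' Permutation p-values for module-trait associations
#'
#' Scrambles the gene -> module assignment (preserving module sizes),
#' recomputes the module eigengenes on each iteration, and records the
#' absolute eigengene-trait correlation. The p-value is the number of
#' null draws at least as large as the observed |r|, divided by
#' \code{n_perm + 1}; an exact zero carries a \code{"floor"} note
#' (< 1/(n_perm + 1)).
#'
#' @param expr genes x samples matrix (complete).
#' @param partition named gene -> module vector.
#' @param samples sample table with residual trait.
#' @param n_perm number of label scrambles (study convention 10,000).
#' @param seed integer seed; fixed seed gives identical p-values.
#' @param group group whose trait correlation is tested.
#' @return data frame (module, r_obs, perm_p, floor_note).
#' @export
permutation_module_pvalue <- function(expr, partition, samples, n_perm = 10000L,
                                      seed = 1L, group = "all") {
  if (n_perm < 1L) stop("n_perm must be at least 1")
  .require_residual(samples)
  partition <- partition[rownames(expr)]
  mods <- setdiff(unique(partition), c("unassigned", "noise", NA))
  if (!length(mods)) stop("no assigned modules in partition")
  sel <- .match_group(samples, group) & !is.na(samples$tbv_residual_cc)
  trait <- samples$tbv_residual_cc[sel]
  cols <- match(samples$sample_id[sel], colnames(expr))

  abs_r <- function(labels) {
    vapply(mods, function(m) {
      idx <- which(labels == m)
      me <- .eigengene(expr[idx, , drop = FALSE])$me
      abs(stats::cor(me[cols], trait))
    }, numeric(1))
  }
  r_obs <- abs_r(partition)
  count <- stats::setNames(integer(length(mods)), mods)
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      r_perm <- abs_r(sample(partition))
      count <- count + (r_perm >= r_obs)
    }
  })
  p <- count / (n_perm + 1)
  data.frame(module = mods, r_obs = unname(r_obs), perm_p = unname(p),
             floor_note = ifelse(count == 0L, paste0("< 1/", n_perm + 1),
                                 NA_character_),
             stringsAsFactors = FALSE)
}

#' Permutation test for a group difference in trait correlation
#'
#' Correlates a per-sample score (an eigengene or a gene-set average) with
#' the TBV residual separately in cases and controls, takes the Fisher-z
#' difference \code{zDiff = atanh(r_case) - atanh(r_control)}, and builds
#' the null by shuffling group labels. Two-sided: p counts null draws with
#' \code{|zDiff|} at least the observed, over \code{n_perm + 1}.
#'
#' @param score named numeric per-sample vector, or a vector aligned with
#'   \code{samples}.
#' @param samples sample table with group and residual trait.
#' @param n_perm permutation count.
#' @param seed integer seed.
#' @return list with \code{r_case}, \code{r_control}, \code{z_diff},
#'   \code{perm_p}.
#' @export
group_difference_permutation <- function(score, samples, n_perm = 10000L, seed = 1L) {
  .require_residual(samples)
  if (!is.null(names(score))) score <- score[samples$sample_id]
  ok <- !is.na(samples$tbv_residual_cc) & !is.na(score)
  score <- score[ok]
  trait <- samples$tbv_residual_cc[ok]
  grp <- samples$group[ok]
  if (sum(grp == "case") < 4L || sum(grp == "control") < 4L) {
    stop("need at least 4 samples per group")
  }
  zdiff <- function(g) {
    atanh(stats::cor(score[g == "case"], trait[g == "case"])) -
      atanh(stats::cor(score[g == "control"], trait[g == "control"]))
  }
  z_obs <- zdiff(grp)
  r_case <- stats::cor(score[grp == "case"], trait[grp == "case"])
  r_control <- stats::cor(score[grp == "control"], trait[grp == "control"])
  count <- 0L
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      if (abs(zdiff(sample(grp))) >= abs(z_obs)) count <- count + 1L
    }
  })
  list(r_case = r_case, r_control = r_control, z_diff = z_obs,
       perm_p = unclass(.perm_p(count, n_perm)))
}

#' Percentile bootstrap confidence interval for a trait correlation
#'
#' Resamples the group's samples with replacement, recomputes the Pearson
#' correlation between the score and the TBV residual, and returns the
#' percentile bounds.
#'
#' @param score per-sample numeric vector (named or aligned).
#' @param samples sample table.
#' @param n_boot resample count (study convention 10,000).
#' @param seed integer seed.
#' @param group group to resample within.
#' @param level confidence level.
#' @return list with \code{r}, \code{ci_low}, \code{ci_high}, \code{n}.
#' @export
bootstrap_ci <- function(score, samples, n_boot = 10000L, seed = 1L,
                         group = "all", level = 0.95) {
  .require_residual(samples)
  if (!is.null(names(score))) score <- score[samples$sample_id]
  sel <- .match_group(samples, group) & !is.na(samples$tbv_residual_cc) & !is.na(score)
  x <- score[sel]
  y <- samples$tbv_residual_cc[sel]
  n <- length(x)
  if (n < 8L) stop("need at least 8 samples in group '", group, "'")
  r <- stats::cor(x, y)
  rb <- numeric(n_boot)
  withr::with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      rb[b] <- suppressWarnings(stats::cor(x[idx], y[idx]))
    }
  })
  rb <- rb[is.finite(rb)]
  alpha <- (1 - level) / 2
  ci <- stats::quantile(rb, c(alpha, 1 - alpha), names = FALSE)
  list(r = r, ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Associate a gene set's average expression with the trait
#'
#' The per-sample mean of the member genes' standardized expression is the
#' subnetwork score; the score is then tested with
#' [module_trait_correlation()]-style correlations per group and a
#' [group_difference_permutation()] between groups.
#'
#' @param gene_set character vector of gene identifiers.
#' @param expr genes x samples matrix.
#' @param samples sample table.
#' @param n_perm permutations for the group-difference test.
#' @param seed integer seed.
#' @return list with \code{score}, \code{association} (data frame over
#'   groups all/case/control) and \code{group_difference}.
#' @export
subnetwork_association <- function(gene_set, expr, samples, n_perm = 10000L,
                                   seed = 1L) {
  found <- intersect(gene_set, rownames(expr))
  if (length(found) == 0L) {
    stop("no genes of the set found in the expression matrix; missing: ",
         paste(utils::head(setdiff(gene_set, rownames(expr)), 10), collapse = ", "))
  }
  xs <- .scale_rows(expr[found, , drop = FALSE])
  score <- colMeans(xs)
  assoc <- do.call(rbind, lapply(c("all", "case", "control"), function(g) {
    sel <- .match_group(samples, g) & !is.na(samples$tbv_residual_cc)
    ct <- .cor_test(score[samples$sample_id[sel]], samples$tbv_residual_cc[sel])
    data.frame(set = "subnetwork", group = g, n = ct$n, r = ct$r, p = ct$p,
               stringsAsFactors = FALSE)
  }))
  gd <- group_difference_permutation(score, samples, n_perm = n_perm, seed = seed)
  list(score = score, n_genes = length(found), association = assoc,
       group_difference = gd)
}
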