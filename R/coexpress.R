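#' Select the soft-threshold power by scale-free topology fit
#'
#' For each candidate power the gene connectivities \code{k_i = sum_j
#' |cor(x_i, x_j)|^beta} are binned into roughly equal-count bins and
#' \code{log10 p(k)} is regressed on \code{log10 mean(k)} per bin. The fit
#' index is the regression R-squared signed by the slope (positive only
#' when the slope is negative, the scale-free direction). The lowest power
#' whose signed fit reaches \code{r2_target} is selected; if none does,
#' the power with the best fit is returned with a warning.
#'
#' @param expr genes x samples matrix without missing values.
#' @param powers candidate integer powers.
#' @param r2_target signed R-squared to reach (study convention 0.90).
#' @param n_bins number of equal-count connectivity bins.
#' @return list with \code{power} and \code{fit_table} (power, signed R2,
#'   slope, mean connectivity).
#' @export
select_soft_power <- function(expr, powers = 1:20, r2_target = 0.9, n_bins = 10L) {
  if (nrow(expr) < 10L || ncol(expr) < 3L) stop("need at least 10 genes and 3 samples")
  xs <- .scale_rows(expr, drop = FALSE)
  ac <- abs(stats::cor(t(xs)))
  fit <- data.frame(power = powers, signed_r2 = NA_real_, slope = NA_real_,
                    mean_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- ac^powers[i]
    k <- colSums(a) - 1
    fit$mean_k[i] <- mean(k)
    brk <- unique(stats::quantile(k, probs = seq(0, 1, length.out = n_bins + 1L)))
    if (length(brk) < 3L) next
    bin <- cut(k, breaks = brk, include.lowest = TRUE)
    width <- diff(brk)
    # equal-count bins: the degree density is count/(total * bin width)
    pk <- tabulate(bin, nbins = nlevels(bin)) / (length(k) * width)
    km <- tapply(k, bin, mean)
    okb <- is.finite(pk) & pk > 0 & km > 0
    if (sum(okb) < 3L) next
    lf <- stats::lm(log10(pk[okb]) ~ log10(km[okb]))
    r2 <- summary(lf)$r.squared
    sl <- stats::coef(lf)[2L]
    fit$slope[i] <- sl
    fit$signed_r2[i] <- if (is.finite(sl) && sl < 0) r2 else -r2
  }
  hit <- which(fit$signed_r2 >= r2_target)
  if (length(hit)) {
    power <- powers[hit[1L]]
  } else {
    power <- powers[which.max(fit$signed_r2)]
    warning("scale-free fit target ", r2_target, " not reached; returning best power ",
            power, " (signed R2 = ", round(max(fit$signed_r2, na.rm = TRUE), 3), ")")
  }
  list(power = power, fit_table = fit)
}

#' Build the weighted (unsigned) adjacency matrix
#'
#' \code{a_ij = |cor(x_i, x_j)|^beta} for \code{i != j}, with unit
#' diagonal. The signed variant uses \code{((1 + cor)/2)^beta}.
#'
#' @param expr genes x samples matrix without missing values.
#' @param beta soft-threshold power.
#' @param unsigned use the unsigned (bidirectional) network (default).
#' @return symmetric adjacency matrix with entries in \[0, 1\].
#' @export
build_adjacency <- function(expr, beta, unsigned = TRUE) {
  if (anyNA(expr)) stop("expression contains missing values; filter or impute upstream")
  xs <- .scale_rows(expr, drop = FALSE)
  cc <- stats::cor(t(xs))
  a <- if (unsigned) abs(cc)^beta else ((1 + cc) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap matrix
#'
#' \code{TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)}
#' with \code{k_i = sum_{u != i} a_iu} and the shared-neighbor sum taken
#' over \code{u != i, j}; \code{TOM_ii = 1}. Entries lie in \[0, 1\] and
#' the matrix is symmetric.
#'
#' @param adjacency symmetric adjacency matrix with unit diagonal.
#' @return the TOM matrix.
#' @export
compute_tom <- function(adjacency) {
  a <- adjacency
  stopifnot(is.matrix(a), nrow(a) == ncol(a))
  k <- rowSums(a) - 1
  num <- a %*% a - a          # sum_{u != i,j} a_iu a_uj + a_ij (unit diagonal)
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  (tom + t(tom)) / 2
}

#' Detect co-expression modules on the TOM dissimilarity
#'
#' Deterministic replacement for dynamic tree cutting. Average-linkage
#' hierarchical clustering of \code{1 - TOM} is cut statically at the
#' \code{cut_quantile} quantile of the merge heights to obtain seed
#' clusters. A seed cluster is accepted when its genes cohere around one
#' eigengene (mean |kME| at least \code{min_mean_kme}); an incoherent
#' cluster (e.g. several modules merged under one branch, or a loose
#' aggregate on unstructured data) is re-cut on its own subtree, up to
#' \code{max_depth} times, so the effective cut height adapts per branch.
#' Clusters below \code{min_module_size} are discarded. Finally every
#' gene is assigned to the seed module with its highest |kME| when that
#' membership reaches \code{kme_reassign_threshold}, otherwise to
#' \code{"unassigned"} (the grey pool); this membership stage both
#' rescues unassigned genes and prunes weakly attached cluster members.
#' Surviving modules are relabelled \code{"M1"}, \code{"M2"}, ... by
#' decreasing size.
#'
#' @param tom TOM matrix from [compute_tom()].
#' @param expr the genes x samples matrix the TOM was built from (used for
#'   eigengene memberships).
#' @param min_module_size smallest allowed module (study convention 30).
#' @param cut_quantile quantile of merge heights for the static cut.
#' @param kme_reassign_threshold minimum |kME| for module membership.
#' @param min_mean_kme module coherence gate on mean |kME|.
#' @param max_depth recursion limit for re-cutting incoherent branches.
#' @return named character vector gene -> module label ("unassigned" for
#'   the grey pool).
#' @export
detect_modules <- function(tom, expr, min_module_size = 30L, cut_quantile = 0.95,
                           kme_reassign_threshold = 0.3, min_mean_kme = 0.5,
                           max_depth = 12L) {
  stopifnot(nrow(tom) == nrow(expr))
  genes <- rownames(expr)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(expr)))
  unassigned <- stats::setNames(rep("unassigned", length(genes)), genes)
  if (length(genes) < min_module_size) return(unassigned)

  xs <- .scale_rows(expr, drop = FALSE)
  coherent <- function(idx) {
    me <- .eigengene(expr[idx, , drop = FALSE])$me
    kme <- as.numeric(stats::cor(t(xs[idx, , drop = FALSE]), me))
    mean(abs(kme)) >= min_mean_kme
  }
  # recursive seed-cluster search: cut each incoherent branch again on its
  # own subtree so the effective cut height adapts per branch
  find_seeds <- function(idx, depth) {
    if (length(idx) < min_module_size) return(list())
    hc <- stats::hclust(stats::as.dist(1 - tom[idx, idx]), method = "average")
    hc$height <- cummax(hc$height)   # guard float-level non-monotonicity
    cl <- stats::cutree(hc, h = stats::quantile(hc$height, cut_quantile))
    if (length(unique(cl)) == 1L) cl <- stats::cutree(hc, k = 2L)
    out <- list()
    for (g in unique(cl)) {
      sub <- idx[cl == g]
      if (length(sub) < min_module_size) next
      if (coherent(sub)) {
        out <- c(out, list(sub))
      } else if (depth > 0L) {
        out <- c(out, find_seeds(sub, depth - 1L))
      }
    }
    out
  }
  seeds <- find_seeds(seq_along(genes), max_depth)
  if (!length(seeds)) return(unassigned)

  # final membership stage: every gene joins the module of its highest
  # |kME| when that reaches the threshold; this rescues unassigned genes
  # and prunes weakly attached seed members in one deterministic pass
  mes <- vapply(seeds, function(idx) .eigengene(expr[idx, , drop = FALSE])$me,
                numeric(ncol(expr)))
  kme <- stats::cor(t(xs), mes)                    # genes x seed modules
  best <- max.col(abs(kme), ties.method = "first")
  bestv <- abs(kme)[cbind(seq_along(genes), best)]
  labels <- ifelse(bestv >= kme_reassign_threshold, paste0("seed", best),
                   "unassigned")
  names(labels) <- genes
  # enforce the size floor after pruning, then relabel by decreasing size
  sz <- table(labels[labels != "unassigned"])
  labels[labels %in% names(sz)[sz < min_module_size]] <- "unassigned"
  sz <- sort(table(labels[labels != "unassigned"]), decreasing = TRUE)
  if (!length(sz)) return(unassigned)
  map <- stats::setNames(paste0("M", seq_along(sz)), names(sz))
  labels[labels != "unassigned"] <- map[labels[labels != "unassigned"]]
  labels
}

#' Compute module eigengenes
#'
#' Per module, genes are z-scored and the first right singular vector over
#' samples is taken as the module eigengene (unit norm, sign aligned so
#' that its correlation with the module's mean standardized expression is
#' nonnegative). The variance-explained fraction is recorded.
#'
#' @param expr genes x samples matrix.
#' @param partition named gene -> module vector; \code{"unassigned"} and
#'   \code{"noise"} labels are skipped.
#' @return list with \code{eigengenes} (modules x samples matrix) and
#'   \code{var_explained} (named vector).
#' @export
compute_module_eigengenes <- function(expr, partition) {
  partition <- partition[rownames(expr)]
  mods <- setdiff(unique(partition), c("unassigned", "noise", NA))
  mods <- mods[order(match(mods, partition))]
  if (!length(mods)) stop("no assigned modules in partition")
  me <- matrix(NA_real_, length(mods), ncol(expr),
               dimnames = list(mods, colnames(expr)))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    idx <- which(partition == m)
    if (length(idx) < 2L) stop("module ", m, " has fewer than 2 genes")
    eg <- .eigengene(expr[idx, , drop = FALSE])
    me[m, ] <- eg$me
    ve[m] <- eg$var_explained
  }
  list(eigengenes = me, var_explained = ve)
}
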