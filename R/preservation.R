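#' Module preservation between a reference and a test dataset
#'
#' Permutation Z statistics asking whether modules defined in the
#' reference dataset keep their density and connectivity structure in a
#' test dataset. Analysis runs on the gene intersection; modules keeping
#' fewer than \code{min_module_size} genes are skipped with a warning.
#'
#' Observed statistics per module (computed in the test data unless
#' noted): mean within-module adjacency (\code{|cor|^beta}), proportion of
#' variance explained by the test-data module eigengene, mean |kME|;
#' connectivity side: correlation over module genes of reference and test
#' intramodular connectivity, and correlation of the vectorized
#' within-module correlation matrices of the two datasets. Each
#' statistic's Z is \code{(obs - mean_perm)/sd_perm} over \code{n_perm}
#' random same-size gene sets drawn from the test data (reference-side
#' quantities are recomputed on the same random set). \code{Z_density}
#' and \code{Z_connectivity} are the medians of their statistic groups
#' and \code{Zsummary} their mean. \code{medianRank} is the median over
#' statistics of the module's observed-value rank (1 = most preserved).
#' Bands follow the usual reading: Zsummary < 2 no evidence, 2-10 weak to
#' moderate, > 10 high preservation.
#'
#' @param expr_ref,expr_test genes x samples matrices (samples may
#'   differ; genes are matched by rowname).
#' @param partition_ref named gene -> module vector from the reference
#'   analysis.
#' @param beta soft power for the adjacency in both datasets.
#' @param n_perm random gene-set draws (default 200).
#' @param seed integer seed.
#' @param min_module_size smallest module analysed after intersection.
#' @return data frame (module, n_genes, Z_density, Z_connectivity,
#'   Zsummary, medianRank, band).
#' @export
module_preservation <- function(expr_ref, expr_test, partition_ref, beta = 6,
                                n_perm = 200L, seed = 1L, min_module_size = 10L) {
  genes <- intersect(rownames(expr_ref), rownames(expr_test))
  if (length(genes) < min_module_size) stop("gene identifiers barely overlap between datasets")
  partition_ref <- partition_ref[genes]
  mods <- setdiff(unique(partition_ref), c("unassigned", "noise", NA))
  sizes <- vapply(mods, function(m) sum(partition_ref == m), integer(1))
  drop <- sizes < min_module_size
  if (any(drop)) {
    warning("skipping module(s) too small after intersection: ",
            paste(mods[drop], collapse = ", "))
    mods <- mods[!drop]
  }
  if (!length(mods)) stop("no module large enough after intersection")

  cr <- stats::cor(t(expr_ref[genes, , drop = FALSE]))
  ct <- stats::cor(t(expr_test[genes, , drop = FALSE]))
  xt <- expr_test[genes, , drop = FALSE]

  stat_names <- c("mean_adj", "prop_var", "mean_kme", "cor_kim", "cor_cor")
  # ref_idx stays the module's genes; test_idx is the module itself for the
  # observed statistic and a random same-size gene set for the null draws,
  # so the null asks how well a random test-side set matches the module
  set_stats <- function(ref_idx, test_idx) {
    art <- abs(cr[ref_idx, ref_idx])^beta
    att <- abs(ct[test_idx, test_idx])^beta
    off <- row(att) != col(att)
    eg <- .eigengene(xt[test_idx, , drop = FALSE])
    kme <- suppressWarnings(stats::cor(t(xt[test_idx, , drop = FALSE]), eg$me))
    low <- lower.tri(att)
    c(mean_adj = mean(att[off]),
      prop_var = eg$var_explained,
      mean_kme = mean(abs(kme), na.rm = TRUE),
      cor_kim = suppressWarnings(stats::cor(rowSums(art) - 1, rowSums(att) - 1)),
      cor_cor = suppressWarnings(
        stats::cor(cr[ref_idx, ref_idx][low], ct[test_idx, test_idx][low])))
  }

  obs <- t(vapply(mods, function(m) {
    idx <- which(partition_ref == m)
    set_stats(idx, idx)
  }, numeric(length(stat_names))))
  rownames(obs) <- mods

  z <- matrix(NA_real_, length(mods), length(stat_names),
              dimnames = list(mods, stat_names))
  withr::with_seed(seed, {
    for (mi in seq_along(mods)) {
      idx <- which(partition_ref == mods[mi])
      nullmat <- t(vapply(seq_len(n_perm), function(i) {
        set_stats(idx, sample.int(length(genes), length(idx)))
      }, numeric(length(stat_names))))
      mu <- colMeans(nullmat, na.rm = TRUE)
      sdv <- apply(nullmat, 2, stats::sd, na.rm = TRUE)
      zz <- (obs[mi, ] - mu) / pmax(sdv, 1e-12)
      zz[abs(obs[mi, ] - mu) < 1e-12] <- 0
      z[mi, ] <- pmin(pmax(zz, -1e6), 1e6)
    }
  })

  z_density <- apply(z[, c("mean_adj", "prop_var", "mean_kme"), drop = FALSE], 1,
                     stats::median)
  z_conn <- apply(z[, c("cor_kim", "cor_cor"), drop = FALSE], 1, stats::median)
  zsummary <- (z_density + z_conn) / 2
  ranks <- apply(-obs, 2, rank, ties.method = "average")
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = 1)
  median_rank <- apply(ranks, 1, stats::median)
  band <- cut(zsummary, breaks = c(-Inf, 2, 10, Inf),
              labels = c("none", "moderate", "high"), right = FALSE)

  data.frame(module = mods,
             n_genes = vapply(mods, function(m) sum(partition_ref == m), integer(1)),
             Z_density = unname(z_density),
             Z_connectivity = unname(z_conn),
             Zsummary = unname(zsummary),
             medianRank = unname(median_rank),
             band = as.character(band),
             stringsAsFactors = FALSE, row.names = NULL)
}
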