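#' Split a group's samples by the sign of the trait residual
#'
#' Samples with negative age-adjusted TBV residual form the smaller-brain
#' subgroup, positive residuals the bigger-brain subgroup. A residual of
#' exactly zero goes to the bigger subgroup (ties broken upward).
#'
#' @param samples sample table with residual trait.
#' @param group group to split.
#' @return list with character vectors \code{small} and \code{big}.
#' @export
split_samples_by_residual <- function(samples, group = "all") {
  .require_residual(samples)
  sel <- .match_group(samples, group) & !is.na(samples$tbv_residual_cc)
  s <- samples[sel, ]
  small <- s$sample_id[s$tbv_residual_cc < 0]
  big <- s$sample_id[s$tbv_residual_cc >= 0]
  if (!length(small) || !length(big)) {
    stop("empty subgroup after splitting at residual 0 in group '", group, "'")
  }
  list(small = small, big = big)
}

#' Classify hub-gene relevance in small- and big-brain subgroups
#'
#' For a supplied gene list (typically PPI-mapped hub genes), gene
#' significance is computed on the full group (GS-ALL) and on the
#' smaller-/bigger-brain subgroups (GS-SM, GS-BG). The relevance threshold
#' is the minimum |GS-ALL| over the supplied list; a gene retains
#' relevance in a subgroup iff its subgroup |GS| reaches that threshold,
#' otherwise it loses relevance. Genes outside the supplied list whose
#' subgroup |GS| reaches the threshold while their |GS-ALL| did not are
#' reported as gained.
#'
#' @param genes gene identifiers to classify (at least 2).
#' @param expr genes x samples matrix.
#' @param samples sample table with residual trait.
#' @param group diagnostic group to analyse.
#' @param scan_genes genes scanned for gains (default: all genes in
#'   \code{expr} not in \code{genes}).
#' @return list with \code{records} (per supplied gene: gs_all, gs_small,
#'   gs_big, status_small, status_big), \code{threshold_all},
#'   \code{gained} (per subgroup), and the 2x2-ready retained/lost counts.
#' @export
classify_gene_relevance <- function(genes, expr, samples, group = "all",
                                    scan_genes = NULL) {
  if (length(genes) < 2L) stop("need at least 2 genes to set a threshold")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("genes absent from expression: ",
                            paste(missing, collapse = ", "))
  split <- split_samples_by_residual(samples, group)
  if (length(split$small) < 4L || length(split$big) < 4L) {
    stop("both subgroups need at least 4 samples")
  }
  gs_for <- function(ids) {
    sub <- samples[samples$sample_id %in% ids, ]
    gs <- gene_significance(expr, sub, group = "all")
    stats::setNames(gs$GS, gs$gene)
  }
  sel_all <- samples$sample_id[.match_group(samples, group) &
                                 !is.na(samples$tbv_residual_cc)]
  gs_all <- gs_for(sel_all)
  gs_small <- gs_for(split$small)
  gs_big <- gs_for(split$big)
  thr <- min(abs(gs_all[genes]), na.rm = TRUE)

  records <- data.frame(
    gene = genes,
    gs_all = unname(gs_all[genes]),
    gs_small = unname(gs_small[genes]),
    gs_big = unname(gs_big[genes]),
    status_small = ifelse(abs(gs_small[genes]) >= thr, "retained", "lost"),
    status_big = ifelse(abs(gs_big[genes]) >= thr, "retained", "lost"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  scan <- if (is.null(scan_genes)) setdiff(rownames(expr), genes)
          else setdiff(scan_genes, genes)
  gained <- list(
    small = scan[!is.na(gs_small[scan]) & abs(gs_small[scan]) >= thr &
                   abs(gs_all[scan]) < thr],
    big = scan[!is.na(gs_big[scan]) & abs(gs_big[scan]) >= thr &
                 abs(gs_all[scan]) < thr]
  )
  counts <- list(
    small = c(retained = sum(records$status_small == "retained"),
              lost = sum(records$status_small == "lost")),
    big = c(retained = sum(records$status_big == "retained"),
            lost = sum(records$status_big == "lost"))
  )
  list(records = records, threshold_all = thr, gained = gained, counts = counts)
}
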