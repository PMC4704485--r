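#' Gene significance: per-gene trait correlation
#'
#' Signed Pearson correlation of each gene's expression with the TBV
#' residual in the requested group, with the Student asymptotic two-sided
#' p-value (df = n - 2). Constant genes get NA with a warning.
#'
#' @param expr genes x samples matrix.
#' @param samples sample table with residual trait.
#' @param group \code{"all"}, \code{"case"} or \code{"control"}.
#' @return data frame (gene, group, GS, GS_p, n).
#' @export
gene_significance <- function(expr, samples, group = "all") {
  .require_residual(samples)
  sel <- .match_group(samples, group) & !is.na(samples$tbv_residual_cc)
  n <- sum(sel)
  if (n < 4L) stop("fewer than 4 samples in group '", group, "'")
  x <- expr[, samples$sample_id[sel], drop = FALSE]
  trait <- samples$tbv_residual_cc[sel]
  sds <- apply(x, 1L, stats::sd)
  const <- sds < .Machine$double.eps^0.5
  if (any(const)) warning(sum(const), " constant gene(s): GS undefined, reported NA")
  gs <- rep(NA_real_, nrow(x))
  gs[!const] <- as.numeric(stats::cor(t(x[!const, , drop = FALSE]), trait))
  r2 <- pmin(gs^2, 1 - .Machine$double.eps)
  tt <- gs * sqrt(n - 2) / sqrt(1 - r2)
  data.frame(gene = rownames(x), group = group, GS = gs,
             GS_p = 2 * stats::pt(-abs(tt), df = n - 2), n = n,
             stringsAsFactors = FALSE)
}

#' Intramodular connectivity (kWithin)
#'
#' \code{GC_i = sum of a_ij} over the other genes of gene i's module.
#' Genes in the unassigned pool get their connectivity within that pool,
#' flagged non-comparable.
#'
#' @param adjacency adjacency matrix from [build_adjacency()].
#' @param partition named gene -> module vector.
#' @return data frame (gene, module, GC, comparable).
#' @export
intramodular_connectivity <- function(adjacency, partition) {
  genes <- rownames(adjacency)
  partition <- partition[genes]
  gc <- stats::setNames(numeric(length(genes)), genes)
  for (m in unique(partition)) {
    idx <- which(partition == m)
    a <- adjacency[idx, idx, drop = FALSE]
    gc[idx] <- rowSums(a) - 1
  }
  data.frame(gene = genes, module = unname(partition), GC = unname(gc),
             comparable = !(partition %in% c("unassigned", "noise")),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Fisher-z difference between two correlations
#'
#' \code{z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1 - 3) + 1/(n2 - 3))}.
#' No p-value is attached: when every module gene is measured the
#' correlations are population quantities and the statistic itself
#' quantifies the group difference.
#'
#' @param r1,r2 correlations.
#' @param n1,n2 the number of observations (genes) behind each.
#' @return the z statistic.
#' @export
fisher_z_diff <- function(r1, n1, r2, n2) {
  if (n1 <= 3L || n2 <= 3L) stop("need more than 3 observations per group")
  (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
}

#' GS-GC reorganization analysis for one module
#'
#' Correlates |GS| with GC across a module's genes in each group and
#' quantifies the group difference with the Fisher-z statistic
#' ([fisher_z_diff()]).
#'
#' @param metrics_case,metrics_control data frames with columns
#'   \code{gene}, \code{GS}, \code{GC} (e.g. merged output of
#'   [gene_significance()] and [intramodular_connectivity()]), already
#'   restricted to the module of interest.
#' @return list with \code{r_case}, \code{r_control}, \code{z_diff},
#'   \code{n_case}, \code{n_control}.
#' @export
gs_gc_analysis <- function(metrics_case, metrics_control) {
  f <- function(d) {
    d <- d[stats::complete.cases(d$GS, d$GC), ]
    if (nrow(d) <= 3L) stop("module has 3 or fewer genes with defined GS and GC")
    list(r = stats::cor(abs(d$GS), d$GC), n = nrow(d))
  }
  a <- f(metrics_case)
  b <- f(metrics_control)
  list(r_case = a$r, r_control = b$r,
       z_diff = fisher_z_diff(a$r, a$n, b$r, b$n),
       n_case = a$n, n_control = b$n)
}

#' Top-k ranking overlap between groups
#'
#' Ranks a module's genes by |GS| (or GC) within each group, takes the top
#' k (study convention 30; ties broken by gene identifier), and counts the
#' overlap.
#'
#' @param metrics_case,metrics_control data frames with \code{gene} and
#'   the ranking column.
#' @param k list length.
#' @param on \code{"GS"} (ranked by absolute value by default) or
#'   \code{"GC"}.
#' @param abs_gs rank GS by magnitude (default) or signed value.
#' @return list with \code{top_case}, \code{top_control},
#'   \code{n_common}, \code{n_different}.
#' @export
rank_and_overlap <- function(metrics_case, metrics_control, k = 30L,
                             on = c("GS", "GC"), abs_gs = TRUE) {
  on <- match.arg(on)
  top <- function(d) {
    if (nrow(d) < k) stop("k = ", k, " exceeds the module size ", nrow(d))
    v <- d[[on]]
    if (on == "GS" && abs_gs) v <- abs(v)
    d$gene[order(-v, d$gene)][seq_len(k)]
  }
  tc <- top(metrics_case)
  tk <- top(metrics_control)
  common <- intersect(tc, tk)
  list(top_case = tc, top_control = tk,
       n_common = length(common), n_different = k - length(common))
}

#' Odds ratio for a 2x2 table with zero-cell correction
#'
#' \code{OR = ad/bc} with the Haldane-Anscombe correction (+0.5 to every
#' cell) applied iff any cell is zero and \code{zero_cell = "haldane"}.
#' The confidence interval is the Woolf logit interval
#' \code{exp(log OR +/- z * sqrt(sum 1/cell))} on the same (possibly
#' corrected) table. The two-sided Fisher exact p (sum of hypergeometric
#' probabilities no larger than the observed one) is computed on the
#' uncorrected table.
#'
#' @param tab 2x2 matrix or length-4 vector (a, b, c, d by row:
#'   rows = groups, columns = in-top/not-in-top).
#' @param zero_cell \code{"haldane"} or \code{"none"}.
#' @param ci_level confidence level.
#' @return list with \code{or_value}, \code{ci_low}, \code{ci_high},
#'   \code{fisher_p}, \code{corrected}.
#' @export
contingency_odds_ratio <- function(tab, zero_cell = c("haldane", "none"),
                                   ci_level = 0.95) {
  zero_cell <- match.arg(zero_cell)
  x <- as.vector(t(as.matrix(tab)))
  if (length(x) != 4L || any(x < 0) || any(x != round(x))) {
    stop("need a 2x2 table of nonnegative integers")
  }
  if (sum(x) == 0L) stop("table is all zero")
  a <- x[1]; b <- x[2]; c <- x[3]; d <- x[4]
  if ((a == 0 || d == 0) && (b == 0 || c == 0)) {
    stop("OR undefined: zero cells in both the numerator and denominator")
  }
  corrected <- zero_cell == "haldane" && any(x == 0)
  xc <- if (corrected) x + 0.5 else x
  or <- (xc[1] * xc[4]) / (xc[2] * xc[3])
  se <- sqrt(sum(1 / xc))
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(or_value = or,
       ci_low = exp(log(or) - z * se),
       ci_high = exp(log(or) + z * se),
       fisher_p = fisher_exact_p(matrix(x, 2, byrow = TRUE)),
       corrected = corrected)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Sums, over the hypergeometric support given the table margins, the
#' probabilities of all tables no more likely than the observed one.
#'
#' @param tab 2x2 matrix (rows = groups).
#' @return the p-value.
#' @export
fisher_exact_p <- function(tab) {
  tab <- as.matrix(tab)
  a <- tab[1, 1]
  m <- sum(tab[1, ])   # row 1 total
  nn <- sum(tab[2, ])  # row 2 total
  kk <- sum(tab[, 1])  # column 1 total
  supp <- max(0, kk - nn):min(m, kk)
  dens <- stats::dhyper(supp, m, nn, kk)
  obs <- stats::dhyper(a, m, nn, kk)
  min(1, sum(dens[dens <= obs * (1 + 1e-7)]))
}

#' Map hub genes onto a protein-interaction network
#'
#' Intersects a hub-gene list with the node set of an undirected edge
#' list (duplicate edges collapsed, self-loops ignored) and reports each
#' mapped gene's degree.
#'
#' @param hub_genes character vector.
#' @param edges two-column data frame or matrix of gene identifiers.
#' @return data frame (gene, degree); empty (with a warning) when nothing
#'   maps.
#' @export
map_hubs_to_ppi <- function(hub_genes, edges) {
  edges <- as.data.frame(edges)[, 1:2]
  names(edges) <- c("from", "to")
  if (nrow(edges) < 1L) stop("edge list is empty")
  edges <- edges[edges$from != edges$to, ]
  key <- ifelse(edges$from < edges$to, paste(edges$from, edges$to),
                paste(edges$to, edges$from))
  edges <- edges[!duplicated(key), ]
  nodes <- unique(c(edges$from, edges$to))
  mapped <- intersect(hub_genes, nodes)
  if (!length(mapped)) {
    warning("no hub genes present in the interaction network")
    return(data.frame(gene = character(0), degree = integer(0)))
  }
  deg <- table(c(edges$from, edges$to))
  data.frame(gene = mapped, degree = as.integer(deg[mapped]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential expression between groups
#'
#' Welch two-sample t-test per gene with a permutation p-value from
#' group-label shuffling (\code{count/(n_perm + 1)}).
#'
#' @param expr genes x samples matrix.
#' @param samples sample table with \code{group}.
#' @param n_perm permutation count (study convention 10,000).
#' @param seed integer seed.
#' @return data frame (gene, t, p, perm_p).
#' @export
differential_expression <- function(expr, samples, n_perm = 10000L, seed = 1L) {
  grp <- samples$group[match(colnames(expr), samples$sample_id)]
  if (sum(grp == "case") < 2L || sum(grp == "control") < 2L) {
    stop("need at least 2 samples per group")
  }
  welch_t <- function(g) {
    x1 <- expr[, g == "case", drop = FALSE]
    x2 <- expr[, g == "control", drop = FALSE]
    n1 <- ncol(x1); n2 <- ncol(x2)
    m1 <- rowMeans(x1); m2 <- rowMeans(x2)
    v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
    (m1 - m2) / sqrt(v1 / n1 + v2 / n2)
  }
  t_obs <- welch_t(grp)
  x1 <- expr[, grp == "case", drop = FALSE]
  x2 <- expr[, grp == "control", drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  v1 <- apply(x1, 1, stats::var); v2 <- apply(x2, 1, stats::var)
  df <- (v1 / n1 + v2 / n2)^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t_obs), df = df)
  count <- integer(nrow(expr))
  withr::with_seed(seed, {
    for (i in seq_len(n_perm)) {
      count <- count + (abs(welch_t(sample(grp))) >= abs(t_obs))
    }
  })
  data.frame(gene = rownames(expr), t = unname(t_obs), p = unname(p),
             perm_p = count / (n_perm + 1), stringsAsFactors = FALSE)
}
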