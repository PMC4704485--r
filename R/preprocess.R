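#' Filter uninformative genes
#'
#' Two array-style filters applied in order. Genes missing in more than
#' \code{max_missing_frac} of samples are removed. Genes whose variance is
#' not significantly greater than the median gene variance are then
#' removed, using a one-sided chi-square variance test:
#' \code{(n - 1) s_i^2 / median(s^2)} against the upper tail of a
#' chi-square with \code{n - 1} degrees of freedom, removing the gene when
#' p > \code{variance_alpha}. Set \code{variance_alpha = NULL} to apply
#' only the missingness rule. Gene order is preserved.
#'
#' @param expr genes x samples numeric matrix (may contain NA).
#' @param max_missing_frac maximum tolerated missing fraction per gene.
#' @param variance_alpha significance level of the variance filter, or
#'   NULL to disable it.
#' @return the filtered matrix.
#' @export
filter_genes <- function(expr, max_missing_frac = 0.5, variance_alpha = 0.05) {
  if (!is.matrix(expr) || nrow(expr) == 0L) stop("expr must be a nonempty matrix")
  miss <- rowMeans(is.na(expr))
  keep <- miss <= max_missing_frac
  expr <- expr[keep, , drop = FALSE]
  if (nrow(expr) == 0L) stop("empty after filtering: all genes exceeded the missingness threshold")
  if (!is.null(variance_alpha)) {
    n_obs <- rowSums(!is.na(expr))
    v <- apply(expr, 1L, stats::var, na.rm = TRUE)
    med <- stats::median(v, na.rm = TRUE)
    if (!is.finite(med) || med <= 0) stop("median gene variance is zero; variance filter undefined")
    p <- stats::pchisq((n_obs - 1) * v / med, df = n_obs - 1, lower.tail = FALSE)
    expr <- expr[p <= variance_alpha, , drop = FALSE]
    if (nrow(expr) == 0L) stop("empty after filtering: no gene variance significantly exceeds the median")
  }
  expr
}

#' Collapse replicate arrays to one column per subject
#'
#' Samples whose \code{replicate_of} field names another sample are
#' replicates of that (primary) sample. \code{policy = "average"} replaces
#' each primary column by the per-gene mean over the primary and its
#' replicates; \code{policy = "pick_labeled"} keeps the designated primary
#' column unchanged. Replicate columns are dropped from both the matrix
#' and the sample table.
#'
#' @param expr genes x samples matrix.
#' @param samples sample table with \code{sample_id} and
#'   \code{replicate_of} columns.
#' @param policy \code{"average"} or \code{"pick_labeled"}.
#' @return list with collapsed \code{expr} and \code{samples}.
#' @export
collapse_replicates <- function(expr, samples, policy = c("average", "pick_labeled")) {
  policy <- match.arg(policy)
  rep_of <- samples$replicate_of
  is_rep <- !is.na(rep_of) & rep_of != ""
  primaries <- samples$sample_id[!is_rep]
  bad <- is_rep & !(rep_of %in% primaries)
  if (any(bad)) {
    stop("replicate_of must reference primary samples (no chains/cycles): ",
         paste(samples$sample_id[bad], collapse = ", "))
  }
  if (policy == "average") {
    for (p in primaries) {
      cols <- c(p, samples$sample_id[is_rep & rep_of == p])
      if (length(cols) > 1L) {
        expr[, p] <- rowMeans(expr[, cols, drop = FALSE], na.rm = TRUE)
      }
    }
  }
  list(expr = expr[, primaries, drop = FALSE],
       samples = samples[!is_rep, , drop = FALSE])
}

#' Age-adjust the trait
#'
#' Fits a smooth trend of TBV on age pooled across groups (or per group)
#' and stores the residuals in \code{tbv_residual_cc}. The smooth trend is
#' a fixed-df cubic regression spline (\code{splines::ns}); \code{method =
#' "linear"} fits a straight line. Residuals have mean zero and are
#' orthogonal to the fitted trend.
#'
#' @param samples sample table with \code{age_years} and \code{tbv_cc}.
#' @param method \code{"spline"} or \code{"linear"}.
#' @param df spline degrees of freedom (ignored for linear).
#' @param pooled fit one trend across groups (default) or one per group.
#' @return the sample table with \code{tbv_residual_cc} filled; the fit
#'   summary (df, trend R-squared) is attached as attribute
#'   \code{"adjustment"}.
#' @export
age_adjust_trait <- function(samples, method = c("spline", "linear"), df = 4L,
                             pooled = TRUE) {
  method <- match.arg(method)
  ok <- stats::complete.cases(samples$age_years, samples$tbv_cc)
  if (sum(ok) < 8L) stop("need at least 8 samples with age and trait")
  if (method == "spline" && df >= sum(ok)) stop("df must be smaller than the number of samples")
  fit_one <- function(d) {
    if (stats::var(d$tbv_cc) == 0) {
      return(list(resid = rep(0, nrow(d)), r2 = NA_real_))
    }
    fml <- if (method == "spline") tbv_cc ~ splines::ns(age_years, df = df)
           else tbv_cc ~ age_years
    fit <- stats::lm(fml, data = d)
    list(resid = stats::residuals(fit), r2 = summary(fit)$r.squared)
  }
  res <- rep(NA_real_, nrow(samples))
  if (pooled) {
    f <- fit_one(samples[ok, ])
    res[ok] <- f$resid
    r2 <- f$r2
  } else {
    r2 <- c()
    for (g in unique(samples$group)) {
      sel <- ok & samples$group == g
      f <- fit_one(samples[sel, ])
      res[sel] <- f$resid
      r2 <- c(r2, stats::setNames(f$r2, g))
    }
  }
  samples$tbv_residual_cc <- res
  attr(samples, "adjustment") <- list(method = method, df = df, pooled = pooled,
                                      trend_r2 = r2)
  samples
}
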