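# internal helpers shared across stages

# row-wise z-score; errors listing offending genes when sd == 0 and
# drop = FALSE, otherwise drops them with a warning
.scale_rows <- function(x, drop = TRUE) {
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (ncol(x) - 1))
  bad <- !is.finite(s) | s < .Machine$double.eps^0.5
  if (any(bad)) {
    if (!drop) {
      stop("zero-variance genes: ", paste(rownames(x)[bad], collapse = ", "))
    }
    warning(sum(bad), " zero-variance gene(s) dropped: ",
            paste(utils::head(rownames(x)[bad], 5), collapse = ", "))
    x <- x[!bad, , drop = FALSE]
    m <- m[!bad]
    s <- s[!bad]
  }
  (x - m) / s
}

# first principal component over samples of a genes x samples block;
# unit norm, sign aligned so cor(me, mean standardized expression) >= 0
.eigengene <- function(x) {
  xs <- .scale_rows(x)
  if (nrow(xs) == 0L) stop("module has no genes with positive variance")
  sv <- svd(xs, nu = 0L, nv = 1L)
  me <- sv$v[, 1L]
  ave <- colMeans(xs)
  s <- suppressWarnings(stats::cor(me, ave))
  if (is.finite(s) && s < 0) me <- -me
  list(me = me, var_explained = sv$d[1L]^2 / sum(sv$d^2))
}

# Pearson r with Student asymptotic two-sided p (df = n - 2)
.cor_test <- function(x, y) {
  n <- length(x)
  r <- suppressWarnings(stats::cor(x, y))
  if (!is.finite(r)) stop("correlation undefined (constant input)")
  r2 <- min(r^2, 1 - .Machine$double.eps)
  tt <- r * sqrt(n - 2) / sqrt(1 - r2)
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

# permutation p with the count/(N + 1) convention; flags an exact zero
.perm_p <- function(count, n_perm) {
  p <- count / (n_perm + 1)
  attr(p, "floor") <- if (count == 0L) paste0("< 1/", n_perm + 1) else NA_character_
  p
}

.match_group <- function(samples, group) {
  group <- match.arg(group, c("all", "case", "control"))
  if (group == "all") rep(TRUE, nrow(samples)) else samples$group == group
}

.require_residual <- function(samples) {
  if (!"tbv_residual_cc" %in% names(samples) || all(is.na(samples$tbv_residual_cc))) {
    stop("age-adjusted trait missing: run age_adjust_trait() first")
  }
  invisible(samples)
}
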