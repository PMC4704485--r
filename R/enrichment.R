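#' Hypergeometric gene-set enrichment against a fixed background
#'
#' Upper-tail hypergeometric test per set: with N background genes, K in
#' the set, n in the query, and k in the overlap, p = P(X >= k) for X ~
#' Hypergeom(N, K, n). Query and set genes are counted inside the
#' background universe. Benjamini-Hochberg q-values are computed across
#' the sets.
#'
#' @param query character vector of gene identifiers.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param background background universe size (study convention 21,405)
#'   or a character vector of background genes.
#' @return data frame (set_name, k, K, n, N, p, q).
#' @export
hypergeometric_enrichment <- function(query, sets, background = 21405L) {
  if (is.character(background)) {
    universe <- unique(background)
    N <- length(universe)
    query <- intersect(unique(query), universe)
    sets <- lapply(sets, intersect, y = universe)
  } else {
    N <- as.integer(background)
    query <- unique(query)
    sets <- lapply(sets, unique)
  }
  n <- length(query)
  if (n > N) stop("query larger than the background universe")
  out <- do.call(rbind, lapply(names(sets), function(s) {
    K <- length(sets[[s]])
    if (K > N) stop("set '", s, "' larger than the background universe")
    k <- length(intersect(query, sets[[s]]))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Read gene sets from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  sets <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) < 3L) stop("malformed GMT line (need name, description, genes)")
    unique(f[-(1:2)])
  })
  names(sets) <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
  sets
}
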