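#' Gene-set over-representation analysis
#'
#' One-sided Fisher's exact test (equivalently, the hypergeometric upper
#' tail) of the overlap between a query protein set and each gene set,
#' against a stated background universe. By proteomics convention the
#' background is the set of proteins actually quantified after filtering,
#' not the whole annotation; set members outside the background are
#' discarded before testing. P-values are adjusted across sets by
#' Benjamini-Hochberg; the q-value column equals the BH-adjusted p (the
#' convention of the standard enrichment tooling this mirrors).
#'
#' @param query character vector of query proteins (e.g. DEPs); must be a
#'   subset of `background`.
#' @param background character vector, the tested universe.
#' @param collection a `GeneSetCollection` from [read_gmt()] or
#'   [simulate_gene_sets()].
#' @param alpha,q_alpha significance thresholds on adjusted p and q-value
#'   (both default 0.05; a set is `enriched` iff both are strictly met).
#' @return `data.frame` sorted by raw p (ties by set name) with columns
#'   `set_name`, `overlap_k`, `set_in_background_K`, `query_n`,
#'   `background_N`, `p_raw`, `p_adj`, `q_value`, `enriched`.
#' @export
fisher_enrichment <- function(query, background, collection,
                              alpha = 0.05, q_alpha = 0.05) {
  if (!length(query) || !length(background))
    stop("query and background must be non-empty")
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  N <- length(background)
  n <- length(query)
  rows <- lapply(seq_along(collection$name), function(i) {
    memb <- intersect(collection$members[[i]], background)
    K <- length(memb)
    if (K == 0L) {
      warning("set ", collection$name[i],
              " has no members in the background; skipped")
      return(NULL)
    }
    k <- length(intersect(memb, query))
    # upper tail P(X >= k), Hypergeometric(N, K, n)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set_name = collection$name[i], overlap_k = k,
               set_in_background_K = K, query_n = n, background_N = N,
               p_raw = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable gene set")
  res$p_adj <- bh_adjust(pmin(pmax(res$p_raw, .Machine$double.xmin), 1))
  res$q_value <- res$p_adj
  res$enriched <- res$p_adj < alpha & res$q_value < q_alpha
  res[order(res$p_raw, res$set_name), , drop = FALSE]
}
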