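# Term over-representation: one-sided hypergeometric test with
# Benjamini-Hochberg FDR over the family of terms passing the
# minimum-overlap filter (filter-then-adjust; stated in output metadata).

#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of
#' drawing at least `k` marked items when `n` items are drawn without
#' replacement from `N` of which `K` are marked. Computed with the exact
#' survival function.
#'
#' @param k observed overlap
#' @param K marked items (term size within the background)
#' @param n draws (query size)
#' @param N population (background size)
#' @return probability in (0, 1]
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (K > N || n > N) stop("require K <= N and n <= N")
  if (k < 0 || k > min(K, n)) stop("require 0 <= k <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q-values preserve input order, satisfy
#' `q >= p` elementwise and are monotone along the sorted-p order.
#'
#' @param pvalues numeric vector of p-values in (0, 1]
#' @return q-values in the same order
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(is.na(pvalues)) || any(pvalues <= 0) || any(pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run term over-representation analysis
#'
#' Tests each term's overlap with the query list against the background by
#' the one-sided hypergeometric test. Terms are intersected with the
#' background before sizing (genes absent from the experiment never
#' inflate a term); terms with overlap below `min_overlap` are excluded
#' before testing, BH adjustment runs over all tested terms, and only
#' results with `p < p_cutoff` are returned, flagged significant when
#' `q < q_report`. Symbols are upper-cased for matching.
#'
#' @param query character vector of query gene symbols (must be contained
#'   in the background)
#' @param background character vector of background gene symbols
#' @param terms named list of terms as from [read_gmt()]
#' @param min_overlap minimum query/term overlap to test (default 4)
#' @param p_cutoff report only terms with `p < p_cutoff` (default 0.01)
#' @param q_report significance flag threshold on q (default 0.05)
#' @return data.frame sorted by `p` then `term_id`: `term_id`, `name`,
#'   `k`, `K`, `n`, `N`, `p`, `q`, `significant`; attribute
#'   `n_tested` records the BH family size
#' @export
run_enrichment <- function(query, background, terms, min_overlap = 4L,
                           p_cutoff = 0.01, q_report = 0.05) {
  if (length(query) == 0L) stop("empty query gene list")
  if (length(background) == 0L) stop("empty background gene list")
  if (length(terms) == 0L) stop("no terms to test")
  query <- unique(toupper(trimws(query)))
  background <- unique(toupper(trimws(background)))
  if (!all(query %in% background)) {
    stop("query genes missing from the background: ",
         paste(utils::head(setdiff(query, background), 5), collapse = ", "))
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(names(terms), function(id) {
    members <- intersect(unique(toupper(trimws(terms[[id]]$genes))),
                         background)
    k <- length(intersect(members, query))
    data.frame(term_id = id, name = terms[[id]]$name, k = k,
               K = length(members), n = n, N = N, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[res$k >= min_overlap, , drop = FALSE]
  n_tested <- nrow(res)
  if (n_tested == 0L) {
    out <- data.frame(term_id = character(0), name = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p = numeric(0), q = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE)
    attr(out, "n_tested") <- 0L
    attr(out, "adjust_family") <- "terms passing min_overlap filter"
    return(out)
  }
  res$p <- vapply(seq_len(n_tested), function(i) {
    hypergeom_upper_tail(res$k[i], res$K[i], res$n[i], res$N[i])
  }, numeric(1))
  res$q <- bh_fdr(res$p)
  res <- res[res$p < p_cutoff, , drop = FALSE]
  res$significant <- res$q < q_report
  res <- res[order(res$p, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_tested") <- n_tested
  attr(res, "adjust_family") <- "terms passing min_overlap filter"
  res
}
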