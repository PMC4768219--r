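# Term overrepresentation by the hypergeometric upper tail, against an
# explicitly supplied background universe.

#' Hypergeometric upper-tail probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of drawing
#' at least `k` annotated genes when `n` genes are drawn from a universe of
#' `N` genes of which `K` carry the term.
#'
#' @param k observed annotated genes in the subset.
#' @param n subset size.
#' @param K annotated genes in the background.
#' @param N background size.
#' @return p-value in [0, 1].
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0) || any(k > n) || any(n > N) ||
      any(k > K) || any(K > N))
    stop("inconsistent counts: need k <= min(n, K), n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term overrepresentation in a gene subset
#'
#' Tests every term annotated to at least one background gene for
#' overrepresentation in `subset` against `background` using
#' [hypergeom_tail()]. The background universe is always supplied
#' explicitly; annotations of genes outside it are ignored.
#'
#' @param subset character vector of gene ids (must be contained in
#'   `background`).
#' @param background character vector of gene ids (the universe).
#' @param annotations data.frame `gene_id`, `term_id`.
#' @param alpha significance level on the (adjusted) p-value.
#' @param adjust `"none"` (default, plain p < alpha) or `"bh"`.
#' @param labels optional data.frame `term_id`, `label`.
#' @return data.frame sorted by p-value: `term_id`, `k`, `n`, `K`, `N`,
#'   `p`, `p_adj`, `significant`, and `label` when provided.
#' @export
enrich <- function(subset, background, annotations, alpha = 0.05,
                   adjust = c("none", "bh"), labels = NULL) {
  adjust <- match.arg(adjust)
  subset <- unique(subset)
  background <- unique(background)
  extra <- setdiff(subset, background)
  if (length(extra))
    stop("subset genes outside the background universe: ",
         paste(utils::head(extra, 5), collapse = ", "))
  ann <- annotations[annotations$gene_id %in% background, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  if (nrow(ann) == 0)
    return(data.frame(term_id = character(), k = integer(), n = integer(),
                      K = integer(), N = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  N <- length(background)
  n <- length(subset)
  K_tab <- table(ann$term_id)
  in_sub <- ann$gene_id %in% subset
  k_tab <- table(ann$term_id[in_sub])
  terms <- names(K_tab)
  k <- as.integer(k_tab[terms]); k[is.na(k)] <- 0L
  K <- as.integer(K_tab)
  p <- hypergeom_tail(k, n, K, N)
  p_adj <- if (adjust == "bh") stats::p.adjust(p, "BH") else p
  out <- data.frame(term_id = terms, k = k, n = n, K = K, N = N, p = p,
                    p_adj = p_adj, significant = p_adj < alpha,
                    stringsAsFactors = FALSE)
  if (!is.null(labels))
    out$label <- labels$label[match(out$term_id, labels$term_id)]
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
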