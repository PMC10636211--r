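# Hypergeometric enrichment of gene sets, computed in log space.

#' Upper-tail hypergeometric enrichment probability
#'
#' For `N` annotated genes of which `n` are differentially expressed, and a
#' term containing `M` genes of which `m` are differentially expressed,
#' returns `P = 1 - sum_{i=0}^{m-1} C(M,i) C(N-M,n-i) / C(N,n)`, the
#' inclusive upper-tail probability `Pr(X >= m)` for `X` hypergeometric.
#' The sum is evaluated as the upper tail directly with log-gamma
#' binomials, so it never overflows and `m = 0` returns exactly 1.
#' Vectorized over all four arguments.
#'
#' @param N Annotated genes total.
#' @param n Differentially expressed genes among `N`.
#' @param M Genes in the term.
#' @param m Differentially expressed genes in the term.
#' @return Probability vector in (0, 1].
#' @export
hypergeometric_p <- function(N, n, M, m) {
  args <- vctrs::vec_recycle_common(N = N, n = n, M = M, m = m)
  N <- args$N; n <- args$n; M <- args$M; m <- args$m
  if (any(N < 0 | M < 0 | n < 0 | m < 0) || any(M > N) || any(n > N) ||
      any(m > pmin(n, M))) {
    stop("invalid enrichment query: need 0 <= m <= min(n, M), M <= N, n <= N")
  }
  vapply(seq_along(N), function(j) {
    hi <- min(n[j], M[j])
    if (m[j] == 0) return(1)
    i <- seq(m[j], hi)
    lt <- lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
      lchoose(N[j], n[j])
    mx <- max(lt)
    min(1, exp(mx) * sum(exp(lt - mx)))
  }, numeric(1))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control; adjusted values are monotone after
#' sorting and never below the raw values.
#'
#' @param p_values Numeric vector of raw p-values.
#' @return Adjusted values.
#' @export
bh_adjust <- function(p_values) {
  p.adjust(p_values, method = "BH")
}

#' Per-term enrichment table from an annotation map and a gene list
#'
#' Builds the (N, n, M, m) quadruple per term from a two-column gene-term
#' annotation and a list of differentially expressed genes, and computes
#' the hypergeometric upper-tail probability for each term. Genes absent
#' from the annotation are ignored (the universe is the annotated genes).
#' Raw probabilities are reported by default; BH adjustment is optional.
#'
#' @param annotations Tibble with columns `gene` and `term` (one row per
#'   pair).
#' @param degs Character vector of differentially expressed gene ids.
#' @param adjust Add a BH-adjusted column.
#' @return A tibble per term: `term`, `N`, `n`, `M`, `m`, `p`, and `padj`
#'   when `adjust = TRUE`, sorted by `p`.
#' @export
enrich_terms <- function(annotations, degs, adjust = FALSE) {
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  ann <- dplyr::distinct(annotations, .data$gene, .data$term)
  universe <- unique(ann$gene)
  degs_in <- intersect(unique(degs), universe)
  N <- length(universe)
  n <- length(degs_in)
  out <- ann |>
    dplyr::group_by(term = .data$term) |>
    dplyr::summarise(M = dplyr::n_distinct(.data$gene),
                     m = sum(unique(.data$gene) %in% degs_in),
                     .groups = "drop") |>
    dplyr::mutate(N = N, n = n,
                  p = hypergeometric_p(N, n, .data$M, .data$m)) |>
    dplyr::select("term", "N", "n", "M", "m", "p") |>
    dplyr::arrange(.data$p, .data$term)
  if (adjust) out$padj <- bh_adjust(out$p)
  out
}
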