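#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mann-Whitney/Wilcoxon two-sample test. With no ties and both groups
#' smaller than 50 the exact null distribution is used; otherwise the normal
#' approximation with midranks, tie-corrected variance and continuity
#' correction.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both groups must be non-empty")
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  nties <- tabulate(as.integer(2 * r))   # midranks live on a half-integer grid
  nties <- nties[nties > 0L]
  if (all(nties == 1L) && n1 < 50 && n2 < 50) {
    p <- if (U > n1 * n2 / 2)
      2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    else
      2 * stats::pwilcox(U, n1, n2)
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  n <- n1 + n2
  tie_term <- sum(nties^3 - nties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * (n + 1 - tie_term)
  if (sigma2 <= 0) return(1)          # every observation tied
  z <- U - mu
  z <- z - sign(z) * 0.5              # continuity correction
  min(1, 2 * stats::pnorm(-abs(z) / sqrt(sigma2)))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in input order and capped at 1.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Log2 fold change of two non-negative means
#'
#' Computed on normalized-scale (de-logged) group means with a small
#' pseudocount so zero means are defined.
#'
#' @param mean_a,mean_b non-negative group means.
#' @param pseudocount added to both means; default `1e-9`.
#' @return `log2((mean_a + pseudocount) / (mean_b + pseudocount))`.
#' @export
log2_fold_change <- function(mean_a, mean_b, pseudocount = 1e-9) {
  if (any(mean_a < 0) || any(mean_b < 0)) stop("means must be non-negative")
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

#' Per-gene differential expression between two cell groups
#'
#' Wilcoxon rank-sum p-values on log-normalized values, BH-FDR across genes,
#' and log2 fold change of the de-logged (normalized-scale) group means.
#' Rows are sorted stably by (fdr, -|log2fc|, symbol).
#'
#' @param values_a,values_b log-normalized matrices (genes x cells) with
#'   identical rownames in identical order.
#' @param pseudocount passed to [log2_fold_change()].
#' @return data.frame (`de_result`) with columns `gene`, `log2fc`, `p_raw`,
#'   `fdr`, `mean_a`, `mean_b`, `frac_expressing_a`, `frac_expressing_b`.
#' @export
differential_expression <- function(values_a, values_b, pseudocount = 1e-9) {
  if (!identical(rownames(values_a), rownames(values_b)))
    stop("gene sets differ; run align_conditions() first")
  if (ncol(values_a) == 0L || ncol(values_b) == 0L)
    stop("both groups must contain at least one cell")
  genes <- rownames(values_a)
  p <- vapply(seq_along(genes), function(i)
    wilcoxon_rank_sum(values_a[i, ], values_b[i, ]), 0)
  mean_a <- rowMeans(expm1(values_a))
  mean_b <- rowMeans(expm1(values_b))
  res <- data.frame(
    gene = genes,
    log2fc = log2_fold_change(mean_a, mean_b, pseudocount),
    p_raw = p,
    fdr = bh_fdr(p),
    mean_a = mean_a,
    mean_b = mean_b,
    frac_expressing_a = rowMeans(values_a > 0),
    frac_expressing_b = rowMeans(values_b > 0),
    row.names = NULL
  )
  res <- res[order(res$fdr, -abs(res$log2fc), res$gene, method = "radix"), ]
  rownames(res) <- NULL
  class(res) <- c("de_result", "data.frame")
  res
}

#' Restrict two expression matrices to their common genes
#'
#' Both matrices are subset to the intersection of their gene sets, in the
#' order the genes appear in the first matrix.
#'
#' @param e_a,e_b `expression_matrix` objects (see [normalize_log()]).
#' @return list with elements `a` and `b`, both over the common genes.
#' @export
align_conditions <- function(e_a, e_b) {
  common <- intersect(rownames(e_a$values), rownames(e_b$values))
  if (length(common) == 0L) stop("no genes in common between the two matrices")
  list(a = subset_genes(e_a, common), b = subset_genes(e_b, common))
}

#' Genes upregulated at given fold-change and FDR thresholds
#'
#' Inclusive thresholds: `log2fc >= lfc_min` and `fdr <= fdr_max`.
#'
#' @param de a `de_result` from [differential_expression()].
#' @param lfc_min minimum log2 fold change (cascade entry uses 0.3,
#'   enrichment uses 1.0).
#' @param fdr_max maximum BH-adjusted p-value; default 0.05.
#' @return character vector of gene symbols.
#' @export
upregulated_genes <- function(de, lfc_min, fdr_max = 0.05) {
  de$gene[de$log2fc >= lfc_min & de$fdr <= fdr_max]
}
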