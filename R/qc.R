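#' Quality-filter a count matrix
#'
#' Cell filters first (detected genes, mitochondrial fraction), then the gene
#' prevalence filter on the retained cells. Boundaries follow the stated
#' rules strictly: cells with *less than* `min_genes` detected genes and
#' *greater than* `max_mito` mitochondrial fraction are removed; genes
#' present in *less than* `min_cells` cells are removed.
#'
#' @param m a [count_matrix()].
#' @param min_cells gene prevalence floor (default 3).
#' @param min_genes detected-genes floor per cell (default 200).
#' @param max_mito mitochondrial-fraction ceiling per cell (default 0.18).
#' @return filtered [count_matrix()]; attribute `"qc_report"` records the
#'   number of cells and genes removed.
#' @export
qc_filter <- function(m, min_cells = 3, min_genes = 200, max_mito = 0.18) {
  stopifnot(inherits(m, "count_matrix"))
  detected <- colSums(m$counts > 0)
  keep_cell <- detected >= min_genes & m$cell_meta$mito_frac <= max_mito
  if (!any(keep_cell)) stop("QC removed every cell (min_genes=", min_genes,
                            ", max_mito=", max_mito, ")")
  counts <- m$counts[, keep_cell, drop = FALSE]
  prevalence <- rowSums(counts > 0)
  keep_gene <- prevalence >= min_cells
  out <- count_matrix(counts[keep_gene, , drop = FALSE],
                      cell_meta = m$cell_meta[keep_cell,
                        setdiff(names(m$cell_meta), c("total_umis", "mito_frac")),
                        drop = FALSE])
  report <- list(cells_removed = sum(!keep_cell), genes_removed = sum(!keep_gene),
                 cells_kept = sum(keep_cell), genes_kept = sum(keep_gene))
  message("QC: removed ", report$cells_removed, " cells and ",
          report$genes_removed, " genes")
  attr(out, "qc_report") <- report
  out
}

#' Log-normalize a count matrix
#'
#' Per-cell counts are scaled to a common total (`target_sum`) and
#' log1p-transformed. The covariates used later for the scaled/regressed copy
#' (total UMIs, mitochondrial fraction) are carried along; covariate
#' regression is applied only when building the PCA/clustering input (see
#' [cluster_snn()]), never to the values used for differential expression and
#' expressing-fraction computations.
#'
#' @param m a QC-filtered [count_matrix()].
#' @param target_sum per-cell total after scaling (default 1e4).
#' @return an `expression_matrix`: list with `values` (genes x cells,
#'   log1p of normalized counts), `cell_meta`, `covariates`, `hvg` (filled by
#'   [select_hvg()]), `target_sum`.
#' @export
normalize_log <- function(m, target_sum = 1e4) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- m$cell_meta$total_umis
  if (any(totals == 0)) stop("zero-total cell present; run qc_filter() first")
  values <- log1p(sweep(m$counts, 2, target_sum / totals, `*`))
  structure(list(values = values,
                 cell_meta = m$cell_meta,
                 covariates = cbind(total_umis = totals,
                                    mito_frac = m$cell_meta$mito_frac),
                 hvg = NULL,
                 target_sum = target_sum),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " cells (target_sum=", x$target_sum, ")\n", sep = "")
  if (!is.null(x$hvg)) cat("  HVG marked:", sum(x$hvg), "\n")
  invisible(x)
}

#' Subset an expression matrix to a gene vector
#'
#' @param e an `expression_matrix`.
#' @param genes character vector; output keeps this order.
#' @return the subset `expression_matrix`.
#' @export
subset_genes <- function(e, genes) {
  stopifnot(inherits(e, "expression_matrix"))
  missing <- setdiff(genes, rownames(e$values))
  if (length(missing)) stop("genes absent from matrix: ",
                            paste(utils::head(missing, 3), collapse = ", "))
  e$values <- e$values[genes, , drop = FALSE]
  if (!is.null(e$hvg)) e$hvg <- e$hvg[genes]
  e
}

#' Mark highly variable genes
#'
#' Ranks genes by a dispersion statistic (variance over mean of the de-logged
#' normalized values) and marks the top `n_top`. Deterministic; ties broken
#' by gene order. Constant genes have dispersion 0 and can never outrank a
#' gene with positive variance.
#'
#' @param e an `expression_matrix`.
#' @param n_top number of genes to mark (clamped to the gene count;
#'   default 4000).
#' @return `e` with logical `hvg` filled in.
#' @export
select_hvg <- function(e, n_top = 4000) {
  stopifnot(inherits(e, "expression_matrix"))
  x <- expm1(e$values)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / max(1, ncol(x) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_top <- min(n_top, nrow(e$values))
  ord <- order(-disp, seq_along(disp))
  hvg <- logical(length(disp))
  hvg[ord[seq_len(n_top)]] <- TRUE
  names(hvg) <- rownames(e$values)
  e$hvg <- hvg
  e
}

# Residuals of each gene on the covariates (total UMIs, mito fraction), then
# per-gene z-scoring with clipping: the standard "scaled data" used only for
# PCA and clustering.
scale_regressed <- function(e, clip = 10) {
  cv <- apply(e$covariates, 2, function(col) {
    s <- stats::sd(col)
    if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
  })
  X <- cbind(1, cv)
  Y <- t(e$values)                       # cells x genes
  beta <- qr.coef(qr(X), Y)
  beta[is.na(beta)] <- 0
  R <- Y - X %*% beta
  s <- sqrt(colSums(R^2) / max(1, nrow(R) - 1))
  s[s == 0] <- 1
  Z <- sweep(R, 2, s, `/`)
  Z[Z > clip] <- clip
  Z[Z < -clip] <- -clip
  Z                                      # cells x genes
}

# PCA scores (cells x n_pcs) of a centered cells x genes matrix. Truncated
# SVD (irlba) when the matrix is large and few components are needed;
# otherwise an exact eigendecomposition in the smaller dimension.
pca_scores <- function(Z, n_pcs) {
  Z <- sweep(Z, 2, colMeans(Z))
  n_pcs <- min(n_pcs, ncol(Z), nrow(Z) - 1)
  if (min(dim(Z)) > 300 && n_pcs < min(dim(Z)) / 3) {
    sv <- irlba::irlba(Z, nv = n_pcs)
    return(sweep(sv$u, 2, sv$d, `*`))
  }
  if (ncol(Z) <= nrow(Z)) {
    eig <- eigen(crossprod(Z), symmetric = TRUE)
    scores <- Z %*% eig$vectors[, seq_len(n_pcs), drop = FALSE]
  } else {
    eig <- eigen(tcrossprod(Z), symmetric = TRUE)
    d <- sqrt(pmax(eig$values[seq_len(n_pcs)], 0))
    scores <- sweep(eig$vectors[, seq_len(n_pcs), drop = FALSE], 2, d, `*`)
  }
  scores
}

#' Cluster cells on a shared-nearest-neighbor graph
#'
#' PCA on the scaled/regressed highly-variable-gene submatrix, k-nearest
#' neighbours in PC space, shared-nearest-neighbor (Jaccard) edge weights,
#' and modularity community detection (Louvain). Deterministic for a fixed
#' seed. Cluster ids are integers ordered by decreasing cluster size.
#'
#' @param e an `expression_matrix` with HVG marked ([select_hvg()]).
#' @param n_pcs number of principal components (default 50).
#' @param k_neighbors neighbours per cell (default 15).
#' @param resolution Louvain resolution (default 1.0).
#' @param seed RNG seed for the community search.
#' @param prune SNN edges with Jaccard weight below this are dropped
#'   (default `1/15`).
#' @return data.frame with columns `cell_id`, `cluster`.
#' @export
cluster_snn <- function(e, n_pcs = 50, k_neighbors = 15, resolution = 1,
                        seed = 0L, prune = 1 / 15) {
  stopifnot(inherits(e, "expression_matrix"))
  if (is.null(e$hvg)) stop("run select_hvg() first")
  n <- ncol(e$values)
  if (n <= k_neighbors) stop("fewer cells (", n, ") than k_neighbors (", k_neighbors, ")")
  eh <- e
  eh$values <- e$values[e$hvg, , drop = FALSE]
  Z <- scale_regressed(eh)
  set.seed(seed)                 # fixes both the truncated SVD and Louvain
  scores <- pca_scores(Z, n_pcs)
  d2 <- as.matrix(stats::dist(scores))
  nn <- t(apply(d2, 1, function(row) order(row)[2:(k_neighbors + 1)]))
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k_neighbors),
                            j = as.vector(t(nn)), x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A)
  S <- methods::as(shared, "TsparseMatrix")
  keep <- S@i < S@j
  i <- S@i[keep] + 1L; j <- S@j[keep] + 1L; s <- S@x[keep]
  w <- s / (2 * k_neighbors - s)          # Jaccard of neighbour sets
  ok <- w >= prune
  g <- igraph::graph_from_data_frame(
    data.frame(from = i[ok], to = j[ok], weight = w[ok]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  member <- igraph::membership(comm)[as.character(seq_len(n))]
  sizes <- sort(table(member), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  data.frame(cell_id = colnames(e$values),
             cluster = as.integer(relabel[as.character(member)]),
             stringsAsFactors = FALSE)
}

#' Label clusters by marker-gene expression
#'
#' Each cluster is labeled by the marker with the highest mean log-normalized
#' expression, provided that marker's mean inside the cluster exceeds its
#' mean elsewhere and at least `min_frac` of the cluster's cells express it;
#' otherwise the cluster is `"unknown"`. When several clusters qualify for
#' the same label only the one with the highest expressing fraction keeps it.
#'
#' @param e an `expression_matrix`.
#' @param clusters data.frame from [cluster_snn()].
#' @param markers named character vector label -> marker gene.
#' @param min_frac expressing-fraction floor (default 0.5).
#' @return data.frame with columns `cell_id`, `cluster`, `label`.
#' @export
annotate_clusters <- function(e, clusters,
                              markers = c(EC = "PECAM1", astrocyte = "S100B",
                                          GSC = "CDKN2A"),
                              min_frac = 0.5) {
  stopifnot(inherits(e, "expression_matrix"))
  absent <- setdiff(markers, rownames(e$values))
  if (length(absent)) stop("marker gene absent from matrix: ",
                           paste(absent, collapse = ", "))
  stopifnot(identical(clusters$cell_id, colnames(e$values)))
  ids <- sort(unique(clusters$cluster))
  stats_tab <- expand.grid(cluster = ids, label = names(markers),
                           stringsAsFactors = FALSE)
  stats_tab$mean_in <- NA_real_; stats_tab$mean_out <- NA_real_
  stats_tab$frac <- NA_real_
  for (r in seq_len(nrow(stats_tab))) {
    g <- markers[[stats_tab$label[r]]]
    inc <- clusters$cluster == stats_tab$cluster[r]
    stats_tab$mean_in[r] <- mean(e$values[g, inc])
    stats_tab$mean_out[r] <- mean(e$values[g, !inc])
    stats_tab$frac[r] <- mean(e$values[g, inc] > 0)
  }
  label_of <- stats::setNames(rep("unknown", length(ids)), ids)
  frac_of <- stats::setNames(rep(NA_real_, length(ids)), ids)
  for (cl in ids) {
    st <- stats_tab[stats_tab$cluster == cl, ]
    st <- st[order(-st$mean_in), ]
    best <- st[1, ]
    if (best$mean_in > best$mean_out && best$frac >= min_frac) {
      label_of[as.character(cl)] <- best$label
      frac_of[as.character(cl)] <- best$frac
    }
  }
  for (lab in names(markers)) {
    cand <- names(label_of)[label_of == lab]
    if (length(cand) > 1) {
      win <- cand[which.max(frac_of[cand])]
      label_of[setdiff(cand, win)] <- "unknown"
    }
  }
  data.frame(cell_id = clusters$cell_id,
             cluster = clusters$cluster,
             label = unname(label_of[as.character(clusters$cluster)]),
             stringsAsFactors = FALSE)
}

#' One-vs-rest marker differential expression per cluster
#'
#' For each cluster, Wilcoxon rank-sum DE of its cells against all other
#' cells; markers are genes with `|log2FC| >= lfc_min` and `fdr <= fdr_max`
#' (both inclusive).
#'
#' @param e an `expression_matrix`.
#' @param clusters data.frame from [cluster_snn()].
#' @param lfc_min absolute log2FC floor (default 0.3).
#' @param fdr_max FDR ceiling (default 0.05).
#' @return named list per cluster: `de` (a `de_result`) and `markers`
#'   (character vector). Singleton clusters are skipped with a warning.
#' @export
marker_de <- function(e, clusters, lfc_min = 0.3, fdr_max = 0.05) {
  stopifnot(inherits(e, "expression_matrix"))
  ids <- sort(unique(clusters$cluster))
  if (length(ids) < 2) stop("need at least 2 clusters for marker DE")
  out <- list()
  for (cl in ids) {
    inc <- clusters$cluster == cl
    if (sum(inc) < 2) {
      warning("cluster ", cl, " is a singleton; skipped")
      next
    }
    de <- differential_expression(e$values[, inc, drop = FALSE],
                                  e$values[, !inc, drop = FALSE])
    out[[as.character(cl)]] <- list(
      de = de,
      markers = de$gene[abs(de$log2fc) >= lfc_min & de$fdr <= fdr_max])
  }
  out
}
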