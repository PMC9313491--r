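#' Enrich for neoplastic cells in a patient tumor matrix
#'
#' Removes cells from de novo clusters whose marker differential-expression
#' list (one-vs-rest, |log2FC| >= `lfc_min`, FDR <= `fdr_max`, upregulated
#' side) contains any exclusion marker: terminally differentiated lineage
#' genes (MBP, PLP1), immune genes (CD14, AIF1) and the astrocyte gene
#' ETNPPL by default.
#'
#' @param e an `expression_matrix` for one patient.
#' @param clusters data.frame from [cluster_snn()].
#' @param exclusion_markers character vector of marker symbols.
#' @param lfc_min,fdr_max marker-DE thresholds (defaults 0.3, 0.05).
#' @return character vector of retained (putatively neoplastic) cell ids.
#' @export
enrich_neoplastic <- function(e, clusters,
                              exclusion_markers = c("MBP", "PLP1", "CD14",
                                                    "AIF1", "ETNPPL"),
                              lfc_min = 0.3, fdr_max = 0.05) {
  stopifnot(inherits(e, "expression_matrix"))
  absent <- setdiff(exclusion_markers, rownames(e$values))
  if (length(absent)) {
    warning("exclusion markers absent from gene list, ignored: ",
            paste(absent, collapse = ", "))
    exclusion_markers <- setdiff(exclusion_markers, absent)
  }
  md <- marker_de(e, clusters, lfc_min = lfc_min, fdr_max = fdr_max)
  drop_cluster <- vapply(md, function(m) {
    up <- m$de$gene[m$de$log2fc >= lfc_min & m$de$fdr <= fdr_max]
    any(exclusion_markers %in% up)
  }, TRUE)
  bad <- as.integer(names(md)[drop_cluster])
  keep <- !(clusters$cluster %in% bad)
  if (!any(keep)) stop("neoplastic enrichment removed every cluster")
  clusters$cell_id[keep]
}

#' Evidence tier for a receptor's average expression
#'
#' `none` when the average is exactly zero, `marginal` when positive but at
#' most the first-quartile reference, `strong` when above it.
#'
#' @param avg_expr average normalized expression (>= 0).
#' @param q1_reference first quartile of per-gene average expression (>= 0).
#' @return character: `"none"`, `"marginal"` or `"strong"` (vectorized over
#'   `avg_expr`).
#' @export
evidence_tier <- function(avg_expr, q1_reference) {
  if (any(avg_expr < 0) || any(q1_reference < 0)) stop("negative expression input")
  ifelse(avg_expr == 0, "none",
         ifelse(avg_expr <= q1_reference, "marginal", "strong"))
}

#' Per-patient receptor evidence tiers
#'
#' For each patient with at least `min_cells` neoplastic cells: genes
#' expressed in at least 3 cells are retained, the matrix is log-normalized,
#' the first-quartile reference is the 25th percentile (linear-interpolation
#' quantile) of per-gene average expression, and each receptor's average is
#' tiered against it with [evidence_tier()].
#'
#' @param matrices named list (patient id -> [count_matrix()] of neoplastic
#'   cells).
#' @param receptors character vector of receptor symbols.
#' @param min_cells minimum neoplastic cells per patient (default 113);
#'   patients below it are excluded.
#' @param min_cells_gene gene prevalence floor (default 3 cells).
#' @param target_sum normalization total (default 1e4).
#' @return data.frame `receptor`, `patient`, `avg_expr`, `q1_reference`,
#'   `tier`, `n_cells`; attribute `"excluded_patients"`.
#' @export
per_patient_receptor_evidence <- function(matrices, receptors, min_cells = 113,
                                          min_cells_gene = 3, target_sum = 1e4) {
  stopifnot(length(names(matrices)) == length(matrices))
  rows <- list()
  excluded <- character(0)
  for (pt in names(matrices)) {
    m <- matrices[[pt]]
    stopifnot(inherits(m, "count_matrix"))
    n <- length(m$cell_ids)
    if (n < min_cells) { excluded <- c(excluded, pt); next }
    keep <- rowSums(m$counts > 0) >= min_cells_gene
    sub <- count_matrix(m$counts[keep, , drop = FALSE],
                        cell_meta = m$cell_meta[, setdiff(names(m$cell_meta),
                          c("total_umis", "mito_frac")), drop = FALSE])
    e <- normalize_log(sub, target_sum = target_sum)
    gene_avg <- rowMeans(e$values)
    q1 <- unname(stats::quantile(gene_avg, 0.25, type = 7))
    for (r in receptors) {
      if (!r %in% rownames(e$values)) {
        warning("receptor ", r, " absent for patient ", pt, "; tier 'none'")
        avg <- 0
      } else {
        avg <- mean(e$values[r, ])
      }
      rows[[paste(r, pt)]] <- data.frame(
        receptor = r, patient = pt, avg_expr = avg, q1_reference = q1,
        tier = evidence_tier(avg, q1), n_cells = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(receptor = character(0), patient = character(0),
               avg_expr = numeric(0), q1_reference = numeric(0),
               tier = character(0), n_cells = integer(0))
  rownames(out) <- NULL
  attr(out, "excluded_patients") <- excluded
  out
}
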