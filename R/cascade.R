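#' Receptors among upregulated genes
#'
#' Stage 1 of the prioritization cascade: intersect the upregulated gene set
#' with the receptor universe of the ligand-receptor pair table.
#'
#' @param up_genes character vector of upregulated genes.
#' @param lr an `lr_pair_table` (columns `ligand`, `receptor`).
#' @return sorted character vector of receptors.
#' @export
intersect_receptors <- function(up_genes, lr) {
  sort(unique(lr$receptor[lr$receptor %in% up_genes]))
}

#' Fraction of cells expressing a gene
#'
#' @param e an `expression_matrix`.
#' @param gene gene symbol (must be present).
#' @param cells cell ids to evaluate over.
#' @return fraction in \[0, 1\] of `cells` with value > 0.
#' @export
fraction_expressing <- function(e, gene, cells) {
  stopifnot(inherits(e, "expression_matrix"))
  if (!gene %in% rownames(e$values)) stop("gene absent from matrix: ", gene)
  mean(e$values[gene, cells] > 0)
}

#' Secreted-ligand expression filter
#'
#' Stage 2: a receptor survives if at least one cognate ligand is annotated
#' as secreted and is expressed in at least `min_frac` of triculture EC cells
#' or triculture astrocyte cells. Ligand expression in GSCs themselves
#' (autocrine) does not satisfy the filter.
#'
#' @param receptors character vector (stage-1 survivors).
#' @param lr an `lr_pair_table`.
#' @param secreted character vector of secreted gene symbols.
#' @param e_tri triculture `expression_matrix`.
#' @param ann_tri annotation data.frame (`cell_id`, `label`) for the
#'   triculture cells; must contain EC and astrocyte cells.
#' @param min_frac expressing-fraction threshold (default 0.10, inclusive).
#' @return named list receptor -> character vector of qualifying ligands
#'   (receptors with none are dropped).
#' @export
filter_secreted_expressed <- function(receptors, lr, secreted, e_tri, ann_tri,
                                      min_frac = 0.10) {
  ec_cells <- ann_tri$cell_id[ann_tri$label == "EC"]
  astro_cells <- ann_tri$cell_id[ann_tri$label == "astrocyte"]
  if (length(ec_cells) == 0 || length(astro_cells) == 0)
    stop("annotation must contain both EC and astrocyte cells")
  out <- list()
  for (r in receptors) {
    ligands <- unique(lr$ligand[lr$receptor == r])
    keep <- character(0)
    for (l in ligands) {
      if (!l %in% secreted) next
      if (!l %in% rownames(e_tri$values)) next
      if (fraction_expressing(e_tri, l, ec_cells) >= min_frac ||
          fraction_expressing(e_tri, l, astro_cells) >= min_frac)
        keep <- c(keep, l)
    }
    if (length(keep)) out[[r]] <- keep
  }
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) where X counts successes in `n` draws without replacement from
#' an urn of `N` items of which `K` are successes. Inclusive of `k`.
#'
#' @param k observed overlap (0 <= k <= min(K, n)).
#' @param K annotated set size in the universe.
#' @param n query size.
#' @param N universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || K > N || n > N || k > min(K, n))
    stop("inconsistent hypergeometric arguments: k=", k, " K=", K,
         " n=", n, " N=", N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Downstream pathway enrichment filter
#'
#' Stage 3: for each receptor, the pathways whose member list contains the
#' receptor symbol are tested for enrichment of the strictly upregulated GSC
#' gene set (hypergeometric upper tail over the common-gene universe). A
#' receptor is kept when at least one such pathway reaches `p <= p_max` (raw
#' p-values, no cross-pathway correction — deliberately permissive, matching
#' the screening intent).
#'
#' @param receptors_with_ligands named list receptor -> ligands, from
#'   [filter_secreted_expressed()].
#' @param gsc_up_strict upregulated gene set at the strict threshold
#'   (log2FC >= 1, FDR <= 0.05).
#' @param sets named list of pathway gene sets ([read_gene_sets()]).
#' @param universe character vector: the common aligned genes.
#' @param de optional `de_result` supplying `log2fc`/`fdr` per receptor.
#' @param p_max per-pathway enrichment threshold (default 0.05).
#' @return data.frame of candidates (`receptor`, `log2fc`, `fdr`, `ligands`
#'   list column, `n_enriched_pathways`), attribute `"enrichment"` holding
#'   the per-(receptor, pathway) test table.
#' @export
enrichment_filter <- function(receptors_with_ligands, gsc_up_strict, sets,
                              universe, de = NULL, p_max = 0.05) {
  if (length(universe) == 0) stop("empty gene universe")
  query <- intersect(gsc_up_strict, universe)
  N <- length(universe)
  n <- length(query)
  detail <- list()
  cand <- list()
  for (r in names(receptors_with_ligands)) {
    containing <- names(sets)[vapply(sets, function(s) r %in% s, TRUE)]
    if (length(containing) == 0) next
    ps <- vapply(containing, function(nm) {
      members <- intersect(sets[[nm]], universe)
      k <- length(intersect(members, query))
      hypergeometric_tail(k, length(members), n, N)
    }, 0)
    detail[[r]] <- data.frame(receptor = r, pathway = containing,
                              p = unname(ps), stringsAsFactors = FALSE)
    n_enriched <- sum(ps <= p_max)
    if (n_enriched >= 1) {
      row <- data.frame(receptor = r, log2fc = NA_real_, fdr = NA_real_,
                        n_enriched_pathways = n_enriched,
                        stringsAsFactors = FALSE)
      row$ligands <- list(receptors_with_ligands[[r]])
      row$enriched_pathways <- list(containing[ps <= p_max])
      cand[[r]] <- row
    }
  }
  out <- if (length(cand)) do.call(rbind, cand) else
    data.frame(receptor = character(0), log2fc = numeric(0), fdr = numeric(0),
               n_enriched_pathways = integer(0))
  if (!nrow(out)) { out$ligands <- list(); out$enriched_pathways <- list() }
  if (!is.null(de) && nrow(out)) {
    idx <- match(out$receptor, de$gene)
    out$log2fc <- de$log2fc[idx]
    out$fdr <- de$fdr[idx]
  }
  out <- out[, c("receptor", "log2fc", "fdr", "ligands",
                 "n_enriched_pathways", "enriched_pathways")]
  rownames(out) <- NULL
  attr(out, "enrichment") <- if (length(detail)) do.call(rbind, c(detail, make.row.names = FALSE)) else
    data.frame(receptor = character(0), pathway = character(0), p = numeric(0))
  out
}

#' Rank receptor candidates by fold change
#'
#' Stage 4: sort by log2 fold change (descending), break ties by lower FDR
#' then by symbol, and keep the first `top_k`.
#'
#' @param cands candidate data.frame ([enrichment_filter()] or the packaged
#'   fixture).
#' @param top_k number of receptors to keep (default 6, clamped).
#' @return the ordered head of `cands`.
#' @export
rank_candidates <- function(cands, top_k = 6) {
  ord <- order(-cands$log2fc, cands$fdr, cands$receptor, method = "radix")
  out <- cands[utils::head(ord, top_k), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Triculture-vs-monoculture upregulation flags per ligand and cell type
#'
#' Within each cell type present in both conditions, a Wilcoxon rank-sum test
#' of the ligand's triculture vs monoculture expression; BH-FDR across the
#' whole ligand-by-cell-type grid; flagged when `fdr <= 0.05` and the fold
#' change is positive.
#'
#' @param e_mono,e_tri aligned `expression_matrix` objects.
#' @param ann_mono,ann_tri annotation data.frames (`cell_id`, `label`).
#' @param ligands character vector of ligand symbols.
#' @param cell_types labels to test (default EC, astrocyte, GSC).
#' @param fdr_max flag threshold (default 0.05).
#' @return data.frame `ligand`, `cell_type`, `log2fc`, `p_raw`, `fdr`,
#'   `flag`.
#' @export
ligand_upregulation_flags <- function(e_mono, e_tri, ann_mono, ann_tri,
                                      ligands,
                                      cell_types = c("EC", "astrocyte", "GSC"),
                                      fdr_max = 0.05) {
  rows <- list()
  for (ty in cell_types) {
    mono_cells <- ann_mono$cell_id[ann_mono$label == ty]
    tri_cells <- ann_tri$cell_id[ann_tri$label == ty]
    if (length(mono_cells) == 0 || length(tri_cells) == 0) {
      warning("cell type ", ty, " absent in one condition; skipped")
      next
    }
    for (l in ligands) {
      if (!l %in% rownames(e_tri$values) || !l %in% rownames(e_mono$values)) next
      x <- e_tri$values[l, tri_cells]
      y <- e_mono$values[l, mono_cells]
      rows[[paste(l, ty)]] <- data.frame(
        ligand = l, cell_type = ty,
        log2fc = log2_fold_change(mean(expm1(x)), mean(expm1(y))),
        p_raw = wilcoxon_rank_sum(x, y),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(ligand = character(0),
                                      cell_type = character(0),
                                      log2fc = numeric(0), p_raw = numeric(0),
                                      fdr = numeric(0), flag = logical(0)))
  out$fdr <- bh_fdr(out$p_raw)
  out$flag <- out$fdr <= fdr_max & out$log2fc > 0
  rownames(out) <- NULL
  out
}

#' Eigengene score of a gene set
#'
#' Genes are standardized across cells (zero-variance genes dropped); the
#' per-cell score is the first principal component in that gene subspace,
#' sign-oriented so it correlates non-negatively with the per-cell mean of
#' the standardized member genes.
#'
#' @param e an `expression_matrix`.
#' @param gene_set character vector of member genes.
#' @return numeric per-cell score vector (named by cell id).
#' @export
eigengene <- function(e, gene_set) {
  stopifnot(inherits(e, "expression_matrix"))
  genes <- intersect(gene_set, rownames(e$values))
  if (length(genes) == 0) stop("no gene of the set is present in the matrix")
  V <- e$values[genes, , drop = FALSE]
  s <- apply(V, 1, stats::sd)
  V <- V[s > 0, , drop = FALSE]
  if (nrow(V) == 0) stop("all set genes have zero variance")
  Z <- t(scale(t(V)))                     # genes x cells, standardized per gene
  X <- t(Z)                               # cells x genes
  sv <- svd(X, nu = 1, nv = 0)
  score <- sv$u[, 1] * sv$d[1]
  ref <- colMeans(Z)
  if (stats::sd(ref) > 0 && stats::cor(score, ref) < 0) score <- -score
  stats::setNames(score, colnames(e$values))
}

#' Run the full receptor prioritization cascade
#'
#' Aligns the two conditions to their common genes, computes triculture-vs-
#' monoculture differential expression in GSCs, then applies the four-stage
#' cascade: (1) intersect upregulated genes (log2FC >= `lfc_entry`,
#' FDR <= `fdr_max`) with the receptor universe; (2) require an expressed
#' cognate secreted ligand in triculture ECs or astrocytes; (3) require at
#' least one enriched receptor-containing pathway against the strictly
#' upregulated set (log2FC >= `lfc_strict`); (4) rank by fold change and keep
#' `top_k`. Ligand upregulation flags are computed for every stage-2 ligand.
#'
#' @param e_mono,e_tri normalized `expression_matrix` objects.
#' @param ann_mono,ann_tri annotation data.frames (`cell_id`, `label`).
#' @param lr `lr_pair_table`.
#' @param secreted secreted gene symbols.
#' @param sets pathway gene sets.
#' @param lfc_entry,lfc_strict,fdr_max DE thresholds (defaults 0.3, 1.0,
#'   0.05).
#' @param min_frac ligand expressing-fraction threshold (default 0.10).
#' @param p_enrich enrichment p threshold (default 0.05).
#' @param top_k receptors to prioritize (default 6).
#' @param de optional precomputed `de_result` for GSC triculture vs
#'   monoculture over the aligned genes; computed when `NULL`.
#' @return `cascade_report`: list with `counts` (stage sizes), `de`,
#'   `candidates`, `top`, `ligand_flags`, `enrichment`, `universe`.
#' @export
run_cascade <- function(e_mono, e_tri, ann_mono, ann_tri, lr, secreted, sets,
                        lfc_entry = 0.3, lfc_strict = 1.0, fdr_max = 0.05,
                        min_frac = 0.10, p_enrich = 0.05, top_k = 6,
                        de = NULL) {
  al <- align_conditions(e_mono, e_tri)
  gsc_mono <- ann_mono$cell_id[ann_mono$label == "GSC"]
  gsc_tri <- ann_tri$cell_id[ann_tri$label == "GSC"]
  if (length(gsc_mono) == 0 || length(gsc_tri) == 0)
    stop("no GSC cells in one of the conditions")
  if (is.null(de))
    de <- differential_expression(al$b$values[, gsc_tri, drop = FALSE],
                                  al$a$values[, gsc_mono, drop = FALSE])
  if (!setequal(de$gene, rownames(al$a$values)))
    stop("supplied DE result does not cover the aligned gene set")
  up_entry <- upregulated_genes(de, lfc_entry, fdr_max)
  up_strict <- upregulated_genes(de, lfc_strict, fdr_max)
  stage1 <- intersect_receptors(up_entry, lr)
  stage2 <- if (length(stage1))
    filter_secreted_expressed(stage1, lr, secreted, al$b, ann_tri, min_frac)
  else list()
  universe <- rownames(al$a$values)
  cands <- enrichment_filter(stage2, up_strict, sets, universe, de = de,
                             p_max = p_enrich)
  top <- rank_candidates(cands, top_k)
  all_ligands <- unique(unlist(cands$ligands))
  flags <- if (length(all_ligands))
    ligand_upregulation_flags(al$a, al$b, ann_mono, ann_tri, all_ligands)
  else data.frame(ligand = character(0), cell_type = character(0),
                  log2fc = numeric(0), p_raw = numeric(0),
                  fdr = numeric(0), flag = logical(0))
  structure(list(
    counts = c(n_upregulated = length(up_entry),
               n_receptors_stage1 = length(stage1),
               n_stage2 = length(stage2),
               n_stage3 = nrow(cands),
               n_top = nrow(top)),
    de = de,
    up_entry = up_entry,
    up_strict = up_strict,
    candidates = cands,
    top = top,
    ligand_flags = flags,
    enrichment = attr(cands, "enrichment"),
    universe = universe),
    class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("cascade_report\n  stage counts: ",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n",
      "  top receptors: ", paste(x$top$receptor, collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Serialize a cascade report to plain-text files
#'
#' Writes `candidates.tsv` (published-table column layout), `top.tsv`,
#' `stage_counts.json`, `enrichment.tsv` and `ligand_flags.tsv`.
#'
#' @param report a `cascade_report`.
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cascade_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  flat <- function(d) {
    d <- d[, c("receptor", "log2fc", "fdr", "ligands", "n_enriched_pathways")]
    d$ligands <- vapply(d$ligands, paste, "", collapse = ",")
    d
  }
  utils::write.table(flat(report$candidates), file.path(dir, "candidates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(flat(report$top), file.path(dir, "top.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(report$counts), file.path(dir, "stage_counts.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.table(report$enrichment, file.path(dir, "enrichment.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$ligand_flags, file.path(dir, "ligand_flags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
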