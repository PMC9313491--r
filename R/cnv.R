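#' Infer per-cell copy-number profiles from expression
#'
#' Reference-anchored windowed relative expression along genomic position:
#' for every annotated gene, the log-normalized value minus the mean over the
#' reference cells (diploid anchor, e.g. ECs and astrocytes); values are
#' clipped to `[-clip, clip]`, centered per cell by subtracting the cell's
#' genome-wide mean relative expression (removing cell-type expression-
#' program shifts that are not positional), and then smoothed per cell with
#' a centered moving average of `window` genes within each chromosome arm
#' (windows are truncated at arm boundaries; arms shorter than the window
#' effectively use the whole arm).
#'
#' @param e an `expression_matrix`.
#' @param ann gene annotation data.frame (columns `gene`, `chrom`, `arm`,
#'   `start`), as from [read_gene_annotation()].
#' @param reference_cells character vector of cell ids to anchor the
#'   reference (non-empty).
#' @param window odd number of genes per smoothing window (default 101).
#' @param clip clip bound for the relative expression (default 3).
#' @param center_cells subtract each cell's genome-wide mean relative
#'   expression before smoothing (default `TRUE`).
#' @return `cnv_profile`: list with `scores` (annotated genes x cells,
#'   smoothed), `arm` (per-gene arm factor), `arm_scores` (arm x cell mean
#'   score), `window`, `reference_cells`.
#' @export
infer_cnv_profile <- function(e, ann, reference_cells, window = 101, clip = 3,
                              center_cells = TRUE) {
  stopifnot(inherits(e, "expression_matrix"))
  if (length(reference_cells) == 0) stop("reference_cells must be non-empty")
  if (window %% 2 != 1) stop("window must be odd")
  ann <- ann[ann$gene %in% rownames(e$values), , drop = FALSE]
  if (nrow(ann) == 0) stop("no annotated gene present in the matrix")
  chrom_key <- suppressWarnings(as.numeric(ann$chrom))
  chrom_key[is.na(chrom_key)] <- 100 + as.integer(factor(ann$chrom[is.na(chrom_key)]))
  ord <- order(chrom_key, ann$arm, ann$start)
  ann <- ann[ord, , drop = FALSE]
  miss <- setdiff(reference_cells, colnames(e$values))
  if (length(miss)) stop("reference cells absent from matrix: ",
                         paste(utils::head(miss, 3), collapse = ", "))
  V <- e$values[ann$gene, , drop = FALSE]
  rel <- V - rowMeans(V[, reference_cells, drop = FALSE])
  rel[rel > clip] <- clip
  rel[rel < -clip] <- -clip
  if (center_cells) rel <- sweep(rel, 2, colMeans(rel))
  arms <- unique(ann$arm)
  scores <- rel
  h <- (window - 1) / 2
  for (a in arms) {
    idx <- which(ann$arm == a)
    n <- length(idx)
    if (n == 0) { warning("arm ", a, " has 0 genes; skipped"); next }
    cs <- apply(rel[idx, , drop = FALSE], 2, cumsum)
    cs <- rbind(0, cs)
    lo <- pmax(seq_len(n) - h, 1)
    hi <- pmin(seq_len(n) + h, n)
    scores[idx, ] <- (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) /
      (hi - lo + 1)
  }
  arm_sums <- rowsum(scores, group = ann$arm)
  arm_scores <- arm_sums / as.vector(table(ann$arm)[rownames(arm_sums)])
  structure(list(scores = scores,
                 arm = ann$arm,
                 genes = ann$gene,
                 arm_scores = arm_scores,
                 window = window,
                 clip = clip,
                 reference_cells = reference_cells),
            class = "cnv_profile")
}

#' @export
print.cnv_profile <- function(x, ...) {
  cat("cnv_profile: ", length(x$genes), " genes x ", ncol(x$scores),
      " cells; window=", x$window, "; arms: ",
      paste(unique(x$arm), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Call arm-level copy-number events per cell type
#'
#' Averages the smoothed profile over cells of each type and arm; an arm is
#' called `gain` when the mean score exceeds `gain_thresh`, `loss` when below
#' `loss_thresh`, otherwise `neutral`.
#'
#' @param profile a `cnv_profile` from [infer_cnv_profile()].
#' @param cell_types named character vector or factor: cell id -> type label
#'   (cells absent from the profile are ignored).
#' @param gain_thresh,loss_thresh call thresholds (defaults +0.1 / -0.1).
#' @return data.frame with columns `cell_type`, `arm`, `mean_score`, `call`.
#' @export
call_arm_events <- function(profile, cell_types,
                            gain_thresh = 0.1, loss_thresh = -0.1) {
  stopifnot(inherits(profile, "cnv_profile"), gain_thresh > 0, loss_thresh < 0)
  cell_types <- cell_types[intersect(names(cell_types), colnames(profile$scores))]
  arms <- rownames(profile$arm_scores)
  out <- list()
  for (ty in sort(unique(as.character(cell_types)))) {
    cells <- names(cell_types)[cell_types == ty]
    mean_score <- rowMeans(profile$arm_scores[, cells, drop = FALSE])
    out[[ty]] <- data.frame(cell_type = ty, arm = arms,
                            mean_score = as.numeric(mean_score),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res$call <- ifelse(res$mean_score > gain_thresh, "gain",
                     ifelse(res$mean_score < loss_thresh, "loss", "neutral"))
  rownames(res) <- NULL
  res
}
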