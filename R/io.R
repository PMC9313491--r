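#' Construct a count matrix object
#'
#' Container for raw integer gene-by-cell UMI counts together with per-cell
#' metadata. Per-cell total UMIs and the mitochondrial fraction (genes whose
#' symbol starts with \code{"MT-"}) are derived at construction time.
#'
#' @param counts integer matrix (genes x cells), non-negative. Row names are
#'   gene symbols, column names cell barcodes, unless `gene_ids`/`cell_ids`
#'   are given explicitly.
#' @param gene_ids character vector of unique gene symbols.
#' @param cell_ids character vector of unique cell barcodes.
#' @param cell_meta data.frame with one row per cell; must contain a
#'   `condition` column (`"mono"` or `"tri"`); an optional `patient` column
#'   is kept. If `NULL`, condition is set to `NA`.
#' @return An object of class `count_matrix` with elements `counts`,
#'   `gene_ids`, `cell_ids`, `cell_meta` (including derived columns
#'   `total_umis` and `mito_frac`).
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         cell_ids = colnames(counts), cell_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids) || is.null(cell_ids))
    stop("gene_ids and cell_ids are required (rownames/colnames or explicit)")
  gene_ids <- as.character(gene_ids)
  cell_ids <- as.character(cell_ids)
  if (length(gene_ids) != nrow(counts))
    stop("gene_ids length (", length(gene_ids), ") != matrix rows (", nrow(counts), ")")
  if (length(cell_ids) != ncol(counts))
    stop("cell_ids length (", length(cell_ids), ") != matrix cols (", ncol(counts), ")")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids: ",
    paste(utils::head(gene_ids[duplicated(gene_ids)], 3), collapse = ", "))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids: ",
    paste(utils::head(cell_ids[duplicated(cell_ids)], 3), collapse = ", "))
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (any(counts != round(counts))) stop("non-integer count entries found")
  storage.mode(counts) <- "double"   # keeps > .Machine$integer.max safe; values are whole numbers
  dimnames(counts) <- list(gene_ids, cell_ids)
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(condition = rep(NA_character_, length(cell_ids)))
  }
  cell_meta <- as.data.frame(cell_meta)
  if (nrow(cell_meta) != length(cell_ids))
    stop("cell_meta must have one row per cell")
  if (!"condition" %in% names(cell_meta)) cell_meta$condition <- NA_character_
  rownames(cell_meta) <- cell_ids
  totals <- colSums(counts)
  mito <- startsWith(gene_ids, "MT-")
  mito_frac <- if (any(mito)) colSums(counts[mito, , drop = FALSE]) / pmax(totals, 1) else rep(0, length(cell_ids))
  mito_frac[totals == 0] <- 0
  cell_meta$total_umis <- as.numeric(totals)
  cell_meta$mito_frac <- as.numeric(mito_frac)
  structure(list(counts = counts, gene_ids = gene_ids, cell_ids = cell_ids,
                 cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", length(x$gene_ids), " genes x ", length(x$cell_ids),
      " cells\n", sep = "")
  cond <- table(x$cell_meta$condition, useNA = "ifany")
  cat("  conditions:", paste(names(cond), cond, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Read a gene-by-cell count matrix
#'
#' Reads either a 10x-style MatrixMarket triplet (`matrix.mtx` +
#' `features.tsv` + `barcodes.tsv` in one directory) or a dense TSV with gene
#' symbols in the first column and barcodes as the header.
#'
#' @param path for `format = "mtx_triplet"`, the directory holding the
#'   triplet; for `format = "tsv"`, the TSV file.
#' @param format one of `"mtx_triplet"`, `"tsv"`.
#' @param cell_meta optional data.frame of per-cell metadata, or the path of a
#'   TSV with columns `barcode`, `condition` (and optionally `patient`).
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("mtx_triplet", "tsv"),
                              cell_meta = NULL) {
  format <- match.arg(format)
  if (format == "mtx_triplet") {
    mtx_file <- file.path(path, "matrix.mtx")
    feat_file <- file.path(path, "features.tsv")
    bc_file <- file.path(path, "barcodes.tsv")
    for (f in c(mtx_file, feat_file, bc_file))
      if (!file.exists(f)) stop("missing file: ", f)
    m <- as.matrix(Matrix::readMM(mtx_file))
    feats <- readLines(feat_file)
    feats <- vapply(strsplit(feats, "\t", fixed = TRUE), `[[`, "", 1L)
    bcs <- readLines(bc_file)
    if (length(feats) != nrow(m))
      stop("dimension mismatch in ", feat_file, ": ", length(feats),
           " features but matrix declares ", nrow(m), " rows")
    if (length(bcs) != ncol(m))
      stop("dimension mismatch in ", bc_file, ": ", length(bcs),
           " barcodes but matrix declares ", ncol(m), " columns")
    gene_ids <- feats; cell_ids <- bcs
  } else {
    if (!file.exists(path)) stop("missing file: ", path)
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    gene_ids <- as.character(tab[[1L]])
    m <- as.matrix(tab[, -1L, drop = FALSE])
    bad <- which(!vapply(seq_len(ncol(m)), function(j) is.numeric(m[, j]) || !anyNA(suppressWarnings(as.numeric(m[, j]))), TRUE))
    if (length(bad)) stop("non-numeric entries in ", path, ", column ", bad[1L] + 1L)
    storage.mode(m) <- "double"
    cell_ids <- colnames(m)
  }
  if (is.character(cell_meta)) cell_meta <- read_cell_meta(cell_meta, cell_ids)
  count_matrix(m, gene_ids, cell_ids, cell_meta)
}

#' Read per-cell metadata
#'
#' @param path TSV with columns `barcode`, `condition`, optional `patient`.
#' @param cell_ids if given, rows are reordered to match and must cover every
#'   barcode.
#' @return data.frame keyed by barcode.
#' @export
read_cell_meta <- function(path, cell_ids = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("barcode", "condition") %in% names(tab)))
    stop("cell metadata ", path, " must have columns 'barcode' and 'condition'")
  if (!is.null(cell_ids)) {
    idx <- match(cell_ids, tab$barcode)
    if (anyNA(idx))
      stop("cell metadata ", path, " is missing barcodes: ",
           paste(utils::head(cell_ids[is.na(idx)], 3), collapse = ", "))
    tab <- tab[idx, , drop = FALSE]
  }
  rownames(tab) <- tab$barcode
  tab[setdiff(names(tab), "barcode")]
}

#' Write a count matrix as an MTX triplet
#'
#' Writes `matrix.mtx`, `features.tsv`, `barcodes.tsv` and `cell_meta.tsv`
#' into `dir`.
#'
#' @param m a [count_matrix()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(m, dir) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- methods::as(Matrix::Matrix(m$counts, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  meta <- data.frame(barcode = m$cell_ids,
                     m$cell_meta[setdiff(names(m$cell_meta),
                                         c("total_umis", "mito_frac"))],
                     check.names = FALSE)
  utils::write.table(meta, file.path(dir, "cell_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a ligand-receptor pair table
#'
#' TSV with columns `ligand` and `receptor`; duplicate pairs are dropped with
#' a warning. The packaged miniature network stands in for literature-curated
#' ligand-receptor interaction databases.
#'
#' @param path TSV file.
#' @return data.frame with columns `ligand`, `receptor`, deduplicated; class
#'   `lr_pair_table`.
#' @export
read_lr_pairs <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% names(tab)))
    stop("ligand-receptor table ", path, " must have columns 'ligand' and 'receptor'")
  tab <- tab[, c("ligand", "receptor")]
  if (nrow(tab) == 0) warning("empty ligand-receptor table: ", path)
  dup <- duplicated(tab)
  if (any(dup)) {
    warning(sum(dup), " duplicate ligand-receptor rows removed from ", path)
    tab <- tab[!dup, , drop = FALSE]
  }
  rownames(tab) <- NULL
  message("loaded ", nrow(tab), " ligand-receptor pairs from ", basename(path))
  class(tab) <- c("lr_pair_table", "data.frame")
  tab
}

#' Read a secreted-protein gene list
#'
#' @param path TSV with a `gene` column (stand-in for a secretome annotation).
#' @return character vector of unique gene symbols.
#' @export
read_secreted <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab))
    stop("secreted gene list ", path, " must have a 'gene' column")
  genes <- unique(as.character(tab$gene))
  if (length(genes) == 0) stop("secreted gene list ", path, " is empty")
  genes
}

#' Read pathway gene sets in GMT format
#'
#' Standard GMT: one set per line, fields `name`, `description`, then member
#' genes, tab-separated. Duplicate genes within a set are removed.
#'
#' @param path GMT file.
#' @return named list of character vectors; attribute `source` carries an
#'   optional collection tag.
#' @param source_tag optional label (e.g. `"KEGG"`).
#' @export
read_gene_sets <- function(path, source_tag = NA_character_) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " in ", path, " has fewer than 3 fields")
    nm <- fields[[1L]]
    if (nm %in% names(sets))
      stop("duplicate gene set name '", nm, "' at line ", i, " in ", path)
    sets[[nm]] <- unique(fields[-(1:2)])
  }
  attr(sets, "source") <- source_tag
  sets
}

#' Write pathway gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation table (gene, chromosome, arm, start)
#'
#' Coordinates are 1-based; genes are ordered within each arm by start
#' position when used for copy-number scoring.
#'
#' @param path TSV with columns `gene`, `chrom`, `arm`, `start`.
#' @return data.frame keyed by gene.
#' @export
read_gene_annotation <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "chrom", "arm", "start")
  if (!all(need %in% names(tab)))
    stop("gene annotation ", path, " must have columns ",
         paste(need, collapse = ", "))
  if (any(tab$start <= 0)) stop("gene annotation ", path, ": non-positive start coordinate")
  chrom_of_arm <- sub("[pq]$", "", tab$arm)
  if (any(chrom_of_arm != as.character(tab$chrom)))
    stop("gene annotation ", path, ": arm does not match chromosome for ",
         tab$gene[which(chrom_of_arm != as.character(tab$chrom))[1L]])
  if (anyDuplicated(tab$gene))
    stop("gene annotation ", path, ": duplicate gene ",
         tab$gene[anyDuplicated(tab$gene)])
  rownames(tab) <- tab$gene
  tab
}

#' Published receptor candidate table (packaged fixture)
#'
#' Returns the 15-row prioritized-receptor table shipped with the package:
#' receptor symbol, log2 fold change (triculture vs monoculture glioma stem
#' cells), BH-adjusted Wilcoxon p-value, cognate secreted ligands expressed in
#' endothelial cells and/or astrocytes, and the number of enriched downstream
#' pathways.
#'
#' @return data.frame with columns `receptor`, `log2fc`, `fdr`, `ligands`
#'   (list column of character vectors), `n_enriched_pathways`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_candidates.tsv", package = "pvnscreen",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$ligands <- strsplit(tab$ligands, ",", fixed = TRUE)
  tab
}

#' Assemble receptor candidates into the published table layout
#'
#' @param candidates data.frame as returned by [enrichment_filter()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(candidates, path) {
  out <- candidates
  out$ligands <- vapply(out$ligands, paste, "", collapse = ",")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
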