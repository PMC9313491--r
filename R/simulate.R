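#' Simulation configuration for a monoculture/triculture experiment
#'
#' Defines the generative model for a paired monoculture vs triculture
#' single-cell experiment with three cell types (EC, astrocyte, GSC):
#' negative-binomial counts with log-normal library sizes, cell-type marker
#' genes, per-type expression programs, GSC-specific chromosome-arm
#' copy-number events (17q gain, 4q loss) present in both conditions, and
#' triculture-specific planted effects: receptor upregulation in GSCs, a GSC
#' downstream response program, and secreted-ligand expression in source
#' cell types.
#'
#' Default cell numbers follow the triculture niche experiment (triculture
#' EC = 1221, astrocyte = 477, GSC = 217; pooled monoculture EC = 1345,
#' astrocyte = 281, GSC = 483).
#'
#' @param n_cells named list with `tri` and `mono` integer vectors (cells per
#'   type).
#' @param n_genes total genes (special genes are carved out of this total).
#' @param library_size_meanlog,library_size_sdlog log-normal library size
#'   parameters (mean UMIs per cell ~ 20k).
#' @param nb_size negative-binomial size (dispersion = 1/size), shared across
#'   genes.
#' @param marker_boost fold boost of each marker gene in its own type.
#' @param program_size,program_boost per-type expression program (genes and
#'   fold boost) giving types a transcriptome-wide identity.
#' @param cnv_gain,cnv_loss multiplicative factors applied to GSC genes on
#'   17q and 4q respectively, in both conditions.
#' @param planted_pairs data.frame with columns `ligand`, `receptor`,
#'   `source` (`"EC"` or `"astrocyte"`), `lfc` (receptor log2FC in triculture
#'   GSCs), `frac` (ligand expressing fraction in the source type in
#'   triculture).
#' @param n_response,response_lfc GSC triculture response program: genes
#'   co-upregulated downstream of the planted receptors (they populate the
#'   receptor pathways in the fixture gene sets).
#' @param n_decoy_pairs additional ligand-receptor pairs with no planted
#'   effect.
#' @param n_pathway_fill,n_decoy_pathways random filler genes per pathway and
#'   number of pathways not tied to any receptor.
#' @param mito_mean_frac expected mitochondrial fraction of a cell's UMIs.
#' @param seed integer seed fixing the full output.
#' @return `sim_config` list.
#' @export
sim_config <- function(n_cells = list(tri = c(EC = 1221, astrocyte = 477, GSC = 217),
                                      mono = c(EC = 1345, astrocyte = 281, GSC = 483)),
                       n_genes = 2000,
                       library_size_meanlog = log(20000),
                       library_size_sdlog = 0.25,
                       nb_size = 2,
                       marker_boost = 8,
                       program_size = 120,
                       program_boost = 4,
                       cnv_gain = 1.5,
                       cnv_loss = 0.5,
                       planted_pairs = default_planted_pairs(),
                       n_response = 40,
                       response_lfc = 1.5,
                       n_decoy_pairs = 20,
                       n_pathway_fill = 10,
                       n_decoy_pathways = 10,
                       mito_mean_frac = 0.05,
                       seed = 1L) {
  stopifnot(all(unlist(n_cells) > 0), n_genes >= 1000,
            nb_size > 0, marker_boost > 0, cnv_gain > 0, cnv_loss > 0)
  if (nrow(planted_pairs) > 0) {
    stopifnot(all(planted_pairs$frac >= 0 & planted_pairs$frac <= 1),
              all(planted_pairs$source %in% c("EC", "astrocyte")))
  }
  structure(list(n_cells = n_cells, n_genes = n_genes,
                 library_size_meanlog = library_size_meanlog,
                 library_size_sdlog = library_size_sdlog,
                 nb_size = nb_size, marker_boost = marker_boost,
                 program_size = program_size, program_boost = program_boost,
                 cnv_gain = cnv_gain, cnv_loss = cnv_loss,
                 planted_pairs = planted_pairs,
                 n_response = n_response, response_lfc = response_lfc,
                 n_decoy_pairs = n_decoy_pairs,
                 n_pathway_fill = n_pathway_fill,
                 n_decoy_pathways = n_decoy_pathways,
                 mito_mean_frac = mito_mean_frac,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted ligand-receptor effects
#'
#' Six pairs echoing the prioritized receptors of the triculture niche study,
#' all with receptor log2FC >= 1 and ligand expressing fraction >= 0.15 so
#' the full cascade should recover each of them.
#'
#' @return data.frame with columns `ligand`, `receptor`, `source`, `lfc`,
#'   `frac`.
#' @export
default_planted_pairs <- function() {
  data.frame(
    ligand   = c("PDGFA", "RSPO3", "SAA1", "FGF5", "APOE", "IL6"),
    receptor = c("PDGFRA", "LGR6", "FPR1", "FGFR4", "LRP8", "F3"),
    source   = c("astrocyte", "astrocyte", "EC", "astrocyte", "EC", "astrocyte"),
    lfc      = c(2.5, 2.0, 2.0, 1.8, 1.9, 1.8),
    frac     = c(0.40, 0.30, 0.35, 0.25, 0.30, 0.30),
    stringsAsFactors = FALSE
  )
}

# Synthetic genome: contiguous arm blocks; 17q and 4q carry >= 150 genes so
# windowed CNV scoring has support. Mitochondrial genes sit outside the
# nuclear annotation.
sim_genome <- function(n_genes, n_mito = 10L) {
  arms <- c("1p", "1q", "2p", "2q", "3p", "3q", "4q", "7p", "17q", "19p")
  n_nuclear <- n_genes - n_mito
  per_arm <- rep(n_nuclear %/% length(arms), length(arms))
  per_arm[seq_len(n_nuclear %% length(arms))] <-
    per_arm[seq_len(n_nuclear %% length(arms))] + 1L
  arm_of <- rep(arms, per_arm)
  genes <- sprintf("G%04d", seq_len(n_nuclear))
  mito <- sprintf("MT-G%02d", seq_len(n_mito))
  ann <- data.frame(gene = genes,
                    chrom = sub("[pq]$", "", arm_of),
                    arm = arm_of,
                    start = unlist(lapply(per_arm, function(k) seq_len(k) * 1e5)),
                    stringsAsFactors = FALSE)
  list(genes = c(genes, mito), mito = mito, annotation = ann)
}

#' Generate a paired monoculture/triculture experiment with known truth
#'
#' Draws gene-by-cell counts for both conditions from the generative model in
#' [sim_config()]. Counts for gene g in cell c are negative binomial with
#' mean `library_size_c * m_g / sum(m)` where `m` is the relative-mean
#' profile of the cell's (type, condition) block, and shared size `nb_size`.
#'
#' @param config a [sim_config()].
#' @return list with `mono` and `tri` ([count_matrix()] objects) and `truth`,
#'   a list holding per-cell true types, per-block relative means, the
#'   planted pair table, CNV arm assignments, the gene annotation and the
#'   companion fixture objects (ligand-receptor table, secreted set, gene
#'   sets).
#' @export
generate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  genome <- sim_genome(config$n_genes)
  genes <- genome$genes
  n_genes <- length(genes)

  pp <- config$planted_pairs
  markers <- c(EC = "PECAM1", astrocyte = "S100B", GSC = "CDKN2A")
  # carve special genes out of ordinary slots on neutral arms (1p..3q)
  neutral_idx <- which(genome$annotation$arm %in% c("1p", "1q", "2p", "2q", "3p", "3q"))
  need <- c(markers, if (nrow(pp)) pp$ligand, if (nrow(pp)) pp$receptor)
  if (anyDuplicated(need)) stop("planted genes must be distinct from each other and from the markers")
  slots <- sample(neutral_idx, length(need) + config$n_response + 2 * config$n_decoy_pairs)
  rename <- genes
  rename[slots[seq_along(need)]] <- need
  response_idx <- slots[length(need) + seq_len(config$n_response)]
  response_genes <- sprintf("RSP%03d", seq_len(config$n_response))
  rename[response_idx] <- response_genes
  decoy_idx <- slots[length(need) + config$n_response +
                       seq_len(2 * config$n_decoy_pairs)]
  decoy_lig <- sprintf("DLG%03d", seq_len(config$n_decoy_pairs))
  decoy_rec <- sprintf("DRC%03d", seq_len(config$n_decoy_pairs))
  rename[decoy_idx] <- c(decoy_lig, decoy_rec)
  genome$annotation$gene <- rename[seq_len(nrow(genome$annotation))]
  genes <- rename
  if (nrow(pp) && !all(c(pp$ligand, pp$receptor) %in% genes))
    stop("planted gene absent from gene list")

  base <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 1)
  names(base) <- genes
  base[markers] <- 1
  if (nrow(pp)) {
    base[pp$receptor] <- 1       # well-expressed so fold changes are estimable
    base[pp$ligand] <- 0.005     # near-off baseline (~3% detection) unless planted on
  }
  base[decoy_rec] <- 1
  base[decoy_lig] <- 0.2
  base[response_genes] <- 0.5
  base[genome$mito] <- sum(base[setdiff(genes, genome$mito)]) *
    config$mito_mean_frac / (1 - config$mito_mean_frac) / length(genome$mito)

  types <- c("EC", "astrocyte", "GSC")
  ordinary <- setdiff(genes, c(need, response_genes, decoy_lig, decoy_rec, genome$mito))
  programs <- list()
  pool <- ordinary
  for (ty in types) {
    programs[[ty]] <- sample(pool, config$program_size)
    pool <- setdiff(pool, programs[[ty]])
  }

  arm_of <- stats::setNames(genome$annotation$arm, genome$annotation$gene)
  block_mean <- function(type, condition) {
    m <- base
    m[markers[[type]]] <- m[markers[[type]]] * config$marker_boost
    m[markers[setdiff(types, type)]] <- 0.02
    m[programs[[type]]] <- m[programs[[type]]] * config$program_boost
    if (type == "GSC") {
      on17q <- names(arm_of)[arm_of == "17q"]
      on4q <- names(arm_of)[arm_of == "4q"]
      m[on17q] <- m[on17q] * config$cnv_gain
      m[on4q] <- m[on4q] * config$cnv_loss
      if (condition == "tri" && nrow(pp))
        m[pp$receptor] <- m[pp$receptor] * 2^pp$lfc
      if (condition == "tri" && config$n_response > 0)
        m[response_genes] <- m[response_genes] * 2^config$response_lfc
    }
    m
  }

  draw_block <- function(type, condition, n, barcode_prefix) {
    m <- block_mean(type, condition)
    M <- matrix(m, nrow = n_genes, ncol = n,
                dimnames = list(genes, NULL))
    if (condition == "tri" && nrow(pp)) {
      for (i in seq_len(nrow(pp))) {
        if (pp$source[i] == type) {
          on <- stats::runif(n) < pp$frac[i]
          M[pp$ligand[i], on] <- 5
        }
      }
    }
    ls <- stats::rlnorm(n, config$library_size_meanlog, config$library_size_sdlog)
    mu <- sweep(M, 2, ls / colSums(M), `*`)
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = config$nb_size),
                     nrow = n_genes,
                     dimnames = list(genes, paste0(barcode_prefix, "-", seq_len(n))))
    counts
  }

  build_condition <- function(condition) {
    nc <- config$n_cells[[condition]]
    blocks <- lapply(types, function(ty)
      draw_block(ty, condition, nc[[ty]], paste0(condition, "_", ty)))
    counts <- do.call(cbind, blocks)
    true_type <- rep(types, nc[types])
    meta <- data.frame(condition = condition, true_type = true_type,
                       stringsAsFactors = FALSE)
    count_matrix(counts, cell_meta = meta)
  }

  mono <- build_condition("mono")
  tri <- build_condition("tri")

  lr <- data.frame(ligand = c(if (nrow(pp)) pp$ligand, decoy_lig),
                   receptor = c(if (nrow(pp)) pp$receptor, decoy_rec),
                   stringsAsFactors = FALSE)
  class(lr) <- c("lr_pair_table", "data.frame")
  secreted <- unique(c(if (nrow(pp)) pp$ligand, decoy_lig))
  sets <- list()
  for (r in unique(lr$receptor)) {
    fill <- sample(ordinary, config$n_pathway_fill)
    member <- if (nrow(pp) && r %in% pp$receptor)
      c(r, sample(response_genes, min(15, length(response_genes))), fill)
    else c(r, fill)
    sets[[paste0("PW_", r)]] <- unique(member)
  }
  for (j in seq_len(config$n_decoy_pathways))
    sets[[sprintf("PW_NULL%02d", j)]] <- sample(ordinary, config$n_pathway_fill + 5)

  truth <- list(markers = markers,
                programs = programs,
                planted_pairs = pp,
                response_genes = response_genes,
                cnv = list(gain = "17q", loss = "4q",
                           gain_factor = config$cnv_gain,
                           loss_factor = config$cnv_loss),
                annotation = genome$annotation,
                base_mean = base,
                lr_pairs = lr, secreted = secreted, gene_sets = sets,
                config = config)
  list(mono = mono, tri = tri, truth = truth)
}

#' Write a complete on-disk fixture bundle
#'
#' Serializes a generated experiment as plain-text files: MTX triplets with
#' cell metadata for both conditions, the ligand-receptor table, secreted
#' list, pathway GMT, gene annotation, per-cell true types, and a JSON
#' manifest recording the ground truth.
#'
#' @param out_dir target directory (created).
#' @param config a [sim_config()].
#' @return the manifest (list), invisibly; written to `manifest.json`.
#' @export
write_fixture_bundle <- function(out_dir, config = sim_config()) {
  exp <- generate_experiment(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(exp$mono, file.path(out_dir, "mono"))
  write_count_matrix(exp$tri, file.path(out_dir, "tri"))
  utils::write.table(
    data.frame(ligand = exp$truth$lr_pairs$ligand,
               receptor = exp$truth$lr_pairs$receptor),
    file.path(out_dir, "lr_pairs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = exp$truth$secreted),
                     file.path(out_dir, "secreted.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_sets(exp$truth$gene_sets, file.path(out_dir, "pathways.gmt"))
  utils::write.table(exp$truth$annotation, file.path(out_dir, "gene_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = config$seed,
    files = list(mono = "mono", tri = "tri", lr_pairs = "lr_pairs.tsv",
                 secreted = "secreted.tsv", pathways = "pathways.gmt",
                 annotation = "gene_annotation.tsv"),
    n_pairs = nrow(exp$truth$lr_pairs),
    planted_pairs = exp$truth$planted_pairs,
    cnv = exp$truth$cnv[c("gain", "loss")],
    markers = as.list(exp$truth$markers),
    n_cells = lapply(config$n_cells, as.list)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate a synthetic patient tumor for evidence tiering
#'
#' One patient's tumor: a neoplastic majority expressing the given receptors,
#' plus optional contaminating clusters marked by lineage genes used for
#' neoplastic enrichment (oligodendrocytes: MBP, PLP1; immune: CD14, AIF1;
#' astrocytes: ETNPPL).
#'
#' @param receptors character vector of receptor symbols to place in the
#'   gene list.
#' @param receptor_mean relative mean of each receptor in neoplastic cells
#'   (0 = absent); recycled over receptors.
#' @param n_cells cells per compartment (named: neoplastic, oligo, immune).
#' @param n_genes total genes.
#' @param nb_size,library_size_meanlog,library_size_sdlog noise model as in
#'   [sim_config()].
#' @param seed integer seed.
#' @return a [count_matrix()] with `true_type` in `cell_meta`.
#' @export
generate_patient_tumor <- function(receptors,
                                   receptor_mean = 1,
                                   n_cells = c(neoplastic = 300, oligo = 60, immune = 60),
                                   n_genes = 1000,
                                   nb_size = 2,
                                   library_size_meanlog = log(10000),
                                   library_size_sdlog = 0.25,
                                   seed = 1L) {
  set.seed(as.integer(seed))
  receptor_mean <- rep_len(receptor_mean, length(receptors))
  lineage <- list(oligo = c("MBP", "PLP1"), immune = c("CD14", "AIF1"))
  genes <- sprintf("PG%04d", seq_len(n_genes))
  special <- c(receptors, unlist(lineage))
  genes[seq_along(special)] <- special
  base <- stats::rlnorm(n_genes, 0, 1)
  names(base) <- genes
  base[receptors] <- 0
  base[unlist(lineage)] <- 0.2
  # per-compartment expression programs so clusters are separable
  pool <- setdiff(genes, special)
  programs <- lapply(stats::setNames(nm = names(n_cells)), function(ty) {
    pg <- sample(pool, min(60, length(pool) %/% length(n_cells)))
    pool <<- setdiff(pool, pg)
    pg
  })
  blocks <- lapply(names(n_cells), function(ty) {
    m <- base
    m[programs[[ty]]] <- m[programs[[ty]]] * 4
    if (ty == "neoplastic") m[receptors] <- receptor_mean
    if (ty %in% names(lineage)) m[lineage[[ty]]] <- 8
    n <- n_cells[[ty]]
    ls <- stats::rlnorm(n, library_size_meanlog, library_size_sdlog)
    mu <- outer(m / sum(m), ls)
    matrix(stats::rnbinom(length(mu), mu = mu, size = nb_size),
           nrow = n_genes,
           dimnames = list(genes, paste0(ty, "-", seq_len(n))))
  })
  counts <- do.call(cbind, blocks)
  meta <- data.frame(condition = "patient",
                     true_type = rep(names(n_cells), n_cells),
                     stringsAsFactors = FALSE)
  count_matrix(counts, cell_meta = meta)
}
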