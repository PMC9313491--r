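#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis in one object. Inputs are
#' either an on-disk fixture bundle (`bundle_dir`, see
#' [write_fixture_bundle()]) or an in-memory simulation (`sim`).
#'
#' @param bundle_dir directory with `mono/`, `tri/`, `lr_pairs.tsv`,
#'   `secreted.tsv`, `pathways.gmt`, `gene_annotation.tsv`; or `NULL`.
#' @param sim a [sim_config()] used when `bundle_dir` is `NULL`.
#' @param out_dir where stage caches and output tables are written.
#' @param min_cells,min_genes,max_mito QC thresholds.
#' @param target_sum normalization total.
#' @param hvg_n highly variable genes.
#' @param n_pcs,k_neighbors,resolution clustering parameters.
#' @param lfc_entry,lfc_strict,fdr_max DE thresholds.
#' @param min_frac,p_enrich,top_k cascade thresholds.
#' @param cnv_window,cnv_clip,gain_thresh,loss_thresh copy-number scoring.
#' @param target_gain,target_loss arms expected to be gained/lost in GSCs.
#' @param evidence_min_cells per-patient neoplastic cell floor.
#' @param seed global seed (clustering).
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(bundle_dir = NULL, sim = sim_config(),
                            out_dir = tempfile("pvn_run_"),
                            min_cells = 3, min_genes = 200, max_mito = 0.18,
                            target_sum = 1e4, hvg_n = 4000,
                            n_pcs = 50, k_neighbors = 15, resolution = 1,
                            lfc_entry = 0.3, lfc_strict = 1.0, fdr_max = 0.05,
                            min_frac = 0.10, p_enrich = 0.05, top_k = 6,
                            cnv_window = 101, cnv_clip = 3,
                            gain_thresh = 0.1, loss_thresh = -0.1,
                            target_gain = "17q", target_loss = "4q",
                            evidence_min_cells = 113,
                            seed = 1L) {
  stopifnot(max_mito > 0, max_mito <= 1, fdr_max > 0, fdr_max <= 1,
            min_frac >= 0, min_frac <= 1, p_enrich > 0, p_enrich <= 1,
            gain_thresh > 0, loss_thresh < 0, cnv_window %% 2 == 1)
  structure(list(bundle_dir = bundle_dir, sim = sim, out_dir = out_dir,
                 min_cells = min_cells, min_genes = min_genes,
                 max_mito = max_mito, target_sum = target_sum, hvg_n = hvg_n,
                 n_pcs = n_pcs, k_neighbors = k_neighbors,
                 resolution = resolution, lfc_entry = lfc_entry,
                 lfc_strict = lfc_strict, fdr_max = fdr_max,
                 min_frac = min_frac, p_enrich = p_enrich, top_k = top_k,
                 cnv_window = cnv_window, cnv_clip = cnv_clip,
                 gain_thresh = gain_thresh, loss_thresh = loss_thresh,
                 target_gain = target_gain, target_loss = target_loss,
                 evidence_min_cells = evidence_min_cells,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialize / restore a pipeline configuration
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON file.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$sim <- if (is.null(cfg$sim)) NULL else unclass(cfg$sim)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sim <- NULL
  if (!is.null(x$sim)) {
    s <- x$sim
    s$n_cells <- lapply(s$n_cells, function(v) unlist(v))
    s$planted_pairs <- as.data.frame(s$planted_pairs)
    sim <- do.call(sim_config, s)
  }
  x$sim <- NULL
  x$bundle_dir <- if (is.null(x$bundle_dir)) NULL else x$bundle_dir
  do.call(pipeline_config, c(x, list(sim = sim)))
}

cache_path <- function(cfg, stage) {
  dir.create(file.path(cfg$out_dir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  file.path(cfg$out_dir, "cache", paste0(stage, ".rds"))
}

load_upstream <- function(cfg, stage) {
  p <- cache_path(cfg, stage)
  if (!file.exists(p))
    stop("missing upstream artifact for stage '", stage,
         "'; run_stage(\"", stage, "\", cfg) first")
  readRDS(p)
}

pipeline_stages <- c("load", "qc", "cluster", "cnv", "de", "cascade")

#' Run one pipeline stage from cached upstream artifacts
#'
#' Stages: `load` (read bundle or simulate), `qc`, `cluster` (normalize, HVG,
#' SNN clustering, annotation), `cnv`, `de`, `cascade`. Each stage caches its
#' artifact under `out_dir/cache/` and the cascade stage writes the output
#' tables.
#'
#' @param name stage name.
#' @param cfg a [pipeline_config()].
#' @return the stage artifact, invisibly.
#' @export
run_stage <- function(name, cfg) {
  if (!name %in% pipeline_stages)
    stop("unknown stage '", name, "'; stages are: ",
         paste(pipeline_stages, collapse = ", "))
  art <- tryCatch(switch(name,
    load = stage_load(cfg),
    qc = stage_qc(cfg),
    cluster = stage_cluster(cfg),
    cnv = stage_cnv(cfg),
    de = stage_de(cfg),
    cascade = stage_cascade(cfg)),
    error = function(e) stop("stage '", name, "' failed: ",
                             conditionMessage(e), call. = FALSE))
  saveRDS(art, cache_path(cfg, name), compress = FALSE)
  invisible(art)
}

stage_load <- function(cfg) {
  if (!is.null(cfg$bundle_dir)) {
    d <- cfg$bundle_dir
    mono <- read_count_matrix(file.path(d, "mono"), "mtx_triplet",
                              cell_meta = file.path(d, "mono", "cell_meta.tsv"))
    tri <- read_count_matrix(file.path(d, "tri"), "mtx_triplet",
                             cell_meta = file.path(d, "tri", "cell_meta.tsv"))
    list(mono = mono, tri = tri,
         lr = read_lr_pairs(file.path(d, "lr_pairs.tsv")),
         secreted = read_secreted(file.path(d, "secreted.tsv")),
         sets = read_gene_sets(file.path(d, "pathways.gmt")),
         annotation = read_gene_annotation(file.path(d, "gene_annotation.tsv")),
         truth = NULL)
  } else {
    exp <- generate_experiment(cfg$sim)
    list(mono = exp$mono, tri = exp$tri,
         lr = exp$truth$lr_pairs, secreted = exp$truth$secreted,
         sets = exp$truth$gene_sets, annotation = exp$truth$annotation,
         truth = exp$truth)
  }
}

stage_qc <- function(cfg) {
  inp <- load_upstream(cfg, "load")
  list(mono = qc_filter(inp$mono, cfg$min_cells, cfg$min_genes, cfg$max_mito),
       tri = qc_filter(inp$tri, cfg$min_cells, cfg$min_genes, cfg$max_mito))
}

stage_cluster <- function(cfg) {
  qc <- load_upstream(cfg, "qc")
  one <- function(m) {
    e <- select_hvg(normalize_log(m, cfg$target_sum), cfg$hvg_n)
    cl <- cluster_snn(e, n_pcs = cfg$n_pcs, k_neighbors = cfg$k_neighbors,
                      resolution = cfg$resolution, seed = cfg$seed)
    ann <- annotate_clusters(e, cl)
    list(e = e, clusters = cl, annotation = ann)
  }
  list(mono = one(qc$mono), tri = one(qc$tri))
}

stage_cnv <- function(cfg) {
  inp <- load_upstream(cfg, "load")
  clu <- load_upstream(cfg, "cluster")
  one <- function(x) {
    ref <- x$annotation$cell_id[x$annotation$label %in% c("EC", "astrocyte")]
    prof <- infer_cnv_profile(x$e, inp$annotation, ref,
                              window = cfg$cnv_window, clip = cfg$cnv_clip)
    types <- stats::setNames(x$annotation$label, x$annotation$cell_id)
    list(profile = prof,
         calls = call_arm_events(prof, types, cfg$gain_thresh, cfg$loss_thresh))
  }
  list(mono = one(clu$mono), tri = one(clu$tri))
}

stage_de <- function(cfg) {
  clu <- load_upstream(cfg, "cluster")
  al <- align_conditions(clu$mono$e, clu$tri$e)
  gsc_mono <- clu$mono$annotation$cell_id[clu$mono$annotation$label == "GSC"]
  gsc_tri <- clu$tri$annotation$cell_id[clu$tri$annotation$label == "GSC"]
  if (length(gsc_mono) == 0 || length(gsc_tri) == 0)
    stop("no GSC cells identified in one of the conditions")
  de <- differential_expression(al$b$values[, gsc_tri, drop = FALSE],
                                al$a$values[, gsc_mono, drop = FALSE])
  list(de = de, aligned = al)
}

stage_cascade <- function(cfg) {
  inp <- load_upstream(cfg, "load")
  clu <- load_upstream(cfg, "cluster")
  cnv <- load_upstream(cfg, "cnv")
  de <- load_upstream(cfg, "de")
  report <- run_cascade(clu$mono$e, clu$tri$e,
                        clu$mono$annotation, clu$tri$annotation,
                        inp$lr, inp$secreted, inp$sets,
                        lfc_entry = cfg$lfc_entry, lfc_strict = cfg$lfc_strict,
                        fdr_max = cfg$fdr_max, min_frac = cfg$min_frac,
                        p_enrich = cfg$p_enrich, top_k = cfg$top_k,
                        de = de$de)
  write_cascade_report(report, cfg$out_dir)
  utils::write.table(rbind(cbind(condition = "mono", cnv$mono$calls),
                           cbind(condition = "tri", cnv$tri$calls)),
                     file.path(cfg$out_dir, "cnv_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- rbind(cbind(condition = "mono", clu$mono$annotation),
               cbind(condition = "tri", clu$tri$annotation))
  utils::write.table(ann, file.path(cfg$out_dir, "cell_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_lines <- c(paste0("pvnscreen ", as.character(utils::packageVersion("pvnscreen"))),
                 paste0("run at ", format(Sys.time())),
                 paste0("seed ", cfg$seed),
                 paste0("params: ", jsonlite::toJSON(
                   unclass(cfg)[setdiff(names(cfg), c("sim", "bundle_dir", "out_dir"))],
                   auto_unbox = TRUE)))
  writeLines(log_lines, file.path(cfg$out_dir, "run_log.txt"))
  report
}

#' Run the full pipeline
#'
#' Executes load -> qc -> cluster -> cnv -> de -> cascade, caching every
#' stage artifact under `out_dir/cache/` and writing output tables
#' (`candidates.tsv`, `top.tsv`, `stage_counts.json`, `enrichment.tsv`,
#' `ligand_flags.tsv`, `cnv_calls.tsv`, `cell_annotation.tsv`,
#' `run_log.txt`) into `out_dir`.
#'
#' @param cfg a [pipeline_config()].
#' @param patient_matrices optional named list of per-patient neoplastic
#'   [count_matrix()] objects; when given, evidence tiers for the top
#'   receptors are computed and written to `evidence.tsv`.
#' @return list with the cached stage artifacts plus `evidence` (or `NULL`).
#' @export
run_pipeline <- function(cfg, patient_matrices = NULL) {
  for (st in pipeline_stages) run_stage(st, cfg)
  arts <- stats::setNames(lapply(pipeline_stages, function(s)
    readRDS(cache_path(cfg, s))), pipeline_stages)
  evidence <- NULL
  if (!is.null(patient_matrices)) {
    evidence <- per_patient_receptor_evidence(
      patient_matrices, arts$cascade$top$receptor,
      min_cells = cfg$evidence_min_cells, target_sum = cfg$target_sum)
    utils::write.table(evidence, file.path(cfg$out_dir, "evidence.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  c(arts, list(evidence = evidence))
}
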