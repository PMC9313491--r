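# Shared fixtures: a small simulated experiment reused across test files, and
# small construction helpers. Everything is generated in code at test time.

small_sim <- function(seed = 42, ...) {
  sim_config(n_cells = list(tri = c(EC = 240, astrocyte = 100, GSC = 60),
                            mono = c(EC = 260, astrocyte = 60, GSC = 100)),
             n_genes = 1000, seed = seed, ...)
}

# computed once per test run
small_exp <- generate_experiment(small_sim())

truth_annotation <- function(m) {
  data.frame(cell_id = m$cell_ids, cluster = as.integer(factor(m$cell_meta$true_type)),
             label = m$cell_meta$true_type, stringsAsFactors = FALSE)
}

# expression_matrix built straight from a dense value matrix (already on the
# log-normalized scale); covariates are benign constants.
make_expr <- function(values) {
  structure(list(values = values,
                 cell_meta = data.frame(condition = rep("tri", ncol(values)),
                                        row.names = colnames(values)),
                 covariates = cbind(total_umis = colSums(values) + 1,
                                    mito_frac = rep(0, ncol(values))),
                 hvg = NULL, target_sum = NA_real_),
            class = "expression_matrix")
}

make_counts <- function(mat, condition = "mono") {
  count_matrix(mat, cell_meta = data.frame(condition = rep(condition, ncol(mat))))
}

# adjusted Rand index between two label vectors
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_idx <- si * sj / n2
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}

# in-memory end-to-end run used by acceptance checks: QC, normalization, HVG,
# SNN clustering, annotation, CNV calls and the four-stage cascade.
run_full_pipeline_mem <- function(sim, seed = sim$seed) {
  exp <- generate_experiment(sim)
  sides <- lapply(exp[c("mono", "tri")], function(m) {
    q <- suppressMessages(qc_filter(m))
    e <- select_hvg(normalize_log(q))
    cl <- cluster_snn(e, seed = seed)
    list(q = q, e = e, ann = annotate_clusters(e, cl))
  })
  report <- run_cascade(sides$mono$e, sides$tri$e,
                        sides$mono$ann, sides$tri$ann,
                        exp$truth$lr_pairs, exp$truth$secreted,
                        exp$truth$gene_sets)
  ref <- sides$tri$ann$cell_id[sides$tri$ann$label %in% c("EC", "astrocyte")]
  prof <- infer_cnv_profile(sides$tri$e, exp$truth$annotation, ref)
  calls <- call_arm_events(prof, stats::setNames(sides$tri$ann$label,
                                                 sides$tri$ann$cell_id))
  list(exp = exp, sides = sides, report = report, calls = calls)
}
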