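test_that("qc_filter applies its boundaries strictly", {
  # 6 genes x 4 cells; MT-M carries the mitochondrial signal
  genes <- c("A", "B", "C", "D", "E", "MT-M")
  m <- matrix(0, 6, 4, dimnames = list(genes, paste0("c", 1:4)))
  m["A", ] <- c(5, 5, 5, 5)
  m["B", ] <- c(5, 5, 5, 0)
  m["C", ] <- c(5, 5, 0, 0)      # detected in exactly 2 cells of those kept
  m["D", ] <- c(5, 0, 0, 0)
  m["E", ] <- c(5, 5, 5, 5)
  m["MT-M", ] <- c(9, 0, 0, 0)   # cell c1: mito = 9/34 > 0.18 -> removed
  cm <- make_counts(m)
  out <- suppressMessages(qc_filter(cm, min_cells = 2, min_genes = 3, max_mito = 0.18))
  expect_false("c1" %in% out$cell_ids)        # mito fraction above ceiling
  expect_false("c4" %in% out$cell_ids)        # only 2 detected genes < 3
  # gene prevalence is evaluated on the retained cells (c2, c3)
  expect_setequal(out$gene_ids, c("A", "B", "E"))

  # boundary: mito fraction exactly 0.18 is retained
  m2 <- matrix(c(82, 18), 2, 1, dimnames = list(c("A", "MT-M"), "c1"))
  out2 <- suppressMessages(qc_filter(make_counts(m2), min_cells = 1,
                                     min_genes = 1, max_mito = 0.18))
  expect_equal(out2$cell_ids, "c1")

  # gene in exactly min_cells cells is retained, in min_cells - 1 removed
  m3 <- matrix(c(1, 1, 1, 0,
                 1, 1, 1, 1), 2, 4, byrow = TRUE,
               dimnames = list(c("G2", "G3"), paste0("c", 1:4)))
  out3 <- suppressMessages(qc_filter(make_counts(m3), min_cells = 4,
                                     min_genes = 1, max_mito = 1))
  expect_identical(out3$gene_ids, "G3")

  expect_error(suppressMessages(qc_filter(cm, min_genes = 100)), "every cell")
})

test_that("qc_filter is idempotent on simulated data", {
  once <- suppressMessages(qc_filter(small_exp$tri))
  twice <- suppressMessages(qc_filter(once))
  expect_identical(once$counts, twice$counts)
})

test_that("normalization scales each cell to the target sum then logs", {
  m <- matrix(c(2, 2), 2, 1, dimnames = list(c("A", "B"), "c1"))
  e <- normalize_log(make_counts(m), target_sum = 4)
  expect_equal(unname(e$values[, 1]), c(log(3), log(3)))

  m2 <- matrix(5, 4, 3, dimnames = list(paste0("g", 1:4), paste0("c", 1:3)))
  e2 <- normalize_log(make_counts(m2), target_sum = 100)
  expect_equal(length(unique(as.vector(e2$values))), 1L)

  q <- suppressMessages(qc_filter(small_exp$mono))
  e3 <- normalize_log(q, target_sum = 1e4)
  expect_equal(unname(colSums(expm1(e3$values))), rep(1e4, ncol(e3$values)),
               tolerance = 1e-8)

  zero <- make_counts(matrix(0, 2, 1, dimnames = list(c("A", "B"), "c1")))
  expect_error(normalize_log(zero), "zero-total")
})

test_that("highly variable gene selection clamps, is monotone, finds planted variance", {
  e <- normalize_log(make_counts(matrix(rpois(10 * 20, 5), 10, 20,
    dimnames = list(paste0("g", 1:10), paste0("c", 1:20)))))
  e <- select_hvg(e, n_top = 4000)
  expect_equal(sum(e$hvg), 10L)

  # constant gene can never outrank a variable one
  m <- matrix(3, 5, 30, dimnames = list(paste0("g", 1:5), paste0("c", 1:30)))
  m[1, ] <- rpois(30, 3)
  e2 <- select_hvg(normalize_log(make_counts(m)), n_top = 1)
  expect_true(e2$hvg[["g1"]])

  # 5 genes with inflated variance among 500 homogeneous genes
  set.seed(1)
  base <- matrix(rpois(500 * 80, 10), 500, 80,
                 dimnames = list(sprintf("g%03d", 1:500), paste0("c", 1:80)))
  hi <- sample(500, 5)
  base[hi, ] <- rpois(5 * 80, 10) * rbinom(5 * 80, 1, 0.5) * 10
  e3 <- select_hvg(normalize_log(make_counts(base)), n_top = 5)
  expect_setequal(names(which(e3$hvg)), rownames(base)[hi])
})

test_that("SNN clustering separates well-separated blobs and is deterministic", {
  set.seed(7)
  n <- 200; g <- 500
  prof1 <- rlnorm(g, 0, 1); prof2 <- rlnorm(g, 0, 1)
  draw_blob <- function(p, prefix) {
    mu <- outer(p / sum(p), rlnorm(n, log(5000), 0.2))
    matrix(rnbinom(g * n, mu = mu, size = 2), g, n,
           dimnames = list(sprintf("g%03d", 1:g), paste0(prefix, 1:n)))
  }
  blob <- cbind(draw_blob(prof1, "a"), draw_blob(prof2, "b"))
  e <- select_hvg(normalize_log(make_counts(blob)))
  cl <- cluster_snn(e, n_pcs = 20, k_neighbors = 15, seed = 1)
  expect_equal(length(unique(cl$cluster)), 2L)
  expect_equal(ari(cl$cluster, rep(1:2, each = n)), 1.0)

  cl2 <- cluster_snn(e, n_pcs = 20, k_neighbors = 15, seed = 1)
  expect_identical(cl, cl2)

  expect_error(cluster_snn(e, k_neighbors = 500), "fewer cells")
})

test_that("the qc-cluster-annotate chain recovers planted cell types", {
  q <- suppressMessages(qc_filter(small_exp$tri))
  e <- select_hvg(normalize_log(q))
  cl <- cluster_snn(e, seed = 42)
  ann <- annotate_clusters(e, cl)
  expect_gte(mean(ann$label == q$cell_meta$true_type), 0.95)
  # majority cluster of each true type is pure
  for (ty in c("EC", "astrocyte", "GSC")) {
    cl_of_ty <- cl$cluster[q$cell_meta$true_type == ty]
    major <- as.integer(names(which.max(table(cl_of_ty))))
    purity <- mean(q$cell_meta$true_type[cl$cluster == major] == ty)
    expect_gte(purity, 0.95)
  }
})

test_that("cluster annotation follows the marker rule and handles failures", {
  genes <- c("PECAM1", "S100B", "CDKN2A")
  v <- matrix(0, 3, 30, dimnames = list(genes, paste0("c", 1:30)))
  cl <- data.frame(cell_id = colnames(v), cluster = rep(1:3, each = 10))
  v["PECAM1", 1:10] <- c(rep(2, 9), 0)      # 90% expressing in cluster 1
  v["S100B", 11:20] <- 2                    # cluster 2 astrocyte
  v["CDKN2A", 21:30] <- rep(c(2, 0), 5)     # 50% expressing: boundary kept
  ann <- annotate_clusters(make_expr(v), cl)
  expect_equal(unique(ann$label[ann$cluster == 1]), "EC")
  expect_equal(unique(ann$label[ann$cluster == 2]), "astrocyte")
  expect_equal(unique(ann$label[ann$cluster == 3]), "GSC")

  # no marker above background -> unknown
  v2 <- v; v2["PECAM1", ] <- 1               # flat everywhere: mean_in == mean_out
  v2["S100B", ] <- 0; v2["CDKN2A", ] <- 0
  ann2 <- annotate_clusters(make_expr(v2), cl)
  expect_true(all(ann2$label == "unknown"))

  # two qualifying clusters for one label: highest fraction wins
  v3 <- matrix(0, 3, 30, dimnames = list(genes, paste0("c", 1:30)))
  v3["PECAM1", 1:10] <- 2
  v3["PECAM1", 11:20] <- rep(c(2, 0), 5)
  ann3 <- annotate_clusters(make_expr(v3), cl)
  expect_equal(unique(ann3$label[ann3$cluster == 1]), "EC")
  expect_equal(unique(ann3$label[ann3$cluster == 2]), "unknown")

  expect_error(annotate_clusters(make_expr(v[1:2, ]), cl), "marker gene absent")

  # label permutation invariance: relabeling clusters permutes, not changes, labels
  cl_perm <- cl; cl_perm$cluster <- c(3L, 1L, 2L)[cl$cluster]
  ann_perm <- annotate_clusters(make_expr(v), cl_perm)
  expect_identical(ann_perm$label, ann$label)
})

test_that("marker DE finds planted markers and is empty for identical clusters", {
  q <- suppressMessages(qc_filter(small_exp$tri))
  e <- normalize_log(q)
  truth <- truth_annotation(q)
  md <- marker_de(e, truth[, c("cell_id", "cluster")])
  ec_cluster <- as.character(truth$cluster[truth$label == "EC"][1])
  expect_true("PECAM1" %in% md[[ec_cluster]]$markers)

  set.seed(2)
  m <- matrix(rpois(200 * 60, 5), 200, 60,
              dimnames = list(sprintf("g%03d", 1:200), paste0("c", 1:60)))
  e2 <- normalize_log(make_counts(m))
  cl2 <- data.frame(cell_id = colnames(m), cluster = rep(1:2, 30))
  md2 <- marker_de(e2, cl2)
  expect_equal(length(md2[["1"]]$markers), 0L)
  expect_equal(length(md2[["2"]]$markers), 0L)

  expect_error(marker_de(e2, data.frame(cell_id = colnames(m), cluster = 1)),
               "at least 2 clusters")
})
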