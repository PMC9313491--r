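lr_tiny <- structure(data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"),
                                stringsAsFactors = FALSE),
                     class = c("lr_pair_table", "data.frame"))

test_that("receptor intersection is plain set logic", {
  expect_equal(intersect_receptors(c("R1", "G9"), lr_tiny), "R1")
  expect_equal(intersect_receptors(character(0), lr_tiny), character(0))
})

test_that("expressing fractions count cells with positive values", {
  v <- matrix(0, 2, 10, dimnames = list(c("G", "H"), paste0("c", 1:10)))
  v["H", 1] <- 3
  e <- make_expr(v)
  expect_equal(fraction_expressing(e, "G", colnames(v)), 0)
  expect_equal(fraction_expressing(e, "H", colnames(v)), 0.1)
  expect_error(fraction_expressing(e, "Z", colnames(v)), "absent")
})

test_that("the secreted-ligand filter applies all three conditions", {
  cells <- c(paste0("ec", 1:20), paste0("as", 1:20))
  ann <- data.frame(cell_id = cells, label = rep(c("EC", "astrocyte"), each = 20))
  v <- matrix(0, 3, 40, dimnames = list(c("L1", "L2", "L3"), cells))
  v["L1", 1:1] <- 1                       # 5% in EC, 0% in astro -> below
  v["L2", 21:24] <- 1                     # 20% in astro -> qualifies
  v["L3", ] <- 1                          # 100% everywhere but not secreted
  e <- make_expr(v)
  lr <- structure(data.frame(ligand = c("L1", "L2", "L3"),
                             receptor = c("Ra", "Rb", "Rc")),
                  class = c("lr_pair_table", "data.frame"))
  out <- filter_secreted_expressed(c("Ra", "Rb", "Rc"), lr,
                                   secreted = c("L1", "L2"), e, ann)
  expect_named(out, "Rb")
  expect_equal(out$Rb, "L2")

  ann_bad <- data.frame(cell_id = cells, label = "EC")
  expect_error(filter_secreted_expressed("Rb", lr, "L2", e, ann_bad),
               "astrocyte")
})

test_that("hypergeometric upper tail matches hand enumeration", {
  expect_equal(hypergeometric_tail(0, 5, 4, 10), 1.0)
  expect_equal(hypergeometric_tail(4, 5, 4, 10), 5 / 210)
  expect_equal(hypergeometric_tail(3, 10, 7, 10), 1.0)   # K = N degenerate urn
  expect_error(hypergeometric_tail(5, 4, 4, 10), "inconsistent")
})

test_that("the enrichment filter keeps receptors with an enriched containing pathway", {
  universe <- sprintf("U%02d", 1:10)
  universe[1] <- "R1"
  query <- universe[1:4]                       # includes R1
  sets <- list(GOOD = c("R1", universe[2:5]),   # size-5 set overlapping query by 4
               OTHER = universe[6:10])
  rec <- list(R1 = "L1")
  out <- enrichment_filter(rec, query, sets, universe)
  expect_equal(out$receptor, "R1")
  expect_equal(out$n_enriched_pathways, 1L)
  expect_equal(out$enriched_pathways[[1]], "GOOD")
  detail <- attr(out, "enrichment")
  expect_equal(detail$p[detail$pathway == "GOOD"], 5 / 210)

  # receptor contained in no pathway is dropped
  out2 <- enrichment_filter(list(R9 = "L9"), query, sets, universe)
  expect_equal(nrow(out2), 0L)

  # empty strict query: k = 0 everywhere, p = 1, everything dropped
  out3 <- enrichment_filter(rec, character(0), sets, universe)
  expect_equal(nrow(out3), 0L)

  # invariance to pathway and member ordering
  sets_shuf <- rev(lapply(sets, rev))
  out4 <- enrichment_filter(rec, query, sets_shuf, universe)
  expect_equal(out4$n_enriched_pathways, out$n_enriched_pathways)
  expect_equal(out4$receptor, out$receptor)

  expect_error(enrichment_filter(rec, query, sets, character(0)), "empty")
})

test_that("candidate ranking sorts by fold change with FDR and symbol tie-breaks", {
  cands <- data.frame(receptor = c("B", "A", "C", "D"),
                      log2fc = c(2, 2, 3, 1),
                      fdr = c(0.01, 0.001, 0.04, 0.0001),
                      stringsAsFactors = FALSE)
  out <- rank_candidates(cands, top_k = 3)
  expect_equal(out$receptor, c("C", "A", "B"))
  expect_equal(nrow(rank_candidates(cands, top_k = 10)), 4L)
})

test_that("ligand upregulation flags require significance and positive sign", {
  cells <- paste0("c", 1:30)
  ann <- data.frame(cell_id = cells, label = rep("astrocyte", 30))
  v_hi <- matrix(2, 2, 30, dimnames = list(c("LUP", "LDN"), cells))
  v_lo <- matrix(0, 2, 30, dimnames = list(c("LUP", "LDN"), cells))
  v_tri <- v_lo; v_tri["LUP", ] <- 2       # up in tri
  v_mono <- v_lo; v_mono["LDN", ] <- 2     # down in tri
  fl <- ligand_upregulation_flags(make_expr(v_mono), make_expr(v_tri),
                                  ann, ann, c("LUP", "LDN"),
                                  cell_types = "astrocyte")
  expect_true(fl$flag[fl$ligand == "LUP"])
  expect_false(fl$flag[fl$ligand == "LDN"])
  expect_lt(fl$fdr[fl$ligand == "LDN"], 0.05)   # significant but wrong sign

  fl2 <- ligand_upregulation_flags(make_expr(v_tri), make_expr(v_tri),
                                   ann, ann, c("LUP", "LDN"),
                                   cell_types = "astrocyte")
  expect_false(any(fl2$flag))

  expect_warning(
    ligand_upregulation_flags(make_expr(v_mono), make_expr(v_tri),
                              ann, ann, "LUP", cell_types = c("astrocyte", "EC")),
    "EC")
})

test_that("eigengene scores summarize a gene set's first principal component", {
  set.seed(5)
  base <- rnorm(40)
  v <- rbind(G1 = base, G2 = 2 * base + 3, G3 = rnorm(40))
  colnames(v) <- paste0("c", 1:40)
  e <- make_expr(v)
  s1 <- eigengene(e, "G1")
  expect_equal(unname(stats::cor(s1, v["G1", ])), 1)

  s12 <- eigengene(e, c("G1", "G2"))
  expect_equal(abs(stats::cor(s12, v["G1", ])), 1)
  expect_gte(stats::cor(s12, rowMeans(scale(t(v[c("G1", "G2"), ])))), 0)

  # orientation rule: flipping the input sign of all genes flips the score,
  # but the returned score always correlates non-negatively with the set mean
  e_neg <- make_expr(-v)
  s_neg <- eigengene(e_neg, c("G1", "G2"))
  expect_gte(stats::cor(s_neg, rowMeans(scale(t(-v[c("G1", "G2"), ])))), 0)

  expect_error(eigengene(e, "ZZ"), "no gene")
  e_const <- make_expr(matrix(1, 1, 5, dimnames = list("K", paste0("c", 1:5))))
  expect_error(eigengene(e_const, "K"), "zero variance")
})

test_that("the full cascade recovers planted pairs with ground-truth labels", {
  q_mono <- suppressMessages(qc_filter(small_exp$mono))
  q_tri <- suppressMessages(qc_filter(small_exp$tri))
  e_mono <- normalize_log(q_mono)
  e_tri <- normalize_log(q_tri)
  rep <- run_cascade(e_mono, e_tri,
                     truth_annotation(q_mono), truth_annotation(q_tri),
                     small_exp$truth$lr_pairs, small_exp$truth$secreted,
                     small_exp$truth$gene_sets)
  pp <- small_exp$truth$planted_pairs
  expect_true(all(pp$receptor %in% rep$candidates$receptor))
  for (i in seq_len(nrow(pp))) {
    ligs <- unlist(rep$candidates$ligands[rep$candidates$receptor == pp$receptor[i]])
    expect_true(pp$ligand[i] %in% ligs)
  }
  # no decoy receptor (zero planted effect) comes through
  expect_false(any(grepl("^DRC", rep$candidates$receptor)))
  # stage counts are monotone nonincreasing
  expect_true(all(diff(unname(rep$counts[-1])) <= 0))
  expect_lte(rep$counts[["n_receptors_stage1"]], rep$counts[["n_upregulated"]])
  # planted source ligands are flagged as upregulated in their source type
  fl <- rep$ligand_flags
  for (i in seq_len(nrow(pp))) {
    row <- fl[fl$ligand == pp$ligand[i] & fl$cell_type == pp$source[i], ]
    expect_true(row$flag)
  }
})
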