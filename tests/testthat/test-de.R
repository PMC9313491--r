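test_that("rank-sum p-values match closed-form small-sample cases", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  x <- c(0.3, 1.7, 2.2, 9.1); y <- c(0.6, 3.3, 4.8)
  expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_rank_sum(y, x))
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("rank-sum normal approximation tolerates heavy ties", {
  # all observations identical: variance collapses, p must be 1
  expect_equal(wilcoxon_rank_sum(rep(2, 60), rep(2, 70)), 1.0)
  # large tied groups against wilcox.test's tie-corrected approximation
  set.seed(4)
  x <- sample(0:3, 80, replace = TRUE)
  y <- sample(0:4, 90, replace = TRUE)
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-10)
})

test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.7), 0.7)
  expect_equal(bh_fdr(c(0.001, 1.0)), c(0.002, 1.0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # monotone when the input is sorted ascending
  set.seed(1)
  p <- sort(runif(50))
  expect_true(all(diff(bh_fdr(p)) >= 0))
})

test_that("log2 fold change has the documented closed form", {
  expect_equal(log2_fold_change(3, 3), 0)
  expect_equal(log2_fold_change(3, 1, pseudocount = 1), 1)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_error(log2_fold_change(-1, 2), "non-negative")
})

test_that("condition alignment intersects gene sets in first-matrix order", {
  va <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("x1", "x2")))
  vb <- matrix(1, 3, 2, dimnames = list(c("B", "C", "D"), c("y1", "y2")))
  al <- align_conditions(make_expr(va), make_expr(vb))
  expect_identical(rownames(al$a$values), c("B", "C"))
  expect_identical(rownames(al$b$values), c("B", "C"))

  al2 <- align_conditions(make_expr(va), make_expr(va))
  expect_identical(al2$a$values, va)

  vz <- matrix(1, 1, 2, dimnames = list("Z", c("y1", "y2")))
  expect_error(align_conditions(make_expr(va), make_expr(vz)), "no genes in common")
})

test_that("upregulated gene selection uses inclusive thresholds and no hidden filters", {
  de <- structure(data.frame(gene = c("A", "B", "C"),
                             log2fc = c(0.30, 1.2, 2.0),
                             p_raw = c(0.01, 0.1, 0.001),
                             fdr = c(0.05, 0.2, 0.001)),
                  class = c("de_result", "data.frame"))
  expect_setequal(upregulated_genes(de, 0.3, 0.05), c("A", "C"))
  expect_setequal(upregulated_genes(de, -Inf, 1), c("A", "B", "C"))
})

test_that("DE results are sorted stably and expose group summaries", {
  set.seed(3)
  va <- matrix(rpois(50 * 20, 4), 50, 20,
               dimnames = list(sprintf("g%02d", 1:50), paste0("a", 1:20)))
  vb <- matrix(rpois(50 * 25, 4), 50, 25,
               dimnames = list(sprintf("g%02d", 1:50), paste0("b", 1:25)))
  de <- differential_expression(log1p(va), log1p(vb))
  expect_equal(nrow(de), 50L)
  expect_true(!is.unsorted(de$fdr))
  expect_true(all(de$fdr >= 0 & de$fdr <= 1))
  expect_equal(sort(de$gene), sprintf("g%02d", 1:50))
  expect_equal(de$frac_expressing_a,
               rowMeans(va > 0)[match(de$gene, rownames(va))],
               ignore_attr = TRUE)
  expect_error(differential_expression(log1p(va), log1p(vb[1:10, ])),
               "align_conditions")
})

test_that("a null simulation selects no genes in most seeds", {
  empties <- 0L
  for (s in 1:10) {
    set.seed(s)
    va <- matrix(rnbinom(1000 * 40, mu = 4, size = 2), 1000, 40,
                 dimnames = list(sprintf("g%04d", 1:1000), paste0("a", 1:40)))
    vb <- matrix(rnbinom(1000 * 40, mu = 4, size = 2), 1000, 40,
                 dimnames = list(sprintf("g%04d", 1:1000), paste0("b", 1:40)))
    de <- differential_expression(log1p(va), log1p(vb))
    if (length(upregulated_genes(de, 0.3, 0.05)) == 0L) empties <- empties + 1L
  }
  expect_gte(empties, 9L)
})
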