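mk_expr <- function(values, genes, samples) {
  matrix(values, length(genes), length(samples),
         dimnames = list(genes, samples))
}

test_that("signature_mean averages log2 expression over present genes", {
  expr <- mk_expr(2, paste0("G", 1:5), paste0("S", 1:3))
  sig <- signature_def("test", paste0("G", 1:5))
  expect_equal(unname(signature_mean(expr, sig)), rep(2, 3))
  expr[, 1] <- 1:5
  expect_equal(unname(signature_mean(expr, sig)[1]), 3)
  # absent member gene: mean over the rest, with a warning
  sig2 <- signature_def("test2", c(paste0("G", 1:5), "MISSING"))
  expect_warning(s <- signature_mean(expr, sig2), "MISSING")
  expect_equal(unname(s[1]), 3)
  expect_error(signature_mean(expr, signature_def("none", "ZZZ")), "no")
})

test_that("signature_mean is linear and permutation-equivariant", {
  set.seed(3)
  expr <- mk_expr(rnorm(50), paste0("G", 1:10), paste0("S", 1:5))
  sig <- signature_def("s", paste0("G", c(2, 5, 7)))
  expect_equal(signature_mean(2 * expr + 1, sig),
               2 * signature_mean(expr, sig) + 1)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(signature_mean(expr[, perm], sig),
               signature_mean(expr, sig)[perm])
})

test_that("select_top_hla2 picks the k most expressed HLA-II genes", {
  genes <- c(hla2_gene_universe(), "OTHER")
  expr <- mk_expr(1, genes, paste0("S", 1:4))
  fixed <- hla2_signature_default()$genes
  expr[fixed, ] <- 10
  sel <- select_top_hla2(expr)
  expect_setequal(sel$genes, fixed)
  # k = 1 with one clear maximum
  expr2 <- mk_expr(1, genes, paste0("S", 1:4))
  expr2["HLA-DQB1", ] <- 5
  expect_equal(select_top_hla2(expr2, k = 1)$genes, "HLA-DQB1")
  # tie at rank k: lexicographically smaller symbol kept
  expr3 <- mk_expr(0, genes, paste0("S", 1:4))
  expr3[c("HLA-DRA", "HLA-DRB1", "HLA-DRB5", "HLA-DQA1"), ] <- 5
  expr3[c("HLA-DPA1", "HLA-DPB1"), ] <- 3  # tied at rank 5
  expect_true("HLA-DPA1" %in% select_top_hla2(expr3, k = 5)$genes)
  expect_false("HLA-DPB1" %in% select_top_hla2(expr3, k = 5)$genes)
  expect_error(select_top_hla2(expr[1:3, ]), "at least")
})

test_that("quantile stratification is rank-based with ties to the lower bin", {
  expect_equal(unname(quantile_stratify(1:8, q = 4)), rep(1:4, each = 2))
  expect_equal(unname(quantile_stratify(rep(5, 6), q = 4)), rep(1L, 6))
  expect_equal(unname(quantile_stratify(1:4, q = 2)), c(1L, 1L, 2L, 2L))
  expect_error(quantile_stratify(1:8, q = 1), "at least 2")
  expect_error(quantile_stratify(1:3, q = 4), "at least")
  # bin sizes differ by at most 1 when there are no ties
  set.seed(9)
  for (rep in 1:10) {
    n <- sample(8:40, 1)
    bins <- quantile_stratify(runif(n), q = 4)
    expect_lte(diff(range(table(bins))), 1)
  }
})

test_that("z-score pathway scores are centered, sensitive and degenerate-safe", {
  set.seed(21)
  expr <- mk_expr(rnorm(60, 5), paste0("G", 1:10), paste0("S", 1:6))
  sig <- signature_def("all", paste0("G", 1:10))
  expect_equal(sum(zscore_pathway_score(expr, sig)), 0, tolerance = 1e-10)
  # one sample shifted +3 SD on every member gene ranks top
  shifted <- expr
  shifted[, 2] <- shifted[, 2] + 3 * apply(expr, 1, sd)
  expect_equal(which.max(zscore_pathway_score(shifted, sig)), c(S2 = 2L))
  # constant matrix: all scores 0
  const <- mk_expr(4, paste0("G", 1:10), paste0("S", 1:6))
  expect_equal(as.vector(zscore_pathway_score(const, sig)), rep(0, 6))
  expect_equal(attr(zscore_pathway_score(expr, sig), "provenance"),
               "zscore_mean")
  expect_error(zscore_pathway_score(expr[, 1, drop = FALSE], sig), "2 samples")
})

test_that("marker immune scores behave as per-set means with a summed total", {
  sets <- immune_marker_sets()[1:3]
  genes <- unique(unlist(lapply(sets, function(s) s$genes)))
  set.seed(5)
  expr <- mk_expr(rnorm(length(genes) * 4, 5), genes, paste0("S", 1:4))
  res <- marker_immune_scores(expr, sets)
  expect_equal(res$scores["T_cells", ], signature_mean(expr, sets$T_cells))
  expect_equal(res$total, colSums(res$scores))
  # doubling one set's expression raises only that set's score
  expr2 <- expr
  expr2[sets$CD8_T_cells$genes, ] <- 2 * expr2[sets$CD8_T_cells$genes, ]
  res2 <- marker_immune_scores(expr2, sets)
  expect_true(all(res2$scores["CD8_T_cells", ] > res$scores["CD8_T_cells", ]))
  expect_equal(res2$scores["T_cells", ], res$scores["T_cells", ])
})

test_that("tissue admixture raises the total immune score", {
  spec0 <- cohort_spec(n_samples = 20, admixture_range = c(0, 0),
                       noise_sd = 0.3, seed = 31)
  spec5 <- cohort_spec(n_samples = 20, admixture_range = c(0.5, 0.5),
                       noise_sd = 0.3, seed = 31)
  t0 <- suppressWarnings(marker_immune_scores(generate_cohort(spec0)$tissue_expr))
  t5 <- suppressWarnings(marker_immune_scores(generate_cohort(spec5)$tissue_expr))
  expect_gt(mean(t5$total), mean(t0$total))
})

test_that("GMT files round-trip signature definitions", {
  path <- withr::local_tempfile(fileext = ".gmt")
  sigs <- functional_category_sets()
  write_gmt(sigs, path)
  back <- read_gmt(path)
  expect_equal(names(back), names(sigs))
  for (nm in names(sigs)) {
    expect_equal(back[[nm]]$genes, sigs[[nm]]$genes)
    expect_equal(back[[nm]]$category, sigs[[nm]]$category)
  }
})
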