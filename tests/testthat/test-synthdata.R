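test_that("cohort specs validate their invariants", {
  expect_error(cohort_spec(hla2_group_props = c(0.5, 0.6, 0.1)), "summing to 1")
  expect_error(cohort_spec(tim_class_props = c(0.5, 0.6, -0.1)), "proportions")
  expect_error(cohort_spec(n_samples = 2), "latent groups")
  expect_error(cohort_spec(hla2_group_means = c(4, 4, 8)), "increasing")
  expect_error(cohort_spec(admixture_range = c(-0.1, 0.5)), "within")
  expect_error(cohort_spec(survival_hr_caiip = 0), "> 0")
})

test_that("generation is deterministic given the seed", {
  spec <- cohort_spec(n_samples = 12, seed = 99)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_spec(n_samples = 12, seed = 100))
  expect_false(identical(c1$organoid_expr, c3$organoid_expr))
})

test_that("zero admixture and zero noise make tissue a copy of the organoid", {
  spec <- cohort_spec(n_samples = 10, admixture_range = c(0, 0),
                      noise_sd = 0, seed = 4)
  cohort <- generate_cohort(spec)
  expect_equal(cohort$tissue_expr, cohort$organoid_expr)
  # per-gene organoid-vs-tissue correlation is 1 for every varying gene
  varying <- apply(cohort$organoid_expr, 1, sd) > 0
  rho <- vapply(which(varying), function(g)
    cor(cohort$organoid_expr[g, ], cohort$tissue_expr[g, ]), numeric(1))
  expect_true(all(abs(rho - 1) < 1e-12))
})

test_that("matrices share dimnames and truth covers every sample", {
  cohort <- default_cohort()
  expect_identical(dimnames(cohort$organoid_expr),
                   dimnames(cohort$tissue_expr))
  expect_setequal(cohort$truth$sample_id, colnames(cohort$organoid_expr))
  expect_setequal(cohort$metadata$sample_id, colnames(cohort$organoid_expr))
  expect_true(all(cohort$variants$sample_id %in% cohort$truth$sample_id))
  expect_true(all(cohort$variants$vaf >= 0 & cohort$variants$vaf <= 1))
  expect_true(all(cohort$metadata$time_os > 0))
})

test_that("higher admixture lowers the organoid-tissue expression correlation", {
  spec <- cohort_spec(n_samples = 90, admixture_range = c(0.05, 0.95),
                      seed = 55)
  cohort <- generate_cohort(spec)
  per_sample_rho <- vapply(seq_len(90), function(i)
    cor(cohort$organoid_expr[, i], cohort$tissue_expr[, i],
        method = "spearman"), numeric(1))
  # across >= 50 samples spanning the admixture range, correlation falls
  # with the latent admixture fraction
  expect_lt(cor(cohort$truth$admixture, per_sample_rho), -0.8)
})

test_that("VAFs show a separable biallelic mode at the specified rate", {
  cohort <- generate_cohort(cohort_spec(n_samples = 90, biallelic_prob = 0.25,
                                        seed = 13))
  vaf <- cohort$variants$vaf
  frac_high <- mean(vaf > 0.8)
  expect_gt(frac_high, 0.15)
  expect_lt(frac_high, 0.35)
  expect_lt(mean(vaf > 0.6 & vaf < 0.8), 0.1)  # trough between the modes
})

test_that("a cohort round-trips losslessly through its TSV directory", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_spec(n_samples = 8, seed = 3))
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(back$organoid_expr, cohort$organoid_expr)
  expect_identical(back$tissue_expr, cohort$tissue_expr)
  for (nm in c("variants", "segments", "fusions", "metadata", "truth"))
    expect_equal(back[[nm]], cohort[[nm]], ignore_attr = TRUE)
  expect_equal(back$msi_loci, cohort$msi_loci, ignore_attr = TRUE)
})

test_that("writing degenerate cohorts yields valid headers-only files", {
  dir <- withr::local_tempdir()
  cohort <- generate_cohort(cohort_spec(n_samples = 3, seed = 3))
  empty <- cohort
  empty$organoid_expr <- cohort$organoid_expr[, 0, drop = FALSE]
  empty$tissue_expr <- cohort$tissue_expr[, 0, drop = FALSE]
  for (nm in c("variants", "segments", "fusions", "msi_loci", "metadata",
               "truth"))
    empty[[nm]] <- cohort[[nm]][0, , drop = FALSE]
  write_cohort(empty, dir)
  m <- read_expression(file.path(dir, "organoid_expression.tsv"))
  expect_equal(ncol(m), 0L)
  md <- read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(md), 0L)
  expect_true(all(c("sample_id", "time_os", "event_os") %in% names(md)))
  # a 3-sample cohort produces 3 sample columns / metadata rows
  dir3 <- withr::local_tempdir()
  write_cohort(cohort, dir3)
  expect_equal(ncol(read_expression(file.path(dir3, "organoid_expression.tsv"))), 3L)
  expect_equal(nrow(read.delim(file.path(dir3, "metadata.tsv"))), 3L)
})

test_that("dialect readers tolerate MAF, SEG and STAR-Fusion headers", {
  dir <- withr::local_tempdir()
  maf <- file.path(dir, "calls.maf")
  writeLines(c(paste("Tumor_Sample_Barcode", "Hugo_Symbol", "HGVSp_Short",
                     "Variant_Classification", "t_vaf", "t_depth", sep = "\t"),
               paste("S1", "TP53", "p.R175H", "missense", "0.95", "400",
                     sep = "\t")), maf)
  v <- read_variants(maf)
  expect_equal(v$gene, "TP53")
  expect_equal(v$vaf, 0.95)
  seg <- file.path(dir, "cn.seg")
  writeLines(c(paste("ID", "chromosome", "loc.start", "loc.end", "seg.mean",
                     sep = "\t"),
               paste("S1", "7", "0", "1000", "0.8", sep = "\t")), seg)
  s <- read_seg(seg)
  expect_equal(s$log2_ratio, 0.8)
  fus <- file.path(dir, "fusions.tsv")
  writeLines(c(paste("sample_id", "#FusionName", "JunctionReadCount",
                     "SpanningFragCount", "FFPM", sep = "\t"),
               paste("S1", "BCR--ABL1", "4", "12", "0.6", sep = "\t")), fus)
  f <- read_fusions(fus)
  expect_equal(f$gene1, "BCR")
  expect_equal(f$gene2, "ABL1")
  expect_equal(f$ffpm, 0.6)
})
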