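test_that("biallelic classification uses a strict VAF boundary and is monotone", {
  expect_true(classify_biallelic(0.95))
  expect_false(classify_biallelic(0.9))  # boundary itself is non-biallelic
  expect_false(classify_biallelic(0.5))
  expect_error(classify_biallelic(1.2), "within")
  expect_error(classify_biallelic(-0.1), "within")
  vafs <- seq(0, 1, by = 0.01)
  flags <- classify_biallelic(vafs)
  expect_false(is.unsorted(flags))  # monotone non-decreasing in VAF
})

test_that("TP53 GOF lookup holds exactly 31 variants and classifies by exact match", {
  tbl <- tp53_gof_table()
  expect_length(tbl, 31L)
  expect_false(anyDuplicated(tbl) > 0)
  expect_equal(classify_tp53_gof(tbl), rep("GOF", 31L))
  expect_equal(classify_tp53_gof("R175H"), "GOF")
  expect_equal(classify_tp53_gof("R282W"), "GOF")
  expect_equal(classify_tp53_gof("R158L"), "NE-GOF")
  # protein-change normalization: p. prefix and case
  expect_equal(classify_tp53_gof(c("p.R175H", "r248w")), c("GOF", "GOF"))
  expect_error(classify_tp53_gof("R175H", gene = "KRAS"), "TP53")
})

test_that("MSI classification follows the five-locus rule", {
  loci <- msi_panel_loci()
  pattern <- function(unstable) setNames(loci %in% unstable, loci)
  expect_equal(classify_msi(pattern(c("BAT-25", "BAT-26"))), "MSI-H")
  expect_equal(classify_msi(pattern(character())), "MSS")
  expect_equal(classify_msi(pattern("D5S346")), "MSI-L")
  expect_error(classify_msi(c(`BAT-25` = TRUE)), "missing")
})

test_that("every one of the 32 locus patterns maps to exactly one status", {
  loci <- msi_panel_loci()
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  colnames(grid) <- loci
  status <- classify_msi(grid)
  # statuses partition the 2^5 patterns into 26 / 5 / 1
  expect_equal(as.vector(table(factor(status, c("MSI-H", "MSI-L", "MSS")))),
               c(26L, 5L, 1L))
  # consistency with the unstable-locus count of each pattern
  counts <- rowSums(grid)
  expect_equal(status, ifelse(counts >= 2, "MSI-H",
                              ifelse(counts == 1, "MSI-L", "MSS")))
})

test_that("mutation frequency counts mutated samples once per gene", {
  cohort <- sprintf("S%d", 1:8)
  v <- data.frame(sample_id = c("S1", "S1", "S2", "S3"),
                  gene = c("KRAS", "KRAS", "KRAS", "TP53"))
  freq <- mutation_frequency(v, cohort)
  expect_equal(unname(freq["KRAS"]), 0.25)  # 2 of 8; duplicate counted once
  expect_equal(unname(freq["TP53"]), 0.125)
  expect_equal(unname(mutation_frequency(v, cohort, genes = "APC")["APC"]), 0)
  all_mut <- data.frame(sample_id = cohort, gene = "APC")
  expect_equal(unname(mutation_frequency(all_mut, cohort)["APC"]), 1.0)
  expect_error(mutation_frequency(v, character()), "empty")
  expect_error(mutation_frequency(v, c("S1", "S2")), "outside")
})

test_that("paired VAF concordance reports overlap and Spearman rho per gene", {
  mk <- function(vafs, n_offset = 0) {
    data.frame(sample_id = sprintf("S%d", seq_along(vafs) + n_offset),
               gene = "KRAS",
               protein_change = sprintf("G%dD", 12 + seq_along(vafs)),
               vaf = vafs)
  }
  a <- mk(c(0.1, 0.2, 0.3, 0.4))
  res <- paired_vaf_concordance(a, a)
  expect_equal(res$shared, 4L)
  expect_equal(res$only_a, 0L)
  expect_equal(res$rho, 1)
  # disjoint call sets: zero overlap, rho missing
  b <- mk(c(0.5, 0.6), n_offset = 10)
  res2 <- paired_vaf_concordance(a, b)
  expect_equal(res2$shared, 0L)
  expect_true(is.na(res2$rho))
  # shared pairs (0.1,0.2),(0.2,0.3),(0.3,0.5),(0.4,0.6): perfectly
  # concordant ranks, rho = 1
  b3 <- a; b3$vaf <- c(0.2, 0.3, 0.5, 0.6)
  expect_equal(paired_vaf_concordance(a, b3)$rho, 1)
  # reversed ranks give rho = -1
  b4 <- a; b4$vaf <- rev(a$vaf)
  expect_equal(paired_vaf_concordance(a, b4)$rho, -1)
})

test_that("annotate_variants derives biallelic and TP53-only GOF flags", {
  v <- data.frame(sample_id = c("S1", "S1", "S2"),
                  gene = c("TP53", "KRAS", "TP53"),
                  protein_change = c("R175H", "G12D", "L130F"),
                  variant_class = "missense",
                  vaf = c(0.95, 0.5, 0.92), depth = 500L)
  av <- annotate_variants(v)
  expect_equal(av$biallelic, c(TRUE, FALSE, TRUE))
  expect_equal(av$gof, c("GOF", NA, "NE-GOF"))
})
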