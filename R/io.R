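# Tabular I/O. Dialects: expression TSV (genes as rows, first column
# `gene`), MAF-like variant TSV (sample_id, gene, protein_change,
# variant_class, vaf, depth), SEG-like TSV (sample_id, chrom, start, end,
# log2_ratio; 0-based half-open), fusion TSV (sample_id, gene1, gene2,
# split_reads, spanning_reads, ffpm; STAR-Fusion '--FusionName' tolerated),
# metadata TSV (sample_id, age, sex, stage, time_os, event_os, time_rfs,
# event_rfs).

# Write a data frame as TSV with doubles rendered at full precision
# (%.17g) so that numeric columns round-trip losslessly.
write_tsv_exact <- function(d, path) {
  d2 <- d
  for (nm in names(d2)) {
    v <- d2[[nm]]
    if (is.double(v)) d2[[nm]] <- sprintf("%.17g", v)
  }
  write.table(d2, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE)
}

#' Read or write an expression matrix TSV
#'
#' Genes as rows; the first column (`gene`) holds symbols, the remaining
#' columns are samples with log2-scale values.
#'
#' @param path File path.
#' @return `read_expression()`: numeric gene-by-sample matrix.
#' @export
read_expression <- function(path) {
  d <- read_tsv(path)
  m <- as.matrix(d[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d[[1]]
  m
}

#' @rdname read_expression
#' @param expr Gene-by-sample numeric matrix.
#' @export
write_expression <- function(expr, path) {
  d <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  write_tsv_exact(d, path)
}

#' Read a MAF-like variant table
#'
#' Accepts the package dialect (`sample_id`, `gene`, `protein_change`,
#' `variant_class`, `vaf`, `depth`) and maps the common MAF column names
#' (`Tumor_Sample_Barcode`, `Hugo_Symbol`, `HGVSp_Short`,
#' `Variant_Classification`) onto it.
#'
#' @param path File path.
#' @return Data frame in the package dialect.
#' @export
read_variants <- function(path) {
  d <- read_tsv(path)
  alias <- c(Tumor_Sample_Barcode = "sample_id", Hugo_Symbol = "gene",
             HGVSp_Short = "protein_change",
             Variant_Classification = "variant_class",
             t_vaf = "vaf", t_depth = "depth")
  for (from in names(alias))
    if (from %in% names(d) && !alias[[from]] %in% names(d))
      names(d)[names(d) == from] <- alias[[from]]
  need <- c("sample_id", "gene", "protein_change", "variant_class", "vaf")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("variant table lacks columns: ", paste(missing, collapse = ", "))
  d
}

#' Read a SEG-like copy-number segment table
#'
#' Columns `sample_id`, `chrom`, `start`, `end`, `log2_ratio`
#' (0-based half-open coordinates); `ID`/`seg.mean`-style SEG headers are
#' mapped onto the dialect.
#'
#' @param path File path.
#' @return Data frame in the package dialect.
#' @export
read_seg <- function(path) {
  d <- read_tsv(path)
  alias <- c(ID = "sample_id", Sample = "sample_id", chromosome = "chrom",
             loc.start = "start", loc.end = "end", seg.mean = "log2_ratio")
  for (from in names(alias))
    if (from %in% names(d) && !alias[[from]] %in% names(d))
      names(d)[names(d) == from] <- alias[[from]]
  need <- c("sample_id", "chrom", "start", "end", "log2_ratio")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("segment table lacks columns: ", paste(missing, collapse = ", "))
  d
}

#' Read a fusion candidate table
#'
#' Columns `sample_id`, `gene1`, `gene2`, `split_reads`, `spanning_reads`,
#' `ffpm`. The STAR-Fusion dialect is tolerated: a `#FusionName` or
#' `FusionName` column of the form `"A--B"` is split into `gene1`/`gene2`,
#' and `JunctionReadCount`/`SpanningFragCount`/`FFPM` are mapped.
#'
#' @param path File path.
#' @return Data frame in the package dialect.
#' @export
read_fusions <- function(path) {
  d <- read_tsv(path)
  alias <- c(`#FusionName` = "FusionName", JunctionReadCount = "split_reads",
             SpanningFragCount = "spanning_reads", FFPM = "ffpm")
  for (from in names(alias))
    if (from %in% names(d) && !alias[[from]] %in% names(d))
      names(d)[names(d) == from] <- alias[[from]]
  if ("FusionName" %in% names(d) && !"gene1" %in% names(d)) {
    parts <- strsplit(as.character(d$FusionName), "--", fixed = TRUE)
    d$gene1 <- vapply(parts, `[`, character(1), 1)
    d$gene2 <- vapply(parts, `[`, character(1), 2)
  }
  need <- c("sample_id", "gene1", "gene2", "split_reads", "spanning_reads",
            "ffpm")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("fusion table lacks columns: ", paste(missing, collapse = ", "))
  d
}

cohort_files <- c(organoid_expr = "organoid_expression.tsv",
                  tissue_expr = "tissue_expression.tsv",
                  variants = "variants.tsv",
                  segments = "segments.tsv",
                  fusions = "fusions.tsv",
                  msi_loci = "msi.tsv",
                  metadata = "metadata.tsv",
                  truth = "truth.tsv")

#' Write or read a synthetic cohort directory
#'
#' `write_cohort()` emits the expression, variant, segment, fusion, MSI,
#' metadata and latent-truth TSVs in the dialects the pipeline readers
#' accept; numeric values are written at full precision so the cohort
#' round-trips losslessly. `read_cohort()` reconstructs the cohort object
#' (the truth file is optional).
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()] (for reading:
#'   any directory written by `write_cohort()`).
#' @param dir Directory path; created if missing.
#' @return `write_cohort()`: the directory, invisibly. `read_cohort()`: a
#'   `synthetic_cohort` list (without `spec`, which is not serialized).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(cohort$organoid_expr, file.path(dir, cohort_files[["organoid_expr"]]))
  write_expression(cohort$tissue_expr, file.path(dir, cohort_files[["tissue_expr"]]))
  for (nm in c("variants", "segments", "fusions", "msi_loci", "metadata"))
    write_tsv_exact(cohort[[nm]], file.path(dir, cohort_files[[nm]]))
  if (!is.null(cohort$truth))
    write_tsv_exact(cohort$truth, file.path(dir, cohort_files[["truth"]]))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  path <- function(nm) file.path(dir, cohort_files[[nm]])
  truth <- if (file.exists(path("truth"))) read_tsv(path("truth")) else NULL
  segments <- read_seg(path("segments"))
  segments$chrom <- as.character(segments$chrom)
  metadata <- read.delim(path("metadata"), sep = "\t", check.names = FALSE,
                         stringsAsFactors = FALSE,
                         colClasses = c(sex = "character"))
  structure(list(
    organoid_expr = read_expression(path("organoid_expr")),
    tissue_expr = read_expression(path("tissue_expr")),
    variants = read_variants(path("variants")),
    segments = segments,
    fusions = read_fusions(path("fusions")),
    msi_loci = read_tsv(path("msi_loci")),
    metadata = metadata,
    truth = truth),
    class = "synthetic_cohort")
}
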