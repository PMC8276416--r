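# Gene-set signature scoring: mean-expression signatures, HLA-II top-gene
# selection, quantile stratification, single-sample z-score pathway scores,
# and marker-mean immune-cell scores.

#' Construct a signature definition
#'
#' @param name Signature name.
#' @param genes Character vector of unique gene symbols.
#' @param category One of `"HLA-I"`, `"HLA-II"`, `"checkpoint_stim"`,
#'   `"checkpoint_inhib"`, `"pathway"`, `"immune_marker"`.
#' @return A `signature_def` object (list with `name`, `category`, `genes`).
#' @export
signature_def <- function(name, genes,
                          category = c("pathway", "HLA-I", "HLA-II",
                                       "checkpoint_stim", "checkpoint_inhib",
                                       "immune_marker")) {
  category <- match.arg(category)
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("signature gene list must be non-empty")
  if (anyDuplicated(genes)) stop("signature gene symbols must be unique")
  structure(list(name = name, category = category, genes = genes),
            class = "signature_def")
}

#' @export
print.signature_def <- function(x, ...) {
  cat(sprintf("<signature_def> %s [%s]: %d genes\n",
              x$name, x$category, length(x$genes)))
  invisible(x)
}

sig_genes <- function(sig) if (inherits(sig, "signature_def")) sig$genes else as.character(sig)

present_genes <- function(expr, sig, what = "signature") {
  genes <- sig_genes(sig)
  present <- intersect(genes, rownames(expr))
  if (length(present) == 0L)
    stop("no ", what, " gene present in the expression matrix")
  missing <- setdiff(genes, present)
  if (length(missing) > 0L)
    warning(sprintf("%d %s gene(s) absent from matrix: %s", length(missing),
                    what, paste(missing, collapse = ", ")))
  present
}

#' Mean-expression signature score
#'
#' Per-sample arithmetic mean of log2 expression over the signature genes
#' present in the matrix. Absent genes are dropped with a warning; an error
#' is raised when none are present.
#'
#' @param expr Gene-by-sample numeric matrix of log2-scale expression
#'   (rownames are gene symbols).
#' @param sig A [signature_def()] or plain character vector of gene symbols.
#' @return Named numeric vector of per-sample scores.
#' @export
signature_mean <- function(expr, sig) {
  present <- present_genes(expr, sig)
  colMeans(expr[present, , drop = FALSE])
}

#' Select the most highly expressed HLA class II genes
#'
#' Ranks candidate HLA-II genes by cohort mean expression in the organoid
#' matrix and keeps the top `k`, breaking ties lexicographically (smaller
#' symbol kept). The study's fixed selection — HLA-DRB1, HLA-DQB1, HLA-DRA,
#' HLA-DRB5, HLA-DPA1 — is available without recomputation via
#' [hla2_signature_default()].
#'
#' @inheritParams signature_mean
#' @param hla2_genes Candidate HLA-II gene symbols.
#' @param k Number of genes to keep; default 5.
#' @return A `signature_def` named `"HLA-II-top"` with the selected genes.
#' @export
select_top_hla2 <- function(expr, hla2_genes = hla2_gene_universe(), k = 5) {
  present <- intersect(hla2_genes, rownames(expr))
  if (length(present) < k)
    stop(sprintf("only %d of %d HLA-II genes present; need at least k = %d",
                 length(present), length(hla2_genes), k))
  means <- rowMeans(expr[present, , drop = FALSE])
  ord <- order(-means, present)  # ties -> lexicographically smaller symbol
  signature_def("HLA-II-top", present[ord][seq_len(k)], category = "HLA-II")
}

#' @rdname select_top_hla2
#' @export
hla2_gene_universe <- function() {
  c("HLA-DRA", "HLA-DRB1", "HLA-DRB5", "HLA-DQA1", "HLA-DQB1",
    "HLA-DPA1", "HLA-DPB1", "CD74", "CIITA")
}

#' @rdname select_top_hla2
#' @export
hla2_signature_default <- function() {
  signature_def("HLA-II-top",
                c("HLA-DRB1", "HLA-DQB1", "HLA-DRA", "HLA-DRB5", "HLA-DPA1"),
                category = "HLA-II")
}

#' Rank-based quantile stratification of per-sample scores
#'
#' Assigns each sample to one of `q` near-equal-size bins by score rank.
#' Bin 1 holds the lowest scores. Tied scores share the minimum rank and are
#' therefore assigned to the lower bin (a fully constant vector is all
#' bin 1).
#'
#' @param scores Numeric vector (names preserved).
#' @param q Number of quantile bins; default 4.
#' @return Integer vector of bin labels in `1..q`.
#' @export
#' @examples
#' quantile_stratify(1:8, q = 4)  # 1 1 2 2 3 3 4 4
quantile_stratify <- function(scores, q = 4) {
  if (q < 2) stop("'q' must be at least 2")
  n <- length(scores)
  if (n < q) stop("need at least q samples")
  r <- rank(scores, ties.method = "min")
  bins <- as.integer(ceiling(r * q / n))
  names(bins) <- names(scores)
  bins
}

#' Single-sample z-score pathway score
#'
#' A monotone single-sample stand-in for gene-set variation scoring: each
#' gene is z-scored across the cohort, and a sample's score is the mean
#' z-score over the signature genes present. Genes with zero cross-sample
#' variance contribute 0. Output carries provenance `"zscore_mean"` so that
#' downstream reports can distinguish it from plain mean expression.
#'
#' @inheritParams signature_mean
#' @return Named numeric vector of per-sample scores with attribute
#'   `provenance = "zscore_mean"`.
#' @export
zscore_pathway_score <- function(expr, sig) {
  if (ncol(expr) < 2) stop("z-score pathway scores need at least 2 samples")
  present <- present_genes(expr, sig)
  m <- expr[present, , drop = FALSE]
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  structure(colMeans(z), provenance = "zscore_mean")
}

#' Marker-mean immune-cell scores and total immune score
#'
#' Applies [signature_mean()] per immune-cell marker set; the total immune
#' score is the sum of the per-population scores, mirroring the use of the
#' summed per-cell-type scores as a bulk infiltration measure.
#'
#' @inheritParams signature_mean
#' @param marker_sets List of [signature_def()] objects (or named list of
#'   gene vectors).
#' @return List with `scores` (population-by-sample matrix, provenance
#'   `"mean_expression"`) and `total` (per-sample summed score).
#' @export
marker_immune_scores <- function(expr, marker_sets = immune_marker_sets()) {
  if (is.null(names(marker_sets)))
    names(marker_sets) <- vapply(marker_sets, function(s) s$name, character(1))
  scores <- t(vapply(marker_sets, function(s) signature_mean(expr, s),
                     numeric(ncol(expr))))
  colnames(scores) <- colnames(expr)
  structure(list(scores = scores, total = colSums(scores)),
            provenance = "mean_expression")
}

#' Read or write gene sets in GMT format
#'
#' GMT is one set per line: name, description, then gene symbols, all
#' tab-separated. The description field stores the signature category when
#' written by `write_gmt()`.
#'
#' @param path File path.
#' @return `read_gmt()`: a named list of `signature_def` objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    cat_tag <- parts[2]
    valid <- c("pathway", "HLA-I", "HLA-II", "checkpoint_stim",
               "checkpoint_inhib", "immune_marker")
    if (!cat_tag %in% valid) cat_tag <- "pathway"
    signature_def(parts[1], unique(parts[-(1:2)]), category = cat_tag)
  })
  setNames(sets, vapply(sets, function(s) s$name, character(1)))
}

#' @rdname read_gmt
#' @param sigs List of `signature_def` objects.
#' @export
write_gmt <- function(sigs, path) {
  lines <- vapply(sigs, function(s) {
    paste(c(s$name, s$category, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
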