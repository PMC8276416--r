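# Variant-level rules: biallelic calling, TP53 gain-of-function lookup,
# five-locus MSI classification, mutation frequencies, paired VAF concordance.

#' The TP53 gain-of-function lookup table
#'
#' Returns the fixed set of 31 TP53 protein changes designated gain-of-function
#' (GOF) on functional-assay evidence (interference with p73, transactivation
#' of genes repressed by wild-type p53, and cooperation with oncogenes in
#' fibroblast transformation). All other TP53 variants are treated as
#' "no evidence of GOF" (NE-GOF).
#'
#' @return Character vector of 31 protein changes in short HGVS form
#'   (no `p.` prefix), e.g. `"R175H"`.
#' @seealso [classify_tp53_gof()]
#' @export
#' @examples
#' length(tp53_gof_table())  # 31
tp53_gof_table <- function() {
  c("S127Y", "P151S", "R156P", "Y163N", "Y163C", "V173L", "R175H", "C176Y",
    "H179R", "H179Q", "L194R", "Y205C", "H214R", "Y220C", "Y234C", "M237I",
    "S241F", "G245C", "G245S", "G245V", "G245D", "R248W", "R248G", "R248Q",
    "R273C", "R273L", "R273H", "R273P", "C275Y", "D281G", "R282W")
}

# Normalize a protein change to the dialect of tp53_gof_table():
# strip a leading "p." (any case) and uppercase. MAF dialects vary.
normalize_protein_change <- function(x) {
  toupper(sub("^[pP]\\.", "", trimws(as.character(x))))
}

#' Classify a variant as biallelic from its variant allele fraction
#'
#' Organoids are pure cancer epithelium, so a variant allele fraction (VAF)
#' strictly greater than the threshold (default 0.9) is taken as evidence
#' that both alleles carry the variant (biallelic mutation or copy-neutral
#' LOH). The boundary value itself is classified non-biallelic.
#'
#' @param vaf Numeric vector of variant allele fractions in `[0, 1]`.
#' @param threshold VAF threshold; default 0.9.
#' @return Logical vector, `TRUE` where `vaf > threshold`.
#' @export
#' @examples
#' classify_biallelic(c(0.5, 0.9, 0.95))  # FALSE FALSE TRUE
classify_biallelic <- function(vaf, threshold = 0.9) {
  vaf <- as.numeric(vaf)
  if (any(!is.finite(vaf)) || any(vaf < 0) || any(vaf > 1))
    stop("'vaf' must be finite and within [0, 1]")
  vaf > threshold
}

#' Classify a TP53 variant as GOF or NE-GOF
#'
#' Exact string match of the normalized protein change against the 31-entry
#' gain-of-function lookup ([tp53_gof_table()]).
#'
#' @param protein_change Character vector of protein changes (with or without
#'   a `p.` prefix).
#' @param gene Optional character vector of gene symbols; all must be
#'   `"TP53"` (the rule is defined for TP53 only).
#' @param table Lookup table of GOF protein changes.
#' @return Character vector with values `"GOF"` or `"NE-GOF"`.
#' @export
#' @examples
#' classify_tp53_gof(c("R175H", "p.R282W", "R158L"))
classify_tp53_gof <- function(protein_change, gene = NULL,
                              table = tp53_gof_table()) {
  if (!is.null(gene) && any(toupper(gene) != "TP53"))
    stop("classify_tp53_gof is defined for TP53 variants only")
  pc <- normalize_protein_change(protein_change)
  ifelse(pc %in% normalize_protein_change(table), "GOF", "NE-GOF")
}

#' Microsatellite instability status from the five-locus PCR panel
#'
#' The panel comprises two mononucleotide repeats (BAT-25, BAT-26) and three
#' dinucleotide repeats (D5S346, D2S123, D17S250). Instability at two or more
#' loci is MSI-high, at exactly one locus MSI-low, at none microsatellite
#' stable.
#'
#' @param locus_unstable Named logical vector (or a data.frame of such rows,
#'   samples in rows) over the five panel loci.
#' @param msi_high_min Minimum unstable-locus count for MSI-H; default 2.
#' @return Character scalar (or vector for a data.frame input) in
#'   `c("MSI-H", "MSI-L", "MSS")`.
#' @export
#' @examples
#' classify_msi(c(`BAT-25` = TRUE, `BAT-26` = TRUE, D5S346 = FALSE,
#'                D2S123 = FALSE, D17S250 = FALSE))
classify_msi <- function(locus_unstable, msi_high_min = 2) {
  loci <- msi_panel_loci()
  if (is.data.frame(locus_unstable) || is.matrix(locus_unstable)) {
    m <- as.data.frame(locus_unstable)
    if (!all(loci %in% colnames(m)))
      stop("missing MSI panel loci: ",
           paste(setdiff(loci, colnames(m)), collapse = ", "))
    return(vapply(seq_len(nrow(m)), function(i) {
      classify_msi(unlist(m[i, loci, drop = TRUE]), msi_high_min)
    }, character(1)))
  }
  if (is.null(names(locus_unstable)) && length(locus_unstable) == 5L)
    names(locus_unstable) <- loci
  if (!all(loci %in% names(locus_unstable)))
    stop("missing MSI panel loci: ",
         paste(setdiff(loci, names(locus_unstable)), collapse = ", "))
  flags <- as.logical(locus_unstable[loci])
  if (any(is.na(flags))) stop("MSI locus flags must be TRUE/FALSE")
  n_unstable <- sum(flags)
  if (n_unstable >= msi_high_min) "MSI-H" else if (n_unstable == 1L) "MSI-L" else "MSS"
}

#' @rdname classify_msi
#' @export
msi_panel_loci <- function() {
  c("BAT-25", "BAT-26", "D5S346", "D2S123", "D17S250")
}

#' Per-gene mutation frequency across a cohort
#'
#' Fraction of cohort samples carrying at least one variant in each gene;
#' multiple variants in one sample count once.
#'
#' @param variants Data frame with at least `sample_id` and `gene` columns.
#' @param samples Character vector of all cohort sample ids (the denominator).
#' @param genes Optional gene universe; defaults to genes seen in `variants`.
#' @return Named numeric vector of fractions in `[0, 1]`, sorted decreasing.
#' @export
mutation_frequency <- function(variants, samples, genes = NULL) {
  samples <- unique(as.character(samples))
  if (length(samples) == 0L) stop("empty cohort")
  stopifnot(all(c("sample_id", "gene") %in% names(variants)))
  if (!all(variants$sample_id %in% samples))
    stop("variants reference samples outside the cohort")
  genes <- genes %||% unique(as.character(variants$gene))
  hits <- unique(variants[, c("sample_id", "gene")])
  counts <- table(factor(hits$gene, levels = genes))
  freq <- setNames(as.numeric(counts) / length(samples), genes)
  sort(freq, decreasing = TRUE)
}

#' Paired variant overlap and per-gene VAF rank concordance
#'
#' Variants are keyed by (sample, gene, protein change). For each gene the
#' function reports how many variants are shared between the two call sets
#' (e.g. organoid DNA vs primary-tumor RNA), how many are private to each,
#' and Spearman's rho over the VAFs of shared variants. Rho is reported as
#' `NA` when fewer than `min_shared` shared variants exist.
#'
#' @param a,b Data frames with columns `sample_id`, `gene`, `protein_change`,
#'   `vaf`.
#' @param min_shared Minimum shared variants for a rho estimate; default 3.
#' @return Data frame with one row per gene: `gene`, `shared`, `only_a`,
#'   `only_b`, `rho`.
#' @export
paired_vaf_concordance <- function(a, b, min_shared = 3) {
  need <- c("sample_id", "gene", "protein_change", "vaf")
  stopifnot(all(need %in% names(a)), all(need %in% names(b)))
  key <- function(d) paste(d$sample_id, d$gene,
                           normalize_protein_change(d$protein_change),
                           sep = "\r")
  a <- a[!duplicated(key(a)), , drop = FALSE]
  b <- b[!duplicated(key(b)), , drop = FALSE]
  ka <- key(a); kb <- key(b)
  genes <- sort(unique(c(as.character(a$gene), as.character(b$gene))))
  out <- lapply(genes, function(g) {
    ia <- a$gene == g; ib <- b$gene == g
    shared_keys <- intersect(ka[ia], kb[ib])
    n_shared <- length(shared_keys)
    rho <- NA_real_
    if (n_shared >= min_shared) {
      va <- a$vaf[ia][match(shared_keys, ka[ia])]
      vb <- b$vaf[ib][match(shared_keys, kb[ib])]
      rho <- suppressWarnings(cor(va, vb, method = "spearman"))
    }
    data.frame(gene = g, shared = n_shared,
               only_a = sum(ia) - n_shared, only_b = sum(ib) - n_shared,
               rho = rho)
  })
  do.call(rbind, out)
}

#' Annotate a variant table with derived biallelic and GOF flags
#'
#' @param variants Data frame with `sample_id`, `gene`, `protein_change`,
#'   `variant_class`, `vaf`, `depth`.
#' @param vaf_biallelic Biallelic VAF threshold; default 0.9.
#' @return The input with added logical `biallelic` and character `gof`
#'   (`"GOF"`/`"NE-GOF"` for TP53, `NA` otherwise) columns.
#' @export
annotate_variants <- function(variants, vaf_biallelic = 0.9) {
  variants$biallelic <- classify_biallelic(variants$vaf, vaf_biallelic)
  variants$gof <- NA_character_
  is_tp53 <- toupper(variants$gene) == "TP53"
  if (any(is_tp53))
    variants$gof[is_tp53] <- classify_tp53_gof(variants$protein_change[is_tp53])
  variants
}
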