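# Unsupervised classification: intrinsic molecular subgroups (k1-k4),
# HLA-II k-means with Ca-IIP calling, and composite template-based TIM
# classification of tissue expression.

scale_rows <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- (m - mu) / ifelse(s > 0, s, 1)
  z[s == 0, ] <- 0
  z
}

run_kmeans <- function(x, k, seed, nstart = 50) {
  with_seed(seed, kmeans(x, centers = k, nstart = nstart, iter.max = 100))
}

#' Intrinsic molecular subgrouping of organoids (k1-k4)
#'
#' K-means over per-sample pathway scores (samples clustered on per-signature
#' standardized scores; fixed seed, multiple restarts) with semantic labels
#' attached by cluster score ranks rather than arbitrary cluster indices:
#' the cluster with the highest mean proliferation score (E2F plus MYC
#' targets) is labelled `k1` (high proliferation), the cluster with the
#' highest mean EMT score is labelled `k4` (mesenchymal), and the remaining
#' clusters fall in the grey zone (`k2`, `k3`, ordered by proliferation
#' score). PCA coordinates of the first two components are returned for
#' plotting.
#'
#' @param pathway_scores Signature-by-sample numeric matrix (e.g. from
#'   [zscore_pathway_score()] over [pathway_sets()]).
#' @param k Number of clusters; default 4.
#' @param seed Integer seed.
#' @param proliferation_sigs Row names averaged for the proliferation rank;
#'   default `c("E2F_TARGETS", "MYC_TARGETS")` (those present are used).
#' @param mesenchymal_sig Row name for the mesenchymal rank; default
#'   `"EMT"`.
#' @param nstart k-means restarts; default 50.
#' @return List of class `subgroup_result`: `subgroup` (per-sample factor
#'   `k1..k4`), `cluster` (raw k-means ids), `pca` (sample-by-2 matrix),
#'   `cluster_means`, `seed`.
#' @export
intrinsic_subgroups <- function(pathway_scores, k = 4, seed = 1,
                                proliferation_sigs = c("E2F_TARGETS", "MYC_TARGETS"),
                                mesenchymal_sig = "EMT", nstart = 50) {
  m <- as.matrix(pathway_scores)
  if (ncol(m) < k) stop("need at least k samples")
  z <- scale_rows(m)
  km <- run_kmeans(t(z), k, seed, nstart)
  if (any(tabulate(km$cluster, k) == 0L)) stop("degenerate empty cluster")
  prolif_rows <- intersect(proliferation_sigs, rownames(m))
  if (length(prolif_rows) == 0L || !mesenchymal_sig %in% rownames(m))
    stop("pathway score matrix lacks the proliferation/EMT anchor signatures")
  prolif <- colMeans(z[prolif_rows, , drop = FALSE])
  emt <- z[mesenchymal_sig, ]
  cl_prolif <- tapply(prolif, km$cluster, mean)
  cl_emt <- tapply(emt, km$cluster, mean)
  id_k1 <- as.integer(names(which.max(cl_prolif)))
  id_k4 <- as.integer(names(which.max(cl_emt)))
  if (id_k1 == id_k4)
    stop("the same cluster maximizes both proliferation and EMT scores; ",
         "subgroup labels are not identifiable")
  rest <- setdiff(sort(unique(km$cluster)), c(id_k1, id_k4))
  rest <- rest[order(-cl_prolif[as.character(rest)])]
  label_map <- setNames(rep(NA_character_, k), as.character(1:k))
  label_map[as.character(id_k1)] <- "k1"
  label_map[as.character(id_k4)] <- paste0("k", k)
  if (length(rest)) label_map[as.character(rest)] <- paste0("k", 1 + seq_along(rest))
  subgroup <- factor(label_map[as.character(km$cluster)],
                     levels = paste0("k", 1:k))
  names(subgroup) <- colnames(m)
  pca <- prcomp(t(z), center = FALSE, scale. = FALSE)$x[, 1:2, drop = FALSE]
  structure(list(subgroup = subgroup, cluster = setNames(km$cluster, colnames(m)),
                 pca = pca,
                 cluster_means = cbind(proliferation = cl_prolif, emt = cl_emt),
                 seed = seed),
            class = "subgroup_result")
}

#' Ca-IIP calling by k-means on HLA class II expression
#'
#' K-means (k = 3, fixed seed, multiple restarts) on per-gene standardized
#' HLA-II expression of the organoid matrix. Clusters are ranked by their
#' mean HLA-II signature (mean expression of the signature genes): the
#' highest is labelled `k2`, the middle `k1`, the lowest `k3`. Samples in
#' `k1` or `k2` form the Higher HLA-II group — cancer cells with intrinsic
#' immunogenic properties (Ca-IIP) — and `k3` the Lower HLA-II group. The
#' binary partition is invariant to k-means cluster-id permutation and to a
#' joint monotone affine rescaling of the HLA-II genes.
#'
#' @param expr Gene-by-sample organoid expression matrix (log2 scale).
#' @param hla2_sig HLA-II signature ([hla2_signature_default()] by default).
#' @param hla2_genes Genes used for clustering; defaults to the HLA-II gene
#'   universe present in the matrix.
#' @param seed Integer seed.
#' @param nstart k-means restarts; default 50.
#' @return List of class `caiip_result`: `hla2_cluster` (factor `k1/k2/k3`),
#'   `group` (factor `Higher HLA-II`/`Lower HLA-II`), `caiip` (logical),
#'   `signature` (per-sample HLA-II signature score), `seed`.
#' @export
caiip_classify <- function(expr, hla2_sig = hla2_signature_default(),
                           hla2_genes = hla2_gene_universe(), seed = 1,
                           nstart = 50) {
  if (ncol(expr) < 3) stop("need at least 3 samples for k = 3 clustering")
  genes <- intersect(hla2_genes, rownames(expr))
  if (length(genes) == 0L) stop("no HLA-II gene present in the matrix")
  m <- expr[genes, , drop = FALSE]
  if (all(apply(m, 1, sd) == 0))
    stop("all-constant HLA-II expression: no cluster structure")
  km <- run_kmeans(t(scale_rows(m)), 3, seed, nstart)
  sig <- signature_mean(expr, hla2_sig)
  cl_sig <- tapply(sig, km$cluster, mean)
  # rank clusters by mean HLA-II signature: lowest -> k3, middle -> k1,
  # highest -> k2 (label semantics follow expression level, not cluster id)
  ord <- order(cl_sig)  # ascending
  label_map <- setNames(c("k3", "k1", "k2"), names(cl_sig)[ord])
  hla2_cluster <- factor(label_map[as.character(km$cluster)],
                         levels = c("k1", "k2", "k3"))
  names(hla2_cluster) <- colnames(expr)
  caiip <- hla2_cluster %in% c("k1", "k2")
  group <- factor(ifelse(caiip, "Higher HLA-II", "Lower HLA-II"),
                  levels = c("Higher HLA-II", "Lower HLA-II"))
  names(group) <- names(caiip) <- colnames(expr)
  structure(list(hla2_cluster = hla2_cluster, group = group, caiip = caiip,
                 signature = sig, seed = seed),
            class = "caiip_result")
}

# Spearman correlation of a sample profile with a binary class-template
# centroid over the union of the two templates' genes.
template_correlation <- function(expr, class_a, class_b) {
  union_genes <- intersect(unique(c(sig_genes(class_a), sig_genes(class_b))),
                           rownames(expr))
  if (length(union_genes) == 0L) stop("empty gene overlap with templates")
  centroid <- function(sig) as.numeric(union_genes %in% sig_genes(sig))
  ca <- centroid(class_a); cb <- centroid(class_b)
  m <- expr[union_genes, , drop = FALSE]
  cor_a <- suppressWarnings(apply(m, 2, cor, y = ca, method = "spearman"))
  cor_b <- suppressWarnings(apply(m, 2, cor, y = cb, method = "spearman"))
  cbind(a = cor_a, b = cor_b)
}

#' Composite TIM classification of primary-tissue expression
#'
#' Two-stage nearest-template assignment on bulk tissue expression. Stage 1
#' assigns each sample to the immunogenic or non-immunogenic class by the
#' higher Spearman correlation of its profile with each class's binary
#' template centroid over the union of template genes (ties go to
#' non-immunogenic with a warning). Stage 2 splits immunogenic samples into
#' normal versus activated stroma the same way (ties to normal stroma).
#' The composite class is: immunogenic + normal stroma = `Active`;
#' immunogenic + activated stroma = `Exhausted`; non-immunogenic = `Desert`.
#'
#' @param tissue_expr Gene-by-sample tissue expression matrix (log2 scale).
#' @param templates Template pairs as returned by [tim_templates()].
#' @return List of class `tim_result`: `tim_class` (factor
#'   `Active/Exhausted/Desert`), `immunogenic` (logical), `stroma` (factor
#'   `normal/activated`, `NA` for non-immunogenic), `similarity` (per-sample
#'   template correlations).
#' @export
tim_classify <- function(tissue_expr, templates = tim_templates()) {
  if (is.null(templates$immune) || is.null(templates$stroma))
    stop("templates must provide 'immune' and 'stroma' pairs")
  imm <- template_correlation(tissue_expr, templates$immune$immunogenic,
                              templates$immune$non_immunogenic)
  ties <- imm[, "a"] == imm[, "b"]
  if (any(ties, na.rm = TRUE))
    warning(sum(ties, na.rm = TRUE),
            " sample(s) equidistant from immune templates; ",
            "assigned non-immunogenic")
  immunogenic <- !is.na(imm[, "a"]) & imm[, "a"] > imm[, "b"]
  stroma <- factor(rep(NA_character_, ncol(tissue_expr)),
                   levels = c("normal", "activated"))
  names(stroma) <- colnames(tissue_expr)
  str_cor <- matrix(NA_real_, ncol(tissue_expr), 2,
                    dimnames = list(colnames(tissue_expr),
                                    c("normal", "activated")))
  if (any(immunogenic)) {
    sc <- template_correlation(tissue_expr[, immunogenic, drop = FALSE],
                               templates$stroma$activated,
                               templates$stroma$normal)
    # ties (including both-NA) default to normal stroma
    stroma[immunogenic] <- ifelse(!is.na(sc[, "a"]) & sc[, "a"] > sc[, "b"],
                                  "activated", "normal")
    str_cor[immunogenic, ] <- sc[, c("b", "a")]
  }
  tim_class <- factor(ifelse(!immunogenic, "Desert",
                      ifelse(stroma == "activated", "Exhausted", "Active")),
                      levels = c("Active", "Exhausted", "Desert"))
  names(tim_class) <- colnames(tissue_expr)
  structure(list(tim_class = tim_class, immunogenic = immunogenic,
                 stroma = stroma,
                 similarity = cbind(immunogenic = imm[, "a"],
                                    non_immunogenic = imm[, "b"], str_cor)),
            class = "tim_result")
}

#' CD8+ T-cell exhaustion score
#'
#' Single-sample z-score-mean of the exhaustion gene set on tissue
#' expression (provenance-tagged stand-in for gene-set variation scoring).
#'
#' @param tissue_expr Gene-by-sample tissue expression matrix.
#' @param exhaustion_sig Exhaustion gene set; default [exhaustion_set()].
#' @return Named per-sample score vector (attribute `provenance`).
#' @export
exhaustion_score <- function(tissue_expr, exhaustion_sig = exhaustion_set()) {
  zscore_pathway_score(tissue_expr, exhaustion_sig)
}
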