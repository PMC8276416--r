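# Default gene lists. The HLA-II list is fixed from the study text; the
# remaining lists are editable placeholders standing in for figure-derived
# and literature-derived memberships (users analysing real data should
# substitute their own GMT files; see the methods vignette).

#' Default immune functional-category signatures
#'
#' Four functional categories of cancer-intrinsic immune-related genes:
#' HLA class I, HLA class II, immune-checkpoint stimulation, and
#' immune-checkpoint inhibition. Scored with [signature_mean()].
#'
#' @return Named list of [signature_def()] objects.
#' @export
functional_category_sets <- function() {
  list(
    `HLA-I` = signature_def("HLA-I",
      c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2", "TAPBP", "NLRC5"),
      category = "HLA-I"),
    `HLA-II` = signature_def("HLA-II", hla2_gene_universe(),
      category = "HLA-II"),
    checkpoint_stim = signature_def("checkpoint_stim",
      c("CD80", "CD86", "CD40", "ICOSLG", "TNFRSF4", "TNFRSF9", "TNFRSF18",
        "CD70"),
      category = "checkpoint_stim"),
    checkpoint_inhib = signature_def("checkpoint_inhib",
      c("CD274", "PDCD1LG2", "IDO1", "CTLA4", "LAG3", "HAVCR2", "BTLA",
        "VTCN1"),
      category = "checkpoint_inhib"))
}

#' Default immune-cell marker sets (marker-mean scoring)
#'
#' Ten immune/stromal cell populations scored by marker-gene means; the sum
#' over populations is the total immune score.
#'
#' @return Named list of [signature_def()] objects.
#' @export
immune_marker_sets <- function() {
  mk <- function(name, genes) signature_def(name, genes, category = "immune_marker")
  list(
    T_cells = mk("T_cells", c("CD3D", "CD3E", "CD2", "CD5")),
    CD8_T_cells = mk("CD8_T_cells", c("CD8A", "CD8B")),
    Cytotoxic_lymphocytes = mk("Cytotoxic_lymphocytes",
                               c("GZMA", "GZMB", "PRF1", "KLRD1")),
    NK_cells = mk("NK_cells", c("NCR1", "KIR2DL3", "NKG7")),
    B_lineage = mk("B_lineage", c("CD19", "MS4A1", "CD79A")),
    Monocytic_lineage = mk("Monocytic_lineage", c("CD14", "CD68", "CSF1R")),
    Myeloid_dendritic = mk("Myeloid_dendritic", c("CD1C", "CLEC10A")),
    Neutrophils = mk("Neutrophils", c("FCGR3B", "CEACAM3", "CSF3R")),
    Endothelial = mk("Endothelial", c("PECAM1", "VWF", "CDH5")),
    Fibroblasts = mk("Fibroblasts", c("COL3A1", "PDGFRB", "DCN")))
}

#' Default TIM class templates
#'
#' Gene templates for the two-stage tumor-immune-microenvironment
#' classification: stage 1 separates immunogenic from non-immunogenic
#' tissue, stage 2 splits the immunogenic class by normal versus activated
#' stroma. Placeholder memberships; replace for real-data use.
#'
#' @return List with `immune` (immunogenic / non_immunogenic pair) and
#'   `stroma` (normal / activated pair), each a list of two
#'   [signature_def()] objects.
#' @export
tim_templates <- function() {
  list(
    immune = list(
      immunogenic = signature_def("immunogenic",
        c("CD8A", "CD3D", "CD3E", "GZMA", "GZMB", "PRF1", "CXCL9", "CXCL10",
          "IFNG", "CCL5"),
        category = "immune_marker"),
      non_immunogenic = signature_def("non_immunogenic",
        c("AXIN2", "LGR5", "ASCL2", "RNF43", "NOTUM", "SOX9", "EPHB2",
          "MYB"),
        category = "pathway")),
    stroma = list(
      normal = signature_def("normal_stroma",
        c("DES", "MYH11", "ACTG2", "CNN1", "SYNPO2", "LMOD1"),
        category = "pathway"),
      activated = signature_def("activated_stroma",
        c("FAP", "ACTA2", "COL1A1", "COL1A2", "TAGLN", "SPARC", "THBS2",
          "INHBA"),
        category = "pathway")))
}

#' Default cancer-pathway signatures for intrinsic subgrouping
#'
#' Hallmark-style pathway gene sets scored per sample with
#' [zscore_pathway_score()]; `E2F_TARGETS` and `MYC_TARGETS` anchor the
#' high-proliferation (k1) label, `EMT` the mesenchymal (k4) label.
#'
#' @return Named list of [signature_def()] objects (category `"pathway"`).
#' @export
pathway_sets <- function() {
  mk <- function(name, genes) signature_def(name, genes, category = "pathway")
  list(
    E2F_TARGETS = mk("E2F_TARGETS",
      c("E2F1", "MCM2", "MCM3", "PCNA", "CCNE1", "CDC6", "RRM2", "TYMS")),
    MYC_TARGETS = mk("MYC_TARGETS",
      c("MYC", "NPM1", "NOLC1", "SRM", "CDK4", "PPRC1")),
    G2M_CHECKPOINT = mk("G2M_CHECKPOINT",
      c("MKI67", "CDK1", "TOP2A", "BIRC5", "AURKA", "PLK1", "BUB1")),
    EMT = mk("EMT",
      c("VIM", "ZEB1", "ZEB2", "SNAI1", "SNAI2", "TWIST1", "CDH2", "FN1")),
    WNT_BETA_CATENIN = mk("WNT_BETA_CATENIN",
      c("AXIN2", "LGR5", "ASCL2", "RNF43", "NOTUM", "TCF7", "LEF1")),
    UNFOLDED_PROTEIN_RESPONSE = mk("UNFOLDED_PROTEIN_RESPONSE",
      c("HSPA5", "XBP1", "ATF4", "DDIT3", "ERN1", "EIF2AK3")),
    INTERFERON_GAMMA_RESPONSE = mk("INTERFERON_GAMMA_RESPONSE",
      c("STAT1", "IRF1", "GBP1", "IDO1", "CXCL9", "CXCL10")))
}

#' Default CD8+ T-cell exhaustion gene set
#'
#' @return A [signature_def()] (category `"pathway"`).
#' @export
exhaustion_set <- function() {
  signature_def("CD8_T_EXHAUSTION",
    c("PDCD1", "LAG3", "HAVCR2", "TIGIT", "TOX", "ENTPD1", "CXCL13",
      "EOMES"),
    category = "pathway")
}
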