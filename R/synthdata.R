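# Synthetic paired organoid/tissue cohort generator. Emulates the latent
# structure the downstream analysis assumes: three HLA-II expression groups
# in the organoids, three tumor-immune-microenvironment (TIM) classes whose
# admixture profiles contaminate the tissue compartment, mutation-TIM
# couplings (APC/KRAS with Desert, FBXW7 with Exhausted), a two-component
# VAF mixture with a biallelic mode, MSI-H concentrated in the Exhausted
# class, and a survival penalty for the low-HLA-II latent group.

#' Specification of a synthetic paired cohort
#'
#' Defaults encode the emulated study conditions: 90 samples, HLA-II latent
#' group means (0, 4, 8) log2 units with noise SD 0.5, TIM class proportions
#' (Active 0.3, Exhausted 0.3, Desert 0.4), tissue immune/stroma admixture
#' fractions drawn from `[0.3, 0.7]`, driver mutation rates APC 0.79,
#' TP53 0.79, KRAS 0.55, FBXW7 0.24, and a hazard ratio of 3 for the
#' low-HLA-II group.
#'
#' @param n_samples,n_genes Cohort dimensions.
#' @param hla2_group_props Proportions of the three latent HLA-II groups
#'   (low, mid, high); must sum to 1.
#' @param hla2_group_means Log2-expression means of the HLA-II gene block per
#'   latent group, strictly increasing.
#' @param tim_class_props Named proportions for Active, Exhausted, Desert.
#' @param intrinsic_group_props Proportions of the four latent intrinsic
#'   subgroups (k1 proliferative, k2/k3 grey zone, k4 mesenchymal).
#' @param admixture_range Interval in `[0, 1]` for the per-sample tissue
#'   immune/stroma admixture fraction.
#' @param mutation_rates Named gene-to-probability map for driver mutations.
#' @param coupling_strengths Data frame (`gene`, `tim_class`, `shift`) of
#'   log-odds shifts applied to a gene's mutation probability in samples of
#'   the given TIM class.
#' @param biallelic_prob Probability a variant's VAF is drawn from the
#'   biallelic (high-VAF) mixture component.
#' @param msi_h_rate,msi_l_rate Marginal rates of MSI-H and MSI-L samples;
#'   MSI-H samples are placed in the Exhausted class.
#' @param survival_hr_caiip Hazard ratio (> 0) for the low-HLA-II latent
#'   group relative to the rest.
#' @param noise_sd Expression noise standard deviation (log2 units).
#' @param seed Integer seed; the full cohort is reproducible from it.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_samples = 90, n_genes = 400,
                        hla2_group_props = c(1, 1, 1) / 3,
                        hla2_group_means = c(0, 4, 8),
                        tim_class_props = c(Active = 0.3, Exhausted = 0.3,
                                            Desert = 0.4),
                        intrinsic_group_props = c(k1 = 0.3, k2 = 0.2,
                                                  k3 = 0.2, k4 = 0.3),
                        admixture_range = c(0.3, 0.7),
                        mutation_rates = c(APC = 0.79, TP53 = 0.79,
                                           KRAS = 0.55, FBXW7 = 0.24),
                        coupling_strengths = data.frame(
                          gene = c("APC", "KRAS", "FBXW7"),
                          tim_class = c("Desert", "Desert", "Exhausted"),
                          shift = c(1.5, 1.5, 1.5)),
                        biallelic_prob = 0.25,
                        msi_h_rate = 0.05, msi_l_rate = 0.05,
                        survival_hr_caiip = 3, noise_sd = 0.5, seed = 1) {
  check_simplex <- function(p, what) {
    # tolerance admits proportions that went through decimal serialization
    if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
      stop(what, " must be non-negative proportions summing to 1")
  }
  check_simplex(hla2_group_props, "hla2_group_props")
  check_simplex(tim_class_props, "tim_class_props")
  check_simplex(intrinsic_group_props, "intrinsic_group_props")
  if (n_samples < 3) stop("n_samples must be at least the number of latent groups")
  if (length(hla2_group_means) != 3 || is.unsorted(hla2_group_means, strictly = TRUE))
    stop("hla2_group_means must be 3 strictly increasing values")
  if (length(admixture_range) != 2 || admixture_range[1] > admixture_range[2] ||
      admixture_range[1] < 0 || admixture_range[2] > 1)
    stop("admixture_range must be an interval within [0, 1]")
  if (survival_hr_caiip <= 0) stop("survival_hr_caiip must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 hla2_group_props = hla2_group_props,
                 hla2_group_means = hla2_group_means,
                 tim_class_props = tim_class_props,
                 intrinsic_group_props = intrinsic_group_props,
                 admixture_range = admixture_range,
                 mutation_rates = mutation_rates,
                 coupling_strengths = coupling_strengths,
                 biallelic_prob = biallelic_prob,
                 msi_h_rate = msi_h_rate, msi_l_rate = msi_l_rate,
                 survival_hr_caiip = survival_hr_caiip,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Gene universe: every default signature/template gene, driver and passenger
# panel genes, padded with filler genes up to n_genes.
passenger_genes <- function() {
  c("BRAF", "PIK3CA", "SMAD4", "TCF7L2", "NF1", "SMARCA4", "KMT2A", "ATRX",
    "POLE", "BRCA2")
}

gene_universe <- function(n_genes) {
  core <- unique(c(
    unlist(lapply(functional_category_sets(), sig_genes)),
    unlist(lapply(immune_marker_sets(), sig_genes)),
    unlist(lapply(pathway_sets(), sig_genes)),
    sig_genes(exhaustion_set()),
    unlist(lapply(unlist(tim_templates(), recursive = FALSE), sig_genes)),
    c("APC", "TP53", "KRAS", "FBXW7"), passenger_genes()))
  if (n_genes < length(core))
    stop("n_genes must be at least ", length(core),
         " to hold the signature gene universe")
  c(core, sprintf("FILLER%04d", seq_len(n_genes - length(core))))
}

aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein_change <- function(n, exclude = character()) {
  repeat {
    pc <- paste0(sample(aa_letters, n, replace = TRUE),
                 sample.int(800, n, replace = TRUE),
                 sample(aa_letters, n, replace = TRUE))
    if (!any(pc %in% exclude)) return(pc)
  }
}

#' Generate a synthetic paired organoid/tissue cohort
#'
#' Draws latent labels (HLA-II group, TIM class, intrinsic subgroup, MSI
#' status), builds the organoid expression matrix from gene-block means plus
#' Gaussian noise, contaminates it with a TIM-class-specific admixture
#' profile at a per-sample fraction to form the tissue matrix, assigns
#' mutations with TIM-coupled log-odds shifts and two-component Beta VAFs
#' (subclonal mode centred ~0.3, biallelic mode centred ~0.95), simulates
#' copy-number segments, fusion candidates (including a cohort-recurrent
#' mis-mapping artifact pair), the five-locus MSI panel, and exponential
#' survival with uniform censoring where the low-HLA-II group's hazard is
#' multiplied by `survival_hr_caiip`. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return A `synthetic_cohort` list: `organoid_expr`, `tissue_expr`
#'   (gene-by-sample matrices sharing dimnames), `variants`, `segments`,
#'   `fusions`, `msi_loci`, `metadata` (clinical + survival columns),
#'   `truth` (latent labels), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_samples
  samples <- sprintf("S%03d", seq_len(n))
  genes <- gene_universe(spec$n_genes)

  ## latent labels
  hla2_group <- sample(1:3, n, replace = TRUE, prob = spec$hla2_group_props)
  tim_class <- sample(names(spec$tim_class_props), n, replace = TRUE,
                      prob = spec$tim_class_props)
  intrinsic <- sample(names(spec$intrinsic_group_props), n, replace = TRUE,
                      prob = spec$intrinsic_group_props)

  ## MSI: MSI-H concentrated in the Exhausted class
  n_msih <- rbinom(1, n, spec$msi_h_rate)
  exh <- which(tim_class == "Exhausted")
  msih_idx <- if (length(exh)) exh[sample.int(length(exh),
                                              min(n_msih, length(exh)))] else integer()
  msi_status <- rep("MSS", n)
  msi_status[msih_idx] <- "MSI-H"
  mss_idx <- which(msi_status == "MSS")
  n_msil <- rbinom(1, length(mss_idx), spec$msi_l_rate)
  if (n_msil > 0) msi_status[sample(mss_idx, n_msil)] <- "MSI-L"
  loci <- msi_panel_loci()
  msi_loci <- matrix(FALSE, n, 5, dimnames = list(samples, loci))
  for (i in seq_len(n)) {
    k <- switch(msi_status[i], `MSI-H` = sample(2:5, 1), `MSI-L` = 1L, 0L)
    if (k > 0) msi_loci[i, sample.int(5, k)] <- TRUE
  }

  ## mutations with TIM-coupled log-odds shifts
  rates <- c(spec$mutation_rates,
             setNames(rep(0.1, length(passenger_genes())), passenger_genes()))
  mut <- matrix(FALSE, n, length(rates),
                dimnames = list(samples, names(rates)))
  for (g in names(rates)) {
    logit <- rep(qlogis(rates[[g]]), n)
    cs <- spec$coupling_strengths
    hit <- cs$gene == g
    for (j in which(hit)) logit[tim_class == cs$tim_class[j]] <- logit[tim_class == cs$tim_class[j]] + cs$shift[j]
    if (g %in% passenger_genes())  # hypermutator phenotype
      logit[msi_status == "MSI-H"] <- qlogis(0.6)
    mut[, g] <- runif(n) < plogis(logit)
  }

  variants <- make_variants(mut, spec)

  ## organoid expression: block means + noise
  base <- runif(length(genes), 3, 7)
  mean_mat <- matrix(base, length(genes), n, dimnames = list(genes, samples))
  hla2 <- intersect(hla2_gene_universe(), genes)
  mean_mat[hla2, ] <- matrix(spec$hla2_group_means[hla2_group],
                             length(hla2), n, byrow = TRUE)
  ps <- pathway_sets()
  prolif_genes <- unique(c(sig_genes(ps$E2F_TARGETS), sig_genes(ps$MYC_TARGETS),
                           sig_genes(ps$G2M_CHECKPOINT)))
  prolif_shift <- c(k1 = 3, k2 = 0.5, k3 = 0, k4 = -1)
  emt_shift <- c(k1 = -1, k2 = 0, k3 = 0.5, k4 = 3)
  mean_mat[prolif_genes, ] <- mean_mat[prolif_genes, ] +
    rep(prolif_shift[intrinsic], each = length(prolif_genes))
  emt_genes <- sig_genes(ps$EMT)
  mean_mat[emt_genes, ] <- mean_mat[emt_genes, ] +
    rep(emt_shift[intrinsic], each = length(emt_genes))
  wnt_genes <- sig_genes(ps$WNT_BETA_CATENIN)
  wnt_on <- mut[, "APC"] | mut[, "KRAS"]
  mean_mat[wnt_genes, ] <- mean_mat[wnt_genes, ] +
    rep(ifelse(wnt_on, 1.5, 0), each = length(wnt_genes))
  upr_genes <- sig_genes(ps$UNFOLDED_PROTEIN_RESPONSE)
  mean_mat[upr_genes, ] <- mean_mat[upr_genes, ] +
    rep(ifelse(mut[, "FBXW7"], 1.5, 0), each = length(upr_genes))
  organoid <- mean_mat + matrix(rnorm(length(mean_mat), 0, spec$noise_sd),
                                nrow(mean_mat))

  ## tissue = (1 - a) * organoid + a * TIM admixture profile + noise
  profiles <- tim_admixture_profiles(genes)
  a <- runif(n, spec$admixture_range[1], spec$admixture_range[2])
  tissue <- organoid
  for (i in seq_len(n))
    tissue[, i] <- (1 - a[i]) * organoid[, i] + a[i] * profiles[, tim_class[i]]
  tissue <- tissue + matrix(rnorm(length(tissue), 0, spec$noise_sd), nrow(tissue))

  segments <- make_segments(samples, msi_status)
  fusions <- make_fusions(samples, genes)

  ## clinical metadata and survival
  age <- pmin(pmax(round(rnorm(n, 64, 10)), 30), 90)
  sex <- sample(c("M", "F"), n, replace = TRUE)
  stage <- sample(c("I", "II", "III", "IV"), n, replace = TRUE,
                  prob = c(0.15, 0.3, 0.35, 0.2))
  low_hla2 <- hla2_group == 1L
  hr_os <- ifelse(low_hla2, spec$survival_hr_caiip, 1)
  surv_os <- sim_survival(n, base_median = 80, hr = hr_os, cens_max = 120)
  hr_rfs <- hr_os * ifelse(intrinsic == "k1", 1.8, 1)
  surv_rfs <- sim_survival(n, base_median = 60, hr = hr_rfs, cens_max = 120)
  metadata <- data.frame(sample_id = samples, age = age, sex = sex,
                         stage = stage,
                         time_os = surv_os$time, event_os = surv_os$event,
                         time_rfs = surv_rfs$time, event_rfs = surv_rfs$event)

  truth <- data.frame(sample_id = samples, hla2_group = hla2_group,
                      tim_class = tim_class, intrinsic_group = intrinsic,
                      msi_status = msi_status, admixture = a)

  structure(list(organoid_expr = organoid, tissue_expr = tissue,
                 variants = variants,
                 segments = segments, fusions = fusions,
                 msi_loci = data.frame(sample_id = samples,
                                       as.data.frame(msi_loci),
                                       check.names = FALSE),
                 metadata = metadata, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

# Shared immune/stroma admixture profile per TIM class: a low epithelial
# baseline with class-defining blocks elevated. One profile per class keeps
# template-based classification well-posed on synthetic data.
tim_admixture_profiles <- function(genes) {
  tpl <- tim_templates()
  prof <- matrix(2, length(genes), 3,
                 dimnames = list(genes, c("Active", "Exhausted", "Desert")))
  elevate <- function(class, sig, value = 8) {
    g <- intersect(sig_genes(sig), genes)
    prof[g, class] <<- value
  }
  markers <- immune_marker_sets()
  lymphoid <- signature_def("lymphoid",
                            unique(unlist(lapply(markers[1:7], sig_genes))))
  stromal <- signature_def("stromal",
                           unique(unlist(lapply(markers[c("Endothelial",
                                                          "Fibroblasts")],
                                                sig_genes))))
  elevate("Active", tpl$immune$immunogenic)
  elevate("Active", tpl$stroma$normal)
  elevate("Active", lymphoid)
  elevate("Exhausted", tpl$immune$immunogenic)
  elevate("Exhausted", tpl$stroma$activated)
  elevate("Exhausted", exhaustion_set())
  elevate("Exhausted", lymphoid)
  elevate("Desert", tpl$immune$non_immunogenic)
  # deserts keep sparse myeloid content and all classes carry vessels and
  # fibroblasts
  elevate("Desert", lymphoid, 4)
  for (cl in c("Active", "Exhausted", "Desert")) elevate(cl, stromal, 6)
  # antigen-presenting cells in the immune infiltrate carry HLA-II
  elevate("Active", signature_def("h2", hla2_gene_universe(), "HLA-II"), 7)
  elevate("Exhausted", signature_def("h2", hla2_gene_universe(), "HLA-II"), 7)
  prof
}

make_variants <- function(mut, spec) {
  gof <- tp53_gof_table()
  idx <- which(mut, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    return(data.frame(sample_id = character(), gene = character(),
                      protein_change = character(), variant_class = character(),
                      vaf = numeric(), depth = integer()))
  nv <- nrow(idx)
  sample_id <- rownames(mut)[idx[, 1]]
  gene <- colnames(mut)[idx[, 2]]
  biallelic_draw <- runif(nv) < spec$biallelic_prob
  vaf <- ifelse(biallelic_draw, rbeta(nv, 38, 2), rbeta(nv, 6, 14))
  vaf <- pmin(pmax(vaf, 0), 1)
  variant_class <- sample(c("missense", "nonsense", "frameshift", "splice",
                            "inframe"),
                          nv, replace = TRUE,
                          prob = c(0.55, 0.15, 0.15, 0.08, 0.07))
  protein_change <- random_protein_change(nv, exclude = gof)
  is_tp53 <- gene == "TP53"
  use_gof <- is_tp53 & runif(nv) < 0.4
  if (any(use_gof))
    protein_change[use_gof] <- sample(gof, sum(use_gof), replace = TRUE)
  variant_class[use_gof] <- "missense"
  depth <- 100L + rpois(nv, 400)
  ord <- order(sample_id, gene)
  data.frame(sample_id = sample_id, gene = gene,
             protein_change = protein_change, variant_class = variant_class,
             vaf = vaf, depth = depth)[ord, , drop = FALSE] |>
    (\(d) {rownames(d) <- NULL; d})()
}

make_segments <- function(samples, msi_status) {
  out <- lapply(seq_along(samples), function(i) {
    sd_i <- if (msi_status[i] == "MSI-H") 0.1 else 0.35
    chroms <- as.character(1:22)
    n_seg <- 2L
    do.call(rbind, lapply(chroms, function(ch) {
      breaks <- sort(c(0, round(runif(n_seg - 1, 2e7, 8e7)), 1e8))
      data.frame(sample_id = samples[i], chrom = ch,
                 start = breaks[-length(breaks)], end = breaks[-1],
                 log2_ratio = round(rnorm(n_seg, 0, sd_i), 4))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

make_fusions <- function(samples, genes) {
  out <- lapply(samples, function(s) {
    k <- rpois(1, 1)
    rows <- if (k > 0) {
      pair <- matrix(sample(genes, 2 * k, replace = FALSE), ncol = 2)
      data.frame(sample_id = s, gene1 = pair[, 1], gene2 = pair[, 2],
                 split_reads = rpois(k, 3), spanning_reads = rpois(k, 12),
                 ffpm = round(rexp(k, 1 / 0.3), 4))
    } else NULL
    # recurrent mis-mapping artifact pair present in ~30% of samples
    if (runif(1) < 0.3) {
      rows <- rbind(rows,
                    data.frame(sample_id = s, gene1 = "FRG1", gene2 = "FRG2",
                               split_reads = 3L, spanning_reads = 8L,
                               ffpm = 0.5))
    }
    rows
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(sample_id = character(), gene1 = character(),
                      gene2 = character(), split_reads = integer(),
                      spanning_reads = integer(), ffpm = numeric())
  rownames(out) <- NULL
  out
}

sim_survival <- function(n, base_median, hr, cens_max) {
  rate <- log(2) / base_median * hr
  t_event <- rexp(n, rate)
  t_cens <- runif(n, cens_max / 5, cens_max)
  time <- pmin(t_event, t_cens)
  data.frame(time = pmax(round(time, 3), 0.001), event = t_event <= t_cens)
}
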