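# Pipeline orchestration: configuration, end-to-end run over a cohort
# (generated or read from a directory), per-sample annotation, association
# scans, and a JSON run manifest.

#' Pipeline configuration
#'
#' Collects every threshold the pipeline uses, at its published default, plus
#' seeds and input/output locations. A configuration round-trips to YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param cohort_dir Directory of cohort TSVs ([write_cohort()] layout), or
#'   `NULL` to generate a cohort from `spec`.
#' @param spec A [cohort_spec()] used when `cohort_dir` is `NULL`.
#' @param vaf_biallelic Biallelic VAF threshold (strict `>`); default 0.9.
#' @param ffpm_min Fusion FFPM threshold (strict `>`); default 0.15.
#' @param cnv_log2 CNV-fraction |log2 ratio| threshold; default 0.4.
#' @param msi_high_min Unstable loci for MSI-H; default 2.
#' @param quantiles HLA-II quantile bins; default 4.
#' @param recurrence_frac Fusion recurrence flag fraction (a stand-in for
#'   manual curation, reported as such); default 0.2.
#' @param kmeans_seed,kmeans_restarts k-means seed and restarts.
#' @param enrichment_B Permutations for enrichment p-values; default 10000.
#' @param enrichment_direction `"enrich_low"` or `"enrich_high"`.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_dir = NULL, spec = NULL,
                            vaf_biallelic = 0.9, ffpm_min = 0.15,
                            cnv_log2 = 0.4, msi_high_min = 2, quantiles = 4,
                            recurrence_frac = 0.2, kmeans_seed = 1,
                            kmeans_restarts = 50, enrichment_B = 10000,
                            enrichment_direction = "enrich_low",
                            out_dir = NULL) {
  if (is.null(cohort_dir) && is.null(spec))
    stop("provide either 'cohort_dir' or a cohort 'spec'")
  structure(list(cohort_dir = cohort_dir, spec = spec,
                 vaf_biallelic = vaf_biallelic, ffpm_min = ffpm_min,
                 cnv_log2 = cnv_log2, msi_high_min = msi_high_min,
                 quantiles = quantiles, recurrence_frac = recurrence_frac,
                 kmeans_seed = kmeans_seed,
                 kmeans_restarts = kmeans_restarts,
                 enrichment_B = enrichment_B,
                 enrichment_direction = enrichment_direction,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  if (!is.null(x$spec)) x$spec <- lapply(unclass(x$spec), function(v) {
    # data frames and named vectors become YAML maps (names survive)
    if (is.data.frame(v) || !is.null(names(v))) as.list(v) else v
  })
  yaml::write_yaml(x, path, precision = 12)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  spec <- NULL
  if (!is.null(x$spec)) {
    s <- x$spec
    if (!is.null(s$coupling_strengths))
      s$coupling_strengths <- as.data.frame(s$coupling_strengths)
    for (nm in c("mutation_rates", "tim_class_props", "intrinsic_group_props"))
      if (!is.null(s[[nm]])) s[[nm]] <- unlist(s[[nm]])
    spec <- do.call(cohort_spec, s)
  }
  args <- x[setdiff(names(x), "spec")]
  do.call(pipeline_config, c(args, list(spec = spec)))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in setdiff(names(x), "spec"))
    cat(sprintf("  %s: %s\n", nm, paste(format(x[[nm]]), collapse = " ")))
  if (!is.null(x$spec))
    cat(sprintf("  spec: synthetic cohort, n = %d, seed = %d\n",
                x$spec$n_samples, x$spec$seed))
  invisible(x)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full immuno-genomic classification pipeline
#'
#' Executes, in order: variant annotation and MSI calling; CNV fraction and
#' fusion filtering; signature scoring (functional categories, HLA-II
#' selection and quantiles, marker immune scores, exhaustion score);
#' unsupervised classification (intrinsic subgroups, Ca-IIP, TIM classes);
#' sample-level enrichment of KRAS-biallelic and TP53-GOF against the
#' cytotoxic-lymphocyte score; and survival association (log-rank for
#' Ca-IIP and the k1 subgroup, multivariate Cox for overall survival).
#' When `config$out_dir` is set, writes `annotation.tsv`,
#' `associations.tsv`, `tests.tsv` and `manifest.json`; rerunning with the
#' same configuration and seeds reproduces these files byte-for-byte.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `annotation` (per-sample table),
#'   `tests` (per-test results table), `associations` (from
#'   [report_associations()]), `enrichment` (full enrichment objects),
#'   `survival`, `manifest`, and intermediate objects (`caiip`, `tim`,
#'   `subgroups`, `fusions`, `mutation_freq`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cohort <- stage("input", {
    if (!is.null(config$cohort_dir)) read_cohort(config$cohort_dir)
    else generate_cohort(config$spec)
  })
  samples <- colnames(cohort$organoid_expr)
  n <- length(samples)

  ## genomics
  variants <- stage("genomics", annotate_variants(cohort$variants,
                                                  config$vaf_biallelic))
  msi <- stage("genomics", {
    m <- cohort$msi_loci
    status <- classify_msi(m[, msi_panel_loci(), drop = FALSE],
                           config$msi_high_min)
    setNames(status, m$sample_id)[samples]
  })
  mut_freq <- stage("genomics", {
    if (nrow(variants)) mutation_frequency(variants, samples) else numeric()
  })

  ## structvar
  cnv <- stage("structvar", {
    f <- cnv_fraction_by_sample(cohort$segments, config$cnv_log2)
    f[samples]
  })
  fusions <- stage("structvar", {
    if (nrow(cohort$fusions))
      flag_recurrent_fusions(cohort$fusions, n_samples = n,
                             recurrence_frac = config$recurrence_frac,
                             ffpm_min = config$ffpm_min)
    else cbind(cohort$fusions, recurrence = integer(), verdict = character())
  })

  ## signatures
  sig <- stage("signatures", {
    cats <- functional_category_sets()
    cat_scores <- t(vapply(cats, function(s)
      suppressWarnings(signature_mean(cohort$organoid_expr, s)), numeric(n)))
    hla2_sig <- select_top_hla2(cohort$organoid_expr)
    hla2_score <- signature_mean(cohort$organoid_expr, hla2_sig)
    immune <- suppressWarnings(marker_immune_scores(cohort$tissue_expr))
    list(cat_scores = cat_scores, hla2_sig = hla2_sig,
         hla2_score = hla2_score,
         hla2_quantile = quantile_stratify(hla2_score, config$quantiles),
         immune = immune,
         cytotoxic = immune$scores["Cytotoxic_lymphocytes", ])
  })

  ## classification
  subgroups <- stage("classify", {
    pw <- pathway_sets()
    pw_scores <- t(vapply(pw, function(s)
      suppressWarnings(zscore_pathway_score(cohort$organoid_expr, s)),
      numeric(n)))
    intrinsic_subgroups(pw_scores, seed = config$kmeans_seed,
                        nstart = config$kmeans_restarts)
  })
  caiip <- stage("classify",
                 caiip_classify(cohort$organoid_expr, sig$hla2_sig,
                                seed = config$kmeans_seed,
                                nstart = config$kmeans_restarts))
  tim <- stage("classify", tim_classify(cohort$tissue_expr))
  exh <- stage("classify", exhaustion_score(cohort$tissue_expr))

  ## enrichment of binary variant events along the cytotoxic score
  enrich <- stage("enrich", {
    member <- function(flag) {
      hit <- unique(variants$sample_id[flag])
      setNames(samples %in% hit, samples)
    }
    events <- list(
      KRAS_biallelic = member(variants$gene == "KRAS" & variants$biallelic),
      TP53_GOF = member(!is.na(variants$gof) & variants$gof == "GOF"))
    lapply(events, function(m) {
      if (sum(m) == 0L || sum(m) == n) return(NULL)
      permutation_pvalue(sig$cytotoxic, m,
                         direction = config$enrichment_direction,
                         B = config$enrichment_B,
                         seed = config$kmeans_seed)
    })
  })

  ## survival
  md <- cohort$metadata[match(samples, cohort$metadata$sample_id), ]
  surv <- stage("survival", {
    lr_caiip <- logrank_test(md$time_os, md$event_os, caiip$group)
    lr_k1 <- logrank_test(md$time_rfs, md$event_rfs,
                          ifelse(subgroups$subgroup == "k1", "k1", "other"))
    covar <- data.frame(
      age = md$age, sex = factor(md$sex),
      late_stage = md$stage %in% c("III", "IV"),
      k1_subgroup = subgroups$subgroup == "k1",
      immunogenic_tim = tim$immunogenic,
      lower_hla2 = caiip$group == "Lower HLA-II")
    cox <- tryCatch(cox_multivariate(md$time_os, md$event_os, covar),
                    error = function(e) conditionMessage(e))
    list(logrank_caiip = lr_caiip, logrank_k1 = lr_k1, cox_os = cox)
  })

  annotation <- data.frame(
    sample_id = samples,
    msi_status = unname(msi),
    cnv_fraction = round(unname(cnv), 6),
    intrinsic_subgroup = as.character(subgroups$subgroup),
    hla2_cluster = as.character(caiip$hla2_cluster),
    caiip_group = as.character(caiip$group),
    hla2_signature = round(unname(sig$hla2_score), 6),
    hla2_quantile = unname(sig$hla2_quantile),
    tim_class = as.character(tim$tim_class),
    exhaustion_score = round(unname(exh), 6),
    total_immune_score = round(unname(sig$immune$total), 6))

  associations <- stage("report", report_associations(annotation, variants))

  tests <- rbind(
    data.frame(test = "enrichment_KRAS_biallelic",
               statistic = enrich$KRAS_biallelic$es_observed %||% NA_real_,
               p_value = enrich$KRAS_biallelic$p_value %||% NA_real_),
    data.frame(test = "enrichment_TP53_GOF",
               statistic = enrich$TP53_GOF$es_observed %||% NA_real_,
               p_value = enrich$TP53_GOF$p_value %||% NA_real_),
    data.frame(test = "logrank_caiip_os",
               statistic = surv$logrank_caiip$statistic,
               p_value = surv$logrank_caiip$p_value),
    data.frame(test = "logrank_k1_rfs",
               statistic = surv$logrank_k1$statistic,
               p_value = surv$logrank_k1$p_value))

  manifest <- list(
    package = "ccotim",
    version = as.character(utils::packageVersion("ccotim")),
    n_samples = n,
    thresholds = config[c("vaf_biallelic", "ffpm_min", "cnv_log2",
                          "msi_high_min", "quantiles", "recurrence_frac",
                          "enrichment_B", "enrichment_direction")],
    recurrence_frac_note = paste("recurrence flag is a stand-in for manual",
                                 "curation of mis-mapping artifacts"),
    seeds = list(kmeans = config$kmeans_seed,
                 cohort = if (!is.null(config$spec)) config$spec$seed),
    kmeans_restarts = config$kmeans_restarts,
    counts = list(variants = nrow(variants),
                  fusions_pass = sum(fusions$verdict == "pass"),
                  fusions_flagged = sum(fusions$verdict == "flagged_recurrent"),
                  msi_h = sum(msi == "MSI-H")))

  result <- structure(list(annotation = annotation, tests = tests,
                           associations = associations, enrichment = enrich,
                           survival = surv, manifest = manifest,
                           caiip = caiip, tim = tim, subgroups = subgroups,
                           fusions = fusions, mutation_freq = mut_freq),
                      class = "pipeline_result")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_exact(annotation, file.path(config$out_dir, "annotation.tsv"))
    write_tsv_exact(associations, file.path(config$out_dir, "associations.tsv"))
    write_tsv_exact(tests, file.path(config$out_dir, "tests.tsv"))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d samples\n", nrow(x$annotation)))
  cat("TIM classes:", paste(names(table(x$annotation$tim_class)),
                            table(x$annotation$tim_class), collapse = ", "), "\n")
  cat("Ca-IIP:", sum(x$annotation$caiip_group == "Higher HLA-II"),
      "Higher /", sum(x$annotation$caiip_group == "Lower HLA-II"), "Lower\n")
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Association scans between mutations and derived labels
#'
#' Per-gene Fisher exact tests of mutation status against the Ca-IIP
#' partition and against the TIM class (2-by-K table), plus a multivariate
#' logistic regression of Exhausted-TIM membership on FBXW7 mutation and
#' hypermutation status (MSI-H). Raw p-values are reported alongside
#' Benjamini-Hochberg adjusted values; degenerate tables (a gene mutated in
#' all or no samples) are flagged non-estimable.
#'
#' @param annotation Per-sample annotation table from [run_pipeline()]
#'   (columns `sample_id`, `caiip_group`, `tim_class`, `msi_status`).
#' @param variants Annotated variant table.
#' @return Data frame with `test`, `gene`, `estimate`, `p_value`, `p_adj`,
#'   `note`.
#' @export
report_associations <- function(annotation, variants) {
  samples <- annotation$sample_id
  genes <- sort(unique(variants$gene))
  mut_mat <- vapply(genes, function(g)
    samples %in% variants$sample_id[variants$gene == g], logical(length(samples)))
  fisher_scan <- function(label, test_name) {
    rows <- lapply(genes, function(g) {
      m <- mut_mat[, g]
      if (all(m) || !any(m))
        return(data.frame(test = test_name, gene = g, estimate = NA_real_,
                          p_value = NA_real_, note = "non-estimable"))
      tab <- table(mutated = m, label = label)
      ft <- fisher.test(tab)
      data.frame(test = test_name, gene = g,
                 estimate = if (!is.null(ft$estimate)) unname(ft$estimate) else NA_real_,
                 p_value = ft$p.value, note = "")
    })
    out <- do.call(rbind, rows)
    out$p_adj <- p.adjust(out$p_value, method = "BH")
    out
  }
  caiip_scan <- fisher_scan(annotation$caiip_group, "mutation_vs_caiip")
  tim_scan <- fisher_scan(annotation$tim_class, "mutation_vs_tim")
  logit <- local({
    exhausted <- annotation$tim_class == "Exhausted"
    fbxw7 <- if ("FBXW7" %in% genes) mut_mat[, "FBXW7"] else rep(FALSE, length(samples))
    hyper <- annotation$msi_status == "MSI-H"
    if (!any(fbxw7) || all(fbxw7) || !any(exhausted) || all(exhausted)) {
      data.frame(test = "exhausted_logistic", gene = c("FBXW7", "hypermutated"),
                 estimate = NA_real_, p_value = NA_real_, note = "non-estimable",
                 p_adj = NA_real_)
    } else {
      dat <- data.frame(exhausted = exhausted, FBXW7 = fbxw7,
                        hypermutated = hyper)
      terms <- if (any(hyper) && !all(hyper)) c("FBXW7", "hypermutated") else "FBXW7"
      fit <- glm(stats::reformulate(terms, "exhausted"), data = dat,
                 family = binomial())
      s <- summary(fit)$coefficients
      keep <- paste0(terms, "TRUE")
      data.frame(test = "exhausted_logistic", gene = terms,
                 estimate = exp(s[keep, "Estimate"]),
                 p_value = s[keep, "Pr(>|z|)"], note = "",
                 p_adj = p.adjust(s[keep, "Pr(>|z|)"], method = "BH"))
    }
  })
  out <- rbind(caiip_scan, tim_scan, logit)
  rownames(out) <- NULL
  out[, c("test", "gene", "estimate", "p_value", "p_adj", "note")]
}
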