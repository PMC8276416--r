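# Copy-number altered fraction and fusion-candidate filtering.

#' Fraction of the segmented exome with altered copy number
#'
#' Ratio of the total length of segments whose log2 copy ratio exceeds
#' `threshold` in absolute value (strictly: `log2 > threshold` or
#' `log2 < -threshold`) to the total length of all provided segments.
#' Coordinates are 0-based half-open, so segment length is `end - start`.
#' The denominator is the segmented region actually supplied; unsegmented
#' genome is ignored.
#'
#' @param segments Data frame with columns `chrom`, `start`, `end`,
#'   `log2_ratio` for a single sample.
#' @param threshold Positive log2-ratio threshold; default 0.4.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' seg <- data.frame(chrom = "1", start = c(0, 30, 40),
#'                   end = c(30, 40, 100),
#'                   log2_ratio = c(0.6, -0.5, 0.1))
#' cnv_fraction(seg)  # (30 + 10) / 100 = 0.4
cnv_fraction <- function(segments, threshold = 0.4) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "log2_ratio") %in% names(segments)))
  if (nrow(segments) == 0L) stop("empty segment list")
  if (!is.numeric(threshold) || threshold <= 0) stop("'threshold' must be > 0")
  len <- as.numeric(segments$end) - as.numeric(segments$start)
  if (any(len <= 0)) stop("segments must satisfy end > start")
  total <- sum(len)
  altered <- segments$log2_ratio > threshold | segments$log2_ratio < -threshold
  sum(len[altered]) / total
}

#' Per-sample CNV fractions for a cohort segment table
#'
#' @param segments Data frame with a `sample_id` column plus the columns of
#'   [cnv_fraction()].
#' @inheritParams cnv_fraction
#' @return Named numeric vector, one fraction per sample.
#' @export
cnv_fraction_by_sample <- function(segments, threshold = 0.4) {
  stopifnot("sample_id" %in% names(segments))
  vapply(split(segments, segments$sample_id), cnv_fraction,
         numeric(1), threshold = threshold)
}

#' Filter a fusion candidate on FFPM and read support
#'
#' A candidate must first exceed the FFPM (fusion fragments per million total
#' reads) threshold, strictly. It must then satisfy an escalating read-support
#' rule: with no split reads at least 20 spanning reads are required; with one
#' split read at least 10; with two or more split reads at least 5. The
#' spanning-read minimum for exactly two split reads is configurable because
#' the escalation between the one-split and many-split tiers admits either
#' reading; the default treats two splits like the many-split tier.
#'
#' @param split_reads,spanning_reads Non-negative integer vectors.
#' @param ffpm Non-negative numeric vector.
#' @param ffpm_min FFPM threshold (strict `>`); default 0.15.
#' @param support_min Named numeric vector giving the minimum spanning reads
#'   for `split0` (no split reads), `split1` (one) and `split2` (two or more).
#' @return Character vector of verdicts: `"pass"`, `"fail_ffpm"`, or
#'   `"fail_support"`.
#' @export
#' @examples
#' filter_fusion(split_reads = c(0, 1, 3), spanning_reads = c(20, 9, 5),
#'               ffpm = 0.5)
filter_fusion <- function(split_reads, spanning_reads, ffpm, ffpm_min = 0.15,
                          support_min = c(split0 = 20, split1 = 10, split2 = 5)) {
  stopifnot(all(split_reads >= 0), all(spanning_reads >= 0), all(ffpm >= 0))
  n <- max(length(split_reads), length(spanning_reads), length(ffpm))
  split_reads <- rep_len(split_reads, n)
  spanning_reads <- rep_len(spanning_reads, n)
  ffpm <- rep_len(ffpm, n)
  need <- ifelse(split_reads == 0, support_min[["split0"]],
          ifelse(split_reads == 1, support_min[["split1"]],
                 support_min[["split2"]]))
  verdict <- ifelse(ffpm <= ffpm_min, "fail_ffpm",
             ifelse(spanning_reads >= need, "pass", "fail_support"))
  verdict
}

#' Flag cohort-recurrent fusion gene pairs for manual review
#'
#' Mis-mapping artifacts tend to produce the same gene pair across many
#' unrelated samples. Pairs present in more than `recurrence_frac` of cohort
#' samples are flagged (verdict `"flagged_recurrent"`) for review; they are
#' not auto-removed, and other candidates keep their filter verdicts. The
#' recurrence cut-off is a stand-in for the study's manual curation and is
#' recorded as such in pipeline output.
#'
#' @param candidates Data frame with `sample_id`, `gene1`, `gene2`,
#'   `split_reads`, `spanning_reads`, `ffpm` (and optionally a precomputed
#'   `verdict` column, otherwise [filter_fusion()] is applied).
#' @param n_samples Cohort size used as denominator; defaults to the number
#'   of distinct sample ids in `candidates`.
#' @param recurrence_frac Fraction of samples above which a pair is flagged
#'   (strict `>`); default 0.2.
#' @inheritParams filter_fusion
#' @return `candidates` with added `recurrence` (sample count per pair) and
#'   `verdict` columns.
#' @export
flag_recurrent_fusions <- function(candidates, n_samples = NULL,
                                   recurrence_frac = 0.2, ffpm_min = 0.15) {
  stopifnot(all(c("sample_id", "gene1", "gene2") %in% names(candidates)))
  if (is.null(candidates$verdict)) {
    candidates$verdict <- filter_fusion(candidates$split_reads,
                                        candidates$spanning_reads,
                                        candidates$ffpm, ffpm_min = ffpm_min)
  }
  n_samples <- n_samples %||% length(unique(candidates$sample_id))
  pair <- paste(pmin(candidates$gene1, candidates$gene2),
                pmax(candidates$gene1, candidates$gene2), sep = "--")
  per_pair <- tapply(candidates$sample_id, pair,
                     function(s) length(unique(s)))
  candidates$recurrence <- as.integer(per_pair[pair])
  flagged <- candidates$recurrence / n_samples > recurrence_frac
  candidates$verdict[flagged] <- "flagged_recurrent"
  candidates
}
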