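# Sample-level Kolmogorov-Smirnov enrichment statistic with permutation
# null: tests whether samples carrying a binary annotation (e.g. KRAS
# biallelic alteration, TP53 GOF mutation) concentrate at one end of a
# continuous per-sample score (e.g. a cytotoxic-lymphocyte score).

# The running sum adds sqrt((N-G)/G) at members and subtracts sqrt(G/(N-G))
# at non-members; the full sum telescopes to 0 and the statistic is the
# maximum prefix sum. Internally the prefix maximum is computed on the
# rescaled integer increments (+(N-G) for members, -G for non-members) and
# divided by sqrt(G*(N-G)) afterwards, which is algebraically identical but
# keeps prefix sums exact, so invariants such as ES >= 0 and permutation
# comparisons are free of float roundoff.
max_prefix_integer <- function(member_ordered, N, G) {
  inc <- ifelse(member_ordered, N - G, -G)
  max(cumsum(inc))
}

es_scale <- function(N, G) 1 / sqrt(G * (N - G))

order_samples <- function(scores, direction, sample_id = NULL) {
  if (any(!is.finite(scores))) stop("scores must be finite")
  sample_id <- sample_id %||% names(scores) %||% as.character(seq_along(scores))
  key <- if (direction == "enrich_low") scores else -scores
  order(key, sample_id)  # stable tie-break by sample id
}

#' Sample-level KS enrichment score
#'
#' Samples are ordered by increasing score (direction `"enrich_low"`; ties
#' broken by sample id for determinism) or decreasing score
#' (`"enrich_high"`). Walking down the ordering, the running sum gains
#' `sqrt((N - G)/G)` at each member and loses `sqrt(G/(N - G))` at each
#' non-member, where `N` is the total sample count and `G` the member count.
#' The enrichment score is the maximum prefix sum; it reaches its ceiling
#' `sqrt(G * (N - G))` when the members occupy the first `G` ranks, and the
#' full sum always telescopes to 0, so the score is non-negative.
#'
#' @param scores Numeric per-sample scores.
#' @param membership Logical per-sample membership flags, aligned with
#'   `scores`.
#' @param direction `"enrich_low"` (default: members expected at low scores)
#'   or `"enrich_high"`.
#' @return The enrichment score (non-negative scalar).
#' @export
#' @examples
#' s <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
#' enrichment_score(s, c(TRUE, TRUE, FALSE, FALSE, FALSE))  # sqrt(6)
enrichment_score <- function(scores, membership,
                             direction = c("enrich_low", "enrich_high")) {
  direction <- match.arg(direction)
  membership <- as.logical(membership)
  stopifnot(length(scores) == length(membership), !anyNA(membership))
  N <- length(scores)
  G <- sum(membership)
  if (G == 0L || G == N)
    stop("membership must be a strict subset: 0 < G < N")
  ord <- order_samples(scores, direction)
  max_prefix_integer(membership[ord], N, G) * es_scale(N, G)
}

#' Permutation p-value for the enrichment score
#'
#' The membership labels are permuted `B` times (preserving the member count
#' `G`); each permutation's maximum enrichment score forms the null
#' distribution, and the p-value is the plain fraction of permutations whose
#' score is at least the observed one:
#' `p = B^-1 * sum_b I(ES_obs <= ES_b)`. The observed score is not added to
#' numerator or denominator (set `add_one = TRUE` for the `(r+1)/(B+1)`
#' variant, off by default).
#'
#' @inheritParams enrichment_score
#' @param B Number of permutations; default 10000.
#' @param seed Integer seed for reproducibility.
#' @param add_one Use the add-one permutation estimator; default `FALSE`.
#' @return An object of class `enrichment_result`: list with `es_observed`,
#'   `null_es` (length `B`), `p_value`, `B`, `seed`, `N`, `G`, `direction`.
#' @export
permutation_pvalue <- function(scores, membership,
                               direction = c("enrich_low", "enrich_high"),
                               B = 10000, seed = 1, add_one = FALSE) {
  direction <- match.arg(direction)
  if (!is.numeric(B) || B < 1) stop("'B' must be a positive integer")
  B <- as.integer(B)
  membership <- as.logical(membership)
  N <- length(scores)
  G <- sum(membership)
  ord <- order_samples(scores, direction)
  m0 <- max_prefix_integer(membership[ord], N, G)
  null_m <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(N, G)  # member positions within the fixed ordering
      inc <- rep(-G, N)
      inc[idx] <- N - G
      max(cumsum(inc))
    }, numeric(1))
  })
  es0 <- m0 * es_scale(N, G)
  null_es <- null_m * es_scale(N, G)
  # indicator evaluated on the exact integer statistics
  p <- if (add_one) (sum(m0 <= null_m) + 1) / (B + 1) else mean(m0 <= null_m)
  structure(list(es_observed = es0, null_es = null_es, p_value = p, B = B,
                 seed = seed, N = N, G = G, direction = direction),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Sample-level KS enrichment: ES = %.4f (N = %d, G = %d, %s)\n",
              x$es_observed, x$N, x$G, x$direction))
  cat(sprintf("Permutation p = %.4g (B = %d, seed = %d)\n",
              x$p_value, x$B, x$seed))
  invisible(x)
}

#' Exact enumeration p-value for the enrichment score
#'
#' Enumerates all `choose(N, G)` placements of the `G` member labels along
#' the score ordering and applies the same indicator as the permutation
#' p-value. Intended as a small-`N` oracle for [permutation_pvalue()].
#'
#' @inheritParams enrichment_score
#' @param max_comb Refuse enumeration beyond this many placements;
#'   default `1e6`.
#' @return Exact p-value in `[0, 1]`.
#' @export
exact_enumeration_pvalue <- function(scores, membership,
                                     direction = c("enrich_low", "enrich_high"),
                                     max_comb = 1e6) {
  direction <- match.arg(direction)
  membership <- as.logical(membership)
  N <- length(scores)
  G <- sum(membership)
  if (choose(N, G) > max_comb)
    stop("choose(N, G) exceeds the enumeration bound")
  ord <- order_samples(scores, direction)
  m0 <- max_prefix_integer(membership[ord], N, G)
  placements <- combn(N, G)
  m_all <- apply(placements, 2, function(idx) {
    inc <- rep(-G, N)
    inc[idx] <- N - G
    max(cumsum(inc))
  })
  mean(m0 <= m_all)
}
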