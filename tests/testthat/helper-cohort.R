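# Shared fixtures and independent oracles, built in code at test time.

# Loop-based prefix-sum oracle for the sample-level KS enrichment score,
# independent of the vectorized implementation path.
es_oracle <- function(scores, member, direction = "enrich_low") {
  ids <- names(scores)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  key <- if (direction == "enrich_low") scores else -scores
  ord <- order(key, ids)
  N <- length(scores)
  G <- sum(member)
  run <- 0
  best <- -Inf
  for (j in ord) {
    run <- run + (if (member[j]) sqrt((N - G) / G) else -sqrt(G / (N - G)))
    if (run > best) best <- run
  }
  best
}

# Memoized default synthetic cohort shared across test files.
default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(cohort_spec(seed = 42))
    cache
  }
})

# Memoized pipeline result on the default cohort (small B for speed).
default_pipeline <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- pipeline_config(spec = cohort_spec(seed = 42),
                             enrichment_B = 200)
      cache <<- run_pipeline(cfg)
    }
    cache
  }
})

# Canonical agreement between recovered HLA-II clusters and latent groups:
# k3 is the low-expression cluster (latent group 1), k1 mid (group 2),
# k2 high (group 3).
hla2_agreement <- function(caiip_result, truth) {
  map <- c(k3 = 1L, k1 = 2L, k2 = 3L)
  mean(map[as.character(caiip_result$hla2_cluster)] == truth$hla2_group)
}
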