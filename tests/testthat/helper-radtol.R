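## Shared fixture builders for the radtol test suite. Everything is built in
## code; no binary fixtures.

PLANTED <- c("PF90001", "PF90002", "PF90003", "PF90004")

## Annotation set from a named count vector, one protein per 5 instances.
aset_from_counts <- function(genome_id, counts) {
  instances <- rep(names(counts), counts)
  n_prot <- max(1L, ceiling(length(instances) / 5L))
  records <- split(instances,
                   rep(seq_len(n_prot), each = 5L)[seq_along(instances)])
  names(records) <- sprintf("%s_p%03d", genome_id, seq_along(records))
  pfam_annotation_set(genome_id, records)
}

## A tiny strongly separated two-class cohort for classifier-level tests:
## cached per session because several test files need it and training
## cohorts are deterministic anyway.
separated_cohort <- local({
  cache <- NULL
  function(seed = 42L) {
    if (is.null(cache)) {
      cache <<- generate_cohort(default_cohort_spec(n_per_class = 20L,
                                                    seed = seed))
    }
    cache
  }
})

separated_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- separated_cohort()
      tab <- build_frequency_table(co$sets, domains = PLANTED)
      cache <<- train_model(tab, co$classes, seed = 99L)
    }
    cache
  }
})

## Seed-free access to the core subsampler (the exported degrade() reseeds;
## distributional tests need consecutive draws from one stream).
.degrade_instances_for_test <- function(aset, fraction) {
  radtol:::.degrade_instances(aset, fraction)
}

## Random multiset of domain counts for oracle tests.
random_counts <- function(n_domains, max_count = 20L) {
  ids <- sprintf("PF%05d", sample.int(99999L, n_domains))
  stats::setNames(sample.int(max_count, n_domains, replace = TRUE), ids)
}

## Independent brute-force frequency oracle: tallies the flattened instance
## list one element at a time, never touching domain_counts().
brute_force_frequencies <- function(aset) {
  flat <- character(0)
  for (rec in aset$records) for (d in rec) flat <- c(flat, d)
  out <- numeric(0)
  for (d in unique(flat)) {
    out[d] <- sum(flat == d) / length(flat)
  }
  out[order(names(out))]
}
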