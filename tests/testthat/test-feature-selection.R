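test_that("universality filter is the cohort-wide intersection", {
  a <- aset_from_counts("gA", c(PF00001 = 2L, PF00002 = 1L))
  b <- aset_from_counts("gB", c(PF00001 = 3L))
  expect_equal(filter_universal(list(a, b)), "PF00001")
  expect_equal(filter_universal(list(a)), c("PF00001", "PF00002"))

  ## brute-force oracle on random cohorts; adding genomes can only shrink it
  with_seed(4, {
    for (i in 1:20) {
      sets <- lapply(1:4, function(g)
        aset_from_counts(paste0("g", g), random_counts(sample(3:12, 1))))
      oracle <- Reduce(intersect,
                       lapply(sets, function(s) names(domain_counts(s))))
      expect_setequal(filter_universal(sets), oracle)
      extra <- aset_from_counts("g_extra", random_counts(5))
      expect_true(all(filter_universal(c(sets, list(extra))) %in%
                        filter_universal(sets)))
    }
  })
})

test_that("abundance filter uses a strict mean-count threshold", {
  sets <- lapply(1:3, function(g)
    aset_from_counts(paste0("g", g), c(PF00001 = 2L, PF00002 = 3L)))
  expect_equal(filter_abundant(sets, c("PF00001", "PF00002")), "PF00002")

  ## brute-force oracle
  with_seed(6, {
    for (i in 1:20) {
      sets <- lapply(1:5, function(g)
        aset_from_counts(paste0("g", g),
                         stats::setNames(sample.int(6, 4, replace = TRUE),
                                         sprintf("PF%05d", 1:4))))
      domains <- sprintf("PF%05d", 1:4)
      means <- vapply(domains, function(d) {
        mean(vapply(sets, function(s) {
          ct <- domain_counts(s)
          if (d %in% names(ct)) as.numeric(ct[[d]]) else 0
        }, numeric(1)))
      }, numeric(1))
      expect_setequal(filter_abundant(sets, domains), domains[means > 2])
    }
  })
})

test_that("Boruta confirms a strongly separated planted feature", {
  hits <- vapply(1:20, function(s) {
    spec <- cohort_spec(
      n_per_class = 20L,
      informative_domains = data.frame(
        domain_id = "PF90001", mean_radiosensitive = 0.08,
        mean_tolerant = 0.02, sd = 0.005),
      n_noise_domains = 20L, total_instances_range = c(1000L, 2000L),
      seed = s
    )
    co <- generate_cohort(spec)
    tab <- build_frequency_table(co$sets)
    keep <- c("PF90001", grep("^PF95", tab$domain_ids, value = TRUE))
    X <- restrict_frequency_table(tab, keep)
    br <- boruta_select(X, co$classes, max_runs = 100L, seed = s + 500L,
                        ntree = 100L)
    "PF90001" %in% br$confirmed
  }, logical(1))
  expect_gte(sum(hits), 19L)
})

test_that("Boruta controls confirmations under a pure-noise null", {
  n_confirmed <- vapply(1:20, function(s) {
    spec <- cohort_spec(
      n_per_class = 20L,
      informative_domains = data.frame(
        domain_id = "PF90001", mean_radiosensitive = 0.03,
        mean_tolerant = 0.03, sd = 0),   # no class difference: pure noise
      n_noise_domains = 20L, total_instances_range = c(1000L, 2000L),
      seed = s
    )
    co <- generate_cohort(spec)
    tab <- build_frequency_table(co$sets)
    X <- restrict_frequency_table(
      tab, grep("^PF95", tab$domain_ids, value = TRUE))
    br <- boruta_select(X, co$classes, max_runs = 50L, seed = s + 900L,
                       ntree = 100L)
    length(br$confirmed)
  }, integer(1))
  expect_lte(mean(n_confirmed), 1)
})

test_that("Boruta results partition the candidates and handle degenerate input", {
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = c(PLANTED, "PF95001"))
  br <- boruta_select(tab, co$classes, max_runs = 30L, seed = 2L, ntree = 100L)
  expect_setequal(c(br$confirmed, br$rejected, br$tentative), tab$domain_ids)
  expect_length(intersect(br$confirmed, br$rejected), 0)
  expect_lte(br$n_iterations, 30L)

  ## max_runs = 0: everything stays tentative
  br0 <- boruta_select(tab, co$classes, max_runs = 0L, seed = 2L)
  expect_equal(br0$n_iterations, 0L)
  expect_setequal(br0$tentative, tab$domain_ids)

  ## single-class labels and zero-variance features
  expect_error(boruta_select(tab, rep("tolerant", 40)), "at least 2")
  tab2 <- tab
  tab2$values <- cbind(tab$values, PF99999 = 0)
  tab2$raw_counts <- cbind(tab$raw_counts, PF99999 = 0L)
  tab2$domain_ids <- c(tab$domain_ids, "PF99999")
  expect_warning(
    br2 <- boruta_select(tab2, co$classes, max_runs = 10L, seed = 2L,
                         ntree = 100L),
    "zero-variance"
  )
  expect_true("PF99999" %in% br2$rejected)
})

test_that("raising the planted effect never hurts its confirmation rate", {
  rate_at_gap <- function(gap) {
    mean(vapply(1:10, function(s) {
      spec <- cohort_spec(
        n_per_class = 15L,
        informative_domains = data.frame(
          domain_id = "PF90001",
          mean_radiosensitive = 0.03 + gap / 2,
          mean_tolerant = 0.03 - gap / 2, sd = 0.004),
        n_noise_domains = 15L, total_instances_range = c(1000L, 2000L),
        seed = s
      )
      co <- generate_cohort(spec)
      tab <- build_frequency_table(co$sets)
      keep <- c("PF90001", grep("^PF95", tab$domain_ids, value = TRUE))
      br <- boruta_select(restrict_frequency_table(tab, keep), co$classes,
                          max_runs = 60L, seed = s + 300L, ntree = 100L)
      "PF90001" %in% br$confirmed
    }, logical(1)))
  }
  rates <- vapply(c(0.002, 0.012, 0.035), rate_at_gap, numeric(1))
  expect_true(all(diff(rates) >= 0))
})

test_that("stepwise pruning strips noise before signal and audits decisions", {
  ## on strongly separated data the pure-noise features carry the lowest
  ## importance, so they are the removal candidates before any planted
  ## feature, the final set keeps signal, and pruning stops at the first
  ## rejected removal
  res <- lapply(1:20, function(s) {
    spec <- cohort_spec(
      n_per_class = 20L,
      informative_domains = data.frame(
        domain_id = c("PF90001", "PF90002"),
        mean_radiosensitive = c(0.016, 0.004),
        mean_tolerant = c(0.004, 0.016),
        sd = 0.001),
      n_noise_domains = 10L, total_instances_range = c(3000L, 6000L),
      seed = s
    )
    co <- generate_cohort(spec)
    tab <- build_frequency_table(co$sets)
    feats <- c("PF90001", "PF90002", "PF95001", "PF95002", "PF95003")
    pr <- stepwise_prune(restrict_frequency_table(tab, feats), co$classes,
                         feats, cv_folds = 5L, seed = s + 40L, ntree = 150L)
    pr
  })
  for (pr in res) {
    expect_lte(nrow(pr$audit), 4L)               # <= n_features - 1 steps
    expect_gte(length(pr$features), 1L)          # never empty
    ## at most the last audited candidate was rejected (stop-on-first-reject)
    n <- nrow(pr$audit)
    if (n > 1L) expect_true(all(pr$audit$accepted[seq_len(n - 1L)]))
    ## noise candidates come up for removal before any planted feature
    cand <- pr$audit$removed_candidate
    first_planted <- match(TRUE, cand %in% c("PF90001", "PF90002"))
    if (!is.na(first_planted) && first_planted > 1L) {
      expect_true(all(grepl("^PF95", cand[seq_len(first_planted - 1L)])))
    }
    ## retained features always include planted signal
    expect_gte(sum(c("PF90001", "PF90002") %in% pr$features), 1L)
  }
  ## noise features are fully stripped in nearly all cohorts
  noise_free <- vapply(res, function(pr) !any(grepl("^PF95", pr$features)),
                       logical(1))
  expect_gte(sum(noise_free), 18L)
})

test_that("a constant feature is the first pruning candidate (zero importance)", {
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED[1L])
  tab$values <- cbind(tab$values, PF99998 = 0.002)
  tab$raw_counts <- cbind(tab$raw_counts, PF99998 = 2L)
  tab$domain_ids <- c(PLANTED[1L], "PF99998")
  pr <- stepwise_prune(tab, co$classes, tab$domain_ids, cv_folds = 5L,
                       seed = 77L, ntree = 150L)
  expect_equal(pr$audit$removed_candidate[1L], "PF99998")
})

test_that("stepwise pruning rejects infeasible fold counts", {
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED)
  expect_error(
    stepwise_prune(tab, co$classes, PLANTED, cv_folds = 25L, seed = 1L),
    "fewer folds"
  )
})
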