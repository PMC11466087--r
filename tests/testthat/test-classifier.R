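test_that("training on the separated cohort is accurate and deterministic", {
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED)
  m1 <- separated_model()
  expect_gte(m1$cv_accuracy, 0.95)
  expect_true(m1$mtry >= 1 && m1$mtry <= length(PLANTED))

  m2 <- train_model(tab, co$classes, seed = 99L)
  expect_equal(m1$cv_accuracy, m2$cv_accuracy)
  r1 <- predict(m1, tab)
  r2 <- predict(m2, tab)
  expect_identical(r1, r2)
})

test_that("training validates classes and fold counts", {
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED)
  expect_error(train_model(tab, rep("tolerant", 40), seed = 1),
               "both classes")
  expect_error(train_model(tab, co$classes, cv_folds = 25L, seed = 1),
               "fewer folds")
})

test_that("label-permuted nulls give chance-level CV accuracy", {
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED)
  null_accs <- vapply(1:20, function(s) {
    y_perm <- with_seed(s, sample(co$classes))
    train_model(tab, y_perm, cv_folds = 5L, n_trees = 200L,
                seed = s)$cv_accuracy
  }, numeric(1))
  expect_gte(mean(null_accs), 0.35)
  expect_lte(mean(null_accs), 0.65)
})

test_that("prediction reports votes, missing predictors and exclusions", {
  m <- separated_model()
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED)
  report <- predict(m, tab)
  expect_equal(nrow(report), 40L)
  expect_true(all(!report$excluded))
  expect_true(all(report$vote_fraction >= 0 & report$vote_fraction <= 1))
  ## a training radiosensitive exemplar classifies radiosensitive
  rs_row <- report[report$genome_id == "RS001", ]
  expect_equal(rs_row$predicted_class, "radiosensitive")
  expect_gt(rs_row$vote_fraction, 0.5)
  ## accuracy on the training cohort itself is near-perfect
  expect_gte(mean(report$predicted_class ==
                    co$classes[report$genome_id]), 0.95)
})

test_that("exclusion rule: >= 2 zero predictors excluded, exactly 1 classified", {
  m <- separated_model()
  g_all_zero <- aset_from_counts("zero4", c(PF95001 = 10L))
  g_one_zero <- aset_from_counts("zero1", c(PF90001 = 5L, PF90002 = 5L,
                                            PF90003 = 5L, PF95001 = 5L))
  g_two_zero <- aset_from_counts("zero2", c(PF90001 = 5L, PF90002 = 5L,
                                            PF95001 = 5L))
  tab <- build_frequency_table(list(g_all_zero, g_one_zero, g_two_zero),
                               domains = m$predictor_domains)
  report <- predict(m, tab)

  r0 <- report[report$genome_id == "zero4", ]
  expect_true(r0$excluded)
  expect_equal(r0$n_zero_predictors, 4L)
  expect_true(is.na(r0$predicted_class))

  r1 <- report[report$genome_id == "zero1", ]
  expect_false(r1$excluded)
  expect_equal(r1$n_zero_predictors, 1L)
  expect_false(is.na(r1$predicted_class))

  r2 <- report[report$genome_id == "zero2", ]
  expect_true(r2$excluded)
  expect_equal(r2$n_zero_predictors, 2L)

  ## raising the threshold can only reduce exclusions
  n_excl <- vapply(1:5, function(th)
    sum(predict(m, tab, exclusion_threshold = th)$excluded), integer(1))
  expect_true(all(diff(n_excl) <= 0))
})

test_that("prediction is invariant to genome row order", {
  m <- separated_model()
  co <- separated_cohort()
  tab_fwd <- build_frequency_table(co$sets, domains = PLANTED)
  tab_rev <- build_frequency_table(rev(co$sets), domains = PLANTED)
  r_fwd <- predict(m, tab_fwd)
  r_rev <- predict(m, tab_rev)
  r_rev_sorted <- r_rev[match(r_fwd$genome_id, r_rev$genome_id), ]
  rownames(r_rev_sorted) <- NULL
  expect_equal(r_fwd, r_rev_sorted)
})

test_that("permutation importance: constant columns score zero, planted dominate", {
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED)
  tab2 <- tab
  tab2$values <- cbind(tab$values, PF99999 = 0.001)
  tab2$raw_counts <- cbind(tab$raw_counts, PF99999 = 1L)
  tab2$domain_ids <- c(PLANTED, "PF99999")
  m2 <- train_model(tab2, co$classes, seed = 99L)
  mdas <- vapply(1:20, function(s) {
    permutation_importance(m2, tab2, co$classes, n_repeats = 3L,
                           seed = s)[["PF99999"]]
  }, numeric(1))
  expect_lte(max(abs(mdas)), 0.5)

  imp <- permutation_importance(m2, tab2, co$classes, n_repeats = 10L,
                                seed = 5L)
  expect_true(all(is.finite(imp)))
  expect_true(all(imp >= -100 & imp <= 100))
})

test_that("the sole informative feature has the largest importance", {
  wins <- vapply(1:20, function(s) {
    spec <- cohort_spec(
      n_per_class = 15L,
      informative_domains = data.frame(
        domain_id = "PF90001", mean_radiosensitive = 0.06,
        mean_tolerant = 0.02, sd = 0.004),
      n_noise_domains = 10L, total_instances_range = c(1000L, 2000L),
      seed = s
    )
    co <- generate_cohort(spec)
    feats <- c("PF90001", "PF95001", "PF95002", "PF95003")
    tab <- build_frequency_table(co$sets, domains = feats)
    m <- train_model(tab, co$classes, cv_folds = 5L, n_trees = 300L,
                     seed = s + 10L)
    imp <- permutation_importance(m, tab, co$classes, n_repeats = 5L,
                                  seed = s + 20L)
    names(which.max(imp)) == "PF90001" && sum(imp == max(imp)) == 1L
  }, logical(1))
  expect_gte(sum(wins), 19L)
})

test_that("model bundles round-trip exactly and reject corruption", {
  m <- separated_model()
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets[1:20], domains = PLANTED)
  dir <- withr::local_tempdir()
  bundle <- file.path(dir, "model")
  save_model(m, bundle)
  m_back <- load_model(bundle)
  expect_identical(predict(m, tab), predict(m_back, tab))
  expect_equal(m_back$predictor_domains, m$predictor_domains)
  expect_equal(m_back$cv_accuracy, m$cv_accuracy)

  ## reordered predictor list in the sidecar leaves predictions unchanged
  meta <- jsonlite::read_json(file.path(bundle, "model.json"),
                              simplifyVector = TRUE)
  meta$predictor_domains <- rev(meta$predictor_domains)
  jsonlite::write_json(meta, file.path(bundle, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  m_rev <- load_model(bundle)
  expect_identical(predict(m, tab), predict(m_rev, tab))

  ## corrupt sidecar: hard error, no partial model
  writeLines("{not json", file.path(bundle, "model.json"))
  expect_error(load_model(bundle), "corrupt model sidecar")

  ## version mismatch names both versions
  meta$format_version <- "999"
  jsonlite::write_json(meta, file.path(bundle, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_model(bundle), "'999'.*'1'")

  expect_error(load_model(file.path(dir, "nope")), "not a model bundle")
})

test_that("vote fractions for the two classes are complementary", {
  m <- separated_model()
  co <- separated_cohort()
  tab <- build_frequency_table(co$sets, domains = PLANTED)
  votes <- predict(m$forest, tab$values[, rownames(m$forest$importance)],
                   type = "vote", norm.votes = TRUE)
  expect_equal(unname(rowSums(votes)), rep(1, nrow(votes)))
})
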