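#' Universality filter
#'
#' Keeps the domains present (instance count >= 1) in every genome of the
#' cohort. This is the first stage of the predictor funnel: a domain that is
#' missing from even one complete training genome cannot be a robust
#' frequency predictor.
#'
#' @param sets List of [pfam_annotation_set()] objects.
#' @return Character vector of Pfam accessions, sorted.
#' @export
filter_universal <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "pfam_annotation_set")))
  universal <- Reduce(intersect, lapply(sets, function(s) names(domain_counts(s))))
  sort(universal)
}

#' Abundance filter
#'
#' Keeps the domains whose mean instance count per genome is strictly greater
#' than `min_mean` (default 2): frequency shifts of domains that occur only
#' once or twice per proteome are dominated by annotation noise.
#'
#' @param sets List of [pfam_annotation_set()] objects.
#' @param domains Candidate domains (subset of the observed universe).
#' @param min_mean Strict lower bound on the per-genome mean count; default 2.
#' @return Character vector of Pfam accessions, sorted.
#' @export
filter_abundant <- function(sets, domains, min_mean = 2) {
  stopifnot(is.list(sets), length(sets) >= 1L, is.character(domains))
  counts <- lapply(sets, domain_counts)
  total <- stats::setNames(numeric(length(domains)), domains)
  for (ct in counts) {
    hit <- intersect(names(ct), domains)
    total[hit] <- total[hit] + ct[hit]
  }
  sort(domains[total / length(sets) > min_mean])
}

## Random-forest permutation importance (mean decrease in accuracy) for a
## design matrix; consumes the RNG stream. With scale = TRUE the importance
## is the Z score of the per-tree accuracy decreases (MDA / SD), the measure
## the Boruta algorithm races against its shadows; with scale = FALSE it is
## the raw mean decrease used for reporting and pruning order.
.rf_importance <- function(x, y, ntree, scale = FALSE) {
  fit <- randomForest::randomForest(
    x = x, y = y, ntree = ntree, importance = TRUE
  )
  randomForest::importance(fit, type = 1, scale = scale)[, 1L]
}

#' Boruta all-relevant feature selection
#'
#' Decides for each candidate domain whether its frequency carries real
#' information about the class labels, by racing it against permuted "shadow"
#' copies of the undecided features. Each iteration (i) appends one shadow
#' copy of every undecided feature with values permuted independently across
#' genomes, (ii) fits a random forest on real + shadow features, (iii) scores
#' every feature by the Z score of its permutation importance (mean decrease
#' in accuracy over trees divided by its standard deviation), and
#' (iv) credits an undecided feature with a "hit" when its importance exceeds
#' the maximum shadow importance. The shadow pool always covers the full
#' candidate set — including already-decided features — so the shadow
#' maximum keeps the severity of "the best of p null features" for the whole
#' run. After each iteration a two-sided binomial
#' test of the hit count against Binomial(n, 1/2), Bonferroni-corrected
#' across all candidate features, confirms (significantly more hits than
#' chance) or rejects (significantly fewer) features. Features still
#' undecided after `max_runs` iterations are tentative.
#'
#' @param X A `frequency_table` restricted to the candidate domains.
#' @param y Class labels (`"radiosensitive"`/`"tolerant"`), one per genome.
#' @param max_runs Maximum number of iterations; default 500.
#' @param alpha Significance level for the binomial test; default 0.05.
#' @param seed Integer seed; the procedure is deterministic given it.
#' @param ntree Trees per internal forest; default 500.
#' @return An object of class `boruta_result`: list with `confirmed`,
#'   `rejected`, `tentative` (partitioning the candidates), `n_iterations`
#'   and `hit_counts`.
#' @export
boruta_select <- function(X, y, max_runs = 500L, alpha = 0.05, seed,
                          ntree = 500L) {
  stopifnot(inherits(X, "frequency_table"))
  y <- .check_classes(y)
  if (length(y) != length(X$genome_ids)) {
    stop("length(y) must equal the number of genomes", call. = FALSE)
  }
  if (any(table(y) < 2L)) stop("need at least 2 genomes per class", call. = FALSE)
  features <- X$domain_ids
  if (length(features) < 1L) stop("no candidate features", call. = FALSE)

  vals <- X$values
  variances <- apply(vals, 2L, stats::var)
  rejected <- features[variances == 0]
  if (length(rejected) > 0L) {
    warning("auto-rejected zero-variance feature(s): ",
            paste(rejected, collapse = ", "), call. = FALSE)
  }
  undecided <- setdiff(features, rejected)
  candidates <- undecided
  n_candidates <- max(1L, length(undecided))
  confirmed <- character(0)
  hits <- stats::setNames(integer(length(undecided)), undecided)
  iter <- 0L

  with_seed(seed, {
    while (length(undecided) > 0L && iter < max_runs) {
      iter <- iter + 1L
      n <- nrow(vals)
      ## shadow copies of every candidate feature (also the already-decided
      ## ones): the shadow-max bar keeps the severity of "best of p null
      ## features" for the whole run, instead of weakening as candidates
      ## are decided
      shadow_src <- candidates
      shadows <- vapply(shadow_src, function(f) vals[sample.int(n), f],
                        numeric(n))
      shadow_names <- paste0("shadow_", seq_along(shadow_src))
      design <- cbind(vals[, c(confirmed, undecided), drop = FALSE],
                      matrix(shadows, nrow = n,
                             dimnames = list(NULL, shadow_names)))
      imp <- .rf_importance(design, y, ntree, scale = TRUE)
      shadow_max <- max(imp[shadow_names])
      hit_now <- undecided[imp[undecided] > shadow_max]
      hits[hit_now] <- hits[hit_now] + 1L

      ## two-sided binomial decision, Bonferroni-corrected across all
      ## candidates entering the race (fixed FWER, as in reference Boruta)
      alpha_corr <- alpha / n_candidates
      h <- hits[undecided]
      p_hi <- stats::pbinom(h - 1L, iter, 0.5, lower.tail = FALSE)
      p_lo <- stats::pbinom(h, iter, 0.5)
      conf_now <- undecided[2 * p_hi < alpha_corr]
      rej_now <- undecided[2 * p_lo < alpha_corr]
      confirmed <- c(confirmed, conf_now)
      rejected <- c(rejected, rej_now)
      undecided <- setdiff(undecided, c(conf_now, rej_now))
    }
  })

  all_hits <- stats::setNames(integer(length(features)), features)
  all_hits[names(hits)] <- hits
  structure(
    list(confirmed = sort(confirmed), rejected = sort(rejected),
         tentative = sort(undecided), n_iterations = iter,
         hit_counts = all_hits),
    class = "boruta_result"
  )
}

#' @export
print.boruta_result <- function(x, ...) {
  cat(sprintf("<boruta_result> %d iterations: %d confirmed, %d rejected, %d tentative\n",
              x$n_iterations, length(x$confirmed), length(x$rejected),
              length(x$tentative)))
  if (length(x$confirmed) > 0L)
    cat("confirmed:", paste(x$confirmed, collapse = ", "), "\n")
  invisible(x)
}

## Stratified k-fold cross-validated accuracy of a random forest on the
## given columns. Consumes the RNG stream; pass `folds` to reuse an
## assignment across feature sets (paired comparison).
.cv_accuracy <- function(vals, y, features, cv_folds, ntree, folds = NULL) {
  if (is.null(folds)) folds <- .stratified_folds(y, cv_folds)
  correct <- 0L
  for (k in seq_len(cv_folds)) {
    test_idx <- which(folds == k)
    train_idx <- which(folds != k)
    fit <- randomForest::randomForest(
      x = vals[train_idx, features, drop = FALSE], y = y[train_idx],
      ntree = ntree
    )
    pred <- predict(fit, vals[test_idx, features, drop = FALSE])
    correct <- correct + sum(pred == y[test_idx])
  }
  correct / length(y)
}

#' Stepwise predictor pruning by permutation importance
#'
#' Greedy backward elimination toward the most parsimonious model: at each
#' step the feature with the lowest mean decrease in accuracy (ties broken by
#' lexicographic domain id) is tentatively removed; the removal is accepted
#' when the cross-validated accuracy of the reduced set is at least that of
#' the current set (ties favour the smaller model), otherwise pruning stops.
#' The final set is never empty.
#'
#' Both accuracies are estimated by repeated stratified cross-validation
#' (`cv_repeats` fold assignments, shared between the current and reduced
#' sets so the comparison is paired); on small cohorts a single fold
#' assignment is quantized to 1/n and too noisy to compare models reliably.
#'
#' @param X A `frequency_table` containing at least the candidate features.
#' @param y Class labels, one per genome.
#' @param features Character vector of candidate domains (>= 2).
#' @param cv_folds Folds for the accuracy comparison; default 10.
#' @param seed Integer seed.
#' @param ntree Trees per forest; default 500.
#' @param cv_repeats Independent fold assignments averaged per accuracy
#'   estimate; default 10.
#' @return List with `features` (the retained domains) and `audit` — a data
#'   frame recording, for each candidate removal, both accuracies and the
#'   decision.
#' @export
stepwise_prune <- function(X, y, features, cv_folds = 10L, seed, ntree = 500L,
                           cv_repeats = 10L) {
  stopifnot(inherits(X, "frequency_table"), is.character(features),
            length(features) >= 2L, all(features %in% X$domain_ids))
  y <- .check_classes(y)
  if (cv_folds > min(table(y))) {
    stop("cv_folds (", cv_folds, ") exceeds the smallest class count (",
         min(table(y)), "); use fewer folds", call. = FALSE)
  }
  vals <- X$values
  audit <- list()
  current <- sort(features)

  with_seed(seed, {
    repeat {
      if (length(current) <= 1L) break
      imp <- .rf_importance(vals[, current, drop = FALSE], y, ntree)
      ## lowest MDA first; ties broken lexicographically by domain id
      ord <- order(imp, names(imp))
      candidate <- names(imp)[ord[1L]]
      reduced <- setdiff(current, candidate)
      ## repeated CV, fold assignments shared across the two feature sets
      ## so the accept/stop comparison is paired
      accs <- vapply(seq_len(cv_repeats), function(r) {
        folds <- .stratified_folds(y, cv_folds)
        c(.cv_accuracy(vals, y, current, cv_folds, ntree, folds),
          .cv_accuracy(vals, y, reduced, cv_folds, ntree, folds))
      }, numeric(2L))
      acc_current <- mean(accs[1L, ])
      acc_reduced <- mean(accs[2L, ])
      accepted <- acc_reduced >= acc_current
      audit[[length(audit) + 1L]] <- data.frame(
        step = length(audit) + 1L, removed_candidate = candidate,
        acc_current = acc_current, acc_reduced = acc_reduced,
        accepted = accepted, stringsAsFactors = FALSE
      )
      if (!accepted) break
      current <- reduced
    }
  })

  audit_df <- if (length(audit) > 0L) do.call(rbind, audit) else
    data.frame(step = integer(0), removed_candidate = character(0),
               acc_current = numeric(0), acc_reduced = numeric(0),
               accepted = logical(0), stringsAsFactors = FALSE)
  list(features = current, audit = audit_df)
}

#' Run the full predictor-selection funnel
#'
#' Chains the four selection stages — universality filter, abundance filter,
#' Boruta, stepwise pruning — and records the feature count entering and
#' leaving each stage. Tentative Boruta features are treated as not selected.
#'
#' @param sets List of [pfam_annotation_set()] training genomes.
#' @param y Class labels, one per genome in `sets`.
#' @param min_mean Abundance threshold; default 2.
#' @param max_runs Boruta iteration cap; default 500.
#' @param alpha Boruta significance level; default 0.05.
#' @param cv_folds Folds for stepwise pruning; default 10.
#' @param seed Integer seed.
#' @param ntree Trees per forest; default 500.
#' @return List with `features` (the final predictors), `stages` (a data
#'   frame of per-stage feature counts and retained lists), `boruta` (the
#'   full [boruta_select()] result) and `stepwise_audit`.
#' @export
select_predictors <- function(sets, y, min_mean = 2, max_runs = 500L,
                              alpha = 0.05, cv_folds = 10L, seed,
                              ntree = 500L) {
  universe <- sort(unique(unlist(lapply(sets, function(s) names(domain_counts(s))),
                                 use.names = FALSE)))
  universal <- filter_universal(sets)
  abundant <- filter_abundant(sets, universal, min_mean = min_mean)
  if (length(abundant) == 0L) {
    stop("no domains survive the universality + abundance filters", call. = FALSE)
  }
  table_all <- build_frequency_table(sets)
  X <- restrict_frequency_table(table_all, abundant)
  boruta <- boruta_select(X, y, max_runs = max_runs, alpha = alpha,
                          seed = seed, ntree = ntree)
  selected <- boruta$confirmed
  if (length(selected) == 0L) {
    stop("Boruta confirmed no features; cannot proceed to pruning", call. = FALSE)
  }
  if (length(selected) >= 2L) {
    pruned <- stepwise_prune(X, y, selected, cv_folds = cv_folds,
                             seed = seed + 1L, ntree = ntree)
    final <- pruned$features
    audit <- pruned$audit
  } else {
    final <- selected
    audit <- NULL
  }
  stages <- data.frame(
    stage = c("universe", "universal", "abundant", "boruta", "stepwise"),
    n_features = c(length(universe), length(universal), length(abundant),
                   length(selected), length(final)),
    stringsAsFactors = FALSE
  )
  stages$features <- c(NA_character_,
                       paste(universal, collapse = ","),
                       paste(abundant, collapse = ","),
                       paste(selected, collapse = ","),
                       paste(final, collapse = ","))
  list(features = final, stages = stages, boruta = boruta,
       stepwise_audit = audit)
}

#' Write a funnel report TSV
#'
#' @param funnel Result of [select_predictors()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_funnel_report <- function(funnel, path) {
  utils::write.table(funnel$stages, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
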