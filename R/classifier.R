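.MODEL_FORMAT_VERSION <- "1"

#' Train the radiation-tolerance random forest
#'
#' Fits a binary random-forest classifier on the relative frequencies of the
#' predictor domains. The number of variables tried at each split (`mtry`) is
#' tuned over `1..n_predictors` by stratified k-fold cross-validated
#' accuracy (the same folds for every candidate, ties resolved toward the
#' smallest `mtry`); the final forest is refit on all genomes at the winning
#' value. Deterministic for a fixed seed.
#'
#' @param X A `frequency_table` restricted to the predictor domains.
#' @param y Class labels (`"radiosensitive"`/`"tolerant"`), one per genome.
#' @param cv_folds Cross-validation folds; default 10. Must not exceed the
#'   smaller class size.
#' @param n_trees Trees in the forest; default 500.
#' @param seed Integer seed.
#' @return An object of class `radtol_model`: predictor domains, the fitted
#'   ensemble, `n_trees`, tuned `mtry`, `cv_accuracy` and training metadata.
#' @export
train_model <- function(X, y, cv_folds = 10L, n_trees = 500L, seed) {
  stopifnot(inherits(X, "frequency_table"))
  y <- .check_classes(y)
  if (length(y) != length(X$genome_ids)) {
    stop("length(y) must equal the number of genomes", call. = FALSE)
  }
  class_sizes <- table(y)
  if (length(unique(y[!is.na(y)])) < 2L || any(class_sizes < 2L)) {
    stop("both classes must be present with at least 2 genomes each",
         call. = FALSE)
  }
  if (cv_folds > min(class_sizes)) {
    stop("cv_folds (", cv_folds, ") exceeds the smallest class count (",
         min(class_sizes), "); use fewer folds", call. = FALSE)
  }
  vals <- X$values
  p <- ncol(vals)
  if (p < 1L) stop("no predictor domains in the table", call. = FALSE)

  with_seed(seed, {
    folds <- .stratified_folds(y, cv_folds)
    accs <- vapply(seq_len(p), function(m) {
      correct <- 0L
      for (k in seq_len(cv_folds)) {
        test_idx <- which(folds == k)
        fit <- randomForest::randomForest(
          x = vals[-test_idx, , drop = FALSE], y = y[-test_idx],
          ntree = n_trees, mtry = m
        )
        pred <- predict(fit, vals[test_idx, , drop = FALSE])
        correct <- correct + sum(pred == y[test_idx])
      }
      correct / length(y)
    }, numeric(1L))
    best_mtry <- which.max(accs)     # ties -> smallest mtry
    forest <- randomForest::randomForest(
      x = vals, y = y, ntree = n_trees, mtry = best_mtry,
      importance = TRUE, keep.inbag = TRUE
    )
  })

  structure(
    list(
      predictor_domains = X$domain_ids,
      forest = forest,
      n_trees = as.integer(n_trees),
      mtry = as.integer(best_mtry),
      cv_accuracy = accs[best_mtry],
      class_labels = tolerance_classes(),
      training_meta = list(
        seed = as.integer(seed), cv_folds = as.integer(cv_folds),
        cohort_size = length(y),
        class_counts = as.list(as.integer(class_sizes)),
        r_version = R.version.string,
        randomForest_version = as.character(utils::packageVersion("randomForest")),
        package_version = as.character(utils::packageVersion("radtol")),
        format_version = .MODEL_FORMAT_VERSION
      )
    ),
    class = "radtol_model"
  )
}

#' @export
print.radtol_model <- function(x, ...) {
  cat(sprintf(
    "<radtol_model> %d predictors (%s), %d trees, mtry %d, CV accuracy %.3f\n",
    length(x$predictor_domains), paste(x$predictor_domains, collapse = ", "),
    x$n_trees, x$mtry, x$cv_accuracy
  ))
  invisible(x)
}

#' Classify genomes with missing-predictor accounting
#'
#' For each genome, counts the predictor domains whose relative frequency is
#' exactly 0 (absent from the annotation). A genome missing
#' `exclusion_threshold` or more predictors is excluded from classification —
#' an absent domain in an incomplete MAG is indistinguishable from a domain
#' lost to assembly gaps — and carries no predicted class. Otherwise the
#' forest votes: the genome is called radiosensitive when more than half the
#' trees vote so, tolerant otherwise (exact ties go to tolerant, the majority
#' class in the training cohort).
#'
#' @param object A `radtol_model`.
#' @param table A `frequency_table`; columns are matched to the model's
#'   predictors by name, absent domains counting as frequency 0.
#' @param exclusion_threshold Minimum number of zero-valued predictors that
#'   triggers exclusion; default 2.
#' @param ... Unused.
#' @return A `data.frame` (one row per genome): `genome_id`,
#'   `predicted_class` (NA when excluded), `vote_fraction` (fraction of trees
#'   voting radiosensitive; NA when excluded), `n_zero_predictors`,
#'   `excluded`.
#' @export
predict.radtol_model <- function(object, table, exclusion_threshold = 2L, ...) {
  stopifnot(inherits(table, "frequency_table"))
  if (length(table$genome_ids) == 0L) stop("empty frequency table", call. = FALSE)
  restricted <- restrict_frequency_table(table, object$predictor_domains)
  vals <- restricted$values
  ## column order must match the forest's training variables
  train_vars <- rownames(object$forest$importance)
  vals <- vals[, train_vars, drop = FALSE]

  n_zero <- as.integer(rowSums(vals == 0))
  excluded <- n_zero >= exclusion_threshold
  votes <- predict(object$forest, vals, type = "vote", norm.votes = TRUE)
  vote_rs <- votes[, "radiosensitive"]
  predicted <- ifelse(vote_rs > 0.5, "radiosensitive", "tolerant")

  data.frame(
    genome_id = table$genome_ids,
    predicted_class = ifelse(excluded, NA_character_, predicted),
    vote_fraction = ifelse(excluded, NA_real_, vote_rs),
    n_zero_predictors = n_zero,
    excluded = excluded,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Permutation importance (mean decrease in accuracy)
#'
#' For each predictor: the baseline per-tree out-of-bag accuracy minus the
#' mean per-tree out-of-bag accuracy after permuting that predictor's column
#' across genomes, averaged over `n_repeats` independent permutations and
#' reported on the percentage scale (x100). Out-of-bag masks come from the
#' fitted ensemble, so no data is reused between a tree's fit and its
#' evaluation.
#'
#' @param model A `radtol_model` (trained with out-of-bag bookkeeping, as
#'   [train_model()] does).
#' @param X The training `frequency_table`.
#' @param y The training class labels.
#' @param n_repeats Number of permutations per predictor; default 20.
#' @param seed Integer seed.
#' @return Named numeric vector: mean decrease in accuracy per predictor, in
#'   percentage points.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 20L, seed) {
  stopifnot(inherits(model, "radtol_model"), inherits(X, "frequency_table"))
  if (n_repeats < 1L) stop("n_repeats must be at least 1", call. = FALSE)
  y <- .check_classes(y)
  forest <- model$forest
  inbag <- forest$inbag
  if (is.null(inbag)) {
    stop("model lacks out-of-bag bookkeeping; retrain with train_model()",
         call. = FALSE)
  }
  restricted <- restrict_frequency_table(X, model$predictor_domains)
  vals <- restricted$values[, rownames(forest$importance), drop = FALSE]
  stopifnot(nrow(vals) == nrow(inbag), length(y) == nrow(vals))
  oob <- inbag == 0L

  per_tree_acc <- function(m) {
    ind <- predict(forest, m, predict.all = TRUE)$individual
    vapply(seq_len(ncol(ind)), function(t) {
      idx <- oob[, t]
      if (!any(idx)) return(NA_real_)
      mean(ind[idx, t] == as.character(y)[idx])
    }, numeric(1L))
  }

  base_acc <- per_tree_acc(vals)
  mda <- stats::setNames(numeric(ncol(vals)), colnames(vals))
  with_seed(seed, {
    for (j in seq_len(ncol(vals))) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        perm <- vals
        perm[, j] <- perm[sample.int(nrow(perm)), j]
        mean(base_acc - per_tree_acc(perm), na.rm = TRUE)
      }, numeric(1L))
      mda[j] <- mean(drops)
    }
  })
  mda * 100
}

#' Save a trained model bundle
#'
#' Writes a directory with `model.json` (format version, predictor domains,
#' tuning results, training metadata) and `ensemble.rds` (the serialized
#' forest). A reloaded model predicts identically.
#'
#' @param model A `radtol_model`.
#' @param path Directory to create (must not be an existing file).
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "radtol_model"))
  if (file.exists(path) && !dir.exists(path)) {
    stop("path exists and is not a directory: ", path, call. = FALSE)
  }
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    format_version = .MODEL_FORMAT_VERSION,
    predictor_domains = model$predictor_domains,
    n_trees = model$n_trees,
    mtry = model$mtry,
    cv_accuracy = model$cv_accuracy,
    class_labels = model$class_labels,
    training_meta = model$training_meta
  )
  jsonlite::write_json(meta, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  saveRDS(model$forest, file.path(path, "ensemble.rds"))
  invisible(path)
}

#' Load a trained model bundle
#'
#' @param path Directory written by [save_model()].
#' @return A `radtol_model`.
#' @export
load_model <- function(path) {
  json_path <- file.path(path, "model.json")
  rds_path <- file.path(path, "ensemble.rds")
  if (!file.exists(json_path) || !file.exists(rds_path)) {
    stop("not a model bundle (missing model.json or ensemble.rds): ", path,
         call. = FALSE)
  }
  meta <- tryCatch(jsonlite::read_json(json_path, simplifyVector = TRUE),
                   error = function(e) {
                     stop("corrupt model sidecar ", json_path, ": ",
                          conditionMessage(e), call. = FALSE)
                   })
  needed <- c("format_version", "predictor_domains", "n_trees", "mtry",
              "cv_accuracy", "class_labels")
  missing_fields <- setdiff(needed, names(meta))
  if (length(missing_fields) > 0L) {
    stop("corrupt model sidecar: missing field(s) ",
         paste(missing_fields, collapse = ", "), call. = FALSE)
  }
  if (!identical(as.character(meta$format_version), .MODEL_FORMAT_VERSION)) {
    stop("model format version mismatch: bundle has '", meta$format_version,
         "', this package reads '", .MODEL_FORMAT_VERSION, "'", call. = FALSE)
  }
  forest <- readRDS(rds_path)
  structure(
    list(
      predictor_domains = meta$predictor_domains,
      forest = forest,
      n_trees = as.integer(meta$n_trees),
      mtry = as.integer(meta$mtry),
      cv_accuracy = as.numeric(meta$cv_accuracy),
      class_labels = meta$class_labels,
      training_meta = meta$training_meta
    ),
    class = "radtol_model"
  )
}

#' Write a classification report TSV
#'
#' @param report Data frame from [predict.radtol_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
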