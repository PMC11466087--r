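## Core subsampler: retains exactly n_keep instances, uniformly without
## replacement across the flattened instance multiset, preserving protein
## grouping. Consumes the RNG stream.
.degrade_instances <- function(aset, fraction) {
  n_total <- aset$total_instances
  n_keep <- round(fraction * n_total)
  if (n_keep == 0L) {
    stop("degradation of genome ", aset$genome_id, " at fraction ", fraction,
         " retains 0 instances", call. = FALSE)
  }
  protein_of <- rep(seq_along(aset$records), lengths(aset$records))
  domain_of <- unlist(aset$records, use.names = FALSE)
  keep <- sort(sample.int(n_total, n_keep))
  records <- split(domain_of[keep],
                   factor(protein_of[keep], levels = seq_along(aset$records)))
  names(records) <- names(aset$records)
  pfam_annotation_set(aset$genome_id, records)
}

#' Simulate an incomplete MAG by annotation subsampling
#'
#' Emulates assembly incompleteness by retaining exactly
#' `round(fraction * total_instances)` domain instances, sampled uniformly
#' without replacement across the genome's flattened instance multiset.
#' Protein grouping is preserved for the retained instances (proteins losing
#' all their domains remain as empty records). Deterministic for a fixed
#' seed.
#'
#' @param aset A [pfam_annotation_set()] with at least one instance.
#' @param fraction Retained completeness in (0, 1].
#' @param seed Integer seed.
#' @return A degraded [pfam_annotation_set()].
#' @export
degrade <- function(aset, fraction, seed) {
  stopifnot(inherits(aset, "pfam_annotation_set"))
  if (!is.numeric(fraction) || length(fraction) != 1L || fraction <= 0 ||
      fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  if (aset$total_instances < 1L) {
    stop("cannot degrade an empty annotation set: ", aset$genome_id,
         call. = FALSE)
  }
  with_seed(seed, .degrade_instances(aset, fraction))
}

#' Classification robustness under simulated MAG incompleteness
#'
#' For each completeness fraction and replicate: degrades every genome,
#' recomputes relative frequencies against the degraded total, classifies,
#' and scores the percent of correct classifications among the non-excluded
#' genomes. Excluded genomes are reported separately, never counted as
#' wrong. Also tallies the distribution of missing (zero-valued) predictors
#' per fraction.
#'
#' @param sets List of [pfam_annotation_set()] objects with known classes.
#' @param classes Character vector of true classes, one per set.
#' @param model A `radtol_model`.
#' @param fractions Completeness levels; default `c(0.9, 0.8, 0.7, 0.6, 0.5)`.
#' @param replicates Replicate degradations per fraction; default 10.
#' @param seed Integer seed.
#' @param exclusion_threshold Passed to [predict.radtol_model()]; default 2.
#' @return An object of class `degradation_report`: `curve` — a data frame
#'   with one row per (fraction, replicate) holding `percent_correct`,
#'   `n_classified` and `n_excluded`; `missing_predictors` — a data frame of
#'   per-fraction counts of genomes by number of zero predictors;
#'   `fractions`.
#' @export
degradation_curve <- function(sets, classes, model,
                              fractions = c(0.9, 0.8, 0.7, 0.6, 0.5),
                              replicates = 10L, seed,
                              exclusion_threshold = 2L) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            length(classes) == length(sets),
            inherits(model, "radtol_model"))
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]", call. = FALSE)
  }
  classes <- as.character(classes)
  curve <- list()
  tallies <- list()

  with_seed(seed, {
    for (f in fractions) {
      for (r in seq_len(replicates)) {
        degraded <- lapply(sets, .degrade_instances, fraction = f)
        tab <- build_frequency_table(degraded,
                                     domains = model$predictor_domains)
        report <- predict(model, tab,
                          exclusion_threshold = exclusion_threshold)
        kept <- !report$excluded
        pc <- if (any(kept)) {
          mean(report$predicted_class[kept] == classes[kept])
        } else NA_real_
        curve[[length(curve) + 1L]] <- data.frame(
          fraction = f, replicate = r, percent_correct = pc,
          n_classified = sum(kept), n_excluded = sum(!kept)
        )
        tallies[[length(tallies) + 1L]] <- data.frame(
          fraction = f, n_zero_predictors = report$n_zero_predictors
        )
      }
    }
  })

  tally_df <- do.call(rbind, tallies)
  missing_df <- as.data.frame(
    table(fraction = tally_df$fraction,
          n_zero_predictors = tally_df$n_zero_predictors),
    stringsAsFactors = FALSE
  )
  missing_df$fraction <- as.numeric(missing_df$fraction)
  missing_df$n_zero_predictors <- as.integer(missing_df$n_zero_predictors)
  names(missing_df)[3L] <- "count"
  structure(
    list(curve = do.call(rbind, curve), missing_predictors = missing_df,
         fractions = fractions),
    class = "degradation_report"
  )
}

#' @export
print.degradation_report <- function(x, ...) {
  agg <- stats::aggregate(percent_correct ~ fraction, data = x$curve, FUN = mean)
  cat("<degradation_report>\n")
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  completeness %.0f%%: mean %.1f%% correct\n",
                100 * agg$fraction[i], 100 * agg$percent_correct[i]))
  }
  invisible(x)
}

#' Write degradation report TSVs
#'
#' Writes the per-replicate curve to `path` and the missing-predictor
#' histogram to `missing_path` (if given).
#'
#' @param report A `degradation_report`.
#' @param path Output TSV for the (fraction, replicate, percent_correct) curve.
#' @param missing_path Optional output TSV for the missing-predictor counts.
#' @return `path`, invisibly.
#' @export
write_degradation_report <- function(report, path, missing_path = NULL) {
  utils::write.table(report$curve, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(missing_path)) {
    utils::write.table(report$missing_predictors, missing_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Screen a genome collection
#'
#' Classifies every genome in a cohort and aggregates the results:
#' classified/excluded counts, per-class counts, the fraction radiosensitive
#' among classified genomes, and a per-phylum breakdown when a taxonomy is
#' supplied.
#'
#' @param sets List of [pfam_annotation_set()] objects.
#' @param model A `radtol_model`.
#' @param taxonomy Optional named character vector mapping genome id to
#'   phylum.
#' @param exclusion_threshold Passed to [predict.radtol_model()]; default 2.
#' @return An object of class `screen_summary`: the per-genome `report` data
#'   frame plus `n_total`, `n_classified`, `n_excluded`, `class_counts`,
#'   `fraction_radiosensitive` and (optionally) `per_phylum`.
#' @export
screen_collection <- function(sets, model, taxonomy = NULL,
                              exclusion_threshold = 2L) {
  stopifnot(is.list(sets), length(sets) >= 1L, inherits(model, "radtol_model"))
  tab <- build_frequency_table(sets, domains = model$predictor_domains)
  report <- predict(model, tab, exclusion_threshold = exclusion_threshold)
  kept <- !report$excluded
  class_counts <- stats::setNames(
    vapply(tolerance_classes(),
           function(cl) sum(report$predicted_class[kept] == cl),
           integer(1L)),
    tolerance_classes()
  )
  per_phylum <- NULL
  if (!is.null(taxonomy)) {
    report$phylum <- unname(taxonomy[report$genome_id])
    sub <- report[kept, , drop = FALSE]
    if (nrow(sub) > 0L) {
      per_phylum <- as.data.frame(
        table(phylum = sub$phylum, predicted_class = sub$predicted_class),
        stringsAsFactors = FALSE
      )
      names(per_phylum)[3L] <- "count"
    }
  }
  structure(
    list(report = report, n_total = nrow(report),
         n_classified = sum(kept), n_excluded = sum(!kept),
         class_counts = class_counts,
         fraction_radiosensitive = if (any(kept))
           unname(class_counts["radiosensitive"]) / sum(kept) else NA_real_,
         per_phylum = per_phylum),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf(
    "<screen_summary> %d genomes: %d classified (%d radiosensitive, %d tolerant), %d excluded\n",
    x$n_total, x$n_classified, x$class_counts["radiosensitive"],
    x$class_counts["tolerant"], x$n_excluded
  ))
  invisible(x)
}
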