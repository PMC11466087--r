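#' Construct a D10 record
#'
#' A `d10_record` collects one species' experimentally determined D10 values —
#' the acute ionizing-radiation dose (in Gy) at which 10% of exposed cells
#' still form viable colonies. Species with several published measurements
#' keep all of them; labelling uses the mean.
#'
#' @param species_id Single string.
#' @param d10_values Numeric vector of positive doses in Gy; at least one.
#' @param phylum Optional phylum annotation.
#' @param source_note Optional free-text provenance note.
#' @return An object of class `d10_record`.
#' @export
d10_record <- function(species_id, d10_values, phylum = NA_character_,
                       source_note = NA_character_) {
  stopifnot(is.character(species_id), length(species_id) == 1L, nzchar(species_id))
  d10_values <- as.numeric(d10_values)
  if (length(d10_values) == 0L || any(!is.finite(d10_values)) || any(d10_values <= 0)) {
    stop("d10_values must be a non-empty vector of positive doses (Gy)",
         call. = FALSE)
  }
  structure(
    list(species_id = species_id, d10_values = d10_values,
         phylum = phylum, source_note = source_note),
    class = "d10_record"
  )
}

#' Labelling configuration
#'
#' Holds the dose cutoff separating radiosensitive from tolerant species.
#' The default of 200 Gy places the radiosensitive class at the bottom of the
#' published D10 distribution, below a wide gap in reported values.
#'
#' @param cutoff_gy Positive dose in Gy; default 200.
#' @return An object of class `labeling_config`.
#' @export
labeling_config <- function(cutoff_gy = 200) {
  stopifnot(is.numeric(cutoff_gy), length(cutoff_gy) == 1L,
            is.finite(cutoff_gy), cutoff_gy > 0)
  structure(list(cutoff_gy = cutoff_gy), class = "labeling_config")
}

#' Mean D10 of a record
#'
#' @param rec A [d10_record()].
#' @return Arithmetic mean of the recorded D10 values, in Gy.
#' @export
mean_d10 <- function(rec) {
  stopifnot(inherits(rec, "d10_record"))
  mean(rec$d10_values)
}

#' Class labels used throughout the package
#' @return Character vector `c("radiosensitive", "tolerant")`.
#' @export
tolerance_classes <- function() c("radiosensitive", "tolerant")

#' Assign a binary tolerance class
#'
#' A species is radiosensitive iff its mean D10 is strictly below the cutoff;
#' a mean exactly at the cutoff is tolerant (the radiosensitive class is
#' defined by "below", so the boundary resolves to strict `<`).
#'
#' @param rec A [d10_record()].
#' @param cfg A [labeling_config()].
#' @return `"radiosensitive"` or `"tolerant"`.
#' @export
assign_class <- function(rec, cfg = labeling_config()) {
  stopifnot(inherits(cfg, "labeling_config"))
  if (mean_d10(rec) < cfg$cutoff_gy) "radiosensitive" else "tolerant"
}

#' Empirical quantile of per-species mean D10 values
#'
#' Diagnostic helper: the dose below which a fraction `q` of species fall,
#' by linear interpolation of the empirical distribution of per-species mean
#' D10 values (`stats::quantile` type 7). It is not used to relabel species;
#' the default labelling keeps the fixed 200 Gy cutoff.
#'
#' @param recs List of [d10_record()] objects, at least two.
#' @param q Fraction strictly between 0 and 1.
#' @return Dose in Gy.
#' @export
quantile_cutoff <- function(recs, q) {
  stopifnot(is.list(recs), length(recs) >= 2L,
            all(vapply(recs, inherits, logical(1L), "d10_record")))
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1) {
    stop("q must lie strictly between 0 and 1", call. = FALSE)
  }
  means <- vapply(recs, mean_d10, numeric(1L))
  unname(stats::quantile(means, probs = q, type = 7))
}

#' Read a label table
#'
#' Format: TSV with header `species_id<TAB>d10_gy[<TAB>phylum]`, one row per
#' measurement. Repeated `species_id` rows aggregate into a single record with
#' several D10 values.
#'
#' @param path Path to a label TSV.
#' @return Named list of [d10_record()] objects, one per species.
#' @export
read_label_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "d10_gy") %in% names(df))) {
    stop("label table needs columns species_id and d10_gy; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  has_phylum <- "phylum" %in% names(df)
  recs <- lapply(split(df, df$species_id), function(rows) {
    d10_record(rows$species_id[1L], rows$d10_gy,
               phylum = if (has_phylum) rows$phylum[1L] else NA_character_)
  })
  recs[order(names(recs))]
}

#' Stratified train/test split
#'
#' Splits labelled genomes into disjoint, exhaustive train and test sets,
#' sampling `round(train_fraction * class size)` genomes per class into the
#' train set so class balance is preserved on small cohorts. Reproducible for
#' a fixed seed.
#'
#' @param labeled Data frame with columns `genome_id` and `class`, or a named
#'   character vector of classes (names = genome ids).
#' @param train_fraction Fraction in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return List with character vectors `train` and `test`.
#' @export
stratified_split <- function(labeled, train_fraction = 0.7, seed) {
  if (is.data.frame(labeled)) {
    ids <- labeled$genome_id
    classes <- labeled$class
  } else {
    ids <- names(labeled)
    classes <- unname(labeled)
  }
  stopifnot(length(ids) == length(classes), anyDuplicated(ids) == 0L)
  if (!is.numeric(train_fraction) || train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  tab <- table(classes)
  if (length(tab) < 2L) stop("both classes must be present", call. = FALSE)
  if (any(tab < 2L)) {
    stop("each class needs at least 2 members to split; counts: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), call. = FALSE)
  }
  train <- character(0)
  with_seed(seed, {
    for (cl in sort(names(tab))) {
      members <- ids[classes == cl]
      n_train <- round(train_fraction * length(members))
      n_train <- max(1L, min(length(members) - 1L, n_train))
      train <- c(train, sample(members, n_train))
    }
  })
  list(train = sort(train), test = sort(setdiff(ids, train)))
}
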