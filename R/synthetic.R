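#' Specification for a planted-signal synthetic cohort
#'
#' Describes a cohort of synthetic annotated genomes in which a small set of
#' informative domains carries a class-conditional frequency shift against a
#' background of uninformative noise domains. Per genome, informative-domain
#' frequencies are drawn from a truncated normal around the class mean, the
#' remaining frequency budget is spread over the noise domains by a symmetric
#' Dirichlet draw, and integer instance counts are realized by a single
#' multinomial draw of the genome's total instance count.
#'
#' @param n_per_class Genomes per class.
#' @param informative_domains Data frame with columns `domain_id`,
#'   `mean_radiosensitive`, `mean_tolerant` (class-mean relative frequencies
#'   in (0,1)) and `sd` (per-genome spread).
#' @param n_noise_domains Number of uninformative background domains.
#' @param noise_concentration Symmetric Dirichlet concentration for the noise
#'   frequency split; default 10. The between-genome coefficient of variation
#'   of a background domain's frequency is roughly `1/sqrt(concentration)`,
#'   so the default gives the ~30% spread typical of conserved domains that
#'   are present in every genome; much smaller values produce dropout-prone,
#'   fat-tailed backgrounds unlike a real universal-domain background.
#' @param total_instances_range Integer `c(min, max)`; each genome's total
#'   Pfam instance count is uniform on this range. The default 3000-6000
#'   matches the instance totals of small bacterial proteomes.
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class,
                        informative_domains,
                        n_noise_domains = 200L,
                        noise_concentration = 10,
                        total_instances_range = c(3000L, 6000L),
                        seed = 1L) {
  stopifnot(is.numeric(n_per_class), n_per_class >= 1L,
            is.data.frame(informative_domains),
            all(c("domain_id", "mean_radiosensitive", "mean_tolerant", "sd")
                %in% names(informative_domains)),
            n_noise_domains >= 1L, n_noise_domains <= 999L,
            noise_concentration > 0,
            length(total_instances_range) == 2L,
            total_instances_range[1L] >= 1L,
            total_instances_range[1L] <= total_instances_range[2L])
  inf <- informative_domains
  if (anyDuplicated(inf$domain_id) > 0L) {
    stop("duplicate informative domain_id", call. = FALSE)
  }
  means <- c(inf$mean_radiosensitive, inf$mean_tolerant)
  if (any(means <= 0 | means >= 1) || any(inf$sd < 0)) {
    stop("informative means must lie in (0,1) and sd must be >= 0",
         call. = FALSE)
  }
  ## a genome's informative draws must leave room for the noise background
  budget <- sum(pmax(inf$mean_radiosensitive, inf$mean_tolerant) + 4 * inf$sd)
  if (budget >= 1) {
    stop("infeasible frequency budget: informative domains can claim ",
         signif(budget, 4), " >= 1 of the per-genome frequency mass",
         call. = FALSE)
  }
  structure(
    list(n_per_class = as.integer(n_per_class),
         informative_domains = inf,
         n_noise_domains = as.integer(n_noise_domains),
         noise_concentration = noise_concentration,
         total_instances_range = as.integer(total_instances_range),
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Default planted-cohort specification
#'
#' Four informative domains with a class-mean frequency gap of 4 standard
#' deviations (two enriched in radiosensitive genomes, two in tolerant ones)
#' against 200 noise domains — the separation regime under which a frequency
#' classifier should succeed, at magnitudes typical of mid-abundance Pfam
#' domains (tens of instances per proteome).
#'
#' @param n_per_class Genomes per class; default 20.
#' @param seed Integer seed; default 1.
#' @param sd Per-genome spread of informative frequencies; default 0.001.
#' @param gap Class-mean difference; default `4 * sd`.
#' @return A [cohort_spec()].
#' @export
default_cohort_spec <- function(n_per_class = 20L, seed = 1L, sd = 0.001,
                                gap = 4 * sd) {
  base <- c(0.008, 0.010, 0.009, 0.011)
  up_in_rs <- c(TRUE, FALSE, TRUE, FALSE)
  cohort_spec(
    n_per_class = n_per_class,
    informative_domains = data.frame(
      domain_id = c("PF90001", "PF90002", "PF90003", "PF90004"),
      mean_radiosensitive = base + ifelse(up_in_rs, gap / 2, -gap / 2),
      mean_tolerant = base + ifelse(up_in_rs, -gap / 2, gap / 2),
      sd = sd,
      stringsAsFactors = FALSE
    ),
    n_noise_domains = 200L,
    seed = seed
  )
}

## Truncated-normal draw by rejection into (lo, hi); the acceptance region
## always has substantial mass for the frequency scales used here.
.rtruncnorm1 <- function(mean, sd, lo = 0, hi = 1) {
  if (sd == 0) return(mean)
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x > lo && x < hi) return(x)
  }
}

#' Generate a planted-signal synthetic cohort
#'
#' Realizes the cohort described by a [cohort_spec()]: annotation sets (with
#' instances grouped into synthetic proteins of 5 instances each), class
#' labels, and a ground-truth ledger recording every drawn frequency and
#' realized count, sufficient to recompute each genome's expected frequency
#' vector. Regeneration from the same spec is bit-identical.
#'
#' @param spec A [cohort_spec()].
#' @return List with `sets` (list of [pfam_annotation_set()]), `classes`
#'   (named character vector) and `ledger` (list with `informative_domains`,
#'   `noise_domains` and per-genome draws).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  inf <- spec$informative_domains
  noise_ids <- sprintf("PF95%03d", seq_len(spec$n_noise_domains))
  noise_ids <- setdiff(noise_ids, inf$domain_id)
  genome_ids <- c(sprintf("RS%03d", seq_len(spec$n_per_class)),
                  sprintf("TL%03d", seq_len(spec$n_per_class)))
  classes <- stats::setNames(
    rep(tolerance_classes(), each = spec$n_per_class), genome_ids
  )

  sets <- vector("list", length(genome_ids))
  genome_ledger <- vector("list", length(genome_ids))
  with_seed(spec$seed, {
    for (g in seq_along(genome_ids)) {
      cl <- classes[[g]]
      cl_means <- if (cl == "radiosensitive") inf$mean_radiosensitive else
        inf$mean_tolerant
      repeat {
        inf_freq <- vapply(seq_len(nrow(inf)), function(i) {
          .rtruncnorm1(cl_means[i], inf$sd[i])
        }, numeric(1L))
        if (sum(inf_freq) < 1) break
      }
      remainder <- 1 - sum(inf_freq)
      gam <- stats::rgamma(length(noise_ids), shape = spec$noise_concentration)
      noise_freq <- remainder * gam / sum(gam)
      freqs <- stats::setNames(c(inf_freq, noise_freq),
                               c(inf$domain_id, noise_ids))
      rng <- spec$total_instances_range
      n_total <- rng[1L] + sample.int(rng[2L] - rng[1L] + 1L, 1L) - 1L
      counts <- stats::setNames(
        as.integer(stats::rmultinom(1L, n_total, freqs)), names(freqs)
      )
      ## flatten, shuffle, and group into synthetic proteins of 5 instances
      instances <- rep(names(counts), counts)
      instances <- instances[sample.int(length(instances))]
      n_prot <- ceiling(length(instances) / 5L)
      records <- split(instances,
                       rep(seq_len(n_prot), each = 5L)[seq_along(instances)])
      names(records) <- sprintf("%s_p%04d", genome_ids[g], seq_len(n_prot))
      sets[[g]] <- pfam_annotation_set(genome_ids[g], records)
      genome_ledger[[g]] <- list(
        genome_id = genome_ids[g], class = cl, total_instances = n_total,
        expected_freq = as.list(freqs),
        counts = as.list(counts[counts > 0L])
      )
    }
  })
  names(genome_ledger) <- genome_ids

  list(
    sets = sets,
    classes = classes,
    ledger = list(
      informative_domains = inf,
      noise_domains = noise_ids,
      class_means = list(
        radiosensitive = stats::setNames(inf$mean_radiosensitive, inf$domain_id),
        tolerant = stats::setNames(inf$mean_tolerant, inf$domain_id)
      ),
      genomes = genome_ledger
    )
  )
}

#' Write an EggNOG-Mapper-style annotation file
#'
#' Emits the `.emapper.annotations` dialect consumed by
#' [read_eggnog_annotations()]: `##` metadata header, a `#query` column
#' header including a `PFAMs` column, one row per protein with
#' comma-separated accessions (`-` when none), and a `##` footer block.
#'
#' @param aset A [pfam_annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_eggnog_annotations <- function(aset, path) {
  stopifnot(inherits(aset, "pfam_annotation_set"))
  cells <- vapply(aset$records, function(d) {
    if (length(d) == 0L) "-" else paste(d, collapse = ",")
  }, character(1L))
  rows <- paste0(names(aset$records), "\t-\t-\t-\t", cells)
  writeLines(c(
    "## synthetic annotation emitted by the radtol cohort generator",
    "#query\tseed_ortholog\tevalue\tscore\tPFAMs",
    rows,
    sprintf("## %d queries scanned", length(aset$records))
  ), path)
  invisible(path)
}

#' Write a synthetic cohort to disk
#'
#' Serializes every genome in the chosen annotation dialect, plus a
#' `labels.tsv` (genome_id, class) and a `ledger.json` with the ground-truth
#' draws.
#'
#' @param cohort Result of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect `"canonical"` (per-protein TSV) or `"eggnog"`.
#' @return Character vector of the per-genome file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("canonical", "eggnog")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (dialect == "canonical") ".pfam.tsv" else ".emapper.annotations"
  paths <- vapply(cohort$sets, function(s) {
    p <- file.path(dir, paste0(s$genome_id, ext))
    if (dialect == "canonical") write_pfam_table(s, p) else
      write_eggnog_annotations(s, p)
    p
  }, character(1L))
  utils::write.table(
    data.frame(genome_id = names(cohort$classes),
               class = unname(cohort$classes)),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  jsonlite::write_json(cohort$ledger, file.path(dir, "ledger.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort directory
#'
#' Loads every annotation file of the given dialect in `dir`, and the
#' `labels.tsv` if present.
#'
#' @param dir Directory written by [write_cohort()] (or hand-assembled).
#' @param dialect `"canonical"` or `"eggnog"`.
#' @return List with `sets` and `classes` (NULL when no labels file).
#' @export
read_cohort <- function(dir, dialect = c("canonical", "eggnog")) {
  dialect <- match.arg(dialect)
  pattern <- if (dialect == "canonical") "\\.pfam\\.tsv$" else
    "\\.emapper\\.annotations$"
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) {
    stop("no ", dialect, " annotation files found in ", dir, call. = FALSE)
  }
  reader <- if (dialect == "canonical") read_pfam_table else
    read_eggnog_annotations
  sets <- lapply(files, function(f) {
    reader(f, sub(pattern, "", basename(f)))
  })
  classes <- NULL
  labels_path <- file.path(dir, "labels.tsv")
  if (file.exists(labels_path)) {
    df <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
    classes <- stats::setNames(df$class, df$genome_id)
  }
  list(sets = sets, classes = classes)
}

#' Generate a synthetic CFU survival assay
#'
#' Counts follow the single-hit exponential survival model with
#' multiplicative lognormal noise: a dosed plate count is
#' `Poisson(baseline_count * 10^(-dose/true_d10) * L)` and a sham count is
#' `Poisson(baseline_count * L)`, where `L` is lognormal with mean 1 and
#' coefficient of variation `cv`.
#'
#' @param true_d10 True D10 in Gy.
#' @param doses Positive doses in Gy.
#' @param cv Coefficient of variation of the multiplicative noise; default
#'   0.05.
#' @param n_technical Technical replicates per dose; default 3.
#' @param n_biological Biological replicates; default 3.
#' @param baseline_count Expected sham plate count; default 500. Values
#'   below 10 warn (the fit will be unstable).
#' @param seed Integer seed.
#' @return A [survival_assay()].
#' @export
generate_survival <- function(true_d10, doses, cv = 0.05, n_technical = 3L,
                              n_biological = 3L, baseline_count = 500,
                              seed = 1L) {
  stopifnot(is.numeric(true_d10), length(true_d10) == 1L, true_d10 > 0,
            length(doses) >= 1L, all(doses > 0), cv >= 0,
            n_technical >= 1L, n_biological >= 1L)
  if (baseline_count < 10) {
    warning("baseline_count < 10: the D10 fit will be unstable", call. = FALSE)
  }
  sigma2 <- log(1 + cv^2)
  rnoise <- function(n) {
    if (cv == 0) rep(1, n) else
      stats::rlnorm(n, meanlog = -sigma2 / 2, sdlog = sqrt(sigma2))
  }
  with_seed(seed, {
    reps <- lapply(seq_len(n_biological), function(b) {
      sham <- stats::rpois(n_technical, baseline_count * rnoise(n_technical))
      dosed <- lapply(doses, function(d) {
        lambda <- baseline_count * 10^(-d / true_d10) * rnoise(n_technical)
        stats::rpois(n_technical, lambda)
      })
      names(dosed) <- as.character(doses)
      list(sham_counts = sham, dosed_counts = dosed)
    })
    survival_assay(reps)
  })
}
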