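#' @keywords internal
"_PACKAGE"

## Pfam accessions are "PF" + exactly 5 digits; annotation sources may append
## a version suffix ("PF00300.23") which is stripped on parse.
.PFAM_RE <- "^PF[0-9]{5}$"

#' Construct a Pfam annotation set
#'
#' A `pfam_annotation_set` holds one genome's Pfam domain annotations grouped
#' by protein. Domain instances form a multiset: the same accession may occur
#' several times within one protein and across proteins, and every occurrence
#' counts toward `total_instances`.
#'
#' @param genome_id Single string identifying the genome.
#' @param records Named list mapping protein id to a character vector of Pfam
#'   accessions (possibly empty). Names must be unique.
#' @param skipped_tokens Number of unparseable accession tokens dropped during
#'   parsing (0 for programmatically built sets).
#' @return An object of class `pfam_annotation_set` with fields `genome_id`,
#'   `records`, `total_instances` and `skipped_tokens`.
#' @export
pfam_annotation_set <- function(genome_id, records, skipped_tokens = 0L) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L, nzchar(genome_id))
  if (length(records) > 0L) {
    if (is.null(names(records)) || anyDuplicated(names(records)) > 0L) {
      stop("protein records must be uniquely named", call. = FALSE)
    }
    bad <- vapply(records, function(d) length(d) > 0L && !all(grepl(.PFAM_RE, d)),
                  logical(1L))
    if (any(bad)) {
      stop("invalid Pfam accession in records for protein(s): ",
           paste(names(records)[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(
      genome_id = genome_id,
      records = records,
      total_instances = sum(lengths(records)),
      skipped_tokens = as.integer(skipped_tokens)
    ),
    class = "pfam_annotation_set"
  )
}

#' @export
print.pfam_annotation_set <- function(x, ...) {
  cat(sprintf(
    "<pfam_annotation_set> %s: %d proteins, %d domain instances, %d unique domains\n",
    x$genome_id, length(x$records), x$total_instances,
    length(unique(unlist(x$records, use.names = FALSE)))
  ))
  invisible(x)
}

## Normalise a raw accession token: strip version suffix, validate.
## Returns NA_character_ for tokens that are not Pfam accessions.
.clean_accession <- function(tokens) {
  tokens <- sub("\\.[0-9]+$", "", trimws(tokens))
  tokens[!grepl(.PFAM_RE, tokens)] <- NA_character_
  tokens
}

## Shared tail of both parsers: split cells into accessions, clean, tally
## skipped tokens, and assemble the annotation set.
.records_from_cells <- function(protein_ids, cells, sep, empty_token, genome_id) {
  skipped <- 0L
  records <- vector("list", length(protein_ids))
  names(records) <- protein_ids
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (is.na(cell) || cell == empty_token || cell == "") {
      records[[i]] <- character(0)
      next
    }
    toks <- strsplit(cell, sep, fixed = TRUE)[[1L]]
    toks <- toks[nzchar(trimws(toks))]
    cleaned <- .clean_accession(toks)
    n_bad <- sum(is.na(cleaned))
    if (n_bad > 0L) {
      warning(sprintf("genome %s, protein %s: skipped %d unparseable Pfam token(s)",
                      genome_id, protein_ids[i], n_bad), call. = FALSE)
      skipped <- skipped + n_bad
    }
    records[[i]] <- cleaned[!is.na(cleaned)]
  }
  pfam_annotation_set(genome_id, records, skipped_tokens = skipped)
}

#' Read an EggNOG-Mapper annotation file
#'
#' Parses the tab-separated `.emapper.annotations` format: `##` metadata lines
#' (header and footer blocks) are skipped, the column header line starts with
#' `#query`, and Pfam assignments live in the `PFAMs` column as a
#' comma-separated list, with `-` meaning no domain. One annotation record is
#' produced per data row (one row per predicted protein). Unknown columns are
#' ignored, so output from different EggNOG-Mapper versions is accepted.
#'
#' @param path Path to an `.emapper.annotations` file.
#' @param genome_id Genome identifier to attach to the parsed set.
#' @return A [pfam_annotation_set()].
#' @export
read_eggnog_annotations <- function(path, genome_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  header_idx <- grep("^#query", lines)
  if (length(header_idx) == 0L) {
    stop("not an EggNOG-Mapper annotation file (no '#query' header line): ",
         path, call. = FALSE)
  }
  header_idx <- header_idx[1L]
  cols <- strsplit(sub("^#", "", lines[header_idx]), "\t", fixed = TRUE)[[1L]]
  pfam_col <- match("PFAMs", cols)
  if (is.na(pfam_col)) {
    stop("EggNOG file lacks a PFAMs column; columns found: ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  body <- lines[seq_along(lines) > header_idx]
  ## everything from the first footer "##" line onward is ignored
  footer <- grep("^##", body)
  if (length(footer) > 0L) body <- body[seq_len(footer[1L] - 1L)]
  body <- body[nzchar(body)]
  if (length(body) == 0L) {
    return(pfam_annotation_set(genome_id, stats::setNames(list(), character(0))))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  protein_ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(protein_ids) > 0L) {
    stop("duplicate query ids in EggNOG file: ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- vapply(fields, function(f) {
    if (length(f) >= pfam_col) f[[pfam_col]] else NA_character_
  }, character(1L))
  .records_from_cells(protein_ids, cells, ",", "-", genome_id)
}

#' Read a canonical per-protein Pfam annotation table
#'
#' The canonical dialect is a two-column TSV with header
#' `protein_id<TAB>pfam_ids`, where `pfam_ids` is a `;`-separated list of Pfam
#' accessions (possibly empty, possibly carrying version suffixes which are
#' stripped).
#'
#' @inheritParams read_eggnog_annotations
#' @return A [pfam_annotation_set()].
#' @export
read_pfam_table <- function(path, genome_id) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty annotation table: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header[1:2], c("protein_id", "pfam_ids"))) {
    stop("expected header 'protein_id<TAB>pfam_ids', got: ", lines[1L],
         call. = FALSE)
  }
  body <- lines[-1L]
  if (length(body) == 0L) stop("annotation table has no data rows: ", path,
                               call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  protein_ids <- vapply(fields, `[[`, character(1L), 1L)
  if (anyDuplicated(protein_ids) > 0L) {
    stop("duplicate protein_id rows (ambiguous proteome): ",
         paste(unique(protein_ids[duplicated(protein_ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- vapply(fields, function(f) {
    if (length(f) >= 2L) f[[2L]] else ""
  }, character(1L))
  .records_from_cells(protein_ids, cells, ";", "", genome_id)
}

#' Write a canonical per-protein Pfam annotation table
#'
#' Inverse of [read_pfam_table()]: `write_pfam_table(read_pfam_table(f))`
#' reproduces the canonical form of `f` byte for byte.
#'
#' @param aset A [pfam_annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pfam_table <- function(aset, path) {
  stopifnot(inherits(aset, "pfam_annotation_set"))
  rows <- vapply(seq_along(aset$records), function(i) {
    paste0(names(aset$records)[i], "\t",
           paste(aset$records[[i]], collapse = ";"))
  }, character(1L))
  writeLines(c("protein_id\tpfam_ids", rows), path)
  invisible(path)
}

#' Tally domain instance counts
#'
#' @param aset A [pfam_annotation_set()].
#' @return Named integer vector of instance counts per domain, sorted by
#'   domain accession.
#' @export
domain_counts <- function(aset) {
  stopifnot(inherits(aset, "pfam_annotation_set"))
  all_domains <- unlist(aset$records, use.names = FALSE)
  if (length(all_domains) == 0L) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(all_domains)
  counts <- stats::setNames(as.integer(tab), names(tab))
  counts[order(names(counts))]
}

#' Relative Pfam domain frequencies of one genome
#'
#' The relative frequency of a domain is its instance count divided by the
#' total number of domain instances in the proteome, so frequencies over all
#' observed domains sum to 1. The denominator counts instances with
#' multiplicity, not unique domains.
#'
#' @param aset A [pfam_annotation_set()] with at least one domain instance.
#' @return Named numeric vector of frequencies in `[0, 1]`.
#' @export
compute_frequencies <- function(aset) {
  stopifnot(inherits(aset, "pfam_annotation_set"))
  if (aset$total_instances == 0L) {
    stop("empty annotation set for genome ", aset$genome_id,
         ": no Pfam instances to normalise (degenerate MAG)", call. = FALSE)
  }
  counts <- domain_counts(aset)
  counts / aset$total_instances
}

#' Build a genomes-by-domains frequency table
#'
#' Stacks per-genome relative frequencies into a matrix. When `domains` is
#' given, columns are restricted to that subset (a domain absent from a genome
#' gets frequency exactly 0, and row sums may then be below 1); otherwise the
#' union of all observed domains is used, and each row sums to 1.
#'
#' @param sets List of [pfam_annotation_set()] objects with unique genome ids.
#' @param domains Optional character vector of Pfam accessions selecting and
#'   ordering the columns.
#' @return An object of class `frequency_table`: list with `values` and
#'   `raw_counts` matrices (genomes as rows), `genome_ids`, `domain_ids` and
#'   per-genome `total_instances`.
#' @export
build_frequency_table <- function(sets, domains = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L,
            all(vapply(sets, inherits, logical(1L), "pfam_annotation_set")))
  genome_ids <- vapply(sets, `[[`, character(1L), "genome_id")
  if (anyDuplicated(genome_ids) > 0L) {
    stop("duplicate genome_id: ",
         paste(unique(genome_ids[duplicated(genome_ids)]), collapse = ", "),
         call. = FALSE)
  }
  count_list <- lapply(sets, domain_counts)
  if (is.null(domains)) {
    domains <- sort(unique(unlist(lapply(count_list, names), use.names = FALSE)))
  } else {
    stopifnot(is.character(domains), anyDuplicated(domains) == 0L)
  }
  raw <- matrix(0L, nrow = length(sets), ncol = length(domains),
                dimnames = list(genome_ids, domains))
  for (i in seq_along(count_list)) {
    hit <- intersect(names(count_list[[i]]), domains)
    raw[i, hit] <- count_list[[i]][hit]
  }
  totals <- vapply(sets, `[[`, numeric(1L), "total_instances")
  if (any(totals == 0)) {
    stop("empty annotation set for genome(s): ",
         paste(genome_ids[totals == 0], collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = raw / totals, raw_counts = raw,
         genome_ids = genome_ids, domain_ids = domains,
         total_instances = stats::setNames(totals, genome_ids)),
    class = "frequency_table"
  )
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> %d genomes x %d domains\n",
              length(x$genome_ids), length(x$domain_ids)))
  invisible(x)
}

#' Restrict a frequency table to a domain subset
#'
#' Domains absent from the table appear as all-zero columns; frequencies are
#' not renormalised (row sums may drop below 1).
#'
#' @param table A `frequency_table`.
#' @param domains Character vector of Pfam accessions.
#' @return A `frequency_table` with columns `domains`, in that order.
#' @export
restrict_frequency_table <- function(table, domains) {
  stopifnot(inherits(table, "frequency_table"), is.character(domains),
            anyDuplicated(domains) == 0L)
  values <- matrix(0, nrow = length(table$genome_ids), ncol = length(domains),
                   dimnames = list(table$genome_ids, domains))
  raw <- matrix(0L, nrow = length(table$genome_ids), ncol = length(domains),
                dimnames = list(table$genome_ids, domains))
  hit <- intersect(domains, table$domain_ids)
  values[, hit] <- table$values[, hit]
  raw[, hit] <- table$raw_counts[, hit]
  structure(
    list(values = values, raw_counts = raw,
         genome_ids = table$genome_ids, domain_ids = domains,
         total_instances = table$total_instances),
    class = "frequency_table"
  )
}

#' Write a frequency table as TSV
#'
#' Genomes as rows, domains as columns, frequencies at full precision
#' (`%.17g`), first column `genome_id`.
#'
#' @param table A `frequency_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frequency_table <- function(table, path) {
  stopifnot(inherits(table, "frequency_table"))
  header <- paste(c("genome_id", table$domain_ids), collapse = "\t")
  rows <- vapply(seq_along(table$genome_ids), function(i) {
    paste(c(table$genome_ids[i], sprintf("%.17g", table$values[i, ])),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), path)
  invisible(path)
}
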