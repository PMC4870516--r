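#' Write cataloged events as a BED-like TSV
#'
#' Writes one row per event in a BED6+ layout (0-based half-open span,
#' `score` fixed at 0) with extra columns carrying the donor, both 3' splice
#' sites and the full UA3E / AIDE-first-exon intervals, so that
#' [read_events_bed()] reproduces the catalog exactly.
#'
#' @param events Events tibble from [catalog_ua3e_events()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_events_bed <- function(events, path) {
  check_columns(events, c("event_id", "gene_id", "chrom", "strand",
                          "shared_donor", "ua3e_start", "ua3e_end",
                          "aide_start", "aide_end", "ua3e_3ss", "aide_3ss"),
                "events")
  bed <- events |>
    mutate(
      start = pmin(.data$shared_donor, .data$ua3e_start, .data$aide_start),
      end = pmax(.data$shared_donor, .data$ua3e_end, .data$aide_end),
      score = 0L
    ) |>
    select("chrom", "start", "end", "event_id", "score", "strand",
           "gene_id", "shared_donor", "ua3e_3ss", "aide_3ss",
           "ua3e_start", "ua3e_end", "aide_start", "aide_end")
  readr::write_tsv(bed, path)
  invisible(path)
}

#' Read events written by [write_events_bed()]
#'
#' @param path Path to the BED-like TSV.
#' @return An events tibble with the same columns as
#'   [catalog_ua3e_events()] output.
#' @export
read_events_bed <- function(path) {
  bed <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(bed, c("chrom", "event_id", "strand", "gene_id",
                       "shared_donor", "ua3e_3ss", "aide_3ss",
                       "ua3e_start", "ua3e_end", "aide_start", "aide_end"),
                "events BED")
  bed |>
    transmute(
      event_id = as.character(.data$event_id),
      gene_id = as.character(.data$gene_id),
      chrom = as.character(.data$chrom),
      strand = as.character(.data$strand),
      shared_donor = as.integer(.data$shared_donor),
      ua3e_start = as.integer(.data$ua3e_start),
      ua3e_end = as.integer(.data$ua3e_end),
      aide_start = as.integer(.data$aide_start),
      aide_end = as.integer(.data$aide_end),
      ua3e_3ss = as.integer(.data$ua3e_3ss),
      aide_3ss = as.integer(.data$aide_3ss)
    )
}

#' Write 3'ss windows as FASTA
#'
#' Each event contributes two records, `event_id|R4` (intronic side) and
#' `event_id|R5` (exonic side).
#'
#' @param windows Windows tibble from [extract_3ss_windows()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_windows_fasta <- function(windows, path) {
  check_columns(windows, c("event_id", "r4", "r5"), "windows")
  seqs <- c(rbind(windows$r4, windows$r5))
  names(seqs) <- c(rbind(paste0(windows$event_id, "|R4"),
                         paste0(windows$event_id, "|R5")))
  rna <- Biostrings::RNAStringSet(seqs)
  Biostrings::writeXStringSet(rna, path)
  invisible(path)
}

#' Read a windows FASTA written by [write_windows_fasta()]
#'
#' @param path FASTA path with `event_id|R4` / `event_id|R5` headers.
#' @return A windows tibble (`event_id`, `r4`, `r5`, realized widths).
#' @export
read_windows_fasta <- function(path) {
  seqs <- as.character(Biostrings::readRNAStringSet(path))
  ids <- sub("\\|R[45]$", "", names(seqs))
  region <- sub("^.*\\|", "", names(seqs))
  tibble(event_id = ids, region = region, seq = unname(seqs)) |>
    tidyr::pivot_wider(names_from = "region", values_from = "seq") |>
    rename(r4 = "R4", r5 = "R5") |>
    mutate(intronic_width = nchar(.data$r4), exonic_width = nchar(.data$r5))
}

#' Read a junction count table
#'
#' @param path TSV with columns `event_id`, `sample_id`, `inclusion`,
#'   `exclusion`.
#' @return A tibble with those columns; counts validated as non-negative
#'   integers.
#' @export
read_junction_counts <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(x, c("event_id", "sample_id", "inclusion", "exclusion"),
                "junction counts")
  check_counts(x$inclusion, "inclusion counts")
  check_counts(x$exclusion, "exclusion counts")
  x
}

#' Read a sample sheet
#'
#' @param path TSV with columns `sample_id` plus any of `stage`, `replicate`,
#'   `condition`.
#' @return A tibble.
#' @export
read_sample_sheet <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(x, "sample_id", "sample sheet")
  x
}
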