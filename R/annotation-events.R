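#' Parse gene models from GTF
#'
#' Reads exon features from a GTF/GFF2 annotation and returns one row per
#' exon with 0-based half-open coordinates, grouped by gene and transcript
#' and ordered 5'->3' in transcript orientation. Duplicate transcripts (same
#' exon chain within a gene, as in UCSC-style redundant annotation) are
#' collapsed to a single representative so downstream event cataloging does
#' not double count.
#'
#' @param gtf Path to a GTF file, or a character vector of GTF text lines.
#' @return A tibble with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end` (0-based half-open) and `exon_rank`
#'   (1 = transcript 5' end).
#' @details GTF input coordinates are 1-based inclusive; they are converted
#'   to the package-internal 0-based half-open convention. Transcripts
#'   declared without any exon feature are dropped with a warning. Malformed
#'   feature lines raise an error naming the offending line number.
#' @examples
#' gtf <- c(
#'   'chr1\ttoy\texon\t1\t100\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
#'   'chr1\ttoy\texon\t201\t300\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
#' )
#' read_gene_models(gtf)
#' @export
read_gene_models <- function(gtf) {
  if (length(gtf) == 1L && !grepl("\n", gtf) && file.exists(gtf)) {
    lines <- readLines(gtf)
  } else {
    lines <- unlist(strsplit(as.character(gtf), "\n", fixed = TRUE))
  }
  body_idx <- which(!grepl("^\\s*(#|$)", lines))
  if (length(body_idx) == 0L) {
    return(empty_gene_models())
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  bad <- body_idx[n_fields < 9L]
  if (length(bad) > 0L) {
    abort(sprintf("Malformed GTF line %d: expected 9 tab-separated fields.",
                  bad[[1L]]))
  }
  starts <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  bad <- body_idx[is.na(starts) | is.na(ends)]
  if (length(bad) > 0L) {
    abort(sprintf("Malformed GTF line %d: non-numeric coordinates.", bad[[1L]]))
  }

  tmp <- tempfile(fileext = ".gtf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  gr <- rtracklayer::import(tmp, format = "gtf")
  meta <- as.data.frame(gr)
  if (!all(c("gene_id", "transcript_id") %in% names(meta))) {
    abort("GTF attributes must include gene_id and transcript_id.")
  }

  exons <- as_tibble(meta) |>
    filter(.data$type == "exon") |>
    transmute(
      gene_id = as.character(.data$gene_id),
      transcript_id = as.character(.data$transcript_id),
      chrom = as.character(.data$seqnames),
      strand = as.character(.data$strand),
      start = as.integer(.data$start - 1L), # GTF 1-based incl. -> 0-based half-open
      end = as.integer(.data$end)
    )

  declared <- as_tibble(meta) |>
    distinct(.data$transcript_id) |>
    pull(.data$transcript_id)
  empty_tx <- setdiff(as.character(declared), unique(exons$transcript_id))
  empty_tx <- empty_tx[!is.na(empty_tx)]
  if (length(empty_tx) > 0L) {
    warn(sprintf("Dropping %d transcript(s) with zero exons: %s",
                 length(empty_tx), paste(empty_tx, collapse = ", ")))
  }
  if (nrow(exons) == 0L) {
    return(empty_gene_models())
  }
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("All exons must be on strand '+' or '-'.")
  }

  models <- exons |>
    group_by(.data$gene_id, .data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    mutate(exon_rank = if (first(.data$strand) == "+") row_number()
           else rev(row_number())) |>
    ungroup() |>
    arrange(.data$gene_id, .data$transcript_id, .data$exon_rank)

  one_chrom <- models |>
    group_by(.data$transcript_id) |>
    summarise(ok = dplyr::n_distinct(.data$chrom) == 1L &&
                dplyr::n_distinct(.data$strand) == 1L)
  if (!all(one_chrom$ok)) {
    abort(sprintf("Transcript(s) span multiple chromosomes or strands: %s",
                  paste(one_chrom$transcript_id[!one_chrom$ok], collapse = ", ")))
  }
  overlapping <- models |>
    group_by(.data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    summarise(ok = all(.data$start >= dplyr::lag(.data$end, default = -1L)))
  if (!all(overlapping$ok)) {
    abort(sprintf("Transcript(s) contain overlapping exons: %s",
                  paste(overlapping$transcript_id[!overlapping$ok], collapse = ", ")))
  }

  collapse_duplicate_transcripts(models)
}

empty_gene_models <- function() {
  tibble(gene_id = character(), transcript_id = character(),
         chrom = character(), strand = character(),
         start = integer(), end = integer(), exon_rank = integer())
}

# Keep one representative per identical exon chain within a gene
# (UCSC-style annotation redundancy would otherwise double-count events).
collapse_duplicate_transcripts <- function(models) {
  chains <- models |>
    group_by(.data$gene_id, .data$transcript_id) |>
    arrange(.data$exon_rank, .by_group = TRUE) |>
    summarise(chain = paste(.data$start, .data$end, sep = "-", collapse = ";"),
              .groups = "drop") |>
    group_by(.data$gene_id, .data$chain) |>
    arrange(.data$transcript_id, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
  models |>
    semi_join(chains, by = c("gene_id", "transcript_id"))
}

#' Catalog UA3E/AIDE events from gene models
#'
#' Identifies upstream alternative 3'-terminal exon (UA3E) events: the
#' terminal exon of a short isoform lying wholly inside an intron of a longer
#' isoform (the AIDE, "alternative isoform with downstream exon(s)"), with
#' both isoforms splicing from the identical donor site. Two filters remove
#' other alternative-processing classes:
#'
#' * cassette filter - the candidate terminal exon's acceptor must not be
#'   used as an internal-exon acceptor by any transcript of the gene;
#' * tandem-APA filter - the UA3E and AIDE acceptors must be distinct
#'   (terminal exons sharing one acceptor are alternative polyadenylation,
#'   not alternative splicing).
#'
#' Duplicate events (same donor and acceptor pair, e.g. seen through several
#' transcript pairs) are collapsed to one.
#'
#' @param models Gene models tibble from [read_gene_models()].
#' @return A tibble with one row per event: `event_id`, `gene_id`, `chrom`,
#'   `strand`, `shared_donor`, `ua3e_3ss`, `aide_3ss` (genomic positions,
#'   0-based boundary coordinates) and the UA3E / AIDE-first-exon intervals.
#'   Genes yielding no events are silently skipped.
#' @export
catalog_ua3e_events <- function(models) {
  check_columns(models, c("gene_id", "transcript_id", "chrom", "strand",
                          "start", "end", "exon_rank"), "models")
  if (nrow(models) == 0L) return(empty_events())
  events <- models |>
    group_by(.data$gene_id) |>
    dplyr::group_map(~ catalog_gene(.x, .y$gene_id)) |>
    bind_rows()
  if (nrow(events) == 0L) return(empty_events())
  events |>
    distinct(.data$gene_id, .data$shared_donor, .data$ua3e_3ss, .data$aide_3ss,
             .keep_all = TRUE) |>
    arrange(.data$chrom, .data$shared_donor, .data$ua3e_3ss)
}

empty_events <- function() {
  tibble(event_id = character(), gene_id = character(), chrom = character(),
         strand = character(), shared_donor = integer(),
         ua3e_start = integer(), ua3e_end = integer(),
         aide_start = integer(), aide_end = integer(),
         ua3e_3ss = integer(), aide_3ss = integer())
}

catalog_gene <- function(exons, gene_id) {
  tx <- split(exons[order(exons$exon_rank), ], exons$transcript_id[order(exons$exon_rank)])
  tx <- lapply(tx, function(e) e[order(e$exon_rank), ])
  n_ex <- vapply(tx, nrow, 0L)
  plus <- exons$strand[1L] == "+"
  donor_of <- function(e) if (plus) e$end else e$start      # 3' boundary of an exon
  acceptor_of <- function(e) if (plus) e$start else e$end   # 5' boundary (3'ss)

  # acceptors of internal exons anywhere in the gene (cassette filter)
  internal_acc <- integer(0)
  for (e in tx) {
    if (nrow(e) > 2L) {
      inner <- e[seq(2L, nrow(e) - 1L), ]
      internal_acc <- c(internal_acc, acceptor_of(inner))
    }
  }

  out <- list()
  for (s_id in names(tx)) {
    s <- tx[[s_id]]
    if (nrow(s) < 2L) next
    term <- s[nrow(s), ]
    up <- s[nrow(s) - 1L, ]
    donor <- donor_of(up)
    t_3ss <- acceptor_of(term)
    for (l_id in setdiff(names(tx), s_id)) {
      l <- tx[[l_id]]
      hit <- which(donor_of(l) == donor & l$exon_rank < n_ex[[l_id]])
      if (length(hit) == 0L) next
      a <- l[hit[[1L]] + 1L, ]
      a_3ss <- acceptor_of(a)
      inside <- if (plus) {
        term$start > donor && term$end <= a$start
      } else {
        term$end < donor && term$start >= a$end
      }
      if (!inside) next
      if (t_3ss %in% internal_acc) next   # cassette exon decoy
      if (t_3ss == a_3ss) next            # tandem-APA decoy
      out[[length(out) + 1L]] <- tibble(
        event_id = sprintf("%s:%d:%d:%d", gene_id, donor, t_3ss, a_3ss),
        gene_id = gene_id, chrom = term$chrom, strand = term$strand,
        shared_donor = as.integer(donor),
        ua3e_start = term$start, ua3e_end = term$end,
        aide_start = a$start, aide_end = a$end,
        ua3e_3ss = as.integer(t_3ss), aide_3ss = as.integer(a_3ss))
    }
  }
  bind_rows(out)
}

#' Extract 3' splice-site sequence windows
#'
#' For each cataloged event, extracts the sequence window centered on the
#' UA3E 3' splice site: an intronic region R4 immediately upstream of the
#' acceptor and an exonic region R5 immediately downstream. Sequences are
#' strand-corrected (sense of the transcript) and reported as RNA (T -> U).
#'
#' @param events Events tibble from [catalog_ua3e_events()].
#' @param genome A FASTA path, a named character vector of sequences, or a
#'   [Biostrings::DNAStringSet].
#' @param width Total window width in nucleotides (default 250).
#' @param intronic_width Width of the intronic part R4; defaults to
#'   `width / 2` (symmetric split around the acceptor).
#' @return A tibble with `event_id`, `r4`, `r5`, `intronic_width`,
#'   `exonic_width`. Windows running off a contig end are truncated with a
#'   warning and the realized widths are recorded.
#' @export
extract_3ss_windows <- function(events, genome, width = 250L,
                                intronic_width = NULL) {
  check_columns(events, c("event_id", "chrom", "strand", "ua3e_3ss"), "events")
  if (width < 2L) abort("`width` must be at least 2.")
  wi <- if (is.null(intronic_width)) as.integer(width %/% 2L) else as.integer(intronic_width)
  we <- as.integer(width) - wi
  if (wi < 1L || we < 1L) abort("window must have at least 1 intronic and 1 exonic nt.")

  seqs <- load_genome(genome)
  missing_chrom <- setdiff(unique(events$chrom), names(seqs))
  if (length(missing_chrom) > 0L) {
    abort(sprintf("Chromosome(s) missing from genome: %s",
                  paste(missing_chrom, collapse = ", ")))
  }

  truncated <- FALSE
  rows <- purrr::pmap(
    list(events$event_id, events$chrom, events$strand, events$ua3e_3ss),
    function(event_id, chrom, strand, a) {
      len <- nchar(seqs[[chrom]])
      if (strand == "+") {
        i0 <- max(0L, a - wi); i1 <- a          # intron [a-wi, a)
        e0 <- a; e1 <- min(len, a + we)         # exon   [a, a+we)
        r4 <- substr(seqs[[chrom]], i0 + 1L, i1)
        r5 <- substr(seqs[[chrom]], e0 + 1L, e1)
      } else {
        i0 <- a; i1 <- min(len, a + wi)         # intron genomically right of 3'ss
        e0 <- max(0L, a - we); e1 <- a
        r4 <- revcomp(substr(seqs[[chrom]], i0 + 1L, i1))
        r5 <- revcomp(substr(seqs[[chrom]], e0 + 1L, e1))
      }
      if (nchar(r4) < wi || nchar(r5) < we) truncated <<- TRUE
      tibble(event_id = event_id,
             r4 = dna_to_rna(r4), r5 = dna_to_rna(r5),
             intronic_width = nchar(r4), exonic_width = nchar(r5))
    })
  if (truncated) {
    warn("Some windows were truncated at contig boundaries; see the recorded widths.")
  }
  bind_rows(rows)
}

load_genome <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    s <- as.character(genome)
  } else if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    s <- as.character(Biostrings::readDNAStringSet(genome))
  } else if (is.character(genome) && !is.null(names(genome))) {
    s <- genome
  } else {
    abort("`genome` must be a FASTA path, a named character vector, or a DNAStringSet.")
  }
  names(s) <- sub("\\s.*$", "", names(s))
  toupper(s)
}

revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

dna_to_rna <- function(x) chartr("Tt", "Uu", toupper(x))
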