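#' Scan a sequence set for a k-mer motif
#'
#' Counts overlapping occurrences of an RNA k-mer in each sequence and
#' returns the 0-based match positions. `N` bases never match.
#'
#' @param seqs Character vector of RNA sequences (alphabet A, C, G, U, N;
#'   T is accepted and read as U). Names, if present, are carried through.
#' @param kmer A single RNA k-mer.
#' @return A tibble with one row per sequence: `seq_id`, `count`,
#'   `positions` (list column of 0-based integer vectors). A k-mer longer
#'   than the sequence yields count 0.
#' @examples
#' scan_motif("UCUUCUU", "UCUU")  # 2 overlapping matches, positions 0 and 3
#' @export
scan_motif <- function(seqs, kmer) {
  kmer <- validate_kmers(kmer, single = TRUE)
  seqs <- chartr("Tt", "Uu", toupper(seqs))
  bad <- grepl("[^ACGUN]", seqs)
  if (any(bad)) {
    abort(sprintf("Sequence(s) contain characters outside {A,C,G,U,N}: %s",
                  paste(which(bad), collapse = ", ")))
  }
  ids <- names(seqs) %||% as.character(seq_along(seqs))
  hits <- gregexpr(paste0("(?=", kmer, ")"), seqs, perl = TRUE)
  rows <- purrr::map2(ids, hits, function(id, h) {
    pos <- as.integer(h)
    pos <- pos[pos > 0L] - 1L # 0-based
    tibble(seq_id = id, count = length(pos), positions = list(pos))
  })
  bind_rows(rows)
}

validate_kmers <- function(kmers, single = FALSE) {
  kmers <- chartr("Tt", "Uu", toupper(as.character(kmers)))
  if (single && length(kmers) != 1L) abort("`kmer` must be a single string.")
  if (length(kmers) == 0L) abort("Motif set must be non-empty.")
  if (any(grepl("[^ACGU]", kmers))) {
    abort("k-mers must be RNA strings over {A,C,G,U}.")
  }
  if (length(unique(nchar(kmers))) != 1L) {
    abort("All k-mers in a motif set must have the same length.")
  }
  kmers
}

#' Built-in pyrimidine-rich (Ptbp-type) hexamer set
#'
#' All hexamers over the \{C, U\} alphabet that contain `UCUU` or `CUCU` as a
#' substring - a deterministic, documented stand-in for polypyrimidine
#' tract-binding protein (Ptbp1/2) consensus motifs. User-supplied motif
#' lists can be passed to [enrich_motifs()] instead.
#'
#' @return A character vector of hexamers, sorted.
#' @export
default_ptbp_motifs <- function() {
  base <- c("C", "U")
  grid <- do.call(expand.grid, rep(list(base), 6))
  hex <- apply(grid, 1, paste0, collapse = "")
  sort(hex[grepl("UCUU", hex, fixed = TRUE) | grepl("CUCU", hex, fixed = TRUE)])
}

#' Motif enrichment in regulated vs background 3'ss windows
#'
#' For each k-mer, builds the presence/absence 2x2 table over the two window
#' sets (restricted to region R4, R5, or their union) and tests
#' over-representation in the regulated set with a one-sided Fisher exact
#' test (two-sided available via `alternative`). P-values are BH-adjusted
#' across all k-mers tested.
#'
#' @param regulated,background Window tibbles (`event_id`, `r4`, `r5`), e.g.
#'   from [extract_3ss_windows()] or [simulate_windows()].
#' @param motifs Character vector of same-length RNA k-mers, e.g.
#'   [default_ptbp_motifs()].
#' @param region `"both"` (presence in either window, default), `"R4"`
#'   (intronic) or `"R5"` (exonic).
#' @param alternative Passed to [stats::fisher.test()]; default `"greater"`.
#' @return A tibble sorted by `p_adj` then `p`: `kmer`,
#'   `n_regulated_with`, `n_regulated_without`, `n_background_with`,
#'   `n_background_without`, `odds_ratio` (sample odds ratio), `p`, `p_adj`,
#'   `region`.
#' @export
enrich_motifs <- function(regulated, background, motifs, region = c("both", "R4", "R5"),
                          alternative = "greater") {
  region <- match.arg(region)
  check_columns(regulated, c("event_id", "r4", "r5"), "regulated")
  check_columns(background, c("event_id", "r4", "r5"), "background")
  if (nrow(regulated) == 0L || nrow(background) == 0L) {
    abort("Both window sets must be non-empty.")
  }
  motifs <- validate_kmers(motifs)

  presence <- function(windows, kmer) {
    has4 <- stringr::str_detect(chartr("Tt", "Uu", toupper(windows$r4)),
                                stringr::fixed(kmer))
    has5 <- stringr::str_detect(chartr("Tt", "Uu", toupper(windows$r5)),
                                stringr::fixed(kmer))
    switch(region, R4 = has4, R5 = has5, both = has4 | has5)
  }

  rows <- purrr::map(motifs, function(kmer) {
    reg <- presence(regulated, kmer)
    bg <- presence(background, kmer)
    a <- sum(reg); b <- sum(!reg); c <- sum(bg); d <- sum(!bg)
    p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2),
                            alternative = alternative)$p.value
    tibble(kmer = kmer, n_regulated_with = a, n_regulated_without = b,
           n_background_with = c, n_background_without = d,
           odds_ratio = sample_odds_ratio(a, b, c, d), p = p)
  })
  bind_rows(rows) |>
    mutate(p_adj = bh_adjust(.data$p), region = region) |>
    arrange(.data$p_adj, .data$p, .data$kmer)
}
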