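# Toy gene-model fixtures built in code. Coordinates in GTF are 1-based
# inclusive; comments give the 0-based half-open equivalents used internally.

gtf_line <- function(chrom, start1, end1, strand, gene, tx) {
  sprintf('%s\ttoy\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
          chrom, start1, end1, strand, gene, tx)
}

# Genuine UA3E/AIDE gene on + strand:
#   long  t1: E1 [100,300) -> A [900,1100) -> E3 [1300,1400)
#   short t2: E1 [100,300) -> T [500,650)   (terminal, inside t1's intron)
# Expected event: donor 300, ua3e_3ss 500, aide_3ss 900.
toy_true_gtf <- function(chrom = "chrT", gene = "gT") {
  c(gtf_line(chrom, 101, 300, "+", gene, paste0(gene, ".t1")),
    gtf_line(chrom, 901, 1100, "+", gene, paste0(gene, ".t1")),
    gtf_line(chrom, 1301, 1400, "+", gene, paste0(gene, ".t1")),
    gtf_line(chrom, 101, 300, "+", gene, paste0(gene, ".t2")),
    gtf_line(chrom, 501, 650, "+", gene, paste0(gene, ".t2")))
}

# Cassette decoy: adds t3 = E1 -> T -> A -> E3, making T an internal exon.
toy_cassette_gtf <- function(chrom = "chrC", gene = "gC") {
  c(toy_true_gtf(chrom, gene),
    gtf_line(chrom, 101, 300, "+", gene, paste0(gene, ".t3")),
    gtf_line(chrom, 501, 650, "+", gene, paste0(gene, ".t3")),
    gtf_line(chrom, 901, 1100, "+", gene, paste0(gene, ".t3")),
    gtf_line(chrom, 1301, 1400, "+", gene, paste0(gene, ".t3")))
}

# Tandem-APA decoy: two terminal exons sharing the acceptor at 500 but with
# different 3' ends.
toy_tandem_apa_gtf <- function(chrom = "chrA", gene = "gA") {
  c(gtf_line(chrom, 101, 300, "+", gene, paste0(gene, ".t1")),
    gtf_line(chrom, 501, 650, "+", gene, paste0(gene, ".t1")),
    gtf_line(chrom, 101, 300, "+", gene, paste0(gene, ".t2")),
    gtf_line(chrom, 501, 900, "+", gene, paste0(gene, ".t2")))
}

# Minus-strand gene with exons listed in descending genomic order:
#   short t2 (5'->3'): E1 [30,40) -> T [14,20); long t1: E1 [30,40) -> A [4,10)
# Donor 30; ua3e_3ss 20 (T's genomic end); aide_3ss 10.
toy_minus_gtf <- function(chrom = "chrM", gene = "gM") {
  c(gtf_line(chrom, 31, 40, "-", gene, paste0(gene, ".t1")),
    gtf_line(chrom, 5, 10, "-", gene, paste0(gene, ".t1")),
    gtf_line(chrom, 31, 40, "-", gene, paste0(gene, ".t2")),
    gtf_line(chrom, 15, 20, "-", gene, paste0(gene, ".t2")))
}

# 40-nt sequence for chrM, written 5'->3' on the + strand.
toy_minus_genome <- function() {
  c(chrM = "ACGTACGTACGTACGTACGTAAAACCCCGGGGTTTTACGT")
}

random_genome <- function(chroms, len = 2000, seed = 1) {
  stopifnot(length(chroms) > 0)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  setNames(vapply(chroms, function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, ""), chroms)
}

# Deterministic junction-count table builder: one event, counts given as a
# stage x replicate matrix of (inclusion, exclusion) pairs.
counts_from_psi <- function(event_id, psi_by_stage, depth, stages, reps = 3) {
  rows <- list()
  samples <- list()
  for (s in seq_along(stages)) {
    for (r in seq_len(reps)) {
      sid <- paste0(stages[s], "_r", r)
      inc <- round(depth * psi_by_stage[s] / 100)
      rows[[length(rows) + 1]] <- tibble::tibble(
        event_id = event_id, sample_id = sid,
        inclusion = inc, exclusion = depth - inc)
      samples[[length(samples) + 1]] <- tibble::tibble(
        sample_id = sid, stage = stages[s], replicate = r)
    }
  }
  list(counts = dplyr::bind_rows(rows),
       samples = dplyr::distinct(dplyr::bind_rows(samples)))
}
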