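test_that("GTF parsing converts coordinates and orders exons 5'->3'", {
  models <- read_gene_models(toy_true_gtf())
  expect_equal(dplyr::n_distinct(models$gene_id), 1)
  expect_equal(dplyr::n_distinct(models$transcript_id), 2)
  t1 <- models[models$transcript_id == "gT.t1", ]
  expect_equal(t1$start, c(100L, 900L, 1300L)) # 0-based half-open
  expect_equal(t1$end, c(300L, 1100L, 1400L))
  expect_equal(t1$exon_rank, 1:3)
})

test_that("minus-strand exons listed in descending order are reordered", {
  models <- read_gene_models(toy_minus_gtf())
  t1 <- models[models$transcript_id == "gM.t1", ]
  t1 <- t1[order(t1$exon_rank), ]
  # rank 1 must be the genomically rightmost exon on the minus strand
  expect_equal(t1$start, c(30L, 4L))
  expect_equal(t1$end, c(40L, 10L))
})

test_that("empty and malformed annotation streams are handled", {
  expect_equal(nrow(read_gene_models(character(0))), 0)
  expect_equal(nrow(read_gene_models("# just a comment")), 0)
  bad <- c(toy_true_gtf(), "chrT\tbroken line without tabs")
  expect_error(read_gene_models(bad), "line 6")
})

test_that("duplicate transcripts are collapsed by exon-chain identity", {
  dup <- c(toy_true_gtf(),
           gtf_line("chrT", 101, 300, "+", "gT", "gT.t2copy"),
           gtf_line("chrT", 501, 650, "+", "gT", "gT.t2copy"))
  models <- read_gene_models(dup)
  expect_equal(dplyr::n_distinct(models$transcript_id), 2)
  expect_equal(nrow(catalog_ua3e_events(models)), 1)
})

test_that("a genuine UA3E/AIDE gene yields exactly one event", {
  ev <- catalog_ua3e_events(read_gene_models(toy_true_gtf()))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$shared_donor, 300L)
  expect_equal(ev$ua3e_3ss, 500L)
  expect_equal(ev$aide_3ss, 900L)
  expect_true(ev$ua3e_3ss != ev$aide_3ss)
})

test_that("cassette and tandem-APA decoys are filtered out", {
  expect_equal(nrow(catalog_ua3e_events(read_gene_models(toy_cassette_gtf()))), 0)
  expect_equal(nrow(catalog_ua3e_events(read_gene_models(toy_tandem_apa_gtf()))), 0)
})

test_that("minus-strand events are cataloged with strand-correct 3'ss", {
  ev <- catalog_ua3e_events(read_gene_models(toy_minus_gtf()))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$shared_donor, 30L)
  expect_equal(ev$ua3e_3ss, 20L)
  expect_equal(ev$aide_3ss, 10L)
})

test_that("window extraction splits around the acceptor and strand-corrects", {
  ev <- catalog_ua3e_events(read_gene_models(toy_true_gtf()))
  genome <- random_genome("chrT", len = 2000, seed = 11)
  w <- extract_3ss_windows(ev, genome, width = 10)
  expect_equal(w$intronic_width, 5)
  expect_equal(w$exonic_width, 5)
  # + strand: R4 is genomic [495,500), R5 is [500,505), T -> U
  expect_equal(w$r4, unname(chartr("T", "U", substr(genome, 496, 500))))
  expect_equal(w$r5, unname(chartr("T", "U", substr(genome, 501, 505))))
})

test_that("minus-strand windows are reverse-complemented (hand-computed)", {
  ev <- catalog_ua3e_events(read_gene_models(toy_minus_gtf()))
  w <- extract_3ss_windows(ev, toy_minus_genome(), width = 4)
  # acceptor at genomic 20: intron slice [20,22) = "AA", exon slice [18,20) = "GT"
  expect_equal(w$r4, "UU")
  expect_equal(w$r5, "AC")
})

test_that("windows are truncated at contig boundaries with a warning", {
  ev <- catalog_ua3e_events(read_gene_models(toy_minus_gtf()))
  expect_warning(w <- extract_3ss_windows(ev, toy_minus_genome(), width = 250),
                 "truncated")
  expect_equal(w$intronic_width, 20)   # only 20 nt right of the acceptor
  expect_equal(w$exonic_width, 20)
  expect_error(extract_3ss_windows(ev, c(other = "ACGT"), width = 4), "chrM")
})

test_that("events round-trip through the BED-like TSV without loss", {
  sim <- simulate_gene_models(n_events = 8, n_cassette = 3, n_tandem_apa = 3,
                              seed = 21)
  ev <- catalog_ua3e_events(read_gene_models(sim$gtf))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_bed(ev, path)
  expect_equal(as.data.frame(read_events_bed(path)), as.data.frame(ev))
})

test_that("mirroring a plus-strand gene to the minus strand is symmetric", {
  len <- 2000L
  plus_gtf <- toy_true_gtf()
  # mirror: position p (1-based) -> len - p + 1, strand flipped
  mirror_line <- function(line) {
    f <- strsplit(line, "\t")[[1]]
    s <- as.integer(f[4]); e <- as.integer(f[5])
    f[4] <- as.character(len - e + 1); f[5] <- as.character(len - s + 1)
    f[7] <- "-"
    paste(f, collapse = "\t")
  }
  minus_gtf <- vapply(plus_gtf, mirror_line, "")
  genome <- random_genome("chrT", len = len, seed = 3)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(genome)))
  ev_p <- catalog_ua3e_events(read_gene_models(plus_gtf))
  ev_m <- catalog_ua3e_events(read_gene_models(unname(minus_gtf)))
  expect_equal(nrow(ev_p), nrow(ev_m))
  w_p <- extract_3ss_windows(ev_p, genome, width = 20)
  w_m <- extract_3ss_windows(ev_m, c(chrT = rc), width = 20)
  expect_equal(w_m$r4, w_p$r4)
  expect_equal(w_m$r5, w_p$r5)
})
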