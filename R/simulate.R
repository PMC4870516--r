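#' Default developmental stage labels
#'
#' The eight-stage ESC-to-glutamatergic-neuron time course used throughout
#' the package: DIV -8, DIV -4, DIV 0, 1, 7, 16, 21 and 28 (days in vitro,
#' negative values preceding plating).
#'
#' @return Character vector of 8 stage labels in developmental order.
#' @export
default_stages <- function() {
  c("DIVm8", "DIVm4", "DIV0", "DIV1", "DIV7", "DIV16", "DIV21", "DIV28")
}

#' Simulate gene models with UA3E events and decoys
#'
#' Builds one synthetic locus per gene on its own contig: true events are
#' two-transcript genes whose short isoform terminates inside an intron of
#' the long isoform (shared donor); cassette decoys add a third transcript
#' using the candidate exon internally; tandem-APA decoys have two terminal
#' exons sharing one acceptor but different 3' ends. Exon boundaries are
#' jittered per gene and strands drawn at random so both orientations are
#' exercised. Byte-reproducible given `seed`.
#'
#' @param n_events Number of genes with a genuine UA3E/AIDE event.
#' @param n_cassette,n_tandem_apa Numbers of decoy genes (default 0).
#' @param locus_length Contig length per gene (default 2500 nt).
#' @param seed RNG seed (required).
#' @return A list with `gtf` (character vector of GTF lines), `genome`
#'   (named character vector of contig sequences), and `truth` (tibble with
#'   `gene_id`, `chrom`, `strand`, `class`, and for true events the expected
#'   `shared_donor`, `ua3e_3ss`, `aide_3ss`).
#' @export
simulate_gene_models <- function(n_events, n_cassette = 0L, n_tandem_apa = 0L,
                                 locus_length = 2500L, seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (n_events < 0 || n_cassette < 0 || n_tandem_apa < 0) {
    abort("Gene counts must be non-negative.")
  }
  classes <- c(rep("true_event", n_events), rep("cassette", n_cassette),
               rep("tandem_apa", n_tandem_apa))
  with_seed(seed, {
    genes <- purrr::imap(classes, function(cls, i) {
      simulate_gene_locus(sprintf("g%04d", i), cls, locus_length)
    })
    gtf <- unlist(purrr::map(genes, "gtf"))
    genome <- setNames(purrr::map_chr(genes, "seq"),
                       purrr::map_chr(genes, "chrom"))
    truth <- bind_rows(purrr::map(genes, "truth"))
    list(gtf = gtf, genome = genome, truth = truth)
  })
}

simulate_gene_locus <- function(gene_id, class, locus_length) {
  chrom <- paste0(gene_id, "_locus")
  strand <- sample(c("+", "-"), 1L)
  # jittered + strand layout (0-based half-open), mirrored for - strand
  e1_start <- 100L + sample.int(50L, 1L)
  e1_end <- e1_start + 150L + sample.int(50L, 1L)      # donor at e1_end
  t_start <- e1_end + 80L + sample.int(60L, 1L)        # UA3E inside intron
  t_end <- t_start + 120L + sample.int(60L, 1L)
  a_start <- t_end + 80L + sample.int(60L, 1L)         # AIDE first exon
  a_end <- a_start + 150L + sample.int(50L, 1L)
  e3_start <- a_end + 80L + sample.int(40L, 1L)
  e3_end <- e3_start + 100L + sample.int(40L, 1L)
  if (e3_end > locus_length) {
    abort("Impossible geometry: exon layout exceeds `locus_length`.")
  }

  flip <- function(s, e) c(locus_length - e, locus_length - s)
  iv <- function(s, e) {
    if (strand == "+") c(s, e) else flip(s, e)
  }
  e1 <- iv(e1_start, e1_end); tt <- iv(t_start, t_end)
  aa <- iv(a_start, a_end); e3 <- iv(e3_start, e3_end)

  tx <- switch(class,
    true_event = list(t1 = list(e1, aa, e3), t2 = list(e1, tt)),
    cassette = list(t1 = list(e1, aa, e3), t2 = list(e1, tt),
                    t3 = list(e1, tt, aa, e3)),
    tandem_apa = {
      t_long <- iv(t_start, t_end + 120L)
      list(t1 = list(e1, tt), t2 = list(e1, t_long))
    })

  gtf <- unlist(purrr::imap(tx, function(exons, tx_name) {
    vapply(exons, function(ex) {
      sprintf('%s\tisocoex_sim\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s.%s";',
              chrom, ex[1] + 1L, ex[2], strand, gene_id, gene_id, tx_name)
    }, "")
  }))

  donor <- if (strand == "+") e1[2] else e1[1]
  ua3e_3ss <- if (strand == "+") tt[1] else tt[2]
  aide_3ss <- if (strand == "+") aa[1] else aa[2]
  truth <- tibble(
    gene_id = gene_id, chrom = chrom, strand = strand, class = class,
    shared_donor = if (class == "true_event") as.integer(donor) else NA_integer_,
    ua3e_3ss = if (class == "true_event") as.integer(ua3e_3ss) else NA_integer_,
    aide_3ss = if (class == "true_event") as.integer(aide_3ss) else NA_integer_
  )
  seq <- paste(sample(c("A", "C", "G", "T"), locus_length, replace = TRUE),
               collapse = "")
  list(chrom = chrom, gtf = gtf, truth = truth, seq = seq)
}

logistic_trajectory <- function(psi_start, psi_end, n_stages, switch_stage,
                                slope) {
  s <- seq_len(n_stages)
  psi_start + (psi_end - psi_start) * plogis(slope * (s - switch_stage))
}

# Beta-binomial draw: correlation rho within a sample's reads.
rbetabinom <- function(n, size, prob, rho) {
  if (rho == 0) return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  p <- rbeta(n, a, b)
  rbinom(n, size, p)
}

#' Simulate a developmental time course of junction counts
#'
#' Each event follows a logistic psi trajectory across stages (increasing,
#' decreasing, or flat with a constant event-specific psi). Per sample, the
#' junction total is Poisson with mean `depth_mean` and the inclusion count
#' is beta-binomial with intra-sample correlation `rho` (replicate
#' overdispersion of splicing ratios).
#'
#' @param n_events Total number of events.
#' @param n_increasing,n_decreasing Events with rising / falling UA3E psi
#'   (the remainder are flat).
#' @param psi_start,psi_end Endpoints (percent) of the planted trajectories
#'   (defaults 5 -> 45, the halfway-switch regime).
#' @param flat_psi_range Range from which flat events draw their constant
#'   psi (default 10-90).
#' @param stages Stage labels (default [default_stages()]).
#' @param replicates_per_stage Replicates per stage (default 3).
#' @param depth_mean Expected junction total per event per sample
#'   (default 100).
#' @param rho Beta-binomial overdispersion in \[0, 1) (default 0.02).
#' @param switch_stage,slope Logistic midpoint (default mid-course) and
#'   steepness (default 1.5 per stage).
#' @param seed RNG seed (required).
#' @return A list with `counts` (event x sample junction counts), `samples`
#'   (sample sheet with `stage`, `replicate`, `condition`), and `truth`
#'   (per-event class and true psi trajectory as a list column).
#' @export
simulate_timecourse_counts <- function(n_events, n_increasing = 0L,
                                       n_decreasing = 0L,
                                       psi_start = 5, psi_end = 45,
                                       flat_psi_range = c(10, 90),
                                       stages = default_stages(),
                                       replicates_per_stage = 3L,
                                       depth_mean = 100,
                                       rho = 0.02,
                                       switch_stage = NULL, slope = 1.5,
                                       seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  if (n_increasing + n_decreasing > n_events) {
    abort("`n_increasing` + `n_decreasing` cannot exceed `n_events`.")
  }
  n_stages <- length(stages)
  if (n_stages < 2L) abort("At least two stages are required.")
  switch_stage <- switch_stage %||% (n_stages + 1) / 2

  with_seed(seed, {
    event_id <- sprintf("ev%04d", seq_len(n_events))
    class <- c(rep("increasing", n_increasing), rep("decreasing", n_decreasing),
               rep("flat", n_events - n_increasing - n_decreasing))
    traj <- purrr::map(class, function(cl) {
      switch(cl,
        increasing = logistic_trajectory(psi_start, psi_end, n_stages,
                                         switch_stage, slope),
        decreasing = logistic_trajectory(psi_end, psi_start, n_stages,
                                         switch_stage, slope),
        flat = rep(runif(1, flat_psi_range[1], flat_psi_range[2]), n_stages))
    })
    samples <- tidyr::expand_grid(stage = factor(stages, levels = stages),
                                  replicate = seq_len(replicates_per_stage)) |>
      mutate(sample_id = paste0(.data$stage, "_r", .data$replicate),
             condition = "timecourse") |>
      select("sample_id", "stage", "replicate", "condition")

    counts <- tidyr::expand_grid(event_idx = seq_len(n_events),
                                 sample_idx = seq_len(nrow(samples))) |>
      mutate(
        event_id = event_id[.data$event_idx],
        sample_id = samples$sample_id[.data$sample_idx],
        psi_true = purrr::map2_dbl(.data$event_idx, .data$sample_idx, function(e, s) {
          traj[[e]][as.integer(samples$stage[s])]
        }),
        total = rpois(n(), depth_mean),
        inclusion = rbetabinom(n(), .data$total, .data$psi_true / 100, rho),
        exclusion = .data$total - .data$inclusion
      ) |>
      select("event_id", "sample_id", "inclusion", "exclusion")

    truth <- tibble(event_id = event_id, class = class, psi_trajectory = traj)
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate knockdown junction counts
#'
#' Three condition groups (control, single knockdown, double knockdown).
#' Dependent events shift their UA3E psi in the same direction in both
#' knockdowns (loss of the repressors de-represses the upstream terminal
#' exon); independent events keep their control psi throughout.
#'
#' @param n_events Total events; the first `n_dependent` respond.
#' @param n_dependent Number of knockdown-dependent events.
#' @param psi_control Control psi (percent) for dependent events
#'   (default 20).
#' @param delta_kd1,delta_kd12 Psi shifts (percentage points) under single /
#'   double knockdown (defaults +20 / +30).
#' @param replicates Replicates per condition (default 3).
#' @param depth_mean,rho As in [simulate_timecourse_counts()].
#' @param seed RNG seed (required).
#' @return A list with `counts`, `samples` (conditions control/kd1/kd12) and
#'   `truth`.
#' @export
simulate_knockdown_counts <- function(n_events, n_dependent = 0L,
                                      psi_control = 20, delta_kd1 = 20,
                                      delta_kd12 = 30, replicates = 3L,
                                      depth_mean = 100, rho = 0.02, seed) {
  if (missing(seed)) abort("`seed` is required.")
  if (rho < 0 || rho >= 1) abort("`rho` must lie in [0, 1).")
  if (n_dependent > n_events) abort("`n_dependent` cannot exceed `n_events`.")
  with_seed(seed, {
    event_id <- sprintf("kd%04d", seq_len(n_events))
    dependent <- seq_len(n_events) <= n_dependent
    base_psi <- if_else(dependent, psi_control, runif(n_events, 10, 90))
    psi_by_cond <- tibble(
      event_id = rep(event_id, each = 3L),
      condition = rep(c("control", "kd1", "kd12"), n_events),
      psi_true = pmin(99, pmax(1, c(t(cbind(
        base_psi,
        base_psi + if_else(dependent, delta_kd1, 0),
        base_psi + if_else(dependent, delta_kd12, 0))))))
    )
    samples <- tidyr::expand_grid(condition = c("control", "kd1", "kd12"),
                                  replicate = seq_len(replicates)) |>
      mutate(sample_id = paste0(.data$condition, "_r", .data$replicate)) |>
      select("sample_id", "condition", "replicate")

    counts <- tidyr::expand_grid(event_id = event_id,
                                 sample_id = samples$sample_id) |>
      left_join(samples, by = "sample_id") |>
      left_join(psi_by_cond, by = c("event_id", "condition")) |>
      mutate(total = rpois(n(), depth_mean),
             inclusion = rbetabinom(n(), .data$total, .data$psi_true / 100, rho),
             exclusion = .data$total - .data$inclusion) |>
      select("event_id", "sample_id", "inclusion", "exclusion")

    truth <- tibble(event_id = event_id, dependent = dependent,
                    psi_control = base_psi)
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Simulate 3'ss windows with planted motifs
#'
#' Background sequence is i.i.d. uniform over \{A, C, G, U\}; the planted
#' hexamer is inserted at one random position (in R4 or R5, equally likely)
#' with a class-specific rate. One motif per window set keeps enrichment
#' tests unambiguous.
#'
#' @param n_regulated,n_background Window counts per class (defaults 100).
#' @param width Total window width (default 250); split half intronic (R4),
#'   half exonic (R5).
#' @param motif Planted RNA k-mer (default "UCUUCU").
#' @param rate_regulated,rate_background Planting probabilities
#'   (defaults 0.6 / 0.1).
#' @param seed RNG seed (required).
#' @return A list with `regulated` and `background` window tibbles
#'   (`event_id`, `r4`, `r5`) and `truth` (planted flags).
#' @export
simulate_windows <- function(n_regulated = 100L, n_background = 100L,
                             width = 250L, motif = "UCUUCU",
                             rate_regulated = 0.6, rate_background = 0.1,
                             seed) {
  if (missing(seed)) abort("`seed` is required.")
  motif <- validate_kmers(motif, single = TRUE)
  half <- width %/% 2L
  if (half < nchar(motif)) abort("Window half-width is shorter than the motif.")
  check_probability(c(rate_regulated, rate_background), "planting rate")

  rand_rna <- function(len) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }
  plant <- function(seq, motif) {
    pos <- sample.int(nchar(seq) - nchar(motif) + 1L, 1L)
    paste0(substr(seq, 1L, pos - 1L), motif,
           substr(seq, pos + nchar(motif), nchar(seq)))
  }
  make_set <- function(n, rate, prefix) {
    planted <- runif(n) < rate
    rows <- purrr::map(seq_len(n), function(i) {
      r4 <- rand_rna(half); r5 <- rand_rna(width - half)
      if (planted[i]) {
        if (runif(1) < 0.5) r4 <- plant(r4, motif) else r5 <- plant(r5, motif)
      }
      tibble(event_id = sprintf("%s%04d", prefix, i), r4 = r4, r5 = r5)
    })
    list(windows = bind_rows(rows), planted = planted)
  }
  with_seed(seed, {
    reg <- make_set(n_regulated, rate_regulated, "reg")
    bg <- make_set(n_background, rate_background, "bg")
    truth <- bind_rows(
      tibble(event_id = reg$windows$event_id, set = "regulated",
             planted = reg$planted),
      tibble(event_id = bg$windows$event_id, set = "background",
             planted = bg$planted))
    list(regulated = reg$windows, background = bg$windows, truth = truth)
  })
}

#' Simulate single-cell marker and isoform profiles
#'
#' Cells are drawn per class (neuron / astrocyte / other). Expressed markers
#' get a strictly positive Poisson count (`rpois(marker_lambda) + 1`), then
#' drop to zero with probability `dropout`; unexpressed markers are zero.
#' "Other" cells express the housekeeping marker but are inconclusive
#' (half double-positive, half double-negative, at random). Per-cell psi is
#' drawn on the logit scale around the class mean and realized as binomial
#' isoform counts at Poisson depth.
#'
#' @param n_neuron,n_astrocyte,n_other Cells per class (defaults 72/18/33,
#'   the observed hippocampal composition).
#' @param psi_mean Named vector of class psi means in percent
#'   (defaults neuron 42.8, astrocyte 4.5, other 20).
#' @param psi_sd_logit Logit-scale SD of per-cell psi (default 0.35).
#' @param marker_lambda Poisson mean for expressed marker counts
#'   (default 8).
#' @param depth_mean Poisson mean of per-cell isoform total (default 200;
#'   floored at 1 so psi is always defined).
#' @param dropout Marker dropout probability (default 0).
#' @param seed RNG seed (required).
#' @return A list with `profiles` (`cell_id`, `gapdh`, `neun`, `gfap`,
#'   `e6`, `e7`) and `truth` (`cell_id`, `true_class`, `true_psi`).
#' @export
simulate_single_cells <- function(n_neuron = 72L, n_astrocyte = 18L,
                                  n_other = 33L,
                                  psi_mean = c(neuron = 42.8, astrocyte = 4.5,
                                               other = 20),
                                  psi_sd_logit = 0.35, marker_lambda = 8,
                                  depth_mean = 200, dropout = 0, seed) {
  if (missing(seed)) abort("`seed` is required.")
  check_probability(dropout, "dropout")
  classes <- c(rep("neuron", n_neuron), rep("astrocyte", n_astrocyte),
               rep("other", n_other))
  with_seed(seed, {
    n <- length(classes)
    marker <- function(expressed) {
      m <- ifelse(expressed, rpois(n, marker_lambda) + 1L, 0L)
      ifelse(runif(n) < dropout, 0L, m)
    }
    other_double_pos <- runif(n) < 0.5
    neun_on <- classes == "neuron" | (classes == "other" & other_double_pos)
    gfap_on <- classes == "astrocyte" | (classes == "other" & other_double_pos)
    true_psi <- 100 * plogis(rnorm(n, qlogis(psi_mean[classes] / 100),
                                   psi_sd_logit))
    total <- pmax(1L, rpois(n, depth_mean))
    e6 <- rbinom(n, total, true_psi / 100)
    profiles <- tibble(
      cell_id = sprintf("cell%04d", seq_len(n)),
      gapdh = marker(rep(TRUE, n)),
      neun = marker(neun_on),
      gfap = marker(gfap_on),
      e6 = e6, e7 = total - e6
    )
    truth <- tibble(cell_id = profiles$cell_id, true_class = classes,
                    true_psi = unname(true_psi))
    list(profiles = profiles, truth = truth)
  })
}
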