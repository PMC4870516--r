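#' Pipeline configuration
#'
#' Collects every tunable threshold of the analysis with its default, plus
#' input paths (all optional - stages without inputs run on the synthetic
#' preset) and the mandatory seed. Every threshold is echoed verbatim into
#' the run report.
#'
#' @param seed RNG seed used by every stochastic stage (required).
#' @param out_dir Output directory; `NULL` (default) keeps results in
#'   memory only.
#' @param gtf,genome_fasta,counts_tsv,sample_sheet_tsv Optional input paths;
#'   when `NULL` the corresponding synthetic preset input is generated.
#' @param n_events,n_increasing,n_decreasing Synthetic preset: number of
#'   cataloged events given trajectories (defaults 200/50/0) when counts are
#'   simulated.
#' @param n_cassette,n_tandem_apa Synthetic preset decoy genes (defaults 25).
#' @param min_total,min_stages Detectability thresholds (defaults 20 / 1).
#' @param alpha_regulation,min_delta_psi Regulation-call thresholds
#'   (defaults 0.05 / 10 percentage points).
#' @param tau_threshold,alpha_trend Trend-class thresholds (defaults 0.4 /
#'   0.005).
#' @param window_width 3'ss window width in nt (default 250).
#' @param n_boot Dip-test Monte-Carlo samples (default 2000).
#' @param depth_mean,rho Synthetic preset count depth and overdispersion
#'   (defaults 100 / 0.02).
#' @param motif Planted/tested hexamer for the synthetic motif stage
#'   (default "UCUUCU").
#' @return A list of class `isocoex_config`.
#' @export
pipeline_config <- function(seed, out_dir = NULL,
                            gtf = NULL, genome_fasta = NULL,
                            counts_tsv = NULL, sample_sheet_tsv = NULL,
                            n_events = 200L, n_increasing = 50L,
                            n_decreasing = 0L,
                            n_cassette = 25L, n_tandem_apa = 25L,
                            min_total = 20L, min_stages = 1L,
                            alpha_regulation = 0.05, min_delta_psi = 10,
                            tau_threshold = 0.4, alpha_trend = 0.005,
                            window_width = 250L, n_boot = 2000L,
                            depth_mean = 100, rho = 0.02,
                            motif = "UCUUCU") {
  if (missing(seed)) abort("`seed` is required.")
  stopifnot(min_total >= 0, min_stages >= 1, alpha_regulation >= 0,
            alpha_regulation <= 1, min_delta_psi >= 0, tau_threshold >= 0,
            alpha_trend >= 0, alpha_trend <= 1, window_width >= 2,
            n_boot >= 1)
  cfg <- as.list(environment())
  class(cfg) <- "isocoex_config"
  cfg
}

run_stage <- function(name, expr) {
  inform(sprintf("[%s] running", name))
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order: event cataloging (from a GTF or
#' the synthetic gene models), psi quantification and detectability (from
#' junction counts or the synthetic time course), developmental regulation
#' calls, nu trend analysis, bimodality testing of the tau distribution,
#' and motif enrichment on 3'ss windows (synthetic planted windows when no
#' annotation/genome pair supplies real ones). Any stage failure aborts with
#' an error naming the stage. With `out_dir` set, stage outputs are written
#' as headered TSVs and the report as JSON plus readable text.
#'
#' @param config An [pipeline_config()] object.
#' @return An `isocoex_report`: a list with `counts` (the record-count
#'   cascade), `dip`, `config` (echo), `results` (the stage tibbles),
#'   `version` and `timestamp`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "isocoex_config")) {
    abort("`config` must come from pipeline_config().")
  }
  t0 <- Sys.time()

  # -- stage: catalog ------------------------------------------------------
  catalog <- run_stage("catalog", {
    if (!is.null(config$gtf)) {
      models <- read_gene_models(config$gtf)
      genome <- if (!is.null(config$genome_fasta)) config$genome_fasta else NULL
    } else {
      sim <- simulate_gene_models(n_events = config$n_events,
                                  n_cassette = config$n_cassette,
                                  n_tandem_apa = config$n_tandem_apa,
                                  seed = config$seed)
      models <- read_gene_models(sim$gtf)
      genome <- sim$genome
    }
    list(models = models, events = catalog_ua3e_events(models),
         genome = genome)
  })
  events <- catalog$events

  # -- stage: quantify -----------------------------------------------------
  quant <- run_stage("quantify", {
    if (!is.null(config$counts_tsv)) {
      counts <- read_junction_counts(config$counts_tsv)
      samples <- read_sample_sheet(config$sample_sheet_tsv)
      truth <- NULL
    } else {
      if (nrow(events) == 0L) abort("no cataloged events to quantify")
      sim <- simulate_timecourse_counts(
        n_events = nrow(events),
        n_increasing = min(config$n_increasing, nrow(events)),
        n_decreasing = min(config$n_decreasing,
                           max(0L, nrow(events) - config$n_increasing)),
        depth_mean = config$depth_mean, rho = config$rho,
        seed = config$seed + 1L)
      # tie simulated trajectories to the cataloged events, in catalog order
      id_map <- setNames(events$event_id, sim$truth$event_id)
      counts <- sim$counts |>
        mutate(event_id = unname(id_map[.data$event_id]))
      truth <- sim$truth |>
        mutate(event_id = unname(id_map[.data$event_id]))
      samples <- sim$samples
    }
    list(psi = psi_table(counts), counts = counts, samples = samples,
         truth = truth)
  })

  detect <- run_stage("detectability", {
    flag_detectable(quant$counts, quant$samples,
                    min_total_per_sample = config$min_total,
                    min_stages = config$min_stages)
  })

  regulation <- run_stage("regulation", {
    keep <- detect$event_id[detect$detectable]
    call_developmental_regulation(
      quant$counts |> filter(.data$event_id %in% keep),
      quant$samples, alpha = config$alpha_regulation,
      min_delta_psi = config$min_delta_psi)
  })

  trends <- run_stage("trends", {
    keep <- detect$event_id[detect$detectable]
    compute_trends(quant$psi |> filter(.data$event_id %in% keep),
                   quant$samples, tau_threshold = config$tau_threshold,
                   alpha = config$alpha_trend)
  })

  bimodality <- run_stage("bimodality", {
    tau <- trends$tau[!is.na(trends$tau)]
    if (length(tau) >= 4) dip_test(tau, n_boot = config$n_boot,
                                   seed = config$seed + 2L)
    else NULL
  })

  motifs <- run_stage("motifs", {
    sim <- simulate_windows(motif = config$motif,
                            width = config$window_width,
                            seed = config$seed + 3L)
    enrich_motifs(sim$regulated, sim$background,
                  default_ptbp_motifs(), region = "both")
  })

  counts_cascade <- list(
    genes = dplyr::n_distinct(catalog$models$gene_id),
    events_cataloged = nrow(events),
    events_quantified = dplyr::n_distinct(quant$counts$event_id),
    detectable = sum(detect$detectable),
    regulated = sum(regulation$regulated, na.rm = TRUE),
    trend_tested = sum(!is.na(trends$tau)),
    increasing = sum(trends$trend_class == "increasing"),
    decreasing = sum(trends$trend_class == "decreasing"),
    none = sum(trends$trend_class == "none" & !is.na(trends$tau)),
    motifs_tested = nrow(motifs),
    motifs_enriched = sum(motifs$p_adj < 0.05)
  )

  report <- structure(list(
    counts = counts_cascade,
    dip = if (!is.null(bimodality)) {
      list(statistic = bimodality$statistic, p_value = bimodality$p_value,
           n = bimodality$n, n_boot = bimodality$n_boot,
           seed = bimodality$seed)
    } else NULL,
    config = config_echo(config),
    results = list(events = events, psi = quant$psi, detectable = detect,
                   regulation = regulation, trends = trends,
                   bimodality = bimodality, motifs = motifs,
                   truth = quant$truth),
    version = as.character(utils::packageVersion("isocoex")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z")
  ), class = "isocoex_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

config_echo <- function(config) {
  echo <- unclass(config)
  echo[vapply(echo, is.null, TRUE)] <- NULL
  echo
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- report$results
  readr::write_tsv(res$events, file.path(out_dir, "events.tsv"))
  readr::write_tsv(res$psi, file.path(out_dir, "psi.tsv"))
  readr::write_tsv(res$detectable, file.path(out_dir, "detectable.tsv"))
  readr::write_tsv(res$regulation, file.path(out_dir, "regulation.tsv"))
  readr::write_tsv(as_tibble(res$trends), file.path(out_dir, "trends.tsv"))
  readr::write_tsv(res$motifs, file.path(out_dir, "motif_enrichment.tsv"))
  json <- list(counts = report$counts, dip = report$dip,
               config = report$config, version = report$version,
               timestamp = report$timestamp)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(utils::capture.output(print(report)),
             file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.isocoex_report <- function(x, ...) {
  cat("isocoex pipeline report (version ", x$version, ", ", x$timestamp,
      ")\n", sep = "")
  cat("record counts:\n")
  for (nm in names(x$counts)) {
    cat(sprintf("  %-18s %d\n", nm, x$counts[[nm]]))
  }
  if (!is.null(x$dip)) {
    cat(sprintf("tau bimodality: dip = %.4f, p = %.4g (n = %d)\n",
                x$dip$statistic, x$dip$p_value, x$dip$n))
  }
  cat("thresholds: ")
  thr <- x$config[c("min_total", "min_stages", "alpha_regulation",
                    "min_delta_psi", "tau_threshold", "alpha_trend",
                    "window_width", "n_boot")]
  cat(paste(names(thr), unlist(thr), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
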