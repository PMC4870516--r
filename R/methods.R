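#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_histogram geom_line geom_area
#'   geom_jitter geom_boxplot geom_vline labs theme_minimal facet_wrap
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a dip test
#'
#' @param x A `dip_test` object.
#' @param ... Unused.
#' @return One-row tibble with `statistic`, `p_value`, `n`, `n_boot`, `seed`.
#' @export
tidy.dip_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value, n = x$n,
         n_boot = x$n_boot, seed = x$seed)
}

#' @rdname tidy.dip_test
#' @export
glance.dip_test <- function(x, ...) tidy(x)

#' One-row summary of a trend table
#'
#' @param x An `isocoex_trends` tibble.
#' @param ... Unused.
#' @return One-row tibble with per-class counts and the thresholds used.
#' @export
glance.isocoex_trends <- function(x, ...) {
  tibble(
    n_events = nrow(x),
    n_tested = sum(!is.na(x$tau)),
    increasing = sum(x$trend_class == "increasing"),
    decreasing = sum(x$trend_class == "decreasing"),
    none = sum(x$trend_class == "none"),
    tau_threshold = attr(x, "tau_threshold") %||% NA_real_,
    alpha = attr(x, "alpha") %||% NA_real_
  )
}

#' One-row summary of a pipeline report
#'
#' @param x An `isocoex_report` object.
#' @param ... Unused.
#' @return One-row tibble of the record-count cascade plus the dip result.
#' @export
glance.isocoex_report <- function(x, ...) {
  out <- as_tibble(x$counts)
  out$dip <- if (is.null(x$dip)) NA_real_ else x$dip$statistic
  out$dip_p <- if (is.null(x$dip)) NA_real_ else x$dip$p_value
  out
}

#' Plot the Kendall tau distribution of a trend table
#'
#' Histogram of per-event tau coloured by trend class, with the
#' classification thresholds marked - the standard view for spotting the
#' bimodal (+/-) structure of regulated events.
#'
#' @param object An `isocoex_trends` tibble.
#' @param bins Histogram bins (default 30).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isocoex_trends <- function(object, bins = 30, ...) {
  thr <- attr(object, "tau_threshold") %||% 0.4
  df <- as_tibble(object) |> filter(!is.na(.data$tau))
  ggplot(df, aes(x = .data$tau, fill = .data$trend_class)) +
    geom_histogram(bins = bins, colour = "grey30", linewidth = 0.2) +
    geom_vline(xintercept = c(-thr, thr), linetype = "dashed") +
    labs(x = expression(paste("Kendall ", tau, " (", nu,
                              " vs developmental stage)")),
         y = "events", fill = "trend") +
    theme_minimal()
}

#' Plot a kernel density estimate
#'
#' @param object An `isocoex_kde` tibble from [kde_density()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isocoex_kde <- function(object, ...) {
  ggplot(as_tibble(object), aes(x = .data$x, y = .data$density)) +
    geom_area(alpha = 0.3, fill = "steelblue") +
    geom_line(colour = "steelblue") +
    labs(x = "value", y = "density") +
    theme_minimal()
}

#' Plot per-cell psi by cell class
#'
#' Box-and-jitter view of per-cell UA3E psi per classified cell type
#' (neurons co-express both isoforms, astrocytes use almost exclusively the
#' downstream isoform).
#'
#' @param profiles Classified cell profiles (with `class`, `e6`, `e7`).
#' @return A ggplot object.
#' @export
plot_cell_psi <- function(profiles) {
  check_columns(profiles, c("class", "e6", "e7"), "profiles")
  if (!"psi" %in% names(profiles)) profiles <- per_cell_psi(profiles)
  df <- profiles |>
    filter(!is.na(.data$psi), .data$class != "excluded")
  ggplot(df, aes(x = .data$class, y = .data$psi)) +
    geom_boxplot(outlier.shape = NA, width = 0.5) +
    geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    labs(x = NULL, y = expression(paste(psi["UA3E"], " (%)"))) +
    theme_minimal()
}

#' Plot psi trajectories over the time course
#'
#' @param psi Long psi tibble (`event_id`, `sample_id`, `psi`).
#' @param samples Sample sheet with `sample_id`, `stage`.
#' @param events Event ids to show (default: first 6).
#' @return A ggplot object faceted by event.
#' @export
plot_psi_trajectory <- function(psi, samples, events = NULL) {
  check_columns(psi, c("event_id", "sample_id", "psi"), "psi")
  check_columns(samples, c("sample_id", "stage"), "samples")
  events <- events %||% head(unique(psi$event_id), 6L)
  df <- psi |>
    filter(.data$event_id %in% events, !is.na(.data$psi)) |>
    inner_join(samples[, c("sample_id", "stage")], by = "sample_id") |>
    mutate(stage = factor(.data$stage, levels = stage_levels(samples$stage)))
  ggplot(df, aes(x = .data$stage, y = .data$psi)) +
    geom_jitter(width = 0.1, alpha = 0.6, size = 1) +
    facet_wrap(~event_id) +
    labs(x = "stage", y = expression(paste(psi, " (%)"))) +
    theme_minimal()
}
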