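#' Classify single cells by marker expression
#'
#' Cells are gated on the housekeeping marker (Gapdh): below `threshold`
#' they are `excluded`. Remaining cells are `neuron` (NeuN+ / Gfap-),
#' `astrocyte` (Gfap+ / NeuN-), or `other` (double-positive or
#' double-negative; these are reported but not assigned a lineage).
#'
#' @param profiles Tibble with `cell_id`, `gapdh`, `neun`, `gfap` (and
#'   typically `e6`, `e7` isoform counts, carried through).
#' @param threshold Minimum count treated as marker presence (default 1).
#' @return The input tibble with a `class` factor column
#'   (neuron/astrocyte/other/excluded) appended.
#' @export
classify_cells <- function(profiles, threshold = 1L) {
  check_columns(profiles, c("cell_id", "gapdh", "neun", "gfap"), "profiles")
  check_counts(profiles$gapdh, "`gapdh`")
  check_counts(profiles$neun, "`neun`")
  check_counts(profiles$gfap, "`gfap`")
  profiles |>
    mutate(class = factor(case_when(
      .data$gapdh < threshold ~ "excluded",
      .data$neun >= threshold & .data$gfap < threshold ~ "neuron",
      .data$gfap >= threshold & .data$neun < threshold ~ "astrocyte",
      TRUE ~ "other"
    ), levels = c("neuron", "astrocyte", "other", "excluded")))
}

#' Cell-type composition of a classified population
#'
#' Percentages are computed over non-excluded cells (cells failing the
#' housekeeping gate do not enter the denominator).
#'
#' @param classified Tibble with a `class` column from [classify_cells()].
#' @return A tibble with `class`, `n`, `fraction` (raw) and `percent`
#'   (rounded to 2 decimals for reporting).
#' @export
summarize_composition <- function(classified) {
  check_columns(classified, "class", "classified")
  kept <- classified |> filter(.data$class != "excluded")
  if (nrow(kept) == 0L) abort("All cells are excluded by the housekeeping gate.")
  kept |>
    count(.data$class, .drop = FALSE) |>
    filter(.data$class != "excluded") |>
    mutate(fraction = .data$n / sum(.data$n),
           percent = round(100 * .data$fraction, 2))
}

#' Per-cell percent-spliced-in of the UA3E isoform
#'
#' psi = 100 * e6 / (e6 + e7) per cell; cells with zero total isoform signal
#' get `NA` and are reported via a message so downstream summaries can note
#' the dropped cells.
#'
#' @param profiles Tibble with `e6` (UA3E isoform) and `e7` (AIDE isoform)
#'   counts.
#' @return The input with a `psi` column appended.
#' @export
per_cell_psi <- function(profiles) {
  check_columns(profiles, c("e6", "e7"), "profiles")
  check_counts(profiles$e6, "`e6`")
  check_counts(profiles$e7, "`e7`")
  out <- profiles |>
    mutate(psi = if_else(.data$e6 + .data$e7 > 0,
                         100 * .data$e6 / (.data$e6 + .data$e7), NA_real_))
  dropped <- sum(is.na(out$psi))
  if (dropped > 0L) {
    inform(sprintf("%d cell(s) with zero isoform counts: psi undefined.", dropped))
  }
  out
}

#' Per-class psi summaries
#'
#' Groups classified cells and summarises per-cell psi with the median (the
#' headline per-group statistic), keeping the raw per-cell values for
#' comparison tests and plotting.
#'
#' @param profiles Classified profiles with `class`, `e6`, `e7` columns
#'   (psi is computed if absent).
#' @param drop_excluded Drop the excluded class (default TRUE).
#' @return A tibble with `class`, `n` (cells with defined psi),
#'   `psi_median`, and `psi_values` (list column).
#' @export
summarize_psi_by_class <- function(profiles, drop_excluded = TRUE) {
  check_columns(profiles, "class", "profiles")
  if (!"psi" %in% names(profiles)) profiles <- per_cell_psi(profiles)
  x <- profiles |> filter(!is.na(.data$psi))
  if (drop_excluded) x <- x |> filter(.data$class != "excluded")
  x |>
    group_by(.data$class) |>
    summarise(n = n(), psi_median = median(.data$psi),
              psi_values = list(.data$psi), .groups = "drop")
}

#' Welch t comparison of two psi groups
#'
#' Two-tailed t test assuming unequal variances (Welch-Satterthwaite
#' degrees of freedom), the standard comparison for per-cell psi between
#' cell classes.
#'
#' @param group_a,group_b Numeric psi vectors (each n >= 2, non-degenerate
#'   variance).
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_a`, `mean_b`,
#'   `median_a`, `median_b`.
#' @export
compare_psi_groups <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L) abort("`group_a` needs at least 2 values.")
  if (length(group_b) < 2L) abort("`group_b` needs at least 2 values.")
  if (var(group_a) == 0) abort("`group_a` has degenerate (zero) variance.")
  if (var(group_b) == 0) abort("`group_b` has degenerate (zero) variance.")
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value,
         mean_a = mean(group_a), mean_b = mean(group_b),
         median_a = median(group_a), median_b = median(group_b))
}
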