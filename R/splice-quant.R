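#' Percent-spliced-in from junction counts
#'
#' Computes psi = 100 * inclusion / (inclusion + exclusion), where
#' `inclusion` counts reads on the shared-donor -> UA3E-acceptor junction and
#' `exclusion` counts reads on the shared-donor -> AIDE-acceptor junction.
#' Both isoforms share all upstream sequence, so these two donor-anchored
#' junctions are the discriminating observations; no exon-body reads enter
#' the estimate.
#'
#' @param inclusion,exclusion Non-negative integer count vectors (recycled
#'   to a common length).
#' @return A numeric vector of psi percentages in \[0, 100\]; `NA` where the
#'   total count is zero (psi undefined).
#' @examples
#' compute_psi(3, 7)   # 30
#' compute_psi(0, 0)   # NA: undefined
#' @export
compute_psi <- function(inclusion, exclusion) {
  check_counts(inclusion, "`inclusion`")
  check_counts(exclusion, "`exclusion`")
  total <- inclusion + exclusion
  if_else(total > 0, 100 * inclusion / total, NA_real_)
}

#' Per-sample psi estimates for a junction count table
#'
#' @param counts Tibble with `event_id`, `sample_id`, `inclusion`,
#'   `exclusion` (one row per event per sample).
#' @return The input with `total`, `psi` (percent, `NA` when `total` is 0)
#'   and `defined` columns appended.
#' @export
psi_table <- function(counts) {
  check_columns(counts, c("event_id", "sample_id", "inclusion", "exclusion"),
                "counts")
  counts |>
    mutate(total = .data$inclusion + .data$exclusion,
           psi = compute_psi(.data$inclusion, .data$exclusion),
           defined = .data$total > 0)
}

#' Flag events detectable by RNA-seq
#'
#' An event is detectable if at least `min_stages` stages support it, where a
#' stage supports the event when the junction total reaches
#' `min_total_per_sample` in every replicate of that stage (`rule = "all"`,
#' the default) or on average across its replicates (`rule = "mean"`). The
#' default `min_stages = 1` encodes detectability "at least at one
#' differentiation stage".
#'
#' @param counts Junction count tibble (`event_id`, `sample_id`,
#'   `inclusion`, `exclusion`).
#' @param samples Sample sheet with `sample_id` and `stage`.
#' @param min_total_per_sample Minimum junction total per sample (default 20).
#' @param min_stages Minimum number of qualifying stages (default 1).
#' @param rule `"all"` (every replicate) or `"mean"` (replicate mean).
#' @return A tibble with `event_id`, `n_stages_supporting`, `detectable`.
#' @export
flag_detectable <- function(counts, samples, min_total_per_sample = 20L,
                            min_stages = 1L, rule = c("all", "mean")) {
  rule <- match.arg(rule)
  check_columns(counts, c("event_id", "sample_id", "inclusion", "exclusion"),
                "counts")
  check_columns(samples, c("sample_id", "stage"), "samples")
  unknown <- setdiff(unique(counts$sample_id), samples$sample_id)
  if (length(unknown) > 0L) {
    abort(sprintf("Sample(s) without a stage label: %s",
                  paste(unknown, collapse = ", ")))
  }
  if (any(is.na(samples$stage))) abort("Sample sheet has missing stage labels.")
  counts |>
    mutate(total = .data$inclusion + .data$exclusion) |>
    inner_join(samples[, c("sample_id", "stage")], by = "sample_id") |>
    group_by(.data$event_id, .data$stage) |>
    summarise(stage_ok = if (rule == "all") all(.data$total >= min_total_per_sample)
              else mean(.data$total) >= min_total_per_sample,
              .groups = "drop_last") |>
    summarise(n_stages_supporting = sum(.data$stage_ok),
              detectable = sum(.data$stage_ok) >= min_stages,
              .groups = "drop")
}

# Pool replicate counts within each level of `group_col`, returning one row
# per event x group with pooled psi.
pool_counts <- function(counts, samples, group_col) {
  counts |>
    inner_join(samples, by = "sample_id") |>
    group_by(.data$event_id, .data[[group_col]]) |>
    summarise(inclusion = sum(.data$inclusion),
              exclusion = sum(.data$exclusion), .groups = "drop") |>
    mutate(total = .data$inclusion + .data$exclusion,
           psi = compute_psi(.data$inclusion, .data$exclusion))
}

# Two-sided Fisher exact p for the 2x2 junction table of two pooled groups.
pair_exact_test <- function(i1, e1, i2, e2) {
  stats::fisher.test(matrix(c(i1, e1, i2, e2), nrow = 2))$p.value
}

# Rao-Scott style design effect for pooled junction counts: the ratio of the
# observed replicate-level Pearson dispersion of inclusion counts to its
# binomial expectation, pooled over all events and groups. Exactly 1 for
# binomial replicates; > 1 under beta-binomial overdispersion. Pooled counts
# are divided by this factor ("effective counts") so that exact tests on
# pooled replicates keep their nominal level despite biological replicate
# variability.
estimate_design_effect <- function(counts, samples, group_col) {
  joined <- counts |>
    inner_join(samples, by = "sample_id") |>
    mutate(total = .data$inclusion + .data$exclusion) |>
    filter(.data$total > 0)
  disp <- joined |>
    group_by(.data$event_id, .data[[group_col]]) |>
    summarise(
      r = n(),
      p_hat = sum(.data$inclusion) / sum(.data$total),
      x2 = sum((.data$inclusion - .data$total * .data$p_hat)^2 /
                 pmax(.data$total * .data$p_hat * (1 - .data$p_hat), 1e-12)),
      .groups = "drop") |>
    filter(.data$r >= 2, .data$p_hat > 0, .data$p_hat < 1)
  if (nrow(disp) == 0L) return(1)
  max(1, sum(disp$x2) / sum(disp$r - 1))
}


#' Call developmentally regulated events from a staged time course
#'
#' Replicate counts are pooled within stage; every consecutive-stage pair is
#' tested with a two-sided Fisher exact test on the pooled
#' (inclusion, exclusion) 2x2 table. The per-event p-value is the minimum
#' pair p-value Bonferroni-scaled by the number of tested pairs, then
#' Benjamini-Hochberg adjusted across events. An event is called regulated
#' when the adjusted p-value is below `alpha` AND the largest absolute
#' pooled-psi change between consecutive stages reaches `min_delta_psi`
#' percentage points (an effect-size gate).
#'
#' @param counts Junction count tibble.
#' @param samples Sample sheet with `sample_id`, `stage`.
#' @param stages Ordered character vector of stage labels; defaults to the
#'   order of first appearance in `samples` (or factor levels when `stage`
#'   is a factor).
#' @param alpha Significance level on the BH-adjusted p-value (default 0.05).
#' @param min_delta_psi Minimum max |delta psi| in percentage points
#'   (default 10).
#' @param overdispersion `"estimate"` (default) applies a Rao-Scott style
#'   design-effect correction: replicate-level dispersion of the inclusion
#'   counts is estimated across all events and the pooled counts divided by
#'   it before testing, so the exact tests keep their nominal level under
#'   beta-binomial replicate noise. `"none"` tests the raw pooled counts.
#'   Delta psi is always computed from the uncorrected pooled counts.
#' @return A tibble with one row per event: `event_id`,
#'   `max_abs_delta_psi`, `direction` (sign of delta psi at the most
#'   significant pair), `n_pairs_tested`, `p`, `p_adj`, `regulated`.
#'   Stage pairs where one side has zero total are skipped (and reported via
#'   a message).
#' @export
call_developmental_regulation <- function(counts, samples, stages = NULL,
                                          alpha = 0.05, min_delta_psi = 10,
                                          overdispersion = c("estimate", "none")) {
  overdispersion <- match.arg(overdispersion)
  check_columns(samples, c("sample_id", "stage"), "samples")
  stages <- stages %||% stage_levels(samples$stage)
  if (length(stages) < 2L) abort("At least two stages are required.")
  phi <- if (overdispersion == "estimate") {
    estimate_design_effect(counts, samples[, c("sample_id", "stage")], "stage")
  } else {
    1
  }
  pooled <- pool_counts(counts, samples[, c("sample_id", "stage")], "stage") |>
    mutate(stage = factor(.data$stage, levels = stages),
           inc_eff = round(.data$inclusion / phi),
           exc_eff = round(.data$exclusion / phi))
  if (any(is.na(pooled$stage))) abort("Unknown stage label in sample sheet.")

  skipped <- 0L
  res <- pooled |>
    group_by(.data$event_id) |>
    dplyr::group_modify(function(d, key) {
      d <- d[order(d$stage), ]
      idx <- match(stages, as.character(d$stage))
      inc <- d$inc_eff[idx]; exc <- d$exc_eff[idx]
      tot <- inc + exc; psi <- d$psi[idx]
      p_pairs <- rep(NA_real_, length(stages) - 1L)
      d_pairs <- rep(NA_real_, length(stages) - 1L)
      for (k in seq_len(length(stages) - 1L)) {
        if (is.na(tot[k]) || is.na(tot[k + 1L]) || tot[k] == 0 || tot[k + 1L] == 0) {
          skipped <<- skipped + 1L
          next
        }
        p_pairs[k] <- pair_exact_test(inc[k], exc[k], inc[k + 1L], exc[k + 1L])
        d_pairs[k] <- psi[k + 1L] - psi[k]
      }
      tested <- which(!is.na(p_pairs))
      if (length(tested) == 0L) {
        return(tibble(max_abs_delta_psi = NA_real_, direction = NA_real_,
                      n_pairs_tested = 0L, p = NA_real_))
      }
      best <- tested[which.min(p_pairs[tested])]
      tibble(
        max_abs_delta_psi = max(abs(d_pairs[tested])),
        direction = sign(d_pairs[best]),
        n_pairs_tested = length(tested),
        p = min(1, p_pairs[best] * length(tested))
      )
    }) |>
    ungroup()
  if (skipped > 0L) {
    inform(sprintf("%d stage pair(s) skipped for zero junction totals.", skipped))
  }
  res |>
    mutate(p_adj = na_bh(.data$p),
           regulated = !is.na(.data$p_adj) & .data$p_adj < alpha &
             .data$max_abs_delta_psi >= min_delta_psi)
}

stage_levels <- function(stage) {
  if (is.factor(stage)) levels(stage) else unique(as.character(stage))
}

#' Call knockdown-dependent events
#'
#' Tests whether an event responds consistently to single and double
#' knockdown: both contrasts (`kd1` vs `control`, `kd12` vs `control`) must
#' pass the pooled Fisher exact test (BH-adjusted across events, within each
#' contrast) and the |delta psi| gate, with delta psi of the same sign in
#' both contrasts.
#'
#' @param counts Junction count tibble.
#' @param samples Sample sheet with `sample_id`, `condition`.
#' @param conditions Named character vector mapping the roles `control`,
#'   `kd1`, `kd12` to condition labels in `samples`.
#' @param alpha Significance level on the BH-adjusted p-values (default 0.05).
#' @param min_delta_psi Minimum |delta psi| per contrast (default 10).
#' @param overdispersion As in [call_developmental_regulation()]: a
#'   design-effect correction estimated from replicate dispersion
#'   (`"estimate"`, default) or none.
#' @return A tibble per event with per-contrast delta psi and adjusted
#'   p-values, and a logical `dependent` flag.
#' @export
call_knockdown_dependence <- function(counts, samples,
                                      conditions = c(control = "control",
                                                     kd1 = "kd1",
                                                     kd12 = "kd12"),
                                      alpha = 0.05, min_delta_psi = 10,
                                      overdispersion = c("estimate", "none")) {
  overdispersion <- match.arg(overdispersion)
  check_columns(samples, c("sample_id", "condition"), "samples")
  missing <- setdiff(unname(conditions), unique(samples$condition))
  if (length(missing) > 0L) {
    abort(sprintf("Condition(s) missing from sample sheet: %s",
                  paste(missing, collapse = ", ")))
  }
  phi <- if (overdispersion == "estimate") {
    estimate_design_effect(counts, samples[, c("sample_id", "condition")],
                           "condition")
  } else {
    1
  }
  pooled <- pool_counts(counts, samples[, c("sample_id", "condition")],
                        "condition")
  wide <- pooled |>
    filter(.data$condition %in% unname(conditions)) |>
    mutate(role = names(conditions)[match(.data$condition, unname(conditions))],
           inc_eff = round(.data$inclusion / phi),
           exc_eff = round(.data$exclusion / phi)) |>
    select("event_id", "role", "inc_eff", "exc_eff", "psi") |>
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("inc_eff", "exc_eff", "psi"))

  contrast <- function(ic, ec, ik, ek) {
    purrr::pmap_dbl(list(ic, ec, ik, ek), function(a, b, c, d) {
      if (a + b == 0 || c + d == 0) return(NA_real_)
      pair_exact_test(a, b, c, d)
    })
  }
  wide |>
    mutate(
      delta_psi_kd1 = .data$psi_kd1 - .data$psi_control,
      delta_psi_kd12 = .data$psi_kd12 - .data$psi_control,
      p_kd1 = contrast(.data$inc_eff_control, .data$exc_eff_control,
                       .data$inc_eff_kd1, .data$exc_eff_kd1),
      p_kd12 = contrast(.data$inc_eff_control, .data$exc_eff_control,
                        .data$inc_eff_kd12, .data$exc_eff_kd12),
      p_adj_kd1 = na_bh(.data$p_kd1),
      p_adj_kd12 = na_bh(.data$p_kd12),
      dependent = !is.na(.data$p_adj_kd1) & !is.na(.data$p_adj_kd12) &
        .data$p_adj_kd1 < alpha & .data$p_adj_kd12 < alpha &
        abs(.data$delta_psi_kd1) >= min_delta_psi &
        abs(.data$delta_psi_kd12) >= min_delta_psi &
        sign(.data$delta_psi_kd1) == sign(.data$delta_psi_kd12) &
        .data$delta_psi_kd1 != 0
    ) |>
    select("event_id", "psi_control", "psi_kd1", "psi_kd12",
           "delta_psi_kd1", "delta_psi_kd12", "p_kd1", "p_kd12",
           "p_adj_kd1", "p_adj_kd12", "dependent")
}

na_bh <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- bh_adjust(p[ok])
  out
}

#' Overlap enrichment between two event sets
#'
#' Builds the 2x2 membership table of two event sets over a common universe
#' and tests association with Fisher's exact test (two-sided by default,
#' using the probability-mass rule: the p-value sums hypergeometric
#' probabilities of all tables at the observed margins that are no more
#' probable than the observed one). The reported odds ratio is the sample
#' (cross-product) odds ratio, not the conditional MLE; when a denominator
#' cell is zero and the numerator cells are positive it is `Inf` by
#' convention.
#'
#' @param set_a,set_b Character vectors of event ids; must be subsets of
#'   `universe`.
#' @param universe Character vector of all eligible event ids.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A one-row tibble: `a_and_b`, `a_only`, `b_only`, `neither`,
#'   `odds_ratio`, `p`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe,
                               alternative = "two.sided") {
  universe <- unique(universe)
  if (length(universe) == 0L) abort("`universe` must be non-empty.")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (length(setdiff(set_a, universe)) > 0L ||
      length(setdiff(set_b, universe)) > 0L) {
    abort("`set_a` and `set_b` must be subsets of `universe`.")
  }
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  a_and_b <- sum(in_a & in_b)
  a_only <- sum(in_a & !in_b)
  b_only <- sum(!in_a & in_b)
  neither <- sum(!in_a & !in_b)
  p <- stats::fisher.test(matrix(c(a_and_b, a_only, b_only, neither), nrow = 2),
                          alternative = alternative)$p.value
  tibble(a_and_b = a_and_b, a_only = a_only, b_only = b_only,
         neither = neither,
         odds_ratio = sample_odds_ratio(a_and_b, a_only, b_only, neither),
         p = p)
}
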