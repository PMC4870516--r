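#' Shannon entropy of an isoform mixture
#'
#' H = -sum(p_i * ln p_i) in nats, with the 0 * ln 0 := 0 convention.
#'
#' @param p Numeric vector of isoform proportions; each in \[0, 1\] and
#'   summing to 1 (tolerance 1e-9).
#' @return Entropy in nats (a single number).
#' @examples
#' shannon_entropy(c(0.5, 0.5))  # ln 2
#' @export
shannon_entropy <- function(p) {
  validate_proportions(p)
  nz <- p[p > 0]
  -sum(nz * log(nz))
}

validate_proportions <- function(p) {
  if (length(p) == 0L || any(is.na(p))) {
    abort("`p` must be a non-empty numeric vector without missing values.")
  }
  if (any(p < 0) || any(p > 1)) abort("Proportions must lie in [0, 1].")
  if (abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("Proportions must sum to 1 (got %.12f).", sum(p)))
  }
  invisible(p)
}

#' Isoform co-expression index nu
#'
#' The effective number of co-expressed isoforms, nu = exp(H) where H is the
#' Shannon entropy (in nats) of the isoform proportion vector - the Hill
#' number of order 1. For two isoforms quantified by percent-spliced-in, nu
#' ranges from 1 (one isoform carries all splicing) to 2 (psi = 50 percent,
#' both isoforms equally abundant).
#'
#' @param p Isoform proportion vector (see [shannon_entropy()]).
#' @return The co-expression index, a single number in \[1, k\] for k
#'   isoforms.
#' @examples
#' coexpression_index(c(0.5, 0.5))  # 2: maximal two-isoform co-expression
#' coexpression_index(c(1, 0))      # 1: a single expressed isoform
#' @export
coexpression_index <- function(p) {
  exp(shannon_entropy(p))
}

#' Co-expression index from two-isoform psi
#'
#' Vectorized convenience wrapper: nu of the mixture
#' (psi/100, 1 - psi/100).
#'
#' @param psi Percent-spliced-in values in \[0, 100\]; `NA` propagates.
#' @return Numeric vector of nu values in \[1, 2\].
#' @export
nu_from_psi <- function(psi) {
  if (any(psi < 0 | psi > 100, na.rm = TRUE)) {
    abort("`psi` must lie in [0, 100].")
  }
  p <- psi / 100
  h <- -(xlogx(p) + xlogx(1 - p))
  exp(h)
}

xlogx <- function(x) ifelse(!is.na(x) & x > 0, x * log(x), 0 * x)

#' Kendall rank correlation with exact or tie-corrected p-value
#'
#' Computes the tie-corrected tau-b from concordant/discordant pair counts.
#' The two-sided p-value is exact - obtained from the full permutation
#' distribution of tau (via the inversion-count recursion) - when n <= 8 and
#' neither vector has ties; otherwise the normal approximation with the
#' tie-corrected variance of the S statistic is used.
#'
#' @param x,y Numeric vectors of equal length (n >= 3). In the trend
#'   analysis `x` is the developmental stage rank and `y` the per-sample nu.
#' @return A one-row tibble: `tau`, `p`, `n`, `method` ("exact" or
#'   "normal"), `degenerate` (TRUE when either vector is constant, in which
#'   case tau = 0 and p = 1 by convention).
#' @export
kendall_tau <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) abort("At least 3 paired observations are required.")
  if (var(x) == 0 || var(y) == 0) {
    return(tibble(tau = 0, p = 1, n = n, method = "degenerate",
                  degenerate = TRUE))
  }
  dx <- sign(outer(x, x, "-")); dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- sum(dx[up] * dy[up])
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  tau <- s / sqrt((n0 - n1) * (n0 - n2))

  has_ties <- n1 > 0 || n2 > 0
  if (!has_ties && n <= 8L) {
    p <- kendall_exact_p(s, n)
    method <- "exact"
  } else {
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v0 <- n * (n - 1) * (2 * n + 5)
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    p <- 2 * pnorm(abs(s) / sqrt(v), lower.tail = FALSE)
    p <- min(1, p)
    method <- "normal"
  }
  tibble(tau = tau, p = p, n = n, method = method, degenerate = FALSE)
}

# Exact two-sided p for Kendall S with distinct x and y: P(|S_perm| >= |s|)
# under the uniform permutation null. The number of permutations of n items
# with q discordant pairs (inversions) follows the Mahonian recursion,
# computed here by iterated polynomial convolution.
kendall_exact_p <- function(s, n) {
  counts <- 1 # distribution of inversions for n = 1: q = 0
  for (k in 2:n) {
    counts <- round(stats::convolve(counts, rev(rep(1, k)), type = "open"))
  }
  q <- seq_along(counts) - 1 # inversion counts 0 .. n0
  n0 <- n * (n - 1) / 2
  s_all <- n0 - 2 * q
  sum(counts[abs(s_all) >= abs(s) - 1e-9]) / sum(counts)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with enforced
#' monotonicity; input order is preserved.
#'
#' @param p Vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  check_probability(p, "p")
  p.adjust(p, method = "BH")
}

#' Per-event co-expression trends over a developmental time course
#'
#' Computes nu per sample from psi, codes developmental time as stage rank,
#' and tests the (stage rank, nu) relationship per event with
#' [kendall_tau()]. By default every replicate contributes its own point;
#' with `per_replicate = FALSE`, nu is averaged within stage first.
#' P-values are BH-adjusted across events and trends classified with
#' [classify_trends()].
#'
#' @param psi Long tibble with `event_id`, `sample_id`, `psi` (e.g. from
#'   [psi_table()]); rows with undefined psi are dropped from that event's
#'   trajectory and `n_points` records what remained.
#' @param samples Sample sheet with `sample_id`, `stage`.
#' @param stages Ordered stage labels (default: order of appearance).
#' @param tau_threshold,alpha Classification thresholds passed to
#'   [classify_trends()]; defaults tau > 0.4 and BH-adjusted p < 0.005.
#' @param per_replicate Use replicate-level nu points (default TRUE).
#' @return A tibble of class `isocoex_trends`: `event_id`, `tau`, `p`,
#'   `p_adj`, `trend_class`, `n_points`.
#' @export
compute_trends <- function(psi, samples, stages = NULL, tau_threshold = 0.4,
                           alpha = 0.005, per_replicate = TRUE) {
  check_columns(psi, c("event_id", "sample_id", "psi"), "psi")
  check_columns(samples, c("sample_id", "stage"), "samples")
  stages <- stages %||% stage_levels(samples$stage)
  pts <- psi |>
    inner_join(samples[, c("sample_id", "stage")], by = "sample_id") |>
    mutate(stage_rank = match(as.character(.data$stage), stages)) |>
    filter(!is.na(.data$psi))
  if (any(is.na(pts$stage_rank))) abort("Unknown stage label in sample sheet.")
  pts <- pts |> mutate(nu = nu_from_psi(.data$psi))
  if (!per_replicate) {
    pts <- pts |>
      group_by(.data$event_id, .data$stage_rank) |>
      summarise(nu = mean(.data$nu), .groups = "drop")
  }
  trends <- pts |>
    group_by(.data$event_id) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 3L) {
        return(tibble(tau = NA_real_, p = NA_real_, n_points = nrow(d)))
      }
      kt <- kendall_tau(d$stage_rank, d$nu)
      tibble(tau = kt$tau, p = kt$p, n_points = kt$n)
    }) |>
    ungroup() |>
    mutate(p_adj = na_bh(.data$p))
  out <- classify_trends(trends, tau_threshold = tau_threshold, alpha = alpha)
  attr(out, "tau_threshold") <- tau_threshold
  attr(out, "alpha") <- alpha
  attr(out, "per_replicate") <- per_replicate
  class(out) <- c("isocoex_trends", class(out))
  out
}

#' Classify trend directions
#'
#' increasing iff tau > `tau_threshold` and p_adj < `alpha`; decreasing iff
#' tau < -`tau_threshold` and p_adj < `alpha`; otherwise none.
#'
#' @param trends Tibble with `tau` and `p_adj` columns.
#' @param tau_threshold Kendall tau threshold (default 0.4).
#' @param alpha BH-adjusted p-value threshold (default 0.005).
#' @return `trends` with a `trend_class` factor column
#'   (increasing/decreasing/none) appended; the per-class counts are
#'   available via `summary()`/[glance.isocoex_trends()].
#' @export
classify_trends <- function(trends, tau_threshold = 0.4, alpha = 0.005) {
  check_columns(trends, c("tau", "p_adj"), "trends")
  trends |>
    mutate(trend_class = factor(case_when(
      !is.na(.data$p_adj) & .data$tau > tau_threshold & .data$p_adj < alpha ~ "increasing",
      !is.na(.data$p_adj) & .data$tau < -tau_threshold & .data$p_adj < alpha ~ "decreasing",
      TRUE ~ "none"
    ), levels = c("increasing", "decreasing", "none")))
}

#' Gaussian kernel density estimate
#'
#' Thin wrapper around [stats::density()] with Silverman's rule-of-thumb
#' bandwidth (`bw.nrd0`), returning the curve as a tibble for reporting and
#' plotting. Zero-variance input falls back to a fixed small bandwidth and
#' is flagged.
#'
#' @param values Numeric vector, n >= 2.
#' @param bw Bandwidth rule or number, as in [stats::density()]
#'   (default "nrd0").
#' @param n_grid Number of grid points (default 512).
#' @return A tibble of class `isocoex_kde` with columns `x`, `density`;
#'   attributes `bandwidth` and `fallback` (TRUE when the zero-variance
#'   fallback was used).
#' @export
kde_density <- function(values, bw = "nrd0", n_grid = 512L) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) abort("At least 2 values are required.")
  fallback <- FALSE
  if (var(values) == 0 && is.character(bw)) {
    bw <- max(abs(values[1]) * 0.01, 0.1)
    fallback <- TRUE
    warn("Zero-variance input: falling back to a fixed bandwidth.")
  }
  d <- stats::density(values, bw = bw, n = n_grid)
  out <- tibble(x = d$x, density = d$y)
  attr(out, "bandwidth") <- d$bw
  attr(out, "fallback") <- fallback
  class(out) <- c("isocoex_kde", class(out))
  out
}
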