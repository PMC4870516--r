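#' Hartigan dip statistic
#'
#' The dip of a sample is the smallest sup-norm distance between its
#' empirical CDF and any unimodal CDF (convex up to the mode, concave
#' after, with an atom allowed at the mode). It is computed exactly by a
#' greatest-convex-minorant / least-concave-majorant sweep over every
#' candidate mode position c: the dip is half the minimum over c of
#' max(dl(c), du(c), dl(c) + du(c) - w(c)), where dl is the misfit of the
#' ECDF above its convex minorant left of the mode, du the misfit below its
#' concave majorant right of the mode, w(c) the ECDF mass at the mode (the
#' jump a unimodal CDF can absorb there), and the third term enforces that
#' the two one-sided fits join monotonically across the modal jump. Both
#' hull sweeps are incremental, so the computation is near-linear after
#' sorting.
#'
#' @param x Numeric vector, n >= 2.
#' @return The dip statistic D, with 1/(2n) <= D <= 1/4. A sample with all
#'   values identical returns the discrete lower bound 1/(2n) (maximal
#'   unimodality) by convention.
#' @examples
#' dip_statistic(c(0, 1))            # 0.25, the maximum
#' dip_statistic(seq(0, 1, 0.125))   # near the 1/(2n) lower bound
#' @export
dip_statistic <- function(x) {
  x <- sort(as.numeric(x[!is.na(x)]))
  n <- length(x)
  if (n < 2L) abort("At least 2 values are required.")
  if (x[1L] == x[n]) return(1 / (2 * n))
  # collapse ties to unique points with ECDF below (lo) / at (hi) each atom
  ux <- unique(x)
  cnt <- tabulate(match(x, ux))
  m <- length(ux)
  hi <- cumsum(cnt) / n
  lo <- c(0, hi[-m])

  low <- 1L; high <- m; D <- 0; mid <- 0
  for (iter in seq_len(m + 1L)) {
    idx <- low:high
    g_idx <- idx[chain_hull(ux[idx], lo[idx], upper = FALSE)]
    l_idx <- idx[chain_hull(ux[idx], hi[idx], upper = TRUE)]
    gcurve <- hull_interp(ux[g_idx], lo[g_idx], ux[idx])
    lcurve <- hull_interp(ux[l_idx], hi[l_idx], ux[idx])
    # best crossover: ECDF tops above the GCM left of it, LCM above ECDF
    # bottoms right of it; the jump at the crossover absorbs that atom.
    dev_g <- hi[idx] - gcurve
    dev_l <- lcurve - lo[idx]
    dev_jump <- lcurve - hi[idx]
    len <- length(idx)
    pre <- c(0, cummax(dev_g))                 # pre[k+1] = max over idx[1..k]
    suf <- c(rev(cummax(rev(dev_l))), 0)       # suf[k] = max over idx[k..len]
    cand <- pmax(pre[seq_len(len)], pmax(dev_jump, suf[seq_len(len) + 1L]))
    cand <- c(cand, pre[len + 1L])             # crossover beyond the window
    mid <- min(cand)
    if (mid <= D + 1e-12) break
    # narrow towards the largest gap between the two hulls
    j <- idx[which.max(lcurve - gcurve)]
    L <- max(g_idx[g_idx <= j])
    U <- min(l_idx[l_idx >= j])
    D <- max(D, tail_misfit(ux, lo, hi, L, left = TRUE),
             tail_misfit(ux, lo, hi, U, left = FALSE))
    if (L == low && U == high) {
      D <- max(D, mid)
      break
    }
    low <- L; high <- U
  }
  max(max(D, mid), 1 / n) / 2
}

# Misfit of the one-sided unimodal tail fit outside the modal interval:
# left  - ECDF jump tops above the GCM of jump bottoms on points 1..L,
#         measured strictly left of the window;
# right - LCM of jump tops on points U..m above the ECDF jump bottoms,
#         measured strictly right of the window.
tail_misfit <- function(ux, lo, hi, K, left = TRUE) {
  m <- length(ux)
  if ((left && K == 1L) || (!left && K == m)) return(0)
  idx <- if (left) seq_len(K) else K:m
  if (left) {
    v <- idx[chain_hull(ux[idx], lo[idx], upper = FALSE)]
    curve <- hull_interp(ux[v], lo[v], ux[idx])
    max(hi[idx[-length(idx)]] - curve[-length(idx)])
  } else {
    v <- idx[chain_hull(ux[idx], hi[idx], upper = TRUE)]
    curve <- hull_interp(ux[v], hi[v], ux[idx])
    max(curve[-1L] - lo[idx[-1L]])
  }
}

# Monotone-chain hull vertex indices (x strictly increasing).
chain_hull <- function(px, py, upper = FALSE) {
  m <- length(px)
  if (m <= 2L) return(seq_len(m))
  sgn <- if (upper) -1 else 1
  h <- integer(m); top <- 0L
  for (i in seq_len(m)) {
    while (top >= 2L) {
      a <- h[top - 1L]; b <- h[top]
      cross <- (py[i] - py[b]) * (px[b] - px[a]) -
        (py[b] - py[a]) * (px[i] - px[b])
      if (sgn * cross <= 0) top <- top - 1L else break
    }
    top <- top + 1L
    h[top] <- i
  }
  h[seq_len(top)]
}

hull_interp <- function(vx, vy, qx) {
  if (length(vx) == 1L) return(rep(vy, length(qx)))
  stats::approx(vx, vy, xout = qx, rule = 2)$y
}

#' Monte-Carlo dip test of unimodality
#'
#' Compares the observed dip statistic against dips of `n_boot` uniform(0,1)
#' samples of the same size (the least-favourable unimodal null). The
#' p-value uses add-one smoothing, (b + 1) / (n_boot + 1), where b counts
#' null dips at least as large as the observed one. Deterministic given
#' `seed`; the caller's RNG state is left untouched.
#'
#' @param x Numeric sample, n >= 4.
#' @param n_boot Number of null samples (default 2000).
#' @param seed RNG seed (required).
#' @return An object of class `dip_test`: a list with `statistic`,
#'   `p_value`, `n`, `n_boot`, `seed`. Supports `print()`, [generics::tidy()]
#'   and [generics::glance()].
#' @export
dip_test <- function(x, n_boot = 2000L, seed) {
  if (missing(seed)) abort("`seed` is required for the Monte-Carlo null.")
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 4L) abort("At least 4 values are required.")
  observed <- dip_statistic(x)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) dip_statistic(runif(n)), 0)
  })
  b <- sum(boots >= observed - 1e-12)
  structure(
    list(statistic = observed, p_value = (b + 1) / (n_boot + 1),
         n = n, n_boot = as.integer(n_boot), seed = seed),
    class = "dip_test"
  )
}

#' @export
print.dip_test <- function(x, ...) {
  cat("Hartigan dip test of unimodality (Monte-Carlo uniform null)\n")
  cat(sprintf("  dip = %.4f, n = %d, p-value = %.4g (%d null samples, seed %s)\n",
              x$statistic, x$n, x$p_value, x$n_boot, format(x$seed)))
  invisible(x)
}
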