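# Independent oracles used across the test suite. Everything here is written
# against the mathematical definitions, not against the package's code paths.

# ---- Kendall ---------------------------------------------------------------

# tau-b by explicit double-loop pair counting.
brute_kendall_tau <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx * dy > 0) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Exact two-sided permutation p-value for Kendall tau (distinct x and y).
enum_kendall_p <- function(x, y) {
  obs <- abs(brute_kendall_tau(x, y))
  perms <- all_permutations(length(y))
  taus <- apply(perms, 1, function(idx) brute_kendall_tau(x, y[idx]))
  mean(abs(taus) >= obs - 1e-9)
}

# ---- Fisher ----------------------------------------------------------------

# Exhaustive fixed-margin enumeration of 2x2 tables (a b / c d).
enum_fisher_p <- function(a, b, c, d, alternative = "two.sided") {
  m1 <- a + b; k <- a + c
  support <- max(0, k - (c + d)):min(k, m1)
  probs <- vapply(support, function(x) {
    exp(lchoose(m1, x) + lchoose(c + d, k - x) - lchoose(a + b + c + d, k))
  }, 0)
  p_obs <- probs[support == a]
  switch(alternative,
    two.sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater = sum(probs[support >= a]),
    less = sum(probs[support <= a]))
}

# ---- Dip -------------------------------------------------------------------

# Dip oracle: binary search on the sup-norm tolerance d; for each candidate
# mode (a unique sample point, where a unimodal CDF may place an atom),
# feasibility of a convex fit left of the mode and a concave fit right of it
# within the ECDF +/- d bands, coupled through the jump at the mode.
oracle_collapse <- function(x) {
  x <- sort(x); n <- length(x)
  ux <- unique(x); cnt <- tabulate(match(x, ux)); m <- length(ux)
  hi <- cumsum(cnt) / n; lo <- c(0, hi[-m])
  list(ux = ux, lo = lo, hi = hi, m = m)
}

oracle_lower_hull <- function(px, py) {
  m <- length(px)
  if (m == 1) return(py)
  h <- integer(m); top <- 0L
  for (i in seq_len(m)) {
    while (top >= 2L) {
      a <- h[top - 1L]; b <- h[top]
      cr <- (py[i] - py[b]) * (px[b] - px[a]) - (py[b] - py[a]) * (px[i] - px[b])
      if (cr <= 0) top <- top - 1L else break
    }
    top <- top + 1L; h[top] <- i
  }
  v <- h[seq_len(top)]
  if (length(v) == 1) rep(py[v], m) else approx(px[v], py[v], xout = px)$y
}
oracle_upper_hull <- function(px, py) -oracle_lower_hull(px, -py)

oracle_left_ok <- function(e, k, d, t) {
  if (k == 1) return(t >= 0)
  j <- seq_len(k)
  ub <- pmin(e$lo[j] + d, t)
  lb <- c(e$hi[j[-k]] - d, -Inf)
  if (any(ub < -1e-12)) return(FALSE)
  all(oracle_lower_hull(e$ux[j], ub) >= lb - 1e-12)
}
oracle_right_ok <- function(e, k, d, t) {
  j <- k:e$m
  lb <- pmax(c(e$hi[k] - d, e$hi[j[-1]] - d), t)
  ub <- pmin(c(e$hi[k] + d, e$lo[j[-1]] + d), 1)
  if (any(lb > 1 + 1e-12)) return(FALSE)
  all(oracle_upper_hull(e$ux[j], lb) <= ub + 1e-12)
}
oracle_mode_ok <- function(e, k, d, iters = 50) {
  if (!oracle_left_ok(e, k, d, 1) || !oracle_right_ok(e, k, d, 0)) return(FALSE)
  lo <- 0; hi <- 1
  for (j in seq_len(iters)) {
    m <- (lo + hi) / 2
    if (oracle_left_ok(e, k, d, m)) hi <- m else lo <- m
  }
  a <- hi
  lo <- 0; hi <- 1
  for (j in seq_len(iters)) {
    m <- (lo + hi) / 2
    if (oracle_right_ok(e, k, d, m)) lo <- m else hi <- m
  }
  a <= lo + 1e-9
}
dip_oracle <- function(x, iters = 40) {
  e <- oracle_collapse(x)
  lo <- 0; hi <- 0.5
  for (j in seq_len(iters)) {
    d <- (lo + hi) / 2
    if (any(vapply(seq_len(e$m), function(k) oracle_mode_ok(e, k, d), TRUE))) {
      hi <- d
    } else {
      lo <- d
    }
  }
  hi
}

# ---- BH --------------------------------------------------------------------

# Step-up adjustment written directly from the definition.
step_up_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# ---- misc ------------------------------------------------------------------

trapezoid <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
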