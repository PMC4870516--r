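test_that("psi is the inclusion fraction of the two junction counts", {
  expect_equal(compute_psi(50, 50), 50)
  expect_equal(compute_psi(0, 37), 0)
  expect_equal(compute_psi(3, 7), 30)
  expect_true(is.na(compute_psi(0, 0)))
  expect_error(compute_psi(-1, 5), "negative")
  expect_error(compute_psi(2.5, 5), "non-integer")
})

test_that("psi and its complement sum to 100 whenever defined", {
  set.seed(4)
  a <- rpois(200, 30); b <- rpois(200, 10)
  ok <- a + b > 0
  expect_equal(compute_psi(a, b)[ok] + compute_psi(b, a)[ok],
               rep(100, sum(ok)))
})

test_that("detectability requires one sufficiently covered stage by default", {
  stages <- c("s1", "s2")
  zero <- counts_from_psi("ev1", c(50, 50), depth = 0, stages = stages)
  expect_false(flag_detectable(zero$counts, zero$samples)$detectable)
  one <- counts_from_psi("ev2", c(40, 40), depth = 25, stages = stages)
  # drop stage s2 coverage below threshold
  one$counts$inclusion[one$counts$sample_id == "s2_r1"] <- 0
  one$counts$exclusion[one$counts$sample_id == "s2_r1"] <- 0
  flags <- flag_detectable(one$counts, one$samples, min_total_per_sample = 20)
  expect_true(flags$detectable)
  expect_equal(flags$n_stages_supporting, 1)
  expect_error(flag_detectable(one$counts, one$samples[-1, ]), "stage label")
})

test_that("detectable count is non-increasing in the coverage threshold", {
  sim <- simulate_timecourse_counts(n_events = 60, n_increasing = 10,
                                    depth_mean = 30, rho = 0.05, seed = 8)
  thresholds <- c(0, 5, 10, 20, 40, 60)
  detected <- vapply(thresholds, function(th) {
    sum(flag_detectable(sim$counts, sim$samples,
                        min_total_per_sample = th)$detectable)
  }, 0)
  expect_true(all(diff(detected) <= 0))
  # brute-force check of the rule at one threshold
  th <- 20
  joined <- dplyr::inner_join(psi_table(sim$counts), sim$samples, "sample_id")
  manual <- tapply(seq_len(nrow(joined)), joined$event_id, function(i) {
    any(tapply(joined$total[i] >= th, joined$stage[i], all))
  })
  flags <- flag_detectable(sim$counts, sim$samples, min_total_per_sample = th)
  expect_equal(flags$detectable, as.logical(manual[flags$event_id]),
               ignore_attr = TRUE)
})

test_that("developmental regulation needs both significance and effect size", {
  stages <- paste0("s", 1:4)
  flat <- counts_from_psi("flat", rep(50, 4), depth = 100, stages = stages)
  res <- call_developmental_regulation(flat$counts, flat$samples)
  expect_false(res$regulated)

  sw <- counts_from_psi("switch", c(5, 5, 45, 45), depth = 200, stages = stages)
  both <- list(counts = rbind(flat$counts, sw$counts), samples = flat$samples)
  res <- call_developmental_regulation(both$counts, both$samples)
  expect_true(res$regulated[res$event_id == "switch"])
  expect_equal(res$direction[res$event_id == "switch"], 1)
  # the per-pair exact test must agree with hypergeometric enumeration:
  # pooled counts for the significant pair are (3*10, 3*190) vs (3*90, 3*110)
  p_pair <- enum_fisher_p(30, 570, 270, 330)
  expect_equal(res$p[res$event_id == "switch"], min(1, p_pair * 3),
               tolerance = 1e-9)

  # |delta psi| = 8 with an overwhelming p still fails the effect-size gate
  small <- counts_from_psi("small", c(46, 46, 54, 54), depth = 100000,
                           stages = stages)
  res <- call_developmental_regulation(small$counts, small$samples)
  expect_true(res$p_adj < 0.05)
  expect_true(res$max_abs_delta_psi < 10)
  expect_false(res$regulated)

  one_stage <- counts_from_psi("x", 50, depth = 100, stages = "only")
  expect_error(call_developmental_regulation(one_stage$counts,
                                             one_stage$samples),
               "two stages")
})

test_that("knockdown dependence requires both contrasts, same sign", {
  mk <- function(event_id, psi_ctrl, psi_kd1, psi_kd12, depth = 400) {
    conds <- c("control", "kd1", "kd12")
    psis <- c(psi_ctrl, psi_kd1, psi_kd12)
    purrr::map2_dfr(conds, psis, function(cond, p) {
      tibble::tibble(event_id = event_id,
                     sample_id = paste0(cond, "_r", 1:3),
                     inclusion = round(depth * p / 100),
                     exclusion = depth - round(depth * p / 100))
    })
  }
  counts <- dplyr::bind_rows(
    mk("dep", 20, 40, 55),      # +20 / +35, both strong
    mk("conflict", 40, 60, 20), # +20 / -20: sign conflict
    mk("kd1only", 20, 40, 20))  # responds to kd1 only
  samples <- tibble::tibble(
    sample_id = c(paste0("control_r", 1:3), paste0("kd1_r", 1:3),
                  paste0("kd12_r", 1:3)),
    condition = rep(c("control", "kd1", "kd12"), each = 3))
  res <- call_knockdown_dependence(counts, samples)
  expect_true(res$dependent[res$event_id == "dep"])
  expect_false(res$dependent[res$event_id == "conflict"])
  expect_false(res$dependent[res$event_id == "kd1only"])
  expect_error(call_knockdown_dependence(counts, samples[1:6, ]), "kd12")
})

test_that("knockdown recovery works on the simulated preset", {
  sim <- simulate_knockdown_counts(n_events = 40, n_dependent = 10,
                                   depth_mean = 150, seed = 12)
  res <- call_knockdown_dependence(sim$counts, sim$samples)
  hits <- res$event_id[res$dependent]
  truth <- sim$truth$event_id[sim$truth$dependent]
  expect_gte(sum(hits %in% truth), 6)
  expect_equal(sum(!hits %in% truth), 0)
})

test_that("overlap enrichment matches exhaustive table enumeration", {
  universe <- sprintf("e%02d", 1:20)
  res <- overlap_enrichment(universe[1:8], universe[4:8], universe)
  expect_equal(res$a_and_b, 5)
  expect_equal(res$p, enum_fisher_p(5, 3, 0, 12), tolerance = 1e-12)

  set.seed(31)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    u <- sprintf("x%03d", seq_len(n))
    a <- sample(u, sample.int(n, 1))
    b <- sample(u, sample.int(n, 1))
    res <- overlap_enrichment(a, b, u)
    expect_equal(res$p, enum_fisher_p(res$a_and_b, res$a_only, res$b_only,
                                      res$neither),
                 tolerance = 1e-9)
  }
})

test_that("overlap enrichment conventions and errors", {
  u <- sprintf("e%02d", 1:10)
  res <- overlap_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$odds_ratio, Inf) # identical halves: documented convention
  expect_true(res$p < 0.05)
  expect_error(overlap_enrichment(u[1:2], u[1:2], character(0)), "non-empty")
  expect_error(overlap_enrichment(c(u, "zz"), u[1:2], u), "subsets")
})

test_that("Fisher p-values are valid (sub-uniform) under independence", {
  set.seed(77)
  n <- 100
  u <- sprintf("x%03d", 1:n)
  p <- replicate(400, {
    overlap_enrichment(sample(u, 40), sample(u, 40), u)$p
  })
  # conservative exact test: P(p <= t) <= t (within binomial noise), and the
  # distribution should not pile up near 0
  for (t in c(0.05, 0.2, 0.5)) {
    expect_lte(mean(p <= t), t + 3 * sqrt(t * (1 - t) / 400))
  }
  expect_gt(mean(p), 0.45)
})

test_that("null time courses are not called regulated above the alpha level", {
  false_calls <- total <- 0
  for (seed in 1:5) {
    sim <- simulate_timecourse_counts(n_events = 80, n_increasing = 0,
                                      depth_mean = 100, rho = 0.02,
                                      seed = seed)
    res <- call_developmental_regulation(sim$counts, sim$samples)
    false_calls <- false_calls + sum(res$regulated, na.rm = TRUE)
    total <- total + nrow(res)
  }
  # BH at alpha = 0.05 with a true null: expected false fraction well below
  # alpha; allow binomial slack
  expect_lte(false_calls / total, 0.05 + 3 * sqrt(0.05 * 0.95 / total))
})

test_that("planted abrupt switches (delta psi 40) are recovered with high sensitivity", {
  # slope 30 turns the logistic trajectory into a step between adjacent stages
  sim <- simulate_timecourse_counts(n_events = 60, n_increasing = 30,
                                    psi_start = 5, psi_end = 45, slope = 30,
                                    depth_mean = 100, rho = 0.02, seed = 3)
  res <- suppressMessages(call_developmental_regulation(sim$counts, sim$samples))
  truth <- sim$truth$event_id[sim$truth$class == "increasing"]
  sens <- mean(res$regulated[match(truth, res$event_id)])
  expect_gte(sens, 0.9)
})
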