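test_that("generators are byte-reproducible given the seed", {
  a <- simulate_gene_models(5, 2, 2, seed = 50)
  b <- simulate_gene_models(5, 2, 2, seed = 50)
  expect_identical(a$gtf, b$gtf)
  expect_identical(a$genome, b$genome)
  c1 <- simulate_timecourse_counts(10, 3, seed = 50)
  c2 <- simulate_timecourse_counts(10, 3, seed = 50)
  expect_identical(c1$counts, c2$counts)
  w1 <- simulate_windows(5, 5, seed = 50)
  w2 <- simulate_windows(5, 5, seed = 50)
  expect_identical(w1$regulated, w2$regulated)
  s1 <- simulate_single_cells(5, 5, 5, seed = 50)
  s2 <- simulate_single_cells(5, 5, 5, seed = 50)
  expect_identical(s1$profiles, s2$profiles)
  # and the generator does not disturb the caller's RNG
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(simulate_gene_models(2, seed = 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("cataloging recovers exactly the planted events", {
  sim <- simulate_gene_models(n_events = 10, n_cassette = 0, n_tandem_apa = 0,
                              seed = 51)
  ev <- catalog_ua3e_events(read_gene_models(sim$gtf))
  expect_equal(nrow(ev), 10)
  sim2 <- simulate_gene_models(n_events = 5, n_cassette = 5, n_tandem_apa = 0,
                               seed = 52)
  ev2 <- catalog_ua3e_events(read_gene_models(sim2$gtf))
  truth2 <- sim2$truth[sim2$truth$class == "true_event", ]
  expect_equal(nrow(ev2), 5)
  expect_setequal(ev2$gene_id, truth2$gene_id)
  m <- match(ev2$gene_id, truth2$gene_id)
  expect_equal(ev2$shared_donor, truth2$shared_donor[m])
  expect_equal(ev2$ua3e_3ss, truth2$ua3e_3ss[m])
  expect_equal(ev2$aide_3ss, truth2$aide_3ss[m])
})

test_that("every generated record appears in its truth table", {
  sim <- simulate_gene_models(4, 2, 1, seed = 53)
  expect_setequal(names(sim$genome), sim$truth$chrom)
  expect_equal(nrow(sim$truth), 7)
  tc <- simulate_timecourse_counts(12, 3, 2, seed = 53)
  expect_setequal(unique(tc$counts$event_id), tc$truth$event_id)
  expect_setequal(unique(tc$counts$sample_id), tc$samples$sample_id)
  sc <- simulate_single_cells(3, 3, 3, seed = 53)
  expect_setequal(sc$profiles$cell_id, sc$truth$cell_id)
  w <- simulate_windows(4, 6, seed = 53)
  expect_setequal(c(w$regulated$event_id, w$background$event_id),
                  w$truth$event_id)
})

test_that("time-course counts match their target psi at high depth", {
  sim <- simulate_timecourse_counts(n_events = 5, n_increasing = 0,
                                    flat_psi_range = c(30, 30),
                                    depth_mean = 1e6, rho = 0, seed = 54)
  pooled <- dplyr::summarise(dplyr::group_by(sim$counts, event_id),
                             psi = 100 * sum(inclusion) /
                               sum(inclusion + exclusion))
  expect_true(all(abs(pooled$psi - 30) < 0.2))
})

test_that("planted trajectories are flat or monotone in expectation", {
  sim <- simulate_timecourse_counts(n_events = 6, n_increasing = 2,
                                    n_decreasing = 2, psi_start = 5,
                                    psi_end = 45, seed = 55)
  traj <- sim$truth$psi_trajectory
  cls <- sim$truth$class
  for (i in seq_along(traj)) {
    nu <- nu_from_psi(traj[[i]])
    if (cls[i] == "increasing") expect_true(all(diff(nu) > 0))
    if (cls[i] == "decreasing") expect_true(all(diff(nu) < 0))
    if (cls[i] == "flat") expect_equal(diff(traj[[i]]), rep(0, 7))
  }
  same <- simulate_timecourse_counts(n_events = 2, n_increasing = 2,
                                     psi_start = 20, psi_end = 20, seed = 55)
  expect_true(all(vapply(same$truth$psi_trajectory,
                         function(t) all(t == 20), TRUE)))
  expect_error(simulate_timecourse_counts(5, 0, rho = 1, seed = 1), "rho")
  expect_error(simulate_timecourse_counts(5, 6, seed = 1), "exceed")
})

test_that("window planting rates behave as configured", {
  all_in <- simulate_windows(n_regulated = 30, n_background = 5,
                             motif = "UCUUCU", rate_regulated = 1,
                             rate_background = 0, seed = 56)
  reg_hit <- vapply(seq_len(30), function(i) {
    scan_motif(all_in$regulated$r4[i], "UCUUCU")$count +
      scan_motif(all_in$regulated$r5[i], "UCUUCU")$count > 0
  }, TRUE)
  expect_true(all(reg_hit))
  # at rate 0, occurrences arise only by chance ~ (1/4)^6 per position
  none <- simulate_windows(n_regulated = 5, n_background = 400,
                           motif = "UCUUCU", rate_regulated = 0,
                           rate_background = 0, seed = 57)
  n_hit <- sum(vapply(seq_len(400), function(i) {
    scan_motif(none$background$r4[i], "UCUUCU")$count +
      scan_motif(none$background$r5[i], "UCUUCU")$count > 0
  }, TRUE))
  expected <- 400 * (1 - (1 - (1 / 4)^6)^(2 * (125 - 5)))
  expect_lt(abs(n_hit - expected), 3 * sqrt(expected) + 3)
  expect_error(simulate_windows(width = 8, motif = "UCUUCUUCUU", seed = 1),
               "shorter")
})

test_that("zero-dropout single cells classify exactly; dropout degrades markers", {
  sim <- simulate_single_cells(20, 20, 20, dropout = 0, seed = 58)
  cls <- classify_cells(sim$profiles)
  expect_equal(as.character(cls$class), sim$truth$true_class)
  drop <- simulate_single_cells(200, 0, 0, dropout = 0.5, seed = 58)
  expect_gt(sum(drop$profiles$neun == 0), 50)
})
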