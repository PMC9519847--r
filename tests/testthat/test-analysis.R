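test_that("maximum absolute off-diagonal weight follows its bounds", {
  xs1 <- generate_patterns(1, 10, seed = 1)
  expect_equal(w_max(hebbian_weights(xs1)), 1)

  M <- matrix(0L, 4, 4); M[1, 3] <- 5L
  expect_equal(w_max(M), 5)
  expect_error(w_max(matrix(1L, 1, 1)), "two neurons")

  xs <- generate_patterns(9, 30, seed = 2)
  wm <- w_max(hebbian_weights(xs))
  expect_lte(wm, 9)
  expect_equal(wm %% 2, 1)
})

test_that("conditional connection histogram is flat for random networks and obeys total probability", {
  N <- 200; c <- 20
  xs <- generate_patterns(10, N, seed = 3)
  W <- hebbian_weights(xs)
  cn <- random_connectivity(N, c, seed = 4)
  h <- conditional_connection_probability(cn, W, n_bins = 11)

  # exact counting identity on any network
  expect_equal(sum(h$p_connected * h$n_pairs, na.rm = TRUE) / sum(h$n_pairs),
               mean(rowSums(cn$C)) / (N - 1))

  # flat at c / (N - 1) within per-bin binomial error (4 sigma)
  base <- c / (N - 1)
  pop <- h$n_pairs >= 50
  tol <- 4 * sqrt(base * (1 - base) / h$n_pairs[pop])
  expect_true(all(abs(h$p_connected[pop] - base) < pmax(tol, 0.04)))
  # empty bins are flagged as NA, never interpolated
  expect_true(all(is.na(h$p_connected[h$n_pairs == 0])))
})

test_that("optimized networks reshape the weight-conditional connection probability", {
  N <- 300; c <- 6; p <- 12
  xs <- generate_patterns(p, N, seed = 5)
  W <- hebbian_weights(xs)
  cn <- random_connectivity(N, c, seed = 6)

  # signal reinforcement favors high-|W| synapses: positive rank correlation
  optp <- optimize_network(cn, xs, anneal_config(epsilon = "p", moves_per_t = 5),
                           seed = 7)
  hp <- conditional_connection_probability(optp$C, W)
  ok <- !is.na(hp$p_connected)
  expect_gt(stats::cor(abs(hp$bin_center[ok]), hp$p_connected[ok],
                       method = "spearman"), 0)

  # noise reduction avoids extreme weights: depressed top-|W| decile
  opt0 <- optimize_network(cn, xs, anneal_config(epsilon = 0, moves_per_t = 5),
                           seed = 8)
  h0 <- conditional_connection_probability(opt0$C, W)
  wm <- w_max(W)
  dec <- stats::quantile(abs(W[!diag(TRUE, N)]) / wm, 0.9)
  top <- abs(h0$bin_center) >= dec
  expect_lt(stats::weighted.mean(h0$p_connected[top], h0$n_pairs[top],
                                 na.rm = TRUE), c / (N - 1))
})

test_that("improvement ratio is exactly 1 with full connectivity", {
  sw <- improvement_sweep(60, 59, config = anneal_config(epsilon = 0),
                          seeds = 1:2, max_p = 30)
  expect_true(all(sw$ratio == 1))
  expect_true(all(sw$p_c_opt == sw$p_c_rand))
})

test_that("field statistics reproduce the optimization signatures across loads", {
  # random networks: zero-noise limit at vanishing load
  fs_rand <- field_statistics_sweep(300, 20, c(0.05, 0.4), seeds = 1)
  expect_equal(fs_rand$mean_aligned_field[1], 1)
  expect_equal(fs_rand$sd_aligned_field[1], 0)
  expect_gt(fs_rand$sd_aligned_field[2], fs_rand$sd_aligned_field[1])

  # noise reduction anti-correlates noise and signal: mean decreases with load
  fs0 <- field_statistics_sweep(300, 12, c(0.5, 1.25),
                                config = anneal_config(epsilon = 0, moves_per_t = 5),
                                seeds = 1)
  expect_lt(fs0$mean_aligned_field[2], fs0$mean_aligned_field[1])

  # signal reinforcement drives the mean up with load
  fsp <- field_statistics_sweep(300, 12, c(0.5, 1.5),
                                config = anneal_config(epsilon = "p", moves_per_t = 5),
                                seeds = 1)
  expect_gt(fsp$mean_aligned_field[2], fsp$mean_aligned_field[1])
  expect_gt(fsp$mean_aligned_field[1], 1)
})

test_that("network and sweep serialization round-trip losslessly", {
  tmp <- tempfile()
  xs <- generate_patterns(4, 25, seed = 9)
  cn <- random_connectivity(25, 5, seed = 10)
  save_network(cn, xs, tmp, meta = list(seed = 10, note = "unit"))
  back <- load_network(tmp)
  expect_identical(back$C$C, cn$C)
  expect_identical(back$patterns$xi, xs$xi)
  expect_equal(back$meta$seed, 10)
  expect_equal(back$meta$N, 25)

  sw <- improvement_sweep(40, 39, seeds = 1, max_p = 20)
  tmp2 <- tempfile()
  write_sweep(sw, tmp2, meta = list(seeds = 1))
  back2 <- read_sweep(tmp2)
  expect_equal(as.data.frame(back2$sweep), as.data.frame(sw))
  expect_s3_class(back2$sweep, "sweep_summary")
})
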