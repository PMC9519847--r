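test_that("row cost matches the quadruple-loop definition and its closed cases", {
  # p = 1: the crosstalk sum over mu != nu is empty
  xs1 <- generate_patterns(1, 20, seed = 1)
  row <- integer(20); row[2:6] <- 1L
  expect_equal(row_cost(1, row, xs1, 0), 0)
  expect_equal(row_cost(1, row, xs1, 5), 25)
  expect_error(row_cost(2, row, xs1, 0), "self-connection")

  for (k in 1:40) {
    inst <- random_row_instance(k)
    eps <- sample(c(0, 1, 3), 1)
    expect_equal(row_cost(inst$i, inst$row, inst$xi, eps),
                 oracle_row_cost(inst$i, inst$row, inst$xi, eps))
  }

  # row noise A relates the cost to the field decomposition: A = c R xi
  inst <- random_row_instance(99)
  A <- row_noise(inst$i, inst$row, pattern_set(inst$xi))
  W <- oracle_hebbian(inst$xi)
  Cm <- matrix(0L, inst$N, inst$N); Cm[inst$i, ] <- inst$row
  h <- oracle_local_field(inst$xi[1, ], W, Cm, inst$c)[inst$i]
  aligned <- h * inst$xi[1, inst$i]
  expect_equal(A[1] / inst$c, aligned - sum(inst$row) / inst$c)
  expect_equal(row_cost(inst$i, inst$row, inst$xi, 2), sum((A - 2)^2))
})

test_that("incremental swap delta equals full recomputation and is an involution", {
  for (k in 1:40) {
    inst <- random_row_instance(k + 200)
    eps <- sample(c(0, 2), 1)
    conn <- which(inst$row == 1L)
    free <- setdiff(which(inst$row == 0L), inst$i)
    if (length(free) == 0) next
    j_out <- conn[1]; j_in <- free[1]
    d <- delta_cost_swap(inst$i, inst$row, inst$xi, eps, j_out, j_in)
    after <- inst$row; after[j_out] <- 0L; after[j_in] <- 1L
    expect_equal(d, row_cost(inst$i, after, inst$xi, eps) -
                    row_cost(inst$i, inst$row, inst$xi, eps))
    # swapping back restores the cost exactly
    d_back <- delta_cost_swap(inst$i, after, inst$xi, eps, j_in, j_out)
    expect_equal(d + d_back, 0)
  }

  # indistinguishable columns: identical pattern columns give a zero delta
  xi <- generate_patterns(3, 8, seed = 5)$xi
  xi[, 4] <- xi[, 5]
  row <- integer(8); row[c(4, 7)] <- 1L
  expect_equal(delta_cost_swap(1, row, pattern_set(xi), 0, 4L, 5L), 0)

  expect_error(delta_cost_swap(1, row, pattern_set(xi), 0, 2L, 5L), "not a current")
  expect_error(delta_cost_swap(1, row, pattern_set(xi), 0, 4L, 7L), "already")
})

test_that("initial temperature estimation follows the probe-average rule", {
  # p = 1, eps = 0: every swap has zero cost change, so the fallback fires
  xs1 <- generate_patterns(1, 15, seed = 6)
  row <- integer(15); row[2:4] <- 1L
  expect_equal(estimate_initial_temperature(1, row, xs1, 0, t_final = 1e-4, seed = 1),
               1e-4)
  expect_error(estimate_initial_temperature(1, row, xs1, 0, n_probe = 5), "at least 10")

  # acceptance-rate calibration: fresh uphill probes at T0 are accepted with
  # probability about accept0
  set.seed(7)
  xs <- generate_patterns(8, 60, seed = 7)
  cn <- random_connectivity(60, 12, seed = 8)
  i <- 3L
  row <- cn$C[i, ]
  T0 <- estimate_initial_temperature(i, row, xs, 0, n_probe = 200, accept0 = 0.8,
                                     seed = 9)
  expect_gt(T0, 0)
  conn <- which(row == 1L); free <- setdiff(which(row == 0L), i)
  deltas <- replicate(500, delta_cost_swap(i, row, xs, 0,
                                           sample(conn, 1), sample(free, 1)))
  up <- deltas[deltas > 0]
  expect_lt(abs(mean(exp(-up / T0)) - 0.8), 0.15)
})

test_that("row annealing preserves structure, never worsens, and recovers exhaustive optima", {
  set.seed(10)
  xs <- generate_patterns(4, 25, seed = 10)
  cn <- random_connectivity(25, 6, seed = 11)
  cfg <- anneal_config(epsilon = 0, moves_per_t = 3, check_every = 25)
  res <- anneal_row(2, cn$C[2, ], xs, cfg, seed = 12)
  expect_equal(sum(res$row), 6)
  expect_equal(res$row[2], 0L)
  expect_lte(res$e_final, res$e_init)
  expect_equal(row_cost(2, res$row, xs, 0), res$e_final)

  # no degrees of freedom when fully connected
  full_row <- rep(1L, 25); full_row[2] <- 0L
  res_full <- anneal_row(2, full_row, xs, cfg, seed = 13)
  expect_identical(res_full$row, full_row)
  expect_equal(res_full$e_final, res_full$e_init)

  # exhaustive-minimum recovery on N = 7, c = 2, p = 2 instances
  hits <- 0
  for (k in 1:100) {
    xi <- generate_patterns(2, 7, seed = k)
    combs <- utils::combn(2:7, 2)
    costs <- apply(combs, 2, function(js) {
      r <- integer(7); r[js] <- 1L; row_cost(1, r, xi, 0)
    })
    r0 <- integer(7); r0[combs[, which.max(costs)]] <- 1L
    out <- anneal_row(1, r0, xi, anneal_config(epsilon = 0, moves_per_t = 10),
                      seed = k + 1000)
    if (out$e_final == min(costs)) hits <- hits + 1
  }
  expect_gte(hits, 90)

  # dominance over a random-restart baseline on tiny instances
  for (k in 1:5) {
    inst <- random_row_instance(k + 400)
    out <- anneal_row(inst$i, inst$row, pattern_set(inst$xi),
                      anneal_config(epsilon = 1, moves_per_t = 10), seed = k)
    rand_costs <- replicate(100, {
      r <- integer(inst$N)
      r[sample(setdiff(seq_len(inst$N), inst$i), inst$c)] <- 1L
      row_cost(inst$i, r, inst$xi, 1)
    })
    expect_lte(out$e_final, min(rand_costs))
  }
})

test_that("network optimization is reproducible, structure-preserving and capacity-improving", {
  xs <- generate_patterns(6, 40, seed = 14)
  cn <- random_connectivity(40, 8, seed = 15)
  cfg <- anneal_config(epsilon = 0, moves_per_t = 3, check_every = 50)
  opt1 <- optimize_network(cn, xs, cfg, seed = 16)
  opt2 <- optimize_network(cn, xs, cfg, seed = 16)
  expect_identical(opt1$C$C, opt2$C$C)
  expect_true(all(rowSums(opt1$C$C) == 8))
  expect_true(all(diag(opt1$C$C) == 0))
  expect_lte(sum(opt1$e_final), sum(opt1$e_init))
  # reported costs match independent re-evaluation
  expect_equal(opt1$e_final[3], row_cost(3, opt1$C$C[3, ], xs, 0))

  # optimized networks store at least as much as random ones (both costs)
  for (cfg_i in list(anneal_config(epsilon = 0, moves_per_t = 5),
                     anneal_config(epsilon = "p", moves_per_t = 5))) {
    wins <- 0
    for (sd in 1:5) {
      rand <- storage_capacity(random_network_builder(120, 12), c = 12,
                               seeds = sd, max_p = 60)
      opt <- storage_capacity(annealed_network_builder(120, 12, cfg_i), c = 12,
                              seeds = sd, max_p = 60)
      if (opt$p_c >= rand$p_c) wins <- wins + 1
    }
    expect_gte(wins, 4)
  }
})
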