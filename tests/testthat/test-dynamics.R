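test_that("local field matches hand arithmetic and the brute-force oracle", {
  # a stored pattern is an exact fixed point of the field when p = 1
  xs <- generate_patterns(1, 30, seed = 1)
  W <- hebbian_weights(xs)
  cn <- random_connectivity(30, 7, seed = 2)
  h <- local_field(xs$xi[1, ], W, cn, norm = 7)
  expect_equal(h, as.numeric(xs$xi[1, ]))

  # hand-computed 3-neuron example
  W3 <- matrix(c(0L, 1L, -1L, 1L, 0L, 1L, -1L, 1L, 0L), 3, 3)
  C3 <- matrix(1L, 3, 3) - diag(1L, 3)
  expect_equal(local_field(c(1L, 1L, -1L), W3, C3, norm = 2), c(1, 0, 0))

  expect_error(local_field(c(1L, 1L, -1L), W3, C3, norm = 0), ">= 1")

  for (k in 1:20) {
    inst <- random_row_instance(k)
    W <- oracle_hebbian(inst$xi)
    cn <- random_connectivity(inst$N, inst$c, seed = k + 500)
    s <- generate_patterns(1, inst$N, seed = k + 900)$xi[1, ]
    expect_equal(local_field(s, W, cn, norm = inst$c),
                 oracle_local_field(s, W, cn$C, inst$c))
  }
})

test_that("threshold update applies sgn with the +1 tie-break and is idempotent on a fixed field", {
  s <- c(1L, 1L, 1L)
  expect_equal(update_state(s, c(0.3, -2, 0)), c(1L, -1L, 1L))
  expect_equal(update_state(s, c(5, 1e-9, 2)), c(1L, 1L, 1L))
  h <- c(-0.5, 0, 3)
  expect_equal(update_state(update_state(s, h), h), update_state(s, h))
  expect_error(update_state(s, c(1, NaN, 0)), "finite")
})

test_that("overlap is the normalized dot product with its symmetries", {
  xi <- generate_patterns(1, 20, seed = 3)$xi[1, ]
  expect_equal(overlap(xi, xi), 1)
  expect_equal(overlap(-xi, xi), -1)
  flipped <- xi; flipped[1:10] <- -flipped[1:10]
  expect_equal(overlap(flipped, xi), 0)
  expect_error(overlap(xi, xi[-1]), "mismatch")
})

test_that("retrieval dynamics converge on stored patterns and respect the stopping rule", {
  xs <- generate_patterns(1, 100, seed = 4)
  W <- hebbian_weights(xs)
  full <- random_connectivity(100, 99, seed = 5)

  r <- run_dynamics(xs$xi[1, ], W, full, xs$xi[1, ])
  expect_equal(r$final_overlap, 1)
  expect_lte(r$iterations_used, 1)
  expect_true(r$converged)

  # the inverse state is the stable spurious attractor
  r_inv <- run_dynamics(-xs$xi[1, ], W, full, xs$xi[1, ])
  expect_equal(r_inv$final_overlap, -1)

  # a 10% corrupted cue falls back into the attractor at p = 1
  s0 <- xs$xi[1, ]; s0[1:10] <- -s0[1:10]
  r_err <- run_dynamics(s0, W, full, xs$xi[1, ])
  expect_equal(r_err$final_overlap, 1)

  # reported overlap always equals an independent recomputation; max_iter binds
  xs2 <- generate_patterns(40, 60, seed = 6)   # far above capacity
  W2 <- hebbian_weights(xs2)
  cn2 <- random_connectivity(60, 20, seed = 7)
  for (nu in c(1, 5, 9)) {
    r2 <- run_dynamics(xs2$xi[nu, ], W2, cn2, xs2$xi[nu, ], max_iter = 15)
    expect_lte(r2$iterations_used, 15)
    expect_equal(r2$final_overlap, overlap(r2$final_state, xs2$xi[nu, ]))
  }
})

test_that("global sign flip of pattern and initial state negates the final overlap", {
  # odd p and odd in-degree keep every field numerator odd, so the sgn(0)
  # tie-break never fires and the dynamics are exactly odd under global flips
  for (k in 1:10) {
    set.seed(k)
    N <- 40
    xs <- generate_patterns(5, N, seed = k)
    W <- hebbian_weights(xs)
    cn <- random_connectivity(N, 9, seed = k + 50)
    s0 <- xs$xi[1, ]
    flip_at <- sample(N, 8)
    s0[flip_at] <- -s0[flip_at]
    r_plus <- run_dynamics(s0, W, cn, xs$xi[1, ])
    r_minus <- run_dynamics(-s0, W, cn, -xs$xi[1, ])
    # overlap with -xi after flipping the cue equals overlap with xi before:
    # the Z2 symmetry means measuring against the flipped pattern is invariant,
    # equivalently the overlap with the *unflipped* pattern is negated
    expect_equal(overlap(r_minus$final_state, xs$xi[1, ]), -r_plus$final_overlap)
    expect_equal(r_minus$final_overlap, r_plus$final_overlap)
  }
})

test_that("aligned field decomposes as signal plus noise with sd growing like sqrt(alpha)", {
  # p = 1: zero crosstalk exactly
  xs <- generate_patterns(1, 50, seed = 8)
  W <- hebbian_weights(xs)
  cn <- random_connectivity(50, 10, seed = 9)
  afs <- aligned_field_stats(xs, W, cn, norm = 10)
  expect_equal(afs$mean, 1)
  expect_equal(afs$sd, 0)

  # entrywise identity aligned = 1 + noise * signal at the stored patterns
  xs2 <- generate_patterns(6, 40, seed = 10)
  W2 <- hebbian_weights(xs2)
  cn2 <- random_connectivity(40, 8, seed = 11)
  afs2 <- aligned_field_stats(xs2, W2, cn2, norm = 8)
  expect_equal(afs2$aligned_field, 1 + afs2$noise * afs2$signal)

  # random diluted network: sd of the aligned field ~ sqrt(p / c)
  sds <- vapply(1:3, function(k) {
    xs3 <- generate_patterns(20, 400, seed = k)
    cn3 <- random_connectivity(400, 40, seed = k + 20)
    aligned_field_stats(xs3, hebbian_weights(xs3), cn3, norm = 40)$sd
  }, numeric(1))
  expect_lt(abs(mean(sds) - sqrt(20 / 40)), 0.15 * sqrt(20 / 40))
})
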