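# Per-neuron connectivity optimization by simulated annealing.
#
# Each neuron i selects which c presynaptic connections to keep by minimizing
#   E_i = sum_nu (A_i^nu - epsilon)^2,
# where A_i^nu = sum_j (W_ij - xi_i^nu xi_j^nu) xi_i^nu xi_j^nu C_ij is the
# unnormalized aligned crosstalk on pattern nu (A = c * R * xi in field
# units).  epsilon = 0 is pure noise reduction; epsilon > 0 reinforces the
# signal by driving the crosstalk toward a positive target.  Rows are
# independent problems, so the network optimization is a loop of independent
# row anneals with per-neuron seed streams.

#' Annealer configuration
#'
#' @param epsilon the crosstalk target, in the unnormalized units of the row
#'   cost: a non-negative number, or the policy strings `"p"` (set to the
#'   current number of stored patterns; the offline signal-reinforcement
#'   default) or `"N/2"` (half the network size; the online default).
#'   `epsilon = 0` is the noise-reduction cost.
#' @param decay geometric cooling factor per temperature step (default 0.99).
#' @param t_final final temperature (default `1e-4`).
#' @param t_init initial temperature; `"auto"` estimates it from the average
#'   uphill cost change of `n_probe` probe swaps so that the initial uphill
#'   acceptance rate is about `accept0`.
#' @param moves_per_t swap proposals attempted at each temperature
#'   (default 1, i.e. the temperature decays at every step).
#' @param n_probe probe moves for the initial-temperature estimate.
#' @param accept0 target initial uphill acceptance rate.
#' @param check_every if positive, re-derive the incremental cost cache from
#'   scratch every `check_every` accepted moves and stop on any discrepancy
#'   (a self-verification mode; default off).
#' @return Object of class `anneal_config`.
#' @export
anneal_config <- function(epsilon = 0, decay = 0.99, t_final = 1e-4,
                          t_init = "auto", moves_per_t = 1L, n_probe = 50L,
                          accept0 = 0.8, check_every = 0L) {
  if (is.character(epsilon)) {
    if (!epsilon %in% c("p", "N/2")) stop('epsilon policy must be "p" or "N/2"')
  } else if (epsilon < 0) {
    stop("epsilon must be non-negative")
  }
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)")
  if (t_final <= 0) stop("t_final must be positive")
  if (!identical(t_init, "auto") && (!is.numeric(t_init) || t_init <= 0)) {
    stop('t_init must be "auto" or a positive number')
  }
  if (n_probe < 10) stop("n_probe must be at least 10")
  if (accept0 <= 0 || accept0 >= 1) stop("accept0 must be in (0, 1)")
  structure(list(epsilon = epsilon, decay = decay, t_final = t_final,
                 t_init = t_init, moves_per_t = as.integer(moves_per_t),
                 n_probe = as.integer(n_probe), accept0 = accept0,
                 check_every = as.integer(check_every)),
            class = "anneal_config")
}

resolve_epsilon <- function(epsilon, p, N) {
  if (is.character(epsilon)) {
    switch(epsilon, "p" = as.numeric(p), "N/2" = N / 2)
  } else {
    as.numeric(epsilon)
  }
}

#' Row cost of one neuron's presynaptic connectivity
#'
#' Evaluates `E_i = sum_nu (A_i^nu - epsilon)^2` exactly (integer arithmetic
#' for integer `epsilon`). With a single stored pattern the crosstalk sum is
#' empty, so `E = p * epsilon^2`.
#'
#' @param i neuron index (1-based).
#' @param C_row binary length-`N` vector with `C_row[i] = 0`.
#' @param patterns a [pattern_set()].
#' @param epsilon non-negative numeric crosstalk target.
#' @return Non-negative numeric cost.
#' @export
row_cost <- function(i, C_row, patterns, epsilon = 0) {
  patterns <- as_pattern_set(patterns)
  if (patterns$p < 1) stop("need at least one pattern")
  if (C_row[i] != 0) stop("self-connection present in row")
  cpp_row_cost(i - 1L, as.integer(C_row), patterns$xi, as.numeric(epsilon))
}

#' Per-pattern aligned crosstalk of one row
#'
#' Returns the vector `A_i^nu` (one entry per stored pattern), the
#' unnormalized aligned noise that the row cost penalizes; `A = c * R * xi`
#' in terms of the field decomposition.
#'
#' @inheritParams row_cost
#' @return Numeric vector of length `p`.
#' @export
row_noise <- function(i, C_row, patterns) {
  patterns <- as_pattern_set(patterns)
  cpp_row_noise(i - 1L, as.integer(C_row), patterns$xi)
}

#' Incremental cost change of a one-out/one-in connection swap
#'
#' Cost change of replacing existing connection `j_out` by new connection
#' `j_in`, computed in `O(p)` from the cached per-pattern crosstalk rather
#' than by re-evaluating the full row cost.
#'
#' @inheritParams row_cost
#' @param j_out column currently connected (`C_row[j_out] = 1`).
#' @param j_in column currently unconnected (`C_row[j_in] = 0`, `j_in != i`).
#' @return Signed numeric cost change `E(after) - E(before)`.
#' @export
delta_cost_swap <- function(i, C_row, patterns, epsilon, j_out, j_in) {
  patterns <- as_pattern_set(patterns)
  cpp_delta_swap(i - 1L, as.integer(C_row), patterns$xi, as.numeric(epsilon),
                 j_out - 1L, j_in - 1L)
}

#' Initial annealing temperature from probe moves
#'
#' Samples `n_probe` random swap moves, averages the positive cost changes
#' and returns `T0 = -mean(dE+) / log(accept0)`, so uphill moves of typical
#' size are initially accepted with probability about `accept0`. If no probe
#' has a positive cost change the row is locally flat or downhill and the
#' final temperature is returned.
#'
#' @inheritParams row_cost
#' @param n_probe number of probe swaps (at least 10).
#' @param accept0 target initial uphill acceptance rate in (0, 1).
#' @param t_final fallback temperature when no uphill probe is found.
#' @param seed integer seed for the probe draws.
#' @return Positive numeric temperature.
#' @export
estimate_initial_temperature <- function(i, C_row, patterns, epsilon = 0,
                                         n_probe = 50L, accept0 = 0.8,
                                         t_final = 1e-4, seed = 1L) {
  if (n_probe < 10) stop("n_probe must be at least 10")
  if (accept0 <= 0 || accept0 >= 1) stop("accept0 must be in (0, 1)")
  patterns <- as_pattern_set(patterns)
  cpp_estimate_t0(i - 1L, as.integer(C_row), patterns$xi, as.numeric(epsilon),
                  as.integer(n_probe), accept0, t_final, as.integer(seed))
}

#' Anneal one neuron's presynaptic row
#'
#' Runs simulated annealing on the row of neuron `i`: at each temperature,
#' `moves_per_t` one-out/one-in swaps are proposed (preserving the in-degree
#' and the zero diagonal); a move is always accepted when it lowers the cost
#' and otherwise with probability `exp(-dE / T)`; the temperature decays
#' geometrically from the (estimated) initial value down to `t_final`. The
#' best configuration seen anywhere along the schedule is returned.
#'
#' @inheritParams row_cost
#' @param config an [anneal_config()]; a character or numeric `epsilon` policy
#'   is resolved against this pattern set.
#' @param seed integer seed for this row's private stream.
#' @return List with `row` (optimized binary vector), `e_init`, `e_final`,
#'   `t0`, `steps` (temperature steps) and `accepted` (accepted moves).
#' @export
anneal_row <- function(i, C_row, patterns, config = anneal_config(), seed = 1L) {
  patterns <- as_pattern_set(patterns)
  if (C_row[i] != 0) stop("self-connection present in row")
  eps <- resolve_epsilon(config$epsilon, patterns$p, patterns$N)
  t_init <- if (identical(config$t_init, "auto")) -1 else config$t_init
  cpp_anneal_row(i - 1L, as.integer(C_row), patterns$xi, eps,
                 config$decay, config$t_final, t_init, config$moves_per_t,
                 config$n_probe, config$accept0, as.integer(seed),
                 config$check_every)
}

#' Optimize the whole connectivity matrix by per-row annealing
#'
#' Applies [anneal_row()] independently to every neuron. Row costs depend
#' only on the neuron's own row, so rows are independent optimization
#' problems; each row draws from its own seed stream derived from `seed`,
#' making the result reproducible regardless of execution order.
#'
#' @param C a [connectivity()] object or binary matrix.
#' @param patterns a [pattern_set()].
#' @param config an [anneal_config()].
#' @param seed master seed; row `i` uses `derive_seed(seed, i)`.
#' @return List with `C` (optimized [connectivity()]), `e_init`, `e_final`
#'   (per-neuron costs) and `t0` (per-neuron initial temperatures).
#' @export
#' @examples
#' xs <- generate_patterns(4, 30, seed = 1)
#' cn <- random_connectivity(30, 5, seed = 1)
#' opt <- optimize_network(cn, xs, anneal_config(epsilon = 0), seed = 1)
#' sum(opt$e_final) <= sum(opt$e_init)
optimize_network <- function(C, patterns, config = anneal_config(), seed = 1L) {
  patterns <- as_pattern_set(patterns)
  C <- as_connectivity(C)
  if (patterns$N != C$N) stop("dimension mismatch")
  eps <- resolve_epsilon(config$epsilon, patterns$p, patterns$N)
  t_init <- if (identical(config$t_init, "auto")) -1 else config$t_init
  res <- cpp_optimize_network(C$C, patterns$xi, eps, config$decay,
                              config$t_final, t_init, config$moves_per_t,
                              config$n_probe, config$accept0,
                              as.integer(seed), config$check_every)
  list(C = connectivity(res$C, mode = C$mode),
       e_init = res$e_init, e_final = res$e_final, t0 = res$t0)
}
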