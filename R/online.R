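# Online structural plasticity: interleaved pattern loading and greedy
# add/prune optimization of each neuron's presynaptic row.
#
# The online rule is the zero-temperature counterpart of the annealer: single
# connection toggles (add if absent, prune if present) are accepted only when
# they strictly lower the row cost, so in-degrees vary freely per neuron.
# Loading proceeds in batches of `batch` patterns, and a new batch is loaded
# only once the network again retrieves more than
# `retrieval_threshold_fraction` of its stored patterns.

#' Online algorithm configuration
#'
#' @param c0 initial in-degree of the random starting connectivity.
#' @param epsilon crosstalk target held constant for the whole run; default
#'   `"N/2"` (resolved to `N / 2` at run time) since the memory load is no
#'   longer fixed.
#' @param batch patterns loaded per batch (default 10).
#' @param trials_per_neuron toggle trials per neuron per sweep (default 10).
#' @param retrieval_threshold_fraction a batch is loaded once
#'   `p_eff > retrieval_threshold_fraction * p` (default 0.9).
#' @param stop_after_unchanged stop after this many consecutive full sweeps
#'   with no accepted toggle (default 50).
#' @param max_outer_iterations hard guard on the total number of sweeps; runs
#'   that hit it are flagged non-equilibrated, not an error.
#' @param max_p cap on the number of patterns pre-drawn for the run.
#' @param max_iter maximum synchronous updates per retrieval test.
#' @return Object of class `online_config`.
#' @export
online_config <- function(c0, epsilon = "N/2", batch = 10L,
                          trials_per_neuron = 10L,
                          retrieval_threshold_fraction = 0.9,
                          stop_after_unchanged = 50L,
                          max_outer_iterations = 2000L,
                          max_p = NULL, max_iter = 100L) {
  if (batch < 1) stop("batch must be at least 1")
  if (retrieval_threshold_fraction <= 0 || retrieval_threshold_fraction >= 1) {
    stop("retrieval_threshold_fraction must be in (0, 1)")
  }
  structure(list(c0 = as.integer(c0), epsilon = epsilon,
                 batch = as.integer(batch),
                 trials_per_neuron = as.integer(trials_per_neuron),
                 retrieval_threshold_fraction = retrieval_threshold_fraction,
                 stop_after_unchanged = as.integer(stop_after_unchanged),
                 max_outer_iterations = as.integer(max_outer_iterations),
                 max_p = max_p, max_iter = as.integer(max_iter)),
            class = "online_config")
}

#' Greedy add/prune trials on one row
#'
#' Performs `trials` single-entry toggles on the row of neuron `i`: a column
#' `j != i` is drawn uniformly; if connected the pruning of the connection is
#' assessed, otherwise its addition; the toggle is kept only when it strictly
#' lowers the row cost. The in-degree may change; the diagonal never does.
#'
#' @inheritParams row_cost
#' @param trials number of toggle trials.
#' @param seed integer seed.
#' @return List with `row` (updated binary vector), `e_trace` (cost after
#'   each trial, starting at the initial cost), `accepted` and `e_final`.
#' @export
greedy_flip_trials <- function(i, C_row, patterns, epsilon, trials = 10L,
                               seed = 1L) {
  patterns <- as_pattern_set(patterns)
  if (C_row[i] != 0) stop("self-connection present in row")
  eps <- resolve_epsilon(epsilon, patterns$p, patterns$N)
  cpp_greedy_trials(i - 1L, as.integer(C_row), patterns$xi, eps,
                    as.integer(trials), as.integer(seed))
}

#' Run the online structural-plasticity algorithm
#'
#' Starts from a random connectivity of in-degree `c0` loaded at the capacity
#' of that random network, then alternates loading `batch` fresh patterns
#' (rebuilding the Hebbian weights exactly) with full greedy sweeps over all
#' neurons until the retrieval criterion `p_eff > 0.9 p` is met again. The
#' run stops when the connectivity is unchanged for `stop_after_unchanged`
#' consecutive sweeps, or at the sweep/pattern guards (flagged, not an
#' error). Retrieval uses error-free initialization, and each neuron's field
#' is normalized by its own current in-degree.
#'
#' @param N number of neurons.
#' @param config an [online_config()].
#' @param master_seed integer master seed; patterns, initial connectivity and
#'   the per-neuron toggle streams all derive private sub-seeds from it.
#' @param p0 initial number of loaded patterns; `NULL` (default) measures the
#'   capacity of the initial random network.
#' @return Object of class `online_trajectory`: list with `trajectory` (data
#'   frame of per-event records: sweep, event type, `p`, `p_eff`, mean/sd
#'   in-degree, total cost), final `C` ([connectivity()], online mode), `p`,
#'   `p_eff`, `c_est` (final mean in-degree) and stop flags.
#' @export
online_run <- function(N, config, master_seed = 1L, p0 = NULL) {
  stopifnot(inherits(config, "online_config"))
  if (config$c0 < 1 || config$c0 > N - 1) stop("need 1 <= c0 <= N - 1")
  eps <- resolve_epsilon(config$epsilon, NA, N)
  if (is.character(config$epsilon) && config$epsilon == "p") {
    stop('the online run holds epsilon constant; use a number or "N/2"')
  }
  C0 <- random_connectivity(N, config$c0, seed = derive_seed(master_seed, 201L))
  if (is.null(p0)) {
    b <- function(p, seed) {
      patterns <- generate_patterns(p, N, seed = derive_seed(master_seed, 202L))
      list(patterns = patterns, W = hebbian_weights(patterns), C = C0,
           norm = config$c0)
    }
    cap <- storage_capacity(b, c = config$c0,
                            seeds = derive_seed(master_seed, 203L),
                            max_p = 8L * config$c0, max_iter = config$max_iter)
    p0 <- max(1L, as.integer(cap$p_c))
  }
  max_p <- config$max_p
  if (is.null(max_p)) max_p <- as.integer(p0 + config$batch * 400L)
  patterns <- generate_patterns(max_p, N, seed = derive_seed(master_seed, 202L))
  res <- cpp_online_run(patterns$xi, C0$C, as.integer(p0), eps,
                        config$batch, config$trials_per_neuron,
                        config$retrieval_threshold_fraction,
                        config$stop_after_unchanged,
                        config$max_outer_iterations,
                        config$max_iter,
                        as.integer(derive_seed(master_seed, 204L)))
  traj <- res$trajectory
  traj$event <- c("sweep", "load", "init")[traj$event + 1L]
  structure(list(trajectory = traj,
                 C = connectivity(res$C, mode = "online"),
                 patterns = pattern_set(patterns$xi[seq_len(res$p), , drop = FALSE]),
                 p = res$p, p_eff = res$p_eff, p0 = p0,
                 c_est = res$c_est,
                 stopped_unchanged = res$stopped_unchanged,
                 hit_sweep_cap = res$hit_sweep_cap,
                 hit_pattern_cap = res$hit_pattern_cap,
                 sweeps = res$sweeps,
                 epsilon = eps),
            class = "online_trajectory")
}

#' @export
print.online_trajectory <- function(x, ...) {
  status <- if (x$stopped_unchanged) "equilibrated (connectivity frozen)"
            else if (x$hit_sweep_cap) "stopped at sweep cap (non-equilibrated)"
            else if (x$hit_pattern_cap) "stopped at pattern cap"
            else "stopped"
  cat(sprintf("<online_trajectory> %d sweeps, p = %d, p_eff = %d, c_est = %.1f; %s\n",
              x$sweeps, x$p, x$p_eff, x$c_est, status))
  invisible(x)
}
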