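# Structural and signal-to-noise analyses of optimized networks, and sweep
# summaries comparing optimized against random connectivity.

#' Maximum absolute off-diagonal Hebbian weight
#'
#' `W^M = max_{i != j} |W[i, j]|`, the normalizer used when histogramming
#' connection probabilities against `W / W^M`. `W^M <= p` always, but it
#' rarely equals `p` for large `p` (that would require two neurons to agree
#' on every stored pattern).
#'
#' @param W integer Hebbian weight matrix (`N >= 2`).
#' @return Non-negative integer.
#' @export
w_max <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) < 2) stop("need at least two neurons")
  diag(W) <- 0L
  max(abs(W))
}

#' Conditional connection probability given the Hebbian weight
#'
#' Estimates `P(C_ij = 1 | W_ij)` by binning all ordered off-diagonal pairs
#' by `W_ij / W^M` over `[-1, 1]` and taking the per-bin frequency of
#' existing connections. For a random connectivity the histogram is flat at
#' `c / (N - 1)`; optimized networks deviate systematically (noise reduction
#' avoids extreme weights, signal reinforcement favors them). The counting
#' identity `sum_bins P(C=1 | bin) P(bin) = mean in-degree / (N - 1)` holds
#' exactly on every network.
#'
#' @param C a [connectivity()] object or binary matrix.
#' @param W Hebbian weight matrix of the same network.
#' @param n_bins number of uniform bins over `[-1, 1]` (default 21; results
#'   should be robust for 11-41 bins).
#' @return Object of class `cond_conn_histogram`: data frame with
#'   `bin_center`, `p_connected` (`NA` for empty bins, never interpolated),
#'   `n_pairs`, `n_connected`; plus attributes `w_max` and `mean_in_degree`.
#' @export
conditional_connection_probability <- function(C, W, n_bins = 21L) {
  C <- as_connectivity(C)
  W <- as.matrix(W)
  if (C$N != nrow(W)) stop("dimension mismatch")
  wm <- w_max(W)
  off <- !diag(TRUE, C$N)
  wr <- if (wm > 0) W[off] / wm else W[off] * 0
  conn <- C$C[off]
  breaks <- seq(-1, 1, length.out = n_bins + 1L)
  bin <- findInterval(wr, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  n_pairs <- tabulate(bin, nbins = n_bins)
  n_conn <- vapply(seq_len(n_bins), function(b) sum(conn[bin == b]), numeric(1))
  out <- data.frame(bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
                    p_connected = ifelse(n_pairs > 0, n_conn / n_pairs, NA_real_),
                    n_pairs = n_pairs,
                    n_connected = as.integer(n_conn))
  structure(out, class = c("cond_conn_histogram", "data.frame"),
            w_max = wm, mean_in_degree = mean(C$in_degree))
}

#' Optimized-versus-random capacity sweep
#'
#' For each `(N, c)` pair and each seed, measures the storage capacity of a
#' random network and of the same network after per-row annealing, and
#' reports the improvement ratio `p_c_opt / p_c_rand`.
#'
#' @param N_values integer vector of network sizes.
#' @param c_values integer vector of in-degrees.
#' @param config an [anneal_config()]; its `epsilon` may be a number or the
#'   `"p"` policy.
#' @param seeds integer vector of seeds (five replicates by convention).
#' @param step,max_p,resolution forwarded to [storage_capacity()].
#' @return Object of class `sweep_summary`: data frame with one row per
#'   `(N, c, seed)` holding `p_c_rand`, `p_c_opt`, `alpha_c_rand`,
#'   `alpha_c_opt` and `ratio`.
#' @export
improvement_sweep <- function(N_values, c_values,
                              config = anneal_config(epsilon = 0),
                              seeds = 1:5,
                              step = NULL, max_p = NULL, resolution = 1L) {
  rows <- list()
  for (N in N_values) {
    for (cc in c_values) {
      if (cc >= N) next
      stp <- if (is.null(step)) max(1L, cc %/% 10L) else step
      mp <- if (is.null(max_p)) 8L * cc else max_p
      for (sd in seeds) {
        rand <- storage_capacity(random_network_builder(N, cc), c = cc,
                                 step = stp, seeds = sd, max_p = mp,
                                 resolution = resolution)
        opt <- storage_capacity(annealed_network_builder(N, cc, config),
                                c = cc, step = stp, seeds = sd, max_p = mp,
                                resolution = resolution)
        rows[[length(rows) + 1L]] <- data.frame(
          N = N, c = cc, seed = sd,
          p_c_rand = rand$p_c, p_c_opt = opt$p_c,
          alpha_c_rand = rand$alpha_c, alpha_c_opt = opt$alpha_c,
          ratio = if (rand$p_c > 0) opt$p_c / rand$p_c else NA_real_)
      }
    }
  }
  structure(do.call(rbind, rows), class = c("sweep_summary", "data.frame"))
}

#' Aligned-field statistics across memory loads
#'
#' For each memory load on the grid, builds the network (random or annealed),
#' clamps it at every stored pattern and tabulates the mean and standard
#' deviation of the aligned local field together with the fraction of
#' patterns retrieved from error-free cues.
#'
#' @param N,c network size and in-degree.
#' @param alpha_grid numeric vector of memory loads (`p = max(1, round(alpha * c))`).
#' @param config `NULL` for random networks, or an [anneal_config()] to
#'   optimize each network before measuring.
#' @param seeds integer seeds; statistics are averaged over seeds.
#' @return Data frame with `alpha`, `p`, `mean_aligned_field`,
#'   `sd_aligned_field`, `fraction_retrieved`.
#' @export
field_statistics_sweep <- function(N, c, alpha_grid, config = NULL,
                                   seeds = 1L) {
  if (any(alpha_grid <= 0)) stop("alpha grid must be positive")
  builder <- if (is.null(config)) random_network_builder(N, c)
             else annealed_network_builder(N, c, config)
  rows <- lapply(alpha_grid, function(alpha) {
    p <- max(1L, as.integer(round(alpha * c)))
    stats_by_seed <- vapply(seeds, function(sd) {
      net <- builder(p, sd)
      afs <- aligned_field_stats(net$patterns, net$W, net$C, net$norm)
      fr <- fraction_retrieved(net$patterns, net$W, net$C, error_fraction = 0,
                               seed = derive_seed(sd, 106L))
      c(afs$mean, afs$sd, fr)
    }, numeric(3))
    data.frame(alpha = alpha, p = p,
               mean_aligned_field = mean(stats_by_seed[1, ]),
               sd_aligned_field = mean(stats_by_seed[2, ]),
               fraction_retrieved = mean(stats_by_seed[3, ]))
  })
  do.call(rbind, rows)
}
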