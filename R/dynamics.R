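# Synchronous retrieval dynamics and the signal/noise decomposition of the
# aligned local field.

#' Local activity field
#'
#' Computes `h_i = (1 / norm_i) * sum_j W[i, j] * C[i, j] * s[j]`, the input
#' each neuron receives through its existing presynaptic connections. Offline
#' the divisor is the common in-degree `c`; online each neuron divides by its
#' own current in-degree.
#'
#' @param s length-`N` state vector with entries in \{-1, +1\}.
#' @param W integer Hebbian weight matrix.
#' @param C a [connectivity()] object or binary matrix.
#' @param norm per-neuron divisor: a scalar or length-`N` vector, all
#'   entries `>= 1`.
#' @return Numeric vector of local fields.
#' @export
local_field <- function(s, W, C, norm) {
  C <- as_connectivity(C)
  N <- C$N
  if (length(s) != N || nrow(W) != N) stop("dimension mismatch")
  norm <- rep_len(as.numeric(norm), N)
  if (any(norm < 1)) stop("norm entries must be >= 1")
  as.numeric((W * C$C) %*% s) / norm
}

#' Threshold update of the network state
#'
#' Applies `s_i <- sgn(h_i)` with the fixed tie-break `sgn(0) := +1`. The
#' tie-break matters because with integer weights the field numerator can be
#' exactly zero; fixing it keeps the map deterministic.
#'
#' @param s current state (only its length is used; the update is a pure
#'   function of `h`).
#' @param h numeric field vector, all entries finite.
#' @return Integer vector of +/-1 states.
#' @export
update_state <- function(s, h) {
  if (length(h) != length(s)) stop("length mismatch")
  if (any(!is.finite(h))) stop("field entries must be finite")
  ifelse(h < 0, -1L, 1L)
}

#' Overlap between a state and a pattern
#'
#' `m = (1/N) sum_j s[j] * xi_nu[j]`, in `[-1, 1]`; 1 is perfect retrieval and
#' -1 the spurious inverse state.
#'
#' @param s state vector.
#' @param xi_nu one pattern row.
#' @return Numeric scalar.
#' @export
overlap <- function(s, xi_nu) {
  if (length(s) != length(xi_nu)) stop("length mismatch")
  sum(as.numeric(s) * as.numeric(xi_nu)) / length(s)
}

#' Run the synchronous retrieval dynamics
#'
#' Iterates the parallel threshold update for up to `max_iter` steps, stopping
#' early as soon as the overlap with the target pattern `xi_nu` is unchanged
#' between consecutive iterations. Because the overlap numerator is an
#' integer, the constancy test is exact; a 2-cycle with constant overlap
#' counts as converged.
#'
#' @param s0 initial +/-1 state.
#' @param W Hebbian weight matrix.
#' @param C connectivity.
#' @param xi_nu target pattern used for the overlap stopping rule.
#' @param max_iter maximum number of synchronous updates (default 100).
#' @return An object of class `retrieval_result`: list with `final_overlap`,
#'   `iterations_used`, `converged`, `final_state` and the per-iteration
#'   `overlap_trajectory` (starting at iteration 0).
#' @export
run_dynamics <- function(s0, W, C, xi_nu, max_iter = 100L) {
  C <- as_connectivity(C)
  if (length(s0) != C$N || length(xi_nu) != C$N) stop("dimension mismatch")
  if (!all(s0 == 1L | s0 == -1L)) stop("state entries must be -1 or +1")
  res <- cpp_run_dynamics(as.integer(s0), as_int_matrix(W), C$C,
                          as.integer(xi_nu), as.integer(max_iter))
  structure(res, class = "retrieval_result")
}

#' @export
print.retrieval_result <- function(x, ...) {
  cat(sprintf("<retrieval_result> final overlap = %.4f after %d iteration(s)%s\n",
              x$final_overlap, x$iterations_used,
              if (x$converged) " (converged)" else " (max_iter reached)"))
  invisible(x)
}

#' Aligned local field statistics at the stored patterns
#'
#' With the network clamped at each stored pattern in turn (no dynamics), the
#' aligned local field `h_i * xi[nu, i]` decomposes as `1 + R * xi` where `R`
#' is the crosstalk from the other stored patterns. Its mean and standard
#' deviation across neurons and patterns diagnose retrieval stability: for a
#' random diluted network the standard deviation grows like `sqrt(p / c)`.
#'
#' @inheritParams local_field
#' @param patterns a [pattern_set()].
#' @return List with per-(neuron, pattern) matrices `aligned_field`, `signal`,
#'   `noise` (all `N x p`), and summary scalars `mean` and `sd` of the aligned
#'   field.
#' @export
aligned_field_stats <- function(patterns, W, C, norm) {
  patterns <- as_pattern_set(patterns)
  C <- as_connectivity(C)
  if (patterns$N != C$N) stop("dimension mismatch")
  norm <- rep_len(as.numeric(norm), C$N)
  if (any(norm < 1)) stop("norm entries must be >= 1")
  WC <- W * C$C
  H <- (WC %*% t(patterns$xi)) / norm      # N x p fields, one column per pattern
  signal <- t(patterns$xi)                 # N x p
  aligned <- H * signal
  list(aligned_field = aligned,
       signal = signal,
       noise = H - signal,
       mean = mean(aligned),
       sd = if (length(aligned) > 1) stats::sd(aligned) else 0)
}

as_int_matrix <- function(W) {
  W <- as.matrix(W)
  storage.mode(W) <- "integer"
  W
}
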