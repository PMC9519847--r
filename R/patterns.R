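# Pattern sets, diluted binary connectivity and integer Hebbian weights.

#' Construct a pattern set
#'
#' A pattern set holds `p` binary activity patterns of `N` neurons each, with
#' entries in \{-1, +1\}. Patterns are the memories the network stores; the
#' Hebbian weight matrix is built from them with [hebbian_weights()].
#'
#' @param xi a `p x N` matrix whose entries are all exactly -1 or +1.
#' @return An object of class `pattern_set`: a list with elements `xi`, `p`
#'   and `N`.
#' @seealso [generate_patterns()]
#' @export
pattern_set <- function(xi) {
  xi <- as.matrix(xi)
  storage.mode(xi) <- "integer"
  if (nrow(xi) > 0 && !all(xi == 1L | xi == -1L)) {
    stop("pattern entries must all be -1 or +1")
  }
  structure(list(xi = xi, p = nrow(xi), N = ncol(xi)), class = "pattern_set")
}

#' @export
print.pattern_set <- function(x, ...) {
  cat(sprintf("<pattern_set> p = %d patterns, N = %d neurons\n", x$p, x$N))
  invisible(x)
}

#' Draw random +/-1 activity patterns
#'
#' Each entry is independently +1 or -1 with probability 1/2, the classic
#' unbiased pattern distribution of the Hopfield model. Draws are consumed
#' row by row, so at a fixed seed the first rows of a larger set coincide
#' with a smaller set: pattern sets are nested in `p`, which makes capacity
#' searches over `p` well defined per seed.
#'
#' @param p number of patterns (may be 0).
#' @param N number of neurons (at least 1).
#' @param seed integer seed; the same seed reproduces the same patterns.
#' @return A [pattern_set()].
#' @export
#' @examples
#' xs <- generate_patterns(p = 3, N = 10, seed = 1)
#' xs$xi
generate_patterns <- function(p, N, seed) {
  if (p < 0 || N < 1) stop("need p >= 0 and N >= 1")
  xi <- matrix(integer(0), nrow = 0, ncol = N)
  if (p > 0) {
    xi <- with_preserved_rng(derive_seed(seed, 1L), {
      matrix(sample(c(-1L, 1L), p * N, replace = TRUE), nrow = p, ncol = N,
             byrow = TRUE)
    })
  }
  pattern_set(xi)
}

# Evaluate `expr` under a temporary RNG state so package randomness never
# disturbs the caller's stream.
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Construct a connectivity object
#'
#' Binary presynaptic connectivity: `C[i, j] = 1` means neuron `j` projects to
#' neuron `i`. Self-connections are forbidden (`C[i, i] = 0`). In `"offline"`
#' mode every neuron has the same in-degree `c`; in `"online"` mode in-degrees
#' vary per neuron (structural plasticity changes them).
#'
#' @param C binary `N x N` matrix with zero diagonal.
#' @param mode `"offline"` (fixed in-degree) or `"online"` (variable).
#' @return Object of class `connectivity`: list with `C`, `N`, `in_degree`,
#'   `mode`.
#' @export
connectivity <- function(C, mode = c("offline", "online")) {
  mode <- match.arg(mode)
  C <- as.matrix(C)
  storage.mode(C) <- "integer"
  if (nrow(C) != ncol(C)) stop("connectivity matrix must be square")
  if (!all(C == 0L | C == 1L)) stop("connectivity entries must be 0 or 1")
  if (any(diag(C) != 0L)) stop("no self-connections allowed (diagonal must be 0)")
  indeg <- as.integer(rowSums(C))
  if (mode == "offline" && length(unique(indeg)) > 1L) {
    stop("offline connectivity requires every row sum to equal the same c")
  }
  structure(list(C = C, N = nrow(C), in_degree = indeg, mode = mode),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat(sprintf("<connectivity> N = %d, mode = %s, mean in-degree = %.2f\n",
              x$N, x$mode, mean(x$in_degree)))
  invisible(x)
}

#' Draw a random diluted connectivity matrix
#'
#' For each of the `N` neurons, its `c` presynaptic partners are chosen
#' uniformly without replacement among the `N - 1` other neurons, so every row
#' of `C` sums exactly to `c` and the diagonal is zero.
#'
#' @param N number of neurons.
#' @param c in-degree, `1 <= c <= N - 1`.
#' @param seed integer seed.
#' @return A [connectivity()] object in offline mode.
#' @export
#' @examples
#' cn <- random_connectivity(N = 20, c = 5, seed = 1)
#' rowSums(cn$C)
random_connectivity <- function(N, c, seed) {
  if (c < 1 || c > N - 1) stop("need 1 <= c <= N - 1")
  C <- with_preserved_rng(derive_seed(seed, 2L), {
    M <- matrix(0L, N, N)
    for (i in seq_len(N)) {
      cand <- seq_len(N)[-i]
      M[i, cand[sample.int(N - 1L, c)]] <- 1L
    }
    M
  })
  connectivity(C, mode = "offline")
}

#' Hebbian weight matrix
#'
#' The integer weight matrix `W[i, j] = sum_mu xi[mu, i] * xi[mu, j]`, the
#' outer-product (Hebbian) rule summed over all stored patterns. `W` is
#' symmetric, every entry has the same parity as `p` and `|W[i, j]| <= p`. The
#' diagonal equals `p` but is never read through a valid connectivity (its
#' zero diagonal masks it).
#'
#' @param patterns a [pattern_set()] with at least one pattern.
#' @return An integer `N x N` matrix.
#' @export
#' @examples
#' xs <- generate_patterns(5, 12, seed = 3)
#' W <- hebbian_weights(xs)
#' all(W == t(W))
hebbian_weights <- function(patterns) {
  patterns <- as_pattern_set(patterns)
  if (patterns$p < 1) stop("need at least one pattern to build Hebbian weights")
  W <- crossprod(patterns$xi)   # integer-valued, exact in doubles below 2^53
  storage.mode(W) <- "integer"
  W
}

# coercion helpers ----------------------------------------------------------

as_pattern_set <- function(x) {
  if (inherits(x, "pattern_set")) return(x)
  pattern_set(x)
}

as_connectivity <- function(x, mode = "offline") {
  if (inherits(x, "connectivity")) return(x)
  # raw matrices with unequal row sums are accepted as online-mode objects
  C <- as.matrix(x)
  rs <- rowSums(C)
  if (length(unique(rs)) > 1L) mode <- "online"
  connectivity(C, mode = mode)
}
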