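# Brute-force reference implementations used as independent oracles.
# Deliberately written as literal nested loops over the defining sums, with
# no shared code with the package internals.

# W_ij = sum_mu xi[mu, i] xi[mu, j]
oracle_hebbian <- function(xi) {
  p <- nrow(xi); N <- ncol(xi)
  W <- matrix(0L, N, N)
  for (i in seq_len(N)) for (j in seq_len(N)) {
    acc <- 0L
    for (mu in seq_len(p)) acc <- acc + xi[mu, i] * xi[mu, j]
    W[i, j] <- acc
  }
  W
}

# h_i = (1 / norm_i) sum_j W_ij C_ij s_j
oracle_local_field <- function(s, W, C, norm) {
  N <- length(s)
  norm <- rep_len(norm, N)
  h <- numeric(N)
  for (i in seq_len(N)) {
    acc <- 0
    for (j in seq_len(N)) acc <- acc + W[i, j] * C[i, j] * s[j]
    h[i] <- acc / norm[i]
  }
  h
}

# E_i = sum_nu (sum_j sum_{mu != nu} xi[mu,i] xi[mu,j] xi[nu,i] xi[nu,j] C_ij - eps)^2
oracle_row_cost <- function(i, C_row, xi, eps) {
  p <- nrow(xi); N <- ncol(xi)
  E <- 0
  for (nu in seq_len(p)) {
    A <- 0
    for (j in seq_len(N)) {
      if (C_row[j] == 1) {
        for (mu in seq_len(p)) {
          if (mu != nu) A <- A + xi[mu, i] * xi[mu, j] * xi[nu, i] * xi[nu, j]
        }
      }
    }
    E <- E + (A - eps)^2
  }
  E
}

# random tiny row instance: patterns, a valid row for neuron i, and i itself
random_row_instance <- function(seed, N_max = 10L, p_max = 5L) {
  set.seed(seed)
  N <- sample(4:N_max, 1)
  p <- sample(1:p_max, 1)
  c <- sample(seq_len(N - 2L), 1)
  xi <- matrix(sample(c(-1L, 1L), p * N, replace = TRUE), p, N)
  i <- sample(seq_len(N), 1)
  row <- integer(N)
  row[sample(setdiff(seq_len(N), i), c)] <- 1L
  list(xi = xi, i = i, row = row, N = N, p = p, c = c)
}
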