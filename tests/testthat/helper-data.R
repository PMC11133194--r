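# small builders shared across test files

rand_array <- function(I, J, K) array(rnorm(I * J * K), c(I, J, K))

# a tiny preprocessed coupled dataset for identity checks
tiny_fit <- function(seed = 42, ranks = c(2, 2, 2), alpha = 0.5,
                     preproc = TRUE, ...) {
  sim <- simulate_t3pcovr(I = 10, J = 4, K = 3, L = 5, ranks = ranks,
                          snr_x = 5, snr_y = 5, seed = seed)
  cd <- if (preproc) preprocess(sim$data) else sim$data
  t3pcovr(cd, ranks = ranks, alpha = alpha, n_starts = 2, seed = seed, ...)
}

# brute-force mode-A unfolding by index arithmetic, used as the oracle
# for the matricization convention
unfold_oracle <- function(Y, mode) {
  d <- dim(Y)
  I <- d[1]; J <- d[2]; K <- d[3]
  switch(mode,
    A = { M <- matrix(0, I, J * K)
          for (i in 1:I) for (j in 1:J) for (k in 1:K)
            M[i, (k - 1) * J + j] <- Y[i, j, k]
          M },
    B = { M <- matrix(0, J, I * K)
          for (i in 1:I) for (j in 1:J) for (k in 1:K)
            M[j, (k - 1) * I + i] <- Y[i, j, k]
          M },
    C = { M <- matrix(0, K, I * J)
          for (i in 1:I) for (j in 1:J) for (k in 1:K)
            M[k, (j - 1) * I + i] <- Y[i, j, k]
          M })
}

# brute-force trilinear prediction: y_ijk = sum_r c_kr sum_p sum_q
# a_ip b_jq g_pqr
predict_oracle <- function(A, G, B, C) {
  I <- nrow(A); J <- nrow(B); K <- nrow(C)
  R <- dim(G)
  out <- matrix(0, I, J * K)
  for (i in 1:I) for (j in 1:J) for (k in 1:K) {
    v <- 0
    for (r in seq_len(R[3])) for (p in seq_len(R[1])) for (q in seq_len(R[2]))
      v <- v + C[k, r] * A[i, p] * B[j, q] * G[p, q, r]
    out[i, (k - 1) * J + j] <- v
  }
  out
}
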