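# Independent oracles used across the suite.

# dense matrix exponential (Matrix::expm) -- brute-force reference for the
# uniformization-based action; only ever used on small state spaces
dense_expm <- function(Q, t) {
  as.matrix(Matrix::expm(Matrix::Matrix(as.matrix(Q) * t)))
}

# classical birth-death closed form for the Moran long-run fixation
# probability (detailed-balance ratio f per copy)
closed_form_pfix <- function(N, f, x0 = 1) {
  if (f == 1) return(x0 / N)
  (1 - f^(-x0)) / (1 - f^(-N))
}

# dense-oracle version of the fixed-times pair quantities at small N
oracle_pair <- function(N, f1, f2, t1, t2, tb) {
  g2a <- two_allele_generator(N, f1)
  a <- dense_expm(g2a$rates, t2 - t1)[2, ]          # from 1 copy
  g2b <- two_allele_generator(N, f2)
  pI <- a[N + 1] * dense_expm(g2b$rates, tb - t2)[2, N + 1]
  g3 <- build_generator(enumerate_states(2L, N), haplotype_fitnesses(c(f1, f2)))
  P3 <- dense_expm(g3$rates, tb - t2)
  tgt <- state_index(g3$space, c(0L, N))
  pT <- sum(vapply(seq_len(N - 1), function(i) {
    a[i + 1] * (i / N) * P3[state_index(g3$space, c(i - 1L, 1L)), tgt]
  }, numeric(1)))
  list(p_I = unname(pI), p_T = unname(pT))
}
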