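# Shared builders for small in-memory fixtures.

# Long-format phenotype table from a J x I matrix with dimnames.
toy_phenos <- function(Y, trait = "t") {
  data.frame(line = rep(rownames(Y), ncol(Y)),
             env = rep(colnames(Y), each = nrow(Y)),
             trait = trait, value = as.vector(Y),
             stringsAsFactors = FALSE)
}

# Random phenotype matrix with standard line/env names.
rand_Y <- function(J, I, seed = 1, mu = 0, sd = 1) {
  set.seed(seed)
  matrix(stats::rnorm(J * I, mu, sd), J, I,
         dimnames = list(paste0("g", seq_len(J)), paste0("E", seq_len(I))))
}

# GRM from a quick simulated panel.
small_grm <- function(J, p = 60, seed = 1) {
  vanraden_grm(simulate_markers(J, p, seed = seed))
}

# Naive double-loop VanRaden GRM used as an independent oracle.
grm_oracle <- function(M) {
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  J <- nrow(M)
  G <- matrix(0, J, J, dimnames = list(rownames(M), rownames(M)))
  for (a in seq_len(J)) for (b in seq_len(J)) {
    s <- 0
    for (k in which(poly))
      s <- s + (M[a, k] - 2 * p[k]) * (M[b, k] - 2 * p[k])
    G[a, b] <- s / denom
  }
  G
}
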