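# shared fixtures and independent oracles

the_tf <- preset("mwc_tf")   # K_A = 140 uM, K_I = 530 nM, eps = 4.5, 2 sites

# brute-force MWC oracle: enumerate all 2^n binding configurations per
# conformation and form active / (active + inactive) term by term
pact_enumerated <- function(K_A, K_I, eps, n, c) {
  weight <- function(K) {
    total <- 0
    for (mask in 0:(2^n - 1)) {
      k <- sum(bitwAnd(mask, 2^(0:(n - 1))) > 0)
      total <- total + (c / K)^k
    }
    total
  }
  wa <- weight(K_A)
  wi <- exp(-eps) * weight(K_I)
  wa / (wa + wi)
}

# random allosteric TFs for property tests (uses current RNG state)
random_tf <- function(n_sites = 2L) {
  allosteric_tf(K_A = 10^runif(1, -7, -3), K_I = 10^runif(1, -9, -5),
                eps = runif(1, -3, 6), n_sites = n_sites)
}

# dense-grid sign-change root scan of a scalar function
grid_roots <- function(f, grid) {
  v <- vapply(grid, f, 0)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1L))
    if (v[i] == 0 || sign(v[i]) != sign(v[i + 1L]))
      roots <- c(roots, uniroot(f, grid[i + 0:1], tol = 1e-13)$root)
  roots
}
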