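# Reference ground truths used across tests: the published assay constants
# for the most-studied neuraminidase inhibitors serve as generating truth.
truth_competitive <- function() {
  assay_truth(km = 100, vmax = 200, mode = "competitive", ki = 0.17,
              ic50 = 0.38, hill = 1, k3 = 0.1410, k4 = 0.0203,
              ksv = 0.15792, ka = 0.24434, n_sites = 1.2897)
}

truth_noncompetitive <- function() {
  assay_truth(km = 100, vmax = 200, mode = "noncompetitive", ki = 4.2,
              ic50 = 3.8, hill = 1)
}

# noiseless rate grid straight from the rate law (bypasses trace simulation)
exact_grid <- function(mode, ki, km = 100, vmax = 200, alpha = 1,
                       substrates = c(50, 100, 200),
                       inhibitors = c(0, 0.19, 0.38, 0.76)) {
  g <- expand.grid(substrate = substrates, inhibitor = inhibitors)
  g$velocity <- mm_velocity(g$substrate, g$inhibitor, km, vmax, mode, ki,
                            alpha)
  rate_grid(g)
}

# independent brute-force oracle: grid search of (k4, k3) over squared error
grid_search_rate_constants <- function(inhibitor, kobs,
                                       k3_range, k4_range, n = 201) {
  k3s <- seq(k3_range[1], k3_range[2], length.out = n)
  k4s <- seq(k4_range[1], k4_range[2], length.out = n)
  best <- c(Inf, NA, NA)
  for (a in k4s) {
    sse <- colSums((outer(inhibitor, k3s) + a - kobs)^2)
    j <- which.min(sse)
    if (sse[j] < best[1]) best <- c(sse[j], k3s[j], a)
  }
  list(k3 = best[2], k4 = best[3])
}

# independent brute-force oracle: 2-D grid over (log10 KA, n) on log residuals
grid_search_double_log <- function(q, f, f0, la_range, n_range, n = 201) {
  las <- seq(la_range[1], la_range[2], length.out = n)
  ns <- seq(n_range[1], n_range[2], length.out = n)
  y <- log10((f0 - f) / f)
  best <- c(Inf, NA, NA)
  for (nn in ns) {
    sse <- colSums((outer(log10(q), rep(1, n)) * nn +
                      matrix(las, length(q), n, byrow = TRUE) - y)^2)
    j <- which.min(sse)
    if (sse[j] < best[1]) best <- c(sse[j], las[j], nn)
  }
  list(ka = 10^best[2], n_sites = best[3])
}

# quench data.frame -> titration helper
titration_from_sim <- function(sp) {
  quench_titration(data.frame(quencher = sp$quencher,
                              replicate = sp$replicate,
                              wavelength = sp$wavelength,
                              intensity = sp$intensity))
}
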