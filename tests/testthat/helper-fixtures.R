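# shared generators for randomized/property tests

rand_simplex <- function(n) {
  x <- stats::runif(n)
  x / sum(x)
}

rand_acetyl <- function() {
  x <- rand_simplex(3)
  acetyl_labeling(x[1], x[2], x[3])
}

rand_mid <- function(species = lookup_species("FFA(16:0)")) {
  ffa_mid(species, rand_simplex(species$carbons + 1L))
}

# exhaustive-enumeration oracle for the de novo multinomial MID:
# every per-unit label assignment in {0,1,2}^n_units, probability-weighted
enumerate_denovo <- function(x0, x1, x2, n_units) {
  probs <- c(x0, x1, x2)
  assign <- as.matrix(expand.grid(rep(list(0:2), n_units)))
  p <- apply(assign, 1, function(a) prod(probs[a + 1L]))
  mass <- rowSums(assign)
  vapply(0:(2 * n_units), function(i) sum(p[mass == i]), numeric(1))
}

# noisy measurement of a true MID: scale to intensities, convolve with
# natural abundance, apply multiplicative log-normal noise, then correct back
measure_mid <- function(true_fractions, species, scale = 1e6, cv = 0.02,
                        p13 = 0.0107) {
  sigma <- sqrt(log(1 + cv^2))
  raw <- natural_abundance_matrix(species$carbons, p13) %*% (scale * true_fractions)
  noisy <- as.numeric(raw) *
    stats::rlnorm(species$carbons + 1L, meanlog = -sigma^2 / 2, sdlog = sigma)
  correct_natural_abundance(iso_vector(species, noisy), p13)
}

# small simulation config reused across tests: 2 tissues + serum, 2 species
tiny_config <- function(seed = 11L, noise_cv = 0.02, beta_zero = FALSE) {
  tissues <- c("liver", "lung")
  rt <- default_route_table()
  rt <- rt[rt$species %in% c("FFA(16:0)", "FFA(18:0)"), ]
  beta <- default_beta_table(tissues, rt$species)
  if (beta_zero) beta$beta <- 0
  simulation_config(
    seed = seed, tissues = tissues, route_table = rt,
    timepoints = 24, replicates = c(`24` = 4L),
    acetyl = default_acetyl_table(tissues),
    g = default_g_table(tissues, rt$species),
    beta = beta,
    intensity = default_intensity_table(tissues, rt$species),
    noise_cv = noise_cv)
}
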