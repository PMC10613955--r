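# Independent oracles and small fixture builders used across the suite.

# Closed-form simple least squares via the normal equations, written
# directly from sums so it shares no code path with fit_scaling().
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  a <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  b <- (sy - a * sx) / n
  list(a = a, b = b)
}

# Standard error of the OLS slope and intercept (known sampling
# distribution for Gaussian noise of sd `sigma` at fixed design x).
ols_se_oracle <- function(x, sigma) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  list(se_a = sigma / sqrt(sxx),
       se_b = sigma * sqrt(1 / n + mean(x)^2 / sxx))
}

# Direct evaluation of the Boltzmann population formula, independent of
# boltzmann_weights() (no minimum subtraction, naive exponentials).
boltzmann_oracle <- function(de_kJmol, T_K = 298, R = 8.3145) {
  q <- exp(-de_kJmol * 1000 / (R * T_K))
  q / sum(q)
}

# A small random but valid study bundle: n_groups singleton carbon groups,
# n_conf conformers, uniform random shieldings and energies.
random_bundle <- function(n_groups = 5, n_conf = 3) {
  asg <- tibble::tibble(
    group_id = sprintf("G%02d", seq_len(n_groups)),
    nucleus = "13C",
    atom_indices = as.list(seq_len(n_groups)),
    delta_exp_ppm = sort(runif(n_groups, 10, 170))
  )
  sh <- tidyr::expand_grid(
    conformer_id = sprintf("c%02d", seq_len(n_conf)),
    atom_index = seq_len(n_groups)
  )
  sh$element <- "C"
  sh$isotropic_shielding_ppm <- runif(nrow(sh), 0, 200)
  en <- tibble::tibble(
    conformer_id = sprintf("c%02d", seq_len(n_conf)),
    rel_energy_kJmol = c(0, if (n_conf > 1) runif(n_conf - 1, 0, 21))
  )
  nmr_study(sh, en, asg)
}

# Exact-line grid cell: per-group shieldings lying exactly on
# sigma = a * delta + b, with optional Gaussian noise.
line_cell <- function(assignments, a = -1.05, b = 186, noise_sd = 0) {
  tibble::tibble(
    group_id = assignments$group_id,
    delta_exp_ppm = assignments$delta_exp_ppm,
    isotropic_shielding_ppm =
      a * assignments$delta_exp_ppm + b +
      rnorm(nrow(assignments), 0, noise_sd)
  )
}
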