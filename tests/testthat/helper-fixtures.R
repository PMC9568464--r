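# Shared fixtures, built in code.

registry <- expert_registry()
rho_priors <- registry_subset(registry, "rho")
delta_priors <- registry_subset(registry, "delta")

# Toy correlation table for the extraction-rule filter: 10 rows of which
# 2 are perfect correlations, 1 has unequal per-variable sizes, 1 has
# n = 5 (< 10) and 1 has n = 600 (> 500); 5 survive.
toy_bosco <- function() {
  correlation_table(data.frame(
    study_id = paste0("s", 1:10),
    r  = c(0.30, 1.00, -1.00, 0.10, 0.50, -0.20, 0.15, 0.70, 0.05, 0.40),
    n1 = c(50,   40,    30,   25,   80,    5,    600,  120,  44,   33),
    n2 = c(50,   40,    30,   20,   80,    5,    600,  120,  44,   33)
  ))
}

# Numeric integral of a prior pdf over its support (quadrature oracle
# for the normalization invariant); half-line supports are mapped to
# (0, 1) by u = x / (1 + x).
prior_mass_numeric <- function(spec) {
  lo <- spec$support[1]; hi <- spec$support[2]
  if (is.finite(hi)) {
    stats::integrate(function(x) prior_pdf(spec, x), lo, hi,
                     rel.tol = 1e-10)$value
  } else {
    stats::integrate(function(u) {
      x <- u / (1 - u)
      prior_pdf(spec, x) / (1 - u)^2
    }, 1e-12, 1 - 1e-12, rel.tol = 1e-10)$value
  }
}

# Brute-force likelihood-ratio kernel maximum over a fine effect grid
# (the "oracle prior" upper bound on any BF10).
corr_kernel_max <- function(r, n, grid_n = 2001) {
  grid <- seq(0, 1 - 1e-9, length.out = grid_n)
  max(vapply(grid, function(rho)
    corr_bf10(r, n, prior_spec("point", value = rho))$log_bf10,
    numeric(1)))
}
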