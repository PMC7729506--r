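# Shared fixtures, built in code.

# Calibrated trilaurin model (beta melt 319.4 K, Delta U 86.7 kJ/mol).
trilaurin_params <- function() calibrate_trilaurin()

# Crossover configuration: T* = 400 K > Tc = 300 K.
crossover_params <- function() ge_params(J = 50, H0 = 400, ln_deg = 2, z = 6)

# Field-free-at-T configuration: ln_deg/H0 chosen so H(T0) = 0.
fieldfree_params <- function(J = 50, z = 4L, T0 = 100) {
  ge_params(J = J, H0 = T0, ln_deg = 2, z = z)
}

# Random valid parameter draws for property tests.
random_ge_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    ge_params(J = runif(1, 10, 100), H0 = runif(1, 50, 3000),
              ln_deg = runif(1, 0.5, 15), z = sample(c(4L, 6L), 1L))
  })
}

# Generating truth for synthetic crystal-memory datasets: lifetimes of
# minutes-to-days within ~2-35 K of the transition, the scale of fat
# crystal-memory experiments.
memory_truth <- function() vft_params(T_star = 317, D_star = 0.05, tau0 = 1)
memory_T_grid <- function() 317 + seq(2.5, 35, length.out = 8)

# Brute-force root oracle: sign-change scan of sigma - tanh((zJ s + H)/T)
# on a dense grid (independent of the package's bracketing/bisection path).
scan_roots <- function(p, T, n = 1e5) {
  H <- field_at(p, T)
  zJ <- p$z * p$J
  s <- seq(-1, 1, length.out = n)
  g <- s - tanh((zJ * s + H) / T)
  i <- which(g[-n] * g[-1] <= 0 & g[-n] != 0)
  vapply(i, function(k) {
    uniroot(function(x) x - tanh((zJ * x + H) / T),
            c(s[k], s[k + 1]), tol = 1e-12)$root
  }, numeric(1))
}
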