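test_that("exact enumeration is symmetric at T* on every small lattice", {
  # H(T*) = 0 makes the Hamiltonian invariant under a global spin flip:
  # an exact symmetry, so the mean order parameter is zero to rounding
  for (q in random_ge_params(6, seed = 501)) {
    lattice <- if (q$z == 4L) "square" else "triangular"
    for (side in 2:4) {
      e <- enumerate_exact(q, lattice, side, tstar(q))
      expect_lt(abs(e$mean_sigma), 1e-10)
    }
  }
})

test_that("a single free site follows the closed-form Boltzmann average", {
  p <- ge_params(J = 50, H0 = 100, ln_deg = 1, z = 4)
  for (T in c(50, 150, 400)) {
    e <- enumerate_exact(p, "square", 1, T)
    expect_equal(e$mean_sigma, tanh(field_at(p, T) / T), tolerance = 1e-12)
  }
})

test_that("enumeration matches an independently coded 16-state sum on 2x2", {
  p <- ge_params(J = 60, H0 = 900, ln_deg = 5, z = 4)
  T <- 330
  h <- p$H0 - T / 2 * p$ln_deg
  # hand-built bond list for the periodic 2x2 square lattice: each bond
  # doubled because opposite neighbours coincide at side 2
  S <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  bonds <- rbind(c(1, 2), c(1, 2), c(3, 4), c(3, 4),
                 c(1, 3), c(1, 3), c(2, 4), c(2, 4))
  E <- -p$J * rowSums(sapply(seq_len(nrow(bonds)), function(b)
         S[, bonds[b, 1]] * S[, bonds[b, 2]])) - h * rowSums(S)
  w <- exp(-(E - min(E)) / T)
  want_sigma <- sum(w * rowSums(S) / 4) / sum(w)
  want_e <- sum(w * E / 4) / sum(w)

  e <- enumerate_exact(p, "square", 2, T)
  expect_equal(e$mean_sigma, want_sigma, tolerance = 1e-12)
  expect_equal(e$mean_energy_per_site, want_e, tolerance = 1e-12)

  expect_error(enumerate_exact(p, "square", 5, T), "too many sites")
  expect_error(enumerate_exact(p, "triangular", 3, T), "does not match")
})

test_that("Metropolis sampling reproduces exact enumeration within error", {
  # one spot check here; the 2x2/3x3 five-temperature sweep runs in the
  # acceptance suite
  p <- ge_params(J = 75.7, H0 = 2105.4, ln_deg = 13.18, z = 4)
  T <- 330
  cfg <- mc_config("square", side = 3, sweeps = 20000, sweeps_per_block = 100,
                   seed = 42, T = T)
  r <- metropolis(p, cfg, init = "random")
  m <- r$blocks$m[-(1:20)]
  e <- enumerate_exact(p, "square", 3, T)
  se <- sd(m) / sqrt(length(m))
  expect_lt(abs(mean(m) - e$mean_sigma), 3 * se + 1e-4)
})

test_that("deep ordered phase and determinism contracts hold", {
  p <- ge_params(J = 75.7, H0 = 2105.4, ln_deg = 13.18, z = 4)
  # T << Tc with positive field: ordered start stays ordered
  cfg <- mc_config("square", side = 8, sweeps = 500, sweeps_per_block = 50,
                   seed = 7, T = 100)
  r <- metropolis(p, cfg, init = "up")
  expect_gt(min(r$blocks$m), 0.99)

  r2 <- metropolis(p, cfg, init = "up")
  expect_identical(r$blocks, r2$blocks)
  expect_identical(r$final_spins, r2$final_spins)

  expect_error(metropolis(p, mc_config("triangular", side = 4, T = 300), "up"),
               "lattice")
})

test_that("hysteresis loop distinguishes discontinuous from crossover", {
  p <- trilaurin_params()
  ramp_area <- function(params, seed, spb, T_lo, T_hi, dT) {
    cfg <- mc_config("triangular", side = 16, seed = seed,
                     ramp = list(T_start = T_lo, T_end = T_hi,
                                 dT_per_block = dT, sweeps_per_block = spb))
    hysteresis_ramp(params, cfg)
  }
  h <- ramp_area(p, seed = 5, spb = 4, T_lo = 305, T_hi = 340, dT = 0.5)
  expect_gt(h$loop_area, 1)
  # superheating: the ordered branch survives above T* for an interval
  just_above <- h$heating$T_K > tstar(p) & h$heating$T_K <= tstar(p) + 1.5
  expect_true(all(h$heating$m[just_above] > 0))

  # slower ramps shrink the loop on average (paired seeds)
  fast <- vapply(1:4, function(s)
    ramp_area(p, s, 4, 305, 340, 0.5)$loop_area, numeric(1))
  slow <- vapply(1:4, function(s)
    ramp_area(p, s, 60, 305, 340, 0.5)$loop_area, numeric(1))
  expect_lt(mean(slow), mean(fast))

  # crossover: loop area statistically indistinguishable from zero
  pc <- crossover_params()
  ca <- vapply(1:8, function(s) {
    cfg <- mc_config("triangular", side = 16, seed = s,
                     ramp = list(T_start = 330, T_end = 470,
                                 dT_per_block = 2, sweeps_per_block = 30))
    hysteresis_ramp(pc, cfg)$loop_area
  }, numeric(1))
  expect_lt(abs(mean(ca)), 3 * sd(ca) / sqrt(length(ca)))
})

test_that("first-passage estimation validates its window and reports censoring", {
  p <- trilaurin_params()
  cfg <- mc_config("triangular", side = 8, sweeps = 4000, sweeps_per_block = 10,
                   seed = 11, T = 322)
  r <- estimate_lifetime_mc(p, 322, cfg, replicas = 4)
  expect_length(r$first_passage_sweeps, 4)
  expect_true(is.finite(r$mean))
  expect_identical(r$n_censored, sum(is.na(r$first_passage_sweeps)))

  expect_error(estimate_lifetime_mc(p, tstar(p) - 1, cfg), "superheated")
  expect_error(estimate_lifetime_mc(p, 400, cfg), "superheated")
  expect_error(estimate_lifetime_mc(p, 322, cfg, replicas = 0), "replicas")
  expect_error(estimate_lifetime_mc(crossover_params(), 401,
                                    mc_config("triangular", side = 8, T = 401)),
               "superheated")
})
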