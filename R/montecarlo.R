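#' Monte Carlo run configuration
#'
#' @param lattice `"square"` (z = 4) or `"triangular"` (z = 6; the natural
#'   choice for hexagonally packed chains).
#' @param side Lattice side, `>= 2`; periodic boundaries.
#' @param sweeps Total sweeps (one sweep = one attempted flip per site).
#' @param sweeps_per_block Sweeps per recorded block.
#' @param seed Master seed; the whole trajectory is reproducible from it.
#' @param T Temperature, Kelvin (fixed-temperature runs), or `NULL` when a
#'   ramp is given.
#' @param ramp Optional list `list(T_start=, T_end=, dT_per_block=,
#'   sweeps_per_block=)` describing a temperature ramp.
#' @return An object of class `"mc_config"`.
#' @export
mc_config <- function(lattice = c("triangular", "square"), side, sweeps = 1000L,
                      sweeps_per_block = 50L, seed = 1L, T = NULL, ramp = NULL) {
  lattice <- match.arg(lattice)
  stopifnot(side >= 2, side == round(side))
  if (is.null(T) && is.null(ramp)) stop_domain("either 'T' or 'ramp' must be given")
  if (!is.null(ramp)) {
    stopifnot(all(c("T_start", "T_end", "dT_per_block") %in% names(ramp)))
    if (ramp$dT_per_block <= 0) stop_domain("'dT_per_block' must be > 0")
    if (is.null(ramp$sweeps_per_block)) ramp$sweeps_per_block <- sweeps_per_block
  } else {
    if (T <= 0) stop_domain("'T' must be > 0 Kelvin")
  }
  structure(list(lattice = lattice, side = as.integer(side),
                 sweeps = as.integer(sweeps),
                 sweeps_per_block = as.integer(sweeps_per_block),
                 seed = as.integer(seed), T = T, ramp = ramp),
            class = "mc_config")
}

.check_lattice_z <- function(p, lattice) {
  z_lat <- if (lattice == "square") 4L else 6L
  if (p$z != z_lat) {
    stop_domain(sprintf("lattice '%s' has z = %d but parameters have z = %d",
                        lattice, z_lat, p$z))
  }
  z_lat
}

#' Metropolis simulation of the pseudo-spin Hamiltonian
#'
#' Single-site Metropolis dynamics at fixed temperature: uniformly random
#' site selection, acceptance `min(1, exp(-dE/T))` with
#' `dE = 2 s_i (J * sum of neighbour spins + H(T))`, all energies in
#' Kelvin.  Identical seed and configuration give bit-identical
#' trajectories.
#'
#' @param p A [ge_params()] object (its `z` must match the lattice).
#' @param cfg An [mc_config()] with a fixed temperature `T`.
#' @param init Initial state: `"up"` (all ordered, sigma = +1), `"down"`,
#'   or `"random"`.
#' @return An object of class `"mc_result"`: list with `blocks` (data.frame
#'   `block`, `T_K`, `m`, `E_per_site_K`, `acc_rate`), `final_spins`,
#'   `config`, and `seed`.
#' @export
metropolis <- function(p, cfg, init = c("up", "down", "random")) {
  stopifnot(inherits(p, "ge_params"), inherits(cfg, "mc_config"))
  init <- match.arg(init)
  if (is.null(cfg$T)) stop_domain("metropolis() needs a fixed-temperature config; use hysteresis_ramp() for ramps")
  .check_lattice_z(p, cfg$lattice)
  lat <- ge_lattice(cfg$lattice, cfg$side)
  set.seed(cfg$seed)
  s <- switch(init,
              up = rep(1L, lat$n_sites),
              down = rep(-1L, lat$n_sites),
              random = sample(c(-1L, 1L), lat$n_sites, replace = TRUE))
  h <- field_at(p, cfg$T)
  nbr0 <- lat$nbr - 1L
  n_blocks <- max(1L, cfg$sweeps %/% cfg$sweeps_per_block)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    res <- mc_block(s, nbr0, p$J, h, cfg$T, cfg$sweeps_per_block)
    s <- res$spins
    rows[[b]] <- data.frame(block = b, T_K = cfg$T, m = res$m_mean,
                            E_per_site_K = res$e_mean, acc_rate = res$acc_rate)
  }
  structure(list(blocks = do.call(rbind, rows), final_spins = s,
                 config = cfg, seed = cfg$seed),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  nb <- nrow(x$blocks)
  cat(sprintf("Metropolis run: %s %dx%d, %d block(s), seed %d\n",
              x$config$lattice, x$config$side, x$config$side, nb, x$seed))
  cat(sprintf("  final block: m = %.4f, E/site = %.4f K, acc = %.3f\n",
              x$blocks$m[nb], x$blocks$E_per_site_K[nb], x$blocks$acc_rate[nb]))
  invisible(x)
}

#' Heating/cooling ramp with hysteresis
#'
#' Ramps the temperature in steps of `dT_per_block`, one Metropolis block
#' per step.  The heating branch starts fully ordered (all sigma = +1) at
#' `T_start`; the cooling branch starts fully melted (all sigma = -1) at
#' `T_end` and descends.  Around a discontinuous transition the branches
#' separate (superheating/supercooling) and enclose a hysteresis loop of
#' area `integral (m_heat - m_cool) dT >= 0`; in the crossover regime the
#' loop area is statistically indistinguishable from zero.
#'
#' @param p A [ge_params()] object.
#' @param cfg An [mc_config()] with a `ramp`.
#' @return List with `heating` and `cooling` block data.frames and
#'   `loop_area` (Kelvin).
#' @export
hysteresis_ramp <- function(p, cfg) {
  stopifnot(inherits(p, "ge_params"), inherits(cfg, "mc_config"))
  if (is.null(cfg$ramp)) stop_domain("config has no ramp schedule")
  .check_lattice_z(p, cfg$lattice)
  lat <- ge_lattice(cfg$lattice, cfg$side)
  nbr0 <- lat$nbr - 1L
  r <- cfg$ramp
  Ts <- seq(r$T_start, r$T_end, by = r$dT_per_block)
  run_branch <- function(temps, s, seed) {
    set.seed(seed)
    rows <- vector("list", length(temps))
    for (i in seq_along(temps)) {
      h <- field_at(p, temps[i])
      res <- mc_block(s, nbr0, p$J, h, temps[i], r$sweeps_per_block)
      s <- res$spins
      rows[[i]] <- data.frame(block = i, T_K = temps[i], m = res$m_mean,
                              E_per_site_K = res$e_mean, acc_rate = res$acc_rate)
    }
    do.call(rbind, rows)
  }
  heat <- run_branch(Ts, rep(1L, lat$n_sites), cfg$seed)
  cool <- run_branch(rev(Ts), rep(-1L, lat$n_sites), cfg$seed + 1L)
  cool_m <- cool$m[match(Ts, cool$T_K)]
  dm <- heat$m - cool_m
  # trapezoid rule on the common grid
  area <- sum((dm[-1L] + dm[-length(dm)]) / 2 * diff(Ts))
  list(heating = heat, cooling = cool, loop_area = area)
}

#' First-passage lifetime of the superheated state by Monte Carlo
#'
#' Starts each replica fully ordered (all sigma = +1) at a temperature in
#' the superheated window `(T*, spinodal_high)` and counts sweeps until the
#' block-mean order parameter first drops to `m <= 0` — a parameter-free
#' proxy for decay of the metastable solid.  Replicas exceeding
#' `max_sweeps` are censored.  Per-replica seeds derive from the master
#' seed by a fixed splitting rule, so replica sets are reproducible.
#'
#' @param p A [ge_params()] object in the discontinuous regime.
#' @param T Temperature, Kelvin, with `T* < T < spinodal_high`.
#' @param cfg An [mc_config()]; its `sweeps` field is the per-replica
#'   `max_sweeps` budget and `sweeps_per_block` the decay-check resolution.
#' @param replicas Number of independent replicas, `>= 1`.
#' @return List with `first_passage_sweeps` (NA when censored),
#'   `n_censored`, `mean`, `sd`, `se` (over uncensored replicas), `T`, and
#'   `seed`.
#' @export
estimate_lifetime_mc <- function(p, T, cfg, replicas = 8L) {
  stopifnot(inherits(p, "ge_params"), inherits(cfg, "mc_config"))
  if (replicas < 1) stop_domain("'replicas' must be >= 1")
  sp <- spinodals(p)
  Ts <- tstar(p)
  if (is.na(sp["spinodal_high"]) || T <= Ts || T >= sp["spinodal_high"]) {
    stop_domain("T outside the superheated window (T*, spinodal_high)")
  }
  .check_lattice_z(p, cfg$lattice)
  lat <- ge_lattice(cfg$lattice, cfg$side)
  nbr0 <- lat$nbr - 1L
  h <- field_at(p, T)
  fp <- rep(NA_real_, replicas)
  for (rrep in seq_len(replicas)) {
    set.seed((cfg$seed + 7919L * rrep) %% 2147483647L)
    s <- rep(1L, lat$n_sites)
    swept <- 0L
    while (swept < cfg$sweeps) {
      res <- mc_block(s, nbr0, p$J, h, T, cfg$sweeps_per_block)
      s <- res$spins
      swept <- swept + cfg$sweeps_per_block
      if (res$m_mean <= 0) { fp[rrep] <- swept; break }
    }
  }
  ok <- !is.na(fp)
  list(first_passage_sweeps = fp, n_censored = sum(!ok),
       mean = if (any(ok)) mean(fp[ok]) else NA_real_,
       sd = if (sum(ok) > 1L) sd(fp[ok]) else NA_real_,
       se = if (sum(ok) > 1L) sd(fp[ok]) / sqrt(sum(ok)) else NA_real_,
       T = T, seed = cfg$seed)
}
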