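#' Mean-field self-consistency solver
#'
#' Finds every fixed point of the mean-field map
#' `sigma = tanh((z J sigma + H(T)) / T)` on `[-1, 1]` at temperature `T`,
#' and labels each root stable, metastable, or unstable.  The map has one or
#' three fixed points; with three, the middle one (map slope > 1) is the
#' unstable hilltop and the two extremal roots are ranked by the variational
#' free energy: lower free energy is the equilibrium (stable) branch, the
#' other is metastable (a supercooled liquid or superheated solid).
#'
#' Roots are bracketed by scanning sigma on 2001 uniform points and refined
#' by bisection to an interval of 1e-12, which leaves the fixed-point
#' residual well below 1e-10.
#'
#' @param p A [ge_params()] object.
#' @param T Temperature, Kelvin, `> 0`.
#' @return An object of class `"ge_meanfield"`: list with `T`, `roots`
#'   (data.frame with columns `sigma`, `stability`, `free_energy`),
#'   and `coexistence` (TRUE when the two extremal roots tie in free
#'   energy, i.e. at `T*`; the positive root is then reported stable by
#'   convention).
#' @seealso [free_energy_per_chain()], [spinodals()], [phase_summary()]
#' @export
solve_sigma <- function(p, T) {
  stopifnot(inherits(p, "ge_params"), is.numeric(T), length(T) == 1L)
  if (!is.finite(T) || T <= 0) stop_domain("'T' must be > 0 Kelvin")
  H <- field_at(p, T)
  zJ <- p$z * p$J
  g <- function(s) s - tanh((zJ * s + H) / T)
  grid <- seq(-1, 1, length.out = 2001L)
  gv <- g(grid)
  roots <- numeric(0)
  for (i in seq_len(length(grid) - 1L)) {
    if (gv[i] == 0) roots <- c(roots, grid[i])
    else if (gv[i] * gv[i + 1L] < 0) {
      lo <- grid[i]; hi <- grid[i + 1L]
      flo <- gv[i]
      while (hi - lo > 1e-12) {
        mid <- (lo + hi) / 2
        fm <- g(mid)
        if (fm == 0) { lo <- mid; hi <- mid; break }
        if (flo * fm < 0) hi <- mid else { lo <- mid; flo <- fm }
      }
      roots <- c(roots, (lo + hi) / 2)
    }
  }
  if (gv[length(gv)] == 0) roots <- c(roots, 1)
  roots <- sort(unique(roots))
  # map slope at fixed point: (zJ/T) sech^2((zJ s + H)/T)
  slope <- (zJ / T) / cosh((zJ * roots + H) / T)^2
  fe <- free_energy_per_chain(p, T, roots)
  stability <- rep("stable", length(roots))
  coex <- FALSE
  if (length(roots) == 3L) {
    stability[2L] <- "unstable"
    f1 <- fe[1L]; f3 <- fe[3L]
    tol <- 1e-9 * max(1, abs(f1), abs(f3))
    if (abs(f1 - f3) <= tol) {
      coex <- TRUE
      stability[c(1L, 3L)] <- c("metastable", "stable")  # positive root by convention
    } else if (f1 < f3) {
      stability[c(1L, 3L)] <- c("stable", "metastable")
    } else {
      stability[c(1L, 3L)] <- c("metastable", "stable")
    }
  } else if (length(roots) != 1L) {
    # tangency: two of three roots merged; keep deterministic labels
    stability <- ifelse(slope < 1, "stable", "unstable")
  }
  structure(
    list(T = T,
         roots = data.frame(sigma = roots, stability = stability,
                            free_energy = fe, map_slope = slope),
         coexistence = coex),
    class = "ge_meanfield"
  )
}

#' @export
print.ge_meanfield <- function(x, ...) {
  cat(sprintf("mean-field solution at T = %.6g K (%d root%s%s)\n",
              x$T, nrow(x$roots), if (nrow(x$roots) > 1) "s" else "",
              if (x$coexistence) ", coexistence" else ""))
  print(x$roots, row.names = FALSE)
  invisible(x)
}

#' Variational mean-field free energy per chain
#'
#' `f(sigma) = (zJ/2) sigma^2 - T ln(2 cosh((zJ sigma + H(T))/T))` in
#' Kelvin per chain.  Its stationary points are exactly the fixed points of
#' the self-consistency map, so it ranks coexisting roots: at `T*` (where
#' `H = 0`) it is even in sigma and the two extremal roots tie.
#'
#' @inheritParams solve_sigma
#' @param sigma Order parameter value(s) in `[-1, 1]`.  Vectorized.
#' @return Free energy value(s), Kelvin per chain.
#' @export
free_energy_per_chain <- function(p, T, sigma) {
  stopifnot(inherits(p, "ge_params"), is.numeric(T), length(T) == 1L, T > 0,
            is.numeric(sigma))
  if (any(abs(sigma) > 1 + 1e-12)) stop_domain("'sigma' must lie in [-1, 1]")
  H <- field_at(p, T)
  zJ <- p$z * p$J
  x <- (zJ * sigma + H) / T
  (zJ / 2) * sigma^2 - T * (log(2) + .log2cosh(x))
}

# log(cosh(x)) = |x| - log 2 + log(1 + exp(-2|x|)), overflow-safe
.log2cosh <- function(x) abs(x) - log(2) + log1p(exp(-2 * abs(x)))

#' Enthalpy per mole of molecule
#'
#' Physical (configurational) energy of the model per mole of molecule:
#' `U = chains * R * (-(zJ/2) sigma^2 - H0 sigma) / 1000` in kJ/mol.
#' Only the energetic part of the Hamiltonian enters; the `-kB T ln D`
#' degeneracy term is entropy and is excluded, and likewise the temperature-
#' dependent part of the field (which originates from that entropy), so the
#' field term uses `H0`, not `H(T)`.
#'
#' @inheritParams free_energy_per_chain
#' @return Enthalpy value(s), kJ per mole of molecule.
#' @export
enthalpy <- function(p, T, sigma) {
  stopifnot(inherits(p, "ge_params"), is.numeric(sigma))
  if (any(abs(sigma) > 1 + 1e-12)) stop_domain("'sigma' must lie in [-1, 1]")
  zJ <- p$z * p$J
  p$chains_per_molecule * .R_GAS * (-(zJ / 2) * sigma^2 - p$H0 * sigma) / 1000
}

#' Spinodal temperatures of the metastable branches
#'
#' For a discontinuous transition (`T* < Tc`) the supercooled-liquid branch
#' persists below `T*` down to `spinodal_low` and the superheated-solid
#' branch persists above `T*` up to `spinodal_high`; at a spinodal the
#' metastable extremal root merges with the unstable root and the
#' self-consistency equation drops from three fixed points to one.  The
#' spinodals are located by bisection on that root-count change, to a
#' temperature resolution of 1e-6 K.  When `T* >= Tc` there is no
#' discontinuity and both values are `NA`.
#'
#' @inheritParams solve_sigma
#' @return Named numeric vector `c(spinodal_low =, spinodal_high =)`,
#'   Kelvin; `NA` entries when absent.
#' @export
spinodals <- function(p) {
  stopifnot(inherits(p, "ge_params"))
  Ts <- tstar(p)
  Tc <- tc_temperature(p)
  if (Ts >= Tc) return(c(spinodal_low = NA_real_, spinodal_high = NA_real_))
  nroots <- function(T) nrow(solve_sigma(p, T)$roots)
  # Three roots exist on an interval containing T* and contained in (0, Tc).
  stopifnot(nroots(Ts) == 3L)
  bisect_edge <- function(lo, hi, three_at_lo) {
    # invariant: root count differs between lo and hi
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if ((nroots(mid) == 3L) == three_at_lo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  # lower edge: scan down from T* until a single root (or T ~ 0)
  lo <- Ts
  step <- max(1, Ts / 64)
  Tlow <- NA_real_
  repeat {
    cand <- lo - step
    if (cand <= 1e-6) { Tlow <- NA_real_; break }  # branch survives to T -> 0
    if (nroots(cand) < 3L) { Tlow <- bisect_edge(cand, lo, FALSE); break }
    lo <- cand
  }
  if (is.na(Tlow)) {
    # check very low T directly: if still 3 roots near zero, no spinodal above 0
    Tlow <- if (nroots(1e-6) == 3L) 0 else bisect_edge(1e-6, Ts, FALSE)
    if (identical(Tlow, 0)) Tlow <- 0
  }
  # upper edge: between T* and Tc the count drops to 1 (slope < 1 above Tc)
  hi <- Ts
  step <- max(1, (Tc - Ts) / 64)
  Thigh <- Tc
  repeat {
    cand <- hi + step
    if (cand >= Tc) { Thigh <- bisect_edge(hi, Tc, TRUE); break }
    if (nroots(cand) < 3L) { Thigh <- bisect_edge(hi, cand, TRUE); break }
    hi <- cand
  }
  c(spinodal_low = Tlow, spinodal_high = Thigh)
}

#' Positive coexistence root magnitude at T*
#'
#' At `T*` the field vanishes and the two extremal roots are `+/- sigma0`
#' with `sigma0 = tanh(zJ sigma0 / T*)`; `sigma0 > 0` requires `T* < Tc`.
#' @inheritParams solve_sigma
#' @return `sigma0` in (0, 1), or 0 when `T* >= Tc`.
#' @export
sigma0_at_tstar <- function(p) {
  Ts <- tstar(p)
  if (Ts >= tc_temperature(p)) return(0)
  sol <- solve_sigma(p, Ts)
  max(sol$roots$sigma)
}

#' Transition enthalpy
#'
#' The jump of the equilibrium enthalpy branch at `T*`:
#' `Delta U = chains * R * 2 H0 sigma0 / 1000` kJ per mole of molecule
#' (the `sigma^2` coupling terms cancel because the coexisting roots are
#' `+/- sigma0`).  Zero when the transition is critical or a crossover.
#'
#' @inheritParams solve_sigma
#' @return Transition enthalpy, kJ/mol.
#' @export
transition_enthalpy <- function(p) {
  stopifnot(inherits(p, "ge_params"))
  s0 <- sigma0_at_tstar(p)
  if (s0 <= 0) return(0)
  p$chains_per_molecule * .R_GAS * 2 * p$H0 * s0 / 1000
}

#' Phase summary: characteristic temperatures, class, spinodals, enthalpy
#'
#' Classifies the transition by the order of `T*` and `Tc`
#' (discontinuous when `T* < Tc`, critical when `T* = Tc` within a
#' relative tolerance of 1e-6, crossover when `T* > Tc`), and collects the
#' spinodal temperatures and the transition enthalpy.
#'
#' @inheritParams solve_sigma
#' @return An object of class `"ge_phase_summary"`: list with `T_star`,
#'   `T_c`, `transition_class`, `spinodal_low`, `spinodal_high` (NA when
#'   absent), and `delta_U` (kJ/mol).
#' @export
phase_summary <- function(p) {
  stopifnot(inherits(p, "ge_params"))
  Ts <- tstar(p)
  Tc <- tc_temperature(p)
  cls <- if (abs(Ts - Tc) / Tc <= 1e-6) "critical"
         else if (Ts < Tc) "discontinuous" else "crossover"
  if (cls == "discontinuous") {
    sp <- spinodals(p)
    dU <- transition_enthalpy(p)
  } else {
    sp <- c(spinodal_low = NA_real_, spinodal_high = NA_real_)
    dU <- 0
  }
  structure(
    list(T_star = Ts, T_c = Tc, transition_class = cls,
         spinodal_low = unname(sp["spinodal_low"]),
         spinodal_high = unname(sp["spinodal_high"]),
         delta_U = dU),
    class = "ge_phase_summary"
  )
}

#' @export
print.ge_phase_summary <- function(x, ...) {
  cat(sprintf("g-e phase summary: %s transition\n", x$transition_class))
  cat(sprintf("  T*  = %.4f K,  Tc = %.4f K\n", x$T_star, x$T_c))
  if (x$transition_class == "discontinuous") {
    cat(sprintf("  spinodals: low = %.4f K, high = %.4f K\n",
                x$spinodal_low, x$spinodal_high))
    cat(sprintf("  Delta U = %.4f kJ/mol\n", x$delta_U))
  }
  invisible(x)
}

#' Branchwise mean-field curve over a temperature grid
#'
#' Tabulates every root of the self-consistency equation over `T_grid`,
#' with its stability label and molar enthalpy — the raw material of an
#' order-parameter or enthalpy-vs-temperature plot with metastable
#' branches.
#'
#' @inheritParams solve_sigma
#' @param T_grid Numeric vector of temperatures, Kelvin, all `> 0`.
#' @return A data.frame with columns `T_K`, `sigma`, `stability`,
#'   `U_kJ_mol`.
#' @export
meanfield_curve <- function(p, T_grid) {
  stopifnot(inherits(p, "ge_params"), is.numeric(T_grid), length(T_grid) > 0)
  rows <- lapply(T_grid, function(T) {
    sol <- solve_sigma(p, T)
    data.frame(T_K = T, sigma = sol$roots$sigma,
               stability = sol$roots$stability,
               U_kJ_mol = enthalpy(p, T, sol$roots$sigma))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
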