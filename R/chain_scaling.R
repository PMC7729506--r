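#' Chain-length parameterization of the g-e model
#'
#' Maps hydrocarbon chain length `L` (number of carbons; real-valued so the
#' short- and long-chain limits can be probed) to model parameters:
#' coupling `J = JC + J0 L` (glycerol-core electrostatics plus dispersion
#' proportional to chain length), excited-chain energy `Ee = E0 L`, and
#' excited-state degeneracy `De = DC * De0(L) * 3^L` where `De0(L)` steps
#' from 1 at `L = 0` to `D0` for any `L > 0` (a zero-length chain has a
#' single state).
#'
#' @param L Chain length in carbons, real, `>= 0`.
#' @param JC Glycerol-core (Keesom/Debye electrostatic) coupling, Kelvin, `>= 0`.
#' @param J0 Dispersion coupling per unit chain length, Kelvin, `>= 0`.
#' @param E0 Excited-chain energy per unit length, Kelvin, `>= 0`.
#' @param D0 Per-chain degeneracy prefactor applying for `L > 0`, `>= 1`.
#' @param DC Glycerol-core degeneracy, `>= 1`.
#' @param z Coordination number.
#' @param chains_per_molecule Chains per molecule (3 for a TAG).
#' @return An object of class `"ge_chain_params"`.
#' @export
chain_params <- function(L, JC, J0, E0, D0 = 1, DC = 1, z = 6L,
                         chains_per_molecule = 3L) {
  stopifnot(is.numeric(L), length(L) == 1L, is.finite(L))
  if (L < 0) stop_domain("'L' must be >= 0")
  if (JC < 0 || J0 < 0 || E0 < 0) stop_domain("'JC', 'J0', 'E0' must be >= 0")
  if (D0 < 1 || DC < 1) stop_domain("'D0' and 'DC' must be >= 1")
  structure(
    list(L = as.numeric(L), JC = as.numeric(JC), J0 = as.numeric(J0),
         E0 = as.numeric(E0), D0 = as.numeric(D0), DC = as.numeric(DC),
         z = as.integer(z), chains_per_molecule = as.integer(chains_per_molecule)),
    class = "ge_chain_params"
  )
}

# step convention: De0 = 1 at L = 0, D0 for any L > 0 (no smoothing)
.de0 <- function(L, D0) if (L > 0) D0 else 1

#' Reduced model parameters at a given chain length
#'
#' Builds the [ge_params()] set implied by the chain-length map:
#' `J = JC + J0 L`, `ln_deg = L ln 3 + ln(DC De0(L))`, and
#' `H0 = (z/4) J + E0 L / 2`, chosen so that `T* = 2 H0 / ln_deg`
#' reproduces `T* = ((z/2)(JC + J0 L) + E0 L) / (L ln 3 + ln(DC De0))`
#' exactly.
#'
#' @param cp A [chain_params()] object.
#' @return A [ge_params()] object.
#' @export
params_of_length <- function(cp) {
  stopifnot(inherits(cp, "ge_chain_params"))
  J <- cp$JC + cp$J0 * cp$L
  ln_deg <- cp$L * log(3) + log(cp$DC * .de0(cp$L, cp$D0))
  if (ln_deg <= 0) {
    stop_domain("no spin-reorientation temperature: ln(De/Dg) = 0 (L = 0 with DC = 1)")
  }
  H0 <- (cp$z / 4) * J + cp$E0 * cp$L / 2
  ge_params(J = J, H0 = H0, ln_deg = ln_deg, z = cp$z,
            chains_per_molecule = cp$chains_per_molecule)
}

#' Ratio Tc / T* as a function of chain length
#'
#' `Tc/T* = z (JC + J0 L) [L ln 3 + ln(DC De0(L))] / [(z/2)(JC + J0 L) + E0 L]`.
#' The ratio tends to 0 as `L -> 0` (with `DC = 1`) and grows linearly and
#' without bound as `L -> Inf` with slope `2 z J0 ln 3 / (z J0 + 2 E0)`:
#' short chains put the system in the crossover regime, long chains deepen
#' the discontinuous transition.
#'
#' @inheritParams params_of_length
#' @return Dimensionless ratio `Tc / T*`.
#' @export
ratio_tc_tstar <- function(cp) {
  stopifnot(inherits(cp, "ge_chain_params"))
  if (cp$L <= 0 && cp$DC <= 1) {
    stop_domain("ratio undefined at L = 0 with DC = 1 (no T*)")
  }
  J <- cp$JC + cp$J0 * cp$L
  num <- cp$z * J * (cp$L * log(3) + log(cp$DC * .de0(cp$L, cp$D0)))
  den <- (cp$z / 2) * J + cp$E0 * cp$L
  num / den
}

#' Critical chain length where T* = Tc
#'
#' Finds, by bisection, the chain length at which `Tc/T*` crosses 1 — the
#' point where the melting transition changes character between
#' discontinuous and crossover, passing through a genuine critical point.
#'
#' @inheritParams params_of_length
#' @param L_lo,L_hi Bracket for the search; `ratio_tc_tstar - 1` must change
#'   sign on it.
#' @return The critical chain length, with `|ratio - 1| <= 1e-9`.
#' @export
critical_length <- function(cp, L_lo, L_hi) {
  stopifnot(inherits(cp, "ge_chain_params"), L_lo >= 0, L_hi > L_lo)
  at <- function(L) {
    cp2 <- cp; cp2$L <- L
    ratio_tc_tstar(cp2) - 1
  }
  f_lo <- at(L_lo); f_hi <- at(L_hi)
  if (f_lo * f_hi > 0) stop_domain("no critical length in range: ratio - 1 does not change sign on the bracket")
  r <- uniroot(at, c(L_lo, L_hi), tol = 1e-13)
  # polish until the ratio itself is within 1e-9 of 1
  L <- r$root
  if (abs(at(L)) > 1e-9) {
    lo <- L_lo; hi <- L_hi; flo <- f_lo
    while (abs(at((lo + hi) / 2)) > 1e-10 && hi - lo > .Machine$double.eps * max(1, hi)) {
      mid <- (lo + hi) / 2
      fm <- at(mid)
      if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
    }
    L <- (lo + hi) / 2
  }
  L
}

#' Scan model character along chain length
#'
#' @inheritParams params_of_length
#' @param L_grid Numeric vector of chain lengths, all `> 0` (or `DC > 1`).
#' @return data.frame with columns `L`, `T_star_K`, `T_c_K`, `ratio`,
#'   `class`.
#' @export
length_scan <- function(cp, L_grid) {
  stopifnot(inherits(cp, "ge_chain_params"), is.numeric(L_grid))
  rows <- lapply(L_grid, function(L) {
    cp2 <- cp; cp2$L <- L
    p <- params_of_length(cp2)
    Ts <- tstar(p); Tc <- tc_temperature(p)
    cls <- if (abs(Ts - Tc) / Tc <= 1e-6) "critical"
           else if (Ts < Tc) "discontinuous" else "crossover"
    data.frame(L = L, T_star_K = Ts, T_c_K = Tc, ratio = Tc / Ts, class = cls)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
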