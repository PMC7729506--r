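#' Reduced g-e model parameters
#'
#' Constructs the parameter set of the reduced two-state (g-e) pseudo-spin
#' model.  Energies are stored divided by the Boltzmann constant, i.e. in
#' Kelvin, so every formula in the package is free of unit constants; the
#' ground-state conventions `Eg = 0`, `Dg = 1` are baked in and only the
#' log degeneracy ratio `ln(De/Dg)` is kept.
#'
#' @param J Nearest-neighbour coupling energy, Kelvin.  Must be positive
#'   (attractive short-range dispersion interaction between chains).
#' @param H0 Zero-temperature field energy scale, Kelvin.
#' @param ln_deg Dimensionless `ln(De/Dg) > 0`: the melted state is more
#'   degenerate than the ordered state.
#' @param z Coordination number: average number of nearest-neighbour chains
#'   (positive integer).
#' @param chains_per_molecule Chains per molecule; 3 for a TAG.
#' @return An object of class `"ge_params"`: a list with the five fields.
#' @examples
#' p <- ge_params(J = 75, H0 = 2100, ln_deg = 12 * log(3), z = 6)
#' tstar(p)
#' tc_temperature(p)
#' @export
ge_params <- function(J, H0, ln_deg, z, chains_per_molecule = 3L) {
  stopifnot(is.numeric(J), length(J) == 1L, is.finite(J),
            is.numeric(H0), length(H0) == 1L, is.finite(H0),
            is.numeric(ln_deg), length(ln_deg) == 1L, is.finite(ln_deg),
            is.numeric(z), length(z) == 1L,
            is.numeric(chains_per_molecule), length(chains_per_molecule) == 1L)
  if (J <= 0) stop_domain("'J' must be > 0 (attractive chain-chain coupling)")
  if (ln_deg <= 0) {
    stop_domain("'ln_deg' must be > 0 (excited state more degenerate than ground state)")
  }
  if (z < 1 || z != round(z)) stop_domain("'z' must be a positive integer")
  if (chains_per_molecule < 1 || chains_per_molecule != round(chains_per_molecule)) {
    stop_domain("'chains_per_molecule' must be a positive integer")
  }
  structure(
    list(J = as.numeric(J), H0 = as.numeric(H0), ln_deg = as.numeric(ln_deg),
         z = as.integer(z), chains_per_molecule = as.integer(chains_per_molecule)),
    class = "ge_params"
  )
}

#' @export
print.ge_params <- function(x, ...) {
  cat("g-e model parameters (energies in Kelvin, E/kB):\n")
  cat(sprintf("  J       = %.6g K   (coupling)\n", x$J))
  cat(sprintf("  H0      = %.6g K   (field scale)\n", x$H0))
  cat(sprintf("  ln_deg  = %.6g     (ln De/Dg)\n", x$ln_deg))
  cat(sprintf("  z       = %d         (coordination)\n", x$z))
  cat(sprintf("  chains  = %d         (per molecule)\n", x$chains_per_molecule))
  if (x$H0 > 0) {
    cat(sprintf("  T*      = %.6g K,  Tc = %.6g K\n", tstar(x), tc_temperature(x)))
  }
  invisible(x)
}

#' Temperature-dependent effective field
#'
#' The pseudo-spin field `H(T) = H0 - (T/2) ln(De/Dg)` (Kelvin): the entropy
#' advantage of the degenerate melted state grows linearly with temperature
#' and eventually overturns the energetic preference for the ordered state.
#'
#' @param p A [ge_params()] object.
#' @param T Temperature(s), Kelvin, `>= 0`.  Vectorized.
#' @return Field value(s) in Kelvin; strictly decreasing and linear in `T`.
#' @export
field_at <- function(p, T) {
  stopifnot(inherits(p, "ge_params"), is.numeric(T))
  if (any(T < 0)) stop_domain("'T' must be >= 0 Kelvin")
  p$H0 - (T / 2) * p$ln_deg
}

#' Spin-reorientation (transition) temperature T*
#'
#' The temperature at which the effective field changes sign,
#' `T* = 2 H0 / ln(De/Dg)`.  Below `T*` the ordered (solid) state is
#' favoured, above it the melted state.
#'
#' @inheritParams field_at
#' @return `T*` in Kelvin.
#' @export
tstar <- function(p) {
  stopifnot(inherits(p, "ge_params"))
  if (p$H0 <= 0) stop_domain("'H0' must be > 0: the field never changes sign")
  2 * p$H0 / p$ln_deg
}

#' Mean-field critical temperature Tc
#'
#' `Tc = z J` in Kelvin units (kB absorbed).  Whether `T*` falls below,
#' at, or above `Tc` decides discontinuous, critical, or crossover
#' behaviour of the melting transition.
#'
#' @inheritParams field_at
#' @return `Tc` in Kelvin.
#' @export
tc_temperature <- function(p) {
  stopifnot(inherits(p, "ge_params"))
  p$z * p$J
}

#' Read / write g-e parameters as flat JSON
#'
#' @param path File path.
#' @return `read_ge_params()` returns a [ge_params()] object;
#'   `write_ge_params()` invisibly returns `path`.
#' @export
read_ge_params <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) stop_input(paste0("cannot parse JSON '", path, "': ", conditionMessage(e))))
  need <- c("J", "H0", "ln_deg", "z")
  miss <- setdiff(need, names(obj))
  if (length(miss)) stop_input(paste0("missing field(s) in '", path, "': ", paste(miss, collapse = ", ")))
  ge_params(J = obj$J, H0 = obj$H0, ln_deg = obj$ln_deg, z = obj$z,
            chains_per_molecule = if (is.null(obj$chains_per_molecule)) 3L else obj$chains_per_molecule)
}

#' @rdname read_ge_params
#' @param p A [ge_params()] object.
#' @export
write_ge_params <- function(p, path) {
  stopifnot(inherits(p, "ge_params"))
  jsonlite::write_json(unclass(p), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
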