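#' Synthetic labeled crystal-memory dataset
#'
#' Emulates a holding time-temperature memory experiment: at each holding
#' temperature above `T*`, an effective lifetime is drawn as the modified
#' VFT lifetime perturbed by multiplicative lognormal noise (times in such
#' experiments span decades, so noise symmetric on the log scale keeps
#' positivity), and each log-spaced candidate holding time is labeled
#' `"persists"` if it is shorter than the effective lifetime, `"lost"`
#' otherwise.  With zero noise the labels are exactly separable by the
#' generating curve.
#'
#' @param vft A [vft_params()] object — the generating truth.
#' @param T_grid Holding temperatures, Kelvin, all `> T_star`.
#' @param times_per_T Candidate holding times per temperature.
#' @param time_range Length-2 vector `(min, max)` minutes; candidate times
#'   are log-spaced across it.
#' @param noise_sigma Lognormal sigma applied to the true lifetime
#'   (0 = noiseless).
#' @param seed Seed; the dataset is deterministic given it.
#' @return data.frame with columns `T` (Kelvin), `holding_time` (minutes),
#'   `label`; attribute `"truth"` carries the generating [vft_params()].
#' @export
gen_memory_dataset <- function(vft, T_grid, times_per_T = 6L,
                               time_range = c(1, 1000), noise_sigma = 0.2,
                               seed = 1L) {
  stopifnot(inherits(vft, "vft_params"), is.numeric(T_grid),
            length(time_range) == 2L, all(time_range > 0),
            time_range[2L] > time_range[1L], times_per_T >= 1L,
            noise_sigma >= 0)
  if (any(T_grid <= vft$T_star)) {
    stop_domain("all holding temperatures must lie above T_star")
  }
  set.seed(seed)
  times <- exp(seq(log(time_range[1L]), log(time_range[2L]),
                   length.out = times_per_T))
  rows <- lapply(T_grid, function(Tk) {
    tau_eff <- vft_lifetime(vft, Tk) * exp(noise_sigma * rnorm(1L))
    data.frame(T = Tk, holding_time = times,
               label = ifelse(times < tau_eff, "persists", "lost"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- vft
  out
}

#' Branchwise mean-field regression fixture
#'
#' Deterministically tabulates the full branch structure (all roots, their
#' stability, and molar enthalpy) over a temperature grid — a regression
#' fixture for order-parameter / enthalpy curves with metastable branches.
#' At `T*` the table contains both coexisting branches with equal `|sigma|`
#' and an enthalpy gap equal to [transition_enthalpy()].
#'
#' @param p A [ge_params()] object.
#' @param T_grid Temperatures, Kelvin.
#' @param path Optional CSV path; when given the table is also written
#'   (comma-separated, header row, '.' decimal).
#' @return data.frame with columns `T_K`, `sigma`, `stability`,
#'   `U_kJ_mol` (invisibly when `path` is given).
#' @export
gen_meanfield_fixture <- function(p, T_grid, path = NULL) {
  out <- meanfield_curve(p, T_grid)
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
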