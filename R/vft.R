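#' Modified Vogel-Fulcher-Tammann lifetime parameters
#'
#' Parameters of the lifetime law of the superheated metastable state,
#' `tau(T) + tau0 = tau0 exp(D* T* / (T - T*))`: the lifetime diverges as
#' `T -> T*+` (the state becomes stable at the transition) and vanishes as
#' `T -> Inf`.
#'
#' @param T_star Transition temperature, Kelvin, `> 0`.
#' @param D_star Dimensionless strength parameter, `> 0`, related to the
#'   barrier between the metastable and equilibrium melted states.
#' @param tau0 Pre-factor time, minutes, `> 0`.
#' @return An object of class `"vft_params"`.
#' @export
vft_params <- function(T_star, D_star, tau0) {
  stopifnot(is.numeric(T_star), is.numeric(D_star), is.numeric(tau0))
  if (T_star <= 0) stop_domain("'T_star' must be > 0")
  if (D_star <= 0) stop_domain("'D_star' must be > 0")
  if (tau0 <= 0) stop_domain("'tau0' must be > 0")
  structure(list(T_star = as.numeric(T_star), D_star = as.numeric(D_star),
                 tau0 = as.numeric(tau0)),
            class = "vft_params")
}

#' @export
print.vft_params <- function(x, ...) {
  cat(sprintf("modified VFT lifetime: T* = %.4g K, D* = %.4g, tau0 = %.4g min\n",
              x$T_star, x$D_star, x$tau0))
  if (!is.null(attr(x, "ci"))) {
    cat("bootstrap 95% CI:\n"); print(attr(x, "ci"))
  }
  invisible(x)
}

#' Lifetime of the superheated metastable state
#'
#' `tau(T) = tau0 (exp(D* T* / (T - T*)) - 1)`, minutes; strictly
#' decreasing and convex on `(T*, Inf)`.  Defined only in the superheated
#' regime `T > T*`.
#'
#' @param v A [vft_params()] object.
#' @param T Temperature(s), Kelvin, all `> T_star`.  Vectorized.
#' @return Lifetime(s) in minutes.
#' @export
vft_lifetime <- function(v, T) {
  stopifnot(inherits(v, "vft_params"), is.numeric(T))
  if (any(T <= v$T_star)) {
    stop_domain("T <= T*: inside/below transition, lifetime undefined (superheated regime only)")
  }
  v$tau0 * expm1(v$D_star * v$T_star / (T - v$T_star))
}

#' Temperature at which the metastable lifetime equals a given time
#'
#' Exact inverse of [vft_lifetime()]:
#' `T = T* + D* T* / ln(1 + tau/tau0)`.
#'
#' @param v A [vft_params()] object.
#' @param tau Lifetime(s), minutes, all `> 0`.  Vectorized.
#' @return Temperature(s), Kelvin.
#' @export
vft_temperature <- function(v, tau) {
  stopifnot(inherits(v, "vft_params"), is.numeric(tau))
  if (any(tau <= 0)) stop_domain("'tau' must be > 0")
  v$T_star + v$D_star * v$T_star / log1p(tau / v$tau0)
}

#' Fit the modified VFT lifetime law to boundary points
#'
#' Fits the linearized law `ln(1 + tau/tau0) = D* T* / (T - T*)` by
#' nonlinear least squares on log-lifetimes: the residuals are
#' `log(tau) - log(tau0 (exp(D* T*/(T - T*)) - 1))`, symmetric under the
#' multiplicative (lognormal) errors typical of such time data.  (A plain
#' least-squares criterion on `ln(1 + tau/tau0)` itself is degenerate when
#' `tau0` is free: inflating `tau0` shrinks every residual, so the scale
#' must be anchored on the observed lifetimes.)  `T*` is kept below
#' `min(T)` and `D*`, `tau0` positive via log parameterization; the search
#' is multistarted.  Confidence intervals come from a seeded nonparametric
#' bootstrap over points.
#'
#' `tau0` and `D*` are only weakly identified when the temperatures span a
#' narrow range — the typical situation for crystal-memory data — hence the
#' `fix_tau0` option.
#'
#' @param T Temperatures, Kelvin (or a 2-column data.frame/list with
#'   elements `T` and `tau`).
#' @param tau Boundary lifetimes, minutes.
#' @param fix_tau0 Optional: fix `tau0` at this value instead of fitting it.
#' @param n_boot Number of bootstrap resamples for the confidence
#'   intervals (default 1000); 0 disables the bootstrap.
#' @param seed Seed for the bootstrap resampling.
#' @return A [vft_params()] object with attributes `rss` (residual sum of
#'   squares in log-lifetime space), `ci` (bootstrap 95% percentile
#'   intervals, rows T_star/D_star/tau0), and `n` (points used).
#' @export
fit_vft <- function(T, tau = NULL, fix_tau0 = NULL, n_boot = 1000L, seed = 1L) {
  if (is.null(tau)) {
    stopifnot(is.list(T), all(c("T", "tau") %in% names(T)))
    tau <- T$tau; T <- T$T
  }
  stopifnot(is.numeric(T), is.numeric(tau), length(T) == length(tau))
  keep <- is.finite(T) & is.finite(tau) & tau > 0
  T <- T[keep]; tau <- tau[keep]
  if (length(unique(T)) < 3L) {
    stop_domain("fit_vft needs at least 3 points with distinct temperatures")
  }
  # log(expm1(y)) without overflow: = y + log(1 - exp(-y))
  logexpm1 <- function(y) ifelse(y > 30, y, log(expm1(y)))
  fit1 <- function(T, tau, warm = NULL) {
    Tmin <- min(T)
    spanT <- max(max(T) - Tmin, 1e-3)
    ltau <- log(tau)
    obj <- function(par) {
      # T* bounded to (0, min(T)) through a logistic offset
      Ts <- Tmin * (1 - stats::plogis(par[1L]))
      D <- exp(par[2L])
      t0 <- if (is.null(fix_tau0)) exp(par[3L]) else fix_tau0
      y <- D * Ts / (T - Ts)
      r <- ltau - (log(t0) + logexpm1(y))
      if (!all(is.finite(r))) return(1e10)
      sum(r^2)
    }
    best <- NULL
    # warm restarts (bootstrap refits) start from the full-data estimate;
    # otherwise multistart over the offset of min(T) above T*: lifetimes
    # diverge at T*, so the offset is usually a modest fraction of the span
    offs <- if (!is.null(warm)) pmin(max(Tmin - warm$T_star, 1e-3), Tmin * 0.9)
            else pmin(spanT * c(0.1, 0.5, 2), Tmin * 0.9)
    for (off in offs) {
      Ts0 <- Tmin - off
      if (!is.null(warm)) {
        D0 <- warm$D_star
        t00 <- warm$tau0
      } else {
        x <- Ts0 / (T - Ts0)
        sl <- stats::cov(x, ltau) / stats::var(x)
        D0 <- max(sl, 1e-4)
        t00 <- if (is.null(fix_tau0)) max(exp(mean(ltau) - sl * mean(x)), 1e-8) else fix_tau0
      }
      par0 <- c(stats::qlogis(1 - off / Tmin), log(D0))
      if (is.null(fix_tau0)) par0 <- c(par0, log(t00))
      fit <- tryCatch(
        optim(par0, obj, method = "Nelder-Mead",
              control = list(maxit = 2000L, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
    }
    if (is.null(best)) stop_domain("VFT fit failed to converge")
    best <- optim(best$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 2000L, reltol = 1e-12))
    Ts <- Tmin * (1 - stats::plogis(best$par[1L]))
    D <- exp(best$par[2L])
    t0 <- if (is.null(fix_tau0)) exp(best$par[3L]) else fix_tau0
    list(T_star = Ts, D_star = D, tau0 = t0, rss = best$value)
  }
  est <- fit1(T, tau)
  if (est$T_star >= min(T)) {
    stop_domain("fitted T* is not below the smallest observed temperature")
  }
  v <- vft_params(est$T_star, est$D_star, est$tau0)
  attr(v, "rss") <- est$rss
  attr(v, "n") <- length(T)
  if (n_boot > 0L) {
    set.seed(seed)
    n <- length(T)
    bs <- matrix(NA_real_, nrow = n_boot, ncol = 3L,
                 dimnames = list(NULL, c("T_star", "D_star", "tau0")))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(T[idx])) < 3L) next
      eb <- tryCatch(fit1(T[idx], tau[idx], warm = est), error = function(e) NULL)
      if (!is.null(eb) && eb$D_star > 0 && eb$tau0 > 0) {
        bs[b, ] <- c(eb$T_star, eb$D_star, eb$tau0)
      }
    }
    ci <- t(apply(bs, 2L, quantile, probs = c(0.025, 0.975), na.rm = TRUE))
    attr(v, "ci") <- ci
    attr(v, "n_boot") <- n_boot
  }
  v
}

#' Classify a holding (temperature, time) pair for crystal memory
#'
#' Below `T*` no melting occurs and memory trivially persists.  Above
#' `T*`, memory persists while the holding time is shorter than the
#' metastable-state lifetime (region I) and is lost once the system has
#' relaxed to the equilibrium melt (region II).  Ties go to region II —
#' conservative for memory-erasure protocols.
#'
#' @param v A [vft_params()] object.
#' @param T Holding temperature(s), Kelvin.
#' @param t Holding time(s), minutes, `> 0`.
#' @return Character vector: `"persists"` (below `T*` or region I) or
#'   `"lost"` (region II).
#' @export
classify_memory <- function(v, T, t) {
  stopifnot(inherits(v, "vft_params"), is.numeric(T), is.numeric(t))
  n <- max(length(T), length(t))
  T <- rep_len(T, n); t <- rep_len(t, n)
  if (any(t <= 0)) stop_domain("'t' must be > 0")
  out <- character(n)
  below <- T <= v$T_star
  out[below] <- "persists"
  if (any(!below)) {
    lt <- vft_lifetime(v, T[!below])
    out[!below] <- ifelse(t[!below] < lt, "persists", "lost")
  }
  out
}

#' Boundary lifetime estimates from labeled memory points
#'
#' Converts labeled holding time-temperature observations into per-
#' temperature boundary estimates suitable for [fit_vft()]: at each
#' temperature carrying both labels, the boundary is the geometric mean of
#' the longest persisting time and the shortest lost time (time data are
#' log-scaled, so the geometric mean is the symmetric choice).
#' Temperatures lacking one of the labels are dropped with a warning.
#'
#' @param points A data.frame with columns `T` (Kelvin), `holding_time`
#'   (minutes), `label` (`"persists"` or `"lost"`), as produced by
#'   [gen_memory_dataset()] or [read_memory_csv()].
#' @return data.frame with columns `T`, `tau` (boundary estimate, minutes).
#' @export
boundary_from_labeled <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("T", "holding_time", "label") %in% names(points)))
  if (any(points$holding_time <= 0)) stop_domain("holding times must be > 0")
  bad <- setdiff(unique(points$label), c("persists", "lost"))
  if (length(bad)) stop_input(paste0("unknown label(s): ", paste(bad, collapse = ", ")))
  out <- lapply(split(points, points$T), function(d) {
    has_p <- any(d$label == "persists"); has_l <- any(d$label == "lost")
    if (!has_p || !has_l) return(NULL)
    t_p <- max(d$holding_time[d$label == "persists"])
    t_l <- min(d$holding_time[d$label == "lost"])
    data.frame(T = d$T[1L], tau = sqrt(t_p * t_l))
  })
  dropped <- sum(vapply(out, is.null, logical(1L)))
  if (dropped > 0L) {
    warning(sprintf("dropped %d temperature(s) lacking both labels", dropped))
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    stop_domain("no temperature has both 'persists' and 'lost' observations")
  }
  rownames(out) <- NULL
  out[order(out$T), , drop = FALSE]
}

#' Read / write labeled memory-point CSV
#'
#' The CSV carries a header with a unit-bearing temperature column:
#' `temperature_K` or `temperature_C` (converted with `T_K = T_C + 273.15`
#' on read), plus `time_min` and `label` in `{persists, lost}`.
#'
#' @param path File path.
#' @return `read_memory_csv()`: data.frame with columns `T` (Kelvin),
#'   `holding_time` (minutes), `label`.
#' @export
read_memory_csv <- function(path) {
  d <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop_input(paste0("cannot read CSV '", path, "': ", conditionMessage(e))))
  tcol <- intersect(c("temperature_K", "temperature_C"), names(d))
  if (length(tcol) != 1L) {
    stop_input("CSV must have exactly one of 'temperature_K' or 'temperature_C'")
  }
  if (!all(c("time_min", "label") %in% names(d))) {
    stop_input("CSV must have columns 'time_min' and 'label'")
  }
  T_K <- if (tcol == "temperature_C") d[[tcol]] + 273.15 else d[[tcol]]
  if (!all(d$label %in% c("persists", "lost"))) {
    stop_input("'label' entries must be 'persists' or 'lost'")
  }
  data.frame(T = T_K, holding_time = d$time_min, label = d$label,
             stringsAsFactors = FALSE)
}

#' @rdname read_memory_csv
#' @param points data.frame with columns `T` (Kelvin), `holding_time`, `label`.
#' @export
write_memory_csv <- function(points, path) {
  stopifnot(is.data.frame(points),
            all(c("T", "holding_time", "label") %in% names(points)))
  out <- data.frame(temperature_K = points$T, time_min = points$holding_time,
                    label = points$label)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
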