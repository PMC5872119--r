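# Delay differential equation mass-action model:
#   dC/dt = r C (1 - C/K) - kappa C P
#   dP/dt = b kappa C_L P_L - kappa C P - delta P
# where X_L is the value of X a lysis delay L minutes in the past. Phage die
# at constant rate delta (the well-mixed equivalent of a fixed EPS level) and
# each infection started L minutes ago releases b phage now.

#' Parameters of the delay-ODE mass-action model
#'
#' @param r Cell growth rate, per minute.
#' @param K Carrying capacity, cells per mL.
#' @param kappa Adsorption rate of phage to cells, mL per minute.
#' @param delta Phage loss rate (the well-mixed analogue of EPS), per minute.
#' @param b Burst size (> 1).
#' @param L Lysis delay, minutes.
#' @param horizon Total minutes to integrate (default 50000).
#' @return An object of class `"ode_params"`.
#' @examples
#' ode_params(kappa = 1e-10, delta = 0.1, b = 10)
#' @export
ode_params <- function(r = 0.03, K = 1e9, kappa, delta, b, L = 20,
                       horizon = 50000) {
  # kappa = 0 is admitted for the decoupled limits (pure decay of P,
  # logistic growth of C); c_bar() then has no finite value
  stopifnot(r > 0, K > 0, kappa >= 0, delta > 0, b > 1, L > 0, horizon > 0)
  structure(list(r = r, K = K, kappa = kappa, delta = delta, b = b, L = L,
                 horizon = horizon),
            class = "ode_params")
}

#' @export
print.ode_params <- function(x, ...) {
  cat(sprintf(
    "delay-ODE parameters: b = %g, delta = %g /min, kappa = %g mL/min,\n",
    x$b, x$delta, x$kappa))
  cat(sprintf("  L = %g min, r = %g /min, K = %g /mL, horizon %g min\n",
              x$L, x$r, x$K, x$horizon))
  if (x$kappa > 0)
    cat(sprintf("  equilibrium C-bar = %g /mL (A upper bound %g)\n",
                c_bar(x), x$K / c_bar(x)))
  invisible(x)
}

#' Equilibrium cell density of the delay-ODE model (C-bar)
#'
#' `C-bar = delta / (kappa (b - 1))`: the cell density at which each burst
#' yields exactly one new productive infection under mass action. Observed
#' densities are referenced to it when computing `A_ode`; its own upper
#' bound gives `A_ub,ode = K / C-bar`.
#'
#' @param params An [ode_params()] object (or a list with `delta`, `kappa`,
#'   `b`).
#' @return Equilibrium density, per mL.
#' @examples
#' c_bar(ode_params(kappa = 1e-10, delta = 0.1, b = 10))  # ~1.11e8
#' @export
c_bar <- function(params) {
  if (params$b <= 1) stop("C-bar requires burst size b > 1")
  if (params$kappa <= 0) stop("C-bar requires kappa > 0")
  params$delta / (params$kappa * (params$b - 1))
}

#' Integrate the delay-ODE model
#'
#' Solves the two-variable delay system with constant history
#' `C(t) = C0, P(t) = P0` on `[-L, 0]`, using the adaptive delay solver in
#' \pkg{deSolve} (dense history interpolation for the lagged terms).
#' Negative excursions are clipped to zero inside the right-hand side. A
#' trajectory whose state falls below `1e-30` is flagged `"underflow"`
#' (effective extinction, the fate of expanding oscillations in this model);
#' one exceeding `1e30` is flagged `"blowup"`; otherwise `"completed"`.
#'
#' The absolute tolerance must sit at the underflow floor: phage transients
#' in the oscillatory regimes pass through densities around 1e-22 per mL and
#' back, and a looser `atol` silently zeroes them, turning a coexistence
#' trajectory into extinction.
#'
#' @param params An [ode_params()] object.
#' @param C0,P0 Initial (and history) densities, per mL.
#' @param dt Output sampling interval in minutes (default 1).
#' @param rtol,atol Solver tolerances (defaults 1e-8 and 1e-30).
#' @return An object of class `"phage_dde"`: list with `params`, `C0`, `P0`,
#'   `trajectory` (data frame `t`, `C`, `P`) and `status`.
#' @examples
#' op <- ode_params(kappa = 3e-11, delta = 0.3, b = 20, horizon = 2000)
#' r <- run_dde(op)
#' r$status
#' @export
run_dde <- function(params, C0 = 1e6, P0 = 1e4, dt = 1,
                    rtol = 1e-8, atol = 1e-30) {
  stopifnot(inherits(params, "ode_params"), C0 >= 0, P0 >= 0, dt > 0)
  p <- params
  deriv <- function(t, y, parms) {
    C <- max(y[1], 0); P <- max(y[2], 0)
    if (t - p$L <= 0) {
      CL <- C0; PL <- P0
    } else {
      lag <- deSolve::lagvalue(t - p$L)
      CL <- max(lag[1], 0); PL <- max(lag[2], 0)
    }
    dC <- p$r * C * (1 - C / p$K) - p$kappa * C * P
    dP <- p$b * p$kappa * CL * PL - p$kappa * C * P - p$delta * P
    list(c(dC, dP))
  }
  times <- seq(0, p$horizon, by = dt)
  out <- deSolve::dede(c(C = C0, P = P0), times, deriv, parms = NULL,
                       rtol = rtol, atol = atol)
  traj <- data.frame(t = out[, "time"], C = out[, "C"], P = out[, "P"])
  clipped <- any(traj$C < 0 | traj$P < 0)
  if (clipped) {
    warning("negative state excursions clipped to 0")
    traj$C <- pmax(traj$C, 0)
    traj$P <- pmax(traj$P, 0)
  }
  status <- if (max(traj$C, traj$P) > 1e30) "blowup"
            else if (nrow(traj) < length(times) ||
                     min(traj$C, traj$P) < 1e-30) "underflow"
            else "completed"
  structure(list(params = p, C0 = C0, P0 = P0, trajectory = traj,
                 status = status),
            class = "phage_dde")
}

#' @export
print.phage_dde <- function(x, ...) {
  cat(sprintf("phage_dde: b = %g, delta = %g, kappa = %g, L = %g (%s)\n",
              x$params$b, x$params$delta, x$params$kappa, x$params$L,
              x$status))
  if (x$status == "completed") {
    a <- a_ode(x)
    cat(sprintf("  A_ode = %.3g (windows %s); upper bound %.3g\n",
                a$A_ode, paste(sprintf("%.3g", a$windows), collapse = ", "),
                a$A_ub_ode))
  }
  invisible(x)
}

#' Amplification statistic A_ode from a delay-ODE trajectory
#'
#' `A_ode = mean(C(t) / C-bar)`, the mean observed cell density relative to
#' the model's equilibrium. The mean is taken in four consecutive windows of
#' 10000 minutes spanning t = 10000 to the horizon end (burn-in excluded);
#' the per-window means are reported alongside their overall mean, and the
#' upper bound `A_ub,ode = K / C-bar`. A trajectory that terminated early
#' (underflow/blowup) has no `A_ode`.
#'
#' @param fit A `"phage_dde"` from [run_dde()].
#' @param burnin Burn-in minutes excluded from averaging (default 10000).
#' @param window_len Averaging window length in minutes (default 10000).
#' @return List with `A_ode` (overall mean; `NA` if extinct), `windows`
#'   (per-window means), `A_ub_ode`, and `status`.
#' @export
a_ode <- function(fit, burnin = 10000, window_len = 10000) {
  stopifnot(inherits(fit, "phage_dde"))
  cb <- c_bar(fit$params)
  A_ub <- fit$params$K / cb
  if (fit$status != "completed")
    return(list(A_ode = NA_real_, windows = numeric(0), A_ub_ode = A_ub,
                status = fit$status))
  tr <- fit$trajectory
  edges <- seq(burnin, fit$params$horizon, by = window_len)
  if (length(edges) < 2L) stop("horizon too short for the averaging windows")
  wins <- vapply(seq_len(length(edges) - 1L), function(k) {
    sel <- tr$t > edges[k] & tr$t <= edges[k + 1L]
    mean(tr$C[sel]) / cb
  }, numeric(1))
  list(A_ode = mean(wins), windows = wins, A_ub_ode = A_ub,
       status = fit$status)
}

#' Trajectory plot of a delay-ODE run
#'
#' @param x A `"phage_dde"`.
#' @param log Axis log spec passed to [graphics::matplot()] (default `"y"`).
#' @param ... Passed on.
#' @return `x`, invisibly.
#' @export
plot.phage_dde <- function(x, log = "y", ...) {
  tr <- x$trajectory
  graphics::matplot(tr$t, pmax(cbind(tr$C, tr$P), 1e-30), type = "l",
                    lty = 1, col = c("forestgreen", "blue"), log = log,
                    xlab = "time (min)", ylab = "density (/mL)", ...)
  graphics::abline(h = c_bar(x$params), lty = 2, col = "forestgreen")
  graphics::legend("bottomright", bty = "n", lty = c(1, 1, 2),
                   col = c("forestgreen", "blue", "forestgreen"),
                   legend = c("cells C", "phage P", "C-bar"))
  invisible(x)
}

#' Grid-to-ODE parameter correspondences
#'
#' Over one time unit (1 grid step == 1 minute), a phage avoids EPS with
#' probability `1 - k_E E` in the grid model and `exp(-delta)` in the ODE
#' model, so `delta = -log(1 - k_E E)` is the equivalent constant loss rate.
#' The same logic at maximum cell density (a full grid versus `K`) gives
#' `kappa = -log(1 - k_C) / K`.
#'
#' @param k_E,E Grid EPS adsorption probability and EPS patch fraction
#'   (`k_E * E < 1`).
#' @return `delta_from_eps()`: loss rate per minute.
#' @examples
#' delta_from_eps(0.35, 0.9)  # ~0.38
#' kappa_from_kc(0.25, 1e9)   # ~2.9e-10
#' @export
delta_from_eps <- function(k_E, E) {
  if (k_E * E >= 1) stop("k_E * E must be < 1")
  if (k_E * E < 0) stop("k_E * E must be non-negative")
  -log(1 - k_E * E)
}

#' @rdname delta_from_eps
#' @param k_C Grid adsorption probability to uninfected cells (0 < k_C < 1).
#' @param K ODE carrying capacity, per mL.
#' @return `kappa_from_kc()`: adsorption rate in mL per minute.
#' @export
kappa_from_kc <- function(k_C, K) {
  if (k_C <= 0 || k_C >= 1) stop("k_C must be strictly in (0, 1)")
  stopifnot(K > 0)
  -log(1 - k_C) / K
}
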