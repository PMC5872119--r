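# Equilibrium-referenced amplification metrics.
#
# At a mass-action equilibrium every successful infection replaces itself:
# (fraction of free-phage losses that are productive infections) x (burst
# size) = 1, i.e. alpha * b = 1. alpha computed from densities observed in a
# spatially structured run therefore measures, via alpha*b, how far the
# spatial system sits above what mass action would sustain.

#' Productive fraction of phage losses (alpha)
#'
#' `alpha = k_C C / (k_C C + k_I I + k_D D + k_E E)`: of all routes by which
#' a free phage leaves the free state, the fraction that are productive
#' infections of uninfected cells. Multiplying by the burst size `b` gives
#' `alpha * b`, which equals 1 at the mass-action equilibrium. alpha is
#' strictly increasing in `C` and strictly decreasing in `I`, `D`, `E`
#' (whenever the corresponding `k` is positive).
#'
#' @param C,I,D,E Global densities (patch fractions) of uninfected cells,
#'   infected cells, debris, and EPS.
#' @param k_C,k_I,k_D,k_E Per-step adsorption probabilities.
#' @return The fraction `alpha`. Errors if every loss route is zero.
#' @examples
#' alpha(C = 0.14, I = 0, D = 0, E = 0.9, k_C = 0.25, k_E = 0.35)  # 0.1
#' @export
alpha <- function(C, I = 0, D = 0, E = 0, k_C, k_I = 0, k_D = 0, k_E = 0) {
  den <- k_C * C + k_I * I + k_D * D + k_E * E
  if (any(den <= 0))
    stop("alpha undefined: no loss route has positive rate")
  k_C * C / den
}

#' Mass-action equilibrium cell density (C-hat)
#'
#' The cell density at which `alpha * b = 1` under mass action. Without
#' superinfection or debris attachment (`k_I = k_D = 0`) it is the constant
#' `C-hat = k_E E / (k_C (b - 1))`. When superinfection and/or debris are
#' active the generalized form `(k_I I + k_D D + k_E E) / (k_C (b - 1))`
#' requires caller-supplied `I` and `D`; because those are dynamic variables
#' whose mass-action equilibrium values differ from the spatial ones, this
#' form is only an approximation and must be requested explicitly.
#'
#' @param b Burst size (> 1).
#' @param E EPS patch fraction.
#' @param k_C,k_E Adsorption probabilities to uninfected cells and EPS.
#' @param k_I,k_D Adsorption probabilities to infected cells and debris
#'   (default 0, required for the exact form).
#' @param I,D Densities of infected cells and debris; supply these to use the
#'   generalized (approximate) form when `k_I` or `k_D` is positive.
#' @return Equilibrium cell density as a patch fraction.
#' @examples
#' c_hat(b = 2, E = 0.1, k_C = 0.25, k_E = 0.35)  # 0.14
#' @export
c_hat <- function(b, E, k_C, k_E, k_I = 0, k_D = 0, I = NULL, D = NULL) {
  if (b <= 1) stop("C-hat requires burst size b > 1")
  if ((k_I > 0 || k_D > 0) && (is.null(I) || is.null(D)))
    stop("with superinfection or debris attachment active, supply observed ",
         "I and D for the generalized (approximate) form of C-hat")
  if (is.null(I)) I <- 0
  if (is.null(D)) D <- 0
  (k_I * I + k_D * D + k_E * E) / (k_C * (b - 1))
}

#' Grid-model amplification A_g and its upper bound
#'
#' `A_g = C_obs / C-hat` is the observed mean cell density relative to the
#' mass-action equilibrium density: the amplification of cell density
#' attributable to spatial structure. Its upper bound, attained when every
#' patch holds a cell, is `A_ub,g = 1 / C-hat = k_C (b - 1) / (k_E E)`.
#' Defined only when the phage death routes are unchanging, i.e. no
#' superinfection (`k_I = 0`) and no debris attachment (`k_D = 0`); when
#' those are active, report `alpha * b` instead.
#'
#' @param C_obs Observed mean cell density (patch fraction); `NULL` to get
#'   only the upper bound.
#' @inheritParams c_hat
#' @return List with `A_g` (or `NA` when `C_obs` is `NULL`), `A_ub_g`, and
#'   `c_hat`.
#' @examples
#' amplification_grid(NULL, b = 60, E = 0.1, k_C = 0.25, k_E = 0.35)$A_ub_g
#' @export
amplification_grid <- function(C_obs, b, E, k_C, k_E, k_I = 0, k_D = 0) {
  if (k_I > 0 || k_D > 0)
    stop("A_g is undefined with superinfection or debris attachment; ",
         "report alpha * b instead")
  ch <- c_hat(b, E, k_C, k_E)
  if (ch <= 0) stop("A_g undefined: C-hat is zero (no EPS, or k_E = 0)")
  list(A_g = if (is.null(C_obs)) NA_real_ else C_obs / ch,
       A_ub_g = 1 / ch,
       c_hat = ch)
}

#' alpha*b implied by A_g
#'
#' Closed-form consequence of the definitions when `k_I = k_D = 0`:
#' `alpha * b = b A_g / (A_g + b - 1)`. Used as an internal consistency
#' check between the two reported statistics at stationarity.
#'
#' @param A_g Amplification statistic (> 0).
#' @param b Burst size (> 1).
#' @return The implied `alpha * b`.
#' @examples
#' alpha_b_from_Ag(40.8, 60)  # ~24.5
#' @export
alpha_b_from_Ag <- function(A_g, b) {
  stopifnot(A_g > 0, b > 1)
  b * A_g / (A_g + b - 1)
}

#' Window-averaged summary of a per-step statistics series
#'
#' Averages the trailing `avg_window` steps of a run: mean densities,
#' per-step `alpha * b` (computed from the instantaneous global densities
#' each step, then averaged) with its 10th-90th percentile span, the
#' spatial-association fractions `C:E` and `P:E` (window means of the
#' per-step fractions of uninfected cells and free phage sitting on
#' EPS-bearing patches), `I:E` (infections on EPS patches over all
#' infections in the window), and the per-burst losses `P->C`, `P->I`,
#' `P->E`, `P->D` (total window losses to each sink divided by total window
#' bursts; `NA` when the window has no bursts). `A_g` and its upper bound
#' are included when defined (`k_I = k_D = 0`, debris off).
#'
#' @param stats Per-step data frame as produced by [run_spatial()].
#' @param params The run's [sim_params()].
#' @param extinct Logical; an extinct run yields a summary of `NA` metrics.
#' @param alpha_of_means Also compute the alternative statistic
#'   `alpha(window-mean densities) * b` (default `TRUE`; reported as
#'   `alpha_b_of_means`).
#' @return A one-row data frame (the run summary).
#' @export
summarize_window <- function(stats, params, extinct = FALSE,
                             alpha_of_means = TRUE) {
  p <- params
  out <- data.frame(
    mode = NA_character_, C = NA_real_, I = NA_real_, D = NA_real_,
    P = NA_real_, alpha_b = NA_real_, alpha_b_q10 = NA_real_,
    alpha_b_q90 = NA_real_, alpha_b_of_means = NA_real_,
    A_g = NA_real_, A_ub_g = NA_real_,
    C_E = NA_real_, P_E = NA_real_, I_E = NA_real_,
    P_to_C = NA_real_, P_to_I = NA_real_, P_to_E = NA_real_,
    P_to_D = NA_real_, bursts = NA_real_, extinct = extinct)
  if (extinct || nrow(stats) < p$avg_window) {
    out$extinct <- TRUE
    return(out)
  }
  w <- stats[seq(nrow(stats) - p$avg_window + 1L, nrow(stats)), ]
  E <- p$eps_fraction_E
  n_eps <- round(E * p$width * p$height)
  ab <- alpha(w$C, w$I, w$D, E, p$k_C, p$k_I, p$k_D, p$k_E) * p$burst_b
  out$C <- mean(w$C); out$I <- mean(w$I); out$D <- mean(w$D)
  out$P <- mean(w$P)
  out$alpha_b <- mean(ab)
  qs <- stats::quantile(ab, c(0.1, 0.9), names = FALSE)
  out$alpha_b_q10 <- qs[1]; out$alpha_b_q90 <- qs[2]
  if (alpha_of_means)
    out$alpha_b_of_means <- alpha(out$C, out$I, out$D, E, p$k_C, p$k_I,
                                  p$k_D, p$k_E) * p$burst_b
  if (p$k_I == 0 && p$k_D == 0 && !p$debris_enabled && E > 0 && p$k_E > 0 &&
      p$burst_b > 1) {
    a <- amplification_grid(out$C, p$burst_b, E, p$k_C, p$k_E)
    out$A_g <- a$A_g; out$A_ub_g <- a$A_ub_g
  }
  ncell <- w$C * p$width * p$height
  nph <- w$P
  out$C_E <- mean(ifelse(ncell > 0, w$cells_on_eps / ncell, NA), na.rm = TRUE)
  out$P_E <- mean(ifelse(nph > 0, w$phage_on_eps / nph, NA), na.rm = TRUE)
  tot_inf <- sum(w$infections_total)
  out$I_E <- if (tot_inf > 0) sum(w$infections_eps) / tot_inf else NA_real_
  tot_b <- sum(w$bursts)
  out$bursts <- tot_b
  if (tot_b > 0) {
    out$P_to_C <- sum(w$loss_C) / tot_b
    out$P_to_I <- sum(w$loss_I) / tot_b
    out$P_to_E <- sum(w$loss_E) / tot_b
    out$P_to_D <- sum(w$loss_D) / tot_b
  }
  out
}

#' Aggregate an ensemble of run summaries into one table row
#'
#' Means over the non-extinct runs of an ensemble (runs differing in seed
#' and/or initial abundances); trials that ended in extinction are excluded
#' from the averages and counted separately. Also reports, for each averaged
#' statistic, the range across runs as a percent of the mean (a repeatability
#' diagnostic). When every run went extinct the row carries `NA` values and
#' the extinction count.
#'
#' @param summaries List of one-row summary data frames
#'   (from [summarize_window()] / `run$summary`).
#' @return A one-row data frame with the ensemble means, `n_runs`,
#'   `n_extinct`, and `max_range_pct` (largest range-as-percent-of-mean over
#'   the mean statistics).
#' @export
summarize_ensemble <- function(summaries) {
  stopifnot(length(summaries) >= 1L)
  all_s <- do.call(rbind, summaries)
  ok <- !all_s$extinct
  cols <- c("C", "I", "D", "P", "alpha_b", "A_g", "A_ub_g", "C_E", "P_E",
            "I_E", "P_to_C", "P_to_I", "P_to_E", "P_to_D")
  out <- data.frame(n_runs = nrow(all_s), n_extinct = sum(!ok))
  if (!any(ok)) {
    for (cl in cols) out[[cl]] <- NA_real_
    out$max_range_pct <- NA_real_
    return(out)
  }
  s <- all_s[ok, , drop = FALSE]
  rng_pct <- c()
  for (cl in cols) {
    v <- s[[cl]]
    out[[cl]] <- mean(v, na.rm = TRUE)
    if (sum(!is.na(v)) > 1L && isTRUE(out[[cl]] != 0))
      rng_pct[cl] <- 100 * diff(range(v, na.rm = TRUE)) / abs(out[[cl]])
  }
  out$max_range_pct <- if (length(rng_pct)) max(rng_pct) else NA_real_
  out
}
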