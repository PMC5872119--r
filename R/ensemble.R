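#' Run a replicated ensemble of grid simulations
#'
#' Runs `n_seeds` trials for each initial-condition pair, spreading the seed
#' budget across the initial conditions (e.g. 15 seeds over 3 initial
#' conditions = 5 trials each), the replication design used for the ensemble
#' tables. Child seeds are derived reproducibly from the master seed in
#' `params$seed` by one `sample.int(.Machine$integer.max, n)` draw, so the
#' whole ensemble regenerates bit-identically from (params, master seed).
#'
#' @param params Baseline [sim_params()]; its `seed` acts as the master seed.
#' @param n_seeds Total number of trials (split across initial conditions).
#' @param initial_conditions List of `c(cell, phage)` initial occupancy
#'   fraction pairs. Default: the baseline 30\%/30\% plus a sparser and a
#'   denser start.
#' @param mode `"spatial"` or `"mass_action"`.
#' @return An object of class `"phage_ensemble"`: list with `runs` (the
#'   per-run summaries, one row each, with seed and initial condition
#'   columns), `ensemble` (the [summarize_ensemble()] row), `params`, `mode`.
#' @examples
#' p <- sim_params(width = 10, height = 10, n_steps = 60, avg_window = 20,
#'                 seed = 1)
#' e <- run_ensemble(p, n_seeds = 3, initial_conditions = list(c(0.3, 0.3)))
#' e$ensemble$n_extinct
#' @export
run_ensemble <- function(params, n_seeds = 15,
                         initial_conditions = list(c(0.3, 0.3), c(0.1, 0.1),
                                                   c(0.5, 0.5)),
                         mode = c("spatial", "mass_action")) {
  mode <- match.arg(mode)
  stopifnot(n_seeds >= 1)
  n_ic <- length(initial_conditions)
  per_ic <- rep(n_seeds %/% n_ic, n_ic)
  extra <- n_seeds %% n_ic
  if (extra > 0) per_ic[seq_len(extra)] <- per_ic[seq_len(extra)] + 1L
  set.seed(params$seed)
  child_seeds <- sample.int(.Machine$integer.max, n_seeds)
  summaries <- vector("list", n_seeds)
  meta <- data.frame(seed = child_seeds, init_cell = NA_real_,
                     init_phage = NA_real_)
  k <- 0L
  for (ic in seq_len(n_ic)) {
    for (j in seq_len(per_ic[ic])) {
      k <- k + 1L
      p <- params
      p$seed <- child_seeds[k]
      p$init_cell_frac <- initial_conditions[[ic]][1]
      p$init_phage_frac <- initial_conditions[[ic]][2]
      meta$init_cell[k] <- p$init_cell_frac
      meta$init_phage[k] <- p$init_phage_frac
      r <- run_spatial(p, mode = mode)
      summaries[[k]] <- r$summary
    }
  }
  runs <- cbind(meta, do.call(rbind, summaries))
  structure(list(runs = runs, ensemble = summarize_ensemble(summaries),
                 params = params, mode = mode),
            class = "phage_ensemble")
}

#' @export
print.phage_ensemble <- function(x, ...) {
  e <- x$ensemble
  cat(sprintf("phage_ensemble: %d %s runs (b = %d, E = %.2g, %s layout)\n",
              e$n_runs, x$mode, x$params$burst_b, x$params$eps_fraction_E,
              x$params$eps_layout))
  if (e$n_extinct == e$n_runs) {
    cat("  all trials went extinct\n")
  } else {
    cat(sprintf("  extinctions %d/%d; means over survivors:\n",
                e$n_extinct, e$n_runs))
    cat(sprintf("    alpha*b = %.3g", e$alpha_b))
    if (!is.na(e$A_g))
      cat(sprintf("  A_g = %.3g (A_ub,g = %.3g)", e$A_g, e$A_ub_g))
    cat(sprintf("\n    C:E = %.2g  P:E = %.2g  I:E = %.2g\n",
                e$C_E, e$P_E, e$I_E))
  }
  invisible(x)
}

#' Sweep burst size and EPS fraction
#'
#' Runs an ensemble for every combination of `bursts` x `eps_fractions`
#' (the factorial design of the main output tables) and stacks the ensemble
#' rows into one table.
#'
#' @param params Baseline [sim_params()] (its `burst_b` / `eps_fraction_E`
#'   are overridden per combination; `seed` is the master seed).
#' @param bursts Integer vector of burst sizes.
#' @param eps_fractions Numeric vector of EPS fractions.
#' @inheritParams run_ensemble
#' @return Data frame with one row per (burst, EPS) combination: columns
#'   `burst`, `eps` plus the [summarize_ensemble()] columns.
#' @export
sweep_burst_eps <- function(params, bursts = c(2, 6, 10, 20, 40, 60),
                            eps_fractions = c(0.1, 0.3, 0.6, 0.9),
                            n_seeds = 15,
                            initial_conditions = list(c(0.3, 0.3),
                                                      c(0.1, 0.1),
                                                      c(0.5, 0.5)),
                            mode = c("spatial", "mass_action")) {
  mode <- match.arg(mode)
  rows <- list()
  for (b in bursts) for (E in eps_fractions) {
    p <- params
    p$burst_b <- as.integer(b)
    p$eps_fraction_E <- E
    e <- run_ensemble(p, n_seeds = n_seeds,
                      initial_conditions = initial_conditions, mode = mode)
    rows[[length(rows) + 1L]] <- cbind(data.frame(burst = b, eps = E),
                                       e$ensemble)
  }
  do.call(rbind, rows)
}

#' Write an ensemble sweep as a TSV table
#'
#' Emits the sweep in the column order of the published summary tables:
#' without debris, `Burst, EPS, Ag, Aub_g, alpha_b, P_to_E, C_E, P_E, I_E`;
#' with debris/superinfection, `EPS, Burst, alpha_b, P_to_C, P_to_I, P_to_E,
#' P_to_D, C_E, P_E, I_E` (no `A_g`, whose baseline is undefined there).
#' Rows where every trial went extinct print `-` values. The `mode` column
#' flags mass-action sweeps.
#'
#' @param sweep Data frame from [sweep_burst_eps()].
#' @param path Output file.
#' @param debris Use the debris-table column order (default `FALSE`).
#' @param mode Mode label written into the table.
#' @return `path`, invisibly.
#' @export
write_sweep_tsv <- function(sweep, path, debris = FALSE, mode = "spatial") {
  cols <- if (debris)
    c("eps", "burst", "alpha_b", "P_to_C", "P_to_I", "P_to_E", "P_to_D",
      "C_E", "P_E", "I_E")
  else
    c("burst", "eps", "A_g", "A_ub_g", "alpha_b", "P_to_E", "C_E", "P_E",
      "I_E")
  tab <- sweep[, c(cols, "n_extinct", "n_runs")]
  tab$mode <- mode
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) ifelse(is.nan(v), NA, v))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "-")
  invisible(path)
}

#' Write a per-step statistics series as TSV
#'
#' Streams the per-step tallies of a run to a TSV time series with the
#' columns `step, C, I, D, P, loss_C, loss_I, loss_E, loss_D, bursts,
#' infections_eps, infections_total` (densities as patch fractions).
#'
#' @param sim A `"phage_sim"` from [run_spatial()] / [run_mass_action()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stats_tsv <- function(sim, path) {
  cols <- c("step", "C", "I", "D", "P", "loss_C", "loss_I", "loss_E",
            "loss_D", "bursts", "infections_eps", "infections_total")
  utils::write.table(sim$stats[, cols], path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Delay-ODE parameter presets for the published coexistence rows
#'
#' The eleven (b, delta, kappa, L, r) parameter sets for which the delay-ODE
#' model sustains coexistence to the 50000-minute horizon, with K = 1e9
#' throughout. Useful as input to [run_dde()] sweeps.
#'
#' @return Data frame with columns `b`, `delta`, `kappa`, `L`, `r`, `K`.
#' @export
dde_presets <- function() {
  data.frame(
    b     = c(10, 10, 10, 10, 10, 20, 20, 20, 60, 60, 60),
    delta = c(0.1, 0.1, 0.05, 0.3, 0.1, 0.3, 0.4, 0.2, 0.3, 0.4, 0.045),
    kappa = c(1e-10, 5e-11, 1e-10, 1e-10, 1e-10, 3e-11, 7e-11, 1e-10,
              5e-11, 5e-11, 3e-11),
    L     = c(20, 20, 20, 20, 25, 20, 20, 20, 25, 20, 21),
    r     = c(0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.03, 0.04, 0.03,
              0.03),
    K     = 1e9)
}
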