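#' Run the spatial grid simulation
#'
#' Initializes the world (EPS placement, then independent cell and phage
#' seeding), iterates `n_steps` time steps of the four global phases (lysis,
#' reproduction, infection, diffusion), records per-step tallies, detects
#' extinction, and window-averages the results. All randomness flows from
#' `params$seed`, so identical parameters give bit-identical results.
#'
#' Extinction is a reported outcome, not an error: cells are extinct when no
#' live (uninfected or infected) cell remains; phage are extinct when no free
#' phage remains *and* no infected cell is latent (a pending burst counts as
#' phage being alive). The run stops at the extinction step.
#'
#' @param params A [sim_params()] object.
#' @param mode `"spatial"` (localized diffusion) or `"mass_action"` (global
#'   shuffling of phage and cells each step; no diffusion). The mass-action
#'   mode requires `eps_layout = "random"`: with global shuffling only the
#'   amount of EPS matters, so a clustered layout is a configuration error.
#' @param keep_grid Keep the final `"phage_grid"` in the result (default
#'   `FALSE`).
#' @return An object of class `"phage_sim"`: list with `params`, `mode`,
#'   `stats` (per-step data frame: densities `C`, `I`, `D` as patch
#'   fractions, free phage `P`, per-sink losses, bursts, infections, and
#'   EPS-association counts), `summary` (see [summarize_window()]),
#'   `extinct` / `extinction_step`, and optionally `final_grid`.
#' @examples
#' p <- sim_params(width = 15, height = 15, n_steps = 50, avg_window = 20,
#'                 seed = 7)
#' r <- run_spatial(p)
#' r$summary$alpha_b
#' @export
run_spatial <- function(params, mode = c("spatial", "mass_action"),
                        keep_grid = FALSE) {
  mode <- match.arg(mode)
  if (mode == "mass_action" && params$eps_layout != "random")
    stop("mass-action runs require eps_layout = \"random\": with global ",
         "shuffling only the amount of EPS matters, not its arrangement")
  set.seed(params$seed)
  g <- new_grid(params)
  g <- place_eps(g, params)
  g <- init_population(g, params)
  kernel <- if (mode == "spatial" && params$sigma > 0)
    diffusion_kernel(params$sigma) else NULL
  nbr <- neighbor_index(params$height, params$width)
  stat_names <- names(collect_step_stats(g, 0L, c(loss_C = 0, loss_I = 0,
                                                  loss_D = 0, loss_E = 0,
                                                  infections_eps = 0)))
  stats <- matrix(NA_real_, params$n_steps, length(stat_names),
                  dimnames = list(NULL, stat_names))
  extinct <- NA_character_
  ext_step <- NA_integer_
  for (s in seq_len(params$n_steps)) {
    st <- if (mode == "spatial") step_spatial(g, params, kernel, nbr)
          else step_mass_action(g, params, nbr)
    g <- st$grid
    stats[s, ] <- collect_step_stats(g, st$bursts, st$tallies)
    cells_alive <- any(g$occ != OCC_EMPTY)
    phage_alive <- sum(g$phage) > 0L || any(g$occ == OCC_INFECTED)
    if (!cells_alive || !phage_alive) {
      extinct <- if (!cells_alive) "cells" else "phage"
      ext_step <- s
      stats <- stats[seq_len(s), , drop = FALSE]
      break
    }
  }
  res <- list(params = params, mode = mode,
              stats = as.data.frame(stats),
              extinct = !is.na(ext_step), extinct_who = extinct,
              extinction_step = ext_step)
  res$summary <- summarize_window(res$stats, params,
                                  extinct = res$extinct)
  if (keep_grid) res$final_grid <- g
  class(res) <- "phage_sim"
  res
}

#' Run the mass-action grid simulation
#'
#' Convenience wrapper for [run_spatial()] with `mode = "mass_action"`:
#' the same finite-population lattice model and parameters, but after each
#' burst (and before new infections) all free phage are reassigned to
#' uniformly random patches, and after reproduction all live cells are
#' reassigned to distinct random patches; localized diffusion is off.
#'
#' @inheritParams run_spatial
#' @return A `"phage_sim"` object (with `mode = "mass_action"`).
#' @export
run_mass_action <- function(params, keep_grid = FALSE) {
  run_spatial(params, mode = "mass_action", keep_grid = keep_grid)
}

#' @export
print.phage_sim <- function(x, ...) {
  cat(sprintf("phage_sim: %s run, %d x %d grid, b = %d, E = %.2g (%s)\n",
              x$mode, x$params$width, x$params$height, x$params$burst_b,
              x$params$eps_fraction_E, x$params$eps_layout))
  if (x$extinct) {
    cat(sprintf("  EXTINCT (%s) at step %d of %d\n", x$extinct_who,
                x$extinction_step, x$params$n_steps))
  } else {
    s <- x$summary
    cat(sprintf("  %d steps; window means over last %d steps:\n",
                x$params$n_steps, x$params$avg_window))
    cat(sprintf("    C = %.4g  I = %.4g  D = %.4g  P = %.4g\n",
                s$C, s$I, s$D, s$P))
    cat(sprintf("    alpha*b = %.3g", s$alpha_b))
    if (!is.na(s$A_g)) cat(sprintf("  A_g = %.3g (upper bound %.3g)",
                                   s$A_g, s$A_ub_g))
    cat("\n")
  }
  invisible(x)
}

#' @export
summary.phage_sim <- function(object, ...) object$summary

#' Trajectory plot of a simulation run
#'
#' Cell, infected and debris densities (left axis, patch fractions) and the
#' free phage count (right axis) against time.
#'
#' @param x A `"phage_sim"`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.phage_sim <- function(x, ...) {
  s <- x$stats
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(s$step, s$C, type = "l", col = "forestgreen",
                 ylim = c(0, max(s$C, s$I, s$D, na.rm = TRUE)),
                 xlab = "step", ylab = "patch fraction", ...)
  graphics::lines(s$step, s$I, col = "orange")
  if (any(s$D > 0)) graphics::lines(s$step, s$D, col = "grey40")
  graphics::par(new = TRUE)
  graphics::plot(s$step, s$P, type = "l", col = "blue", axes = FALSE,
                 xlab = "", ylab = "")
  graphics::axis(4, col.axis = "blue")
  graphics::mtext("free phage", 4, line = 2.5, col = "blue")
  graphics::legend("topright", bty = "n", lty = 1,
                   col = c("forestgreen", "orange", "blue"),
                   legend = c("uninfected C", "infected I", "phage P"))
  invisible(x)
}
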