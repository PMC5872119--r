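#' Parameters for one grid simulation run
#'
#' Collects and validates the full parameterization of a spatial (or shuffled
#' mass-action) lattice run: grid geometry, burst size, EPS abundance and
#' layout, per-step adsorption probabilities to each sink, cell reproduction
#' probability, phage diffusion, lifespans, run length and seeding.
#'
#' Phage movement may be given either as `diffuse_fraction` -- the fraction of
#' a patch's phage that leaves the patch each step -- or directly as the
#' kernel scale `sigma`; the two are related by a monotone bijection (see
#' [sigma_from_leave_fraction()]). Exactly one of the two may be supplied;
#' the other is derived.
#'
#' @param width,height Grid dimensions in patches. The lattice is a torus:
#'   neighborhoods wrap on both axes, so there are no boundary effects.
#' @param burst_b Burst size: free phage released per lysis (integer >= 1).
#' @param eps_fraction_E Fraction of patches bearing EPS, in \[0, 1\]. The
#'   realized count is exactly `round(E * width * height)` patches.
#' @param eps_layout `"random"` (EPS patches sampled without replacement) or
#'   `"clustered_rows"` (a contiguous band filled row by row from row 0).
#' @param k_C,k_I,k_D,k_E Per-step adsorption probabilities of a free phage to
#'   an uninfected cell, infected cell, debris, and EPS, each in \[0, 1\].
#'   Adsorption to an uninfected cell is a productive infection; the other
#'   three sinks kill the phage.
#' @param cell_repro_prob Per-step probability that an uninfected cell
#'   reproduces (daughter placed in an empty neighboring patch, orthogonal
#'   neighbors preferred).
#' @param diffuse_fraction Per-step fraction of a patch's phage that leaves
#'   the patch; must lie in (0, 8/9) since the 3x3 kernel's leave fraction is
#'   bounded by 8/9. Use 0 for no diffusion.
#' @param sigma Scale of the truncated bivariate-normal diffusion kernel
#'   (alternative to `diffuse_fraction`).
#' @param infected_lifespan Steps from infection to lysis (default 20).
#' @param debris_enabled If `TRUE`, a lysed cell leaves debris that adsorbs
#'   (kills) phage for `debris_lifespan` steps.
#' @param debris_lifespan Steps debris persists after lysis (default 2).
#' @param n_steps Total steps to simulate (default 10000).
#' @param avg_window Trailing steps over which summaries are averaged
#'   (default 3000; must not exceed `n_steps`).
#' @param init_cell_frac,init_phage_frac Initial occupancy: fraction of
#'   patches seeded with one uninfected cell, and fraction seeded with a full
#'   burst (`burst_b`) of free phage. The two samples are independent, so a
#'   patch may receive both.
#' @param seed Integer RNG seed making the run reproducible.
#'
#' @return An object of class `"sim_params"`: a named list with the fields
#'   above plus the derived `sigma`/`diffuse_fraction`.
#' @examples
#' p <- sim_params(width = 20, height = 20, burst_b = 10,
#'                 eps_fraction_E = 0.3, seed = 1)
#' p$sigma
#' @seealso [run_spatial()], [run_mass_action()], [diffusion_kernel()]
#' @export
sim_params <- function(width = 100, height = 100,
                       burst_b = 10,
                       eps_fraction_E = 0.3,
                       eps_layout = c("random", "clustered_rows"),
                       k_C = 0.25, k_I = 0, k_D = 0, k_E = 0.35,
                       cell_repro_prob = 0.1,
                       diffuse_fraction = NULL, sigma = NULL,
                       infected_lifespan = 20,
                       debris_enabled = FALSE, debris_lifespan = 2,
                       n_steps = 10000, avg_window = 3000,
                       init_cell_frac = 0.3, init_phage_frac = 0.3,
                       seed = 1L) {
  eps_layout <- match.arg(eps_layout)
  stopifnot(width >= 1, height >= 1,
            burst_b >= 1, burst_b == as.integer(burst_b),
            infected_lifespan >= 1, debris_lifespan >= 1,
            n_steps >= 1, avg_window >= 1, avg_window <= n_steps)
  for (nm in c("k_C", "k_I", "k_D", "k_E", "cell_repro_prob",
               "eps_fraction_E", "init_cell_frac", "init_phage_frac")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single probability in [0, 1]", nm))
  }
  if (!is.null(diffuse_fraction) && !is.null(sigma))
    stop("supply either 'diffuse_fraction' or 'sigma', not both")
  if (is.null(diffuse_fraction) && is.null(sigma))
    diffuse_fraction <- 0.2
  if (is.null(sigma)) {
    if (diffuse_fraction < 0 || diffuse_fraction >= 8 / 9)
      stop("'diffuse_fraction' must lie in [0, 8/9): the 3x3 kernel cannot ",
           "scatter more than 8/9 of a patch's phage in one step")
    sigma <- if (diffuse_fraction == 0) 0 else
      sigma_from_leave_fraction(diffuse_fraction)
  } else {
    if (sigma < 0) stop("'sigma' must be non-negative")
    diffuse_fraction <- if (sigma == 0) 0 else
      1 - diffusion_kernel(sigma)$w_center
  }
  p <- list(width = as.integer(width), height = as.integer(height),
            burst_b = as.integer(burst_b),
            eps_fraction_E = eps_fraction_E, eps_layout = eps_layout,
            k_C = k_C, k_I = k_I, k_D = k_D, k_E = k_E,
            cell_repro_prob = cell_repro_prob,
            diffuse_fraction = diffuse_fraction, sigma = sigma,
            infected_lifespan = as.integer(infected_lifespan),
            debris_enabled = isTRUE(debris_enabled),
            debris_lifespan = as.integer(debris_lifespan),
            n_steps = as.integer(n_steps), avg_window = as.integer(avg_window),
            init_cell_frac = init_cell_frac, init_phage_frac = init_phage_frac,
            seed = as.integer(seed))
  class(p) <- "sim_params"
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Grid simulation parameters (%d x %d torus)\n", x$width, x$height))
  cat(sprintf("  burst size b = %d; EPS E = %.3g (%s layout)\n",
              x$burst_b, x$eps_fraction_E, x$eps_layout))
  cat(sprintf("  adsorption k_C = %.3g, k_I = %.3g, k_D = %.3g, k_E = %.3g\n",
              x$k_C, x$k_I, x$k_D, x$k_E))
  cat(sprintf("  cell reproduction = %.3g; diffuse fraction = %.4g (sigma = %.4g)\n",
              x$cell_repro_prob, x$diffuse_fraction, x$sigma))
  cat(sprintf("  infected lifespan = %d; debris %s\n", x$infected_lifespan,
              if (x$debris_enabled)
                sprintf("on (lifespan %d, k_D = %.3g)", x$debris_lifespan, x$k_D)
              else "off"))
  cat(sprintf("  %d steps, trailing window %d; init cells %.2g, phage %.2g; seed %d\n",
              x$n_steps, x$avg_window, x$init_cell_frac, x$init_phage_frac,
              x$seed))
  invisible(x)
}

#' Read simulation parameters from a YAML/JSON-style config file
#'
#' The file is a flat key-value mapping whose keys mirror the [sim_params()]
#' argument names. Keys not present fall back to the defaults; `overrides`
#' (a named list, e.g. from a command line) take precedence over the file.
#'
#' @param path Path to a YAML (or JSON, which YAML subsumes) config file.
#' @param overrides Named list of values overriding the file.
#' @return A `"sim_params"` object.
#' @export
read_sim_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must be a mapping of parameter names")
  cfg[names(overrides)] <- overrides
  known <- names(formals(sim_params))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(sim_params, cfg)
}
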