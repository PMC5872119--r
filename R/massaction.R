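# Mass-action counterpart of the spatial grid: identical parameters and
# finite population, but global random relocation abolishes spatial structure.

#' Globally shuffle the free phage
#'
#' Every free phage is independently placed on a uniformly random patch
#' (multinomial allocation); the total count is unchanged exactly.
#'
#' @param grid A `"phage_grid"`.
#' @return The shuffled grid.
#' @export
shuffle_phage <- function(grid) {
  P <- sum(grid$phage)
  N <- length(grid$phage)
  if (P == 0L) return(grid)
  counts <- stats::rmultinom(1L, P, rep.int(1, N))[, 1L]
  grid$phage <- matrix(as.integer(counts), nrow(grid$phage), ncol(grid$phage))
  grid
}

#' Globally shuffle the cells
#'
#' The entire population of live cells (infected and uninfected, with
#' infection ages preserved) is reassigned to a uniform random sample of
#' distinct patches, keeping at most one cell per patch. Debris and EPS stay
#' where they are.
#'
#' @param grid A `"phage_grid"`.
#' @return The shuffled grid.
#' @export
shuffle_cells <- function(grid) {
  live <- which(grid$occ != OCC_EMPTY)
  n <- length(live)
  if (n == 0L) return(grid)
  occ <- grid$occ[live]
  age <- grid$age[live]
  grid$occ[] <- OCC_EMPTY
  grid$age[] <- 0L
  dest <- sample.int(length(grid$occ), n)
  grid$occ[dest] <- occ
  grid$age[dest] <- age
  grid
}

# One step of the mass-action grid: lysis -> phage shuffle (after burst,
# before new infections) -> reproduction -> cell shuffle -> infection.
# No localized diffusion.
step_mass_action <- function(grid, params, nbr) {
  l <- lysis_phase(grid, params)
  g <- shuffle_phage(l$grid)
  g <- reproduction_phase(g, params, nbr)
  g <- shuffle_cells(g)
  inf <- infection_phase(g, params)
  g <- inf$grid
  g$step <- g$step + 1L
  list(grid = g, bursts = l$bursts, tallies = inf$tallies)
}
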