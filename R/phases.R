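# The four global phases of one time step of the spatial model.
# Each phase runs across the whole grid before the next begins.

#' Lysis phase
#'
#' Ages every infected cell by one step, then bursts those whose age has
#' reached `infected_lifespan`: the cell is removed and `burst_b` free phage
#' are added to its patch. When debris is enabled the patch gains (or
#' refreshes) a debris marker with `debris_lifespan` steps remaining; existing
#' debris counters decrement first and expire at zero. A cell infected at
#' step t therefore lyses exactly `infected_lifespan` steps later.
#'
#' @param grid A `"phage_grid"`.
#' @param params A [sim_params()] object.
#' @return List with the updated `grid` and `bursts` (number of lysis events).
#' @export
lysis_phase <- function(grid, params) {
  inf <- grid$occ == OCC_INFECTED
  d <- grid$debris > 0L
  if (any(d)) grid$debris[d] <- grid$debris[d] - 1L
  if (!any(inf)) return(list(grid = grid, bursts = 0L))
  grid$age[inf] <- grid$age[inf] + 1L
  bursting <- inf & grid$age >= params$infected_lifespan
  nb <- sum(bursting)
  if (nb > 0L) {
    grid$phage[bursting] <- grid$phage[bursting] + params$burst_b
    grid$occ[bursting] <- OCC_EMPTY
    grid$age[bursting] <- 0L
    if (params$debris_enabled)
      grid$debris[bursting] <- params$debris_lifespan
  }
  list(grid = grid, bursts = nb)
}

#' Reproduction phase
#'
#' Each uninfected cell independently reproduces with probability
#' `cell_repro_prob`. Eligibility and candidate patches are judged on the
#' pre-phase occupancy snapshot: the daughter goes to a uniformly chosen
#' empty orthogonal neighbor, or, when none is empty, to a uniformly chosen
#' empty diagonal neighbor; a cell whose eight neighbors all hold live cells
#' cannot reproduce. Placements are applied sequentially in random cell order
#' so no two daughters land on the same patch. Cells themselves never move.
#'
#' @inheritParams lysis_phase
#' @param nbr Precomputed neighbor indices (internal; computed if missing).
#' @return The updated grid.
#' @export
reproduction_phase <- function(grid, params, nbr = NULL) {
  if (params$cell_repro_prob <= 0) return(grid)
  un <- which(grid$occ == OCC_UNINFECTED)
  if (!length(un)) return(grid)
  rep_idx <- un[stats::runif(length(un)) < params$cell_repro_prob]
  if (!length(rep_idx)) return(grid)
  if (is.null(nbr)) nbr <- neighbor_index(nrow(grid$occ), ncol(grid$occ))
  snapshot_empty <- grid$occ == OCC_EMPTY  # pre-phase occupancy
  taken <- !snapshot_empty                 # daughters also claim patches
  if (length(rep_idx) > 1L) rep_idx <- sample(rep_idx)
  for (i in rep_idx) {
    nb <- nbr$orth[i, ]
    cand <- nb[snapshot_empty[nb] & !taken[nb]]
    if (!length(cand)) {
      nb <- nbr$diag[i, ]
      cand <- nb[snapshot_empty[nb] & !taken[nb]]
    }
    if (length(cand)) {
      tgt <- if (length(cand) == 1L) cand else
        cand[sample.int(length(cand), 1L)]
      grid$occ[tgt] <- OCC_UNINFECTED
      taken[tgt] <- TRUE
    }
  }
  grid
}

# Per-phage sequential adsorption within one patch. `types` is the character
# vector of entity types present with positive adsorption probability, in
# c("C", "I", "D", "E"). Each phage draws one Bernoulli trial per present
# type in a uniformly random order, stopping at the first success. A success
# against the uninfected cell converts it to infected immediately, so later
# phage in the same patch face k_I instead of k_C.
# Returns c(loss_C, loss_I, loss_D, loss_E, remaining_phage, cell_infected).
adsorb_patch_sequential <- function(n_phage, types, params) {
  loss <- c(C = 0L, I = 0L, D = 0L, E = 0L)
  ks <- c(C = params$k_C, I = params$k_I, D = params$k_D, E = params$k_E)
  infected_now <- FALSE
  remaining <- n_phage
  for (ph in seq_len(n_phage)) {
    nt <- length(types)
    if (nt == 0L) break
    ord <- if (nt == 1L) 1L else sample.int(nt)
    for (j in ord) {
      ty <- types[j]
      if (stats::runif(1L) < ks[[ty]]) {
        loss[[ty]] <- loss[[ty]] + 1L
        remaining <- remaining - 1L
        if (ty == "C") {
          infected_now <- TRUE
          types <- setdiff(types, "C")
          if (params$k_I > 0 && !("I" %in% types)) types <- c(types, "I")
        }
        break
      }
    }
  }
  c(loss, remaining = remaining, infected = as.integer(infected_now))
}

#' Infection phase
#'
#' Within each patch, free phage are processed one at a time. A phage runs
#' one Bernoulli trial per entity type present (uninfected cell `k_C`,
#' infected cell `k_I`, debris `k_D`, EPS `k_E`) in a uniformly random order
#' of the present types, stopping at the first success. Success against an
#' uninfected cell is a productive infection and converts the cell to
#' infected (age 0) immediately, so later phage this step see it as an
#' infected cell; success against an infected cell (superinfection), debris,
#' or EPS removes the phage. A phage that fails every trial stays free until
#' the next step. Patches whose only positive-probability sink is a single
#' killing sink are resolved with one binomial draw, which has exactly the
#' same distribution as the sequential rule.
#'
#' @inheritParams lysis_phase
#' @return List with the updated `grid` and `tallies`: named numeric vector
#'   `loss_C` (productive infections), `loss_I`, `loss_D`, `loss_E`,
#'   `infections_eps` (new infections on EPS-bearing patches).
#' @export
infection_phase <- function(grid, params) {
  tal <- c(loss_C = 0, loss_I = 0, loss_D = 0, loss_E = 0, infections_eps = 0)
  has_ph <- grid$phage > 0L
  if (!any(has_ph)) return(list(grid = grid, tallies = tal))
  kC <- params$k_C; kI <- params$k_I; kD <- params$k_D; kE <- params$k_E
  t_C <- has_ph & grid$occ == OCC_UNINFECTED & kC > 0
  t_I <- has_ph & grid$occ == OCC_INFECTED & kI > 0
  t_D <- has_ph & grid$debris > 0L & kD > 0
  t_E <- has_ph & grid$eps & kE > 0
  n_types <- t_C + t_I + t_D + t_E
  # fast path: exactly one killing sink present, no uninfected cell in play
  for (sink in c("I", "D", "E")) {
    mask <- switch(sink, I = t_I, D = t_D, E = t_E) & n_types == 1L
    idx <- which(mask)
    if (!length(idx)) next
    k <- switch(sink, I = kI, D = kD, E = kE)
    lost <- stats::rbinom(length(idx), grid$phage[idx], k)
    grid$phage[idx] <- grid$phage[idx] - lost
    tal[[paste0("loss_", sink)]] <- tal[[paste0("loss_", sink)]] + sum(lost)
  }
  # general path: uninfected cell present and/or multiple sink types
  gen <- which(n_types > 1L | (t_C & n_types == 1L))
  for (i in gen) {
    types <- c("C", "I", "D", "E")[c(t_C[i], t_I[i], t_D[i], t_E[i])]
    res <- adsorb_patch_sequential(grid$phage[i], types, params)
    grid$phage[i] <- res[["remaining"]]
    if (res[["infected"]] == 1L) {
      grid$occ[i] <- OCC_INFECTED
      grid$age[i] <- 0L
      if (grid$eps[i]) tal[["infections_eps"]] <- tal[["infections_eps"]] + 1
    }
    tal[["loss_C"]] <- tal[["loss_C"]] + res[["C"]]
    tal[["loss_I"]] <- tal[["loss_I"]] + res[["I"]]
    tal[["loss_D"]] <- tal[["loss_D"]] + res[["D"]]
    tal[["loss_E"]] <- tal[["loss_E"]] + res[["E"]]
  }
  list(grid = grid, tallies = tal)
}

#' Diffusion phase
#'
#' Phage diffusion is computed deterministically and synchronously from the
#' pre-phase counts: each patch's real-valued new load is the kernel-weighted
#' sum over its 3x3 torus neighborhood of the source counts. The load is then
#' converted to an integer by stochastic rounding -- `floor(load)` plus one
#' with probability equal to the fractional part -- which is unbiased, so the
#' total phage count is conserved in expectation.
#'
#' @inheritParams lysis_phase
#' @param kernel A [diffusion_kernel()]; `NULL` (e.g. `diffuse_fraction = 0`)
#'   leaves the grid unchanged.
#' @return The updated grid.
#' @export
diffusion_phase <- function(grid, kernel) {
  if (is.null(kernel)) return(grid)
  P <- grid$phage
  if (sum(P) == 0L) return(grid)
  load <- kernel$w_center * P
  for (s in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L)))
    load <- load + kernel$w_orth * shift_mat(P, s[1], s[2])
  for (s in list(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L)))
    load <- load + kernel$w_diag * shift_mat(P, s[1], s[2])
  fl <- floor(load)
  frac <- load - fl
  add <- stats::runif(length(frac)) < frac
  grid$phage <- matrix(as.integer(fl + add), nrow(P), ncol(P))
  grid
}

# One full step of the spatial model: lysis -> reproduction -> infection ->
# diffusion, each phase global. Returns grid plus the step's tallies.
step_spatial <- function(grid, params, kernel, nbr) {
  l <- lysis_phase(grid, params)
  g <- reproduction_phase(l$grid, params, nbr)
  inf <- infection_phase(g, params)
  g <- diffusion_phase(inf$grid, kernel)
  g$step <- g$step + 1L
  list(grid = g, bursts = l$bursts, tallies = inf$tallies)
}

# Per-step global tallies recorded after all phases of a step.
collect_step_stats <- function(grid, bursts, tallies) {
  N <- length(grid$occ)
  un <- grid$occ == OCC_UNINFECTED
  inf <- grid$occ == OCC_INFECTED
  c(step = grid$step,
    C = sum(un) / N, I = sum(inf) / N, D = sum(grid$debris > 0L) / N,
    P = sum(grid$phage),
    loss_C = tallies[["loss_C"]], loss_I = tallies[["loss_I"]],
    loss_D = tallies[["loss_D"]], loss_E = tallies[["loss_E"]],
    bursts = bursts,
    infections_eps = tallies[["infections_eps"]],
    infections_total = tallies[["loss_C"]],
    cells_on_eps = sum(un & grid$eps),
    phage_on_eps = sum(grid$phage[grid$eps]))
}
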