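# Independent oracles used across the test files. These re-derive expected
# behavior by brute force or closed form and must stay independent of the
# package internals they check.

# Numerically integrate the bivariate normal density of scale sigma over the
# nine unit squares of the 3x3 neighborhood and renormalize. Independent
# route to the diffusion kernel weights (which use the factorized CDF form).
oracle_kernel_numeric <- function(sigma) {
  dens <- function(x, y) exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  cellmass <- function(cx, cy)
    pracma::integral2(dens, cx - 0.5, cx + 0.5, cy - 0.5, cy + 0.5,
                      reltol = 1e-10)$Q
  center <- cellmass(0, 0)
  orth <- cellmass(1, 0)
  diag <- cellmass(1, 1)
  tot <- center + 4 * orth + 4 * diag
  list(w_center = center / tot, w_orth = orth / tot, w_diag = diag / tot)
}

# Lag-1 Moran's I over the 8-neighbor torus graph for a count matrix.
moran_i <- function(m) {
  H <- nrow(m); W <- ncol(m)
  z <- m - mean(m)
  num <- 0
  for (s in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))) {
    sh <- m[((seq_len(H) - 1 - s[1]) %% H) + 1,
            ((seq_len(W) - 1 - s[2]) %% W) + 1, drop = FALSE]
    num <- num + sum(z * (sh - mean(m)))
  }
  Wsum <- 8 * H * W
  (H * W / Wsum) * num / sum(z^2)
}

# Brute-force per-phage adsorption simulation for one patch following the
# stated rule directly: each phage tries each present entity type in a
# uniformly random order with one Bernoulli trial per type, stopping at the
# first success; a cell hit flips the cell to infected for later phage.
oracle_adsorb_patch <- function(n_phage, has_cell, has_eps, has_debris,
                                k_C, k_I, k_D, k_E) {
  loss <- c(C = 0L, I = 0L, D = 0L, E = 0L)
  cell_state <- if (has_cell) "uninfected" else "none"
  free <- 0L
  for (ph in seq_len(n_phage)) {
    types <- character(0)
    if (cell_state == "uninfected" && k_C > 0) types <- c(types, "C")
    if (cell_state == "infected" && k_I > 0) types <- c(types, "I")
    if (has_debris && k_D > 0) types <- c(types, "D")
    if (has_eps && k_E > 0) types <- c(types, "E")
    if (length(types) > 1) types <- sample(types)
    hit <- FALSE
    for (ty in types) {
      k <- switch(ty, C = k_C, I = k_I, D = k_D, E = k_E)
      if (runif(1) < k) {
        loss[[ty]] <- loss[[ty]] + 1L
        if (ty == "C") cell_state <- "infected"
        hit <- TRUE
        break
      }
    }
    if (!hit) free <- free + 1L
  }
  c(loss, free = free)
}

# Low-density mean-field (expectation) recursion for the mass-action grid
# with k_I = k_D = 0 and no debris: lysis -> (phage uniform) -> reproduction
# -> (cells uniform) -> infection, ignoring multi-phage saturation and
# daughter-placement collisions (valid when P/N and densities are small).
oracle_mass_action_meanfield <- function(p, steps) {
  N <- p$width * p$height
  E <- p$eps_fraction_E
  u <- round(p$init_cell_frac * N)
  P <- round(p$init_phage_frac * N) * p$burst_b
  iage <- rep(0, p$infected_lifespan)
  # marginal per-phage probabilities in a patch holding a cell and maybe EPS
  kC_eff <- (1 - E) * p$k_C + E * p$k_C * (1 - p$k_E / 2)
  kE_cell <- p$k_E * (1 - p$k_C / 2)
  out <- matrix(NA_real_, steps, 3, dimnames = list(NULL, c("step", "C", "P")))
  for (s in seq_len(steps)) {
    burst <- iage[length(iage)]
    iage <- c(0, iage[-length(iage)])
    P <- P + p$burst_b * burst
    n <- u + sum(iage)
    u <- u + u * p$cell_repro_prob * (1 - (n / N)^8)
    frac_u <- u / N
    # Poisson phage-per-patch saturation: at most one infection per cell
    newinf <- u * (1 - exp(-(P / N) * kC_eff))
    lossE <- P * E * ((1 - frac_u) * p$k_E + frac_u * kE_cell)
    P <- P - newinf - lossE
    u <- u - newinf
    iage[1] <- newinf
    out[s, ] <- c(s, u / N, P)
  }
  as.data.frame(out)
}

# Small helper: spatial/mass-action extinction step on the 3x3 world used by
# the mass-action limit test (capped at n_steps).
ext_step_3x3 <- function(mode, seed, d) {
  p <- sim_params(width = 3, height = 3, burst_b = 4, eps_fraction_E = 0.3,
                  k_C = 0.3, k_E = 0.3, cell_repro_prob = 0.2,
                  diffuse_fraction = d, n_steps = 300, avg_window = 50,
                  init_cell_frac = 0.6, init_phage_frac = 0.3, seed = seed)
  r <- run_spatial(p, mode = mode)
  if (r$extinct) r$extinction_step else 300L
}
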