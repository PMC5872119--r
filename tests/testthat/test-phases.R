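make_world <- function(W = 5, H = 5, ...) {
  args <- list(width = W, height = H, cell_repro_prob = 0,
               eps_fraction_E = 0, init_cell_frac = 0,
               init_phage_frac = 0, seed = 1)
  extra <- list(...)
  if (!("sigma" %in% names(extra))) args$diffuse_fraction <- 0
  p <- do.call(sim_params, c(args, extra))
  list(p = p, g = new_grid(p))
}

test_that("lysis removes cells after exactly the infected lifespan and seeds debris", {
  w <- make_world(burst_b = 6, debris_enabled = TRUE, debris_lifespan = 2,
                  infected_lifespan = 20)
  w$g$occ[3, 3] <- 2L
  w$g$age[3, 3] <- 19L
  out <- lysis_phase(w$g, w$p)
  expect_equal(out$bursts, 1L)
  expect_equal(out$grid$occ[3, 3], 0L)
  expect_equal(out$grid$phage[3, 3], 6L)
  expect_equal(out$grid$debris[3, 3], 2L)
  # debris expires after two further phases
  g <- lysis_phase(out$grid, w$p)$grid
  expect_equal(g$debris[3, 3], 1L)
  g <- lysis_phase(g, w$p)$grid
  expect_equal(g$debris[3, 3], 0L)
  # no infected cells: nothing happens
  w2 <- make_world()
  out2 <- lysis_phase(w2$g, w2$p)
  expect_equal(out2$bursts, 0L)
  expect_identical(out2$grid$occ, w2$g$occ)
  # a younger infected cell just ages
  w3 <- make_world(infected_lifespan = 20)
  w3$g$occ[2, 2] <- 2L
  w3$g$age[2, 2] <- 5L
  out3 <- lysis_phase(w3$g, w3$p)
  expect_equal(out3$bursts, 0L)
  expect_equal(out3$grid$age[2, 2], 6L)
})

test_that("a fresh burst refreshes debris on a debris-bearing patch", {
  w <- make_world(burst_b = 4, debris_enabled = TRUE, debris_lifespan = 2)
  w$g$occ[2, 2] <- 2L
  w$g$age[2, 2] <- 19L
  w$g$debris[2, 2] <- 1L
  g <- lysis_phase(w$g, w$p)$grid
  expect_equal(g$debris[2, 2], 2L)
})

test_that("reproduction respects crowding, probability, and orthogonal preference", {
  # fully surrounded cell never reproduces
  w <- make_world()
  w$p$cell_repro_prob <- 1
  w$g$occ[] <- 1L  # every patch occupied
  set.seed(5)
  g <- reproduction_phase(w$g, w$p)
  expect_identical(g$occ, w$g$occ)

  # zero probability leaves the grid unchanged
  w2 <- make_world()
  w2$g$occ[3, 3] <- 1L
  g2 <- reproduction_phase(w2$g, w2$p)  # cell_repro_prob = 0
  expect_identical(g2$occ, w2$g$occ)

  # lone cell on an empty grid: daughter uniform over the 4 orthogonal
  # neighbors, never diagonal
  w3 <- make_world()
  w3$p$cell_repro_prob <- 1
  w3$g$occ[3, 3] <- 1L
  counts <- integer(4)
  orth <- rbind(c(2, 3), c(4, 3), c(3, 2), c(3, 4))
  set.seed(11)
  n_trials <- 10000
  for (i in seq_len(n_trials)) {
    g <- reproduction_phase(w3$g, w3$p)
    new <- which(g$occ == 1L & (row(g$occ) != 3 | col(g$occ) != 3),
                 arr.ind = FALSE)
    expect_length(new, 1L)
    hit <- which(apply(orth, 1, function(rc)
      g$occ[rc[1], rc[2]] == 1L))
    expect_length(hit, 1L)  # daughter is orthogonal, never diagonal
    counts[hit] <- counts[hit] + 1L
  }
  # binomial 3-sd band around 1/4 for each orthogonal neighbor
  tol <- 3 * sqrt(0.25 * 0.75 / n_trials)
  expect_true(all(abs(counts / n_trials - 0.25) < tol))

  # orthogonal neighbors all occupied: daughter must go diagonal
  w4 <- make_world()
  w4$p$cell_repro_prob <- 1
  w4$g$occ[3, 3] <- 1L
  for (rc in list(c(2, 3), c(4, 3), c(3, 2), c(3, 4)))
    w4$g$occ[rc[1], rc[2]] <- 2L
  set.seed(6)
  g4 <- reproduction_phase(w4$g, w4$p)
  dn <- which(g4$occ == 1L)
  dn <- setdiff(dn, which(row(g4$occ) == 3 & col(g4$occ) == 3))
  expect_length(dn, 1L)
  rc <- c((dn - 1) %% 5 + 1, (dn - 1) %/% 5 + 1)
  expect_true(abs(rc[1] - 3) == 1 && abs(rc[2] - 3) == 1)
})

test_that("two daughters never land on the same patch", {
  # two parents share a single empty patch between them
  w <- make_world(W = 3, H = 3)
  w$p$cell_repro_prob <- 1
  w$g$occ[] <- 2L           # block everything with infected cells
  w$g$occ[2, 1] <- 1L       # two parents
  w$g$occ[2, 3] <- 1L
  w$g$occ[2, 2] <- 0L       # the only empty patch
  for (s in 1:25) {
    set.seed(s)
    g <- reproduction_phase(w$g, w$p)
    expect_equal(sum(g$occ == 1L), 3L)  # exactly one daughter placed
  }
})

test_that("infection follows the first-success rule with immediate conversion", {
  # k_C = 1, k_I = 0: first phage infects, the rest stay free
  w <- make_world(k_C = 1, k_I = 0)
  w$g$occ[2, 2] <- 1L
  w$g$phage[2, 2] <- 5L
  set.seed(3)
  out <- infection_phase(w$g, w$p)
  expect_equal(out$tallies[["loss_C"]], 1)
  expect_equal(out$grid$phage[2, 2], 4L)
  expect_equal(out$grid$occ[2, 2], 2L)
  expect_equal(out$grid$age[2, 2], 0L)

  # no sinks present: no losses at all
  w2 <- make_world()
  w2$g$phage[1, 1] <- 50L
  out2 <- infection_phase(w2$g, w2$p)
  expect_equal(sum(out2$tallies[c("loss_C", "loss_I", "loss_D", "loss_E")]), 0)
  expect_equal(out2$grid$phage[1, 1], 50L)

  # k_C = 0: cells are never infected even with phage on top of them
  w3 <- make_world(k_C = 0, k_E = 0.5)
  w3$g$occ[2, 2] <- 1L
  w3$g$phage[2, 2] <- 100L
  set.seed(4)
  out3 <- infection_phase(w3$g, w3$p)
  expect_equal(out3$grid$occ[2, 2], 1L)
  expect_equal(out3$tallies[["loss_C"]], 0)
})

test_that("EPS-only adsorption matches the binomial oracle", {
  w <- make_world(k_E = 0.35)
  w$g$eps[2, 2] <- TRUE
  w$g$phage[2, 2] <- 10000L
  set.seed(21)
  losses <- replicate(100, {
    out <- infection_phase(w$g, w$p)
    out$tallies[["loss_E"]]
  })
  # per-rep: Binomial(10000, 0.35), mean 3500, sd 47.7
  se <- sqrt(10000 * 0.35 * 0.65) / sqrt(100)
  expect_lt(abs(mean(losses) - 3500), 3 * se)
})

test_that("mixed-sink patches agree with the brute-force sequential oracle", {
  # uninfected cell + EPS in one patch exercises the sequential path
  w <- make_world(k_C = 0.3, k_E = 0.4, k_I = 0.2)
  w$g$eps[2, 2] <- TRUE
  w$g$occ[2, 2] <- 1L
  w$g$phage[2, 2] <- 40L
  set.seed(31)
  impl <- replicate(400, {
    out <- infection_phase(w$g, w$p)
    c(out$tallies[["loss_C"]], out$tallies[["loss_I"]],
      out$tallies[["loss_E"]], out$grid$phage[2, 2])
  })
  set.seed(32)
  orac <- replicate(400, {
    r <- oracle_adsorb_patch(40, has_cell = TRUE, has_eps = TRUE,
                             has_debris = FALSE, k_C = 0.3, k_I = 0.2,
                             k_D = 0, k_E = 0.4)
    c(r[["C"]], r[["I"]], r[["E"]], r[["free"]])
  })
  for (i in 1:4) {
    se <- sqrt(var(impl[i, ]) / 400 + var(orac[i, ]) / 400)
    expect_lt(abs(mean(impl[i, ]) - mean(orac[i, ])), 4 * max(se, 0.01))
  }
})

test_that("diffusion spreads by kernel weights and conserves phage", {
  # point source: expected remaining and orthogonal loads from the kernel
  w <- make_world(W = 9, H = 9, sigma = 1)
  w$g$phage[5, 5] <- 1000L
  kern <- diffusion_kernel(1)
  set.seed(41)
  reps <- replicate(300, {
    g <- diffusion_phase(w$g, kern)
    c(center = g$phage[5, 5], orth = g$phage[4, 5], total = sum(g$phage))
  })
  expect_lt(abs(mean(reps["center", ]) - 1000 * kern$w_center), 0.15)
  expect_lt(abs(mean(reps["orth", ]) - 1000 * kern$w_orth), 0.15)
  # stochastic rounding is unbiased: mean total within 3 binomial sd
  sd_bound <- 0.5 * sqrt(81)  # each patch's rounding Bernoulli has sd <= 0.5
  expect_lt(abs(mean(reps["total", ]) - 1000), 3 * sd_bound / sqrt(300))

  # uniform field is (almost surely) a fixed point of one phase
  wu <- make_world(W = 17, H = 13, sigma = 1)
  wu$g$phage[] <- 7L
  set.seed(42)
  gu <- diffusion_phase(wu$g, kern)
  expect_equal(sum(gu$phage), 7L * 17L * 13L)
  expect_true(all(gu$phage == 7L))
})

test_that("a one-patch world traces the full infection-lysis cycle by hand", {
  # 1x1 world seeded with one cell and a full burst (b = 5) of phage,
  # k_C = 1, k_I = 0, lifespan 20
  fx <- make_fixture("one_patch")
  r <- run_spatial(fx$params)
  s <- r$stats
  # step 1: exactly one phage infects the cell (first-success, k_I = 0),
  # the other four stay free
  expect_equal(s$C[1], 0)
  expect_equal(s$I[1], 1)
  expect_equal(s$P[1], 4)
  expect_equal(s$infections_total[1], 1)
  # latent period: the infected cell is immune to the remaining phage
  expect_true(all(s$bursts[1:20] == 0))
  expect_true(all(s$P[1:20] == 4))
  # step 21: lysis releases b = 5 phage into the now-empty patch
  expect_equal(s$bursts[21], 1)
  expect_equal(s$I[21], 0)
  expect_equal(s$P[21], 9)
  # no cell left: the phage persist (no sinks), cells extinct
  expect_true(r$extinct)
  expect_equal(r$extinct_who, "cells")
})

test_that("identical seed and parameters give bit-identical runs", {
  p <- sim_params(width = 12, height = 12, burst_b = 8, eps_fraction_E = 0.3,
                  n_steps = 120, avg_window = 40, seed = 77)
  r1 <- run_spatial(p)
  r2 <- run_spatial(p)
  expect_identical(r1$stats, r2$stats)
  expect_identical(r1$summary, r2$summary)
  m1 <- run_mass_action(p)
  m2 <- run_mass_action(p)
  expect_identical(m1$stats, m2$stats)
})
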