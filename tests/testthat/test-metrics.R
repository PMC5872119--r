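test_that("alpha is the productive fraction of phage losses", {
  # only cells present: every loss is an infection
  expect_equal(alpha(C = 0.4, k_C = 0.25), 1)
  # equilibrium self-consistency: at C = C-hat, alpha * b = 1
  ch <- c_hat(b = 10, E = 0.9, k_C = 0.25, k_E = 0.35)
  expect_equal(ch, 0.14)
  expect_equal(alpha(C = ch, E = 0.9, k_C = 0.25, k_E = 0.35), 0.1)
  expect_equal(alpha(C = ch, E = 0.9, k_C = 0.25, k_E = 0.35) * 10, 1)
  expect_error(alpha(C = 0, E = 0, k_C = 0.25, k_E = 0.35), "undefined")
})

test_that("alpha is monotone in each density", {
  set.seed(81)
  for (i in 1:50) {
    k <- runif(4, 0.05, 0.9)
    C <- runif(1, 0.05, 0.9); I <- runif(1, 0, 0.5)
    D <- runif(1, 0, 0.5); E <- runif(1, 0.05, 0.9)
    base <- alpha(C, I, D, E, k[1], k[2], k[3], k[4])
    expect_gt(alpha(C + 0.01, I, D, E, k[1], k[2], k[3], k[4]), base)
    expect_lt(alpha(C, I + 0.01, D, E, k[1], k[2], k[3], k[4]), base)
    expect_lt(alpha(C, I, D + 0.01, E, k[1], k[2], k[3], k[4]), base)
    expect_lt(alpha(C, I, D, E + 0.01, k[1], k[2], k[3], k[4]), base)
  }
})

test_that("C-hat has the closed form and scaling of the equilibrium density", {
  expect_equal(c_hat(b = 2, E = 0.1, k_C = 0.25, k_E = 0.35), 0.14)
  expect_equal(c_hat(b = 2, E = 0, k_C = 0.25, k_E = 0.35), 0)
  # doubling (b - 1) halves C-hat
  expect_equal(c_hat(b = 3, E = 0.1, k_C = 0.25, k_E = 0.35),
               c_hat(b = 2, E = 0.1, k_C = 0.25, k_E = 0.35) / 2)
  expect_error(c_hat(b = 1, E = 0.1, k_C = 0.25, k_E = 0.35), "b > 1")
  # generalized form needs observed I and D
  expect_error(c_hat(b = 2, E = 0.1, k_C = 0.25, k_E = 0.35, k_I = 0.2),
               "supply observed")
  expect_equal(c_hat(b = 2, E = 0.1, k_C = 0.25, k_E = 0.35,
                     k_I = 0.2, k_D = 0.1, I = 0.1, D = 0.05),
               (0.2 * 0.1 + 0.1 * 0.05 + 0.035) / 0.25)
})

test_that("grid amplification and its upper bound behave as defined", {
  a <- amplification_grid(0.14, b = 2, E = 0.1, k_C = 0.25, k_E = 0.35)
  expect_equal(a$A_g, 1)  # observed density at the equilibrium
  expect_equal(a$A_ub_g, 1 / a$c_hat)
  # A_g * C-hat recovers the observed density exactly
  a2 <- amplification_grid(0.37, b = 10, E = 0.6, k_C = 0.25, k_E = 0.35)
  expect_equal(a2$A_g * a2$c_hat, 0.37)
  expect_lte(a2$A_g, a2$A_ub_g)
  expect_error(amplification_grid(0.3, b = 10, E = 0.6, k_C = 0.25,
                                  k_E = 0.35, k_I = 0.2), "alpha")
})

test_that("alpha*b from A_g agrees with the direct computation at any instant", {
  set.seed(82)
  for (i in 1:50) {
    b <- sample(2:60, 1)
    E <- runif(1, 0.05, 0.95); k_C <- runif(1, 0.05, 0.95)
    k_E <- runif(1, 0.05, 0.95); C <- runif(1, 0.001, 0.95)
    ch <- c_hat(b, E, k_C, k_E)
    direct <- alpha(C, E = E, k_C = k_C, k_E = k_E) * b
    via_Ag <- alpha_b_from_Ag(C / ch, b)
    expect_equal(via_Ag, direct, tolerance = 1e-12)
  }
  expect_equal(alpha_b_from_Ag(1, 7), 1)  # A_g = 1 gives alpha*b = 1
})

test_that("window summaries average constant series exactly", {
  p <- sim_params(width = 10, height = 10, burst_b = 10,
                  eps_fraction_E = 0.3, n_steps = 10, avg_window = 5,
                  seed = 1)
  n_eps_cells <- 6; n_cells <- 20; n_ph <- 200; ph_eps <- 30
  stats <- data.frame(step = 1:10, C = n_cells / 100, I = 0.05, D = 0,
                      P = n_ph, loss_C = 4, loss_I = 0, loss_D = 0,
                      loss_E = 16, bursts = 2, infections_eps = 3,
                      infections_total = 4, cells_on_eps = n_eps_cells,
                      phage_on_eps = ph_eps)
  s <- summarize_window(stats, p)
  expect_equal(s$C, 0.2)
  expect_equal(s$C_E, 6 / 20)
  expect_equal(s$P_E, 30 / 200)
  expect_equal(s$I_E, 3 / 4)
  expect_equal(s$P_to_C, 4 / 2)
  expect_equal(s$P_to_E, 16 / 2)
  expect_equal(s$alpha_b_q10, s$alpha_b_q90)  # constant series has no spread
  expect_equal(s$alpha_b, s$alpha_b_of_means)
  # alpha*b consistent with the direct formula on the window means
  expect_equal(s$alpha_b,
               alpha(0.2, 0.05, 0, 0.3, 0.25, 0, 0, 0.35) * 10)
  # A_g consistency: A_g * C-hat = mean C
  expect_equal(s$A_g * c_hat(10, 0.3, 0.25, 0.35), s$C)
})

test_that("every association fraction is 1 when all patches bear EPS", {
  p <- sim_params(width = 5, height = 5, burst_b = 5, eps_fraction_E = 1,
                  n_steps = 4, avg_window = 2, seed = 1)
  stats <- data.frame(step = 1:4, C = 0.2, I = 0, D = 0, P = 50,
                      loss_C = 1, loss_I = 0, loss_D = 0, loss_E = 5,
                      bursts = 1, infections_eps = 1, infections_total = 1,
                      cells_on_eps = 5, phage_on_eps = 50)
  s <- summarize_window(stats, p)
  expect_equal(s$C_E, 1)
  expect_equal(s$P_E, 1)
  expect_equal(s$I_E, 1)
})

test_that("summaries flag missing per-burst losses when no bursts occurred", {
  p <- sim_params(width = 5, height = 5, n_steps = 4, avg_window = 2,
                  seed = 1)
  stats <- data.frame(step = 1:4, C = 0.2, I = 0, D = 0, P = 10,
                      loss_C = 0, loss_I = 0, loss_D = 0, loss_E = 1,
                      bursts = 0, infections_eps = 0, infections_total = 0,
                      cells_on_eps = 1, phage_on_eps = 1)
  s <- summarize_window(stats, p)
  expect_true(is.na(s$P_to_E))
})

test_that("ensembles average survivors and report extinctions separately", {
  p <- sim_params(width = 5, height = 5, n_steps = 4, avg_window = 2,
                  seed = 1)
  mk <- function(ab, extinct = FALSE) {
    stats <- data.frame(step = 1:4, C = ab / 10, I = 0, D = 0, P = 10,
                        loss_C = 1, loss_I = 0, loss_D = 0, loss_E = 1,
                        bursts = 1, infections_eps = 0, infections_total = 1,
                        cells_on_eps = 0, phage_on_eps = 0)
    summarize_window(stats, p, extinct = extinct)
  }
  # 5 extinct, 10 surviving: means over the 10 survivors only
  runs <- c(lapply(1:10, function(i) mk(2)), lapply(1:5, function(i)
    mk(9, extinct = TRUE)))
  e <- summarize_ensemble(runs)
  expect_equal(e$n_runs, 15)
  expect_equal(e$n_extinct, 5)
  expect_equal(e$C, 0.2)
  # identical runs: mean equals the value, zero range
  e2 <- summarize_ensemble(lapply(1:3, function(i) mk(2)))
  expect_equal(e2$C, 0.2)
  expect_true(is.na(e2$max_range_pct) || e2$max_range_pct == 0)
  # all extinct: NA row with the count
  e3 <- summarize_ensemble(lapply(1:15, function(i) mk(2, extinct = TRUE)))
  expect_equal(e3$n_extinct, 15)
  expect_true(is.na(e3$alpha_b))
})
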