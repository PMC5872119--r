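# Occupant codes used in the occupancy matrix
OCC_EMPTY <- 0L
OCC_UNINFECTED <- 1L
OCC_INFECTED <- 2L

#' Create an empty grid world
#'
#' Builds the torus lattice of patches for a run: per-patch EPS flag,
#' occupant (empty / uninfected / infected with age), debris countdown and
#' free-phage count, all stored as `height x width` matrices (row = y,
#' column = x). Use [place_eps()] and [init_population()] to populate it.
#'
#' @param params A [sim_params()] object.
#' @return An object of class `"phage_grid"`.
#' @export
new_grid <- function(params) {
  H <- params$height; W <- params$width
  structure(list(eps = matrix(FALSE, H, W),
                 occ = matrix(OCC_EMPTY, H, W),
                 age = matrix(0L, H, W),
                 debris = matrix(0L, H, W),
                 phage = matrix(0L, H, W),
                 step = 0L),
            class = "phage_grid")
}

#' Assign EPS to patches
#'
#' Flags exactly `round(E * width * height)` patches as bearing EPS. With the
#' `"random"` layout the patches are sampled without replacement, so the
#' realized EPS fraction is exact and identical across seeds. With
#' `"clustered_rows"` whole rows are filled from row 0 upward until the
#' allotment is reached (final partial row filled left to right), producing a
#' single contiguous band; on a torus the band's position is immaterial.
#' EPS is immutable for the life of the run.
#'
#' @param grid A fresh `"phage_grid"` with no EPS assigned.
#' @param params A [sim_params()] object (`eps_fraction_E`, `eps_layout`).
#' @return The grid with EPS assigned.
#' @export
place_eps <- function(grid, params) {
  E <- params$eps_fraction_E
  if (E < 0 || E > 1) stop("EPS fraction must be in [0, 1]")
  if (any(grid$eps)) stop("grid already has EPS assigned")
  N <- length(grid$eps)
  n_eps <- round(E * N)
  if (n_eps == 0) return(grid)
  if (params$eps_layout == "random") {
    grid$eps[sample.int(N, n_eps)] <- TRUE
  } else {
    # fill rows 0, 1, ... (matrix rows) until the allotment is reached
    W <- ncol(grid$eps)
    full_rows <- n_eps %/% W
    if (full_rows > 0) grid$eps[seq_len(full_rows), ] <- TRUE
    rem <- n_eps - full_rows * W
    if (rem > 0) grid$eps[full_rows + 1L, seq_len(rem)] <- TRUE
  }
  grid
}

#' Seed the initial cell and phage populations
#'
#' Places one uninfected cell on `init_cell_frac` of the patches (sampled
#' without replacement) and a full burst (`burst_b` free phage) on an
#' independently sampled `init_phage_frac` of the patches. Because the two
#' samples are independent, a patch may receive both a cell and phage.
#'
#' @param grid A `"phage_grid"` (EPS already placed).
#' @param params A [sim_params()] object.
#' @return The seeded grid.
#' @export
init_population <- function(grid, params) {
  N <- length(grid$occ)
  n_cell <- round(params$init_cell_frac * N)
  n_ph <- round(params$init_phage_frac * N)
  if (n_cell > 0) grid$occ[sample.int(N, n_cell)] <- OCC_UNINFECTED
  if (n_ph > 0) grid$phage[sample.int(N, n_ph)] <- params$burst_b
  grid
}

# Precompute torus neighbor linear indices: rows = patch, cols = 4 orthogonal
# or 4 diagonal neighbors. Matrices are H x W column-major.
neighbor_index <- function(H, W) {
  N <- H * W
  idx <- seq_len(N) - 1L
  y <- idx %% H          # 0-based row
  x <- idx %/% H         # 0-based column
  at <- function(dy, dx) ((x + dx) %% W) * H + ((y + dy) %% H) + 1L
  list(orth = cbind(at(-1L, 0L), at(1L, 0L), at(0L, -1L), at(0L, 1L)),
       diag = cbind(at(-1L, -1L), at(-1L, 1L), at(1L, -1L), at(1L, 1L)))
}

# Torus-shift a matrix: result[y, x] = m[y - dy, x - dx] (wrapping)
shift_mat <- function(m, dy, dx) {
  H <- nrow(m); W <- ncol(m)
  m[((seq_len(H) - 1L - dy) %% H) + 1L, ((seq_len(W) - 1L - dx) %% W) + 1L,
    drop = FALSE]
}

#' @export
print.phage_grid <- function(x, ...) {
  cat(sprintf("phage_grid %d x %d (step %d)\n", ncol(x$occ), nrow(x$occ),
              x$step))
  cat(sprintf("  uninfected %d | infected %d | debris %d | free phage %d | EPS patches %d\n",
              sum(x$occ == OCC_UNINFECTED), sum(x$occ == OCC_INFECTED),
              sum(x$debris > 0L), sum(x$phage), sum(x$eps)))
  invisible(x)
}

#' Per-patch data frame view of a grid
#'
#' @param x A `"phage_grid"`.
#' @param ... Unused.
#' @return A data frame with 0-based row-major coordinates and columns
#'   `x`, `y`, `eps`, `occupant` (`"empty"`, `"uninfected"`, `"infected"`),
#'   `infected_age`, `debris_remaining`, `phage`.
#' @export
as.data.frame.phage_grid <- function(x, ...) {
  H <- nrow(x$occ); W <- ncol(x$occ)
  # row-major: iterate y (rows) outer, x (cols) inner
  xs <- rep(0:(W - 1L), times = H)
  ys <- rep(0:(H - 1L), each = W)
  li <- xs * H + ys + 1L  # linear index into column-major matrices
  data.frame(x = xs, y = ys,
             eps = as.integer(x$eps[li]),
             occupant = c("empty", "uninfected", "infected")[x$occ[li] + 1L],
             infected_age = x$age[li],
             debris_remaining = x$debris[li],
             phage = x$phage[li])
}

#' Write / read a grid snapshot as CSV
#'
#' The per-patch CSV uses 0-based row-major coordinates and the column
#' layout of [as.data.frame.phage_grid()]. The round trip is lossless.
#'
#' @param grid A `"phage_grid"`.
#' @param path File path.
#' @return `write_grid_csv()` returns `path` invisibly; `read_grid_csv()`
#'   returns a `"phage_grid"`.
#' @export
write_grid_csv <- function(grid, path) {
  utils::write.csv(as.data.frame(grid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @export
read_grid_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "eps", "occupant", "infected_age", "debris_remaining",
            "phage")
  if (!all(need %in% names(df))) stop("not a grid snapshot CSV")
  W <- max(df$x) + 1L; H <- max(df$y) + 1L
  if (nrow(df) != W * H) stop("grid CSV is not a complete lattice")
  li <- df$x * H + df$y + 1L
  g <- structure(list(eps = matrix(FALSE, H, W), occ = matrix(0L, H, W),
                      age = matrix(0L, H, W), debris = matrix(0L, H, W),
                      phage = matrix(0L, H, W), step = 0L),
                 class = "phage_grid")
  g$eps[li] <- df$eps == 1
  g$occ[li] <- match(df$occupant, c("empty", "uninfected", "infected")) - 1L
  g$age[li] <- as.integer(df$infected_age)
  g$debris[li] <- as.integer(df$debris_remaining)
  g$phage[li] <- as.integer(df$phage)
  g
}

#' Occupancy map of a grid
#'
#' Image plot of the lattice: EPS shading in the background, cells and
#' free-phage presence overlaid, in the style of a biofilm snapshot.
#'
#' @param x A `"phage_grid"`.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.phage_grid <- function(x, ...) {
  H <- nrow(x$occ); W <- ncol(x$occ)
  graphics::image(0:(W), 0:(H), t(ifelse(x$eps, 1, 0)),
                  col = c("lemonchiffon", "grey90"), useRaster = TRUE,
                  xlab = "x", ylab = "y", ...)
  ph <- which(x$phage > 0L, arr.ind = TRUE)
  if (nrow(ph)) graphics::points(ph[, 2] - 0.5, ph[, 1] - 0.5, pch = ".",
                                 col = "blue", cex = 2)
  un <- which(x$occ == OCC_UNINFECTED, arr.ind = TRUE)
  if (nrow(un)) graphics::points(un[, 2] - 0.5, un[, 1] - 0.5, pch = 15,
                                 col = "forestgreen", cex = 0.5)
  inf <- which(x$occ == OCC_INFECTED, arr.ind = TRUE)
  if (nrow(inf)) graphics::points(inf[, 2] - 0.5, inf[, 1] - 0.5, pch = 15,
                                  col = "orange", cex = 0.5)
  invisible(x)
}

#' Deterministic tiny test worlds
#'
#' Named fixtures for tests and worked examples:
#' \describe{
#'   \item{`one_patch`}{1x1 world, all interactions forced into one patch.}
#'   \item{`cross`}{3x3 world, a single uninfected cell at the center and a
#'     single phage in a corner.}
#'   \item{`band`}{10x10 world with a 3-row clustered EPS band (rows 0-2).}
#'   \item{`stationary`}{20x20 clustered-EPS world burned in for 500 steps so
#'     the window statistics start near stationarity.}
#' }
#'
#' @param name Fixture name.
#' @param seed Seed used for the fixture's own randomness (default 42).
#' @return A list with elements `params` (a `"sim_params"`) and `grid`
#'   (a `"phage_grid"`).
#' @export
make_fixture <- function(name = c("one_patch", "cross", "band", "stationary"),
                         seed = 42L) {
  name <- match.arg(name)
  switch(name,
    one_patch = {
      p <- sim_params(width = 1, height = 1, burst_b = 5, eps_fraction_E = 0,
                      k_C = 1, k_E = 0, cell_repro_prob = 0,
                      diffuse_fraction = 0, n_steps = 30, avg_window = 1,
                      init_cell_frac = 1, init_phage_frac = 1, seed = seed)
      g <- new_grid(p)
      g$occ[1, 1] <- OCC_UNINFECTED
      g$phage[1, 1] <- 1L
      list(params = p, grid = g)
    },
    cross = {
      p <- sim_params(width = 3, height = 3, burst_b = 5, eps_fraction_E = 0,
                      k_C = 1, k_E = 0, cell_repro_prob = 0,
                      diffuse_fraction = 0.5, n_steps = 100, avg_window = 10,
                      init_cell_frac = 0, init_phage_frac = 0, seed = seed)
      g <- new_grid(p)
      g$occ[2, 2] <- OCC_UNINFECTED
      g$phage[1, 1] <- 1L
      list(params = p, grid = g)
    },
    band = {
      p <- sim_params(width = 10, height = 10, burst_b = 10,
                      eps_fraction_E = 0.3, eps_layout = "clustered_rows",
                      n_steps = 500, avg_window = 100, seed = seed)
      g <- place_eps(new_grid(p), p)
      set.seed(seed)
      g <- init_population(g, p)
      list(params = p, grid = g)
    },
    stationary = {
      p <- sim_params(width = 20, height = 20, burst_b = 10,
                      eps_fraction_E = 0.3, eps_layout = "clustered_rows",
                      n_steps = 500, avg_window = 100, seed = seed)
      r <- run_spatial(p, keep_grid = TRUE)
      list(params = p, grid = r$final_grid)
    })
}
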