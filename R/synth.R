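#' Build a per-cell event-probability matrix
#'
#' The generator's central object: a matrix `P` the same shape as a grid,
#' giving each cell an independent per-step probability of emitting an
#' event. Entries are drawn from a named family and rescaled so the maximum
#' entry equals `p_max`; the family controls how skewed event generation is
#' across cells (uniform = spatially homogeneous activity, power-law = a few
#' dominant cells, exponential = in between).
#'
#' @param nx,ny Grid shape (columns, rows).
#' @param kind `"uniform"`, `"powerlaw"` or `"exponential"`.
#' @param p_max Maximum per-step emission probability (default 0.1).
#' @param exponent Tail exponent of the power-law family (default 2.5).
#' @param rate Rate of the exponential family (default 1).
#' @param seed Optional integer seed.
#' @return A `ny x nx` numeric matrix with entries in `[0, p_max]`, row
#'   `iy + 1`, column `ix + 1` matching the 0-based row-major cell ids of a
#'   matching [rect_grid()].
#' @export
make_probability_matrix <- function(nx, ny,
                                    kind = c("uniform", "powerlaw",
                                             "exponential"),
                                    p_max = 0.1, exponent = 2.5, rate = 1,
                                    seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  n <- nx * ny
  raw <- switch(kind,
    uniform = stats::runif(n),
    # Pareto tail via inverse CDF; heavy imbalance across cells
    powerlaw = (1 - stats::runif(n))^(-1 / (exponent - 1)),
    exponential = stats::rexp(n, rate = rate))
  p <- raw / max(raw) * p_max
  matrix(p, nrow = ny, ncol = nx, byrow = TRUE)
}

#' Generate events from a probability matrix
#'
#' At every time step `t = 1..T`, each grid cell independently emits an
#' event with its probability `P_ij`; an emitted event is placed uniformly
#' at random inside its cell and stamped `t`. Several cells may fire in the
#' same step, so the output generally contains parallel (same-timestamp)
#' events, which [build_chronnet()] handles through its combination rule.
#'
#' @param P Probability matrix from [make_probability_matrix()] (rows = y,
#'   columns = x; all entries in `[0, 1]`).
#' @param T_steps Number of time steps (>= 1).
#' @param grid Optional `rect_grid` fixing the coordinate frame; defaults to
#'   the unit-cell grid `[0, nx] x [0, ny]`.
#' @param seed Optional integer seed (same seed, same events).
#' @return An `event_table`, time-sorted, with events ordered by cell id
#'   within each step.
#' @export
generate_from_matrix <- function(P, T_steps, grid = NULL, seed = NULL) {
  if (any(P < 0 | P > 1)) stop("probabilities must lie in [0, 1]")
  T_steps <- as.integer(T_steps)
  if (T_steps < 1L) stop("T_steps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  ny <- nrow(P); nx <- ncol(P)
  if (is.null(grid)) grid <- rect_grid(0, nx, 0, ny, nx, ny)
  w <- (grid$x_max - grid$x_min) / grid$nx
  h <- (grid$y_max - grid$y_min) / grid$ny
  # cell order: row-major ids 0..nx*ny-1 (iy*nx + ix)
  pvec <- as.vector(t(P))
  ncell <- nx * ny
  fires <- which(matrix(stats::runif(ncell * T_steps), nrow = ncell) < pvec,
                 arr.ind = TRUE)
  if (!nrow(fires)) {
    return(event_table(numeric(), numeric(), numeric()))
  }
  ord <- order(fires[, 2L], fires[, 1L])     # by time step, then cell id
  cell <- fires[ord, 1L] - 1L
  t <- fires[ord, 2L]
  ix <- cell %% nx; iy <- cell %/% nx
  x <- grid$x_min + (ix + stats::runif(length(cell))) * w
  y <- grid$y_min + (iy + stats::runif(length(cell))) * h
  event_table(x, y, t)
}

#' Four-period regime scenario with sparse outliers
#'
#' Emulates a data set whose active region moves through four spatial blocks
#' in four equal time intervals: during interval `q`, the cells of quadrant
#' `q` of the grid emit with probability `p_in` per step while every other
#' cell emits with the tiny background probability `p_out`, producing a few
#' outlier events outside the active region. The planted label of an event
#' is its interval index (1–4), the ground truth for event clustering.
#'
#' Defaults (20 x 20 grid, `T_steps = 12000`, `p_in = 0.02`,
#' `p_out = 1e-5`) give four well-separated temporal clusters of roughly
#' 6000 events each plus tens of outliers. Quadrants are numbered 1 =
#' lower-left, 2 = lower-right, 3 = upper-left, 4 = upper-right.
#'
#' @param nx,ny Grid shape (even numbers; default 20 x 20).
#' @param T_steps Total number of steps, divisible by 4 (default 12000).
#' @param p_in Per-step emission probability inside the active quadrant.
#' @param p_out Background per-step probability elsewhere.
#' @param seed Optional integer seed.
#' @return A list: `events` (`event_table`), `labels` (planted interval per
#'   event), `grid` (the `rect_grid`), `period_of_cell` (quadrant index per
#'   cell id).
#' @export
four_period_scenario <- function(nx = 20L, ny = 20L, T_steps = 12000L,
                                 p_in = 0.02, p_out = 1e-5, seed = NULL) {
  T_steps <- as.integer(T_steps)
  if (T_steps %% 4L != 0L) stop("T_steps must be divisible by 4")
  if (nx %% 2L || ny %% 2L) stop("nx and ny must be even (quadrant blocks)")
  if (!is.null(seed)) set.seed(seed)
  grid <- rect_grid(0, nx, 0, ny, nx, ny)
  ids <- 0:(nx * ny - 1L)
  ix <- ids %% nx; iy <- ids %/% nx
  quadrant <- 1L + (ix >= nx / 2) + 2L * (iy >= ny / 2)
  len <- T_steps %/% 4L
  parts <- lapply(1:4, function(q) {
    P <- matrix(p_out, nrow = ny, ncol = nx)
    P[matrix(c(iy[quadrant == q] + 1L, ix[quadrant == q] + 1L), ncol = 2)] <- p_in
    ev <- generate_from_matrix(P, len, grid = grid)
    ev$t <- ev$t + (q - 1L) * len
    ev
  })
  events <- as_event_table(do.call(rbind, lapply(parts, as.data.frame)))
  labels <- rep(1:4, times = vapply(parts, nrow, 0L))
  list(events = events, labels = labels, grid = grid,
       period_of_cell = quadrant)
}

#' Alternating Gaussian burst scenario
#'
#' Events arrive in bursts that cycle through a set of spatial centers: each
#' burst emits `events_per_burst` points drawn from an isotropic Gaussian
#' around its center, stamped with consecutive integer timestamps across the
#' whole record. With two or three centers this plants as many
#' spatiotemporal clusters, with regime changes exactly at the burst
#' boundaries.
#'
#' The default coordinate domain is `[0, 1000]^2` — against a 10 x 10 grid a
#' spread of `sigma = 100` then straddles a few cells per center. Centers
#' should sit at least ~8 standard deviations apart so the planted clusters
#' barely overlap (the defaults are 8.5 sigma apart); with closer centers a
#' non-negligible share of events falls into cells dominated by a
#' neighbouring cluster and the planted labels stop being clean ground
#' truth. `gaussian_centers()` returns well-separated default layouts.
#'
#' @param centers Matrix or data.frame of center coordinates (one row per
#'   center, columns x, y); at least 2. Defaults to two diagonal centers at
#'   (200, 200) and (800, 800).
#' @param sigma Isotropic Gaussian spread, coordinate units (> 0).
#' @param n_bursts Number of bursts (cycled through the centers in order).
#' @param events_per_burst Events per burst (default 25000).
#' @param seed Optional integer seed.
#' @return A list: `events` (`event_table`), `labels` (center index per
#'   event), `boundaries` (1-based event index at which each new burst
#'   starts, excluding the first), `centers`.
#' @export
alternating_gaussians <- function(centers = gaussian_centers(2),
                                  sigma = 100, n_bursts = 40L,
                                  events_per_burst = 25000L, seed = NULL) {
  centers <- as.matrix(centers)
  if (nrow(centers) < 2L) stop("need at least 2 centers")
  if (sigma <= 0) stop("sigma must be positive")
  if (!is.null(seed)) set.seed(seed)
  burst_center <- rep_len(seq_len(nrow(centers)), n_bursts)
  n <- n_bursts * events_per_burst
  lab <- rep(burst_center, each = events_per_burst)
  x <- stats::rnorm(n, mean = centers[lab, 1L], sd = sigma)
  y <- stats::rnorm(n, mean = centers[lab, 2L], sd = sigma)
  list(events = event_table(x, y, seq_len(n)),
       labels = lab,
       boundaries = (seq_len(n_bursts - 1L)) * events_per_burst + 1L,
       centers = centers)
}

#' @rdname alternating_gaussians
#' @param k Number of centers (2 or 3).
#' @export
gaussian_centers <- function(k) {
  switch(as.character(k),
         "2" = rbind(c(200, 200), c(800, 800)),
         "3" = rbind(c(100, 100), c(900, 100), c(500, 900)),
         stop("built-in layouts exist for 2 or 3 centers"))
}

#' Sample a chaotic trajectory as an event stream
#'
#' Integrates the Lorenz or Roessler equations with a fixed-step
#' fourth-order Runge-Kutta scheme, discards a transient, and emits the
#' projection of the trajectory onto two axes as events with consecutive
#' integer timestamps — a deterministic event stream whose chronnet inherits
#' the attractor's geometry. Parameter defaults are the classical chaotic
#' regimes: Lorenz `sigma = 10, beta = 8/3, rho = 28` (projection x, y;
#' duration 200, step 0.01); Roessler `a = 0.2, b = 0.2, c = 5.7`
#' (projection x, z; duration 1000, step 0.02).
#'
#' @param system `"lorenz"` or `"rossler"`.
#' @param params Named list overriding the system parameters.
#' @param duration Integration horizon in model time units (default: 200
#'   for Lorenz, 1000 for Roessler).
#' @param dt Fixed integration/sampling step (default: 0.01 Lorenz, 0.02
#'   Roessler).
#' @param projection Length-2 character vector of state variables to emit as
#'   (x, y) event coordinates (default: `c("x","y")` Lorenz,
#'   `c("x","z")` Roessler).
#' @param init Initial state (length 3); defaults `(1, 1, 1)` for Lorenz and
#'   `(1, 1, 0)` for Roessler. The attractor shape is insensitive to it once
#'   the transient is discarded.
#' @param burn_in Transient discarded before sampling, in time units
#'   (default 10).
#' @param seed Optional seed; when given, the initial condition is jittered
#'   uniformly in `[-0.5, 0.5]^3` so different seeds sample different
#'   stretches of the attractor.
#' @return An `event_table` with `T = duration / dt` events, timestamps
#'   `1, 2, ...`.
#' @export
sample_trajectory <- function(system = c("lorenz", "rossler"),
                              params = list(), duration = NULL, dt = NULL,
                              projection = NULL, init = NULL, burn_in = 10,
                              seed = NULL) {
  system <- match.arg(system)
  defs <- switch(system,
    lorenz = list(params = list(sigma = 10, beta = 8 / 3, rho = 28),
                  duration = 200, dt = 0.01, projection = c("x", "y"),
                  init = c(x = 1, y = 1, z = 1)),
    rossler = list(params = list(a = 0.2, b = 0.2, c = 5.7),
                   duration = 1000, dt = 0.02, projection = c("x", "z"),
                   init = c(x = 1, y = 1, z = 0)))
  p <- utils::modifyList(defs$params, params)
  duration <- duration %||% defs$duration
  dt <- dt %||% defs$dt
  projection <- projection %||% defs$projection
  init <- init %||% defs$init
  names(init) <- c("x", "y", "z")
  if (dt <= 0) stop("dt must be positive")
  if (!all(projection %in% c("x", "y", "z")) || length(projection) != 2L) {
    stop("projection must name two of x, y, z")
  }
  if (!is.null(seed)) {
    set.seed(seed)
    init <- init + stats::runif(3, -0.5, 0.5)
  }
  deriv <- switch(system,
    lorenz = function(t, s, pr) {
      list(c(pr$sigma * (s["y"] - s["x"]),
             s["x"] * (pr$rho - s["z"]) - s["y"],
             s["x"] * s["y"] - pr$beta * s["z"]))
    },
    rossler = function(t, s, pr) {
      list(c(-s["y"] - s["z"],
             s["x"] + pr$a * s["y"],
             pr$b + s["z"] * (s["x"] - pr$c)))
    })
  times <- seq(0, burn_in + duration, by = dt)
  sol <- deSolve::rk4(y = init, times = times, func = deriv, parms = p)
  keep <- sol[, "time"] > burn_in + 1e-12
  traj <- sol[keep, , drop = FALSE]
  n <- min(nrow(traj), round(duration / dt))
  traj <- traj[seq_len(n), , drop = FALSE]
  event_table(traj[, projection[1L]], traj[, projection[2L]], seq_len(n))
}
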