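#' Swarm configuration
#'
#' Parameters of the particle swarm: population 20, 50 iterations, inertia
#' 0.8, velocity clamp 6, and the canonical acceleration factors
#' `c1 = c2 = 2`. Velocities are clamped symmetrically to `[-vmax, vmax]`
#' per dimension.
#'
#' @param population Number of particles.
#' @param iterations Number of iterations; termination is iteration-count
#'   only.
#' @param inertia Inertia weight applied to the previous velocity.
#' @param c1,c2 Cognitive (pbest) and social (gbest) acceleration factors.
#' @param vmax Per-dimension velocity clamp.
#' @param rand_per_dimension Draw `rand1`/`rand2` independently per dimension
#'   (default) or once per particle per update.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(population = 20, iterations = 50, inertia = 0.8,
                         c1 = 2, c2 = 2, vmax = 6,
                         rand_per_dimension = TRUE) {
  stopifnot(population >= 1, iterations >= 1, vmax > 0)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2, vmax = vmax,
                 rand_per_dimension = isTRUE(rand_per_dimension)),
            class = "swarm_config")
}

#' Design window for one amplicon
#'
#' The interval of admissible forward-primer start positions for the next
#' amplicon. Coordinates are "unwrapped": on a circular template they may
#' exceed the template length and are reduced modulo its length at decode
#' time, so a window sliding through the origin stays a plain interval.
#'
#' @param fs_min,fs_max First and last admissible forward start (inclusive).
#' @return An object of class `design_window`.
#' @export
design_window <- function(fs_min, fs_max) {
  fs_min <- as.integer(fs_min); fs_max <- as.integer(fs_max)
  if (fs_max < fs_min) {
    rlang::abort("empty design window", class = "swarmprimer_infeasible")
  }
  structure(list(fs_min = fs_min, fs_max = fs_max), class = "design_window")
}

# Admissible (unwrapped) forward starts: inside the window and, when a
# conserved mask is present, able to host at least a minimum-length primer
# entirely within conserved sequence.
window_feasible_starts <- function(window, ctx) {
  fs <- window$fs_min:window$fs_max
  if (is.null(ctx$mask)) return(fs)
  ok <- vapply(fs, function(p) {
    all(ctx$mask[circular_positions(wrap_position(p, ctx$L), ctx$constraints$len_min, ctx$L)])
  }, logical(1))
  fs[ok]
}

swarm_ranges <- function(window, constraints) {
  rbind(Fs = c(window$fs_min, window$fs_max),
        Fl = c(constraints$len_min, constraints$len_max),
        Rl = c(constraints$len_min, constraints$len_max),
        Pl = c(constraints$product_min, constraints$product_max))
}

#' Initialize a swarm in a design window
#'
#' Particles are drawn uniformly: forward start over the window, primer
#' lengths over the admissible length range, product length over the product
#' window; each of the four velocity components is uniform in \[0, 1\].
#' Deterministic given the R random seed.
#'
#' @param window A [design_window()].
#' @param cfg A [swarm_config()].
#' @param constraints A [design_constraints()].
#' @param feasible_starts Optional integer vector of admissible forward
#'   starts (the window intersected with the conserved regions); when
#'   supplied, initial Fs values are drawn uniformly from this set instead
#'   of the raw interval.
#' @return A list with `positions` and `velocities`
#'   (`population` x 4 matrices, columns Fs/Fl/Rl/Pl).
#' @export
initialize_swarm <- function(window, cfg = swarm_config(),
                             constraints = design_constraints(),
                             feasible_starts = NULL) {
  if (window$fs_max - window$fs_min + 1L < 1L ||
      (!is.null(feasible_starts) && length(feasible_starts) == 0L)) {
    rlang::abort("design window admits no particle", class = "swarmprimer_infeasible")
  }
  rng <- swarm_ranges(window, constraints)
  n <- cfg$population
  positions <- cbind(
    if (is.null(feasible_starts)) stats::runif(n, rng["Fs", 1], rng["Fs", 2])
    else as.numeric(feasible_starts[sample.int(length(feasible_starts), n,
                                               replace = TRUE)]),
    stats::runif(n, rng["Fl", 1], rng["Fl", 2]),
    stats::runif(n, rng["Rl", 1], rng["Rl", 2]),
    stats::runif(n, rng["Pl", 1], rng["Pl", 2]))
  velocities <- matrix(stats::runif(4L * n), nrow = n)
  colnames(positions) <- colnames(velocities) <- rownames(rng)
  list(positions = positions, velocities = velocities)
}

#' One particle update step
#'
#' Applies the canonical velocity and position update:
#' `v' = w*v + c1*rand1*(pbest - x) + c2*rand2*(gbest - x)`, with each
#' velocity component clamped to `[-vmax, vmax]`, then `x' = x + v'`.
#' Positions stay continuous; rounding to integer coordinates and clipping
#' into the legal ranges happen at decode time.
#'
#' @param position,velocity Numeric length-4 vectors (Fs, Fl, Rl, Pl).
#' @param pbest,gbest Personal-best and global-best positions.
#' @param cfg A [swarm_config()].
#' @return A list with updated `position` and `velocity`.
#' @export
update_particle <- function(position, velocity, pbest, gbest,
                            cfg = swarm_config()) {
  k <- length(position)
  r1 <- if (cfg$rand_per_dimension) stats::runif(k) else rep(stats::runif(1), k)
  r2 <- if (cfg$rand_per_dimension) stats::runif(k) else rep(stats::runif(1), k)
  v <- cfg$inertia * velocity + cfg$c1 * r1 * (pbest - position) +
    cfg$c2 * r2 * (gbest - position)
  v <- pmin(pmax(v, -cfg$vmax), cfg$vmax)
  list(position = position + v, velocity = v)
}

decode_positions <- function(X, rng) {
  Xi <- round(X)
  for (d in 1:4) Xi[, d] <- pmin(pmax(Xi[, d], rng[d, 1]), rng[d, 2])
  storage.mode(Xi) <- "integer"
  Xi
}

#' Optimize one design window with particle swarm optimization
#'
#' Runs the swarm over integer-coded primer-pair candidates
#' `{Fs, Fl, Rl, Pl}` inside the window, scoring each against the full
#' constraint set. Each iteration evaluates every particle, updates personal
#' and global bests, and moves the swarm; the global-best fitness history is
#' therefore nonincreasing. Deterministic given the R random seed.
#'
#' @param window A [design_window()].
#' @param template A [template_sequence()].
#' @param regions Optional conserved-region tibble; when supplied, the
#'   `conserved` penalty keeps primers inside conserved sequence and a window
#'   with no admissible conserved forward start is reported infeasible.
#' @param constraints A [design_constraints()].
#' @param weights A [constraint_weights()].
#' @param thermo A [thermo_params()].
#' @param swarm A [swarm_config()].
#' @param .ctx Internal: a prebuilt evaluation context (shared memoization).
#' @return An object of class `swarm_result`: `best` (one-row tibble with
#'   decoded primers and penalty breakdown), `position`, `fitness`,
#'   `history` (per-iteration best fitness), `evaluations`, `config`.
#' @export
optimize_window <- function(window, template, regions = NULL,
                            constraints = design_constraints(),
                            weights = constraint_weights(),
                            thermo = thermo_params(),
                            swarm = swarm_config(), .ctx = NULL) {
  ctx <- .ctx %||% make_eval_context(template, constraints, weights, thermo, regions)
  fs_ok <- window_feasible_starts(window, ctx)
  if (length(fs_ok) == 0L) {
    rlang::abort("no admissible conserved forward start in window",
                 class = "swarmprimer_infeasible")
  }
  rng <- swarm_ranges(window, constraints)
  sw <- initialize_swarm(window, swarm, constraints,
                         feasible_starts = if (!is.null(ctx$mask)) fs_ok)
  X <- sw$positions; V <- sw$velocities
  n <- swarm$population
  pbest_pos <- matrix(NA_real_, n, 4)
  pbest_fit <- rep(Inf, n)
  gbest_pos <- NULL; gbest_fit <- Inf; gbest_int <- NULL
  history <- numeric(swarm$iterations)
  evals <- 0L

  for (it in seq_len(swarm$iterations)) {
    Xi <- decode_positions(X, rng)
    for (i in seq_len(n)) {
      fs <- wrap_position(Xi[i, 1], ctx$L)
      res <- eval_pair_ctx(fs, Xi[i, 2], Xi[i, 3], Xi[i, 4], ctx)
      evals <- evals + 1L
      if (res$fitness < pbest_fit[i]) {
        pbest_fit[i] <- res$fitness
        pbest_pos[i, ] <- Xi[i, ]
      }
      if (res$fitness < gbest_fit) {
        gbest_fit <- res$fitness
        gbest_pos <- Xi[i, ]
        gbest_int <- list(fs = fs, fl = Xi[i, 2], rl = Xi[i, 3], pl = Xi[i, 4])
      }
    }
    history[it] <- gbest_fit
    if (it < swarm$iterations) {
      R1 <- matrix(if (swarm$rand_per_dimension) stats::runif(4L * n)
                   else rep(stats::runif(n), 4L), n, 4)
      R2 <- matrix(if (swarm$rand_per_dimension) stats::runif(4L * n)
                   else rep(stats::runif(n), 4L), n, 4)
      V <- swarm$inertia * V + swarm$c1 * R1 * (pbest_pos - X) +
        swarm$c2 * R2 * (sweep(-X, 2, gbest_pos, "+"))
      V <- pmin(pmax(V, -swarm$vmax), swarm$vmax)
      X <- X + V
      for (d in 1:4) X[, d] <- pmin(pmax(X[, d], rng[d, 1]), rng[d, 2])
    }
  }
  best_res <- eval_pair_ctx(gbest_int$fs, gbest_int$fl, gbest_int$rl,
                            gbest_int$pl, ctx)
  structure(
    list(best = breakdown_row(gbest_int$fs, gbest_int$fl, gbest_int$rl,
                              gbest_int$pl, best_res),
         position = gbest_pos, fitness = gbest_fit, history = history,
         evaluations = evals, window = window, config = swarm),
    class = "swarm_result")
}

#' @export
print.swarm_result <- function(x, ...) {
  cat(sprintf("<swarm_result> fitness %.3f after %d evaluations (window %d..%d)\n",
              x$fitness, x$evaluations, x$window$fs_min, x$window$fs_max))
  invisible(x)
}

#' Exhaustively score every candidate pair in a window
#'
#' Enumerates the full integer grid `{Fs, Fl, Rl, Pl}` admissible in the
#' window and returns the best-scoring pair. Intended as a ground-truth
#' optimum for small windows (the grid size is capped); the swarm optimizer
#' can match but never beat it.
#'
#' @inheritParams optimize_window
#' @param max_grid Refuse grids larger than this many candidates.
#' @return A list with `best` (one-row tibble), `optimum` (its fitness) and
#'   `n` (grid size).
#' @export
enumerate_window <- function(window, template, regions = NULL,
                             constraints = design_constraints(),
                             weights = constraint_weights(),
                             thermo = thermo_params(), max_grid = 2e5,
                             .ctx = NULL) {
  ctx <- .ctx %||% make_eval_context(template, constraints, weights, thermo, regions)
  grid <- expand.grid(fs = window$fs_min:window$fs_max,
                      fl = constraints$len_min:constraints$len_max,
                      rl = constraints$len_min:constraints$len_max,
                      pl = constraints$product_min:constraints$product_max)
  if (nrow(grid) > max_grid) {
    rlang::abort(sprintf("window grid too large to enumerate (%d candidates)",
                         nrow(grid)), class = "swarmprimer_input_error")
  }
  best_fit <- Inf; best <- NULL
  for (i in seq_len(nrow(grid))) {
    fs <- wrap_position(grid$fs[i], ctx$L)
    res <- eval_pair_ctx(fs, grid$fl[i], grid$rl[i], grid$pl[i], ctx)
    if (res$fitness < best_fit) {
      best_fit <- res$fitness
      best <- breakdown_row(fs, grid$fl[i], grid$rl[i], grid$pl[i], res)
    }
  }
  list(best = best, optimum = best_fit, n = nrow(grid))
}
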