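#' Unit velocity vectors with the zero-speed convention
#'
#' Agents with zero speed contribute the zero vector rather than an
#' undefined direction.
#'
#' @param velocities N x 2 matrix of velocities.
#' @return N x 2 matrix of unit (or zero) vectors.
#' @keywords internal
unit_velocities <- function(velocities) {
  sp <- sqrt(rowSums(velocities^2))
  out <- velocities
  nz <- sp > 0
  out[nz, ] <- velocities[nz, , drop = FALSE] / sp[nz]
  out[!nz, ] <- 0
  out
}

#' Global order (polarization)
#'
#' The angular order parameter: the norm of the population-mean unit
#' velocity vector, `GO = || (1/N) sum_i v_i / ||v_i|| ||`, with zero-speed
#' agents contributing the zero vector.  Values near 1 indicate strong
#' alignment.
#'
#' @param velocities N x 2 matrix of velocities.
#' @return A number in `[0, 1]`.
#' @export
global_order <- function(velocities) {
  velocities <- rbind(velocities)
  u <- unit_velocities(velocities)
  sqrt(sum(colMeans(u)^2))
}

#' Topological local order
#'
#' The normalized topological vectorial order parameter: for each agent,
#' the unit velocities of its `k + 1` topologically nearest agents
#' (including itself, by minimum-image Euclidean distance) are summed and
#' the norm taken; the per-agent norms are averaged and divided by `k + 1`
#' so that a perfectly aligned population scores 1.  Ties in the k-th
#' distance break by smaller agent index.
#'
#' @param positions N x 2 matrix of wrapped positions.
#' @param velocities N x 2 matrix of velocities.
#' @param k Neighborhood size (default 5), requiring `N >= k + 1`.
#' @param space A [periodic_space()].
#' @return A number in `[0, 1]`.
#' @export
local_order <- function(positions, velocities, k = 5, space) {
  N <- nrow(positions)
  if (N < k + 1)
    stop("local_order needs at least k + 1 agents", call. = FALSE)
  u <- unit_velocities(velocities)
  D <- torus_dist_matrix(positions, space)
  norms <- vapply(seq_len(N), function(i) {
    nb <- order(D[i, ], seq_len(N))[seq_len(k + 1)]
    sqrt(sum(colSums(u[nb, , drop = FALSE])^2))
  }, numeric(1))
  mean(norms) / (k + 1)
}

#' Mean distance between all pairs
#'
#' `sum_{i != j} d_ij / (N (N - 1))` with minimum-image Euclidean
#' distances; equals the mean over unordered pairs.
#'
#' @param positions N x 2 matrix of wrapped positions (`N >= 2`).
#' @param space A [periodic_space()].
#' @return Mean pairwise torus distance.
#' @export
mean_pair_distance <- function(positions, space) {
  N <- nrow(positions)
  if (N < 2) stop("mean_pair_distance needs at least 2 agents", call. = FALSE)
  D <- torus_dist_matrix(positions, space)
  sum(D) / (N * (N - 1))
}

#' Time to reach a target
#'
#' First recorded timestep at which the minimum-image agent-target distance
#' falls to or below `threshold` (default 5 distance units).
#'
#' @param agent_xy T x 2 matrix of agent positions over time.
#' @param target_xy T x 2 matrix (or length-2 vector, recycled) of target
#'   positions.
#' @param space A [periodic_space()].
#' @param threshold Proximity threshold (> 0).
#' @param times Optional vector of timestep labels (defaults to
#'   `0, 1, ...`).
#' @return A list with `time` (the timestep, or `NA` if never reached) and
#'   `censored` (`TRUE` if the run ended before reaching the target).
#' @export
decision_time <- function(agent_xy, target_xy, space, threshold = 5,
                          times = NULL) {
  if (threshold <= 0) stop("threshold must be positive", call. = FALSE)
  agent_xy <- rbind(agent_xy)
  if (is.null(dim(target_xy)))
    target_xy <- matrix(target_xy, nrow(agent_xy), 2, byrow = TRUE)
  d <- min_image_displacement(agent_xy, target_xy, space)
  dist <- sqrt(d[, 1]^2 + d[, 2]^2)
  if (is.null(times)) times <- seq_len(nrow(agent_xy)) - 1L
  hit <- which(dist <= threshold)
  if (length(hit) == 0) list(time = NA_real_, censored = TRUE)
  else list(time = times[hit[1]], censored = FALSE)
}

#' Time-averaged normalized distance to a target
#'
#' Mean minimum-image agent-target distance after a burn-in, divided by the
#' arena side, reported as `d / L`.
#'
#' @inheritParams decision_time
#' @param burn_in Number of leading records to drop.
#' @return Mean distance divided by `space$L`.
#' @export
mean_target_distance <- function(agent_xy, target_xy, space, burn_in = 0) {
  agent_xy <- rbind(agent_xy)
  if (is.null(dim(target_xy)))
    target_xy <- matrix(target_xy, nrow(agent_xy), 2, byrow = TRUE)
  if (burn_in >= nrow(agent_xy))
    stop("burn_in must be smaller than the run length", call. = FALSE)
  keep <- seq(burn_in + 1L, nrow(agent_xy))
  d <- min_image_displacement(agent_xy[keep, , drop = FALSE],
                              target_xy[keep, , drop = FALSE], space)
  mean(sqrt(d[, 1]^2 + d[, 2]^2)) / space$L
}

#' Order-parameter series of a simulation
#'
#' Computes global order, normalized topological local order, and mean pair
#' distance at every recorded timestep of a simulation (or of a trajectory
#' table read back from CSV).
#'
#' @param x A `ringflock_sim` or a trajectory `data.frame` with columns
#'   `t, agent, x, y, vx, vy`.
#' @param k Local-order neighborhood size; local order is `NA` when
#'   `N < k + 1`.
#' @param space A [periodic_space()]; taken from the simulation when `x` is
#'   a `ringflock_sim`.
#' @return A `data.frame` with columns `t, GO, LO, mean_pair_dist`.
#' @export
trajectory_metrics <- function(x, k = 5, space = NULL) {
  if (inherits(x, "ringflock_sim")) {
    space <- x$space
    times <- x$time
    get_step <- function(s) list(pos = cbind(x$x[s, ], x$y[s, ]),
                                 vel = cbind(x$vx[s, ], x$vy[s, ]))
    n_steps <- length(times)
  } else {
    if (is.null(space)) stop("space is required for a trajectory table",
                             call. = FALSE)
    times <- sort(unique(x$t))
    get_step <- function(s) {
      rows <- x[x$t == times[s], ]
      rows <- rows[order(rows$agent), ]
      list(pos = cbind(rows$x, rows$y), vel = cbind(rows$vx, rows$vy))
    }
    n_steps <- length(times)
  }
  GO <- LO <- MPD <- rep(NA_real_, n_steps)
  for (s in seq_len(n_steps)) {
    st <- get_step(s)
    N <- nrow(st$pos)
    GO[s] <- global_order(st$vel)
    if (N >= k + 1) LO[s] <- local_order(st$pos, st$vel, k, space)
    if (N >= 2) MPD[s] <- mean_pair_distance(st$pos, space)
  }
  data.frame(t = times, GO = GO, LO = LO, mean_pair_dist = MPD)
}
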