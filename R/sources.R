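#' Environmental target specification
#'
#' A target is a point stimulus that excites each agent's ring through a
#' Gaussian receptive field of amplitude `h0`.  It is either static or
#' performs a random walk with per-axis speed `v_t`.
#'
#' @param position Length-2 position (will be wrapped by the simulation).
#' @param motion `"static"` or `"random_walk"`.
#' @param v_t Per-axis random-walk step size (>= 0).
#' @param h0 Receptive-field amplitude of the target.
#' @param sigma Optional per-target receptive width; defaults to the
#'   configuration's global `sigma`.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(position, motion = c("static", "random_walk"),
                        v_t = 0, h0 = 0.0025, sigma = NULL) {
  motion <- match.arg(motion)
  if (length(position) != 2L || !all(is.finite(position)))
    stop("position must be a finite length-2 vector", call. = FALSE)
  if (v_t < 0) stop("v_t must be non-negative", call. = FALSE)
  if (!is.null(sigma) && sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  structure(list(position = as.numeric(position), motion = motion,
                 v_t = v_t, h0 = h0, sigma = sigma,
                 velocity = c(0, 0)),
            class = "target_spec")
}

#' Advance a random-walk target by one step
#'
#' Default walk: each axis moves by `v_t * xi` with `xi` uniform on
#' `{-1, +1}`, then wraps.  With `walk = "velocity"` the increments act on
#' the target's velocity instead, and the position integrates it.  Static
#' targets are returned unchanged (consuming no randomness).
#'
#' @param target A [target_spec()].
#' @param space A [periodic_space()].
#' @param walk `"position"` (default) or `"velocity"`.
#' @return The updated target.
#' @export
advance_target <- function(target, space, walk = c("position", "velocity")) {
  walk <- match.arg(walk)
  if (target$motion != "random_walk" || target$v_t == 0) return(target)
  xi <- sample(c(-1, 1), 2L, replace = TRUE)
  if (walk == "position") {
    target$position <- wrap_position(target$position + target$v_t * xi, space)
  } else {
    target$velocity <- target$velocity + target$v_t * xi
    target$position <- wrap_position(target$position + target$velocity, space)
  }
  target
}

#' Social-coupling rule
#'
#' Every agent is a sensory target of every other agent's ring.  The control
#' parameter is the total social attraction `h_t_s`; the per-conspecific
#' amplitude is `h_t_s / N`, which keeps the phase diagram comparable across
#' population sizes.  Variants:
#' * `"baseline"` — constant amplitude `h_t_s / N`;
#' * `"short_range_repulsion"` — amplitude is a step function of distance:
#'   `h_rep < 0` below the collision radius `r_c`, else `h_t_s / N`;
#' * `"distance_decay"` — amplitude `(h_t_s / N) * exp(-d / (zeta * L))`,
#'   so `zeta * L` is the characteristic length of social attraction.
#'
#' @param h_t_s Total social attraction (per-conspecific amplitude times
#'   population size).
#' @param variant One of `"baseline"`, `"short_range_repulsion"`,
#'   `"distance_decay"`.
#' @param r_c Collision radius (> 0; repulsion variant).
#' @param h_rep Repulsive amplitude (< 0; repulsion variant).
#' @param zeta Decay length as a fraction of the arena side (> 0; decay
#'   variant).
#' @return An object of class `social_coupling`.
#' @export
social_coupling <- function(h_t_s, variant = c("baseline",
                                               "short_range_repulsion",
                                               "distance_decay"),
                            r_c = NULL, h_rep = NULL, zeta = NULL) {
  variant <- match.arg(variant)
  if (variant == "short_range_repulsion") {
    if (is.null(r_c) || r_c <= 0)
      stop("r_c must be a positive number", call. = FALSE)
    if (is.null(h_rep) || h_rep >= 0)
      stop("h_rep must be negative", call. = FALSE)
  }
  if (variant == "distance_decay" && (is.null(zeta) || zeta <= 0))
    stop("zeta must be a positive number", call. = FALSE)
  structure(list(h_t_s = h_t_s, variant = variant, r_c = r_c,
                 h_rep = h_rep, zeta = zeta),
            class = "social_coupling")
}

#' Sensory sources seen by one agent
#'
#' Composes the list of point sources driving agent `i`'s ring this
#' timestep: one source per non-coincident conspecific (bearing by the
#' minimum-image convention, amplitude by the [social_coupling()] variant)
#' plus one source per environmental target.  Conspecifics exactly
#' coincident with the focal agent have no defined bearing and are skipped
#' for that step.
#'
#' @param i Index of the focal agent.
#' @param positions N x 2 matrix of all agent positions (frozen at the start
#'   of the step).
#' @param targets List of [target_spec()] objects.
#' @param coupling A [social_coupling()] or `NULL` for asocial agents.
#' @param space A [periodic_space()].
#' @return A list with numeric vectors `bearings` and `amplitudes` (possibly
#'   empty).
#' @export
compose_sources <- function(i, positions, targets = list(), coupling = NULL,
                            space) {
  bearings <- numeric(0)
  amplitudes <- numeric(0)
  N <- nrow(positions)
  if (!is.null(coupling) && N > 1) {
    others <- setdiff(seq_len(N), i)
    a <- positions[rep(i, length(others)), , drop = FALSE]
    b <- positions[others, , drop = FALSE]
    d <- min_image_displacement(a, b, space)
    keep <- !(d[, 1] == 0 & d[, 2] == 0)
    if (any(keep)) {
      d <- d[keep, , drop = FALSE]
      th <- wrap_angle(atan2(d[, 2], d[, 1]))
      dist <- sqrt(d[, 1]^2 + d[, 2]^2)
      h0s <- coupling$h_t_s / N
      amp <- switch(coupling$variant,
        baseline = rep(h0s, length(th)),
        short_range_repulsion = ifelse(dist < coupling$r_c,
                                       coupling$h_rep, h0s),
        distance_decay = h0s * exp(-dist / (coupling$zeta * space$L)))
      bearings <- c(bearings, th)
      amplitudes <- c(amplitudes, amp)
    }
  }
  for (tg in targets) {
    d <- min_image_displacement(positions[i, ], tg$position, space)
    if (all(d == 0)) next
    bearings <- c(bearings, wrap_angle(atan2(d[2], d[1])))
    amplitudes <- c(amplitudes, tg$h0)
  }
  list(bearings = bearings, amplitudes = amplitudes)
}
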