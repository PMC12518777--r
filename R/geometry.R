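#' Periodic square arena
#'
#' A two-dimensional square world of side `L` with periodic boundaries.
#' All positions produced by the package live in `[0, L)` per coordinate and
#' distances/bearings follow the minimum-image convention: the shortest of
#' all periodic images is used.
#'
#' @param L Side length of the arena (dimensionless distance units, > 0).
#' @return An object of class `periodic_space`.
#' @examples
#' sp <- periodic_space(1000)
#' wrap_position(c(1005, -3), sp)
#' @export
periodic_space <- function(L) {
  if (!is.numeric(L) || length(L) != 1L || !is.finite(L) || L <= 0)
    stop("L must be a single positive number", call. = FALSE)
  structure(list(L = as.numeric(L)), class = "periodic_space")
}

#' @export
print.periodic_space <- function(x, ...) {
  cat("Periodic 2-D arena, side L =", x$L, "\n")
  invisible(x)
}

#' Wrap positions into the arena
#'
#' Each coordinate is reduced modulo `L` into `[0, L)`.  Wrapping is
#' idempotent.  `p` may be a length-2 vector or an n x 2 matrix.
#'
#' @param p A 2-D point or an n x 2 matrix of points.
#' @param space A [periodic_space()].
#' @return Wrapped point(s) of the same shape as `p`.
#' @export
wrap_position <- function(p, space) {
  p %% space$L
}

#' Minimum-image displacement on the torus
#'
#' The shortest vector from `a` to `b` under periodic boundaries.  Each
#' component lies in `(-L/2, L/2]`; a tie at exactly half the arena resolves
#' to `+L/2`.  Both arguments may be n x 2 matrices (recycled row-wise).
#'
#' @param a,b 2-D points (or n x 2 matrices) already wrapped into the arena.
#' @param space A [periodic_space()].
#' @return Displacement vector(s), same shape as the inputs.
#' @export
min_image_displacement <- function(a, b, space) {
  L <- space$L
  d <- (b - a) %% L
  d - L * (d > L / 2)
}

#' World bearing of one point from another
#'
#' Angle of the minimum-image displacement from `a` to `b`, measured
#' counterclockwise from the world +x axis, in `[0, 2*pi)`.
#'
#' @param a,b 2-D points (or n x 2 matrices).
#' @param space A [periodic_space()].
#' @return Bearing(s) in radians.  Coincident points (zero minimum-image
#'   displacement) are a degenerate bearing and raise an error; callers that
#'   can tolerate coincidence must skip such pairs.
#' @export
bearing <- function(a, b, space) {
  d <- min_image_displacement(a, b, space)
  if (is.matrix(d)) {
    if (any(d[, 1] == 0 & d[, 2] == 0))
      stop("degenerate bearing: coincident points", call. = FALSE)
    wrap_angle(atan2(d[, 2], d[, 1]))
  } else {
    if (all(d == 0))
      stop("degenerate bearing: coincident points", call. = FALSE)
    wrap_angle(atan2(d[2], d[1]))
  }
}

#' Canonicalize an angle into \[0, 2*pi)
#'
#' @param theta Angle(s) in radians.
#' @return Equivalent angle(s) in `[0, 2*pi)`.  Idempotent.
#' @export
wrap_angle <- function(theta) {
  theta %% (2 * pi)
}

#' Circular distance between angles
#'
#' `min(|d|, 2*pi - |d|)` for the canonical difference `d`; the metric used
#' in every Gaussian receptive field and in the ring connectivity, so that
#' angular separations respect the ring topology.
#'
#' @param theta1,theta2 Angles in radians (vectorized).
#' @return Distance(s) in `[0, pi]`; zero iff the angles agree mod `2*pi`.
#' @export
circ_dist <- function(theta1, theta2) {
  d <- abs(wrap_angle(theta1 - theta2))
  pmin(d, 2 * pi - d)
}

#' Minimum-image Euclidean distance matrix
#'
#' Pairwise torus distances between rows of an n x 2 position matrix.
#'
#' @param positions n x 2 matrix of wrapped positions.
#' @param space A [periodic_space()].
#' @return n x n symmetric distance matrix with zero diagonal.
#' @export
torus_dist_matrix <- function(positions, space) {
  L <- space$L
  half_wrap <- function(v) {
    d <- (outer(v, v, "-")) %% L
    d - L * (d > L / 2)
  }
  dx <- half_wrap(positions[, 1])
  dy <- half_wrap(positions[, 2])
  sqrt(dx^2 + dy^2)
}

#' Receptive-field centers on the ring
#'
#' Neuron `i` of an `Ns`-neuron ring encodes the direction
#' `2*pi*(i-1)/Ns` relative to the zero of the agent's reference frame.
#' In the egocentric mode the origin is the agent's current heading, so the
#' centers rotate with the body; in the allocentric mode the origin is a
#' world-anchored angle fixed between frame switches.
#'
#' @param mode `"ego"` or `"allo"` (affects only the caller's choice of
#'   `origin`; the geometry is identical).
#' @param origin The frame origin as a world angle (heading for ego mode,
#'   the allocentric anchor otherwise).
#' @param Ns Number of neurons.
#' @return Vector of `Ns` world angles in `[0, 2*pi)`.
#' @export
receptive_centers <- function(mode = c("ego", "allo"), origin, Ns) {
  match.arg(mode)
  wrap_angle(origin + ring_angles(Ns))
}

#' Ring positions of the neurons
#'
#' @param Ns Number of neurons.
#' @return `2*pi*(i-1)/Ns` for `i = 1..Ns`.
#' @export
ring_angles <- function(Ns) {
  2 * pi * (seq_len(Ns) - 1) / Ns
}
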