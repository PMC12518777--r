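#' Neural-field ring-attractor network
#'
#' `Ns` real membrane potentials `u_i` on a ring with modified-cosine
#' connectivity, evolved by an Euler discretization of Amari-type neural
#' field dynamics:
#' `u_i <- u_i + dt * ( -u_i + (1/Ns) sum_j J_ij tanh(beta u_j) - h_b + h_i )`.
#' Here `beta` is the slope of the tanh output nonlinearity and plays the
#' role of an inverse noise parameter: the dynamics themselves are
#' deterministic, and shallow output (small `beta`) blurs differences in
#' input.
#'
#' @param Ns Number of neurons (>= 3).
#' @param beta Output slope (> 0).
#' @param nu Connectivity exponent; see [build_connectivity()].
#' @param h_b Global inhibition.
#' @param dt Euler time step (0 < dt < 1 for a contractive map).
#' @param u Optional initial potentials; defaults to i.i.d. uniform on
#'   `[-u0, u0]` drawn from the current RNG stream (the all-zero state is a
#'   symmetric fixed point, so a small perturbation is needed to break
#'   symmetry).
#' @param u0 Half-width of the random initialization.
#' @param J Optional precomputed connectivity (pass a zero matrix for the
#'   zero-recurrence control).
#' @return An object of class `field_network`.
#' @export
field_network <- function(Ns, beta, nu = 0.5, h_b = 0, dt = 0.3, u = NULL,
                          u0 = 0.01, J = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("beta must be a positive number", call. = FALSE)
  if (!is.numeric(dt) || dt <= 0)
    stop("dt must be a positive number", call. = FALSE)
  if (is.null(J)) J <- build_connectivity(Ns, nu)
  if (is.null(u)) u <- stats::runif(Ns, -u0, u0)
  if (length(u) != Ns) stop("u must have length Ns", call. = FALSE)
  structure(list(Ns = as.integer(Ns), u = as.numeric(u), beta = beta,
                 nu = nu, h_b = h_b, dt = dt, J = J),
            class = "field_network")
}

#' @export
print.field_network <- function(x, ...) {
  cat("Neural-field ring attractor: Ns =", x$Ns, " beta =", x$beta,
      " nu =", x$nu, " h_b =", x$h_b, " dt =", x$dt, "\n")
  cat("  range of u: [", format(min(x$u), digits = 4), ",",
      format(max(x$u), digits = 4), "]\n")
  invisible(x)
}

#' Output nonlinearity of the neural field
#'
#' `F_i = tanh(beta * u_i)`, each in `(-1, 1)`, odd in `u`.
#'
#' @param u Membrane potentials.
#' @param beta Output slope.
#' @return Firing-rate outputs.
#' @export
field_output <- function(u, beta) {
  tanh(beta * u)
}

#' One Euler step of the neural-field dynamics
#'
#' @param net A [field_network()].
#' @param h Per-neuron external current (default zero).
#' @return The network with updated potentials.  Signals an error if the
#'   potentials leave the finite range (unreachable for `dt < 1` with
#'   bounded input).
#' @export
field_step <- function(net, h = 0) {
  u <- net$u
  h <- rep_len(h, net$Ns)
  rec <- as.numeric(net$J %*% tanh(net$beta * u)) / net$Ns
  u <- u + net$dt * (-u + rec - net$h_b + h)
  if (!all(is.finite(u)))
    stop("numerical blow-up in neural-field step", call. = FALSE)
  net$u <- u
  net
}

#' Velocity readout of the neural field
#'
#' `v = (v0/Ns) * sum_i max(0, tanh(beta u_i)) (cos center_i, sin center_i)`.
#' Only positive activities contribute; both direction and speed are shaped
#' by the bump profile.  Returns the zero vector when all potentials are
#' non-positive.
#'
#' @param net A [field_network()].
#' @param centers Receptive-field centers in the agent's current frame.
#' @param v0 Speed constant.
#' @return Length-2 velocity vector.
#' @export
field_velocity <- function(net, centers, v0) {
  w <- pmax(0, tanh(net$beta * net$u))
  (v0 / net$Ns) * c(sum(w * cos(centers)), sum(w * sin(centers)))
}

#' Heading readout for the constant-speed model variant
#'
#' In the direction-only model the agent always moves at speed `v0` and the
#' ring decides only the heading:
#' `H = atan2( sum_i max(0, tanh(beta u_i)) sin(center_i),
#'             sum_i max(0, tanh(beta u_i)) cos(center_i) )`,
#' wrapped to `[0, 2*pi)`.
#'
#' @param net A [field_network()].
#' @param centers Receptive-field centers in the agent's current frame.
#' @return Heading in `[0, 2*pi)`, or `NA_real_` when every activity is
#'   non-positive (the caller keeps the previous heading in that case).
#' @export
heading_only_readout <- function(net, centers) {
  w <- pmax(0, tanh(net$beta * net$u))
  cx <- sum(w * cos(centers))
  cy <- sum(w * sin(centers))
  if (cx == 0 && cy == 0) return(NA_real_)
  wrap_angle(atan2(cy, cx))
}
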