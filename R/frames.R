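#' Sample the reference-frame mode for one timestep
#'
#' Under the switching policy each agent independently employs an egocentric
#' frame with probability `omega` and an allocentric frame with probability
#' `1 - omega`, i.i.d. per agent per timestep.
#'
#' @param n Number of agents.
#' @param omega Probability of the egocentric mode, in `[0, 1]`.
#' @return Logical vector: `TRUE` = egocentric.
#' @export
sample_frame_mode <- function(n, omega) {
  if (omega < 0 || omega > 1) stop("omega must be in [0, 1]", call. = FALSE)
  stats::runif(n) < omega
}

#' Re-anchor a ring state across a reference-frame switch
#'
#' When an agent switches frames, the zero of the new frame is the agent's
#' heading at the end of the previous step, and the ring state is rotated so
#' that the world direction encoded by the activity bump is preserved to
#' within one neuron (`2*pi/Ns`): neuron `i` encoded world angle
#' `old_origin + 2*pi*(i-1)/Ns`; the state is circularly shifted by
#' `round(delta * Ns / (2*pi))` indices with `delta = old_origin -
#' new_origin`.  A switch out of the egocentric frame has zero shift by
#' construction, since the new allocentric origin is set to the heading that
#' was the egocentric origin.
#'
#' @param state Ring state vector (spin states or membrane potentials).
#' @param old_origin World angle that was the zero of the outgoing frame
#'   (the heading for an egocentric frame, the anchor for an allocentric
#'   one).
#' @param new_origin World angle that becomes the zero of the incoming
#'   frame (the agent's current heading, per the continuous re-anchoring
#'   rule).
#' @return The shifted state vector.
#' @export
apply_frame_switch <- function(state, old_origin, new_origin) {
  Ns <- length(state)
  delta <- wrap_angle(old_origin - new_origin)
  k <- round(delta * Ns / (2 * pi)) %% Ns
  if (k == 0) return(state)
  idx0 <- (seq_len(Ns) - 1L - k) %% Ns + 1L  # new position i takes old i - k
  state[idx0]
}
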