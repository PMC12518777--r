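#' Ring connectivity matrix
#'
#' Modified-cosine synaptic weights
#' `J[i, j] = cos(pi * (circ_dist(alpha_i, alpha_j) / pi)^nu)` with
#' `alpha_i = 2*pi*(i-1)/Ns`.  The kernel is circulant and symmetric with
#' unit diagonal; it implements local excitation and long-range inhibition
#' on the ring.  `nu = 1` gives a plain cosine (excitatory and inhibitory
#' synapses in roughly equal numbers); `nu < 1` narrows the excitatory
#' neighborhood and broadens inhibition.
#'
#' @param Ns Number of neurons (>= 3).
#' @param nu Connectivity exponent (> 0).
#' @return `Ns` x `Ns` numeric matrix.
#' @export
build_connectivity <- function(Ns, nu = 1) {
  if (!is.numeric(Ns) || length(Ns) != 1L || Ns < 3 || Ns != round(Ns))
    stop("Ns must be an integer >= 3", call. = FALSE)
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0)
    stop("nu must be a positive number", call. = FALSE)
  alpha <- ring_angles(Ns)
  D <- circ_dist(outer(alpha, alpha, "-"), 0)
  cos(pi * (D / pi)^nu)
}

#' Spin-system ring-attractor network
#'
#' `Ns` binary neurons (spins, active `+1` / inactive `-1`) on a ring with
#' modified-cosine connectivity, governed by the Hamiltonian
#' `H = -[ (1/Ns) sum_{i != j} J_ij s_i s_j + sum_i (h_i - h_b) s_i ]`
#' and updated by stochastic single-spin dynamics at inverse temperature
#' `beta` (see [equilibrate()]).
#'
#' @param Ns Number of neurons (>= 3).
#' @param beta Inverse temperature (>= 0); small `beta` means noisy dynamics.
#' @param nu Connectivity exponent (> 0); see [build_connectivity()].
#' @param h_b Global inhibition constant subtracted from every local field.
#' @param T0 Equilibration sweeps per movement step; `T0 * Ns` single-spin
#'   update attempts are performed between moves.
#' @param states Optional initial state vector in `{-1, +1}`; defaults to
#'   i.i.d. uniform spins drawn from the current RNG stream.
#' @param J Optional precomputed connectivity (pass `0` times the usual
#'   matrix for the zero-recurrence control).
#' @return An object of class `spin_network`.
#' @export
spin_network <- function(Ns, beta, nu = 1, h_b = 0, T0 = 10, states = NULL,
                         J = NULL) {
  if (!is.numeric(beta) || length(beta) != 1L || beta < 0)
    stop("beta must be a non-negative number", call. = FALSE)
  if (!is.numeric(T0) || T0 < 1)
    stop("T0 must be a positive integer", call. = FALSE)
  if (is.null(J)) J <- build_connectivity(Ns, nu)
  if (is.null(states)) {
    states <- sample(c(-1L, 1L), Ns, replace = TRUE)
  } else {
    states <- as.integer(states)
    if (length(states) != Ns || !all(states %in% c(-1L, 1L)))
      stop("states must be a length-Ns vector over {-1, +1}", call. = FALSE)
  }
  structure(list(Ns = as.integer(Ns), states = states, beta = beta, nu = nu,
                 h_b = h_b, T0 = as.integer(T0), J = J),
            class = "spin_network")
}

#' @export
print.spin_network <- function(x, ...) {
  cat("Spin-system ring attractor: Ns =", x$Ns, " beta =", x$beta,
      " nu =", x$nu, " h_b =", x$h_b, "\n")
  cat("  active spins:", sum(x$states == 1L), "of", x$Ns, "\n")
  invisible(x)
}

#' Gaussian sensory field on the ring (spin model)
#'
#' Each source at world bearing `theta` with amplitude `h0` drives neuron
#' `i` through a normalized Gaussian receptive field,
#' `h_i = h0 / sqrt(2*pi*sigma^2) * exp(-circ_dist(center_i, theta)^2 / (2*sigma^2))`,
#' summed over sources.
#'
#' @param centers Receptive-field centers as world angles
#'   (see [receptive_centers()]).
#' @param bearings World bearings of the sources (radians).
#' @param amplitudes Source amplitudes (`h0` per source; negative for
#'   repulsive sources).
#' @param sigma Receptive-field width in radians (> 0).
#' @return Numeric vector `h` of per-neuron external fields.
#' @export
spin_sensory_field <- function(centers, bearings, amplitudes, sigma) {
  gaussian_ring_field(centers, bearings, amplitudes, sigma, normalized = TRUE)
}

#' Gaussian sensory field on the ring (neural-field model)
#'
#' As [spin_sensory_field()] but without the `1/sqrt(2*pi*sigma^2)`
#' normalizing prefactor: `h_i = h0 * exp(-d^2 / (2*sigma^2))`.  The two
#' formulations deliberately follow their respective model definitions
#' rather than sharing one convention.
#'
#' @inheritParams spin_sensory_field
#' @return Numeric vector `h` of per-neuron external currents.
#' @export
field_sensory_field <- function(centers, bearings, amplitudes, sigma) {
  gaussian_ring_field(centers, bearings, amplitudes, sigma, normalized = FALSE)
}

gaussian_ring_field <- function(centers, bearings, amplitudes, sigma,
                                normalized) {
  if (!is.numeric(sigma) || sigma <= 0)
    stop("sigma must be a positive number", call. = FALSE)
  if (length(bearings) == 0L) return(numeric(length(centers)))
  stopifnot(length(bearings) == length(amplitudes))
  pref <- if (normalized) 1 / sqrt(2 * pi * sigma^2) else 1
  d <- (outer(centers, bearings, "-") + pi) %% (2 * pi) - pi  # circular diff
  as.numeric(exp(-d^2 / (2 * sigma^2)) %*% (amplitudes * pref))
}

#' Network energy
#'
#' `H = -[ (1/Ns) * sum_{i != j} J_ij s_i s_j + sum_i (h_i - h_b) s_i ]`.
#' Self-pairs are excluded: with binary spins the `i = j` term is a
#' state-independent constant and cannot affect the dynamics.
#'
#' @param net A [spin_network()].
#' @param h Per-neuron external field (default zero).
#' @return The energy (a single number).
#' @export
hamiltonian <- function(net, h = 0) {
  s <- net$states
  Ns <- net$Ns
  h <- rep_len(h, Ns)
  # remove the self-pairs J_ii * s_i^2 = trace(J) (1 per neuron for the
  # standard kernel, 0 in the zero-recurrence control)
  quad <- as.numeric(s %*% net$J %*% s) - sum(diag(net$J))
  -(quad / Ns + sum((h - net$h_b) * s))
}

#' Energy difference of a single spin flip
#'
#' `dH` for flipping spin `i`, computed from the local field
#' `m_i = sum_j J_ij s_j` as
#' `dH = 2 s_i * ( (2/Ns) (m_i - s_i) + h_i - h_b )`; equals the difference
#' of two full [hamiltonian()] evaluations exactly (the factor `2/Ns`
#' reflects each pair appearing twice in the double sum).
#'
#' @param net A [spin_network()].
#' @param i Neuron index (1-based).
#' @param h Per-neuron external field (default zero).
#' @return The energy difference.
#' @export
flip_delta <- function(net, i, h = 0) {
  Ns <- net$Ns
  if (i < 1 || i > Ns) stop("neuron index out of range", call. = FALSE)
  h <- rep_len(h, Ns)
  s <- net$states
  m_i <- sum(net$J[i, ] * s)
  2 * s[i] * ((2 / Ns) * (m_i - net$J[i, i] * s[i]) + h[i] - net$h_b)
}

#' Stochastic equilibration of the spin network
#'
#' Performs `attempts` single-spin update attempts (default `T0 * Ns`): each
#' attempt picks a neuron uniformly at random and flips it with certainty if
#' the energy difference is negative or zero, and with probability
#' `exp(-beta * dH)` if it is positive.  The induced chain has the Boltzmann
#' distribution `exp(-beta * H)` as its stationary law.  Randomness comes
#' from R's RNG, so runs are reproducible under [set.seed()].
#'
#' @param net A [spin_network()].
#' @param h Per-neuron external field (default zero).
#' @param attempts Number of update attempts (default `T0 * Ns`).
#' @return The network with updated `states`.
#' @export
equilibrate <- function(net, h = 0, attempts = NULL) {
  Ns <- net$Ns
  if (is.null(attempts)) attempts <- net$T0 * Ns
  h <- rep_len(h, Ns)
  out <- cpp_spin_equilibrate(matrix(net$states, ncol = 1L), net$J,
                              matrix(h, ncol = 1L), net$h_b, net$beta,
                              as.integer(attempts))
  net$states <- as.integer(out[, 1L])
  net
}

#' Velocity readout of the spin network
#'
#' The speed vector is the mean of the unit vectors encoded by the active
#' spins, scaled by `v0`:
#' `v = (v0/Ns) * sum_{i: s_i = +1} (cos center_i, sin center_i)`.
#' Both direction and magnitude depend on the bump; the zero vector results
#' when no spin is active or active directions cancel.
#'
#' @param net A [spin_network()] (or a raw `{-1, +1}` state vector).
#' @param centers Receptive-field centers in the agent's current frame.
#' @param v0 Speed constant.
#' @return Length-2 velocity vector.
#' @export
spin_velocity <- function(net, centers, v0) {
  s <- if (inherits(net, "spin_network")) net$states else as.integer(net)
  act <- s == 1L
  Ns <- length(s)
  (v0 / Ns) * c(sum(cos(centers[act])), sum(sin(centers[act])))
}

#' Exact Boltzmann distribution of a small spin ring
#'
#' Enumerates all `2^Ns` states and returns their normalized Boltzmann
#' weights `exp(-beta * H)`, indexed so that bit `i` of the (0-based) state
#' index is set iff spin `i` is active.  Intended as an exact reference for
#' chain-convergence checks on small rings.
#'
#' @param net A [spin_network()] with `Ns <= 16`.
#' @param h Per-neuron external field (default zero).
#' @return Numeric vector of length `2^Ns` summing to one.
#' @export
boltzmann_distribution <- function(net, h = 0) {
  Ns <- net$Ns
  if (Ns > 16) stop("enumeration limited to Ns <= 16", call. = FALSE)
  n_states <- 2^Ns
  energies <- numeric(n_states)
  for (idx in seq_len(n_states) - 1L) {
    bits <- bitwAnd(bitwShiftR(idx, seq_len(Ns) - 1L), 1L)
    net$states <- as.integer(2L * bits - 1L)
    energies[idx + 1L] <- hamiltonian(net, h)
  }
  w <- exp(-net$beta * (energies - min(energies)))
  w / sum(w)
}

#' Empirical state distribution of the spin chain
#'
#' Runs the single-spin dynamics on a small ring and tallies the states
#' visited, for comparison against [boltzmann_distribution()].
#'
#' @param net A [spin_network()] with `Ns <= 20`.
#' @param h Per-neuron external field (default zero).
#' @param n_samples Number of recorded samples.
#' @param burn_sweeps Burn-in, in sweeps of `Ns` attempts.
#' @param thin Attempts between recorded samples (default one sweep).
#' @return Numeric vector of length `2^Ns` of visit frequencies.
#' @export
spin_chain_distribution <- function(net, h = 0, n_samples = 1e5,
                                    burn_sweeps = 1000, thin = NULL) {
  Ns <- net$Ns
  if (is.null(thin)) thin <- Ns
  h <- rep_len(h, Ns)
  counts <- cpp_spin_chain_counts(net$states, net$J, h, net$h_b, net$beta,
                                  burn_sweeps * Ns, n_samples,
                                  as.integer(thin))
  counts / sum(counts)
}
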