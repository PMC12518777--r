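# Shared builders for small deterministic fixtures.

# Contiguous arc of `width` active spins starting at index `from` (1-based),
# the rest inactive.
arc_state <- function(Ns, from, width) {
  s <- rep(-1L, Ns)
  idx <- ((from - 1L + seq_len(width) - 1L) %% Ns) + 1L
  s[idx] <- 1L
  s
}

# Circular mean (as a world angle) of the ring angles of the active spins.
arc_center <- function(states, Ns = length(states)) {
  a <- ring_angles(Ns)[states == 1L]
  wrap_angle(atan2(sum(sin(a)), sum(cos(a))))
}

# Signed smallest angular difference a - b in (-pi, pi].
angle_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d - 2 * pi * (d > pi)
}

# Algebraic (Kasa) circle fit; returns the fitted radius.
fit_circle_radius <- function(x, y) {
  A <- cbind(2 * x, 2 * y, 1)
  sol <- qr.solve(A, x^2 + y^2)
  sqrt(sol[3] + sol[1]^2 + sol[2]^2)
}
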