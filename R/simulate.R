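#' Run a full simulation
#'
#' Initializes a population of ring-attractor agents and advances it for
#' `config$steps` synchronous steps.  Initialization: positions i.i.d.
#' uniform in the arena, headings i.i.d. uniform in `[0, 2*pi)`, spin states
#' i.i.d. uniform over `{-1, +1}` (spin back-end) or membrane potentials
#' i.i.d. uniform in `[-u0, u0]` (field back-ends), allocentric anchors at
#' the world +x axis (or per-agent random, by configuration).  All
#' randomness flows from `config$seed`; two runs with the same
#' configuration are identical.
#'
#' Each step: (1) under the switching policy, frame modes are resampled and
#' re-anchoring applied where the mode changed; (2) positions are frozen and
#' every agent's sensory field is composed from conspecifics and targets in
#' its own frame; (3) networks update (spin: `T0 * Ns` stochastic update
#' attempts; field: one Euler step); (4) velocities are read out;
#' (5) all agents move synchronously (spin: unit time per step; field:
#' `dt`); (6) headings follow the velocity (retained at zero speed) and
#' egocentric origins follow the headings; (7) targets advance.
#'
#' @param config A [ringflock_config()].
#' @return An object of class `ringflock_sim` holding the recorded
#'   trajectory (see [as.data.frame.ringflock_sim()]), the target
#'   trajectory, the configuration, and the final state.
#' @examples
#' cfg <- ringflock_config("field", "allo", N = 5, steps = 50, seed = 1,
#'                         coupling = social_coupling(0.08))
#' sim <- run_simulation(cfg)
#' summary(sim)
#' @export
run_simulation <- function(config) {
  if (!inherits(config, "ringflock_config"))
    stop("config must be a ringflock_config", call. = FALSE)
  set.seed(config$seed)
  ctx <- rf_context(config)
  st <- rf_init_state(config, ctx)

  steps <- config$steps
  re <- config$record_every
  rec_idx <- which((seq_len(steps + 1L) - 1L) %% re == 0L |
                     seq_len(steps + 1L) == steps + 1L)
  rec_t <- rec_idx - 1L
  n_rec <- length(rec_t)
  N <- config$N
  nt <- length(st$targets)
  rec <- list(
    t = rec_t,
    x = matrix(NA_real_, n_rec, N), y = matrix(NA_real_, n_rec, N),
    vx = matrix(NA_real_, n_rec, N), vy = matrix(NA_real_, n_rec, N),
    heading = matrix(NA_real_, n_rec, N),
    ego = matrix(NA, n_rec, N),
    tx = if (nt) matrix(NA_real_, n_rec, nt) else NULL,
    ty = if (nt) matrix(NA_real_, n_rec, nt) else NULL,
    net = if (config$record_network)
      array(NA_real_, c(n_rec, config$Ns, N)) else NULL)

  slot <- 1L
  record <- function(st, slot) {
    rec$x[slot, ] <<- st$pos[, 1]; rec$y[slot, ] <<- st$pos[, 2]
    rec$vx[slot, ] <<- st$vel[, 1]; rec$vy[slot, ] <<- st$vel[, 2]
    rec$heading[slot, ] <<- st$heading
    rec$ego[slot, ] <<- st$ego
    if (nt) {
      rec$tx[slot, ] <<- vapply(st$targets, function(tg) tg$position[1],
                                numeric(1))
      rec$ty[slot, ] <<- vapply(st$targets, function(tg) tg$position[2],
                                numeric(1))
    }
    if (!is.null(rec$net)) rec$net[slot, , ] <<- st$net
  }
  record(st, slot)
  if (steps > 0) {
    for (t in seq_len(steps)) {
      st <- rf_step(st, config, ctx)
      if (t == rec_t[slot + 1L]) {
        slot <- slot + 1L
        record(st, slot)
      }
    }
  }
  structure(list(config = config, space = ctx$space, time = rec_t,
                 x = rec$x, y = rec$y, vx = rec$vx, vy = rec$vy,
                 heading = rec$heading, ego = rec$ego,
                 target_x = rec$tx, target_y = rec$ty,
                 network = rec$net,
                 final = st),
            class = "ringflock_sim")
}

# Precomputed run constants.
rf_context <- function(config) {
  J <- if (config$recurrence) build_connectivity(config$Ns, config$nu)
       else matrix(0, config$Ns, config$Ns)
  list(space = periodic_space(config$L),
       J = J,
       alpha = ring_angles(config$Ns),
       spin = config$model == "spin",
       attempts = as.integer(config$T0 * config$Ns),
       # degenerate switch probabilities take the pure-frame code path, so
       # they consume no randomness and coincide with "allo"/"ego" runs
       genuine_switch = config$frame == "switch" &&
         config$omega > 0 && config$omega < 1)
}

rf_init_state <- function(config, ctx) {
  N <- config$N
  Ns <- config$Ns
  pos <- matrix(stats::runif(2 * N, 0, config$L), N, 2)
  heading <- stats::runif(N, 0, 2 * pi)
  anchor <- if (config$allo_origin == "random") stats::runif(N, 0, 2 * pi)
            else rep(0, N)
  ego <- switch(config$frame,
                ego = rep(TRUE, N),
                allo = rep(FALSE, N),
                switch = if (ctx$genuine_switch) sample_frame_mode(N, config$omega)
                         else rep(config$omega >= 0.5, N))
  net <- if (ctx$spin)
    matrix(sample(c(-1L, 1L), Ns * N, replace = TRUE), Ns, N)
  else
    matrix(stats::runif(Ns * N, -config$u0, config$u0), Ns, N)
  origin <- ifelse(ego, heading, anchor)
  list(pos = pos, heading = heading, vel = matrix(0, N, 2),
       ego = ego, origin = origin, net = net,
       targets = config$targets)
}

# Ns x N matrix of per-neuron external fields for all agents, from frozen
# positions.  Vectorized over all (agent, source) pairs; agrees with the
# per-agent composition compose_sources() + the Gaussian ring field (tested
# for equivalence).
rf_sensory_matrix <- function(st, config, ctx) {
  N <- config$N
  Ns <- config$Ns
  alpha <- ctx$alpha
  L <- config$L
  sigma <- config$sigma
  pref <- if (ctx$spin) 1 / sqrt(2 * pi * sigma^2) else 1
  Hmat <- matrix(0, Ns, N)

  if (!is.null(config$coupling) && N > 1) {
    cp <- config$coupling
    mi <- function(v) {
      d <- outer(v, v, function(a, b) b - a) %% L
      d - L * (d > L / 2)
    }
    dx <- mi(st$pos[, 1])
    dy <- mi(st$pos[, 2])
    theta <- atan2(dy, dx)        # bearing of agent j seen from agent i
    dist <- sqrt(dx^2 + dy^2)
    h0s <- cp$h_t_s / N
    amp <- switch(cp$variant,
      baseline = matrix(h0s, N, N),
      short_range_repulsion = ifelse(dist < cp$r_c, cp$h_rep, h0s),
      distance_decay = h0s * exp(-dist / (cp$zeta * L)))
    amp[dist == 0] <- 0           # self and coincident pairs: no source
    Hmat <- Hmat + cpp_gauss_fields(alpha, as.vector(t(st$origin - theta)),
                                    as.vector(t(amp)), N, N, sigma, pref)
  }
  for (tg in st$targets) {
    b <- matrix(tg$position, N, 2, byrow = TRUE)
    d <- min_image_displacement(st$pos, b, ctx$space)
    ok <- !(d[, 1] == 0 & d[, 2] == 0)
    if (!any(ok)) next
    theta_t <- atan2(d[, 2], d[, 1])
    sg <- tg$sigma %||% sigma
    pf <- if (ctx$spin) 1 / sqrt(2 * pi * sg^2) else 1
    Hmat <- Hmat + cpp_gauss_fields(alpha, st$origin - theta_t,
                                    ifelse(ok, tg$h0, 0), N, 1L, sg, pf)
  }
  Hmat
}

# One synchronous simulation step (internal fast path; the exported
# simulation_step() wraps it).
rf_step <- function(st, config, ctx) {
  N <- config$N
  Ns <- config$Ns
  alpha <- ctx$alpha
  space <- ctx$space

  # (1) frame switching with continuous re-anchoring
  if (ctx$genuine_switch) {
    new_ego <- sample_frame_mode(N, config$omega)
    changed <- which(new_ego != st$ego)
    for (a in changed) {
      old_origin <- st$origin[a]
      new_origin <- st$heading[a]
      st$net[, a] <- apply_frame_switch(st$net[, a], old_origin, new_origin)
      st$origin[a] <- new_origin
    }
    st$ego <- new_ego
  }
  st$origin[st$ego] <- st$heading[st$ego]

  # (2) sensory fields from frozen positions, in each agent's own frame
  Hmat <- rf_sensory_matrix(st, config, ctx)

  # (3) network update
  if (ctx$spin) {
    st$net <- cpp_spin_equilibrate(st$net, ctx$J, Hmat, config$h_b,
                                   config$beta, ctx$attempts)
  } else {
    U <- st$net
    U <- U + config$dt *
      (-U + (ctx$J %*% tanh(config$beta * U)) / Ns - config$h_b + Hmat)
    if (!all(is.finite(U)))
      stop("numerical blow-up in neural-field step", call. = FALSE)
    st$net <- U
  }

  # (4) velocity readout in world coordinates
  C <- outer(alpha, st$origin, "+")
  cosC <- cos(C); sinC <- sin(C)
  if (config$model == "spin") {
    A <- st$net == 1L
    vx <- (config$v0 / Ns) * colSums(cosC * A)
    vy <- (config$v0 / Ns) * colSums(sinC * A)
  } else if (config$model == "field") {
    W <- pmax(0, tanh(config$beta * st$net))
    vx <- (config$v0 / Ns) * colSums(cosC * W)
    vy <- (config$v0 / Ns) * colSums(sinC * W)
  } else { # field_heading_only: constant speed, ring decides direction
    W <- pmax(0, tanh(config$beta * st$net))
    cx <- colSums(cosC * W)
    cy <- colSums(sinC * W)
    hd <- ifelse(cx == 0 & cy == 0, st$heading, wrap_angle(atan2(cy, cx)))
    vx <- config$v0 * cos(hd)
    vy <- config$v0 * sin(hd)
  }
  st$vel <- cbind(vx, vy, deparse.level = 0)

  # (5) synchronous move: one movement step per simulation step in both
  # back-ends (dt scales only the neural relaxation within a step)
  st$pos <- wrap_position(st$pos + st$vel, space)

  # (6) heading follows the velocity; retained at zero speed
  moving <- vx != 0 | vy != 0
  st$heading[moving] <- wrap_angle(atan2(vy[moving], vx[moving]))
  st$origin[st$ego] <- st$heading[st$ego]

  # (7) targets advance
  if (length(st$targets))
    st$targets <- lapply(st$targets, advance_target, space = space,
                         walk = config$target_walk)
  st
}

#' Advance a simulation state by one step
#'
#' Public single-step interface over the same update used by
#' [run_simulation()], for stepwise inspection and testing.  `state` is a
#' list with elements `pos` (N x 2), `heading`, `vel` (N x 2), `ego`
#' (logical), `origin`, `net` (Ns x N), and `targets`.
#'
#' @param state A state list, e.g. from [simulation_init()].
#' @param config The [ringflock_config()].
#' @return The updated state list.
#' @export
simulation_step <- function(state, config) {
  rf_step(state, config, rf_context(config))
}

#' Draw an initial simulation state
#'
#' @param config A [ringflock_config()].  Consumes the current RNG stream
#'   (call [set.seed()] first for reproducibility); [run_simulation()] does
#'   the seeding itself.
#' @return A state list as used by [simulation_step()].
#' @export
simulation_init <- function(config) {
  rf_init_state(config, rf_context(config))
}
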