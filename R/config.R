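#' Simulation configuration
#'
#' Builds and validates the full set of parameters for [run_simulation()].
#' Defaults depend on the model back-end and follow the base parameter sets
#' used throughout the package's experiment presets:
#' * spin back-end: `Ns = 100`, `v0 = 10`, `sigma = 2*pi/Ns`, `nu = 1`,
#'   `beta = 400`, `h_b = 0`, `L = 1000`, `T0 = 10`;
#' * field back-ends: `Ns = 100`, `v0 = 0.05`, `sigma = 0.4`, `nu = 0.5`,
#'   `beta = 1000`, `h_b = 0`, `L = 1000`, `dt = 0.3`, `u0 = 0.01`.
#'
#' @param model `"spin"`, `"field"`, or `"field_heading_only"` (constant
#'   speed, ring decides direction only).
#' @param frame `"allo"`, `"ego"`, or `"switch"` (random per-step frame
#'   choice with egocentric probability `omega`).
#' @param omega Egocentric probability for the switching policy.
#' @param N Number of agents (>= 1).
#' @param Ns Neurons per ring (>= 3).
#' @param beta Inverse noise parameter (spin: inverse temperature; field:
#'   tanh slope).
#' @param nu Connectivity exponent.
#' @param h_b Global inhibition.
#' @param v0 Speed constant.
#' @param sigma Receptive-field width (radians).
#' @param L Arena side length.
#' @param steps Number of simulation steps.
#' @param dt Euler step (field back-ends).
#' @param T0 Equilibration sweeps per step (spin back-end).
#' @param u0 Initial-potential half-width (field back-ends).
#' @param coupling A [social_coupling()], or `NULL` for asocial agents.
#' @param targets List of [target_spec()] objects.
#' @param seed Integer master seed; every source of randomness in the run
#'   flows from it.
#' @param record_every Thinning interval for the trajectory record.
#' @param record_network Also record every agent's ring state (spin states
#'   or membrane potentials) at each recorded step.  Off by default because
#'   of size; recording never alters the dynamics.
#' @param allo_origin `"zero"` (all allocentric anchors at the world +x
#'   axis) or `"random"` (per-agent random anchors; the anchoring choice
#'   does not affect the dynamics, only the neuron indexing).
#' @param target_walk `"position"` or `"velocity"`; see [advance_target()].
#' @param recurrence `FALSE` sets all synaptic weights to zero (the
#'   feed-forward control in which agents merely drift toward their summed
#'   sensory input).
#' @return An object of class `ringflock_config`.
#' @export
ringflock_config <- function(model = c("spin", "field", "field_heading_only"),
                             frame = c("allo", "ego", "switch"),
                             omega = 0,
                             N = 1,
                             Ns = 100,
                             beta = NULL,
                             nu = NULL,
                             h_b = 0,
                             v0 = NULL,
                             sigma = NULL,
                             L = 1000,
                             steps = 1000,
                             dt = 0.3,
                             T0 = 10,
                             u0 = 0.01,
                             coupling = NULL,
                             targets = list(),
                             seed = 1,
                             record_every = 1,
                             record_network = FALSE,
                             allo_origin = c("zero", "random"),
                             target_walk = c("position", "velocity"),
                             recurrence = TRUE) {
  model <- match.arg(model)
  frame <- match.arg(frame)
  allo_origin <- match.arg(allo_origin)
  target_walk <- match.arg(target_walk)
  spin <- model == "spin"
  if (is.null(beta)) beta <- if (spin) 400 else 1000
  if (is.null(nu)) nu <- if (spin) 1 else 0.5
  if (is.null(v0)) v0 <- if (spin) 10 else 0.05
  if (is.null(sigma)) sigma <- if (spin) 2 * pi / Ns else 0.4

  chk <- function(ok, field, what) {
    if (!ok) stop(sprintf("invalid configuration: %s %s", field, what),
                  call. = FALSE)
  }
  chk(is.numeric(N) && N >= 1 && N == round(N), "N",
      "must be a positive integer")
  chk(is.numeric(Ns) && Ns >= 3 && Ns == round(Ns), "Ns",
      "must be an integer >= 3")
  chk(is.numeric(beta) && beta >= 0, "beta", "must be >= 0")
  chk(is.numeric(nu) && nu > 0, "nu", "must be > 0")
  chk(is.numeric(v0) && v0 > 0, "v0", "must be > 0")
  chk(is.numeric(sigma) && sigma > 0, "sigma", "must be > 0")
  chk(is.numeric(L) && L > 0, "L", "must be > 0")
  chk(is.numeric(steps) && steps >= 0 && steps == round(steps), "steps",
      "must be a non-negative integer")
  chk(is.numeric(dt) && dt > 0 && dt < 1, "dt", "must be in (0, 1)")
  chk(is.numeric(T0) && T0 >= 1, "T0", "must be >= 1")
  chk(is.numeric(u0) && u0 > 0, "u0", "must be > 0")
  chk(is.numeric(omega) && omega >= 0 && omega <= 1, "omega",
      "must be in [0, 1]")
  chk(is.numeric(seed) && seed == round(seed), "seed", "must be an integer")
  chk(is.numeric(record_every) && record_every >= 1, "record_every",
      "must be >= 1")
  chk(is.null(coupling) || inherits(coupling, "social_coupling"), "coupling",
      "must be a social_coupling object or NULL")
  chk(is.list(targets) &&
        all(vapply(targets, inherits, logical(1), "target_spec")), "targets",
      "must be a list of target_spec objects")
  chk(isTRUE(recurrence) || isFALSE(recurrence), "recurrence",
      "must be TRUE or FALSE")
  chk(isTRUE(record_network) || isFALSE(record_network), "record_network",
      "must be TRUE or FALSE")

  structure(list(model = model, frame = frame, omega = omega, N = as.integer(N),
                 Ns = as.integer(Ns), beta = beta, nu = nu, h_b = h_b,
                 v0 = v0, sigma = sigma, L = L, steps = as.integer(steps),
                 dt = dt, T0 = as.integer(T0), u0 = u0, coupling = coupling,
                 targets = targets, seed = as.integer(seed),
                 record_every = as.integer(record_every),
                 record_network = record_network,
                 allo_origin = allo_origin, target_walk = target_walk,
                 recurrence = recurrence),
            class = "ringflock_config")
}

#' @export
print.ringflock_config <- function(x, ...) {
  cat("ringflock configuration\n")
  cat(sprintf("  model: %s   frame: %s%s\n", x$model, x$frame,
              if (x$frame == "switch") sprintf(" (omega = %g)", x$omega)
              else ""))
  cat(sprintf("  N = %d agents, Ns = %d neurons, steps = %d, seed = %d\n",
              x$N, x$Ns, x$steps, x$seed))
  cat(sprintf("  beta = %g, nu = %g, h_b = %g, v0 = %g, sigma = %g, L = %g\n",
              x$beta, x$nu, x$h_b, x$v0, x$sigma, x$L))
  if (x$model == "spin") cat(sprintf("  T0 = %d sweeps/step\n", x$T0))
  else cat(sprintf("  dt = %g, u0 = %g\n", x$dt, x$u0))
  if (!is.null(x$coupling))
    cat(sprintf("  social coupling: %s, h_t^s = %g\n",
                x$coupling$variant, x$coupling$h_t_s))
  if (length(x$targets))
    cat(sprintf("  %d environmental target(s)\n", length(x$targets)))
  if (!x$recurrence) cat("  zero-recurrence control (J = 0)\n")
  invisible(x)
}

# ---- presets ---------------------------------------------------------------

preset_table <- function() {
  list(
    # Single-agent free motion in the ordered phase: circular orbit (ego)
    # vs straight path (allo).
    "free-ego-ordered" = function(seed)
      ringflock_config("spin", "ego", N = 1, beta = 400, steps = 2000,
                       seed = seed),
    "free-allo-ordered" = function(seed)
      ringflock_config("spin", "allo", N = 1, beta = 400, steps = 2000,
                       seed = seed),
    # Static-target seeking, spin back-end.
    "target-static" = function(seed)
      ringflock_config("spin", "allo", N = 1, beta = 100, steps = 2000,
                       targets = list(target_spec(c(500, 500))), seed = seed),
    # Spin collective motion / aggregation band (reduced scale: N = 20,
    # 6000 steps; the full-scale study uses N = 80 and 10000+ steps).
    "collective-spin-allo" = function(seed)
      ringflock_config("spin", "allo", N = 20, beta = 400, steps = 6000,
                       coupling = social_coupling(0.1), seed = seed)
    ,
    "collective-spin-ego" = function(seed)
      ringflock_config("spin", "ego", N = 20, beta = 400, steps = 6000,
                       coupling = social_coupling(0.1), seed = seed),
    "aggregation-spin-ego" = function(seed)
      ringflock_config("spin", "ego", N = 20, beta = 400, steps = 4000,
                       coupling = social_coupling(0.4), seed = seed),
    # Neural-field collective motion (reduced scale: N = 20).
    "collective-field-allo" = function(seed)
      ringflock_config("field", "allo", N = 20, beta = 1000, steps = 20000,
                       coupling = social_coupling(0.08), seed = seed),
    "collective-field-ego" = function(seed)
      ringflock_config("field", "ego", N = 20, beta = 1000, steps = 20000,
                       coupling = social_coupling(0.08), seed = seed),
    # Random frame switching at the high-order egocentric fraction.
    "switch-field" = function(seed)
      ringflock_config("field", "switch", omega = 0.8, N = 20, beta = 1000,
                       steps = 20000, coupling = social_coupling(0.08),
                       seed = seed),
    # Feed-forward control: no recurrent synapses, small arena; agents
    # coalesce into a slow aggregate.
    "zero-recurrence" = function(seed)
      ringflock_config("field", "allo", N = 20, beta = 100, steps = 8000,
                       L = 100, coupling = social_coupling(0.36),
                       recurrence = FALSE, seed = seed)
  )
}

#' Experiment presets
#'
#' Named, validated configurations for the scenarios studied with the
#' package: free single-agent motion, target seeking, spin and neural-field
#' collective motion, frame switching, and the zero-recurrence control.
#' Several presets run at a reduced scale (fewer agents and/or steps than
#' the full-scale study conditions); their descriptions say so.
#'
#' @param name Preset name; call `preset_names()` for the list.
#' @param seed Master seed to embed in the configuration.
#' @return A [ringflock_config()].
#' @export
preset_config <- function(name, seed = 1) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(names(tab), collapse = ", ")), call. = FALSE)
  tab[[name]](seed)
}

#' @rdname preset_config
#' @export
preset_names <- function() names(preset_table())

# ---- serialization ---------------------------------------------------------

config_to_list <- function(config) {
  out <- unclass(config)
  if (!is.null(out$coupling)) out$coupling <- unclass(out$coupling)
  out$targets <- lapply(out$targets, function(tg) {
    tg <- unclass(tg)
    tg$velocity <- NULL
    tg
  })
  out$coupling <- out$coupling[!vapply(out$coupling, is.null, logical(1))]
  out
}

#' Write a configuration file
#'
#' Serializes a [ringflock_config()] to JSON (default) or YAML, chosen by
#' the file extension.  `load_config(write_config(config, path))` restores
#' an identical configuration.
#'
#' @param config A [ringflock_config()].
#' @param path Output path ending in `.json`, `.yaml`, or `.yml`.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  lst <- config_to_list(config)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(path)
}

#' Load and validate a configuration file
#'
#' Reads a JSON or YAML configuration, rejects unknown keys, fills defaults
#' for absent ones, and validates every field through [ringflock_config()].
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @param quiet Suppress the echo of the resolved configuration.
#' @return A validated [ringflock_config()].
#' @export
load_config <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lst <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(ringflock_config))
  unknown <- setdiff(names(lst), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(lst$coupling)) {
    cp <- lst$coupling
    lst$coupling <- social_coupling(cp$h_t_s,
                                    variant = cp$variant %||% "baseline",
                                    r_c = cp$r_c, h_rep = cp$h_rep,
                                    zeta = cp$zeta)
  }
  if (!is.null(lst$targets)) {
    if (is.data.frame(lst$targets)) lst$targets <- split(lst$targets,
                                                         seq_len(nrow(lst$targets)))
    lst$targets <- lapply(lst$targets, function(tg) {
      tg <- as.list(tg)
      sg <- tg$sigma
      if (!is.null(sg) && all(is.na(sg))) sg <- NULL  # JSON null round trip
      target_spec(unlist(tg$position), motion = tg$motion %||% "static",
                  v_t = tg$v_t %||% 0, h0 = tg$h0 %||% 0.0025,
                  sigma = sg)
    })
  }
  config <- do.call(ringflock_config, lst)
  if (!quiet) {
    message("resolved configuration:")
    print(config)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
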