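small_cfg <- function(model = "spin", frame = "allo", steps = 40, ...) {
  ringflock_config(model, frame, N = 5, Ns = 16, steps = steps,
                   coupling = social_coupling(0.2), seed = 7, ...)
}

test_that("runs are fully reproducible from the seed", {
  for (model in c("spin", "field", "field_heading_only")) {
    a <- run_simulation(small_cfg(model))
    b <- run_simulation(small_cfg(model))
    expect_identical(a$x, b$x)
    expect_identical(a$heading, b$heading)
    expect_identical(a$final$net, b$final$net)
  }
})

test_that("a zero-step run records only the initial state", {
  cfg <- small_cfg(steps = 0)
  sim <- run_simulation(cfg)
  expect_equal(sim$time, 0)
  expect_equal(dim(sim$x), c(1, 5))
  expect_true(all(sim$vx == 0))
})

test_that("record thinning keeps the first and last steps", {
  cfg <- small_cfg(steps = 43, record_every = 10)
  sim <- run_simulation(cfg)
  expect_equal(sim$time, c(0, 10, 20, 30, 40, 43))
  full <- run_simulation(small_cfg(steps = 43))
  # thinning only drops rows; the dynamics are unchanged
  expect_equal(sim$x, full$x[full$time %in% sim$time, ])
})

test_that("degenerate switching takes the pure-frame code paths", {
  for (model in c("spin", "field")) {
    allo <- run_simulation(small_cfg(model, "allo"))
    sw0 <- run_simulation(small_cfg(model, "switch", omega = 0))
    expect_identical(allo$x, sw0$x)
    expect_identical(allo$heading, sw0$heading)
    ego <- run_simulation(small_cfg(model, "ego"))
    sw1 <- run_simulation(small_cfg(model, "switch", omega = 1))
    expect_identical(ego$x, sw1$x)
  }
})

test_that("speeds never exceed the speed constant", {
  for (model in c("spin", "field", "field_heading_only")) {
    cfg <- ringflock_config(model, "switch", omega = 0.5, N = 6, Ns = 20,
                            steps = 60, coupling = social_coupling(0.3),
                            seed = 3)
    sim <- run_simulation(cfg)
    expect_true(all(sqrt(sim$vx^2 + sim$vy^2) <= cfg$v0 + 1e-12))
  }
})

test_that("the dynamics are invariant under global translation", {
  # deterministic back-end so state stepping consumes no randomness
  cfg <- ringflock_config("field", "allo", N = 6, Ns = 20, steps = 0,
                          coupling = social_coupling(0.3), seed = 5)
  set.seed(5)
  st <- simulation_init(cfg)
  shift <- c(137.5, -412.25)
  st2 <- st
  st2$pos <- wrap_position(st$pos + rep(shift, each = 6), periodic_space(cfg$L))
  for (i in 1:30) {
    st <- simulation_step(st, cfg)
    st2 <- simulation_step(st2, cfg)
  }
  expect_equal(st2$pos,
               wrap_position(st$pos + rep(shift, each = 6),
                             periodic_space(cfg$L)),
               tolerance = 1e-9)
  expect_equal(st2$heading, st$heading, tolerance = 1e-9)
})

test_that("relabeling agents permutes the trajectories", {
  cfg <- ringflock_config("field", "allo", N = 5, Ns = 16, steps = 0,
                          coupling = social_coupling(0.25), seed = 6)
  set.seed(6)
  st <- simulation_init(cfg)
  perm <- c(3, 1, 5, 2, 4)
  st2 <- st
  st2$pos <- st$pos[perm, ]
  st2$heading <- st$heading[perm]
  st2$origin <- st$origin[perm]
  st2$net <- st$net[, perm]
  for (i in 1:25) {
    st <- simulation_step(st, cfg)
    st2 <- simulation_step(st2, cfg)
  }
  expect_equal(st2$pos, st$pos[perm, ], tolerance = 1e-9)
  expect_equal(st2$heading, st$heading[perm], tolerance = 1e-9)
})

test_that("a frozen ego bump orbits and a frozen allo bump runs straight", {
  Ns <- 100
  bump <- arc_state(Ns, 31, 50)          # half-ring arc: the ordered state
  alpha_c <- arc_center(bump)            # its deviation in the ego frame
  cfg <- ringflock_config("spin", "ego", N = 1, Ns = Ns, beta = 1e4,
                          steps = 0, seed = 1)
  set.seed(1)
  st <- simulation_init(cfg)
  st$net[, 1] <- bump
  st$heading[1] <- 0; st$origin[1] <- 0; st$pos[1, ] <- c(500, 500)
  hh <- numeric(60)
  for (i in 1:60) { st <- simulation_step(st, cfg); hh[i] <- st$heading[1] }
  turns <- angle_diff(hh[-1], hh[-60])
  expect_equal(circ_dist(turns, alpha_c), rep(0, 59), tolerance = 1e-9)

  cfg2 <- ringflock_config("spin", "allo", N = 1, Ns = Ns, beta = 1e4,
                           steps = 0, seed = 1)
  set.seed(1)
  st <- simulation_init(cfg2)
  st$net[, 1] <- bump
  st$origin[1] <- 0; st$pos[1, ] <- c(500, 500)
  hh <- numeric(60)
  for (i in 1:60) { st <- simulation_step(st, cfg2); hh[i] <- st$heading[1] }
  expect_equal(sd(hh), 0)
})

test_that("heading is retained when the readout is silent", {
  cfg <- ringflock_config("field", "allo", N = 2, Ns = 10, steps = 0, seed = 2)
  set.seed(2)
  st <- simulation_init(cfg)
  st$net[] <- -1            # all potentials negative: zero velocity
  h0 <- st$heading
  st <- simulation_step(st, cfg)
  expect_true(all(st$vel == 0))
  expect_equal(st$heading, h0)
})

test_that("the batched sensory field equals the per-agent composition", {
  set.seed(8)
  for (model in c("spin", "field")) {
    cfg <- ringflock_config(model, "ego", N = 7, Ns = 12, steps = 0,
                            coupling = social_coupling(
                              0.16, "short_range_repulsion",
                              r_c = 200, h_rep = -0.02),
                            targets = list(target_spec(c(300, 700),
                                                       h0 = 0.01)),
                            seed = 8)
    st <- simulation_init(cfg)
    ctx <- ringflock:::rf_context(cfg)
    st$origin[st$ego] <- st$heading[st$ego]
    Hfast <- ringflock:::rf_sensory_matrix(st, cfg, ctx)
    sp <- periodic_space(cfg$L)
    for (a in 1:7) {
      centers <- ring_angles(12) + st$origin[a]
      src <- compose_sources(a, st$pos, st$targets, cfg$coupling, sp)
      h <- ringflock:::gaussian_ring_field(centers, src$bearings,
                                           src$amplitudes, cfg$sigma,
                                           normalized = model == "spin")
      expect_equal(Hfast[, a], h, tolerance = 1e-12)
    }
  }
})

test_that("recording ring states never perturbs the dynamics", {
  plain <- run_simulation(small_cfg("spin"))
  with_net <- run_simulation(small_cfg("spin", record_network = TRUE))
  expect_identical(plain$x, with_net$x)
  expect_identical(plain$heading, with_net$heading)
  expect_null(plain$network)
  expect_equal(dim(with_net$network), c(41, 16, 5))
  expect_true(all(with_net$network %in% c(-1, 1)))
  # field back-end records membrane potentials
  wf <- run_simulation(small_cfg("field", record_network = TRUE))
  expect_true(all(is.finite(wf$network)))
  expect_equal(wf$network[41, , 3], wf$final$net[, 3])
  # the dump lands in a companion CSV
  path <- file.path(tempdir(), "net-dump.csv")
  write_trajectory(with_net, path)
  ndf <- read.csv(paste0(path, ".network.csv"))
  expect_equal(ncol(ndf), 2 + 16)
  expect_equal(nrow(ndf), 41 * 5)
  expect_equal(unlist(ndf[ndf$t == 40 & ndf$agent == 2, -(1:2)],
                      use.names = FALSE),
               with_net$network[41, , 2])
  unlink(c(path, paste0(path, ".network.csv")))
})

test_that("invalid configurations name the offending field", {
  expect_error(ringflock_config("spin", "allo", beta = -1), "beta")
  expect_error(ringflock_config("spin", "allo", N = 0), "N")
  expect_error(ringflock_config("spin", "allo", sigma = -0.1), "sigma")
  expect_error(ringflock_config("spin", "switch", omega = 2), "omega")
  expect_error(ringflock_config("field", "allo", dt = 1.5), "dt")
})
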