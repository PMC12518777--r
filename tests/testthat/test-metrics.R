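sp <- periodic_space(1000)

test_that("global order is the norm of the mean unit velocity", {
  v <- matrix(rep(c(10, 0), each = 80), 80, 2)
  expect_equal(global_order(v), 1)
  v2 <- rbind(matrix(rep(c(1, 0), each = 40), 40, 2),
              matrix(rep(c(-1, 0), each = 40), 40, 2))
  expect_equal(global_order(v2), 0)
  # all-zero velocities contribute zero vectors
  expect_equal(global_order(matrix(0, 10, 2)), 0)
  # speed does not matter, only direction
  set.seed(51)
  dirs <- runif(30, 0, 2 * pi)
  sp1 <- runif(30, 0.1, 5)
  expect_equal(global_order(cbind(cos(dirs), sin(dirs))),
               global_order(cbind(sp1 * cos(dirs), sp1 * sin(dirs))))
})

test_that("global order is rotation and relabeling invariant", {
  set.seed(52)
  v <- matrix(rnorm(40), 20, 2)
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  expect_equal(global_order(v %*% t(R)), global_order(v))
  expect_equal(global_order(v[sample(20), ]), global_order(v))
})

test_that("global order of random directions scales like 1/sqrt(N)", {
  set.seed(53)
  mean_go <- function(N, reps = 400) {
    mean(replicate(reps, {
      th <- runif(N, 0, 2 * pi)
      global_order(cbind(cos(th), sin(th)))
    }))
  }
  g1 <- mean_go(32)
  g2 <- mean_go(512)
  exponent <- log(g1 / g2) / log(512 / 32)
  expect_lt(abs(exponent - 0.5), 0.05)
})

test_that("local order attains 1 for alignment and 0 for cancellation", {
  set.seed(54)
  pos <- matrix(runif(40, 0, 1000), 20, 2)
  v <- matrix(rep(c(1, 0), each = 20), 20, 2)
  expect_equal(local_order(pos, v, k = 5, space = sp), 1)
  # six agents, single neighborhood, three against three
  pos6 <- cbind(1:6, rep(0, 6))
  v6 <- rbind(matrix(rep(c(1, 0), each = 3), 3, 2),
              matrix(rep(c(-1, 0), each = 3), 3, 2))
  expect_equal(local_order(pos6, v6, k = 5, space = sp), 0)
  expect_error(local_order(pos6, v6, k = 6, space = sp), "k \\+ 1")
})

test_that("local order equals global order when the neighborhood is everyone", {
  set.seed(55)
  pos <- matrix(runif(16, 0, 1000), 8, 2)
  v <- matrix(rnorm(16), 8, 2)
  expect_equal(local_order(pos, v, k = 7, space = sp), global_order(v))
})

test_that("local order matches a brute-force neighbor search", {
  set.seed(56)
  N <- 15
  pos <- matrix(runif(2 * N, 0, 1000), N, 2)
  v <- matrix(rnorm(2 * N), N, 2)
  k <- 5
  # independent oracle: explicit per-agent loop over sorted torus distances
  u <- v / sqrt(rowSums(v^2))
  acc <- 0
  for (i in 1:N) {
    d <- sapply(1:N, function(j)
      sqrt(sum(min_image_displacement(pos[i, ], pos[j, ], sp)^2)))
    nb <- order(d, seq_len(N))[1:(k + 1)]
    acc <- acc + sqrt(sum(colSums(u[nb, , drop = FALSE])^2))
  }
  expect_equal(local_order(pos, v, k, sp), acc / N / (k + 1))
})

test_that("mean pair distance matches hand values and the uniform law", {
  expect_equal(mean_pair_distance(rbind(c(0, 0), c(7, 0)), sp), 7)
  expect_equal(mean_pair_distance(matrix(5, 4, 2), sp), 0)
  expect_error(mean_pair_distance(matrix(1, 1, 2), sp), "2 agents")
  # uniform points on the torus concentrate near 0.3826 L
  set.seed(57)
  mpd <- mean(replicate(30, {
    mean_pair_distance(matrix(runif(400, 0, 1000), 200, 2), sp)
  }))
  expect_equal(mpd, 382.6, tolerance = 0.01)
})

test_that("decision time follows first-passage kinematics", {
  # already within threshold at the start
  traj <- rbind(c(0, 0), c(1, 0))
  expect_equal(decision_time(traj, c(3, 0), sp)$time, 0)
  # straight approach at unit speed from distance 20, threshold 5
  xs <- cbind(seq(0, 30, by = 1), 0)
  res <- decision_time(xs, c(20, 0), sp, threshold = 5)
  expect_false(res$censored)
  expect_equal(res$time, 15)     # ceil((20 - 5) / 1)
  # stationary agent beyond threshold is censored
  res2 <- decision_time(matrix(rep(c(0, 0), 10), ncol = 2, byrow = TRUE),
                        c(500, 0), sp)
  expect_true(res2$censored)
  expect_true(is.na(res2$time))
})

test_that("mean target distance is the normalized post-burn-in average", {
  agent <- cbind(rep(100, 10), rep(100, 10))
  expect_equal(mean_target_distance(agent, c(100, 100), sp), 0)
  # orbit at fixed radius r gives r / L
  th <- seq(0, 2 * pi, length.out = 50)
  orbit <- cbind(500 + 30 * cos(th), 500 + 30 * sin(th))
  expect_equal(mean_target_distance(orbit, c(500, 500), sp), 30 / 1000)
  # recomputation oracle on an arbitrary trajectory
  set.seed(58)
  a <- matrix(runif(40, 0, 1000), 20, 2)
  tg <- matrix(runif(40, 0, 1000), 20, 2)
  keep <- 6:20
  d <- sapply(keep, function(i)
    sqrt(sum(min_image_displacement(a[i, ], tg[i, ], sp)^2)))
  expect_equal(mean_target_distance(a, tg, sp, burn_in = 5), mean(d) / 1000)
  expect_error(mean_target_distance(a, tg, sp, burn_in = 20), "burn_in")
})

test_that("metrics recomputed from the emitted CSV match the in-memory ones", {
  cfg <- ringflock_config("spin", "allo", N = 8, Ns = 16, steps = 30,
                          coupling = social_coupling(0.2), seed = 13)
  sim <- run_simulation(cfg)
  m1 <- trajectory_metrics(sim)
  path <- file.path(tempdir(), "traj-roundtrip.csv")
  write_trajectory(sim, path)
  df <- read_trajectory(path)
  m2 <- trajectory_metrics(df, space = periodic_space(cfg$L))
  expect_equal(m2$GO, m1$GO, tolerance = 1e-9)
  expect_equal(m2$LO, m1$LO, tolerance = 1e-9)
  expect_equal(m2$mean_pair_dist, m1$mean_pair_dist, tolerance = 1e-9)
  unlink(c(path, paste0(path, ".targets.csv")))
})
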