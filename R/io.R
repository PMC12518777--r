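#' Write a trajectory to CSV
#'
#' One row per agent per recorded timestep, columns
#' `t,agent,x,y,vx,vy,heading,frame_mode`.  Target trajectories, when
#' present, go to a companion file `<path>.targets.csv` with columns
#' `t,target,x,y`.
#'
#' If the run recorded ring states (`record_network = TRUE`), they go to
#' `<path>.network.csv`: one row per agent per recorded step, columns
#' `t, agent, n1..nNs` (spin states or membrane potentials).
#'
#' @param sim A `ringflock_sim`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(sim, path) {
  df <- as.data.frame(sim)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(sim$network)) {
    dm <- dim(sim$network)                 # n_rec x Ns x N
    flat <- matrix(aperm(sim$network, c(3, 1, 2)), dm[1] * dm[3], dm[2])
    ndf <- data.frame(t = rep(sim$time, each = dm[3]),
                      agent = rep(seq_len(dm[3]), dm[1]), flat)
    names(ndf) <- c("t", "agent", paste0("n", seq_len(dm[2])))
    utils::write.csv(ndf, paste0(path, ".network.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  if (!is.null(sim$target_x)) {
    nt <- ncol(sim$target_x)
    tdf <- data.frame(
      t = rep(sim$time, each = nt),
      target = rep(seq_len(nt), length(sim$time)),
      x = as.vector(t(sim$target_x)),
      y = as.vector(t(sim$target_y)))
    utils::write.csv(tdf, paste0(path, ".targets.csv"), row.names = FALSE,
                     quote = FALSE)
  }
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path Path written by [write_trajectory()].
#' @return A trajectory `data.frame` accepted by [trajectory_metrics()].
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Flatten a simulation to a long trajectory table
#'
#' @param x A `ringflock_sim`.
#' @param row.names,optional,... Ignored (S3 signature).
#' @return `data.frame` with columns `t, agent, x, y, vx, vy, heading,
#'   frame_mode`.
#' @export
as.data.frame.ringflock_sim <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  N <- x$config$N
  data.frame(
    t = rep(x$time, each = N),
    agent = rep(seq_len(N), length(x$time)),
    x = as.vector(t(x$x)),
    y = as.vector(t(x$y)),
    vx = as.vector(t(x$vx)),
    vy = as.vector(t(x$vy)),
    heading = as.vector(t(x$heading)),
    frame_mode = ifelse(as.vector(t(x$ego)), "ego", "allo"))
}

#' @export
print.ringflock_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("ringflock simulation: %s model, %s frame, N = %d, %d steps\n",
              cfg$model, cfg$frame, cfg$N, cfg$steps))
  cat(sprintf("  recorded %d timesteps (record_every = %d), seed = %d\n",
              length(x$time), cfg$record_every, cfg$seed))
  invisible(x)
}

#' Summarize a simulation
#'
#' Order parameters time-averaged over an analysis window at the end of the
#' run (by default the final third of the recorded steps).
#'
#' @param object A `ringflock_sim`.
#' @param window Fraction of recorded steps, from the end, to average over.
#' @param k Local-order neighborhood size.
#' @param ... Ignored.
#' @return An object of class `summary.ringflock_sim` with the metric
#'   series and window means.
#' @export
summary.ringflock_sim <- function(object, window = 1 / 3, k = 5, ...) {
  m <- trajectory_metrics(object, k = k)
  n <- nrow(m)
  keep <- seq(max(1L, n - floor(window * n) + 1L), n)
  means <- colMeans(m[keep, c("GO", "LO", "mean_pair_dist"), drop = FALSE],
                    na.rm = TRUE)
  structure(list(config = object$config, metrics = m, window = window,
                 GO_mean = unname(means["GO"]),
                 LO_mean = unname(means["LO"]),
                 mpd_mean = unname(means["mean_pair_dist"])),
            class = "summary.ringflock_sim")
}

#' @export
print.summary.ringflock_sim <- function(x, ...) {
  print(x$config)
  cat(sprintf("time averages over the final %.0f%% of recorded steps:\n",
              100 * x$window))
  cat(sprintf("  global order GO   = %.4f\n", x$GO_mean))
  cat(sprintf("  local order LO    = %.4f\n", x$LO_mean))
  cat(sprintf("  mean pair distance = %.4f\n", x$mpd_mean))
  invisible(x)
}

#' Plot agent trajectories
#'
#' Draws the recorded positions of each agent in the periodic arena; wraps
#' are broken into separate segments so trajectories do not streak across
#' the box.
#'
#' @param x A `ringflock_sim`.
#' @param agents Which agents to draw (default all, capped at 20).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ringflock_sim <- function(x, agents = NULL, ...) {
  L <- x$config$L
  if (is.null(agents)) agents <- seq_len(min(x$config$N, 20L))
  graphics::plot(NA, xlim = c(0, L), ylim = c(0, L), asp = 1,
                 xlab = "x", ylab = "y", ...)
  cols <- grDevices::hcl.colors(length(agents), "Dark 3")
  for (j in seq_along(agents)) {
    a <- agents[j]
    px <- x$x[, a]; py <- x$y[, a]
    jump <- c(FALSE, abs(diff(px)) > L / 2 | abs(diff(py)) > L / 2)
    px[jump] <- NA  # break line segments at wrap-arounds
    graphics::lines(px, py, col = cols[j])
  }
  invisible(x)
}
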