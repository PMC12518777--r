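#' Parameter sweep over the phase plane
#'
#' Runs one simulation per grid cell over `beta`, total social attraction
#' `h_t_s`, and (optionally) the egocentric probability `omega`, and
#' summarizes each run by its window-averaged order parameters.  Cell seeds
#' derive deterministically from the base configuration's seed, so the
#' sweep is reproducible and cells are independent of grid ordering.
#'
#' @param base A [ringflock_config()] providing every non-swept parameter.
#' @param beta Vector of inverse noise values.
#' @param h_t_s Vector of total social attraction values.
#' @param omega Vector of egocentric probabilities (default: the base
#'   configuration's value).
#' @param window Fraction of recorded steps, from the end, averaged into
#'   the summary (default the final third).
#' @return `data.frame` with one row per cell: `beta, h_t_s, omega, seed,
#'   GO_mean, LO_mean, mpd_mean`.
#' @export
sweep_grid <- function(base, beta = base$beta,
                       h_t_s = if (!is.null(base$coupling))
                         base$coupling$h_t_s else 0,
                       omega = base$omega, window = 1 / 3) {
  grid <- expand.grid(beta = beta, h_t_s = h_t_s, omega = omega,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- base
    cfg$beta <- grid$beta[i]
    cfg$omega <- grid$omega[i]
    if (grid$h_t_s[i] > 0) {
      cp <- base$coupling
      if (is.null(cp)) cp <- social_coupling(grid$h_t_s[i])
      else cp$h_t_s <- grid$h_t_s[i]
      cfg$coupling <- cp
    }
    cfg$seed <- (base$seed + 7919L * i) %% .Machine$integer.max
    sm <- summary(run_simulation(cfg), window = window)
    data.frame(beta = grid$beta[i], h_t_s = grid$h_t_s[i],
               omega = grid$omega[i], seed = cfg$seed,
               GO_mean = sm$GO_mean, LO_mean = sm$LO_mean,
               mpd_mean = sm$mpd_mean)
  })
  do.call(rbind, rows)
}
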