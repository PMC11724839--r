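# shared fixtures: configurations and small simulated trials built in code

noiseless_config <- function(seed = 1, n_per_side = 2, ...) {
  simulation_config(n_perturbations_per_side = n_per_side, seed = seed,
                    noise_sd = c(sway = 0, vel = 0, grf = 0),
                    marker_noise_sd = 0, force_noise_sd = 0, ...)
}

# cache one noiseless simulated trial per session; several test files use it
cached_trial <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- noiseless_config(seed = 1, n_per_side = 2)
      st <- simulate_trial(cfg)
      res <- analyze_trial(st$trial, generate_static_trial(cfg))
      cache <<- list(cfg = cfg, trial = st$trial, truth = st$truth, res = res)
    }
    cache
  }
})

# minimal marker set for hand-built kinematic fixtures: a vertical trunk at
# the origin with pelvis markers around it
flat_markers <- function(n, trunk_tilt_deg = 0, trunk_len = 0.45) {
  th <- trunk_tilt_deg * pi / 180
  rep_row <- function(v) matrix(rep(v, each = n), n, 3)
  pelvis <- c(0, 0, 0.95)
  m <- list(SACR = rep_row(pelvis + c(-0.12, 0, 0.02)),
            LASI = rep_row(pelvis + c(0.10, 0.12, 0)),
            RASI = rep_row(pelvis + c(0.10, -0.12, 0)))
  centroid <- (m$SACR + m$LASI + m$RASI) / 3
  mid <- centroid + trunk_len * rep_row(c(sin(th), 0, cos(th)))[, 1:3]
  m$C7 <- mid + rep_row(c(-0.05, 0, 0))
  m$CLAV <- mid + rep_row(c(0.05, 0, 0))
  m
}
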