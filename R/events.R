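#' Detect heel-strike and toe-off events from marker coordinates
#'
#' Coordinate-based extremum method: heel strikes are the per-cycle maxima
#' of the heel marker's anterior-posterior position relative to the pelvis
#' origin (centroid of SACR, LASI, RASI) and toe-offs the per-cycle minima
#' of the toe marker's relative AP position.  Alternation within a side is
#' enforced by discarding the weaker of two same-type events with no
#' opposite event between them.
#'
#' @param markers named list of n x 3 marker matrices including `LHEE`,
#'   `RHEE`, `LTOE`, `RTOE`, `SACR`, `LASI`, `RASI` (gap-filled and
#'   filtered).
#' @param rate marker sampling rate (Hz).
#' @param min_prominence_frac prominence gate for candidate extrema, as a
#'   fraction of the relative-AP excursion.
#' @return data frame with columns `time`, `side` (`"left"`/`"right"`) and
#'   `type` (`"heel_strike"`/`"toe_off"`), sorted by time; zero rows (with
#'   a warning) when fewer than two cycles are present.
#' @export
detect_gait_events <- function(markers, rate, min_prominence_frac = 0.1) {
  pelvis_x <- (markers$SACR[, 1] + markers$LASI[, 1] + markers$RASI[, 1]) / 3
  out <- list()
  for (side in c("left", "right")) {
    pre <- if (side == "left") "L" else "R"
    rel_h <- markers[[paste0(pre, "HEE")]][, 1] - pelvis_x
    rel_t <- markers[[paste0(pre, "TOE")]][, 1] - pelvis_x
    prom_h <- min_prominence_frac * diff(range(rel_h, na.rm = TRUE)) / 2
    prom_t <- min_prominence_frac * diff(range(rel_t, na.rm = TRUE)) / 2
    strikes <- local_maxima(rel_h, prom_h)
    offs <- local_maxima(-rel_t, prom_t)
    ev <- rbind(
      data.frame(idx = strikes,
                 type = rep("heel_strike", length(strikes)),
                 strength = rel_h[strikes]),
      data.frame(idx = offs, type = rep("toe_off", length(offs)),
                 strength = -rel_t[offs])
    )
    ev <- ev[order(ev$idx), , drop = FALSE]
    ## alternation: of two same-type events with no opposite event between
    ## them keep the stronger extremum
    keep <- rep(TRUE, nrow(ev))
    i <- 1L
    while (i < nrow(ev)) {
      nxt <- which(keep & seq_len(nrow(ev)) > i)
      if (!length(nxt)) break
      j <- nxt[1]
      if (keep[i] && ev$type[j] == ev$type[i]) {
        if (ev$strength[j] >= ev$strength[i]) keep[i] <- FALSE else keep[j] <- FALSE
        i <- if (keep[i]) i else j
      } else i <- j
    }
    ev <- ev[keep, , drop = FALSE]
    if (sum(ev$type == "heel_strike") < 2) {
      warning(sprintf("fewer than two gait cycles detected on the %s side", side))
      next
    }
    out[[side]] <- data.frame(time = (ev$idx - 1) / rate, side = side,
                              type = ev$type)
  }
  if (!length(out))
    return(data.frame(time = numeric(), side = character(), type = character()))
  res <- do.call(rbind, out)
  res <- res[order(res$time), ]
  rownames(res) <- NULL
  res
}

event_times <- function(events, side_, type_) {
  events$time[events$side == side_ & events$type == type_]
}

#' Fraction of the gait cycle at which a time instant falls
#'
#' The gait cycle of a side spans two consecutive heel strikes of that
#' side; the fraction is `(t - previous strike) / (next strike - previous
#' strike)`.
#'
#' @param t time (s).
#' @param events event table from [detect_gait_events()].
#' @param side `"left"` or `"right"`.
#' @return fraction in `[0, 1]`.
#' @export
gait_cycle_fraction <- function(t, events, side) {
  strikes <- event_times(events, side, "heel_strike")
  prev <- strikes[strikes <= t]
  nxt <- strikes[strikes > t]
  if (!length(prev) || !length(nxt))
    abort_stumblr("time falls outside any complete gait cycle",
                  "undefined_fraction")
  prev <- max(prev); nxt <- min(nxt)
  (t - prev) / (nxt - prev)
}

#' Detect belt-speed perturbations and attribute them to a stance side
#'
#' A perturbation is a belt-speed excursion exceeding the steady speed
#' (trial median) by more than `dev_threshold` that returns to the steady
#' speed; onset and end are refined to the samples where the speed actually
#' departs from and rejoins the steady value.  The perturbed side is the
#' limb whose most recent event at onset is a heel strike with no
#' subsequent toe-off (ties resolved to the later striker).
#'
#' @param belt_speed belt-speed series (m/s).
#' @param rate sampling rate of the belt series (Hz).
#' @param events event table from [detect_gait_events()].
#' @param meta trial metadata list; `prosthetic_side` maps sides to
#'   intact/prosthetic labels and `block` indexes the walking block.
#' @param dev_threshold departure that flags a perturbation (m/s).
#' @return data frame of perturbation records: `id`, `side`, `side_label`,
#'   `onset`, `duration`, `cycle_fraction`, `block`, `side_ordinal`.
#' @export
detect_perturbations <- function(belt_speed, rate, events, meta,
                                 dev_threshold = 0.05) {
  steady <- median(belt_speed)
  dev <- belt_speed - steady
  above <- dev > dev_threshold
  if (!any(above))
    return(data.frame(id = integer(), side = character(),
                      side_label = character(), onset = numeric(),
                      duration = numeric(), cycle_fraction = numeric(),
                      block = integer(), side_ordinal = integer()))
  runs <- logical_runs(above)
  tiny <- 1e-9
  recs <- list()
  for (r in seq_len(nrow(runs))) {
    i1 <- runs[r, "start"]; i2 <- runs[r, "end"]
    while (i1 > 1L && dev[i1 - 1L] > tiny) i1 <- i1 - 1L
    while (i2 < length(dev) && dev[i2 + 1L] > tiny) i2 <- i2 + 1L
    if (i2 >= length(dev))
      abort_stumblr("belt speed excursion never returns to the steady speed",
                    "malformed_trial")
    onset <- (i1 - 1) / rate
    duration <- (i2 + 1 - i1) / rate
    ## stance side: most recent heel strike without a later toe-off
    cand <- list()
    for (side in c("left", "right")) {
      se <- events[events$side == side & events$time <= onset, , drop = FALSE]
      if (!nrow(se)) next
      last <- se[nrow(se), ]
      cand[[side]] <- list(in_stance = last$type == "heel_strike",
                           last_strike = max(se$time[se$type == "heel_strike"]))
    }
    if (!length(cand))
      abort_stumblr("no gait events precede a perturbation onset",
                    "malformed_trial")
    in_stance <- vapply(cand, function(x) x$in_stance, logical(1))
    strikes <- vapply(cand, function(x) x$last_strike, numeric(1))
    pool <- if (any(in_stance)) strikes[in_stance] else strikes
    side <- names(pool)[which.max(pool)]
    recs[[r]] <- data.frame(
      id = r, side = side,
      side_label = if (side == meta$prosthetic_side) "prosthetic" else "intact",
      onset = onset, duration = duration,
      cycle_fraction = gait_cycle_fraction(onset, events, side),
      block = meta$block %||% 1L, side_ordinal = NA_integer_)
  }
  out <- do.call(rbind, recs)
  out$side_ordinal <- as.integer(stats::ave(out$onset, out$side, out$block,
                                            FUN = seq_along))
  out
}

#' Segment a perturbation's recovery sequence into four steps
#'
#' The perturbation step runs from the perturbed limb's heel strike
#' preceding onset to the first contralateral heel strike after onset; the
#' first recovery step from that contralateral strike to the next
#' perturbed-side strike; the second and third recovery steps continue
#' alternately.  Stance sides: `pert` and `rec2` belong to the perturbed
#' limb, `rec1` and `rec3` to the contralateral limb.
#'
#' @param pert one perturbation record (a row of
#'   [detect_perturbations()]'s output, or any list with `onset` and
#'   `side`).
#' @param events event table from [detect_gait_events()].
#' @return data frame with one row per step: `label`, `stance_side`,
#'   `start`, `end`.
#' @export
segment_recovery_steps <- function(pert, events) {
  side <- pert$side
  contra <- if (side == "left") "right" else "left"
  s_pert <- event_times(events, side, "heel_strike")
  s_contra <- event_times(events, contra, "heel_strike")
  s0 <- s_pert[s_pert <= pert$onset]
  if (!length(s0))
    abort_stumblr("no perturbed-side heel strike precedes the onset",
                  "truncated_recovery")
  s0 <- max(s0)
  pick <- function(pool, after) {
    v <- pool[pool > after]
    if (length(v)) min(v) else NA_real_
  }
  c1 <- pick(s_contra, pert$onset)
  p1 <- pick(s_pert, c1)
  c2 <- pick(s_contra, p1)
  p2 <- pick(s_pert, c2)
  bounds <- c(s0, c1, p1, c2, p2)
  if (anyNA(bounds)) {
    missing <- STEP_LABELS[which(is.na(bounds)) - 1L]
    abort_stumblr(paste("insufficient post-perturbation events; missing steps:",
                        paste(unique(missing), collapse = ", ")),
                  "truncated_recovery")
  }
  data.frame(label = STEP_LABELS,
             stance_side = c(side, contra, side, contra),
             start = bounds[1:4], end = bounds[2:5])
}
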