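#' Analyse one perturbation walking block
#'
#' Runs the full single-trial pipeline: preprocessing (gap filling,
#' zero-phase filtering, median filtering), gait-event detection,
#' belt-speed perturbation detection, recovery-step segmentation, the three
#' step metrics, and screening.
#'
#' @param trial a raw `trial_recording`.
#' @param bw a `body_weight` (from [body_weight_from_static()]) or the
#'   `static_trial` it derives from.
#' @param cfg a [pipeline_config()].
#' @return list with `step_metrics` (one row per perturbation x step),
#'   `screening` (one row per perturbation), `perturbations`, `events` and
#'   the preprocessed trial.
#' @export
analyze_trial <- function(trial, bw, cfg = pipeline_config()) {
  if (inherits(bw, "static_trial")) bw <- body_weight_from_static(bw)
  trial <- preprocess_trial(trial, cfg)
  events <- detect_gait_events(trial$markers, trial$marker_rate)
  perts <- detect_perturbations(trial$belt_speed, trial$force_rate, events,
                                trial$meta, cfg$belt_dev_threshold)
  theta <- trunk_angle_series(trial$markers, projection = cfg$trunk_projection)
  omega <- trunk_angular_velocity_series(theta, trial$marker_rate)
  grf_pct <- lapply(trial$forces, function(f)
    normalize_to_bw(grf_magnitude_series(f), bw))
  load_thr_pct <- normalize_to_bw(cfg$load_onset_force, bw)
  screening <- screen_perturbations(perts, trial, events, cfg)

  rows <- list()
  for (i in seq_len(nrow(perts))) {
    seg <- try(segment_recovery_steps(perts[i, ], events), silent = TRUE)
    if (inherits(seg, "try-error")) next
    for (s in seq_len(nrow(seg))) {
      sway <- step_trunk_sway(theta, trial$marker_rate, seg[s, ])
      pv <- step_peak_flexion_velocity(omega, trial$marker_rate, seg[s, ])
      pg <- try(step_peak_grf(grf_pct[[seg$stance_side[s]]], trial$force_rate,
                              seg[s, ], load_thr_pct,
                              cfg$peak_prominence_pct), silent = TRUE)
      grf_val <- if (inherits(pg, "try-error")) NA_real_ else pg$value
      grf_flag <- if (inherits(pg, "try-error")) TRUE else pg$flagged
      rows[[length(rows) + 1]] <- data.frame(
        pert_id = perts$id[i], side = perts$side[i],
        side_label = perts$side_label[i], label = seg$label[s],
        stance_side = seg$stance_side[s], start = seg$start[s],
        end = seg$end[s], trunk_sway = sway, peak_flexion_velocity = pv$value,
        vel_flagged = pv$flagged, peak_grf = grf_val, grf_flagged = grf_flag)
    }
  }
  step_metrics <- if (length(rows)) do.call(rbind, rows) else
    data.frame()
  if (nrow(step_metrics)) {
    m <- match(step_metrics$pert_id, screening$id)
    step_metrics$include_kinematic <- screening$include_kinematic[m]
    step_metrics$include_kinetic <- screening$include_kinetic[m]
    step_metrics$snp <- trial$meta$snp_condition
    step_metrics$block <- trial$meta$block %||% 1L
  }
  screening$snp <- trial$meta$snp_condition
  list(step_metrics = step_metrics, screening = screening,
       perturbations = perts, events = events, trial = trial)
}

#' Run the full analysis over a set of trials
#'
#' Executes preprocess, event detection, metrics and screening for every
#' trial, pools the per-step metrics over trials (each perturbation is one
#' analysis unit), and runs the inference layer separately for intact-side
#' and prosthetic-side perturbations: mixed-design repeated measures ANOVA
#' per metric, Bonferroni post-hoc comparisons per step, a Welch contrast
#' of first-recovery-step asymmetry per metric, and the handrail tally.
#' Re-running with the same inputs and configuration reproduces identical
#' outputs.
#'
#' @param trials list of `trial_recording`s (or a directory containing
#'   trial-bundle subdirectories readable by [read_trial_bundle()]).
#' @param static a `static_trial` used for body-weight normalisation.
#' @param cfg a [pipeline_config()].
#' @param out_dir optional directory for the interface files
#'   (`step_metrics.csv`, `screening.csv`, `anova_results.json`,
#'   `posthoc.csv`, `welch.csv`, `handrail_counts.csv`, `manifest.json`).
#' @return list with `step_metrics`, `screening`, `anova`, `posthoc`,
#'   `welch`, `handrail_counts` and `body_weight`.
#' @export
run_analysis <- function(trials, static, cfg = pipeline_config(),
                         out_dir = NULL) {
  if (is.character(trials)) {
    dirs <- list.dirs(trials, recursive = FALSE)
    if (!length(dirs))
      abort_stumblr("no trial bundles found in input directory", "io_error")
    trials <- lapply(dirs, read_trial_bundle)
  }
  if (!length(trials))
    abort_stumblr("no trials to analyse", "io_error")
  bw <- body_weight_from_static(static)
  per_trial <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    trials[[i]]$meta$block <- i
    per_trial[[i]] <- analyze_trial(trials[[i]], bw, cfg)
  }
  metrics <- do.call(rbind, lapply(seq_along(per_trial), function(i) {
    sm <- per_trial[[i]]$step_metrics
    if (nrow(sm)) sm$unit <- paste0("b", i, "p", sm$pert_id)
    sm
  }))
  screening <- do.call(rbind, lapply(seq_along(per_trial), function(i) {
    sc <- per_trial[[i]]$screening
    sc$block <- i
    sc
  }))

  metric_cols <- c(sway = "trunk_sway", vel = "peak_flexion_velocity",
                   grf = "peak_grf")
  anova_res <- list(); posthoc_res <- list(); welch_res <- list()
  for (side in c("intact", "prosthetic")) {
    for (mname in names(metric_cols)) {
      fam <- if (mname == "grf") "include_kinetic" else "include_kinematic"
      sub <- metrics[metrics$side_label == side & metrics[[fam]] &
                       !is.na(metrics[[metric_cols[mname]]]), , drop = FALSE]
      key <- paste(side, mname, sep = ".")
      cols <- c(unit = "unit", group = "snp", step = "label",
                value = metric_cols[[mname]])
      enough <- nrow(sub) > 0 &&
        all(table(factor(sub$snp, c("inactive", "active"))) >= 8)
      if (enough) {
        anova_res[[key]] <- mixed_anova(sub, cols = cols,
                                        sphericity_alpha = cfg$sphericity_alpha)
        ph <- bonferroni_posthoc(sub, cols = cols,
                                 family_size = cfg$posthoc_family)
        ph$side <- side; ph$metric <- mname
        sig <- any(anova_res[[key]]$effects$p[c(1, 3)] < 0.05)
        ph$exploratory <- !sig
        posthoc_res[[key]] <- ph
      }
    }
  }
  for (mname in names(metric_cols)) {
    fam <- if (mname == "grf") "include_kinetic" else "include_kinematic"
    rec1 <- metrics[metrics$label == "rec1" & metrics[[fam]] &
                      !is.na(metrics[[metric_cols[mname]]]), , drop = FALSE]
    ok <- nrow(rec1) > 0 &&
      all(table(factor(rec1$side_label, c("intact", "prosthetic")),
                factor(rec1$snp, c("inactive", "active"))) >= 2)
    if (ok)
      welch_res[[mname]] <- welch_asymmetry_test(
        rec1, cols = c(side = "side_label", group = "snp",
                       value = metric_cols[[mname]]))
  }
  handrail <- handrail_count_table(screening)

  result <- list(step_metrics = metrics, screening = screening,
                 anova = anova_res, posthoc = posthoc_res,
                 welch = welch_res, handrail_counts = handrail,
                 body_weight = bw)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    data.table::fwrite(metrics, file.path(out_dir, "step_metrics.csv"))
    data.table::fwrite(screening, file.path(out_dir, "screening.csv"))
    anova_json <- lapply(anova_res, function(a)
      list(effects = a$effects, mauchly = a$mauchly,
           epsilon_gg = a$epsilon_gg, corrected = a$corrected,
           n_per_group = a$n_per_group))
    jsonlite::write_json(anova_json, file.path(out_dir, "anova_results.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (length(posthoc_res))
      data.table::fwrite(do.call(rbind, posthoc_res),
                         file.path(out_dir, "posthoc.csv"))
    if (length(welch_res)) {
      wdf <- do.call(rbind, lapply(names(welch_res), function(nm)
        data.frame(metric = nm, estimate = welch_res[[nm]]$estimate,
                   se = welch_res[[nm]]$se, t = welch_res[[nm]]$t,
                   df = welch_res[[nm]]$df, p = welch_res[[nm]]$p)))
      data.table::fwrite(wdf, file.path(out_dir, "welch.csv"))
    }
    data.table::fwrite(as.data.frame(handrail),
                       file.path(out_dir, "handrail_counts.csv"))
    cfg_file <- tempfile(fileext = ".json")
    jsonlite::write_json(unclass(cfg), cfg_file, auto_unbox = TRUE,
                         digits = NA)
    manifest <- list(n_trials = length(trials),
                     config = unclass(cfg),
                     config_md5 = unname(tools::md5sum(cfg_file)),
                     body_weight_n = bw$value,
                     r_version = as.character(getRversion()))
    unlink(cfg_file)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}
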