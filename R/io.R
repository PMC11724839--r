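#' Write a trial bundle to disk
#'
#' One directory per trial: `markers.csv` (time, marker, x, y, z, valid),
#' `forces.csv` (time, plate, fx, fy, fz), `belt.csv` (time, speed),
#' `meta.json`, and optionally `ground_truth.json`.
#'
#' @param trial a `trial_recording`.
#' @param dir output directory (created if needed).
#' @param truth optional `ground_truth` to store alongside.
#' @return `dir`, invisibly.
#' @export
write_trial_bundle <- function(trial, dir, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- nrow(trial$markers[[1]])
  tm <- (seq_len(nm) - 1) / trial$marker_rate
  mk <- data.table::rbindlist(lapply(names(trial$markers), function(m) {
    data.table::data.table(time = tm, marker = m,
                           x = trial$markers[[m]][, 1],
                           y = trial$markers[[m]][, 2],
                           z = trial$markers[[m]][, 3],
                           valid = trial$marker_valid[[m]])
  }))
  data.table::fwrite(mk, file.path(dir, "markers.csv"))
  nf <- nrow(trial$forces$left)
  tf <- (seq_len(nf) - 1) / trial$force_rate
  fo <- data.table::rbindlist(lapply(names(trial$forces), function(p) {
    data.table::data.table(time = tf, plate = p,
                           fx = trial$forces[[p]][, 1],
                           fy = trial$forces[[p]][, 2],
                           fz = trial$forces[[p]][, 3])
  }))
  data.table::fwrite(fo, file.path(dir, "forces.csv"))
  data.table::fwrite(data.table::data.table(time = tf,
                                            speed = trial$belt_speed),
                     file.path(dir, "belt.csv"))
  meta <- trial$meta
  meta$marker_rate <- trial$marker_rate
  meta$force_rate <- trial$force_rate
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  if (!is.null(truth))
    jsonlite::write_json(unclass(truth), file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' Read a trial bundle written by [write_trial_bundle()]
#'
#' @param dir bundle directory.
#' @return a `trial_recording` (with `truth` attached as attribute
#'   `"truth"` when `ground_truth.json` is present).
#' @export
read_trial_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  mk <- data.table::fread(file.path(dir, "markers.csv"))
  markers <- list(); valid <- list()
  for (m in unique(mk$marker)) {
    sub <- mk[mk$marker == m, ]
    markers[[m]] <- cbind(sub$x, sub$y, sub$z)
    valid[[m]] <- as.logical(sub$valid)
  }
  fo <- data.table::fread(file.path(dir, "forces.csv"))
  forces <- list()
  for (p in unique(fo$plate)) {
    sub <- fo[fo$plate == p, ]
    forces[[p]] <- cbind(fx = sub$fx, fy = sub$fy, fz = sub$fz)
  }
  belt <- data.table::fread(file.path(dir, "belt.csv"))$speed
  trial <- structure(list(
    marker_rate = meta$marker_rate, force_rate = meta$force_rate,
    markers = markers, marker_valid = valid, forces = forces,
    belt_speed = belt,
    meta = meta[setdiff(names(meta), c("marker_rate", "force_rate"))]
  ), class = "trial_recording")
  gt_path <- file.path(dir, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    gt <- lapply(gt, function(x) if (is.list(x) && !is.data.frame(x))
      lapply(x, unlist) else x)
    attr(trial, "truth") <- structure(gt, class = "ground_truth")
  }
  trial
}
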