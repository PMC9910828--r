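# On-disk dataset layout: a manifest CSV (one row per trial: ids, factors,
# event times, movement time, relative path) plus one delimited time-series
# file per trial (columns time_ms, radial_pos, radial_vel, then one column
# per muscle) and per-participant calibration files. Time-series files carry
# a provenance header line recording the EMG processing state.

#' Write a dataset to the manifest + time-series layout
#'
#' @param dataset An `emg_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "trials"), showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "calibration"), showWarnings = FALSE)
  rows <- lapply(dataset$trials, function(tr) {
    path <- sprintf("trials/p%02d_t%04d.csv", as.integer(tr$participant_id),
                    as.integer(tr$trial_id))
    df <- data.frame(time_ms = tr$time_ms, tr$kin, tr$emg,
                     check.names = FALSE)
    con <- file(file.path(dir, path), "w")
    writeLines(sprintf("# emg_state: %s", tr$emg_state), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
    cbind(data.frame(trial_id = tr$trial_id,
                     participant_id = tr$participant_id,
                     stringsAsFactors = FALSE),
          as.data.frame(tr$condition, stringsAsFactors = FALSE),
          as.data.frame(as.list(tr$events)),
          data.frame(mt_ms = tr$mt %||% NA_real_, fs = tr$fs,
                     target_distance_cm = tr$geometry$target_distance_cm,
                     target_radius_cm = tr$geometry$target_radius_cm,
                     path = path))
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  for (p in names(dataset$calibrations)) {
    cal <- dataset$calibrations[[p]]
    for (i in seq_along(cal$holds)) {
      path <- file.path(dir, "calibration",
                        sprintf("p%02d_hold%d.csv", as.integer(p), i))
      con <- file(path, "w")
      writeLines(sprintf("# emg_state: %s", cal$state), con)
      writeLines(sprintf("# entry_ms: %g", cal$entry_ms[i]), con)
      utils::write.csv(as.data.frame(cal$holds[[i]]), con, row.names = FALSE)
      close(con)
    }
  }
  writeLines(dataset$design$task_id, file.path(dir, "task_id.txt"))
  invisible(dir)
}

#' Read a dataset from the manifest + time-series layout
#'
#' @param dir Directory written by [write_dataset()] (or assembled by hand
#'   for real recordings, following the same layout).
#' @param design Optional `task_design`; defaults to the task named in the
#'   directory's `task_id.txt`.
#' @return An `emg_dataset`.
#' @export
read_dataset <- function(dir, design = NULL) {
  if (is.null(design)) {
    design <- task_design(readLines(file.path(dir, "task_id.txt"))[1])
  }
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  factor_names <- names(design$factors)
  event_names <- c("target_onset", "perturbation", "jump", "start_exit",
                   "target_entry")
  trials <- lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    lines <- readLines(file.path(dir, row$path))
    state <- sub("^# emg_state: ", "", lines[1])
    df <- utils::read.csv(text = lines[-1])
    muscles <- setdiff(names(df), c("time_ms", "radial_pos", "radial_vel"))
    events <- vapply(event_names, function(e)
      if (e %in% names(row)) as.numeric(row[[e]]) else NA_real_, numeric(1))
    structure(list(
      trial_id = row$trial_id, participant_id = row$participant_id,
      condition = as.list(row[factor_names]),
      fs = row$fs, time_ms = df$time_ms, events = events,
      emg = as.matrix(df[muscles]), emg_state = state,
      kin = as.matrix(df[c("radial_pos", "radial_vel")]),
      geometry = list(target_distance_cm = row$target_distance_cm,
                      target_radius_cm = row$target_radius_cm),
      aligned_to = NULL,
      mt = if (is.na(row$mt_ms)) NA_real_ else row$mt_ms,
      ground_truth = NULL
    ), class = "trial_recording")
  })
  participants <- sort(unique(manifest$participant_id))
  calibrations <- list()
  for (p in participants) {
    files <- file.path(dir, "calibration",
                       sprintf("p%02d_hold%d.csv", as.integer(p), 1:4))
    holds <- list(); entry <- numeric(4); state <- "raw"
    for (i in 1:4) {
      lines <- readLines(files[i])
      state <- sub("^# emg_state: ", "", lines[1])
      entry[i] <- as.numeric(sub("^# entry_ms: ", "", lines[2]))
      holds[[i]] <- as.matrix(utils::read.csv(text = lines[-(1:2)]))
    }
    calibrations[[as.character(p)]] <-
      structure(list(holds = holds, entry_ms = entry,
                     fs = trials[[1]]$fs, state = state),
                class = "calibration_set")
  }
  structure(list(design = design, config = NULL, schedule = NULL,
                 trials = trials, calibrations = calibrations,
                 participants = participants),
            class = "emg_dataset")
}
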