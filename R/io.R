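# CSV dialects shared by the simulator, the fitting stages and the CLI.

# write.csv truncates doubles to 15 significant digits, which is enough to
# perturb near-tied nonlinear fits on reload; serialize numerics losslessly.
write_csv_full <- function(df, path) {
  for (cn in names(df)) {
    if (is.double(df[[cn]])) {
      x <- sprintf("%.17g", df[[cn]])
      x[is.na(df[[cn]])] <- NA
      df[[cn]] <- x
    }
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write/read a blood dataset as CSV
#'
#' Columns: `time_min`, `source` (`auto`/`manual`), `wb_activity`,
#' `plasma_activity`, `parent_fraction` (the latter two `NA` for automated
#' rows). A `subject` column is added when `subject_id` is given.
#'
#' @param dataset A [blood_dataset()].
#' @param path CSV path.
#' @param subject_id Optional subject identifier column value.
#' @export
write_blood_csv <- function(dataset, path, subject_id = NULL) {
  df <- rbind(
    data.frame(time_min = dataset$auto_times_s / 60, source = "auto",
               wb_activity = dataset$auto_wb_activity,
               plasma_activity = NA_real_, parent_fraction = NA_real_),
    data.frame(time_min = dataset$manual_times_min, source = "manual",
               wb_activity = dataset$manual_wb_activity,
               plasma_activity = dataset$manual_plasma_activity,
               parent_fraction = dataset$manual_parent_fraction)
  )
  if (!is.null(subject_id)) df <- cbind(subject = subject_id, df)
  write_csv_full(df, path)
  invisible(path)
}

#' @rdname write_blood_csv
#' @param subject When the CSV holds several subjects, which one to load.
#' @export
read_blood_csv <- function(path, subject = NULL) {
  df <- read.csv(path)
  if (!is.null(subject)) df <- df[df$subject == subject, , drop = FALSE]
  a <- df[df$source == "auto", , drop = FALSE]
  m <- df[df$source == "manual", , drop = FALSE]
  a <- a[order(a$time_min), ]; m <- m[order(m$time_min), ]
  blood_dataset(a$time_min * 60, a$wb_activity, m$time_min, m$wb_activity,
                m$plasma_activity, m$parent_fraction)
}

#' Write/read time-activity curves as CSV
#'
#' Columns: `subject`, `region`, `frame_start_s`, `frame_dur_s`, `activity`.
#'
#' @param tacs Named list of [time_activity_curve()] objects.
#' @param path CSV path.
#' @param subject_id Subject identifier.
#' @param append Append to an existing file.
#' @export
write_tacs_csv <- function(tacs, path, subject_id, append = FALSE) {
  rows <- do.call(rbind, lapply(tacs, function(tac) {
    data.frame(subject = subject_id, region = tac$region,
               frame_start_s = tac$frame_start_s,
               frame_dur_s = tac$frame_dur_s, activity = tac$activity)
  }))
  if (append && file.exists(path)) {
    old <- read.csv(path)
    rows <- rbind(old, rows)
  }
  write_csv_full(rows, path)
  invisible(path)
}

#' @rdname write_tacs_csv
#' @export
read_tacs_csv <- function(path) {
  df <- read.csv(path)
  out <- list()
  for (sid in unique(df$subject)) {
    sdf <- df[df$subject == sid, ]
    out[[sid]] <- setNames(lapply(unique(sdf$region), function(r) {
      rdf <- sdf[sdf$region == r, ]
      rdf <- rdf[order(rdf$frame_start_s), ]
      time_activity_curve(r, rdf$frame_start_s, rdf$frame_dur_s, rdf$activity)
    }), unique(sdf$region))
  }
  out
}

#' Write the regional V_T table as CSV
#'
#' Columns: `subject_id`, `region`, `VT`, `VT_se`, `K1`, `k2`, `k3`, `k4`,
#' `rss`, `converged`, `pvc`.
#'
#' @param fits Data frame of per-subject, per-region fit summaries.
#' @param path CSV path.
#' @export
write_vt_csv <- function(fits, path) {
  write.csv(fits, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vt_csv
#' @export
read_vt_csv <- function(path) read.csv(path)
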