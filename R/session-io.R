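#' Write a session to disk
#'
#' Lays out a session directory readable by [read_session()]: one CSV per
#' trial for the combined EEG+EOG recording (31 labelled columns, microvolts)
#' and for the IMU trace (`xz`, `yz`), a baseline CSV, and a JSON sidecar with
#' markers and metadata. Numeric values are written with 17 significant
#' digits so the round trip is exact.
#'
#' @param session A [session()].
#' @param path Directory to create/overwrite.
#' @return A tibble manifest: `file`, `md5`.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "session"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(path))
    abort(paste0("Cannot create directory: ", path),
          class = "turnintent_io_error")

  write_num_csv <- function(m, file) {
    df <- as.data.frame(m)
    df[] <- lapply(df, function(col) formatC(col, format = "g", digits = 17))
    write.csv(df, file, row.names = FALSE, quote = FALSE)
  }

  files <- character(0)
  f <- file.path(path, "asr_baseline.csv")
  write_num_csv(session$asr_baseline$samples, f)
  files <- c(files, f)

  meta <- list(
    subject_id = session$subject_id,
    fs_eeg = if (length(session$trials)) session$trials[[1]]$eeg$fs else 500,
    fs_imu = if (length(session$trials)) session$trials[[1]]$imu$fs else 50,
    baseline_fs = session$asr_baseline$fs,
    n_trials = length(session$trials),
    trials = lapply(session$trials, function(tr) {
      gt <- tr$ground_truth
      list(basal_end = tr$basal_end,
           t0 = tr$eeg$t0,
           third_step_marks = tr$third_step_marks,
           ground_truth = if (is.null(gt)) NULL else as.list(gt))
    }))

  for (i in seq_along(session$trials)) {
    tr <- session$trials[[i]]
    tag <- sprintf("trial_%02d", i)
    f_eeg <- file.path(path, paste0(tag, "_eeg.csv"))
    f_imu <- file.path(path, paste0(tag, "_imu.csv"))
    write_num_csv(cbind(tr$eeg$samples, tr$eog$samples), f_eeg)
    write_num_csv(cbind(xz = tr$imu$xz, yz = tr$imu$yz), f_imu)
    files <- c(files, f_eeg, f_imu)
  }

  f_meta <- file.path(path, "session.json")
  jsonlite::write_json(meta, f_meta, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  files <- c(files, f_meta)

  tibble::tibble(file = basename(files),
                 md5 = unname(tools::md5sum(files)))
}

#' Read a session directory
#'
#' Inverse of [write_session()]. EEG and EOG channels are normalized to the
#' canonical montage order whatever their column order on disk; non-finite
#' samples and EEG/IMU duration mismatches beyond one IMU sample period are
#' rejected.
#'
#' @param path Session directory.
#' @param channels A [channel_set()] describing the expected montage.
#' @return A [session()].
#' @export
read_session <- function(path, channels = channel_set()) {
  f_meta <- file.path(path, "session.json")
  if (!file.exists(f_meta))
    abort(paste0("No session.json in ", path), class = "turnintent_io_error")
  meta <- jsonlite::read_json(f_meta, simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)

  read_num_csv <- function(file) {
    m <- as.matrix(read.csv(file, check.names = FALSE))
    if (any(!is.finite(m)))
      abort(paste0("Non-finite samples in ", basename(file)),
            class = "turnintent_data_error")
    m
  }

  base_m <- read_num_csv(file.path(path, "asr_baseline.csv"))
  baseline <- recording(base_m, fs = meta$baseline_fs)

  trials <- lapply(seq_len(meta$n_trials), function(i) {
    tag <- sprintf("trial_%02d", i)
    tmeta <- meta$trials[[i]]
    m <- read_num_csv(file.path(path, paste0(tag, "_eeg.csv")))
    parts <- split_eeg_eog(m, colnames(m), channels)
    imu_m <- read_num_csv(file.path(path, paste0(tag, "_imu.csv")))
    t0 <- if (is.null(tmeta$t0)) 0 else tmeta$t0
    gt <- tmeta$ground_truth
    if (!is.null(gt)) gt <- tibble::as_tibble(gt)
    trial(
      eeg = recording(parts$eeg, fs = meta$fs_eeg,
                      labels = channels$eeg_labels, t0 = t0),
      eog = recording(parts$eog, fs = meta$fs_eeg,
                      labels = channels$eog_labels, t0 = t0),
      imu = imu_trace(imu_m[, "xz"], imu_m[, "yz"], fs = meta$fs_imu, t0 = t0),
      basal_end = tmeta$basal_end,
      third_step_marks = unlist(tmeta$third_step_marks),
      ground_truth = gt)
  })

  session(trials, baseline, subject_id = meta$subject_id)
}
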