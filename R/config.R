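#' Analysis frequency bands
#'
#' The five bands the pipeline isolates before covariance extraction:
#' alpha (8-14 Hz), low beta (15-22 Hz), high beta (23-30 Hz), low gamma
#' (31-40 Hz) and broadband (8-40 Hz).
#'
#' @return A tibble with columns `band` (label), `low_hz`, `high_hz`.
#' @export
standard_bands <- function() {
  tibble::tibble(
    band    = c("8-14", "15-22", "23-30", "31-40", "8-40"),
    low_hz  = c(8, 15, 23, 31, 8),
    high_hz = c(14, 22, 30, 40, 40))
}

#' Construct a band specification
#'
#' @param band A label such as `"8-40"`, or a numeric `c(low, high)` in Hz.
#' @param custom_band Allow bands outside the five standard ones.
#' @return A `band_spec` list with `low_hz`, `high_hz`, `band`.
#' @export
band_spec <- function(band = "8-40", custom_band = FALSE) {
  std <- standard_bands()
  if (is.character(band)) {
    band <- gsub("_", "-", band)
    i <- match(band, std$band)
    if (is.na(i)) {
      parts <- suppressWarnings(as.numeric(strsplit(band, "-")[[1]]))
      if (length(parts) != 2 || anyNA(parts))
        abort(paste0("Unknown band label: ", band),
              class = "turnintent_config_error")
      return(band_spec(parts, custom_band = custom_band))
    }
    lo <- std$low_hz[i]; hi <- std$high_hz[i]; lab <- std$band[i]
  } else {
    lo <- band[1]; hi <- band[2]
    lab <- paste0(format(lo), "-", format(hi))
    i <- which(std$low_hz == lo & std$high_hz == hi)
    if (!length(i) && !custom_band)
      abort(paste0("Band ", lab, " is not one of the five standard bands; ",
                   "set `custom_band = TRUE` to allow it."),
            class = "turnintent_config_error")
  }
  if (!(lo > 0 && hi > lo))
    abort("Band must satisfy 0 < low < high.",
          class = "turnintent_config_error")
  structure(list(low_hz = lo, high_hz = hi, band = lab), class = "band_spec")
}

#' Run configuration
#'
#' Bundles every tunable the decoding pipeline uses: artifact filter, band,
#' classifier, epoch geometry, decision rule and class-window placement.
#' Defaults reproduce the study protocol: 1.2 s epochs slid every 0.2 s, a
#' decision after 5 consecutive intent epochs (pseudo-online; 4 online), a
#' 0.4 s true-positive margin (0.6 s online), a 2 s refractory period between
#' counted false positives, a walking-class window at \[-6.0, -4.8) s and an
#' intent window at \[-1.4, -0.2) s relative to the detected turn.
#'
#' @param artifact_filter One of `"hinf"`, `"asr"`, `"none"`.
#' @param band Band label or `c(low, high)` Hz; see [band_spec()].
#' @param classifier One of `"mdm"`, `"mdm_filter"`, `"ts_lda"`, `"ts_svm"`.
#' @param epoch_len_s,shift_s Epoch length and slide step, seconds.
#' @param mode Consecutive intent classifications required for a command.
#' @param tp_margin_s Maximum anticipation (s) for a decision to count as TP.
#' @param refractory_s Minimum time between counted false positives.
#' @param walk_window,intent_window Class windows (s, relative to the turn,
#'   half-open `[start, end)`), each of width `epoch_len_s`.
#' @param custom_band Allow non-standard bands.
#' @param rng_seed Optional integer seed recorded with the configuration.
#' @return A `run_config` object.
#' @export
run_config <- function(artifact_filter = c("hinf", "asr", "none"),
                       band = "8-40",
                       classifier = c("mdm", "mdm_filter", "ts_lda", "ts_svm"),
                       epoch_len_s = 1.2,
                       shift_s = 0.2,
                       mode = 5L,
                       tp_margin_s = 0.4,
                       refractory_s = 2.0,
                       walk_window = c(-6.0, -4.8),
                       intent_window = c(-1.4, -0.2),
                       custom_band = FALSE,
                       rng_seed = NULL) {
  artifact_filter <- match.arg(artifact_filter)
  classifier <- match.arg(classifier)
  band <- if (inherits(band, "band_spec")) band else
    band_spec(band, custom_band = custom_band)
  if (epoch_len_s <= 0 || shift_s <= 0)
    abort("epoch_len_s and shift_s must be positive.",
          class = "turnintent_config_error")
  ratio <- epoch_len_s / shift_s
  if (abs(ratio - round(ratio)) > 1e-9)
    abort("epoch_len_s must be an integer multiple of shift_s.",
          class = "turnintent_config_error")
  for (w in list(walk = walk_window, intent = intent_window)) {
    if (abs(diff(w) - epoch_len_s) > 1e-9)
      abort("Class windows must have width equal to epoch_len_s.",
            class = "turnintent_config_error")
  }
  if (mode < 1) abort("mode must be >= 1.", class = "turnintent_config_error")
  structure(
    list(artifact_filter = artifact_filter, band = band,
         classifier = classifier,
         epoch_len_s = epoch_len_s, shift_s = shift_s, mode = as.integer(mode),
         tp_margin_s = tp_margin_s, refractory_s = refractory_s,
         walk_window = walk_window, intent_window = intent_window,
         rng_seed = rng_seed),
    class = "run_config")
}

#' Online preset of the run configuration
#'
#' Same pipeline with the decision rule used in the live two-phase protocol:
#' 4 consecutive intent epochs and a 0.6 s margin.
#'
#' @param ... Overrides passed to [run_config()].
#' @export
run_config_online <- function(...) {
  args <- list(...)
  defaults <- list(mode = 4L, tp_margin_s = 0.6)
  do.call(run_config, utils::modifyList(defaults, args))
}

#' Load a run configuration from a YAML or JSON file
#'
#' Unspecified fields take the pipeline defaults (see [run_config()]).
#'
#' @param path Path to a YAML/JSON file, or `NULL` for pure defaults.
#' @return A `run_config`.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(run_config())
  if (!file.exists(path))
    abort(paste0("Config file not found: ", path),
          class = "turnintent_config_error")
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warn(paste0("Ignoring unknown config fields: ",
                paste(extra, collapse = ", ")))
  raw <- raw[intersect(names(raw), known)]
  if (!is.null(raw$band) && is.numeric(raw$band) && length(raw$band) == 2)
    raw$band <- as.numeric(raw$band)
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat("  artifact filter :", x$artifact_filter, "\n")
  cat("  band            :", x$band$band, "Hz\n")
  cat("  classifier      :", x$classifier, "\n")
  cat(sprintf("  epochs          : %.1f s every %.1f s\n",
              x$epoch_len_s, x$shift_s))
  cat(sprintf("  decision        : mode %d, TP margin %.1f s, refractory %.1f s\n",
              x$mode, x$tp_margin_s, x$refractory_s))
  cat(sprintf("  class windows   : walk [%.1f, %.1f) s, intent [%.1f, %.1f) s\n",
              x$walk_window[1], x$walk_window[2],
              x$intent_window[1], x$intent_window[2]))
  invisible(x)
}
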