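#' Write a recording as a flat binary matrix with a JSON sidecar
#'
#' Samples are stored as little-endian float64, column-major
#' (time-by-channel), in `<prefix>.bin`; channel labels, sampling rate,
#' subject, eye state and provenance go to `<prefix>.json`. The round-trip
#' through [read_recording_matrix()] is bit-identical.
#'
#' @param rec An [eeg_recording()].
#' @param prefix Output path prefix (without extension).
#' @return The prefix, invisibly.
#' @export
write_recording_matrix <- function(rec, prefix) {
  stopifnot(inherits(rec, "eeg_recording"))
  con <- file(paste0(prefix, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.vector(rec$samples), con, size = 8, endian = "little")
  meta <- list(
    subject_id = rec$subject_id, eye_state = rec$eye_state,
    sampling_rate_hz = rec$sfreq, channels = rec$channels,
    n_samples = nrow(rec$samples), unit = "uV",
    order = "column-major time x channel", dtype = "float64-le",
    provenance = rec$provenance
  )
  jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a recording from a flat binary matrix + JSON sidecar
#'
#' @param prefix Path prefix used by [write_recording_matrix()].
#' @return An [eeg_recording()].
#' @export
read_recording_matrix <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, ".json"), simplifyVector = TRUE)
  n <- meta$n_samples * length(meta$channels)
  con <- file(paste0(prefix, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  samples <- matrix(x, meta$n_samples, length(meta$channels))
  prov <- meta$provenance
  if (is.data.frame(prov)) prov <- lapply(seq_len(nrow(prov)), function(i) as.list(prov[i, ]))
  eeg_recording(samples, as.numeric(meta$sampling_rate_hz),
    channels = meta$channels,
    subject_id = meta$subject_id, eye_state = meta$eye_state,
    provenance = if (length(prov)) prov else list()
  )
}

# Fixed-width ASCII field for EDF headers.
.edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer: 16-bit samples, physical dimension
#' uV, one-second data records. The physical range is set per channel to
#' +/- (1.05 x max |amplitude|), so quantization error is below 0.1 uV for
#' signals within +/-200 uV. Any trailing partial second is dropped.
#'
#' @param rec An [eeg_recording()] with integer sampling rate.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"), rec$sfreq == round(rec$sfreq))
  ns <- length(rec$channels)
  spr <- as.integer(rec$sfreq) # samples per 1-s record
  n_rec <- nrow(rec$samples) %/% spr
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  x <- rec$samples[seq_len(n_rec * spr), , drop = FALSE]
  pmax_ <- pmax(apply(abs(x), 2, max) * 1.05, 1)
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field(paste("subject", rec$subject_id), 80),
    .edf_field(paste("recording", rec$eye_state), 80),
    "01.01.00", "00.00.00",
    .edf_field(256 + ns * 256, 8),
    .edf_field("", 44),
    .edf_field(n_rec, 8),
    .edf_field(1, 8),
    .edf_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    list(rec$channels, 16),
    list(rep("AgAgCl electrode", ns), 80),
    list(rep("uV", ns), 8),
    list(sprintf("%.6g", -pmax_), 8),
    list(sprintf("%.6g", pmax_), 8),
    list(rep(dmin, ns), 8),
    list(rep(dmax, ns), 8),
    list(rep("", ns), 80),
    list(rep(spr, ns), 8),
    list(rep("", ns), 32)
  )
  for (fd in fields) {
    writeChar(paste0(vapply(fd[[1]], .edf_field, "", width = fd[[2]]), collapse = ""),
      con,
      eos = NULL
    )
  }
  scale <- (dmax - dmin) / (2 * pmax_)
  for (r in seq_len(n_rec)) {
    seg <- x[seq((r - 1) * spr + 1, r * spr), , drop = FALSE]
    dig <- round(sweep(seg, 2, -pmax_, `-`) * rep(scale, each = spr)) + dmin
    writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Reads 16-bit EDF files with uV (or mV, auto-scaled with a warning)
#' physical dimension and maps channel labels to the canonical 10-20 set.
#'
#' @param path EDF file path.
#' @param subject_id,eye_state Metadata not representable in plain EDF.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = "S000", eye_state = "EC") {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nb) readChar(con, nb, useBytes = TRUE)
  rd(8) # version
  rd(80); rd(80); rd(8); rd(8) # patient, recording, date, time
  rd(8) # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- trimws(vapply(seq_len(ns), function(i) rd(16), ""))
  vapply(seq_len(ns), function(i) rd(80), "") # transducer
  dims <- trimws(vapply(seq_len(ns), function(i) rd(8), ""))
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(80), "") # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  vapply(seq_len(ns), function(i) rd(32), "")
  if (length(unique(spr)) != 1) stop("channels with differing sampling rates are not supported")
  bad_dim <- !(tolower(dims) %in% c("uv", "µv", "mv"))
  if (any(bad_dim)) {
    stop("unsupported physical dimension(s): ", paste(unique(dims[bad_dim]), collapse = ", "))
  }
  unit_scale <- ifelse(tolower(dims) == "mv", 1000, 1)
  if (any(unit_scale != 1)) warning("mV channels auto-scaled to uV")
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  x <- matrix(0, n_rec * spr[1], ns)
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = spr[1] * ns, size = 2, endian = "little")
    seg <- matrix(raw, spr[1], ns)
    rows <- seq((r - 1) * spr[1] + 1, r * spr[1])
    x[rows, ] <- (sweep(seg, 2, dmin, `-`) * rep(gain, each = spr[1])) +
      rep(pmin_, each = spr[1])
  }
  x <- x * rep(unit_scale, each = nrow(x))
  eeg_recording(x, spr[1] / rec_dur,
    channels = normalize_channel_labels(labels),
    subject_id = subject_id, eye_state = eye_state,
    provenance = list(list(step = "read_edf", params = list(path = path)))
  )
}

#' Write cohort tables to disk
#'
#' Writes the tidy feature table, metadata, group statistics, clinical
#' correlations (CSV) and the model report (JSON) into a directory; a
#' machine-readable run log with the configuration hash accompanies them.
#'
#' @param result A study result list from [run_study()].
#' @param dir Output directory (created if absent).
#' @return The directory, invisibly.
#' @export
write_study_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$features, file.path(dir, "features.csv"), row.names = FALSE)
  utils::write.csv(result$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  utils::write.csv(result$stats, file.path(dir, "group_stats.csv"), row.names = FALSE)
  utils::write.csv(result$correlations, file.path(dir, "correlations.csv"), row.names = FALSE)
  model <- result$model
  model_json <- list(
    coefficients = model$coefficients,
    cv_mean_auc = model$cv_mean_auc,
    cv_sensitivity = model$cv_sensitivity,
    cv_specificity = model$cv_specificity,
    auc_ci_95 = model$auc_ci_95,
    youden_cutoff = model$roc$youden_cutoff,
    separable = model$separable, seed = model$seed
  )
  jsonlite::write_json(model_json, file.path(dir, "model_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  jsonlite::write_json(result$run_log, file.path(dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Write a generated cohort to disk
#'
#' Serializes a cohort from [generate_cohort()]: the metadata table and the
#' ground-truth artifact table as CSV, and every recording either as EDF or
#' as flat binary matrix + JSON sidecar under `dir/recordings/`.
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param format `"matrix"` (bit-exact) or `"edf"` (16-bit).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("matrix", "edf")) {
  format <- match.arg(format)
  rec_dir <- file.path(dir, "recordings")
  dir.create(rec_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$meta, file.path(dir, "meta.csv"), row.names = FALSE)
  art <- cohort$artifacts
  if (is.null(art)) {
    art <- tibble::tibble(
      subject_id = character(), eye_state = character(), start_s = numeric(),
      end_s = numeric(), kind = character(), channel = character(),
      peak_uv = numeric()
    )
  }
  utils::write.csv(art, file.path(dir, "artifacts.csv"), row.names = FALSE)
  for (sub in names(cohort$recordings)) {
    for (st in c("EO", "EC")) {
      rec <- cohort$recordings[[sub]][[st]]
      stem <- file.path(rec_dir, paste0(sub, "_", st))
      if (format == "edf") {
        write_edf(rec, paste0(stem, ".edf"))
      } else {
        write_recording_matrix(rec, stem)
      }
    }
  }
  invisible(dir)
}

#' Save / load a preprocessing configuration
#'
#' JSON round-trip of a [preprocess_config()]: `load_pipeline_config()`
#' restores an object equal to the one saved.
#'
#' @param config A [preprocess_config()].
#' @param path File path.
#' @return `save_pipeline_config()` the path, invisibly;
#'   `load_pipeline_config()` the configuration.
#' @export
save_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "preprocess_config"))
  jsonlite::write_json(unclass(config), path,
    auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname save_pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- preprocess_config(
    band = as.numeric(raw$band),
    notch = if (is.null(raw$notch)) NULL else as.numeric(raw$notch),
    resample_hz = if (is.null(raw$resample_hz)) NULL else as.numeric(raw$resample_hz),
    epoch_s = as.numeric(raw$epoch_s),
    reject_uv = as.numeric(raw$reject_uv),
    ica = isTRUE(raw$ica),
    ica_seed = as.integer(raw$ica_seed)
  )
  cfg
}
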