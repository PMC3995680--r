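# Domain types and plain-CSV readers/writers for raw recordings, epoch tables,
# bout labels, subject covariates and calorimetry tables. All accelerations are
# in milli-g (mg); 1 G = 1000 mg. Sample indexing is 0-based and sampling is
# uniform by contract (no timestamp column).

DEVICE_RANGE_MG <- 6000
DEVICE_RESOLUTION_MG <- 3

#' Calibration task taxonomy
#'
#' The eleven calibration tasks and their locomotive/nonlocomotive class.
#' Nonlocomotive tasks are posture-varying lifestyle activities (desk work,
#' playing a handheld game, sweeping, tidying, floor washing, ball throwing);
#' locomotive tasks are gait-based (stair climbing, walking, jogging).
#'
#' @return A data.frame with columns `activity` and `true_class`.
#' @export
grpaca_activities <- function() {
  data.frame(
    activity = c("desk work", "Nintendo DS", "sweeping up", "clearing away",
                 "washing the floor", "throwing a ball",
                 "climbing down", "climbing up", "normal walking",
                 "brisk walking", "jogging"),
    true_class = c(rep("nonlocomotive", 6), rep("locomotive", 5)),
    stringsAsFactors = FALSE
  )
}

#' Construct a triaxial recording
#'
#' A uniformly sampled three-axis acceleration series in mg with the device
#' limits of the waist-worn monitor this package models (±6000 mg range,
#' 3 mg resolution, nominal 32 Hz sampling).
#'
#' @param ax,ay,az Numeric vectors of equal length, acceleration in mg along
#'   the vertical (x), anteroposterior (y) and mediolateral (z) axes.
#' @param sampling_rate_hz Sampling rate in Hz (default 32).
#' @param device_range_mg Absolute measurement limit in mg (default 6000).
#' @param resolution_mg Device resolution in mg (default 3); informational,
#'   raw inputs are not re-quantized.
#' @return An object of class `triaxial_recording`.
#' @export
triaxial_recording <- function(ax, ay, az, sampling_rate_hz = 32,
                               device_range_mg = DEVICE_RANGE_MG,
                               resolution_mg = DEVICE_RESOLUTION_MG) {
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(ax)
  if (n == 0L) stop("recording must contain at least one sample")
  if (length(ay) != n || length(az) != n)
    stop("axis vectors must have equal length")
  if (anyNA(ax) || anyNA(ay) || anyNA(az))
    stop("recording contains missing values; parsers never coerce silently")
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be a positive real")
  bad <- which(abs(ax) > device_range_mg | abs(ay) > device_range_mg |
                 abs(az) > device_range_mg)
  if (length(bad))
    stop(sprintf(
      "sample %d exceeds the device measurement range of ±%d mg",
      bad[1] - 1L, device_range_mg))
  structure(
    list(samples = data.frame(ax = ax, ay = ay, az = az),
         sampling_rate_hz = sampling_rate_hz,
         device_range_mg = device_range_mg,
         resolution_mg = resolution_mg),
    class = "triaxial_recording"
  )
}

#' @export
length.triaxial_recording <- function(x) nrow(x$samples)

#' @export
print.triaxial_recording <- function(x, ...) {
  cat(sprintf("<triaxial_recording: %d samples @ %g Hz (%.1f s)>\n",
              length(x), x$sampling_rate_hz,
              length(x) / x$sampling_rate_hz))
  invisible(x)
}

RAW_HEADER <- "sample_index,ax_mg,ay_mg,az_mg"

# read.csv with colClasses = "numeric" errors out on malformed numeric fields,
# which is exactly the reject-don't-coerce contract.
.read_strict_csv <- function(path, header, col_classes) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop(sprintf("empty file (no samples): %s", path))
  if (trimws(first) != header)
    stop(sprintf("format error in %s: expected header '%s', found '%s'",
                 path, header, first))
  utils::read.csv(path, colClasses = col_classes, stringsAsFactors = FALSE)
}

#' Read a raw triaxial recording from CSV
#'
#' Expects the exact header `sample_index,ax_mg,ay_mg,az_mg`. Values outside
#' the ±6000 mg device range are a range error naming the offending row;
#' malformed numeric fields are rejected, never coerced.
#'
#' @param path Path to a raw recording CSV.
#' @param sampling_rate_hz Sampling rate in Hz (default 32).
#' @return A [triaxial_recording()].
#' @export
read_raw_recording <- function(path, sampling_rate_hz = 32) {
  df <- .read_strict_csv(path, RAW_HEADER, rep("numeric", 4))
  if (nrow(df) == 0L) stop(sprintf("no samples in %s", path))
  triaxial_recording(df$ax_mg, df$ay_mg, df$az_mg,
                     sampling_rate_hz = sampling_rate_hz)
}

#' Write a raw triaxial recording to CSV
#'
#' @param recording A [triaxial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw_recording <- function(recording, path) {
  stopifnot(inherits(recording, "triaxial_recording"))
  df <- data.frame(sample_index = seq_len(length(recording)) - 1L,
                   ax_mg = recording$samples$ax,
                   ay_mg = recording$samples$ay,
                   az_mg = recording$samples$az)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an epoch feature table
#'
#' Per-epoch synthetic-acceleration summaries: USA (unfiltered synthetic
#' acceleration, per-axis epoch mean removed), FSA (filtered synthetic
#' acceleration, gravity removed by the high-pass filter) and their ratio.
#' The ratio is undefined (`NA`) for movement-free epochs where FSA falls
#' below the movement floor.
#'
#' @param epoch_index 0-based epoch indices.
#' @param n_samples Samples per epoch.
#' @param usa_mg,fsa_mg Non-negative epoch features in mg.
#' @param ratio USA/FSA, `NA` where undefined.
#' @return A data.frame of class `epoch_features`.
#' @export
epoch_features <- function(epoch_index, n_samples, usa_mg, fsa_mg, ratio) {
  if (any(usa_mg < 0) || any(fsa_mg < 0))
    stop("usa_mg and fsa_mg must be non-negative")
  out <- data.frame(epoch_index = as.integer(epoch_index),
                    n_samples = as.integer(n_samples),
                    usa_mg = as.numeric(usa_mg),
                    fsa_mg = as.numeric(fsa_mg),
                    ratio = as.numeric(ratio))
  class(out) <- c("epoch_features", "data.frame")
  out
}

#' Construct an activity bout
#'
#' A subject-by-task steady-state segment: its true activity class and the
#' epoch features computed from its recording.
#'
#' @param subject_id Subject identifier.
#' @param activity Task label (see [grpaca_activities()] for the calibration
#'   taxonomy; custom labels are allowed for simulated tasks).
#' @param true_class `"nonlocomotive"` or `"locomotive"`.
#' @param epochs An [epoch_features()] table with at least one row.
#' @param steady_state_min Steady-state duration in minutes (informational).
#' @return An object of class `activity_bout`.
#' @export
activity_bout <- function(subject_id, activity, true_class, epochs,
                          steady_state_min = NA_real_) {
  true_class <- match.arg(true_class, c("nonlocomotive", "locomotive"))
  if (!inherits(epochs, "data.frame") || nrow(epochs) == 0L)
    stop("bout must contain at least one epoch")
  structure(list(subject_id = as.character(subject_id),
                 activity = as.character(activity),
                 true_class = true_class,
                 epochs = epochs,
                 steady_state_min = steady_state_min),
            class = "activity_bout")
}

EPOCH_HEADER <- "subject_id,activity,epoch_index,usa_mg,fsa_mg,ratio,predicted_class"

#' Write an epoch feature table to CSV
#'
#' Emits `subject_id,activity,epoch_index,usa_mg,fsa_mg,ratio,predicted_class`
#' with features printed to six decimals; an undefined ratio is written as an
#' empty field.
#'
#' @param features An [epoch_features()] table (or data.frame with the same
#'   columns, optionally already carrying `subject_id`/`activity`/
#'   `predicted_class` columns).
#' @param path Output path.
#' @param subject_id,activity Bout metadata used when `features` does not
#'   carry its own columns.
#' @param predicted_class Optional per-epoch class labels; when omitted they
#'   are computed with the default classifier configuration.
#' @return `path`, invisibly.
#' @export
write_epoch_table <- function(features, path, subject_id = "unknown",
                              activity = "unknown", predicted_class = NULL) {
  if (nrow(features) == 0L) stop("features must be non-empty")
  sid <- if ("subject_id" %in% names(features)) features$subject_id else subject_id
  act <- if ("activity" %in% names(features)) features$activity else activity
  if (is.null(predicted_class)) {
    predicted_class <- if ("predicted_class" %in% names(features))
      features$predicted_class else classify_epoch(features, classifier_config())
  }
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  lines <- c(EPOCH_HEADER,
             paste(sid, act, features$epoch_index,
                   fmt(features$usa_mg), fmt(features$fsa_mg),
                   fmt(features$ratio), predicted_class, sep = ","))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read an epoch feature table from CSV
#'
#' @param path Path to an epoch CSV written by [write_epoch_table()].
#' @return A data.frame with columns `subject_id`, `activity`, `epoch_index`,
#'   `usa_mg`, `fsa_mg`, `ratio` (NA when the field is empty) and
#'   `predicted_class`.
#' @export
read_epoch_table <- function(path) {
  df <- .read_strict_csv(path, EPOCH_HEADER,
                         c("character", "character", "integer",
                           "numeric", "numeric", "numeric", "character"))
  df
}

#' Read a subject covariate table
#'
#' Expects `subject_id,sex_code,age_yr,weight_kg,height_cm,rmr_kcal_min`;
#' sex is coded 0 = boy, 1 = girl. A `bmi` column (kg/m^2) is derived.
#'
#' @param path Path to the subjects CSV.
#' @return A data.frame of subjects.
#' @export
read_subjects <- function(path) {
  hdr <- "subject_id,sex_code,age_yr,weight_kg,height_cm,rmr_kcal_min"
  df <- .read_strict_csv(path, hdr,
                         c("character", "integer", rep("numeric", 4)))
  validate_subjects(df)
}

#' Validate a subject table
#'
#' Checks coding and positivity constraints and derives BMI.
#' @param df A data.frame with the subject columns.
#' @return The validated data.frame with a derived `bmi` column.
#' @export
validate_subjects <- function(df) {
  need <- c("subject_id", "sex_code", "age_yr", "weight_kg", "height_cm",
            "rmr_kcal_min")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing subject columns: ", paste(miss, collapse = ", "))
  if (!all(df$sex_code %in% c(0L, 1L)))
    stop("sex_code must be 0 (boy) or 1 (girl)")
  if (any(df$weight_kg <= 0) || any(df$height_cm <= 0) ||
      any(df$rmr_kcal_min <= 0))
    stop("weight, height and resting metabolic rate must be positive")
  df$bmi <- df$weight_kg / (df$height_cm / 100)^2
  df
}

#' Write a subject covariate table
#' @param subjects Subject data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  cols <- c("subject_id", "sex_code", "age_yr", "weight_kg", "height_cm",
            "rmr_kcal_min")
  utils::write.csv(subjects[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calorimetry table
#'
#' Expects `subject_id,activity,vo2_l_min,vco2_l_min` (L/min). A respiratory
#' quotient outside (0.6, 1.3) raises a warning, not an error.
#'
#' @param path Path to the calorimetry CSV.
#' @return A data.frame of gas-exchange measures.
#' @export
read_calorimetry <- function(path) {
  hdr <- "subject_id,activity,vo2_l_min,vco2_l_min"
  df <- .read_strict_csv(path, hdr,
                         c("character", "character", "numeric", "numeric"))
  if (any(df$vo2_l_min < 0) || any(df$vco2_l_min < 0))
    stop("gas volumes must be non-negative")
  rq <- ifelse(df$vo2_l_min > 0, df$vco2_l_min / df$vo2_l_min, NA_real_)
  if (any(!is.na(rq) & (rq <= 0.6 | rq >= 1.3)))
    warning("respiratory quotient outside (0.6, 1.3) for some rows")
  df
}

#' Write a calorimetry table
#' @param calorimetry Calorimetry data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calorimetry <- function(calorimetry, path) {
  cols <- c("subject_id", "activity", "vo2_l_min", "vco2_l_min")
  utils::write.csv(calorimetry[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a bout-label table
#'
#' Expects `subject_id,activity,true_class,start_sample,end_sample`
#' (half-open 0-based sample interval into the subject's raw recording).
#'
#' @param path Path to the bout-label CSV.
#' @return A data.frame of bout labels.
#' @export
read_bout_labels <- function(path) {
  hdr <- "subject_id,activity,true_class,start_sample,end_sample"
  df <- .read_strict_csv(path, hdr,
                         c("character", "character", "character",
                           "integer", "integer"))
  if (!all(df$true_class %in% c("nonlocomotive", "locomotive")))
    stop("true_class must be 'nonlocomotive' or 'locomotive'")
  df
}

#' Write a bout-label table
#' @param labels Bout-label data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bout_labels <- function(labels, path) {
  cols <- c("subject_id", "activity", "true_class", "start_sample",
            "end_sample")
  utils::write.csv(labels[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
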