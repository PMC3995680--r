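# Seeded generators for triaxial waveforms and full calibration cohorts.
#
# The physics emulated: a waist-worn device sees a 1000 mg gravity vector
# whose orientation is fixed during steady gait but drifts slowly (below the
# 0.7 Hz filter cut-off) during posture-varying lifestyle activities, plus a
# dynamic movement component (fundamental + one half-amplitude harmonic) and
# white Gaussian sensor noise. Slow reorientation passes into USA (epoch mean
# subtraction does not remove it) but not into FSA (the high-pass does),
# which is what makes the USA/FSA ratio separate the two classes.

#' Construct an activity waveform profile
#'
#' @param name Task label.
#' @param true_class `"nonlocomotive"` or `"locomotive"`.
#' @param gait_freq_hz Gait fundamental in Hz (locomotive profiles; must be
#'   >= 1.5 so the movement passes the 0.7 Hz filter untouched). `NULL` for
#'   nonlocomotive profiles, whose irregular movement frequency is drawn per
#'   bout from 1.2-2.8 Hz.
#' @param dyn_amp_mg Dominant-axis dynamic amplitude in mg.
#' @param tilt_freq_hz Frequency of the slow gravity reorientation in Hz;
#'   must be below the 0.7 Hz cut-off when present.
#' @param tilt_range_deg Peak-to-peak tilt excursion in degrees (waist tilt
#'   as a great-circle rotation in the x-z plane).
#' @param noise_sd_mg White sensor-noise SD per axis in mg.
#' @param target_mets_mean,target_mets_sd Informational intensity targets in
#'   METs (the cohort generator derives measured METs from the planted branch
#'   response, not from these).
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(name, true_class, gait_freq_hz = NULL,
                             dyn_amp_mg, tilt_freq_hz = NULL,
                             tilt_range_deg = 0, noise_sd_mg = 10,
                             target_mets_mean = NA_real_,
                             target_mets_sd = NA_real_) {
  true_class <- match.arg(true_class, c("nonlocomotive", "locomotive"))
  if (true_class == "locomotive") {
    if (is.null(gait_freq_hz) || gait_freq_hz < 1.5)
      stop("locomotive profiles need gait_freq_hz >= 1.5")
  }
  if (!is.null(tilt_freq_hz) && tilt_freq_hz >= 0.7)
    stop("tilt_freq_hz must lie below the 0.7 Hz filter cut-off")
  if (dyn_amp_mg < 0 || noise_sd_mg < 0 || tilt_range_deg < 0)
    stop("amplitudes must be non-negative")
  structure(list(name = name, true_class = true_class,
                 gait_freq_hz = gait_freq_hz, dyn_amp_mg = dyn_amp_mg,
                 tilt_freq_hz = tilt_freq_hz,
                 tilt_range_deg = tilt_range_deg,
                 noise_sd_mg = noise_sd_mg,
                 target_mets_mean = target_mets_mean,
                 target_mets_sd = target_mets_sd),
            class = "activity_profile")
}

#' Default profiles for the eleven calibration tasks
#'
#' Amplitudes are scaled so that bout FSA, pushed through the planted branch
#' equations, lands at child-typical intensities (sedentary desk work near
#' 1.2 METs up to jogging near 6.5); tilt excursions give nonlocomotive
#' ratios well above and locomotive ratios below the classification
#' boundary, with ball throwing and stair descent closest to it.
#'
#' @return A named list of [activity_profile()] objects.
#' @export
default_activity_profiles <- function() {
  p <- list(
    activity_profile("desk work", "nonlocomotive", dyn_amp_mg = 10,
                     tilt_freq_hz = 0.05, tilt_range_deg = 30,
                     noise_sd_mg = 4, target_mets_mean = 1.2),
    activity_profile("Nintendo DS", "nonlocomotive", dyn_amp_mg = 7,
                     tilt_freq_hz = 0.04, tilt_range_deg = 25,
                     noise_sd_mg = 4, target_mets_mean = 1.1),
    activity_profile("sweeping up", "nonlocomotive", dyn_amp_mg = 215,
                     tilt_freq_hz = 0.08, tilt_range_deg = 45,
                     noise_sd_mg = 10, target_mets_mean = 3.0),
    activity_profile("clearing away", "nonlocomotive", dyn_amp_mg = 225,
                     tilt_freq_hz = 0.06, tilt_range_deg = 55,
                     noise_sd_mg = 10, target_mets_mean = 3.0),
    activity_profile("washing the floor", "nonlocomotive", dyn_amp_mg = 420,
                     tilt_freq_hz = 0.07, tilt_range_deg = 60,
                     noise_sd_mg = 12, target_mets_mean = 4.6),
    activity_profile("throwing a ball", "nonlocomotive", dyn_amp_mg = 300,
                     tilt_freq_hz = 0.10, tilt_range_deg = 32,
                     noise_sd_mg = 10, target_mets_mean = 3.7),
    activity_profile("climbing down", "locomotive", gait_freq_hz = 2.0,
                     dyn_amp_mg = 430, tilt_freq_hz = 0.15,
                     tilt_range_deg = 20, noise_sd_mg = 10,
                     target_mets_mean = 2.3),
    activity_profile("climbing up", "locomotive", gait_freq_hz = 1.8,
                     dyn_amp_mg = 1370, tilt_freq_hz = 0.15,
                     tilt_range_deg = 20, noise_sd_mg = 10,
                     target_mets_mean = 5.3),
    activity_profile("normal walking", "locomotive", gait_freq_hz = 1.9,
                     dyn_amp_mg = 510, tilt_freq_hz = 0.10,
                     tilt_range_deg = 5, noise_sd_mg = 8,
                     target_mets_mean = 2.6),
    activity_profile("brisk walking", "locomotive", gait_freq_hz = 2.1,
                     dyn_amp_mg = 700, tilt_freq_hz = 0.10,
                     tilt_range_deg = 6, noise_sd_mg = 8,
                     target_mets_mean = 3.2),
    activity_profile("jogging", "locomotive", gait_freq_hz = 2.5,
                     dyn_amp_mg = 1730, tilt_freq_hz = 0.10,
                     tilt_range_deg = 7, noise_sd_mg = 10,
                     target_mets_mean = 6.4)
  )
  names(p) <- vapply(p, function(x) x$name, character(1))
  p
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(expr)
}

#' Simulate a triaxial waveform for one activity bout
#'
#' Gravity of 1000 mg magnitude, fixed or rotating in the x-z plane per the
#' tilt parameters; a dynamic component (fundamental plus one half-amplitude
#' harmonic on the vertical axis, 30% side components); white Gaussian noise;
#' optional quantization to the 3 mg device resolution. Deterministic given
#' `seed`; with `seed = NULL` it consumes the current RNG stream.
#'
#' @param profile An [activity_profile()].
#' @param duration_s Duration in seconds (>= 10, one full epoch).
#' @param sampling_rate_hz Sampling rate in Hz (default 32).
#' @param seed Optional integer seed.
#' @param quantize Round to 3 mg steps (default FALSE).
#' @param amp_scale,tilt_scale Per-bout multipliers on `dyn_amp_mg` and
#'   `tilt_range_deg` (subject-level intensity variation).
#' @return A [triaxial_recording()].
#' @export
simulate_signal <- function(profile, duration_s = 60, sampling_rate_hz = 32,
                            seed = NULL, quantize = FALSE, amp_scale = 1,
                            tilt_scale = 1) {
  stopifnot(inherits(profile, "activity_profile"))
  if (duration_s < 10) stop("duration_s must be at least one 10-s epoch")
  .with_seed(seed, {
    n <- as.integer(round(duration_s * sampling_rate_hz))
    t <- (seq_len(n) - 1L) / sampling_rate_hz

    half_tilt <- tilt_scale * profile$tilt_range_deg / 2 * pi / 180
    phi <- if (!is.null(profile$tilt_freq_hz) && half_tilt > 0) {
      half_tilt * sin(2 * pi * profile$tilt_freq_hz * t +
                        stats::runif(1, 0, 2 * pi))
    } else rep(0, n)
    gx <- 1000 * cos(phi); gz <- 1000 * sin(phi)

    f0 <- if (!is.null(profile$gait_freq_hz)) profile$gait_freq_hz
          else stats::runif(1, 1.2, 2.8)
    A <- amp_scale * profile$dyn_amp_mg
    ph <- stats::runif(4, 0, 2 * pi)
    dx <- A * sin(2 * pi * f0 * t + ph[1]) +
      0.5 * A * sin(2 * pi * 2 * f0 * t + ph[2])
    dy <- 0.3 * A * sin(2 * pi * f0 * t + ph[3])
    dz <- 0.3 * A * sin(2 * pi * f0 * t + ph[4])

    s <- profile$noise_sd_mg
    ax <- gx + dx + stats::rnorm(n, 0, s)
    ay <- dy + stats::rnorm(n, 0, s)
    az <- gz + dz + stats::rnorm(n, 0, s)
    clamp <- function(v) pmin(pmax(v, -6000), 6000)
    ax <- clamp(ax); ay <- clamp(ay); az <- clamp(az)
    if (quantize) {
      q <- function(v) round(v / 3) * 3
      ax <- q(ax); ay <- q(ay); az <- q(az)
    }
    triaxial_recording(ax, ay, az, sampling_rate_hz = sampling_rate_hz)
  })
}

#' Cohort generation specification
#'
#' Defaults reproduce the calibration study's design: 68 children in four
#' sex x age-band strata (42 boys: 15 aged 6-9 and 27 aged 10-12; 26 girls:
#' 14 and 12), branch-linear METs responses with the published slopes and
#' intercepts, and residual SD 0.65 METs (the scale of the published
#' regression RMSE).
#'
#' @param n_boys_young,n_boys_old,n_girls_young,n_girls_old Stratum sizes
#'   (ages 6-9 and 10-12).
#' @param branch_models Planted METs responses per branch:
#'   `list(nonlocomotive = list(slope, intercept), locomotive = ...)`.
#' @param residual_sd Residual SD of measured METs around the planted
#'   response, in METs.
#' @param separatrix The designed USA/FSA boundary between the two classes'
#'   bout ratio distributions (documentation of the planted geometry).
#' @param duration_s Bout length in seconds (default 60, six epochs).
#' @param profiles Task profiles (default [default_activity_profiles()]).
#' @param rq_range Range the respiratory quotient is drawn from.
#' @param quantize Quantize waveforms to the 3 mg resolution.
#' @param seed Master seed; all cohort randomness flows from it through one
#'   sequential RNG stream.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_boys_young = 15, n_boys_old = 27,
                        n_girls_young = 14, n_girls_old = 12,
                        branch_models = list(
                          nonlocomotive = list(slope = 0.013, intercept = 1.220),
                          locomotive = list(slope = 0.005, intercept = 0.944)),
                        residual_sd = 0.65, separatrix = 1.15,
                        duration_s = 60,
                        profiles = default_activity_profiles(),
                        rq_range = c(0.8, 0.95), quantize = FALSE,
                        seed = 1L) {
  counts <- c(n_boys_young, n_boys_old, n_girls_young, n_girls_old)
  if (any(counts < 0)) stop("stratum counts must be non-negative")
  if (sum(counts) == 0L) stop("cohort must contain at least one subject")
  if (residual_sd < 0) stop("residual_sd must be non-negative")
  structure(list(n_boys_young = n_boys_young, n_boys_old = n_boys_old,
                 n_girls_young = n_girls_young, n_girls_old = n_girls_old,
                 branch_models = branch_models, residual_sd = residual_sd,
                 separatrix = separatrix, duration_s = duration_s,
                 profiles = profiles, rq_range = rq_range,
                 quantize = quantize, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Anthropometry models: child weight/height roughly linear in age with
# sex-specific offsets (calibrated to the study cohort's marginal means);
# seated RMR scales with weight at about 0.022 kcal/min per kg.
.simulate_subjects <- function(spec) {
  strata <- data.frame(
    sex_code = c(0L, 0L, 1L, 1L),
    lo = c(6, 10, 6, 10), hi = c(9.99, 12.99, 9.99, 12.99),
    n = c(spec$n_boys_young, spec$n_boys_old, spec$n_girls_young,
          spec$n_girls_old))
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    if (st$n == 0L) next
    age <- stats::runif(st$n, st$lo, st$hi)
    w_int <- if (st$sex_code == 0L) 5.9 else 4.6
    weight <- pmax(14, 2.8 * age + w_int + stats::rnorm(st$n, 0, 5))
    height <- pmax(105, 6.5 * age + 75.5 + stats::rnorm(st$n, 0, 5.5))
    rmr <- pmax(0.5, 0.022 * weight + 0.25 + stats::rnorm(st$n, 0, 0.08))
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%03d", k + seq_len(st$n)),
      sex_code = st$sex_code, age_yr = age, weight_kg = weight,
      height_cm = height, rmr_kcal_min = rmr, stringsAsFactors = FALSE)
    k <- k + st$n
  }
  validate_subjects(do.call(rbind, rows))
}

#' Simulate a full calibration cohort
#'
#' For every subject x task: a waveform from the task profile (with per-bout
#' intensity jitter), epoch features through the actual preprocessing
#' pipeline, and a measured METs value drawn as the planted branch response
#' to the bout-mean FSA plus Normal(0, residual SD) noise. VO2/VCO2 are
#' back-computed from METs x RMR through the Weir equation with a respiratory
#' quotient drawn uniformly from `rq_range`, so indirect calorimetry inverts
#' exactly to the generating METs.
#'
#' @param spec A [cohort_spec()].
#' @param fspec,espec Filter and epoching specifications used to featurize
#'   the generated waveforms.
#' @param keep_recordings Attach each bout's raw [triaxial_recording()]
#'   (memory-heavy; needed only when raw CSVs will be written).
#' @return An object of class `grpaca_cohort`: a list with `spec`,
#'   `subjects`, `bouts` (list of [activity_bout()]), `epochs` (combined
#'   epoch table), `calorimetry`, `bout_labels` and `mets` (the generated
#'   measured METs per subject x activity).
#' @export
simulate_cohort <- function(spec = cohort_spec(), fspec = filter_spec(),
                            espec = epoching_spec(),
                            keep_recordings = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  .with_seed(spec$seed, {
    subjects <- .simulate_subjects(spec)
    n_samp <- as.integer(round(spec$duration_s * fspec$sampling_rate_hz))
    bouts <- vector("list", nrow(subjects) * length(spec$profiles))
    epoch_rows <- vector("list", length(bouts))
    cal_rows <- vector("list", length(bouts))
    met_rows <- vector("list", length(bouts))
    lab_rows <- vector("list", length(bouts))
    b <- 0L
    for (i in seq_len(nrow(subjects))) {
      subj <- subjects[i, ]
      for (prof in spec$profiles) {
        b <- b + 1L
        rec <- simulate_signal(prof, duration_s = spec$duration_s,
                               sampling_rate_hz = fspec$sampling_rate_hz,
                               quantize = spec$quantize,
                               amp_scale = stats::runif(1, 0.85, 1.15),
                               tilt_scale = stats::runif(1, 0.85, 1.15))
        feats <- compute_epoch_features(rec, fspec, espec)
        bouts[[b]] <- activity_bout(subj$subject_id, prof$name,
                                    prof$true_class, feats,
                                    steady_state_min = spec$duration_s / 60)
        if (keep_recordings) bouts[[b]]$recording <- rec
        bm <- spec$branch_models[[prof$true_class]]
        fsa_bout <- mean(feats$fsa_mg)
        mets <- bm$intercept + bm$slope * fsa_bout +
          stats::rnorm(1, 0, spec$residual_sd)
        mets <- max(mets, 0.1)
        rq <- stats::runif(1, spec$rq_range[1], spec$rq_range[2])
        ee <- mets * subj$rmr_kcal_min
        vo2 <- ee / (3.941 + 1.106 * rq)
        epoch_rows[[b]] <- data.frame(subject_id = subj$subject_id,
                                      activity = prof$name, feats,
                                      stringsAsFactors = FALSE)
        cal_rows[[b]] <- data.frame(subject_id = subj$subject_id,
                                    activity = prof$name, vo2_l_min = vo2,
                                    vco2_l_min = rq * vo2,
                                    stringsAsFactors = FALSE)
        met_rows[[b]] <- data.frame(subject_id = subj$subject_id,
                                    activity = prof$name,
                                    measured_mets = mets,
                                    fsa_bout_mg = fsa_bout,
                                    stringsAsFactors = FALSE)
        lab_rows[[b]] <- data.frame(subject_id = subj$subject_id,
                                    activity = prof$name,
                                    true_class = prof$true_class,
                                    start_sample = 0L, end_sample = n_samp,
                                    stringsAsFactors = FALSE)
      }
    }
    structure(list(spec = spec, subjects = subjects, bouts = bouts,
                   epochs = do.call(rbind, epoch_rows),
                   calorimetry = do.call(rbind, cal_rows),
                   bout_labels = do.call(rbind, lab_rows),
                   mets = do.call(rbind, met_rows)),
              class = "grpaca_cohort")
  })
}

#' @export
print.grpaca_cohort <- function(x, ...) {
  cat(sprintf("<grpaca_cohort: %d subjects, %d bouts, %d epochs (seed %d)>\n",
              nrow(x$subjects), length(x$bouts), nrow(x$epochs),
              x$spec$seed))
  invisible(x)
}

#' Write a cohort bundle to a directory
#'
#' Emits `subjects.csv`, `calorimetry.csv`, `bout_labels.csv`, `epochs.csv`
#' and a `manifest.yaml` echoing the generation parameters; raw per-bout
#' waveform CSVs are regenerable from the seed and written only on request.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @param write_recordings Also write per-bout raw recording CSVs under
#'   `raw/` (off by default; they are bulky and reproducible from the seed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_recordings = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_subjects(cohort$subjects, file.path(dir, "subjects.csv"))
  write_calorimetry(cohort$calorimetry, file.path(dir, "calorimetry.csv"))
  write_bout_labels(cohort$bout_labels, file.path(dir, "bout_labels.csv"))
  write_epoch_table(cohort$epochs, file.path(dir, "epochs.csv"))
  spec <- cohort$spec
  manifest <- list(
    seed = spec$seed, duration_s = spec$duration_s,
    residual_sd = spec$residual_sd, separatrix = spec$separatrix,
    strata = list(boys_6_9 = spec$n_boys_young, boys_10_12 = spec$n_boys_old,
                  girls_6_9 = spec$n_girls_young,
                  girls_10_12 = spec$n_girls_old),
    branch_models = spec$branch_models,
    n_subjects = nrow(cohort$subjects), n_bouts = length(cohort$bouts))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  if (write_recordings) {
    if (is.null(cohort$bouts[[1]]$recording))
      stop("cohort carries no recordings; rerun simulate_cohort(",
           "keep_recordings = TRUE)")
    rawdir <- file.path(dir, "raw")
    dir.create(rawdir, showWarnings = FALSE)
    for (bt in cohort$bouts) {
      fn <- sprintf("%s__%s.csv", bt$subject_id, gsub("[^A-Za-z0-9]+", "_",
                                                      bt$activity))
      write_raw_recording(bt$recording, file.path(rawdir, fn))
    }
  }
  invisible(dir)
}
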