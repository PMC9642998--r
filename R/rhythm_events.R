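#' Time-stamped cardiac fiducial points for one recording
#'
#' Container for the fiducial series of a single ECG (or optical-mapping)
#' recording: atrial activations (P), ventricular activations (R) and,
#' when a delineator provides them, QRS onsets/offsets and T-wave ends.
#' All times are seconds, zero-based from recording start.
#'
#' @param p_times,r_times Strictly increasing times, s. Either may be empty.
#' @param qrs_onsets,qrs_offsets,t_ends Optional strictly increasing times, s.
#' @param species Species tag ("zebrafish", "mouse", ...); selects
#'   species-dependent defaults such as the sinus-arrest threshold.
#' @param duration Recording duration, s; defaults to just past the last
#'   fiducial.
#' @return An object of class `fiducial_series`.
#' @export
fiducial_series <- function(p_times = numeric(), r_times = numeric(),
                            qrs_onsets = NULL, qrs_offsets = NULL,
                            t_ends = NULL, species = "zebrafish",
                            duration = NULL) {
  chk <- function(x, nm) {
    if (is.null(x)) return(invisible(NULL))
    if (any(!is.finite(x))) stop(nm, " contains non-finite times")
    if (any(x < 0)) stop(nm, " contains negative times")
    if (is.unsorted(x, strictly = TRUE)) stop(nm, " must be strictly increasing")
  }
  chk(p_times, "p_times"); chk(r_times, "r_times")
  chk(qrs_onsets, "qrs_onsets"); chk(qrs_offsets, "qrs_offsets"); chk(t_ends, "t_ends")
  last <- suppressWarnings(max(c(p_times, r_times, qrs_onsets, qrs_offsets, t_ends, 0)))
  if (is.null(duration)) duration <- last + 0.5
  if (duration < last) stop("duration is earlier than the last fiducial")
  structure(list(p_times = p_times, r_times = r_times,
                 qrs_onsets = qrs_onsets, qrs_offsets = qrs_offsets,
                 t_ends = t_ends, species = species, duration = duration),
            class = "fiducial_series")
}

#' ECG interval summary
#'
#' Computes the standard interval set from a fiducial series: per-beat and
#' mean PP and RR intervals, heart rate (60 / mean RR, bpm), and — when the
#' needed fiducial classes are present — PR interval, QRS duration and QT
#' interval. Missing fiducial classes yield `NULL` fields, never zeros.
#'
#' PR pairs each P with the earliest unused R that follows it within
#' `pr_window` (greedy, in time order); QRS and QT need QRS onset/offset and
#' T-end fiducials and are paired positionally.
#'
#' @param f A \code{\link{fiducial_series}}.
#' @param pr_window Longest P-to-R delay accepted as conduction, s.
#' @return List with `pp`, `rr`, `pr`, `qrs`, `qt` (per-beat vectors or
#'   `NULL`), their means `mean_pp` etc., `hr_bpm`, and `n_beats`. With fewer
#'   than 2 R waves `hr_bpm` is `NA` and a flag `hr_defined = FALSE` is set.
#' @examples
#' f <- fiducial_series(r_times = c(0, 0.5, 1, 1.5))
#' compute_intervals(f)$hr_bpm  # 120
#' @export
compute_intervals <- function(f, pr_window = 0.3) {
  stopifnot(inherits(f, "fiducial_series"))
  out <- list(pp = NULL, rr = NULL, pr = NULL, qrs = NULL, qt = NULL,
              mean_pp = NULL, mean_rr = NULL, mean_pr = NULL,
              mean_qrs = NULL, mean_qt = NULL,
              hr_bpm = NA_real_, hr_defined = FALSE,
              n_beats = length(f$r_times))
  if (length(f$p_times) >= 2) {
    out$pp <- diff(f$p_times); out$mean_pp <- mean(out$pp)
  }
  if (length(f$r_times) >= 2) {
    out$rr <- diff(f$r_times); out$mean_rr <- mean(out$rr)
    out$hr_bpm <- 60 / out$mean_rr; out$hr_defined <- TRUE
  }
  if (length(f$p_times) && length(f$r_times)) {
    pairs <- pair_p_to_r(f$p_times, f$r_times, pr_window)
    pr <- pairs$r_time - pairs$p_time
    if (length(pr)) { out$pr <- pr; out$mean_pr <- mean(pr) }
  }
  if (!is.null(f$qrs_onsets) && !is.null(f$qrs_offsets)) {
    k <- min(length(f$qrs_onsets), length(f$qrs_offsets))
    if (k) { out$qrs <- f$qrs_offsets[1:k] - f$qrs_onsets[1:k]; out$mean_qrs <- mean(out$qrs) }
  }
  if (!is.null(f$qrs_onsets) && !is.null(f$t_ends)) {
    k <- min(length(f$qrs_onsets), length(f$t_ends))
    if (k) { out$qt <- f$t_ends[1:k] - f$qrs_onsets[1:k]; out$mean_qt <- mean(out$qt) }
  }
  out
}

# greedy one-to-one pairing of each P to the earliest unused R at or after it,
# accepted when the delay is within `window`; returns paired times and the
# indices of orphan P waves (no R within the window)
pair_p_to_r <- function(p, r, window) {
  paired_p <- numeric(); paired_r <- numeric(); orphan <- integer()
  j <- 1L
  for (i in seq_along(p)) {
    while (j <= length(r) && r[j] < p[i]) j <- j + 1L
    if (j <= length(r) && r[j] - p[i] <= window) {
      paired_p <- c(paired_p, p[i]); paired_r <- c(paired_r, r[j])
      j <- j + 1L
    } else {
      orphan <- c(orphan, i)
    }
  }
  list(p_time = paired_p, r_time = paired_r, orphan_p = orphan)
}

#' Detect sinus-arrest episodes
#'
#' Calls one sinus-arrest (SA) episode for every PP interval strictly greater
#' than the threshold; an interval exactly at the threshold is not called.
#' The zebrafish convention is a fixed 1.5 s threshold. For other species no
#' fixed rule is established, so the default falls back to twice the median
#' PP interval of the recording — a package convention, documented as such.
#' When P fiducials are absent the detector runs on RR intervals with a
#' warning (RR is the measurable proxy for PP in recordings without atrial
#' delineation).
#'
#' @param f A \code{\link{fiducial_series}}.
#' @param threshold Pause threshold, s. Default: 1.5 for species
#'   `"zebrafish"`, otherwise `2 * median(PP)`.
#' @return Data frame of episode calls: `kind` ("SA"), `onset`, `offset` (the
#'   two P times flanking the pause, s), `evidence` (the PP gap, s), `index`
#'   (index of the P wave starting the pause).
#' @export
detect_sa_episodes <- function(f, threshold = NULL) {
  stopifnot(inherits(f, "fiducial_series"))
  times <- f$p_times
  if (length(times) < 2) {
    if (length(f$r_times) >= 2) {
      warning("no P fiducials; running sinus-arrest detection on RR intervals")
      times <- f$r_times
    } else stop("need at least 2 P (or R) times")
  }
  gaps <- diff(times)
  if (is.null(threshold)) {
    threshold <- if (identical(f$species, "zebrafish")) 1.5 else 2 * stats::median(gaps)
  }
  if (threshold <= 0) stop("threshold must be positive")
  i <- which(gaps > threshold)
  data.frame(kind = rep("SA", length(i)), onset = times[i], offset = times[i + 1],
             evidence = gaps[i], index = i)
}

#' Detect atrioventricular-block episodes
#'
#' Calls one atrioventricular-block (AVB) episode for every P wave that is
#' not followed by an R wave within the pairing window, using greedy
#' one-to-one P-to-R matching in time order. The rule is a package
#' convention (screening tables report AVB only as observed counts, with no
#' published detection rule): the default window is `median(PR) + 4 * sd(PR)`
#' of the provisional P-to-next-R delays of the recording.
#'
#' @param f A \code{\link{fiducial_series}} with both P and R series.
#' @param pr_window Pairing window, s; `NULL` for the data-driven default.
#' @return Data frame of episode calls: `kind` ("AVB"), `onset` (the orphan P
#'   time), `offset` (`onset + pr_window`, capped at the recording duration),
#'   `evidence` (orphan P index).
#' @export
detect_avb_episodes <- function(f, pr_window = NULL) {
  stopifnot(inherits(f, "fiducial_series"))
  if (!length(f$p_times) || !length(f$r_times)) stop("need both P and R series")
  if (is.null(pr_window)) {
    nxt <- vapply(f$p_times, function(p) {
      r <- f$r_times[f$r_times >= p]
      if (length(r)) r[1] - p else NA_real_
    }, numeric(1))
    nxt <- nxt[is.finite(nxt)]
    if (length(nxt) < 2) stop("cannot derive a pairing window; supply pr_window")
    pr_window <- stats::median(nxt) + 4 * stats::sd(nxt)
  }
  if (pr_window <= 0) stop("pr_window must be positive")
  orphan <- pair_p_to_r(f$p_times, f$r_times, pr_window)$orphan_p
  data.frame(kind = rep("AVB", length(orphan)),
             onset = f$p_times[orphan],
             offset = pmin(f$p_times[orphan] + pr_window, f$duration),
             evidence = orphan)
}

#' Sinus-node recovery time after overdrive pacing
#'
#' SANRT is the delay from the last pacing stimulus to the first spontaneous
#' beat; the corrected form (cSANRT) subtracts the resting cycle length
#' measured before the pacing protocol.
#'
#' @param pace_times Times of the pacing train, s (non-empty).
#' @param spontaneous_beats Beat times, s; at least one must fall strictly
#'   after the last pace (absence models suppressed sinus-node function and
#'   raises an error).
#' @param resting_cl Resting cycle length before pacing, s.
#' @return List with `last_pace_time`, `first_spontaneous_time`,
#'   `resting_cycle_length`, `sanrt`, `csanrt` (all s).
#' @examples
#' sanrt(10.0, 10.35, 0.22)  # sanrt 0.35, csanrt 0.13
#' @export
sanrt <- function(pace_times, spontaneous_beats, resting_cl) {
  if (!length(pace_times)) stop("pace_times is empty")
  if (resting_cl <= 0) stop("resting_cl must be positive")
  last_pace <- max(pace_times)
  post <- spontaneous_beats[spontaneous_beats > last_pace]
  if (!length(post)) stop("no spontaneous beat after the last pace (suppressed sinus-node function)")
  first_beat <- min(post)
  list(last_pace_time = last_pace, first_spontaneous_time = first_beat,
       resting_cycle_length = resting_cl,
       sanrt = first_beat - last_pace,
       csanrt = first_beat - last_pace - resting_cl)
}

#' Cycle-length variation of a beat series
#'
#' Index of pacemaker irregularity: the sample standard deviation (n-1
#' denominator) of successive cycle lengths, or optionally their coefficient
#' of variation.
#'
#' @param beat_times At least 3 beat times, s.
#' @param metric `"sd"` (default, s) or `"cv"` (dimensionless).
#' @return The variation metric; `NA` with a warning for fewer than 3 beats.
#' @export
cl_variation <- function(beat_times, metric = c("sd", "cv")) {
  metric <- match.arg(metric)
  if (length(beat_times) < 3) {
    warning("fewer than 3 beats; cycle-length variation undefined")
    return(NA_real_)
  }
  cl <- diff(beat_times)
  if (metric == "sd") stats::sd(cl) else stats::sd(cl) / mean(cl)
}

#' Detect R peaks in a sampled ECG waveform
#'
#' Band-pass filters the trace (0.5 Hz high-pass; low-pass at 200 Hz or just
#' below Nyquist, whichever is lower), builds a polarity-invariant
#' rectified-derivative envelope smoothed over ~10 ms, thresholds it at a
#' fraction of the rolling 99.5th percentile, and reports one peak per
#' supra-threshold region (the sample of largest absolute filtered amplitude),
#' with a refractory lockout.
#'
#' @param waveform Numeric vector of samples, mV (or a data frame with a `mv`
#'   column as produced by \code{\link{gen_ecg_waveform}}).
#' @param fs Sampling rate, Hz (> 0; mouse-like content needs > 400).
#' @param threshold_frac Envelope threshold as a fraction of the rolling
#'   99.5th percentile.
#' @param refractory Minimum spacing between reported peaks, s.
#' @return Peak times, s (sample-centre convention, first sample at 0).
#' @export
detect_r_peaks <- function(waveform, fs, threshold_frac = 0.3, refractory = 0.03) {
  if (is.data.frame(waveform)) waveform <- waveform$mv
  if (fs <= 0) stop("fs must be positive")
  x <- as.numeric(waveform)
  if (any(!is.finite(x))) stop("waveform contains non-finite samples")
  n <- length(x)
  if (n < 8) return(numeric())
  hi <- 0.5 / (fs / 2)
  lo <- min(200, 0.45 * fs) / (fs / 2)
  bp <- signal::filtfilt(signal::butter(2, c(hi, lo), type = "pass"), x)
  env <- abs(c(0, diff(bp))) * fs
  w <- max(1L, round(0.01 * fs))
  env <- stats::filter(env, rep(1 / w, w), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  # rolling high percentile in 2 s blocks, interpolated across block centres
  block <- max(w + 1L, round(2 * fs))
  starts <- seq(1L, n, by = block)
  qs <- vapply(starts, function(s) stats::quantile(env[s:min(n, s + block - 1L)], 0.995,
                                                   names = FALSE), numeric(1))
  centers <- pmin(starts + block / 2, n)
  thr <- if (length(qs) > 1) {
    stats::approx(centers, qs, xout = seq_len(n), rule = 2)$y
  } else rep(qs, n)
  # floor at half the global level so beat-free stretches (pauses, tails) do
  # not collapse the threshold onto the noise floor
  thr <- threshold_frac * pmax(thr, 0.8 * stats::quantile(env, 0.995, names = FALSE),
                               1e-12)
  above <- env > thr & env > 1e-9
  if (!any(above)) return(numeric())
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts_r <- ends - runs$lengths + 1L
  keep <- runs$values
  peaks <- mapply(function(s, e) s - 1L + which.max(abs(bp[s:e])),
                  starts_r[keep], ends[keep])
  # refractory lockout: keep the larger of two conflicting peaks
  peaks <- peaks[order(peaks)]
  out <- integer()
  for (p in peaks) {
    if (length(out) && (p - out[length(out)]) / fs < refractory) {
      if (abs(bp[p]) > abs(bp[out[length(out)]])) out[length(out)] <- p
    } else out <- c(out, p)
  }
  (out - 1L) / fs
}
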