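#' Specification for a synthetic arrhythmic beat train
#'
#' Describes a fiducial-level recording to be generated by
#' \code{\link{gen_beat_train}}: a near-periodic atrial (P) rhythm with
#' optional injected sinus pauses and dropped ventricular responses, emulating
#' the kind of recordings behind an ECG screen (zebrafish-like at ~100 bpm or
#' mouse-like at ~500 bpm).
#'
#' @param hr Mean heart rate in bpm (> 0).
#' @param n Number of beats (P waves) to generate.
#' @param cl_jitter_sd SD of the Gaussian jitter added to each cycle length, s.
#' @param sa_pauses List of `c(index, pause_s)` pairs (or a 2-column matrix):
#'   the cycle starting at P-wave `index` is lengthened by `pause_s` seconds.
#' @param avb_drops Integer indices of P waves whose ventricular response (R)
#'   is dropped.
#' @param pr_mean,pr_sd Mean and SD of the P-to-R conduction interval, s.
#' @param species Species tag carried into the generated series.
#' @param seed RNG seed making the train reproducible.
#' @return An object of class `beat_train_spec`.
#' @export
beat_train_spec <- function(hr = 100, n = 200, cl_jitter_sd = 0,
                            sa_pauses = list(), avb_drops = integer(),
                            pr_mean = 0.12, pr_sd = 0, species = "zebrafish",
                            seed = 1L) {
  stopifnot(hr > 0, n >= 2, cl_jitter_sd >= 0, pr_mean > 0, pr_sd >= 0)
  if (is.matrix(sa_pauses)) sa_pauses <- lapply(seq_len(nrow(sa_pauses)), function(i) sa_pauses[i, ])
  for (p in sa_pauses) {
    if (length(p) != 2L || p[2] <= 0) stop("each pause must be c(index, pause_s) with pause_s > 0")
    if (p[1] < 1 || p[1] >= n) stop("pause index out of range")
  }
  avb_drops <- as.integer(avb_drops)
  if (any(avb_drops < 1 | avb_drops > n)) stop("AVB drop index out of range")
  structure(list(hr = hr, n = as.integer(n), cl_jitter_sd = cl_jitter_sd,
                 sa_pauses = sa_pauses, avb_drops = avb_drops,
                 pr_mean = pr_mean, pr_sd = pr_sd, species = species,
                 seed = as.integer(seed)),
            class = "beat_train_spec")
}

#' Generate a synthetic beat train with ground truth
#'
#' Builds P-wave times from cumulative cycle lengths (base cycle `60/hr` plus
#' Gaussian jitter), lengthens specified cycles by the configured sinus-pause
#' durations, and places R waves one conduction delay after each P except at
#' the indices marked as atrioventricular-block drops. The injected events are
#' returned as machine-readable ground truth so detector performance can be
#' scored exactly.
#'
#' @param spec A \code{\link{beat_train_spec}}.
#' @return List with `fiducials` (a \code{\link{fiducial_series}}) and `truth`
#'   (list with data frames `sa` — index, onset, offset, gap of every injected
#'   pause — and `avb` — index and time of every dropped response).
#' @export
gen_beat_train <- function(spec) {
  stopifnot(inherits(spec, "beat_train_spec"))
  base_cl <- 60 / spec$hr
  cls <- withr_seed(spec$seed, {
    cl <- base_cl + stats::rnorm(spec$n - 1, 0, spec$cl_jitter_sd)
    pr <- spec$pr_mean + stats::rnorm(spec$n, 0, spec$pr_sd)
    list(cl = pmax(cl, 0.2 * base_cl), pr = pmax(pr, 0.2 * spec$pr_mean))
  })
  cl <- cls$cl
  sa_idx <- vapply(spec$sa_pauses, `[`, numeric(1), 1)
  sa_len <- vapply(spec$sa_pauses, `[`, numeric(1), 2)
  if (length(sa_idx)) cl[sa_idx] <- cl[sa_idx] + sa_len
  p_times <- cumsum(c(0, cl))
  r_times <- p_times + cls$pr
  dropped <- sort(unique(spec$avb_drops))
  if (length(dropped)) r_times <- r_times[-dropped]
  duration <- max(p_times, r_times) + base_cl
  fid <- fiducial_series(p_times = p_times, r_times = r_times,
                         species = spec$species, duration = duration)
  truth <- list(
    sa = data.frame(index = as.integer(sa_idx),
                    onset = p_times[sa_idx], offset = p_times[sa_idx + 1],
                    gap = if (length(sa_idx)) cl[sa_idx] else numeric()),
    avb = data.frame(index = dropped, p_time = p_times[dropped])
  )
  list(fiducials = fid, truth = truth)
}

#' Render a stylized ECG waveform from fiducial times
#'
#' Places Gaussian deflections at the fiducial times (a small P hump, a tall
#' narrow R spike with a small S undershoot, and a broad T hump after each R)
#' on a regular sampling grid, plus white noise. The morphology is stylized,
#' not biophysical: it is intended for exercising the R-peak detector with a
#' known answer, not for emulating real electrode recordings.
#'
#' @param f A \code{\link{fiducial_series}}.
#' @param fs Sampling rate, Hz (must resolve the QRS width; >= 200).
#' @param noise_sd SD of additive white noise, mV.
#' @param seed RNG seed for the noise.
#' @return Data frame with columns `time_s` and `mv`.
#' @export
gen_ecg_waveform <- function(f, fs, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(f, "fiducial_series"), fs > 0, noise_sd >= 0)
  qrs_sd <- 0.004
  if (fs < 200) stop("fs too low to place QRS deflections; need >= 200 Hz")
  t <- seq(0, f$duration, by = 1 / fs)
  x <- numeric(length(t))
  add <- function(x, centers, amp, sd) {
    for (c0 in centers) {
      i <- which(t >= c0 - 5 * sd & t <= c0 + 5 * sd)
      x[i] <- x[i] + amp * exp(-0.5 * ((t[i] - c0) / sd)^2)
    }
    x
  }
  if (length(f$p_times)) x <- add(x, f$p_times, 0.15, 0.015)
  if (length(f$r_times)) {
    x <- add(x, f$r_times, 1.0, qrs_sd)
    x <- add(x, f$r_times + 0.012, -0.25, qrs_sd)
    x <- add(x, f$r_times + 0.12, 0.3, 0.03)
  }
  if (noise_sd > 0) x <- x + withr_seed(seed, stats::rnorm(length(t), 0, noise_sd))
  data.frame(time_s = t, mv = x)
}

#' Specification of the analytic surrogate pacemaker population
#'
#' A closed-form stand-in for the ODE population used as a fast oracle: the
#' log firing rate of a variant under each condition is an affine function of
#' the log parameter scalings, `log(rate_c) = log(base_c) + sum_j coef[j, c] *
#' log(s_j) (+ noise)`. With zero noise the map is deterministic and
#' analytically invertible, so selection effects can be enumerated exactly.
#'
#' The default elasticity matrix is an arbitrary but structured choice: its
#' signs are set so that selecting variants that are slow at baseline, extra
#' responsive to isoproterenol and under-responsive to carbachol shifts
#' G_CaL, G_Na and v_RyR down, v_NCX up, and G_KACh down — the qualitative
#' structure this family of screens is meant to resolve. The magnitudes carry
#' no biophysical meaning.
#'
#' @param base_rates Named numeric: firing rate (bpm) of the nominal variant
#'   under `baseline`, `iso`, `cch`.
#' @param coef Elasticity matrix, rows = parameter names, columns = the three
#'   conditions.
#' @param noise_sd SD of Gaussian noise added to each log rate (0 = exact).
#' @return An object of class `surrogate_spec`.
#' @export
surrogate_spec <- function(base_rates = c(baseline = 350, iso = 440, cch = 270),
                           coef = default_surrogate_coef(),
                           noise_sd = 0) {
  stopifnot(all(c("baseline", "iso", "cch") %in% names(base_rates)),
            all(base_rates > 0), noise_sd >= 0,
            is.matrix(coef), all(c("baseline", "iso", "cch") %in% colnames(coef)))
  structure(list(base_rates = base_rates[c("baseline", "iso", "cch")],
                 coef = coef[, c("baseline", "iso", "cch"), drop = FALSE],
                 noise_sd = noise_sd),
            class = "surrogate_spec")
}

#' Default surrogate elasticities
#'
#' @return Matrix of log-rate elasticities, parameters x conditions.
#' @export
default_surrogate_coef <- function() {
  params <- c("G_Na", "G_CaL", "G_CaT", "G_to", "G_sus", "G_Kr", "G_Ks",
              "G_f", "G_bNa", "G_bCa", "G_KACh", "v_NCX", "v_RyR", "v_up")
  m <- matrix(0, nrow = length(params), ncol = 3,
              dimnames = list(params, c("baseline", "iso", "cch")))
  m["G_Na", ]   <- c(0.30, 0.30, 0.30)
  m["G_CaL", ]  <- c(0.50, 0.42, 0.45)
  m["G_CaT", ]  <- c(0.10, 0.10, 0.10)
  m["G_to", ]   <- c(-0.04, -0.04, -0.04)
  m["G_sus", ]  <- c(-0.04, -0.04, -0.04)
  m["G_Kr", ]   <- c(-0.08, -0.08, -0.08)
  m["G_Ks", ]   <- c(-0.04, -0.04, -0.04)
  m["G_f", ]    <- c(0.20, 0.26, 0.20)
  m["G_bNa", ]  <- c(0.08, 0.08, 0.08)
  m["G_bCa", ]  <- c(0.04, 0.04, 0.04)
  m["G_KACh", ] <- c(0.00, 0.00, -0.60)
  m["v_NCX", ]  <- c(-0.20, -0.14, -0.20)
  m["v_RyR", ]  <- c(0.40, 0.40, 0.40)
  m["v_up", ]   <- c(0.10, 0.10, 0.10)
  m
}

#' Evaluate the surrogate population map
#'
#' @param spec A \code{\link{surrogate_spec}}.
#' @param scalings Named numeric vector of positive scalings, or a matrix with
#'   one row per variant and parameter names as columns.
#' @param seed RNG seed for the noise term (ignored when `noise_sd = 0`).
#' @return Data frame with columns `rate_baseline`, `rate_iso`, `rate_cch`
#'   (bpm), one row per variant.
#' @export
surrogate_rates <- function(spec, scalings, seed = 1L) {
  stopifnot(inherits(spec, "surrogate_spec"))
  if (!is.matrix(scalings)) scalings <- matrix(scalings, nrow = 1,
                                               dimnames = list(NULL, names(scalings)))
  missing <- setdiff(colnames(scalings), rownames(spec$coef))
  if (length(missing)) stop("no surrogate coefficient for parameter(s): ",
                            paste(missing, collapse = ", "))
  if (any(scalings <= 0)) stop("scalings must be positive")
  ls <- log(scalings)
  lr <- ls %*% spec$coef[colnames(scalings), , drop = FALSE]
  lr <- sweep(lr, 2, log(spec$base_rates), "+")
  if (spec$noise_sd > 0) {
    lr <- lr + withr_seed(seed, matrix(stats::rnorm(length(lr), 0, spec$noise_sd),
                                       nrow = nrow(lr)))
  }
  out <- exp(lr)
  data.frame(rate_baseline = out[, "baseline"], rate_iso = out[, "iso"],
             rate_cch = out[, "cch"])
}

# evaluate expr under a temporary RNG state so generators do not disturb the
# caller's stream
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(list = ".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
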