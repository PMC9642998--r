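#' Default parameter table of the mouse SAN pacemaker myocyte model
#'
#' Baseline values of the model parameters: maximal conductances (pA/pF per
#' mV of driving force, i.e. nS/pF), maximal transport and flux rates, the
#' carbachol pharmacology constants, and the activation-shift parameters used
#' by the autonomic condition transforms (mV, zero at baseline).
#'
#' @return Named numeric vector in the order expected by the compiled
#'   right-hand side.
#' @export
san_default_params <- function() {
  c(G_CaL  = 0.45,    # L-type Ca2+ conductance, nS/pF
    G_CaT  = 0.45,    # T-type Ca2+ conductance, nS/pF
    G_Na   = 0.5,     # fast (Nav1.5) Na+ conductance, nS/pF
    G_f    = 0.3,     # funny-current conductance, nS/pF
    G_Kr   = 0.5,     # rapid delayed-rectifier K+ conductance, nS/pF
    G_Ks   = 0.1,     # slow delayed-rectifier K+ conductance, nS/pF
    G_to   = 0.6,     # transient-outward K+ conductance, nS/pF
    G_sus  = 0.05,    # sustained K+ conductance, nS/pF
    G_KACh = 0.04,    # acetylcholine-activated K+ conductance, nS/pF
    G_bNa  = 0.003,   # background Na+ conductance, nS/pF
    G_bCa  = 0.0005,  # background Ca2+ conductance, nS/pF
    P_NaK  = 2.0,     # Na+/K+ pump maximal current, pA/pF
    v_NCX  = 0.002,   # Na+/Ca2+ exchanger maximal transport rate
    v_RyR  = 0.5,     # ryanodine-receptor maximal release flux, 1/ms
    v_up   = 0.01,    # SERCA maximal uptake flux, mM/ms
    cch_dose  = 0,    # carbachol dose, uM (engaged by the CCh transform)
    y_shift   = 0,    # funny-current activation shift, mV
    kach_K05  = 0.1,  # IKACh half-activation dose, uM
    kach_hill = 1.5,  # IKACh Hill coefficient
    ca_shift  = 0)    # ICaL/ICaT activation shift, mV
}

# parameters that the population screen varies multiplicatively
san_scalable_params <- function() {
  c("G_CaL", "G_CaT", "G_Na", "G_f", "G_Kr", "G_Ks", "G_to", "G_sus",
    "G_KACh", "G_bNa", "G_bCa", "P_NaK", "v_NCX", "v_RyR", "v_up")
}

# gate steady states at voltage V, matching the compiled right-hand side
san_initial_state <- function(V = -60) {
  c(V = V,
    dL = 1 / (1 + exp(-(V + 20.3) / 4.2)),
    fL = 1 / (1 + exp((V + 37.4) / 5.3)),
    dT = 1 / (1 + exp(-(V + 38.3) / 5.5)),
    fT = 1 / (1 + exp((V + 58.7) / 3.8)),
    h  = 1 / (1 + exp((V + 66) / 6)),
    pa = 1 / (1 + exp(-(V + 21.5) / 7.5)),
    n  = 1 / (1 + exp(-(V - 10) / 14)),
    q  = 1 / (1 + exp((V + 49) / 13)),
    r  = 1 / (1 + exp(-(V - 5) / 14)),
    y  = 1 / (1 + exp((V + 80) / 9)),
    Casub = 2e-4, Cai = 2e-4, CaJSR = 0.3, CaNSR = 1.0)
}

#' Mouse sinoatrial-node pacemaker cell model
#'
#' Constructs the single-cell mouse SAN myocyte ODE model used throughout the
#' package: a coupled-clock formulation in the Zhang/Kurata/Kharche lineage
#' with a membrane clock (If, ICaL, ICaT, INa, IKr, IKs, Ito, Isus, IKACh,
#' INaK, INCX and background Na+/Ca2+ currents) and a calcium clock
#' (SR release, uptake and transfer with a submembrane space). The
#' formulation is authored and tuned in this package so that the nominal cell
#' fires spontaneously near the mouse heart rate and accelerates under
#' isoproterenol and decelerates under carbachol; the right-hand side is
#' compiled C code integrated with \pkg{deSolve}.
#'
#' @param params Named baseline parameter vector; defaults to
#'   \code{\link{san_default_params}}. Supplied values override defaults by
#'   name.
#' @return An object of class `pacemaker_model` with fields `state_names`,
#'   `param_table`, `init_state` and `metadata`.
#' @export
pacemaker_model <- function(params = NULL) {
  p <- san_default_params()
  if (!is.null(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad)) stop("unknown model parameter(s): ", paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  init <- san_initial_state()
  structure(list(
    state_names = names(init),
    param_table = p,
    init_state = init,
    metadata = paste("sanpop mouse SAN myocyte model v0.1;",
                     "coupled-clock single-cell formulation",
                     "(Zhang/Kurata/Kharche lineage), package-authored,",
                     "tuned to mouse SAN physiology")),
    class = "pacemaker_model")
}

#' @export
print.pacemaker_model <- function(x, ...) {
  cat("Mouse SAN pacemaker cell model\n")
  cat(" ", x$metadata, "\n", sep = "")
  cat("  states:", length(x$state_names), " parameters:", length(x$param_table), "\n")
  invisible(x)
}

#' Autonomic condition transforms
#'
#' Loads the baseline / isoproterenol (ISO) / carbachol (CCh) condition
#' transforms from a structured configuration file. Each transform lists
#' multiplicative effects (`scale`), additive activation shifts in mV
#' (`shift`) and, for CCh, the agonist dose engaging the
#' acetylcholine-activated K+ current. The shipped configuration encodes
#' beta-adrenergic up-modulation of the L-type Ca2+ current and SR uptake
#' with positive activation shifts of ICaL/ICaT and If for ISO, and IKACh
#' activation at 0.3 uM carbachol (the ex vivo superfusion dose) with a small
#' negative If shift for CCh.
#'
#' @param path Path to a YAML configuration; defaults to the file shipped in
#'   `inst/extdata/san_conditions.yaml`.
#' @return Named list of objects of class `condition_transform` (always
#'   including `baseline`, the identity).
#' @export
condition_transforms <- function(path = NULL) {
  if (is.null(path)) path <- system.file("extdata", "san_conditions.yaml",
                                         package = "sanpop", mustWork = TRUE)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$conditions)) stop("configuration has no 'conditions' section")
  out <- lapply(names(cfg$conditions), function(nm) {
    c0 <- cfg$conditions[[nm]]
    tr <- list(condition = nm,
               scale = unlist(c0$scale) %||% numeric(),
               shift = unlist(c0$shift) %||% numeric(),
               kach_dose = c0$kach_dose_uM %||% NULL)
    if (length(tr$scale) && any(tr$scale <= 0)) {
      stop("condition '", nm, "' has a non-positive scale factor")
    }
    structure(tr, class = "condition_transform")
  })
  names(out) <- names(cfg$conditions)
  if (!"baseline" %in% names(out)) {
    out$baseline <- structure(list(condition = "baseline", scale = numeric(),
                                   shift = numeric(), kach_dose = NULL),
                              class = "condition_transform")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a condition transform to a parameter map
#'
#' Returns a new parameter map with the transform's multiplicative effects
#' and activation shifts applied and, for carbachol, the agonist dose set;
#' untargeted entries are returned unchanged and the input is not modified.
#'
#' @param params Named numeric parameter map.
#' @param transform A `condition_transform` (one element of
#'   \code{\link{condition_transforms}}).
#' @return The transformed parameter map.
#' @export
apply_condition <- function(params, transform) {
  stopifnot(inherits(transform, "condition_transform"))
  targets <- c(names(transform$scale), names(transform$shift))
  bad <- setdiff(targets, names(params))
  if (length(bad)) stop("condition transform targets unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  out <- params
  if (length(transform$scale)) {
    out[names(transform$scale)] <- out[names(transform$scale)] * transform$scale
  }
  if (length(transform$shift)) {
    out[names(transform$shift)] <- out[names(transform$shift)] + transform$shift
  }
  if (!is.null(transform$kach_dose)) {
    if (!"cch_dose" %in% names(out)) stop("parameter map lacks 'cch_dose'")
    out["cch_dose"] <- transform$kach_dose
  }
  out
}

#' IKACh dose-activation function
#'
#' Hill activation of the acetylcholine-activated K+ current by the agonist
#' dose, as used inside the model: `dose^h / (dose^h + K05^h)` (0 at dose 0).
#'
#' @param dose Agonist (carbachol) dose, uM.
#' @param K05 Half-activation dose, uM.
#' @param hill Hill coefficient.
#' @return Activation in [0, 1).
#' @export
kach_activation <- function(dose, K05 = 0.1, hill = 1.5) {
  ifelse(dose > 0, dose^hill / (dose^hill + K05^hill), 0)
}

#' Extract beat (upstroke) times from a membrane-potential trace
#'
#' A beat is an upward crossing of a fixed threshold (default -20 mV) with
#' positive slope; crossing times are refined by linear interpolation between
#' the flanking samples, and crossings closer than the refractory floor to
#' the previous accepted beat are ignored.
#'
#' @param time Strictly increasing sample times, s.
#' @param em Membrane potential samples, mV (same length as `time`).
#' @param threshold Crossing threshold, mV.
#' @param refractory Minimum beat-to-beat spacing, s.
#' @return Beat times, s (possibly empty).
#' @export
extract_beats <- function(time, em, threshold = -20, refractory = 0.03) {
  if (length(time) != length(em)) stop("time and em must have equal length")
  if (length(time) < 2) return(numeric())
  if (is.unsorted(time, strictly = TRUE)) stop("time must be strictly increasing")
  i <- which(em[-length(em)] < threshold & em[-1] >= threshold)
  if (!length(i)) return(numeric())
  frac <- (threshold - em[i]) / (em[i + 1] - em[i])
  ct <- time[i] + frac * (time[i + 1] - time[i])
  out <- ct[1]
  for (b in ct[-1]) if (b - out[length(out)] >= refractory) out <- c(out, b)
  out
}

#' Simulate the pacemaker model under a condition
#'
#' Integrates the stiff initial-value problem from the model's stored resting
#' state and analyzes firing on the terminal window only. Parameter scalings
#' (the randomized quantities of a population variant) are applied
#' multiplicatively before the condition transform. Integrator failures are
#' downgraded to a status flag so population runs never abort.
#'
#' @param model A \code{\link{pacemaker_model}}.
#' @param scalings Named positive multiplicative scalings of model
#'   parameters, or `NULL` for the nominal cell.
#' @param transform A `condition_transform`, or one of `"baseline"`, `"iso"`,
#'   `"cch"` to use the shipped configuration.
#' @param duration Total simulated time, s.
#' @param analysis_window Terminal window analyzed for beats, s
#'   (< `duration`).
#' @param dt Output sampling interval, s.
#' @param rtol,atol Integrator tolerances.
#' @param beat_threshold,refractory Beat-detection settings, mV and s.
#' @param cv_limit Steadiness criterion: maximum coefficient of variation of
#'   the last (up to) 10 cycle lengths.
#' @return An object of class `san_sim`: list with `time` (s), `em_trace`
#'   (mV), `beat_times` (s), `cycle_lengths` (s), `firing_rate` (bpm, `NA`
#'   unless `status == "ok"`), `steady`, `status` (one of `"ok"`,
#'   `"no_firing"`, `"integration_failure"`) and `condition`.
#' @examples
#' \donttest{
#' m <- pacemaker_model()
#' s <- simulate_pacemaker(m, duration = 20, analysis_window = 8)
#' s$firing_rate
#' }
#' @export
simulate_pacemaker <- function(model, scalings = NULL, transform = "baseline",
                               duration = 150, analysis_window = 20,
                               dt = 0.001, rtol = 1e-6, atol = 1e-8,
                               beat_threshold = -20, refractory = 0.03,
                               cv_limit = 0.02) {
  stopifnot(inherits(model, "pacemaker_model"),
            duration > analysis_window, analysis_window > 0)
  if (is.character(transform)) transform <- condition_transforms()[[match.arg(
    transform, c("baseline", "iso", "cch"))]]
  p <- model$param_table
  if (!is.null(scalings)) {
    bad <- setdiff(names(scalings), names(p))
    if (length(bad)) stop("scaling names not in the parameter table: ",
                          paste(bad, collapse = ", "))
    if (any(scalings < 0)) stop("scalings must be non-negative")
    p[names(scalings)] <- p[names(scalings)] * scalings
  }
  p <- apply_condition(p, transform)
  times_ms <- seq(0, duration * 1000, by = dt * 1000)
  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = model$init_state, times = times_ms, func = "san_derivs",
      parms = p, dllname = "sanpop", initfunc = "san_initparms",
      method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000)),
    error = function(e) NULL)
  res <- list(time = numeric(), em_trace = numeric(), beat_times = numeric(),
              cycle_lengths = numeric(), firing_rate = NA_real_,
              steady = FALSE, status = "integration_failure",
              condition = transform$condition)
  class(res) <- "san_sim"
  if (is.null(out) || nrow(out) < length(times_ms) ||
      any(!is.finite(out[, "V"]))) {
    return(res)
  }
  res$time <- out[, "time"] / 1000
  res$em_trace <- out[, "V"]
  beats <- extract_beats(res$time, res$em_trace, beat_threshold, refractory)
  res$beat_times <- beats
  win <- beats[beats >= duration - analysis_window]
  if (length(win) < 2) {
    res$status <- "no_firing"
    return(res)
  }
  cl <- diff(win)
  res$cycle_lengths <- cl
  res$firing_rate <- 60 / mean(cl)
  tail_cl <- utils::tail(cl, 10)
  res$steady <- length(tail_cl) >= 2 &&
    stats::sd(tail_cl) / mean(tail_cl) < cv_limit
  res$status <- "ok"
  res
}

#' @export
print.san_sim <- function(x, ...) {
  cat("SAN simulation [", x$condition, "]: status=", x$status, sep = "")
  if (x$status == "ok") {
    cat(sprintf(", %d beats, rate %.1f bpm, steady=%s",
                length(x$beat_times), x$firing_rate, x$steady))
  }
  cat("\n")
  invisible(x)
}
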