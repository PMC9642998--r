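#' Configuration of a model population
#'
#' Describes the randomized population: how many variants, which parameters
#' are varied, and the width of the variability. Each varied parameter of
#' each variant receives an independent multiplicative scaling factor
#' `exp(e)` with `e ~ Normal(0, sigma)`; `sigma` is the standard deviation of
#' the underlying normal on the log scale (so the median factor is 1), the
#' standard population-of-models convention. The reference width is
#' sigma = 0.26 with 10,000 variants.
#'
#' @param n_variants Number of variants (>= 1).
#' @param sigma SD of log scaling factors (>= 0).
#' @param varied_params Character vector of parameter names to vary; defaults
#'   to the model's scalable conductances and transport/flux rates.
#' @param seed RNG seed.
#' @return Object of class `population_config`.
#' @export
population_config <- function(n_variants = 10000, sigma = 0.26,
                              varied_params = san_scalable_params(),
                              seed = 1L) {
  if (length(varied_params) == 0) stop("varied_params must be non-empty")
  stopifnot(n_variants >= 1, sigma >= 0)
  structure(list(n_variants = as.integer(n_variants), sigma = sigma,
                 varied_params = varied_params, seed = as.integer(seed)),
            class = "population_config")
}

#' Sample the population scaling factors
#'
#' Draws the full matrix of per-variant, per-parameter multiplicative scaling
#' factors in one reproducible pass, so the result is identical for a given
#' seed regardless of how the variants are later executed or ordered.
#'
#' @param config A \code{\link{population_config}}.
#' @return Numeric matrix, `n_variants` rows x varied parameters columns; all
#'   entries positive, log-median 0.
#' @export
sample_scalings <- function(config) {
  stopifnot(inherits(config, "population_config"))
  k <- length(config$varied_params)
  withr_seed(config$seed, {
    m <- matrix(exp(stats::rnorm(config$n_variants * k, 0, config$sigma)),
                nrow = config$n_variants, ncol = k,
                dimnames = list(NULL, config$varied_params))
    m
  })
}

#' Run a population of model variants under the three conditions
#'
#' Simulates every variant at baseline and under isoproterenol and carbachol
#' and records its firing rates and fractional rate responses. Two engines
#' are available: the full stiff-ODE pacemaker model, and the analytic
#' surrogate population map (\code{\link{surrogate_rates}}), which is exact,
#' instantaneous, and used for fast pipeline validation. Per-variant results
#' depend only on the variant's own scalings, so execution order is
#' irrelevant; individual integrator failures are recorded as discarded
#' variants, never raised.
#'
#' @param scalings Scaling matrix from \code{\link{sample_scalings}} (or any
#'   matrix with parameter-named columns).
#' @param engine `"ode"` or `"surrogate"`.
#' @param model A \code{\link{pacemaker_model}} (ODE engine).
#' @param transforms Named list of condition transforms with elements
#'   `baseline`, `iso`, `cch` (ODE engine); defaults to the shipped
#'   configuration.
#' @param surrogate A \code{\link{surrogate_spec}} (surrogate engine).
#' @param duration,analysis_window,dt Simulation settings passed to
#'   \code{\link{simulate_pacemaker}} (ODE engine).
#' @param progress Print a dot every 25 variants (ODE engine).
#' @return Data frame with one row per variant: `id`, one column per varied
#'   parameter (the scaling factors), `rate_baseline`, `rate_iso`,
#'   `rate_cch` (bpm), `delta_iso`, `delta_cch` (fractional change vs own
#'   baseline), `sim_ok` (all three simulations fired and were steady),
#'   `status` (`"ok"` pending filtering) and `label` (`"unlabeled"`).
#' @export
run_population <- function(scalings, engine = c("surrogate", "ode"),
                           model = NULL, transforms = NULL, surrogate = NULL,
                           duration = 30, analysis_window = 10, dt = 0.001,
                           progress = FALSE) {
  engine <- match.arg(engine)
  stopifnot(is.matrix(scalings), !is.null(colnames(scalings)))
  n <- nrow(scalings)
  if (engine == "surrogate") {
    if (is.null(surrogate)) surrogate <- surrogate_spec()
    rates <- surrogate_rates(surrogate, scalings)
    sim_ok <- rep(TRUE, n)
  } else {
    if (is.null(model)) model <- pacemaker_model()
    if (is.null(transforms)) transforms <- condition_transforms()
    rates <- data.frame(rate_baseline = rep(NA_real_, n),
                        rate_iso = NA_real_, rate_cch = NA_real_)
    sim_ok <- rep(FALSE, n)
    for (i in seq_len(n)) {
      s <- scalings[i, ]
      sims <- lapply(transforms[c("baseline", "iso", "cch")], function(tr) {
        simulate_pacemaker(model, scalings = s, transform = tr,
                           duration = duration,
                           analysis_window = analysis_window, dt = dt)
      })
      ok <- vapply(sims, function(x) x$status == "ok" && x$steady, logical(1))
      if (all(ok)) {
        rates$rate_baseline[i] <- sims$baseline$firing_rate
        rates$rate_iso[i] <- sims$iso$firing_rate
        rates$rate_cch[i] <- sims$cch$firing_rate
        sim_ok[i] <- TRUE
      }
      if (progress && i %% 25 == 0) cat(".")
    }
    if (progress) cat("\n")
  }
  out <- data.frame(id = seq_len(n), scalings, rates,
                    delta_iso = rates$rate_iso / rates$rate_baseline - 1,
                    delta_cch = rates$rate_cch / rates$rate_baseline - 1,
                    sim_ok = sim_ok,
                    status = "ok", label = "unlabeled",
                    stringsAsFactors = FALSE)
  attr(out, "varied_params") <- colnames(scalings)
  out
}

#' Filter non-physiological variants
#'
#' Marks a variant as discarded when any condition failed to produce steady
#' firing (lack of firing activity, integrator failure or unsteady terminal
#' behavior) or when any of its rates falls outside broad physiological
#' bounds. Record counts are conserved: every input row comes back with
#' status `"ok"` or `"discarded"`.
#'
#' @param records Population data frame from \code{\link{run_population}}.
#' @param rate_bounds Admissible rate interval, bpm (applied to all three
#'   conditions).
#' @return The records with `status` set; discarded rows get label
#'   `"unlabeled"`.
#' @export
filter_physiological <- function(records, rate_bounds = c(60, 900)) {
  stopifnot(is.data.frame(records), length(rate_bounds) == 2)
  rates <- records[, c("rate_baseline", "rate_iso", "rate_cch")]
  in_bounds <- apply(rates, 1, function(r) {
    all(is.finite(r)) && all(r >= rate_bounds[1]) && all(r <= rate_bounds[2])
  })
  bad <- !records$sim_ok | !in_bounds
  records$status <- ifelse(bad, "discarded", "ok")
  records$label[bad] <- "unlabeled"
  records
}

#' Reference triplet of the nominal cell
#'
#' Computes the classification reference — baseline rate, fractional
#' isoproterenol response and fractional carbachol response — from the
#' unscaled model (the nominal wild-type cell), using the same engine and
#' settings as the population run.
#'
#' @inheritParams run_population
#' @return List with `rate_baseline`, `delta_iso`, `delta_cch`.
#' @export
reference_response <- function(engine = c("surrogate", "ode"), model = NULL,
                               transforms = NULL, surrogate = NULL,
                               duration = 30, analysis_window = 10,
                               dt = 0.001) {
  engine <- match.arg(engine)
  if (engine == "surrogate") {
    if (is.null(surrogate)) surrogate <- surrogate_spec()
    s <- rep(1, nrow(surrogate$coef))
    names(s) <- rownames(surrogate$coef)
    r <- surrogate_rates(surrogate, s)
    list(rate_baseline = r$rate_baseline,
         delta_iso = r$rate_iso / r$rate_baseline - 1,
         delta_cch = r$rate_cch / r$rate_baseline - 1)
  } else {
    if (is.null(model)) model <- pacemaker_model()
    if (is.null(transforms)) transforms <- condition_transforms()
    sims <- lapply(transforms[c("baseline", "iso", "cch")], function(tr) {
      simulate_pacemaker(model, transform = tr, duration = duration,
                         analysis_window = analysis_window, dt = dt)
    })
    if (any(vapply(sims, function(x) x$status != "ok", logical(1)))) {
      stop("the nominal model failed to fire; cannot build a reference")
    }
    rb <- sims$baseline$firing_rate
    list(rate_baseline = rb,
         delta_iso = sims$iso$firing_rate / rb - 1,
         delta_cch = sims$cch$firing_rate / rb - 1)
  }
}

#' Classify variants into SSS-like and WT-like phenotypes
#'
#' A variant is SSS-like when, relative to the reference (nominal) cell, it
#' shows all three of: a slower baseline firing rate, a larger fractional
#' response to isoproterenol, and a smaller-magnitude response to carbachol.
#' All inequalities are strict — a variant tied with the reference on any
#' criterion is WT-like — and every other non-discarded variant is WT-like.
#' Discarded variants stay unlabeled.
#'
#' @param records Filtered population data frame
#'   (\code{\link{filter_physiological}}).
#' @param reference Reference triplet from \code{\link{reference_response}}.
#' @return The records with `label` set to `"SSS_like"` / `"WT_like"` /
#'   `"unlabeled"`.
#' @export
classify_variants <- function(records, reference) {
  stopifnot(is.data.frame(records),
            all(c("rate_baseline", "delta_iso", "delta_cch") %in% names(records)))
  ref <- unlist(reference[c("rate_baseline", "delta_iso", "delta_cch")])
  if (any(!is.finite(ref))) stop("reference contains non-finite entries")
  ok <- records$status == "ok"
  sss <- ok &
    records$rate_baseline < ref["rate_baseline"] &
    records$delta_iso > ref["delta_iso"] &
    abs(records$delta_cch) < abs(ref["delta_cch"])
  records$label[ok] <- ifelse(sss[ok], "SSS_like", "WT_like")
  records$label[!ok] <- "unlabeled"
  records
}

#' Compare parameter scalings between the two phenotype groups
#'
#' For every varied parameter, contrasts the scaling-factor distributions of
#' the SSS-like and WT-like subpopulations: group medians with their boxplot
#' notch intervals (\code{\link{notch_interval}}), the two-sided Wilcoxon
#' rank-sum p-value (\code{\link{wilcoxon_rank_sum}}), the direction of the
#' median difference (sign of SSS - WT) and a significance flag at `alpha`.
#'
#' @param records Labeled population data frame
#'   (\code{\link{classify_variants}}).
#' @param params Parameters to compare; defaults to the varied parameters
#'   recorded on the population.
#' @param alpha Significance level.
#' @return Data frame with one row per parameter: `parameter`, `median_wt`,
#'   `median_sss`, `notch_wt_lower`, `notch_wt_upper`, `notch_sss_lower`,
#'   `notch_sss_upper`, `p`, `direction` (-1, 0, 1), `significant`.
#' @export
compare_groups <- function(records, params = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(records))
  if (is.null(params)) params <- attr(records, "varied_params")
  if (is.null(params)) stop("no varied-parameter list; supply `params`")
  sss <- records[records$label == "SSS_like", , drop = FALSE]
  wt <- records[records$label == "WT_like", , drop = FALSE]
  if (nrow(sss) == 0) stop("the SSS-like group is empty")
  if (nrow(wt) == 0) stop("the WT-like group is empty")
  rows <- lapply(params, function(pn) {
    xs <- sss[[pn]]; xw <- wt[[pn]]
    ns <- notch_interval(xs); nw <- notch_interval(xw)
    w <- wilcoxon_rank_sum(xs, xw)
    md <- stats::median(xs) - stats::median(xw)
    data.frame(parameter = pn,
               median_wt = stats::median(xw), median_sss = stats::median(xs),
               notch_wt_lower = nw[["lower"]], notch_wt_upper = nw[["upper"]],
               notch_sss_lower = ns[["lower"]], notch_sss_upper = ns[["upper"]],
               p = w$p, direction = sign(md), significant = w$p < alpha,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Partition counts of a labeled population
#'
#' @param records Labeled population data frame.
#' @return Named integer vector `c(n_sss, n_wt, n_discarded, n_total)`.
#' @export
population_counts <- function(records) {
  c(n_sss = sum(records$label == "SSS_like"),
    n_wt = sum(records$label == "WT_like"),
    n_discarded = sum(records$status == "discarded"),
    n_total = nrow(records))
}
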