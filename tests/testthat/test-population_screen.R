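test_that("scaling factors follow the log-normal population convention", {
  # sigma = 0: every factor exactly 1
  cfg0 <- population_config(n_variants = 5, sigma = 0, seed = 1)
  expect_true(all(sample_scalings(cfg0) == 1))

  # reproducibility
  cfg <- population_config(n_variants = 50, sigma = 0.26, seed = 42)
  expect_identical(sample_scalings(cfg), sample_scalings(cfg))

  # n = 10,000: per-parameter SD of log factors within 0.26 +/- 0.01,
  # log-median near 0
  big <- population_config(n_variants = 10000, sigma = 0.26, seed = 3)
  m <- sample_scalings(big)
  expect_equal(dim(m), c(10000L, length(san_scalable_params())))
  sds <- apply(log(m), 2, sd)
  expect_true(all(abs(sds - 0.26) < 0.01))
  expect_true(all(abs(apply(log(m), 2, median)) < 0.02))
  expect_true(all(m > 0))

  expect_error(population_config(varied_params = character()), "non-empty")
})

test_that("population records conserve counts and are order-independent", {
  cfg <- population_config(n_variants = 300, sigma = 0.26,
                           varied_params = rownames(default_surrogate_coef()),
                           seed = 11)
  sc <- sample_scalings(cfg)
  rec <- run_population(sc, engine = "surrogate")
  expect_equal(nrow(rec), 300L)
  expect_equal(rec$delta_iso, rec$rate_iso / rec$rate_baseline - 1)

  # shuffling variant order changes no per-variant value
  perm <- sample(nrow(sc))
  rec2 <- run_population(sc[perm, ], engine = "surrogate")
  expect_equal(rec2$rate_baseline, rec$rate_baseline[perm])
  expect_equal(rec2$rate_cch, rec$rate_cch[perm])
})

test_that("a single unscaled variant run through the population op matches direct simulation", {
  m <- pacemaker_model()
  sc <- matrix(1, nrow = 1, ncol = length(san_scalable_params()),
               dimnames = list(NULL, san_scalable_params()))
  rec <- run_population(sc, engine = "ode", model = m,
                        duration = 12, analysis_window = 5)
  direct <- lapply(c("baseline", "iso", "cch"), function(cc) {
    simulate_pacemaker(m, transform = cc, duration = 12, analysis_window = 5)
  })
  expect_identical(rec$rate_baseline, direct[[1]]$firing_rate)
  expect_identical(rec$rate_iso, direct[[2]]$firing_rate)
  expect_identical(rec$rate_cch, direct[[3]]$firing_rate)
})

test_that("a small ODE population runs, filters and classifies end to end", {
  cfg <- population_config(n_variants = 6, sigma = 0.26, seed = 19)
  sc <- sample_scalings(cfg)
  rec <- run_population(sc, engine = "ode", duration = 12, analysis_window = 5)
  rec <- filter_physiological(rec)
  expect_true(all(rec$status %in% c("ok", "discarded")))
  ref <- reference_response(engine = "ode", duration = 12, analysis_window = 5)
  rec <- classify_variants(rec, ref)
  cts <- population_counts(rec)
  expect_equal(unname(cts["n_sss"] + cts["n_wt"] + cts["n_discarded"]),
               unname(cts["n_total"]))
})

test_that("non-physiological variants are discarded, others retained", {
  # surrogate population plus a hand-built pathological variant
  cfg <- population_config(n_variants = 50, sigma = 0.1,
                           varied_params = rownames(default_surrogate_coef()),
                           seed = 2)
  rec <- run_population(sample_scalings(cfg), engine = "surrogate")
  rec$rate_cch[3] <- NA; rec$sim_ok[3] <- FALSE        # no firing under CCh
  rec$rate_baseline[7] <- 20                           # below rate bounds
  out <- filter_physiological(rec)
  expect_identical(out$status[3], "discarded")
  expect_identical(out$status[7], "discarded")
  expect_equal(sum(out$status == "ok") + sum(out$status == "discarded"), 50L)
  expect_equal(sum(out$status == "discarded"), 2L)
})

test_that("classification requires all three criteria with ties going to WT", {
  ref <- list(rate_baseline = 400, delta_iso = 0.2, delta_cch = -0.2)
  rec <- data.frame(
    id = 1:4,
    rate_baseline = c(380, 400, 380, 380),
    rate_iso = c(380 * 1.3, 400 * 1.3, 380 * 1.1, 380 * 1.3),
    rate_cch = c(380 * 0.9, 400 * 0.9, 380 * 0.9, 380 * 0.7),
    sim_ok = TRUE, status = "ok", label = "unlabeled",
    stringsAsFactors = FALSE)
  rec$delta_iso <- rec$rate_iso / rec$rate_baseline - 1
  rec$delta_cch <- rec$rate_cch / rec$rate_baseline - 1
  out <- classify_variants(rec, ref)
  expect_identical(out$label,
                   c("SSS_like",  # dominates on all three criteria
                     "WT_like",   # ties reference baseline rate
                     "WT_like",   # smaller ISO response
                     "WT_like"))  # larger CCh response magnitude
  expect_error(classify_variants(rec, list(rate_baseline = NaN,
                                           delta_iso = 0.2, delta_cch = -0.2)),
               "non-finite")
})

test_that("group comparison flags a constructed shift with the right direction", {
  set.seed(8)
  n <- 120
  rec <- data.frame(
    id = 1:n,
    G_CaL = exp(rnorm(n, 0, 0.2)), G_Na = exp(rnorm(n, 0, 0.2)),
    rate_baseline = 400, rate_iso = 480, rate_cch = 320,
    delta_iso = 0.2, delta_cch = -0.2,
    sim_ok = TRUE, status = "ok",
    label = rep(c("SSS_like", "WT_like"), each = n / 2),
    stringsAsFactors = FALSE)
  rec$G_CaL[rec$label == "SSS_like"] <-
    rec$G_CaL[rec$label == "SSS_like"] * 0.6
  cmp <- compare_groups(rec, params = c("G_CaL", "G_Na"))
  g <- cmp[cmp$parameter == "G_CaL", ]
  expect_true(g$significant)
  expect_equal(g$direction, -1)
  expect_true(g$notch_sss_upper < g$notch_wt_lower)  # notches do not overlap
  expect_false(cmp$significant[cmp$parameter == "G_Na"])

  # monotone alpha: parameters flagged at 0.01 are a subset of those at 0.05
  cmp01 <- compare_groups(rec, params = c("G_CaL", "G_Na"), alpha = 0.01)
  expect_true(all(cmp01$parameter[cmp01$significant] %in%
                  cmp$parameter[cmp$significant]))

  none <- rec[rec$label == "WT_like", ]
  expect_error(compare_groups(none, params = "G_CaL"), "SSS-like group is empty")
})

test_that("selection shift: slow-baseline selection lowers positively coupled scalings", {
  # brute-force oracle on a gridded two-parameter surrogate population:
  # log-rate is a known linear map, so enumerate every grid point exactly
  coef <- matrix(0, 2, 3, dimnames = list(c("G_CaL", "v_NCX"),
                                          c("baseline", "iso", "cch")))
  coef["G_CaL", ] <- c(0.5, 0.5, 0.5)   # positively rate-coupled
  coef["v_NCX", ] <- c(-0.2, -0.2, -0.2) # negatively rate-coupled
  sp <- surrogate_spec(coef = coef)
  g <- seq(-0.5, 0.5, length.out = 41)
  grid <- as.matrix(expand.grid(G_CaL = exp(g), v_NCX = exp(g)))
  rates <- surrogate_rates(sp, grid)
  slow <- rates$rate_baseline < sp$base_rates[["baseline"]]
  expect_lt(median(grid[slow, "G_CaL"]), median(grid[, "G_CaL"]))
  expect_gt(median(grid[slow, "v_NCX"]), median(grid[, "v_NCX"]))

  # pipeline classification equals brute-force enumeration of the inequalities
  rec <- run_population(grid, engine = "surrogate", surrogate = sp)
  rec <- filter_physiological(rec, rate_bounds = c(0, Inf))
  ref <- reference_response(engine = "surrogate", surrogate = sp)
  rec <- classify_variants(rec, ref)
  expected <- ifelse(
    rates$rate_baseline < ref$rate_baseline &
      (rates$rate_iso / rates$rate_baseline - 1) > ref$delta_iso &
      abs(rates$rate_cch / rates$rate_baseline - 1) < abs(ref$delta_cch),
    "SSS_like", "WT_like")
  expect_identical(rec$label, expected)
})
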