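test_that("open-pore fit recovers the baseline of pure and contaminated traces", {
  # constant trace: exact degenerate fit
  m <- fit_open_pore(current_trace(rep(72, 2000), 1e4))
  expect_equal(m$I0, 72)
  expect_equal(m$sigma0, 0)

  # seeded Gaussian baseline: moments recovered to +/- 0.05 pA
  set.seed(1)
  m <- fit_open_pore(current_trace(rnorm(1e5, 72, 1.5), 1e4))
  expect_equal(m$I0, 72, tolerance = 0.05 / 72)
  expect_equal(m$sigma0, 1.5, tolerance = 0.05 / 1.5)

  # bimodal trace: the highest-current peak wins, not a weighted average
  set.seed(2)
  x <- c(rnorm(9e4, 72, 1.5), rnorm(1e4, 10, 1.5))
  m <- fit_open_pore(current_trace(x, 1e4))
  expect_equal(m$I0, 72, tolerance = 0.1 / 72)
  # ... even when blockade samples dominate
  set.seed(3)
  x <- c(rnorm(3e4, 72, 1.5), rnorm(7e4, 10, 1.5))
  m <- fit_open_pore(current_trace(x, 1e4))
  expect_equal(m$I0, 72, tolerance = 0.1 / 72)

  # flat histogram: no identifiable peak
  set.seed(4)
  expect_error(fit_open_pore(current_trace(runif(5e4, 0, 100), 1e4)),
               "no identifiable")
  expect_error(fit_open_pore(current_trace(rnorm(500, 72, 1), 1e4)),
               "too short")
})

test_that("a square pulse is extracted with exact boundaries and features", {
  base <- rep(72, 1000)
  base[101:150] <- 6.48  # 50 samples at 9% of 72 pA
  tr <- current_trace(base, 1e4)
  opm <- fit_open_pore(tr)
  evs <- extract_events(tr, opm, k_sigma = 3)
  expect_length(evs, 1)
  e <- compute_features(evs[[1]], opm)
  expect_equal(e$start_index, 100)  # 0-based half-open
  expect_equal(e$end_index, 150)
  expect_equal(e$dwell_ms, 5.0)
  expect_equal(e$rel_current_pct, 9.0)
  expect_equal(e$mean_residual_pA, 6.48)
  expect_true(is.na(e$rel_sigma))  # sigma0 = 0: undefined, not infinite

  # a trace never below threshold yields no events
  expect_length(extract_events(current_trace(rep(72, 1000), 1e4), opm), 0)
})

test_that("extraction is identical to a sample-by-sample threshold scan", {
  for (s in 1:5) {
    sim <- simulate_trace(sim_config(duration_s = 8, capture_rate_Hz = 6,
                                     seed = s), default_signatures())
    opm <- fit_open_pore(sim$trace)
    got <- extract_events(sim$trace, opm)
    want <- oracle_threshold_scan(sim$trace$samples, opm$I0 - 3 * opm$sigma0)
    expect_equal(length(got), nrow(want))
    expect_equal(vapply(got, `[[`, numeric(1), "start_index"), want$start_index)
    expect_equal(vapply(got, `[[`, numeric(1), "end_index"), want$end_index)
  }
})

test_that("detection recovers simulated ground truth", {
  # restrict to the regime where recovery is well-posed: deep blockades
  # (rel current well below the 3-sigma threshold) and dwell >= 0.5 ms
  sim <- simulate_trace(sim_config(duration_s = 60, capture_rate_Hz = 5,
                                   seed = 12), default_signatures()["nY125"])
  det <- detect_events(sim$trace)
  m <- match_events(det$events, sim$events)
  truth_ok <- sim$events$dwell_ms >= 0.5 & sim$events$mean_rel_current_pct <= 20
  matched <- !is.na(m$match)
  expect_gte(sum(matched[m$match %in% which(truth_ok)]) / sum(truth_ok), 0.95)
  dd <- vapply(seq_along(det$events), function(i) {
    j <- m$match[i]
    if (is.na(j)) return(NA_real_)
    (det$events[[i]]$end_index - det$events[[i]]$start_index) -
      (sim$events$end_index[j] - sim$events$start_index[j])
  }, numeric(1))
  expect_true(all(abs(dd[matched]) <= 2))
})

test_that("features equal a direct recomputation from raw samples", {
  set.seed(21)
  opm <- structure(list(I0 = 72, sigma0 = 1.5, fit = list()),
                   class = "open_pore_model")
  for (r in 1:5) {
    n <- sample(3:60, 1)
    x <- runif(n, 4, 20)
    e <- porePTM:::blockade_event(100L, 100L + n, x, 1e4)
    e <- compute_features(e, opm)
    expect_equal(e$dwell_ms, n / 1e4 * 1000)
    expect_equal(e$mean_residual_pA, sum(x) / n)
    expect_equal(e$rel_current_pct, 100 * mean(x) / 72)
    expect_equal(e$rel_sigma, sqrt(sum((x - mean(x))^2) / (n - 1)) / 1.5)
  }
  # 26 samples at 10 kHz -> 2.6 ms
  e <- compute_features(porePTM:::blockade_event(0L, 26L, rep(6.48, 26), 1e4), opm)
  expect_equal(e$dwell_ms, 2.6)
  expect_equal(e$rel_sigma, 0)
})

test_that("local extrema match hand enumeration and alternate strictly", {
  opm <- structure(list(I0 = 100, sigma0 = 0, fit = list()),
                   class = "open_pore_model")
  mk <- function(x) compute_features(porePTM:::blockade_event(0L, length(x),
                                                              x, 1e4), opm)
  # monotone: no interior extrema
  e <- extract_local_extrema(mk(seq(50, 10, length.out = 8)), 0)
  expect_equal(nrow(e$extrema), 0)
  # 1-2 sample events: empty
  expect_equal(nrow(extract_local_extrema(mk(c(5, 9)), 0)$extrema), 0)

  e <- extract_local_extrema(mk(c(50, 30, 60, 20, 70)), 0)
  expect_equal(e$extrema[, "rel_current_pct"], c(30, 60, 20))
  expect_equal(e$extrema[, "kind"], c(-1, 1, -1))
  expect_equal(e$extrema[, "t_s"], c(1, 2, 3) / 1e4)
  expect_true(all(diff(e$extrema[, "t_s"]) > 0))
})

test_that("extrema pruning equals the naive prominence scan", {
  set.seed(33)
  opm <- structure(list(I0 = 72, sigma0 = 1.5, fit = list()),
                   class = "open_pore_model")
  for (r in 1:20) {
    n <- sample(5:120, 1)
    x <- 6 + cumsum(rnorm(n, 0, 1.2))
    prom <- sample(c(0, 0.5, 1.5, 3), 1)
    e <- compute_features(porePTM:::blockade_event(0L, n, x, 1e4), opm)
    e <- extract_local_extrema(e, min_prominence = prom)
    want <- oracle_extrema(x, prom)
    expect_equal(nrow(e$extrema), nrow(want))
    if (nrow(want)) {
      expect_equal(e$extrema[, "t_s"] * 1e4 + 1, want$index)
      expect_equal(e$extrema[, "rel_current_pct"], 100 * want$value / 72)
      k <- e$extrema[, "kind"]
      if (length(k) > 1) expect_true(all(diff(k) != 0))  # strict alternation
    }
  }
})

test_that("event filters keep the documented inclusive windows", {
  opm <- structure(list(I0 = 72, sigma0 = 1.5, fit = list()),
                   class = "open_pore_model")
  mk <- function(dwell_ms, rel = 10) {
    n <- as.integer(round(dwell_ms * 10))  # 10 kHz
    compute_features(porePTM:::blockade_event(0L, n, rep(72 * rel / 100, n), 1e4),
                     opm)
  }
  evs <- lapply(c(0.1, 0.2, 2.58, 100.0, 150), mk)
  kept <- filter_events(evs)
  expect_length(kept, 3)
  expect_equal(attr(kept, "n_discarded"), 2)
  # 2.58 ms renders as 26 samples at 10 kHz, i.e. a measured dwell of 2.6 ms
  expect_equal(vapply(kept, `[[`, numeric(1), "dwell_ms"), c(0.2, 2.6, 100))

  # relative-current window
  expect_length(filter_events(list(mk(5, rel = 45))), 0)
  expect_length(filter_events(list(mk(5, rel = 40))), 1)

  # idempotent and order-preserving
  again <- filter_events(kept)
  expect_equal(vapply(again, `[[`, numeric(1), "dwell_ms"),
               vapply(kept, `[[`, numeric(1), "dwell_ms"))
})

test_that("population Gaussian fits recover two-level wt statistics", {
  set.seed(7)
  v <- c(rnorm(5000, 9.0, 2.0), rnorm(5000, 17.1, 2.0))
  fit <- fit_population_gaussians(v, K = 2)
  expect_equal(fit$components$mean[1], 9.0, tolerance = 0.2 / 9)
  expect_equal(fit$components$mean[2], 17.1, tolerance = 0.2 / 17.1)
  expect_equal(fit$components$sd, c(2, 2), tolerance = 0.1)
  expect_equal(sum(fit$components$weight), 1)

  # K = 1 on a single population: mean within 3 SE
  set.seed(8)
  v1 <- rnorm(2000, 9, 2)
  f1 <- fit_population_gaussians(v1, K = 1)
  expect_lt(abs(f1$components$mean - 9), 3 * 2 / sqrt(2000))

  # degenerate: identical values
  fd <- fit_population_gaussians(rep(9, 100), K = 1)
  expect_equal(fd$components$mean, 9)
  expect_equal(fd$components$sd, 0)
  expect_error(fit_population_gaussians(rep(9, 100), K = 2), "identical")
  expect_error(fit_population_gaussians(rnorm(20), K = 1), "at least 50")
})
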