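# Open-pore baseline fitting, threshold event extraction, per-event features,
# local-extrema sequences, the standard event filters, and Gaussian fits to
# relative-current populations.

#' Fit the open-pore current distribution
#'
#' The baseline (I0, sigma0) is estimated by fitting a Gaussian to the peak
#' of the current histogram with the highest mean current — the open-pore
#' mode, not a blockade mode. The histogram uses Freedman-Diaconis bins;
#' candidate peaks are local maxima of the bin counts, the highest-current
#' one is selected, a first-pass width comes from the peak's full width at
#' half maximum, and the Gaussian is then least-squares fitted to the bins
#' within three of those widths of the mode (falling back to weighted moments
#' if the fit does not converge).
#'
#' @param trace A [current_trace()].
#' @param min_samples Minimum trace length for a meaningful fit.
#' @return An object of class `open_pore_model` with fields `I0`, `sigma0`
#'   and `fit` (bin width, window and method used).
#' @examples
#' tr <- current_trace(rnorm(1e4, 72, 1.5), 10000)
#' fit_open_pore(tr)
#' @export
fit_open_pore <- function(trace, min_samples = 1000) {
  stopifnot(inherits(trace, "current_trace"))
  x <- trace$samples
  if (length(x) < min_samples) {
    stop("trace too short for open-pore fit: ", length(x), " < ", min_samples)
  }
  if (stats::sd(x) == 0) {
    return(open_pore_model(x[1], 0, list(method = "degenerate")))
  }
  h <- graphics::hist(x, breaks = "FD", plot = FALSE)
  cnt <- h$counts; mids <- h$mids
  nb <- length(cnt)
  if (nb < 3L) stop("no identifiable open-pore peak: histogram too coarse")
  # local maxima (plateau-tolerant at the scale of single bins)
  is_peak <- cnt >= c(-Inf, cnt[-nb]) & cnt >= c(cnt[-1], -Inf) &
    cnt >= 0.05 * max(cnt)
  peaks <- which(is_peak)
  med_cnt <- stats::median(cnt)
  if (!length(peaks) || max(cnt[peaks]) - med_cnt < 3 * sqrt(med_cnt + 1)) {
    stop("no identifiable open-pore peak: flat current histogram")
  }
  mode_bin <- peaks[which.max(mids[peaks])]
  # FWHM around the selected peak -> first-pass sigma
  half <- cnt[mode_bin] / 2
  lo <- mode_bin; while (lo > 1L && cnt[lo - 1L] >= half) lo <- lo - 1L
  hi <- mode_bin; while (hi < nb && cnt[hi + 1L] >= half) hi <- hi + 1L
  bw <- mids[2] - mids[1]
  sigma_est <- max((mids[hi] - mids[lo] + bw) / 2.3548, bw / 2)
  win <- which(abs(mids - mids[mode_bin]) <= 3 * sigma_est)
  wm <- mids[win]; wc <- cnt[win]
  fit <- tryCatch({
    nf <- stats::nls(wc ~ A * exp(-(wm - mu)^2 / (2 * s^2)),
                     start = list(A = cnt[mode_bin], mu = mids[mode_bin],
                                  s = sigma_est),
                     control = stats::nls.control(maxiter = 200, warnOnly = FALSE))
    co <- stats::coef(nf)
    list(I0 = unname(co["mu"]), sigma0 = abs(unname(co["s"])), method = "nls")
  }, error = function(e) NULL)
  if (is.null(fit) || abs(fit$I0 - mids[mode_bin]) > 3 * sigma_est) {
    # sample moments within the peak window (exact for quasi-discrete peaks)
    w <- x[x >= mids[mode_bin] - 3 * sigma_est &
             x <= mids[mode_bin] + 3 * sigma_est]
    fit <- list(I0 = mean(w),
                sigma0 = if (length(w) > 1L) stats::sd(w) else 0,
                method = "moments")
  }
  open_pore_model(fit$I0, fit$sigma0,
                  list(bin_width = bw, window_pA = range(wm),
                       method = fit$method))
}

open_pore_model <- function(I0, sigma0, fit = list()) {
  if (I0 <= 0) stop("open-pore current I0 must be positive")
  if (sigma0 < 0) stop("sigma0 must be non-negative")
  structure(list(I0 = I0, sigma0 = sigma0, fit = fit),
            class = "open_pore_model")
}

#' @export
print.open_pore_model <- function(x, ...) {
  cat(sprintf("<open_pore_model> I0 = %.3f pA, sigma0 = %.3f pA (%s fit)\n",
              x$I0, x$sigma0, x$fit$method %||% "?"))
  invisible(x)
}

#' Extract blockade events by thresholding
#'
#' An event is a maximal run of consecutive samples below the detection
#' threshold `I0 - k_sigma * sigma0`. Boundaries are the first and last
#' sub-threshold samples (0-based, half-open indexing); events touching the
#' trace boundaries are discarded because their dwell cannot be measured.
#'
#' @param trace A [current_trace()].
#' @param opm An [fit_open_pore()] model for this trace (or a stated
#'   reference trace).
#' @param k_sigma Threshold depth in baseline SDs (default 3).
#' @return List of `blockade_event` objects in time order, features unset
#'   (see [compute_features()]).
#' @export
extract_events <- function(trace, opm, k_sigma = 3) {
  stopifnot(inherits(trace, "current_trace"), inherits(opm, "open_pore_model"))
  thr <- opm$I0 - k_sigma * opm$sigma0
  below <- trace$samples < thr
  if (!any(below)) return(list())
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  # drop runs touching the trace boundaries
  keep[keep & (starts == 1L | ends == length(below))] <- FALSE
  idx <- which(keep)
  lapply(idx, function(i) {
    s0 <- starts[i] - 1L  # 0-based start
    e0 <- ends[i]         # half-open end
    blockade_event(s0, e0, trace$samples[starts[i]:ends[i]],
                   trace$sampling_rate)
  })
}

blockade_event <- function(start_index, end_index, samples, sampling_rate) {
  structure(list(start_index = start_index, end_index = end_index,
                 samples = samples, sampling_rate = sampling_rate,
                 dwell_ms = NA_real_, mean_residual_pA = NA_real_,
                 rel_current_pct = NA_real_, rel_sigma = NA_real_,
                 I0 = NA_real_, sigma0 = NA_real_, extrema = NULL),
            class = "blockade_event")
}

#' @export
print.blockade_event <- function(x, ...) {
  cat(sprintf("<blockade_event> [%d, %d) %d samples", x$start_index,
              x$end_index, length(x$samples)))
  if (!is.na(x$dwell_ms)) {
    cat(sprintf(", dwell %.3f ms, I/I0 %.1f%%", x$dwell_ms, x$rel_current_pct))
  }
  cat("\n")
  invisible(x)
}

#' Compute per-event features
#'
#' Populates dwell time (ms), mean residual current I (pA), relative current
#' 100 * I / I0 (percent) and relative noise sigma / sigma0, where sigma is
#' the SD of the event's samples and (I0, sigma0) come from the open-pore
#' model used for detection. With `sigma0 = 0` the relative noise is
#' undefined and reported as `NA` rather than infinite.
#'
#' @param event A `blockade_event` (or list thereof).
#' @param opm The [fit_open_pore()] model used for detection.
#' @return The event(s) with feature fields populated.
#' @export
compute_features <- function(event, opm) {
  if (is.list(event) && !inherits(event, "blockade_event")) {
    return(lapply(event, compute_features, opm = opm))
  }
  stopifnot(inherits(event, "blockade_event"), length(event$samples) >= 1)
  event$dwell_ms <- (event$end_index - event$start_index) /
    event$sampling_rate * 1000
  event$mean_residual_pA <- mean(event$samples)
  event$rel_current_pct <- 100 * event$mean_residual_pA / opm$I0
  s <- if (length(event$samples) > 1L) stats::sd(event$samples) else 0
  event$rel_sigma <- if (opm$sigma0 > 0) s / opm$sigma0 else NA_real_
  event$I0 <- opm$I0
  event$sigma0 <- opm$sigma0
  event
}

#' Extract the local-extrema sequence of an event
#'
#' Plateaus (runs of equal samples) are collapsed to their first sample,
#' strict interior local minima and maxima of the collapsed sequence are
#' located, and shallow adjacent extrema pairs are pruned smallest-first
#' until every adjacent pair differs by at least `min_prominence` (pA). The
#' surviving sequence alternates strictly between minima and maxima and is
#' emitted as (time within event in seconds, relative current in percent).
#' Events of one or two samples have no interior extrema and yield an empty
#' sequence. The default prominence of one baseline SD suppresses pure-noise
#' extrema.
#'
#' @param event A `blockade_event` with features computed (or list thereof).
#' @param min_prominence Minimum pA difference between adjacent extrema;
#'   defaults to the event's `sigma0`.
#' @return The event with an `extrema` matrix (columns `t_s`,
#'   `rel_current_pct`, plus `kind` +1 for maxima / -1 for minima).
#' @export
extract_local_extrema <- function(event, min_prominence = NULL) {
  if (is.list(event) && !inherits(event, "blockade_event")) {
    return(lapply(event, extract_local_extrema, min_prominence = min_prominence))
  }
  stopifnot(inherits(event, "blockade_event"))
  if (is.na(event$rel_current_pct)) {
    stop("compute_features() must be called before extract_local_extrema()")
  }
  if (is.null(min_prominence)) {
    min_prominence <- if (is.na(event$sigma0)) 0 else event$sigma0
  }
  y <- event$samples
  ext <- local_extrema_indices(y, min_prominence)
  if (nrow(ext) == 0L) {
    event$extrema <- matrix(numeric(0), 0, 3,
                            dimnames = list(NULL, c("t_s", "rel_current_pct",
                                                    "kind")))
    return(event)
  }
  event$extrema <- cbind(t_s = (ext[, "index"] - 1) / event$sampling_rate,
                         rel_current_pct = 100 * ext[, "value"] / event$I0,
                         kind = ext[, "kind"])
  event
}

# Core extrema routine on a raw sample vector. Returns a matrix with 1-based
# `index`, `value` and `kind` (+1 max, -1 min).
local_extrema_indices <- function(y, min_prominence = 0) {
  n <- length(y)
  empty <- matrix(numeric(0), 0, 3,
                  dimnames = list(NULL, c("index", "value", "kind")))
  if (n < 3L) return(empty)
  # collapse plateaus: first index of each run of equal values
  r <- rle(y)
  pos <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  u <- r$values
  m <- length(u)
  if (m < 3L) return(empty)
  d1 <- diff(u)
  turn <- which(d1[-length(d1)] * d1[-1] < 0) + 1L  # strict interior extrema
  if (!length(turn)) return(empty)
  idx <- pos[turn]; val <- u[turn]
  kind <- ifelse(u[turn] > u[turn - 1L], 1, -1)
  # prune shallow adjacent pairs, smallest difference first
  repeat {
    if (length(val) == 0L) break
    if (length(val) == 1L) {
      # a lone extremum has no adjacent pair; keep it only if it stands out
      # against the event ends by the required prominence
      prom <- min(abs(val - y[1]), abs(val - y[n]))
      if (prom < min_prominence) val <- numeric(0)
      break
    }
    dd <- abs(diff(val))
    j <- which.min(dd)
    if (dd[j] >= min_prominence) break
    keep <- setdiff(seq_along(val), c(j, j + 1L))
    idx <- idx[keep]; val <- val[keep]; kind <- kind[keep]
  }
  if (!length(val)) return(empty)
  cbind(index = idx, value = val, kind = kind)
}

#' Filter events on dwell time and relative current
#'
#' Keeps events whose dwell lies in `dwell_range_ms` and whose average
#' relative current lies in `rel_current_range_pct`, boundaries inclusive —
#' discarding events that are too short, too long, or that do not block the
#' current sufficiently. Order is preserved and the operation is idempotent.
#'
#' @param events List of `blockade_event`s with features computed.
#' @param dwell_range_ms Inclusive dwell window in ms (default 0.2 to 100).
#' @param rel_current_range_pct Inclusive relative-current window in percent
#'   (default 0 to 40).
#' @return The surviving events, with attributes `n_kept` and `n_discarded`.
#' @export
filter_events <- function(events, dwell_range_ms = c(0.2, 100.0),
                          rel_current_range_pct = c(0, 40)) {
  stopifnot(is.list(events))
  if (length(events) == 0L) {
    return(structure(events, n_kept = 0L, n_discarded = 0L))
  }
  dw <- vapply(events, `[[`, numeric(1), "dwell_ms")
  rc <- vapply(events, `[[`, numeric(1), "rel_current_pct")
  if (anyNA(dw) || anyNA(rc)) {
    stop("filter_events requires compute_features() to have been run")
  }
  keep <- dw >= dwell_range_ms[1] & dw <= dwell_range_ms[2] &
    rc >= rel_current_range_pct[1] & rc <= rel_current_range_pct[2]
  structure(events[keep], n_kept = sum(keep), n_discarded = sum(!keep))
}

#' Convert events to an event table
#'
#' @param events List of `blockade_event`s with features (and optionally
#'   extrema) computed.
#' @param trace_id Identifier recorded in the `trace_id` column.
#' @param label Optional class label vector (recycled if length 1).
#' @return A data frame in the event-table schema
#'   (see [validate_event_table()]).
#' @export
events_to_table <- function(events, trace_id = "trace", label = NULL) {
  n <- length(events)
  tab <- data.frame(
    event_id = seq_len(n),
    trace_id = rep(trace_id, length.out = max(n, 0L)),
    start_index = vapply(events, `[[`, numeric(1), "start_index"),
    end_index = vapply(events, `[[`, numeric(1), "end_index"),
    dwell_ms = vapply(events, `[[`, numeric(1), "dwell_ms"),
    mean_residual_pA = vapply(events, `[[`, numeric(1), "mean_residual_pA"),
    rel_current_pct = vapply(events, `[[`, numeric(1), "rel_current_pct"),
    rel_sigma = vapply(events, `[[`, numeric(1), "rel_sigma"),
    n_extrema = vapply(events, function(e) {
      if (is.null(e$extrema)) NA_integer_ else nrow(e$extrema)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  if (n == 0L) {
    tab <- tab[0, , drop = FALSE]
  }
  if (!is.null(label)) tab$label <- rep(label, length.out = n)
  tab
}

#' Full detection pipeline on one trace
#'
#' Fits the open-pore model, extracts events at `k_sigma` baseline SDs,
#' computes features and local extrema, and applies the standard filters.
#'
#' @inheritParams extract_events
#' @inheritParams filter_events
#' @param min_prominence Extrema prominence in pA (default: fitted sigma0).
#' @return List with `opm`, `events` (filtered, features and extrema
#'   populated) and `summary` (counts).
#' @export
detect_events <- function(trace, k_sigma = 3, dwell_range_ms = c(0.2, 100.0),
                          rel_current_range_pct = c(0, 40),
                          min_prominence = NULL) {
  opm <- fit_open_pore(trace)
  evs <- extract_events(trace, opm, k_sigma = k_sigma)
  evs <- compute_features(evs, opm)
  evs <- extract_local_extrema(evs, min_prominence = min_prominence)
  n_raw <- length(evs)
  evs <- filter_events(evs, dwell_range_ms, rel_current_range_pct)
  list(opm = opm, events = evs,
       summary = list(I0 = opm$I0, sigma0 = opm$sigma0, n_detected = n_raw,
                      n_kept = attr(evs, "n_kept"),
                      n_discarded = attr(evs, "n_discarded")))
}

#' Fit Gaussian components to a relative-current population
#'
#' Maximum-likelihood fit of a K-component Gaussian mixture (via
#' expectation-maximization as implemented in \pkg{mclust}, unequal
#' variances) to the relative-current values of an event population, as used
#' to summarize blockade populations from relative-current histograms.
#' Components are reported sorted by mean.
#'
#' @param values Numeric vector of relative currents (percent); at least 50.
#' @param K Number of components (1, 2 or 3).
#' @return An object of class `population_fit` with a `components` data
#'   frame (`weight`, `mean`, `sd`) and the model log-likelihood.
#' @examples
#' set.seed(1)
#' v <- c(rnorm(500, 9, 2), rnorm(500, 17.1, 2))
#' fit_population_gaussians(v, K = 2)
#' @export
fit_population_gaussians <- function(values, K) {
  stopifnot(is.numeric(values), K %in% 1:3)
  if (length(values) < 50L) {
    stop("need at least 50 values for a population fit, got ", length(values))
  }
  if (stats::sd(values) == 0) {
    if (K != 1L) stop("all values identical: only K = 1 is identifiable")
    comp <- data.frame(weight = 1, mean = values[1], sd = 0)
    return(structure(list(K = 1L, components = comp, loglik = NA_real_),
                     class = "population_fit"))
  }
  # Mclust() resolves mclustBIC in the caller's frame; alias it locally
  mclustBIC <- mclust::mclustBIC
  fit <- tryCatch(
    mclust::Mclust(values, G = K, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$parameters)) {
    stop("population Gaussian fit failed to converge (K = ", K,
         ", n = ", length(values), ", sd = ", signif(stats::sd(values), 3), ")")
  }
  p <- fit$parameters
  sds <- sqrt(if (length(p$variance$sigmasq) == 1L) {
    rep(p$variance$sigmasq, K)
  } else p$variance$sigmasq)
  comp <- data.frame(weight = p$pro, mean = as.numeric(p$mean), sd = sds)
  comp <- comp[order(comp$mean), , drop = FALSE]
  rownames(comp) <- NULL
  if (any(comp$weight < 0) || abs(sum(comp$weight) - 1) > 1e-6) {
    stop("population fit returned invalid component weights")
  }
  structure(list(K = as.integer(K), components = comp, loglik = fit$loglik),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("<population_fit> %d Gaussian component(s)\n", x$K))
  for (i in seq_len(nrow(x$components))) {
    cat(sprintf("  %.2f : %.2f +/- %.2f %%\n", x$components$weight[i],
                x$components$mean[i], x$components$sd[i]))
  }
  invisible(x)
}
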