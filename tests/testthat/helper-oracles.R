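# Independent reference implementations used to cross-check the package.
# These are deliberately naive (per-sample loops, no vectorization) and stay
# separate from the code paths they verify.

# Sample-by-sample threshold scan: returns data.frame of 0-based half-open
# event boundaries, interior events only.
oracle_threshold_scan <- function(samples, threshold) {
  starts <- integer(0); ends <- integer(0)
  in_event <- FALSE
  s <- 0L
  for (i in seq_along(samples)) {
    if (samples[i] < threshold) {
      if (!in_event) { in_event <- TRUE; s <- i }
    } else if (in_event) {
      in_event <- FALSE
      # i - 1 is the 1-based last sub-threshold sample, which is also the
      # 0-based half-open end of the run
      starts <- c(starts, s); ends <- c(ends, i - 1L)
    }
  }
  # run still open at the trace end, or starting at sample 1, is dropped
  keep <- starts > 1L
  data.frame(start_index = starts[keep] - 1L, end_index = ends[keep])
}

# Naive extrema finder mirroring the documented rule: plateau collapse,
# strict interior turning points, then smallest-first pruning of adjacent
# pairs below the prominence, with the lone-extremum rule against the ends.
oracle_extrema <- function(y, min_prominence = 0) {
  n <- length(y)
  if (n < 3) return(data.frame(index = integer(0), value = numeric(0)))
  idx <- integer(0); val <- numeric(0)
  i <- 1L
  u <- numeric(0); pos <- integer(0)
  while (i <= n) {                      # plateau collapse
    if (length(u) == 0 || y[i] != u[length(u)]) {
      u <- c(u, y[i]); pos <- c(pos, i)
    }
    i <- i + 1L
  }
  if (length(u) >= 3) {
    for (j in 2:(length(u) - 1L)) {
      if ((u[j] - u[j - 1]) * (u[j + 1] - u[j]) < 0) {
        idx <- c(idx, pos[j]); val <- c(val, u[j])
      }
    }
  }
  repeat {
    if (length(val) == 0) break
    if (length(val) == 1) {
      if (min(abs(val - y[1]), abs(val - y[n])) < min_prominence) {
        idx <- integer(0); val <- numeric(0)
      }
      break
    }
    dd <- abs(diff(val))
    j <- which.min(dd)
    if (dd[j] >= min_prominence) break
    idx <- idx[-c(j, j + 1L)]; val <- val[-c(j, j + 1L)]
  }
  data.frame(index = idx, value = val)
}

# Scalar, per-sample 3-part loss computation.
oracle_three_part_loss <- function(probs, a, y, eps = 1e-12) {
  n <- nrow(probs)
  l_cls <- l_ass <- l_rein <- numeric(n)
  for (i in seq_len(n)) {
    p_true <- max(probs[i, y[i]], eps)
    nll <- -log(p_true)
    v <- if (which.max(probs[i, ]) == y[i]) 1 else 0
    ai <- min(max(a[i], eps), 1 - eps)
    l_cls[i] <- nll
    l_ass[i] <- -(v * log(ai) + (1 - v) * log(1 - ai))
    l_rein[i] <- a[i] * nll
  }
  list(L_cls = mean(l_cls), L_assess = mean(l_ass),
       L_reinforce = mean(l_rein),
       L_total = mean(l_cls) + mean(l_ass) + mean(l_rein))
}

# Mann-Whitney AUROC of score for predicting a binary outcome.
oracle_auroc <- function(score, outcome) {
  r <- rank(score)
  n1 <- sum(outcome); n0 <- sum(!outcome)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  (sum(r[outcome]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Simulate, detect and label events for classifier tests: returns matched
# detected events with true class labels.
make_labeled_events <- function(config, signatures, class_mix = NULL) {
  sim <- if (is.null(class_mix)) simulate_trace(config, signatures)
  else simulate_trace(config, signatures, class_mix)
  det <- detect_events(sim$trace)
  m <- match_events(det$events, sim$events)
  keep <- !is.na(m$match)
  list(events = det$events[keep], labels = m$labels[keep],
       sim = sim, det = det, recall = m$recall)
}

# Two well-separated single-level classes (non-overlapping relative-current
# ranges ~5-10% vs ~25-35%); a threshold rule classifies them perfectly.
separable_signatures <- function() {
  list(A = class_signature("A", data.frame(rel_mean = 7.5, rel_sd = 0.8, frac = 1), 2.5),
       B = class_signature("B", data.frame(rel_mean = 30, rel_sd = 1.5, frac = 1), 2.5))
}
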