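# Synthetic current-trace simulator. Generates Gaussian open-pore baseline
# with Poisson blockade arrivals; each blockade carries one or two residual
# current levels and a log-normal dwell time, parameterized per peptide class.
# Ground-truth annotations are exact (sample indices, level boundaries, drawn
# level currents), so detection and classification can be scored without
# experimental recordings.

#' Define a peptide class signature
#'
#' A signature describes the blockade phenotype of one peptide class: its
#' residual-current levels (mean and SD of the relative current in percent of
#' the open-pore current, plus the fraction of the dwell spent in each level)
#' and its dwell-time distribution. Dwell times are log-normal — strictly
#' positive with a heavy right tail, as observed in nanopore dwell
#' histograms — parameterized so that `dwell_median_ms` is the distribution
#' median.
#'
#' @param name Class label.
#' @param levels Data frame with columns `rel_mean` (mean relative current,
#'   percent, in (0, 100)), `rel_sd` (between-event SD, percent) and `frac`
#'   (fraction of the dwell spent at this level; must sum to 1). One row per
#'   level, in temporal order.
#' @param dwell_median_ms Median dwell time (ms); must give a median in
#'   (0.05, 500) ms.
#' @param dwell_sdlog SD of log dwell (dimensionless spread of the log-normal).
#' @param level_source,dwell_source `"measured"` if the defaults come from
#'   reported single-channel statistics, `"placeholder"` otherwise.
#' @param notes Free text.
#' @return An object of class `class_signature`.
#' @export
class_signature <- function(name, levels, dwell_median_ms, dwell_sdlog = 0.4,
                            level_source = "measured",
                            dwell_source = "measured", notes = "") {
  stopifnot(is.data.frame(levels),
            all(c("rel_mean", "rel_sd", "frac") %in% names(levels)))
  if (any(levels$rel_mean <= 0 | levels$rel_mean >= 100)) {
    stop("level rel_mean must lie in (0, 100) percent")
  }
  if (abs(sum(levels$frac) - 1) > 1e-8) stop("level dwell fractions must sum to 1")
  if (dwell_median_ms <= 0.05 || dwell_median_ms >= 500) {
    stop("dwell median must lie in (0.05, 500) ms")
  }
  structure(list(name = name, levels = levels,
                 dwell_median_ms = dwell_median_ms, dwell_sdlog = dwell_sdlog,
                 level_source = level_source, dwell_source = dwell_source,
                 notes = notes),
            class = "class_signature")
}

#' @export
print.class_signature <- function(x, ...) {
  cat(sprintf("<class_signature> %s: %d level(s), dwell median %.2f ms [%s/%s]\n",
              x$name, nrow(x$levels), x$dwell_median_ms,
              x$level_source, x$dwell_source))
  for (i in seq_len(nrow(x$levels))) {
    cat(sprintf("  level %d: %.1f +/- %.1f %% for %.0f%% of dwell\n", i,
                x$levels$rel_mean[i], x$levels$rel_sd[i], 100 * x$levels$frac[i]))
  }
  invisible(x)
}

#' Default signatures for the alpha-synuclein C-terminal peptide panel
#'
#' Eight signatures covering the unmodified peptide (wt) and seven
#' phosphorylated (p) / nitrated (n) variants of the 124-140 fragment.
#' Measured defaults: wt is a two-level blockade with relative currents
#' 9.0 +/- 2.0 % and 17.1 +/- 2.0 %, and the triple-nitrated peptide has the
#' deepest blockade at 7.2 +/- 1.0 %. Fitted dwell medians: wt 2.58 ms,
#' pY125 0.55 ms, nY125 4.51 ms, pS129 3.62 ms, pY125pS129 0.45 ms,
#' nY125nY133nY136 5.18 ms, nY125pS129 4.51 ms.
#'
#' Relative-current levels are not reported for the single-PTM peptides
#' (only qualitatively "lower than wt"), so those entries are placeholders
#' flagged `level_source = "placeholder"` and should be overridden when
#' calibrating against a recording; the placeholders respect the reported
#' qualitative ordering (single PTMs below wt's lower level, nY136 two-level
#' like wt but less separated, nY125pS129 between nY125 and pS129).
#'
#' @return Named list of [class_signature()] objects.
#' @examples
#' sigs <- default_signatures()
#' sigs$wt
#' @export
default_signatures <- function() {
  lev <- function(m, s, f = 1) data.frame(rel_mean = m, rel_sd = s, frac = f)
  sigs <- list(
    wt = class_signature("wt",
      data.frame(rel_mean = c(9.0, 17.1), rel_sd = c(2.0, 2.0),
                 frac = c(0.5, 0.5)),
      dwell_median_ms = 2.58,
      notes = "two-level blockade, higher residual level last (PI then PII)"),
    pY125 = class_signature("pY125", lev(7.8, 1.5), 0.55,
      level_source = "placeholder",
      notes = "single level, lower relative current than wt"),
    nY125 = class_signature("nY125", lev(8.3, 1.5), 4.51,
      level_source = "placeholder",
      notes = "single level, lower relative current than wt"),
    pS129 = class_signature("pS129", lev(8.8, 1.5), 3.62,
      level_source = "placeholder"),
    nY136 = class_signature("nY136",
      data.frame(rel_mean = c(10.0, 14.5), rel_sd = c(2.0, 2.0),
                 frac = c(0.5, 0.5)),
      dwell_median_ms = 2.6,
      level_source = "placeholder", dwell_source = "placeholder",
      notes = "two-level like wt, less pronounced separation"),
    pY125pS129 = class_signature("pY125pS129", lev(7.5, 1.5), 0.45,
      level_source = "placeholder"),
    nY125nY133nY136 = class_signature("nY125nY133nY136", lev(7.2, 1.0), 5.18,
      notes = "deepest blockade of the panel"),
    nY125pS129 = class_signature("nY125pS129", lev(8.5, 1.5), 4.51,
      level_source = "placeholder", dwell_source = "placeholder",
      notes = "between nY125 and pS129; dwell comparable to nY125")
  )
  sigs
}

#' Simulation configuration
#'
#' Defaults mirror the recording conditions of the single-channel
#' measurements the simulator emulates: open-pore baseline 72 +/- 1.5 pA at
#' +100 mV in 1 M KCl, 10 kHz sampling. The capture rate is the Poisson
#' arrival rate of blockade events and plays the role of the analyte
#' concentration via the capture-rate law (see [fit_capture_rate()]).
#'
#' @param open_pore_pA Baseline mean current (pA).
#' @param open_pore_sd_pA Baseline noise SD (pA).
#' @param sampling_rate_Hz Sampling rate (Hz).
#' @param capture_rate_Hz Total event arrival rate (Hz).
#' @param duration_s Recording length (s).
#' @param within_event_sd_pA Within-event current noise SD (pA); defaults to
#'   the baseline SD.
#' @param low_pass_Hz Optional corner frequency of a first-order smoothing
#'   stage applied after event insertion; `NULL` (default) disables it so
#'   ground-truth boundaries stay exact.
#' @param min_gap_s Minimum baseline gap enforced between events (s).
#' @param seed Integer seed; fixed seed gives bit-reproducible output.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(open_pore_pA = 72, open_pore_sd_pA = 1.5,
                       sampling_rate_Hz = 10000, capture_rate_Hz = 5,
                       duration_s = 10, within_event_sd_pA = open_pore_sd_pA,
                       low_pass_Hz = NULL, min_gap_s = 1e-3, seed = NULL) {
  stopifnot(open_pore_pA > 0, open_pore_sd_pA >= 0, sampling_rate_Hz > 0,
            capture_rate_Hz >= 0, duration_s > 0, min_gap_s >= 0)
  structure(list(open_pore_pA = open_pore_pA, open_pore_sd_pA = open_pore_sd_pA,
                 sampling_rate_Hz = sampling_rate_Hz,
                 capture_rate_Hz = capture_rate_Hz, duration_s = duration_s,
                 within_event_sd_pA = within_event_sd_pA,
                 low_pass_Hz = low_pass_Hz, min_gap_s = min_gap_s, seed = seed),
            class = "sim_config")
}

#' Draw dwell times from a class signature
#'
#' Log-normal draws with median `dwell_median_ms` and log-SD `dwell_sdlog`.
#' Exposed so the dwell model can be checked at scale without building full
#' traces.
#'
#' @param signature A [class_signature()].
#' @param n Number of draws.
#' @return Numeric vector of dwell times (ms).
#' @export
r_dwell_ms <- function(signature, n) {
  stats::rlnorm(n, meanlog = log(signature$dwell_median_ms),
                sdlog = signature$dwell_sdlog)
}

#' Simulate a current trace with ground-truth annotations
#'
#' The baseline is Gaussian; event start times follow a Poisson process at
#' `capture_rate_Hz`; each event's class is drawn from `class_mix`; its dwell
#' is log-normal and its per-level relative current is drawn from the class
#' signature (between-event variation), with within-event Gaussian noise on
#' top. Overlapping arrivals (and arrivals violating the minimum gap or
#' touching the trace boundary) are rejected and redrawn so annotations stay
#' unambiguous.
#'
#' @param config A [sim_config()].
#' @param signatures Named list of [class_signature()]s.
#' @param class_mix Named numeric vector of class fractions summing to 1;
#'   default uniform over `signatures`.
#' @return A list of class `pore_simulation` with elements `trace`
#'   (a [current_trace()]), `events` (ground-truth data frame: class,
#'   0-based half-open sample indices, true dwell in ms) and `levels`
#'   (per-level boundaries and drawn relative currents).
#' @examples
#' sim <- simulate_trace(sim_config(duration_s = 2, seed = 1),
#'                       default_signatures()["wt"])
#' nrow(sim$events)
#' @export
simulate_trace <- function(config, signatures = default_signatures(),
                           class_mix = NULL) {
  stopifnot(inherits(config, "sim_config"), length(signatures) >= 1)
  if (is.null(names(signatures))) {
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  }
  if (is.null(class_mix)) {
    class_mix <- stats::setNames(rep(1 / length(signatures), length(signatures)),
                                 names(signatures))
  }
  unknown <- setdiff(names(class_mix), names(signatures))
  if (length(unknown)) stop("unknown class name(s): ", paste(unknown, collapse = ", "))
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-6) {
    stop("class_mix must be non-negative and sum to 1")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  rate <- config$sampling_rate_Hz
  n <- as.integer(round(config$duration_s * rate))
  gap0 <- max(1L, as.integer(round(config$min_gap_s * rate)))
  med_len <- vapply(signatures[names(class_mix)[class_mix > 0]],
                    function(s) s$dwell_median_ms / 1000 * rate, numeric(1))
  if (length(med_len) && any(med_len + 2 * gap0 >= n)) {
    stop("infeasible config: typical event longer than the trace")
  }
  samples <- stats::rnorm(n, config$open_pore_pA, config$open_pore_sd_pA)

  n_events <- stats::rpois(1, config$capture_rate_Hz * config$duration_s)
  classes <- if (n_events > 0) {
    sample(names(class_mix), n_events, replace = TRUE, prob = class_mix)
  } else character(0)

  gap <- max(1L, as.integer(round(config$min_gap_s * rate)))
  margin <- gap  # keep events away from the trace boundaries
  # occupied intervals, grown by the minimum gap
  occ_start <- integer(0); occ_end <- integer(0)

  ev <- list(); lv <- list()
  kept <- 0L
  for (k in seq_len(n_events)) {
    sig <- signatures[[classes[k]]]
    placed <- FALSE
    for (attempt in 1:100) {
      dwell_ms <- r_dwell_ms(sig, 1)
      len <- max(nrow(sig$levels), as.integer(round(dwell_ms / 1000 * rate)))
      if (len + 2L * margin >= n) break  # event longer than trace: unplaceable
      start <- sample.int(n - len - 2L * margin, 1) + margin  # 0-based start
      end <- start + len
      # reject overlap with existing events (gap-padded)
      if (length(occ_start)) {
        clash <- any(start < occ_end + gap & end + gap > occ_start)
        if (clash) next
      }
      placed <- TRUE
      break
    }
    if (!placed) next
    kept <- kept + 1L
    occ_start <- c(occ_start, start); occ_end <- c(occ_end, end)

    nl <- nrow(sig$levels)
    lens <- floor(sig$levels$frac * len)
    lens[nl] <- len - sum(lens[-nl])
    lens <- pmax(lens, 1L)
    if (sum(lens) != len) lens[nl] <- lens[nl] - (sum(lens) - len)
    rels <- stats::rnorm(nl, sig$levels$rel_mean, sig$levels$rel_sd)
    rels <- pmin(pmax(rels, 0.5), 99)
    off <- start
    for (l in seq_len(nl)) {
      idx <- (off + 1L):(off + lens[l])  # 1-based into samples
      samples[idx] <- stats::rnorm(lens[l], config$open_pore_pA * rels[l] / 100,
                                   config$within_event_sd_pA)
      lv[[length(lv) + 1L]] <- data.frame(
        event_id = kept, level = l, start_index = off, end_index = off + lens[l],
        rel_current_pct = rels[l])
      off <- off + lens[l]
    }
    ev[[kept]] <- data.frame(
      event_id = kept, class = sig$name, start_index = start, end_index = end,
      dwell_ms = len / rate * 1000, dwell_drawn_ms = dwell_ms,
      mean_rel_current_pct = sum(rels * lens) / len)
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(event_id = integer(0), class = character(0),
               start_index = integer(0), end_index = integer(0),
               dwell_ms = numeric(0), dwell_drawn_ms = numeric(0),
               mean_rel_current_pct = numeric(0))
  levels <- if (length(lv)) do.call(rbind, lv) else
    data.frame(event_id = integer(0), level = integer(0),
               start_index = integer(0), end_index = integer(0),
               rel_current_pct = numeric(0))
  ord <- order(events$start_index)
  events <- events[ord, , drop = FALSE]
  # renumber chronologically
  id_map <- stats::setNames(seq_len(nrow(events)), events$event_id)
  events$event_id <- seq_len(nrow(events))
  if (nrow(levels)) {
    levels$event_id <- as.integer(id_map[as.character(levels$event_id)])
    levels <- levels[order(levels$event_id, levels$level), , drop = FALSE]
  }
  rownames(events) <- NULL; rownames(levels) <- NULL

  if (!is.null(config$low_pass_Hz)) {
    a <- exp(-2 * pi * config$low_pass_Hz / rate)
    samples <- as.numeric(stats::filter(samples * (1 - a), a, method = "recursive",
                                        init = samples[1]))
  }

  trace <- current_trace(samples, rate,
                         metadata = list(simulated = "true",
                                         open_pore_pA = config$open_pore_pA,
                                         open_pore_sd_pA = config$open_pore_sd_pA))
  structure(list(trace = trace, events = events, levels = levels,
                 config = config),
            class = "pore_simulation")
}

#' @export
print.pore_simulation <- function(x, ...) {
  cat(sprintf("<pore_simulation> %.1f s @ %g Hz, %d events\n",
              x$config$duration_s, x$config$sampling_rate_Hz, nrow(x$events)))
  if (nrow(x$events)) print(table(x$events$class))
  invisible(x)
}

#' Simulate a mixture sample
#'
#' Convenience wrapper over [simulate_trace()] for mixture experiments:
#' event classes are drawn i.i.d. from `ratio` (e.g. `c(wt = 0.6,
#' pY125 = 0.4)` for a 3:2 mixture).
#'
#' @param config A [sim_config()].
#' @param signatures Named list of [class_signature()]s.
#' @param ratio Named positive fractions summing to 1.
#' @return A `pore_simulation` (see [simulate_trace()]).
#' @export
simulate_mixture <- function(config, signatures = default_signatures(), ratio) {
  if (is.null(names(ratio)) || any(!nzchar(names(ratio)))) {
    stop("ratio must be a named vector of class fractions")
  }
  if (any(ratio <= 0) || abs(sum(ratio) - 1) > 1e-6) {
    stop("ratio entries must be positive and sum to 1")
  }
  simulate_trace(config, signatures, class_mix = ratio)
}

#' Write / read ground-truth annotations as TSV
#'
#' @param truth A `pore_simulation` or a list with `events` and `levels`
#'   data frames.
#' @param path Base TSV path; level boundaries are written to
#'   `<path>` with the level table appended after a `#LEVELS` marker line.
#' @return `read_ground_truth` returns a list with `events` and `levels`.
#' @export
write_ground_truth <- function(truth, path) {
  con <- textConnection("out", "w", local = TRUE)
  utils::write.table(truth$events, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines("#LEVELS", con)
  utils::write.table(truth$levels, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "#LEVELS")
  if (length(sep) != 1L) stop("not a ground-truth file (missing #LEVELS): ", path)
  ev <- utils::read.delim(text = lines[seq_len(sep - 1L)],
                          stringsAsFactors = FALSE)
  lv <- utils::read.delim(text = lines[-seq_len(sep)], stringsAsFactors = FALSE)
  list(events = ev, levels = lv)
}

#' Match detected events to ground-truth annotations
#'
#' Greedy overlap matching: each detected event is assigned the annotated
#' event it overlaps (half-open sample intervals); annotations claimed by an
#' earlier detection are not reused. Used to score detection recall and to
#' transfer class labels onto detected events.
#'
#' @param events List of `blockade_event`s (detected).
#' @param truth Ground-truth `events` data frame from [simulate_trace()].
#' @return List with `match` (per detected event, the row index into `truth`
#'   or `NA`), `recall` (fraction of annotated events recovered), and
#'   `labels` (the matched class labels, `NA` where unmatched).
#' @export
match_events <- function(events, truth) {
  n <- length(events)
  match_idx <- rep(NA_integer_, n)
  used <- logical(nrow(truth))
  if (n && nrow(truth)) {
    d_start <- vapply(events, `[[`, numeric(1), "start_index")
    d_end <- vapply(events, `[[`, numeric(1), "end_index")
    pos <- findInterval(d_start, truth$start_index)
    for (i in seq_len(n)) {
      for (j in unique(pmax(c(pos[i], pos[i] + 1L), 1L))) {
        if (j <= nrow(truth) && !used[j] &&
            d_start[i] < truth$end_index[j] && d_end[i] > truth$start_index[j]) {
          match_idx[i] <- j
          used[j] <- TRUE
          break
        }
      }
    }
  }
  list(match = match_idx,
       recall = if (nrow(truth)) sum(used) / nrow(truth) else NA_real_,
       labels = ifelse(is.na(match_idx), NA_character_,
                       truth$class[match_idx]))
}
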