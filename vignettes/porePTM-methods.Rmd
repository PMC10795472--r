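---
title: "porePTM: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{porePTM: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

porePTM analyzes single-channel nanopore recordings of peptide
translocation, with the goal of telling apart post-translational
modifications (PTMs) — phosphorylation (p) and nitration (n) — of the
C-terminal fragment (residues 124–140) of alpha-synuclein, as sensed by an
engineered aerolysin pore. This vignette describes the models the package
implements, the assumptions behind them, and the design choices that were
genuinely open.

## The measurement model

A recording is a current time series sampled at a fixed rate (10 kHz by
default). The unobstructed pore conducts a stable *open-pore current*
$I_0$ with Gaussian noise of SD $\sigma_0$ (defaults 72 pA and 1.5 pA at
+100 mV in 1 M KCl). When a single peptide enters the pore it transiently
blocks the current: a *blockade event*. Each event is summarized by

* its **dwell time** (ms) — the residence time of the molecule;
* its **relative current** $100 \cdot I/I_0$ (%) — the mean residual
  current during the event as a fraction of the baseline; deeper blockade
  means a lower value;
* its **relative noise** $\sigma/\sigma_0$;
* its **local-extrema sequence** — the ordered turning points of the
  event's samples, each a (time within event, relative current) pair.

The unmodified (wt) peptide produces a characteristic two-level blockade:
a deeper level at $9.0 \pm 2.0\%$ followed by a shallower one at
$17.1 \pm 2.0\%$ relative current, with a fitted dwell of 2.58 ms. PTMs
shift these statistics — phosphorylation shortens dwell (pY125: 0.55 ms,
pY125pS129: 0.45 ms), nitration lengthens it (nY125: 4.51 ms,
nY125nY133nY136: 5.18 ms), and the triple-nitrated peptide blocks deepest
($7.2 \pm 1.0\%$). These are the signatures the classifier must resolve.

## The synthetic-data generator

No experimental recordings are distributed, so the simulator
(`simulate_trace()`) is the package's canonical data source. It emulates:

* a Gaussian open-pore baseline (mean `open_pore_pA`, SD
  `open_pore_sd_pA`);
* Poisson event arrivals at `capture_rate_Hz`, with overlapping or
  boundary-touching placements rejected and redrawn, and a minimum
  baseline gap (default 1 ms) between events so annotations stay
  unambiguous;
* per event, a class drawn from the configured mixture, a log-normal
  dwell, and one or two residual-current levels whose per-event values are
  drawn from the class signature (between-event spread) with Gaussian
  within-event noise on top.

Choices worth stating explicitly:

* **Dwell times are log-normal.** Dwell-time histograms of nanopore
  events are strictly positive with heavy right tails; the log-normal is
  the simplest family with both properties. The distribution is
  parameterized so that the published fitted dwell value is the
  **median**; the log-SD (default 0.4) sets a realistic spread and is a
  package choice, as no dispersion is reported.
* **Two-level events play the deeper level first** (the shallower
  residual level occupies the last fraction of the event), with a 50/50
  time split by default; both are configurable per signature.
* **Within-event noise defaults to $\sigma_0$.** No within-event noise
  figure is reported; using the baseline noise keeps the trace visually
  and statistically homogeneous.
* **Unreported level means are placeholders.** Only wt (9.0/17.1%) and
  the triple-nitrated peptide (7.2%) have published relative-current
  values. The other six signatures carry placeholder levels flagged
  `level_source = "placeholder"`, chosen to respect the published
  qualitative ordering (single PTMs below wt's deep level; nY136
  two-level like wt but less separated; nY125pS129 between nY125 and
  pS129). They are defaults to be overridden when calibrating against a
  real recording, not measurements.
* **The optional low-pass stage** is a first-order recursive smoother
  applied after event insertion; it is off by default so that ground-truth
  boundaries remain exact.

Passing tests on these data shows the pipeline recovers what the
generator put in; it does not certify performance on experimental
recordings, whose noise is neither white nor Gaussian (1/f components,
baseline drift, unresolved fast events at the filter corner are all
absent from the simulator).

## Event detection

`fit_open_pore()` histograms the trace with Freedman–Diaconis bins, takes
the local count maximum with the **highest current** (the open-pore mode,
never a blockade mode), estimates a first-pass width from the peak's
FWHM, and least-squares fits a Gaussian to the bins within three of those
widths. The FWHM-derived window matters: at $10^5$ samples the FD bin
width is ~0.09 pA, so a window of a fixed few bins would span a tiny
fraction of the peak and leave the width ill-conditioned against counting
noise. If the fit fails or wanders, sample moments within the window are
used instead (exact for quasi-discrete traces).

`extract_events()` applies the detection rule: an event is a maximal run
of samples below $I_0 - k\sigma_0$ with $k = 3$ by default. Indexing is
0-based and half-open; dwell counts sub-threshold samples only; events
touching the trace boundaries are discarded since their dwell is
unmeasurable. The implementation (run-length encoding) is tested for exact
equivalence against a naive per-sample scan.

`extract_local_extrema()` collapses plateaus, takes strict interior
turning points, then prunes adjacent extrema pairs smallest-first until
every adjacent pair differs by at least the prominence threshold (default
$1\sigma_0$ — pure baseline noise produces fluctuations of that order, so
smaller excursions are uninformative). The surviving sequence alternates
strictly between minima and maxima. Whether extrema should be computed on
raw or filtered samples, and with what prominence rule, is not pinned down
by the source analysis; both are exposed as configuration.

The standard event filters keep dwell in [0.2, 100] ms and relative
current in [0, 40]%, boundaries inclusive.

`fit_population_gaussians()` summarizes a relative-current population
with a K-component Gaussian mixture fitted by maximum likelihood
(expectation-maximization via **mclust**, unequal variances,
deterministic hierarchical initialization). A hand-rolled EM would add
nothing over this well-tested implementation; degenerate inputs (all
values identical) are handled before dispatch.

## The classifier and the assessment network

Each event is represented by its rescaled extrema sequence: times
multiplied by $f_t = 10^3$ and relative currents by $f_c = 10^{-2}$, so
both channels are of order one (the rescale factors are fixed constants,
stored with the model). Sequences longer than `max_len` (default 32) are
tail-truncated — the head is always kept, because the early extrema carry
the entry signature of the event — and flagged; events with no extrema get
a single sentinel pair $(0, \text{rel current})$ so every event remains
classifiable.

Two networks read each sequence:

* the **classifier**: an LSTM with state size 128 (no activation on the
  readout) whose final state feeds 6 fully connected hidden layers of
  width 256 with ReLU, ending in a softmax over the classes;
* the **assessment network**: a scaled-down reader — LSTM state 32, 3
  hidden layers of width 64 with tanh — ending in a single sigmoid that
  scores whether the classifier's call is correct.

Variable-length sequences are zero-padded per batch with a mask; masked
steps carry the recurrent state through unchanged, so the readout is the
state at each sequence's last valid element and predictions are invariant
to padding (tested).

Both networks train jointly on the **3-part loss**

$$L = \underbrace{\overline{-\log p_{y}}}_{L_\text{cls}}
    + \underbrace{\overline{\mathrm{BCE}(a, v)}}_{L_\text{assess}}
    + \underbrace{\overline{a \cdot (-\log p_{y})}}_{L_\text{reinforce}},$$

where $p_y$ is the predicted probability of the true class, $a$ the
assessment score, and $v \in \{0,1\}$ the *actual prediction validity* —
recomputed from the classifier's current argmax at every training step.
Whether the reinforcement term back-propagates through $a$ is an open
modeling choice; the default treats $a$ as a constant scale (the term
then reweights the classification gradient by the assessor's trust), with
`detach_assessment = FALSE` available as a documented switch.

The networks and their gradients are implemented directly in base R
(BLAS-backed matrix arithmetic) with an Adam optimizer; analytic
gradients are verified against finite differences in the test suite.
Training hyperparameters are package choices: Adam at learning rate
$10^{-3}$, batch 256, up to 50 epochs with early stopping (patience 10)
on the validation 3-part loss, everything seeded. Events split
chronologically — first 75% train, last 25% validate — because
single-channel recordings drift over time and a random split would leak
that drift across the boundary. Optional per-class weights on
$L_\text{cls}$ are off by default.

## Selection percentage and evaluation

`select_by_confidence()` keeps the $\lceil p/100 \cdot N \rceil$ events
with the highest assessment scores (stable ties by event order). The
threshold is an order statistic of the evaluation set itself, which is
what "translating" a confidence threshold into a selection percentage
means operationally. Accuracy-versus-selection curves, column-normalized
confusion matrices (columns = actual class, rows = assigned class,
columns summing to 100%), and mixture-assignment percentages are computed
by the evaluation module; mixture assignment reports percentages of *all*
events with an explicit unassigned bucket, so either convention (with or
without low-confidence exclusion) is expressible and totals always reach
100%. Mixture experiments use the holdout protocol: the model is trained
on pure-class recordings only. SEs come from independent
simulation+classification repeats (default 5).

## Quantification

Blockade frequency is $f_\text{sig} = N_\text{events}/T$ after the
standard filters. Calibration fits the capture-rate law
$f_\text{sig} = k_\text{on} [\text{analyte}]$ by least squares
**through the origin** (the law has no intercept; a free-intercept fit is
reported as a linearity diagnostic only). Event counting is Poisson, so
the frequency variance grows with concentration; `weights = 1/c` gives
the matching inverse-variance fit and makes the reported slope SE
trustworthy across a concentration range spanning orders of magnitude.
Concentration is estimated by inversion, $\hat c = f_\text{sig}/k_\text{on}$,
with first-order error propagation. No published value of $k_\text{on}$
exists for this system, so calibration always comes from user data or
simulation.

## Problem sizes used in the tests

The shipped test suite and the acceptance script run entirely on
simulated data at desk scale: traces of 2–820 s at 10 kHz and 5 Hz
capture rate (up to ~4,000 events per run), two-class training with
~2,000 events per class, the eight-class panel at ~250 events per class
over 12 epochs, and mixture evaluation over 5 independent simulated
recordings per design. These sizes were chosen so that every property
(oracle equivalence, ground-truth recovery, separable-class accuracy,
selection trade-off, mixture percentages, capture-rate recovery) is
measured with comfortable statistical margins while a full run of the
suite stays in the minutes range on a single CPU. They are two to three
orders of magnitude below the half-million-event experimental datasets
the protocols are modeled on, which is why the suite checks *mechanisms*
(does confidence selection increase accuracy?) rather than absolute
published accuracies.

## Known limitations

* The simulator's noise model is white and Gaussian; real recordings
  have colored noise, drift, and bandwidth-limited event edges.
* Placeholder signature levels are informed guesses; conclusions about
  specific peptide classes require calibrating signatures on real data.
* Multi-level step segmentation (CUSUM/HMM level finding) is out of
  scope: the classifier consumes extrema sequences, not fitted levels.
* Training on a single CPU limits practical dataset sizes; the
  architecture matches the published one, but at experimental scale
  (hundreds of thousands of events) a GPU framework would be the right
  tool.
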