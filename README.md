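# porePTM

Nanopore signal analysis for detecting peptide post-translational
modifications (PTMs).

Engineered aerolysin nanopores can distinguish phosphorylated and
nitrated variants of the alpha-synuclein C-terminal peptide
(residues 124–140) from the ionic-current blockades single molecules
produce while translocating the pore. porePTM implements the full
analysis chain for such recordings, for electrophysiologists and
single-molecule proteomics groups who need a tested, scriptable pipeline:

* **Event detection** — fit the open-pore baseline $(I_0, \sigma_0)$ by a
  Gaussian fit to the highest-current histogram peak, extract blockades as
  maximal runs below $I_0 - 3\sigma_0$, compute dwell time, relative
  current $100\,I/I_0$, relative noise $\sigma/\sigma_0$ and the
  local-extrema sequence of each event, and apply the standard filters
  (dwell 0.2–100 ms, relative current 0–40%).
* **Classification with a rejection option** — a jointly trained pair of
  networks: an LSTM (state 128) + 6×256 ReLU MLP softmax classifier over
  peptide classes, and a smaller LSTM (state 32) + 3×64 tanh MLP sigmoid
  *assessment network* that predicts whether each call is correct. Both
  optimize the 3-part loss
  $L = L_\text{cls} + L_\text{assess} + L_\text{reinforce}$
  (classification cross-entropy, assessment cross-entropy against the
  actual prediction validity, and the classification loss scaled by the
  assessment score). The assessment score converts a confidence threshold
  into a **selection percentage**, trading coverage for accuracy.
* **Evaluation** — chronological 75/25 train/validation splits,
  column-normalized confusion matrices, accuracy-vs-selection curves, and
  holdout mixture-assignment percentages.
* **Quantification** — blockade frequency and the capture-rate law
  $f_\text{sig} = k_\text{on}\,[\text{analyte}]$, fitted through the
  origin and inverted to estimate concentration.
* **Simulation** — a ground-truth trace generator parameterized by the
  measured per-peptide signatures (wt two-level blockade at
  9.0 ± 2.0% / 17.1 ± 2.0% relative current, class-specific log-normal
  dwell times, Gaussian baseline 72 ± 1.5 pA at 10 kHz), so every stage is
  testable without experimental data.

The neural networks, their backpropagation and the Adam optimizer are
implemented in base R on BLAS matrix arithmetic and verified against
finite-difference gradients in the test suite.

## Worked example

Simulate a wild-type / phospho-Y125 mixture recording, detect events,
train the joint classifier, and evaluate it:

```r
library(porePTM)

sigs <- default_signatures()[c("wt", "pY125")]
sim  <- simulate_trace(sim_config(duration_s = 820, capture_rate_Hz = 5,
                                  seed = 21),
                       sigs, class_mix = c(wt = 0.5, pY125 = 0.5))
det  <- detect_events(sim$trace)
det$opm
#> <open_pore_model> I0 = 71.999 pA, sigma0 = 1.500 pA (nls fit)

m    <- match_events(det$events, sim$events)   # ground-truth labels
keep <- !is.na(m$match)
seqs <- prepare_sequences(det$events[keep])
fit  <- pore_classifier(seqs, m$labels[keep],
                        classifier_config(epochs = 10, seed = 21))
fit
#> <pore_classifier> 2 classes: pY125, wt
#>   trained 10 epochs (best 9), 2956 train / 986 validation events
#>   final validation accuracy 0.984 (100% selection)
```

`I0` and `sigma0` are the fitted open-pore mean and noise (the simulator
was configured at 72 and 1.5 pA). The validation accuracy is computed on
the last-in-time 25% of events at 100% selection; lowering the selection
percentage (`select_by_confidence()`, `accuracy_vs_selection()`) keeps
only events the assessment network trusts and raises accuracy further.
Classifying five independently simulated 1:1 mixture recordings with this
model and tallying assignments:

```r
res <- assign_mixture(preds, selection_pct = 100)  # preds: 5 repeats
#>         class percent   se
#>         pY125    50.7 0.46
#>            wt    49.3 0.46
#>  (unassigned)     0.0 0.00
```

i.e. the holdout model recovers the equimolar design within half a
percent (SE over the 5 repeats).

A thin command-line front end covering the same pipeline
(`simulate`, `detect`, `train`, `classify`, `evaluate`, `quantify`,
`convert`, `inspect`) ships in `inst/cli/porePTM`.

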