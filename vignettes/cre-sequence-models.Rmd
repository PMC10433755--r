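---
title: "Modelling the sequence predictability of regulatory peaks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the sequence predictability of regulatory peaks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

Functional-genomics assays — STARR-seq and UMI-STARR-seq (episomal
enhancer-activity readouts), DNase-seq/ATAC-seq/FAIRE-seq (chromatin
accessibility), and histone ChIP-seq (H3K4me1, H3K4me3, H3K27ac) — all
produce peak calls that are routinely used as positive training data for
sequence models of cis-regulatory elements. But the assays measure
different things, and their peaks relate to the underlying active sequence
differently: accessibility and STARR peaks tend to center on it, while
modified-histone peaks often flank it. `cresignal` implements the pipeline
for quantifying that difference: how accurately can peaks from each assay
be told apart from matched genomic background using DNA sequence alone?

The pipeline is: summit-centered window extraction, exclusion-aware
control sampling, k-mer count featurization, an ensemble of
L2-regularized logistic regressions fit by SGD, chromosome-arm holdout
cross-validation scored by ROC AUC, cross-assay application of a trained
enhancer model, and the statistics used to compare model predictions with
dual-luciferase reporter measurements.

## The classifier

Each candidate region contributes a fixed-width window (default 501 bp)
centered on its peak summit, the single base of maximal signal recorded in
narrowPeak column 10. Windows are featurized as overlapping k-mer counts
for k = 6, 7, 8 on the forward strand; reverse complements are not
collapsed, and any window of the sequence containing a non-ACGT character
is skipped. The vocabulary is built from the training sequences only —
words first seen at prediction time are ignored — which matters under
chromosome holdout because the test arm cannot contribute features.

The model is an ensemble of 48 logistic regressions, each minimizing

$$\frac{1}{n}\sum_i \ell_{\text{log}}(y_i, \sigma(w^\top x_i + b)) +
\frac{\alpha}{2}\lVert w \rVert^2, \qquad \alpha = 0.01,$$

by stochastic gradient descent over raw counts (no scaling), intercept
unpenalized. Every member sees the full training set — no bootstrap
resampling of rows or features — so members differ only through the
random order in which SGD visits examples. The ensemble probability is
the arithmetic mean of member probabilities, and a region is called an
enhancer when that probability exceeds 0.5.

Cross-validation partitions sequences into five folds by chromosome arm
(2L, 2R, 3L, 3R, X). Controls inherit their source peak's arm, so folds
stay balanced and no training sequence ever shares an arm with a test
sequence. We report the AUC of the pooled out-of-fold predictions as the
headline number (pooling is the only aggregation that yields a single
ROC curve) with per-fold AUCs alongside.

### Numerical choices

The SGD learning rate follows an inverse-scaling schedule
$\eta_t = \eta_0 / (1 + \eta_0 \alpha t)$ with $\eta_0 = 0.02$, and
training stops early when the mean epoch loss fails to improve by 1e-3
for 5 consecutive epochs (all configurable; `max_epochs = 1000` is the
hard cap). The weight vector uses lazy scaling so the per-step L2 decay
is O(1). Member seeds are derived from the base seed by an integer hash
(`derive_seed`) to avoid correlated shuffling streams. ROC AUC is
computed by the Mann-Whitney rank identity with average ranks on ties.
Binary calls use a fixed 0.5 threshold.

Two width conventions appear in common descriptions of this design (501
vs 500 bp); a model's vocabulary is width-sensitive, so the package
standardizes on one configurable width, default 501, with the window
`[summit - 250, summit + 251)`, and cross-assay application reuses the
training width (enforced, with an error on mismatch). Windows that would
run past a chromosome end are dropped, not clipped, so every feature
vector has the same basis.

## Control regions

Each retained peak contributes one control region of exactly the window
width, placed on the same arm, excluded from coding sequence and from
*all* of the assay's peaks, and non-overlapping with other controls. The
placement distribution is uniform over the positions feasible at the time
of each draw (the same conditional law as rejection sampling, but drawn
directly from the free-gap structure, so placement fails only when no
feasible position exists). Same-arm placement keeps the chromosome folds
balanced; both it and the mutual-overlap ban are exposed as flags because
genome-shuffling tools differ in their defaults.

## What the simulator emulates — and what it does not

`simulate_genome` draws i.i.d. bases at a target GC content (default
0.42, near the *D. melanogaster* euchromatin) for five arms, default
500 kb each. That default is a packing decision: each assay needs one
non-overlapping 501-bp control per peak outside coding sequence and
peaks, and at 1,000 peaks per assay the sequential placement process
needs roughly 300 kb per arm before the free space jams; 500 kb leaves
comfortable headroom while keeping a full study run in minutes.

`plant_peaks` places mutually non-overlapping peaks (width a truncated
normal; the summit recorded at the midpoint) and, for a `signal_strength`
fraction of them, overwrites the reference with PWM-sampled instances of
transcription-factor-like motifs (GATA-, AP-1- and GAGA-like consensus
by default) centered at `summit + summit_offset_bp`. Substitution only —
coordinates never shift. A positive offset reproduces the geometry of
histone-mark peaks that flank rather than center on the active sequence:
with the offset beyond ±250 bp the planted signal lies wholly outside the
extraction window, and model accuracy should collapse to chance. Every
planted instance is recorded in a ledger, so tests can verify window
containment claims exactly rather than statistically.

The simulator does *not* emulate repeat structure, GC heterogeneity,
nucleosome positioning, or correlated motif grammar; a high AUC on
synthetic data therefore demonstrates that the pipeline recovers planted
signal under the stated geometry, not that real peaks are equally
predictable. Conversely the null configuration (`signal_strength = 0`)
is a true null — windows and controls are exchangeable draws from the
same base process — so AUC near 0.5 is a leakage check.

`simulate_luciferase` emulates a dual-reporter plate: per-replicate
firefly and renilla luminescence, a single negative-control fragment with
true relative activity 1, and a fixed `round(active_fraction *
n_fragments)` truly active fragments at a chosen fold activity.
Replicate noise is log-normal on the firefly/renilla ratio (ratios of
positive intensities; the parameterization is by coefficient of
variation). The number of active fragments is fixed rather than binomial
so that recovery runs estimate test power, not compounded sampling noise.

## Statistics

The reporter analysis normalizes each replicate's firefly signal by its
own renilla, expresses fragment ratios relative to the mean
negative-control ratio, and tests each fragment against 1 with a
one-sample t-test at the Bonferroni threshold α/m. The "active" call
additionally requires mean activity above 1 — the hypothesis of interest
is elevated activity, but the test itself is kept two-sided. Predicted
enhancer fractions are compared with luciferase hit counts by the exact
two-sided binomial test (minimum-likelihood convention). Mann-Whitney
comparisons use exact enumeration for combined samples of at most 12
without ties and the tie-/continuity-corrected normal approximation
otherwise. Accuracy-versus-geometry associations across assay datasets
use the Pearson product-moment test; on the published eight-dataset
table this reproduces the printed coverage (p < 0.001) and peak-count
(p = 0.2637) results, while the printed width p-value is not recoverable
from the rounded printed inputs and is not asserted anywhere in the
package.

One property of this normalization chain deserves emphasis. Because
every fragment on a plate is divided by the *same* estimated
negative-control mean, the 20 t-statistics share a common location shift
whose magnitude, relative to each test's standard error, is approximately
standard normal regardless of the replicate CV. Bonferroni correction
controls the tests' nominal error, but the shared reference correlates
and shifts them jointly: in the package's null simulations the realized
family-wise error is about 0.05 — roughly double what the same tests
achieve against an exactly known reference (≈0.015), and right at the
conventional bound rather than comfortably under it. This is a property
of normalizing by a measured control, not of the implementation; plates
with more negative-control replicates would shrink it.

## Problem sizes used in the checks

Signal-recovery runs use five 500-kb arms, 1,000 peaks of width
150 ± 40 bp, two planted motif instances per signal peak, and the full
48-member ensemble under five-fold arm holdout (2,000 sequences per
run). At these sizes a full recovery run takes about a minute on one
core. Expected behavior: pooled AUC above 0.95 at `signal_strength = 1`
with centered motifs, chance level (0.45–0.55) at zero signal, and a
drop of at least 0.15 when motifs sit 400 bp from the summit. Luciferase
checks use the published design point (20 fragments, 45% active, fold 4,
CV 0.15, 6 replicates), where the Bonferroni procedure should flag about
9 fragments, and 1,000 null plates for the family-wise error bound.

## Known limitations

- The interval engine holds everything in memory as `GRanges`; it is
  meant for genomes up to the hundreds of megabases, not for
  population-scale interval databases.
- Sequential uniform control placement can still fail at extreme
  densities (it errors rather than silently dropping peaks); give the
  genome more room or relax the overlap ban if that happens.
- The SGD ensemble is deliberately faithful to its reference
  configuration (log loss, L2 α = 0.01, per-epoch shuffling, 48
  members); it is not tuned for maximum accuracy, and no alternative
  classifiers are provided.
- Cross-assay reports use the full called peak interval for the overlap
  flag (a window-based alternative is available via `on_window`);
  denominators count only peaks whose windows fit on the chromosome.
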