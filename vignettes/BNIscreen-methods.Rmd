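---
title: "BNIscreen: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{BNIscreen: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

BNIscreen implements the two computational arms of a biological
nitrification inhibitor (BNI) screen: quantifying inhibition of
ammonia-oxidizing archaea (AOA) and bacteria (AOB) from nitrite time series,
and predicting inhibitory activity from molecular structure with a
graph-attention network. This vignette explains the models, the tunable
parameters, the synthetic generators used for validation, and the design
decisions taken where several defensible choices existed.

## The inhibition statistic (AOI%)

Ammonia oxidizers convert ammonia to nitrite, so the nitrite accumulation
rate of a batch culture is a direct activity readout (measured
colorimetrically via the Griess reaction; `absorbanceToNitrite()` converts
plate absorbances through a linear standard curve and reports the fit's
R-squared).

Ammonia oxidation inhibition is expressed relative to the solvent (DMSO)
control, after subtracting the nitrite level recorded immediately before
inhibitor addition from all later measurements. Writing
$\Delta N(t) = \bar N(t) - \bar N(t_{add}^-)$ for the replicate-mean
increment since the last pre-addition timepoint,

$$\mathrm{AOI}(t) = 100 \left(1 - \frac{\Delta N_{trt}(t)}{\Delta N_{ctl}(t)}\right).$$

Choices embedded in `computeAoi()`:

* **The exact algebra is a package decision.** "Percent inhibition relative
  to the control, baseline-subtracted" admits several formulas; the
  ratio-of-increments form above is the minimal one consistent with that
  description. It is isolated in a single function so it can be swapped.
* **No clipping.** A stimulated culture yields negative AOI; a treated
  culture whose nitrite declines after addition yields AOI above 100%. Both
  are reported as-is, since screens do observe both behaviors.
* **Undefined below a control floor.** When the control increment is below
  `epsilon` (default 1 uM) the ratio is numerically meaningless; those
  timepoints are flagged and excluded from summaries rather than reported.
* **Two summaries.** Endpoint AOI (the headline, matching the distinction
  between persistent and transient inhibition) and maximum AOI are both
  emitted.
* Replicate uncertainty propagates to the AOI scale by the delta method on
  the ratio of means; per-timepoint significance is a two-sided t-test of
  replicate-level increments, treated versus control.

Group comparisons follow the screen's standard battery: Kruskal-Wallis
across compounds per strain and dose, Dunn's post-hoc z-tests with
Bonferroni adjustment (implemented in-package on tie-corrected ranks),
a Wilcoxon rank-sum contrast of pooled AOA versus AOB values per dose, and
Shapiro-Wilk normality diagnostics alongside. `clusterHeatmap()` clusters
the compound-by-strain AOI matrix with Euclidean distances; complete linkage
is the default (the choice is configurable because the analysis tradition
does not fix it), missing cells are imputed as 0% inhibition with a flag,
and rows/columns are sorted by label before clustering so results do not
depend on input order. Dendrograms are serialized as Newick.

## The culture simulator

Because raw culture series are rarely published, `simulateCulture()`
generates them with known ground truth. The control accumulates nitrite
along a logistic curve toward a carrying concentration $K$ — the simplest
saturating form with an interpretable rate; its rate constant is
parameterized so the peak production rate equals `max_rate` (uM/h). From the
addition time $t_{add}$, the treated culture's instantaneous production rate
is multiplied by

$$1 - f \cdot 2^{-(t - t_{add})/\tau},$$

where $f$ is the planted inhibition fraction and $\tau$ the recovery
half-time; $\tau = \infty$ encodes persistent inhibition and finite $\tau$
the transient inhibition seen for recoverable compounds. Trajectories are
integrated with `deSolve` (the control has a closed form, used as an
independent oracle in the tests); replicates differ only by Gaussian
observation noise, truncated at zero nitrite.

Defaults describe a typical batch assay: baseline 5 uM, carrying capacity
500 uM, peak rate 5 uM/h, twice-daily sampling for ten days, addition at
48 h (early exponential phase), triplicates, 5 uM noise.

**What the recovery tests use and why.** The AOI statistic is a ratio of
increments, so it tracks the planted rate multiplier $1-f$ exactly only
where the control curve is locally linear. The recovery property is
therefore checked with addition at the logistic inflection (114 h under the
defaults) and a 12-h post-addition window, where the statistic recovers
$100f$ within two percentage points across $f \in \{0, .25, .5, .75, 1\}$.
With addition during early exponential growth the same pipeline still ranks
inhibition strengths correctly (AOI is monotone in $f$) but the absolute
AOI value is not $100f$ — an intrinsic property of increment-ratio
statistics, not an implementation artifact.

## Structure arm: labels, tautomers, splits

**Labeling.** Compounds with EC50 strictly below 20 mg/L are positive;
values at or exactly on the threshold are negative (a literal reading of
"below"). Right-censored records (">20") are negative when the bound is at
or above the threshold and are rejected as unlabelable when below it. No
EC50 estimation from raw dose-response data is attempted.

**Tautomer augmentation.** `enumerateTautomers()` implements nine named
transformation classes — keto-enol, imine-enamine, amide-imidic acid,
lactam-lactim, pyridine-pyridol, generic heteroatom proton transfer, nitro
protonation/deprotonation, thione-thiol, azole tautomerism — as explicit
graph rewrites on the kekulized heavy-atom skeleton. Eight classes are
specializations of one 1,3 proton-shift engine
(H-D-C=A becomes D=C-A-H, realized by flipping the two bond orders and
letting valence re-perception move the hydrogen); the nitro class adds an
aci-nitro shift and protonation/deprotonation rewrites that change hydrogen
count and net charge. The named classes fix *which* shifts exist but not
their precise patterns, so the patterns are frozen in a versioned rule set
(`bni-taut-1`): augmentation counts are reproducible only for a fixed rule
version. Products are re-canonicalized by the chemistry toolkit;
unsanitizable products are dropped non-fatally. Enumeration is one-step by
default (a `steps` argument enables k-step closure) — shallow enumeration
matches the roughly five-fold expansions typical of this kind of
augmentation — deterministic (members sorted canonically after the parent)
and capped at 32 members per compound, a cap that does not bind at realistic
densities. Tautomers inherit the parent's label: all forms of a compound are
assumed to share its inhibition potential, including the charge-shifted
nitro forms.

**Leakage-free splits.** The unit of split assignment is the tautomer group.
`makeGroupSplits()` shuffles groups under a seed and allocates them to
80/10/10 train/validation/test partitions with largest-remainder rounding
(realized sizes within one group of the target), independently for each of
five repeats. Stratification by label is available but off by default.
Cross-parent duplicate tautomers are resolved to the first parent with a
warning and recorded in the dataset manifest, since real libraries do
contain shared tautomers. One augmentation pass is shared by all repeats and
noted in the manifest.

## The classifier

`buildGatModel()` assembles, per molecule graph (atoms featurized by element
one-hot over ten common elements plus "other" — unknown elements degrade
gracefully — degree, formal charge, aromaticity and hydrogen count; bonds by
kekulized order, ring and conjugation flags):

1. a stack of graph-attention convolution layers (attention over incoming
   arcs with additive edge-feature terms, multi-head, ELU),
2. one multi-head self-attention layer over node embeddings with a residual
   connection (its attention matrices are what attribution reads),
3. a readout concatenating global max pooling and global mean pooling,
4. two fully connected layers ending in a single activity logit.

Training minimizes class-weighted binary cross-entropy (inverse-frequency
weights, toggleable) with full-batch Adam and early stopping on validation
loss; the best-validation parameters are restored. All randomness —
initialization, dropout masks — derives from one configuration seed, so
runs are exactly reproducible. Forward/backward passes are implemented
natively on block-diagonal graph batches, and every gradient is verified
against finite differences in the test suite.

Defaults (`gatConfig()`): 3 GAT layers, hidden width 64, 4 heads, dropout
0.2, learning rate 1e-3, at most 300 epochs, patience 30 — a conservative
configuration for small datasets. The planted-SAR benchmark uses the lighter
`benchmarkConfig()` (2 layers, width 32, learning rate 5e-3, at most 80
epochs, patience 12): the planted rule is strongly structured, convergence
is fast, and the smaller model keeps the full five-repeat, two-arm benchmark
in the minutes range. The decision threshold is fixed at 0.5.

**Pretraining hook.** `pretrainLogP()` trains the same trunk with a
regression head on an additive-fragment lipophilicity surrogate
(`makeLogPSurrogate()`: fixed per-atom contributions summed over the
molecule) and returns trunk weights; `gatConfig(pretrained_state = ...)`
fine-tunes from them with a freshly initialized classification head. The
surrogate is fully synthetic: it preserves the transfer-learning mechanism
without an external corpus, and no claim is made that it improves accuracy —
the benchmark task is learnable from scratch.

## Attribution

**Attention weights.** The self-attention layer's per-head matrices are
averaged over heads; the attention each atom receives is averaged over
querying atoms and normalized to sum to one. This correction (head
averaging + column aggregation + normalization) is one of several
defensible readings of "corrected attention weights" and is isolated in
`attentionAtomWeights()` so alternatives can be swapped.

**Shapley values.** Matched instances of a configurable substructure
vocabulary (`alertPatterns()`: beta-hydroxy acid, aryl amine C-NH-c, aryl
ether c-O-C, aryl hydroxyl c-OH, ortho acyl phenol O-c-c-C=O, plus common
decorations and the thiourea pharmacophore of the synthetic benchmark) are
the players of a cooperative game whose value is the model's probability
with absent players' atoms feature-masked. Masking zeroes node features
rather than deleting nodes, keeping graph topology fixed and avoiding
message-passing artifacts from disconnected fragments; atoms outside every
pattern (the scaffold) stay visible, defining the baseline. Exact
enumeration is used up to 12 players, Monte-Carlo permutation sampling
beyond (requiring at least 10 samples per player); efficiency — values sum
to the intact prediction minus the baseline — holds exactly for the
enumerated case and within tolerance for the sampled one. Overlapping
instances are allowed; a shared atom stays visible if any covering player is
present. `reportStructuralAlerts()` aggregates per-pattern values by their
mean over predicted positives — an aggregation decision, since no canonical
choice exists.

## The synthetic structure-activity benchmark

`generateSarDataset()` decorates ring scaffolds (benzene, cyclohexane,
pyridine, naphthalene, piperidine, furan) with substituents from a fixed
vocabulary (hydroxyl, methyl/ethyl, methoxy, carboxyl, acetyl, acetoxy,
amino, chloro, amide) and attaches a thiourea fragment — itself a classic
nitrification-inhibitor motif — to the positive half. Before label noise the
label equals the substructure-match indicator by construction (and is
verified against the matcher); labels are then flipped with probability 5%,
and EC50 values of 5 mg/L (positives) and 100 mg/L (negatives) are assigned
from the final labels so the threshold labeler is exercised end to end,
mirroring a two-dose (5 and 20 mg/L) screen design. Compounds are kept
pairwise distinct.

The benchmark (`runSarBenchmark()`) uses 300 compounds, 5% label noise and
five split repeats. What passing it shows: the full pipeline — generation,
canonicalization, featurization, group splits, training, evaluation,
attribution — recovers a planted structure-activity rule from noisy labels
at above 0.85 held-out accuracy, does not degrade under tautomer
augmentation, collapses to majority-class performance when labels are
shuffled (the anti-leakage control), and re-identifies the planted motif in
its attribution rankings. What it does not show: performance on real
inhibition data, whose labels are far noisier, whose actives are rarer and
whose mechanisms are not single-substructure rules. The synthetic task is a
correctness instrument, not a performance claim.

## Numerical choices and degenerate inputs

* Attention softmaxes subtract a shared maximum before exponentiation;
  grouped softmax denominators carry a 1e-12 guard.
* Self-loops with zero edge features are added to every node so attention
  is defined for isolated atoms; a single-atom molecule is a valid graph
  (methane gives a finite logit).
* Max pooling breaks ties by first index; clustering sorts labels before
  computing distances; tautomer members are ordered canonically — all
  tie-breaks are deterministic.
* Early stopping requires a 1e-6 validation-loss improvement; non-finite
  losses abort with a diagnostic rather than continuing.
* Invalid SMILES fail with an error naming the offending input at parse
  time, in both the readers and the generators.

## Known limitations

* The chemistry layer inherits OpenBabel's aromaticity and valence models;
  exotic tautomer chemistry (e.g. ring-chain tautomerism) is out of scope,
  as are 3-D conformers, pKa prediction and canonical-tautomer scoring.
* The simulator does not model strain physiology (pH optima, growth lags)
  or dose-response curves; EC50s are assigned, not fitted.
* The classifier is a single-task model; AOA and AOB datasets are meant to
  be trained separately.
* Attention saliency is a heuristic; only the Shapley values carry an
  axiomatic interpretation, and they are relative to the chosen pattern
  vocabulary and masking semantics.
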