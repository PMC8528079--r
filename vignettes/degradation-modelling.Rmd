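---
title: "Modelling per-nucleotide RNA degradation with degkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling per-nucleotide RNA degradation with degkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degkit)
```

## The problem

Unformulated mRNA molecules fall apart by in-line hydrolysis: the 2'-OH of
each ribose can attack its own backbone phosphate, cleaving the chain at
that dinucleotide linkage. The reaction is strongly accelerated at
nucleotides that are *not* base-paired, which makes degradation a
sequence-and-structure prediction problem: given an RNA sequence and its
secondary structure, how fast does each linkage cleave, and hence how long
does the whole molecule survive?

degkit implements the computational core of that workflow: per-nucleotide
degradation models trained on chemical-probing profiles, the evaluation
metrics used to benchmark such models, the curation procedures that make
benchmark test sets honestly blind, whole-molecule half-life prediction,
and model ensembling. A seeded synthetic generator with a planted
ground-truth model makes every stage testable without any experimental
download.

## The windowed linear degradation model

The core model predicts the degradation of nucleotide $k$ as a linear
function of the one-hot identities of the nucleotides around it:

$$
Y_k \;=\; \sum_{i=k-w}^{k+w}\;\sum_{n \in \{A,C,G,U\}} \beta_{i,n}\, I_{i,n}
\;+\; \sum_{i=k-w}^{k+w}\;\sum_{s \in \{H,E,I,M,B,S\}} \beta_{i,s}\, I_{i,s}
\;+\; \beta_0 ,
$$

where $I_{i,n}$ indicates the nucleotide identity at offset $i$ and
$I_{i,s}$ its loop-type class: stem (S), hairpin (H), internal loop (I),
bulge (B), multiloop (M), or external loop (E). With the default window
half-width $w = 12$ — 25 positions, 10 indicator channels each — the model
has $10(2w+1) + 1 = 251$ parameters (`n_parameters(12)`).

Modelling choices worth spelling out:

* **Padding.** Offsets that fall outside the molecule contribute all-zero
  indicator blocks. No padding channel is added by default (a dedicated
  padding channel is a documented alternative, switchable by extending the
  featurizer), so edge positions simply see fewer active features.
* **Dangle merging.** Loop-type annotation distinguishes terminal dangles
  (X) from external loops (E), but featurization merges X into E, keeping
  the six loop channels of the parameter accounting. The merge lives in
  `featurize()`, not in the annotator, so the annotation itself stays
  seven-class.
* **Regularization.** `fit_degscore()` solves ridge-penalized least
  squares in closed form with the intercept unpenalized, default
  $\lambda = 0.15$. The one-hot design is exactly collinear (channel
  indicators sum to one per in-range offset), so *coefficients* are not
  identifiable at $\lambda \to 0$ even though *predictions* are; the ridge
  penalty picks the minimum-norm representative and keeps the solve well
  conditioned. $\lambda = 0.15$ is small relative to the tens of thousands
  of pooled training rows, so shrinkage bias on predictions is negligible;
  it matters only for interpreting individual coefficients.
* **One model per data type.** Degradation conditions (e.g. Mg²⁺/pH 10 vs
  Mg²⁺/50 °C) are modelled independently; `target` is mandatory and never
  defaulted. Multi-target weight sharing is a plausible extension but not
  a default.
* **Boosted variant.** `fit_degscore_xgb()` trains gradient-boosted trees
  on the *identical* featurization. Defaults (400 rounds, depth 6,
  learning rate 0.3, single thread, seeded) give the trees enough
  capacity to match or surpass the linear training fit on datasets of a
  few hundred constructs; trees approximate a dense linear signal slowly,
  so starving them of rounds would misrepresent the comparison.

## Structure features

`parse_dotbracket()` builds a pair table from nested dot-bracket strings.
Pseudoknot brackets are rejected explicitly rather than silently broken:
the intended inputs are MFE structures, which are nested by construction.
Lone pairs are permitted and annotated S.

`assign_loop_types()` classifies unpaired positions by their enclosing
loop: hairpin; internal loop (unpaired on both strands between two
helices) vs bulge (one strand); multiloop when the loop has at least three
participating helices (the closing pair plus two or more children) —
loops with exactly two helices and unpaired nucleotides on both strands
are internal loops, a boundary the seven-letter alphabet leaves open and
which we resolve by branch count. At the top level, terminal unpaired
runs flanking at least one helix are dangles (X) and runs between helices
are external (E); a fully unpaired molecule is all E, since there is no
stem for a dangle to flank.

`extract_motifs()` produces the complete loop decomposition (stems,
hairpins with loop size, internal loops with strand lengths and a
symmetry flag, bulges, multiloops, exterior), and its position sets
partition the molecule — the invariant behind per-motif signal
aggregation. `graph_distance_matrix()` computes shortest paths over
backbone plus base-pair edges, the distance embedding commonly fed to
structure-aware models.

Coordinates are 1-based inside the package, following R convention. The
two external formats that are 0-based stay 0-based: BED-like window files
(half-open, as in BED) and sparse base-pair-probability triplets;
readers convert at the boundary.

## Evaluation

`mcrmse()` implements the multi-target benchmark metric: per data type,
the RMSE over all scored nucleotides pooled across constructs, then the
unweighted mean over data types. Pooling (a single $n$ per column) is the
default; per-construct averaging is available via `per_construct = TRUE`
since the convention is ambiguous in general.

`fraction_within_error()` counts predictions closer to the measurement
than the measurement's own uncertainty, with a *strict* inequality
$|\hat y - y| < \sigma$: under Gaussian errors a perfect predictor of the
truth scores the 1-sigma mass, about 68.3%, which is the natural ceiling
for the statistic, and strictness makes the degenerate $\sigma = 0$ case
score zero rather than rewarding exact ties. `sn_ratio()` is the
two-level mean of value over error used to filter constructs.
Non-finite measurements are mask-excluded from every metric, mirroring
the fact that labels exist only on the scored 5' prefix.

## Dataset curation

`apply_sn_filter()` annotates (never deletes) records with the three
criteria: profile minimum above `min_value`, maximum below `max_value`,
and SHAPE signal-to-noise above 1. The profile-minimum default is 0.5 as
the curation rule is conventionally stated; because a minimum of
−0.5 is an equally plausible reading (background-subtracted profiles
routinely dip slightly below zero), the threshold is an explicit
argument rather than a constant.

`cluster_split()` builds blind splits: Ward-linkage hierarchical
clustering on the pairwise sequence-distance matrix, flat clusters at a
cophenetic height of 0.5, every cluster of ≤ 3 members sent wholly to the
private test set, optional top-up by single seeded-random members of
randomly-chosen larger clusters, and the remainder assigned to public
test or training *at cluster granularity*. Ward linkage formally assumes
Euclidean inputs; applying it directly to sequence distances reproduces
the established curation practice, so fidelity wins over formality here
(we use `hclust(method = "ward.D2")`, the squared-update Ward variant
matching scipy's `ward`). Records are sorted by id before clustering, so
the assignment is invariant to input order and deterministic given the
seed.

Sequence distance is normalized Hamming for equal lengths and
$1 - \text{matches}/\max(\text{lengths})$ from a global alignment
(match 1, mismatch 0, gap open 0, gap extend 1) otherwise; the metric
underlying "50% similarity" curation is not standardized, and Hamming is
the least-assumption default for libraries of near-identical variants.

## Whole-mRNA half-life

The whole-molecule degradation rate is the sum of per-linkage rates,
$k_{\mathrm{deg}}^{\mathrm{mRNA}} = \sum_i k_{\mathrm{deg},i}$, and the
half-life is $t_{1/2} = \ln 2 / k_{\mathrm{deg}}^{\mathrm{mRNA}}$.
`total_rate()` sums model predictions over a probed window — the region
an RT-PCR readout actually covers — supplied per construct in a BED-like
file. Predictions should be made on the *full* molecule and then summed
over the window: untranslated regions pair with the coding sequence, so
predicting on an excised window alone gives a different (and wrong)
answer; a test fixes this behaviour with a construct whose 5' UTR pairs
into its CDS. `length_normalized_rate()` divides by the *window* length
by default (full-molecule length would be the alternative reading;
window length is what the summation actually covers).

Model outputs are treated as relative rates: comparisons use Spearman
rank correlation (`compare_predictors()`), so no calibration to absolute
s⁻¹ units is attempted. The same function estimates an experimental
noise ceiling by resampling measured rates within their standard errors
and correlating back against the means.

## Ensembling

`ga_ensemble()` jointly selects at most `max_members` member predictors
and their blend weights by a genetic algorithm minimizing MCRMSE on the
optimization split. The chromosome is a membership bitmask plus raw
weight genes mapped through a softmax (so weights are automatically
nonnegative and normalized); defaults are population 64, 200
generations, mutation rate 0.05, uniform crossover, tournament
selection, elitism of 2. No published hyperparameters exist for this
step, so these are ordinary GA middle-of-the-road settings, fixed once.
The best single member is seeded into the initial population, so with
elitism the returned ensemble provably never scores worse on the
optimized split than the best member. Joint selection-and-weighting is
implemented (rather than select-then-fit) because the two interact;
overfitting the optimization split is possible and expected — held-out
scores from `score_ensemble()` may be worse, which is the honest
behaviour of leaderboard-style ensembling.

## The synthetic generator

`synthetic_dataset()` emulates the structure of community benchmark
datasets: uniform lengths 102–130 nt; generative nested structures
(randomized helices of 2–8 stacked pairs closed by Watson–Crick or GU
pairs, hairpins of 3–8 nt, bulges and internal loops of 1–3 nt,
occasional multiloops and two-helix exteriors, terminal dangles);
labels only on a scored 5' prefix of ⌈0.64·length⌉ nucleotides
(mimicking 68 scored of 107); per-nucleotide Gaussian noise with sigma
drawn as `noise_sd × Uniform(0.5, 1.5)` around a planted windowed linear
model per data type (intercept 2, coefficient scale 0.05 — profiles of
order 2 with structure-driven variation of order a few tenths, inside
the curation bounds); and a planted fraction (default 10%) of
signal/noise failures implemented by 25-fold sigma inflation.

Structures are built generatively, not by thermodynamic folding, which
keeps the package engine-free; when real MFE structures and base-pair
probabilities are available they are simply supplied as inputs. The
generator therefore does *not* emulate: thermodynamically consistent
ensembles, sequence-dependent structure (the sequence is drawn to match
the structure, not vice versa), correlated errors along the molecule,
attenuation or ligation biases of sequencing readouts, or the designed
sequence families of human-curated libraries (tests that need cluster
structure build variant families explicitly). Passing tests on synthetic
data demonstrate algorithmic correctness — recovery of a planted model,
metric identities, split contracts — not biological accuracy on real
degradation data.

## Problem sizes and numerical checks

The test suite runs entirely on synthetic data: planted-model recovery
uses 500 constructs at noise 0.05 (recovered MCRMSE against noise-free
planted labels is well under 0.01, asserted ≤ 0.02); the within-error
ceiling uses 10⁵ simulated nucleotides; the genetic algorithm is checked
on 10 members over 600 pooled values; graph distances are verified
exhaustively against a breadth-first-search oracle on every nested
structure up to length 12, and the ridge solver against an iterative
optimizer. `scripts/acceptance.R` re-runs the same pipeline end to end
from a single seed and writes the headline numbers as JSON.

## Limitations

* Only nested secondary structures are supported; pseudoknotted inputs
  are rejected rather than approximated.
* The linear model's coefficients are interpretable only up to the
  one-hot collinearity discussed above; compare models on predictions,
  not raw coefficients.
* Boosted models serialize through xgboost's own format, not the
  package's JSON schema.
* RDAT chemical-mapping archives are not parsed; the JSON-lines dialect,
  FASTA, and text matrices are the supported interchange formats.
* Real benchmark leaderboard scores are not reproducible offline — they
  require the original experimental datasets and trained neural-network
  weights; this package reproduces the *procedures*, and its synthetic
  pipeline quantifies them under controlled conditions.
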