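---
title: "Classifying co-occurring reaction types from 1H NMR difference spectra"
author: "ReactionSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying co-occurring reaction types from 1H NMR difference spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ReactionSpectra)
```

## The problem

When two chemical reactions run simultaneously in one vessel, the 1H NMR
spectrum of the mixture changes in ways that superimpose the fingerprints of
both transformations.  `ReactionSpectra` asks whether the *types* of the two
co-occurring reactions can be recognized automatically from nothing but the
difference between the spectra recorded after and before the reactions — no
structure elucidation, no peak assignment.

The unit of information is the **reaction spectrum**: each compound's stick
spectrum (chemical shift, proton count pairs) is fuzzified with triangular
functions, binned on a fixed ppm grid, and the pooled reactant spectrum is
subtracted from the product spectrum.  For a mixture of two reactions the
two reaction spectra are summed, because the difference operator is linear
in the species present.

## The descriptor

For a peak at shift $\delta$ integrating to $h$ protons, fuzzification
replaces the stick with an isoceles triangle centred at $\delta$ with
support $[\delta - w, \delta + w]$ and **area** $h$ (apex height $h/w$).
The default half width is $w = 0.1$ ppm, a tolerance matched to the typical
error of empirical shift prediction; the parameter is exposed because the
appropriate tolerance depends on where the shift lists come from.  Area
(rather than apex) normalization is the convention used throughout because
it makes binning conserve the integral: summing all 120 bins of a compound's
binned spectrum returns its proton count exactly.

Binning integrates the piecewise-linear spectrum analytically over
half-open intervals $[k w_b, (k+1) w_b)$ with $w_b = 0.1$ ppm over 0–12 ppm,
giving 120 variables.  The integration is exact (piecewise polynomial), not
sampled; a fine-grid quadrature oracle exists only in the test suite.  A peak
sitting exactly on a bin edge needs no assignment rule — its two half-areas
split by integration.  Mass outside 0–12 ppm is dropped with a warning and
reported through `clippedMass()`; shifts that far out do not occur for
protons bonded to carbon.

The reaction spectrum at conversion $y$ is

$$ \mathbf{r} = y \left[ \mathrm{bin}(\mathrm{product}) -
   \mathrm{bin}(\mathrm{reactants}) \right], $$

because the unreacted fraction of the reactants is present both before and
after the reaction and cancels in the difference.  Two consequences are used
as tests: the descriptor is exactly linear in $y$, and if hydrogens are
conserved the descriptor sums to zero at every yield.  Multiple reactants
are pooled by concatenating shift lists at their stated proton counts; no
stoichiometric weighting is applied (1:1 stoichiometry).

A two-reaction mixture with reaction spectra $A$ and $B$ is encoded as

$$ \mathrm{MIXTURE} = \mathrm{NORM} \cdot (\mathrm{RATIO} \cdot A + B), $$

where RATIO is the molar ratio of the first reaction relative to the second
and NORM a global integration-normalization factor.  The default is
RATIO = NORM = 1 and full conversion.  RATIO applies to the first-listed
reaction of the pair, which is always the one whose type comes earlier in
the registry, so perturbation experiments are reproducible.

## Mixture classes and partitions

Six reaction types give $\binom{6}{2} = 15$ unordered cross-type pairs,
labelled A–O lexicographically over the type registry.  `enumerateMixtures()`
produces exactly one mixture per unordered cross-type reaction pair, so the
total is $\sum_{i<j} n_i n_j$.

Two train/test splits of different difficulty are provided:

* **mixture-level** (`partitionMixtures()`): the mixtures are split at
  random.  The same reaction usually appears on both sides, combined with
  different partners — an easier, partially leaky setting.
* **reaction-level** (`partitionReactions()`): the *reactions* are split,
  with per-type counts, and mixtures are enumerated within each side.  No
  reaction is shared, so the test set probes generalization to genuinely
  unseen reactions.

## Classifiers

**Toroidal Kohonen SOM** (`trainSOM()`).  A `rows x cols` grid on a torus
(every neuron has 8 neighbours; the topological metric is the toroidal
Chebyshev distance).  Weights initialize from per-variable
Normal(mean, sd) of the training data.  For epoch $t$ of $T$, the learning
rate is $\eta_0 (1 - t/T)$ and the neighbourhood span
$\mathrm{round}(s_0 (1 - t/T))$; every neuron at distance $d \le s$ of the
winner updates by the triangular factor $\eta (1 - d/(s+1))$, a form chosen
so the farthest included neuron still moves.  Defaults: $\eta_0 = 0.1$,
75 cycles (midpoint of the customary 50–100), $s_0$ = half the smaller grid
dimension.  The schedule decays per epoch, with the presentation order
reshuffled every epoch; training is bitwise deterministic under a seed.
After training, neurons are labelled by the classes of the training
mixtures that activate them: single-class neurons carry that class,
multi-class neurons are *conflicts* (their plurality class is retained for
classification; an exact tie is undecided), and empty neurons borrow the
label of the nearest labelled neuron — a fallback chosen so that test
objects are not discarded, with ties broken toward the smaller row-major
index.  Ensembles of independently trained maps vote by plurality,
excluding undecided votes; vote ties are undecided.

**Counter-propagation network** (`trainCPNN()`).  The same Kohonen input
layer plus an output layer holding one value per reaction type.  Winners
are found from the input layer alone; the output weights of the winner's
neighbourhood move toward the object's binary type-target vector (ones at
the two types present) with the same kernel and schedule — the standard
counter-propagation scheme.  Output weights start at the uninformative
midpoint 0.5 and remain in $[0,1]$ because every update is convex.  A
mixture class is predicted only when *exactly two* output values are
strictly above the 0.5 threshold; otherwise the object is undecided.
Values equal to the threshold do not count as above it.

**Random forest** (`trainRF()`).  1000 unpruned trees by default (the
benchmark below uses 300), $\lfloor\sqrt{p}\rfloor$ variables per split,
delegated to the `randomForest` package.  The vote fraction of the
winning class is attached to every prediction as a reliability measure;
vote ties are broken deterministically in class-registry order and flagged.
OOB accuracy is computed from the OOB vote matrix with the same tie rule.
The classification target is the 15-way mixture class, not two independent
6-way type calls.  `yRandomize()` retrains on label-scrambled data and
`reliabilityTable()` stratifies accuracy by vote probability.

## The synthetic generator

The original benchmark data (181 photocycloadditions with predicted
shifts) are proprietary, so `generateReactions()` emulates their
statistical structure.  Each of six templates mirrors the chemistry of a
photocycloaddition family through a hydrogen-conserving *signature*:
olefinic/aromatic protons disappear from a type-characteristic region and
reappear as saturated ring protons elsewhere (e.g. the [2+2] C=C + C=C
family loses olefinic H at 5.3–6.3 ppm and gains cyclobutane H at
2.2–3.0 ppm).  Signature positions are re-sampled inside their regions for
every reaction, giving intra-type variability.  Each reaction also carries
3–10 *spectator* peaks (uniform over 0.5–9.5 ppm, 1–3 protons each) that
drift by Normal(0, 0.15 ppm) between reactant and product, leaving small
non-cancelling residuals of the same scale as empirical shift-prediction
error.  Per-type counts default to 20/31/20/73/10/27 (181 reactions).

What the generator does *not* emulate: multiplet structure and coupling,
correlated shift errors within a molecule, solvent/concentration effects,
and the real (unknown) within-type descriptor variance of curated reaction
databases.  Passing benchmarks on synthetic data therefore demonstrate that
the pipeline recovers the designed signal structure under realistic noise,
not performance on any particular experimental dataset.

## Benchmark conditions and what they show

The package's acceptance benchmark (see `scripts/acceptance.R` and the
test suite) runs the full pipeline on the default dataset: 12421 mixtures;
a 8280/4141 mixture-level split; a reaction-level split with per-type
training counts 16/23/16/56/8/21; a 300-tree forest; a 25×25 SOM ensemble
of five, 50 cycles, trained on a 2000-mixture subsample (which keeps at
least two objects per neuron); five 100-tree y-randomization retrains.
These sizes are the package's CI-scale choices; the classifiers accept the
full-scale settings (49×49 maps, 1000 trees) unchanged.

The benchmark asserts *qualitative orderings*, not the irreproducible
accuracies of any external dataset: the supervised forest outperforms the
unsupervised map ensemble; unseen-reaction (reaction-level) accuracy falls
below mixture-level accuracy; label scrambling collapses accuracy to near
the no-information rate; accuracy rises monotonically with the vote
probability threshold; and accuracy degrades monotonically as conversion
drops (90 → 70%) and as the molar ratio grows (1 → 5).

## Numerical choices and degenerate inputs

* Exact winner ties in a SOM go to the smallest row-major neuron index —
  the same rule in the C++ training kernel and the R classification path.
* Zero-variance input variables initialize their weight components to the
  constant column value (sd 0 is allowed).
* `lr0 = 0` leaves SOM weights at their initialization and CPNN output
  weights at 0.5 — useful for inspecting initializations.
* An empty `ShiftList` is valid (zero spectrum); an empty *product*
  spectrum is not a valid reaction.
* Raising the CPNN threshold never changes a decided class to a different
  class: the set of outputs above a higher threshold is a subset of those
  above a lower one, so a decision can only be kept or withdrawn.  (A
  decision *can* appear on raising the threshold when more than two
  outputs exceeded the lower one — the rule is not monotone in that
  direction, which is inherent to the exactly-two condition.)
* All stochastic steps (generator, initializations, shuffles, bootstrap,
  scrambles) flow through R's RNG and accept explicit seeds; sub-seeds for
  ensembles and repeats are drawn reproducibly from the master seed.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
rs <- generateReactions(counts = c(6, 6, 6, 6, 6, 6), seed = 7)
ms <- enumerateMixtures(rs)        # 15 classes x 36 = 540 mixtures
p  <- partitionMixtures(ms, trainSize = 360, seed = 8)

rf <- trainRF(descriptors(p$train), mixtureClasses(p$train),
              nTrees = 300, seed = 9)
pred <- rfPredict(rf, descriptors(p$test))
mixtureAccuracy(pred$predicted, mixtureClasses(p$test))

reliabilityTable(pred, mixtureClasses(p$test))
runBattery(rf, p$test, seed = 10)
```

## Known limitations

* The approach is blind to reactions whose centres carry no C–H protons;
  such types are encoded only through secondary shift perturbations.
* The mixture model assumes exactly two co-occurring reactions of distinct
  types; same-type pairs and higher-order mixtures are out of scope.
* SOM/CPNN performance depends strongly on map size, cycles and training
  subsample; the defaults favour reproducibility and runtime over peak
  accuracy.
* The synthetic benchmark bounds what can be claimed about experimental
  data (see above).
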