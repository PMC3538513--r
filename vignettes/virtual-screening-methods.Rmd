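---
title: "Descriptor-space virtual screening: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Descriptor-space virtual screening: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ligscreen)
```

# The screening problem

Ligand-based virtual screening triages a large compound library — millions
of structures — down to a short list worth assaying against a target such
as the Src tyrosine kinase. `ligscreen` implements the descriptor-space
formulation of this problem: every molecule is mapped to a fixed vector of
98 1D/2D molecular descriptors, known inhibitors define the positive class,
*putative* non-inhibitors are manufactured from the chemical-space family
structure of the library, and a binary classifier (or a plain similarity
rule) flags candidate actives. Screening quality is judged by yield (the
fraction of known actives recovered), the virtual-hit rate, and an upper
bound on the false-hit rate in which every unconfirmed hit counts as false.

# The descriptor registry

The 98 descriptors fall into four classes, computed on the
hydrogen-suppressed molecular graph:

* **18 simple properties** — atom, ring and bond counts, molecular weight,
  rotatable bonds, H-bond donors/acceptors, aromatic and heterocyclic ring
  counts.
* **3 chemical properties** — total Sanderson electronegativity, total
  atomic polarizability (both sums of published atomic contributions,
  attached hydrogens included) and ALogP, an abbreviated Wildman–Crippen
  atom-contribution logP (a reduced type set of ~30 contribution classes;
  the full published scheme distinguishes over a hundred).
* **35 connectivity and shape indices** — Wiener, Harary, Schultz and
  Gutman indices, Balaban J, path counts, valence/delta/solvation chi
  indices, Kier kappa and kappa-alpha shape indices, the flexibility
  index, and radius/eccentricity/centralization measures of the distance
  matrix.
* **42 electrotopological-state sums** — Kier–Hall atom E-states summed
  over 24 atom types, four aggregate sums, 13 hydrogen E-state type sums
  and the donor hydrogen E-state sum.

Where the literature offers competing parameterizations, the convention is
fixed and documented at the definition site; the ones that deserve mention:

* *Gravitational index*: `sum over heavy-atom pairs of m_i m_j / d_ij^2`
  with topological distance and attached-H masses folded into their heavy
  atom; geometric variants need 3D coordinates, which this package
  deliberately avoids.
* *Pogliani index*: sum over heavy atoms of valence electrons over
  principal quantum number.
* *Centralization*: `2W - n * min_i sigma_i` with `sigma_i` the distance
  degree; zero exactly on vertex-transitive graphs such as unsubstituted
  rings.
* *Eccentricity*: the sum (not the maximum) of atomic eccentricities.
* *Total path count*: all simple paths up to length 10 (exhaustive
  enumeration stays cheap on drug-like graphs; unbounded enumeration would
  be exponential on dense fused systems).
* *Hydrogen E-state*: the published hydride-group formulation is not fully
  specified by its sources, so the package derives hydrogen E-states from
  the Kier–Hall relative electronegativity `KHE = (deltav - delta)/N^2`
  with `KHE(H) = -0.2`, summing perturbations over heavy atoms. Polar X–H
  hydrogens score high and pure hydrocarbons low, which is the property the
  downstream statistics rely on; absolute values are a package convention
  and no literature golden values are asserted for them.

Degenerate cases map to 0 rather than NaN: a single-atom graph has no
paths, so every index whose formula divides by a path count or distance is
emitted as 0 and the descriptor vector stays finite — keeping the
downstream linear algebra total is worth more than distinguishing "zero"
from "undefined" in a feature vector.

## Chemistry conventions

Molecules enter as SMILES or SDF (V2000); OpenBabel (via
ChemmineR/ChemmineOB) parses the connection table, after which the package
applies its own uniform conventions so that every descriptor sees the same
chemistry regardless of input format: explicit hydrogens are folded into
attached-H counts and missing ones are assigned from charge-adjusted
standard valences; aromaticity is re-perceived with a Hückel-style 4n+2
electron count over the smallest set of smallest rings. The perception
handles the common heteroaromatics (pyridine, pyrrole, furan, thiophene,
imidazole, fused bicyclics such as naphthalene and the purines) and
correctly rejects cyclohexane and quinones; aromaticity that only emerges
on the perimeter of a fused system (azulene) is not detected — a known
limitation shared with simple per-ring perception schemes. Multi-fragment
inputs (salts) keep the largest fragment with a warning, since counter-ions
carry no screening signal.

# The four screening engines

All engines operate on descriptors min–max scaled to the unit interval by
a `fit_scaling()` model captured on a reference library. The scaling
convention is applied uniformly to all engines so that their comparison is
on equal footing — RBF kernels and Euclidean distances are scale-sensitive,
and the Tanimoto coefficient is only meaningful for non-negative vectors.

**Hard-margin RBF-SVM** (`train_svm`). The dual soft-margin problem is
solved by libsvm (through e1071) under the kernel
`K(x_i, x_j) = exp(-|x_j - x_i|^2 / (2 sigma^2))`; the package evaluates
its own decision function `f(x) = sum_i alpha_i y_i K(x, x_i) + b` from
the extracted support vectors, with the orientation normalized so that a
positive score always means "inhibitor" (libsvm's native sign depends on
training-data order). Defaults `c = 100000` — a penalty so high that
training errors are effectively forbidden on separable data — and
`sigma = 1.2`, the cross-validation optimum reported for this descriptor
space at production scale.

**Tanimoto similarity search** (`similarity_screen`). A library compound is
a hit when its best similarity to any known active strictly exceeds the
cut-off; 0.9 by default, the strict end of the conventional 0.8–0.9 range.

**k-nearest neighbour** (`train_knn`/`knn_predict`). Majority vote over the
k nearest training compounds, `k = 1` by default. Distance ties resolve by
training index so predictions are reproducible.

**Probabilistic neural network** (`train_pnn`/`pnn_predict`). A
Parzen-window Bayes classifier: per-class Gaussian kernel densities
`f_i(x) = (1/n_i) sum exp(-sum_j ((x_j - x_ij)/sigma_j)^2)` compared as
`h_i c_i f_i(x)` with equal priors and costs by default. Two numerical
choices matter here. First, the per-class `1/n_i` normalization is the
default: with a heavily imbalanced training set the unnormalized sum
degenerates into a majority-class detector, and sensitivities in the
mid-90s are only reachable with genuine per-class densities. Second, all
accumulation is done in the log domain: at the default `sigma = 0.02` on
unit-scaled descriptors a single kernel term is `exp(-thousands)`, which
underflows to zero in linear arithmetic and would turn every far query
into a spurious tie.

**Tie rules.** Every exact tie — an SVM score of zero, a split kNN vote, a
PNN density tie — resolves to the non-inhibitor class. A screen exists to
concentrate evidence of activity; a tie is not evidence.

# Putative negatives from chemical-space families

Known non-inhibitors are rarely published, so the negative class is
manufactured: the library is clustered into compound families
(`cluster_families`, k-means with seeded k-means++ initialization over 20
restarts keeping the lowest within-cluster sum of squares), and from every
family containing no known active, a few representatives — the members
nearest the family centroid — are taken as putative non-inhibitors
(`select_putative_negatives`, 2 per family by default; "representative" is
deliberately interpreted as nearest-to-centroid because it is
deterministic and defensible). The production-scale analysis behind this
design grouped 13.7M compounds into 8,423 families; at package scale the
family count is a free parameter. The contamination argument — that
undiscovered actives make up a small fraction of active-free families and
the resulting label noise is well below what a hard-margin SVM tolerates —
is a data-dependent estimate, documented here but not assertable as a
computable property.

# The evaluation harness

`confusion_stats` computes sensitivity `SE = 100·TP/(TP+FN)`, specificity
`SP = 100·TN/(TN+FP)`, overall accuracy Q and the Matthews coefficient
`C = (TP·TN - FN·FP)/sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP))`; C is reported
as undefined (never 0) when a marginal vanishes. `five_fold_cv` splits the
data into five random folds — stratified by class by default, because at a
37:1 imbalance an unstratified split can lose the minority class from a
fold — and reports per-fold counts plus mean, SD and standard error rows.
One layout quirk is intentional: in the summary rows the SE/SP/Q means are
percentages while their SD and standard error are on the proportion scale,
matching the conventional report layout of this kind of study (the shipped
reference tables in `extdata/` follow it, and the package reproduces every
cell of those tables from their integer confusion counts).

Screening-level statistics (`screening_metrics`) report yield, virtual-hit
rate, and the false-hit-rate *bound* `100·FP/(TP+FP)` under the convention
that every hit not in the known-active set is counted false — in an
unlabelled library the true rate is at most this value.
`family_novelty` asks whether a screen finds activity or merely recognizes
family membership: it counts hits in families containing no training
active, and reports the flagged fraction of each training family (a
membership detector flags most of a training family; an activity detector
does not).

# The synthetic benchmark

Classifier behaviour is validated on generated data living directly in
descriptor space, decoupling classifier correctness from descriptor
correctness (the chemistry path is exercised separately by 35 packaged
drug-like molecules with golden values from independent tooling).

`generate_synthetic_library` draws spherical Gaussian families in the unit
hypercube: per-coordinate spread 0.05 and minimum inter-centroid
separation 1.0 — roughly twice a family's RMS radius in 98 dimensions, so
families are distinct but their tails touch. Two active families stand in
for congeneric inhibitor series; eight inactive families for background
chemistry; the default 50 actives against 2,000 putative negatives
mirrors a screening-scale class imbalance.

Two features of real screens need explicit modelling:

* **Near-active inactive families.** Real inhibitor series are surrounded
  by close analogues without activity. Two of the inactive families are
  therefore placed at distance 0.4 from an active centroid
  (`near_separation`). Without them, every neighbourhood of an active
  would be exclusively active and "similar non-inhibitor" would be
  unlearnable by construction — no screen could demonstrate selectivity.
* **Similarity-defined decoys.** The hard part of a screen is the library
  slice that *looks* like the actives. `sample_similar_decoys` constructs
  it the way similarity screens define it: candidates drawn around the
  active centroids across a spectrum of radii are kept only if their best
  Tanimoto coefficient against the training actives reaches 0.9.

What passing the benchmark does and does not show: it demonstrates that
the engines implement their decision rules correctly, that the hard-margin
SVM is the most selective of the four on tight actives flanked by learnable
near-negatives, and that plain similarity search flags essentially the
whole similar slice. It does not demonstrate performance on real
chemistry — Gaussian families have no activity cliffs, no assay noise, no
descriptor correlation structure beyond what the geometry induces, and the
generated classes are separable in a way real inhibitor sets are not.

Problem sizes were chosen to characterize behaviour well at interactive
cost: cross-validation on 2,050 compounds, decoy screens of 10,000, family
recovery on 2,050 across 10 families. The family-recovery check runs on a
library generated without near-active families: partition recovery is a
property of the separated regime, and the near-active regime violates
separation by design.

# Known limitations

* Aromaticity perception is per-SSSR-ring; perimeter-only aromatic systems
  are missed.
* The ALogP type set is abbreviated; absolute logP values are approximate
  (monotonicity and finiteness are the tested contracts).
* Hydrogen E-state values follow a package convention (above), not a
  literature table.
* The PNN evaluates all training kernels per query; screening very large
  libraries with it is quadratic work. The SVM and Tanimoto engines
  vectorize over support vectors/actives and are the practical choices at
  scale.
* No probability calibration, no non-RBF kernels, no 3D descriptors — all
  deliberately out of scope.
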