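---
title: "Representational generalization across levels of visual abstraction: methods"
author: "depictRSA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Representational generalization across levels of visual abstraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(depictRSA)
```

# The question and the measurement model

Humans recognize a line drawing or a rough sketch of an object as easily as a
photograph, even though the three renderings share few pixels. `depictRSA`
provides the analysis machinery for asking whether a visual system — a
convolutional network layer, or human similarity judgments — carries object
representations that *generalize* across such levels of visual abstraction
(depiction types: photo, drawing, sketch).

The core tool is representational similarity analysis. For one depiction type
and one layer, the response patterns to $n$ objects are compared pairwise
with the correlation distance

$$ d(i, j) = 1 - r_{ij}, $$

where $r_{ij}$ is the Pearson correlation between the activation rows of
stimuli $i$ and $j$. The resulting $n \times n$ representational
dissimilarity matrix (RDM, `computeRDM()`) is symmetric with a zero diagonal
and entries in $[0, 2]$. Because Pearson correlation is invariant to
per-pattern location and scale, no feature normalization is applied before
the distance. Two RDMs over the same objects are compared by the Spearman
rank correlation of their strictly-lower-triangle vectors
(`rdmSpearman()`; average ranks for ties; alignment is always by object
label, never by row position). Computing this correlation between the RDMs
of two depiction types in each layer yields the *cross-depiction profile*
(`crossDepictionProfile()`): e.g. a photo-to-drawing similarity per layer.

The diagonal and upper triangle are excluded from every comparison; the
lower-triangle order is fixed and documented (row-major below the diagonal:
$d_{21}, d_{31}, d_{32}, d_{41}, \dots$) so that vectorized RDMs always
carry their label provenance.

# The synthetic generator: planted ground truth

Real stimulus sets and pretrained networks are outside this package's scope;
instead every pipeline stage is exercised on synthetic data whose structure
is known exactly, so correctness is checked by *parameter recovery*.

`generateActivations(syntheticConfig(...))` draws, for each object $o$, a
shared latent $z_o \in \mathbb{R}^L$ and, per depiction $d$, an independent
idiosyncratic latent $u_{o,d}$. Layer $l$ represents stimulus $(o, d)$ as a
random linear map (one map per layer, shared across depictions, mirroring
shared network weights) of

$$ \alpha_l\, z_o + \sqrt{1 - \alpha_l^2}\, u_{o,d}, $$

plus isotropic Gaussian measurement noise. The per-layer shared fraction
$\alpha_l \in [0, 1]$ is the single dial controlling cross-depiction
representational similarity: $\alpha_l = 1$ makes the depictions'
pre-map representations identical (recovered profile correlation exactly 1
at zero noise), $\alpha_l = 0$ makes them independent (expected correlation
0), and the recovered correlation is monotone in $\alpha_l$ in between. A
rising-then-falling $\alpha$ profile across layers therefore plants the
qualitative signature of interest — cross-depiction similarity that peaks at
intermediate processing stages.

Defaults mirror the stimulus design the package targets: 42 objects, 21
manmade and 21 natural, each rendered in three depiction types (126 stimuli);
`latentDim = 12`, `noiseSd = 0.1`, 64-feature layers with the concave profile
`(0.3, 0.6, 0.9, 0.6, 0.3)`.

A superordinate *class signal* of strength `classSignal` is added along a
latent direction with opposite signs for manmade and natural objects:

* `classSignalMode = "shared"` puts it in $z_o$, so the class is decodable
  within every depiction *and transfers across depictions* (through the
  shared map);
* `classSignalMode = "depiction"` puts it in each $u_{o,d}$ along
  *mutually orthogonal* per-depiction directions, so the class is decodable
  within a depiction but cannot transfer across depictions by construction.
  Orthogonality (rather than independent random directions) is deliberate:
  independent directions have a random mutual angle, which makes
  cross-depiction transfer bimodal across generator draws (sometimes aligned,
  sometimes anti-aligned) instead of null.

What the generator does **not** emulate: real images' spatial statistics,
inter-layer feature hierarchies (all layers see the same latent draw, only
through different random maps), receptive-field structure, or any
object-frequency effects in behavior. Passing the recovery tests shows the
*estimators and tests* behave correctly; it is not evidence about any
particular network or observer.

Companion generators produce triplet odd-one-out trials from a known
similarity matrix (`generateTripletTrials()`, deterministic arg-min chooser
with uniform tie-breaking, or a softmax chooser with temperature), paired
binary outcome tables with controlled concordance
(`generatePairedOutcomes()`, parameterized by the joint success probability
with its Fréchet feasibility bounds enforced), and synthetic image pairs
(`generateImages()`): a filled, speckle-textured polygon and a contour
rendering of the *same* polygon. Fills are uniformly darker than the gray
background and contours brighter, so the two rendering styles occupy
opposite pixel-intensity regimes — which is what makes pixel-level RDMs
depiction-dominated, the baseline the analysis is designed to beat.

# Inference procedures

All randomization tests share one p-value convention (`oneSidedP()`): with
$B$ permutations,

$$ p = \frac{1 + \#\{\text{null} \ge \text{observed}\}}{1 + B}, $$

the add-one form that counts the observed statistic into its own null. It is
strictly positive, valid under exchangeability, and bit-reproducible: every
`PermutationResult` records its seed and $B$.

* **Mantel test** (`mantelTest()`): the null relabels the objects of one RDM
  — one random permutation applied jointly to rows and columns, preserving
  the RDM's geometry — and recomputes the Spearman correlation. Cell-wise
  shuffling is never used. `mantelTestExact()` enumerates all $n!$
  relabelings for small $n$ and anchors the Monte-Carlo version in tests.
* **Correlation difference** (`rdmCorrelationDifferenceTest()`): observed
  $\rho(\text{shared}, x) - \rho(\text{shared}, y)$; the null relabels the
  shared RDM and recomputes both correlations. The generalized form
  (`rdmPairDifferenceTest()`) compares two correlations with no shared RDM
  (e.g. the same depiction pair in two networks) by applying one relabeling
  jointly to one side of each correlation; comparing a run to itself then
  gives an observed difference of exactly zero and $p = 1$.
* **Across-layer variation** (`acrossLayerVariationTest()`): observed
  statistic $\sum_l (\rho_l - \bar\rho)^2$; the null draws one relabeling
  per depiction — identical across layers, independent between the two
  depictions — and recomputes all layerwise correlations.
* **Sign permutation** (`signPermutationTest()`): flips the sign of each
  object's accuracy with probability 1/2 and compares the flipped mean
  against the network accuracy. The flip is applied to the accuracy values
  themselves, exactly as the procedure is usually stated, although values in
  $[0,1]$ make this a one-sided, highly conservative null; a
  `flipDifferences` flag exposes the variant that flips per-object
  human-minus-network differences instead, without presuming which was
  intended.
* **Decoding null** (`decodingPermutationNull()`): repeats the full
  cross-validated classification with randomly shuffled class labels.

Classical tests: `mcnemarTest()` computes $(b-c)^2/(b+c)$ on the discordant
counts without continuity correction (the correction is available behind a
flag); `independentTTest()` is the pooled-variance two-sample t;
`tostEquivalence()` runs two one-sided paired t-tests against user-supplied
bounds — the bounds are a required input, since no default can be justified —
reporting the larger of the two one-sided p-values, with degenerate
zero-variance inputs resolved to their limits (0 inside the bounds, 1
outside). `bhFDR()` applies the Benjamini–Hochberg step-up; families are an
explicit configuration (`fdrWithinFamilies()`), applied per analysis and
logged in the output table.

## A caution about the across-layer variation test

The relabeling null destroys the RDM correlation, so the null distribution
of $\sum_l (\rho_l - \bar\rho)^2$ reflects the dispersion of *near-zero*
correlation estimates. The sampling dispersion of a correlation estimate,
however, depends on the correlation's level. When the true profile is flat
at a *high* correlation, the observed dispersion (driven by per-layer
feature sampling) is not the dispersion the null models, and the test
rejects more often than its nominal level; at flat levels near the null's
own regime the level holds. The package therefore pairs the divergent-profile
power check with a *matched* flat control at the same baseline correlation,
and users comparing profiles that are uniformly high should treat small
p-values from this test with care.

# Decoding

`cvDecode()` implements leave-$N$-out classification: per iteration,
`nTest = 6` stimuli are drawn uniformly without replacement as the test
sample and a linear SVM (`e1071::svm`, cost 1, no feature scaling — scaling
is exposed as an off-by-default option) is trained on the rest to separate
manmade from natural patterns; accuracies are averaged over
`nIter = 1000` draws with the standard error taken across iterations. Test
draws are not stratified; an all-one-class *test* fold is legitimate and
scored as-is, but a draw whose *training* split lacks a class is rejected,
redrawn, and counted (`nRedrawn`). With 42 stimuli and $N = 6$ that cannot
happen; the guard protects smaller synthetic sets.

`crossDecode()` trains on one depiction's patterns and tests on another's.
The same object ids are held out of the training depiction that are tested
in the testing depiction, so no object identity leaks across the split —
with shared object ids this is the only leakage-safe reading of "the same
procedure". `crossDecode(a, a)` reproduces `cvDecode(a)` exactly under the
same seed, which the tests assert.

A note on "chance level": for a *single* noise dataset, leave-$N$-out
accuracy is not centered on 0.5 — the fold composition anti-correlates with
the training class balance, and a fixed random dataset has idiosyncratic
separability, so individual datasets swing well above or below 0.5. Chance
is a property of the *average* over label shuffles or generator draws, and
that is what the test suite asserts.

# Triplet behavior and label scoring

From odd-one-out trials (three objects shown, the least-similar one chosen),
`tripletSimilarity()` estimates the similarity of a pair $(x, y)$ as the
fraction of trials containing both in which the *third* object was chosen —
the probability the pair survives together, independent of context. Per-pair
co-occurrence counts are reported, and pairs that never co-occurred are
explicitly undefined (`NA`), never imputed: `choiceSimilarityToRDM()`
(behavioral dissimilarity $1 - \hat{sim}$) refuses to build an RDM while any
pair is undefined, listing the offenders. The deterministic simulator with
exhaustive triplets over 8 objects recovers the planted similarity ranking
with Spearman $\ge 0.9$, verified in the tests against an independent
brute-force counting oracle.

`labelAccuracy()` scores naming responses against a data-driven synonym key
(a table or TSV; the canonical label is just another row), case-insensitive
after trimming; per-object accuracy is the fraction of correct respondents.

# Multidimensional scaling

`mdsEmbed()` minimizes the raw metric stress
$\sum_{i<j} (\delta_{ij} - d_{ij})^2$ by SMACOF majorization (Guttman
transform). No installed optimizer targets exactly this loss with controlled
restarts, so the majorization loop is implemented here: the first start is
the classical-scaling solution (with an $10^{-8}$ jitter to avoid coincident
points stalling the transform), the rest are seeded random configurations,
and the best final stress wins. Convergence is declared when the stress
decreases by less than $10^{-10}$ relative per iteration (cap 500
iterations). Exact planar configurations are recovered to numerical
precision, and `stress(dims = 3) <= stress(dims = 2)` by nestedness — both
asserted in tests. The embedding is used for super-RDMs
(`superRDM()`), the joint RDM over all objects × depictions, whose
within-depiction blocks equal the per-depiction RDMs exactly.

# The network adapter

The adapter makes the pipeline runnable end-to-end from images without any
external deep-learning framework, using a compact pure-R convolutional
network (`tinyCNN()`: conv/ReLU/max-pool blocks, two fully connected layers,
softmax; im2col convolutions with same-padding).

* `preprocessImage()` standardizes a stimulus: foreground detection (alpha
  channel when present, otherwise a background-color mask — the mode is
  recorded per image), bounding-box crop, aspect-preserving rescale onto a
  square gray canvas (default 224 px with a 5% margin; bounding-box fit was
  chosen over area-preserving scaling and the margin is configurable), and
  per-channel $(x - \mu)/\sigma$ normalization. The normalization constants
  default to the canonical natural-image channel statistics but are plain
  configuration data, because "zero mean, unit variance" is ambiguous
  between per-image and dataset statistics.
* `extractFeatures()` returns one stimuli × features matrix per named layer,
  flattening convolutional maps (channels × height × width), in input order.
* `top1AccuracyHierarchy()` scores a prediction correct when it equals the
  target class or lies in the target's hyponym (descendant) closure of an
  is-a taxonomy supplied as a static edge list (TSV), via `igraph`; no live
  lexical-database queries, for offline reproducibility.
* `finetune()` trains with SGD + momentum (defaults 0.001 / 0.7) while every
  layer up to `freezeBoundary` keeps its parameters bit-for-bit; gradients
  are verified against finite differences in the test suite.

# Orchestration, seeding, determinism

`runExperiment1(analysisConfig(...))` executes the full graph — generate (or
load) activations, per-layer per-depiction RDMs, cross-depiction profile,
Mantel and across-layer variation tests, super-RDM MDS, intra- and
cross-depiction decoding, triplet simulation → similarity recovery → fit to
each layer's RDMs, and a consolidated FDR table — writing tidy CSVs, JSON
test records with seed and permutation counts, optional PNG figures, and a
manifest with the config hash. One global seed fans out to per-stage seeds by
a fixed counter scheme (stage $k$ uses $(\text{seed} + 104729\,k) \bmod
(2^{31}-1)$), so stages are individually reproducible and a rerun with the
same config is byte-identical on every CSV. `runComparison()` contrasts two
completed runs per layer and depiction pair with the generalized
correlation-difference test plus BH-FDR across the family.

# Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run at deliberately modest sizes:
calibration of the Mantel test uses 200 replicate pairs of 20-object RDMs at
500 permutations; recovery uses the 42-object design over the
$\alpha$ grid $\{0, .25, .5, .75, 1\}$ with 30 seeds against a 420-object
(10×) oracle; profile-shape checks use 50 seeds; the decoding permutation
null's type-I error uses 100 replicates at 200 permutations with a 4-iteration
inner cross-validation (the permutation test's validity does not depend on
the inner iteration count, only its power does); end-to-end determinism uses
a 3-layer, 42-object run. These sizes are the package's own choices for
routine verification; all counts are arguments, and study-scale runs simply
increase them.

# Known limitations

* The latent generator is an engineering stand-in for real stimuli, not a
  statistical model of them; recovery results validate the code, not any
  substantive claim.
* The across-layer variation test is anti-conservative for flat profiles at
  high correlation levels (see the caution above).
* The sign-permutation construction flips nonnegative accuracy values, which
  makes its null extremely easy to exceed; it is implemented as stated, with
  the difference-flipping variant available.
* TOST equivalence bounds must be supplied by the analyst.
* The tiny network is a testing vehicle; nothing in the package ships or
  downloads pretrained weights, and headline accuracies of real pretrained
  models are out of scope.
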