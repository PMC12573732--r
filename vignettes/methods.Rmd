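---
title: "Models and methods behind aphidQTL"
author: "aphidQTL maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aphidQTL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

aphidQTL re-implements, as one tested toolchain, the quantitative-genetics
inference chain used to map host-plant acceptance and survival in an F2
cross between pea-aphid host races: marker QC and de-novo linkage mapping,
Marey-map rearrangement detection, single-QTL genome scans, regional
heritability mapping (RHM), analytic detection power, and chemosensory-gene
enrichment. This vignette records the models, the defaults and why they
were chosen, the numerical conventions, and what the synthetic data
generator does and does not emulate.

## The cross and its peculiarities

The design is an F2 intercross between two fully homozygous, divergent
host-race backgrounds (an alfalfa-specialised and a pea-specialised clone),
giving double-heterozygous F1s and 192 F2 clones. Two features dominate
every model in the package:

* **Achiasmatic males.** Pea-aphid males produce no crossovers, so every
  recombination event observed in the F2 is maternal. Each F2 receives one
  *intact* paternal F1 haplotype per chromosome. All recombination-fraction
  likelihoods, HMM transition kernels and the simulator share this
  structure: the paternal contribution is a per-chromosome coin flip, never
  a recombinant.
* **The X chromosome.** Aphid males are X0. The package models the father
  as hemizygous: a single paternal X haplotype transmitted genome-wide, so
  X markers segregate in two genotype classes (homozygote vs heterozygote,
  which homozygote depending on the allele the father carried). Scans,
  distortion tests and relatedness computations all accept 2-class
  chromosomes; the per-statistic degrees of freedom follow the class count.
  The source study maps the X but does not state its genotype coding; this
  pseudo-backcross convention is this package's documented choice.

## Synthetic data generator

The generator (`crossConfig()`, `simulateFounders()`,
`simulateF2Genotypes()`, `simulatePhenotypes()`, `simulateGenePositions()`)
replaces the study's deposited reads; it defines the conditions every
downstream test runs under.

* Chromosome lengths default to the study map (A1 172 cM/160 Mb, A2
  112/130, A3 114/135, X 204/133) and marker counts to the filtered scan
  set (170/112/62/140): that is the marker density the scans actually
  consumed. The raw 6443-marker RAD scale is out of scope.
* Maternal crossovers are a no-interference Poisson process on the cM
  scale (expected count = length/100, positions uniform), making the
  Haldane map function exactly correct and giving map estimation a
  closed-form target. Interference models are deliberately not offered.
* Genotyping errors are symmetric single-step confusions (AA↔AB,
  AB↔either homozygote; never AA↔BB in one step) at rate ε = 0.001 by
  default; double miscalls are rare in RAD data. Missing calls are injected
  at 0.05, a realistic rate for depth-filtered RAD genotypes; the study
  does not print its rate.
* QC-violating markers are planted on request (monomorphic-across-races,
  heterozygous-founder, segregation-distorted) so the filter rules can be
  tested against a known truth record.
* Phenotypes come in two modes. *Direct* mode builds clone means as QTL
  effects + a genomic polygenic value + environmental noise, rescaling the
  genetic and residual parts so the realized latent heritability equals the
  target exactly; acceptance is emitted on the proportion scale (base 0.4,
  SD 0.12, clipped to [0, 1]), survival as a spike-at-17 clone mean, and
  survival counts as binomial(4) draws on a logit scale. *Mechanistic* mode
  simulates the observation grid itself - 17 timepoints × 4 replicates,
  per-step death hazard (QTL-shifted for survival traits), probing-given-
  alive from a clone-level liability - and summarises it exactly as the
  assays were summarised: acceptance = probing/alive observations, survival
  = mean time-steps alive, count = replicates alive at the end.
* Default target heritabilities are the study's genome-wide estimates
  (pea acceptance 0.097, alfalfa acceptance 0.299, pea survival 0.388,
  alfalfa survival 0.148). The default alfalfa-acceptance architecture
  places a QTL at A3 ~68 cM (~15% PVE). The reported survival QTL PVEs
  (10% and 7%) exceed that trait's heritability estimate of 0.148 - the
  familiar Beavis inflation of detected effects in a small cross - so the
  default architecture scales them proportionally into the heritability
  budget (8.7% and 6.1%) rather than reproduce an impossible variance
  decomposition.
* Chemosensory genes default to the 179-gene census (70 OR, 60 GR, 19 IR,
  11 OBP, 10 CSP, 9 SNMP) with optional spatial clustering around
  Poisson-process centres (normal scatter, SD 0.5 Mb), emulating tandem
  arrays.

What the generator does **not** emulate: read-level data, endosymbiont
effects, population structure among clones, genotyping error correlated
with depth, segregation distortion from viability selection (planted
distortion is iid), or linked gene-dense/gene-poor compartments. Passing
tests therefore demonstrate the statistical machinery under the stated
design, not robustness to every artefact of real RAD data.

## Marker QC and linkage mapping

`filterMarkers()` applies, in order: (1) the informativeness rule (both
founders of one race homozygous for one allele, both of the other race for
the other, both F1s heterozygous); (2) a segregation-distortion chi-square
against 1:2:1 (2 df) on autosomes or 1:1 (1 df) on the X, removing markers
with p < 0.001 - the tolerance the original mapping software was run with;
(3) redundancy collapse, keeping the least-missing marker of each identical
F2 signature. All-missing markers are removed first; markers with partially
missing founder genotypes are evaluated on what is available and annotated.

`estimateRFMatrix()` estimates the female recombination fraction for every
marker pair by maximum likelihood under the achiasmatic model. The nine
two-locus genotype-cell probabilities are linear in r, so the EM update has
closed form and is vectorised across all pairs at once. A fixed
contamination floor of 2ε keeps error-corrupted cells that are otherwise
impossible (e.g. AA×BB between tightly linked markers) from zeroing the
likelihood. LOD = log10 L(r̂) − log10 L(0.5); unlinked pairs fit to r̂ = 0.5
and LOD = 0 even across paternal-coupling mismatches (autosome×X pairs).

Grouping is single linkage at a LOD threshold, matching the threshold
semantics of the original grouping software: groups below the size floor
are dissolved and singletons re-attached to their best group above a join
threshold (defaults 31 / 20 / 3 at the full design scale, where the
perfect-cosegregation LOD ceiling is n·log10 2 ≈ 57; reduced-scale presets
lower the thresholds with n). `lodThresholdScan()` reproduces the
plateau-finding step - the range of thresholds over which exactly four
groups appear.

Ordering (`orderMarkers()`) minimises the sum of adjacent recombination
fractions by greedy chaining plus 2-opt refinement from randomised starts,
run 10 times; markers whose rank range across runs exceeds 2 positions are
flagged and removed, mirroring the repeated-ordering consistency filter.
Orientation is fixed by physical positions when available, else by anchoring
the lexicographically first marker. Map distances are Haldane,
d = −50·ln(1−2r̂), consistently with the simulator; co-segregating markers
share a position; adjacent r̂ ≥ 0.5 is capped at 50 cM and flagged.

`errorLodFlag()` computes per-genotype error LODs from the leave-one-out
HMM posterior: log10 of the posterior odds that the call is an error given
the flanking markers, divided by the prior odds ε/(1−ε). Markers whose
maximum exceeds 5 are flagged, following the error-LOD screening step.
A genuine recombination adjacent to a terminal marker can give a mildly
positive value; the threshold of 5 corresponds to decisive evidence.

## Marey maps and rearrangements

`segmentMarey()` walks the physical positions in map order, splitting at
direction changes and at physical jumps above a threshold (default 2 Mb;
for sparse marker panels a density-aware threshold - several times the
median marker gap - avoids mistaking sampling gaps for breakpoints, and the
pipeline uses max(2 Mb, 8× median gap)). Segments shorter than 5 markers
are merged into neighbours so single displaced markers cannot fragment a
block; orientation is the sign of the Spearman correlation of cM with bp
within the block (ties inherit a neighbour's orientation); ids follow
physical order, so the result reads like "+3, −1, −2".

`minInversionEvents()` counts the minimum number of signed reversals
transforming the observed signed permutation into the identity, by
bidirectional breadth-first search (exhaustive, exact; bounded at 10
blocks). Reversals are the only move - the study counts "inversion events" -
so a transposition costs the reversals needed to mimic it.
`detectSuppression()` reports runs of ≥ 3 markers at one map position
spanning ≥ 2 Mb of assembly: recombination-suppressed regions.

## Genome scans

`calcGenoprob()` runs the forward-backward algorithm of the intercross HMM
adapted to achiasmatic males: hidden state = (maternal allele, paternal
haplotype), maternal transitions by Haldane r per interval, paternal state
constant per chromosome (2 states on the X), emissions confusing classes at
rate ε. Posteriors are evaluated at markers and at pseudo-positions on a
1 cM default step.

The acceptance traits are proportions with irregular distributions, so
their scan is nonparametric: a Kruskal-Wallis statistic generalised to
probability-weighted genotype classes (midranks, tie correction), with
LOD = H/(2 ln 10). At a fully informative marker this reduces *exactly* to
the standard Kruskal-Wallis H - the unit tests assert equality to 1e-10
against `kruskal.test`.

Survival (mean time-steps alive) spikes at its upper bound, so its scan is
a two-part model: class-specific spike probability π_g plus, among
non-spike clones, class-specific Normal(μ_g, σ) with common σ. At
pseudo-positions the fit is an EM over the genotype mixture (tolerance
1e-8 on the log-likelihood, 200 iterations max, batched across positions),
not multiple imputation - deterministic and testable against the closed-form
marker-level ML. The joint LOD is the scan statistic; spike-only and
quantitative-only component LODs are reported.

Significance uses 1000 trait permutations (95th percentile of genome-wide
maxima, empirical quantile type 7 so thresholds are reproducible), support
intervals are 1.5-LOD drops expanded to flanking markers, and variance
explained is PVE = 1 − 10^(−(2/n)·LOD). The study does not print its LOD
scores or thresholds, so its PVE values (15%, 10%, 7%) function here as
simulation effect-size presets, not as targets.

## Regional heritability mapping

RHM asks whether SNPs in a 20 cM window explain trait variance beyond the
genome-wide background: y = μ + g_r + g_b + e with g_r ~ N(0, Vr·K_window)
and g_b ~ N(0, Vb·K_rest), where the relatedness matrices are VanRaden
first-method GRMs (0/1/2 dosages, centred by 2p̂, scaled by 2Σp̂(1−p̂),
ridge 1e-6·I) built from the window SNPs and from *all other* SNPs
respectively. Windows slide 10 cM; a terminal window is anchored at
length − 20; windows with < 3 SNPs are skipped. Under this tiling the
study-scale map gives 59 windows; the study reports 57, and no obvious
tiling convention reproduces that count exactly, so the tiling here is
documented and the count reported rather than forced.

The study fitted these models in a Bayesian sampler; this package
substitutes deterministic REML (bounded quasi-Newton on log-variances from
5 dispersed fixed start points) so results are seed-free and testable.
Posterior means shrink toward the prior where REML can hit the zero
boundary; boundary components are reported as 0 and flagged, and no attempt
is made to match posterior summaries numerically. The binomial survival
count (alive at the end, out of 4 trials) is fitted by penalised
quasi-likelihood on the logit scale - iterating the working response and
weights with warm-started REML each cycle until the variance estimates move
< 1e-5, with the ±0.5 continuity adjustment for 0/4 and 4/4 clones - and
the fitted residual is converted back to the logit scale so heritabilities
are comparable with the Gaussian fit.

The permutation null follows the regional-permutation scheme: permute the
rows/columns of the *regional* matrix only, leaving the trait and the
background matrix intact, so overall heritability is preserved while any
regional contribution is destroyed; 1000 permutations per window and the
95th percentile of permuted Vr as a *suggestive* cutoff. This is a lenient
criterion by construction (no multiple-testing correction across windows),
exactly as the study describes its own.

## Detection power

`qtlDetectionPower()` implements the simple closed-form power method for a
marker-based QTL test in an F2: with QTL heritability h² and the QTL on
average half a marker spacing from the test marker, the marker captures
h²ρ² of the phenotypic variance, ρ = 1 − 2r at Haldane r(spacing/2). The
1-df additive test statistic is noncentral F(1, n−2) with
λ = n·h²ρ²/(1 − h²ρ²), and power is the upper tail beyond the α critical
value. Splitting a trait's heritability over k equal-effect QTL divides h²
by k. This form reproduces the study's printed six-value power table to
within 0.005 and agrees with a direct Monte-Carlo of the marker F-test to
within 0.003; a 2-df (additive+dominance) variant is exposed behind a flag
but the 1-df form is the default the printed values support.

## Gene-region overlap and enrichment

Gene positions are single points (midpoints); containment is half-open
[start, end) in bp, so a gene exactly at a region end is outside. Regions
may be multi-segment; overlapping regions are merged only for the
deduplicated union count, never per-region. The permutation enrichment
resamples the subset *among all annotated chemosensory genes* (without
replacement, 10,000 times), matching the study's randomisation unit - not
genome-wide repositioning - and reports observed, expected, SD, z and the
add-one p-value. The category test is Fisher's exact test with the
minimum-likelihood two-sided rule; the one-sided tail in the observed
direction and the conditional-ML odds ratio are reported alongside. On the
printed counts (39 of 60 in-region genes are ORs; 70 of 179 genes are ORs)
the two-sided p is 7.5e-07; the study prints 6.429e-07 from a table
construction it does not fully specify - same order, same conclusion.

## Pipeline, seeds and problem sizes

`runPipeline()` executes simulate → QC → map → Marey → scans → RHM → power
→ enrichment from one `runConfig()`, writing every intermediate as plain
text and a JSON report. Each stage derives its seed from the master seed by
stable name hashing, so disabling one stage never shifts another's
randomness; a fixed master seed gives a byte-identical report. Full-scale
defaults mirror the study (192 F2s, 1000 scan permutations, 1000 RHM
permutations per window, 10,000 enrichment resamples). Because permuting
every window's REML fit is the dominant cost, the pipeline permutes the
top-Vr windows per trait (configurable) and leaves exhaustive per-window
permutation to `regionalPermutationTest()`. The `reduced` preset (96 F2s,
fewer markers, 100-permutation scans, 50 RHM permutations, wider windows)
exists for smoke runs and completes on one CPU in minutes; the test suite
uses these reduced sizes, chosen as the smallest scale at which every
statistical convention still operates unchanged.

## Known limitations

* REML/PQL point estimates stand in for the study's Bayesian posteriors;
  interval statements about Vr are permutation-based only.
* The reversal-only inversion count is a lower bound that ignores
  transpositions as primitive events; the study's complex A1 arrangement is
  described in its discussion as inversions plus a translocation, but its
  printed minimum event count follows the reversal accounting implemented
  here.
* Marey segmentation assumes a mostly collinear backbone and labelled
  assembly coordinates; it is not a general-purpose synteny caller.
* The X convention (hemizygous father, two classes genome-wide) is a
  modelling choice the source study leaves unstated; alternative codings
  would change X-linked scan statistics in detail, not in kind.
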