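---
title: "Methods: QTL mapping from shallow whole-genome sequencing of F2 populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTL mapping from shallow whole-genome sequencing of F2 populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thinqtl)
```

# Overview

`thinqtl` implements a complete quantitative-genetics workflow for
biparental F2 populations genotyped by very shallow (~0.1-0.2x)
whole-genome sequencing, as used in flowering-time studies of Arabidopsis
crosses between early- and late-flowering backgrounds. At that coverage
most variant sites receive zero reads in a given plant and a heterozygous
site with a single read is indistinguishable from a homozygote, so
genotypes cannot be called site by site; the pipeline instead reconstructs
whole-chromosome genotype mosaics. The stages are:

1. **Variant filtering** (parental markers): a hard soft-filter expression
   plus an automated "corrected" filter based on Gaussian fits to the
   quality annotations, with centromere/telomere/TE region exclusion.
2. **Genotype reconstruction**: a three-state hidden Markov model over
   sparse per-site allele counts per F2 plant.
3. **Cross assembly**: crossover breakpoints become population markers; a
   fixed QC cascade removes unreliable individuals and markers.
4. **QTL mapping**: Haley-Knott regression scans, permutation thresholds,
   two-locus scans, stepwise penalized-LOD model selection, Bayes credible
   intervals, signed additive effects and explained variance.
5. **Phenotype statistics**: broad-sense heritability, vernalization
   sensitivity, knockout/knockdown classification, pairwise contrasts with
   multiplicity control, delta-delta-Ct expression and growth-trajectory
   analysis.

A synthetic-data generator produces every input with known ground truth;
all statistical guarantees quoted below are computed by the test suite and
the acceptance script, not asserted.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated.

* **Genome**: five chromosomes of 30, 20, 23, 19 and 27 Mb at a uniform
  4 cM/Mb - Arabidopsis-like scale; configurable. Optional exclusion
  regions place a 2-Mb centromeric zone mid-chromosome and 100-kb
  telomeric zones at the ends.
* **Meiosis**: each F2 plant fuses two independent gametes; crossovers per
  gamete per chromosome are Poisson with mean equal to the genetic length
  in Morgans (Haldane model, no interference), placed uniformly in
  physical coordinates. Interference is deliberately not modelled: all
  map-distance arithmetic in the pipeline is Haldane-consistent, and none
  of the tested quantities depend on crossover spacing beyond the expected
  counts. Genotype frequencies at any locus converge to 1:2:1.
* **Sequencing**: depth per site per plant is Poisson(`mean_coverage`),
  independent across sites; the ALT read count is binomial with success
  probability `error_rate`, 0.5 or `1 - error_rate` under AA, AB, BB.
  Default coverage 0.2x, default `error_rate` 0.01 per read.
* **Marker density**: 70,000 raw parental variants genome-wide. After the
  two-tier filter ~48,000 remain, giving roughly 8,700 informative
  (nonzero-depth) sites per plant at 0.2x - comfortably above the
  7,000-site sample filter, and the same order as real shallow-WGS marker
  sets.
* **Quality annotations**: two-component inlier/outlier model - QD
  inliers N(25, 3) vs. an outlier mode at N(3, 1); FS half-normal (strand
  bias is non-negative); MQ a point mass at 60 for inliers; rank-sum
  annotations near zero for inliers and negatively displaced for
  outliers. The defaults give the corrected filter a well-separated
  dominant peak, which is the regime it is designed for.
* **Phenotypes**: trait = baseline (30, a days-to-flowering scale) + per
  QTL (-a, d, +a for AA/AB/BB) + Normal(0, residual SD). Days-to-flowering
  censoring (values above 125 recoded to exactly 130) is applied on
  export, not during simulation, mirroring how unflowered plants are
  scored at the end of an experiment. Replicated-line designs add a
  Normal(0, `line_sd`) line effect and a multiplicative vernalization
  shift (default 0.5, i.e. log2 sensitivity 1).

What the generator does **not** emulate: read-level artifacts (mapping
bias, duplicated reads, base-quality variation), linked-variant haplotype
errors, segregation distortion from selection, crossover interference, and
G×E. Tests passing under these conditions therefore demonstrate that the
algorithms are correct and well-calibrated under their stated model, not
that real data meet that model.

# Variant filtering

The soft filter flags records with
`QD < 5.0 || FS > 60.0 || MQ < 50.0 || MQRankSum < -12.5 || ReadPosRankSum < -8.0`.
All comparisons are strict, so boundary values pass, and a missing
annotation never triggers its clause.

The corrected filter then works on soft-passing records. Region exclusion
(0-based half-open BED intervals against 1-based variant positions) is
applied first, and the Gaussian fits use only region-passing records; a
variant inside a centromere is `region_fail` regardless of its
annotations. A two-component normal mixture is fitted to QD by EM
(deterministic initialisation at the 25%/75% quantiles, at most 100
iterations, log-likelihood tolerance 1e-6, SD floor 1e-6), and single
Gaussians to FS and MQRankSum by moments. Records outside the dominant
QD peak +-2.5 SD, FS +-2.5 SD, MQRankSum +-4 SD, or with MQ below the
fixed 50 threshold, are `corrected_fail`. FS is fitted on the raw
(untransformed) scale; this is configurable. Each removed record carries
exactly one primary failure reason - the first stage that removed it.

Re-applying the filter to its own output with the *stored* fitted
intervals changes nothing (exact idempotence). Refitting on filtered
output instead would tighten the intervals slightly, because truncated
samples have smaller SDs; the `fits` argument exists for this reason.

On the default QD mixture (80% N(25,3), 20% N(3,1), n = 10,000) the filter
removes >= 95% of outliers while losing <= 2% of inliers - the inlier loss
is the ~1.24% two-sided tail mass outside +-2.5 SD, plus fitting noise.

When two parental VCFs are supplied, only biallelic SNPs are kept
(multiallelic and indel records are flagged), and the parent contributing
more variants becomes the ALT source; ties break deterministically to
parent 1. The ALT-parent choice orients effect signs downstream.

# Genotype reconstruction

Per chromosome, the HMM has states AA, AB, BB with the F2 prior
(1/4, 1/2, 1/4). Emissions are binomial: ALT count k of depth n with
success probability eps, 0.5, 1 - eps; zero-depth sites emit uniformly and
thus contribute nothing. Transitions between adjacent sites use the F2
two-locus genotype matrix at the Haldane recombination fraction implied by
the physical gap times cM/Mb (default 4; the true genetic map of a real
cross is unknown at this stage, and reconstruction accuracy is insensitive
to modest rate misspecification because information accumulates over many
sites between crossovers).

Decoding is by Viterbi in log space with ties broken toward staying in the
current state (favouring fewer crossovers); posteriors come from scaled
forward-backward, and the forward and backward total likelihoods agree to
1e-8 relative as an internal consistency check. On short inputs (<= 8
sites) both the Viterbi path and the total likelihood equal exhaustive
enumeration over all 3^T paths to 1e-10 - the oracle the test suite uses.
Sites deeper than 50 reads are proportionally down-scaled before emission:
shallow libraries produce such pile-ups almost exclusively at collapsed
repeats, where the binomial model would otherwise be overconfident.

Before reconstruction, organellar contigs are dropped, sites whose depth
deviates from the sample mean by more than 5 SD are zeroed (depth
statistics are computed over **all** sites including zero-depth ones - a
contaminated nonzero-only SD would let extreme pile-ups mask themselves),
and samples with fewer than 7,000 informative sites are rejected. If the
depth SD is zero the deviation rule is skipped with a warning rather than
removing everything.

Under the default conditions (0.2x, eps = 0.01, 20 plants), site-level
Viterbi accuracy is >= 99% and accuracy is non-decreasing in coverage over
0.05-0.5x. Crossovers are called at state changes, with the breakpoint at
the midpoint of the bracketing informative-site interval and confidence
equal to the smaller flanking-segment mean posterior; adjacent AA/BB
segments are one state change flagged non-canonical (a collapsed double
crossover). A single HMM pass replaces the multi-stage sliding-window
refinement of earlier genome-reconstruction tools; the simulation-based
accuracy and recall checks above are the validation of that design choice.

# Cross assembly

The union of all crossover breakpoints across the population partitions
each chromosome; each interval becomes one marker at its midpoint, and a
plant's genotype at a marker is its segment state there, or missing when
the flanking-segment posterior falls below 0.95.

QC runs in a fixed order, and every removal is logged with stage and
reason:

1. individuals with called genotypes below 0.5x the population median
   called-marker count (the "low number of called markers" rule, which the
   original protocol leaves unquantified);
2. for every pair with genotype identity >= 0.9 over shared non-missing
   markers, the member with fewer called markers is removed (tie: the
   later id). Unrelated F2 plants have expected identity
   sum P(state)^2 = 6/16 = 37.5%, so the 0.9 cutoff only fires on
   duplicates or contamination;
3. individuals with more than 25 genome-wide crossovers (about twice the
   expected median of ~10 under the default genome; AA<->BB transitions
   count as two);
4. markers missing in more than 10% of individuals;
5. markers failing the 1:2:1 chi-square goodness-of-fit (df = 2, no
   continuity correction, expected counts from non-missing individuals) at
   p < 1e-7. Counts (100, 20, 0) give chi-square = 220.0 and removal;
   (30, 60, 30) give 0 and retention.

Adjacent-marker recombination fractions are then estimated by direct 1-D
maximum likelihood over the F2 two-locus table (`optimize` on the
log-likelihood; the no-recombinant boundary case returns r = 0 exactly)
and converted to cM by the inverse Haldane function, capped at r = 0.49 to
stay finite. A literal EM iteration has the same stationary point; the
direct search is simpler and robust. Physical marker order is trusted
throughout - no order re-estimation.

Crosses round-trip losslessly through a rotated-CSV ("csvr") file:
phenotype rows first, then one row per marker (id, chromosome, cM,
genotype codes A/H/B, `-` for missing). Physical positions are recoverable
from the `chrom_pos` marker ids.

# QTL mapping

Genotype probabilities at markers and at a pseudomarker grid (default
2 cM - the conventional scan resolution; the original analysis pipeline
does not print its grid step) are computed by forward-backward along each
chromosome, with observed marker genotypes emitting their state with
probability 1 - 1e-4. Missing genotypes are handled automatically by the
sum over states, weighted by their conditional probabilities.

The Haley-Knott scan regresses the phenotype on the conditional additive
predictor `P(BB) - P(AA)` and dominance predictor `P(AB)`;
`LOD = (n/2) log10(RSS0/RSS1)` against the intercept-only null, with RSS1
floored at `1e-12 x TSS` so noiseless fixtures stay finite. The scan
matches a direct least-squares oracle to 1e-8 at every position.

Permutation thresholds shuffle the phenotype vector against the whole
genotype matrix (preserving marker correlation; no stratification - a
single population), record the genome-wide maximum LOD per permutation,
and take the empirical 1 - alpha quantile; 1,000 permutations at
alpha = 0.05 for production scans, 100 in the two-locus scan and in the
scaled test settings. Under null phenotypes the genome-wide type-I error
at the 95% threshold lies within the binomial 99% band around 5% (tested
at 200 trials).

The two-locus scan fits, for every pair of grid positions (coarse 10 cM
default; pairs scale quadratically), the full model (two loci plus four
interaction terms) and the additive model; the interaction LOD is their
difference and its threshold comes from the permuted maximum interaction
LOD. Pairs closer than one grid step on the same chromosome are excluded
to avoid collinear designs.

Multiple-QTL selection is additive-only (each QTL contributes additive and
dominance terms, no epistasis terms - matching the single-population
design where two-locus scans found no reproducible interactions). Forward
search adds the position maximizing the model LOD up to `max_qtl` (8),
then backward elimination removes the cheapest QTL down to the empty
model; the model maximizing `pLOD = LOD - penalty x nQTL` over the whole
path is returned, with the trait's own permutation threshold as the
penalty (the conventional choice when dedicated penalty calibrations are
not available). An empty model (pLOD 0) is a valid outcome for null
traits. Collinear duplicates of one true locus are eliminated on the
backward pass.

The 95% Bayes credible interval normalizes `10^LOD` over the chromosome's
evaluation grid, accumulates positions from the highest mass until 95% is
covered, takes the enclosing contiguous run, and expands strictly outward
to the nearest genotyped markers on each side - the conventional credible
interval for a QTL peak, reported in bp. Grid endpoints are interpolated
to bp through the marker map.

Additive effects are reported as
`a = (mean late-parent homozygote - mean early-parent homozygote)/2`, so a
positive effect means the early parent's allele promotes flowering
(reduces the trait). Per-QTL explained variance (PEV) is the drop-one RSS
share `100 (RSS_without - RSS_full)/TSS`; model PEV is
`100 (1 - RSS_full/TSS)`. At the validated scales (PEV-50 QTL, n = 200),
the scan peak lands within 5 cM of the truth and the Bayes interval covers
the truth in >= 90% of replicates, and PEV estimates are unbiased within
+-6 points at n = 400.

Window summaries tile the genome in non-overlapping 100-kb windows and sum
LOD over all supplied scans at the window center, conserving the total -
the standard way to overlay many population x trait scans.

# Phenotype statistics

* **Broad-sense heritability**: method-of-moments one-way random-effects
  ANOVA. With mean squares between/within lines and the unbalanced-design
  effective replicate number `k0 = (N - sum n_i^2 / N)/(g - 1)`,
  `H^2 = var_line/(var_line + var_error)`, clipped to [0, 1]. Invariant to
  affine trait rescaling; recovers a 9:1 variance ratio (60 lines x 12
  replicates) within 0.87-0.93.
* **Vernalization sensitivity**: per-line
  `log2(mean trait unvernalized / mean trait vernalized)`, the vernalized
  arm already on the comparable scale (cold period subtracted on
  ingestion). Swapping arms negates the value exactly.
* **KO/KD classification**: mutant lines with mean relative expression
  below 5 a.u. are knockouts; the boundary value 5.0 is assigned to KD,
  since values *below* 5 define the knockout class. Wild-type rows are
  rejected.
* **Correlations**: Pearson on untransformed line means, two-sided p,
  df = n - 2.
* **Pairwise contrasts**: Mann-Whitney U (exact when both sides have <= 8
  values and no ties; normal approximation with tie and continuity
  corrections otherwise - all-tied groups short-circuit to p = 1, where
  the approximation would be 0/0) or two-sided Student's t, with
  Benjamini-Hochberg, Bonferroni or no correction. Zero-variance t inputs
  follow the degenerate rule: equal means p = 1, unequal p = 0 with a
  warning. BH-adjusted p-values are monotone in raw-p order and never
  below raw p.
* **delta-delta-Ct**: `2^-ddCt` against a reference gene, calibrated by
  convention to biological replicate 1 of the reference accession.
* **Growth**: plants below 500 px on any analysis-range day, or below
  5,000 px throughout the late stage (default: the final third of measured
  days; the exact "later stage" window is a configurable choice) are
  excluded. `RGR = (ln A_d18 - ln A_d11)/7` per plant. Per-day
  mutant-vs-wild-type contrasts reuse the contrast machinery. Trajectory
  vectors of daily `log2(mutant mean/wild-type mean)` are clustered by
  Ward linkage on Euclidean distance into k = 3 groups by default (the
  observed larger/crossing/smaller archetypes); interior missing days are
  linearly interpolated per line, ends are not extrapolated and NA days
  are dropped from the distance.
* Group summaries average line means (not pooled replicates); the censored
  DTF value 130 enters means as-is, with exclusion available as a
  sensitivity switch.

# Numerical choices and degenerate inputs

* EM SD floor 1e-6; all-identical annotation values warn and retain
  everything.
* HMM works in scaled probability space (forward-backward) and log space
  (Viterbi); per-site emission rescaling prevents underflow at any depth.
* RSS floor 1e-12 x TSS keeps LODs finite on noiseless fixtures; constant
  phenotypes return an all-zero profile with a warning.
* Recombination-fraction estimates are capped at 0.49 before the inverse
  Haldane transform.
* Depth cap 50 reads per site before emission; configurable.
* Zero-depth-variance samples skip the depth-SD rule with a warning.
* All generators and permutation routines are bit-reproducible under a
  fixed seed.

# Problem sizes used in validation

The test suite and acceptance script run at the scales stated above: 20
plants at 0.2x for reconstruction accuracy; 50 replicates of n = 200 for
QTL recovery; 200 null trials at 100 permutations for threshold
calibration; n = 10,000 variants for the filter; 60 lines x 12 replicates
for heritability. These sizes make every check reproducible on a single
CPU in minutes while keeping the binomial/stochastic acceptance bands
meaningful.

# Known limitations

* The depth model is independent-Poisson; real shallow WGS has mild
  overdispersion and mappability structure. The depth-SD site filter and
  the 50-read cap absorb most of the practical difference.
* The HMM assumes a known uniform cM/Mb scale for transitions; strongly
  non-uniform recombination landscapes would misplace breakpoints within
  (but not across) low-marker regions.
* Genetic-map estimation ignores genotyping error in the marker matrix
  (error handling lives in the reconstruction stage upstream).
* The two-locus scan reports interaction calls against a permutation
  threshold but performs no multiple-population meta-analysis.
* Trajectory clustering treats days as equally spaced coordinates;
  irregular imaging schedules would need a time-warped distance.
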