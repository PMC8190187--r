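---
title: "Methods: chromosome structure and allelic reactivation of the inactive X"
author: "xistruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromosome structure and allelic reactivation of the inactive X}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and numerical choices
behind the pipeline. The package analyses allele-resolved Hi-C contact
matrices and allele-resolved expression/accessibility tables from a hybrid
(mus x cas) cell system in which the inactive X chromosome (Xi) can be
reactivated through reprogramming. Every stage is paired with a synthetic
generator that plants the structure the stage is meant to recover, so all
claims the package makes are backed by parameter-recovery tests rather
than by inspection of downloaded data.

## Contact-matrix model and normalisation

A `ContactMatrix` is a symmetric, non-negative matrix over a table of
equal-width bins (0-based, half-open coordinates; the resolution is a
property of the file, never inferred). Three states are tracked: `raw`
integer counts, `balanced` (ICE), and `observed_over_expected`.

Bin filtering masks bins that fail any of three criteria: mappability
below 0.5, zero restriction-enzyme sites, or a total count strictly below
a matrix-wise heuristic threshold: the x-position of the lowest-x local
maximum of a kernel density estimate of the per-bin totals (Gaussian
kernel, Silverman's bandwidth, 512 grid points spanning the data range).
The threshold targets the artifact mode that dead bins form near zero;
on a strictly unimodal distribution it degenerates to the single mode and
will flag everything below it, so it should only be applied to matrices
that can actually contain dead bins. The analysis drivers therefore skip
it on simulated matrices generated without artifact bins. Whether "the
lowest maximum of the density estimate" denotes the mode position or the
density value is ambiguous on its face; we use the position (an x-value is
the only choice with count units).

Balancing is iterative correction (ICE) to equal row sums (relative
tolerance `1e-5`, at most 200 iterations, total signal preserved).
Observed-over-expected divides each entry by the mean value of its
distance class, computed over unmasked pairs only; empty or zero classes
yield missing values. Masked bins propagate as `NA`, never as zeros.

In-silico mixing emulates a mixed cell population: both inputs are scaled
to a common total ("depth matching") before the convex combination, so
the mixing ratio reads as a cell fraction rather than a read fraction.

## Compartments

PC1 is the leading eigenvector of the Pearson correlation matrix of the
O/E matrix, computed separately for the two mega-domain arms when a split
point is given (default 75.6 Mb, the Dxz4 boundary on chrX; 100-kb bins).
Without the split, PC1 of a mega-domain matrix tracks the mega-domains
themselves; splitting removes that dominant structure and exposes the
A/B checkerboard on each arm. Each arm's eigenvector is oriented so it
correlates positively with GC content (A = GC-rich = positive).

Calibration fits a two-component unequal-variance Gaussian mixture to the
PC1 values after symmetric 2.5%-per-tail trimming (the trim applies to
fitting only; every bin receives a calibrated value). The fit is
delegated to mclust (model "V"), whose hierarchical initialisation makes
it deterministic; the trimming, intersection and rescaling logic is the
package's own. The centring point is the intersection of the two weighted
component densities between the means, found by bisection to `1e-12`; the
unit test and the acceptance script verify it against a dense grid scan.
After centring, positive values are divided by the maximum positive value
and negative values by the absolute minimum, so the track spans [-1, +1]
with A strictly positive. If the two component means coincide, the
calibration falls back to centring at the trimmed median with a warning.

Segment counting merges runs of same-label unmasked bins and drops
segments shorter than 300 kb without re-merging across the gap; masked
bins break runs, as they would in a bedtools-style merge of per-bin
intervals. In recovery tests the planted count is therefore evaluated on
the observable (unmasked) lattice.

Saddle aggregation ranks bins by PC1 into 50 equal-count categories (ties
broken by bin index) and averages log2 O/E per category pair. Strength
takes the top and bottom 20% of bins by PC1 and summarises each class
pair by the median log2 O/E; the overall strength is (AA + BB)/2 - AB,
a formula we fixed ourselves since only the per-class numbers have a
stated definition.

## Subcompartments

The similarity matrix is built exactly in this order: O/E, ICE, clipping
of entries above the 90th percentile, Pearson correlation, zeroed
diagonal, then a linear rescale mapping the 5th/95th percentiles of the
correlation values onto -1/+1 with clipping outside. Spatial clusters
come from k-means on the 12 leading eigenvectors, each weighted by its
signed eigenvalue, with k-means++ seeding and Lloyd refinement, best of
10 restarts by total within-cluster sum of squares, under a caller-set
seed. Negative eigenvalues among the top 12 are kept with their sign.

Cluster labels are transferred between samples by re-clustering and
aligning to a reference: the optimal bijective relabelling on the k x k
contingency table, solved as a maximum-weight bipartite matching and
verified against an exhaustive permutation oracle for k <= 6.

Consolidation to the five subcompartments (A1, A2, AB, B1, B2) uses
average-linkage hierarchical clustering on the rows of the cluster
interaction matrix with the self-interaction diagonal left out: the
grouping should reflect how a cluster interacts with the rest of the
chromosome, not its internal cohesion, and the diagonal otherwise
dominates the distance for strongly self-associating clusters. Groups are
named in order of descending mean reference PC1 of their member bins,
ties broken by the smallest member cluster id. The published account of
this consolidation is qualitative, so this concrete rule is a design
choice of the package.

Inter-mega-domain interaction fractions restrict to cross-boundary pairs
more than 8.2 Mb apart, mark the top 20% by value as strong (quantile
threshold; ties at the threshold are included, so a constant matrix gives
fraction 1), and report per cluster the strong fraction among qualifying
pairs touching it.

## TADs, insulation and domain scores

The insulation score of bin b is the mean contact value in the
`window x window` square just off the diagonal at b (default 10 bins =
500 kb at the 50-kb working resolution; the reference method's "default
parameters" are not printed, so the window is exposed as a parameter),
log2-ratioed against the chromosome-wide mean. Scores are smoothed with a
centred 7-bin moving average that shrinks symmetrically at the ends.
Borders are local minima of the smoothed track below -0.086, with the
leftmost bin of an equal-valued plateau winning. The cutoff applies to
the smoothed score. ICE balancing of a finite chromosome inflates
near-terminal rows, which bows the insulation profile near the ends; the
recovery tests use 1,000-bin chromosomes where the interior is flat.

TADs tile each contiguous unmasked region between consecutive borders (a
border bin closes the TAD to its left); fragments shorter than 3 bins are
dropped, and mask gaps break TADs because a domain score across an
unmappable stretch is meaningless. The domain score of a TAD is the sum
of contacts within it divided by the total contacts of its bins with the
whole chromosome — on a uniform matrix a k-bin TAD on an n-bin chromosome
scores k/n. It is invariant to global scaling.

The relative domain score places a middle timepoint on the start-to-end
axis, (mid - start)/(end - start), with TADs whose start and end scores
differ by less than 0.01 reported missing. Because ICE gives both input
matrices equal row sums, the relative score of a depth-matched mixture
equals the mixing ratio essentially exactly — the property used to argue
that a heterogeneous NPC/ESC population cannot explain intermediate
domain scores unless every TAD sits at one common ratio. Early/late TAD
classification is 1-D k-means with k = 2 ("early" = larger centre), with
the fraction of TADs above a 0.2 relative-score threshold reported
alongside as a cross-check; k-means is authoritative when they disagree.

Relative per-TAD omics trajectories (peak counts, mean expression) use
the same start-to-end rescaling, excluding TADs with fewer than 15 peaks
in the end state (peaks) or a flat start-to-end difference (expression).

## Allelic expression and accessibility

Reads are assigned to a parental genome by the rule: unmapped if both
mapping qualities are 0, otherwise the strictly greater alignment score
wins, with equal scores ambiguous. The allelic ratio is mus/(mus + cas),
missing when both counts are zero. The gene funnel first drops genes
without usable sequence polymorphisms, then genes whose cas expression
falls strictly below the 25th percentile (type-7 linear-interpolation
quantile; ties kept). The percentile is computed on the reference-state
cas counts; the published description does not say per which sample, and
the inactive-state reference is the one state where cas expression is
unconfounded by reactivation. Absolute allelic expression multiplies bulk
counts by the ratio to correct for SNP-density bias.

All classification thresholds are strict as printed: escapees have
reference ratio > 0.14, a gene counts as reactivated at a sample once its
ratio exceeds 0.14 there, and reactivation analyses are restricted to
genes with both endpoint ratios strictly inside (0.4, 0.6). Differential
peaks are peaks with no >= 1 bp overlap with any baseline peak; per
cluster they are normalised by the end sample so the baseline maps to 0
and the end state to 1. Peaks are assigned to clusters by midpoint, genes
by TSS. Promoter accessibility sums signal x overlap over TSS +/- 2 kb.
Escapee distances are TSS-to-TSS, with escapees measured to the nearest
other escapee. Rank-sum comparisons between clusters use the unpaired
two-sided Wilcoxon test with R defaults and no multiplicity correction.

## What the generators emulate — and what they do not

`generate_contact_maps` builds the expected matrix as depth x power-law
decay (exponent 1) x compartment checkerboard (contrast 0.3 by default,
alternating segments of ~1.2 Mb, minimum 400 kb) x intra-TAD enrichment
(2x, scaled by a per-timepoint attenuation schedule 0 / 0.5 / 1 on the
inactive allele) x cross-boundary damping (0.4) for the two mega-domains,
then draws Poisson counts at 5e6 contacts per matrix and masks 5% of bins
(which then fail either the mappability or the restriction-site filter).
These defaults are the study conditions of the recovery tests. TADs nest
inside compartment segments by default so the two recoveries are not
confounded.

`simulate_cluster_matrix` plants 12 clusters drawn from 5 interaction
archetypes: short contiguous segments (6 bins = 300 kb at 50-kb bins, the
scale of real subcompartment domains) in balanced random order, an
archetype-level affinity gradient (0.1), a strong same-cluster
self-affinity (5) that makes each cluster individually identifiable, and
a small per-cluster-pair jitter (0.01), at 4e7 contacts. Two design
points matter and were fixed during development: the segment order must
be random (a periodic layout confounds genomic distance with cluster
pair and biases the decay estimate), and segments must be short (the
residual distance-composition bias in the cluster interaction means
shrinks with segment length, and with 300-kb segments it is an order of
magnitude below the archetype gradient). Eigenvalue weighting makes the
k-means feature space sensitive to unbalanced eigenvalues, so the planted
blocks are given equal sizes; with 10 restarts the global optimum is then
found reliably.

`generate_allelic_counts` draws a shared Gamma expression factor per gene
and sample and Poisson counts per allele around it, so counts are
marginally negative binomial (dispersion 0.1) while the allelic ratio
carries only sampling noise — biological expression variability hits both
alleles of a gene together, which is what makes endpoint ratios of
biallelic genes concentrate inside (0.4, 0.6) at realistic depth.
Escapees hold ratio 0.3 throughout; silenced genes sit at 0.02 and switch
to 0.5 at a planted per-gene timepoint. `generate_peak_sets` lays peaks
on a non-overlapping grid so baseline and new peaks never collide, and
accrues new peaks per cluster according to a monotone schedule.

None of the generators model translocations, copy-number changes, loop
anchors/corner peaks, trans contacts, read-level errors or mapping bias;
passing recovery tests therefore demonstrates correctness of the
estimators under the stated noise models, not robustness to artifacts
the generators do not produce.

## Problem sizes, determinism and limitations

The recovery tests run on 1,700-bin (compartments), 1,000-bin (TADs,
mixing) and 720-bin (subcompartments) chromosomes; these sizes keep every
stage's signal at the planted operating point while the whole suite runs
in well under a minute per stage. All generators and both clustering
stages are deterministic given their seed. The bundled worked fixture
(seed 42) regenerates byte-identically, and its manifest of expected
outputs is computed by independent brute-force loops at generation time;
numeric manifest comparisons allow 1e-12 for the JSON round trip of
non-terminating binary fractions, while counts, sets and timepoints are
compared exactly.

Known limitations: the first-max count threshold assumes a bimodal
row-sum distribution and over-masks clean unimodal matrices; ICE edge
inflation bows insulation near chromosome ends; the consolidation rule
and the overall-strength formula are package design choices where the
published description is qualitative; and the full-scale published
results derive from deposited sequencing data that these desk-scale
synthetic conditions do not reproduce.
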