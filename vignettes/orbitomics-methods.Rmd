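---
title: "Methods: models, parameters and design choices in orbitomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in orbitomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbitomics)
```

orbitomics implements the computational layer of a longitudinal genetics
monitoring program for short-duration spaceflight crews: relative telomere
length from monochrome multiplex qPCR (MMqPCR), cell-free DNA (cfDNA)
fragmentomics, tissue-of-origin deconvolution from transcription start site
(TSS) nucleosome footprints, panel-of-normals validation of clonal
hematopoiesis (CHIP) variants with longitudinal variant allele frequency
(VAF) tracking, and two-timepoint variant-set comparison. This vignette is
the package's own account of the underlying models, the parameters that
matter, and the design choices made where the methods literature leaves the
details open.

## Telomere quantification from MMqPCR

MMqPCR measures a telomere (T) and a single-copy albumin (A) amplicon in one
reaction. For each target we fit an ordinary least squares standard curve

$$C_q = \beta_0 + \beta_1 \log_{10}(m),$$

over a 3-fold dilution series (50 ng down to 50/81 ≈ 0.617 ng, five points,
triplicate wells), and derive the amplification efficiency
$E = 10^{-1/\beta_1} - 1$. Perfect doubling gives $\beta_1 = -1/\log_{10} 2
\approx -3.32$ and $E = 1$. Unknown wells are converted to ng-equivalents by
inverting the curve, $m = 10^{(C_q - \beta_0)/\beta_1}$, and relative
telomere length is the ratio $T/A$. Curves with $\beta_1 \ge 0$ or
$|\beta_1| < 0.5$ are rejected as degenerate rather than propagated.

Choices the protocol literature does not pin down:

* **Replicate aggregation.** Triplicate wells are aggregated by the *median*
  Cq, which tolerates one failed well; a (sample, target) whose replicate SD
  exceeds 0.5 Cq is flagged. Whether aggregation happens on the Cq or the
  quantity scale is not standardized; the median-Cq choice is applied
  uniformly and is exactly invertible in the noise-free limit.
* **Cross-plate normalization** divides every ratio by the same-plate ratio
  of a shared genomic-DNA reference sample, so the reference maps to 1.0 on
  every plate and multiplicative batch effects cancel exactly.
* **Baseline normalization.** Each subject's values are expressed as fold
  change versus the mean of a baseline phase. The default baseline is the
  pre-flight phase; a combined pre+post baseline is available
  (`baseline = "prepost"`) because display conventions differ between the
  two in practice.
* **Phase grouping.** Timepoints map to phases as pre = L-92/L-44/L-3,
  inflight = FD1–FD3, r1 = R+1, recovery = R+45/R+82 (`mission_phases()`),
  and the mapping is configurable.

Timepoint effects are tested with a one-way within-subjects ANOVA: cell
means per subject × phase, the classical partition
$SS_{total} = SS_{subjects} + SS_{time} + SS_{error}$, and
$F = MS_{time}/MS_{error}$ on $(k-1, (k-1)(n-1))$ degrees of freedom.
Sphericity is assumed (no Greenhouse–Geisser correction), matching the plain
repeated-measures ANOVA convention for this assay; unbalanced designs are an
error rather than silently imputed. Pairwise phase contrasts use the Tukey
studentized-range statistic $q = |\bar y_i - \bar y_j| / \sqrt{MS_{error}/n}$
with p-values from the studentized range distribution with $(k, df_{error})$
parameters.

## cfDNA fragmentomics

Fragment sizes are histogrammed over [50, 1000) bp in 5 bp bins;
out-of-range fragments are counted separately rather than dropped silently.
The reported mode is the most frequent raw length (ties broken to the
smallest), so a mono-nucleosomal peak reads as ~167 bp rather than a bin
midpoint.

Per-chromosome abundance uses RPKM,
$\mathrm{RPKM}_c = n_c / (L_c/10^3) / (N/10^6)$, which removes both
chromosome length and library size. Cell-free mitochondrial DNA enrichment
is $\mathrm{RPKM}_{chrM}$ divided by the *median autosomal* RPKM — the
median is robust to a single aberrant autosome, and sex chromosomes are
excluded from the denominator (but kept in the table) so that subject sex
does not shift the reference.

Group comparisons use a two-sided Wilcoxon rank-sum test. For pooled sizes
up to 12 the p-value is exact by complete enumeration of group assignments
with midranks under ties; larger samples use the normal approximation with
the standard tie-corrected variance and no continuity correction. The exact
path is implemented in the package because the usual implementations decline
to compute exact p-values in the presence of ties, and deep-sequencing
summary statistics tie routinely.

## TSS nucleosome footprints and tissue of origin

cfDNA fragments protect roughly one nucleosome (~150–170 bp), so coverage
around a TSS carries the chromatin state of the cells that shed the DNA:
expressed genes show a nucleosome-depleted region and weak phasing, silent
genes show strong ~190 bp phased coverage. The pipeline:

1. **Coverage**: each fragment contributes to every bin of the window
   $[-W, +W]$ it overlaps (default $W = 1000$ bp, bin $b = 10$ bp);
   minus-strand genes are mirrored so bin order is always 5′→3′. Full
   interval overlap is the default; a midpoint mode would sharpen phasing
   slightly but discards the protection-length information.
2. **Neighborhood normalization**: each profile is divided by its own window
   mean, making profiles mean-1 and depth-invariant without genome-wide
   background tracks.
3. **Periodicity**: the nucleosome-band amplitude is computed from the DFT
   of (profile − 1) as the band energy $\frac{2}{N}\sqrt{\sum_{k \in B}
   |X_k|^2}$ over frequency indices whose period $Nb/k$ falls in the band
   (default [160, 210] bp, bracketing canonical mono-nucleosome spacing).
   The energy form was chosen over the band-mean of single-bin magnitudes
   because a tone at a non-integer cycle count (e.g. 190 bp in a 2000 bp
   window) leaks across adjacent bins: summing band energy recovers the tone
   amplitude to within ~8%, whereas the bin average underestimates it by
   about half. For an integer-cycle tone the estimator is exact.
4. **Correlation and ranking**: amplitudes are correlated (Pearson) across
   genes with each tissue's $\log(x+1)$ expression from a reference matrix;
   genes with fewer than 20 overlapping fragments are excluded, and at least
   10 shared genes are required. Contributing tissues anti-correlate
   (expression ↔ lost periodicity), so the display value is $-r$ and
   tissues are ranked by it. Per-sample pseudo-bulk expression matrices can
   be supplied in place of the tissue atlas.
5. **Clustering**: sample × tissue display matrices are clustered with Ward
   linkage (`ward.D2`) on Euclidean distances; technical replicates are
   averaged on the display scale (arithmetic mean).

## CHIP variants against a panel of normals

Deep targeted sequencing (~15,000× consensus depth) of CHIP-associated genes
yields per-locus alt/depth counts after UMI consensus collapsing: one call
per UMI family by strict majority, discarding tied families and families
below 2 reads, which suppresses the raw error rate quadratically
(empirically ≤ 5 × 10⁻⁴ at a 10⁻² read error and family size 3).

Position-specific noise is modelled by pooling 27 normal samples per locus.
Each subject pileup is tested for alt enrichment over the pool with a
one-sided Fisher exact test — the hypergeometric upper tail of the 2×2
table, computed in closed form — and Bonferroni-corrected over the family
$m = \text{loci} \times \text{samples tested in the run}$, a deliberately
conservative family definition since the literature leaves it open.
Variants passing in at least one sample are *rescued* at every other
timepoint of that subject at the nominal 0.05 level (no correction at the
rescue stage: the discovery stage already controls the family-wise error,
and rescue only annotates an already-validated variant's trajectory).
Trajectories carry Wilson 95% score intervals, which remain sensible at
VAFs near zero where Wald intervals collapse.

VAF stability across timepoints is tested as homogeneity of proportions in
the 2×k alt/ref table: an exact conditional (multivariate hypergeometric)
enumeration ordered by the chi-square statistic when the total alt count is
≤ 10, and the chi-square approximation otherwise. At mission depth the
approximation is well calibrated (empirical size 5% ± 2% at α = 0.05) and a
VAF doubling of 0.05 → 0.10 is rejected essentially always.

Variant-set comparison between two timepoints uses `(chrom, pos, ref, alt)`
as variant identity; annotation strings (taken as given from upstream
annotation) are *not* part of identity, so one variant with two consequence
terms counts as two (variant, annotation) pairs but one shared variant.
Records are first subset to clean biallelic SNVs (single-base ref and alt,
positions with more than one alt allele in the same set removed); filters
that need alignment-level evidence (repeat context, read quality, position
bias) are out of scope. Severity uses the Ensembl consequence ordering
(VEP ~release 107), shipped as a constant, rank 1 most severe.

## The synthetic-data generator

The generator produces every input the analyses consume, with the
statistical structure the analyses assume, so recovery can be tested end to
end without sequencing data. It is first-class, tested code — not a fixture.

* **Genome**: 4 chromosomes of 2–5 Mb plus chrM at its true 16,569 bp.
  Real-genome sizes are configuration, not code; the small default keeps
  every test in seconds-to-minutes.
* **Expression reference**: each tissue receives a block of marker genes
  with shifted log-normal expression (meanlog 3 vs 0 background, sdlog 0.5),
  emulating a tissue-specific expression atlas.
* **Fragments**: midpoints around each TSS follow the intensity
  $(1 + a_g\cos(2\pi d/p))(1 - c_g e^{-d^2/2\sigma^2})$ with period
  $p = 190$ bp, NDR width σ = 75 bp, phasing $a_g = A(1 - e_g)$ and central
  depletion $c_g = A e_g$, where $e_g$ is the rank-normalized
  mixture-weighted expression of gene $g$ and $A$ is
  `phasing_amplitude_max` (default 0.6). The rank transform encodes only the
  direction of the expression–periodicity relationship without assuming a
  scale; tying both footprint features to the single knob $A$ guarantees
  that $A = 0$ yields statistically flat coverage, a property the test suite
  checks by goodness of fit. Lengths are normal (167 ± 10 bp) truncated at
  50 bp by resampling; minus-strand genes are mirrored. Coordinates are
  0-based half-open (BED) throughout the generator; the pileup/variant world
  is 1-based (VCF), with conversion explicit at the boundary.
* **Pileups**: consensus-level alt counts are drawn directly as
  $\mathrm{Bin}(d, e)$ background and $\mathrm{Bin}(d, v + e(1-v))$ at clone
  loci (clone and error additive on the non-clonal fraction), with defaults
  $d = 15{,}000$, $e = 10^{-3}$, 27 normals that never carry clones.
  Read-level UMI families are simulated only where the consensus collapser
  itself is under test.
* **qPCR plates**: $C_q = \beta_0 - \log_{10}(m)/\log_{10}(1+E) +
  \mathcal N(0, \sigma)$ with per-target efficiencies (default 0.9),
  standards at the five 3-fold masses, triplicate wells, an optional plate
  shift and an on-plate reference sample. Default Cq noise 0.05.
* **Chromosome counts**: chrM reads are binomial at `mt_fraction`; the rest
  multinomial proportional to chromosome length.

What the generator does *not* emulate: GC and mappability bias, fragment
sequence content, tissue-specific fragment-length shifts, UMI family-size
distributions, PCR duplicates and index hopping, or inter-locus error-rate
variation in the panel. Passing recovery tests therefore demonstrates the
correctness and statistical calibration of the analysis code under the
stated model, not robustness to every artefact of real cfDNA or targeted
sequencing data. In-flight dried-blood-spot noise characteristics are not
publicly established; the defaults are chosen for testability.

## Numerical choices and degenerate inputs

* All generators route randomness through a seed-restoring helper; a fixed
  seed gives bitwise-identical tables.
* The ANOVA returns $F = 0, p = 1$ when $SS_{time} = 0$ (including the
  all-equal table where $MS_{error}$ is also 0), and $F = \infty, p = 0$
  when only $MS_{error}$ vanishes.
* Fisher p-values come from `phyper` directly; `alt = 0` gives exactly 1.
* Exact enumerations (Wilcoxon ≤ 12 pooled observations, VAF stability ≤ 10
  total alt reads) use a 10⁻⁹ statistic tolerance when comparing against the
  observed value to absorb floating-point ties.
* Ward heights are non-decreasing by construction; clustering rejects NaN
  input instead of propagating it.
* Degenerate qPCR curves (non-negative or near-zero slope), missing plate
  references, subjects without baseline, unbalanced ANOVA designs, windows
  not divisible by the bin width, empty Fourier bands, zero-variance score
  vectors and low-coverage profiles all raise typed errors.

## Problem sizes used in the shipped checks

The packaged property checks run the deconvolution recovery at 3 tissues ×
300 genes × 200,000 fragments over 20 seeds with a 4-point mixture sweep;
the CHIP error/power simulations at 100 loci × 4 subjects × 6 timepoints,
depth 15,000, panel of 27, 200 seeds; the VAF-stability calibration at 1,000
seeds; and the qPCR recovery at 100 simulated plates. These sizes were
chosen so that the full suite completes in a few minutes on a single core
while keeping Monte-Carlo error well inside the asserted margins.

## Known limitations

* Deconvolution reports correlation rankings, not quantitative mixture
  proportions.
* The panel of normals is assumed clean; no leave-one-out contamination
  handling.
* No GC correction, no per-bin copy number, no BAM/FASTQ parsing in the
  core — fragment tables and pileups are the interface.
* Consequence severity is a static ordering; it does not track Ensembl
  releases at runtime.
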