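---
title: "Element-level PAV analysis with pavkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Element-level PAV analysis with pavkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pavkit)
```

## The problem

In eukaryotic pangenome studies built on the map-to-pan strategy, each
sample's short reads are aligned to a linear pangenome and the presence or
absence of a genomic region in that sample is inferred from how much of the
region its reads cover. Classical analyses use whole genes as the unit,
which is blind to partial losses: a deleted exon, CDS segment, UTR or
promoter-proximal interval leaves the gene-level coverage high enough to be
called "present". pavkit performs the same coverage-based calling at the
level of genic *elements* — exons, CDS, UTRs, and fixed-width
upstream/downstream bins — as well as arbitrary BED-defined target regions,
and then carries the resulting binary presence/absence (PAV) matrix through
the standard downstream analyses: pangenome classification, pan/core
growth-curve estimation, gene-family roll-up, and phenotype association.

## Coverage model

For a region $r$ of length $L_r$ and sample $s$, per-base depth $d_i$ is
computed from the aligned blocks of reads passing the filters (mapped,
primary, non-duplicate, non-QC-fail, MAPQ $\ge$ `mapq_min`, default 0).
Bases under read deletions (CIGAR `D`) and splice gaps (`N`) are *not*
counted: coverage means aligned-base support. Soft-clipped read ends do not
contribute either, since they are not aligned blocks. The coverage fraction
is

$$C_{r,s} = \frac{\#\{i : d_i \ge m\}}{L_r}, \qquad m = \texttt{min\_depth} \ (\text{default } 1).$$

$C$ is monotone non-increasing in $m$. Coverage values are rounded to 4
decimals when profiles are built and written, and all equality comparisons
downstream (notably neighbor merging) happen at that precision. Alongside
BAM input, a 3-column per-base depth table (chrom, 1-based position, depth)
is accepted; the two routes are exactly equivalent and are tested against a
brute-force per-base interval-stabbing count on fixtures up to 10 kb.

Parent rows of type `gene` are evaluated over the whole gene span (introns
included — the gene-region coverage a practitioner expects), while BED
"region" parents made of discontinuous intervals are aggregated over the
union of their member intervals so annotation gaps do not dilute coverage.

## Element derivation

GFF3 is read 1-based inclusive and converted once, at the parsing boundary,
to 0-based half-open coordinates used everywhere internally and in BED
output; this keeps a single conversion point and matches each format's
native dialect. For each gene the package emits the gene body,
per-transcript exons, CDS, and UTRs, plus `upstream_bins` (default 10)
flanking bins of `bin_width` (default 100 bp) on each side — the
100 bp × 10 layout commonly used for promoter-proximal scans. Where a GFF
lacks explicit UTR features but has CDS, UTRs are derived as exon minus
CDS, assigned 5'/3' by strand; GFF files vary too much to rely on explicit
UTR rows. Elements contributed by several transcripts with identical
(start, end, type) are consolidated into one record listing all
contributors; partially overlapping elements stay distinct, since only
exact duplicates are redundant. Ranks run 5'→3' in gene orientation (exon 1
of a minus-strand gene is the rightmost), matching biological numbering;
flank bins are numbered nearest-to-gene = 1, which keeps "the 501–600 bp
upstream bin" readable as rank 6 regardless of strand. Flanks are clipped
to `[0, chrom_length)` and dropped when clipping empties them, so
coordinates can never go negative.

Six representative-transcript modes control which transcripts contribute
elements: `longest_cds`, `longest_exon`, `longest_transcript`,
`highest_coverage` (requires a first coverage pass), `all`, and `gene_body`
(no sub-elements). Ties in the single-transcript modes break
deterministically to the lexicographically smallest transcript id.

## PAV calling

**Fixed threshold.** Present iff $C_{r,s} \ge t$. The boundary case is
resolved as *present*: coverage exactly at the user's threshold is treated
as meeting it. Typical thresholds in published analyses are 0.5 for
plant cohorts and 0.8 for stringent human tumor analyses; the package
defaults to 0.5.

**Adaptive threshold.** Per region, the coverage values across samples are
split into two clusters by exact one-dimensional 2-means: an exhaustive
breakpoint scan over the sorted values minimising within-cluster sum of
squares. This is deterministic — no random initialisation, unlike general
k-means — and optimal for $k = 2$ in 1-D. The higher cluster is called
present. When all values are equal, or the two cluster means are closer
than `min_gap` (default 0.1), the region is called all-present: a gap that
small is indistinguishable from sampling noise in coverage fractions, and
forcing a split would fabricate absences in unimodal rows. The split point
(midpoint between the clusters) is recorded per row for provenance. We fix
the cluster count at two because the calling target is binary; rows with
genuinely multimodal coverage will be split at their widest
variance-reducing boundary.

Rows that come out all-absent are retained in the matrix; the downstream
classification marks them `absent_everywhere` and the growth-curve and
association stages exclude them explicitly, which keeps the bookkeeping in
one place.

**Gene families.** A family is present in a sample iff any member gene is
present (logical OR). Members absent from the matrix are ignored with a
warning; families with no resolvable member are dropped.

## Pangenome classification and growth curves

With $m$ = number of samples carrying the region and $N$ the cohort size:
core ($m = N$), private ($m = 1$), softcore
($\lceil f \cdot N \rceil \le m < N$ with `softcore_fraction` $f = 0.99$ by
default), distributed (all other $m \ge 1$), `absent_everywhere` ($m = 0$).
The private rule is checked before the softcore rule; the two can only
collide in cohorts so small that $\lceil f N \rceil \le 1$, where "exactly
one carrier" is the more informative label. The categories are exclusive
and exhaustive by construction, which the test suite asserts on random
fixtures.

Growth curves are estimated by resampling: for each repetition one random
permutation of the samples is drawn, and for every $n$ the first $n$
samples of that permutation form the subset; pan = regions present in at
least one member, core = regions present in all members. A permutation
prefix is a uniformly distributed without-replacement subset at every $n$,
so the per-$n$ means are unbiased, and nesting makes pan non-decreasing and
core non-increasing along each repetition's chain — the qualitative shape a
growth curve must have, and a property we assert for every repetition. We
chose nested prefixes over independent per-$n$ subsets for exactly that
within-repetition monotonicity; the cost is a positive correlation between
points of one repetition, so dispersion bands should be read per-$n$.
The sampled means are validated against exhaustive enumeration over all
$\binom{N}{n}$ subsets on toy matrices and against the analytic expected
accumulation curve (`vegan::specaccum(method = "exact")`) on larger random
fixtures. Grouped estimation runs the same procedure inside each sample
group.

## Phenotype association

Only regions that vary in the cohort are informative, so core and
absent-everywhere rows are skipped by default. Samples missing a trait are
dropped per test, never imputed.

**Discrete traits** are tested with Fisher's exact test on the 2 × k table
of presence/absence against trait levels. For k = 2 the conditional
(hypergeometric) distribution is enumerated directly; for k > 2 all tables
with the observed margins are enumerated when the total is at most 200,
otherwise a seeded Monte Carlo estimate over `r2dtable` draws (100,000
replicates, reported as such) is used. The two-sided p-value sums the
probabilities of tables no more probable than the observed one, with a
relative tie tolerance of $10^{-7}$ guarding against floating-point
equality — the same convention the standard implementations use. A zero
margin makes the table degenerate; p is reported as 1 with a flag.

**Continuous traits** are tested with the Wilcoxon rank-sum test comparing
trait values between the presence and absence groups. The published
description of this step is ambiguous between comparing *coverage* and
comparing *phenotype values* across PAV groups; comparing phenotype values
is the biologically meaningful reading and is the default, and
`continuous_mode = "coverage"` exposes the other reading rather than
guessing silently. For combined sizes up to 30 the exact null distribution
of the rank sum is computed by dynamic programming over doubled midranks,
so ties are handled exactly; the two-sided p is twice the smaller tail,
capped at 1 (hence two identical groups give p = 1). Beyond 30 samples, a
normal approximation with tie correction and continuity correction is
used and agrees with `stats::wilcox.test` to numerical precision.

Benjamini–Hochberg adjustment (via `stats::p.adjust`) is applied per trait
across testable regions; untestable regions (empty PAV group, degenerate
table) are flagged and excluded from the adjustment so they cannot dilute
it. The reported effect summary — difference in presence fraction between
extreme trait levels, or difference in group medians — is descriptive
plumbing for the plots, not an inferential quantity.

### Calibration fixture design

The null-calibration check (fraction of raw p < 0.05 under independent
phenotypes) needs a cohort in which Fisher's exact test is not dominated by
discreteness: at 20 samples its null rejection rate at $\alpha = 0.05$ is
only ≈ 0.02, an intrinsic property of the exact test, not an
implementation artifact. A pre-test calculation showed ≈ 0.047 at 100
samples with Bernoulli(0.5) presence and Bernoulli(0.5) group labels, so
the calibration fixture uses 1,000 regions × 100 samples with those
conditions for both tests.

## The synthetic-cohort generator

`cohort_spec()` defines the study conditions; the defaults are the
validation conditions used throughout: 20 samples × 50 genes, each gene
3 exons × 300 bp with 200 bp introns and 100 bp terminal UTRs, 10 × 100 bp
flanking bins, genes alternating strand every 4 kb on one chromosome,
background depth 20×, half the genes eligible for deletion, per-sample
whole-gene deletion rate 0.3 and per-bin flank deletion rate 0.02 — values
chosen once as a plausible mid-range for distributed-gene frequencies in
published plant pangenomes. Gene 1 carries a second transcript duplicating
two exons, so consolidation is always exercised.

Deletion units are whole gene spans and individual flank bins. Because
every derived element is then either fully inside a deleted interval or
fully intact, each coverage value is exactly 0 or 1 under deterministic
tiling and the truth PAV matrix is unambiguous — this is what makes the
end-to-end check exact (zero discordant cells) rather than statistical,
and what makes adaptive calling provably agree with the fixed threshold on
this fixture. Deterministic tiling (evenly spaced, error-free reads; or
constant-depth tables in depth mode) is the default; a Poisson mode
(per-base depths or read counts with mean `background_depth`) supports
statistical tests. Depth-table output bypasses BAM writing and is exactly
equivalent on the coverage side; BAM mode writes genuine sorted, indexed
BAMs through the same readers used for real data.

Phenotypes: one discrete trait tracks the PAV of the most balanced variable
gene with a 0.05 label-confusion rate; one continuous trait is
$10 + 3 \cdot \text{presence} + \mathcal{N}(0, 1)$ (a 3-standard-deviation
shift, i.e. a strong planted effect); one null discrete and one null
continuous trait are independent of everything.

What the generator does **not** emulate: sequencing errors, mappability
and repeat structure, GC bias, partial element truncations, copy-number
gains, or alignment artifacts at deletion breakpoints. Passing the
truth-recovery check therefore demonstrates the correctness of the
bookkeeping (coordinates, coverage counting, thresholding) — not robustness
of PAV calling on noisy real alignments, where threshold choice and
alignment artifacts remain the user's responsibility.

## Numerical and degenerate-input choices

* Coverage precision: 4 decimals in profiles and TSVs; merging compares at
  that precision and concatenates rank labels (`"2-4"`); merging is
  idempotent.
* Fixed-threshold equality counts as present; adaptive split records its
  cut point per row.
* Fisher tie tolerance $10^{-7}$ relative; enumeration limit 200; Monte
  Carlo $10^5$ replicates with a $(h+1)/(B+1)$ estimate so p is never 0.
* Wilcoxon exact limit $n_1 + n_2 \le 30$; doubled midranks keep the DP
  integral under ties.
* Zero-length regions are rejected at construction; chromosome-edge flanks
  are clipped, empty ones dropped; a chromosome missing from a BAM or
  depth table yields an all-zero depth vector with a warning.
* All resampling and Monte Carlo paths take explicit seeds, recorded in
  outputs; batch reruns with the same configuration and seed are
  byte-identical, which the suite asserts via checksums.

## Validation problem sizes

The test suite validates: truth recovery and adaptive/fixed agreement on
the default 20 × 50 cohort (≈ 29,000 matrix cells); coverage against
brute-force pileup on fixtures up to 10 kb; Fisher against full
margin-constrained enumeration on every 2×2 table with total ≤ 30 and
every 2×3 table with total ≤ 12 plus 300 random larger tables, at
$10^{-12}$; Wilcoxon against full $\binom{N}{n_1}$ permutation enumeration
for all group splits with $N \le 10$, at $10^{-12}$; growth curves against
exhaustive subset enumeration on 4-sample matrices and the analytic
accumulation curve on 10-sample matrices; and null calibration on 1,000
regions × 100 samples. These sizes were chosen to make every oracle exact
or tightly bounded while keeping the suite fast on a laptop.

## Known limitations

* CRAM input, BigWig export and GC-bias correction are out of scope.
* The adaptive caller fixes $k = 2$; true multi-modal coverage (e.g.
  copy-number series) is collapsed to presence/absence.
* No covariate adjustment, population-structure correction or kinship
  modelling in the association stage; significant hits in structured
  cohorts need external confirmation.
* Interactive HTML reports and genome-browser integration are deliberately
  absent; the plotting functions emit static images with sidecar TSVs so
  every rendered number is machine-checkable.
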