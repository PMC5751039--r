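---
title: "Population-scale read-depth CNV detection: models and design choices"
author: "cnvpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-scale read-depth CNV detection: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Copy number variants (CNVs) leave a dosage signature in whole-genome
resequencing: a heterozygous deletion halves the local read depth, a
duplication raises it by half, and so on. Turning that signal into reliable
population-level calls is hard for three reasons that this package is built
around:

1. **Fragmented, gap-rich assemblies.** Livestock, crop and draft genomes
   carry thousands of scaffolds and assembly gaps. Depth in gap windows is
   an artifact, and per-scaffold processing must cost nothing.
2. **Segmental duplications (SDs) and multi-mapping.** Reads from a
   duplicated locus map ambiguously and the aligner smears them across all
   assembly copies, so raw depth underestimates the true ("absolute") copy
   number — and misassembled (false) duplications produce phantom
   heterozygous-deletion signals.
3. **Population genotyping.** Individual depth thresholds alone are noisy;
   frequency, cross-sample correlation and mixture-model genotyping turn
   per-window evidence into integer copy numbers comparable across samples.

`cnvpop` implements the whole chain — per-sample window depth, absolute /
GC / sex corrections, normalization, multi-criteria CNVR discovery,
Gaussian-mixture genotyping to VCF — plus a synthetic-population simulator
and evaluation metrics, so every step is testable without external data.

## Window grid

The reference (all sequences, scaffolds included) is cut into overlapping
sliding windows of `window_size` bases with a step of exactly half the
window, 0-based half-open. Windows with more than 50 % N bases are removed,
but the *index space is the pre-filter enumeration*: depth vectors and the
duplicated-window record stay aligned no matter how many windows the gap
filter removes. Trailing partial windows are dropped — depth statistics on
truncated windows are biased and a partial window adds at most half a
window of blind spot per scaffold.

Window size trades resolution against counting noise. As a rule of thumb
800-bp windows suit ×5–10 coverage, 400 bp suits ×20, and 200 bp suits ×50;
the package exposes the choice and never enforces it. Only N/n bases count
as gap; soft-masked (lowercase) sequence is ordinary sequence.

## Per-sample depth and the correction chain

Depth is the number of reads whose **alignment center** falls in the
window; both mates of a pair count independently, and reads failing the
`0x504` mask (unmapped, secondary, duplicate) never count. The center of
the 0-based half-open aligned span `[s, e)` is `floor((s + e) / 2)`; with
the half-window step each center lands in exactly two windows (one at the
chromosome edges).

Corrections are applied in a fixed order, because each is defined in terms
of the previous stage:

1. **Absolute copy number correction.** Windows whose sequences align at
   ≥ 97 % identity are linked in a *duplicated-window record*; the raw
   depths of linked windows are summed. Smearing a locus's reads over its
   assembly copies conserves their total, so the sum restores the absolute
   copy number regardless of how many copies the assembly has. Windows with
   more than 20 similar loci are treated as low-complexity: they stay in
   the grid (deleting them would punch holes into region assembly) but are
   left self-linked, i.e. uncorrected.
2. **GC correction.** Each window's depth is scaled by
   `mean(depth | GC = 40%) / mean(depth | GC = bin)`, with 1 % GC bins on
   the window GC fraction. Bins holding fewer than `min_bin_windows`
   (default 100) windows borrow the nearest populated bin. The bias model
   is fitted per sample, so cohorts mixing platforms are corrected sample
   by sample; windows in the 40 % bin are fixed points by construction.
   Bin means are computed over all windows, candidate CNV windows included
   — at realistic CNV rates the contamination of a 1 % bin is negligible.
3. **Sex chromosome correction.** If the sample's median depth on the
   user-named X/Z chromosome is below 0.6× its median on the remaining
   placed chromosomes, the sample is called heterogametic and its
   sex-chromosome depths are doubled. Unplaced scaffolds are never
   corrected — which is precisely why X-origin scaffolds later surface as
   high-frequency CNVRs. The autosomal median is taken jointly over all
   placed non-sex chromosomes, not averaged per chromosome.
4. **Normalization.** All depths are divided by the genome-wide median, so
   copy number 2 sits at 1.0. The median (not the mean) is used because
   the majority of the genome is copy-normal and the median is unmoved by
   CNV tails.

The normalized profile is written as a small per-sample text file (header
plus one row per window at full float precision), so population assembly
never re-touches alignments and samples can be processed independently and
in parallel.

### The duplicated-window similarity search

The record is built from *nonoverlapping* windows: each window is seeded
with exact 16-mers (one every 100 bp) matched genome-wide, and every
candidate locus is verified by full-window gap-free identity
(matches / window size, forward strand only — the simulator's and the
method's target duplications are direct repeats). Hits are assigned to the
nonoverlapping window containing their midpoint. The nonoverlapping links
are transferred to the overlapping analysis grid by shifting each partner
by the query's offset inside its covering nonoverlapping window(s) and
taking the union; this mapping is an approximation (a partner shifted by up
to half a window still lies inside the duplicate for any locus longer than
a couple of windows), and region-level copy numbers use the median over
member windows, which absorbs the boundary windows it slightly miscorrects.

## Population CNVR discovery

Profiles are stacked into a samples × windows matrix. A window is an
**individual candidate** for a sample when its normalized depth is both

* beyond the sample's genome-wide mean ± 2 SD, and
* beyond the empirical heterozygous bounds 0.65 (loss) / 1.35 (gain);

depths below 0.25 / above 1.75 are homozygous candidates outright. For
strictly self-bred species the empirical bounds are replaced by the
homozygous 0.25 / 1.75 bounds. The per-sample genome-wide mean/SD (rather
than per-window statistics across samples) is the chosen reading of the
individual criterion; it keeps the criterion meaningful for small cohorts
and is configurable in principle by pre-standardizing the matrix.

**Population selection** keeps windows with alternative allele frequency
≥ 0.05 — counted as (het + 2·hom) / (2N), ordinary diploid allele counting
— or at least 2 homozygous carriers; optionally every window with a single
carrier can be retained for small high-coverage cohorts. A **correlation
criterion** then requires each candidate to correlate (Pearson across
samples, Student *t* at *P* = 0.01, positive direction) with an adjacent
nonoverlapping candidate window — "adjacent nonoverlapping" meaning two
grid steps, i.e. one full window, away. Zero-variance columns (e.g. all
samples homozygously deleted) have no defined correlation and are kept;
membership then relies on the run rule alone.

**Regions** are runs of more than 4 sequential candidate windows (span ≥ 5),
tolerating at most one unselected window in any four consecutive positions
(never two in a row); tolerated windows are excluded from region depth.
Windows removed by the gap filter break runs. Adjacent regions are then
**merged** when the gap between them is smaller than 20 % of their combined
length *and* their per-sample region depths are significantly positively
correlated — this is what stitches regions fragmented by assembly gaps,
and the positive-direction requirement keeps anti-correlated neighbours
(distinct events) apart. The sweep is strictly left-to-right and repeats
to a fixpoint, which makes the result independent of call order. A region
whose carriers include both losses and gains is labelled `mixed` and
genotyped as multi-allelic.

## Genotyping

A sample's copy number in a region is first estimated as **2 × the median
normalized depth over the region's member windows**. The estimates of all
samples are then clustered with a **truncated stick-breaking
Dirichlet-process Gaussian mixture** fitted by variational EM: Beta
posteriors on the stick fractions (concentration α = 1, truncation at 10
components), point estimates for component means and variances, and a
deterministic quantile initialization so a fixed seed gives a fixed answer.
After convergence, components below the weight floor `1/(10 n)` are pruned
and components whose means lie within 0.25 CN of a heavier one are merged
(0.25 being half the smallest copy-number separation worth genotyping),
with a short EM polish after each edit — the truncated variational fit
happily parks several components on one well-separated cluster, and the
merge step is what turns that into one component per copy-number class.

Integer copy numbers are assigned **per component**: every member of a
cluster receives the rounded (half-up, floored at 0) component mean, so
genotypes are cluster-coherent by construction. Clustering quality is the
mean silhouette width over the assignment (1-D Euclidean distance),
reported in the VCF `SIL` field but never used to drop calls — no
silhouette cutoff is imposed; filtering is the user's decision. A
single-component region is flagged `single-cluster` with an undefined
silhouette. Regions are genotyped independently with seed `base + k`, so
any execution order (or parallel schedule) yields identical output.

The VCF (4.2) uses symbolic ALTs (`<DEL>`, `<DUP>`, both for mixed), INFO
`END/SVTYPE/SVLEN/AF/SIL` and `GT:CN` per sample. GT is derived from CN
only where the biallelic reading is unambiguous (loss with CN ≤ 2; gain
with CN in 2–4); anything else gets `./.` with CN carried, which keeps
multi-allelic regions representable without inventing phase.

## The simulator

The simulator generates the study conditions the package is validated
under, at desk scale:

* **Reference**: i.i.d. uniform random sequence (5 Mb by default) with
  nonoverlapping planted events: `assembled_SD` (a 5-kb donor duplicated
  in tandem — the reference carries both copies), `collapsed_SD` (the
  reference keeps one copy while every individual's genome is recorded as
  duplicated), polymorphic deletions/duplications with an allele
  frequency, optional N-gap runs, optional sex chromosome.
* **Genotypes**: polymorphic events sampled under Hardy–Weinberg at the
  event's frequency; SD events assigned a uniform copy number in 2–6 per
  individual; trios drawn parent-first with one transmitted allele each,
  Mendelian by construction.
* **Counts**: Poisson per half-window bin at rate
  `coverage/read_length × step × m`, where `m` is CN/2 inside ordinary
  events and collapsed SDs, CN/4 over both copies of an assembled SD
  (multi-mapping splits reads evenly between identical copies), and 0 over
  gaps. Window counts are sums of adjacent bins, so overlapping windows
  share signal exactly as read-center counting would. ×20 coverage of
  copy-normal sequence is the default. Optionally the same draws are
  emitted as minimal single-end SAM records whose recomputed centers land
  in the same bins, making the SAM counting path testable end to end.

What the simulator deliberately does **not** model: sequencing errors,
GC-dependent fragmentation (a GC bias curve can be switched on, but is off
by default), mapping-quality structure, inverted or diverged duplications,
and breakpoints off the window lattice's resolution. Passing tests on this
generator therefore demonstrates the *algorithmic* contracts — conservation
under smearing, threshold behaviour, Mendelian consistency — not robustness
to platform artifacts on real data.

## Numerical choices and degenerate inputs

* Correlation on fewer than 4 samples (t-test df < 2) is skipped; the
  criterion simply does not apply to such cohorts.
* Zero-variance depth columns are "correlation-failing" everywhere a
  correlation is asked for, and undefined correlations are never
  significant.
* GC bins with no populated neighbour at all raise an error instructing a
  different reference bin rather than silently scaling by garbage.
* Mixture variances are floored at `max(1e-6, var(x)·1e-6)`; component
  means tie-break by rounding half-up.
* The merge sweep and region scan are strictly left-to-right, making
  results independent of input order; sample order only permutes outputs.
* All randomness (simulator, genotyping) flows from explicit integer
  seeds; regenerating any artifact from the same seed is bit-identical.

## Validation scale

The packaged checks run the full chain on: the scaled SD design (5 Mb, 20
tandem 5-kb SDs, 30 individuals at copy number 2–6, ×20 coverage, 400-bp
windows), a 5-Mb / 30-sample population with twelve planted 5-kb CNVs at
allele frequency 0.2 plus a matched CNV-free null genome (800-bp windows),
fifty 100-sample mixture-genotyping regions with cluster σ = 0.1, and ten
simulated trios pushed through detection, genotyping and Mendelian
scoring. These sizes keep a complete run in tens of seconds while leaving
every per-window statistic comfortably out of the small-sample regime.

## Known limitations

* Breakpoints are window-quantized; no sub-window refinement is attempted.
* The similarity search is forward-strand and gap-free; highly diverged or
  inverted duplications will not be linked (the >97 % identity regime it
  targets is also where multi-mapping smearing actually happens).
* Single-sample CNV calling is out of scope — the criteria are population
  criteria by design.
* The Mendelian score covers biallelic losses and gains up to copy number
  4; mixed/multi-allelic regions are reported but not scored.
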