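---
title: "Quantifying a global reduction in cohesin binding: models, defaults and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying a global reduction in cohesin binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cohesinscape)
```

# Scope

`cohesinscape` analyzes an isogenic two-condition ChIP-seq experiment —
wild-type cells versus cells with a partially disabled cohesin-loading
pathway (the Nipbl-haploinsufficiency situation of Cornelia de Lange
syndrome) — and asks three questions: where does cohesin bind, how much is
binding reduced genome-wide, and how does the reduction map onto gene
expression and chromatin contacts. This vignette records the models, every
tunable that matters, the numerical conventions, and what the synthetic
validation does and does not establish.

# The peak-calling model

Single-end reads arrive as one or more candidate alignments each (an
aligner reporting all best hits in repeats). The generative model is a
mixture: the genome carries K enriched regions, region $i$ emitting reads
at rate $\lambda_i$ per bp, and background emitting at $\lambda_0$; each
read originated from exactly one of its candidate alignments.

* **Candidate regions** come from a greedy merge: all alignments sorted by
  position, merged while the gap (end-to-next-start) is at most `max_gap`
  (default 100 bp), regions with fewer than `min_reads` supporting
  alignments dropped. The merge is an explicit, parameterized approximation
  of windowing schemes whose published parameters are not available.
* **EM.** E-step: the weight of alignment $k$ of read $j$ is proportional
  to the rate at its location ($\lambda_i$ inside region $i$, else
  $\lambda_0$), renormalized so each read's weights sum to 1; uniquely
  mapping reads keep weight 1. M-step: $C_i=$ summed weights in region $i$,
  $\lambda_i = C_i/w_i$, and $\lambda_0$ = residual mass over the
  non-region genome, floored at one read per genome. Initialization is
  uniform per read (maximum entropy). Iteration stops when the largest
  per-alignment weight change drops below `tol` (default 1e-3) or at
  `max_iter` (default 100; the state is then flagged, not an error). The
  observed-data log-likelihood $\sum_j \log \sum_k \lambda(x_{jk})$ (minus
  a constant) is recorded per iteration and is non-decreasing.
* **Scoring.** $p_i = P(X \ge \mathrm{round}(C_i))$ for
  $X \sim \mathrm{Poisson}(\lambda_0 w_i)$. Rounding puts fractional
  EM-weighted counts onto the integer support; summits are the leftmost
  maximum of weighted coverage, and output ordering (p-value, then
  coordinate) is deterministic, so runs are bit-reproducible.
* **FDR.** The control (preimmune IgG) library is processed by the
  identical pipeline, independently; the empirical FDR at threshold $t$ is
  $N_{ctl}(t)\,(D_{smp}/D_{ctl}) / \max(N_{smp}(t),1)$ with depths counted
  in reads. The default calling threshold is $p < 10^{-4}$.

**Why `min_reads` defaults to 7.** At the default background density
(~0.003 reads/bp, see below) a chance clump of 5–6 reads spans so little
sequence that $\lambda_0 w$ is far below 1 and its Poisson tail already
clears $10^{-4}$; a support floor below the smallest count that can ever be
called only inflates the control peak count. Seven is the smallest count
reaching the calling threshold under that background rate; with it the
control-relative FDR sits near 2%, matching the regime reported for the
original experiment, while recovery of peaks of strength ≥ 20 expected
reads is unaffected (it is 100% across seeds). Both `min_reads` and
`max_gap` remain exposed parameters.

# The synthetic experiment

The generator builds a miniature isogenic study with known truth:

* 3 chromosomes × 1 Mb, 60 non-overlapping genes (3–7 exons, CDS inset so
  UTR windows exist), 120 planted peaks with summits ≥ 700 bp apart, zone
  fractions promoter/gene-body/downstream/intergenic = 15/25/10/50%,
  strengths (expected WT reads) log-uniform on [5, 200], two thirds of
  peaks carrying an embedded consensus of a synthetic 12-bp CTCF-like PWM.
* One pair of identical 2-kb repeat blocks; one peak sits at the center of
  one copy, at the geometric-mean strength (≈ 32) so it is representative.
  Reads falling inside a block are emitted with one alignment per copy.
* Libraries: per-peak reads are Poisson with mean $s_i$ (WT),
  $f\,s_i$ (mutant, default $f = 0.65$), 0 (preimmune); the remainder of
  each library is uniform background. Read midpoints are jittered uniformly
  within ±150 bp of the summit — a flat approximation of a ~200–400 bp
  sonication fragment window, with no explicit fragment-size model.
* Library sizes default to 9,000 reads each. This was chosen to match the
  genome-wide read density of the real libraries being emulated (several
  million aligned reads over a ~2.6 Gb genome ≈ 0.003 reads/bp), because
  that density — not the raw read count — controls the Poisson null, the
  background clustering behavior, and the control FDR. Library sizes are
  equal across conditions by default; under the absolute-strength read
  model above, the RPKM ratio at peak bins then equals $1/f$ exactly, which
  is what makes the reduction factor identifiable from bin ratios. A
  ~15% shallower mutant library (as in the real design) is available via
  `total_reads_mut` and is exercised by the depth-matched subsampling
  analysis.
* Expression: 10 WT and 9 mutant replicates; linear intensities
  $2^{(b + \delta + \varepsilon)}$ with baselines $b \sim U(8, 14)$ (so
  nearly all values fall inside the 300–20,000 analysis window), noise
  $\varepsilon \sim N(0, 0.25^2)$ per replicate, and mutant shifts
  $\delta$: bound genes are shifted down with probability 0.74 and up with
  0.26, by 0.8 log₂ units; unbound genes are shifted with probability 0.3
  (split evenly), because dysregulation is biased toward, not exclusive
  to, bound genes. 0.8 log₂ at 0.25 noise puts typical shifted genes
  comfortably past the 1.2-fold / p < 0.05 cutoffs with 10 + 9 replicates,
  a plausible microarray effect size.
* 3C: band intensity = frequency × primer efficiency × lognormal noise;
  control-template bands (equimolar ligation products) carry efficiency ×
  noise. Default band noise is 0.05 (log scale), the repeatability of gel
  densitometry; two biological × three technical replicates mirror the
  real design. Truth files (peaks, repeats, labels) are first-class TSV
  outputs, so evaluation never reaches into generator internals.

# Binding-reduction estimators

`bin_log_ratios()` tiles the genome into 100-bp bins, counts EM weights per
bin (multi-mapping reads therefore count once), converts to RPKM, and
reports log₂(WT/mutant) over bins with reads in both conditions (bins empty
in either are excluded and counted; the log of zero is undefined). The mean
over bins restricted to peak intervals gives $\hat f = 2^{-\text{mean}}$.
Two small-sample biases partially cancel: zero-truncation of low-count bins
pulls ratios toward 1, while the concavity of the log pulls them apart;
at the default depths the estimator lands within ±0.05 of $f = 0.65$
averaged over seeds. `subsample_and_call()` draws reads (not alignments)
without replacement so multi-mapping reads travel whole.

# Annotation conventions

Windows are strand-aware: on a − gene, "upstream" means larger coordinates,
and the TSS is `end − 1` under the package-wide 0-based half-open
convention. Precedence is fixed: promoter, 5′UTR, intron, exon, 3′UTR,
downstream, intergenic, tested globally across genes (a peak in gene A's
intron and gene B's promoter is promoter). When CDS coordinates are
annotated, "exon" means *coding* exon: UTRs are themselves exonic, so
without that reading the 3′UTR category (tested after intron and exon)
would be unreachable. UTR windows drop the 500 bp adjacent to the TSS/TTS,
which the promoter/downstream windows already cover; without CDS
annotation the UTR categories are skipped and flagged, never silently
merged. The random baseline places length-matched intervals uniformly
(chromosome ∝ length, uniform start, clipped) with no GC or mappability
matching, and enrichment is observed% over the mean random%.

# Motif analysis

Scores are $\sum_p \log_2\frac{p_{p,b} + c}{q_b + c}$ with pseudocount
$c = 10^{-3}$ applied at score time on both PWM and background, maximized
over windows and both strands; windows containing N are void. Because the
pseudocount makes scores an affine transform of any other convention,
absolute thresholds are never copied between analyses: the threshold is
always re-calibrated as the smallest score whose frequency among random
200-bp genomic regions is at most the target FDR (default 4.7%,
n = 1000). The hypergeometric enrichment treats peaks + random regions as
the population and peak sequences as the draw.

# KS running enrichment

$D(r) = (\#\text{bound with rank} \le r)/B - r/N$; $d = D(r^\*)$ at the
rank maximizing $|D|$ (leftmost on ties); $d > 0$ means bound genes
concentrate at the top of the given ranking. Two ranking modes: *signed*
(fold change ascending: most downregulated first) and *absolute*
(|log₂ FC| descending); ties break by gene id for determinism. The p-value
uses the asymptotic Kolmogorov distribution with effective sample size
$B$ — no exact formula is claimed for this statistic, so a permutation
p-value (`n_perm`) is provided as the reference alternative. At
$B = 100, N = 2000$ the nominal 0.05 level realizes a type-I error of
≈ 0.04 over 1000 null simulations; as $B/N$ grows toward 1 the
approximation turns conservative (the true null is the finite-population
two-sample statistic scaled by $1 - B/N$).

The pipeline's own differential-expression step is a plain Welch t
(optionally with permutation p-values), provided as plumbing for synthetic
runs; analyses of real microarray data should feed their moderated
statistics (fold change, p) directly into `build_target_table()`, which
only does accounting: significance = p below threshold and fold change
beyond 1.2 in either direction, up/down exclusive rows, region columns
non-exclusive, with bound-of-changed and down-of-bound percentages.

# 3C quantification

$\text{frequency} = \frac{\text{test}/\text{template}}
{\text{test}_{ref}/\text{template}_{ref}}$, replicate-wise: the template
division cancels primer efficiency, the reference (constitutive
interaction) division cancels sample-wide factors; any single
multiplicative factor (gel exposure, input amount, efficiency) leaves the
frequency invariant. Technical replicates are averaged within biological
replicates before testing, to avoid pseudo-replication; the condition
comparison is a Welch t-test (the original figure legends name no test;
this choice is ours, with a permutation option).

# Problem sizes and determinism

Validation runs use the default desk-scale conditions above: full-pipeline
properties over 10 seeds, subsampling at 100 replicates, motif and
annotation baselines at n = 1000, KS calibration over 1000 null and 100
planted simulations. Every random step takes an explicit seed; one global
seed fans out to per-stage seeds through a fixed affine map
(`derive_seed`), so a stage can be re-run in isolation and reproduce its
slice of a full run; identical seeds give byte-identical outputs.

# What the synthetic validation shows — and does not

Passing tests establish that the implementations recover what they plant:
the caller's FDR behaves against a true null control, EM rescues peaks
inside duplicated sequence that unique-read calling misses, the bin-ratio
estimator recovers a planted global reduction within ±0.05, the calibrated
motif threshold realizes its target FDR out of sample, the KS statistic is
calibrated and powerful at realistic effect sizes, and the 3C arithmetic
is exact under its invariances. They do **not** show that real data meet
the generator's assumptions: real backgrounds are non-uniform (chromatin
accessibility, mappability), fragment-size distributions are not flat,
repeats are families rather than perfect pairs, microarray noise is not
homoscedastic lognormal, and real binding reductions need not be a single
global factor.

Two desk-scale caveats deserve emphasis. First, 120 peaks over 60 genes
saturates the bound-gene fraction (~75% of genes end up cohesin-bound),
so the end-to-end KS p-value on the default run is weak by construction —
the statistic's calibration and power are demonstrated where the contrast
exists (1000 genes, 100 bound). Second, the share of peaks lost by the
mutant (~12% at $f=0.65$) depends on how much of the strength distribution
sits near the calling threshold, and is therefore not comparable to
genome-scale percentages; the reduction *factor*, not the peak-count drop,
is the transferable quantity.
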