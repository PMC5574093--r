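# cohesinscape

Differential cohesin ChIP-seq analysis with EM peak calling, expression
integration, and chromosome-conformation (3C) quantification.

## The problem

NIPBL loads the cohesin ring onto chromatin. Heterozygous loss of *NIPBL* —
the most common cause of Cornelia de Lange syndrome — reduces Nipbl by only
~30%, yet produces wide-ranging developmental defects. The working model is
that a *global, partial* reduction of cohesin binding preferentially
weakens gene activation at cohesin-bound genes (especially at promoters),
partly by loosening promoter–enhancer contacts. Testing that model requires
a pipeline that can (i) call binding sites from ChIP-seq reads **including
multi-mapping reads in repeats**, (ii) quantify a genome-wide *reduction*
in binding rather than a redistribution, (iii) relate binding to expression
change with a rank statistic, and (iv) normalize 3C band intensities into
interaction frequencies. `cohesinscape` implements that pipeline for
analysts working with isogenic WT / mutant designs, together with a
synthetic-experiment generator with planted ground truth so every stage can
be validated quantitatively.

## The methods at the core

* **EM peak caller.** Reads (each with one or more candidate alignments)
  are clustered into candidate regions by a greedy merge (gap ≤ `max_gap`).
  The data are modeled as K enriched regions plus background: region *i*
  has Poisson rate λᵢ = Cᵢ/wᵢ and the rest of the genome rate λ₀. The
  E-step sets alignment weights ∝ the rate at their location (renormalized
  per read); the M-step re-estimates Cᵢ as summed weights and λ₀ from the
  residual mass. Regions are scored with the Poisson upper tail
  P(X ≥ round(Cᵢ)) under X ~ Poisson(λ₀·wᵢ), and an empirical FDR is taken
  relative to an independently processed preimmune-IgG control:
  FDR(t) = N_ctl(t)·(D_smp/D_ctl)/max(N_smp(t),1).
* **Binding-reduction quantification.** Depth-matched subsampled peak
  counts; overlap classification (common / WT-only); per-100-bp-bin
  log₂(RPKM_WT/RPKM_mut) histograms whose mean, restricted to peak bins,
  estimates the global reduction factor as 2^(−mean); rank-ordered
  tag-density matrices; peak-width summaries.
* **Annotation.** Strand-aware windows (promoter = 2500 bp upstream /
  500 bp downstream of the TSS; downstream = 500/2500 around the TTS) with
  the fixed precedence promoter → 5′UTR → intron → exon → 3′UTR →
  downstream → intergenic, and enrichment against 1000 length-matched
  random placements.
* **Motif scoring.** PWM log-odds scanning (both strands, pseudocount
  1e-3) of 200-bp summit sequences; the score threshold is calibrated to a
  target FDR (default 4.7%) on random genomic regions; enrichment is a
  hypergeometric upper tail.
* **KS running enrichment.** With genes ranked by expression fold change
  and a bound/unbound flag per gene, D(r) = (#bound ≤ r)/B − r/N; the
  statistic d is D at the rank maximizing |D|, with an asymptotic
  Kolmogorov p-value (effective n = B) and a permutation alternative.
* **3C normalization.** frequency = (test/control-template) /
  (reference test/reference control-template), cancelling primer
  efficiencies and sample-wide factors; conditions are compared by Welch
  t-test on biological replicates after technical averaging.

## Worked example

```r
library(cohesinscape)

run <- run_all(pipeline_config(), seed = 1)
round(run$report[c("wt_peak_count", "mut_peak_count",
                   "reduction_factor_estimate", "percent_down_of_bound",
                   "c3_ratio_mut_over_wt")], 3)
#>             wt_peak_count             mut_peak_count
#>                   114.000                    100.000
#> reduction_factor_estimate      percent_down_of_bound
#>                     0.698                     71.739
#>      c3_ratio_mut_over_wt
#>                     0.431
```

Read it as: from a synthetic isogenic experiment with 120 planted peaks and
a true mutant binding-reduction factor f = 0.65, the caller finds 114 WT
peaks and 100 mutant peaks (weak sites drop below the calling threshold in
the mutant); the peak-bin log-ratio estimator recovers the planted
reduction (0.70 vs 0.65 true, within its small-sample bias); 71.7% of
significantly changed cohesin-bound genes are downregulated (74% planted);
and the normalized 3C interaction ratio reflects the planted halving of a
promoter–enhancer contact (0.43 vs 0.5 true with two biological
replicates). Individual stages are available as plain functions
(`call_peaks()`, `bin_log_ratios()`, `assign_region()`, `calibrate_fdr()`,
`ks_running_enrichment()`, `build_target_table()`,
`normalize_interaction()`, …); the methods vignette
(`vignettes/cohesin-binding-pipeline.Rmd`) documents the models, defaults
and limitations.

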