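# End-to-end orchestration of the synthetic experiment and every analysis
# stage, from a single config and a single seed. Stage seeds are derived
# from the global seed with a fixed affine map, so any stage can be re-run
# in isolation and reproduce its part of a full run. Ground-truth files are
# consulted only by the evaluation fields of the report, never by the
# analysis stages themselves.

#' Full pipeline configuration
#'
#' Extends [sim_config()] with the analysis parameters of every stage,
#' defaulting to the study's printed values where one exists: peak p-value
#' cutoff 1e-4, 100-bp bins, 4-kb density windows, 1000 random-placement
#' replicates, 200-bp summit sequences, motif target FDR 4.7%, fold-change
#' cutoff 1.2 with p < 0.05, promoter window 2500/500 bp and downstream
#' window 500/2500 bp around TSS/TTS.
#'
#' @param ... named overrides.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- c(sim_config(), list(
    p_threshold = 1e-4, max_gap = 100, min_reads = 7,
    bin = 100, density_window = 4000, density_bins = 50,
    reps_subsample = 100, reps_random = 1000,
    summit_width = 200, target_fdr = 0.047, n_random_motif = 1000,
    fold_threshold = 1.2, expr_p_threshold = 0.05,
    n_wt_reps = 10, n_mut_reps = 9,
    effect = list(p_down = 0.74, p_up = 0.26, p_unbound = 0.3, size = 0.8),
    expr_noise_sd = 0.25,
    c3_noise_sd = 0.05, c3_true_ratio = 0.5, c3_n_bio = 2, c3_n_tech = 3
  ))
  over <- list(...)
  sim_names <- names(sim_config())
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  # re-validate the simulation slice
  do.call(sim_config, cfg[sim_names])
  cfg
}

validate_pipeline_config <- function(config) {
  required <- names(pipeline_config())
  missing_f <- setdiff(required, names(config))
  if (length(missing_f)) {
    stop("config missing field(s): ", paste(missing_f, collapse = ", "),
         call. = FALSE)
  }
  with(config, {
    stopifnot(p_threshold > 0, p_threshold < 1, max_gap >= 0,
              min_reads >= 1, bin > 0, density_window %% 2 == 0,
              density_window %% density_bins == 0, reps_subsample >= 1,
              reps_random >= 1, summit_width > 0, target_fdr > 0,
              target_fdr < 1, fold_threshold > 0, expr_p_threshold > 0,
              n_wt_reps >= 2, n_mut_reps >= 2,
              effect$p_down + effect$p_up <= 1, c3_noise_sd >= 0,
              c3_true_ratio > 0)
  })
  invisible(config)
}

#' Run the complete pipeline on a synthetic experiment
#'
#' Simulates the genome and the three libraries (WT, mutant, preimmune),
#' calls peaks for WT and mutant against the preimmune control, quantifies
#' the binding reduction (peak counts, depth-matched subsampled counts,
#' peak-bin log-ratios, width medians), annotates WT peaks with the
#' precedence rule and a random baseline, calibrates the motif threshold
#' and scores summits, simulates and integrates expression (KS running
#' enrichment, target-gene table), and runs the 3C normalization on a
#' simulated band-intensity table. Deterministic given `seed`.
#'
#' @param config list from [pipeline_config()].
#' @param seed global integer seed.
#' @param out_dir optional directory; when given, intermediate tables and a
#'   `report.tsv` of headline numbers are written there.
#' @param sequence generate genome sequence and run the motif stage (the
#'   only stage that needs sequence).
#' @return List of stage results plus `report`, a named numeric vector of
#'   headline quantities.
#' @export
run_all <- function(config = pipeline_config(), seed = 1, out_dir = NULL,
                    sequence = TRUE) {
  validate_pipeline_config(config)
  sim_names <- names(sim_config())
  scfg <- do.call(sim_config, config[sim_names])
  sim <- simulate_genome(scfg, seed = seed, sequence = sequence)
  truth <- sim$truth
  sizes <- truth$chrom_sizes

  wt <- simulate_chip_reads(truth, "WT", seed = seed)
  mut <- simulate_chip_reads(truth, "mutant", seed = seed)
  pre <- simulate_chip_reads(truth, "preimmune", seed = seed)

  wt_call <- call_peaks(wt, pre, sizes, p_threshold = config$p_threshold,
                        max_gap = config$max_gap,
                        min_reads = config$min_reads)
  mut_call <- call_peaks(mut, pre, sizes, p_threshold = config$p_threshold,
                         max_gap = config$max_gap,
                         min_reads = config$min_reads)
  wt_peaks <- wt_call$peaks
  mut_peaks <- mut_call$peaks

  cls <- classify_peaks(wt_peaks, mut_peaks)
  depth_mut <- length(unique(mut$read_id))
  sub <- subsample_and_call(wt_call$sample_state$aln, depth_mut, sizes,
                            reps = config$reps_subsample,
                            p_threshold = config$p_threshold,
                            max_gap = config$max_gap,
                            min_reads = config$min_reads, seed = seed)
  ratio_peakbins <- bin_log_ratios(wt_call$sample_state$aln,
                                   mut_call$sample_state$aln, sizes,
                                   bin = config$bin,
                                   restrict = truth$peaks)
  ratio_genome <- bin_log_ratios(wt_call$sample_state$aln,
                                 mut_call$sample_state$aln, sizes,
                                 bin = config$bin)
  widths_wt <- peak_width_stats(wt_peaks, bin = config$bin)
  widths_mut <- peak_width_stats(mut_peaks, bin = config$bin)

  fmap <- build_feature_map(sim$genes, sizes,
                            promoter_up = config$promoter_up,
                            promoter_down = config$promoter_down,
                            downstream_up = config$downstream_up,
                            downstream_down = config$downstream_down)
  annot <- region_distribution(wt_peaks, fmap)
  enrich <- random_baseline(wt_peaks, fmap, reps = config$reps_random,
                            seed = seed)

  motif <- NULL
  if (sequence) {
    cal <- calibrate_fdr(truth$pwm, sim$genome, target = config$target_fdr,
                         n_random = config$n_random_motif,
                         width = config$summit_width, seed = seed)
    seqs <- extract_summit_sequences(wt_peaks, sim$genome,
                                     width = config$summit_width)
    hits <- scan_peaks(seqs, truth$pwm, cal$threshold,
                       fdr = cal$fdr_at_threshold)
    n_rand_hits <- sum(cal$scores >= cal$threshold)
    motif <- list(calibration = cal, hits = hits,
                  enrichment_p = motif_enrichment(sum(hits$has_motif),
                                                  nrow(hits), n_rand_hits,
                                                  length(cal$scores)))
  }

  labels <- truth_gene_labels(truth, sim$genes)
  ex <- simulate_expression(labels, n_wt = config$n_wt_reps,
                            n_mut = config$n_mut_reps,
                            effect = config$effect,
                            noise_sd = config$expr_noise_sd, seed = seed)
  de <- differential_expression(ex$expr)
  flags <- assign_bound_flags(sim$genes, wt_peaks, region = "all",
                              promoter_up = config$promoter_up,
                              promoter_down = config$promoter_down,
                              downstream_up = config$downstream_up,
                              downstream_down = config$downstream_down)
  fc <- stats::setNames(de$fold_change, de$gene_id)
  ranked <- rank_genes(fc, "signed")
  bound_by_gene <- stats::setNames(flags$gene_region, sim$genes$gene_id)
  ks <- ks_running_enrichment(bound_by_gene[ranked])
  targets <- build_target_table(de, flags,
                                fold_threshold = config$fold_threshold,
                                p_threshold = config$expr_p_threshold)

  interactions <- data.frame(
    pair_id = c("reference", "promoter_enhancer"),
    freq_wt = c(1, 1), freq_mut = c(1, config$c3_true_ratio),
    is_reference = c(TRUE, FALSE), stringsAsFactors = FALSE)
  c3_raw <- simulate_3c(interactions, noise_sd = config$c3_noise_sd,
                        n_bio = config$c3_n_bio, n_tech = config$c3_n_tech,
                        seed = seed)
  c3_norm <- collapse_technical(normalize_interaction(c3_raw))
  pe <- c3_norm[c3_norm$pair_id == "promoter_enhancer", ]
  c3_cmp <- compare_conditions(pe$frequency[pe$sample == "mutant"],
                               pe$frequency[pe$sample == "WT"])

  report <- c(
    wt_peak_count = nrow(wt_peaks),
    mut_peak_count = nrow(mut_peaks),
    peak_count_reduction_pct = 100 * (1 - nrow(mut_peaks) /
                                        max(nrow(wt_peaks), 1)),
    wt_fdr = wt_call$fdr_estimate,
    mut_fdr = mut_call$fdr_estimate,
    subsampled_wt_mean_peaks = sub$mean,
    common_peaks = unname(cls$counts["common_a"]),
    wt_only_peaks = unname(cls$counts["a_only"]),
    mean_log2_ratio_peak_bins = ratio_peakbins$mean,
    reduction_factor_estimate = 2^(-ratio_peakbins$mean),
    mean_log2_ratio_genome = ratio_genome$mean,
    median_width_wt = widths_wt$median,
    median_width_mut = widths_mut$median,
    promoter_enrichment = enrich$enrichment[enrich$category == "promoter"],
    intergenic_percent = annot$percent[annot$category == "intergenic"],
    ks_d = ks$d, ks_p = ks$p_value,
    n_significant_genes = targets$n_significant,
    n_bound_significant = targets$n_bound,
    percent_bound = targets$percent_bound,
    percent_down_of_bound = targets$percent_down_of_bound,
    c3_ratio_mut_over_wt = c3_cmp$ratio, c3_p = c3_cmp$p_value)
  if (!is.null(motif)) {
    report <- c(report,
                motif_threshold = motif$calibration$threshold,
                motif_fdr = motif$calibration$fdr_at_threshold,
                percent_peaks_with_motif = 100 *
                  mean(motif$hits$has_motif),
                motif_enrichment_p = motif$enrichment_p)
  }

  out <- list(sim = sim, wt_call = wt_call, mut_call = mut_call,
              classify = cls, subsample = sub,
              ratio_peakbins = ratio_peakbins, ratio_genome = ratio_genome,
              annotation = annot, enrichment = enrich, motif = motif,
              expression = ex, de = de, flags = flags, ks = ks,
              targets = targets, c3 = list(normalized = c3_norm,
                                           comparison = c3_cmp),
              report = report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_simulation(sim, out_dir)
    write_bed(cbind(wt_peaks[c("chrom", "start", "end")],
                    name = sprintf("wt_peak_%d", seq_len(nrow(wt_peaks))),
                    score = wt_peaks$expected_count),
              file.path(out_dir, "wt_peaks.bed"))
    write_bed(cbind(mut_peaks[c("chrom", "start", "end")],
                    name = sprintf("mut_peak_%d", seq_len(nrow(mut_peaks))),
                    score = mut_peaks$expected_count),
              file.path(out_dir, "mut_peaks.bed"))
    utils::write.table(data.frame(quantity = names(report),
                                  value = unname(report)),
                       file.path(out_dir, "report.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
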