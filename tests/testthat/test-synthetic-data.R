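small_cfg <- function(...) {
  sim_config(n_chrom = 2, chrom_len = 4e5, n_genes = 12, n_peaks = 24,
             total_reads_wt = 2500, total_reads_mut = 2500,
             total_reads_preimmune = 2500, ...)
}

test_that("the generator is deterministic given a seed", {
  a <- simulate_genome(small_cfg(), seed = 5)
  b <- simulate_genome(small_cfg(), seed = 5)
  expect_identical(a$truth$peaks, b$truth$peaks)
  expect_identical(as.character(a$genome), as.character(b$genome))
  expect_identical(a$genes, b$genes)
  c <- simulate_genome(small_cfg(), seed = 6)
  expect_false(identical(a$truth$peaks, c$truth$peaks))

  r1 <- simulate_chip_reads(a$truth, "WT", seed = 9)
  r2 <- simulate_chip_reads(a$truth, "WT", seed = 9)
  expect_identical(r1, r2)

  # layout identical whether or not sequence is generated
  d <- simulate_genome(small_cfg(), seed = 5, sequence = FALSE)
  expect_identical(a$truth$peaks, d$truth$peaks)
  expect_null(d$genome)
})

test_that("motif_fraction = 1 embeds the consensus at every planted peak", {
  sim <- simulate_genome(small_cfg(motif_fraction = 1), seed = 2)
  expect_true(all(sim$truth$peaks$has_motif))
  cons <- cohesinscape:::pwm_consensus(sim$truth$pwm)
  seqs <- extract_summit_sequences(sim$truth$peaks, sim$genome, width = 40)
  expect_true(all(grepl(cons, seqs, fixed = TRUE)))
})

test_that("repeat block copies are byte-identical in sequence", {
  sim <- simulate_genome(small_cfg(), seed = 4)
  rp <- sim$truth$repeats
  expect_equal(nrow(rp), 1)
  s1 <- Biostrings::subseq(sim$genome[[rp$chrom1]], rp$start1 + 1,
                           rp$start1 + rp$length)
  s2 <- Biostrings::subseq(sim$genome[[rp$chrom2]], rp$start2 + 1,
                           rp$start2 + rp$length)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("reads inside repeats carry one alignment per identical copy", {
  sim <- simulate_genome(small_cfg(), seed = 4, sequence = FALSE)
  rp <- sim$truth$repeats
  aln <- simulate_chip_reads(sim$truth, "WT", seed = 4)
  n_per_read <- table(aln$read_id)
  multi <- aln[aln$read_id %in% names(n_per_read)[n_per_read > 1], ]
  expect_gt(nrow(multi), 0)
  in_block <- function(a) {
    (a$chrom == rp$chrom1 & a$start >= rp$start1 &
       a$end <= rp$start1 + rp$length) |
      (a$chrom == rp$chrom2 & a$start >= rp$start2 &
         a$end <= rp$start2 + rp$length)
  }
  expect_true(all(in_block(multi)))
  expect_equal(as.numeric(tapply(multi$weight, multi$read_id, sum)),
               rep(1, length(unique(multi$read_id))), tolerance = 1e-12)
  # any read fully inside a block must have been mirrored
  uniq <- aln[aln$read_id %in% names(n_per_read)[n_per_read == 1], ]
  expect_false(any(in_block(uniq)))
})

test_that("f = 1 at equal depth gives per-peak count ratios near 1", {
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_genome(small_cfg(f = 1), seed = s, sequence = FALSE)
    wt <- simulate_chip_reads(sim$truth, "WT", seed = s)
    mut <- simulate_chip_reads(sim$truth, "mutant", seed = s)
    tp <- sim$truth$peaks
    cw <- cohesinscape:::count_overlaps(tp, wt)
    cm <- cohesinscape:::count_overlaps(tp, mut)
    sum(cm) / sum(cw)
  }, numeric(1))
  # binomial error on ~ total peak reads per seed
  expect_equal(mean(ratios), 1, tolerance = 0.03)
})

test_that("preimmune reads show no enrichment at planted peaks", {
  enr <- vapply(1:20, function(s) {
    sim <- simulate_genome(small_cfg(), seed = s, sequence = FALSE)
    pre <- simulate_chip_reads(sim$truth, "preimmune", seed = s)
    tp <- sim$truth$peaks
    mids <- floor((pre$start + pre$end) / 2)
    mid_df <- data.frame(chrom = pre$chrom, start = mids, end = mids + 1)
    in_peaks <- sum(cohesinscape:::overlaps_any(mid_df, tp))
    frac_genome <- sum(tp$end - tp$start) / sum(sim$truth$chrom_sizes)
    (in_peaks / nrow(pre)) / frac_genome
  }, numeric(1))
  expect_equal(mean(enr), 1, tolerance = 0.15)
})

test_that("zero requested reads yields an empty library", {
  sim <- simulate_genome(small_cfg(), seed = 1, sequence = FALSE)
  expect_equal(nrow(simulate_chip_reads(sim$truth, "WT", total_reads = 0,
                                        seed = 1)), 0)
})

test_that("expression simulation honors effect configuration", {
  labs <- data.frame(gene_id = sprintf("g%03d", 1:200),
                     bound = rep(c(TRUE, FALSE), each = 100))
  ex1 <- simulate_expression(labs, seed = 3)
  ex2 <- simulate_expression(labs, seed = 3)
  expect_identical(ex1, ex2)

  # no effect: WT and mutant gene means agree up to replicate noise
  ex0 <- simulate_expression(labs, effect = list(p_down = 0, p_up = 0,
                                                 p_unbound = 0, size = 0),
                             noise_sd = 0.1, seed = 7)
  wt <- rowMeans(log2(ex0$expr[, grep("^wt_", names(ex0$expr))]))
  mut <- rowMeans(log2(ex0$expr[, grep("^mut_", names(ex0$expr))]))
  expect_lt(max(abs(wt - mut)), 0.35)
  expect_true(all(ex0$truth$direction == "none"))

  # deterministic downregulation of every bound gene at large effect
  exd <- simulate_expression(labs, effect = list(p_down = 1, p_up = 0,
                                                 p_unbound = 0, size = 2),
                             noise_sd = 0.1, seed = 7)
  wt <- rowMeans(log2(exd$expr[, grep("^wt_", names(exd$expr))]))
  mut <- rowMeans(log2(exd$expr[, grep("^mut_", names(exd$expr))]))
  expect_true(all(mut[labs$bound] < wt[labs$bound]))
  expect_error(simulate_expression(labs, effect = list(p_down = 0.8,
                                                       p_up = 0.3,
                                                       p_unbound = 0,
                                                       size = 1)),
               "exceed 1")
})

test_that("3C simulation is deterministic and proportional when noiseless", {
  inter <- data.frame(pair_id = c("ref", "pairA", "pairB"),
                      freq_wt = c(1, 2, 0.5), freq_mut = c(1, 1, 0.5),
                      is_reference = c(TRUE, FALSE, FALSE))
  a <- simulate_3c(inter, efficiencies = c(ref = 1, pairA = 3, pairB = 0.5),
                   noise_sd = 0, seed = 2)
  b <- simulate_3c(inter, efficiencies = c(ref = 1, pairA = 3, pairB = 0.5),
                   noise_sd = 0, seed = 2)
  expect_identical(a, b)
  # noiseless: test intensity = frequency x efficiency exactly
  wtA <- a[a$pair_id == "pairA" & a$sample == "WT", ]
  expect_true(all(wtA$test_intensity == 2 * 3))
  expect_true(all(wtA$template_intensity == 3))
  expect_error(simulate_3c(inter, efficiencies = -1), "positive")
  expect_error(simulate_3c(inter[2:3, ]), "reference")
})
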