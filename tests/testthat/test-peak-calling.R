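two_chrom <- c(chr1 = 1e5, chr2 = 1e5)

test_that("greedy merge respects the gap rule and the support floor", {
  aln <- mk_aln("chr1", c(100, 150, 900), len = 36)
  r <- build_candidate_regions(aln, max_gap = 200, min_reads = 1)
  expect_equal(nrow(r$regions), 2)
  expect_equal(r$regions$start, c(100, 900))
  expect_equal(r$regions$end, c(186, 936))
  expect_equal(r$regions$n_align, c(2L, 1L))

  r <- build_candidate_regions(aln, max_gap = 1e6, min_reads = 1)
  expect_equal(nrow(r$regions), 1)

  r <- build_candidate_regions(aln, max_gap = 200, min_reads = 3)
  expect_equal(nrow(r$regions), 0)
  expect_true(all(is.na(r$region_of)))

  # chromosomes never merge
  aln2 <- mk_aln(c("chr1", "chr2"), c(100, 100))
  r <- build_candidate_regions(aln2, max_gap = 1e6, min_reads = 1)
  expect_equal(nrow(r$regions), 2)

  expect_equal(nrow(build_candidate_regions(aln[0, ])$regions), 0)
})

test_that("EM with unique reads converges immediately to raw counts", {
  aln <- mk_aln("chr1", c(100, 120, 140, 5000, 5020))
  reg <- build_candidate_regions(aln, max_gap = 100, min_reads = 2)
  st <- run_em(aln, reg, genome_size = 1e5)
  expect_equal(st$iterations, 1)
  expect_true(st$converged)
  expect_equal(st$regions$expected_count, c(3, 2))
  expect_equal(st$aln$weight, rep(1, 5))
})

test_that("a torn multi-mapping read shifts toward the denser region", {
  # region 1: 9 unique reads; region 2: 1 unique read; equal widths;
  # one read with an alignment in each
  s1 <- seq(1000, 1160, by = 20)        # 9 reads spanning 196 bp
  s2 <- seq(50000, 50160, by = 20)[1:9]
  aln <- cohesinscape::alignments(
    read_id = c(sprintf("u%02d", 1:9), "v01", "m", "m"),
    chrom = "chr1",
    start = c(s1, 50000, 1080, 50080),
    end = c(s1, 50000, 1080, 50080) + 36)
  # force equal-width regions by stretching the lone unique read so both
  # regions span 196 bp
  aln$end[aln$read_id == "v01"] <- 50196
  reg <- build_candidate_regions(aln, max_gap = 300, min_reads = 2)
  expect_equal(nrow(reg$regions), 2)
  st <- run_em(aln, reg, genome_size = 1e5, tol = 1e-10, max_iter = 500)
  w1 <- st$aln$weight[st$aln$read_id == "m" & st$aln$start == 1080]
  expect_gt(w1, 0.5)
  # matches the independent fixed-point solution of the two-region system
  W <- reg$regions$width[1]
  expect_equal(reg$regions$width[2], W)
  expect_equal(w1, two_region_fixed_point(9, 1, W, 1e5), tolerance = 1e-6)
})

test_that("tol = 1 stops after exactly one iteration", {
  aln <- cohesinscape::alignments(c("a", "m", "m"), "chr1",
                                  c(100, 120, 5000),
                                  c(136, 156, 5036))
  reg <- build_candidate_regions(aln, max_gap = 100, min_reads = 1)
  st <- run_em(aln, reg, genome_size = 1e5, tol = 1)
  expect_equal(st$iterations, 1)
})

test_that("per-read weights stay normalized through EM", {
  for (s in 1:3) {
    sim <- simulate_genome(sim_config(n_chrom = 2, chrom_len = 3e5,
                                      n_genes = 8, n_peaks = 16,
                                      total_reads_wt = 2000),
                           seed = s, sequence = FALSE)
    wt <- simulate_chip_reads(sim$truth, "WT", seed = s)
    reg <- build_candidate_regions(wt)
    st <- run_em(wt, reg, genome_size = sum(sim$truth$chrom_sizes))
    sums <- tapply(st$aln$weight, st$aln$read_id, sum)
    expect_lt(max(abs(sums - 1)), 1e-9)
    # log-likelihood is non-decreasing
    if (length(st$loglik) > 1) {
      expect_true(all(diff(st$loglik) > -1e-8))
    }
  }
})

test_that("Poisson scoring matches direct series summation", {
  # expected_count 5 against lambda0 * width = 1
  reg <- list(regions = data.frame(region_id = 1L, chrom = "chr1",
                                   start = 0, end = 100, width = 100,
                                   n_align = 5L))
  aln <- mk_aln("chr1", c(0, 20, 40, 60, 64), len = 36)
  reg$region_of <- rep(1L, 5)
  st <- run_em(aln, reg, genome_size = 100)
  st$lambda0 <- 1 / 100  # fix the null at lambda0 * width = 1
  st$regions$expected_count <- 5
  pk <- score_regions(st)
  expect_equal(pk$p_value, 1 - poisson_cdf_series(4, 1), tolerance = 1e-12)
  expect_equal(pk$p_value, 0.00365984682734371, tolerance = 1e-9)

  # zero count scores 1; widening at fixed count raises p
  st$regions$expected_count <- 0
  expect_equal(score_regions(st)$p_value, 1)
  st$regions$expected_count <- 5
  p_narrow <- score_regions(st)$p_value
  st$regions$width <- 200
  expect_gt(score_regions(st)$p_value, p_narrow)

  st$lambda0 <- 0
  expect_error(score_regions(st), "positive")
})

test_that("summits sit at the leftmost maximum of weighted coverage", {
  aln <- mk_aln("chr1", c(100, 110, 120, 300, 300, 310, 500, 510), len = 36)
  reg <- build_candidate_regions(aln, max_gap = 50, min_reads = 1)
  st <- run_em(aln, reg, genome_size = 1e5)
  pk <- score_regions(st)
  expect_equal(nrow(pk), 3)
  # deepest coverage starts where the third read stacks on the first two
  expect_equal(pk$summit[1], 120)
  expect_equal(pk$summit[2], 310)
  # two-way tie across [510,536): leftmost position wins
  expect_equal(pk$summit[3], 510)
})

test_that("control-relative FDR handles degenerate configurations", {
  set.seed(1)
  bg <- mk_aln("chr1", sort(round(runif(40) * 9e4)))
  pk <- mk_aln("chr1", rep(c(95000, 95010, 95020), each = 5),
               read_id = sprintf("p%02d", 1:15))
  smp <- cohesinscape::alignments(c(bg$read_id, paste0("x", pk$read_id)),
                                  c(bg$chrom, pk$chrom),
                                  c(bg$start, pk$start),
                                  c(bg$end, pk$end))
  # control with no enrichment: zero control peaks -> FDR 0
  res <- call_peaks(smp, bg, c(chr1 = 1e5), min_reads = 5)
  expect_gt(nrow(res$peaks), 0)
  expect_equal(res$fdr_estimate, 0)
  # sample used as its own control at equal depth -> FDR 1
  res2 <- call_peaks(smp, smp, c(chr1 = 1e5), min_reads = 5)
  expect_equal(res2$fdr_estimate, 1)
  expect_error(call_peaks(smp[0, ], bg, c(chr1 = 1e5)), "nonempty")
})

test_that("unique-read calls equal the naive Poisson window oracle", {
  for (s in 1:3) {
    sim <- simulate_genome(sim_config(n_chrom = 2, chrom_len = 3e5,
                                      n_genes = 8, n_peaks = 16,
                                      repeat_pairs = 0,
                                      peak_in_repeat = FALSE,
                                      total_reads_wt = 2500),
                           seed = s, sequence = FALSE)
    wt <- simulate_chip_reads(sim$truth, "WT", seed = s)
    expect_false(anyDuplicated(wt$read_id) > 0)
    core <- cohesinscape:::peak_call_core(wt, sim$truth$chrom_sizes)
    mine <- core$scored[core$scored$p_value < 1e-4, ]
    oracle <- naive_poisson_caller(wt, sim$truth$chrom_sizes)
    expect_equal(nrow(mine), nrow(oracle))
    expect_equal(mine$chrom, oracle$chrom)
    expect_equal(mine$start, oracle$start)
    expect_equal(mine$end, oracle$end)
    expect_equal(mine$expected_count, oracle$count)
    expect_equal(mine$p_value, oracle$p_value, tolerance = 1e-9)
  }
})

test_that("planted strong peaks are recovered with a clean control FDR", {
  stats <- t(vapply(1:10, function(s) {
    sim <- simulate_genome(sim_config(), seed = s, sequence = FALSE)
    wt <- simulate_chip_reads(sim$truth, "WT", seed = s)
    pre <- simulate_chip_reads(sim$truth, "preimmune", seed = s)
    res <- call_peaks(wt, pre, sim$truth$chrom_sizes)
    strong <- sim$truth$peaks[sim$truth$peaks$strength >= 20, ]
    c(rec = mean(cohesinscape:::overlaps_any(strong, res$peaks)),
      fdr = res$fdr_estimate)
  }, numeric(2)))
  expect_gte(mean(stats[, "rec"]), 0.9)
  expect_lte(mean(stats[, "fdr"]), 0.05)
})
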