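test_that("RPKM arithmetic is as defined", {
  # 10 reads in a 500-bp region of a 1M-read library -> 20 RPKM
  expect_equal(rpkm(10, 500, 1e6), 20)
})

test_that("subsampling at full depth is degenerate and reproducible", {
  sim <- simulate_genome(sim_config(n_chrom = 2, chrom_len = 3e5,
                                    n_genes = 8, n_peaks = 16,
                                    total_reads_wt = 2000),
                         seed = 2, sequence = FALSE)
  wt <- simulate_chip_reads(sim$truth, "WT", seed = 2)
  sz <- sim$truth$chrom_sizes
  full <- cohesinscape:::peak_call_core(wt, sz)$scored
  n_full <- sum(full$p_value < 1e-4)
  sub <- subsample_and_call(wt, length(unique(wt$read_id)), sz, reps = 3,
                            seed = 1)
  expect_equal(sub$counts, rep(n_full, 3))
  expect_equal(sub$sd, 0)

  one <- subsample_and_call(wt, 1500, sz, reps = 1, seed = 9)
  two <- subsample_and_call(wt, 1500, sz, reps = 1, seed = 9)
  expect_equal(one$counts, two$counts)
  expect_error(subsample_and_call(wt, 1e6, sz), "exceeds")
})

test_that("peak overlap classification partitions exhaustively", {
  a <- genomic_intervals("chr1", c(100, 500, 900), c(200, 600, 1000))
  expect_equal(unname(classify_peaks(a, a)$counts),
               c(3, 0, 3, 0))
  b <- genomic_intervals("chr1", c(5000, 7000), c(5100, 7100))
  expect_equal(unname(classify_peaks(a, b)$counts), c(0, 3, 0, 2))
  # 1-bp overlap counts as common
  b2 <- genomic_intervals("chr1", 199, 300)
  cl <- classify_peaks(a, b2)
  expect_equal(cl$common_a, 1L)
  b3 <- genomic_intervals("chr1", 200, 300)  # abutting, zero overlap
  expect_equal(length(classify_peaks(a, b3)$common_a), 0)

  # conservation property on random sets
  set.seed(4)
  for (i in 1:5) {
    sa <- sort(sample(1e5, 30)) * 10
    sb <- sort(sample(1e5, 20)) * 10
    pa <- genomic_intervals("chr1", sa, sa + 150)
    pb <- genomic_intervals("chr1", sb, sb + 150)
    cl <- classify_peaks(pa, pb)
    expect_equal(unname(cl$counts["common_a"] + cl$counts["a_only"]), 30)
    expect_equal(unname(cl$counts["common_b"] + cl$counts["b_only"]), 20)
  }
})

test_that("bin log-ratios cancel depth and respect exclusions", {
  sz <- c(chr1 = 1e5)
  # A: 8 reads of a 1M-read library; B: 4 reads of 0.5M -> log2 ratio 0.
  # Library sizes come from distinct read ids, so park the extra depth
  # on a far-away bin.
  mk_lib <- function(n_bin, n_far, prefix) {
    cohesinscape::alignments(
      sprintf("%s%07d", prefix, seq_len(n_bin + n_far)),
      "chr1", c(rep(520, n_bin), rep(90000, n_far)),
      c(rep(556, n_bin), rep(90036, n_far)))
  }
  a <- mk_lib(8, 992, "a")
  b <- mk_lib(4, 496, "b")
  r <- bin_log_ratios(a, b, sz, bin = 100)
  bin5 <- r$bins[r$bins$start == 500, ]
  expect_equal(bin5$log2_ratio, log2((8 / 1000) / (4 / 500)))
  expect_equal(bin5$log2_ratio, 0)

  # antisymmetry
  r_ab <- bin_log_ratios(a, b, sz)
  r_ba <- bin_log_ratios(b, a, sz)
  expect_equal(r_ab$bins$log2_ratio, -r_ba$bins$log2_ratio)
  expect_equal(r_ab$mean, -r_ba$mean)

  # bins present in only one condition are excluded and counted
  a2 <- cohesinscape::alignments("x1", "chr1", 3000, 3036)
  a_plus <- rbind(a, a2)
  r2 <- bin_log_ratios(a_plus, b, sz)
  expect_equal(r2$n_excluded, 1)
  expect_false(3000 %in% r2$bins$start)

  # disjoint libraries: empty histogram flag
  r3 <- bin_log_ratios(a2, b, sz)
  expect_true(r3$empty)
})

test_that("tag density matrices center signal and sort rows", {
  sz <- c(chr1 = 1e5)
  peaks <- data.frame(chrom = "chr1", start = 49800, end = 50200,
                      summit = 50000)
  reads <- mk_aln("chr1", 50000 - 18 + round(seq(-40, 40, by = 10)))
  m <- tag_density_matrix(peaks, reads, sz, window = 4000, n_bins = 40)
  expect_equal(dim(m$matrix), c(1, 40))
  center_bins <- 20:21
  expect_equal(which.max(m$matrix[1, ]) %in% center_bins, TRUE)
  expect_equal(sum(m$matrix) * length(unique(reads$read_id)) / 1e6,
               length(unique(reads$read_id)), tolerance = 1e-9)

  # rows sorted by descending signal; sorting is idempotent
  peaks2 <- data.frame(chrom = "chr1",
                       start = c(19800, 49800), end = c(20200, 50200),
                       summit = c(20000, 50000))
  weak <- mk_aln("chr1", 20000 + round(seq(-30, 30, by = 30)),
                 read_id = sprintf("w%02d", 1:3))
  m2 <- tag_density_matrix(peaks2, rbind(reads, weak), sz,
                           window = 4000, n_bins = 40)
  expect_equal(m2$order, c(2, 1))
  expect_true(sum(m2$matrix[1, ]) >= sum(m2$matrix[2, ]))

  # anchor at a chromosome edge is truncated and flagged
  edge <- data.frame(chrom = "chr1", start = 0, end = 200, summit = 100)
  m3 <- tag_density_matrix(edge, reads, sz, window = 4000, n_bins = 40)
  expect_true(m3$truncated[1])
})

test_that("uniform background signal yields near-flat density rows", {
  sz <- c(chr1 = 2e5)
  set.seed(8)
  bg <- mk_aln("chr1", sort(round(runif(20000) * (2e5 - 36))),
               read_id = sprintf("b%05d", 1:20000))
  peaks <- data.frame(chrom = "chr1", start = seq(20000, 180000, 20000),
                      end = seq(20000, 180000, 20000) + 400)
  peaks$summit <- peaks$start + 200
  m <- tag_density_matrix(peaks, bg, sz, window = 4000, n_bins = 10)
  col_means <- colMeans(m$matrix)
  expect_lt(max(col_means) / min(col_means), 1.35)
})

test_that("peak width statistics follow the stated conventions", {
  pk <- genomic_intervals("chr1", c(0, 1000, 2000), c(300, 1500, 2700))
  ws <- peak_width_stats(pk)
  expect_equal(ws$median, 500)
  expect_equal(ws$histogram$count[ws$histogram$from == 300], 1L)
  expect_equal(sum(ws$histogram$count), 3)

  expect_equal(peak_width_stats(pk[1, ])$median, 300)
  # even count: midpoint of the central pair
  pk2 <- genomic_intervals("chr1", c(0, 1000), c(400, 1600))
  expect_equal(peak_width_stats(pk2)$median, 500)
  # left-closed binning: width 400 falls in [400,500)
  expect_equal(ws <- peak_width_stats(pk2)$histogram$count[5], 1L)
  expect_error(peak_width_stats(pk[0, ]), "no peaks")
})
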