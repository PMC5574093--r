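# Quantifying the global reduction of binding between conditions:
# depth-matched subsampled peak counts, overlap classification, 100-bp bin
# log-ratios of normalized coverage, rank-ordered tag-density matrices and
# peak-width summaries. Downstream of the caller, the counting unit is the
# fractional EM weight of each alignment, never the raw alignment count, so
# multi-mapping reads are counted once.

#' Reads-per-kilobase-per-million normalization
#'
#' @param count read (weight) count in a region.
#' @param width_bp region width in bp.
#' @param depth library size in reads.
#' @return RPKM value(s).
#' @export
rpkm <- function(count, width_bp, depth) {
  count / (width_bp / 1000) / (depth / 1e6)
}

#' Subsample a library to a target depth and re-call peaks
#'
#' Emulates the depth-matching control for peak-count comparisons: when one
#' library is shallower, the deeper one is repeatedly subsampled (without
#' replacement, at the read level, so all alignments of a multi-mapping read
#' travel together) to the same number of reads, and peaks are called from
#' each subsample alone.
#'
#' @param aln alignment data frame.
#' @param n_target reads per subsample (must not exceed library depth).
#' @param chrom_sizes named chromosome lengths.
#' @param reps number of subsampling replicates.
#' @param p_threshold,max_gap,min_reads caller parameters.
#' @param seed integer seed (replicate r uses a seed derived from it).
#' @return List: `mean`, `sd`, `counts` (peak count per replicate).
#' @export
subsample_and_call <- function(aln, n_target, chrom_sizes, reps = 100,
                               p_threshold = 1e-4, max_gap = 100,
                               min_reads = 7, seed = 1) {
  stopifnot(reps >= 1)
  ids <- unique(aln$read_id)
  if (n_target > length(ids)) {
    stop("n_target exceeds number of reads", call. = FALSE)
  }
  counts <- vapply(seq_len(reps), function(r) {
    keep <- with_seed(derive_seed(seed, 40 + r), sample(ids, n_target))
    sub <- aln[aln$read_id %in% keep, , drop = FALSE]
    scored <- peak_call_core(sub, chrom_sizes, max_gap = max_gap,
                             min_reads = min_reads)$scored
    sum(scored$p_value < p_threshold)
  }, numeric(1))
  list(mean = mean(counts), sd = stats::sd(counts), counts = counts)
}

#' Classify peaks as common or condition-specific
#'
#' A peak of set A is "common" when it overlaps any peak of set B by at
#' least `min_overlap` bp (default 1), otherwise "A only"; the partition is
#' exhaustive from A's perspective, and counts are reported from both
#' perspectives because one A peak may hit several B peaks.
#'
#' @param peaks_a,peaks_b peak data frames.
#' @param min_overlap minimum overlap in bp.
#' @return List: `common_a` / `a_only` (row indices into `peaks_a`),
#'   `common_b` / `b_only` (into `peaks_b`), and a `counts` vector.
#' @export
classify_peaks <- function(peaks_a, peaks_b, min_overlap = 1L) {
  hit_a <- overlaps_any(peaks_a, peaks_b, min_overlap)
  hit_b <- overlaps_any(peaks_b, peaks_a, min_overlap)
  list(common_a = which(hit_a), a_only = which(!hit_a),
       common_b = which(hit_b), b_only = which(!hit_b),
       counts = c(common_a = sum(hit_a), a_only = sum(!hit_a),
                  common_b = sum(hit_b), b_only = sum(!hit_b)))
}

# Weighted counts of alignment midpoints per fixed-size genomic bin.
bin_counts <- function(aln, chrom_sizes, bin) {
  chroms <- names(chrom_sizes)
  n_bins <- ceiling(chrom_sizes / bin)
  offset <- stats::setNames(cumsum(c(0, n_bins[-length(n_bins)])), chroms)
  mid <- floor((aln$start + aln$end) / 2)
  idx <- offset[aln$chrom] + floor(mid / bin) + 1
  total <- sum(n_bins)
  agg <- rowsum(aln$weight, idx)
  counts <- numeric(total)
  counts[as.integer(rownames(agg))] <- agg[, 1]
  list(counts = counts, offset = offset, n_bins = n_bins)
}

#' Histogram of per-bin log2 coverage ratios between two conditions
#'
#' Segments the genome into non-overlapping bins (default 100 bp), counts
#' the EM-weighted reads of each condition per bin, normalizes to RPKM, and
#' returns the log2(A/B) ratio for every bin with reads in both conditions
#' (bins empty in either are excluded and counted). The mean of the
#' distribution summarizes the global binding shift; restricted to bins
#' inside true or called peaks, `2^-mean` estimates the binding-reduction
#' factor.
#'
#' @param aln_a,aln_b alignment data frames (weights as counting unit).
#' @param chrom_sizes named chromosome lengths.
#' @param bin bin width in bp.
#' @param restrict optional interval data frame; only bins overlapping it
#'   are kept.
#' @return List: `bins` (data frame `chrom`, `start`, `end`, `count_a`,
#'   `count_b`, `log2_ratio`), `mean` (of log2 ratios), `n_excluded`
#'   (bins nonzero in exactly one condition).
#' @export
bin_log_ratios <- function(aln_a, aln_b, chrom_sizes, bin = 100,
                           restrict = NULL) {
  stopifnot(bin > 0)
  a <- bin_counts(aln_a, chrom_sizes, bin)
  b <- bin_counts(aln_b, chrom_sizes, bin)
  depth_a <- length(unique(aln_a$read_id))
  depth_b <- length(unique(aln_b$read_id))
  chroms <- names(chrom_sizes)
  chrom_of <- rep(chroms, a$n_bins)
  start_of <- unlist(lapply(a$n_bins, function(k) (seq_len(k) - 1) * bin),
                     use.names = FALSE)
  keep_mask <- rep(TRUE, length(a$counts))
  if (!is.null(restrict)) {
    bins_df <- data.frame(chrom = chrom_of, start = start_of,
                          end = pmin(start_of + bin, chrom_sizes[chrom_of]),
                          stringsAsFactors = FALSE)
    keep_mask <- overlaps_any(bins_df, restrict)
  }
  both <- a$counts > 0 & b$counts > 0 & keep_mask
  one <- xor(a$counts > 0, b$counts > 0) & keep_mask
  if (!any(both)) {
    return(list(bins = NULL, mean = NA_real_, n_excluded = sum(one),
                empty = TRUE))
  }
  ra <- rpkm(a$counts[both], bin, depth_a)
  rb <- rpkm(b$counts[both], bin, depth_b)
  lr <- log2(ra / rb)
  bins <- data.frame(chrom = chrom_of[both], start = start_of[both],
                     end = pmin(start_of[both] + bin,
                                chrom_sizes[chrom_of[both]]),
                     count_a = a$counts[both], count_b = b$counts[both],
                     log2_ratio = lr, stringsAsFactors = FALSE)
  list(bins = bins, mean = mean(lr), n_excluded = sum(one), empty = FALSE)
}

#' Tag-density matrix around anchor peaks
#'
#' For each anchor peak, EM-weighted read midpoints of a signal library are
#' binned across a window centered on the peak center (or summit when
#' present), normalized to reads per million of the signal library, and rows
#' are sorted by descending tag count of the designated sort track (the
#' anchors' own condition by default) -- the heatmap-style matrix used to
#' compare binding strength across conditions or against any other signal
#' track.
#'
#' @param anchor_peaks peak data frame (uses `summit` if present, else the
#'   interval center).
#' @param signal_aln alignment data frame providing the signal.
#' @param chrom_sizes named chromosome lengths.
#' @param window full window width (bp, even).
#' @param n_bins number of bins (must divide `window`).
#' @param sort_by optional numeric vector (one per anchor) to sort rows by,
#'   descending; defaults to each row's own total. `NULL` order is stable
#'   for ties.
#' @return List: `matrix` (anchors x bins, reads per million), `order`
#'   (permutation applied to anchors), `offsets` (bin start offsets),
#'   `truncated` (logical per anchor: window clipped at a chromosome end).
#' @export
tag_density_matrix <- function(anchor_peaks, signal_aln, chrom_sizes,
                               window = 4000, n_bins = 50, sort_by = NULL) {
  stopifnot(window %% 2 == 0, window %% n_bins == 0)
  n <- nrow(anchor_peaks)
  center <- if ("summit" %in% names(anchor_peaks)) anchor_peaks$summit
            else floor((anchor_peaks$start + anchor_peaks$end) / 2)
  half <- window / 2
  binw <- window / n_bins
  depth <- length(unique(signal_aln$read_id))
  truncated <- (center - half < 0) |
    (center + half > chrom_sizes[anchor_peaks$chrom])
  m <- matrix(0, nrow = n, ncol = n_bins)
  mid <- floor((signal_aln$start + signal_aln$end) / 2)
  win <- data.frame(chrom = anchor_peaks$chrom, start = center - half,
                    end = center + half)
  mids_df <- data.frame(chrom = signal_aln$chrom, start = mid,
                        end = mid + 1, stringsAsFactors = FALSE)
  win$row <- seq_len(n)
  win_clip <- clip_to_chrom(win, chrom_sizes)
  hits <- GenomicRanges::findOverlaps(as_granges(mids_df),
                                      as_granges(win_clip))
  anchor_row <- win_clip$row[S4Vectors::subjectHits(hits)]
  read_i <- S4Vectors::queryHits(hits)
  off <- mid[read_i] - (center[anchor_row] - half)
  bin_i <- pmin(floor(off / binw) + 1, n_bins)
  idx <- (bin_i - 1) * n + anchor_row  # column-major linear index
  agg <- rowsum(signal_aln$weight[read_i], idx)
  m[as.integer(rownames(agg))] <- agg[, 1]
  m <- m / depth * 1e6
  key <- if (is.null(sort_by)) rowSums(m) else sort_by
  o <- order(-key)
  list(matrix = m[o, , drop = FALSE], order = o,
       offsets = seq(-half, half - binw, by = binw),
       truncated = unname(truncated[o]))
}

#' Peak width summary
#'
#' Median width and a histogram of widths in fixed (default 100-bp)
#' left-closed bins. The median of an even-sized sample is the midpoint of
#' the central pair.
#'
#' @param peaks peak data frame (>= 1 row).
#' @param bin histogram bin width (bp).
#' @return List: `median`, `histogram` (data frame `from`, `to`, `count`).
#' @export
peak_width_stats <- function(peaks, bin = 100) {
  if (nrow(peaks) == 0) stop("no peaks", call. = FALSE)
  w <- peaks$end - peaks$start
  breaks <- seq(0, (max(w) %/% bin + 1) * bin, by = bin)
  counts <- table(cut(w, breaks = breaks, right = FALSE))
  list(median = stats::median(w),
       histogram = data.frame(from = breaks[-length(breaks)],
                              to = breaks[-1],
                              count = as.integer(counts)))
}
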