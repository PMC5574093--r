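# PWM log-odds scanning of peak-summit sequences, FDR calibration against
# random genomic regions, and a hypergeometric enrichment test. Because the
# pseudocount makes absolute log-odds values an affine transform of any
# other convention, thresholds are always calibrated on the genome at hand,
# never copied between analyses.

# Per-position log2 score matrix (L x 4) with pseudocount on both PWM and
# background.
logodds_matrix <- function(pwm) {
  pc <- pwm$pseudocount
  log2((pwm$mat + pc) / matrix(pwm$bg + pc, nrow = nrow(pwm$mat), ncol = 4,
                               byrow = TRUE))
}

# Best log-odds score over all windows of each sequence, both strands.
# Windows containing a non-ACGT base score -Inf. Sequences shorter than the
# motif are an error.
scan_best_scores <- function(seqs, pwm, both_strands = TRUE) {
  sm <- logodds_matrix(pwm)
  L <- nrow(sm)
  if (any(nchar(seqs) < L)) {
    stop("sequence shorter than motif length ", L, call. = FALSE)
  }
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  # reverse-complement scoring = scanning the forward sequence with the
  # reverse-complemented matrix
  sm_rc <- sm[L:1, 4:1, drop = FALSE]
  vapply(seqs, function(s) {
    v <- code[strsplit(toupper(s), "")[[1]]]
    n_win <- length(v) - L + 1
    best <- -Inf
    for (mat in if (both_strands) list(sm, sm_rc) else list(sm)) {
      sc <- numeric(n_win)
      for (p in seq_len(L)) {
        vi <- v[p:(p + n_win - 1)]
        col <- mat[p, ][vi]
        col[is.na(vi)] <- -Inf
        sc <- sc + col
      }
      best <- max(best, sc)
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
}

#' Best PWM log-odds score of a sequence
#'
#' `score(window) = sum over positions of log2((p_pos,base + pc) /
#' (bg_base + pc))`, maximized over all windows on both strands (the
#' reverse complement scores identically to scanning the opposite strand).
#' Windows containing `N` are excluded (score `-Inf` if no valid window).
#'
#' @param sequence character string (alphabet A, C, G, T, N).
#' @param pwm `pwm` object.
#' @param both_strands scan the reverse complement too.
#' @return Best score (possibly `-Inf`).
#' @export
logodds_score <- function(sequence, pwm, both_strands = TRUE) {
  scan_best_scores(sequence, pwm, both_strands)
}

#' Extract summit-centered sequences
#'
#' `width`-bp windows centered on each peak summit, clipped at chromosome
#' ends (clipped windows flagged).
#'
#' @param peaks peak data frame with a `summit` column.
#' @param genome `DNAStringSet`.
#' @param width window width (bp).
#' @return Character vector of sequences with attribute `clipped`
#'   (logical per peak).
#' @export
extract_summit_sequences <- function(peaks, genome, width = 200) {
  if (!all(peaks$chrom %in% names(genome))) {
    stop("peak chromosome absent from genome", call. = FALSE)
  }
  sizes <- chrom_sizes(genome)
  half <- floor(width / 2)
  start <- peaks$summit - half
  end <- start + width
  clipped <- start < 0 | end > sizes[peaks$chrom]
  start <- pmax(start, 0)
  end <- pmin(end, sizes[peaks$chrom])
  seqs <- vapply(seq_len(nrow(peaks)), function(i) {
    as.character(Biostrings::subseq(genome[[peaks$chrom[i]]],
                                    start[i] + 1, end[i]))
  }, character(1))
  attr(seqs, "clipped") <- unname(clipped)
  seqs
}

#' Calibrate a motif-score threshold against random genomic regions
#'
#' Scores `n_random` uniformly placed `width`-bp regions; the false
#' discovery rate at threshold t is the fraction of random regions with
#' best score >= t. The chosen threshold is the smallest t whose FDR does
#' not exceed `target`; if even the largest threshold exceeds the target,
#' that largest threshold is returned with `reached = FALSE`.
#'
#' @param pwm `pwm` object.
#' @param genome `DNAStringSet`.
#' @param target target FDR.
#' @param n_random number of random regions.
#' @param width region width (bp).
#' @param thresholds ascending score thresholds; defaults to the sorted
#'   unique random-region scores.
#' @param seed integer seed.
#' @return List: `curve` (data frame `threshold`, `fdr`), `threshold`,
#'   `fdr_at_threshold`, `reached`, `scores` (random-region scores).
#' @export
calibrate_fdr <- function(pwm, genome, target = 0.047, n_random = 1000,
                          width = 200, thresholds = NULL, seed = 1) {
  sizes <- chrom_sizes(genome)
  scores <- with_seed(derive_seed(seed, 61), {
    ch <- sample(names(sizes), n_random, replace = TRUE,
                 prob = sizes / sum(sizes))
    start <- floor(stats::runif(n_random) * (sizes[ch] - width))
    seqs <- vapply(seq_len(n_random), function(i) {
      as.character(Biostrings::subseq(genome[[ch[i]]], start[i] + 1,
                                      start[i] + width))
    }, character(1))
    scan_best_scores(seqs, pwm)
  })
  if (is.null(thresholds)) thresholds <- sort(unique(scores))
  if (is.unsorted(thresholds)) {
    stop("thresholds must be ascending", call. = FALSE)
  }
  fdr <- vapply(thresholds, function(t) mean(scores >= t), numeric(1))
  ok <- which(fdr <= target)
  reached <- length(ok) > 0
  chosen <- if (reached) thresholds[ok[1]] else thresholds[length(thresholds)]
  list(curve = data.frame(threshold = thresholds, fdr = fdr),
       threshold = chosen,
       fdr_at_threshold = if (reached) fdr[ok[1]] else fdr[length(fdr)],
       reached = reached, scores = scores)
}

#' Scan peak sequences and flag motif occurrences at a threshold
#'
#' @param seqs character vector of sequences.
#' @param pwm `pwm` object.
#' @param threshold score threshold (e.g. from [calibrate_fdr()]).
#' @param fdr calibrated FDR at the threshold (carried through for
#'   reporting).
#' @return data frame `score`, `has_motif`.
#' @export
scan_peaks <- function(seqs, pwm, threshold, fdr = NA_real_) {
  score <- scan_best_scores(seqs, pwm)
  structure(data.frame(score = score, has_motif = score >= threshold),
            threshold = threshold, fdr = fdr)
}

#' Hypergeometric motif-enrichment test
#'
#' Population = peak sequences plus random regions; successes = all
#' sequences scoring above threshold; draw = the peak sequences. Returns
#' the upper-tail probability of observing at least the seen number of
#' motif-positive peaks.
#'
#' @param n_hits_in_peaks,n_peaks,n_hits_in_random,n_random counts.
#' @return Upper-tail hypergeometric p-value.
#' @export
motif_enrichment <- function(n_hits_in_peaks, n_peaks, n_hits_in_random,
                             n_random) {
  if (n_hits_in_peaks > n_peaks || n_hits_in_random > n_random ||
      any(c(n_hits_in_peaks, n_peaks, n_hits_in_random, n_random) < 0)) {
    stop("inconsistent counts", call. = FALSE)
  }
  k <- n_hits_in_peaks + n_hits_in_random
  stats::phyper(n_hits_in_peaks - 1, k, n_peaks + n_random - k, n_peaks,
                lower.tail = FALSE)
}
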