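# AREM-style peak calling: candidate regions from a greedy gap merge, EM
# re-weighting of multi-mapping reads against region enrichment rates,
# Poisson upper-tail scoring against a data-driven background rate, and an
# empirical FDR taken relative to an independently processed preimmune
# control.

#' Build candidate regions by greedy gap merging
#'
#' All alignments of all reads (multi-mapping included) are sorted by
#' position; alignments separated by at most `max_gap` bp (gap measured
#' between the end of one alignment and the start of the next; overlapping
#' alignments always merge) share a region. Regions supported by fewer than
#' `min_reads` candidate alignments are dropped and their alignments revert
#' to background.
#'
#' @param aln alignment data frame (see [read_alignments()]).
#' @param max_gap maximum gap (bp) between alignments in one region.
#' @param min_reads minimum candidate alignments per region.
#' @return List with `regions` (data frame `region_id`, `chrom`, `start`,
#'   `end`, `width`, `n_align`) and `region_of` (integer per input
#'   alignment; `NA` = background).
#' @export
build_candidate_regions <- function(aln, max_gap = 100, min_reads = 7) {
  stopifnot(max_gap >= 0, min_reads >= 1)
  n <- nrow(aln)
  empty <- list(regions = data.frame(region_id = integer(),
                                     chrom = character(), start = numeric(),
                                     end = numeric(), width = numeric(),
                                     n_align = integer(),
                                     stringsAsFactors = FALSE),
                region_of = rep(NA_integer_, n))
  if (n == 0) return(empty)
  o <- order(aln$chrom, aln$start, aln$end)
  ch <- aln$chrom[o]
  s <- aln$start[o]
  e <- aln$end[o]
  new_chrom <- c(TRUE, ch[-1] != ch[-n])
  # Running max of end within chromosome runs.
  run_id <- cumsum(new_chrom)
  cme <- stats::ave(e, run_id, FUN = cummax)
  breaks <- new_chrom | c(TRUE, s[-1] > cme[-n] + max_gap)
  cluster <- cumsum(breaks)
  cl_n <- tabulate(cluster)
  keep <- cl_n >= min_reads
  if (!any(keep)) return(empty)
  new_id <- cumsum(keep)
  new_id[!keep] <- NA_integer_
  region_sorted <- new_id[cluster]
  kept <- which(!is.na(region_sorted))
  regions <- data.frame(
    region_id = seq_len(sum(keep)),
    chrom = ch[kept][!duplicated(region_sorted[kept])],
    start = as.numeric(tapply(s[kept], region_sorted[kept], min)),
    end = as.numeric(tapply(e[kept], region_sorted[kept], max)),
    stringsAsFactors = FALSE)
  regions$width <- regions$end - regions$start
  regions$n_align <- as.integer(table(region_sorted[kept]))
  region_of <- integer(n)
  region_of[o] <- region_sorted
  list(regions = regions, region_of = region_of)
}

#' Run EM re-weighting of multi-mapping reads
#'
#' The generative model is a mixture of K enriched regions plus background:
#' each read arose from exactly one of its candidate alignments, with a
#' Poisson rate `lambda_i = expected_count_i / width_i` inside region i and
#' a genome-wide background rate `lambda0` outside. The E-step sets the
#' weight of each alignment proportional to the rate at its location,
#' renormalized per read (uniquely mapping reads keep weight 1 throughout);
#' the M-step re-estimates `expected_count_i` as the summed weights in
#' region i, and `lambda0` from the residual read mass over the non-region
#' genome (floored at one read per genome). Iteration stops when the largest
#' per-alignment weight change falls below `tol` or at `max_iter` (the
#' returned state is then flagged, not an error). The observed-data
#' log-likelihood is recorded each iteration.
#'
#' @param aln alignment data frame.
#' @param regions result of [build_candidate_regions()].
#' @param genome_size total genome length (bp).
#' @param lambda0_init optional starting background rate (reads/bp);
#'   defaults to total reads / genome size.
#' @param tol convergence tolerance on per-alignment weight change.
#' @param max_iter iteration cap.
#' @return An `em_state` list: `regions` (with `expected_count`, `lambda`),
#'   `lambda0`, `iterations`, `converged`, `loglik` (trace), `aln` (weights
#'   updated), `genome_size`.
#' @export
run_em <- function(aln, regions, genome_size, lambda0_init = NULL,
                   tol = 1e-3, max_iter = 100) {
  stopifnot(tol > 0, max_iter >= 1, genome_size > 0)
  reg <- regions$regions
  r_of <- regions$region_of
  n_aln <- nrow(aln)
  read_f <- factor(aln$read_id)
  n_reads <- nlevels(read_f)
  ridx <- as.integer(read_f)
  n_per_read <- tabulate(ridx, nbins = n_reads)
  is_multi_read <- n_per_read > 1
  mi <- which(is_multi_read[ridx])
  w <- aln$weight
  nr <- nrow(reg)
  width <- reg$width
  total_region_width <- sum(width)
  out_len <- max(genome_size - total_region_width, 1)

  r0 <- ifelse(is.na(r_of), 0L, r_of)
  # Fixed unique-read mass per region.
  u <- numeric(nr)
  ui <- setdiff(which(r0 > 0), mi)
  if (length(ui)) {
    agg <- rowsum(w[ui], r0[ui])
    u[as.integer(rownames(agg))] <- agg[, 1]
  }
  rm_m <- r0[mi]
  ridx_m <- ridx[mi]
  mread_f <- factor(ridx_m)
  mread_i <- as.integer(mread_f)
  wm <- w[mi]

  lambda0 <- if (is.null(lambda0_init)) n_reads / genome_size else lambda0_init
  loglik <- numeric(0)
  converged <- FALSE
  iterations <- 0
  cnt <- u
  repeat {
    iterations <- iterations + 1
    # M-step: expected counts and rates from current weights.
    cnt <- u
    if (length(mi)) {
      inreg <- rm_m > 0
      if (any(inreg)) {
        agg <- rowsum(wm[inreg], rm_m[inreg])
        cnt[as.integer(rownames(agg))] <- cnt[as.integer(rownames(agg))] +
          agg[, 1]
      }
    }
    lambda0 <- max((n_reads - sum(cnt)) / out_len, 1 / genome_size)
    lam <- if (nr) cnt / width else numeric(0)
    # Observed-data log-likelihood (up to a constant): the intensity
    # integrates to n_reads, so only the per-read log-sum-of-rates varies.
    rate_all <- ifelse(r0 > 0, lam[pmax(r0, 1)], lambda0)
    per_read <- rowsum(rate_all, ridx)
    loglik <- c(loglik, sum(log(per_read[, 1])) - n_reads)
    # E-step on multi-mapping alignments only.
    if (length(mi) == 0) {
      converged <- TRUE
      break
    }
    rate_m <- ifelse(rm_m > 0, lam[pmax(rm_m, 1)], lambda0)
    denom <- rowsum(rate_m, mread_i)[, 1]
    w_new <- rate_m / denom[mread_i]
    delta <- max(abs(w_new - wm))
    wm <- w_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (iterations >= max_iter) break
  }
  w[mi] <- wm
  aln$weight <- w
  reg$expected_count <- cnt
  reg$lambda <- if (nr) cnt / width else numeric(0)
  structure(list(regions = reg, lambda0 = lambda0, iterations = iterations,
                 converged = converged, loglik = loglik, aln = aln,
                 genome_size = genome_size),
            class = "em_state")
}

# Leftmost position (0-based) of maximum weighted coverage per region.
region_summits <- function(state) {
  reg <- state$regions
  if (nrow(reg) == 0) return(numeric(0))
  aln <- state$aln
  summit <- numeric(nrow(reg))
  for (ch in unique(reg$chrom)) {
    ai <- aln$chrom == ch
    cov <- IRanges::coverage(IRanges::IRanges(aln$start[ai] + 1,
                                              aln$end[ai]),
                             weight = aln$weight[ai])
    ri <- which(reg$chrom == ch)
    ends <- pmin(reg$end[ri], length(cov))
    v <- IRanges::Views(cov, start = reg$start[ri] + 1, end = ends)
    summit[ri] <- IRanges::viewWhichMaxs(v) - 1
  }
  summit
}

#' Score candidate regions as peaks
#'
#' Each region's p-value is the Poisson upper tail
#' `P(X >= round(expected_count))` for `X ~ Poisson(lambda0 * width)`:
#' fractional expected counts (from EM weights) are rounded onto the
#' integer support. The summit is the leftmost position of maximal weighted
#' read coverage within the region.
#'
#' @param state `em_state` from [run_em()].
#' @return Peak data frame: `chrom`, `start`, `end`, `summit`,
#'   `expected_count`, `p_value`, ordered by position.
#' @export
score_regions <- function(state) {
  if (state$lambda0 <= 0) {
    stop("background rate must be positive", call. = FALSE)
  }
  reg <- state$regions
  if (nrow(reg) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), summit = numeric(),
                      expected_count = numeric(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  }
  mu <- state$lambda0 * reg$width
  k <- round(reg$expected_count)
  p <- stats::ppois(k - 1, mu, lower.tail = FALSE)
  data.frame(chrom = reg$chrom, start = reg$start, end = reg$end,
             summit = region_summits(state),
             expected_count = reg$expected_count, p_value = p,
             stringsAsFactors = FALSE)
}

# Full single-library pipeline: regions -> EM -> scored regions.
peak_call_core <- function(aln, chrom_sizes, max_gap = 100, min_reads = 7,
                           tol = 1e-3, max_iter = 100) {
  regions <- build_candidate_regions(aln, max_gap = max_gap,
                                     min_reads = min_reads)
  state <- run_em(aln, regions, genome_size = sum(chrom_sizes), tol = tol,
                  max_iter = max_iter)
  list(scored = score_regions(state), state = state,
       depth = length(unique(aln$read_id)))
}

#' Call peaks against a preimmune control
#'
#' Runs the full candidate-region / EM / Poisson pipeline independently on
#' the sample and on the control library, then reports peaks below the
#' p-value cutoff with a control-relative empirical false discovery rate:
#' `FDR(t) = N_control(t) * (depth_sample / depth_control) /
#' max(N_sample(t), 1)`, where `N(t)` counts peaks with `p < t` and depth is
#' the number of reads. A per-threshold FDR evaluated at each peak's own
#' p-value is attached to every peak.
#'
#' @param sample_aln,control_aln alignment data frames (both nonempty).
#' @param chrom_sizes named vector of chromosome lengths.
#' @param p_threshold Poisson p-value cutoff for calling.
#' @param max_gap,min_reads,tol,max_iter caller parameters (see
#'   [build_candidate_regions()], [run_em()]).
#' @return List: `peaks` (BED6-like data frame with `summit`,
#'   `expected_count`, `p_value`, `fdr`, sorted by p-value then position),
#'   `fdr_estimate` (at `p_threshold`), `n_sample`, `n_control`,
#'   `sample_state`, `control_state`.
#' @export
call_peaks <- function(sample_aln, control_aln, chrom_sizes,
                       p_threshold = 1e-4, max_gap = 100, min_reads = 7,
                       tol = 1e-3, max_iter = 100) {
  if (nrow(sample_aln) == 0 || nrow(control_aln) == 0) {
    stop("sample and control read sets must be nonempty", call. = FALSE)
  }
  smp <- peak_call_core(sample_aln, chrom_sizes, max_gap, min_reads, tol,
                        max_iter)
  ctl <- peak_call_core(control_aln, chrom_sizes, max_gap, min_reads, tol,
                        max_iter)
  if (ctl$depth > 100 * smp$depth) {
    warning("control is >100x deeper than sample; FDR scaling unstable")
  }
  scale <- smp$depth / ctl$depth
  cp <- sort(ctl$scored$p_value)
  sp <- sort(smp$scored$p_value)
  n_at <- function(p_sorted, t) {
    # count of p-values strictly below t
    findInterval(t, p_sorted, left.open = TRUE)
  }
  fdr_at <- function(t) {
    pmin(n_at(cp, t) * scale / pmax(n_at(sp, t), 1), Inf)
  }
  peaks <- smp$scored
  peaks$fdr <- vapply(peaks$p_value, fdr_at, numeric(1))
  fdr_estimate <- fdr_at(p_threshold)
  peaks <- peaks[peaks$p_value < p_threshold, , drop = FALSE]
  peaks <- peaks[order(peaks$p_value, peaks$chrom, peaks$start), ,
                 drop = FALSE]
  rownames(peaks) <- NULL
  list(peaks = peaks, fdr_estimate = fdr_estimate,
       n_sample = nrow(peaks),
       n_control = n_at(cp, p_threshold),
       sample_state = smp$state, control_state = ctl$state)
}
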