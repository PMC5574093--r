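# Independent oracles used to cross-check the pipeline implementations.
# These deliberately share no code with the package: plain loops, direct
# series summation, exhaustive enumeration.

# Single-pass Poisson window caller for unique-mapping reads: greedy gap
# clustering per chromosome, raw read counts, background rate from
# out-of-region mass, Poisson upper tail by direct series summation.
naive_poisson_caller <- function(aln, chrom_sizes, max_gap = 100,
                                 min_reads = 7, p_threshold = 1e-4) {
  stopifnot(!anyDuplicated(aln$read_id))
  regions <- list()
  for (ch in sort(unique(aln$chrom))) {
    a <- aln[aln$chrom == ch, , drop = FALSE]
    a <- a[order(a$start, a$end), , drop = FALSE]
    cl <- integer(nrow(a))
    cl[1] <- 1
    maxend <- a$end[1]
    if (nrow(a) > 1) {
      for (i in 2:nrow(a)) {
        cl[i] <- cl[i - 1] + (a$start[i] > maxend + max_gap)
        maxend <- max(maxend, a$end[i])
      }
    }
    for (k in unique(cl)) {
      idx <- cl == k
      if (sum(idx) >= min_reads) {
        regions[[length(regions) + 1]] <-
          list(chrom = ch, start = min(a$start[idx]),
               end = max(a$end[idx]), count = sum(idx))
      }
    }
  }
  G <- sum(chrom_sizes)
  if (!length(regions)) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), count = numeric(),
                      p_value = numeric()))
  }
  total_w <- sum(vapply(regions, function(r) r$end - r$start, numeric(1)))
  in_mass <- sum(vapply(regions, function(r) r$count, numeric(1)))
  lambda0 <- max((nrow(aln) - in_mass) / max(G - total_w, 1), 1 / G)
  out <- do.call(rbind, lapply(regions, function(r) {
    mu <- lambda0 * (r$end - r$start)
    k <- round(r$count)
    p <- 1 - poisson_cdf_series(k - 1, mu)
    data.frame(chrom = r$chrom, start = r$start, end = r$end,
               count = r$count, p_value = p, stringsAsFactors = FALSE)
  }))
  out[out$p_value < p_threshold, , drop = FALSE]
}

# P(X <= k) for X ~ Poisson(mu), by iterative term accumulation.
poisson_cdf_series <- function(k, mu) {
  if (k < 0) return(0)
  term <- exp(-mu)
  acc <- term
  j <- 0
  while (j < k) {
    j <- j + 1
    term <- term * mu / j
    acc <- acc + term
  }
  min(acc, 1)
}

# Brute-force best PWM log-odds score: explicit double loop over windows
# and positions, both strands.
naive_best_score <- function(seq, pwm_obj, both_strands = TRUE) {
  pc <- pwm_obj$pseudocount
  mat <- log2((pwm_obj$mat + pc) /
                matrix(pwm_obj$bg + pc, nrow(pwm_obj$mat), 4, byrow = TRUE))
  score_one <- function(s) {
    chars <- strsplit(s, "")[[1]]
    L <- nrow(mat)
    if (length(chars) < L) stop("too short")
    best <- -Inf
    for (i in seq_len(length(chars) - L + 1)) {
      sc <- 0
      for (p in seq_len(L)) {
        b <- chars[i + p - 1]
        if (!b %in% c("A", "C", "G", "T")) { sc <- -Inf; break }
        sc <- sc + mat[p, b]
      }
      best <- max(best, sc)
    }
    best
  }
  fwd <- score_one(seq)
  if (!both_strands) return(fwd)
  rc <- paste(rev(chartr("ACGT", "TGCA",
                         strsplit(seq, "")[[1]])), collapse = "")
  max(fwd, score_one(rc))
}

# Hand fixed-point iteration of the two-region EM system: one 2-alignment
# read torn between region 1 (n1 unique reads) and region 2 (n2 unique
# reads), equal widths W, genome size G, total reads n1 + n2 + 1.
two_region_fixed_point <- function(n1, n2, W, G, iters = 500) {
  w1 <- 0.5
  for (i in seq_len(iters)) {
    lam1 <- (n1 + w1) / W
    lam2 <- (n2 + 1 - w1) / W
    w1 <- lam1 / (lam1 + lam2)
  }
  w1
}

# Tiny alignment table builder (single-end, length len).
mk_aln <- function(chrom, start, len = 36, read_id = NULL) {
  if (is.null(read_id)) read_id <- sprintf("r%04d", seq_along(start))
  cohesinscape::alignments(read_id, chrom, start, start + len)
}

# Gene-model row builder with simple two-exon structure.
mk_gene <- function(gene_id, chrom, strand, start, end,
                    exon_starts = NULL, exon_ends = NULL,
                    cds_start = NA, cds_end = NA) {
  if (is.null(exon_starts)) {
    third <- floor((end - start) / 3)
    exon_starts <- c(start, start + 2 * third)
    exon_ends <- c(start + third, end)
  }
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  start = start, end = end, stringsAsFactors = FALSE)
  g$exon_starts <- list(exon_starts)
  g$exon_ends <- list(exon_ends)
  if (!is.na(cds_start)) {
    g$cds_start <- cds_start
    g$cds_end <- cds_end
  }
  g$tss <- if (strand == "+") start else end - 1
  g$tts <- if (strand == "+") end - 1 else start
  g
}
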