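# Synthetic isogenic WT / mutant ChIP-seq experiment with planted truth.
#
# The generator emulates the study design the pipeline is built for: an
# immunoprecipitation library from wild-type cells, a matched library from
# cells with a globally reduced cohesin-loading capacity (every planted
# peak's expected read yield multiplied by a factor f in (0,1]), and a
# preimmune-IgG library with no enrichment at all. Repeat blocks (pairs of
# identical sequence) create genuine multi-mapping reads so that the EM
# caller's re-weighting has something to rescue.

# Run expr with a private RNG stream; restores the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a per-stage seed from one global seed; keeps results < 2^31.
derive_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

#' Default configuration of the synthetic experiment
#'
#' Desk-scale defaults: 3 chromosomes of 1 Mb, 60 genes, 120 planted peaks
#' with log-uniform strengths spanning 5-200 expected reads, two thirds of
#' peaks carrying an embedded consensus motif, one pair of identical 2-kb
#' repeat blocks with a peak planted inside, 9,000 reads per library
#' (about 0.003 reads per bp, matching the genome-wide read density of the
#' real mammalian libraries this emulates -- the quantity that controls the
#' Poisson background and the control-relative FDR), and a mutant
#' binding-reduction factor f = 0.65. Library sizes are equal by default;
#' set `total_reads_mut` to emulate unequal sequencing depth.
#'
#' @param ... named overrides of any default.
#' @return Named list of configuration values.
#' @export
sim_config <- function(...) {
  cfg <- list(
    n_chrom = 3, chrom_len = 1e6,
    n_genes = 60, n_peaks = 120,
    motif_fraction = 2 / 3,
    zone_fractions = c(promoter = 0.15, gene_body = 0.25,
                       downstream = 0.10, intergenic = 0.50),
    strength_range = c(5, 200),
    repeat_pairs = 1, repeat_len = 2000, peak_in_repeat = TRUE,
    f = 0.65,
    total_reads_wt = 9000, total_reads_mut = 9000,
    total_reads_preimmune = 9000,
    read_len = 36, jitter = 150,
    promoter_up = 2500, promoter_down = 500,
    downstream_up = 500, downstream_down = 2500
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  if (cfg$f <= 0 || cfg$f > 1) stop("f must be in (0, 1]", call. = FALSE)
  if (cfg$motif_fraction < 0 || cfg$motif_fraction > 1) {
    stop("motif_fraction must be in [0, 1]", call. = FALSE)
  }
  cfg
}

#' A synthetic CTCF-like PWM
#'
#' A 12-bp informative position weight matrix used by the simulator to embed
#' motif instances at planted peaks. It is a synthetic stand-in shaped like a
#' zinc-finger binding preference (one dominant base per position), not an
#' empirically derived CTCF matrix. Also shipped as
#' `inst/extdata/ctcf_like_synthetic.meme`.
#'
#' @param pseudocount pseudocount stored for scoring.
#' @return A `pwm` object.
#' @export
ctcf_like_pwm <- function(pseudocount = 1e-3) {
  cons <- c("C", "C", "A", "C", "C", "A", "G", "G", "T", "G", "G", "C")
  second <- c("T", "G", "G", "T", "A", "G", "A", "A", "C", "A", "T", "A")
  # heterogeneous column informativeness, as in empirical matrices; a
  # near-continuous score distribution makes FDR calibration fine-grained
  strength <- c(0.97, 0.86, 0.72, 0.91, 0.81, 0.66, 0.94, 0.88, 0.76,
                0.92, 0.84, 0.62)
  mat <- t(vapply(seq_along(cons), function(i) {
    p <- stats::setNames(rep((1 - strength[i]) * 0.2, 4),
                         c("A", "C", "G", "T"))
    p[second[i]] <- (1 - strength[i]) * 0.6
    p[cons[i]] <- strength[i]
    p
  }, numeric(4)))
  rownames(mat) <- NULL
  pwm(mat, pseudocount = pseudocount, name = "CTCF_like_synthetic")
}

pwm_consensus <- function(x) {
  paste(colnames(x$mat)[max.col(x$mat, ties.method = "first")],
        collapse = "")
}

#' Generate the synthetic genome, gene models and planted truth
#'
#' Places non-overlapping genes in regular slots along each chromosome, then
#' plants peaks in configurable fractions of promoter, gene-body, downstream
#' and intergenic zones (summits kept >= 700 bp apart so that planted peaks
#' never merge), marks a motif-bearing subset, and optionally drops one peak
#' into a duplicated repeat block so it is only reachable through
#' multi-mapping reads. The in-repeat peak receives the geometric-mean
#' strength of the configured range, a representative value. Random sequence
#' is generated last and repeat copies are made byte-identical, so layouts
#' are reproducible whether or not sequence is requested.
#'
#' @param config list from [sim_config()].
#' @param seed integer seed; identical seeds give identical output.
#' @param sequence logical; generate chromosome sequence (needed only for
#'   motif analyses).
#' @return List with `genome` (`DNAStringSet` or `NULL`), `genes` (gene data
#'   frame), and `truth` (list: `chrom_sizes`, `peaks`, `repeats`, `pwm`,
#'   `config`, `seed`). `truth$peaks` columns include `summit`, `strength`,
#'   `has_motif`, `in_repeat`, `zone` and the per-gene binding zones used to
#'   derive bound-gene labels.
#' @export
simulate_genome <- function(config = sim_config(), seed = 1,
                            sequence = TRUE) {
  with_seed(derive_seed(seed, 1), {
    chroms <- paste0("chr", seq_len(config$n_chrom))
    sizes <- stats::setNames(rep(config$chrom_len, config$n_chrom), chroms)
    per_chr <- ceiling(config$n_genes / config$n_chrom)
    slot <- floor(config$chrom_len / per_chr)
    margin <- 6000
    if (slot <= 2 * margin + 8000) {
      stop("chromosomes too short for requested gene count", call. = FALSE)
    }

    genes <- do.call(rbind, lapply(seq_along(chroms), function(ci) {
      n_here <- min(per_chr, config$n_genes - (ci - 1) * per_chr)
      if (n_here <= 0) return(NULL)
      slot_start <- (seq_len(n_here) - 1) * slot
      max_len <- slot - 2 * margin
      len <- round(stats::runif(n_here, 8000, min(30000, max_len)))
      offset <- vapply(max_len - len, function(m) {
        round(stats::runif(1, 0, m))
      }, numeric(1))
      start <- slot_start + margin + offset
      data.frame(gene_id = sprintf("g%s_%02d", ci, seq_len(n_here)),
                 chrom = chroms[ci], strand = sample(c("+", "-"), n_here,
                                                    replace = TRUE),
                 start = start, end = start + len, stringsAsFactors = FALSE)
    }))
    rownames(genes) <- NULL

    # Exon structure: 3-7 exons from sorted internal breakpoints, with
    # intronic gaps; CDS trimmed 600-1200 bp inside each gene end so UTR
    # windows survive the 500-bp interior trim used in annotation.
    ex <- lapply(seq_len(nrow(genes)), function(i) {
      len <- genes$end[i] - genes$start[i]
      k <- sample(3:7, 1)
      cuts <- sort(stats::runif(2 * k - 2, 0.05, 0.95)) * len
      bounds <- round(c(0, cuts, len)) + genes$start[i]
      starts <- bounds[seq(1, 2 * k, by = 2)]
      ends <- pmax(bounds[seq(2, 2 * k, by = 2)], starts + 1)
      list(starts = starts, ends = pmin(ends, genes$end[i]))
    })
    genes$exon_starts <- lapply(ex, `[[`, "starts")
    genes$exon_ends <- lapply(ex, `[[`, "ends")
    genes$cds_start <- genes$start + round(stats::runif(nrow(genes),
                                                        600, 1200))
    genes$cds_end <- genes$end - round(stats::runif(nrow(genes), 600, 1200))
    genes <- validate_genes(genes)

    # Intergenic gaps kept clear of gene-derived windows.
    pad <- 3200
    occupied <- data.frame(chrom = genes$chrom,
                           start = pmax(genes$start - pad, 0),
                           end = pmin(genes$end + pad, sizes[genes$chrom]))
    gaps <- do.call(rbind, lapply(chroms, function(ch) {
      occ <- occupied[occupied$chrom == ch, , drop = FALSE]
      occ <- occ[order(occ$start), , drop = FALSE]
      gs <- c(0, occ$end)
      ge <- c(occ$start, sizes[ch])
      keep <- ge - gs > 3000
      data.frame(chrom = ch, start = gs[keep], end = ge[keep],
                 stringsAsFactors = FALSE)
    }))

    # Repeat block pairs in distinct intergenic gaps.
    repeats <- NULL
    if (config$repeat_pairs > 0) {
      wide <- which(gaps$end - gaps$start > config$repeat_len + 2000)
      if (length(wide) < 2 * config$repeat_pairs) {
        stop("not enough intergenic space for repeat blocks", call. = FALSE)
      }
      pick <- sample(wide, 2 * config$repeat_pairs)
      centers <- floor((gaps$start[pick] + gaps$end[pick]) / 2)
      bs <- centers - floor(config$repeat_len / 2)
      idx1 <- seq(1, length(pick), by = 2)
      idx2 <- idx1 + 1
      repeats <- data.frame(chrom1 = gaps$chrom[pick[idx1]],
                            start1 = bs[idx1],
                            chrom2 = gaps$chrom[pick[idx2]],
                            start2 = bs[idx2],
                            length = config$repeat_len,
                            stringsAsFactors = FALSE)
    }

    zf <- config$zone_fractions
    n_zone <- floor(config$n_peaks * zf)
    n_zone["intergenic"] <- config$n_peaks - sum(n_zone[c("promoter",
                                                          "gene_body",
                                                          "downstream")])
    half_w <- 200

    place_on_genes <- function(n, zone) {
      if (n == 0) {
        return(data.frame(chrom = character(), summit = numeric(),
                          zone = character(), gene_id = character(),
                          in_repeat = logical(), stringsAsFactors = FALSE))
      }
      gi <- sample(nrow(genes), n)
      g <- genes[gi, ]
      plus <- g$strand == "+"
      summit <- switch(zone,
        promoter = {
          off <- round(stats::runif(n, -2300, 300))
          ifelse(plus, g$tss + off, g$tss - off)
        },
        gene_body = {
          lo <- g$start + 1000
          hi <- g$end - 1000
          round(lo + stats::runif(n) * (hi - lo))
        },
        downstream = {
          off <- round(stats::runif(n, 800, 2200))
          ifelse(plus, g$tts + off, g$tts - off)
        })
      data.frame(chrom = g$chrom, summit = summit, zone = zone,
                 gene_id = g$gene_id, in_repeat = FALSE,
                 stringsAsFactors = FALSE)
    }

    placed <- rbind(place_on_genes(n_zone["promoter"], "promoter"),
                    place_on_genes(n_zone["gene_body"], "gene_body"),
                    place_on_genes(n_zone["downstream"], "downstream"))

    n_inter <- n_zone["intergenic"]
    inter <- data.frame(chrom = character(), summit = numeric(),
                        zone = character(), gene_id = character(),
                        in_repeat = logical(), stringsAsFactors = FALSE)
    if (!is.null(repeats) && config$peak_in_repeat && n_inter > 0) {
      inter <- rbind(inter, data.frame(
        chrom = repeats$chrom1[1],
        summit = repeats$start1[1] + floor(config$repeat_len / 2),
        zone = "intergenic", gene_id = NA_character_, in_repeat = TRUE,
        stringsAsFactors = FALSE))
      n_inter <- n_inter - 1
    }
    gap_ok <- gaps[gaps$end - gaps$start > 2 * (half_w + 600), , drop = FALSE]
    taken_summits <- c()
    taken_chrom <- c()
    all_prev <- rbind(placed, inter)
    tries <- 0
    while (n_inter > 0) {
      tries <- tries + 1
      if (tries > 200 * config$n_peaks) {
        stop("could not place intergenic peaks; configuration infeasible",
             call. = FALSE)
      }
      gi <- sample(nrow(gap_ok), 1)
      s <- round(stats::runif(1, gap_ok$start[gi] + half_w + 600,
                              gap_ok$end[gi] - half_w - 600))
      near_rep <- FALSE
      if (!is.null(repeats)) {
        near_rep <- any((gap_ok$chrom[gi] == repeats$chrom1 &
                           abs(s - (repeats$start1 + config$repeat_len / 2)) <
                             config$repeat_len) |
                        (gap_ok$chrom[gi] == repeats$chrom2 &
                           abs(s - (repeats$start2 + config$repeat_len / 2)) <
                             config$repeat_len))
      }
      prev <- c(all_prev$summit[all_prev$chrom == gap_ok$chrom[gi]],
                taken_summits[taken_chrom == gap_ok$chrom[gi]])
      if (!near_rep && (length(prev) == 0 || min(abs(prev - s)) >= 1000)) {
        taken_summits <- c(taken_summits, s)
        taken_chrom <- c(taken_chrom, gap_ok$chrom[gi])
        n_inter <- n_inter - 1
      }
    }
    if (length(taken_summits)) {
      inter <- rbind(inter, data.frame(chrom = taken_chrom,
                                       summit = taken_summits,
                                       zone = "intergenic",
                                       gene_id = NA_character_,
                                       in_repeat = FALSE,
                                       stringsAsFactors = FALSE))
    }
    peaks <- rbind(placed, inter)
    # truth interval = the planted read footprint (summit +/- jitter)
    peaks$start <- peaks$summit - config$jitter
    peaks$end <- peaks$summit + config$jitter
    lo <- config$strength_range[1]
    hi <- config$strength_range[2]
    peaks$strength <- exp(stats::runif(nrow(peaks), log(lo), log(hi)))
    peaks$strength[peaks$in_repeat] <- sqrt(lo * hi)
    peaks$has_motif <- seq_len(nrow(peaks)) %in%
      sample(nrow(peaks), round(config$motif_fraction * nrow(peaks)))
    o <- order(peaks$chrom, peaks$start)
    peaks <- peaks[o, c("chrom", "start", "end", "summit", "strength",
                        "has_motif", "in_repeat", "zone", "gene_id")]
    rownames(peaks) <- NULL
    peaks$peak_id <- sprintf("truth_%03d", seq_len(nrow(peaks)))

    truth <- list(chrom_sizes = sizes, peaks = peaks, repeats = repeats,
                  pwm = ctcf_like_pwm(), config = config, seed = seed)

    genome <- NULL
    if (sequence) {
      genome <- with_seed(derive_seed(seed, 2), {
        seqs <- lapply(chroms, function(ch) {
          paste(sample(c("A", "C", "G", "T"), sizes[ch], replace = TRUE),
                collapse = "")
        })
        g <- Biostrings::DNAStringSet(unlist(seqs))
        names(g) <- chroms
        cons <- Biostrings::DNAString(pwm_consensus(truth$pwm))
        L <- length(cons)
        mp <- peaks[peaks$has_motif, , drop = FALSE]
        for (i in seq_len(nrow(mp))) {
          at <- mp$summit[i] - floor(L / 2) + 1  # 1-based subseq
          Biostrings::subseq(g[[mp$chrom[i]]], at, at + L - 1) <- cons
        }
        if (!is.null(repeats)) {
          for (i in seq_len(nrow(repeats))) {
            block <- Biostrings::subseq(g[[repeats$chrom1[i]]],
                                        repeats$start1[i] + 1,
                                        repeats$start1[i] + repeats$length[i])
            Biostrings::subseq(g[[repeats$chrom2[i]]],
                               repeats$start2[i] + 1,
                               repeats$start2[i] + repeats$length[i]) <- block
          }
        }
        g
      })
    }
    list(genome = genome, genes = genes, truth = truth)
  })
}

#' Simulate a ChIP-seq read library from the planted truth
#'
#' Per-peak read counts are Poisson with mean `strength` (WT), `f * strength`
#' (mutant), or 0 (preimmune); remaining reads are uniform background. Read
#' midpoints are jittered uniformly within +/- `jitter` bp of the summit,
#' a flat approximation of a ~200-400 bp sonication fragment window. Any
#' read falling entirely inside a repeat block is emitted with one alignment
#' per identical copy (uniform initial weights), exactly what an aligner
#' reporting all best hits would produce.
#'
#' @param truth `truth` list from [simulate_genome()].
#' @param condition one of `"WT"`, `"mutant"`, `"preimmune"`.
#' @param total_reads library size; defaults to the configured size for the
#'   condition.
#' @param seed integer seed.
#' @return Alignment data frame (as [read_alignments()]).
#' @export
simulate_chip_reads <- function(truth, condition = c("WT", "mutant",
                                                     "preimmune"),
                                total_reads = NULL, seed = 1) {
  condition <- match.arg(condition)
  cfg <- truth$config
  if (is.null(total_reads)) {
    total_reads <- switch(condition, WT = cfg$total_reads_wt,
                          mutant = cfg$total_reads_mut,
                          preimmune = cfg$total_reads_preimmune)
  }
  if (total_reads == 0) {
    return(alignments(character(), character(), numeric(), numeric())[0, ])
  }
  read_len <- cfg$read_len
  sizes <- truth$chrom_sizes
  if (read_len > min(sizes)) {
    stop("read_len longer than shortest chromosome", call. = FALSE)
  }
  mult <- switch(condition, WT = 1, mutant = cfg$f, preimmune = 0)
  with_seed(derive_seed(seed, switch(condition, WT = 11, mutant = 12,
                                     preimmune = 13)), {
    pk <- truth$peaks
    n_peak <- if (mult > 0) stats::rpois(nrow(pk), mult * pk$strength)
              else integer(nrow(pk))
    if (sum(n_peak) > total_reads) {
      stop("total_reads smaller than expected peak reads; increase depth",
           call. = FALSE)
    }
    mid <- round(rep(pk$summit, n_peak) +
                   stats::runif(sum(n_peak), -cfg$jitter, cfg$jitter))
    pk_chrom <- rep(pk$chrom, n_peak)
    n_bg <- total_reads - sum(n_peak)
    bg_chrom <- sample(names(sizes), n_bg, replace = TRUE,
                       prob = sizes / sum(sizes))
    bg_start <- floor(stats::runif(n_bg) * (sizes[bg_chrom] - read_len))
    chrom <- c(pk_chrom, bg_chrom)
    start <- c(pmin(pmax(mid - floor(read_len / 2), 0),
                    sizes[pk_chrom] - read_len), bg_start)
    read_id <- sprintf("%s_r%07d", tolower(condition),
                       seq_len(total_reads))
    df <- data.frame(read_id = read_id, chrom = chrom, start = start,
                     end = start + read_len, stringsAsFactors = FALSE)
    # Mirror alignments across identical repeat copies.
    rep_df <- truth$repeats
    if (!is.null(rep_df)) {
      extra <- list()
      for (i in seq_len(nrow(rep_df))) {
        len <- rep_df$length[i]
        in1 <- df$chrom == rep_df$chrom1[i] &
          df$start >= rep_df$start1[i] & df$end <= rep_df$start1[i] + len
        in2 <- df$chrom == rep_df$chrom2[i] &
          df$start >= rep_df$start2[i] & df$end <= rep_df$start2[i] + len
        if (any(in1)) {
          extra[[length(extra) + 1]] <- data.frame(
            read_id = df$read_id[in1], chrom = rep_df$chrom2[i],
            start = df$start[in1] - rep_df$start1[i] + rep_df$start2[i],
            end = df$end[in1] - rep_df$start1[i] + rep_df$start2[i],
            stringsAsFactors = FALSE)
        }
        if (any(in2)) {
          extra[[length(extra) + 1]] <- data.frame(
            read_id = df$read_id[in2], chrom = rep_df$chrom1[i],
            start = df$start[in2] - rep_df$start2[i] + rep_df$start1[i],
            end = df$end[in2] - rep_df$start2[i] + rep_df$start1[i],
            stringsAsFactors = FALSE)
        }
      }
      if (length(extra)) df <- rbind(df, do.call(rbind, extra))
    }
    alignments(df$read_id, df$chrom, df$start, df$end)
  })
}

#' Simulate a WT / mutant expression table
#'
#' Emulates a two-condition microarray-style experiment with 10 wild-type
#' and 9 mutant replicates. Genes bound by cohesin receive a mutant
#' expression shift with probability `p_down` (downward) or `p_up` (upward);
#' unbound genes receive a shift with probability `p_unbound`, split evenly
#' between directions (dysregulation in the mutant is not exclusive to bound
#' genes, only biased toward them). Values are linear intensities
#' `2^(baseline + shift + noise)` with baselines uniform on log2 8-14, so
#' most genes fall inside the 300-20,000 analysis window.
#'
#' @param gene_labels data frame with `gene_id` and logical `bound`.
#' @param n_wt,n_mut replicate counts.
#' @param effect list: `p_down`, `p_up` (given bound; must sum to <= 1),
#'   `p_unbound`, `size` (absolute log2 shift).
#' @param noise_sd per-replicate log2 noise standard deviation.
#' @param seed integer seed.
#' @return List with `expr` (gene_id, wt_1..wt_n, mut_1..mut_n) and `truth`
#'   (gene_id, bound, direction, shift).
#' @export
simulate_expression <- function(gene_labels, n_wt = 10, n_mut = 9,
                                effect = list(p_down = 0.74, p_up = 0.26,
                                              p_unbound = 0.3, size = 0.8),
                                noise_sd = 0.25, seed = 1) {
  if (effect$p_down + effect$p_up > 1 + 1e-12) {
    stop("p_down + p_up must not exceed 1", call. = FALSE)
  }
  n <- nrow(gene_labels)
  with_seed(derive_seed(seed, 21), {
    dir <- character(n)
    u <- stats::runif(n)
    bound <- gene_labels$bound
    dir[bound] <- ifelse(u[bound] < effect$p_down, "down",
                         ifelse(u[bound] < effect$p_down + effect$p_up,
                                "up", "none"))
    dir[!bound] <- ifelse(u[!bound] < effect$p_unbound / 2, "down",
                          ifelse(u[!bound] < effect$p_unbound, "up", "none"))
    shift <- ifelse(dir == "down", -effect$size,
                    ifelse(dir == "up", effect$size, 0))
    base <- stats::runif(n, 8, 14)
    wt <- matrix(2^(base + stats::rnorm(n * n_wt, sd = noise_sd)),
                 nrow = n)
    mut <- matrix(2^(base + shift + stats::rnorm(n * n_mut, sd = noise_sd)),
                  nrow = n)
    colnames(wt) <- sprintf("wt_%d", seq_len(n_wt))
    colnames(mut) <- sprintf("mut_%d", seq_len(n_mut))
    expr <- data.frame(gene_id = gene_labels$gene_id, wt, mut,
                       stringsAsFactors = FALSE)
    truth <- data.frame(gene_id = gene_labels$gene_id, bound = bound,
                        direction = dir, shift = shift,
                        stringsAsFactors = FALSE)
    list(expr = expr, truth = truth)
  })
}

#' Derive bound-gene labels from the planted truth
#'
#' A gene is labelled bound when any planted peak overlaps its gene region
#' (promoter window, gene body, or downstream window), the same windows used
#' by [assign_bound_flags()] on called peaks.
#'
#' @param truth `truth` list from [simulate_genome()].
#' @param genes gene data frame from the same simulation.
#' @return data frame `gene_id`, `bound` plus per-window logicals.
#' @export
truth_gene_labels <- function(truth, genes) {
  pk <- truth$peaks[, c("chrom", "start", "end")]
  flags <- assign_bound_flags(genes, pk, region = "all",
                              promoter_up = truth$config$promoter_up,
                              promoter_down = truth$config$promoter_down,
                              downstream_up = truth$config$downstream_up,
                              downstream_down = truth$config$downstream_down)
  data.frame(gene_id = genes$gene_id, bound = flags$gene_region,
             promoter = flags$promoter, gene_body = flags$gene_body,
             downstream = flags$downstream, stringsAsFactors = FALSE)
}

#' Simulate 3C band intensities
#'
#' Each anchor-target pair yields, per sample and replicate, a test-template
#' band whose intensity is `frequency x efficiency x lognormal noise` and a
#' control-template band (`efficiency x noise`) made from equimolar ligation
#' products, the primer-efficiency proxy. A constitutive reference pair
#' (frequency identical across samples) anchors the normalization.
#'
#' @param interactions data frame: `pair_id`, `freq_wt`, `freq_mut`,
#'   logical `is_reference` (exactly one TRUE).
#' @param efficiencies named positive vector of primer efficiencies per
#'   pair; single value recycled.
#' @param noise_sd log-normal noise sd (0 = noiseless).
#' @param n_bio,n_tech biological / technical replicates per sample.
#' @param seed integer seed.
#' @return data frame: `pair_id`, `sample`, `bio_rep`, `tech_rep`,
#'   `test_intensity`, `template_intensity`, `is_reference`.
#' @export
simulate_3c <- function(interactions, efficiencies = 1, noise_sd = 0.1,
                        n_bio = 2, n_tech = 3, seed = 1) {
  if (sum(interactions$is_reference) != 1) {
    stop("exactly one reference (constitutive) pair required", call. = FALSE)
  }
  if (any(efficiencies <= 0)) {
    stop("primer efficiencies must be positive", call. = FALSE)
  }
  eff <- rep_len(efficiencies, nrow(interactions))
  if (!is.null(names(efficiencies)) && length(efficiencies) > 1) {
    eff <- efficiencies[interactions$pair_id]
  }
  with_seed(derive_seed(seed, 31), {
    grid <- expand.grid(i = seq_len(nrow(interactions)),
                        sample = c("WT", "mutant"),
                        bio_rep = seq_len(n_bio),
                        tech_rep = seq_len(n_tech),
                        stringsAsFactors = FALSE)
    freq <- ifelse(grid$sample == "WT",
                   interactions$freq_wt[grid$i],
                   interactions$freq_mut[grid$i])
    e <- eff[grid$i]
    noise <- function(n) exp(stats::rnorm(n, sd = noise_sd))
    data.frame(pair_id = interactions$pair_id[grid$i],
               sample = grid$sample, bio_rep = grid$bio_rep,
               tech_rep = grid$tech_rep,
               test_intensity = freq * e * noise(nrow(grid)),
               template_intensity = e * noise(nrow(grid)),
               is_reference = interactions$is_reference[grid$i],
               stringsAsFactors = FALSE)
  })
}

#' Write a simulated experiment to disk
#'
#' Truth files are first-class outputs so downstream evaluation never has to
#' reach into generator internals.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(sim$genome)) {
    Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  }
  write_genes(sim$genes, file.path(dir, "genes.tsv"))
  tp <- sim$truth$peaks
  utils::write.table(tp, file.path(dir, "truth_peaks.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(sim$truth$repeats)) {
    utils::write.table(sim$truth$repeats, file.path(dir, "truth_repeats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_pwm(sim$truth$pwm, file.path(dir, "motif.meme"))
  invisible(dir)
}
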