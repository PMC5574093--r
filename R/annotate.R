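# Genomic feature annotation with a fixed precedence rule and a
# length-matched random-placement baseline for enrichment.

FEATURE_ORDER <- c("promoter", "utr5", "intron", "exon", "utr3",
                   "downstream", "intergenic")

#' Build the feature map from gene models
#'
#' Derives strand-aware windows per gene: promoter (`promoter_up` bp
#' upstream to `promoter_down` bp downstream of the TSS, defaults 2500/500),
#' downstream (`downstream_up` bp upstream to `downstream_down` bp
#' downstream of the TTS, defaults 500/2500), exons, introns, and -- when
#' CDS coordinates are annotated -- 5' and 3' UTRs (exonic sequence outside
#' the CDS, minus the `utr_trim` bp interior adjacent to the TSS or TTS,
#' which the promoter/downstream windows already cover). On '-' strand genes
#' "upstream" means larger coordinates. All windows are clipped to
#' chromosome bounds. Without CDS annotation the UTR categories are skipped
#' and flagged, never silently merged into exon/intron.
#'
#' @param genes gene data frame (see [read_genes()]).
#' @param chrom_sizes named chromosome lengths.
#' @param promoter_up,promoter_down,downstream_up,downstream_down window
#'   extents in bp.
#' @param utr_trim interior trim at TSS/TTS for UTR windows.
#' @return A `feature_map`: named list of interval data frames in
#'   precedence order (`promoter`, `utr5`, `intron`, `exon`, `utr3`,
#'   `downstream`), with attribute `has_utr`.
#' @export
build_feature_map <- function(genes, chrom_sizes, promoter_up = 2500,
                              promoter_down = 500, downstream_up = 500,
                              downstream_down = 2500, utr_trim = 500) {
  pw <- anchored_window(genes$tss, promoter_up, promoter_down, genes$strand)
  dw <- anchored_window(genes$tts, downstream_up, downstream_down,
                        genes$strand)
  promoter <- data.frame(chrom = genes$chrom, start = pw[, "start"],
                         end = pw[, "end"], stringsAsFactors = FALSE)
  downstream <- data.frame(chrom = genes$chrom, start = dw[, "start"],
                           end = dw[, "end"], stringsAsFactors = FALSE)
  exon <- data.frame(
    chrom = rep(genes$chrom, lengths(genes$exon_starts)),
    start = unlist(genes$exon_starts, use.names = FALSE),
    end = unlist(genes$exon_ends, use.names = FALSE),
    stringsAsFactors = FALSE)
  introns <- lapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    if (length(es) < 2) return(NULL)
    data.frame(chrom = genes$chrom[i], start = ee[-length(ee)],
               end = es[-1], stringsAsFactors = FALSE)
  })
  intron <- do.call(rbind, introns)
  if (is.null(intron)) {
    intron <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  }
  intron <- intron[intron$start < intron$end, , drop = FALSE]

  has_utr <- all(c("cds_start", "cds_end") %in% names(genes))
  utr5 <- utr3 <- NULL
  if (has_utr) {
    # "exon" means coding exon when UTRs are annotated: otherwise the
    # 3' UTR category (tested after intron and exon) would be unreachable,
    # since UTRs are themselves exonic sequence
    cds <- data.frame(chrom = genes$chrom, start = genes$cds_start,
                      end = genes$cds_end, stringsAsFactors = FALSE)
    gr_ex <- as_granges(exon)
    gr_cds <- as_granges(cds)
    inter <- GenomicRanges::intersect(gr_ex, gr_cds, ignore.strand = TRUE)
    exon <- data.frame(chrom = as.character(GenomicRanges::seqnames(inter)),
                       start = GenomicRanges::start(inter) - 1,
                       end = GenomicRanges::end(inter),
                       stringsAsFactors = FALSE)
  }
  if (has_utr) {
    mk_utr <- function(kind) {
      out <- lapply(seq_len(nrow(genes)), function(i) {
        g <- genes[i, ]
        plus <- g$strand == "+"
        # genomic span of the UTR
        span <- if ((kind == "utr5") == plus) {
          c(g$start, g$cds_start)        # gene start side
        } else {
          c(g$cds_end, g$end)            # gene end side
        }
        if (span[1] >= span[2]) return(NULL)
        # drop the trim bp adjacent to the gene end it touches
        if ((kind == "utr5") == plus) span[1] <- span[1] + utr_trim
        else span[2] <- span[2] - utr_trim
        if (span[1] >= span[2]) return(NULL)
        es <- genes$exon_starts[[i]]
        ee <- genes$exon_ends[[i]]
        s <- pmax(es, span[1])
        e <- pmin(ee, span[2])
        keep <- s < e
        if (!any(keep)) return(NULL)
        data.frame(chrom = g$chrom, start = s[keep], end = e[keep],
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, out)
      if (is.null(out)) {
        out <- data.frame(chrom = character(), start = numeric(),
                          end = numeric(), stringsAsFactors = FALSE)
      }
      out
    }
    utr5 <- mk_utr("utr5")
    utr3 <- mk_utr("utr3")
  }
  fm <- list(promoter = clip_to_chrom(promoter, chrom_sizes),
             utr5 = if (has_utr) clip_to_chrom(utr5, chrom_sizes),
             intron = clip_to_chrom(intron, chrom_sizes),
             exon = clip_to_chrom(exon, chrom_sizes),
             utr3 = if (has_utr) clip_to_chrom(utr3, chrom_sizes),
             downstream = clip_to_chrom(downstream, chrom_sizes))
  attr(fm, "has_utr") <- has_utr
  attr(fm, "chrom_sizes") <- chrom_sizes
  class(fm) <- "feature_map"
  fm
}

#' Assign each peak to one genomic feature category
#'
#' Categories are tested in the fixed precedence order promoter, 5' UTR,
#' intron, exon, 3' UTR, downstream, intergenic; a peak overlapping windows
#' of several categories (of any gene -- precedence is global across genes)
#' is assigned to the first. Overlap means >= 1 bp with any window of the
#' category. Every peak receives exactly one category.
#'
#' @param peaks peak data frame.
#' @param fmap `feature_map` from [build_feature_map()].
#' @return Factor of categories (levels in precedence order), one per peak.
#' @export
assign_region <- function(peaks, fmap) {
  known <- names(attr(fmap, "chrom_sizes"))
  if (nrow(peaks) && !all(peaks$chrom %in% known)) {
    stop("peak chromosome absent from feature map", call. = FALSE)
  }
  cats <- FEATURE_ORDER
  out <- rep("intergenic", nrow(peaks))
  unassigned <- rep(TRUE, nrow(peaks))
  for (cat in setdiff(cats, "intergenic")) {
    windows <- fmap[[cat]]
    if (is.null(windows) || nrow(windows) == 0) next
    hit <- unassigned & overlaps_any(peaks, windows)
    out[hit] <- cat
    unassigned <- unassigned & !hit
  }
  factor(out, levels = cats)
}

#' Category distribution of a peak set
#'
#' @param peaks peak data frame (>= 1 row).
#' @param fmap `feature_map`.
#' @return data frame `category`, `count`, `percent` (percentages sum
#'   to 100).
#' @export
region_distribution <- function(peaks, fmap) {
  if (nrow(peaks) == 0) stop("no peaks", call. = FALSE)
  cat <- assign_region(peaks, fmap)
  counts <- table(cat)
  data.frame(category = names(counts), count = as.integer(counts),
             percent = 100 * as.integer(counts) / nrow(peaks),
             stringsAsFactors = FALSE)
}

#' Enrichment of the observed category distribution over random placement
#'
#' Draws `reps` random peak sets, each with the same number and lengths as
#' the input (uniform start over the chromosome, chromosome sampled
#' proportional to its length, interval clipped at the chromosome end),
#' assigns categories with the same precedence rule, and averages the
#' per-category percentages; enrichment is observed% / mean random%.
#' No GC or mappability matching is attempted -- lengths only.
#'
#' @param peaks peak data frame.
#' @param fmap `feature_map`.
#' @param reps number of random replicates.
#' @param seed integer seed.
#' @return data frame `category`, `observed_percent`, `expected_percent`,
#'   `enrichment` (`Inf` when the random expectation is zero).
#' @export
random_baseline <- function(peaks, fmap, reps = 1000, seed = 1) {
  stopifnot(reps >= 1)
  sizes <- attr(fmap, "chrom_sizes")
  obs <- region_distribution(peaks, fmap)
  n <- nrow(peaks)
  widths <- peaks$end - peaks$start
  cats <- FEATURE_ORDER
  rand_pct <- with_seed(derive_seed(seed, 51), {
    # replicates drawn in batches (equal-size replicates, so pooled
    # category fractions equal the mean of per-replicate percentages)
    chunk <- max(1L, min(reps, floor(2e6 / max(n, 1))))
    counts <- stats::setNames(numeric(length(cats)), cats)
    total_drawn <- 0
    done <- 0
    while (done < reps) {
      r <- min(chunk, reps - done)
      total <- r * n
      ch <- sample(names(sizes), total, replace = TRUE,
                   prob = sizes / sum(sizes))
      start <- floor(stats::runif(total) * sizes[ch])
      w <- rep(widths, r)
      rnd <- data.frame(chrom = ch, start = start,
                        end = pmin(start + w, sizes[ch]),
                        stringsAsFactors = FALSE)
      rnd <- rnd[rnd$start < rnd$end, , drop = FALSE]
      cat <- assign_region(rnd, fmap)
      counts <- counts + table(cat)
      total_drawn <- total_drawn + nrow(rnd)
      done <- done + r
    }
    100 * counts / total_drawn
  })
  expected <- as.numeric(rand_pct[cats])
  observed <- stats::setNames(obs$percent, obs$category)[cats]
  data.frame(category = cats, observed_percent = unname(observed),
             expected_percent = expected,
             enrichment = ifelse(expected > 0, unname(observed) / expected,
                                 Inf),
             stringsAsFactors = FALSE)
}

#' Overlap of two peak sets from both perspectives
#'
#' Counts peaks of A overlapping any peak of B (>= 1 bp) and vice versa;
#' both numbers are reported because a single broad peak on one side can
#' absorb several on the other.
#'
#' @param peaks_a,peaks_b peak data frames.
#' @return Named vector: `a_overlapping`, `b_overlapping`, `a_only`,
#'   `b_only`.
#' @export
overlap_sets <- function(peaks_a, peaks_b) {
  a_hit <- overlaps_any(peaks_a, peaks_b)
  b_hit <- overlaps_any(peaks_b, peaks_a)
  c(a_overlapping = sum(a_hit), b_overlapping = sum(b_hit),
    a_only = sum(!a_hit), b_only = sum(!b_hit))
}
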