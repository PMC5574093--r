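# Expression preprocessing (probe filtering, gene collapse, z-scores, fold
# changes), the KS running-enrichment statistic linking binding presence to
# expression rank, and target-gene accounting.

#' Filter probe intensities to the analysis window
#'
#' Retains values between 300 and 20,000 inclusive ("below 300" and "above
#' 20,000" are removed, so the boundary values stay).
#'
#' @param values numeric vector of probe intensities.
#' @param lower,upper inclusive bounds.
#' @return Logical mask of retained probes.
#' @export
filter_probes <- function(values, lower = 300, upper = 20000) {
  values >= lower & values <= upper
}

#' Collapse probes to genes by median
#'
#' @param values numeric probe values.
#' @param genes gene id per probe.
#' @return Named numeric vector of per-gene medians (the median of an
#'   even-sized set is the midpoint of the central pair). Genes with no
#'   probes simply do not appear.
#' @export
collapse_probes <- function(values, genes) {
  tapply(values, genes, stats::median)
}

#' Z-score standardization across genes
#'
#' `(v - mean) / sd` with the population (divide-by-n) standard deviation:
#' the number of SDs a gene's expression lies from the mean over all genes.
#'
#' @param values numeric vector with >= 2 distinct values.
#' @return Standardized vector (mean 0, sd 1).
#' @export
zscore <- function(values) {
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))
  if (s == 0) stop("zero variance; z-scores undefined", call. = FALSE)
  (values - m) / s
}

# Asymptotic Kolmogorov upper tail Q(x) = 2 sum_{k>=1} (-1)^{k-1} e^{-2k^2x^2}
kolmogorov_q <- function(x) {
  if (x <= 0) return(1)
  k <- 1:100
  q <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * x^2))
  min(max(q, 0), 1)
}

#' KS running-enrichment of binding along an expression ranking
#'
#' With genes ranked (rank 1 first) and a bound/unbound flag per gene, the
#' running enrichment score is `D(r) = (#bound with rank <= r)/B - r/N`,
#' the cumulative excess of bound genes over the uniform expectation; the
#' signed statistic `d` is `D` at the rank maximizing `|D|` (leftmost on
#' ties). `d > 0` means bound genes concentrate at the top of the given
#' ranking. The p-value uses the asymptotic Kolmogorov distribution with
#' effective sample size B (the number of bound genes); a permutation
#' alternative is available via `n_perm`.
#'
#' @param bound_flags logical vector in ranked order (rank 1 first).
#' @param n_perm if > 0, also compute a permutation p-value from `n_perm`
#'   random re-assignments of the flags.
#' @param seed seed for the permutation p-value.
#' @return List: `d`, `rank_at_max`, `p_value`, `curve` (`D(r)`, r = 1..N),
#'   `n_genes`, `n_bound`, `degenerate`, and `p_perm` when requested.
#' @export
ks_running_enrichment <- function(bound_flags, n_perm = 0, seed = 1) {
  bound_flags <- as.logical(unname(bound_flags))
  N <- length(bound_flags)
  stopifnot(N >= 2)
  B <- sum(bound_flags)
  if (B == 0 || B == N) {
    return(list(d = 0, rank_at_max = NA_integer_, p_value = 1,
                curve = rep(0, N), n_genes = N, n_bound = B,
                degenerate = TRUE))
  }
  D <- cumsum(bound_flags) / B - seq_len(N) / N
  r_star <- which.max(abs(D))
  d <- D[r_star]
  p <- kolmogorov_q(sqrt(B) * abs(d))
  out <- list(d = d, rank_at_max = r_star, p_value = p, curve = D,
              n_genes = N, n_bound = B, degenerate = FALSE)
  if (n_perm > 0) {
    d_obs <- abs(d)
    hits <- with_seed(derive_seed(seed, 71), {
      sum(vapply(seq_len(n_perm), function(i) {
        Dp <- cumsum(sample(bound_flags)) / B - seq_len(N) / N
        max(abs(Dp)) >= d_obs
      }, logical(1)))
    })
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  out
}

#' Rank genes by expression fold change
#'
#' Two ranking modes: `"signed"` ranks from most downregulated to most
#' upregulated (fold change ascending), so `d > 0` in
#' [ks_running_enrichment()] means bound genes concentrate among
#' downregulated genes; `"absolute"` ranks by `|log2 fold change|`
#' descending (largest changes first). Ties are broken by gene id, so
#' rankings are deterministic.
#'
#' @param fold_change named (by gene id) vector of mutant/WT fold changes.
#' @param mode `"signed"` or `"absolute"`.
#' @return Character vector of gene ids in rank order.
#' @export
rank_genes <- function(fold_change, mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  ids <- names(fold_change)
  o <- switch(mode,
              signed = order(fold_change, ids),
              absolute = order(-abs(log2(fold_change)), ids))
  ids[o]
}

#' Per-gene fold change and Welch test from an expression table
#'
#' A plain two-sample Welch t statistic (optionally with a permutation
#' p-value) for simulated data; analyses of real microarray tables should
#' supply their own moderated-statistic results, which
#' [build_target_table()] accepts directly.
#'
#' @param expr expression data frame: `gene_id` plus `wt_*` and `mut_*`
#'   replicate columns (linear scale).
#' @param n_perm if > 0, permutation p-values replace the t p-values.
#' @param seed permutation seed.
#' @return data frame `gene_id`, `wt_mean`, `mut_mean`, `fold_change`
#'   (mutant/WT), `p_value`.
#' @export
differential_expression <- function(expr, n_perm = 0, seed = 1) {
  wt <- as.matrix(expr[, grep("^wt_", names(expr)), drop = FALSE])
  mut <- as.matrix(expr[, grep("^mut_", names(expr)), drop = FALSE])
  welch <- function(a, b) {
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- apply(a, 1, stats::var); vb <- apply(b, 1, stats::var)
    se2 <- va / na + vb / nb
    t <- (mb - ma) / sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
    2 * stats::pt(abs(t), df, lower.tail = FALSE)
  }
  p <- welch(wt, mut)
  if (n_perm > 0) {
    all <- cbind(wt, mut)
    # permutation on the Welch p directly: count permuted p <= observed p
    hits <- with_seed(derive_seed(seed, 72), {
      h <- numeric(nrow(all))
      for (i in seq_len(n_perm)) {
        idx <- sample(ncol(all))
        pp <- welch(all[, idx[seq_len(ncol(wt))], drop = FALSE],
                    all[, idx[-seq_len(ncol(wt))], drop = FALSE])
        h <- h + (pp <= p)
      }
      h
    })
    p <- (hits + 1) / (n_perm + 1)
  }
  data.frame(gene_id = expr$gene_id, wt_mean = rowMeans(wt),
             mut_mean = rowMeans(mut),
             fold_change = rowMeans(mut) / rowMeans(wt), p_value = p,
             stringsAsFactors = FALSE)
}

#' Flag genes bound in promoter, gene body and downstream windows
#'
#' A gene is bound in a region class when any peak overlaps the strand-aware
#' window by >= 1 bp: promoter = `promoter_up` bp upstream to
#' `promoter_down` bp downstream of the TSS; downstream = `downstream_up`
#' bp upstream to `downstream_down` bp downstream of the TTS; gene body =
#' the annotated gene interval; gene region = the union of all three.
#'
#' @param genes gene data frame.
#' @param peaks peak data frame.
#' @param region `"all"` for every flag, or one class.
#' @param promoter_up,promoter_down,downstream_up,downstream_down window
#'   extents (bp).
#' @return data frame of logical flags `promoter`, `gene_body`,
#'   `downstream`, `gene_region` (or the single requested column).
#' @export
assign_bound_flags <- function(genes, peaks,
                               region = c("all", "gene_region", "promoter",
                                          "gene_body", "downstream"),
                               promoter_up = 2500, promoter_down = 500,
                               downstream_up = 500, downstream_down = 2500) {
  region <- match.arg(region)
  pw <- anchored_window(genes$tss, promoter_up, promoter_down, genes$strand)
  dw <- anchored_window(genes$tts, downstream_up, downstream_down,
                        genes$strand)
  win_hit <- function(start, end) {
    df <- data.frame(chrom = genes$chrom, start = pmax(start, 0), end = end,
                     stringsAsFactors = FALSE)
    overlaps_any(df, peaks)
  }
  promoter <- win_hit(pw[, "start"], pw[, "end"])
  gene_body <- win_hit(genes$start, genes$end)
  downstream <- win_hit(dw[, "start"], dw[, "end"])
  flags <- data.frame(promoter = promoter, gene_body = gene_body,
                      downstream = downstream,
                      gene_region = promoter | gene_body | downstream)
  if (region == "all") flags else flags[, region, drop = FALSE]
}

#' Target-gene accounting table
#'
#' Cross-tabulates significantly changed genes (|fold change| beyond
#' `fold_threshold` in either direction and p below `p_threshold`) against
#' their cohesin-binding status: rows total / upregulated / downregulated,
#' columns total / gene region / promoter / gene body / downstream / none.
#' A gene may appear in several region columns but in exactly one of the
#' up/down rows. Derived percentages: bound-over-total and
#' downregulated-over-bound.
#'
#' @param de data frame with `gene_id`, `fold_change` (mutant/WT),
#'   `p_value` (e.g. [differential_expression()] output or an external
#'   moderated-statistic table).
#' @param flags data frame from [assign_bound_flags()] (rows parallel to
#'   `de`).
#' @param fold_threshold,p_threshold significance cutoffs.
#' @return List: `table` (3 x 6 matrix), `percent_bound` (gene-region-bound
#'   share of changed genes), `percent_down_of_bound`, `n_significant`,
#'   `n_bound`.
#' @export
build_target_table <- function(de, flags, fold_threshold = 1.2,
                               p_threshold = 0.05) {
  stopifnot(fold_threshold > 0, p_threshold > 0)
  fc <- de$fold_change
  sig <- de$p_value < p_threshold &
    (fc > fold_threshold | fc < 1 / fold_threshold)
  up <- sig & fc > 1
  down <- sig & fc < 1
  cols <- function(mask) {
    c(total = sum(mask),
      gene_region = sum(mask & flags$gene_region),
      promoter = sum(mask & flags$promoter),
      gene_body = sum(mask & flags$gene_body),
      downstream = sum(mask & flags$downstream),
      none = sum(mask & !flags$gene_region))
  }
  tab <- rbind(total = cols(sig), upregulated = cols(up),
               downregulated = cols(down))
  n_sig <- tab["total", "total"]
  n_bound <- tab["total", "gene_region"]
  list(table = tab,
       percent_bound = if (n_sig > 0) 100 * n_bound / n_sig else NA_real_,
       percent_down_of_bound = if (n_bound > 0) {
         100 * tab["downregulated", "gene_region"] / n_bound
       } else NA_real_,
       n_significant = n_sig, n_bound = n_bound)
}

#' Reconstruct a per-gene table from published marginal target counts
#'
#' Given the marginal counts of a published target-gene table (rows
#' up/downregulated, columns gene region / promoter / gene body /
#' downstream / none), builds a synthetic per-gene data frame whose flag
#' marginals reproduce those counts exactly (the joint arrangement of
#' overlapping region flags is arbitrary, which does not affect any
#' marginal statistic). Fold changes and p-values are set comfortably
#' inside/outside the cutoffs. Useful for checking the accounting
#' arithmetic against published tables.
#'
#' @param counts data frame with columns `direction` (`"up"`/`"down"`),
#'   `total`, `gene_region`, `promoter`, `gene_body`, `downstream`, `none`.
#' @return List: `de` and `flags` as accepted by [build_target_table()].
#' @export
expand_target_counts <- function(counts) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    stopifnot(r$gene_region + r$none == r$total,
              r$promoter <= r$gene_region, r$gene_body <= r$gene_region,
              r$downstream <= r$gene_region)
    n <- r$total
    g <- r$gene_region
    promoter <- gene_body <- downstream <- rep(FALSE, n)
    promoter[seq_len(r$promoter)] <- TRUE
    # place gene-body flags at the tail of the bound block so the union of
    # the region flags covers exactly the first g genes
    if (r$gene_body > 0) gene_body[(g - r$gene_body + 1):g] <- TRUE
    if (r$promoter + r$gene_body < g) {
      stop("promoter + gene body flags cannot cover the bound block",
           call. = FALSE)
    }
    if (r$downstream > 0) downstream[seq_len(r$downstream)] <- TRUE
    fc <- if (r$direction == "up") 2 else 0.5
    data.frame(direction = r$direction, fold_change = fc, p_value = 0.001,
               promoter = promoter, gene_body = gene_body,
               downstream = downstream,
               gene_region = c(rep(TRUE, g), rep(FALSE, n - g)),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  all$gene_id <- sprintf("gene_%03d", seq_len(nrow(all)))
  list(de = all[, c("gene_id", "fold_change", "p_value")],
       flags = all[, c("promoter", "gene_body", "downstream",
                       "gene_region")])
}
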