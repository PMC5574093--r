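# Chromosome conformation capture (3C) quantification: band intensities are
# normalized against a control template (primer-efficiency proxy) and a
# constitutive reference interaction, then compared between conditions.

#' Normalize 3C band intensities into interaction frequencies
#'
#' For every measurement, `frequency = (test / control_template) /
#' (reference_test / reference_control_template)`, replicate-wise: dividing
#' by the control-template band cancels the pair's primer efficiency, and
#' dividing by the same quantity at the constitutive reference locus
#' cancels sample-wide multiplicative factors (input amount, gel exposure).
#' The reference pair therefore has frequency 1 in every replicate by
#' construction.
#'
#' @param measurements data frame with columns `pair_id`, `sample`,
#'   `bio_rep`, `tech_rep` (optional), `test_intensity`,
#'   `template_intensity`, logical `is_reference` (exactly one reference
#'   pair per sample/replicate combination).
#' @return The input with a `frequency` column appended.
#' @export
normalize_interaction <- function(measurements) {
  m <- measurements
  req <- c("pair_id", "sample", "bio_rep", "test_intensity",
           "template_intensity", "is_reference")
  missing_cols <- setdiff(req, names(m))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"tech_rep" %in% names(m)) m$tech_rep <- 1L
  bad <- m$template_intensity <= 0 |
    (m$is_reference & m$test_intensity <= 0)
  if (any(bad)) {
    stop("nonpositive control intensity for pair '", m$pair_id[bad][1], "'",
         call. = FALSE)
  }
  key <- interaction(m$sample, m$bio_rep, m$tech_rep, drop = TRUE)
  ref <- m[m$is_reference, , drop = FALSE]
  ref_key <- interaction(ref$sample, ref$bio_rep, ref$tech_rep, drop = TRUE)
  if (anyDuplicated(ref_key) || !all(levels(key) %in% as.character(ref_key))) {
    stop("need exactly one reference measurement per sample/replicate",
         call. = FALSE)
  }
  ref_ratio <- (ref$test_intensity / ref$template_intensity)[
    match(as.character(key), as.character(ref_key))]
  m$frequency <- (m$test_intensity / m$template_intensity) / ref_ratio
  m
}

#' Average technical replicates within biological replicates
#'
#' Technical PCR replicates are averaged before any testing so that only
#' biological replicates contribute degrees of freedom.
#'
#' @param normalized output of [normalize_interaction()].
#' @return data frame `pair_id`, `sample`, `bio_rep`, `frequency`.
#' @export
collapse_technical <- function(normalized) {
  agg <- stats::aggregate(frequency ~ pair_id + sample + bio_rep,
                          data = normalized, FUN = mean)
  agg[order(agg$pair_id, agg$sample, agg$bio_rep), , drop = FALSE]
}

#' Compare normalized interaction frequencies between conditions
#'
#' Ratio of means and a two-sided Welch t-test on per-(biological-)
#' replicate normalized frequencies; a permutation p-value is available for
#' very small replicate numbers.
#'
#' @param freqs_a,freqs_b numeric vectors (>= 2 replicates each).
#' @param n_perm if > 0, a label-permutation p-value is also returned.
#' @param seed permutation seed.
#' @return List: `ratio` (mean A / mean B), `p_value`, optional `p_perm`.
#' @export
compare_conditions <- function(freqs_a, freqs_b, n_perm = 0, seed = 1) {
  if (length(freqs_a) < 2 || length(freqs_b) < 2) {
    stop("need >= 2 replicates per condition", call. = FALSE)
  }
  ratio <- mean(freqs_a) / mean(freqs_b)
  if (stats::var(freqs_a) == 0 && stats::var(freqs_b) == 0) {
    p <- if (mean(freqs_a) == mean(freqs_b)) 1 else 0
  } else {
    p <- stats::t.test(freqs_a, freqs_b)$p.value
  }
  out <- list(ratio = ratio, p_value = p)
  if (n_perm > 0) {
    obs <- abs(mean(freqs_a) - mean(freqs_b))
    pool <- c(freqs_a, freqs_b)
    na <- length(freqs_a)
    hits <- with_seed(derive_seed(seed, 81), {
      sum(vapply(seq_len(n_perm), function(i) {
        idx <- sample(length(pool), na)
        abs(mean(pool[idx]) - mean(pool[-idx])) >= obs
      }, logical(1)))
    })
    out$p_perm <- (hits + 1) / (n_perm + 1)
  }
  out
}
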