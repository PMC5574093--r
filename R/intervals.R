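#' Genomic interval conventions
#'
#' All coordinates inside the package are 0-based, half-open (`[start, end)`),
#' i.e. the BED convention. Intervals are plain data frames with columns
#' `chrom`, `start`, `end` and optionally `name`, `score`, `strand`. A single
#' convention everywhere removes off-by-one drift between modules; anything
#' 1-based (e.g. GRanges used internally for overlap queries) is converted at
#' the boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open.
#' @param strand optional strand vector, each element one of `"+"`, `"-"`, `"."`.
#' @param name,score optional name/score columns.
#' @return A validated interval data frame.
#' @export
genomic_intervals <- function(chrom, start, end, strand = NULL, name = NULL,
                              score = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(name)) df$name <- as.character(name)
  if (!is.null(score)) df$score <- as.numeric(score)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
  df
}

#' Validate an interval data frame
#'
#' Rejects (never silently coerces) invariant-violating input:
#' missing columns, empty chromosome names, non-finite or negative
#' coordinates, `start >= end`, unknown strand symbols.
#'
#' @param df data frame with at least `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `df`, invisibly.
#' @export
validate_intervals <- function(df, what = "interval") {
  req <- c("chrom", "start", "end")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table lacks column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) return(invisible(df))
  if (any(!nzchar(df$chrom) | is.na(df$chrom))) {
    stop(sprintf("%s: empty chromosome name", what), call. = FALSE)
  }
  if (any(!is.finite(df$start)) || any(!is.finite(df$end))) {
    stop(sprintf("%s: non-finite coordinates", what), call. = FALSE)
  }
  if (any(df$start < 0)) {
    stop(sprintf("%s: negative start coordinate", what), call. = FALSE)
  }
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("%s: start >= end at record %d (%s:%g-%g)", what, bad[1],
                 df$chrom[bad[1]], df$start[bad[1]], df$end[bad[1]]),
         call. = FALSE)
  }
  if ("strand" %in% names(df) && !all(df$strand %in% c("+", "-", "."))) {
    stop(sprintf("%s: strand must be one of '+', '-', '.'", what),
         call. = FALSE)
  }
  invisible(df)
}

# 0-based half-open data frame -> 1-based closed GRanges (internal).
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[strand == "."] <- "*"
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L,
                                          end = df$end),
                         strand = strand)
}

# Logical: does each interval in `query` overlap (>= min_overlap bp) any in
# `subject`? Both 0-based half-open data frames.
overlaps_any <- function(query, subject, min_overlap = 1L) {
  if (nrow(subject) == 0 || nrow(query) == 0) {
    return(rep(FALSE, nrow(query)))
  }
  IRanges::overlapsAny(as_granges(query), as_granges(subject),
                       minoverlap = min_overlap, ignore.strand = TRUE)
}

# Count subject intervals hit by each query interval.
count_overlaps <- function(query, subject, min_overlap = 1L) {
  if (nrow(subject) == 0 || nrow(query) == 0) {
    return(rep(0L, nrow(query)))
  }
  GenomicRanges::countOverlaps(as_granges(query), as_granges(subject),
                               minoverlap = min_overlap,
                               ignore.strand = TRUE)
}

# Strand-aware window around an anchor position (0-based).
# `up` bases upstream and `down` bases downstream of the anchor, where
# upstream means smaller coordinates on '+' and larger coordinates on '-'.
# The anchor base itself counts as the first downstream base.
anchored_window <- function(anchor, up, down, strand) {
  plus <- strand == "+"
  start <- ifelse(plus, anchor - up, anchor - down + 1)
  end <- ifelse(plus, anchor + down, anchor + up + 1)
  cbind(start = start, end = end)
}

# Clip interval data frame to [0, chrom length); drops emptied records.
clip_to_chrom <- function(df, chrom_sizes) {
  if (nrow(df) == 0) return(df)
  len <- unname(chrom_sizes[df$chrom])
  if (any(is.na(len))) {
    stop("interval on chromosome absent from chrom_sizes", call. = FALSE)
  }
  df$start <- pmax(df$start, 0)
  df$end <- pmin(df$end, len)
  df[df$start < df$end, , drop = FALSE]
}
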