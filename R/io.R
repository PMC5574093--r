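#' Read a BED file
#'
#' Reads BED3/BED6-style files into the package's 0-based half-open interval
#' data frame. Column 4 becomes `name`, column 5 `score`, column 6 `strand`.
#' Input order is preserved and every record is validated; malformed input is
#' an error, never a silent coercion.
#'
#' @param path path to a tab-separated BED file.
#' @return Interval data frame (see [genomic_intervals()]).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 columns",
                 which(nf < 3)[1]), call. = FALSE)
  }
  ncol <- min(nf)
  m <- matrix(unlist(lapply(fields, `[`, seq_len(ncol))),
              ncol = ncol, byrow = TRUE)
  start <- suppressWarnings(as.numeric(m[, 2]))
  end <- suppressWarnings(as.numeric(m[, 3]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1]),
         call. = FALSE)
  }
  df <- data.frame(chrom = m[, 1], start = start, end = end,
                   stringsAsFactors = FALSE)
  if (ncol >= 4) df$name <- m[, 4]
  if (ncol >= 5) df$score <- suppressWarnings(as.numeric(m[, 5]))
  if (ncol >= 6) df$strand <- m[, 6]
  validate_intervals(df, what = basename(path))
  df
}

#' Write intervals as BED
#'
#' Inverse of [read_bed()]: `read_bed(write_bed(x, f))` returns `x` with
#' records in the same order.
#'
#' @param df interval data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(df))
  # BED columns are positional: stop at the first absent optional column.
  keep <- c("chrom", "start", "end")
  for (extra in c("name", "score", "strand")) {
    if (extra %in% cols) keep <- c(keep, extra) else break
  }
  out <- df[, keep, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read aligned reads with multi-mapping groups
#'
#' Consumes a BED-like file of read alignments in which column 4 carries the
#' read identifier; rows sharing a read id are alternative alignments of the
#' same (multi-mapping) read. Each read's alignment probabilities are
#' initialized uniformly over its alignments, the maximum-entropy starting
#' point for the EM re-weighting in [run_em()].
#'
#' @param path BED file with >= 4 columns (column 4 = read id).
#' @return Alignment data frame with columns `read_id`, `chrom`, `start`,
#'   `end`, `weight`, sorted so that alignments of one read are contiguous.
#'   Weights of each read sum to 1.
#' @export
read_alignments <- function(path) {
  df <- read_bed(path)
  if (nrow(df) == 0) {
    return(data.frame(read_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!"name" %in% names(df)) {
    stop("alignment file needs a 4th column with read ids", call. = FALSE)
  }
  alignments(df$name, df$chrom, df$start, df$end)
}

#' Build an alignment table from vectors
#'
#' @param read_id read identifiers; repeated ids are alternative alignments.
#' @param chrom,start,end alignment coordinates (0-based half-open).
#' @return Alignment data frame as in [read_alignments()].
#' @export
alignments <- function(read_id, chrom, start, end) {
  df <- data.frame(read_id = as.character(read_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  validate_intervals(df, what = "alignments")
  df <- df[order(df$read_id), , drop = FALSE]
  width <- df$end - df$start
  w_by_read <- tapply(width, df$read_id, function(w) length(unique(w)))
  if (any(w_by_read > 1)) {
    stop("alignments of unequal length within read '",
         names(w_by_read)[w_by_read > 1][1], "'", call. = FALSE)
  }
  n_aln <- table(df$read_id)
  df$weight <- 1 / as.numeric(n_aln[df$read_id])
  rownames(df) <- NULL
  df
}

#' Write alignments as BED
#'
#' @param aln alignment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(aln, path) {
  write_bed(data.frame(chrom = aln$chrom, start = aln$start, end = aln$end,
                       name = aln$read_id, stringsAsFactors = FALSE), path)
}

#' Read a MEME-minimal position weight matrix
#'
#' Parses the first `letter-probability matrix` block of a MEME-minimal text
#' file, along with the optional `Background letter frequencies` line
#' (uniform if absent). Rows must sum to 1 within 1e-6. The pseudocount is a
#' property of scoring, not of the file, and is applied in
#' [logodds_score()].
#'
#' @param path MEME-minimal text file.
#' @param pseudocount pseudocount stored with the PWM for later scoring.
#' @return A `pwm` object: list with `mat` (L x 4 probability matrix, columns
#'   A, C, G, T), `bg` (background frequencies), `pseudocount`, `name`.
#' @export
read_pwm <- function(path, pseudocount = 1e-3) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  bg <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    vals <- as.numeric(toks[seq(2, length(toks), by = 2)])
    names(vals) <- toks[seq(1, length(toks), by = 2)]
    bg <- vals[c("A", "C", "G", "T")]
  }
  name_i <- grep("^MOTIF", lines)
  name <- if (length(name_i)) {
    strsplit(trimws(lines[name_i[1]]), "\\s+")[[1]][2]
  } else "motif"
  hdr_i <- grep("letter-probability matrix", lines)
  if (!length(hdr_i)) {
    stop("no letter-probability matrix block in ", path, call. = FALSE)
  }
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[hdr_i[1]]))
  rows <- lines[(hdr_i[1] + 1):(hdr_i[1] + w)]
  mat <- do.call(rbind, lapply(rows, function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  }))
  if (ncol(mat) != 4 || nrow(mat) != w || anyNA(mat)) {
    stop("malformed letter-probability matrix in ", path, call. = FALSE)
  }
  colnames(mat) <- c("A", "C", "G", "T")
  pwm(mat, bg = bg, pseudocount = pseudocount, name = name)
}

#' Construct a PWM object
#'
#' @param mat L x 4 matrix of per-position base probabilities (columns
#'   A, C, G, T); each row must sum to 1 within 1e-6.
#' @param bg background frequencies over A, C, G, T (sum 1 within 1e-6).
#' @param pseudocount nonnegative pseudocount applied at score time.
#' @param name motif name.
#' @return A `pwm` object.
#' @export
pwm <- function(mat, bg = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                pseudocount = 1e-3, name = "motif") {
  mat <- as.matrix(mat)
  colnames(mat) <- c("A", "C", "G", "T")
  if (any(abs(rowSums(mat) - 1) > 1e-6)) {
    stop("PWM row(s) do not sum to 1 within 1e-6", call. = FALSE)
  }
  if (abs(sum(bg) - 1) > 1e-6) {
    stop("background frequencies do not sum to 1 within 1e-6", call. = FALSE)
  }
  if (pseudocount < 0) stop("pseudocount must be >= 0", call. = FALSE)
  structure(list(mat = mat, bg = bg, pseudocount = pseudocount, name = name),
            class = "pwm")
}

#' Write a PWM in MEME-minimal format
#'
#' @param x `pwm` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.6f C %.6f G %.6f T %.6f",
                       x$bg[1], x$bg[2], x$bg[3], x$bg[4]), "",
               sprintf("MOTIF %s", x$name),
               sprintf("letter-probability matrix: alength= 4 w= %d",
                       nrow(x$mat))), con)
  writeLines(apply(x$mat, 1, function(r) {
    paste(sprintf("%.6f", r), collapse = " ")
  }), con)
  invisible(path)
}

#' Read gene models
#'
#' Accepts either a header-carrying TSV with columns `gene_id`, `chrom`,
#' `strand`, `start`, `end`, `exon_starts`, `exon_ends` (comma-separated,
#' 0-based half-open; optional `cds_start`, `cds_end` enabling UTR-aware
#' annotation) or a BED12 file (in which case `thickStart`/`thickEnd` supply
#' the CDS). TSS is `start` on '+' genes and `end - 1` on '-' genes; TTS is
#' the opposite end.
#'
#' @param path gene model file (TSV with header, or BED12).
#' @return Gene data frame with columns `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `tss`, `tts`, optional `cds_start`/`cds_end`, and
#'   list-columns `exon_starts`, `exon_ends`.
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  first <- readLines(path, n = 1)
  if (grepl("^gene_id\t", first)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    req <- c("gene_id", "chrom", "strand", "start", "end",
             "exon_starts", "exon_ends")
    missing_cols <- setdiff(req, names(df))
    if (length(missing_cols)) {
      stop("gene table lacks column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    genes <- data.frame(gene_id = df$gene_id, chrom = df$chrom,
                        strand = df$strand, start = as.numeric(df$start),
                        end = as.numeric(df$end), stringsAsFactors = FALSE)
    genes$exon_starts <- lapply(strsplit(as.character(df$exon_starts), ","),
                                as.numeric)
    genes$exon_ends <- lapply(strsplit(as.character(df$exon_ends), ","),
                              as.numeric)
    if (all(c("cds_start", "cds_end") %in% names(df))) {
      genes$cds_start <- as.numeric(df$cds_start)
      genes$cds_end <- as.numeric(df$cds_end)
    }
  } else {
    bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(bed) < 12) {
      stop("gene BED must be BED12 or a TSV with a gene_id header",
           call. = FALSE)
    }
    genes <- data.frame(gene_id = bed[[4]], chrom = bed[[1]],
                        strand = bed[[6]], start = as.numeric(bed[[2]]),
                        end = as.numeric(bed[[3]]), stringsAsFactors = FALSE)
    genes$cds_start <- as.numeric(bed[[7]])
    genes$cds_end <- as.numeric(bed[[8]])
    sizes <- lapply(strsplit(as.character(bed[[11]]), ","), as.numeric)
    offs <- lapply(strsplit(as.character(bed[[12]]), ","), as.numeric)
    genes$exon_starts <- Map(function(s, o) s + o, genes$start, offs)
    genes$exon_ends <- Map(`+`, genes$exon_starts, sizes)
  }
  validate_genes(genes)
}

validate_genes <- function(genes) {
  validate_intervals(genes, what = "genes")
  if (!all(genes$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  for (i in seq_len(nrow(genes))) {
    es <- genes$exon_starts[[i]]
    ee <- genes$exon_ends[[i]]
    if (length(es) != length(ee) || any(es >= ee) ||
        any(es < genes$start[i]) || any(ee > genes$end[i]) ||
        is.unsorted(es, strictly = TRUE)) {
      stop("invalid exon structure for gene ", genes$gene_id[i],
           call. = FALSE)
    }
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  genes$tts <- ifelse(genes$strand == "+", genes$end - 1, genes$start)
  genes
}

#' Write gene models as TSV
#'
#' @param genes gene data frame (see [read_genes()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genes <- function(genes, path) {
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    strand = genes$strand, start = genes$start,
                    end = genes$end,
                    exon_starts = vapply(genes$exon_starts, paste,
                                         character(1), collapse = ","),
                    exon_ends = vapply(genes$exon_ends, paste,
                                       character(1), collapse = ","),
                    stringsAsFactors = FALSE)
  if (all(c("cds_start", "cds_end") %in% names(genes))) {
    out$cds_start <- genes$cds_start
    out$cds_end <- genes$cds_end
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a header-checked TSV
#'
#' @param path TSV file with a header row.
#' @param required character vector of column names that must be present.
#' @return data frame.
#' @export
read_table <- function(path, required = character()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(basename(path), " lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a genome FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that trims FASTA
#' descriptions to the sequence name.
#'
#' @param path FASTA file.
#' @return `DNAStringSet` named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Chromosome sizes of a genome
#'
#' @param genome `DNAStringSet`.
#' @return Named numeric vector of sequence lengths.
#' @export
chrom_sizes <- function(genome) {
  stats::setNames(as.numeric(Biostrings::width(genome)), names(genome))
}
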