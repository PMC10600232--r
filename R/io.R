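# Readers/writers for the plain-text formats the pipeline touches, plus the
# interval algebra shared by every stage. All internal coordinates are 0-based
# half-open (BED convention); SNP positions are accepted 1-based (VCF-like)
# and shifted on read. Chromosome names are compared as exact strings.

#' Validate a set of genomic intervals
#'
#' Checks the basic interval invariants used throughout the package:
#' non-empty chromosome names, `start >= 0`, `end > start`.
#'
#' @param x data.frame with columns `chrom`, `start`, `end`.
#' @param what label used in error messages.
#' @return `x`, invisibly; errors otherwise.
#' @keywords internal
check_intervals <- function(x, what = "interval") {
  stopifnot(is.data.frame(x), all(c("chrom", "start", "end") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(as.character(x$chrom)))) {
    stop(what, ": chromosome names must be non-empty")
  }
  if (any(x$start < 0)) stop(what, ": start must be >= 0")
  if (any(x$end <= x$start)) stop(what, ": end must be > start")
  invisible(x)
}

# 0-based half-open data.frame -> 1-based closed GRanges
as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = as.character(x$chrom),
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

#' Overlapping pairs between two interval sets
#'
#' Reports every pair of intervals, one from `a` and one from `b`, that share
#' at least one base on the same chromosome (exact string match), together
#' with the overlap length. Half-open arithmetic: abutting intervals
#' (`[0,10)` vs `[10,20)`) do not overlap.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @return data.frame with columns `query` (row index in `a`), `subject`
#'   (row index in `b`) and `overlap` (shared bases,
#'   `min(ends) - max(starts) > 0`).
#' @examples
#' a <- data.frame(chrom = "chr1", start = 0, end = 10)
#' b <- data.frame(chrom = "chr1", start = c(10, 5), end = c(20, 8))
#' intervals_overlap(a, b)  # only the second b interval, overlap 3
#' @export
intervals_overlap <- function(a, b) {
  check_intervals(a, "a")
  check_intervals(b, "b")
  if (nrow(a) == 0L || nrow(b) == 0L) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  }
  gra <- as_granges(a)
  grb <- as_granges(b)
  hits <- GenomicRanges::findOverlaps(gra, grb, minoverlap = 1L)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[q], b$end[s]) - pmax(a$start[q], b$start[s])
  data.frame(query = q, subject = s, overlap = as.integer(ov))
}

#' Read ATAC-seq peaks from a narrowPeak file
#'
#' Parses the 10-column ENCODE narrowPeak dialect (BED6+4). The peak
#' significance is taken from the `-log10(p-value)` column (column 8) and the
#' summit is reconstructed from the offset in column 10
#' (`summit = start + offset`).
#'
#' @param path path to a narrowPeak file (no header).
#' @param sample_id sample identifier attached to every peak; defaults to the
#'   file name without extension.
#' @return data.frame of peaks with columns `chrom`, `start`, `end`, `name`,
#'   `summit` (absolute, 0-based), `score` (-log10 p, non-negative) and
#'   `sample_id`.
#' @export
read_narrowpeak <- function(path, sample_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    return(empty_peaks())
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "", blank.lines.skip = TRUE)
  if (nrow(raw) == 0L) {
    return(empty_peaks())
  }
  if (ncol(raw) != 10L) {
    stop("narrowPeak file must have 10 columns, found ", ncol(raw))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("malformed narrowPeak row at line ", bad[1L],
           " (column ", col, " not numeric)")
    }
    v
  }
  start <- num(2L)
  end <- num(3L)
  pval <- num(8L)
  offset <- num(10L)
  peaks <- data.frame(
    chrom = raw[[1L]], start = as.integer(start), end = as.integer(end),
    name = raw[[4L]], summit = as.integer(start + offset), score = pval,
    sample_id = sample_id, stringsAsFactors = FALSE
  )
  check_intervals(peaks, "narrowPeak")
  bad <- which(offset < 0 | offset >= (end - start))
  if (length(bad)) {
    stop("narrowPeak line ", bad[1L], ": summit offset ", offset[bad[1L]],
         " outside peak of length ", end[bad[1L]] - start[bad[1L]])
  }
  if (any(peaks$score < 0)) stop("narrowPeak: negative -log10(p) score")
  peaks
}

empty_peaks <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), summit = integer(), score = numeric(),
             sample_id = character(), stringsAsFactors = FALSE)
}

#' Write peaks to a narrowPeak file
#'
#' Inverse of [read_narrowpeak()]: emits the 10-column dialect with the
#' summit encoded as an offset from `start`.
#'
#' @param peaks data.frame as returned by [read_narrowpeak()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    if ("name" %in% names(peaks)) peaks$name else ".",
    0L, ".", 0, peaks$score, -1, peaks$summit - peaks$start
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from a TSV table
#'
#' Expects a header line with at least `chrom`, `start`, `end`, `strand`,
#' `gene_id`; any further columns (e.g. a logical `cosmic` membership flag)
#' are carried through. The TSS is derived from the strand: `start` for `+`,
#' `end - 1` for `-`.
#'
#' @param path path to the TSV file.
#' @return data.frame of gene models with a computed `tss` column.
#' @export
read_gene_table <- function(path) {
  stopifnot(file.exists(path))
  genes <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "start", "end", "strand", "gene_id")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  gene_models(genes)
}

#' Construct gene models from a data.frame
#'
#' Validates intervals and strands, rejects duplicate gene ids and computes
#' the TSS (`start` on `+`, `end - 1` on `-`).
#'
#' @param genes data.frame with `chrom`, `start`, `end`, `strand`, `gene_id`.
#' @return the same data.frame with a `tss` column added.
#' @export
gene_models <- function(genes) {
  check_intervals(genes, "gene")
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  ok <- genes$strand %in% c("+", "-")
  if (!all(ok)) {
    stop("unknown strand symbol '", genes$strand[!ok][1L],
         "' (must be + or -)")
  }
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  genes
}

#' Write gene models to TSV
#' @param genes data.frame of gene models.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes[setdiff(names(genes), "tss")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-SNP allelic counts
#'
#' TSV with header columns `chrom`, `pos` (1-based), `ref`, `alt`,
#' `wgs_ref`, `wgs_alt`, `atac_ref`, `atac_alt`, `sample_id`. Positions are
#' stored 0-based internally; all counts must be non-negative integers
#' (all-zero rows are accepted and removed by downstream filters).
#'
#' @param path path to the TSV file.
#' @return data.frame of SNP allelic records with 0-based `pos`.
#' @export
read_allelic_counts <- function(path) {
  stopifnot(file.exists(path))
  snps <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
  need <- c("chrom", "pos", "ref", "alt", "wgs_ref", "wgs_alt",
            "atac_ref", "atac_alt", "sample_id")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("allelic count table missing column(s): ",
                         paste(miss, collapse = ", "))
  counts <- c("wgs_ref", "wgs_alt", "atac_ref", "atac_alt")
  for (col in counts) {
    if (any(snps[[col]] < 0)) stop("negative count in column ", col)
    snps[[col]] <- as.integer(snps[[col]])
  }
  if (any(snps$pos < 1)) stop("1-based positions must be >= 1")
  snps$pos <- as.integer(snps$pos) - 1L
  snps
}

#' Write per-SNP allelic counts (positions back to 1-based)
#' @param snps data.frame of SNP records with internal 0-based `pos`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_allelic_counts <- function(snps, path) {
  out <- snps
  out$pos <- out$pos + 1L
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromatin-state segmentation from BED4
#'
#' @param path BED4 file: `chrom`, `start`, `end`, state label; no header.
#' @return data.frame with columns `chrom`, `start`, `end`, `state`.
#' @export
read_state_bed <- function(path) {
  stopifnot(file.exists(path))
  seg <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           col.names = c("chrom", "start", "end", "state"))
  check_intervals(seg, "state segment")
  seg
}

#' Read a numeric matrix from TSV (first column = row labels)
#' @param path TSV with a header; first column holds row names.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                          check.names = FALSE, quote = "")
  as.matrix(df)
}

#' Write a numeric matrix to TSV
#' @param mat matrix with dimnames.
#' @param path output path.
#' @param id_col header name of the row-label column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE)
  names(df)[1L] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
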