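# Fragment records: reading BED-style fragment files, length filtering,
# interval assignment, and end-motif extraction.
#
# Coordinates are BED-style 0-based half-open throughout the package; a
# fragment's length is end - start in bp.

#' Construct a per-sample fragment container
#'
#' @param sample_id Sample identifier.
#' @param fragments `data.frame` with columns `chrom`, `start`, `end` (BED
#'   0-based half-open) and optionally `motif5` / `motif3` (4-mer end
#'   motifs, `NA` when unknown). A `length` column is (re)computed.
#' @return An object of class `sample_fragments`: a list with elements
#'   `sample_id`, `fragments`, `total_reads` (the retained fragment count,
#'   used as the depth denominator downstream).
#' @export
sample_fragments <- function(sample_id, fragments) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end") %in% names(fragments)))
  if (nrow(fragments)) {
    bad <- which(!(fragments$start < fragments$end) | fragments$start < 0)
    if (length(bad))
      stop("invalid fragment interval(s) at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
  }
  fragments$length <- fragments$end - fragments$start
  structure(list(sample_id = as.character(sample_id),
                 fragments = fragments,
                 total_reads = nrow(fragments)),
            class = "sample_fragments")
}

#' @export
print.sample_fragments <- function(x, ...) {
  cat("<sample_fragments> ", x$sample_id, ": ", x$total_reads,
      " fragments\n", sep = "")
  invisible(x)
}

#' Read a fragment BED file
#'
#' Parses a 3+ column tab-separated BED file of sequenced cfDNA fragments.
#' Columns 4 and 5, when present, are taken as the 5' and 3' 4-mer end
#' motifs. No length filtering is applied here; see [filter_by_length()].
#'
#' @param path Path to the BED file. Lines starting with `#` are skipped.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @return A [sample_fragments] object.
#' @export
read_fragment_bed <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (!any(keep)) {
    return(sample_fragments(sample_id, data.frame(
      chrom = character(0), start = integer(0), end = integer(0))))
  }
  lineno <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncols <- lengths(parts)
  if (any(ncols < 3L))
    stop("line ", lineno[which(ncols < 3L)[1L]], ": fewer than 3 columns")
  chrom <- vapply(parts, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 2L)))
  end   <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": malformed coordinates")
  bad <- which(start >= end | start < 0L)
  if (length(bad))
    stop("line ", lineno[bad[1L]], ": invalid interval (start >= end)")
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (any(ncols >= 5L)) {
    get_col <- function(j) toupper(vapply(parts, function(p)
      if (length(p) >= j) p[[j]] else NA_character_, ""))
    df$motif5 <- get_col(4L)
    df$motif3 <- get_col(5L)
  }
  sample_fragments(sample_id, df)
}

#' Write fragments as BED
#'
#' Three required columns plus motif columns 4-5 when motifs are present.
#'
#' @param x A [sample_fragments] object.
#' @param path Output path.
#' @export
write_fragment_bed <- function(x, path) {
  stopifnot(inherits(x, "sample_fragments"))
  fr <- x$fragments
  cols <- c("chrom", "start", "end")
  if (!is.null(fr$motif5) && !is.null(fr$motif3))
    cols <- c(cols, "motif5", "motif3")
  write.table(fr[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Retain fragments by insert size
#'
#' Keeps fragments whose length lies in `[min_bp, max_bp]`, both bounds
#' inclusive, and updates `total_reads`. The defaults retain inserts
#' between 20 and 500 bp, the standard cfDNA analysis window; the retained
#' count is the per-sample denominator for normalized depth.
#'
#' @param x A [sample_fragments] object.
#' @param min_bp,max_bp Inclusive length bounds in bp.
#' @return A filtered [sample_fragments] object.
#' @export
filter_by_length <- function(x, min_bp = 20, max_bp = 500) {
  stopifnot(inherits(x, "sample_fragments"))
  if (min_bp > max_bp) stop("min_bp must be <= max_bp")
  keep <- x$fragments$length >= min_bp & x$fragments$length <= max_bp
  fr <- x$fragments[keep, , drop = FALSE]
  rownames(fr) <- NULL
  sample_fragments(x$sample_id, fr)
}

# interval data.frame -> GRanges (1-based closed, as GenomicRanges expects)
.as_granges <- function(df) {
  GRanges(seqnames = df$chrom,
          ranges = IRanges(start = df$start + 1L, end = df$end))
}

#' Assign fragments to overlapping regions
#'
#' A fragment is assigned to every region it overlaps by at least
#' `min_overlap_bp`; a fragment spanning several regions is therefore
#' counted once per region (the multi-assignment convention used for all
#' region-level metrics). Fragments overlapping no region appear nowhere
#' in the result.
#'
#' @param fragments `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open) or a [sample_fragments] object.
#' @param regions `data.frame` of regions with `chrom`, `start`, `end` and
#'   an identifier column `id` (falls back to `exon_id`, then `name`, then
#'   row numbers).
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return Named list, one element per region (in input order), each an
#'   integer vector of fragment row indices; empty for regions with no
#'   overlapping fragment.
#' @export
overlap_assign <- function(fragments, regions, min_overlap_bp = 1L) {
  if (inherits(fragments, "sample_fragments")) fragments <- fragments$fragments
  ids <- regions$id
  if (is.null(ids)) ids <- regions$exon_id
  if (is.null(ids)) ids <- regions$name
  if (is.null(ids)) ids <- as.character(seq_len(nrow(regions)))
  out <- rep(list(integer(0)), nrow(regions))
  names(out) <- ids
  if (!nrow(fragments) || !nrow(regions)) return(out)
  hits <- findOverlaps(.as_granges(fragments), .as_granges(regions),
                       minoverlap = as.integer(min_overlap_bp))
  if (length(hits)) {
    sp <- split(queryHits(hits),
                factor(subjectHits(hits), levels = seq_len(nrow(regions))))
    out <- setNames(lapply(sp, as.integer), ids)
  }
  out
}

#' Extract 4-mer end motifs from a reference sequence
#'
#' Populates `motif5` with the first four reference bases of each fragment
#' interval and `motif3` with, by default, the reverse complement of the
#' last four bases (reading into the fragment from its 3' end, the
#' convention of the end-motif literature). `three_prime = "plus"` instead
#' records the plus-strand sequence literally, matching a naive
#' `bedtools getfasta` extraction without strand awareness. Motif windows
#' containing non-ACGT bases (e.g. N) yield `NA` motifs, which excludes
#' those fragments from motif counting.
#'
#' @param x A [sample_fragments] object; all fragments must be length >= 4.
#' @param reference A named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or a path to a FASTA file.
#' @param three_prime `"revcomp"` (default) or `"plus"`; recorded in the
#'   `motif_mode` attribute of the result.
#' @return `x` with `motif5`/`motif3` columns populated.
#' @export
extract_end_motifs <- function(x, reference,
                               three_prime = c("revcomp", "plus")) {
  stopifnot(inherits(x, "sample_fragments"))
  three_prime <- match.arg(three_prime)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- Biostrings::readDNAStringSet(reference)
  if (inherits(reference, "DNAStringSet")) {
    seqs <- setNames(as.character(reference), names(reference))
    # FASTA headers may carry descriptions; keep the first token
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else {
    seqs <- reference
  }
  fr <- x$fragments
  if (!nrow(fr)) return(x)
  if (any(fr$length < 4L)) stop("all fragments must be >= 4 bp for motifs")
  miss <- setdiff(unique(fr$chrom), names(seqs))
  if (length(miss)) stop("reference missing chromosome(s): ",
                         paste(miss, collapse = ", "))
  m5 <- character(nrow(fr)); m3 <- character(nrow(fr))
  for (ch in unique(fr$chrom)) {
    s <- toupper(seqs[[ch]])
    i <- which(fr$chrom == ch)
    if (any(fr$end[i] > nchar(s)) || any(fr$start[i] < 0L))
      stop("fragment interval outside reference on ", ch)
    m5[i] <- substring(s, fr$start[i] + 1L, fr$start[i] + 4L)
    m3[i] <- substring(s, fr$end[i] - 3L, fr$end[i])
  }
  if (three_prime == "revcomp") m3 <- revcomp(m3)
  ok5 <- grepl("^[ACGT]{4}$", m5); ok3 <- grepl("^[ACGT]{4}$", m3)
  fr$motif5 <- ifelse(ok5, m5, NA_character_)
  fr$motif3 <- ifelse(ok3, m3, NA_character_)
  out <- sample_fragments(x$sample_id, fr)
  attr(out, "motif_mode") <- three_prime
  out
}
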