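# Region systems: the targeted exon panel with first-coding-exon (E1)
# designation, TFBS collections ranked by experimental support, ATAC
# open-chromatin sets per cancer type, and commercial gene-list subsetting.

#' Construct a panel definition from exon records
#'
#' Builds the gene -> exon map and designates each gene's E1 feature
#' window: the coding exon with transcript rank 1 when present, otherwise
#' the lowest-rank coding exon on the panel ("closest" in transcript
#' order to the transcription start site). Genes with no coding exon are
#' excluded from the E1 map with a warning.
#'
#' @param exons `data.frame` with columns `chrom`, `start`, `end`, `gene`,
#'   `exon_rank` (positive integer, transcript order), `is_coding`
#'   (logical).
#' @return An object of class `panel_def`: list with `exons` (the input
#'   plus an `exon_id` column `GENE:exonRANK`), `genes`, and `e1_map`
#'   (named character vector gene -> exon_id).
#' @export
panel_def <- function(exons) {
  req <- c("chrom", "start", "end", "gene", "exon_rank", "is_coding")
  stopifnot(is.data.frame(exons), all(req %in% names(exons)))
  if (!nrow(exons)) stop("panel has no exons")
  if (any(exons$start >= exons$end)) stop("exon with start >= end")
  if (any(exons$exon_rank < 1L)) stop("exon_rank must be >= 1")
  if (anyDuplicated(exons[, c("gene", "exon_rank")]))
    stop("duplicated (gene, exon_rank)")
  exons$gene <- toupper(trimws(as.character(exons$gene)))
  exons$exon_id <- paste0(exons$gene, ":exon", exons$exon_rank)
  # canonical order: gene, then rank; makes E1 designation and feature
  # column order independent of input record order
  exons <- exons[order(exons$gene, exons$exon_rank), , drop = FALSE]
  rownames(exons) <- NULL
  genes <- unique(exons$gene)
  e1 <- character(0)
  for (g in genes) {
    sub <- exons[exons$gene == g & exons$is_coding, , drop = FALSE]
    if (!nrow(sub)) {
      warning("gene ", g, " has no coding exon; excluded from E1 features")
      next
    }
    e1[g] <- sub$exon_id[which.min(sub$exon_rank)]
  }
  structure(list(exons = exons, genes = genes, e1_map = e1),
            class = "panel_def")
}

#' @export
print.panel_def <- function(x, ...) {
  cat("<panel_def> ", length(x$genes), " genes, ", nrow(x$exons),
      " exons (", sum(x$exons$is_coding), " coding), ",
      length(x$e1_map), " E1 designations\n", sep = "")
  invisible(x)
}

#' Load a panel BED file
#'
#' Expects a tab-separated BED6-style file: chrom, start, end, gene,
#' exon_rank, is_coding (0/1 or TRUE/FALSE).
#'
#' @param path Path to the panel BED.
#' @return A [panel_def] object.
#' @export
load_panel <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(df) < 6L) stop("panel BED needs 6 columns")
  names(df)[1:6] <- c("chrom", "start", "end", "gene", "exon_rank",
                      "is_coding")
  df$is_coding <- as.logical(as.integer(df$is_coding))
  panel_def(df)
}

#' Write a panel definition as BED
#' @param panel A [panel_def] object.
#' @param path Output path.
#' @export
write_panel_bed <- function(panel, path) {
  stopifnot(inherits(panel, "panel_def"))
  ex <- panel$exons
  write.table(data.frame(ex$chrom, ex$start, ex$end, ex$gene,
                         ex$exon_rank, as.integer(ex$is_coding)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Subset a panel to a gene list
#'
#' Retains exons whose gene is in both the panel and the supplied list
#' (e.g. the genes of a commercial cfDNA panel), recomputes the E1 map on
#' the subset, and records the intersection size and the fraction of the
#' list covered by the panel.
#'
#' @param panel A [panel_def] object.
#' @param gene_list Character vector of gene symbols (matched after
#'   trimming and uppercasing).
#' @return A [panel_def] for the subset, with attributes
#'   `n_genes_common` and `list_coverage` (fraction of `gene_list` present
#'   on the panel).
#' @export
subset_panel <- function(panel, gene_list) {
  stopifnot(inherits(panel, "panel_def"))
  gl <- unique(toupper(trimws(as.character(gene_list))))
  common <- intersect(panel$genes, gl)
  if (!length(common)) stop("no genes in common between panel and list")
  out <- panel_def(panel$exons[panel$exons$gene %in% common,
                               setdiff(names(panel$exons), "exon_id"),
                               drop = FALSE])
  attr(out, "n_genes_common") <- length(common)
  attr(out, "list_coverage") <- length(common) / length(gl)
  out
}

#' Read a one-symbol-per-line gene list
#' @param path Path to a plain-text file, one gene symbol per line.
#' @return Character vector of normalized symbols.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- toupper(trimws(x))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Select top TFBS sites per transcription factor
#'
#' For each TF, sites are ranked by experimental support (descending; ties
#' broken by chrom then start ascending) and the top `top_n` retained. TFs
#' with fewer than `top_n` sites are discarded, so every retained TF
#' contributes exactly `top_n` sites. The default of 5000 matches the
#' site count used with GTRD meta-cluster collections.
#'
#' @param sites `data.frame` with columns `chrom`, `start`, `end`, `tf`,
#'   `exp_count` (number of experiments supporting the site).
#' @param top_n Sites to keep per TF.
#' @return An object of class `tfbs_collection`: list of per-TF
#'   `data.frame`s, each with exactly `top_n` rows; attribute `top_n`.
#' @export
select_tfbs_sites <- function(sites, top_n = 5000L) {
  req <- c("chrom", "start", "end", "tf", "exp_count")
  stopifnot(is.data.frame(sites), all(req %in% names(sites)))
  out <- list()
  for (tf in unique(sites$tf)) {
    sub <- sites[sites$tf == tf, , drop = FALSE]
    if (nrow(sub) < top_n) next
    ord <- order(-sub$exp_count, sub$chrom, sub$start)
    sub <- sub[ord[seq_len(top_n)], , drop = FALSE]
    rownames(sub) <- NULL
    out[[tf]] <- sub
  }
  structure(out, class = "tfbs_collection", top_n = as.integer(top_n))
}

#' Load a GTRD-style TFBS interval file
#'
#' Tab-separated with a header naming at least chrom/start/end, a TF
#' identifier column and an experiment-support count column.
#'
#' @param path Path to the interval file.
#' @param tf_col,count_col Column names holding the TF symbol and the
#'   experimental support count.
#' @return `data.frame` suitable for [select_tfbs_sites()].
#' @export
load_tfbs_sites <- function(path, tf_col = "tf", count_col = "exp_count") {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, comment.char = "")
  names(df)[match(tf_col, names(df))] <- "tf"
  names(df)[match(count_col, names(df))] <- "exp_count"
  stopifnot(all(c("chrom", "start", "end", "tf", "exp_count") %in% names(df)))
  df
}

#' Load per-cancer-type open chromatin region sets
#'
#' One BED file per cancer type (ATAC-seq consensus peaks).
#'
#' @param paths Named character vector; names are cancer-type labels.
#' @return An object of class `atac_region_set`: named list of interval
#'   `data.frame`s (`chrom`, `start`, `end`).
#' @export
load_atac_regions <- function(paths) {
  if (is.null(names(paths)) || any(!nzchar(names(paths))))
    stop("paths must be named by cancer type")
  if (anyDuplicated(names(paths))) stop("duplicate cancer-type labels")
  out <- lapply(paths, function(p) {
    df <- tryCatch(
      read.table(p, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#"),
      error = function(e) data.frame())
    if (!nrow(df)) {
      warning("empty region file: ", p)
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    }
    names(df)[1:3] <- c("chrom", "start", "end")
    df[, c("chrom", "start", "end")]
  })
  structure(out, class = "atac_region_set")
}

#' Build an ATAC region set from in-memory interval tables
#' @param region_list Named list of `data.frame`s with `chrom`, `start`,
#'   `end`.
#' @return An `atac_region_set`.
#' @export
atac_region_set <- function(region_list) {
  if (is.null(names(region_list)) || anyDuplicated(names(region_list)))
    stop("region_list must have unique names")
  structure(region_list, class = "atac_region_set")
}
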