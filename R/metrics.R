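# The fragmentomics feature classes. All entropies are plug-in
# (maximum-likelihood) Shannon entropies in nats; the motif diversity
# score is normalized by log(256) and therefore base-independent.

#' Normalized read depth
#'
#' Fragment count overlapping a region, divided by the region size in bp,
#' divided by the sample's total retained fragment count. Vectorized over
#' regions.
#'
#' @param assigned_count Fragments assigned to the region(s).
#' @param region_bp Region size(s) in bp; must be positive.
#' @param total_reads Total retained fragments in the sample; must be
#'   positive.
#' @return Numeric normalized depth.
#' @examples
#' normalized_depth(4, 100, 10)  # 0.004
#' @export
normalized_depth <- function(assigned_count, region_bp, total_reads) {
  if (any(region_bp <= 0)) stop("region_bp must be positive")
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  assigned_count / region_bp / total_reads
}

#' Shannon entropy of a count distribution
#'
#' Plug-in estimator \eqn{H = -\sum p_i \log p_i} in nats, with
#' \eqn{p_i = c_i / n}. Empty distributions (n = 0) return `NA`; the
#' missing value is imputed later from training data.
#'
#' @param counts Non-negative numeric vector of counts (e.g. fragment
#'   length counts from `table()`).
#' @return Entropy in nats, or `NA_real_` for an empty distribution.
#' @examples
#' shannon_entropy(c(3, 1))  # -(0.75 log 0.75 + 0.25 log 0.25)
#' @export
shannon_entropy <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

# fragment length bins as printed ranges: 0-100, 101-150, 151-200,
# 201-250, 251-300, >300 (integer lengths, upper-inclusive)
.BIN_BREAKS <- c(101L, 151L, 201L, 251L, 301L)
.BIN_LABELS <- c("0-100", "101-150", "151-200", "201-250", "251-300",
                 ">300")

#' Fragment-size bin proportions
#'
#' Proportion of fragments in the six size bins 0-100, 101-150, 151-200,
#' 201-250, 251-300 and >300 bp (integer lengths; each upper edge
#' inclusive as printed). Six features per region.
#'
#' @param lengths Integer fragment lengths.
#' @return Named numeric 6-vector summing to 1, or all-`NA` when empty.
#' @export
fragment_bin_proportions <- function(lengths) {
  if (!length(lengths))
    return(setNames(rep(NA_real_, 6L), .BIN_LABELS))
  idx <- findInterval(lengths, .BIN_BREAKS) + 1L
  setNames(tabulate(idx, nbins = 6L) / length(lengths), .BIN_LABELS)
}

#' Small fragment fraction
#'
#' Proportion of fragments with length <= 150 bp, the sub-mononucleosome
#' fraction enriched in tumor-derived cfDNA.
#'
#' @param lengths Integer fragment lengths.
#' @return Fraction in `[0, 1]`, or `NA_real_` when empty.
#' @export
small_fragment_fraction <- function(lengths) {
  if (!length(lengths)) return(NA_real_)
  mean(lengths <= 150)
}

#' Motif diversity score (MDS)
#'
#' Normalized Shannon entropy of the 4-mer end-motif distribution:
#' \eqn{\mathrm{MDS} = -\sum_{i=1}^{256} P_i \log P_i / \log 256}, where
#' unobserved motifs contribute zero. Bounded in `[0, 1]`; 1 for a
#' uniform motif usage, 0 when a single motif dominates completely. The
#' 5' and 3' motifs of each fragment are conventionally pooled into one
#' count vector before calling this.
#'
#' @param motif_counts Named non-negative counts; names must be ACGT
#'   4-mers.
#' @return MDS in `[0, 1]`, or `NA_real_` when the total count is zero.
#' @export
motif_diversity_score <- function(motif_counts) {
  if (length(motif_counts)) {
    keys <- names(motif_counts)
    if (is.null(keys) || !all(keys %in% .ALL_MOTIFS))
      stop("motif_counts must be named by ACGT 4-mers")
  }
  n <- sum(motif_counts)
  if (n == 0 || !length(motif_counts)) return(NA_real_)
  shannon_entropy(as.numeric(motif_counts)) / log(256)
}

# pooled motif counts for a set of fragment rows; NA motifs are dropped
.motif_counts <- function(fr, idx) {
  m <- c(fr$motif5[idx], fr$motif3[idx])
  m <- m[!is.na(m)]
  if (!length(m)) return(numeric(0))
  tab <- table(factor(m, levels = .ALL_MOTIFS))
  cnt <- as.numeric(tab)
  names(cnt) <- .ALL_MOTIFS
  cnt[cnt > 0]
}

# distinct fragments overlapping any interval of `regions` -> indices
.pooled_fragment_idx <- function(fragments, regions) {
  if (!nrow(regions) || !nrow(fragments)) return(integer(0))
  hits <- findOverlaps(.as_granges(fragments), .as_granges(regions),
                       minoverlap = 1L)
  unique(queryHits(hits))
}

# distinct fragment indices per region group (e.g. per TF, per cancer
# type, per gene) from one overlap pass; returns a list of index vectors
.grouped_distinct_idx <- function(fr_gr, regions_gr, group) {
  group <- as.factor(group)
  out <- rep(list(integer(0)), nlevels(group))
  names(out) <- levels(group)
  if (!length(fr_gr) || !length(regions_gr)) return(out)
  hits <- findOverlaps(fr_gr, regions_gr, minoverlap = 1L)
  if (!length(hits)) return(out)
  sp <- split(queryHits(hits), group[subjectHits(hits)])
  for (g in names(sp)) out[[g]] <- unique(sp[[g]])
  out
}

#' Fragment-length entropy over TFBS sets
#'
#' For each retained transcription factor, pools the distinct fragments
#' of the sample that overlap any of its binding sites (all reads in the
#' sample are eligible, not only exonic ones) and computes the Shannon
#' entropy of the pooled fragment-length distribution: one feature per
#' TF. TFs whose sites capture no fragment yield `NA`.
#'
#' @param x A [sample_fragments] object.
#' @param tfbs A `tfbs_collection` from [select_tfbs_sites()].
#' @return Named numeric vector, one entropy (nats) per TF.
#' @export
tfbs_entropy <- function(x, tfbs) {
  stopifnot(inherits(x, "sample_fragments"),
            inherits(tfbs, "tfbs_collection"))
  vapply(tfbs, function(sites) {
    idx <- .pooled_fragment_idx(x$fragments, sites)
    if (!length(idx)) return(NA_real_)
    shannon_entropy(table(x$fragments$length[idx]))
  }, numeric(1))
}

#' Fragment-length entropy over open-chromatin sets
#'
#' As [tfbs_entropy()], but pooling fragments over the accessible-
#' chromatin intervals of each cancer type: one feature per cancer type.
#'
#' @param x A [sample_fragments] object.
#' @param atac An `atac_region_set`.
#' @return Named numeric vector, one entropy (nats) per cancer type.
#' @export
atac_entropy <- function(x, atac) {
  stopifnot(inherits(x, "sample_fragments"),
            inherits(atac, "atac_region_set"))
  vapply(atac, function(regions) {
    idx <- .pooled_fragment_idx(x$fragments, regions)
    if (!length(idx)) return(NA_real_)
    shannon_entropy(table(x$fragments$length[idx]))
  }, numeric(1))
}

#' Full-gene normalized depth for one sample
#'
#' Distinct fragments overlapping any exon of the gene, divided by the
#' summed exon footprint in bp and by the sample total; a fragment
#' spanning two exons of the same gene counts once by default
#' (`distinct = FALSE` counts it per exon instead).
#'
#' @param x A [sample_fragments] object.
#' @param panel A [panel_def] object.
#' @param distinct Count a multi-exon-spanning fragment once per gene
#'   (default) or once per overlapped exon.
#' @return Named numeric vector, one depth per gene.
#' @export
full_gene_depth <- function(x, panel, distinct = TRUE) {
  stopifnot(inherits(x, "sample_fragments"), inherits(panel, "panel_def"))
  vapply(panel$genes, function(g) {
    ex <- panel$exons[panel$exons$gene == g, , drop = FALSE]
    if (distinct) {
      cnt <- length(.pooled_fragment_idx(x$fragments, ex))
    } else {
      cnt <- sum(lengths(overlap_assign(x$fragments, ex)))
    }
    normalized_depth(cnt, sum(ex$end - ex$start), x$total_reads)
  }, numeric(1))
}

.METRIC_NAMES <- c("depth_all_exons", "depth_full_gene", "depth_E1",
                   "entropy_all_exons", "entropy_E1",
                   "mds_all_exons", "mds_E1",
                   "smallfrag_all_exons", "smallfrag_E1",
                   "fragment_bins", "tfbs_entropy", "atac_entropy",
                   "combined")

#' Recognized fragmentomics metric names
#' @return Character vector of the 13 metric-class names.
#' @export
metric_names <- function() .METRIC_NAMES

#' Construct a feature table
#'
#' @param values Numeric sample x feature matrix with unique row and
#'   column names.
#' @param labels Factor of phenotype labels aligned with rows (optional).
#' @param metric_name One of [metric_names()].
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(values, labels = NULL, metric_name) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)),
            !anyDuplicated(colnames(values)))
  metric_name <- match.arg(metric_name, .METRIC_NAMES)
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(values))
    labels <- factor(labels)
  }
  structure(list(values = values, labels = labels,
                 metric_name = metric_name),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", x$metric_name, ": ", nrow(x$values),
      " samples x ", ncol(x$values), " features\n", sep = "")
  invisible(x)
}

# per-sample, per-exon summaries used by all exon-level metrics;
# exons_gr lets callers reuse a pre-built GRanges across samples
.sample_exon_stats <- function(x, panel, exons_gr = NULL) {
  fr <- x$fragments
  exon_ids <- panel$exons$exon_id
  if (is.null(exons_gr)) exons_gr <- .as_granges(panel$exons)
  assign <- rep(list(integer(0)), length(exon_ids))
  names(assign) <- exon_ids
  if (nrow(fr)) {
    hits <- findOverlaps(.as_granges(fr), exons_gr, minoverlap = 1L)
    if (length(hits)) {
      sp <- split(queryHits(hits),
                  factor(subjectHits(hits), levels = seq_along(exon_ids)))
      assign <- setNames(lapply(sp, as.integer), exon_ids)
    }
  }
  list(
    count = vapply(assign, length, integer(1)),
    entropy = vapply(assign, function(i)
      if (length(i)) shannon_entropy(table(fr$length[i])) else NA_real_,
      numeric(1)),
    smallfrag = vapply(assign, function(i)
      small_fragment_fraction(fr$length[i]), numeric(1)),
    bins = vapply(assign, function(i)
      fragment_bin_proportions(fr$length[i]), numeric(6)),
    mds = if (!is.null(fr$motif5)) vapply(assign, function(i) {
      cnt <- .motif_counts(fr, i)
      if (!length(cnt)) NA_real_ else motif_diversity_score(cnt)
    }, numeric(1)) else rep(NA_real_, length(exon_ids))
  )
}

#' Compute all fragmentomics feature tables for a cohort
#'
#' Runs every metric class over a list of samples: the exon-level metrics
#' (normalized depth, length entropy, MDS, small-fragment fraction,
#' size-bin proportions) at all panel exons, full-gene depth, the E1
#' column subsets, TFBS and open-chromatin length entropies when region
#' collections are supplied, and the column-wise combination of all
#' computed tables. Regions with no overlapping fragments yield 0 for
#' depth (zero coverage is meaningful) and `NA` for the distributional
#' metrics (imputed from training data at modelling time).
#'
#' @param samples List of [sample_fragments] (already length-filtered);
#'   fragments need motif columns for the MDS tables.
#' @param panel A [panel_def] object.
#' @param tfbs Optional `tfbs_collection`.
#' @param atac Optional `atac_region_set`.
#' @param labels Optional phenotype labels aligned with `samples` (or a
#'   named vector keyed by sample id).
#' @param gene_depth_distinct Passed to [full_gene_depth()].
#' @return Named list of [feature_table]s (class `feature_table_set`),
#'   with a `meta` attribute recording the entropy base, the imputation
#'   policy, and the motif pooling mode.
#' @export
compute_feature_tables <- function(samples, panel, tfbs = NULL,
                                   atac = NULL, labels = NULL,
                                   gene_depth_distinct = TRUE) {
  stopifnot(length(samples) >= 1L, inherits(panel, "panel_def"))
  ids <- unname(vapply(samples, function(s) s$sample_id, ""))
  if (anyDuplicated(ids)) stop("duplicate sample ids")
  if (!is.null(labels)) {
    if (!is.null(names(labels))) labels <- labels[ids]
    labels <- factor(unname(labels))
  }
  exon_ids <- panel$exons$exon_id
  exon_bp <- panel$exons$end - panel$exons$start
  n <- length(samples)

  depth <- entropy <- smallfrag <- mds <-
    matrix(NA_real_, n, length(exon_ids), dimnames = list(ids, exon_ids))
  bins <- matrix(NA_real_, n, 6L * length(exon_ids))
  gene_depth <- matrix(NA_real_, n, length(panel$genes),
                       dimnames = list(ids, panel$genes))
  tf_mat <- if (!is.null(tfbs))
    matrix(NA_real_, n, length(tfbs), dimnames = list(ids, names(tfbs)))
  at_mat <- if (!is.null(atac))
    matrix(NA_real_, n, length(atac), dimnames = list(ids, names(atac)))

  # region GRanges are built once and shared across samples
  exons_gr <- .as_granges(panel$exons)
  exon_gene <- factor(panel$exons$gene, levels = panel$genes)
  gene_bp <- vapply(split(exon_bp, exon_gene), sum, numeric(1))
  if (!is.null(tfbs)) {
    tf_df <- do.call(rbind, lapply(tfbs, function(s)
      s[, c("chrom", "start", "end")]))
    tf_group <- factor(rep(names(tfbs), vapply(tfbs, nrow, integer(1))),
                       levels = names(tfbs))
    tf_gr <- .as_granges(tf_df)
  }
  if (!is.null(atac)) {
    at_df <- do.call(rbind, lapply(atac, function(r)
      r[, c("chrom", "start", "end")]))
    at_group <- factor(rep(names(atac), vapply(atac, nrow, integer(1))),
                       levels = names(atac))
    at_gr <- .as_granges(at_df)
  }
  pooled_entropy <- function(idx_list, lens) vapply(idx_list, function(i)
    if (length(i)) shannon_entropy(table(lens[i])) else NA_real_,
    numeric(1))

  for (i in seq_len(n)) {
    s <- samples[[i]]
    st <- .sample_exon_stats(s, panel, exons_gr)
    depth[i, ] <- normalized_depth(st$count, exon_bp, s$total_reads)
    entropy[i, ] <- st$entropy
    smallfrag[i, ] <- st$smallfrag
    bins[i, ] <- as.vector(st$bins)   # 6 rows x exons, column-major
    mds[i, ] <- st$mds
    fr_gr <- .as_granges(s$fragments)
    lens <- s$fragments$length
    gidx <- .grouped_distinct_idx(fr_gr, exons_gr, exon_gene)
    gcnt <- if (gene_depth_distinct) lengths(gidx)
      else vapply(split(st$count, exon_gene), sum, numeric(1))
    gene_depth[i, ] <- normalized_depth(gcnt, gene_bp, s$total_reads)
    if (!is.null(tfbs))
      tf_mat[i, ] <- pooled_entropy(
        .grouped_distinct_idx(fr_gr, tf_gr, tf_group), lens)
    if (!is.null(atac))
      at_mat[i, ] <- pooled_entropy(
        .grouped_distinct_idx(fr_gr, at_gr, at_group), lens)
  }
  colnames(bins) <- as.vector(vapply(exon_ids, function(e)
    paste0(e, ":", .BIN_LABELS), character(6)))
  rownames(bins) <- ids

  qual <- function(m, prefix) {
    colnames(m) <- paste0(prefix, "@", colnames(m)); m
  }
  e1 <- unname(panel$e1_map)
  tabs <- list(
    depth_all_exons = feature_table(qual(depth, "depth"), labels,
                                    "depth_all_exons"),
    depth_full_gene = feature_table(qual(gene_depth, "genedepth"), labels,
                                    "depth_full_gene"),
    depth_E1 = feature_table(qual(depth[, e1, drop = FALSE], "depth"),
                             labels, "depth_E1"),
    entropy_all_exons = feature_table(qual(entropy, "entropy"), labels,
                                      "entropy_all_exons"),
    entropy_E1 = feature_table(qual(entropy[, e1, drop = FALSE], "entropy"),
                               labels, "entropy_E1"),
    smallfrag_all_exons = feature_table(qual(smallfrag, "smallfrag"),
                                        labels, "smallfrag_all_exons"),
    smallfrag_E1 = feature_table(qual(smallfrag[, e1, drop = FALSE],
                                      "smallfrag"), labels, "smallfrag_E1"),
    fragment_bins = feature_table(qual(bins, "bins"), labels,
                                  "fragment_bins")
  )
  has_motifs <- !all(is.na(mds))
  if (has_motifs) {
    tabs$mds_all_exons <- feature_table(qual(mds, "mds"), labels,
                                        "mds_all_exons")
    tabs$mds_E1 <- feature_table(qual(mds[, e1, drop = FALSE], "mds"),
                                 labels, "mds_E1")
  }
  if (!is.null(tfbs))
    tabs$tfbs_entropy <- feature_table(qual(tf_mat, "tfbs"), labels,
                                       "tfbs_entropy")
  if (!is.null(atac))
    tabs$atac_entropy <- feature_table(qual(at_mat, "atac"), labels,
                                       "atac_entropy")
  tabs <- tabs[intersect(.METRIC_NAMES, names(tabs))]
  # E1 columns keep their all-exon names, so qualify by table name here
  comb <- do.call(cbind, lapply(names(tabs), function(mn) {
    v <- tabs[[mn]]$values
    colnames(v) <- paste0(mn, "|", colnames(v))
    v
  }))
  tabs$combined <- feature_table(comb, labels, "combined")
  structure(tabs, class = "feature_table_set",
            meta = list(entropy_base = "nats",
                        entropy_estimator = "plug-in ML",
                        imputation = "depth:0; distributional:training median",
                        mds_pooling = "5'+3' pooled"))
}

#' Extract one metric's feature table from a computed set
#'
#' E1 variants are column subsets of the corresponding all-exon tables
#' (features are computed once at all exons and the E1 columns
#' extracted); `combined` is the column-wise concatenation of all other
#' tables.
#'
#' @param tables A `feature_table_set` from [compute_feature_tables()].
#' @param metric_name One of [metric_names()].
#' @return A [feature_table].
#' @export
assemble_features <- function(tables, metric_name) {
  stopifnot(inherits(tables, "feature_table_set"))
  metric_name <- match.arg(metric_name, .METRIC_NAMES)
  if (is.null(tables[[metric_name]]))
    stop("metric not available in this set: ", metric_name)
  tables[[metric_name]]
}

#' Write a feature table as TSV with a JSON sidecar
#'
#' The TSV has `sample_id`, `phenotype`, then one column per feature; the
#' sidecar records the metric name and the numerical conventions used.
#'
#' @param ft A [feature_table].
#' @param path Output TSV path; the sidecar is written to `<path>.json`.
#' @param meta Optional metadata list (e.g. the `meta` attribute of the
#'   feature set).
#' @export
write_feature_table <- function(ft, path, meta = NULL) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(sample_id = rownames(ft$values),
                   phenotype = if (is.null(ft$labels)) NA
                               else as.character(ft$labels),
                   ft$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(metric = ft$metric_name), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
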