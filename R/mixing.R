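# In silico dilution: down-sampling fragment sets and mixing
# healthy/cancer donor pairs at fixed read-share ratios to emulate
# low-tumor-fraction specimens, plus the full train/validation mixing
# design and log-decade binning by calculated ctDNA fraction.

#' The five standard healthy:cancer mixing ratios
#'
#' 50:50, 75:25, 90:10, 95:5 and 99:1 (healthy:partner shares of the
#' total read count).
#'
#' @return `data.frame` with columns `ratio` (label), `healthy_share`,
#'   `partner_share` (proportions summing to 1).
#' @export
mixing_ratios <- function() {
  h <- c(50, 75, 90, 95, 99)
  data.frame(ratio = sprintf("%d:%d", h, 100 - h),
             healthy_share = h / 100,
             partner_share = (100 - h) / 100,
             stringsAsFactors = FALSE)
}

#' Down-sample fragments without replacement
#'
#' Uniform sample of exactly `n` fragments, deterministic given `seed`
#' (the in-memory analogue of shuffling a fragment BED and taking the
#' first `n` lines).
#'
#' @param x A [sample_fragments] object.
#' @param n Number of fragments to keep; must not exceed the available
#'   count.
#' @param seed Integer seed.
#' @return A [sample_fragments] object with exactly `n` fragments.
#' @export
downsample <- function(x, n, seed) {
  stopifnot(inherits(x, "sample_fragments"))
  n <- as.integer(n)
  if (n < 0L) stop("n must be non-negative")
  if (n > x$total_reads)
    stop("insufficient reads: requested ", n, " of ", x$total_reads)
  idx <- with_seed(seed, sample.int(x$total_reads, n))
  fr <- x$fragments[idx, , drop = FALSE]
  rownames(fr) <- NULL
  sample_fragments(x$sample_id, fr)
}

#' Mix two down-sampled fragment sets at a fixed ratio
#'
#' Draws the partner share of `total_reads` from the partner sample and
#' the remaining healthy share from the healthy sample (the healthy share
#' absorbs rounding so the output holds exactly `total_reads` fragments),
#' then concatenates them. Each fragment's source is retained in an
#' `origin` audit column.
#'
#' @param healthy A [sample_fragments] object (the healthy backbone).
#' @param partner A [sample_fragments] object (cancer donor, or a second
#'   healthy donor for control mixtures); must not be the same sample.
#' @param ratio One row of [mixing_ratios()] (or any list with
#'   `healthy_share` and `partner_share` summing to 1).
#' @param total_reads Total fragments in the mixture.
#' @param seed Integer seed; healthy and partner draws use child seeds.
#' @param mix_id Identifier for the mixed sample.
#' @return A [sample_fragments] object of exactly `total_reads` fragments
#'   with fields `n_healthy` / `n_partner`.
#' @export
mix_fragments <- function(healthy, partner, ratio, total_reads, seed,
                          mix_id = NULL) {
  stopifnot(inherits(healthy, "sample_fragments"),
            inherits(partner, "sample_fragments"))
  if (healthy$sample_id == partner$sample_id)
    stop("healthy and partner must be different samples")
  if (abs(ratio$healthy_share + ratio$partner_share - 1) > 1e-9)
    stop("ratio shares must sum to 1")
  n_partner <- as.integer(round(total_reads * ratio$partner_share))
  n_healthy <- as.integer(total_reads) - n_partner
  dh <- downsample(healthy, n_healthy, derive_seed(seed, 1L))
  dp <- downsample(partner, n_partner, derive_seed(seed, 2L))
  fh <- dh$fragments; fp <- dp$fragments
  fh$origin <- healthy$sample_id
  fp$origin <- partner$sample_id
  cols <- intersect(names(fh), names(fp))
  fr <- rbind(fh[, cols, drop = FALSE], fp[, cols, drop = FALSE])
  rownames(fr) <- NULL
  if (is.null(mix_id))
    mix_id <- paste0(healthy$sample_id, "+", partner$sample_id, "@",
                     ratio$ratio)
  out <- sample_fragments(mix_id, fr)
  out$n_healthy <- n_healthy
  out$n_partner <- n_partner
  out
}

#' Calculated ctDNA fraction of a mixture
#'
#' The tumor fraction of the partner sample scaled by the partner's share
#' of the mixed reads: mixing a partner of tumor fraction 0.2 at a 5%
#' read share yields a calculated fraction of 0.01. Healthy partners
#' (tumor fraction 0) give 0 at any ratio.
#'
#' @param partner_tumor_fraction Tumor fraction of the partner in `[0,1]`.
#' @param partner_share Partner share of the mixed reads in `[0,1]`.
#' @return The product, in `[0,1]`.
#' @export
calculated_ctdna_fraction <- function(partner_tumor_fraction,
                                      partner_share) {
  if (any(partner_tumor_fraction < 0 | partner_tumor_fraction > 1) ||
      any(partner_share < 0 | partner_share > 1))
    stop("inputs must lie in [0,1]")
  partner_tumor_fraction * partner_share
}

.BIN_LEVELS <- c("[1e-04,0.001)", "[0.001,0.01)", "[0.01,0.1)", "[0.1,1]")

#' Assign a calculated ctDNA fraction to a log-decade bin
#'
#' Half-open decade bins `[1e-4,1e-3)`, `[1e-3,1e-2)`, `[1e-2,1e-1)` and
#' the right-closed top bin `[0.1, 1]`. Positive fractions below 1e-4 are
#' labeled `"sub-detection"` (excluded from binned AUROCs); non-positive
#' fractions (healthy-healthy control mixtures) return `NA`.
#'
#' @param fraction Numeric vector of calculated ctDNA fractions.
#' @return Character vector of bin labels.
#' @export
assign_fraction_bin <- function(fraction) {
  out <- rep(NA_character_, length(fraction))
  pos <- !is.na(fraction) & fraction > 0
  idx <- findInterval(fraction[pos], c(1e-4, 1e-3, 1e-2, 1e-1))
  out[pos] <- c("sub-detection", .BIN_LEVELS)[idx + 1L]
  out
}

#' The four log-decade ctDNA fraction bin labels, lowest first
#' @return Character vector of length 4.
#' @export
fraction_bin_levels <- function() .BIN_LEVELS

#' Enumerate the full mixing design
#'
#' Every (healthy, cancer) donor pair at every ratio, plus every ordered
#' (healthy, other healthy) pair at every ratio as class-balance
#' controls: `|H| * |C| * |R|` cancer mixtures and `|H| * (|H|-1) * |R|`
#' control mixtures, in deterministic order, each with a derived seed and
#' its calculated ctDNA fraction and bin.
#'
#' @param healthy_ids Character vector of healthy donor ids.
#' @param cancer_ids Character vector of cancer donor ids (disjoint from
#'   `healthy_ids`).
#' @param tumor_fractions Named numeric vector giving each cancer donor's
#'   tumor fraction.
#' @param ratios `data.frame` as from [mixing_ratios()].
#' @param total_reads Reads per mixture.
#' @param master_seed Master seed; each mixture gets a derived child.
#' @return `data.frame` of mixture specifications (`spec_id`,
#'   `healthy_id`, `partner_id`, `partner_is_cancer`, `ratio`,
#'   `healthy_share`, `partner_share`, `total_reads`, `seed`,
#'   `partner_tumor_fraction`, `calculated_fraction`, `fraction_bin`).
#' @export
enumerate_design <- function(healthy_ids, cancer_ids, tumor_fractions,
                             ratios = mixing_ratios(),
                             total_reads = 10000L, master_seed = 1L) {
  healthy_ids <- as.character(healthy_ids)
  cancer_ids <- as.character(cancer_ids)
  if (length(intersect(healthy_ids, cancer_ids)))
    stop("healthy and cancer id sets must be disjoint")
  if (length(healthy_ids) < 2L)
    stop("need >= 2 healthy samples for control mixtures")
  if (!all(cancer_ids %in% names(tumor_fractions)))
    stop("tumor_fractions must cover all cancer ids")
  ca <- expand.grid(ri = seq_len(nrow(ratios)), partner_id = cancer_ids,
                    healthy_id = healthy_ids, stringsAsFactors = FALSE)
  ca$partner_is_cancer <- TRUE
  hh <- expand.grid(ri = seq_len(nrow(ratios)), partner_id = healthy_ids,
                    healthy_id = healthy_ids, stringsAsFactors = FALSE)
  hh <- hh[hh$partner_id != hh$healthy_id, , drop = FALSE]
  hh$partner_is_cancer <- FALSE
  de <- rbind(ca, hh)
  de$ratio <- ratios$ratio[de$ri]
  de$healthy_share <- ratios$healthy_share[de$ri]
  de$partner_share <- ratios$partner_share[de$ri]
  de$ri <- NULL
  de$total_reads <- as.integer(total_reads)
  de$seed <- vapply(seq_len(nrow(de)), function(i)
    derive_seed(master_seed, 505L, i), integer(1))
  de$partner_tumor_fraction <-
    ifelse(de$partner_is_cancer,
           unname(tumor_fractions[de$partner_id]), 0)
  de$calculated_fraction <-
    calculated_ctdna_fraction(de$partner_tumor_fraction, de$partner_share)
  de$fraction_bin <- assign_fraction_bin(de$calculated_fraction)
  de <- de[, c("healthy_id", "partner_id", "partner_is_cancer", "ratio",
               "healthy_share", "partner_share", "total_reads", "seed",
               "partner_tumor_fraction", "calculated_fraction",
               "fraction_bin")]
  rownames(de) <- NULL
  de$spec_id <- sprintf("mix%05d", seq_len(nrow(de)))
  de[, c("spec_id", setdiff(names(de), "spec_id"))]
}

#' Materialize one mixture specification
#'
#' @param spec One row of [enumerate_design()] output.
#' @param fragment_sets Named list of [sample_fragments] keyed by donor
#'   id.
#' @return A mixed [sample_fragments] object (id = `spec_id`).
#' @export
realize_mixture <- function(spec, fragment_sets) {
  h <- fragment_sets[[spec$healthy_id]]
  p <- fragment_sets[[spec$partner_id]]
  if (is.null(h) || is.null(p))
    stop("fragment_sets missing donor ", spec$healthy_id, " or ",
         spec$partner_id)
  mix_fragments(h, p,
                list(ratio = spec$ratio,
                     healthy_share = spec$healthy_share,
                     partner_share = spec$partner_share),
                spec$total_reads, spec$seed, mix_id = spec$spec_id)
}

#' Down-sample a cohort to a series of sequencing depths
#'
#' One cohort per requested depth, each sample independently down-sampled
#' without replacement; depths exceeding a sample's read count are
#' skipped for that sample with a warning. Used to assess how metric
#' performance degrades with total sequencing depth.
#'
#' @param samples Named list of [sample_fragments].
#' @param depths Integer vector of target read counts.
#' @param master_seed Master seed; per-(depth, sample) child seeds are
#'   derived.
#' @return Named list (one element per depth, named by the depth) of
#'   lists of down-sampled [sample_fragments].
#' @export
depth_downsample_series <- function(samples, depths, master_seed = 1L) {
  out <- list()
  for (d in seq_along(depths)) {
    depth <- as.integer(depths[d])
    coh <- list()
    for (s in seq_along(samples)) {
      x <- samples[[s]]
      if (x$total_reads < depth) {
        warning("sample ", x$sample_id, " has fewer than ", depth,
                " reads; skipped at this depth")
        next
      }
      coh[[x$sample_id]] <- downsample(x, depth,
                                       derive_seed(master_seed, d, s))
    }
    out[[as.character(depth)]] <- coh
  }
  out
}
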