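# Synthetic cohort generator. The paper-style analysis runs on real
# patient cohorts; this module provides a fully synthetic stand-in with
# the statistical structure the pipeline assumes (phenotype-modulated
# exon coverage, nucleosome-patterned fragment lengths, phenotype-shifted
# end-motif usage, and sample-level tumor fraction), so every downstream
# stage is testable without any data download. All distributional choices
# are stand-ins, not estimates from data.

#' Configuration for the synthetic cohort generator
#'
#' Defines a toy genome, an exon panel, and per-phenotype generative
#' processes for fragment placement, length and end motifs. The `healthy`
#' phenotype is the baseline process; each non-healthy phenotype is a
#' "tumor" process whose fragments are mixed into a sample according to
#' its tumor fraction.
#'
#' Effect-size knobs (all revert to the null, healthy-identical process
#' at their neutral value):
#' * `depth_effect` - non-healthy per-exon depth multipliers alternate
#'   `depth_effect` and `1/depth_effect` across exons, emulating
#'   expression/copy-number-driven coverage shifts (neutral at 1);
#' * `length_effect` - weight moved from the mononucleosome (~167 bp)
#'   length component to the short (~110 bp) component, emulating the
#'   elevated sub-150 bp fraction of tumor cfDNA (neutral at 0);
#' * `motif_effect` - degree to which the tumor motif concentration is
#'   flattened toward uniform relative to the CC-biased healthy usage
#'   (neutral at 0).
#'
#' @param seed Master seed; all per-sample seeds derive from it.
#' @param n_genes Genes on the toy panel.
#' @param exons_per_gene Integer range `c(min, max)` of exons per gene.
#' @param exon_length_bp Integer range of exon lengths in bp.
#' @param genome_length_bp Toy genome length.
#' @param phenotypes Labels; must include `"healthy"`.
#' @param n_samples_per_phenotype Samples per phenotype.
#' @param reads_per_sample Fragments per sample.
#' @param depth_effect,length_effect,motif_effect Effect sizes as above.
#' @param depth_multipliers Optional explicit map phenotype -> per-exon
#'   positive multiplier vector (overrides `depth_effect`).
#' @param length_model Optional map phenotype -> list(weights, means,
#'   sds) for the short/mono/di truncated-normal mixture; defaults to
#'   short N(110,15), mono N(167,15), di N(330,30) with healthy weights
#'   (0.10, 0.80, 0.10).
#' @param motif_concentration Optional map phenotype -> Dirichlet
#'   concentration vector over the 256 motifs.
#' @param tumor_fraction Named vector phenotype -> tumor fraction in
#'   `[0,1]` for that phenotype's samples; healthy is fixed at 0.
#'   Defaults to 1 for non-healthy phenotypes (the phenotype process
#'   fully expressed; lower values are exercised by the mixing module).
#' @param off_target_fraction Fraction of fragments placed uniformly
#'   outside the exon footprint (so overlap filtering is exercised).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 6L,
                       exons_per_gene = c(2L, 4L),
                       exon_length_bp = c(120L, 300L),
                       genome_length_bp = 100000L,
                       phenotypes = c("healthy", "cancer"),
                       n_samples_per_phenotype = 60L,
                       reads_per_sample = 10000L,
                       depth_effect = 3,
                       length_effect = 0.15,
                       motif_effect = 0.5,
                       depth_multipliers = NULL,
                       length_model = NULL,
                       motif_concentration = NULL,
                       tumor_fraction = NULL,
                       off_target_fraction = 0.10) {
  if (!"healthy" %in% phenotypes) stop("phenotypes must include 'healthy'")
  if (reads_per_sample <= 0) stop("reads_per_sample must be positive")
  if (off_target_fraction < 0 || off_target_fraction > 1)
    stop("off_target_fraction must lie in [0,1]")
  if (depth_effect <= 0) stop("depth_effect must be positive")
  if (length_effect < 0 || length_effect > 0.8)
    stop("length_effect must lie in [0, 0.8]")
  if (motif_effect < 0 || motif_effect > 1)
    stop("motif_effect must lie in [0,1]")
  if (is.null(tumor_fraction)) {
    tumor_fraction <- setNames(rep(1, length(phenotypes)), phenotypes)
  }
  tumor_fraction["healthy"] <- 0
  if (any(tumor_fraction < 0 | tumor_fraction > 1))
    stop("tumor_fraction must lie in [0,1]")
  if (!is.null(length_model)) {
    for (lm in length_model) {
      if (abs(sum(lm$weights) - 1) > 1e-8)
        stop("length mixture weights must sum to 1")
    }
  }
  if (!is.null(depth_multipliers)) {
    for (dm in depth_multipliers)
      if (any(dm <= 0)) stop("depth multipliers must be positive")
  }
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 exons_per_gene = as.integer(exons_per_gene),
                 exon_length_bp = as.integer(exon_length_bp),
                 genome_length_bp = as.integer(genome_length_bp),
                 phenotypes = phenotypes,
                 n_samples_per_phenotype =
                   as.integer(n_samples_per_phenotype),
                 reads_per_sample = as.integer(reads_per_sample),
                 depth_effect = depth_effect,
                 length_effect = length_effect,
                 motif_effect = motif_effect,
                 depth_multipliers = depth_multipliers,
                 length_model = length_model,
                 motif_concentration = motif_concentration,
                 tumor_fraction = tumor_fraction,
                 off_target_fraction = off_target_fraction),
            class = "sim_config")
}

#' Generate the toy reference sequence
#'
#' Uniform ACGT sequence of exactly `genome_length_bp` bases on a single
#' synthetic chromosome; deterministic given the config seed.
#'
#' @param config A [sim_config].
#' @return Character string (possibly empty).
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$genome_length_bp
  if (n == 0L) return("")
  with_seed(derive_seed(config$seed, 101L),
            paste(sample(.BASES, n, replace = TRUE), collapse = ""))
}

#' Write the toy reference as FASTA
#' @param reference Character string from [generate_reference()].
#' @param path Output FASTA path.
#' @param chrom Sequence name (default `"chrS1"`, the synthetic
#'   chromosome used by [generate_panel()]).
#' @export
write_reference_fasta <- function(reference, path, chrom = "chrS1") {
  seq <- Biostrings::DNAStringSet(reference)
  names(seq) <- chrom
  Biostrings::writeXStringSet(seq, path)
  invisible(path)
}

#' Generate the toy exon panel
#'
#' Lays non-overlapping coding exons gene by gene along the synthetic
#' chromosome, with random exon counts, lengths, and inter-exon /
#' inter-gene gaps; ranks are contiguous from 1 within each gene.
#' Deterministic given the config seed. Errors if the requested panel
#' cannot fit on the genome.
#'
#' @param config A [sim_config].
#' @return A [panel_def] object on chromosome `chrS1`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_genes < 1L) stop("n_genes must be >= 1")
  with_seed(derive_seed(config$seed, 202L), {
    rows <- list()
    pos <- 500L
    for (g in seq_len(config$n_genes)) {
      gene <- sprintf("G%02d", g)
      k <- if (config$exons_per_gene[1] == config$exons_per_gene[2])
        config$exons_per_gene[1]
      else sample(config$exons_per_gene[1]:config$exons_per_gene[2], 1L)
      for (e in seq_len(k)) {
        len <- sample(config$exon_length_bp[1]:config$exon_length_bp[2], 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = "chrS1", start = pos, end = pos + len, gene = gene,
          exon_rank = e, is_coding = TRUE, stringsAsFactors = FALSE)
        pos <- pos + len + sample(200:600, 1L)  # intron-scale gap
      }
      pos <- pos + sample(1000:3000, 1L)        # intergenic gap
    }
    exons <- do.call(rbind, rows)
    if (max(exons$end) + 500L > config$genome_length_bp)
      stop("genome_length_bp too small for the requested panel ",
           "(needs at least ", max(exons$end) + 500L, " bp)")
    panel_def(exons)
  })
}

# default per-phenotype generative parameters derived from the effect
# sizes; returns list(depth, length, motif) for one phenotype
.pheno_params <- function(config, panel, phenotype) {
  n_ex <- nrow(panel$exons)
  dm <- config$depth_multipliers[[phenotype]]
  if (is.null(dm)) {
    dm <- if (phenotype == "healthy") rep(1, n_ex)
    else rep(c(config$depth_effect, 1 / config$depth_effect),
             length.out = n_ex)
  }
  if (length(dm) != n_ex)
    stop("depth multiplier vector must have one entry per exon")
  lm <- config$length_model[[phenotype]]
  if (is.null(lm)) {
    w <- c(short = 0.10, mono = 0.80, di = 0.10)
    if (phenotype != "healthy") {
      w["short"] <- w["short"] + config$length_effect
      w["mono"] <- w["mono"] - config$length_effect
    }
    lm <- list(weights = w, means = c(110, 167, 330), sds = c(15, 15, 30))
  }
  mc <- config$motif_concentration[[phenotype]]
  if (is.null(mc)) {
    # healthy cfDNA end motifs are biased (CC-starting motifs over-used);
    # tumor usage flattens toward uniform with motif_effect
    base <- ifelse(startsWith(.ALL_MOTIFS, "CC"), 8, 1.5)
    if (phenotype != "healthy")
      base <- (1 - config$motif_effect) * base +
        config$motif_effect * mean(base)
    mc <- base
  }
  if (length(mc) != 256L) stop("motif concentration must have 256 entries")
  list(depth = dm, length = lm, motif = mc)
}

# draw fragments from one origin process
.draw_fragments <- function(n, params, panel, config, motif_probs) {
  ex <- panel$exons
  exon_bp <- ex$end - ex$start
  off <- runif(n) < config$off_target_fraction
  n_on <- sum(!off)
  lens <- rtrunc_norm_mix(n, params$length$weights, params$length$means,
                          params$length$sds)
  start <- integer(n)
  if (n_on) {
    exon_idx <- sample.int(nrow(ex), n_on, replace = TRUE,
                           prob = params$depth * exon_bp)
    center <- ex$start[exon_idx] +
      floor(runif(n_on) * exon_bp[exon_idx])
    start[!off] <- center - lens[!off] %/% 2L
  }
  if (any(off)) {
    # uniform start among the gaps between exons, weighted by gap length
    bnd <- sort(c(0L, ex$start, ex$end, config$genome_length_bp))
    gs <- bnd[seq(1L, length(bnd), 2L)]
    ge <- bnd[seq(2L, length(bnd), 2L)]
    keep <- ge > gs
    gs <- gs[keep]; ge <- ge[keep]
    gi <- sample.int(length(gs), sum(off), replace = TRUE, prob = ge - gs)
    start[off] <- gs[gi] + floor(runif(sum(off)) * (ge[gi] - gs[gi]))
  }
  start <- pmax.int(start, 0L)
  start <- pmin.int(start, config$genome_length_bp - lens)
  m5 <- .ALL_MOTIFS[sample.int(256L, n, replace = TRUE, prob = motif_probs)]
  m3 <- .ALL_MOTIFS[sample.int(256L, n, replace = TRUE, prob = motif_probs)]
  data.frame(chrom = "chrS1", start = start, end = start + lens,
             motif5 = m5, motif3 = m3, stringsAsFactors = FALSE)
}

#' Simulate one cfDNA sample
#'
#' Each fragment independently (i) originates from the tumor process with
#' probability `tumor_fraction`, otherwise from the healthy process;
#' (ii) falls off-target with the configured probability, otherwise in an
#' exon chosen proportionally to the origin phenotype's depth multiplier
#' times exon length; (iii) draws its length from the origin's truncated
#' normal mixture on `[20, 500]` bp; and (iv) draws 5'/3' end motifs
#' from the origin's per-sample motif distribution (a Dirichlet draw from
#' the phenotype concentration, one per sample and origin). On-target
#' fragments are centred uniformly within the chosen exon.
#'
#' @param config A [sim_config].
#' @param phenotype One of `config$phenotypes`.
#' @param tumor_fraction Tumor fraction in `[0,1]`; defaults to the
#'   config's per-phenotype value.
#' @param sample_seed Integer seed for this sample (see [derive_seed()]).
#' @param panel Optional pre-generated [panel_def] (regenerated from the
#'   config when omitted).
#' @param sample_id Identifier for the sample.
#' @return A [sample_fragments] object with `phenotype` and
#'   `tumor_fraction` fields (class `synthetic_sample`).
#' @export
simulate_sample <- function(config, phenotype,
                            tumor_fraction = NULL,
                            sample_seed = derive_seed(config$seed, 1L, 1L),
                            panel = NULL,
                            sample_id = paste0(phenotype, "_s1")) {
  stopifnot(inherits(config, "sim_config"))
  if (!phenotype %in% config$phenotypes)
    stop("unknown phenotype: ", phenotype)
  if (is.null(tumor_fraction))
    tumor_fraction <- unname(config$tumor_fraction[phenotype])
  if (phenotype == "healthy") tumor_fraction <- 0
  if (tumor_fraction < 0 || tumor_fraction > 1)
    stop("tumor_fraction must lie in [0,1]")
  if (is.null(panel)) panel <- generate_panel(config)
  p_healthy <- .pheno_params(config, panel, "healthy")
  p_tumor <- .pheno_params(config, panel, phenotype)
  out <- with_seed(sample_seed, {
    n <- config$reads_per_sample
    from_tumor <- runif(n) < tumor_fraction
    probs_h <- rgamma(256L, p_healthy$motif)
    probs_h <- probs_h / sum(probs_h)
    probs_t <- rgamma(256L, p_tumor$motif)
    probs_t <- probs_t / sum(probs_t)
    parts <- list()
    if (any(!from_tumor))
      parts$h <- .draw_fragments(sum(!from_tumor), p_healthy, panel,
                                 config, probs_h)
    if (any(from_tumor))
      parts$t <- .draw_fragments(sum(from_tumor), p_tumor, panel,
                                 config, probs_t)
    fr <- do.call(rbind, parts)
    fr <- fr[order(fr$start, fr$end), , drop = FALSE]
    rownames(fr) <- NULL
    fr
  })
  s <- sample_fragments(sample_id, out)
  s$phenotype <- phenotype
  s$tumor_fraction <- tumor_fraction
  class(s) <- c("synthetic_sample", class(s))
  s
}

#' Simulate a full cohort
#'
#' `n_samples_per_phenotype` samples per phenotype, with per-sample seeds
#' derived deterministically from the config seed (phenotype index and
#' sample index), so any sample can be regenerated in isolation.
#'
#' @param config A [sim_config].
#' @return Object of class `synthetic_cohort`: list with `samples` (list
#'   of [simulate_sample()] outputs), `labels` (`data.frame` with
#'   `sample_id`, `phenotype`, `tumor_fraction`), `panel`, and `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  panel <- generate_panel(config)
  samples <- list()
  labels <- list()
  for (p in seq_along(config$phenotypes)) {
    ph <- config$phenotypes[p]
    for (i in seq_len(config$n_samples_per_phenotype)) {
      id <- sprintf("%s_s%02d", ph, i)
      s <- simulate_sample(config, ph,
                           sample_seed = derive_seed(config$seed, p, i),
                           panel = panel, sample_id = id)
      samples[[id]] <- s
      labels[[id]] <- data.frame(sample_id = id, phenotype = ph,
                                 tumor_fraction = s$tumor_fraction,
                                 stringsAsFactors = FALSE)
    }
  }
  structure(list(samples = samples,
                 labels = do.call(rbind, c(labels, make.row.names = FALSE)),
                 panel = panel, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", length(x$samples), " samples (",
      paste(names(table(x$labels$phenotype)), collapse = "/"), "), ",
      x$config$reads_per_sample, " fragments each\n", sep = "")
  invisible(x)
}

#' Write cohort phenotype labels as TSV
#' @param cohort A `synthetic_cohort`.
#' @param path Output path.
#' @export
write_labels_tsv <- function(cohort, path) {
  write.table(cohort$labels, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Generate a toy TFBS site collection
#'
#' Random binding-site intervals over the toy genome with Poisson
#' experimental-support counts, in the raw format expected by
#' [select_tfbs_sites()]. Some sites fall inside the exon footprint so
#' TF-level pooling captures on-target fragments.
#'
#' @param config A [sim_config].
#' @param n_tf Number of transcription factors.
#' @param sites_per_tf Sites per TF.
#' @param site_width Site width in bp.
#' @return `data.frame` with `chrom`, `start`, `end`, `tf`, `exp_count`.
#' @export
generate_tfbs_sites <- function(config, n_tf = 2L, sites_per_tf = 60L,
                                site_width = 30L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 303L), {
    lim <- config$genome_length_bp - site_width
    do.call(rbind, lapply(seq_len(n_tf), function(t) {
      start <- sort(sample.int(lim, sites_per_tf))
      data.frame(chrom = "chrS1", start = start, end = start + site_width,
                 tf = sprintf("TF%02d", t),
                 exp_count = rpois(sites_per_tf, 20) + 1L,
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Generate toy open-chromatin region sets
#'
#' One random interval set per cancer-type label over the toy genome.
#'
#' @param config A [sim_config].
#' @param types Cancer-type labels.
#' @param regions_per_type Intervals per type.
#' @param region_width Interval width in bp.
#' @return An `atac_region_set`.
#' @export
generate_atac_sets <- function(config, types = c("TYPE_A", "TYPE_B"),
                               regions_per_type = 40L,
                               region_width = 400L) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, 404L), {
    lim <- config$genome_length_bp - region_width
    atac_region_set(setNames(lapply(seq_along(types), function(i) {
      start <- sort(sample.int(lim, regions_per_type))
      data.frame(chrom = "chrS1", start = start,
                 end = start + region_width, stringsAsFactors = FALSE)
    }), types))
  })
}
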