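test_that("normalized depth follows count / bp / total and its symmetries", {
  expect_equal(normalized_depth(4, 100, 10), 0.004)
  expect_equal(normalized_depth(0, 100, 10), 0)
  # doubling count and total leaves depth unchanged
  expect_equal(normalized_depth(8, 100, 20), 0.004)
  expect_error(normalized_depth(1, 0, 10), "region_bp")
  expect_error(normalized_depth(1, 100, 0), "total_reads")
})

test_that("Shannon entropy matches closed forms and the brute-force oracle", {
  expect_equal(shannon_entropy(c(5)), 0)
  expect_equal(shannon_entropy(c(3, 3)), log(2))
  expect_equal(shannon_entropy(c(3, 1)),
               -(0.75 * log(0.75) + 0.25 * log(0.25)))
  expect_true(is.na(shannon_entropy(numeric(0))))
  expect_error(shannon_entropy(c(-1, 2)), "non-negative")

  set.seed(21)
  for (i in 1:50) {
    k <- sample(1:10, 1)
    cnt <- sample(1:40, k, replace = TRUE)
    h <- shannon_entropy(cnt)
    expect_equal(h, bf_entropy(cnt))
    expect_gte(h, 0)
    expect_lte(h, log(k) + 1e-12)
  }
})

test_that("fragment size bins respect the printed boundaries", {
  expect_equal(unname(fragment_bin_proportions(c(50, 120, 160, 210, 280,
                                                 350))),
               rep(1 / 6, 6))
  expect_equal(unname(fragment_bin_proportions(rep(167, 9))),
               c(0, 0, 1, 0, 0, 0))
  # upper-inclusive edges: 100 in the first bin, 101 in the second
  expect_equal(unname(fragment_bin_proportions(100)), c(1, 0, 0, 0, 0, 0))
  expect_equal(unname(fragment_bin_proportions(101)), c(0, 1, 0, 0, 0, 0))
  expect_equal(unname(fragment_bin_proportions(300)), c(0, 0, 0, 0, 1, 0))
  expect_equal(unname(fragment_bin_proportions(301)), c(0, 0, 0, 0, 0, 1))
  expect_true(all(is.na(fragment_bin_proportions(integer(0)))))

  set.seed(4)
  for (i in 1:20) {
    lens <- sample(20:500, sample(1:100, 1), replace = TRUE)
    p <- fragment_bin_proportions(lens)
    expect_equal(sum(p), 1)          # every length in exactly one bin
  }
})

test_that("small fragment fraction uses the inclusive 150 bp cut", {
  expect_equal(small_fragment_fraction(c(100, 150, 151, 200)), 0.5)
  expect_equal(small_fragment_fraction(rep(167, 5)), 0)
  expect_equal(small_fragment_fraction(rep(150, 5)), 1)
  expect_true(is.na(small_fragment_fraction(integer(0))))
})

test_that("motif diversity score is the normalized 256-motif entropy", {
  uni <- setNames(rep(2, 256), all_motifs())
  expect_equal(motif_diversity_score(uni), 1)
  expect_equal(motif_diversity_score(c(ACGT = 10)), 0)
  expect_equal(motif_diversity_score(c(ACGT = 5, TTTT = 5)),
               log(2) / log(256))
  expect_true(is.na(motif_diversity_score(setNames(numeric(0),
                                                   character(0)))))
  expect_error(motif_diversity_score(c(ACGN = 1)), "4-mers")

  # label-permutation invariance and oracle agreement
  set.seed(9)
  for (i in 1:30) {
    k <- sample(1:50, 1)
    cnt <- setNames(sample(1:20, k, replace = TRUE),
                    sample(all_motifs(), k))
    m <- motif_diversity_score(cnt)
    expect_equal(m, bf_mds(cnt))
    expect_gte(m, 0); expect_lte(m, 1)
    perm <- setNames(unname(cnt), sample(all_motifs(), k))
    expect_equal(motif_diversity_score(perm), m)
  }
})

test_that("TFBS entropy pools distinct fragments across a TF's sites", {
  # two sites; three distinct fragments with lengths 150, 167, 167
  sites <- list(T1 = data.frame(chrom = "chr1",
                                start = c(100L, 1000L),
                                end = c(200L, 1100L),
                                tf = "T1", exp_count = c(3L, 3L)))
  tfbs <- structure(sites, class = "tfbs_collection", top_n = 2L)
  sf <- make_fragments(c(120L, 130L, 1010L), c(150L, 167L, 167L))
  h <- tfbs_entropy(sf, tfbs)
  expect_equal(unname(h["T1"]), bf_entropy(c(1, 2)))
  expect_equal(unname(h["T1"]), 0.6365142, tolerance = 1e-6)

  # sites capturing only 167 bp fragments -> zero entropy
  only167 <- make_fragments(c(120L, 1010L), c(167L, 167L))
  expect_equal(unname(tfbs_entropy(only167, tfbs)["T1"]), 0)

  # disjoint sites -> missing
  far <- make_fragments(5000L, 167L)
  expect_true(is.na(tfbs_entropy(far, tfbs)["T1"]))
})

test_that("open-chromatin entropy reduces to whole-sample entropy when regions cover all", {
  sf <- make_fragments(c(0L, 300L, 600L, 900L), c(100L, 167L, 167L, 320L))
  atac <- atac_region_set(list(
    ALL = data.frame(chrom = "chr1", start = 0L, end = 5000L),
    NONE = data.frame(chrom = "chr2", start = 0L, end = 5000L),
    MID = data.frame(chrom = "chr1", start = c(250L, 850L),
                     end = c(500L, 1000L))))
  h <- atac_entropy(sf, atac)
  expect_equal(unname(h["ALL"]),
               shannon_entropy(table(sf$fragments$length)))
  expect_true(is.na(h["NONE"]))
  # MID captures the 167 at 300 and the 320 at 900 -> two equal counts
  expect_equal(unname(h["MID"]), log(2))
})

test_that("full gene depth counts distinct fragments once per gene", {
  ex <- data.frame(chrom = "chr1", start = c(0L, 300L),
                   end = c(100L, 400L), gene = "G1",
                   exon_rank = 1:2, is_coding = TRUE)
  p1 <- panel_def(ex)
  # 3 fragments on exon 1, 2 on exon 2, disjoint; 100 total reads
  filler <- make_fragments(rep(10000L, 99), rep(100L, 99))
  on <- data.frame(chrom = "chr1",
                   start = c(10L, 20L, 30L, 310L, 320L),
                   end = c(60L, 70L, 80L, 360L, 370L))
  sf <- sample_fragments("s1", rbind(on, filler$fragments[1:95, 1:3]))
  expect_equal(unname(full_gene_depth(sf, p1)["G1"]), 5 / 200 / 100)

  # a single fragment spanning both exons counts once (twice with the
  # per-exon counting mode)
  span <- sample_fragments("s2", rbind(
    data.frame(chrom = "chr1", start = 50L, end = 350L),
    filler$fragments[1:99, 1:3]))
  expect_equal(unname(full_gene_depth(span, p1)["G1"]), 1 / 200 / 100)
  expect_equal(unname(full_gene_depth(span, p1, distinct = FALSE)["G1"]),
               2 / 200 / 100)

  # single-exon gene reduces to the exon's normalized depth
  p2 <- panel_def(ex[1, ])
  cnt <- length(overlap_assign(sf$fragments, p2$exons)[[1]])
  expect_equal(unname(full_gene_depth(sf, p2)["G1"]),
               normalized_depth(cnt, 100, sf$total_reads))
})

test_that("feature tables have the expected shapes and column relations", {
  cfg <- quick_config(seed = 31L)
  coh <- simulate_cohort(cfg)
  labels <- setNames(coh$labels$phenotype, coh$labels$sample_id)
  tfbs <- select_tfbs_sites(generate_tfbs_sites(cfg, sites_per_tf = 30L),
                            top_n = 20L)
  atac <- generate_atac_sets(cfg)
  ft <- compute_feature_tables(coh$samples, coh$panel, tfbs = tfbs,
                               atac = atac, labels = labels)
  n_ex <- nrow(coh$panel$exons)   # 3 genes x 2 exons = 6
  expect_equal(n_ex, 6L)
  expect_equal(ncol(ft$depth_all_exons$values), 6L)
  expect_equal(ncol(ft$depth_full_gene$values), 3L)
  expect_equal(ncol(ft$fragment_bins$values), 36L)
  expect_equal(ncol(ft$tfbs_entropy$values), 2L)
  expect_equal(ncol(ft$atac_entropy$values), 2L)

  # E1 variants are column subsets of the all-exon tables
  expect_true(all(colnames(ft$depth_E1$values) %in%
                    colnames(ft$depth_all_exons$values)))
  expect_true(all(colnames(ft$entropy_E1$values) %in%
                    colnames(ft$entropy_all_exons$values)))
  # combined is the column-wise concatenation of the other 12
  others <- setdiff(names(ft), "combined")
  expect_equal(length(others), 12L)
  expect_equal(ncol(ft$combined$values),
               sum(vapply(ft[others], function(t) ncol(t$values), 1L)))
  expect_identical(assemble_features(ft, "depth_E1"), ft$depth_E1)
  expect_error(assemble_features(ft, "nope"))

  # depth imputes zero; distributional metrics leave NA for empty regions
  expect_true(all(ft$depth_all_exons$values >= 0))
  expect_false(anyNA(ft$depth_all_exons$values))
})

test_that("feature tables are invariant to fragment input order", {
  cfg <- quick_config(seed = 8L, n_samples_per_phenotype = 2L)
  coh <- simulate_cohort(cfg)
  shuffled <- lapply(coh$samples, function(s) {
    set.seed(1)
    fr <- s$fragments[sample(nrow(s$fragments)), , drop = FALSE]
    rownames(fr) <- NULL
    sample_fragments(s$sample_id, fr)
  })
  f1 <- compute_feature_tables(coh$samples, coh$panel)
  f2 <- compute_feature_tables(shuffled, coh$panel)
  for (m in names(f1))
    expect_equal(f1[[m]]$values, f2[[m]]$values)
})

test_that("per-exon depth conserves assigned fragment counts exactly", {
  cfg <- quick_config(seed = 17L, n_samples_per_phenotype = 2L)
  coh <- simulate_cohort(cfg)
  ft <- compute_feature_tables(coh$samples, coh$panel)
  bp <- coh$panel$exons$end - coh$panel$exons$start
  for (s in coh$samples) {
    counts <- lengths(overlap_assign(s$fragments, coh$panel$exons))
    depth <- ft$depth_all_exons$values[s$sample_id, ]
    recovered <- depth * bp * s$total_reads
    expect_equal(unname(recovered), unname(counts), tolerance = 1e-10)
  }
})

test_that("exon MDS equals the oracle on pooled 5'/3' motif counts", {
  cfg <- quick_config(seed = 23L, n_samples_per_phenotype = 1L,
                      reads_per_sample = 400L)
  coh <- simulate_cohort(cfg)
  s <- coh$samples[[1]]
  ft <- compute_feature_tables(list(s), coh$panel)
  assign <- overlap_assign(s$fragments, coh$panel$exons)
  for (e in seq_along(assign)) {
    idx <- assign[[e]]
    motifs <- c(s$fragments$motif5[idx], s$fragments$motif3[idx])
    motifs <- motifs[!is.na(motifs)]
    want <- if (length(motifs)) bf_mds(table(motifs)) else NA_real_
    expect_equal(unname(ft$mds_all_exons$values[1, e]), want)
  }
})

test_that("feature tables round-trip to TSV with a JSON sidecar", {
  cfg <- quick_config(seed = 2L, n_samples_per_phenotype = 2L,
                      reads_per_sample = 300L)
  coh <- simulate_cohort(cfg)
  ft <- compute_feature_tables(coh$samples, coh$panel,
                               labels = setNames(coh$labels$phenotype,
                                                 coh$labels$sample_id))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_feature_table(ft$depth_all_exons, f, meta = attr(ft, "meta"))
  back <- read.delim(f, check.names = FALSE)
  expect_equal(nrow(back), 4L)
  expect_equal(back$sample_id, rownames(ft$depth_all_exons$values))
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(side$metric, "depth_all_exons")
  expect_equal(side$entropy_base, "nats")
})
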