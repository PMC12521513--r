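# Small fixtures shared across test files; everything is built in code.

# a hand-laid three-gene panel on one toy chromosome
toy_panel <- function() {
  panel_def(data.frame(
    chrom = "chr1",
    start = c(100L, 500L, 1000L, 1500L, 2200L, 3000L),
    end   = c(200L, 700L, 1300L, 1700L, 2500L, 3200L),
    gene  = c("GA", "GA", "GB", "GB", "GC", "GC"),
    exon_rank = c(1L, 2L, 1L, 2L, 1L, 2L),
    is_coding = TRUE,
    stringsAsFactors = FALSE))
}

# fragments at given (start, length) pairs on one chromosome
make_fragments <- function(starts, lengths, chrom = "chr1",
                           sample_id = "s1") {
  sample_fragments(sample_id, data.frame(
    chrom = rep_len(chrom, length(starts)), start = as.integer(starts),
    end = as.integer(starts + lengths), stringsAsFactors = FALSE))
}

# a small cohort configuration that runs in well under a second
quick_config <- function(seed = 11L, n_samples_per_phenotype = 5L,
                         reads_per_sample = 1000L, ...) {
  sim_config(seed = seed, n_genes = 3L, exons_per_gene = c(2L, 2L),
             genome_length_bp = 20000L,
             n_samples_per_phenotype = n_samples_per_phenotype,
             reads_per_sample = reads_per_sample, ...)
}

# uniform random fragment table for property tests
random_fragments <- function(n, max_pos = 1000L, chroms = "chr1") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample(1:120, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

random_regions <- function(n, max_pos = 1000L, chroms = "chr1") {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample(1:200, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             id = paste0("r", seq_len(n)), stringsAsFactors = FALSE)
}
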