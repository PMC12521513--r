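# Independent brute-force oracles used to validate the package's
# implementations. Deliberately naive: explicit loops, no shared code
# with the package internals.

# Shannon entropy from an explicit probability vector
bf_entropy <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / n
      h <- h - p * log(p)
    }
  }
  h
}

# motif diversity score over the full 256-motif space
bf_mds <- function(motif_counts) {
  full <- setNames(rep(0, 256), all_motifs())
  full[names(motif_counts)] <- motif_counts
  n <- sum(full)
  if (n == 0) return(NA_real_)
  h <- 0
  for (c in full) {
    if (c > 0) {
      p <- c / n
      h <- h - p * log(p)
    }
  }
  h / log(256)
}

# all-pairs interval overlap on BED half-open coordinates
bf_overlap <- function(fragments, regions, min_overlap = 1L) {
  out <- rep(list(integer(0)), nrow(regions))
  for (r in seq_len(nrow(regions))) {
    hit <- integer(0)
    for (f in seq_len(nrow(fragments))) {
      if (fragments$chrom[f] != regions$chrom[r]) next
      ov <- min(fragments$end[f], regions$end[r]) -
        max(fragments$start[f], regions$start[r])
      if (ov >= min_overlap) hit <- c(hit, f)
    }
    out[[r]] <- hit
  }
  out
}

# all-pairs Mann-Whitney AUROC, ties counting one half
bf_auroc <- function(scores, labels, positive) {
  pos <- which(labels == positive)
  neg <- which(labels != positive)
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) tot <- tot + 1
      else if (scores[i] == scores[j]) tot <- tot + 0.5
    }
  }
  tot / (length(pos) * length(neg))
}

# mixing-design sizes by explicit enumeration
bf_design_counts <- function(n_healthy, n_cancer, n_ratios) {
  cancer <- 0L
  control <- 0L
  for (h in seq_len(n_healthy)) {
    for (c in seq_len(n_cancer)) cancer <- cancer + n_ratios
    for (h2 in seq_len(n_healthy)) {
      if (h2 != h) control <- control + n_ratios
    }
  }
  c(cancer = cancer, control = control)
}
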