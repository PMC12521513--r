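# Shared internal helpers: seed management, truncated-normal mixtures,
# the 4-mer motif universe.

# modulus for derived seeds; largest prime below 2^31 so derived seeds
# always fit in an R integer
.SEED_MOD <- 2147483629

#' Derive a reproducible child seed from a master seed
#'
#' Stable integer hash used everywhere the package needs per-sample or
#' per-replicate randomness: child streams are a deterministic function of
#' the master seed and one or more index keys, so partial re-runs (one
#' sample, one replicate) reproduce exactly what a full run would produce.
#'
#' The hash is `x <- master; for each key k_i: x <- (31 x + m_i k_i) mod p`
#' with `p` the largest prime below 2^31 and fixed odd multipliers `m_i`.
#'
#' @param master Integer master seed.
#' @param ... Integer keys (e.g. phenotype index, sample index).
#' @return A positive integer seed strictly below 2^31.
#' @examples
#' derive_seed(1L, 3L, 7L)
#' @export
derive_seed <- function(master, ...) {
  keys <- as.double(c(...))
  mult <- c(1000003, 7919, 104729, 1299709)
  x <- as.double(master) %% .SEED_MOD
  for (i in seq_along(keys)) {
    m <- mult[(i - 1L) %% length(mult) + 1L]
    x <- (x * 31 + (keys[i] %% .SEED_MOD) * m) %% .SEED_MOD
  }
  as.integer(x %% (.SEED_MOD - 1)) + 1L
}

# Evaluate code under a given RNG seed without disturbing the caller's
# random stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Draw n integer lengths from a truncated normal mixture on [lower, upper].
# Components with sd = 0 are point masses at their mean. Sampling is by
# inverse-CDF within the truncation window, then rounding to integer bp.
rtrunc_norm_mix <- function(n, weights, means, sds, lower = 20, upper = 500) {
  stopifnot(length(weights) == length(means), length(means) == length(sds))
  if (n == 0L) return(integer(0))
  comp <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  out <- numeric(n)
  for (j in seq_along(weights)) {
    idx <- which(comp == j)
    if (!length(idx)) next
    if (sds[j] <= 0) {
      out[idx] <- means[j]
    } else {
      lo <- pnorm(lower, means[j], sds[j])
      hi <- pnorm(upper, means[j], sds[j])
      out[idx] <- qnorm(runif(length(idx), lo, hi), means[j], sds[j])
    }
  }
  pmin.int(pmax.int(as.integer(round(out)), as.integer(lower)),
           as.integer(upper))
}

.BASES <- c("A", "C", "G", "T")

#' The 256 possible 4-mer end motifs
#'
#' All ACGT 4-mers in lexicographic order; the fixed key set over which the
#' motif diversity score is normalized.
#'
#' @return Character vector of length 256.
#' @export
all_motifs <- function() {
  g <- expand.grid(.BASES, .BASES, .BASES, .BASES,
                   stringsAsFactors = FALSE)[, 4:1]
  sort(do.call(paste0, g))
}

# cached copy used internally
.ALL_MOTIFS <- local({
  g <- expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                   c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                   stringsAsFactors = FALSE)[, 4:1]
  sort(do.call(paste0, g))
})

# vectorized reverse complement for plain character motifs
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
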