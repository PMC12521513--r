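---
title: "Fragmentomics metrics and phenotype classification for targeted cfDNA panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragmentomics metrics and phenotype classification for targeted cfDNA panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelfrag)
```

## The problem

Cell-free DNA (cfDNA) in plasma is fragmented non-randomly: nucleosome
occupancy, transcription-factor binding and nuclease preferences leave
tumor-of-origin signatures in fragment *coverage*, *length* and *end
sequence*. Most fragmentomics methods were developed for whole-genome
sequencing, but clinical cfDNA assays are deep **targeted exon panels**.
`panelfrag` implements a panel-native fragmentomics workflow:

1. compute a family of fragmentomics feature classes from fragment
   intervals over panel exons and auxiliary region systems;
2. restrict panels to commercial gene lists and quantify the cost;
3. build in silico low-tumor-fraction samples by down-sampling and
   mixing fragment sets;
4. evaluate how well each feature class predicts phenotype with a
   repeated, nested-CV elastic-net classifier summarized by one-vs-rest
   AUROC.

Because the cohorts such analyses are usually run on are
controlled-access, the package ships a synthetic cohort generator with
the statistical structure the analysis assumes, so the entire pipeline
is exercised end-to-end by tests without any external data.

## Fragment model and metrics

Fragments are BED-style 0-based half-open intervals; a fragment's length
is `end - start`. Fragments with inserts outside **[20, 500] bp**
(inclusive; `filter_by_length()`) are discarded, and the retained count
is the per-sample denominator `N` below. Region assignment requires a
**minimum 1 bp overlap**, and a fragment overlapping several regions
contributes to each of them (`overlap_assign()`).

The 13 feature classes (`metric_names()`):

| class | definition | features |
|---|---|---|
| `depth_all_exons` | count / exon bp / `N` | 1 per exon |
| `depth_full_gene` | distinct fragments over a gene's exons / summed bp / `N` | 1 per gene |
| `depth_E1` | depth at the first coding exon | 1 per gene |
| `entropy_all_exons`, `entropy_E1` | Shannon entropy of the per-region fragment-length distribution | 1 per exon / gene |
| `mds_all_exons`, `mds_E1` | end-motif diversity score | 1 per exon / gene |
| `smallfrag_all_exons`, `smallfrag_E1` | fraction of lengths ≤ 150 bp | 1 per exon / gene |
| `fragment_bins` | proportions in 0–100, 101–150, 151–200, 201–250, 251–300, >300 bp | 6 per exon |
| `tfbs_entropy` | length entropy of fragments pooled over a TF's binding sites | 1 per TF |
| `atac_entropy` | length entropy over a cancer type's open-chromatin regions | 1 per type |
| `combined` | column-wise concatenation of the other 12 | sum |

Entropies are plug-in (maximum-likelihood) estimators in nats,
$H = -\sum_i p_i \ln p_i$ with $p_i = c_i/n$; no small-sample bias
correction is applied, and the estimator choice is recorded in the
feature-set metadata. The motif diversity score pools each fragment's 5'
and 3' 4-mers and normalizes over the full 256-motif space,
$\mathrm{MDS} = H(P_{256}) / \ln 256 \in [0,1]$, so it is independent of
the logarithm base. The E1 window of a gene is its coding exon of
transcript rank 1, or — when that exon is not on the panel — the
lowest-rank coding exon present. "Closest" is interpreted in transcript
rank order rather than genomic distance, because the E1 signal is
motivated by TSS-proximal coverage; E1 tables are column subsets
extracted after all-exon computation, never recomputed.

Two conventions the literature leaves open are exposed as flags:

* **3' motif strand.** By default the 3' motif is the reverse complement
  of the last four reference bases (reading into the fragment from its
  end); `three_prime = "plus"` records the plus-strand sequence
  literally, which is what a strand-unaware `bedtools getfasta`-style
  extraction yields. The mode used is stored on the returned object.
* **Multi-exon-spanning fragments in full-gene depth** count once per
  gene by default (`distinct = TRUE`); per-exon counting is available.

Missing values arise when a region captures no fragments. Zero coverage
is biologically meaningful, so depth features impute 0 at computation
time; the distributional features (entropy, MDS, bins, small-fragment
fraction) are left `NA` and imputed with per-feature **training-fold
medians** inside the classifier, never from held-out data.

## Region systems

* **Panel**: BED6+ with gene, exon rank and coding flag
  (`load_panel()`); `subset_panel()` intersects with a commercial gene
  list (symbols normalized by trimming/uppercasing; alias resolution is
  out of scope) and reports the coverage fraction.
* **TFBS**: GTRD-style interval tables with an experimental-support
  count. Per TF the top `top_n` sites by support are kept (ties break by
  chromosome, then start) and TFs with fewer than `top_n` sites are
  dropped, so every retained TF has exactly `top_n` sites; 5000 is the
  conventional full-scale value, toy collections use smaller `top_n`.
* **ATAC**: one interval set per cancer type (`load_atac_regions()`),
  each yielding one pooled-entropy feature.

## The classifier stack

`fit_penalized_multinomial()` minimizes the penalized multinomial
log-likelihood
$-\tfrac1N \ell(\beta) + \lambda[(1-\alpha)\tfrac12\|\beta\|_2^2 +
\alpha\|\beta\|_1]$ via glmnet with unpenalized intercepts. Features are
z-scored with training statistics (explicitly, rather than relying on
the solver's internal standardization, so scaling is solver-independent
and provably training-only); two-class problems use the binomial family,
which is the same model and measurably faster. Predictions are computed
from dense coefficients stored at the target $\lambda$ (verified
bit-identical to the solver's own predictions).

`run_repeated_cv()` implements the evaluation design:

* **Outer CV**: stratified 10-fold (stratification is a design choice —
  with classes as small as a dozen samples, unstratified folds routinely
  lose a class from a training fold). One fold assignment per repeat is
  shared across *all* metric tables, so metrics are compared on
  identical splits.
* **Hyperparameters**: 10 candidates per repeat by Latin hypercube over
  $\alpha \in [0,1]$ and $\lambda \in [10^{-4}, 10^{1}]$ (log scale; the
  original sampling ranges are not published, this default spans ridge
  to lasso and near-unpenalized to fully-shrunk on standardized
  features). Selection maximizes the mean **macro-averaged one-vs-rest
  AUROC** over a nested stratified 5-fold inner CV — the multiclass
  reduction is unspecified in the source design, macro-averaging is this
  package's choice and is recorded here; ties break to smaller
  $\lambda$, then smaller $\alpha$.
* **Class balance**: minority classes are up-sampled with replacement to
  the majority count inside training folds only.
* **Repeats**: 25 by default, each with a derived seed; medians over
  repeats are the headline summaries, and `auroc_deltas()` compares
  gene-set subsets against the full panel.
* AUROC uses the Mann–Whitney form with ties counted ½.

Leakage is treated as a testable property: imputation medians, scaling,
up-sampling and hyperparameter selection all derive from training rows
only, and the test suite includes an instrumentation check that poisons
held-out rows and verifies the fitted model is unchanged.

For the mixing experiment, `evaluate_split()` follows the split-sample
protocol: donors are split before any mixing, hyperparameters are
selected by the same 5-fold inner CV within the training cohort, and
the validation cohort is scored once per repeat.

## In silico dilution

`mix_fragments()` emulates the shuffle-and-take-n down-sampling of
fragment files: the partner (cancer, or a second healthy donor for
controls) contributes `round(total * share)` fragments and the healthy
backbone the exact remainder, at the standard healthy:cancer ratios
50:50, 75:25, 90:10, 95:5, 99:1. `enumerate_design()` expands every
(healthy, cancer) pair and every *ordered* (healthy, other-healthy) pair
over the ratios — the ordered-pair reading is the only one consistent
with the design's closed forms $|H||C||R|$ and $|H|(|H|-1)|R|$ (e.g. 32
healthy × 71 cancer × 5 ratios = 11,360 plus 32 × 31 × 5 = 4,960,
totalling 16,320 training mixtures). Each mixture's **calculated ctDNA
fraction** is the donor tumor fraction times the cancer read share, and
results are binned by log decade: $[10^{-4},10^{-3})$,
$[10^{-3},10^{-2})$, $[10^{-2},10^{-1})$, $[10^{-1},1]$ (the top bin
right-closed; only the outer two bins are named in the source text, the
log-decade partition of the interior is inferred). Fractions below
$10^{-4}$ are labelled sub-detection and excluded from binned AUROCs;
control mixtures (fraction 0) serve as the negative class in every bin.
The 100 M-read full-scale total is a parameter; the desk-scale default
is 10,000 reads per mixture.

## The synthetic cohort generator

The generator is a stand-in, not an estimate from data: the underlying
study analyzed real cohorts and published no generative model. It
emulates the features the pipeline's statistics key on:

* **Lengths**: a truncated-normal mixture on [20, 500] bp with short
  N(110, 15), mononucleosome N(167, 15) and dinucleosome N(330, 30)
  components; healthy weights (0.10, 0.80, 0.10). The 167 bp mode
  reflects single-histone protection; `length_effect` moves weight from
  the mono to the short component, emulating the elevated sub-150 bp
  fraction of tumor-derived cfDNA.
* **Coverage**: exons are chosen proportionally to per-phenotype depth
  multipliers × exon length. `depth_effect` alternates gain/loss
  multipliers ($e$, $1/e$) across exons for non-healthy phenotypes,
  emulating expression- and copy-number-driven coverage shifts; 10% of
  fragments fall off-target so overlap filtering is exercised.
* **End motifs**: per-sample motif probabilities are Dirichlet draws
  from per-phenotype concentrations; the healthy profile over-weights
  CC-initiated motifs (echoing the known CCNN preference of healthy
  plasma) and `motif_effect` flattens the tumor profile toward uniform.
* **Tumor fraction**: each fragment originates from the tumor process
  with probability equal to the sample's tumor fraction, otherwise from
  the healthy process — the same mixture structure the dilution
  experiment manipulates.

Every effect knob has a neutral value (`depth_effect = 1`,
`length_effect = 0`, `motif_effect = 0`) at which all phenotypes share
the healthy process exactly; this is the null configuration used for
calibration tests. One statistical subtlety matters there: on a single
fixed null cohort, repeated CV with fresh folds re-measures the *same*
chance label–feature alignment, so per-metric median AUROCs deviate
from 0.5 with the dataset-level sd (≈ 0.05 at 60 samples/class) no
matter how many fold-repeats are run. Calibration checks in this
package therefore replicate over independent null cohorts (5 cohorts ×
5 fold-repeats), which shrinks the median's sd to ≈ 0.02 and makes a
±0.07 calibration band a meaningful ≈3σ criterion. Defaults (2 × 60 samples, 10,000 fragments/sample,
`depth_effect = 3`, `length_effect = 0.15`, `motif_effect = 0.5`) define
the standard test conditions. Per-sample seeds are a stable hash of the
master seed and sample indices (`derive_seed()`), so any sample can be
regenerated in isolation and cohorts are byte-reproducible.

What the generator does **not** model: sequencing error, GC bias, UMI
structure, mapping artifacts, inter-donor biological variability beyond
the Dirichlet motif draw, or realistic genome structure (one synthetic
chromosome, uniform base composition). Tests passing on synthetic data
therefore validate the pipeline's *arithmetic and statistical
machinery*, not clinical performance claims; absolute AUROCs on real
cohorts are out of scope.

## Numerical choices and degenerate inputs

* Entropy of an empty region is `NA` (imputed later), of a single
  length 0.
* Bin boundaries are integer and upper-inclusive as printed (100 → bin
  1, 101 → bin 2, 300 → bin 5, 301 → bin 6).
* Length-filter bounds are inclusive at both 20 and 500.
* Mixture share rounding is absorbed by the healthy backbone so totals
  are exact to the fragment.
* glmnet is fitted on a short decreasing λ path ending at the target
  (warm starts; convergence threshold 10⁻⁶); single-feature tables are
  padded with an all-zero dummy column the penalty forces to zero.
* Fold assignment deals shuffled class members to folds in rotation with
  a per-class starting offset, so small classes do not pile into early
  folds.
* Reported problem sizes in the test suite — 6-gene panels, 10,000
  fragments per sample, 10,000-read mixtures, 25 ML repeats — are the
  package's desk-scale study conditions; all are plain parameters that
  scale to full-size inputs.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1, n_samples_per_phenotype = 20,
                  reads_per_sample = 5000)
cohort <- simulate_cohort(cfg)
tfbs <- select_tfbs_sites(generate_tfbs_sites(cfg), top_n = 40)
atac <- generate_atac_sets(cfg)
tables <- compute_feature_tables(
  cohort$samples, cohort$panel, tfbs = tfbs, atac = atac,
  labels = setNames(cohort$labels$phenotype, cohort$labels$sample_id))
cv <- run_repeated_cv(tables, cv_config(n_repeats = 5, master_seed = 2))
summary(cv)
plot(cv)
```

## Known limitations

* One synthetic chromosome; multi-chromosome panels are supported by the
  IO and metric layers but not emitted by the generator.
* Gene symbols are matched by normalized string equality; no alias
  tables.
* No GC correction of features (deliberate — the metrics are used
  uncorrected), no BAM/CRAM input (fragments arrive as BED), no
  ctDNA-fraction estimation from variants (fractions are inputs).
* The AUROC of very small classes in inner folds can be undefined;
  candidates are then compared on the folds where it exists.
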