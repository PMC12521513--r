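# Phenotype classification: elastic-net penalized multinomial logistic
# regression (glmnet) evaluated by repeated stratified k-fold CV, with
# hyperparameters chosen per outer fold by Latin hypercube sampling and a
# nested inner CV, class up-sampling inside training folds only, and
# one-vs-rest AUROC as the performance measure.

#' Cross-validation configuration
#'
#' Defaults mirror the standard design: 10 outer folds, 5 inner folds, 10
#' Latin-hypercube hyperparameter candidates, 25 repeats with distinct
#' derived seeds, and class up-sampling. `lambda_range` is sampled on the
#' log scale.
#'
#' @param outer_folds,inner_folds Fold counts (>= 2).
#' @param n_hyper Hyperparameter candidates per repeat.
#' @param n_repeats Repeats with distinct fold seeds.
#' @param upsample Up-sample minority classes inside training folds.
#' @param alpha_range Elastic-net mixing range within `[0,1]`.
#' @param lambda_range Positive penalty-strength range (log-uniform).
#' @param master_seed Master seed; all fold and sampling seeds derive
#'   from it.
#' @return Object of class `cv_config`.
#' @export
cv_config <- function(outer_folds = 10L, inner_folds = 5L, n_hyper = 10L,
                      n_repeats = 25L, upsample = TRUE,
                      alpha_range = c(0, 1),
                      lambda_range = c(1e-4, 1e1),
                      master_seed = 1L) {
  stopifnot(outer_folds >= 2L, inner_folds >= 2L, n_hyper >= 1L,
            n_repeats >= 1L, alpha_range[1] >= 0, alpha_range[2] <= 1,
            alpha_range[1] <= alpha_range[2],
            lambda_range[1] > 0, lambda_range[1] <= lambda_range[2])
  structure(list(outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 n_hyper = as.integer(n_hyper),
                 n_repeats = as.integer(n_repeats),
                 upsample = isTRUE(upsample),
                 alpha_range = alpha_range,
                 lambda_range = lambda_range,
                 master_seed = as.integer(master_seed)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Partitions samples into `k` folds, approximately class-stratified:
#' within each class, shuffled members are dealt to folds in rotation.
#' Deterministic given the seed; the same assignment is reused across all
#' metric tables within a repeat so metrics are compared on identical
#' splits.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param k Number of folds (>= 2, <= number of samples).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`.
#' @export
make_folds <- function(labels, k, seed) {
  labels <- factor(labels)
  n <- length(labels)
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop("k exceeds the number of samples")
  fold <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      # rotate the starting fold between classes so small classes do not
      # all pile into fold 1
      fold[idx] <- (offset + seq_along(idx) - 1L) %% k + 1L
      offset <- offset + length(idx)
    }
  })
  fold
}

#' Latin hypercube sample of elastic-net hyperparameters
#'
#' `n` (alpha, lambda) pairs whose projections occupy `n` distinct
#' equal-probability strata on each axis; alpha is stratified uniformly
#' on its range and lambda uniformly on the log scale.
#'
#' @param n Number of candidates.
#' @param alpha_range,lambda_range As in [cv_config()].
#' @param seed Integer seed.
#' @return `data.frame` with columns `alpha` and `lambda`.
#' @export
latin_hypercube_hyperparams <- function(n, alpha_range = c(0, 1),
                                        lambda_range = c(1e-4, 1e1),
                                        seed = 1L) {
  stopifnot(n >= 1L, lambda_range[1] > 0)
  u <- with_seed(seed, lhs::randomLHS(as.integer(n), 2L))
  data.frame(
    alpha = alpha_range[1] + u[, 1] * diff(alpha_range),
    lambda = exp(log(lambda_range[1]) +
                   u[, 2] * diff(log(lambda_range))))
}

#' Up-sample minority classes to the majority count
#'
#' Returns row indices in which every class keeps its original members
#' and minority classes add members resampled with replacement until all
#' classes match the majority count. Applied inside training folds only;
#' held-out data is never touched.
#'
#' @param labels Factor (or coercible) of class labels.
#' @param seed Integer seed.
#' @return Integer vector of row indices.
#' @export
upsample_indices <- function(labels, seed) {
  if (!length(labels)) stop("empty class set")
  labels <- factor(labels)   # unused levels are dropped
  tab <- table(labels)
  if (any(tab == 0L)) stop("empty class")
  target <- max(tab)
  with_seed(seed, {
    unlist(lapply(levels(labels), function(cl) {
      idx <- which(labels == cl)
      extra <- target - length(idx)
      c(idx, if (extra > 0L) sample(idx, extra, replace = TRUE))
    }), use.names = FALSE)
  })
}

# training-column medians for imputation; all-NA columns fall back to 0
.col_medians <- function(X) {
  med <- apply(X, 2L, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  med
}

.impute <- function(X, medians) {
  if (!anyNA(X)) return(X)
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- medians[j]
  }
  X
}

.col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2L) return(rep(1, ncol(X)))
  mu <- colMeans(X)
  sqrt(pmax(colSums(X^2) - n * mu^2, 0) / (n - 1L))
}

#' Fit a penalized multinomial logistic regression
#'
#' Minimizes the penalized negative multinomial log-likelihood
#' \deqn{-\frac{1}{N}\ell(\beta) + \lambda\left[\frac{1-\alpha}{2}
#'   \|\beta\|_2^2 + \alpha \|\beta\|_1\right]}
#' with unpenalized intercepts, via glmnet (binomial family for two
#' classes). Features are z-scored with statistics computed from the
#' training rows passed here; new rows are transformed with the same
#' statistics. Missing entries are replaced by the supplied training
#' medians before scaling.
#'
#' @param X Numeric training matrix (samples x features).
#' @param y Factor of class labels (>= 2 classes present).
#' @param alpha Elastic-net mixing in `[0,1]` (0 = ridge, 1 = lasso).
#' @param lambda Penalty strength (> 0).
#' @param medians Optional named vector of per-feature imputation values
#'   (computed from `X` when omitted).
#' @return Object of class `penalized_multinomial` with a
#'   [predict.penalized_multinomial()] method returning class
#'   probabilities.
#' @export
fit_penalized_multinomial <- function(X, y, alpha, lambda,
                                      medians = NULL) {
  y <- factor(y)
  y <- droplevels(y)
  if (nlevels(y) < 2L) stop("y must contain at least two classes")
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(medians)) medians <- .col_medians(X)
  X <- .impute(X, medians)
  if (any(!is.finite(X))) stop("non-finite values in X after imputation")
  center <- colMeans(X)
  scale <- .col_sds(X)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- sweep(sweep(X, 2L, center), 2L, scale, "/")
  fam <- if (nlevels(y) == 2L) "binomial" else "multinomial"
  # glmnet needs >= 2 columns; pad single-feature problems with an
  # all-zero dummy whose coefficient is necessarily zero
  pad <- ncol(Xs) == 1L
  Xfit <- if (pad) cbind(Xs, `.dummy` = 0) else Xs
  # short decreasing path ending at the target lambda (warm starts make
  # the path fit cheaper and more stable than a single-lambda fit)
  path <- sort(unique(lambda * c(100, 10, 1)), decreasing = TRUE)
  fit <- glmnet::glmnet(Xfit, y, family = fam, alpha = alpha,
                        lambda = path, standardize = FALSE,
                        thresh = 1e-6)
  # dense coefficients at the target lambda, so scoring is a plain
  # matrix product; glmnet can truncate the path on difficult fits, in
  # which case fall back to its interpolating coef()
  j <- which(abs(fit$lambda - lambda) <= 1e-9 * max(lambda, 1))
  if (length(j) == 1L) {
    if (fam == "binomial") {
      a0 <- unname(fit$a0[j])
      beta <- matrix(as.numeric(fit$beta[, j]), ncol = 1L)
    } else {
      a0 <- fit$a0[, j]
      beta <- vapply(fit$beta, function(b) as.numeric(b[, j]),
                     numeric(ncol(Xfit)))
      if (!is.matrix(beta)) beta <- matrix(beta, nrow = 1L)
    }
  } else {
    cf <- stats::coef(fit, s = lambda)
    if (fam == "binomial") {
      cf <- as.matrix(cf)
      a0 <- unname(cf[1L, 1L])
      beta <- matrix(cf[-1L, 1L], ncol = 1L)
    } else {
      a0 <- vapply(cf, function(m) as.matrix(m)[1L, 1L], numeric(1))
      beta <- vapply(cf, function(m) as.matrix(m)[-1L, 1L],
                     numeric(ncol(Xfit)))
      if (!is.matrix(beta)) beta <- matrix(beta, nrow = 1L)
    }
  }
  if (pad) beta <- beta[-nrow(beta), , drop = FALSE]
  structure(list(fit = fit, family = fam, classes = levels(y),
                 alpha = alpha, lambda = lambda, medians = medians,
                 center = center, scale = scale, a0 = a0, beta = beta),
            class = "penalized_multinomial")
}

#' Class probabilities from a fitted penalized multinomial model
#' @param object A `penalized_multinomial` model.
#' @param newx Matrix of new rows (original feature scale; `NA`s are
#'   imputed with the training medians).
#' @param ... Unused.
#' @return Matrix of class probabilities, one column per class.
#' @export
predict.penalized_multinomial <- function(object, newx, ...) {
  if (!is.matrix(newx)) newx <- as.matrix(newx)
  newx <- .impute(newx, object$medians)
  Xs <- sweep(sweep(newx, 2L, object$center), 2L, object$scale, "/")
  if (object$family == "binomial") {
    p2 <- 1 / (1 + exp(-(object$a0 + as.numeric(Xs %*% object$beta))))
    out <- cbind(1 - p2, p2)
  } else {
    eta <- sweep(Xs %*% object$beta, 2L, object$a0, "+")
    eta <- exp(eta - apply(eta, 1L, max))
    out <- eta / rowSums(eta)
  }
  colnames(out) <- object$classes
  rownames(out) <- rownames(newx)
  out
}

#' One-vs-rest AUROC
#'
#' Probability that a randomly chosen positive sample outscores a
#' randomly chosen negative one, ties counting one half (the
#' Mann-Whitney form of the area under the ROC curve).
#'
#' @param scores Numeric scores (e.g. predicted probability of the
#'   positive phenotype).
#' @param labels Class labels aligned with `scores`.
#' @param positive The label treated as positive.
#' @return AUROC in `[0,1]`, or `NA_real_` when either class is absent.
#' @export
one_vs_rest_auroc <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# macro-average of one-vs-rest AUROCs over the classes present in labels
.macro_auroc <- function(prob, labels) {
  labels <- as.character(labels)
  present <- intersect(colnames(prob), unique(labels))
  if (length(unique(labels)) < 2L) return(NA_real_)
  mean(vapply(present, function(cl)
    one_vs_rest_auroc(prob[, cl], labels, cl), numeric(1)),
    na.rm = TRUE)
}

#' Select hyperparameters by nested cross-validation
#'
#' Evaluates each candidate with a stratified `inner_k`-fold CV on the
#' training data only (imputation medians, scaling and up-sampling are
#' recomputed inside each inner training fold), scores candidates by the
#' mean macro-averaged one-vs-rest AUROC over inner folds, and returns
#' the winner; ties break to the smaller lambda, then the smaller alpha.
#'
#' @param X,y Training matrix and labels.
#' @param candidates `data.frame` with columns `alpha`, `lambda`.
#' @param inner_k Inner fold count.
#' @param seed Integer seed for the inner folds and up-sampling.
#' @param upsample Balance classes inside inner training folds.
#' @return One-row `data.frame` (`alpha`, `lambda`) plus a `mean_auroc`
#'   attribute.
#' @export
nested_cv_select <- function(X, y, candidates, inner_k = 5L, seed = 1L,
                             upsample = TRUE) {
  stopifnot(nrow(candidates) >= 1L)
  y <- factor(y)
  if (nrow(candidates) == 1L) return(candidates[1L, , drop = FALSE])
  folds <- make_folds(y, inner_k, derive_seed(seed, 11L))
  scores <- matrix(NA_real_, nrow(candidates), inner_k)
  for (f in seq_len(inner_k)) {
    tr <- which(folds != f); te <- which(folds == f)
    if (length(unique(y[te])) < 2L) next
    med <- .col_medians(X[tr, , drop = FALSE])
    rows <- if (upsample)
      tr[upsample_indices(y[tr], derive_seed(seed, 13L, f))] else tr
    for (ci in seq_len(nrow(candidates))) {
      m <- fit_penalized_multinomial(X[rows, , drop = FALSE], y[rows],
                                     candidates$alpha[ci],
                                     candidates$lambda[ci],
                                     medians = med)
      pr <- predict(m, X[te, , drop = FALSE])
      scores[ci, f] <- .macro_auroc(pr, y[te])
    }
  }
  mean_sc <- rowMeans(scores, na.rm = TRUE)
  mean_sc[!is.finite(mean_sc)] <- -Inf
  ord <- order(-mean_sc, candidates$lambda, candidates$alpha)
  best <- candidates[ord[1L], , drop = FALSE]
  attr(best, "mean_auroc") <- mean_sc[ord[1L]]
  best
}

# Train on the training rows of one outer fold: impute from training
# medians, select hyperparameters by nested CV, up-sample, refit.
# Everything the model learns comes from train_idx rows only.
.train_outer <- function(X, y, train_idx, candidates, inner_k, seed,
                         upsample = TRUE) {
  Xtr <- X[train_idx, , drop = FALSE]
  ytr <- factor(y[train_idx])
  med <- .col_medians(Xtr)
  best <- nested_cv_select(Xtr, ytr, candidates, inner_k, seed, upsample)
  rows <- if (upsample)
    upsample_indices(ytr, derive_seed(seed, 17L))
  else seq_along(ytr)
  fit_penalized_multinomial(Xtr[rows, , drop = FALSE], ytr[rows],
                            best$alpha, best$lambda, medians = med)
}

#' Repeated nested cross-validation over fragmentomics metrics
#'
#' For each repeat, one stratified fold assignment is drawn and shared by
#' every metric table (so metrics are compared on identical splits). Per
#' metric and outer fold, hyperparameters are selected by nested inner
#' CV on the training fold, the model is refit on the (up-sampled)
#' training fold and scored on the held-out fold; out-of-fold
#' probabilities are pooled within the repeat and converted to one
#' one-vs-rest AUROC per phenotype. Medians over repeats are the
#' headline summaries (see [summary.frag_cv()]).
#'
#' @param tables Named list of [feature_table]s sharing sample ids and
#'   labels (e.g. a `feature_table_set`).
#' @param config A [cv_config].
#' @param metrics Optional subset of metric names to evaluate.
#' @return Object of class `frag_cv` with elements `results`
#'   (`data.frame`: `metric`, `phenotype`, `rep`, `seed`, `auroc`),
#'   `config`, `classes`, `n_samples`.
#' @export
run_repeated_cv <- function(tables, config = cv_config(),
                            metrics = NULL) {
  stopifnot(inherits(config, "cv_config"))
  tables <- tables[!vapply(tables, is.null, TRUE)]
  if (!is.null(metrics)) tables <- tables[metrics]
  stopifnot(length(tables) >= 1L)
  ids <- rownames(tables[[1L]]$values)
  labels <- tables[[1L]]$labels
  if (is.null(labels)) stop("feature tables must carry phenotype labels")
  for (t in tables) {
    if (!identical(rownames(t$values), ids))
      stop("feature tables have misaligned sample ids")
  }
  y <- factor(labels)
  res <- list()
  for (r in seq_len(config$n_repeats)) {
    rseed <- derive_seed(config$master_seed, 700L, r)
    folds <- make_folds(y, config$outer_folds, rseed)
    cands <- latin_hypercube_hyperparams(config$n_hyper,
                                         config$alpha_range,
                                         config$lambda_range,
                                         derive_seed(rseed, 19L))
    for (mn in names(tables)) {
      X <- tables[[mn]]$values
      prob <- matrix(NA_real_, length(y), nlevels(y),
                     dimnames = list(ids, levels(y)))
      for (f in seq_len(config$outer_folds)) {
        tr <- which(folds != f); te <- which(folds == f)
        model <- .train_outer(X, y, tr, cands, config$inner_folds,
                              derive_seed(rseed, 23L, f),
                              config$upsample)
        pr <- predict(model, X[te, , drop = FALSE])
        prob[te, colnames(pr)] <- pr
      }
      for (cl in levels(y)) {
        res[[length(res) + 1L]] <- data.frame(
          metric = mn, phenotype = cl, rep = r, seed = rseed,
          auroc = one_vs_rest_auroc(prob[, cl], as.character(y), cl),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(results = do.call(rbind, res), config = config,
                 classes = levels(y), n_samples = length(y)),
            class = "frag_cv")
}

#' @export
print.frag_cv <- function(x, ...) {
  cat("<frag_cv> ", length(unique(x$results$metric)), " metric(s), ",
      length(x$classes), " phenotype(s), ", x$config$n_repeats,
      " repeats on ", x$n_samples, " samples\n", sep = "")
  cat("median AUROC by metric:\n")
  med <- sort(tapply(x$results$auroc, x$results$metric, median,
                     na.rm = TRUE), decreasing = TRUE)
  print(round(med, 3))
  invisible(x)
}

#' Median AUROC per metric and phenotype
#' @param object A `frag_cv` object.
#' @param ... Unused.
#' @return Matrix of medians over repeats (metrics x phenotypes).
#' @export
summary.frag_cv <- function(object, ...) {
  r <- object$results
  tab <- tapply(r$auroc, list(r$metric, r$phenotype), median, na.rm = TRUE)
  tab[unique(r$metric), , drop = FALSE]
}

#' Boxplots of AUROC by metric
#' @param x A `frag_cv` object.
#' @param ... Passed to [graphics::boxplot()].
#' @export
plot.frag_cv <- function(x, ...) {
  r <- x$results
  graphics::boxplot(auroc ~ metric, data = r, las = 2,
                    ylab = "one-vs-rest AUROC", xlab = "", ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey50")
  invisible(x)
}

#' Median AUROC deltas between a full panel and a gene subset
#'
#' `median(subset) - median(full)` per (metric, phenotype): the cost, in
#' median AUROC, of restricting the panel to a commercial gene list.
#'
#' @param full,subset `frag_cv` objects for the full panel and the
#'   subset panel (same metrics and phenotypes).
#' @return `data.frame` with `metric`, `phenotype`, `median_full`,
#'   `median_subset`, `delta`.
#' @export
auroc_deltas <- function(full, subset) {
  stopifnot(inherits(full, "frag_cv"), inherits(subset, "frag_cv"))
  mf <- summary(full); ms <- summary(subset)
  stopifnot(identical(dimnames(mf), dimnames(ms)))
  out <- expand.grid(metric = rownames(mf), phenotype = colnames(mf),
                     stringsAsFactors = FALSE)
  out$median_full <- mf[cbind(out$metric, out$phenotype)]
  out$median_subset <- ms[cbind(out$metric, out$phenotype)]
  out$delta <- out$median_subset - out$median_full
  out
}

#' Train on one cohort, score another
#'
#' The split-sample protocol of the mixing experiment: per repeat,
#' hyperparameters are selected by nested CV within the training cohort,
#' the model is refit on the full (up-sampled) training cohort, and the
#' held-out cohort is scored once. No validation information reaches
#' training.
#'
#' @param train_tables,valid_tables Named lists of [feature_table]s with
#'   matching metric names; the training tables must carry labels.
#' @param config A [cv_config]; `inner_folds` drives the tuning CV.
#' @param metrics Optional subset of metric names.
#' @return Object of class `frag_validation`: `data.frame` `scores` with
#'   one row per (metric, rep, validation sample) and one probability
#'   column per class, plus `classes` and `config`.
#' @export
evaluate_split <- function(train_tables, valid_tables,
                           config = cv_config(), metrics = NULL) {
  stopifnot(inherits(config, "cv_config"))
  if (!is.null(metrics)) {
    train_tables <- train_tables[metrics]
    valid_tables <- valid_tables[metrics]
  }
  mns <- intersect(names(train_tables), names(valid_tables))
  stopifnot(length(mns) >= 1L)
  y <- factor(train_tables[[1L]]$labels)
  rows <- list()
  for (r in seq_len(config$n_repeats)) {
    rseed <- derive_seed(config$master_seed, 800L, r)
    cands <- latin_hypercube_hyperparams(config$n_hyper,
                                         config$alpha_range,
                                         config$lambda_range,
                                         derive_seed(rseed, 19L))
    for (mn in mns) {
      X <- train_tables[[mn]]$values
      model <- .train_outer(X, y, seq_along(y), cands,
                            config$inner_folds,
                            derive_seed(rseed, 29L), config$upsample)
      V <- valid_tables[[mn]]$values
      pr <- predict(model, V)
      df <- data.frame(metric = mn, rep = r,
                       sample_id = rownames(V),
                       stringsAsFactors = FALSE)
      for (cl in colnames(pr)) df[[paste0("p_", cl)]] <- pr[, cl]
      rows[[length(rows) + 1L]] <- df
    }
  }
  structure(list(scores = do.call(rbind, rows), classes = levels(y),
                 config = config),
            class = "frag_validation")
}

#' Healthy-vs-cancer AUROC per ctDNA fraction bin
#'
#' For each metric, repeat and log-decade fraction bin: positives are the
#' cancer mixtures whose calculated ctDNA fraction falls in the bin,
#' negatives are all healthy-healthy control mixtures, and the score is
#' the predicted probability of the positive class. Median over repeats
#' summarizes each bin.
#'
#' @param fv A `frag_validation` from [evaluate_split()] on mixture
#'   samples.
#' @param design The [enumerate_design()] rows describing the scored
#'   mixtures (matched by `spec_id` = sample id).
#' @param positive The cancer class label whose probability is used.
#' @return `data.frame` with `metric`, `rep`, `fraction_bin`, `auroc`,
#'   `n_pos`, `n_neg`.
#' @export
mixing_bin_auroc <- function(fv, design, positive) {
  stopifnot(inherits(fv, "frag_validation"))
  sc <- fv$scores
  m <- match(sc$sample_id, design$spec_id)
  if (anyNA(m)) stop("scores contain samples absent from the design")
  sc$bin <- design$fraction_bin[m]
  sc$is_cancer <- design$partner_is_cancer[m]
  pcol <- paste0("p_", positive)
  if (!pcol %in% names(sc)) stop("no probability column for ", positive)
  out <- list()
  for (mn in unique(sc$metric)) {
    for (r in unique(sc$rep)) {
      sub <- sc[sc$metric == mn & sc$rep == r, , drop = FALSE]
      neg <- sub[!sub$is_cancer, , drop = FALSE]
      for (b in .BIN_LEVELS) {
        pos <- sub[sub$is_cancer & !is.na(sub$bin) & sub$bin == b, ,
                   drop = FALSE]
        if (!nrow(pos) || !nrow(neg)) next
        scores <- c(pos[[pcol]], neg[[pcol]])
        labs <- rep(c("pos", "neg"), c(nrow(pos), nrow(neg)))
        out[[length(out) + 1L]] <- data.frame(
          metric = mn, rep = r, fraction_bin = b,
          auroc = one_vs_rest_auroc(scores, labs, "pos"),
          n_pos = nrow(pos), n_neg = nrow(neg),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
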