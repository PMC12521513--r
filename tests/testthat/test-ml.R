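test_that("stratified folds balance classes and are reproducible", {
  y <- rep(c("a", "b"), each = 50)
  f <- make_folds(y, 10L, seed = 4L)
  expect_equal(as.vector(table(f)), rep(10L, 10))
  for (k in 1:10)
    expect_equal(as.vector(table(y[f == k])), c(5L, 5L))
  expect_identical(f, make_folds(y, 10L, seed = 4L))
  expect_false(identical(f, make_folds(y, 10L, seed = 5L)))
  expect_error(make_folds(y, 1L, seed = 1L), "k must be")
  expect_error(make_folds(y[1:5], 10L, seed = 1L), "exceeds")
})

test_that("Latin hypercube candidates stratify both axes", {
  hp <- latin_hypercube_hyperparams(10L, seed = 8L)
  expect_equal(nrow(hp), 10L)
  # one alpha per decile of [0,1]
  expect_equal(sort(floor(hp$alpha * 10)), 0:9)
  # one lambda per log-scale decile of [1e-4, 1e1]
  u <- (log(hp$lambda) - log(1e-4)) / (log(10) - log(1e-4))
  expect_equal(sort(floor(u * 10)), 0:9)
  expect_identical(hp, latin_hypercube_hyperparams(10L, seed = 8L))

  one <- latin_hypercube_hyperparams(1L, c(0.2, 0.4), c(0.1, 1), seed = 1L)
  expect_gte(one$alpha, 0.2); expect_lte(one$alpha, 0.4)
  expect_gte(one$lambda, 0.1); expect_lte(one$lambda, 1)
})

test_that("up-sampling balances to the majority class without touching it", {
  y <- c(rep("big", 10), rep("small", 3))
  idx <- upsample_indices(y, seed = 2L)
  expect_equal(as.vector(table(y[idx])), c(10L, 10L))
  expect_true(all(1:13 %in% idx))          # originals all retained
  balanced <- rep(c("a", "b"), each = 4)
  expect_equal(sort(upsample_indices(balanced, seed = 1L)), 1:8)
  expect_error(upsample_indices(character(0), seed = 1L), "empty class")
})

test_that("the penalty limit and separable cases behave as theory says", {
  set.seed(5)
  X <- matrix(rnorm(40 * 4), 40, 4,
              dimnames = list(paste0("s", 1:40), paste0("f", 1:4)))
  y <- factor(rep(c("a", "b"), c(30, 10)))
  # huge lambda: no coefficients survive, probabilities = class frequencies
  m <- fit_penalized_multinomial(X, y, alpha = 0.5, lambda = 1e6)
  expect_true(all(m$beta == 0))
  pr <- predict(m, X)
  expect_equal(unname(pr[1, "b"]), 0.25, tolerance = 0.01)

  # perfectly separable two-class toy: training AUROC 1
  Xs <- matrix(c(rnorm(10, -3), rnorm(10, 3)), ncol = 1,
               dimnames = list(paste0("s", 1:20), "f1"))
  ys <- factor(rep(c("lo", "hi"), each = 10))
  ms <- fit_penalized_multinomial(Xs, ys, alpha = 0.5, lambda = 0.01)
  sc <- predict(ms, Xs)[, "hi"]
  expect_equal(one_vs_rest_auroc(sc, as.character(ys), "hi"), 1.0)

  # lasso is at least as sparse as ridge at the same penalty
  set.seed(6)
  Xw <- matrix(rnorm(60 * 10), 60, 10,
               dimnames = list(paste0("s", 1:60), paste0("f", 1:10)))
  yw <- factor(rep(c("a", "b"), each = 30))
  l1 <- fit_penalized_multinomial(Xw, yw, alpha = 1, lambda = 0.1)
  l2 <- fit_penalized_multinomial(Xw, yw, alpha = 0, lambda = 0.1)
  expect_gte(sum(l1$beta == 0), sum(l2$beta == 0))

  expect_error(fit_penalized_multinomial(X, factor(rep("a", 40)),
                                         0.5, 0.1), "two classes")
})

test_that("multiclass probabilities are calibrated rows summing to one", {
  set.seed(15)
  X <- matrix(rnorm(90 * 5), 90, 5,
              dimnames = list(paste0("s", 1:90), paste0("f", 1:5)))
  X[1:30, 1] <- X[1:30, 1] + 3
  X[31:60, 2] <- X[31:60, 2] + 3
  y <- factor(rep(c("a", "b", "c"), each = 30))
  m <- fit_penalized_multinomial(X, y, 0.5, 0.01)
  pr <- predict(m, X)
  expect_equal(colnames(pr), c("a", "b", "c"))
  expect_equal(unname(rowSums(pr)), rep(1, 90))
  expect_gt(mean(pr[1:30, "a"]), mean(pr[31:90, "a"]))
})

test_that("one-vs-rest AUROC matches hand values and the pairwise oracle", {
  expect_equal(one_vs_rest_auroc(c(0.9, 0.8, 0.7, 0.1),
                                 c("p", "p", "n", "n"), "p"), 1.0)
  expect_equal(one_vs_rest_auroc(c(0.9, 0.4, 0.6, 0.2),
                                 c("p", "p", "n", "n"), "p"), 0.75)
  expect_equal(one_vs_rest_auroc(rep(0.5, 6),
                                 rep(c("p", "n"), 3), "p"), 0.5)
  expect_true(is.na(one_vs_rest_auroc(c(0.1, 0.2), c("p", "p"), "p")))

  set.seed(33)
  for (i in 1:30) {
    n <- sample(4:50, 1)
    sc <- round(runif(n), 2)       # rounding forces ties
    lab <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(one_vs_rest_auroc(sc, lab, "p"), bf_auroc(sc, lab, "p"))
  }
})

test_that("AUROC agrees with pROC on random instances", {
  skip_if_not_installed("pROC")
  set.seed(44)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    sc <- runif(n)
    lab <- sample(c("p", "n"), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    want <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(lab, sc, levels = c("n", "p"),
                          direction = "<"))))
    expect_equal(one_vs_rest_auroc(sc, lab, "p"), want)
  }
})

test_that("nested CV selection favours working candidates and breaks ties", {
  cands <- data.frame(alpha = c(0.5), lambda = c(0.1))
  expect_equal(nested_cv_select(matrix(rnorm(20), 10),
                                factor(rep(c("a", "b"), 5)), cands),
               cands, ignore_attr = TRUE)

  # tied scores break to the smaller lambda: on a cleanly separable toy
  # both small lambdas reach inner AUROC 1
  set.seed(9)
  Xt <- cbind(c(rnorm(20, -4), rnorm(20, 4)), rnorm(40))
  yt <- factor(rep(c("a", "b"), each = 20))
  dup <- data.frame(alpha = c(0.5, 0.5), lambda = c(0.01, 0.001))
  best <- nested_cv_select(Xt, yt, dup, inner_k = 4L, seed = 3L)
  expect_equal(best$lambda, 0.001)

  # a degenerate huge-lambda candidate loses to a usable one
  set.seed(10)
  Xs <- matrix(c(rnorm(30, -3), rnorm(30, 3)), ncol = 1)
  ys <- factor(rep(c("lo", "hi"), each = 30))
  mix <- data.frame(alpha = c(0.5, 0.5), lambda = c(1e6, 0.01))
  best <- nested_cv_select(Xs, ys, mix, inner_k = 3L, seed = 4L)
  expect_equal(best$lambda, 0.01)
})

test_that("repeated CV emits one AUROC per metric, phenotype and repeat", {
  cfg <- quick_config(seed = 61L, n_samples_per_phenotype = 15L,
                      reads_per_sample = 800L)
  coh <- simulate_cohort(cfg)
  ft <- compute_feature_tables(coh$samples, coh$panel,
                               labels = setNames(coh$labels$phenotype,
                                                 coh$labels$sample_id))
  cv <- run_repeated_cv(ft[c("depth_all_exons", "entropy_all_exons")],
                        cv_config(outer_folds = 5L, inner_folds = 3L,
                                  n_hyper = 4L, n_repeats = 3L,
                                  master_seed = 2L))
  expect_s3_class(cv, "frag_cv")
  expect_equal(nrow(cv$results), 3L * 2L * 2L)  # repeats x metrics x classes
  expect_true(all(cv$results$auroc >= 0 & cv$results$auroc <= 1))
  s <- summary(cv)
  expect_equal(dim(s), c(2L, 2L))

  # identical feature tables share folds, so per-repeat AUROCs agree
  twin <- ft["depth_all_exons"]
  twin$depth_twin <- twin$depth_all_exons
  cv2 <- run_repeated_cv(twin, cv_config(outer_folds = 5L,
                                         inner_folds = 3L, n_hyper = 4L,
                                         n_repeats = 2L, master_seed = 2L))
  r <- cv2$results
  expect_equal(r$auroc[r$metric == "depth_all_exons"],
               r$auroc[r$metric == "depth_twin"])
})

test_that("training is blind to held-out rows", {
  set.seed(70)
  X <- matrix(rnorm(60 * 6), 60, 6,
              dimnames = list(paste0("s", 1:60), paste0("f", 1:6)))
  y <- factor(rep(c("a", "b"), each = 30))
  cands <- latin_hypercube_hyperparams(4L, seed = 2L)
  train <- 1:48
  m1 <- panelfrag:::.train_outer(X, y, train, cands, 3L, 5L, TRUE)
  poisoned <- X
  poisoned[49:60, ] <- 1e6          # poison the held-out rows
  m2 <- panelfrag:::.train_outer(poisoned, y, train, cands, 3L, 5L, TRUE)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$a0, m2$a0)
  expect_identical(m1$medians, m2$medians)
  expect_identical(m1$center, m2$center)
})

test_that("summaries and gene-set deltas reduce to simple arithmetic", {
  mk <- function(aurocs) {
    structure(list(results = data.frame(
      metric = "depth_all_exons", phenotype = "cancer",
      rep = seq_along(aurocs), seed = 1L, auroc = aurocs),
      config = cv_config(n_repeats = length(aurocs)),
      classes = c("cancer", "healthy"), n_samples = 10L),
      class = "frag_cv")
  }
  full <- mk(c(0.9, 0.92, 0.94))
  expect_equal(unname(summary(full)["depth_all_exons", "cancer"]), 0.92)
  sub <- mk(c(0.85, 0.9, 0.80))
  d <- auroc_deltas(full, sub)
  expect_equal(d$delta, 0.85 - 0.92)
  expect_equal(auroc_deltas(full, full)$delta, 0)
})

test_that("split evaluation scores every validation sample per metric and repeat", {
  cfg <- quick_config(seed = 71L, n_samples_per_phenotype = 12L,
                      reads_per_sample = 600L)
  coh <- simulate_cohort(cfg)
  lab <- setNames(coh$labels$phenotype, coh$labels$sample_id)
  ft <- compute_feature_tables(coh$samples, coh$panel, labels = lab)
  tr <- c(1:8, 13:20); va <- c(9:12, 21:24)
  subset_ft <- function(t, idx)
    feature_table(t$values[idx, , drop = FALSE],
                  t$labels[idx], t$metric_name)
  train <- lapply(ft["depth_all_exons"], subset_ft, idx = tr)
  valid <- lapply(ft["depth_all_exons"], subset_ft, idx = va)
  fv <- evaluate_split(train, valid,
                       cv_config(inner_folds = 3L, n_hyper = 3L,
                                 n_repeats = 2L, master_seed = 3L))
  expect_equal(nrow(fv$scores), 2L * length(va))
  expect_true(all(c("p_cancer", "p_healthy") %in% names(fv$scores)))
  expect_equal(fv$scores$p_cancer + fv$scores$p_healthy,
               rep(1, nrow(fv$scores)))
})
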