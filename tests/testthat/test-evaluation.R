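# Folds, ROC/AUC, stringency metrics, retrieval and cross-validation.

test_that("stratified folds balance positives and are seed-deterministic", {
  labels <- rep(c(1, 0), c(20, 80))
  f <- stratified_folds(labels, k = 10, seed = 2)
  pos_per_fold <- table(f[labels == 1])
  neg_per_fold <- table(f[labels == 0])
  expect_true(all(pos_per_fold == 2))
  expect_true(all(neg_per_fold == 8))
  expect_identical(f, stratified_folds(labels, k = 10, seed = 2))
  expect_false(identical(f, stratified_folds(labels, k = 10, seed = 3)))
  expect_warning(stratified_folds(rep(c(1, 0), c(5, 95)), k = 10, seed = 1),
                 "single-class")
  expect_error(stratified_folds(labels, k = 1), class = "kinsub_argument_error")
})

test_that("AUC equals Mann-Whitney pair counting with half-ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(c(5, 4, 1, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.3, 6), rep(c(1, 0), 3)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "kinsub_argument_error")
  withr::with_seed(10, {
    for (rep in 1:200) {
      n <- sample(2:8, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, 0.25), n, replace = TRUE)
      expect_equal(roc_auc(scores, labels), oracle_auc(scores, labels))
    }
  })
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(11, {
    scores <- rnorm(40)
    labels <- rbinom(40, 1, 0.4)
  })
  a <- roc_auc(scores, labels)
  expect_equal(roc_auc(exp(scores), labels), a)
  expect_equal(roc_auc(2 * scores + 7, labels), a)
})

test_that("confusion metrics follow their defining formulas", {
  m <- metrics_from_confusion(tp = 8, fp = 5, tn = 85, fn = 2)
  o <- oracle_metrics(tp = 8, fp = 5, tn = 85, fn = 2)
  expect_equal(m$sn, 0.800, tolerance = 1e-3)
  expect_equal(m$sp, o$sp)
  expect_equal(m$pre, o$pre)
  expect_equal(m$f1, o$f1)
  expect_equal(m$mcc, 0.6641, tolerance = 1e-4)
  perfect <- metrics_from_confusion(10, 0, 90, 0)
  expect_equal(unlist(perfect[c("sn", "sp", "pre", "f1", "mcc")]),
               c(sn = 1, sp = 1, pre = 1, f1 = 1, mcc = 1))
  nothing <- metrics_from_confusion(0, 0, 90, 10)
  expect_equal(nothing$pre, 0)
  expect_equal(nothing$sn, 0)
  expect_true(nothing$degenerate)
  # random triples against the oracle
  withr::with_seed(12, {
    for (rep in 1:50) {
      c4 <- rmultinom(1, 60, rep(0.25, 4))[, 1] + 1
      m <- metrics_from_confusion(c4[1], c4[2], c4[3], c4[4])
      o <- oracle_metrics(c4[1], c4[2], c4[3], c4[4])
      expect_equal(unlist(m[c("sn", "sp", "pre", "f1", "mcc")]),
                   unlist(o), ignore_attr = TRUE)
    }
  })
})

test_that("specificity-targeted thresholds maximize Sn over feasible points", {
  scores <- c(1:10, 10.5)  # 10 negatives scored 1..10, one positive on top
  labels <- c(rep(0, 10), 1)
  m <- metrics_at_specificity(scores, labels, sp_target = 0.9)
  expect_equal(m$sp, 0.9)            # threshold admits exactly one negative
  expect_equal(m$threshold, 10)
  m1 <- metrics_at_specificity(scores, labels, sp_target = 1.0)
  expect_equal(m1$sp, 1)
  expect_gt(m1$threshold, 10)
  # perfectly separated classes reach Sn = 1 at any stringency
  sep <- metrics_at_specificity(c(1, 2, 3, 9, 10), c(0, 0, 0, 1, 1), 0.95)
  expect_equal(sep$sn, 1)
  expect_error(metrics_at_specificity(scores, labels, 0),
               class = "kinsub_argument_error")
})

test_that("realized Sp >= target and Sn does not drop when relaxing it", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      scores <- rnorm(60)
      labels <- rbinom(60, 1, 0.3)
      if (sum(labels) == 0 || sum(labels) == 60) next
      sns <- c()
      for (tgt in c(0.95, 0.9, 0.8, 0.5)) {
        m <- metrics_at_specificity(scores, labels, tgt)
        expect_gte(m$sp, tgt)
        sns <- c(sns, m$sn)
      }
      expect_true(all(diff(sns) >= -1e-12))
    }
  })
})

test_that("top-percentile retrieval counts positives among top ranks", {
  scores <- c(seq(1, 0.91, length.out = 10), seq(0.5, 0.05, length.out = 90))
  labels <- rep(c(1, 0), c(10, 90))
  r <- top_percentile_retrieval(scores, labels, c(10, 100))
  expect_equal(r$n_true, c(10, 10))
  expect_equal(r$recall, c(1, 1))
  expect_equal(r$n_top, c(10, 100))
  expect_error(top_percentile_retrieval(scores, labels, 0),
               class = "kinsub_argument_error")
  # null expectation: ~10% of top-10% under random ranking
  counts <- withr::with_seed(14, vapply(1:40, function(i)
    top_percentile_retrieval(rnorm(100), labels, 10)$n_true, numeric(1)))
  expect_gt(mean(counts), 0.3)
  expect_lt(mean(counts), 2.5)
})

test_that("cross-validation is deterministic and skips single-class folds", {
  b <- generate_dataset(synth_spec(n_substrates = 12, n_kinases = 2,
                                   positives_per_kinase = 12, seed = 31))
  kin <- select_model_kinases(b$adjacency, 10)[1]
  cfg <- ksr_config(min_positives = 10)
  e1 <- cross_validate(b, kin, cfg, seed = 9)
  e2 <- cross_validate(b, kin, cfg, seed = 9)
  expect_identical(e1$scores, e2$scores)
  expect_identical(e1$pooled_auc, e2$pooled_auc)
  # 5-positive kinase with k = 10 folds: some folds have no positive
  b2 <- generate_dataset(synth_spec(n_substrates = 10, n_kinases = 2,
                                    positives_per_kinase = 5, seed = 32))
  kin2 <- colnames(b2$adjacency)[1]
  warns <- testthat::capture_warnings(
    e3 <- cross_validate(b2, kin2, ksr_config(min_positives = 5), seed = 1))
  expect_true(any(grepl("single-class|AUC skipped", warns)))
  expect_true(anyNA(e3$fold_auc))
  expect_false(is.na(e3$pooled_auc))
})

test_that("tidy/glance/autoplot expose the evaluation report", {
  b <- generate_dataset(synth_spec(n_substrates = 12, n_kinases = 2,
                                   positives_per_kinase = 12, seed = 33))
  kin <- select_model_kinases(b$adjacency, 10)[1]
  e <- suppressWarnings(
    cross_validate(b, kin, ksr_config(min_positives = 10), seed = 1))
  td <- tidy(e)
  expect_equal(nrow(td), 2)  # two stringency levels
  expect_true(all(c("kinase", "ablation", "sp_target", "sn", "mcc") %in%
                    names(td)))
  gl <- glance(e)
  expect_equal(nrow(gl), 1)
  expect_true(gl$pooled_auc >= 0 && gl$pooled_auc <= 1)
  p <- autoplot(e)
  expect_s3_class(p, "ggplot")
  # pooled ROC is monotone nondecreasing in both coordinates
  expect_true(all(diff(e$roc$fpr) >= 0))
  expect_true(all(diff(e$roc$tpr) >= 0))
})
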