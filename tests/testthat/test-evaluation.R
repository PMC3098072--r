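test_that("confusion metrics match hand computation and the oracle", {
  # TP=3, FP=1, TN=2, FN=2
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 1, 1, 0)
  m <- metrics_at_threshold(scores, labels, 0.5)
  expect_equal(m$tp, 3); expect_equal(m$fp, 1)
  expect_equal(m$tn, 2); expect_equal(m$fn, 2)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 60)   # 3/5 as a percentage
  o <- oracle_metrics(scores, labels, 0.5)
  for (col in names(o)) expect_equal(m[[col]], o[[col]], info = col)
})

test_that("a perfectly separating threshold scores all metrics at their maxima", {
  scores <- c(2, 1.5, -1, -2)
  labels <- c(1, 1, 0, 0)
  m <- metrics_at_threshold(scores, labels, 0)
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 100)
  expect_equal(m$accuracy, 100)
  expect_equal(m$mcc, 1)
  expect_equal(m$f1, 1)
})

test_that("all-positive calling on a balanced set gives Sn 100 / Sp 0 / Acc 50 / MCC 0", {
  gtppred:::with_seed(21, {
    scores <- runif(40)
    labels <- rep(c(1, 0), 20)
    m <- metrics_at_threshold(scores, labels, min(scores))  # ties called positive
    expect_equal(m$sensitivity, 100)
    expect_equal(m$specificity, 0)
    expect_equal(m$accuracy, 50)
    expect_equal(m$mcc, 0)
  })
})

test_that("single-class inputs use the zero-denominator convention", {
  m <- metrics_at_threshold(c(0.2, 0.6), c(1, 1), 0.5)
  expect_equal(m$mcc, 0)
  expect_equal(m$specificity, 0)
  expect_error(metrics_at_threshold(numeric(0), integer(0), 0), "empty")
  expect_error(metrics_at_threshold(1:3, c(0, 1), 0), "length")
})

test_that("threshold sweeps cover inclusive endpoints with monotone Sn/Sp", {
  gtppred:::with_seed(22, {
    scores <- runif(200)
    labels <- rbinom(200, 1, 0.5)
    sw <- sweep_thresholds(scores, labels, 0, 1, 0.1)
    expect_equal(nrow(sw), 11)
    expect_equal(sw$threshold, seq(0, 1, 0.1))
    expect_true(all(diff(sw$sensitivity) <= 1e-9))
    expect_true(all(diff(sw$specificity) >= -1e-9))
  })
  sw_svm <- sweep_thresholds(c(-0.5, 0.5), c(0, 1), -1, 1, 0.1)
  expect_equal(nrow(sw_svm), 21)
  expect_error(sweep_thresholds(1:2, c(0, 1), 1, 0), "lo < hi")
})

test_that("degenerate constant scores give a two-regime sweep", {
  sw <- sweep_thresholds(rep(0.5, 10), rep(c(0, 1), 5), 0, 1, 0.1)
  below <- sw[sw$threshold <= 0.5, -1]
  above <- sw[sw$threshold > 0.5, -1]
  expect_true(all(vapply(below, function(col) length(unique(col)) == 1, TRUE)))
  expect_true(all(vapply(above, function(col) length(unique(col)) == 1, TRUE)))
})

test_that("threshold selection is lexicographic and order-invariant", {
  rows <- ann_sweep_single()
  expect_equal(select_threshold(rows), 0.2)           # unique MCC maximum
  rows2 <- ann_sweep_pssm()
  expect_equal(select_threshold(rows2), 0.2)          # accuracy breaks MCC tie

  gtppred:::with_seed(23, {
    shuf <- rows2[sample(nrow(rows2)), ]
    expect_equal(select_threshold(shuf), select_threshold(rows2))
  })

  # all rows identical -> lowest threshold
  flat <- rows[rep(1, 5), ]
  flat$threshold <- seq(0.1, 0.5, 0.1)
  expect_equal(select_threshold(flat), 0.1)

  # precision participates when present, after MCC and accuracy
  tie <- data.frame(threshold = c(0.1, 0.2), mcc = 0.5, accuracy = 70,
                    precision = c(0.6, 0.9),
                    sensitivity = c(70, 10), specificity = c(70, 95))
  expect_equal(select_threshold(tie), 0.2)
})

test_that("ROC/AUC behaves on separable, symmetric and random scores", {
  sep <- roc_auc(c(3, 2, -1, -4), c(1, 1, 0, 0))
  expect_equal(sep$auc, 1.0)

  gtppred:::with_seed(24, {
    scores <- rnorm(300)
    labels <- rbinom(300, 1, 0.4)
    a <- roc_auc(scores, labels)$auc
    a_neg <- roc_auc(-scores, labels)$auc
    expect_equal(a + a_neg, 1, tolerance = 1e-12)
  })
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("internal AUC agrees with an external reference implementation", {
  skip_if_not_installed("pROC")
  gtppred:::with_seed(25, {
    scores <- rnorm(500)
    labels <- rbinom(500, 1, 0.3)
    ours <- roc_auc(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  })
})

test_that("PR curve points are ordered by recall with sane endpoints", {
  gtppred:::with_seed(26, {
    scores <- rnorm(100)
    labels <- rbinom(100, 1, 0.5)
    pr <- pr_curve(scores, labels)
    expect_true(all(diff(pr$recall) >= 0))
    expect_equal(max(pr$recall), 1)
    expect_true(all(pr$precision >= 0 & pr$precision <= 1))
  })
})

test_that("metrics match the brute-force oracle over random score/label sets", {
  gtppred:::with_seed(27, {
    for (rep in 1:50) {
      n <- sample(5:60, 1)
      scores <- round(rnorm(n), 2)
      labels <- rbinom(n, 1, runif(1, 0.2, 0.8))
      thr <- sample(scores, 1) + sample(c(-0.005, 0, 0.005), 1)
      m <- metrics_at_threshold(scores, labels, thr)
      o <- oracle_metrics(scores, labels, thr)
      for (col in names(o)) {
        expect_equal(m[[col]], o[[col]], tolerance = 1e-12, info = col)
      }
    }
  })
})

test_that("five-fold cross-validation partitions each class evenly, once", {
  cfg <- small_config(seed = 41, n_chains = 15)
  chains <- generate_chains(cfg)
  ds <- build_dataset(extract_patterns_all(chains, "SRT"), "main", seed = 5)
  cv <- five_fold_cv(ds, "binary", "svm", seed = 6)

  expect_length(cv$fold, ds$n_pos + ds$n_neg)
  expect_setequal(unique(cv$fold), 1:5)          # every pattern in exactly one fold
  tab <- table(cv$fold, cv$labels)
  expect_true(all(abs(tab[, "1"] - mean(tab[, "1"])) <= 1))  # stratified

  cv2 <- five_fold_cv(ds, "binary", "svm", seed = 6)
  expect_identical(cv$fold, cv2$fold)
  expect_equal(cv$averaged, cv2$averaged)

  # averaged accuracy lies between per-fold extremes at every threshold
  accs <- sapply(cv$per_fold, `[[`, "accuracy")
  expect_true(all(cv$averaged$accuracy >= apply(accs, 1, min) - 1e-9))
  expect_true(all(cv$averaged$accuracy <= apply(accs, 1, max) + 1e-9))
  # and equals the arithmetic fold mean
  expect_equal(cv$averaged$mcc, rowMeans(sapply(cv$per_fold, `[[`, "mcc")))
})

test_that("chain-level splitting keeps each chain's patterns in one fold", {
  cfg <- small_config(seed = 43, n_chains = 15)
  chains <- generate_chains(cfg)
  ds <- build_dataset(extract_patterns_all(chains, "SRT"), "main", seed = 5)
  cv <- five_fold_cv(ds, "binary", "svm", seed = 7, split_by_chain = TRUE)
  per_chain <- tapply(cv$fold, ds$patterns$chain_id,
                      function(f) length(unique(f)))
  expect_true(all(per_chain == 1))
})

test_that("cross-validation refuses datasets with under five patterns per class", {
  ds <- separable_dataset(n_per_class = 4)
  expect_error(five_fold_cv(ds, "binary", "svm", seed = 1), "at least 5")
})

test_that("residue composition separates classes and sums to 100 percent", {
  chains <- list(labeled_chain("a", "GGGAC", c(1, 1, 1, 0, 0)),
                 labeled_chain("b", "GKTAC", c(1, 0, 0, 0, 0)))
  comp <- composition_analysis(chains)
  expect_equal(sum(comp$interacting_pct), 100, tolerance = 1e-9)
  expect_equal(sum(comp$noninteracting_pct), 100, tolerance = 1e-9)
  expect_equal(comp$interacting_pct[comp$residue == "G"], 100)
  expect_equal(comp$difference, comp$interacting_pct - comp$noninteracting_pct)

  expect_error(composition_analysis(list(labeled_chain("c", "AC", c(0, 0)))),
               "interacting")
})
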