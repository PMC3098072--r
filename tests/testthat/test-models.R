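test_that("both backends separate a linearly separable toy set perfectly", {
  ds <- separable_dataset()
  x <- encode_patterns(ds)
  y <- attr(x, "labels")

  for (backend in c("svm", "ann")) {
    model <- train_model(ds, "binary", backend, seed = 1)
    s <- score_model(model, x)
    expect_gt(min(s[y == "positive"]), max(s[y == "negative"]),
              label = paste(backend, "margin"))
    m <- metrics_at_threshold(s, as.integer(y == "positive"),
                              mean(c(min(s[y == "positive"]),
                                     max(s[y == "negative"]))))
    expect_equal(m$accuracy, 100, info = backend)
  }
})

test_that("training and scoring are deterministic given the seed", {
  ds <- separable_dataset()
  x <- encode_patterns(ds)
  for (backend in c("svm", "ann")) {
    s1 <- score_model(train_model(ds, "binary", backend, seed = 5), x)
    s2 <- score_model(train_model(ds, "binary", backend, seed = 5), x)
    expect_identical(s1, s2, info = backend)
  }
})

test_that("scores are equivariant to input ordering and typed by dimension", {
  ds <- separable_dataset()
  x <- encode_patterns(ds)
  model <- train_model(ds, "binary", "svm", seed = 2)

  perm <- gtppred:::with_seed(3, sample(nrow(x)))
  expect_equal(score_model(model, x[perm, ]), score_model(model, x)[perm])

  expect_identical(score_model(model, x[0, , drop = FALSE]), numeric(0))
  expect_error(score_model(model, x[, 1:100]), "357")
})

test_that("raising SVM cost never lowers training accuracy on separable data", {
  ds <- separable_dataset()
  x <- encode_patterns(ds)
  y <- as.integer(attr(x, "labels") == "positive")
  accs <- vapply(c(0.01, 1, 100), function(cost) {
    m <- train_model(ds, "binary", "svm",
                     hyperparameters = list(cost = cost), seed = 1)
    metrics_at_threshold(score_model(m, x), y, 0)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("degenerate training inputs are refused", {
  ds <- separable_dataset()
  ds$patterns <- ds$patterns[ds$patterns$label == "positive", ]
  expect_error(train_model(ds, "binary", "svm", seed = 1), "single class")
})

test_that("cross-validated MCC on permuted labels is near zero", {
  # permutation null: scores cannot beat chance when labels are shuffled.
  # The best-over-thresholds MCC is a maximum statistic, so it is averaged
  # over a few permutations to estimate its null level.
  cfg <- small_config(seed = 31, n_chains = 25)
  chains <- generate_chains(cfg)
  ds <- build_dataset(extract_patterns_all(chains, "SRT"), "main", seed = 8)
  null_mcc <- vapply(1:3, function(p) {
    perm <- ds
    perm$patterns$label <- gtppred:::with_seed(9 + p,
                                               sample(ds$patterns$label))
    cv <- five_fold_cv(perm, "binary", "svm", seed = 10)
    max(abs(cv$averaged$mcc))
  }, numeric(1))
  expect_lt(mean(null_mcc), 0.15)
})

test_that("threshold setting is range-checked per backend", {
  ds <- separable_dataset()
  m_svm <- train_model(ds, "binary", "svm", seed = 1)
  expect_equal(set_threshold(m_svm, -0.4)$threshold, -0.4)
  expect_error(set_threshold(m_svm, 1.5), "range")
  m_ann <- train_model(ds, "binary", "ann", seed = 1)
  expect_error(set_threshold(m_ann, -0.1), "range")
})

test_that("models survive a save/load round trip and verify their manifest", {
  ds <- separable_dataset()
  model <- set_threshold(train_model(ds, "binary", "svm", seed = 4), 0.25)
  dir <- withr::local_tempdir()
  save_model(model, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- load_model(dir)
  expect_equal(back$threshold, 0.25)
  x <- encode_patterns(ds)
  expect_equal(score_model(back, x), score_model(model, x))

  # a manifest disagreeing with the stored weights is refused
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  manifest$encoding <- "pssm"
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(dir), "encoding")
})

test_that("per-protein prediction yields N, N-1 and N-2 scores", {
  ds_srt <- separable_dataset()
  models <- list(
    srt = train_model(ds_srt, "binary", "svm", seed = 1),
    dpt = train_model(make_kmer_dataset("DPT"), "binary", "svm", seed = 1),
    tpt = train_model(make_kmer_dataset("TPT"), "binary", "svm", seed = 1))
  seq20 <- paste(rep(c("G", "A", "K", "T"), 5), collapse = "")
  pred <- predict_protein(seq20, models)
  expect_equal(nrow(pred$srt), 20)
  expect_equal(nrow(pred$dpt), 19)
  expect_equal(nrow(pred$tpt), 18)
  tbl <- as.data.frame(pred)
  expect_equal(nrow(tbl), 20)
  expect_true(all(is.na(tbl$dpt_score[20])))
  expect_true(all(is.na(tbl$tpt_score[19:20])))
})

test_that("thresholds above the score range silence all combined calls", {
  ds <- separable_dataset()
  models <- list(srt = set_threshold(train_model(ds, "binary", "svm",
                                                 seed = 1), 1))
  pred <- predict_protein(strrep("A", 25), models)
  expect_true(all(pred$combined == 0))
})

test_that("combined calls take the union of covering k-mer calls", {
  ds_tpt <- make_kmer_dataset("TPT")
  tpt <- train_model(ds_tpt, "binary", "svm", seed = 1)
  seq <- strrep("A", 20)
  pred <- predict_protein(seq, list(tpt = tpt))
  # force a single positive tripeptide call starting at position 5
  pred2 <- pred
  pred2$tpt$call[] <- 0L
  pred2$tpt$call[pred2$tpt$start == 5] <- 1L
  combined <- integer(20)
  for (s in pred2$tpt$start[pred2$tpt$call == 1]) combined[s:(s + 2)] <- 1L
  expect_equal(combined, c(rep(0, 4), 1, 1, 1, rep(0, 13)))

  # and the union rule in predict_protein itself agrees with the tracks
  votes <- integer(20)
  for (s in pred$tpt$start[pred$tpt$call == 1]) votes[s:(s + 2)] <- 1L
  expect_equal(pred$combined, votes)
})

test_that("the SRT prediction track equals direct pattern scoring", {
  ds <- separable_dataset()
  model <- train_model(ds, "binary", "svm", seed = 1)
  seq <- "GKTAGKTAGKTAGKTA"
  pred <- predict_protein(seq, list(srt = model))
  chain <- labeled_chain("q", seq, integer(nchar(seq)))
  x <- encode_patterns(extract_patterns(chain, "SRT"), "binary")
  expect_equal(pred$srt$score, score_model(model, x))
})

test_that("PSSM models demand a profile at prediction time", {
  cfg <- small_config(seed = 17, n_chains = 10)
  chains <- generate_chains(cfg)
  profs <- generate_profiles(chains, cfg)
  ds <- build_dataset(extract_patterns_all(chains, "SRT"), "main", seed = 2)
  model <- train_model(ds, "pssm", "svm", profiles = profs, seed = 2)
  expect_error(predict_protein("ACDEFGHIKLMNPQRSTVWY", list(srt = model)),
               "profile")
})
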