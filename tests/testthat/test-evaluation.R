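test_that("confusion statistics reproduce reference worked examples", {
  st <- confusion_stats(confusion_counts(tp = 320, tn = 12651, fp = 13, fn = 21))
  expect_equal(round(st$SE, 2), 93.84)
  expect_equal(round(st$SP, 2), 99.90)
  expect_equal(round(st$Q, 2), 99.74)
  expect_equal(round(st$C, 3), 0.948)

  st2 <- confusion_stats(confusion_counts(tp = 330, tn = 12395, fp = 269, fn = 11))
  expect_equal(round(st2$C, 3), 0.722)

  perfect <- confusion_stats(confusion_counts(tp = 50, tn = 200, fp = 0, fn = 0))
  expect_equal(c(perfect$SE, perfect$SP, perfect$Q, perfect$C),
               c(100, 100, 100, 1))
})

test_that("C is reported undefined (not 0) when a marginal vanishes", {
  st <- confusion_stats(confusion_counts(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(st$C))
  expect_output(print(st), "undefined")
})

test_that("every printed cell of the three reference CV tables reproduces", {
  ref <- utils::read.delim(system.file("extdata", "cv_reference_counts.tsv",
                                       package = "ligscreen"))
  for (r in seq_len(nrow(ref))) {
    st <- confusion_stats(confusion_counts(tp = ref$TP[r], tn = ref$TN[r],
                                           fp = ref$FP[r], fn = ref$FN[r]))
    info <- paste(ref$engine[r], "fold", ref$fold[r])
    expect_equal(round(st$SE, 2), ref$SE[r], info = info)
    expect_equal(round(st$SP, 2), ref$SP[r], info = info)
    expect_equal(round(st$Q, 2), ref$Q[r], info = info)
    expect_equal(round(st$C, 3), ref$C[r], info = info)
    # marginals match the printed testing-set sizes
    expect_equal(ref$TP[r] + ref$FN[r], ref$test_pos[r], info = info)
    expect_equal(ref$TN[r] + ref$FP[r], ref$test_neg[r], info = info)
  }
})

test_that("the Average/SD/SE summary rows reproduce from the per-fold values", {
  ref <- utils::read.delim(system.file("extdata", "cv_reference_counts.tsv",
                                       package = "ligscreen"))
  smr <- utils::read.delim(system.file("extdata", "cv_reference_summary.tsv",
                                       package = "ligscreen"))
  for (eng in unique(ref$engine)) {
    df <- ref[ref$engine == eng, ]
    stats <- lapply(seq_len(nrow(df)), function(r)
      confusion_stats(confusion_counts(tp = df$TP[r], tn = df$TN[r],
                                       fp = df$FP[r], fn = df$FN[r])))
    folds <- data.frame(SE = sapply(stats, `[[`, "SE"),
                        SP = sapply(stats, `[[`, "SP"),
                        Q = sapply(stats, `[[`, "Q"),
                        C = sapply(stats, `[[`, "C"))
    sm <- cv_summary(folds)
    pr <- smr[smr$engine == eng, ]
    expect_equal(round(unname(sm["mean", c("SE", "SP", "Q")]), 2),
                 unlist(pr[pr$stat == "mean", c("SE", "SP", "Q")],
                        use.names = FALSE), info = eng)
    expect_equal(round(unname(sm["mean", "C"]), 3),
                 pr[pr$stat == "mean", "C"], info = eng)
    expect_equal(round(unname(sm["sd", ]), 4),
                 unlist(pr[pr$stat == "sd", c("SE", "SP", "Q", "C")],
                        use.names = FALSE), info = eng)
    expect_equal(round(unname(sm["se", ]), 4),
                 unlist(pr[pr$stat == "se", c("SE", "SP", "Q", "C")],
                        use.names = FALSE), info = eng)
  }
})

test_that("Q equals the prevalence-weighted mean of SE and SP", {
  set.seed(31)
  for (i in 1:200) {
    cc <- confusion_counts(tp = sample(0:50, 1) + 1, tn = sample(0:500, 1) + 1,
                           fp = sample(0:20, 1), fn = sample(0:20, 1))
    st <- confusion_stats(cc)
    P <- cc$TP + cc$FN; N <- cc$TN + cc$FP
    expect_equal(st$Q, (st$SE * P + st$SP * N) / (P + N), tolerance = 1e-10)
  }
})

test_that("Matthews C agrees with the correlation-form oracle", {
  set.seed(17)
  for (i in 1:1000) {
    tp <- sample(1:30, 1); tn <- sample(1:300, 1)
    fp <- sample(1:25, 1); fn <- sample(1:25, 1)
    st <- confusion_stats(confusion_counts(tp, tn, fp, fn))
    truth <- c(rep(1, tp + fn), rep(0, tn + fp))
    pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
    expect_lt(abs(st$C - suppressWarnings(stats::cor(truth, pred))), 1e-12)
  }
})

test_that("five_fold_cv partitions the data into near-equal stratified folds", {
  set.seed(2)
  X <- matrix(runif(100 * 4), 100)
  y <- rep(c(1, -1), each = 50)
  fold <- ligscreen:::.make_folds(y, 5L, seed = 3L)
  expect_equal(sort(unique(fold)), 1:5)
  expect_true(all(table(fold) == 20))
  expect_true(all(table(fold[y > 0]) == 10))   # stratification
  expect_identical(fold, ligscreen:::.make_folds(y, 5L, seed = 3L))
})

test_that("five_fold_cv on separable blobs yields near-perfect folds", {
  bl <- make_blobs(n_per = 50, d = 6, seed = 41)
  cv <- five_fold_cv(bl$X, bl$y, engine = "svm", seed = 9)
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(sum(cv$folds$n_test_pos), 50)
  expect_gt(cv$summary["mean", "SE"], 95)
  expect_gt(cv$summary["mean", "SP"], 95)
  cv2 <- five_fold_cv(bl$X, bl$y, engine = "svm", seed = 9)
  expect_identical(cv$folds, cv2$folds)        # same seed, same counts
  # report renderer has 5 fold rows + header + separator + 3 summary rows
  expect_length(cv_report_markdown(cv), 10L)
})

test_that("cross-validation runs every engine through the uniform interface", {
  bl <- make_blobs(n_per = 25, d = 5, seed = 43)
  for (eng in c("knn", "pnn", "tanimoto")) {
    cv <- five_fold_cv(bl$X, bl$y, engine = eng,
                       params = list(cutoff = 0.95), seed = 11)
    expect_equal(nrow(cv$folds), 5L, info = eng)
    expect_true(all(is.finite(cv$folds$Q)), info = eng)
  }
})

test_that("screening metrics reproduce the large-library worked examples", {
  lib_ids <- sprintf("m%04d", 1:1000)
  actives <- lib_ids[1:44]
  hits <- c(actives[1:31], lib_ids[900:950])    # 31 of 44 actives recovered
  rep <- screening_metrics(hits, actives, length(lib_ids))
  expect_equal(round(rep$yield, 2), 70.45)
  expect_equal(rep$n_hits, 82L)
  expect_equal(rep$FP_bound, 51L)
  # zero hits
  rep0 <- screening_metrics(character(), actives, 1000)
  expect_equal(rep0$yield, 0)
  expect_equal(rep0$hit_rate, 0)
  expect_true(is.na(rep0$false_hit_bound))
  # exact recovery
  rep1 <- screening_metrics(actives, actives, 1000)
  expect_equal(rep1$yield, 100)
  expect_equal(rep1$false_hit_bound, 0)
})

test_that("family novelty separates hits outside the training families", {
  ids <- sprintf("c%02d", 1:40)
  families <- setNames(rep(1:4, each = 10), ids)
  train_actives <- ids[1:5]                     # family 1
  # 15 of 44-style: here 6 of 8 hits outside family 1
  hits <- c(ids[6:7], ids[11:14], ids[21:22])
  nov <- family_novelty(hits, families, train_actives)
  expect_equal(nov$n_outside, 6L)
  expect_equal(nov$pct_outside, 75)
  expect_equal(nov$training_families, 1L)
  frac <- nov$family_positive_fraction
  expect_equal(frac$fraction[frac$family == 1], 0.2)
  # all hits inside training families -> 0%
  nov0 <- family_novelty(ids[6:8], families, train_actives)
  expect_equal(nov0$pct_outside, 0)
  expect_error(family_novelty("nope", families, train_actives), "no family")
})

test_that("constructed blob screen puts all hits outside training families", {
  bl <- make_blob_library()
  rownames(bl$X) <- bl$ids
  fit <- cluster_families(bl$X, k = 3, seed = 2)
  fams <- assign_to_families(fit, bl$X)
  train_actives <- names(fams)[fams == 1][1:5]
  forced_hits <- names(fams)[fams == 2][1:10]
  nov <- family_novelty(forced_hits, fams, train_actives)
  expect_equal(nov$pct_outside, 100)
})
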