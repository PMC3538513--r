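test_that("two-point symmetric SVM has boundary at the midpoint", {
  X <- matrix(c(-1, 1), ncol = 1)
  m <- train_svm(X, c(-1, 1), c = 1e5, sigma = 1.2)
  expect_equal(m$b, 0, tolerance = 1e-6)
  expect_gt(svm_decision(m, matrix(0.5))$score, 0)
  expect_lt(svm_decision(m, matrix(-0.5))$score, 0)
  # exact tie at the midpoint resolves to the non-inhibitor class
  expect_equal(svm_decision(m, matrix(0))$label, -1L)
})

test_that("hard-margin SVM separates separable blobs with 100% training accuracy", {
  bl <- make_blobs(n_per = 30, seed = 3)
  m <- train_svm(bl$X, bl$y)
  pred <- svm_decision(m, bl$X)
  expect_equal(pred$label, bl$y)
  # duplicate of a training point gets its own label with margin >= 1
  expect_gte(abs(svm_decision(m, bl$X[1, , drop = FALSE])$score), 1 - 1e-6)
})

test_that("trained SVMs satisfy dual feasibility", {
  for (seed in 1:3) {
    bl <- make_blobs(n_per = 25, seed = seed)
    m <- train_svm(bl$X, bl$y)
    expect_lt(abs(sum(m$alpha_y)), 1e-6)          # sum alpha_i y_i = 0
    expect_true(all(abs(m$alpha_y) <= m$c + 1e-6)) # 0 <= alpha_i <= c
  }
})

test_that("SVM decision equals the libsvm engine's own decision values", {
  bl <- make_blobs(n_per = 20, seed = 11)
  yf <- factor(ifelse(bl$y > 0, "1", "-1"), levels = c("1", "-1"))
  fit <- e1071::svm(bl$X, yf, type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * 1.2^2), cost = 1e5, scale = FALSE)
  m <- train_svm(bl$X, bl$y)
  q <- matrix(runif(10 * ncol(bl$X)), 10)
  pl <- predict(fit, q, decision.values = TRUE)
  dv <- as.numeric(attr(pl, "decision.values"))
  sc <- svm_decision(m, q)
  # identical decision surface (libsvm's sign convention is data-order
  # dependent; ours is fixed to positive = inhibitor)
  expect_equal(abs(sc$score), abs(dv), tolerance = 1e-8)
  expect_equal(sc$label == 1L, as.character(pl) == "1")
})

test_that("SVM far-field score tends to the bias", {
  bl <- make_blobs(n_per = 15, seed = 5)
  m <- train_svm(bl$X, bl$y)
  far <- matrix(1e3, 1, ncol(bl$X))
  expect_equal(svm_decision(m, far)$score, m$b, tolerance = 1e-8)
})

test_that("kNN voting, distance ties and vote ties follow the contracts", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  y <- c(1, 1, -1, -1)
  m1 <- train_knn(X, y, k = 1)
  expect_equal(knn_predict(m1, matrix(1))$label, 1L)       # exact training point
  m3 <- train_knn(X, y, k = 3)
  expect_equal(knn_predict(m3, matrix(0.9))$label, 1L)     # votes (+1,+1,-1)
  m2 <- train_knn(X, y, k = 2)
  expect_equal(knn_predict(m2, matrix(1.5))$label, -1L)    # tie (+1,-1) -> -1
  # distance tie resolved by training index: queries at 0.5 see rows 1 and 2
  mt <- train_knn(matrix(c(0, 1), ncol = 1), c(-1, 1), k = 1)
  expect_equal(knn_predict(mt, matrix(0.5))$label, -1L)
  expect_error(train_knn(X, y, k = 9), "k <=")
})

test_that("kNN k=1 self-prediction is perfect on distinct training vectors", {
  bl <- make_blobs(n_per = 20, seed = 8)
  m <- train_knn(bl$X, bl$y, k = 1)
  expect_equal(knn_predict(m, bl$X)$label, bl$y)
})

test_that("PNN density rule: proximity wins for every sigma, ties go negative", {
  X <- matrix(c(0, 1), ncol = 1)
  y <- c(1, -1)
  for (s in c(0.02, 0.2, 2, 20)) {
    m <- train_pnn(X, y, sigma = s)
    expect_equal(pnn_predict(m, matrix(0.2))$label, 1L, info = s)
    expect_equal(pnn_predict(m, matrix(0.8))$label, -1L, info = s)
    expect_equal(pnn_predict(m, matrix(0.5))$label, -1L, info = s)  # tie
  }
  expect_error(train_pnn(X, c(1, 1)), "both classes")
})

test_that("PNN with vanishing sigma reduces to 1-NN on 50 queries", {
  bl <- make_blobs(n_per = 30, d = 8, seed = 13)
  set.seed(99)
  q <- matrix(runif(50 * 8), 50)
  knn1 <- knn_predict(train_knn(bl$X, bl$y, 1), q)$label
  for (s in c(1e-2, 1e-3)) {
    pnn <- pnn_predict(train_pnn(bl$X, bl$y, sigma = s), q)$label
    expect_equal(pnn, knn1, info = s)
  }
  # common rescaling of all sigma_j leaves small-sigma labels unchanged
  p1 <- pnn_predict(train_pnn(bl$X, bl$y, sigma = rep(1e-3, 8)), q)$label
  p2 <- pnn_predict(train_pnn(bl$X, bl$y, sigma = rep(2e-3, 8)), q)$label
  expect_equal(p1, p2)
})

test_that("PNN is invariant to class presentation order and never underflows", {
  bl <- make_blobs(n_per = 25, d = 6, seed = 21)
  ord <- order(bl$y)                      # all -1 first
  rev_ord <- rev(ord)
  q <- matrix(runif(20 * 6), 20)
  pa <- pnn_predict(train_pnn(bl$X[ord, ], bl$y[ord], sigma = 0.02), q)
  pb <- pnn_predict(train_pnn(bl$X[rev_ord, ], bl$y[rev_ord], sigma = 0.02), q)
  expect_equal(pa$label, pb$label)
  expect_true(all(is.finite(pa$score)))   # log-domain survives sigma = 0.02
})

test_that("similarity screening flags by best similarity against the cutoff", {
  set.seed(4)
  A <- matrix(runif(3 * 10), 3); rownames(A) <- paste0("a", 1:3)
  lib <- rbind(A[1, ], matrix(runif(2 * 10), 2))
  rownames(lib) <- c("copy", "r1", "r2")
  scr <- similarity_screen(A, lib, cutoff = 0.9)
  expect_true(scr["copy", "hit"])                  # identical copy: sim = 1
  expect_equal(scr["copy", "best_active"], "a1")
  # disjoint support: zero similarity everywhere, no hits even at cutoff 0
  Z <- cbind(diag(2), matrix(0, 2, 8)); rownames(Z) <- c("z1", "z2")
  L <- cbind(matrix(0, 2, 2), diag(2), matrix(0, 2, 6))
  scr0 <- similarity_screen(Z, L, cutoff = 0)
  expect_false(any(scr0$hit))
  # cutoff 0 flags every row with any nonzero similarity
  scr1 <- similarity_screen(A, lib, cutoff = 0)
  expect_true(all(scr1$hit))
  expect_error(similarity_screen(A[0, , drop = FALSE], lib), "empty active")
})

test_that("engines are pure functions of (model, query)", {
  bl <- make_blobs(n_per = 15, seed = 17)
  q <- matrix(runif(5 * ncol(bl$X)), 5)
  ms <- train_svm(bl$X, bl$y)
  mk <- train_knn(bl$X, bl$y, 1)
  mp <- train_pnn(bl$X, bl$y)
  expect_identical(svm_decision(ms, q), svm_decision(ms, q))
  expect_identical(knn_predict(mk, q), knn_predict(mk, q))
  expect_identical(pnn_predict(mp, q), pnn_predict(mp, q))
})

test_that("models round-trip through the JSON container", {
  bl <- make_blobs(n_per = 12, seed = 23)
  q <- matrix(runif(6 * ncol(bl$X)), 6)
  tmp <- withr::local_tempfile(fileext = ".json")
  for (eng in c("svm", "knn", "pnn", "tanimoto")) {
    m <- ligscreen:::.train_engine(eng, bl$X, bl$y, list())
    write_model(m, tmp)
    back <- read_model(tmp)
    expect_equal(ligscreen:::.predict_engine(back, q)$label,
                 ligscreen:::.predict_engine(m, q)$label, info = eng)
    expect_equal(ligscreen:::.predict_engine(back, q)$score,
                 ligscreen:::.predict_engine(m, q)$score,
                 tolerance = 1e-12, info = eng)
  }
})
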