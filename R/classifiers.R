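# The four screening engines, all operating on the shared scaled descriptor
# space: hard-margin RBF-SVM, Tanimoto similarity search, k-nearest
# neighbour, and a Parzen-window probabilistic neural network. Every engine
# is a pure function of (model, query); every tie resolves to the
# non-inhibitor class (-1) -- a tie is not evidence of activity.

.rbf_kernel <- function(X, Y, sigma) {
  # K(x, y) = exp(-|x - y|^2 / (2 sigma^2)), rows of X against rows of Y
  d2 <- outer(rowSums(X^2), rep(1, nrow(Y))) -
    2 * X %*% t(Y) + outer(rep(1, nrow(X)), rowSums(Y^2))
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * sigma^2))
}

.as_label <- function(y) {
  y <- as.numeric(as.character(y))
  stopifnot(all(y %in% c(-1, 1)))
  y
}

.as_matrix_query <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != d)
    stop("query dimension ", ncol(x), " does not match model dimension ", d)
  x
}

#' Train a hard-margin RBF-kernel SVM
#'
#' Solves the dual soft-margin problem max sum(alpha) - 1/2 sum alpha_i
#' alpha_j y_i y_j K(x_i, x_j) with 0 <= alpha_i <= c, sum alpha_i y_i = 0
#' (libsvm's SMO, via e1071, is the QP engine) under the RBF kernel
#' K(x_i, x_j) = exp(-|x_j - x_i|^2 / (2 sigma^2)). The defaults c = 100000
#' (an essentially hard margin: training errors are prohibitively penalized)
#' and sigma = 1.2 are the values selected by cross-validation in the source
#' screening study.
#'
#' @param X n x d matrix of scaled descriptors.
#' @param y labels in \{-1, +1\} (+1 = inhibitor).
#' @param c margin (error penalty) parameter, > 0.
#' @param sigma RBF kernel width, > 0.
#' @return A `vs_svm` model: support vectors, coefficients alpha_i y_i,
#'   bias b, and the hyperparameters.
#' @export
train_svm <- function(X, y, c = 1e5, sigma = 1.2) {
  stopifnot(is.matrix(X), all(is.finite(X)), c > 0, sigma > 0)
  y <- .as_label(y)
  if (length(unique(y)) < 2L) stop("both classes must be present to train an SVM")
  yf <- factor(ifelse(y > 0, "1", "-1"), levels = c("1", "-1"))
  fit <- e1071::svm(X, yf, type = "C-classification", kernel = "radial",
                    gamma = 1 / (2 * sigma^2), cost = c, scale = FALSE)
  # libsvm orients its decision function toward the class that appears
  # first in the training data; normalize so positive score = inhibitor
  s <- if (fit$levels[fit$labels[1]] == "1") 1 else -1
  structure(list(SV = fit$SV, alpha_y = s * as.numeric(fit$coefs),
                 b = -s * fit$rho, sigma = sigma, c = c, d = ncol(X),
                 n_train = nrow(X)),
            class = "vs_svm")
}

#' SVM decision function
#'
#' f(x) = sum_i alpha_i y_i K(x, x_i) + b; label = sign(f), with f = 0
#' resolving to -1. Far from all support vectors every kernel value decays
#' to 0 and the score tends to the bias b.
#'
#' @param model a `vs_svm`.
#' @param x query vector or matrix of row queries.
#' @return data.frame with one row per query: `label` (+1/-1), `score`.
#' @export
svm_decision <- function(model, x) {
  stopifnot(inherits(model, "vs_svm"))
  x <- .as_matrix_query(x, model$d)
  K <- .rbf_kernel(x, model$SV, model$sigma)
  score <- as.numeric(K %*% model$alpha_y) + model$b
  data.frame(label = ifelse(score > 0, 1L, -1L), score = score,
             row.names = rownames(x))
}

#' @export
print.vs_svm <- function(x, ...) {
  cat("<vs_svm> ", nrow(x$SV), " support vectors (of ", x$n_train,
      " training compounds), sigma = ", x$sigma, ", c = ", x$c, "\n", sep = "")
  invisible(x)
}

#' k-nearest-neighbour classifier
#'
#' Stores the training matrix; prediction takes the k training compounds at
#' smallest Euclidean distance (distance ties broken by training index) and
#' votes by majority, vote ties resolving to -1. The source study found
#' k = 1 best. The score is the mean neighbour label (vote margin).
#'
#' @param X n x d matrix of scaled descriptors.
#' @param y labels in \{-1, +1\}.
#' @param k neighbour count, 1 <= k <= n.
#' @return A `vs_knn` model.
#' @export
train_knn <- function(X, y, k = 1L) {
  stopifnot(is.matrix(X), all(is.finite(X)))
  y <- .as_label(y)
  stopifnot(k >= 1L, k <= nrow(X))
  structure(list(X = X, y = y, k = as.integer(k), d = ncol(X)),
            class = "vs_knn")
}

#' @rdname train_knn
#' @param model a `vs_knn`.
#' @param x query vector or matrix of row queries.
#' @return data.frame with one row per query: `label`, `score`.
#' @export
knn_predict <- function(model, x) {
  stopifnot(inherits(model, "vs_knn"))
  x <- .as_matrix_query(x, model$d)
  d2 <- outer(rowSums(x^2), rep(1, nrow(model$X))) -
    2 * x %*% t(model$X) + outer(rep(1, nrow(x)), rowSums(model$X^2))
  score <- numeric(nrow(x))
  for (q in seq_len(nrow(x))) {
    ord <- order(d2[q, ], seq_len(ncol(d2)))   # distance ties -> lowest index
    score[q] <- mean(model$y[ord[seq_len(model$k)]])
  }
  data.frame(label = ifelse(score > 0, 1L, -1L), score = score,
             row.names = rownames(x))
}

#' @export
print.vs_knn <- function(x, ...) {
  cat("<vs_knn> ", nrow(x$X), " training compounds, k = ", x$k, "\n", sep = "")
  invisible(x)
}

#' Probabilistic neural network (Parzen-window Bayes classifier)
#'
#' Class densities are Gaussian Parzen estimates over the training
#' compounds, f_i(x) = (1/n_i) sum over class-i members of
#' exp(-sum_j ((x_j - x_ij)/sigma_j)^2); the query is assigned to the class
#' maximizing h_i c_i f_i(x) (priors h and misclassification costs c equal
#' by default), exact ties resolving to -1. The per-class 1/n_i
#' normalization is the default (`class_norm = FALSE` gives the unnormalized
#' sum, which degenerates to the majority class under heavy imbalance).
#' Accumulation is done in the log domain so the small default width
#' sigma = 0.02 cannot underflow both densities to a spurious tie.
#'
#' @param X n x d matrix of scaled descriptors.
#' @param y labels in \{-1, +1\}; both classes must be non-empty.
#' @param sigma smoothing width: a scalar shared by all descriptors or a
#'   length-d vector of per-descriptor widths sigma_j.
#' @param priors,costs named numeric pairs for classes `"1"` and `"-1"`.
#' @param class_norm divide each class sum by its class size n_i.
#' @return A `vs_pnn` model.
#' @export
train_pnn <- function(X, y, sigma = 0.02,
                      priors = c(`1` = 0.5, `-1` = 0.5),
                      costs = c(`1` = 1, `-1` = 1),
                      class_norm = TRUE) {
  stopifnot(is.matrix(X), all(is.finite(X)), all(sigma > 0))
  y <- .as_label(y)
  if (!all(c(-1, 1) %in% y)) stop("both classes must be non-empty")
  stopifnot(length(sigma) %in% c(1L, ncol(X)))
  structure(list(Xpos = X[y > 0, , drop = FALSE],
                 Xneg = X[y < 0, , drop = FALSE],
                 sigma = sigma, priors = priors, costs = costs,
                 class_norm = class_norm, d = ncol(X)),
            class = "vs_pnn")
}

.log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# log of (prior * cost * density) for one class block, log-domain
.pnn_class_logscore <- function(x, Xc, sigma, prior, cost, class_norm) {
  Z <- sweep(Xc, 2, x, "-")
  Z <- sweep(Z, 2, rep(sigma, length.out = ncol(Xc)), "/")
  expo <- -rowSums(Z^2)
  ls <- .log_sum_exp(expo)
  if (class_norm) ls <- ls - log(nrow(Xc))
  ls + log(prior) + log(cost)
}

#' @rdname train_pnn
#' @param model a `vs_pnn`.
#' @param x query vector or matrix of row queries.
#' @return data.frame with one row per query: `label`, `score` (the
#'   log-ratio log(h c f)_+1 - log(h c f)_-1).
#' @export
pnn_predict <- function(model, x) {
  stopifnot(inherits(model, "vs_pnn"))
  x <- .as_matrix_query(x, model$d)
  score <- numeric(nrow(x))
  for (q in seq_len(nrow(x))) {
    lp <- .pnn_class_logscore(x[q, ], model$Xpos, model$sigma,
                              model$priors[["1"]], model$costs[["1"]],
                              model$class_norm)
    ln <- .pnn_class_logscore(x[q, ], model$Xneg, model$sigma,
                              model$priors[["-1"]], model$costs[["-1"]],
                              model$class_norm)
    score[q] <- lp - ln
  }
  data.frame(label = ifelse(score > 0, 1L, -1L), score = score,
             row.names = rownames(x))
}

#' @export
print.vs_pnn <- function(x, ...) {
  cat("<vs_pnn> ", nrow(x$Xpos), " active / ", nrow(x$Xneg),
      " inactive training compounds, sigma = ",
      paste(unique(x$sigma), collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity screen
#'
#' Flags every library compound whose best Tanimoto similarity to any known
#' active exceeds the cut-off (strictly greater). Both matrices must be
#' scaled by the same [fit_scaling()] model. All-zero vector pairs have no
#' defined similarity and are treated as dissimilar here (the scalar
#' [tanimoto()] errors instead).
#'
#' @param actives m x d scaled matrix of known actives (rownames = ids).
#' @param library n x d scaled matrix to screen.
#' @param cutoff similarity cut-off in \[0, 1\]; default 0.9, the strict
#'   value used by the source study (typical similarity searches use
#'   0.8-0.9).
#' @return data.frame per library row: `hit` (logical), `best_sim`,
#'   `best_active` (id of the most similar active).
#' @export
similarity_screen <- function(actives, library, cutoff = 0.9) {
  stopifnot(is.matrix(actives), is.matrix(library),
            ncol(actives) == ncol(library),
            cutoff >= 0, cutoff <= 1)
  if (nrow(actives) == 0L) stop("empty active set")
  sim <- .tanimoto_matrix(library, actives)
  sim[is.na(sim)] <- 0
  best <- apply(sim, 1, max)
  bidx <- apply(sim, 1, which.max)
  aid <- rownames(actives)
  if (is.null(aid)) aid <- as.character(seq_len(nrow(actives)))
  data.frame(hit = best > cutoff, best_sim = best, best_active = aid[bidx],
             row.names = rownames(library), stringsAsFactors = FALSE)
}

# uniform prediction interface used by the evaluation harness; params is a
# list of engine hyperparameters
.train_engine <- function(engine, X, y, params = list()) {
  switch(engine,
    svm = do.call(train_svm, c(list(X = X, y = y),
                               params[names(params) %in% c("c", "sigma")])),
    knn = do.call(train_knn, c(list(X = X, y = y),
                               params[names(params) %in% "k"])),
    pnn = do.call(train_pnn, c(list(X = X, y = y),
                               params[names(params) %in%
                                        c("sigma", "priors", "costs", "class_norm")])),
    tanimoto = {
      cutoff <- if (!is.null(params$cutoff)) params$cutoff else 0.9
      structure(list(actives = X[y > 0, , drop = FALSE], cutoff = cutoff,
                     d = ncol(X)),
                class = "vs_tanimoto")
    },
    stop("unknown engine: ", engine))
}

.predict_engine <- function(model, X) {
  if (inherits(model, "vs_svm")) svm_decision(model, X)
  else if (inherits(model, "vs_knn")) knn_predict(model, X)
  else if (inherits(model, "vs_pnn")) pnn_predict(model, X)
  else if (inherits(model, "vs_tanimoto")) {
    scr <- similarity_screen(model$actives, .as_matrix_query(X, model$d),
                             model$cutoff)
    data.frame(label = ifelse(scr$hit, 1L, -1L), score = scr$best_sim,
               row.names = rownames(scr))
  } else stop("not a ligscreen model")
}

#' Serialize / restore a trained engine
#'
#' Portable JSON container: engine name, hyperparameters and training
#' payload (support vectors and coefficients for the SVM; the training
#' matrix otherwise).
#'
#' @param model a trained `vs_svm` / `vs_knn` / `vs_pnn` / `vs_tanimoto`.
#' @param path JSON file path.
#' @return `path` invisibly (write); the model (read).
#' @export
write_model <- function(model, path) {
  engine <- sub("^vs_", "", class(model)[1])
  payload <- unclass(model)
  for (f in c("priors", "costs"))      # keep class names through JSON
    if (!is.null(payload[[f]])) payload[[f]] <- as.list(payload[[f]])
  jsonlite::write_json(list(engine = engine, payload = payload), path,
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  p <- obj$payload
  for (f in c("SV", "X", "Xpos", "Xneg", "actives"))
    if (!is.null(p[[f]])) p[[f]] <- as.matrix(p[[f]])
  for (f in c("priors", "costs"))
    if (!is.null(p[[f]])) p[[f]] <- unlist(p[[f]])
  structure(p, class = paste0("vs_", obj$engine))
}

#' Write predictions as TSV
#'
#' Columns: `id`, `label`, `score`, `engine`.
#'
#' @param pred data.frame from a predict function (rownames = ids).
#' @param engine engine name recorded in the table.
#' @param path output path.
#' @export
write_predictions <- function(pred, engine, path) {
  df <- data.frame(id = rownames(pred), label = pred$label,
                   score = pred$score, engine = engine)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select a hyperparameter by cross-validated Matthews correlation
#'
#' Evaluates each candidate value with [five_fold_cv()] and returns the one
#' maximizing the mean Matthews coefficient, mirroring how the kernel width,
#' neighbour count and smoothing width were chosen in the source study.
#'
#' @param X,y training data.
#' @param engine `"svm"`, `"knn"` or `"pnn"`.
#' @param param name of the hyperparameter to tune (`"sigma"` or `"k"`).
#' @param grid candidate values.
#' @param params fixed hyperparameters.
#' @param seed fold seed.
#' @return list(best = chosen value, results = data.frame(value, mean_C)).
#' @export
tune_engine <- function(X, y, engine, param, grid, params = list(), seed = 1L) {
  res <- data.frame(value = grid, mean_C = NA_real_)
  for (i in seq_along(grid)) {
    p <- params; p[[param]] <- grid[i]
    cv <- five_fold_cv(X, y, engine = engine, params = p, seed = seed)
    res$mean_C[i] <- cv$summary["mean", "C"]
  }
  list(best = grid[which.max(res$mean_C)], results = res)
}
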