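# Validation harness: confusion statistics, stratified 5-fold cross
# validation, screening-level yield / hit-rate statistics, and the
# family-novelty analysis that asks whether a screen finds actives or
# merely recognizes compound-family membership.

#' Confusion counts
#'
#' @param tp,tn,fp,fn non-negative integers: true/false positives/negatives
#'   (positives = inhibitors).
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0,
            tp + tn + fp + fn > 0)
  structure(list(TP = as.numeric(tp), TN = as.numeric(tn),
                 FP = as.numeric(fp), FN = as.numeric(fn)),
            class = "confusion_counts")
}

#' @rdname confusion_counts
#' @param truth,pred label vectors in \{-1, +1\}.
#' @export
confusion_from_labels <- function(truth, pred) {
  truth <- .as_label(truth); pred <- .as_label(pred)
  stopifnot(length(truth) == length(pred))
  confusion_counts(tp = sum(truth > 0 & pred > 0),
                   tn = sum(truth < 0 & pred < 0),
                   fp = sum(truth < 0 & pred > 0),
                   fn = sum(truth > 0 & pred < 0))
}

#' Sensitivity, specificity, accuracy and Matthews correlation
#'
#' SE = 100 TP/(TP+FN), SP = 100 TN/(TN+FP),
#' Q = 100 (TP+TN)/(TP+TN+FP+FN), and the Matthews coefficient
#' C = (TP TN - FN FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)).
#' C is reported as NA (undefined), not 0, when any marginal is zero.
#'
#' @param counts a [confusion_counts()].
#' @return A `performance_stats` object: `SE`, `SP`, `Q` (percent), `C`.
#' @export
confusion_stats <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$TP; tn <- counts$TN; fp <- counts$FP; fn <- counts$FN
  se <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  q <- 100 * (tp + tn) / (tp + tn + fp + fn)
  denom <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  cc <- if (denom > 0) (tp * tn - fn * fp) / sqrt(denom) else NA_real_
  structure(list(SE = se, SP = sp, Q = q, C = cc, counts = counts),
            class = "performance_stats")
}

#' @export
print.performance_stats <- function(x, ...) {
  cat(sprintf("SE = %.2f%%  SP = %.2f%%  Q = %.2f%%  C = %s\n",
              x$SE, x$SP, x$Q,
              if (is.na(x$C)) "undefined" else sprintf("%.3f", x$C)))
  invisible(x)
}

# stratified fold ids: class proportions preserved, fold sizes within 1
.make_folds <- function(y, folds, seed, stratified = TRUE) {
  n <- length(y)
  fold <- integer(n)
  .with_seed(seed, {
    if (stratified) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
      }
    } else {
      fold <- sample(rep(seq_len(folds), length.out = n))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of a screening engine
#'
#' Splits the labelled library into `folds` random groups of approximately
#' equal size (stratified by class, so the minority inhibitor class cannot
#' vanish from a fold under heavy imbalance), trains the requested engine
#' on each set of `folds - 1` groups and tests on the held-out group, and
#' reports per-fold confusion counts and statistics plus their mean,
#' standard deviation and standard error (SD/sqrt(folds)). In the summary
#' rows SE/SP/Q means are percentages while their SD and standard error are
#' on the proportion scale, matching the conventional report layout.
#'
#' @param X n x d descriptor matrix (scaled).
#' @param y labels in \{-1, +1\}.
#' @param engine `"svm"`, `"knn"`, `"pnn"` or `"tanimoto"`.
#' @param params list of engine hyperparameters (see the train functions).
#' @param folds number of folds (default 5).
#' @param seed integer; the split is deterministic given (y, folds, seed).
#' @param stratified preserve class proportions per fold (default TRUE).
#' @return list with `folds` (data.frame: fold, n_train_pos, n_test_pos,
#'   TP, FN, SE, n_train_neg, n_test_neg, TN, FP, SP, Q, C) and `summary`
#'   (matrix, rows mean/sd/se, columns SE/SP/Q/C).
#' @export
five_fold_cv <- function(X, y, engine = "svm", params = list(), folds = 5L,
                         seed = 1L, stratified = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y), nrow(X) >= folds)
  y <- .as_label(y)
  fold <- .make_folds(y, folds, seed, stratified)
  rows <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f; te <- !tr
    if (length(unique(y[tr])) < 2L)
      stop("fold ", f, " leaves a single-class training set; ",
           "use a different seed or stratified = TRUE")
    model <- .train_engine(engine, X[tr, , drop = FALSE], y[tr], params)
    pred <- .predict_engine(model, X[te, , drop = FALSE])
    cc <- confusion_from_labels(y[te], pred$label)
    st <- confusion_stats(cc)
    rows[[f]] <- data.frame(
      fold = f,
      n_train_pos = sum(y[tr] > 0), n_test_pos = sum(y[te] > 0),
      TP = cc$TP, FN = cc$FN, SE = st$SE,
      n_train_neg = sum(y[tr] < 0), n_test_neg = sum(y[te] < 0),
      TN = cc$TN, FP = cc$FP, SP = st$SP, Q = st$Q, C = st$C)
  }
  df <- do.call(rbind, rows)
  list(folds = df, summary = cv_summary(df), engine = engine, seed = seed)
}

#' Summary rows (mean / SD / standard error) for per-fold statistics
#'
#' @param df per-fold data.frame with columns SE, SP, Q (percent) and C.
#' @return 3 x 4 matrix, rows `mean`, `sd`, `se`; SE/SP/Q dispersion on the
#'   proportion scale.
#' @export
cv_summary <- function(df) {
  m <- c(SE = mean(df$SE), SP = mean(df$SP), Q = mean(df$Q), C = mean(df$C))
  s <- c(SE = stats::sd(df$SE / 100), SP = stats::sd(df$SP / 100),
         Q = stats::sd(df$Q / 100), C = stats::sd(df$C))
  rbind(mean = m, sd = s, se = s / sqrt(nrow(df)))
}

#' Render a cross-validation result as a markdown table
#'
#' One row per fold plus Average/SD/SE rows; percentages to 2 decimals and
#' C to 3, matching the conventional report layout.
#'
#' @param cv result of [five_fold_cv()].
#' @return character vector of markdown lines.
#' @export
cv_report_markdown <- function(cv) {
  df <- cv$folds; sm <- cv$summary
  fmt <- function(...) paste(..., sep = " | ")
  lines <- c(
    fmt("fold", "train/test +", "TP", "FN", "SE", "train/test -", "TN", "FP",
        "SP", "Q", "C"),
    fmt("---", "---", "---", "---", "---", "---", "---", "---", "---", "---", "---"))
  for (r in seq_len(nrow(df))) {
    lines <- c(lines, fmt(
      df$fold[r],
      paste0(df$n_train_pos[r], "/", df$n_test_pos[r]),
      df$TP[r], df$FN[r], sprintf("%.2f%%", df$SE[r]),
      paste0(df$n_train_neg[r], "/", df$n_test_neg[r]),
      df$TN[r], df$FP[r], sprintf("%.2f%%", df$SP[r]),
      sprintf("%.2f%%", df$Q[r]), sprintf("%.3f", df$C[r])))
  }
  lines <- c(lines,
    fmt("Average", "", "", "", sprintf("%.2f%%", sm["mean", "SE"]), "", "", "",
        sprintf("%.2f%%", sm["mean", "SP"]), sprintf("%.2f%%", sm["mean", "Q"]),
        sprintf("%.3f", sm["mean", "C"])),
    fmt("SD", "", "", "", sprintf("%.4f", sm["sd", "SE"]), "", "", "",
        sprintf("%.4f", sm["sd", "SP"]), sprintf("%.4f", sm["sd", "Q"]),
        sprintf("%.4f", sm["sd", "C"])),
    fmt("SE", "", "", "", sprintf("%.4f", sm["se", "SE"]), "", "", "",
        sprintf("%.4f", sm["se", "SP"]), sprintf("%.4f", sm["se", "Q"]),
        sprintf("%.4f", sm["se", "C"])))
  lines
}

#' Screening-level performance statistics
#'
#' For a virtual screen of a large library: yield = 100 TP/(TP+FN) over the
#' known actives, the virtual-hit count and rate over the whole library,
#' and the false-hit-rate upper bound 100 FP/(TP+FP) in which every hit not
#' in the known-active set counts as a false positive. In an unlabelled
#' library some of those hits may be real undiscovered actives, so the true
#' false-hit rate is at most equal to and likely below this bound.
#'
#' @param hit_ids ids flagged by the screen.
#' @param active_ids known-active ids (must be library members).
#' @param library_size total number of compounds screened, >= 1.
#' @return A `screening_report`: `yield`, `n_hits`, `hit_rate`,
#'   `false_hit_bound` (all percentages except `n_hits`; `false_hit_bound`
#'   is NA when there are no hits).
#' @export
screening_metrics <- function(hit_ids, active_ids, library_size) {
  stopifnot(library_size >= 1)
  hit_ids <- unique(as.character(hit_ids))
  active_ids <- unique(as.character(active_ids))
  tp <- sum(hit_ids %in% active_ids)
  fn <- sum(!active_ids %in% hit_ids)
  fp <- sum(!hit_ids %in% active_ids)
  structure(list(
    yield = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    n_hits = length(hit_ids),
    hit_rate = 100 * length(hit_ids) / library_size,
    false_hit_bound = if (tp + fp > 0) 100 * fp / (tp + fp) else NA_real_,
    TP = tp, FN = fn, FP_bound = fp, library_size = library_size),
    class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat(sprintf(
    "yield %.2f%% (%d/%d known actives); %d virtual hits (%.2f%% of %d); false-hit bound %s\n",
    x$yield, x$TP, x$TP + x$FN, x$n_hits, x$hit_rate, x$library_size,
    if (is.na(x$false_hit_bound)) "undefined"
    else sprintf("%.2f%%", x$false_hit_bound)))
  invisible(x)
}

#' Family-novelty analysis of screening hits
#'
#' Counts the hits whose chemical-space family contains no training active
#' (candidate novel scaffolds), and reports for each family that does
#' contain a training active the fraction of its library members flagged by
#' the screen. A screen that merely recognizes family membership flags most
#' members of the training families; one that discriminates activity leaves
#' those fractions low while still finding hits in unseen families.
#'
#' @param hit_ids ids flagged by the screen.
#' @param families named integer vector: library compound id -> family id
#'   (e.g. from [assign_to_families()]).
#' @param training_active_ids ids of the actives used in training.
#' @return list: `n_outside`, `pct_outside` (of hits, percent),
#'   `training_families` (family ids containing training actives) and
#'   `family_positive_fraction` (data.frame: family, n_members, n_hits,
#'   fraction for each training family).
#' @export
family_novelty <- function(hit_ids, families, training_active_ids) {
  hit_ids <- unique(as.character(hit_ids))
  stopifnot(!is.null(names(families)))
  missing <- setdiff(hit_ids, names(families))
  if (length(missing))
    stop("hits with no family assignment: ", paste(missing, collapse = ", "))
  train_fams <- sort(unique(families[names(families) %in% training_active_ids]))
  hit_fams <- families[hit_ids]
  n_out <- sum(!hit_fams %in% train_fams)
  frac <- do.call(rbind, lapply(train_fams, function(f) {
    members <- names(families)[families == f]
    data.frame(family = f, n_members = length(members),
               n_hits = sum(members %in% hit_ids),
               fraction = mean(members %in% hit_ids))
  }))
  list(n_outside = n_out,
       pct_outside = if (length(hit_ids)) 100 * n_out / length(hit_ids) else 0,
       training_families = train_fams,
       family_positive_fraction = frac)
}
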