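# Chemical-space operations: descriptor scaling, Tanimoto similarity,
# family clustering, putative-negative generation.

# evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Min-max scaling against a reference library
#'
#' Captures the per-descriptor minimum and maximum over a reference library
#' so any compound set can be mapped to the unit hypercube that the
#' Tanimoto coefficient and the distance-based engines operate in. Columns
#' constant in the reference are flagged and map to 0; values outside the
#' reference range clip to \[0, 1\].
#'
#' @param mat n x d numeric matrix (rows = compounds).
#' @param reference name recorded for provenance.
#' @return A `scaling_model`.
#' @export
fit_scaling <- function(mat, reference = "reference") {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L, all(is.finite(mat)))
  mn <- apply(mat, 2, min); mx <- apply(mat, 2, max)
  structure(list(min = mn, max = mx, constant = mx == mn,
                 reference = reference, d = ncol(mat)),
            class = "scaling_model")
}

#' @rdname fit_scaling
#' @param model a `scaling_model`.
#' @export
apply_scaling <- function(model, mat) {
  stopifnot(inherits(model, "scaling_model"))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  stopifnot(ncol(mat) == model$d)
  rng <- model$max - model$min
  rng[model$constant] <- 1
  out <- sweep(sweep(mat, 2, model$min, "-"), 2, rng, "/")
  out[, model$constant] <- 0
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}

#' @export
print.scaling_model <- function(x, ...) {
  cat("<scaling_model> reference '", x$reference, "', ", x$d,
      " descriptors (", sum(x$constant), " constant)\n", sep = "")
  invisible(x)
}

#' Tanimoto similarity between scaled descriptor vectors
#'
#' sim(i,j) = sum(x_i x_j) / (sum(x_i^2) + sum(x_j^2) - sum(x_i x_j)) for
#' non-negative scaled vectors; symmetric, in \[0, 1\]. Undefined when both
#' vectors are all-zero (an error, so callers must handle it).
#'
#' @param x,y numeric vectors scaled to \[0, 1\].
#' @return Similarity value in \[0, 1\].
#' @export
tanimoto <- function(x, y) {
  stopifnot(length(x) == length(y))
  xy <- sum(x * y); xx <- sum(x * x); yy <- sum(y * y)
  if (xx + yy == 0) stop("tanimoto undefined: both vectors are all-zero")
  xy / (xx + yy - xy)
}

# rows of `lib` against rows of `ref`: n x m Tanimoto matrix, vectorized
.tanimoto_matrix <- function(lib, ref) {
  cross <- lib %*% t(ref)
  nl <- rowSums(lib^2); nr <- rowSums(ref^2)
  denom <- outer(nl, nr, "+") - cross
  out <- cross / denom
  out[denom == 0] <- NA_real_
  out
}

# seeded k-means++ centre initialization
.kmeanspp_centers <- function(mat, k) {
  n <- nrow(mat)
  centers <- matrix(NA_real_, k, ncol(mat))
  idx <- sample.int(n, 1)
  centers[1, ] <- mat[idx, ]
  if (k > 1) {
    d2 <- rowSums(sweep(mat, 2, centers[1, ], "-")^2)
    for (c in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[c, ] <- mat[idx, ]
      d2 <- pmin(d2, rowSums(sweep(mat, 2, centers[c, ], "-")^2))
    }
  }
  centers
}

#' Cluster a compound library into chemical-space families
#'
#' k-means partition of the scaled descriptor space, with seeded k-means++
#' initialization so the family map is reproducible from (matrix, k, seed).
#' Families are the unit of putative-negative generation and of the
#' hit-novelty analysis.
#'
#' @param mat n x d scaled descriptor matrix; rownames are compound ids
#'   (generated when absent).
#' @param k requested family count (the production-scale screen in the
#'   source study used 8,423 families over 13.7M compounds; fixture-scale
#'   work uses far fewer).
#' @param seed integer seed.
#' @param iter_max maximum Lloyd iterations.
#' @param nstart number of k-means++ starts; the run with the lowest
#'   within-cluster sum of squares is kept.
#' @return A `family_assignment`: `family` (named integer vector),
#'   `centroids` (k' x d), `k`, `seed`.
#' @export
cluster_families <- function(mat, k, seed = 1L, iter_max = 50L, nstart = 20L) {
  stopifnot(is.matrix(mat), all(is.finite(mat)), k >= 1L, nstart >= 1L)
  if (k > nrow(mat)) stop("k (", k, ") exceeds number of compounds (", nrow(mat), ")")
  ids <- rownames(mat)
  if (is.null(ids)) ids <- paste0("cpd_", seq_len(nrow(mat)))
  fit <- .with_seed(seed, {
    best <- NULL
    for (s in seq_len(nstart)) {
      centers <- .kmeanspp_centers(mat, k)
      centers <- centers[!duplicated(centers), , drop = FALSE]
      f <- suppressWarnings(stats::kmeans(mat, centers = centers,
                                          iter.max = iter_max))
      if (is.null(best) || sum(f$withinss) < sum(best$withinss)) best <- f
    }
    best
  })
  if (nrow(fit$centers) < k)
    warning("only ", nrow(fit$centers), " of ", k, " families are non-empty")
  fam <- as.integer(fit$cluster)
  names(fam) <- ids
  structure(list(family = fam, centroids = unname(fit$centers),
                 k = nrow(fit$centers), seed = as.integer(seed),
                 withinss = sum(fit$withinss)),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("<family_assignment> ", length(x$family), " compounds in ", x$k,
      " families (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Assign new compounds to existing families
#'
#' Each row maps to the family with the nearest (Euclidean) centroid; exact
#' ties resolve to the lowest family id.
#'
#' @param assignment a `family_assignment`.
#' @param mat m x d scaled descriptor matrix.
#' @return Integer family id per row, named by rownames.
#' @export
assign_to_families <- function(assignment, mat) {
  stopifnot(inherits(assignment, "family_assignment"))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  stopifnot(ncol(mat) == ncol(assignment$centroids))
  cen <- assignment$centroids
  # squared distances via the expansion |x-c|^2 = |x|^2 - 2 x.c + |c|^2
  d2 <- outer(rowSums(mat^2), rep(1, nrow(cen))) -
    2 * mat %*% t(cen) + outer(rep(1, nrow(mat)), rowSums(cen^2))
  out <- apply(d2, 1, which.min)   # which.min takes the first (lowest id) on ties
  out <- as.integer(out)
  names(out) <- rownames(mat)
  out
}

#' Select putative negatives from inhibitor-free families
#'
#' From every family containing no known active, picks up to `per_family`
#' representative compounds: the members nearest their family centroid
#' (ties by id order). The result never intersects the active set; this is
#' asserted on every call. The rationale is that a family with no known
#' active is unlikely to harbour many undiscovered ones, so its central
#' members can stand in as a putative non-inhibitor class.
#'
#' @param assignment a `family_assignment` fitted on the library.
#' @param mat the scaled matrix the assignment was fitted on (rows must
#'   match `names(assignment$family)`).
#' @param active_ids character vector of known-active compound ids.
#' @param per_family representatives per eligible family (default 2).
#' @return Character vector of selected compound ids.
#' @export
select_putative_negatives <- function(assignment, mat, active_ids,
                                      per_family = 2L) {
  stopifnot(inherits(assignment, "family_assignment"), per_family >= 1L)
  ids <- names(assignment$family)
  stopifnot(!is.null(rownames(mat)), identical(rownames(mat), ids))
  active_fams <- unique(assignment$family[ids %in% active_ids])
  eligible <- setdiff(unique(assignment$family), active_fams)
  if (!length(eligible)) {
    warning("every family contains a known active; no putative negatives")
    return(character())
  }
  picked <- character()
  for (f in sort(eligible)) {
    members <- which(assignment$family == f)
    cen <- assignment$centroids[f, ]
    d2 <- rowSums(sweep(mat[members, , drop = FALSE], 2, cen, "-")^2)
    ord <- members[order(d2, ids[members])]
    picked <- c(picked, ids[ord[seq_len(min(per_family, length(ord)))]])
  }
  stopifnot(!any(picked %in% active_ids))
  picked
}

#' Serialize / restore a family assignment
#'
#' Portable JSON container (seed, k, centroid matrix, id-to-family map) so
#' screens are reproducible across sessions.
#'
#' @param assignment a `family_assignment`.
#' @param path JSON file path.
#' @return `path` invisibly (write); `family_assignment` (read).
#' @export
write_family_assignment <- function(assignment, path) {
  stopifnot(inherits(assignment, "family_assignment"))
  obj <- list(seed = assignment$seed, k = assignment$k,
              centroids = assignment$centroids,
              ids = names(assignment$family),
              family = unname(assignment$family))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_family_assignment
#' @export
read_family_assignment <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fam <- as.integer(obj$family)
  names(fam) <- obj$ids
  structure(list(family = fam, centroids = as.matrix(obj$centroids),
                 k = as.integer(obj$k), seed = as.integer(obj$seed),
                 withinss = NA_real_),
            class = "family_assignment")
}
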