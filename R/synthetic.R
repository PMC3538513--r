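# Synthetic descriptor-space libraries with controlled family structure.
#
# Classifier and clustering behaviour is tested on generated data living
# directly in descriptor space: spherical Gaussian families in the unit
# hypercube whose centroids are kept at a guaranteed minimum separation.
# This decouples classifier correctness from descriptor correctness (the
# chemistry path is exercised by the packaged molecule fixtures instead).

#' Specification for a synthetic labelled library
#'
#' Defaults describe a moderately separated chemical space: per-coordinate
#' family spread 0.05 in the unit cube and a minimum inter-centroid
#' distance of 1.0 — about twice a family's RMS radius in 98 dimensions —
#' so families are distinct but their tails touch.
#'
#' Real inhibitor collections are tight congeneric series surrounded by
#' chemically similar families that carry no activity; screening libraries
#' are dominated by such look-alikes, and discriminating them from the
#' actives is the hard part of a screen. `n_near_families` inactive
#' families are therefore placed at the short distance `near_separation`
#' from active-family centroids (the remaining inactive families keep the
#' full separation). Without them every descriptor-space neighbourhood of
#' an active is exclusively active and the "similar non-inhibitor" concept
#' would be unlearnable by construction.
#'
#' @param n_active,n_inactive compound counts (>= 1).
#' @param d descriptor-space dimension (default 98, the registry size).
#' @param n_active_families,n_inactive_families family counts; active and
#'   inactive families are disjoint. `n_near_families` of the inactive
#'   families (must not exceed `n_inactive_families`) are near-active.
#' @param separation minimum Euclidean distance between family centroids.
#' @param near_separation distance from a near-active inactive family's
#'   centroid to its parent active centroid.
#' @param n_near_families how many inactive families are near-active.
#' @param spread per-coordinate standard deviation within a family.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 50L, n_inactive = 2000L, d = 98L,
                           n_active_families = 2L, n_inactive_families = 8L,
                           separation = 1.0, near_separation = 0.4,
                           n_near_families = 2L, spread = 0.05, seed = 1L) {
  stopifnot(n_active >= 1L, n_inactive >= 1L, d >= 2L,
            n_active_families >= 1L, n_inactive_families >= 1L,
            n_near_families >= 0L, n_near_families <= n_inactive_families,
            separation > 0, near_separation > 0, spread > 0)
  structure(list(n_active = as.integer(n_active),
                 n_inactive = as.integer(n_inactive), d = as.integer(d),
                 n_active_families = as.integer(n_active_families),
                 n_inactive_families = as.integer(n_inactive_families),
                 separation = separation, near_separation = near_separation,
                 n_near_families = as.integer(n_near_families),
                 spread = spread, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# rejection-sample k centroids in [0.2, 0.8]^d at pairwise distance >= sep
.draw_centroids <- function(k, d, sep, max_tries = 200L) {
  cen <- matrix(NA_real_, k, d)
  cen[1, ] <- stats::runif(d, 0.2, 0.8)
  for (i in seq_len(k)[-1]) {
    placed <- FALSE
    for (t in seq_len(max_tries)) {
      cand <- stats::runif(d, 0.2, 0.8)
      if (min(sqrt(rowSums(sweep(cen[seq_len(i - 1), , drop = FALSE], 2,
                                 cand, "-")^2))) >= sep) {
        cen[i, ] <- cand; placed <- TRUE; break
      }
    }
    if (!placed)
      stop("could not place ", k, " centroids at separation ", sep,
           " in ", d, " dimensions; lower the separation or family count")
  }
  cen
}

#' Generate a synthetic labelled descriptor library
#'
#' Draws family centroids at the requested separation, then samples each
#' compound from a spherical Gaussian around its family centroid. Compounds
#' are spread round-robin over their class's families, so family sizes
#' differ by at most one. Ground-truth family ids are returned so that
#' clustering recovery is checkable.
#'
#' @param spec a [synthetic_spec()].
#' @return list: `X` (n x d matrix, rownames `act_*` / `dec_*`), `y`
#'   (labels +1/-1), `family` (true family id per row; active families come
#'   first), `centroids`, `spec`.
#' @export
generate_synthetic_library <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(spec$seed, {
    n_far <- spec$n_inactive_families - spec$n_near_families
    k_sep <- spec$n_active_families + n_far
    cen_sep <- .draw_centroids(k_sep, spec$d, spec$separation)
    cen_act <- cen_sep[seq_len(spec$n_active_families), , drop = FALSE]
    cen_far <- cen_sep[-seq_len(spec$n_active_families), , drop = FALSE]
    cen_near <- NULL
    if (spec$n_near_families > 0L) {
      parent <- rep(seq_len(spec$n_active_families),
                    length.out = spec$n_near_families)
      cen_near <- t(vapply(parent, function(p) {
        dir <- stats::rnorm(spec$d)
        cen_act[p, ] + dir / sqrt(sum(dir^2)) * spec$near_separation
      }, numeric(spec$d)))
    }
    # family ids: actives, then near-active inactive, then far inactive
    cen <- rbind(cen_act, cen_near, cen_far)
    fam_act <- rep(seq_len(spec$n_active_families), length.out = spec$n_active)
    fam_ina <- rep(spec$n_active_families + seq_len(spec$n_inactive_families),
                   length.out = spec$n_inactive)
    fam <- c(fam_act, fam_ina)
    n <- length(fam)
    X <- cen[fam, , drop = FALSE] +
      matrix(stats::rnorm(n * spec$d, 0, spec$spread), n, spec$d)
    rownames(X) <- c(sprintf("act_%03d", seq_len(spec$n_active)),
                     sprintf("dec_%04d", seq_len(spec$n_inactive)))
    y <- c(rep(1, spec$n_active), rep(-1, spec$n_inactive))
    list(X = X, y = y, family = fam, centroids = cen, spec = spec)
  })
}

#' Sample decoys similar to the active families
#'
#' Emulates a screening library of compounds structurally similar to known
#' actives -- the hardest decoy regime, defined the way similarity screens
#' define it: a candidate qualifies when its best Tanimoto coefficient
#' against the scaled training actives reaches `cutoff` (default 0.9).
#' Candidates are drawn around the active-family centroids across a
#' spectrum of radii (family spread inflated by Unif(1, `max_inflate`)) and
#' rejection-sampled against the similarity criterion, so accepted decoys
#' range from deep inside the active clouds to their outskirts.
#'
#' @param lib a library from [generate_synthetic_library()].
#' @param n number of decoys to return.
#' @param scaling the [fit_scaling()] model shared with the screen.
#' @param actives_scaled scaled matrix of the training actives.
#' @param cutoff minimum best-similarity for acceptance.
#' @param max_inflate largest spread multiplier sampled.
#' @param seed integer seed.
#' @param max_tries rejection-sampling budget in batches of `n`.
#' @return n x d matrix (unscaled space) with rownames `sim_*`.
#' @export
sample_similar_decoys <- function(lib, n, scaling, actives_scaled,
                                  cutoff = 0.9, max_inflate = 5,
                                  seed = 1L, max_tries = 50L) {
  stopifnot(n >= 1L, max_inflate >= 1, inherits(scaling, "scaling_model"))
  spec <- lib$spec
  .with_seed(seed, {
    kept <- NULL
    # candidates come from the similarity neighbourhood of the actives:
    # the active families themselves and any near-active inactive families
    src <- seq_len(spec$n_active_families + spec$n_near_families)
    for (t in seq_len(max_tries)) {
      fam <- sample(src, n, replace = TRUE)
      r <- stats::runif(n, 1, max_inflate)
      cand <- lib$centroids[fam, , drop = FALSE] +
        matrix(stats::rnorm(n * spec$d, 0, spec$spread), n, spec$d) * r
      sim <- .tanimoto_matrix(apply_scaling(scaling, cand), actives_scaled)
      best <- apply(sim, 1, max, na.rm = TRUE)
      kept <- rbind(kept, cand[best >= cutoff, , drop = FALSE])
      if (nrow(kept) >= n) break
    }
    if (nrow(kept) < n)
      stop("could not sample ", n, " similar decoys at cutoff ", cutoff)
    kept <- kept[seq_len(n), , drop = FALSE]
    rownames(kept) <- sprintf("sim_%05d", seq_len(n))
    kept
  })
}

#' Packaged fixture molecules
#'
#' A small set of parseable drug-like SMILES spanning the descriptor space
#' (alkanes, aromatics, N/O/S heterocycles, an anilino-quinazoline
#' kinase-inhibitor-like scaffold, charged species, a selenium compound for
#' the missing-parameter path), shipped as plain text under `extdata`.
#' Golden descriptor values computed with independent tooling accompany
#' them in `fixture_golden.tsv`.
#'
#' @return data.frame with columns `smiles`, `name`.
#' @export
fixture_molecules <- function() {
  path <- system.file("extdata", "fixture_molecules.smi",
                      package = "ligscreen", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  data.frame(smiles = vapply(parts, `[`, "", 1),
             name = vapply(parts, function(p) paste(p[-1], collapse = " "), ""),
             stringsAsFactors = FALSE)
}

#' @rdname fixture_molecules
#' @export
fixture_golden_values <- function() {
  utils::read.delim(system.file("extdata", "fixture_golden.tsv",
                                package = "ligscreen", mustWork = TRUE),
                    check.names = FALSE, stringsAsFactors = FALSE)
}
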