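# Independent brute-force graph oracles for descriptor checks. These are
# deliberately written without igraph (plain BFS / recursive enumeration)
# so they share no code path with the implementation they verify.

oracle_adjacency <- function(mol) {
  n <- nrow(mol$atoms)
  A <- matrix(FALSE, n, n)
  if (nrow(mol$bonds)) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- TRUE
    A[cbind(mol$bonds$j, mol$bonds$i)] <- TRUE
  }
  A
}

# all-pairs shortest path by per-vertex BFS
oracle_distances <- function(mol) {
  A <- oracle_adjacency(mol)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(A[v, ] & !is.finite(dist))
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

oracle_wiener <- function(mol) {
  D <- oracle_distances(mol)
  sum(D[upper.tri(D)])
}

oracle_harary <- function(mol) {
  D <- oracle_distances(mol)
  sum(1 / D[upper.tri(D)])
}

# simple-path counts by exhaustive depth-first enumeration; each path
# counted once (started from its lower endpoint ordering is handled by
# halving the doubled count)
oracle_path_counts <- function(mol, maxlen = 6L) {
  A <- oracle_adjacency(mol)
  n <- nrow(A)
  counts <- numeric(maxlen)
  recurse <- function(path) {
    v <- path[length(path)]
    for (w in which(A[v, ])) {
      if (w %in% path) next
      len <- length(path)   # new path has `len` edges
      if (len <= maxlen) {
        counts[len] <<- counts[len] + 1
        if (len < maxlen) recurse(c(path, w))
      }
    }
  }
  for (s in seq_len(n)) recurse(s)
  counts / 2
}

oracle_eccentricities <- function(mol) {
  D <- oracle_distances(mol)
  apply(D, 1, max)
}

# random relabeling of a molgraph's atoms (descriptors must be invariant)
permute_molgraph <- function(mol, perm) {
  inv <- order(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  rownames(atoms) <- NULL
  bonds <- mol$bonds
  if (nrow(bonds)) {
    bonds$i <- inv[bonds$i]
    bonds$j <- inv[bonds$j]
  }
  molgraph(atoms, bonds, id = mol$id)
}

# small labelled two-blob dataset for classifier checks
make_blobs <- function(n_per = 20, d = 5, sep = 4, sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d, 0, sd), n_per, d),
             matrix(rnorm(n_per * d, sep / sqrt(d), sd), n_per, d))
  X <- (X - min(X)) / (max(X) - min(X))   # into [0,1]
  list(X = X, y = rep(c(-1, 1), each = n_per))
}

# scaled 3-blob toy library with known family structure
make_blob_library <- function(k = 3, n_per = 30, d = 8, sep = 6, sd = 0.25,
                              seed = 5) {
  set.seed(seed)
  cen <- matrix(runif(k * d, 0, 1), k, d) * sep
  fam <- rep(seq_len(k), each = n_per)
  X <- cen[fam, ] + matrix(rnorm(k * n_per * d, 0, sd), k * n_per, d)
  rownames(X) <- sprintf("c%03d", seq_len(nrow(X)))
  sc <- fit_scaling(X, "blobs")
  list(X = apply_scaling(sc, X), fam = fam, ids = rownames(X))
}

fixture_graphs <- function() {
  fm <- fixture_molecules()
  mols <- lapply(seq_len(nrow(fm)), function(i)
    suppressWarnings(parse_smiles(fm$smiles[i], id = fm$name[i])))
  names(mols) <- fm$name
  mols
}
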