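# Molecular connectivity and shape indices (registry class 3, 35 values).
# Definitions follow the standard topological-index literature (Kier & Hall
# connectivity/kappa formalism; Todeschini & Consonni compilation); each
# index states its formula at the definition site. All indices are computed
# on the hydrogen-suppressed graph; any index undefined on a degenerate
# graph (single atom, vanishing path count) is emitted as 0.

# Kier-Hall valence delta: deltav = Zeff - nH for second-row atoms,
# (Zeff - nH)/(Z - Zeff - 1) for higher rows, with Zeff = valence electrons
# minus formal charge (an anion gains an electron, a cation loses one).
.valence_delta <- function(mol) {
  el <- mol$atoms$element
  zv <- .finite0(.element_param(el, "zv")) - mol$atoms$charge
  z <- .finite0(.element_param(el, "z"))
  pqn <- .element_param(el, "pqn")
  dv <- zv - mol$atoms$nH
  hi <- !is.na(pqn) & pqn > 2
  dv[hi] <- (zv[hi] - mol$atoms$nH[hi]) / pmax(z[hi] - zv[hi] - 1, 1)
  dv
}

# per-atom hybridization for Kier alpha: sp if triple or cumulated double
# bonds, sp2 if any double bond or aromatic, else sp3
.hybridization <- function(mol) {
  n <- n_atoms(mol)
  ndb <- integer(n); ntb <- integer(n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    o <- mol$bonds$order[k]
    if (o == 2) { ndb[mol$bonds$i[k]] <- ndb[mol$bonds$i[k]] + 1L
                  ndb[mol$bonds$j[k]] <- ndb[mol$bonds$j[k]] + 1L }
    if (o == 3) { ntb[mol$bonds$i[k]] <- ntb[mol$bonds$i[k]] + 1L
                  ntb[mol$bonds$j[k]] <- ntb[mol$bonds$j[k]] + 1L }
  }
  ifelse(ntb > 0 | ndb >= 2, "sp", ifelse(ndb > 0 | mol$atoms$aromatic, "sp2", "sp3"))
}

.kier_alpha_sum <- function(mol) {
  hyb <- .hybridization(mol)
  key <- paste(mol$atoms$element, hyb, sep = ".")
  a <- .kier_alpha[key]
  miss <- is.na(a)
  a[miss] <- .kier_alpha[paste(mol$atoms$element[miss], "sp3", sep = ".")]
  a[is.na(a)] <- 0
  sum(a)
}

# counts of simple paths by length (edges), each path counted once;
# lengths 1..maxlen
.path_counts <- function(mol, maxlen = 10L) {
  counts <- numeric(maxlen)
  if (!nrow(mol$bonds)) return(counts)
  g <- mol_igraph(mol)
  for (v in seq_len(n_atoms(mol))) {
    ps <- igraph::all_simple_paths(g, from = as.character(v), cutoff = maxlen)
    len <- vapply(ps, length, 1L) - 1L
    len <- len[len >= 1L]
    if (length(len)) {
      t <- tabulate(len, nbins = maxlen)
      counts <- counts + t
    }
  }
  counts / 2
}

# all 2-paths (i-j-k, i<k) as a 3-column matrix of atom indices
.two_paths <- function(mol) {
  if (!nrow(mol$bonds)) return(matrix(integer(), ncol = 3))
  n <- n_atoms(mol)
  adj <- vector("list", n)
  for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  out <- list()
  for (m in seq_len(n)) {
    nb <- adj[[m]]
    if (length(nb) >= 2) {
      cmb <- utils::combn(sort(nb), 2)
      out[[length(out) + 1L]] <- cbind(cmb[1, ], m, cmb[2, ])
    }
  }
  if (!length(out)) return(matrix(integer(), ncol = 3))
  do.call(rbind, out)
}

#' Molecular connectivity and shape descriptors
#'
#' The 35 topological indices of the registry's connectivity/shape class:
#' Schultz and Gutman molecular topological indices, Wiener and Harary
#' indices, a gravitational topological index (sum over heavy-atom pairs of
#' m_i m_j / d_ij^2 with attached-H masses folded in), molecular path counts
#' of length 1-6 and the total path count (simple paths up to length 10),
#' Balaban J, 0-2nd order valence connectivity and delta-chi indices,
#' the Pogliani index (sum of valence electrons over principal quantum
#' number), 0-2nd order solvation connectivity indices, Kier kappa and
#' kappa-alpha shape indices of orders 1-3, the Kier flexibility index,
#' topological radius, Petitjean graph-theoretical shape coefficient,
#' eccentricity (sum of atomic eccentricities), centralization
#' (2W - n * min distance-degree), and a connectivity-based logP estimate
#' (linear in the first-order valence chi index).
#'
#' @param mol a [molgraph] (connected; parsed molecules always are).
#' @return Named numeric vector of length 35, in registry order.
#' @export
connectivity_shape <- function(mol) {
  n <- n_atoms(mol)
  deg <- mol_degree(mol)
  D <- mol_distances(mol)
  dv <- .valence_delta(mol)
  pc <- .path_counts(mol, maxlen = 10L)
  off <- upper.tri(D)
  wiener <- sum(D[off])
  harary <- sum(1 / D[off])
  mass <- .finite0(.element_param(mol$atoms$element, "mass")) +
    mol$atoms$nH * .element_param("H", "mass")
  grav <- if (n > 1) {
    mm <- outer(mass, mass)
    sum((mm / D^2)[off])
  } else 0
  # Schultz MTI = sum_i [(A + D) v]_i with v the degree vector
  A <- matrix(0, n, n)
  if (nrow(mol$bonds)) {
    A[cbind(mol$bonds$i, mol$bonds$j)] <- 1
    A[cbind(mol$bonds$j, mol$bonds$i)] <- 1
  }
  schultz <- sum((A + D) %*% deg)
  gutman <- sum((outer(deg, deg) * D)[off])
  # Balaban J = B/(mu+1) * sum over edges (s_i s_j)^(-1/2), s = distance sums
  s <- rowSums(D)
  B <- nrow(mol$bonds); mu <- B - n + 1L
  balaban <- if (B > 0)
    B / (mu + 1) * sum(1 / sqrt(s[mol$bonds$i] * s[mol$bonds$j])) else 0
  tp <- .two_paths(mol)
  chi0 <- sum(1 / sqrt(deg))
  chi0v <- sum(1 / sqrt(dv[dv > 0]))
  chi1 <- if (B > 0) sum(1 / sqrt(deg[mol$bonds$i] * deg[mol$bonds$j])) else 0
  chi1v <- if (B > 0) {
    p <- dv[mol$bonds$i] * dv[mol$bonds$j]
    sum(1 / sqrt(p[p > 0]))
  } else 0
  chi2 <- if (nrow(tp)) sum(1 / sqrt(deg[tp[, 1]] * deg[tp[, 2]] * deg[tp[, 3]])) else 0
  chi2v <- if (nrow(tp)) {
    p <- dv[tp[, 1]] * dv[tp[, 2]] * dv[tp[, 3]]
    sum(1 / sqrt(p[p > 0]))
  } else 0
  pogliani <- sum((.finite0(.element_param(mol$atoms$element, "zv")) -
                     mol$atoms$charge) /
                    .finite0(.element_param(mol$atoms$element, "pqn")))
  # solvation connectivity ^mXs = 1/2^(m+1) sum over m-paths
  # (prod L)/sqrt(prod delta), L = principal quantum number
  L <- .finite0(.element_param(mol$atoms$element, "pqn"))
  solv0 <- sum(L / sqrt(deg)) / 2
  solv1 <- if (B > 0)
    sum(L[mol$bonds$i] * L[mol$bonds$j] /
          sqrt(deg[mol$bonds$i] * deg[mol$bonds$j])) / 4 else 0
  solv2 <- if (nrow(tp))
    sum(L[tp[, 1]] * L[tp[, 2]] * L[tp[, 3]] /
          sqrt(deg[tp[, 1]] * deg[tp[, 2]] * deg[tp[, 3]])) / 8 else 0
  # Kier kappa shape indices
  P1 <- pc[1]; P2 <- pc[2]; P3 <- pc[3]
  kappa1 <- n * (n - 1)^2 / P1^2
  kappa2 <- (n - 1) * (n - 2)^2 / P2^2
  kappa3 <- if (n %% 2 == 1) (n - 1) * (n - 3)^2 / P3^2
            else (n - 3) * (n - 2)^2 / P3^2
  alpha <- .kier_alpha_sum(mol)
  ka <- n + alpha
  kappa1a <- ka * (ka - 1)^2 / (P1 + alpha)^2
  kappa2a <- (ka - 1) * (ka - 2)^2 / (P2 + alpha)^2
  kappa3a <- if (n %% 2 == 1) (ka - 1) * (ka - 3)^2 / (P3 + alpha)^2
             else (ka - 3) * (ka - 2)^2 / (P3 + alpha)^2
  flex <- kappa1a * kappa2a / n
  ecc <- apply(D, 1, max)
  radius <- min(ecc); diam <- max(ecc)
  shape <- if (radius > 0) (diam - radius) / radius else 0
  centralization <- 2 * wiener - n * min(s)
  out <- c(SchultzMTI = schultz, GutmanMTI = gutman, Wiener = wiener,
           Harary = harary, Gravitational = grav,
           PathCount1 = pc[1], PathCount2 = pc[2], PathCount3 = pc[3],
           PathCount4 = pc[4], PathCount5 = pc[5], PathCount6 = pc[6],
           TotalPathCount = sum(pc),
           BalabanJ = balaban,
           Chiv0 = chi0v, Chiv1 = chi1v, Chiv2 = chi2v,
           DeltaChi0 = chi0 - chi0v, DeltaChi1 = chi1 - chi1v,
           DeltaChi2 = chi2 - chi2v,
           Pogliani = pogliani,
           SolvChi0 = solv0, SolvChi1 = solv1, SolvChi2 = solv2,
           Kappa1 = kappa1, Kappa2 = kappa2, Kappa3 = kappa3,
           KappaAlpha1 = kappa1a, KappaAlpha2 = kappa2a, KappaAlpha3 = kappa3a,
           KierFlex = flex,
           TopoRadius = radius, ShapeCoef = shape,
           Eccentricity = sum(ecc), Centralization = centralization,
           LogPChi = 0.406 + 0.884 * chi1v)
  .finite0(out)
}
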