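# Kier-Hall electrotopological state (E-state) machinery.
#
# Intrinsic state     I_i = ((2/N_i)^2 * deltav_i + 1) / delta_i
# Pair perturbation   dI_ij = (I_i - I_j) / (d_ij + 1)^2   (d = bond-count
#                     graph distance; bonded atoms divide by 4)
# Atom E-state        S_i = I_i + sum_j dI_ij
#
# The 24 typed sums aggregate S_i over atoms matching a Kier-Hall atom-type
# signature (s = single, d = double, t = triple, a = aromatic bond; trailing
# Hn = attached hydrogen count); atoms matching no listed type still
# contribute to the aggregate sums. Because dI_ij = -dI_ji, the heavy-atom
# E-state total always equals the intrinsic-state total.

.estate_type_names <- c(
  "sCH3", "dCH2", "ssCH2", "dsCH", "aaCH", "sssCH", "dssC", "aasC", "aaaC",
  "sssC", "sNH3", "sNH2", "ssNH2", "dNH", "ssNH", "aaNH", "dsN", "aaN",
  "sssN", "ddsN", "aOH", "sOH", "ssO", "sSH")

.hestate_type_names <- c(
  "HsOH", "HdNH", "HsSH", "HsNH2", "HssNH", "HaaNH", "HtCH", "HdCH2",
  "HdsCH", "HaaCH", "HCsats", "HCsatu", "Havin")

# per-atom bond-pattern signature: counts of non-aromatic single/double/
# triple bonds and aromatic bonds to heavy neighbours
.bond_signature <- function(mol) {
  n <- n_atoms(mol)
  ns <- integer(n); nd <- integer(n); nt <- integer(n); na <- integer(n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$bonds$aromatic[k]) { na[i] <- na[i] + 1L; na[j] <- na[j] + 1L }
    else if (mol$bonds$order[k] == 1) { ns[i] <- ns[i] + 1L; ns[j] <- ns[j] + 1L }
    else if (mol$bonds$order[k] == 2) { nd[i] <- nd[i] + 1L; nd[j] <- nd[j] + 1L }
    else { nt[i] <- nt[i] + 1L; nt[j] <- nt[j] + 1L }
  }
  list(ns = ns, nd = nd, nt = nt, na = na)
}

# E-state atom type per heavy atom ("" when no listed type matches)
.estate_types <- function(mol) {
  sig <- .bond_signature(mol)
  el <- mol$atoms$element; h <- mol$atoms$nH
  n <- n_atoms(mol)
  # aromatic neighbour lookup for the aOH / sOH split (phenolic vs aliphatic)
  arom_nbr <- rep(FALSE, n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (mol$atoms$aromatic[j]) arom_nbr[i] <- TRUE
    if (mol$atoms$aromatic[i]) arom_nbr[j] <- TRUE
  }
  type <- character(n)
  for (a in seq_len(n)) {
    e <- el[a]; ns <- sig$ns[a]; nd <- sig$nd[a]; nt <- sig$nt[a]; na <- sig$na[a]
    ha <- h[a]
    type[a] <- if (e == "C") {
      if (ha == 3 && ns == 1 && nd + nt + na == 0) "sCH3"
      else if (ha == 2 && nd == 1 && ns + nt + na == 0) "dCH2"
      else if (ha == 2 && ns == 2 && nd + nt + na == 0) "ssCH2"
      else if (ha == 1 && nd == 1 && ns == 1 && na == 0) "dsCH"
      else if (ha == 1 && na == 2) "aaCH"
      else if (ha == 1 && ns == 3 && nd + nt + na == 0) "sssCH"
      else if (ha == 0 && nd == 1 && ns == 2 && na == 0) "dssC"
      else if (ha == 0 && na == 2 && ns == 1) "aasC"
      else if (ha == 0 && na == 3) "aaaC"
      else if (ha == 0 && ns >= 3 && nd + nt + na == 0) "sssC"
      else ""
    } else if (e == "N") {
      if (ha == 3 && ns == 1) "sNH3"
      else if (ha == 2 && ns == 1 && nd + nt + na == 0) "sNH2"
      else if (ha == 2 && ns == 2) "ssNH2"
      else if (ha == 1 && nd == 1 && ns == 0 && na == 0) "dNH"
      else if (ha == 1 && ns == 2 && nd + nt + na == 0) "ssNH"
      else if (ha == 1 && na == 2) "aaNH"
      else if (ha == 0 && nd == 2 && ns == 1) "ddsN"
      else if (ha == 0 && nd == 1 && ns == 1 && na == 0) "dsN"
      else if (ha == 0 && na == 2) "aaN"
      else if (ha == 0 && ns == 3 && nd + nt + na == 0) "sssN"
      else ""
    } else if (e == "O") {
      if (ha == 1 && ns == 1 && arom_nbr[a]) "aOH"
      else if (ha == 1 && ns == 1) "sOH"
      else if (ha == 0 && ns == 2 && nd + nt + na == 0) "ssO"
      else ""
    } else if (e == "S") {
      if (ha == 1 && ns == 1) "sSH"
      else ""
    } else ""
  }
  type
}

# per-atom E-state values S_i (heavy atoms). Isolated atoms (degree 0) have
# no defined intrinsic state; 0 by the package's degenerate-value convention.
.estate_values <- function(mol) {
  n <- n_atoms(mol)
  deg <- mol_degree(mol)
  dv <- .valence_delta(mol)
  pqn <- .finite0(.element_param(mol$atoms$element, "pqn"))
  I <- ifelse(deg > 0 & pqn > 0, ((2 / pqn)^2 * dv + 1) / deg, 0)
  if (n == 1L) return(I)
  D <- mol_distances(mol)
  pert <- (outer(I, I, "-")) / (D + 1)^2
  S <- I + rowSums(pert)
  S
}

# Hydrogen E-state, built on the Kier-Hall relative electronegativity
# KHE_i = (deltav_i - delta_i)/N_i^2 with KHE(H) = -0.2: the hydride group
# on atom i gets HS_i = nH_i * sum_j (KHE_j - KHE_H)/(d_ij + 1)^2 over all
# heavy atoms j (j = i included at distance 0). This is a package
# convention; it preserves the field-standard qualitative ordering (polar
# X-H hydrogens score high) without asserting literature golden values.
.hestate_values <- function(mol) {
  n <- n_atoms(mol)
  deg <- mol_degree(mol)
  dv <- .valence_delta(mol)
  pqn <- pmax(.finite0(.element_param(mol$atoms$element, "pqn")), 1)
  khe <- (dv - deg) / pqn^2
  D <- mol_distances(mol)
  hs <- numeric(n)
  for (a in seq_len(n)) {
    if (mol$atoms$nH[a] == 0) next
    hs[a] <- mol$atoms$nH[a] * sum((khe + 0.2) / (D[a, ] + 1)^2)
  }
  hs
}

# hydride type per heavy atom carrying hydrogens ("" when nH = 0)
.hestate_types <- function(mol, types = .estate_types(mol)) {
  sig <- .bond_signature(mol)
  el <- mol$atoms$element
  n <- n_atoms(mol)
  # unsaturated-neighbour lookup for the HCsats/HCsatu split
  unsat <- sig$nd > 0 | sig$nt > 0 | sig$na > 0
  unsat_or_het_nbr <- rep(FALSE, n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
    if (unsat[j] || el[j] != "C") unsat_or_het_nbr[i] <- TRUE
    if (unsat[i] || el[i] != "C") unsat_or_het_nbr[j] <- TRUE
  }
  out <- character(n)
  for (a in seq_len(n)) {
    if (mol$atoms$nH[a] == 0) next
    e <- el[a]; ty <- types[a]
    out[a] <- if (e == "O") "HsOH"
    else if (e == "S") "HsSH"
    else if (e == "N") {
      if (ty == "dNH") "HdNH"
      else if (ty == "ssNH") "HssNH"
      else if (ty == "aaNH") "HaaNH"
      else "HsNH2"                      # sNH2/sNH3/ssNH2 and other N-H
    } else if (e == "C") {
      if (sig$nt[a] > 0) "HtCH"
      else if (ty == "dCH2") "HdCH2"
      else if (ty == "dsCH") "HdsCH"
      else if (ty == "aaCH") "HaaCH"
      else if (!unsat[a]) { if (unsat_or_het_nbr[a]) "HCsatu" else "HCsats" }
      else "Havin"                      # remaining unsaturated C-H
    } else "Havin"
  }
  out
}

#' Electrotopological-state descriptors
#'
#' The 42 E-state descriptors: sums of atom E-state values S_i over the 24
#' Kier-Hall atom types of the registry, aggregate S sums over all heavy
#' atoms, all carbons, all heteroatoms and all H-bond acceptors, the 13
#' hydrogen E-state type sums, and the hydrogen E-state sum over H-bond
#' donors. Types absent from the molecule contribute 0.
#'
#' @param mol a [molgraph].
#' @return Named numeric vector of length 42, in registry order.
#' @export
estate_sums <- function(mol) {
  S <- .estate_values(mol)
  types <- .estate_types(mol)
  sums <- vapply(.estate_type_names,
                 function(t) sum(S[types == t]), numeric(1))
  names(sums) <- paste0("S", .estate_type_names)
  el <- mol$atoms$element
  agg <- c(SHeavyTotal = sum(S),
           SCarbonTotal = sum(S[el == "C"]),
           SHeteroTotal = sum(S[el != "C"]),
           SHBAccTotal = sum(S[.is_hb_acceptor(mol)]))
  hs <- .hestate_values(mol)
  htypes <- .hestate_types(mol, types)
  hsums <- vapply(.hestate_type_names,
                  function(t) sum(hs[htypes == t]), numeric(1))
  names(hsums) <- paste0("S", .hestate_type_names)
  hdon <- c(SHHBDonTotal = sum(hs[.is_hb_donor(mol)]))
  c(sums, agg, hsums, hdon)
}
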