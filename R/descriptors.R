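#' The 98-descriptor registry
#'
#' Fixed, ordered registry of the 98 1D/2D molecular descriptors computed by
#' this package: 18 simple molecular properties, 3 chemical properties, 35
#' molecular connectivity and shape indices, and 42 electrotopological-state
#' sums. The order defines the column layout of every descriptor matrix the
#' package produces.
#'
#' @return data.frame with columns `name`, `class`
#'   (`simple`/`chemical`/`connectivity_shape`/`estate`) and 0-based `index`.
#' @export
descriptor_registry <- function() {
  simple <- c("nC", "nN", "nO", "nP", "nS", "nAtoms", "nRings", "nBonds",
              "nBondsNonH", "MW", "nRotatable", "nHBDon", "nHBAcc",
              "nAromRing5", "nAromRing6", "nRingN", "nRingO", "nRingS")
  chemical <- c("SandersonEN", "Polarizability", "ALogP")
  conn <- c("SchultzMTI", "GutmanMTI", "Wiener", "Harary", "Gravitational",
            paste0("PathCount", 1:6), "TotalPathCount", "BalabanJ",
            paste0("Chiv", 0:2), paste0("DeltaChi", 0:2), "Pogliani",
            paste0("SolvChi", 0:2), paste0("Kappa", 1:3),
            paste0("KappaAlpha", 1:3), "KierFlex", "TopoRadius",
            "ShapeCoef", "Eccentricity", "Centralization", "LogPChi")
  es <- c(paste0("S", .estate_type_names),
          "SHeavyTotal", "SCarbonTotal", "SHeteroTotal", "SHBAccTotal",
          paste0("S", .hestate_type_names), "SHHBDonTotal")
  d <- data.frame(
    name = c(simple, chemical, conn, es),
    class = rep(c("simple", "chemical", "connectivity_shape", "estate"),
                c(length(simple), length(chemical), length(conn), length(es))),
    stringsAsFactors = FALSE)
  d$index <- seq_len(nrow(d)) - 1L
  stopifnot(nrow(d) == 98L, !anyDuplicated(d$name))
  d
}

# replace non-finite values arising from degenerate graphs (single atoms,
# vanishing path counts) by 0 so downstream linear algebra stays total
.finite0 <- function(x) {
  x[!is.finite(x)] <- 0
  x
}

# --- hydrogen-bond conventions (documented package defaults) ---------------
# donor: N or O carrying at least one hydrogen
# acceptor: N or O that is not positively charged
.is_hb_donor <- function(mol) mol$atoms$element %in% c("N", "O") & mol$atoms$nH > 0
.is_hb_acceptor <- function(mol) mol$atoms$element %in% c("N", "O") & mol$atoms$charge <= 0

#' Simple molecular property descriptors
#'
#' The 18 count-based descriptors: atom counts of C/N/O/P/S, heavy-atom
#' total, SSSR ring count, bond counts with and without hydrogens, molecular
#' weight (average masses, attached H included), rotatable bonds (single,
#' acyclic, both atoms non-terminal, amide C-N excluded), H-bond donors and
#' acceptors, 5- and 6-membered aromatic ring counts, and N-/O-/S-containing
#' ring counts.
#'
#' @param mol a [molgraph].
#' @return Named numeric vector of length 18, in registry order.
#' @export
simple_properties <- function(mol) {
  el <- mol$atoms$element
  rings <- mol_sssr(mol)
  deg <- mol_degree(mol)
  ring_bond <- rep(FALSE, nrow(mol$bonds))
  if (length(rings) && nrow(mol$bonds)) {
    key <- paste(pmin(mol$bonds$i, mol$bonds$j), pmax(mol$bonds$i, mol$bonds$j))
    for (r in rings) {
      ii <- r; jj <- c(r[-1], r[1])
      ring_bond[match(paste(pmin(ii, jj), pmax(ii, jj)), key)] <- TRUE
    }
  }
  # amide C-N: C double-bonded to O, single bond C-N
  amide <- rep(FALSE, nrow(mol$bonds))
  if (nrow(mol$bonds)) {
    has_carbonyl <- rep(FALSE, n_atoms(mol))
    for (k in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[k] == 2) {
        i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
        if (el[i] == "C" && el[j] == "O") has_carbonyl[i] <- TRUE
        if (el[j] == "C" && el[i] == "O") has_carbonyl[j] <- TRUE
      }
    }
    for (k in seq_len(nrow(mol$bonds))) {
      i <- mol$bonds$i[k]; j <- mol$bonds$j[k]
      if (mol$bonds$order[k] == 1 &&
          ((el[i] == "C" && has_carbonyl[i] && el[j] == "N") ||
           (el[j] == "C" && has_carbonyl[j] && el[i] == "N")))
        amide[k] <- TRUE
    }
  }
  rot <- 0L
  if (nrow(mol$bonds)) {
    rot <- sum(mol$bonds$order == 1 & !mol$bonds$aromatic & !ring_bond &
               deg[mol$bonds$i] >= 2 & deg[mol$bonds$j] >= 2 & !amide)
  }
  ring_is_arom <- vapply(rings, function(r) all(mol$atoms$aromatic[r]), TRUE)
  ring_size <- vapply(rings, length, 1L)
  ring_has <- function(sym) sum(vapply(rings, function(r) any(el[r] == sym), TRUE))
  mw <- sum(.finite0(.element_param(el, "mass"))) +
    sum(mol$atoms$nH) * .element_param("H", "mass")
  c(nC = sum(el == "C"), nN = sum(el == "N"), nO = sum(el == "O"),
    nP = sum(el == "P"), nS = sum(el == "S"),
    nAtoms = n_atoms(mol),
    nRings = length(rings),
    nBonds = nrow(mol$bonds) + sum(mol$atoms$nH),
    nBondsNonH = nrow(mol$bonds),
    MW = mw,
    nRotatable = rot,
    nHBDon = sum(.is_hb_donor(mol)),
    nHBAcc = sum(.is_hb_acceptor(mol)),
    nAromRing5 = sum(ring_is_arom & ring_size == 5L),
    nAromRing6 = sum(ring_is_arom & ring_size == 6L),
    nRingN = ring_has("N"), nRingO = ring_has("O"), nRingS = ring_has("S"))
}

# ---------------------------------------------------------------------------
# Abbreviated Wildman-Crippen style atom-contribution logP. Atoms are sorted
# into a reduced set of contribution classes (hydrocarbon vs heteroatom-
# substituted carbon, aromatic carbon, amine/amide/aromatic/charged nitrogen,
# hydroxyl/ether/carbonyl oxygen, halogens, S, P, and hydrogens by attached
# element); contribution values follow the published increments for the
# corresponding classes. Unparameterized elements contribute 0.
# ---------------------------------------------------------------------------
.alogp <- function(mol) {
  el <- mol$atoms$element
  n <- n_atoms(mol)
  deg <- mol_degree(mol)
  arom <- mol$atoms$aromatic
  has_db <- rep(FALSE, n); has_tb <- rep(FALSE, n); het_nbr <- rep(FALSE, n)
  nbr_unsat <- rep(FALSE, n)
  if (nrow(mol$bonds)) for (k in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[k]; j <- mol$bonds$j[k]; o <- mol$bonds$order[k]
    if (o == 2) { has_db[i] <- TRUE; has_db[j] <- TRUE }
    if (o == 3) { has_tb[i] <- TRUE; has_tb[j] <- TRUE }
    if (!el[j] %in% c("C", "H")) het_nbr[i] <- TRUE
    if (!el[i] %in% c("C", "H")) het_nbr[j] <- TRUE
  }
  total <- 0
  for (a in seq_len(n)) {
    e <- el[a]; h <- mol$atoms$nH[a]
    contrib <- 0; hcontrib <- 0.1230   # H on carbon
    if (e == "C") {
      if (arom[a]) contrib <- if (deg[a] >= 3) 0.2955 else 0.1581
      else if (has_tb[a]) contrib <- 0.0017
      else if (has_db[a]) contrib <- if (het_nbr[a]) -0.2783 else 0.1551
      else if (het_nbr[a]) contrib <- if (deg[a] >= 3) -0.2051 else -0.2035
      else contrib <- if (deg[a] >= 3) 0.0000 else 0.1441
    } else if (e == "N") {
      hcontrib <- 0.2142               # H on nitrogen
      if (mol$atoms$charge[a] > 0) contrib <- -1.9500
      else if (arom[a]) contrib <- -0.3239
      else if (has_db[a] || has_tb[a]) contrib <- -0.3396
      else if (h >= 2) contrib <- -1.0190
      else if (h == 1) contrib <- -0.7096
      else contrib <- -0.3187
    } else if (e == "O") {
      hcontrib <- -0.2677              # H on oxygen
      if (mol$atoms$charge[a] < 0) contrib <- -1.3260
      else if (arom[a]) contrib <- 0.1552
      else if (has_db[a]) contrib <- -0.1526
      else if (h == 1) contrib <- -0.2893
      else contrib <- -0.0684
    } else {
      contrib <- switch(e, F = 0.4202, Cl = 0.6895, Br = 0.8456, I = 0.8857,
                        S = if (arom[a]) 0.6237 else 0.6482, P = 0.8612, 0)
    }
    total <- total + contrib + h * hcontrib
  }
  total
}

#' Chemical property descriptors
#'
#' Total Sanderson electronegativity (sum over all atoms, attached hydrogens
#' included), total atomic polarizability (sum of published atomic static
#' polarizabilities, attached hydrogens included) and ALogP (an abbreviated
#' Wildman-Crippen style atom-contribution octanol/water logP). Elements
#' missing from a parameter table contribute 0 with a warning.
#'
#' @param mol a [molgraph].
#' @return Named numeric vector of length 3, in registry order.
#' @export
chemical_properties <- function(mol) {
  el <- mol$atoms$element
  sand <- .element_param(el, "sand")
  pol <- .element_param(el, "polar")
  if (anyNA(sand) || anyNA(pol))
    warning("molecule '", mol$id, "': no chemical-property parameters for ",
            paste(unique(el[is.na(sand) | is.na(pol)]), collapse = ", "),
            "; contribution set to 0")
  nHtot <- sum(mol$atoms$nH)
  c(SandersonEN = sum(.finite0(sand)) + nHtot * .element_param("H", "sand"),
    Polarizability = sum(.finite0(pol)) + nHtot * .element_param("H", "polar"),
    ALogP = .alogp(mol))
}

#' Compute the full 98-descriptor vector for one molecule
#'
#' Concatenates [simple_properties()], [chemical_properties()],
#' [connectivity_shape()] and [estate_sums()] in registry order. All values
#' are finite; indices undefined on degenerate graphs are 0 by convention.
#'
#' @param mol a [molgraph].
#' @return Named numeric vector of length 98 with attribute `id`.
#' @export
compute_descriptor_vector <- function(mol) {
  v <- c(simple_properties(mol), chemical_properties(mol),
         connectivity_shape(mol), estate_sums(mol))
  reg <- descriptor_registry()
  stopifnot(length(v) == 98L, identical(names(v), reg$name))
  v <- .finite0(v)
  attr(v, "id") <- mol$id
  v
}

#' Featurize a molecule library into a descriptor matrix
#'
#' @param mols list of [molgraph] objects (or a single one).
#' @return n x 98 numeric matrix, rownames = molecule identifiers, columns
#'   named per the registry; attribute `n_failed` counts molecules whose
#'   featurization failed (dropped with a warning).
#' @export
featurize_library <- function(mols) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  stopifnot(length(mols) >= 1L)
  rows <- vector("list", length(mols)); ids <- character(length(mols))
  ok <- logical(length(mols))
  for (k in seq_along(mols)) {
    v <- tryCatch(compute_descriptor_vector(mols[[k]]), error = function(e) NULL)
    if (is.null(v)) {
      warning("featurization failed for molecule ", k, " ('", mols[[k]]$id, "')")
      next
    }
    rows[[k]] <- v; ids[k] <- mols[[k]]$id; ok[k] <- TRUE
  }
  if (!any(ok)) stop("featurization failed for every molecule")
  m <- do.call(rbind, rows[ok])
  rownames(m) <- make.unique(ids[ok])
  structure(m, n_failed = sum(!ok))
}

#' Write / read a descriptor table
#'
#' Tab-separated text: first column `id`, then the 98 registry-named
#' descriptor columns; header row mandatory.
#'
#' @param mat descriptor matrix from [featurize_library()].
#' @param path output path.
#' @return `path` invisibly (write); descriptor matrix (read).
#' @export
write_descriptor_table <- function(mat, path) {
  stopifnot(is.matrix(mat), ncol(mat) == 98L)
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_table
#' @export
read_descriptor_table <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  stopifnot(names(df)[1] == "id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  stopifnot(identical(colnames(m), descriptor_registry()$name))
  m
}
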