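#' Molecular graph objects
#'
#' A `molgraph` is the hydrogen-suppressed chemical graph on which all
#' descriptors are computed. Explicit hydrogens present in the input are
#' folded into per-atom attached-H counts; missing hydrogens are filled in
#' from standard valence rules (charge-adjusted). Aromaticity is perceived
#' uniformly with a Hueckel-style 4n+2 electron count over the smallest set
#' of smallest rings, so descriptor values are internally consistent
#' regardless of how the input was kekulized.
#'
#' @importFrom methods as
#' @param atoms data.frame with columns `element` (symbol), `charge`
#'   (integer formal charge, e), `nH` (attached hydrogen count) and
#'   `aromatic` (logical).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices),
#'   `order` (1, 2 or 3) and `aromatic` (logical). May have zero rows.
#' @param id source identifier.
#' @return An object of class `molgraph`.
#' @export
molgraph <- function(atoms, bonds, id = "") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  bonds <- as.data.frame(bonds, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "charge", "nH", "aromatic") %in% names(atoms)))
  if (nrow(bonds) == 0L)
    bonds <- data.frame(i = integer(), j = integer(), order = integer(),
                        aromatic = logical())
  stopifnot(all(c("i", "j", "order", "aromatic") %in% names(bonds)))
  n <- nrow(atoms)
  if (nrow(bonds) > 0L) {
    if (any(bonds$i < 1L | bonds$i > n | bonds$j < 1L | bonds$j > n))
      stop("bond endpoint out of range for molecule '", id, "'")
    if (any(bonds$i == bonds$j))
      stop("self-bond in molecule '", id, "'")
    key <- paste(pmin(bonds$i, bonds$j), pmax(bonds$i, bonds$j))
    if (anyDuplicated(key))
      stop("duplicate bond in molecule '", id, "'")
  }
  if (any(atoms$nH < 0)) stop("negative attached-H count in molecule '", id, "'")
  structure(list(atoms = atoms, bonds = bonds, id = as.character(id)),
            class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat("<molgraph> ", x$id, ": ", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds, ", sum(x$atoms$nH), " attached H\n", sep = "")
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$atoms)

# heavy-atom degree vector
mol_degree <- function(mol) {
  d <- integer(n_atoms(mol))
  if (nrow(mol$bonds)) {
    t1 <- tabulate(mol$bonds$i, nbins = n_atoms(mol))
    t2 <- tabulate(mol$bonds$j, nbins = n_atoms(mol))
    d <- t1 + t2
  }
  d
}

mol_igraph <- function(mol) {
  igraph::graph_from_data_frame(
    d = if (nrow(mol$bonds)) mol$bonds[, c("i", "j")] else
      data.frame(i = integer(), j = integer()),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n_atoms(mol))))
}

# all-pairs topological distance matrix (bond counts)
mol_distances <- function(mol) {
  if (n_atoms(mol) == 1L) return(matrix(0, 1, 1))
  d <- igraph::distances(mol_igraph(mol))
  o <- order(as.integer(rownames(d)))
  d[o, o, drop = FALSE]
}

# sum of bond orders per heavy atom (kekulized orders; excludes H)
mol_bond_order_sum <- function(mol) {
  bos <- numeric(n_atoms(mol))
  if (nrow(mol$bonds)) {
    for (k in seq_len(nrow(mol$bonds))) {
      bos[mol$bonds$i[k]] <- bos[mol$bonds$i[k]] + mol$bonds$order[k]
      bos[mol$bonds$j[k]] <- bos[mol$bonds$j[k]] + mol$bonds$order[k]
    }
  }
  bos
}

# ---------------------------------------------------------------------------
# Ring perception: smallest set of smallest rings (SSSR).
#
# Horton-style construction: candidate cycles are the shortest cycle through
# each edge (shortest path between the endpoints in the graph with that edge
# removed); candidates are sorted by length and selected greedily under
# GF(2) independence of their edge-incidence vectors until the cyclomatic
# number mu = E - V + components is reached. Exact for the small molecular
# graphs this package handles.
# ---------------------------------------------------------------------------
mol_sssr <- function(mol) {
  nb <- nrow(mol$bonds)
  n <- n_atoms(mol)
  if (nb == 0L || n < 3L) return(list())
  g <- mol_igraph(mol)
  comps <- igraph::components(g)$no
  mu <- nb - n + comps
  if (mu <= 0L) return(list())
  cands <- list()
  for (k in seq_len(nb)) {
    g2 <- igraph::delete_edges(g, k)
    u <- as.character(mol$bonds$i[k]); v <- as.character(mol$bonds$j[k])
    sp <- suppressWarnings(igraph::shortest_paths(g2, from = u, to = v)$vpath[[1]])
    if (length(sp) == 0L) next
    verts <- as.integer(names(sp))
    cands[[length(cands) + 1L]] <- verts     # ordered around the ring
  }
  if (!length(cands)) return(list())
  cands <- cands[order(vapply(cands, length, 1L))]
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bond_keys <- edge_key(mol$bonds$i, mol$bonds$j)
  basis <- matrix(0L, nrow = 0L, ncol = nb)   # reduced GF(2) rows
  rings <- list()
  for (cyc in cands) {
    m <- length(cyc)
    ii <- cyc; jj <- c(cyc[-1], cyc[1])
    vec <- integer(nb)
    vec[match(edge_key(ii, jj), bond_keys)] <- 1L
    red <- vec
    if (nrow(basis)) {
      for (r in seq_len(nrow(basis))) {
        piv <- which(basis[r, ] == 1L)[1]
        if (red[piv] == 1L) red <- (red + basis[r, ]) %% 2L
      }
    }
    if (any(red == 1L)) {
      basis <- rbind(basis, red)
      rings[[length(rings) + 1L]] <- cyc
      if (length(rings) == mu) break
    }
  }
  rings
}

# ---------------------------------------------------------------------------
# Aromaticity perception (Hueckel-style, applied uniformly to every parsed
# molecule). A SSSR ring is aromatic when every ring atom can carry a p
# orbital and the ring pi-electron count is 4n+2:
#   * atom with a double bond to another ring atom (any ring)  -> 1 electron
#   * C with an exocyclic double bond to a non-ring atom       -> 0 electrons
#   * N/O/S without a double bond (lone pair in the ring)      -> 2 electrons
#   * any other saturated C                                    -> not aromatic
# Fused bicyclics whose aromaticity only emerges from the perimeter ring
# (e.g. azulene) are not detected; this limitation is documented.
# ---------------------------------------------------------------------------
perceive_aromaticity <- function(mol) {
  mol$atoms$aromatic <- FALSE
  if (nrow(mol$bonds)) mol$bonds$aromatic <- FALSE
  rings <- mol_sssr(mol)
  if (!length(rings)) return(mol)
  n <- n_atoms(mol)
  in_ring <- rep(FALSE, n)
  for (r in rings) in_ring[r] <- TRUE
  dbl <- mol$bonds[mol$bonds$order == 2, , drop = FALSE]
  has_dbl_to_ring <- rep(FALSE, n); has_dbl_exo <- rep(FALSE, n)
  if (nrow(dbl)) {
    for (k in seq_len(nrow(dbl))) {
      i <- dbl$i[k]; j <- dbl$j[k]
      if (in_ring[j]) has_dbl_to_ring[i] <- TRUE else has_dbl_exo[i] <- TRUE
      if (in_ring[i]) has_dbl_to_ring[j] <- TRUE else has_dbl_exo[j] <- TRUE
    }
  }
  edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  bond_keys <- edge_key(mol$bonds$i, mol$bonds$j)
  arom_atom <- rep(FALSE, n); arom_bond <- rep(FALSE, nrow(mol$bonds))
  for (r in rings) {
    pi <- 0; ok <- TRUE
    for (a in r) {
      el <- mol$atoms$element[a]
      if (has_dbl_to_ring[a]) pi <- pi + 1
      else if (has_dbl_exo[a]) pi <- pi + 0
      else if (el %in% c("N", "O", "S")) pi <- pi + 2
      else { ok <- FALSE; break }
    }
    if (ok && pi %% 4 == 2) {
      arom_atom[r] <- TRUE
      ii <- r; jj <- c(r[-1], r[1])
      arom_bond[match(edge_key(ii, jj), bond_keys)] <- TRUE
    }
  }
  mol$atoms$aromatic <- arom_atom
  if (nrow(mol$bonds)) mol$bonds$aromatic <- arom_bond
  mol
}

# ---------------------------------------------------------------------------
# Implicit hydrogen assignment. Valence = charge-adjusted default valence
# (cations of N/P/O/S gain their charge, every other charged atom loses
# |charge|); hypervalent S/P step up to the smallest allowed valence covering
# the bond-order sum. Explicit hydrogens already folded count toward the
# total; metals and unparameterized elements receive none.
# ---------------------------------------------------------------------------
.implicit_h <- function(element, charge, bosum, explicitH) {
  nh <- integer(length(element))
  for (a in seq_along(element)) {
    el <- element[a]
    base <- .element_param(el, "defval")
    if (is.na(base)) { nh[a] <- explicitH[a]; next }
    ch <- charge[a]
    if (ch > 0 && el %in% c("N", "P", "O", "S")) base <- base + ch
    else if (ch != 0) base <- max(0, base - abs(ch))
    val <- base
    allowed <- .hyper_valences[[el]]
    if (!is.null(allowed) && ch == 0) {
      need <- bosum[a] + explicitH[a]
      fit <- allowed[allowed >= need]
      val <- if (length(fit)) fit[1] else base
    }
    nh[a] <- explicitH[a] + max(0, val - bosum[a] - explicitH[a])
  }
  nh
}

# Fallback for records ChemmineR cannot hold: a molecule with atoms but no
# bonds (e.g. methane, a bare ion). Reads the atom lines straight from the
# raw V2000 record; anything else is a genuine parse failure.
.molgraph_bondless <- function(lines, id = "") {
  if (length(lines) < 4L) stop("invalid connection table for molecule '", id, "'")
  counts <- lines[4]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L || nbonds != 0L)
    stop("invalid connection table for molecule '", id, "'")
  atom_lines <- lines[5:(4 + natoms)]
  element <- trimws(substr(atom_lines, 32, 34))
  charge <- .decode_charge(suppressWarnings(as.integer(substr(atom_lines, 37, 39))))
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0, natoms)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      for (p in seq_len(f[1])) charge[f[2 * p]] <- f[2 * p + 1]
    }
  }
  keepH <- element != "H"
  if (!any(keepH)) stop("molecule '", id, "' has no heavy atoms")
  element <- element[keepH]; charge <- charge[keepH]
  if (length(element) > 1L) {
    warning("molecule '", id, "': ", length(element),
            " fragments; keeping largest (1 heavy atom)")
    element <- element[1]; charge <- charge[1]
  }
  nH <- .implicit_h(element, charge, 0, 0L)
  molgraph(data.frame(element = element, charge = charge, nH = nH,
                      aromatic = FALSE, stringsAsFactors = FALSE),
           data.frame(i = integer(), j = integer(), order = integer(),
                      aromatic = logical()),
           id = id)
}

# decode the V2000 atom-block charge field
.decode_charge <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

# Build a molgraph from the raw lines of one V2000 record. Structured
# parsing is delegated to ChemmineR; bondless records (which ChemmineR
# cannot hold) are read from the atom lines directly. Folds explicit
# hydrogens, assigns implicit ones, keeps the largest fragment, perceives
# aromaticity.
.molgraph_from_sdflines <- function(lines, id = "") {
  if (length(lines) < 4L) stop("invalid record for molecule '", id, "'")
  natoms <- suppressWarnings(as.integer(substr(lines[4], 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(lines[4], 4, 6)))
  if (is.na(natoms) || is.na(nbonds) || natoms < 1L)
    stop("invalid connection table for molecule '", id, "'")
  if (nbonds == 0L) return(.molgraph_bondless(lines, id))
  sdf1 <- suppressWarnings(ChemmineR::read.SDFset(lines))
  ab <- ChemmineR::atomblock(sdf1[[1]])
  bb <- ChemmineR::bondblock(sdf1[[1]])
  if (!is.matrix(ab) || nrow(ab) < 1L ||
      !all(grepl("^[A-Za-z]{1,2}_[0-9]+$", rownames(ab))))
    stop("invalid connection table for molecule '", id, "'")
  element <- sub("_[0-9]+$", "", rownames(ab))
  n <- length(element)
  charge <- if ("C6" %in% colnames(ab)) .decode_charge(ab[, "C6"]) else rep(0, n)
  # M CHG property lines override atom-block charge codes (V2000 spec)
  chg_lines <- grep("^M  CHG", lines, value = TRUE)
  if (length(chg_lines)) {
    charge <- rep(0, n)
    for (ln in chg_lines) {
      f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "\\s+")[[1]])
      cnt <- f[1]
      for (p in seq_len(cnt)) charge[f[2 * p]] <- f[2 * p + 1]
    }
  }
  if (is.matrix(bb) && nrow(bb) >= 1L && ncol(bb) >= 3L) {
    bi <- as.integer(bb[, 1]); bj <- as.integer(bb[, 2]); bo <- as.integer(bb[, 3])
  } else if (is.numeric(bb) && length(bb) >= 3L) {    # single-bond molecule
    bi <- as.integer(bb[1]); bj <- as.integer(bb[2]); bo <- as.integer(bb[3])
  } else {                                            # bondless molecule
    bi <- integer(); bj <- integer(); bo <- integer()
  }
  # fold explicit hydrogens
  isH <- element == "H"
  explicitH <- integer(n)
  if (any(isH)) {
    keepb <- rep(TRUE, length(bi))
    for (k in seq_along(bi)) {
      if (isH[bi[k]] && !isH[bj[k]]) { explicitH[bj[k]] <- explicitH[bj[k]] + 1L; keepb[k] <- FALSE }
      else if (isH[bj[k]] && !isH[bi[k]]) { explicitH[bi[k]] <- explicitH[bi[k]] + 1L; keepb[k] <- FALSE }
      else if (isH[bi[k]] && isH[bj[k]]) keepb[k] <- FALSE
    }
    bi <- bi[keepb]; bj <- bj[keepb]; bo <- bo[keepb]
    newidx <- cumsum(!isH); newidx[isH] <- NA
    bi <- newidx[bi]; bj <- newidx[bj]
    element <- element[!isH]; charge <- charge[!isH]; explicitH <- explicitH[!isH]
    n <- length(element)
  }
  if (n == 0L) stop("molecule '", id, "' has no heavy atoms")
  bonds <- data.frame(i = bi, j = bj, order = bo, aromatic = FALSE)
  # keep largest fragment (most heavy atoms; ties by lowest first atom index)
  g <- igraph::graph_from_data_frame(
    bonds[, c("i", "j")], directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  cmp <- igraph::components(g)
  memb <- cmp$membership[order(as.integer(names(cmp$membership)))]
  if (cmp$no > 1L) {
    keep_cmp <- which.max(cmp$csize)
    keep <- which(memb == keep_cmp)
    warning("molecule '", id, "': ", cmp$no,
            " fragments; keeping largest (", length(keep), " heavy atoms)")
    newidx <- rep(NA_integer_, n); newidx[keep] <- seq_along(keep)
    sel <- bonds$i %in% keep & bonds$j %in% keep
    bonds <- bonds[sel, , drop = FALSE]
    bonds$i <- newidx[bonds$i]; bonds$j <- newidx[bonds$j]
    element <- element[keep]; charge <- charge[keep]; explicitH <- explicitH[keep]
    n <- length(keep)
  }
  bosum <- numeric(n)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    bosum[bonds$i[k]] <- bosum[bonds$i[k]] + bonds$order[k]
    bosum[bonds$j[k]] <- bosum[bonds$j[k]] + bonds$order[k]
  }
  nH <- .implicit_h(element, charge, bosum, explicitH)
  atoms <- data.frame(element = element, charge = charge, nH = nH,
                      aromatic = FALSE, stringsAsFactors = FALSE)
  mol <- molgraph(atoms, bonds, id = id)
  perceive_aromaticity(mol)
}

#' Parse a SMILES string into a molecular graph
#'
#' Parsing is delegated to OpenBabel (via ChemmineR/ChemmineOB); the
#' kekulized connection table is then converted to a hydrogen-suppressed
#' [molgraph] with package-uniform aromaticity perception and implicit-H
#' assignment. For dot-separated multi-fragment input only the fragment with
#' the most heavy atoms is kept (a warning reports the drop).
#'
#' @param smiles a single SMILES string.
#' @param id identifier stored on the graph (default: the SMILES itself).
#' @return A [molgraph].
#' @examples
#' \donttest{
#' mol <- parse_smiles("CCO")
#' mol$atoms$nH   # 3 2 1
#' }
#' @export
parse_smiles <- function(smiles, id = smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  .check_smiles_syntax(smiles)
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF", source = smiles)),
    error = function(e) NULL)
  lines <- if (is.null(txt)) character() else strsplit(txt, "\n", fixed = TRUE)[[1]]
  tryCatch(.molgraph_from_sdflines(lines, id = id),
           error = function(e) stop("could not parse SMILES: '", smiles, "'",
                                    call. = FALSE))
}

# Syntactic pre-validation of a SMILES string. OpenBabel silently repairs
# some malformed input (an unclosed branch parses as if truncated), so the
# parse-error contract is enforced here: legal character set, balanced
# branches and brackets, paired ring-closure labels.
.check_smiles_syntax <- function(smiles) {
  fail <- function() stop("could not parse SMILES: '", smiles, "'", call. = FALSE)
  if (grepl("[^A-Za-z0-9@+\\-\\[\\]()=#$:/\\\\%.*]", smiles)) fail()
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L; brack <- 0L
  for (ch in chars) {
    if (ch == "(") depth <- depth + 1L
    else if (ch == ")") { depth <- depth - 1L; if (depth < 0L) fail() }
    else if (ch == "[") { brack <- brack + 1L; if (brack > 1L) fail() }
    else if (ch == "]") { brack <- brack - 1L; if (brack < 0L) fail() }
  }
  if (depth != 0L || brack != 0L) fail()
  # ring-closure labels outside brackets must pair up
  stripped <- gsub("\\[[^]]*\\]", "A", smiles)
  labels <- c(
    regmatches(stripped, gregexpr("%[0-9]{2}", stripped))[[1]],
    strsplit(gsub("%[0-9]{2}", "", stripped), "")[[1]])
  labels <- labels[grepl("^(%[0-9]{2}|[0-9])$", labels)]
  if (length(labels) && any(table(labels) %% 2 != 0)) fail()
  invisible(TRUE)
}

#' Read molecules from a SMILES or SDF file
#'
#' `.smi` files hold one molecule per line (SMILES, optionally followed by a
#' whitespace-separated identifier); `.sdf` files are MDL V2000. Records that
#' fail to parse are skipped with a warning; the skip count is attached as
#' attribute `n_failed`.
#'
#' @param path file path.
#' @param format `"smi"` or `"sdf"`; default guessed from the extension.
#' @return List of [molgraph] objects with attribute `n_failed`.
#' @export
read_molecules <- function(path, format = c("auto", "smi", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smi"
  mols <- list(); failed <- 0L
  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) {
      warning("empty molecule file: ", path)
      return(structure(list(), n_failed = 0L))
    }
    for (ln in lines) {
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      smi <- parts[1]
      id <- if (length(parts) > 1L) paste(parts[-1], collapse = " ") else smi
      m <- tryCatch(parse_smiles(smi, id = id), error = function(e) NULL)
      if (is.null(m)) {
        warning("skipping unparseable record: '", smi, "'")
        failed <- failed + 1L
      } else mols[[length(mols) + 1L]] <- m
    }
  } else {
    sdfstr <- suppressWarnings(ChemmineR::read.SDFstr(path))
    recs <- as(sdfstr, "list")
    if (!length(recs) || all(!vapply(recs, function(r) length(r) >= 4L, TRUE))) {
      warning("empty molecule file: ", path)
      return(structure(list(), n_failed = 0L))
    }
    for (k in seq_along(recs)) {
      lines <- recs[[k]]
      id <- if (length(lines) && nzchar(trimws(lines[1]))) trimws(lines[1])
            else paste0("mol_", k)
      m <- tryCatch(.molgraph_from_sdflines(lines, id = id),
                    error = function(e) NULL)
      if (is.null(m)) {
        warning("skipping unreadable SDF record ", k)
        failed <- failed + 1L
      } else mols[[length(mols) + 1L]] <- m
    }
  }
  structure(mols, n_failed = failed)
}

#' Write molecular graphs to an SDF (V2000) file
#'
#' Attached hydrogens stay implicit (hydrogen-suppressed connection table);
#' formal charges are written as `M CHG` lines. Used for round-tripping
#' graphs through standard tooling.
#'
#' @param mols a [molgraph] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molgraph")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    n <- n_atoms(mol); nb <- nrow(mol$bonds)
    writeLines(c(mol$id, "  ligscreen          2D", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb), con)
    for (a in seq_len(n))
      writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                         0, 0, 0, mol$atoms$element[a]), con)
    if (nb) for (k in seq_len(nb))
      writeLines(sprintf("%3d%3d%3d  0  0  0  0",
                         mol$bonds$i[k], mol$bonds$j[k], mol$bonds$order[k]), con)
    chg <- which(mol$atoms$charge != 0)
    if (length(chg))
      writeLines(paste0("M  CHG", sprintf("%3d", length(chg)),
                        paste0(sprintf("%4d%4d", chg, mol$atoms$charge[chg]),
                               collapse = "")), con)
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
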