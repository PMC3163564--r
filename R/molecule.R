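# Molecular graphs parsed from SMILES.
#
# Parsing is delegated to OpenBabel (via ChemmineOB).  Two serializations of
# the same parsed molecule are combined: SDF supplies elements and kekulized
# bond orders (so the two carboxyl oxygens stay distinguishable, unlike MOL2's
# delocalized O.co2 representation), and MOL2 atom types supply aromatic
# perception (the SYBYL *.ar suffix).  Both preserve the SMILES heavy-atom
# input order.  Hydrogens stay implicit; per-atom hydrogen counts are
# recovered from standard valences.  Scope: neutral organic molecules --
# formal charges are not modelled.

.element_z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53
)

.element_valence <- c(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

.ob_convert <- function(to, smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", to, source = smiles)),
    error = function(e) ""
  )
  if (!nzchar(trimws(out))) stop(sprintf("cannot parse SMILES: '%s'", smiles))
  out
}

#' Parse a SMILES string into a molecular graph
#'
#' Converts the SMILES to an internal graph handle with a stable atom
#' ordering (the input order of the SMILES heavy atoms, 1-based).
#' Stereochemistry is retained in the stored SMILES but ignored by
#' substructure matching, which is constitution-only.  Dot-separated
#' (multi-fragment) SMILES are kept as one entity.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molecule_graph`: a list with `natoms`, an
#'   `atoms` data frame (element symbol, atomic number, aromatic flag,
#'   hydrogen count `nH`, heavy-atom degree, total connectivity `X`, ring
#'   membership `in_ring`), a `bonds` data frame (`i`, `j`, `order`,
#'   `aromatic`, `in_ring`), an adjacency list `adj`, and the input `smiles`.
#' @examples
#' mol <- parse_molecule("CCO")
#' mol$natoms
#' @export
parse_molecule <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(trimws(smiles))) {
    stop("'smiles' must be a single non-empty string")
  }
  sdf <- .ob_convert("SDF", smiles)
  sdf_lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  if (length(sdf_lines) < 4L) stop(sprintf("cannot parse SMILES: '%s'", smiles))
  counts <- sdf_lines[4]
  n <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(n) || n < 1L) stop(sprintf("cannot parse SMILES (no atoms): '%s'", smiles))

  atom_lines <- sdf_lines[4L + seq_len(n)]
  elem <- trimws(substr(atom_lines, 32, 34))
  if (nb > 0L) {
    bond_lines <- sdf_lines[4L + n + seq_len(nb)]
    bi <- as.integer(substr(bond_lines, 1, 3))
    bj <- as.integer(substr(bond_lines, 4, 6))
    b_order <- as.integer(substr(bond_lines, 7, 9))
  } else {
    bi <- bj <- b_order <- integer(0)
  }

  # aromatic perception from MOL2 atom types
  mol2 <- .ob_convert("MOL2", smiles)
  m2_lines <- strsplit(mol2, "\n", fixed = TRUE)[[1]]
  a_start <- match("@<TRIPOS>ATOM", trimws(m2_lines))
  aromatic <- rep(FALSE, n)
  if (!is.na(a_start)) {
    k <- 0L
    for (ln in m2_lines[-seq_len(a_start)]) {
      if (startsWith(trimws(ln), "@<TRIPOS>")) break
      if (!nzchar(trimws(ln))) next
      k <- k + 1L
      if (k > n) break
      f <- strsplit(trimws(ln), "[[:space:]]+")[[1]]
      aromatic[k] <- grepl("\\.ar$", f[[6]])
    }
  }

  adj <- vector("list", n)
  for (k in seq_along(bi)) {
    adj[[bi[k]]] <- c(adj[[bi[k]]], bj[k])
    adj[[bj[k]]] <- c(adj[[bj[k]]], bi[k])
  }

  ring_bond <- .ring_bonds(n, bi, bj)
  in_ring <- rep(FALSE, n)
  in_ring[c(bi[ring_bond], bj[ring_bond])] <- TRUE
  b_arom <- ring_bond & aromatic[bi] & aromatic[bj]

  z <- unname(.element_z[elem])
  z[is.na(z)] <- 0L
  is_h_atom <- elem == "H"
  heavy_degree <- integer(n)
  explicit_h <- integer(n)
  bondsum <- integer(n)
  for (k in seq_along(bi)) {
    a <- bi[k]; o <- bj[k]
    bondsum[a] <- bondsum[a] + b_order[k]
    bondsum[o] <- bondsum[o] + b_order[k]
    if (is_h_atom[o]) explicit_h[a] <- explicit_h[a] + 1L else
      heavy_degree[a] <- heavy_degree[a] + 1L
    if (is_h_atom[a]) explicit_h[o] <- explicit_h[o] + 1L else
      heavy_degree[o] <- heavy_degree[o] + 1L
  }
  val <- unname(.element_valence[elem])
  implicit_h <- pmax(0L, ifelse(is.na(val), 0L, val) - bondsum)
  nH <- as.integer(implicit_h) + explicit_h
  nH[is_h_atom] <- 0L

  structure(list(
    natoms = n,
    atoms = data.frame(
      elem = elem, Z = z, aromatic = aromatic, nH = nH,
      degree = heavy_degree,
      X = heavy_degree + explicit_h + as.integer(implicit_h),
      in_ring = in_ring, stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      i = bi, j = bj, order = as.numeric(b_order), aromatic = b_arom,
      in_ring = ring_bond, stringsAsFactors = FALSE
    ),
    adj = adj,
    smiles = smiles
  ), class = "molecule_graph")
}

# A bond is a ring bond iff its endpoints stay connected after removing it.
.ring_bonds <- function(n, bi, bj) {
  nb <- length(bi)
  if (nb == 0L) return(logical(0))
  res <- logical(nb)
  for (k in seq_len(nb)) {
    adj <- vector("list", n)
    for (m in seq_len(nb)) {
      if (m == k) next
      adj[[bi[m]]] <- c(adj[[bi[m]]], bj[m])
      adj[[bj[m]]] <- c(adj[[bj[m]]], bi[m])
    }
    seen <- logical(n)
    queue <- bi[k]
    seen[queue] <- TRUE
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      for (nx in adj[[cur]]) {
        if (!seen[nx]) { seen[nx] <- TRUE; queue <- c(queue, nx) }
      }
    }
    res[k] <- seen[bj[k]]
  }
  res
}

#' @export
print.molecule_graph <- function(x, ...) {
  cat(sprintf("<molecule_graph> %d atoms, %d bonds\n", x$natoms, nrow(x$bonds)))
  cat("  SMILES:", x$smiles, "\n")
  invisible(x)
}
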