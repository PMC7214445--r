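# Molecule structure: an explicit-hydrogen molecular graph parsed from SMILES.
# A `bde_mol` is a list(smiles, atoms, bonds) where
#   atoms: element, charge, radical, isotope, parity, aromatic, degree, n_h,
#          ring_size (0 = not in a ring, otherwise size of smallest ring)
#   bonds: a1, a2 (a1 < a2), order, ring_size
# Atom order is the order OpenBabel emits for the *canonical* SMILES with
# hydrogens appended, so two SMILES spellings of the same molecule always
# yield the identical structure.

# Extract per-atom aromatic flags and chirality tags from a SMILES string by
# tokenizing its atom symbols. OpenBabel preserves the order of SMILES atoms
# (including bracket hydrogens) at the head of its SDF output; hydrogens it
# adds itself come after.
smiles_atom_tokens <- function(smiles) {
  pat <- "\\[[^]]*\\]|Cl|Br|[BCNOPSFIbcnops]"
  toks <- regmatches(smiles, gregexpr(pat, smiles))[[1]]
  aromatic <- grepl("^\\[?[0-9]*[a-z]", toks)
  chirality <- ifelse(grepl("@@", toks), "CW",
                      ifelse(grepl("@", toks), "CCW", "none"))
  sym <- sub("^\\[?[0-9]*([A-Za-z][a-z]?).*$", "\\1", toks)
  data.frame(token = toks, symbol = toupper(substr(sym, 1, 1)),
             aromatic = aromatic, chirality = chirality,
             stringsAsFactors = FALSE)
}

# Smallest-ring sizes for every bond and atom. Leaves are stripped first so
# the per-bond breadth-first search (smallest ring through a bond is 1 + the
# shortest alternative path between its endpoints) only runs inside the
# cyclic core; acyclic molecules cost one linear pass.
ring_sizes <- function(n_atoms, bonds) {
  nb <- nrow(bonds)
  a1 <- bonds$a1; a2 <- bonds$a2
  deg <- tabulate(c(a1, a2), nbins = n_atoms)
  alive_bond <- rep(TRUE, nb)
  alive_atom <- deg > 0L
  repeat {
    leaf <- which(alive_atom & deg == 1L)
    if (!length(leaf)) break
    for (b in which(alive_bond)) {
      if (a1[b] %in% leaf || a2[b] %in% leaf) {
        alive_bond[b] <- FALSE
        deg[a1[b]] <- deg[a1[b]] - 1L
        deg[a2[b]] <- deg[a2[b]] - 1L
      }
    }
    alive_atom[leaf] <- FALSE
  }
  bond_ring <- integer(nb)
  core <- which(alive_bond)
  if (length(core)) {
    adj <- vector("list", n_atoms)
    for (i in core) {
      adj[[a1[i]]] <- c(adj[[a1[i]]], i)
      adj[[a2[i]]] <- c(adj[[a2[i]]], i)
    }
    for (b in core) {
      src <- a1[b]; dst <- a2[b]
      dist <- rep(NA_integer_, n_atoms); dist[src] <- 0L
      queue <- src
      while (length(queue) && is.na(dist[dst])) {
        v <- queue[1]; queue <- queue[-1]
        for (e in adj[[v]]) {
          if (e == b) next
          w <- if (a1[e] == v) a2[e] else a1[e]
          if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
        }
      }
      bond_ring[b] <- if (is.na(dist[dst])) 0L else dist[dst] + 1L
    }
  }
  atom_ring <- integer(n_atoms)
  for (b in which(bond_ring > 0L)) {
    for (a in c(a1[b], a2[b]))
      atom_ring[a] <- if (atom_ring[a] == 0L) bond_ring[b]
                      else min(atom_ring[a], bond_ring[b])
  }
  list(bond = bond_ring, atom = atom_ring)
}

# Assemble a bde_mol from a parsed molblock + the canonical SMILES it came
# from. `tokens` may be NULL (no aromatic/chirality annotation available).
.finish_mol <- function(pm, canonical, tokens = NULL) {
  atoms <- pm$atoms; bonds <- pm$bonds
  n <- nrow(atoms)
  atoms$aromatic <- FALSE
  atoms$chirality <- "none"
  if (!is.null(tokens)) {
    nt <- nrow(tokens)
    if (nt > n ||
        !identical(toupper(substr(atoms$element[seq_len(nt)], 1, 1)),
                   tokens$symbol))
      stop("internal: SMILES atom tokens do not align with the parsed atoms",
           call. = FALSE)
    atoms$aromatic[seq_len(nt)] <- tokens$aromatic
    atoms$chirality[seq_len(nt)] <- tokens$chirality
  } else {
    atoms$chirality <- ifelse(atoms$parity == 1L, "CW",
                              ifelse(atoms$parity == 2L, "CCW", "none"))
  }
  # normalize bond orientation a1 < a2
  swap <- bonds$a1 > bonds$a2
  tmp <- bonds$a1[swap]; bonds$a1[swap] <- bonds$a2[swap]; bonds$a2[swap] <- tmp
  deg <- tabulate(c(bonds$a1, bonds$a2), nbins = n)
  # OpenBabel does not always emit M RAD on write; infer unpaired electrons
  # for neutral C/H/N/O atoms from the bond-order sum (kekulized orders).
  bosum <- numeric(n)
  for (i in seq_len(nrow(bonds))) {
    bosum[bonds$a1[i]] <- bosum[bonds$a1[i]] + bonds$order[i]
    bosum[bonds$a2[i]] <- bosum[bonds$a2[i]] + bonds$order[i]
  }
  expected <- c(C = 4, N = 3, O = 2, H = 1)
  neutral <- atoms$charge == 0L & atoms$element %in% names(expected)
  inferred <- ifelse(neutral, pmax(0, expected[atoms$element] - bosum), 0)
  # MDL RAD convention: 1 = singlet carbene, 2 = doublet, 3 = triplet
  from_code <- c(0, 2, 1, 2)[atoms$radical + 1L]
  atoms$unpaired <- as.integer(pmax(inferred, from_code))
  atoms$radical <- ifelse(atoms$unpaired == 1L, 2L,
                          ifelse(atoms$unpaired >= 2L, 3L, 0L))
  is_h <- atoms$element == "H"
  n_h <- tabulate(c(bonds$a1[is_h[bonds$a2]], bonds$a2[is_h[bonds$a1]]), nbins = n)
  atoms$degree <- deg
  atoms$n_h <- n_h
  rs <- ring_sizes(n, bonds)
  atoms$ring_size <- rs$atom
  bonds$ring_size <- rs$bond
  structure(list(smiles = canonical, atoms = atoms, bonds = bonds),
            class = "bde_mol")
}

#' Parse SMILES into explicit-hydrogen molecular graphs
#'
#' Canonicalizes each input and builds the explicit-hydrogen graph used by
#' enumeration and featurization. Atom order is determined by the canonical
#' SMILES, so any spelling of the same molecule yields an identical graph.
#'
#' @param smiles character vector of SMILES strings.
#' @return a list of `bde_mol` objects (a single `bde_mol` if the input has
#'   length one).
#' @examples
#' m <- parse_mol("CCO")
#' nrow(m$atoms)  # 9: 3 heavy atoms + 6 hydrogens
#' @export
parse_mol <- function(smiles) {
  can <- canonicalize_smiles(smiles)
  titles <- paste0("m", seq_along(can))
  src <- paste0(can, "\t", titles, "\n", collapse = "")
  sdf <- ob_convert("SMI", "SDF", src, add_h = TRUE)
  recs <- split_sdf(sdf)
  if (length(recs) != length(can))
    stop("SMILES parse error: OpenBabel dropped a record", call. = FALSE)
  mols <- vector("list", length(can))
  for (i in seq_along(recs)) {
    pm <- parse_molblock(recs[i])
    mols[[i]] <- .finish_mol(pm, can[i], smiles_atom_tokens(can[i]))
  }
  if (length(mols) == 1L) mols[[1]] else mols
}

#' @export
print.bde_mol <- function(x, ...) {
  cat("<bde_mol> ", x$smiles, ": ", nrow(x$atoms), " atoms (",
      sum(x$atoms$element != "H"), " heavy), ", nrow(x$bonds), " bonds\n",
      sep = "")
  invisible(x)
}

# Molblock for a bde_mol or an atom/bond subset of it.
mol_to_molblock <- function(mol, title = "mol") {
  write_molblock(mol$atoms, mol$bonds, title)
}

.allowed_elements <- c("C", "H", "N", "O")

#' Build a validated closed-shell molecule record
#'
#' Checks the domain contract for parent molecules: elements restricted to
#' C/H/N/O, zero net charge and no unpaired electrons. Returns the canonical
#' SMILES, the heavy-atom count and the molecular formula.
#'
#' @param smiles a single SMILES string.
#' @return a list of class `molecule_record` with elements `smiles`,
#'   `n_heavy`, `formula` (named integer vector over C, H, N, O) and `mol`
#'   (the parsed `bde_mol`).
#' @examples
#' molecule_record("CCO")$formula
#' @export
molecule_record <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  mol <- parse_mol(smiles)
  el <- mol$atoms$element
  if (!all(el %in% .allowed_elements))
    stop("molecule '", smiles, "' contains element(s) outside C/H/N/O: ",
         paste(setdiff(unique(el), .allowed_elements), collapse = ", "),
         call. = FALSE)
  if (sum(mol$atoms$charge) != 0L || any(mol$atoms$charge != 0L))
    stop("molecule '", smiles, "' is charged; only neutral molecules are accepted",
         call. = FALSE)
  if (any(mol$atoms$unpaired != 0L))
    stop("molecule '", smiles, "' is open-shell; only closed-shell molecules are accepted",
         call. = FALSE)
  n_heavy <- sum(el != "H")
  if (n_heavy < 1L) stop("molecule must contain at least one heavy atom", call. = FALSE)
  formula <- vapply(.allowed_elements, function(e) sum(el == e), 0L)
  structure(list(smiles = mol$smiles, n_heavy = n_heavy, formula = formula,
                 mol = mol),
            class = "molecule_record")
}

# Parity column only, without a full molblock parse.
.parity_of_block <- function(text) {
  ln <- strsplit(text, "\n", fixed = TRUE)[[1]]
  na <- as.integer(substr(ln[4], 1, 3))
  if (is.na(na) || na == 0L) return(integer(0))
  p <- suppressWarnings(as.integer(substr(ln[4L + seq_len(na)], 40, 42)))
  p[is.na(p)] <- 0L
  p
}

# Number of assignable tetrahedral stereocenters (specified or potential) in
# each molblock, using OpenBabel's stereo perception: after an SDF -> SDF
# round trip the atom parity field is 1/2 for specified centers and 3 for
# perceived-but-unspecified ones.
count_stereocenters <- function(blocks) {
  vapply(stereocenter_atoms(blocks), sum, 0L, USE.NAMES = FALSE)
}

# Per-atom stereocenter mask for each block (memoized: fragments such as [H]
# or small radicals recur constantly during enumeration).
stereocenter_atoms <- function(blocks) {
  out <- vector("list", length(blocks))
  key <- vapply(blocks, function(b) sub("^[^\n]*\n", "", b), "",
                USE.NAMES = FALSE)
  hit <- vapply(key, function(k) !is.null(.ob_cache$ster[[k]]), NA)
  if (any(hit))
    out[hit] <- lapply(key[hit], function(k) .ob_cache$ster[[k]])
  if (any(!hit)) {
    recs <- molblocks_reperceive(blocks[!hit])
    masks <- lapply(recs, function(r) .parity_of_block(r) %in% c(1L, 2L, 3L))
    out[!hit] <- masks
    for (i in seq_along(masks)) .ob_cache$ster[[key[!hit][i]]] <- masks[[i]]
  }
  out
}
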