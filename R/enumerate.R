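# Homolytic cleavage enumeration: every acyclic single bond of the
# explicit-hydrogen graph is broken into two radical fragments; candidate
# cleavages that would create a new stereocenter are marked invalid, and the
# remaining ones are deduplicated by (parent, sorted radical pair, bond type).

.bond_priority <- c(C = 1L, N = 2L, O = 3L, H = 4L)

#' Bond-type label for a cleaved bond
#'
#' Joins the element symbols of the two bonded atoms with `-`, ordered by the
#' fixed priority C < N < O with H always last. This yields the nine labels
#' C-H, C-C, N-H, C-N, C-O, O-H, N-O, N-N, O-O.
#'
#' @param el1,el2 element symbols of the two bonded atoms (vectorized).
#' @return character vector of labels.
#' @examples
#' bond_type_label("H", "C")  # "C-H"
#' bond_type_label("O", "N")  # "N-O"
#' @export
bond_type_label <- function(el1, el2) {
  if (!all(c(el1, el2) %in% names(.bond_priority)))
    stop("bond between elements outside C/H/N/O", call. = FALSE)
  p1 <- .bond_priority[el1]; p2 <- .bond_priority[el2]
  unname(ifelse(p1 <= p2, paste0(el1, "-", el2), paste0(el2, "-", el1)))
}

# All nine bond-type labels, in priority order.
bond_type_levels <- function() {
  c("C-H", "C-C", "N-H", "C-N", "C-O", "O-H", "N-O", "N-N", "O-O")
}

# Internal: molblocks of the two fragments obtained by deleting bond b.
# Returns list(blocks = c(block1, block2), atom_sets = list(idx1, idx2),
# tips = c(atom in frag1, atom in frag2)) or signals invalid-bond error.
.fragment_blocks <- function(mol, bond_index, title = "frag") {
  bonds <- mol$bonds
  if (bond_index < 1L || bond_index > nrow(bonds))
    stop("bond index ", bond_index, " out of range", call. = FALSE)
  if (bonds$order[bond_index] != 1L)
    stop("bond ", bond_index, " is not a single bond", call. = FALSE)
  if (bonds$ring_size[bond_index] != 0L)
    stop("bond ", bond_index, " is in a ring and cannot be cleaved", call. = FALSE)
  u <- bonds$a1[bond_index]; v <- bonds$a2[bond_index]
  keep <- bonds[-bond_index, , drop = FALSE]
  n <- nrow(mol$atoms)
  comp <- integer(n)
  # BFS from u over remaining bonds
  adj <- vector("list", n)
  for (i in seq_len(nrow(keep))) {
    adj[[keep$a1[i]]] <- c(adj[[keep$a1[i]]], keep$a2[i])
    adj[[keep$a2[i]]] <- c(adj[[keep$a2[i]]], keep$a1[i])
  }
  comp[u] <- 1L; queue <- u
  while (length(queue)) {
    a <- queue[1]; queue <- queue[-1]
    for (w in adj[[a]]) if (comp[w] == 0L) { comp[w] <- 1L; queue <- c(queue, w) }
  }
  comp[comp == 0L] <- 2L
  mk <- function(side, tip) {
    idx <- which(comp == side)
    atoms <- mol$atoms[idx, , drop = FALSE]
    # the cleaved atom gains one unpaired electron and loses any stereo parity
    at_tip <- match(tip, idx)
    atoms$radical[at_tip] <- 2L
    atoms$parity[at_tip] <- 0L
    remap <- match(seq_len(n), idx)
    bsub <- keep[comp[keep$a1] == side, , drop = FALSE]
    bsub$a1 <- remap[bsub$a1]; bsub$a2 <- remap[bsub$a2]
    list(block = write_molblock(atoms, bsub, title), idx = idx)
  }
  f1 <- mk(1L, u); f2 <- mk(2L, v)
  list(blocks = c(f1$block, f2$block), atom_sets = list(f1$idx, f2$idx),
       tips = c(u, v), tip_pos = c(match(u, f1$idx), match(v, f2$idx)))
}

#' Cleave one bond homolytically
#'
#' Breaks the addressed acyclic single bond of the explicit-hydrogen graph
#' and returns the canonical SMILES of the two radical fragments.
#'
#' @param mol a `bde_mol` (from [parse_mol()]) or a SMILES string.
#' @param bond_index 1-based index into the molecule's bond table.
#' @return character vector of length two: the canonical radical SMILES, in
#'   lexicographic order.
#' @examples
#' m <- parse_mol("C")
#' cleave_bond(m, 1)  # "[CH3]" and "[H]"
#' @export
cleave_bond <- function(mol, bond_index) {
  if (is.character(mol)) mol <- parse_mol(mol)
  fr <- .fragment_blocks(mol, bond_index)
  rads <- molblocks_to_can(fr$blocks)
  sort_c(rads)
}

# Locale-independent sort (radix method compares raw bytes, i.e. C
# collation), so radical-pair ordering is stable across platforms.
sort_c <- function(x) {
  if (!length(x)) return(character(0))
  sort(x, method = "radix")
}

#' Does cleaving a bond create a new stereocenter?
#'
#' A cleavage is flagged when either radical fragment contains more
#' assignable tetrahedral stereocenters (specified or perceivable
#' unspecified) than the parent molecule contributes to that fragment's
#' atoms. Such dissociations have configuration-dependent enthalpies and are
#' excluded from unique-cleavage counts.
#'
#' @inheritParams cleave_bond
#' @return logical scalar.
#' @examples
#' m <- parse_mol("CCC(C)(C)O")  # 2-methyl-2-butanol
#' # cleaving a methyl C-H makes the quaternary carbon a stereocenter
#' @export
creates_new_stereocenter <- function(mol, bond_index) {
  if (is.character(mol)) mol <- parse_mol(mol)
  fr <- .fragment_blocks(mol, bond_index)
  parent_centers <- stereocenter_atoms(mol_to_molblock(mol))[[1]]
  # the radical atom itself is never a stereocenter (trivalent, fast inversion)
  frag_counts <- mapply(function(mask, tip) sum(mask[-tip]),
                        stereocenter_atoms(fr$blocks), fr$tip_pos)
  contrib <- vapply(fr$atom_sets, function(idx) sum(parent_centers[idx]), 0L)
  any(frag_counts > contrib)
}

#' Enumerate homolytic cleavages of a molecule
#'
#' Generates one candidate cleavage per acyclic single bond of the
#' explicit-hydrogen graph. Candidates whose fragments gain a new
#' stereocenter are marked invalid; among valid candidates, duplicates are
#' collapsed by the key (parent, sorted radical pair, bond type), and the
#' first occurrence of each key carries `is_unique = TRUE`.
#'
#' @param mol a `bde_mol`, a `molecule_record`, or a SMILES string
#'   (validated as neutral and closed-shell).
#' @return data.frame with columns `parent_smiles`, `bond_index`,
#'   `bond_type`, `radical1`, `radical2`, `is_valid`, `is_unique`.
#' @examples
#' ec <- enumerate_cleavages("C")
#' sum(ec$is_unique)  # methane has a single unique cleavage
#' @export
enumerate_cleavages <- function(mol) {
  if (is.character(mol)) mol <- molecule_record(mol)
  if (inherits(mol, "molecule_record")) mol <- mol$mol
  if (any(mol$atoms$unpaired != 0L) || any(mol$atoms$charge != 0L))
    stop("cleavage enumeration requires a neutral, closed-shell molecule",
         call. = FALSE)
  res <- enumerate_cleavages_many(list(mol))[[1]]
  res
}

# Batched enumeration over a list of bde_mol. All OpenBabel calls are pooled;
# stereo perception is only consulted for fragments containing a carbon that
# could *newly* become a stereocenter (degree 4, at most one hydrogen, not
# already perceived as a center in the parent) — for all other fragments the
# perceivable centers are a subset of the parent's, so no new center can
# appear.
enumerate_cleavages_many <- function(mols) {
  nmol <- length(mols)
  per_bond <- list()   # one record per candidate bond
  blocks <- character(0)
  stereo_need <- logical(0)
  tip_pos_all <- integer(0)
  # parent stereocenters (specified or potential) by full perception; the
  # parity column of a freshly parsed SMILES only covers specified ones
  parent_center_list <- stereocenter_atoms(vapply(mols, mol_to_molblock, ""))
  for (mi in seq_len(nmol)) {
    mol <- mols[[mi]]
    at <- mol$atoms; bd <- mol$bonds
    n <- nrow(at); nb <- nrow(bd)
    cand <- which(bd$order == 1L & bd$ring_size == 0L)
    if (!length(cand)) next
    # precomputed per-atom molblock lines (tip line is patched per fragment)
    atom_lines <- sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0%3d  0  0  0  0  0  0  0  0  0",
      at$element, at$parity)
    tip_line <- sprintf(
      "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
      at$element)
    adj <- vector("list", n)
    for (i in seq_len(nb)) {
      adj[[bd$a1[i]]] <- c(adj[[bd$a1[i]]], i)
      adj[[bd$a2[i]]] <- c(adj[[bd$a2[i]]], i)
    }
    parent_centers <- parent_center_list[[mi]]
    new_center_possible <- at$element == "C" & at$degree == 4L & at$n_h <= 1L &
      !parent_centers
    chg <- at$charge; iso <- at$isotope; rad <- at$radical
    for (bi in cand) {
      u <- bd$a1[bi]; v <- bd$a2[bi]
      # component of u with bond bi removed
      comp <- logical(n); comp[u] <- TRUE; queue <- u
      while (length(queue)) {
        a <- queue[1]; queue <- queue[-1]
        for (e in adj[[a]]) {
          if (e == bi) next
          w <- if (bd$a1[e] == a) bd$a2[e] else bd$a1[e]
          if (!comp[w]) { comp[w] <- TRUE; queue <- c(queue, w) }
        }
      }
      mk <- function(side_mask, tip) {
        idx <- which(side_mask)
        remap <- integer(n); remap[idx] <- seq_along(idx)
        bsel <- which(side_mask[bd$a1] & side_mask[bd$a2] &
                      seq_len(nb) != bi)
        al <- atom_lines[idx]
        al[remap[tip]] <- tip_line[tip]
        bl <- sprintf("%3d%3d%3d  0  0  0  0", remap[bd$a1[bsel]],
                      remap[bd$a2[bsel]], bd$order[bsel])
        prop <- sprintf("M  RAD  1%4d%4d", remap[tip], 2L)
        extra <- character(0)
        for (vset in list(list("CHG", chg), list("ISO", iso))) {
          vz <- which(vset[[2]][idx] != 0L)
          if (length(vz))
            extra <- c(extra, paste0("M  ", vset[[1]],
                                     sprintf("%3d", length(vz)),
                                     paste0(sprintf("%4d%4d", vz,
                                                    vset[[2]][idx][vz]),
                                            collapse = "")))
        }
        hdr <- sprintf("frag\n bdegnn\n\n%3d%3d  0  0  1  0  0  0  0  0999 V2000",
                       length(idx), length(bl))
        list(block = paste(c(hdr, al, bl, prop, extra, "M  END", "$$$$", ""),
                           collapse = "\n"),
             idx = idx, tip_at = remap[tip],
             need = any(new_center_possible[idx] & idx != tip))
      }
      f1 <- mk(comp, u); f2 <- mk(!comp, v)
      blocks <- c(blocks, f1$block, f2$block)
      stereo_need <- c(stereo_need, f1$need, f2$need)
      tip_pos_all <- c(tip_pos_all, f1$tip_at, f2$tip_at)
      per_bond[[length(per_bond) + 1L]] <- list(
        mol = mi, bond = bi,
        contrib = c(sum(parent_centers[f1$idx]), sum(parent_centers[f2$idx])),
        bt = bond_type_label(at$element[u], at$element[v]))
    }
  }
  frag_can <- molblocks_to_can(blocks)
  frag_count <- integer(length(blocks))
  if (any(stereo_need)) {
    masks <- stereocenter_atoms(blocks[stereo_need])
    tp <- tip_pos_all[stereo_need]
    frag_count[stereo_need] <- vapply(seq_along(masks), function(i) {
      m <- masks[[i]]
      sum(m[-tp[i]])
    }, 0L)
  }
  # assemble result tables
  res <- rep(list(data.frame(parent_smiles = character(0),
                             bond_index = integer(0), bond_type = character(0),
                             radical1 = character(0), radical2 = character(0),
                             is_valid = logical(0), is_unique = logical(0),
                             stringsAsFactors = FALSE)), nmol)
  if (!length(per_bond)) return(res)
  mol_i <- vapply(per_bond, `[[`, 0L, "mol")
  bond_i <- vapply(per_bond, `[[`, 0L, "bond")
  bt <- vapply(per_bond, `[[`, "", "bt")
  k2 <- 2L * seq_along(per_bond)
  rpair <- mapply(function(a, b) sort_c(c(a, b)),
                  frag_can[k2 - 1L], frag_can[k2], SIMPLIFY = FALSE)
  r1 <- vapply(rpair, `[`, "", 1L)
  r2 <- vapply(rpair, `[`, "", 2L)
  contrib <- do.call(rbind, lapply(per_bond, `[[`, "contrib"))
  valid <- !(frag_count[k2 - 1L] > contrib[, 1] |
             frag_count[k2] > contrib[, 2])
  for (mi in unique(mol_i)) {
    sel <- which(mol_i == mi)
    df <- data.frame(parent_smiles = mols[[mi]]$smiles,
                     bond_index = bond_i[sel], bond_type = bt[sel],
                     radical1 = r1[sel], radical2 = r2[sel],
                     is_valid = valid[sel], stringsAsFactors = FALSE)
    key <- paste(df$radical1, df$radical2, df$bond_type, sep = "|")
    df$is_unique <- df$is_valid & !duplicated(ifelse(df$is_valid, key, NA),
                                              incomparables = NA)
    res[[mi]] <- df
  }
  res
}

#' Write enumerated cleavages to CSV
#'
#' @param cleavages data.frame from [enumerate_cleavages()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_cleavages_csv <- function(cleavages, path) {
  utils::write.csv(
    cleavages[, c("parent_smiles", "bond_index", "bond_type",
                  "radical1", "radical2", "is_valid")],
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
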