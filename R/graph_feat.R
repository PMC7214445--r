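# Categorical graph representation for the network: every atom and every
# directed edge is mapped to a discrete class. Atom classes combine element,
# chirality tag, aromaticity, smallest-ring bucket, degree and hydrogen
# count; edge classes combine the ordered endpoint symbols with the ring
# bucket. A frozen vocabulary maps class keys to dense integer ids, with id 0
# reserved for keys never seen in training.

ring_bucket <- function(sz) {
  ifelse(sz == 0L, "none",
         ifelse(sz >= 6L, "6+", as.character(sz)))
}

#' Atom class key
#'
#' @param mol a `bde_mol`.
#' @param atom_index 1-based atom index (explicit-hydrogen graph).
#' @return a single string encoding (symbol, chirality, aromatic, ring
#'   bucket, degree, hydrogen-neighbor count).
#' @examples
#' atom_class_key(parse_mol("C"), 1)  # "C|none|FALSE|none|4|4"
#' @export
atom_class_key <- function(mol, atom_index) {
  a <- mol$atoms[atom_index, ]
  paste(a$element, a$chirality, a$aromatic, ring_bucket(a$ring_size),
        a$degree, a$n_h, sep = "|")
}

#' Bond (directed-edge) class key
#'
#' @param mol a `bde_mol`.
#' @param bond_index 1-based bond index.
#' @param direction 1 for a1 -> a2, 2 for a2 -> a1.
#' @return a single string encoding (start symbol, end symbol, ring bucket).
#' @examples
#' bond_class_key(parse_mol("CO"), 1, 1)  # "C|O|none"
#' @export
bond_class_key <- function(mol, bond_index, direction = 1L) {
  b <- mol$bonds[bond_index, ]
  ends <- if (direction == 1L) c(b$a1, b$a2) else c(b$a2, b$a1)
  paste(mol$atoms$element[ends[1]], mol$atoms$element[ends[2]],
        ring_bucket(b$ring_size), sep = "|")
}

#' Build the directed molecular graph for the network
#'
#' Converts a molecule into the graph consumed by the model: one node per
#' atom of the explicit-hydrogen graph and two directed edges per bond
#' (edges `2k-1` and `2k` are the two directions of bond `k`). The molecule
#' is canonicalized first, so the graph is independent of the input atom
#' order.
#'
#' @param mol a `bde_mol` or SMILES string.
#' @return a list of class `bde_graph`: `n_atoms`, `atom_keys`, `edge_src`,
#'   `edge_dst`, `edge_keys`, `bond_of_edge`, `reverse_edge`, `bond_types`,
#'   and the underlying `mol`.
#' @examples
#' g <- build_graph("C")
#' length(g$edge_src)  # 8 directed edges (4 bonds)
#' @export
build_graph <- function(mol) {
  if (is.character(mol)) mol <- parse_mol(mol)
  nb <- nrow(mol$bonds)
  atom_keys <- vapply(seq_len(nrow(mol$atoms)),
                      function(i) atom_class_key(mol, i), "")
  edge_src <- edge_dst <- integer(2L * nb)
  edge_keys <- character(2L * nb)
  if (nb > 0L) {
    edge_src[seq(1L, 2L * nb, 2L)] <- mol$bonds$a1
    edge_dst[seq(1L, 2L * nb, 2L)] <- mol$bonds$a2
    edge_src[seq(2L, 2L * nb, 2L)] <- mol$bonds$a2
    edge_dst[seq(2L, 2L * nb, 2L)] <- mol$bonds$a1
    rb <- ring_bucket(mol$bonds$ring_size)
    el <- mol$atoms$element
    edge_keys[seq(1L, 2L * nb, 2L)] <- paste(el[mol$bonds$a1], el[mol$bonds$a2], rb, sep = "|")
    edge_keys[seq(2L, 2L * nb, 2L)] <- paste(el[mol$bonds$a2], el[mol$bonds$a1], rb, sep = "|")
  }
  bond_of_edge <- rep(seq_len(nb), each = 2L)
  reverse_edge <- as.integer(bond_of_edge * 2L - (seq_len(2L * nb) %% 2L == 0L))
  bond_types <- if (nb > 0L)
    bond_type_label(mol$atoms$element[mol$bonds$a1], mol$atoms$element[mol$bonds$a2])
  else character(0)
  structure(list(n_atoms = nrow(mol$atoms), atom_keys = atom_keys,
                 edge_src = edge_src, edge_dst = edge_dst,
                 edge_keys = edge_keys, bond_of_edge = bond_of_edge,
                 reverse_edge = reverse_edge, bond_types = bond_types,
                 smiles = mol$smiles, mol = mol),
            class = "bde_graph")
}

#' Build a frozen class vocabulary from graphs
#'
#' Assigns dense integer ids (1, 2, ...) to every atom and edge class key
#' observed in the supplied graphs. Id 0 is reserved for unknown keys met at
#' inference time.
#'
#' @param graphs list of `bde_graph` objects.
#' @return a list of class `bde_vocab` with named integer maps `atom` and
#'   `bond`, and `frozen = TRUE`.
#' @export
vocab_build <- function(graphs) {
  ak <- sort_c(unique(unlist(lapply(graphs, `[[`, "atom_keys"))))
  bk <- sort_c(unique(unlist(lapply(graphs, `[[`, "edge_keys"))))
  structure(list(atom = stats::setNames(seq_along(ak), ak),
                 bond = stats::setNames(seq_along(bk), bk),
                 frozen = TRUE),
            class = "bde_vocab")
}

#' @export
print.bde_vocab <- function(x, ...) {
  cat("<bde_vocab>", length(x$atom), "atom classes,", length(x$bond),
      "edge classes\n")
  invisible(x)
}

#' Encode a graph against a vocabulary
#'
#' Resolves class keys to integer ids. Keys absent from the vocabulary map to
#' the reserved id 0 (an "unknown chemistry" embedding row).
#'
#' @param vocab a frozen `bde_vocab`.
#' @param graph a `bde_graph`.
#' @return the graph with integer vectors `atom_ids` and `edge_ids` added.
#' @export
encode_graph <- function(vocab, graph) {
  if (!inherits(vocab, "bde_vocab") || !isTRUE(vocab$frozen))
    stop("vocabulary must be built (frozen) before encoding", call. = FALSE)
  aid <- unname(vocab$atom[graph$atom_keys])
  bid <- unname(vocab$bond[graph$edge_keys])
  aid[is.na(aid)] <- 0L
  bid[is.na(bid)] <- 0L
  graph$atom_ids <- as.integer(aid)
  graph$edge_ids <- as.integer(bid)
  graph
}
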