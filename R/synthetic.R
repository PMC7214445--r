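# Synthetic molecules and ground-truth labels. The label oracle is a
# graph-local fixture, not a thermochemical model: each bond's value is a
# per-bond-type base plus a deterministic offset that depends only on the
# radius-2 environment of the bond's endpoints, plus optional Gaussian noise.
# Because the offset is radius-2 local, a network whose receptive field spans
# the molecule can represent the oracle exactly, which is what makes held-out
# error a meaningful learnability measure.

#' Oracle parameters
#'
#' @param base_bde named numeric, kcal/mol base value per bond-type label.
#'   Defaults are near chemical values so synthetic tables look plausible.
#' @param env_amplitude half-width (kcal/mol) of the uniform environment
#'   offset (default 5).
#' @param noise_sigma standard deviation (kcal/mol) of Gaussian label noise
#'   (default 0).
#' @return list of class `oracle_params`.
#' @export
oracle_params <- function(base_bde = c("C-H" = 99, "C-C" = 85, "N-H" = 93,
                                       "C-N" = 80, "C-O" = 85, "O-H" = 105,
                                       "N-O" = 55, "N-N" = 65, "O-O" = 45),
                          env_amplitude = 5, noise_sigma = 0) {
  stopifnot(all(base_bde > 0), env_amplitude >= 0, noise_sigma >= 0)
  structure(list(base_bde = base_bde, env_amplitude = env_amplitude,
                 noise_sigma = noise_sigma),
            class = "oracle_params")
}

#' 32-bit FNV-1a string hash
#'
#' Salt-free and platform-independent (pure arithmetic on UTF-8 bytes), so
#' oracle labels are reproducible across sessions and machines.
#'
#' @param s character vector.
#' @return numeric vector of hash values in \[0, 2^32).
#' @export
fnv1a32 <- function(s) {
  vapply(s, function(x) {
    h <- 2166136261
    for (b in utf8ToInt(enc2utf8(x))) {
      h <- bitwXor_dbl(h, b %% 256)
      # h * 16777619 mod 2^32 without losing precision
      lo <- h %% 65536; hi <- h %/% 65536
      h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
      h <- h %% 4294967296
    }
    h
  }, 0, USE.NAMES = FALSE)
}

# XOR for doubles holding 32-bit values (bitwXor works on <= 31-bit ints).
bitwXor_dbl <- function(a, b) {
  hi_a <- a %/% 65536; lo_a <- a %% 65536
  hi_b <- b %/% 65536; lo_b <- b %% 65536
  bitwXor(as.integer(hi_a), as.integer(hi_b)) * 65536 +
    bitwXor(as.integer(lo_a), as.integer(lo_b))
}

# Canonical radius-2 environment string of a bond: each endpoint is described
# by (element, degree) plus the sorted list of its other neighbors, each with
# bond order, (element, degree) and the sorted elements of *their* further
# neighbors. Independent of atom numbering by sorting at every level.
bond_env_string <- function(mol, bond_index) {
  b <- mol$bonds[bond_index, ]
  el <- mol$atoms$element; deg <- mol$atoms$degree
  nbrs <- function(a) {
    rows <- which(mol$bonds$a1 == a | mol$bonds$a2 == a)
    other <- ifelse(mol$bonds$a1[rows] == a, mol$bonds$a2[rows],
                    mol$bonds$a1[rows])
    list(atoms = other, orders = mol$bonds$order[rows])
  }
  shell <- function(a, excl) {
    nb <- nbrs(a)
    keep <- nb$atoms != excl
    items <- mapply(function(w, o) {
      nb2 <- nbrs(w)
      far <- nb2$atoms[nb2$atoms != a]
      paste0(o, el[w], deg[w], "[", paste(sort_c(el[far]), collapse = ""), "]")
    }, nb$atoms[keep], nb$orders[keep])
    paste0(el[a], deg[a], "{", paste(sort_c(unlist(items)), collapse = ","), "}")
  }
  sides <- sort_c(c(shell(b$a1, b$a2), shell(b$a2, b$a1)))
  paste0(b$order, ":", sides[1], "||", sides[2])
}

#' Oracle BDE label for one bond
#'
#' `base_bde[bond_type] + f(environment) + N(0, noise_sigma)`, where `f` maps
#' the FNV-1a hash of the bond's canonical radius-2 environment string
#' uniformly onto \[-env_amplitude, +env_amplitude\]. Noise (if any) is drawn
#' from the caller's RNG stream.
#'
#' @param params an `oracle_params`.
#' @param mol a `bde_mol`.
#' @param bond_index 1-based bond index (vectorized).
#' @return numeric vector of labels in kcal/mol.
#' @export
oracle_bde <- function(params, mol, bond_index) {
  bt <- bond_type_label(mol$atoms$element[mol$bonds$a1[bond_index]],
                        mol$atoms$element[mol$bonds$a2[bond_index]])
  base <- params$base_bde[bt]
  if (anyNA(base)) stop("no base value for bond type ", bt[is.na(base)][1],
                        call. = FALSE)
  env <- vapply(bond_index, function(b) bond_env_string(mol, b), "")
  u <- (fnv1a32(env) + 0.5) / 4294967296
  off <- params$env_amplitude * (2 * u - 1)
  noise <- if (params$noise_sigma > 0)
    stats::rnorm(length(bond_index), 0, params$noise_sigma) else 0
  unname(base + off + noise)
}

# ---- molecule generator -----------------------------------------------------

.valence <- c(C = 4L, N = 3L, O = 2L)

# One random heavy-atom skeleton: a valence-respecting random tree over
# {C,N,O}, optionally one ring closure and occasional double bonds. Returns a
# heavy-atom molblock (hydrogens are left implicit; the toolkit fills them).
.random_skeleton <- function(max_heavy, p_ring, p_double, element_probs) {
  k <- sample(2:max_heavy, 1L)
  els <- sample(names(element_probs), k, replace = TRUE, prob = element_probs)
  fv <- .valence[els]
  a1 <- a2 <- integer(k - 1L)
  for (i in seq_len(k)[-1]) {
    open <- which(fv[seq_len(i - 1L)] > 0L)
    if (!length(open)) return(NULL)
    j <- if (length(open) == 1L) open else sample(open, 1L)
    a1[i - 1L] <- j; a2[i - 1L] <- i
    fv[j] <- fv[j] - 1L; fv[i] <- fv[i] - 1L
  }
  order <- rep(1L, k - 1L)
  if (k >= 3L && stats::runif(1) < p_ring) {
    adj <- matrix(FALSE, k, k)
    adj[cbind(a1, a2)] <- TRUE
    adj[cbind(a2, a1)] <- TRUE
    cand <- which(outer(fv > 0, fv > 0, `&`) & !adj & upper.tri(adj),
                  arr.ind = TRUE)
    if (nrow(cand)) {
      pick <- cand[sample.int(nrow(cand), 1L), ]
      a1 <- c(a1, pick[1]); a2 <- c(a2, pick[2]); order <- c(order, 1L)
      fv[pick] <- fv[pick] - 1L
    }
  }
  for (bi in sample.int(length(a1))) {
    if (stats::runif(1) < p_double && fv[a1[bi]] > 0L && fv[a2[bi]] > 0L) {
      order[bi] <- 2L
      fv[a1[bi]] <- fv[a1[bi]] - 1L
      fv[a2[bi]] <- fv[a2[bi]] - 1L
    }
  }
  zero <- integer(k)
  write_molblock(
    data.frame(element = els, charge = zero, radical = zero,
               isotope = zero, parity = zero, stringsAsFactors = FALSE),
    data.frame(a1 = a1, a2 = a2, order = order), "gen")
}

#' Generate random valence-valid C/H/O/N molecules
#'
#' Random heavy-atom trees over {C, N, O} with optional single ring closures
#' and occasional double bonds, hydrogen-completed and canonicalized.
#' Duplicates are removed; generation is deterministic per seed.
#'
#' @param n number of unique molecules to generate.
#' @param max_heavy maximum heavy-atom count (default 9).
#' @param seed integer seed.
#' @param p_ring probability of attempting one ring closure (default 0.25).
#' @param p_double per-bond probability of upgrading to a double bond
#'   (default 0.15).
#' @param element_probs sampling weights for C, N, O.
#' @return data.frame with columns `smiles`, `n_heavy`, `nC`, `nH`, `nN`, `nO`.
#' @export
gen_molecules <- function(n, max_heavy = 9L, seed = 1L, p_ring = 0.25,
                          p_double = 0.15,
                          element_probs = c(C = 0.7, N = 0.15, O = 0.15)) {
  stopifnot(n >= 1L, max_heavy >= 2L)
  set.seed(seed)
  seen <- character(0)
  out <- list()
  tries <- 0L
  while (length(seen) < n && tries < 60L * n) {
    blocks <- character(0)
    want <- min(4L * (n - length(seen)), 4000L)
    while (length(blocks) < want && tries < 60L * n) {
      tries <- tries + 1L
      blk <- .random_skeleton(max_heavy, p_ring, p_double, element_probs)
      if (!is.null(blk)) blocks <- c(blocks, blk)
    }
    can <- molblocks_to_can(blocks)
    new <- !duplicated(can) & !(can %in% seen)
    seen <- c(seen, can[new])
  }
  if (length(seen) < n)
    stop("could not generate ", n, " unique molecules", call. = FALSE)
  seen <- seen[seq_len(n)]
  mols <- parse_mol(seen)
  if (inherits(mols, "bde_mol")) mols <- list(mols)
  el_count <- function(m, e) sum(m$atoms$element == e)
  data.frame(smiles = seen,
             n_heavy = vapply(mols, function(m) sum(m$atoms$element != "H"), 0L),
             nC = vapply(mols, el_count, 0L, "C"),
             nH = vapply(mols, el_count, 0L, "H"),
             nN = vapply(mols, el_count, 0L, "N"),
             nO = vapply(mols, el_count, 0L, "O"),
             stringsAsFactors = FALSE)
}

# ---- labeled datasets -------------------------------------------------------

#' Enumerate and oracle-label a set of molecules
#'
#' Runs cleavage enumeration over many molecules (OpenBabel calls are pooled
#' in chunks) and labels each unique valid cleavage with the environment
#' oracle. Noise, if any, is drawn from the caller's RNG stream.
#'
#' @param smiles character vector of (closed-shell) molecule SMILES.
#' @param params an `oracle_params`.
#' @param chunk molecules per enumeration chunk.
#' @return data.frame with one row per unique valid cleavage: columns of
#'   [enumerate_cleavages()] plus `bde_kcal_mol`.
#' @export
gen_cleavage_table <- function(smiles, params = oracle_params(),
                               chunk = 200L) {
  out <- list()
  for (start in seq(1L, length(smiles), chunk)) {
    idx <- start:min(start + chunk - 1L, length(smiles))
    mols <- parse_mol(smiles[idx])
    if (inherits(mols, "bde_mol")) mols <- list(mols)
    enums <- enumerate_cleavages_many(mols)
    for (i in seq_along(mols)) {
      df <- enums[[i]]
      df <- df[df$is_unique, , drop = FALSE]
      if (!nrow(df)) next
      df$bde_kcal_mol <- oracle_bde(params, mols[[i]], df$bond_index)
      out[[length(out) + 1L]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic BDE training corpus
#'
#' Generates molecules, enumerates their unique valid cleavages, labels them
#' with the environment oracle (plus noise), and splits train/dev/test *by
#' parent molecule* so no molecule contributes bonds to two splits.
#'
#' @param n_train,n_dev,n_test molecules per split (defaults 2000/250/250);
#'   every split molecule contributes at least one labeled bond.
#' @param params an `oracle_params`.
#' @param max_heavy maximum heavy atoms per molecule.
#' @param seed integer seed controlling molecules, noise and the split.
#' @return list with data.frames `train`, `dev`, `test` (columns
#'   `parent_smiles`, `bond_index`, `bond_type`, `radical1`, `radical2`,
#'   `bde_kcal_mol`).
#' @export
gen_bde_dataset <- function(n_train = 2000L, n_dev = 250L, n_test = 250L,
                            params = oracle_params(), max_heavy = 9L,
                            seed = 1L) {
  n <- n_train + n_dev + n_test
  # a few molecules have no valid unique cleavage (every acyclic single bond
  # would create a stereocenter, or there is none); they contribute no
  # labeled bonds and must not occupy a split slot, so draw a small surplus
  mols <- gen_molecules(ceiling(1.02 * n) + 10L, max_heavy = max_heavy,
                        seed = seed)
  set.seed(seed + 1L)
  tab <- gen_cleavage_table(mols$smiles, params)
  usable <- mols$smiles[mols$smiles %in% unique(tab$parent_smiles)]
  if (length(usable) < n)
    stop("too few molecules with labeled bonds for the requested split sizes",
         call. = FALSE)
  usable <- usable[seq_len(n)]
  tab <- tab[tab$parent_smiles %in% usable, , drop = FALSE]
  ord <- sample.int(n)
  split_of <- integer(n)
  split_of[ord[seq_len(n_train)]] <- 1L
  split_of[ord[n_train + seq_len(n_dev)]] <- 2L
  split_of[ord[n_train + n_dev + seq_len(n_test)]] <- 3L
  sp <- split_of[match(tab$parent_smiles, usable)]
  keep <- c("parent_smiles", "bond_index", "bond_type", "radical1",
            "radical2", "bde_kcal_mol")
  list(train = tab[sp == 1L, keep], dev = tab[sp == 2L, keep],
       test = tab[sp == 3L, keep])
}

#' Generate a synthetic site-of-metabolism dataset
#'
#' Each molecule's distinct acyclic C-H abstraction sites get oracle BDEs
#' (symmetry-equivalent hydrogens share one environment, hence one oracle
#' value, and are represented once; keeping duplicates would make the
#' perfect-label classifier unable to separate a site from its symmetric
#' twins). The labeled site is the weakest C-H bond, replaced with
#' probability `label_noise` by a uniformly chosen C-H bond (uniform
#' relabeling, so `label_noise = 1` destroys all signal).
#'
#' @param n molecules (each with at least two acyclic C-H bonds).
#' @param label_noise probability of relabeling a molecule's site.
#' @param seed integer seed.
#' @param params an `oracle_params`.
#' @param max_heavy maximum heavy atoms per molecule.
#' @return data.frame with columns `smiles`, `bond_index`, `bde_kcal_mol`,
#'   `is_site`.
#' @export
gen_metabolism_dataset <- function(n, label_noise = 0, seed = 1L,
                                   params = oracle_params(), max_heavy = 9L) {
  mols <- gen_molecules(ceiling(1.3 * n) + 10L, max_heavy = max_heavy,
                        seed = seed)
  parsed <- parse_mol(mols$smiles)
  if (inherits(parsed, "bde_mol")) parsed <- list(parsed)
  set.seed(seed + 1L)
  rows <- list()
  kept <- 0L
  for (m in parsed) {
    if (kept >= n) break
    ch <- which(m$bonds$order == 1L & m$bonds$ring_size == 0L &
                bond_type_label(m$atoms$element[m$bonds$a1],
                                m$atoms$element[m$bonds$a2]) == "C-H")
    # one bond per distinct environment: symmetric hydrogens collapse
    env <- vapply(ch, function(b) bond_env_string(m, b), "")
    ch <- ch[!duplicated(env)]
    if (length(ch) < 2L) next
    kept <- kept + 1L
    bde <- oracle_bde(params, m, ch)
    site <- ch[which.min(bde)]
    if (stats::runif(1) < label_noise) site <- ch[sample.int(length(ch), 1L)]
    rows[[kept]] <- data.frame(smiles = m$smiles, bond_index = ch,
                               bde_kcal_mol = bde, is_site = ch == site,
                               stringsAsFactors = FALSE)
  }
  if (kept < n) stop("not enough molecules with two or more C-H bonds",
                     call. = FALSE)
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Generate a synthetic sooting-tendency (YSI) dataset
#'
#' Each molecule is represented by the two radicals of its weakest (oracle)
#' acyclic single bond; its value is the sum of the two radical weights plus
#' Gaussian noise with standard deviation `noise_sigma * ysi_std` (so the
#' stored per-record uncertainty is the true noise scale when
#' `noise_sigma = 1`).
#'
#' @param n molecules to generate; molecules with no acyclic single bond are
#'   dropped, so the returned data may have slightly fewer rows.
#' @param radical_weights optional named numeric of true weights; radicals
#'   not covered get weights drawn from N(40, 15).
#' @param noise_sigma noise multiplier (0 = noiseless).
#' @param seed integer seed.
#' @param params an `oracle_params`.
#' @param max_heavy maximum heavy atoms per molecule.
#' @return list with `data` (data.frame `smiles`, `ysi`, `ysi_std`,
#'   `radical1`, `radical2`) and `weights` (named numeric of true weights).
#' @export
gen_ysi_dataset <- function(n, radical_weights = NULL, noise_sigma = 0,
                            seed = 1L, params = oracle_params(),
                            max_heavy = 9L) {
  mols <- gen_molecules(n, max_heavy = max_heavy, seed = seed)
  parsed <- parse_mol(mols$smiles)
  if (inherits(parsed, "bde_mol")) parsed <- list(parsed)
  # a molecule with no acyclic single bond has no weakest cleavage: skip it
  has_bond <- vapply(parsed, function(m)
    any(m$bonds$order == 1L & m$bonds$ring_size == 0L), NA)
  parsed <- parsed[has_bond]
  smiles <- mols$smiles[has_bond]
  n <- length(parsed)
  if (n < 2L) stop("too few molecules with a cleavable bond", call. = FALSE)
  set.seed(seed + 1L)
  blocks <- character(0)
  for (m in parsed) {
    cand <- which(m$bonds$order == 1L & m$bonds$ring_size == 0L)
    bde <- oracle_bde(params, m, cand)
    weakest <- cand[which.min(bde)]
    blocks <- c(blocks, .fragment_blocks(m, weakest)$blocks)
  }
  rads <- molblocks_to_can(blocks)
  r1 <- character(n); r2 <- character(n)
  for (i in seq_len(n)) {
    pair <- sort_c(rads[c(2L * i - 1L, 2L * i)])
    r1[i] <- pair[1]; r2[i] <- pair[2]
  }
  uniq <- sort_c(unique(c(r1, r2)))
  w <- stats::setNames(stats::rnorm(length(uniq), 40, 15), uniq)
  if (!is.null(radical_weights))
    w[names(radical_weights)] <- radical_weights
  sig <- stats::runif(n, 0.5, 2)
  ysi <- unname(w[r1] + w[r2]) + stats::rnorm(n, 0, noise_sigma * sig)
  list(data = data.frame(smiles = smiles, ysi = ysi, ysi_std = sig,
                         radical1 = r1, radical2 = r2,
                         stringsAsFactors = FALSE),
       weights = w)
}
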