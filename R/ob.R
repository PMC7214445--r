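# Low-level OpenBabel plumbing: format conversion, SMILES validation and
# V2000 molblock reading/writing. Everything chemistry-aware above this file
# works on the parsed molecule structure returned by parse_molblock().

# Characters permitted in a C/H/O/N SMILES (incl. bracket-atom syntax).
.smiles_charset <- "^[A-Za-z0-9@+\\-\\[\\]()=#:/\\\\%.]+$"

#' Validate SMILES syntax
#'
#' Cheap structural checks applied before handing a string to the chemistry
#' toolkit, which silently repairs some malformed inputs (an unbalanced
#' parenthesis, for instance). Checks: non-empty, no whitespace, allowed
#' character set, balanced `()` and `[]`, and paired ring-closure digits.
#'
#' @param smiles character vector of SMILES strings.
#' @return invisibly `TRUE`; stops with an error naming the first offending
#'   input otherwise.
#' @keywords internal
validate_smiles_syntax <- function(smiles) {
  for (s in smiles) {
    fail <- function(why) stop("invalid SMILES '", s, "': ", why, call. = FALSE)
    if (!is.character(s) || length(s) != 1L || is.na(s) || !nzchar(s))
      fail("empty or not a string")
    if (grepl("[[:space:]]", s)) fail("contains whitespace")
    if (!grepl(.smiles_charset, s, perl = TRUE)) fail("illegal character")
    chars <- strsplit(s, "")[[1]]
    if (cumsum((chars == "(") - (chars == ")"))[length(chars)] != 0 ||
        any(cumsum((chars == "(") - (chars == ")")) < 0))
      fail("unbalanced parentheses")
    depth <- cumsum((chars == "[") - (chars == "]"))
    if (depth[length(chars)] != 0 || any(depth < 0) || any(depth > 1))
      fail("unbalanced brackets")
    # ring closure digits outside brackets must pair up
    outside <- depth == 0 & chars %in% as.character(0:9)
    # drop digits that belong to %nn two-digit closures: treat %nn as one token
    toks <- regmatches(s, gregexpr("%[0-9]{2}|[0-9]", s))[[1]]
    # recount only digits outside brackets
    stripped <- gsub("\\[[^]]*\\]", "", s)
    toks <- regmatches(stripped, gregexpr("%[0-9]{2}|[0-9]", stripped))[[1]]
    if (length(toks) %% 2L != 0L) fail("unpaired ring-closure digit")
    tab <- table(toks)
    if (any(tab %% 2L != 0L)) fail("unpaired ring-closure digit")
  }
  invisible(TRUE)
}

# One call into OpenBabel. `source` is the full multi-record text.
ob_convert <- function(from, to, source, add_h = FALSE) {
  opts <- if (add_h) data.frame(names = "h", args = "")
          else data.frame(names = character(0), args = character(0))
  ChemmineOB::convertFormat(from, to, source, options = opts)
}

#' Canonicalize SMILES strings
#'
#' Returns the isomeric canonical SMILES for each input, as produced by
#' OpenBabel's canonical SMILES writer (stereo descriptors and isotopes are
#' preserved). Canonicalization is idempotent: applying it to its own output
#' returns the same string.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES, same length as the input.
#' @examples
#' canonicalize_smiles("OCC")          # same string as canonicalize_smiles("CCO")
#' canonicalize_smiles(c("C", "N"))
#' @export
canonicalize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1L)
  validate_smiles_syntax(smiles)
  titles <- paste0("m", seq_along(smiles))
  src <- paste0(smiles, "\t", titles, "\n", collapse = "")
  out <- ob_convert("SMI", "CAN", src)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) p[2], "")
  can <- vapply(parts, function(p) p[1], "")
  res <- can[match(titles, got)]
  if (anyNA(res) || any(!nzchar(res))) {
    bad <- smiles[is.na(res) | !nzchar(res)][1]
    stop("SMILES parse error for input '", bad, "'", call. = FALSE)
  }
  res
}

# ---- V2000 molblock I/O -----------------------------------------------------

# Parse one V2000 molblock (character scalar, no trailing $$$$ needed) into
# list(title, atoms, bonds). atoms: element, charge, radical, isotope, parity.
parse_molblock <- function(text) {
  ln <- strsplit(text, "\n", fixed = TRUE)[[1]]
  if (length(ln) < 4L) stop("truncated molblock", call. = FALSE)
  counts <- ln[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  if (is.na(na) || is.na(nb)) stop("bad molblock counts line", call. = FALSE)
  element <- character(na); parity <- integer(na)
  if (na > 0L) {
    al <- ln[4L + seq_len(na)]
    element <- trimws(substr(al, 32, 34))
    parity  <- suppressWarnings(as.integer(substr(al, 40, 42)))
    parity[is.na(parity)] <- 0L
  }
  a1 <- a2 <- order <- integer(nb)
  if (nb > 0L) {
    bl <- ln[4L + na + seq_len(nb)]
    a1 <- as.integer(substr(bl, 1, 3))
    a2 <- as.integer(substr(bl, 4, 6))
    order <- as.integer(substr(bl, 7, 9))
  }
  charge <- integer(na); radical <- integer(na); isotope <- integer(na)
  for (l in ln[-seq_len(4L + na + nb)]) {
    key <- substr(l, 1, 6)
    if (key %in% c("M  CHG", "M  RAD", "M  ISO")) {
      tok <- as.integer(strsplit(trimws(substr(l, 7, nchar(l))), "[[:space:]]+")[[1]])
      n <- tok[1]
      for (i in seq_len(n)) {
        at <- tok[2L * i]; val <- tok[2L * i + 1L]
        if (key == "M  CHG") charge[at] <- val
        if (key == "M  RAD") radical[at] <- val
        if (key == "M  ISO") isotope[at] <- val
      }
    }
  }
  list(title = ln[1],
       atoms = data.frame(element = element, charge = charge,
                          radical = radical, isotope = isotope,
                          parity = parity, stringsAsFactors = FALSE),
       bonds = data.frame(a1 = a1, a2 = a2, order = order))
}

# Split multi-record SDF text into molblock strings, in order.
split_sdf <- function(text) {
  recs <- strsplit(text, "$$$$\n", fixed = TRUE)[[1]]
  recs <- recs[vapply(recs, function(r) grepl("V2000", r, fixed = TRUE), NA)]
  # strip possible leading newline left by the split
  sub("^\n+", "", recs)
}

# Write a V2000 molblock for an atom/bond table pair. `atoms` needs columns
# element, charge, radical, isotope, parity (parity written into the atom
# block so OpenBabel re-perceives assigned stereo on 0D input).
write_molblock <- function(atoms, bonds, title = "mol") {
  na <- nrow(atoms); nb <- nrow(bonds)
  hdr <- sprintf("%s\n bdegnn\n\n%3d%3d  0  0  1  0  0  0  0  0999 V2000",
                 title, na, nb)
  al <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0%3d  0  0  0  0  0  0  0  0  0",
                atoms$element, atoms$parity)
  bl <- if (nb > 0L) sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
        else character(0)
  mline <- function(key, val) {
    idx <- which(val != 0L)
    out <- character(0)
    while (length(idx)) {
      chunk <- idx[seq_len(min(8L, length(idx)))]
      idx <- idx[-seq_len(min(8L, length(idx)))]
      out <- c(out, paste0("M  ", key, sprintf("%3d", length(chunk)),
                           paste0(sprintf("%4d%4d", chunk, val[chunk]), collapse = "")))
    }
    out
  }
  prop <- c(mline("CHG", atoms$charge), mline("RAD", atoms$radical),
            mline("ISO", atoms$isotope))
  paste(c(hdr, al, bl, prop, "M  END", "$$$$", ""), collapse = "\n")
}

# Session caches for expensive per-fragment OpenBabel results, keyed by the
# molblock body (identical fragments recur constantly during enumeration).
.ob_cache <- new.env(parent = emptyenv())
.ob_cache$can <- new.env(parent = emptyenv())
.ob_cache$ster <- new.env(parent = emptyenv())

# Batch: molblocks (character vector) -> canonical SMILES (same order),
# memoized across calls.
molblocks_to_can <- function(blocks) {
  if (!length(blocks)) return(character(0))
  key <- vapply(blocks, function(b) sub("^[^\n]*\n", "", b), "",
                USE.NAMES = FALSE)
  res <- character(length(blocks))
  hit <- vapply(key, function(k) !is.null(.ob_cache$can[[k]]), NA)
  if (any(hit))
    res[hit] <- vapply(key[hit], function(k) .ob_cache$can[[k]], "")
  if (all(hit)) return(res)
  fresh <- .molblocks_to_can_nocache(blocks[!hit])
  res[!hit] <- fresh
  kf <- key[!hit]
  for (i in seq_along(fresh)) .ob_cache$can[[kf[i]]] <- fresh[i]
  res
}

.molblocks_to_can_nocache <- function(blocks) {
  titles <- paste0("f", seq_along(blocks))
  blocks <- mapply(function(b, t) sub("^[^\n]*", t, b), blocks, titles)
  out <- ob_convert("SDF", "CAN", paste(blocks, collapse = ""))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  got <- vapply(parts, function(p) p[2], "")
  can <- vapply(parts, function(p) p[1], "")
  res <- can[match(titles, got)]
  if (anyNA(res)) stop("OpenBabel failed to canonicalize a fragment", call. = FALSE)
  res
}

# Batch: molblocks -> re-perceived molblocks (stereo parity filled in).
molblocks_reperceive <- function(blocks) {
  if (!length(blocks)) return(character(0))
  out <- ob_convert("SDF", "SDF", paste(blocks, collapse = ""))
  recs <- split_sdf(out)
  if (length(recs) != length(blocks))
    stop("OpenBabel dropped a record during stereo perception", call. = FALSE)
  recs
}
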