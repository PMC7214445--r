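# Trust assessment for predictions: project the final-layer bond embeddings
# of the training corpus to a low-dimensional space with PCA and look up the
# nearest training bonds for any query bond. Predictions whose neighbors are
# chemically similar bonds with consistent BDEs are more trustworthy.

#' Build a bond-embedding nearest-neighbor index
#'
#' Embeds every listed training bond with the model (final message-passing
#' layer edge state), fits a principal component analysis, and stores the
#' projected corpus with per-row references.
#'
#' @param model a trained `bde_model`.
#' @param training_bonds data.frame with columns `parent_smiles`,
#'   `bond_index`, `bde_kcal_mol`.
#' @param proj_dim projection dimension (default 10).
#' @return a list of class `bde_index`: `rotation`, `center`, `corpus`
#'   (projected embeddings), `refs`, `var_explained`.
#' @export
build_index <- function(model, training_bonds, proj_dim = 10L) {
  stopifnot(nrow(training_bonds) >= 1L)
  if (nrow(training_bonds) < proj_dim)
    stop("corpus (", nrow(training_bonds), " bonds) smaller than projection ",
         "dimension ", proj_dim, call. = FALSE)
  smiles <- unique(training_bonds$parent_smiles)
  emb <- matrix(NA_real_, nrow(training_bonds), model$config$state_dim)
  for (s in smiles) {
    p <- predict_bde(model, s)
    e <- attr(p, "embeddings")
    rows <- which(training_bonds$parent_smiles == s)
    emb[rows, ] <- e[training_bonds$bond_index[rows], , drop = FALSE]
  }
  pca <- stats::prcomp(emb, center = TRUE, scale. = FALSE, rank. = proj_dim)
  ve <- sum(pca$sdev[seq_len(proj_dim)]^2) / sum(pca$sdev^2)
  structure(list(rotation = pca$rotation, center = pca$center,
                 corpus = pca$x[, seq_len(proj_dim), drop = FALSE],
                 refs = training_bonds[, c("parent_smiles", "bond_index",
                                           "bde_kcal_mol")],
                 var_explained = ve, proj_dim = as.integer(proj_dim)),
            class = "bde_index")
}

#' @export
print.bde_index <- function(x, ...) {
  cat("<bde_index>", nrow(x$corpus), "bonds,", x$proj_dim,
      sprintf("components (%.1f%% variance)\n", 100 * x$var_explained))
  invisible(x)
}

#' Nearest training bonds for a query bond
#'
#' Euclidean distances in the PCA-projected embedding space, ascending; ties
#' broken by corpus order.
#'
#' @param index a `bde_index`.
#' @param model the `bde_model` the index was built with.
#' @param query_smiles SMILES of the query molecule.
#' @param query_bond 1-based bond index in the query molecule.
#' @param k number of neighbors (default 10).
#' @return data.frame with columns `rank`, `parent_smiles`, `bond_index`,
#'   `bde_kcal_mol`, `distance`.
#' @export
nearest_bonds <- function(index, model, query_smiles, query_bond, k = 10L) {
  if (k > nrow(index$corpus))
    stop("k = ", k, " exceeds corpus size ", nrow(index$corpus), call. = FALSE)
  p <- predict_bde(model, query_smiles)
  if (query_bond < 1L || query_bond > nrow(p))
    stop("query bond index out of range", call. = FALSE)
  e <- attr(p, "embeddings")[query_bond, ]
  q <- as.numeric((e - index$center) %*% index$rotation[, seq_len(index$proj_dim)])
  d2 <- rowSums(sweep(index$corpus, 2L, q)^2)
  ord <- order(d2)[seq_len(k)]     # order() is stable: ties keep corpus order
  out <- index$refs[ord, , drop = FALSE]
  out$distance <- sqrt(d2[ord])
  out <- cbind(rank = seq_len(k), out)
  rownames(out) <- NULL
  out
}
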