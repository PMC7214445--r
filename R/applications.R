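# Downstream models driven by per-bond BDEs: a weakest-bond site-of-
# metabolism classifier evaluated by a tolerance-sweep ROC, and the
# radical-fragment sooting-tendency (YSI) regression.

#' Weakest bond of a molecule
#'
#' @param bdes named numeric vector: bond id -> BDE (kcal/mol).
#' @return list with `bond` (integer id) and `bde`. Ties are broken by the
#'   smallest bond id.
#' @examples
#' weakest_bond(c("1" = 100, "2" = 90))
#' @export
weakest_bond <- function(bdes) {
  if (!length(bdes)) stop("empty BDE map", call. = FALSE)
  ids <- as.integer(names(bdes))
  if (anyNA(ids)) ids <- seq_along(bdes)
  ord <- order(bdes, ids)
  list(bond = ids[ord[1]], bde = unname(bdes[ord[1]]))
}

#' Candidate oxidation sites within an energy tolerance
#'
#' All bonds whose BDE lies within `tol` kcal/mol of the molecule's minimum.
#' `tol = 0` returns exactly the argmin set.
#'
#' @param bdes named numeric vector: bond id -> BDE.
#' @param tol tolerance in kcal/mol (>= 0).
#' @return integer vector of bond ids.
#' @examples
#' candidate_sites(c("1" = 100, "2" = 90, "3" = 91), 1.5)  # bonds 2 and 3
#' @export
candidate_sites <- function(bdes, tol) {
  stopifnot(tol >= 0, length(bdes) >= 1L)
  ids <- as.integer(names(bdes))
  if (anyNA(ids)) ids <- seq_along(bdes)
  ids[bdes <= min(bdes) + tol]
}

#' ROC of the weakest-bond site classifier over a tolerance sweep
#'
#' Bonds are pooled across molecules. For each tolerance on a grid of all
#' distinct within-molecule BDE gaps, a bond is predicted positive iff its
#' BDE is within the tolerance of its own molecule's minimum; the pooled
#' confusion matrix gives one ROC point. AUC is the trapezoid area with
#' endpoints (0,0) and (1,1). Only within-molecule BDE differences matter, so
#' the curve is invariant to shifting all BDEs of one molecule by a constant.
#'
#' @param dataset data.frame with columns `smiles`, `bond_index`,
#'   `bde_kcal_mol`, `is_site` (logical); every molecule needs at least one
#'   site.
#' @return a list of class `bde_roc`: `curve` (data.frame of tolerance, tpr,
#'   fpr, precision, recall) and `auc`.
#' @export
roc_from_tolerance_sweep <- function(dataset) {
  stopifnot(all(c("smiles", "bond_index", "bde_kcal_mol", "is_site")
                %in% names(dataset)))
  n_sites <- tapply(dataset$is_site, dataset$smiles, sum)
  if (any(n_sites == 0L))
    stop("molecule without a labeled site: ",
         names(n_sites)[n_sites == 0L][1], call. = FALSE)
  rel <- dataset$bde_kcal_mol -
    stats::ave(dataset$bde_kcal_mol, dataset$smiles, FUN = min)
  tau <- sort(unique(rel))
  pos <- dataset$is_site
  P <- sum(pos); N <- sum(!pos)
  tpr <- fpr <- prec <- numeric(length(tau))
  for (i in seq_along(tau)) {
    pred <- rel <= tau[i]
    tp <- sum(pred & pos); fp <- sum(pred & !pos)
    tpr[i] <- tp / P
    fpr[i] <- if (N > 0L) fp / N else 0
    prec[i] <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  }
  curve <- data.frame(tolerance = tau, tpr = tpr, fpr = fpr,
                      precision = prec, recall = tpr)
  x <- c(0, fpr, 1); y <- c(0, tpr, 1)
  auc <- sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  structure(list(curve = curve, auc = auc), class = "bde_roc")
}

#' @export
print.bde_roc <- function(x, ...) {
  cat("<bde_roc>", nrow(x$curve), "tolerance points, AUC =",
      round(x$auc, 4), "\n")
  invisible(x)
}

# Design matrix of radical counts for the YSI regression: one row per
# molecule, one column per kept radical; entries are how many of the
# molecule's two fragments are that radical (2 for symmetric cleavages).
.ysi_design <- function(r1, r2, radicals) {
  X <- matrix(0, length(r1), length(radicals),
              dimnames = list(NULL, radicals))
  for (i in seq_along(r1)) {
    X[i, r1[i]] <- X[i, r1[i]] + 1
    X[i, r2[i]] <- X[i, r2[i]] + 1
  }
  X
}

#' Fit the radical-fragment YSI model
#'
#' Weighted least squares of measured values on the two weakest-bond
#' radicals of each molecule, weighted by `1 / ysi_std^2`, with no intercept:
#' a molecule's value is the sum of its two radical weights. Radicals seen in
#' fewer than two molecules are dropped, and molecules containing a dropped
#' radical are excluded (with a warning).
#'
#' @param dataset data.frame with columns `smiles`, `ysi`, `ysi_std`,
#'   `radical1`, `radical2`.
#' @param min_support minimum number of molecules a radical must appear in
#'   (default 2).
#' @return a list of class `ysi_model`: `weights` (named numeric),
#'   `se` (analytic standard errors from the weighted normal equations),
#'   `kept_radicals`, `n_used`, `residual_norm` (weighted RSS), `dropped`.
#' @export
fit_ysi <- function(dataset, min_support = 2L) {
  stopifnot(all(c("smiles", "ysi", "ysi_std", "radical1", "radical2")
                %in% names(dataset)), all(dataset$ysi_std > 0))
  support <- table(c(dataset$radical1, dataset$radical2))
  kept <- names(support)[support >= min_support]
  use <- dataset$radical1 %in% kept & dataset$radical2 %in% kept
  if (!all(use))
    warning(sum(!use), " molecule(s) dropped: weakest-bond radical seen in ",
            "fewer than ", min_support, " molecules", call. = FALSE)
  d <- dataset[use, , drop = FALSE]
  kept <- sort_c(intersect(kept, unique(c(d$radical1, d$radical2))))
  if (!nrow(d) || !length(kept))
    stop("no molecules left after dropping unsupported radicals", call. = FALSE)
  X <- .ysi_design(d$radical1, d$radical2, kept)
  w <- 1 / d$ysi_std^2
  fit <- stats::lm.wfit(X, d$ysi, w)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[is.na(fit$coefficients)]
    stop("rank-deficient radical design; aliased radicals: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  coef <- fit$coefficients
  XtWX <- crossprod(X * sqrt(w))
  se <- sqrt(diag(solve(XtWX)))
  res <- d$ysi - as.numeric(X %*% coef)
  structure(list(weights = stats::setNames(as.numeric(coef), kept),
                 se = stats::setNames(as.numeric(se), kept),
                 kept_radicals = kept, n_used = nrow(d),
                 residual_norm = sum(w * res^2),
                 dropped = dataset$smiles[!use]),
            class = "ysi_model")
}

#' @export
print.ysi_model <- function(x, ...) {
  cat("<ysi_model>", length(x$weights), "radical weights fitted on",
      x$n_used, "molecules; weighted RSS =", signif(x$residual_norm, 4), "\n")
  invisible(x)
}

#' Predict with a fitted YSI model
#'
#' @param object a `ysi_model`.
#' @param newdata data.frame with columns `radical1`, `radical2`.
#' @param ... unused.
#' @return numeric predictions (NA where a radical has no fitted weight).
#' @export
predict.ysi_model <- function(object, newdata, ...) {
  w <- object$weights
  unname(w[newdata$radical1] + w[newdata$radical2])
}

#' Leave-one-out cross-validation of the YSI model
#'
#' Each molecule is withheld in turn; the model is refitted on the remainder
#' and used to predict the withheld value. Folds where the held-out
#' molecule's radicals lose their support (or the fit fails) are marked
#' unavailable.
#'
#' @param dataset as for [fit_ysi()].
#' @param min_support as for [fit_ysi()].
#' @return list with `predictions` (data.frame of `smiles`, `ysi`,
#'   `predicted`, `available`) and `weighted_loss`
#'   (sum of `(pred - ysi)^2 / ysi_std^2` over available folds).
#' @export
loo_cv_ysi <- function(dataset, min_support = 2L) {
  n <- nrow(dataset)
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fold <- dataset[-i, , drop = FALSE]
    fit <- tryCatch(
      suppressWarnings(fit_ysi(fold, min_support = min_support)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (!(dataset$radical1[i] %in% fit$kept_radicals) ||
        !(dataset$radical2[i] %in% fit$kept_radicals)) next
    pred[i] <- predict(fit, dataset[i, , drop = FALSE])
  }
  avail <- !is.na(pred)
  loss <- sum((pred[avail] - dataset$ysi[avail])^2 / dataset$ysi_std[avail]^2)
  list(predictions = data.frame(smiles = dataset$smiles, ysi = dataset$ysi,
                                predicted = pred, available = avail),
       weighted_loss = loss)
}
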