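# Weakest-bond site classifier and the radical-fragment YSI regression.

test_that("weakest bond and candidate sites follow the tolerance contract", {
  expect_identical(weakest_bond(c("1" = 100, "2" = 90))$bond, 2L)
  expect_identical(weakest_bond(c("3" = 5, "7" = 5, "9" = 5))$bond, 3L) # tie
  expect_identical(weakest_bond(c("4" = 42))$bond, 4L)
  expect_error(weakest_bond(numeric(0)), "empty")

  b <- c("1" = 100, "2" = 90, "3" = 91)
  expect_setequal(candidate_sites(b, 1.5), c(2L, 3L))
  expect_identical(candidate_sites(b, 0), 2L)
  expect_setequal(candidate_sites(b, Inf), c(1L, 2L, 3L))
  # monotone in the tolerance
  taus <- c(0, 0.5, 1, 2, 5, 20)
  for (i in seq_len(length(taus) - 1L)) {
    expect_true(all(candidate_sites(b, taus[i]) %in%
                    candidate_sites(b, taus[i + 1L])))
  }
})

.mk_metab <- function(bdes_list, sites) {
  do.call(rbind, lapply(seq_along(bdes_list), function(i) {
    data.frame(smiles = paste0("mol", i),
               bond_index = seq_along(bdes_list[[i]]),
               bde_kcal_mol = bdes_list[[i]],
               is_site = seq_along(bdes_list[[i]]) %in% sites[[i]])
  }))
}

test_that("tolerance-sweep ROC reaches AUC 1 on separable labels", {
  d <- .mk_metab(list(c(90, 95, 100), c(88, 93), c(99, 91, 95, 97)),
                 list(1L, 1L, 2L))   # site is always the weakest bond
  roc <- roc_from_tolerance_sweep(d)
  expect_equal(roc$auc, 1.0)
  expect_true(all(diff(roc$curve$tpr) >= 0))
  expect_true(all(diff(roc$curve$fpr) >= 0))
  # single molecule: TPR hits 1 at FPR 0 for tolerances below the first gap
  d1 <- .mk_metab(list(c(90, 95, 100)), list(1L))
  r1 <- roc_from_tolerance_sweep(d1)
  expect_equal(r1$curve$tpr[1], 1)
  expect_equal(r1$curve$fpr[1], 0)
  expect_error(roc_from_tolerance_sweep(.mk_metab(list(c(1, 2)), list(integer(0)))),
               "without a labeled site")
})

test_that("ROC is invariant to per-molecule BDE shifts", {
  set.seed(9)
  bdes <- replicate(20, 90 + rnorm(5, 0, 3), simplify = FALSE)
  sites <- lapply(bdes, function(b) sample(seq_along(b), 1L))
  d0 <- .mk_metab(bdes, sites)
  shifted <- lapply(seq_along(bdes), function(i) bdes[[i]] + 100 * i)
  d1 <- .mk_metab(shifted, sites)
  expect_equal(roc_from_tolerance_sweep(d0)$auc,
               roc_from_tolerance_sweep(d1)$auc)
})

test_that("pooled ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  bdes <- replicate(40, 90 + rnorm(6, 0, 4), simplify = FALSE)
  sites <- lapply(bdes, function(b) sample(seq_along(b), 1L))
  d <- .mk_metab(bdes, sites)
  roc <- roc_from_tolerance_sweep(d)
  # score each bond by its within-molecule gap to the minimum (negated so
  # larger = more likely a site) and hand it to pROC
  rel <- d$bde_kcal_mol - stats::ave(d$bde_kcal_mol, d$smiles, FUN = min)
  ref <- suppressMessages(pROC::auc(pROC::roc(d$is_site, -rel, quiet = TRUE)))
  expect_equal(roc$auc, as.numeric(ref), tolerance = 1e-9)
})

.mk_ysi <- function(n_mol, seed, sigma_noise = 0, n_rad = 8) {
  set.seed(seed)
  radicals <- paste0("[R", seq_len(n_rad), "]")
  w <- stats::setNames(rnorm(n_rad, 40, 12), radicals)
  r1 <- sample(radicals, n_mol, TRUE)
  r2 <- sample(radicals, n_mol, TRUE)
  sig <- runif(n_mol, 0.5, 2)
  ysi <- w[r1] + w[r2] + rnorm(n_mol, 0, sigma_noise * sig)
  list(data = data.frame(smiles = paste0("m", seq_len(n_mol)),
                         ysi = unname(ysi), ysi_std = sig,
                         radical1 = r1, radical2 = r2,
                         stringsAsFactors = FALSE),
       weights = w)
}

test_that("noiseless YSI weights are recovered exactly", {
  syn <- .mk_ysi(60, seed = 11)
  fit <- suppressWarnings(fit_ysi(syn$data))
  expect_true(all(abs(fit$weights - syn$weights[fit$kept_radicals]) < 1e-8))
  # symmetric molecule: count-2 column
  sym <- data.frame(smiles = c("s1", "s2", "s3"),
                    ysi = c(2 * 30, 30 + 50, 2 * 50), ysi_std = 1,
                    radical1 = c("[A]", "[A]", "[B]"),
                    radical2 = c("[A]", "[B]", "[B]"))
  f2 <- fit_ysi(sym)
  expect_equal(unname(f2$weights[c("[A]", "[B]")]), c(30, 50))
})

test_that("WLS fit equals the normal-equations solution", {
  syn <- .mk_ysi(25, seed = 3, sigma_noise = 1)
  fit <- suppressWarnings(fit_ysi(syn$data))
  d <- syn$data[syn$data$radical1 %in% fit$kept_radicals &
                syn$data$radical2 %in% fit$kept_radicals, ]
  X <- matrix(0, nrow(d), length(fit$kept_radicals),
              dimnames = list(NULL, fit$kept_radicals))
  for (i in seq_len(nrow(d))) {
    X[i, d$radical1[i]] <- X[i, d$radical1[i]] + 1
    X[i, d$radical2[i]] <- X[i, d$radical2[i]] + 1
  }
  W <- diag(1 / d$ysi_std^2)
  ref <- solve(t(X) %*% W %*% X, t(X) %*% W %*% d$ysi)
  expect_equal(unname(fit$weights), as.numeric(ref), tolerance = 1e-10)
})

test_that("under-supported radicals are dropped with their molecules", {
  d <- data.frame(smiles = paste0("m", 1:5),
                  ysi = c(60, 80, 100, 80, 95), ysi_std = 1,
                  radical1 = c("[A]", "[A]", "[B]", "[B]", "[Z]"),
                  radical2 = c("[A]", "[B]", "[B]", "[A]", "[A]"))
  expect_warning(fit <- fit_ysi(d), "dropped")
  expect_false("[Z]" %in% fit$kept_radicals)
  expect_identical(fit$n_used, 4L)
  expect_equal(unname(fit$weights[c("[A]", "[B]")]), c(30, 50))
})

test_that("aliased radicals raise a rank-deficiency error", {
  # A and B always co-occur: only their sum is identified
  d <- data.frame(smiles = paste0("m", 1:4),
                  ysi = c(80, 80, 80, 80), ysi_std = 1,
                  radical1 = c("[A]", "[A]", "[B]", "[B]"),
                  radical2 = c("[B]", "[B]", "[A]", "[A]"))
  expect_error(fit_ysi(d), "rank-deficient")
})

test_that("noisy recovery stays within analytic standard errors", {
  # over seeds, ~95% of fitted weights should fall within 3 SE of truth
  hits <- 0L; total <- 0L
  for (seed in 1:20) {
    syn <- .mk_ysi(50, seed = seed, sigma_noise = 1)
    fit <- suppressWarnings(fit_ysi(syn$data))
    dev <- abs(fit$weights - syn$weights[fit$kept_radicals]) / fit$se
    hits <- hits + sum(dev <= 3)
    total <- total + length(dev)
  }
  expect_gte(hits / total, 0.95)
})

test_that("leave-one-out CV is exact on noiseless data and counts folds", {
  syn <- .mk_ysi(40, seed = 21)
  cv <- suppressWarnings(loo_cv_ysi(syn$data))
  expect_identical(nrow(cv$predictions), 40L)
  avail <- cv$predictions$available
  expect_true(any(avail))
  expect_true(all(abs(cv$predictions$predicted[avail] -
                      cv$predictions$ysi[avail]) < 1e-6))
  expect_equal(cv$weighted_loss, 0, tolerance = 1e-10)
  # loss grows with noise on matched seeds
  losses <- vapply(c(0.3, 1, 3), function(s) {
    syn <- .mk_ysi(40, seed = 5, sigma_noise = s)
    suppressWarnings(loo_cv_ysi(syn$data))$weighted_loss
  }, 0)
  expect_true(losses[1] < losses[3])
})
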