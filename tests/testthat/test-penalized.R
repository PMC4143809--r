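make_gene_fixture <- function(seed = 61, n = 400, p = 6, beta = 0.6,
                              causal = 2L) {
  set.seed(seed)
  G <- matrix(rbinom(n * p, 2, 0.3), n, p,
              dimnames = list(NULL, sprintf("snp%d", seq_len(p))))
  L <- exp(cbind(log(2) + beta * G[, causal], log(2),
                 log(2) - beta * G[, causal]))
  list(Y = rdirichlet(n, L), G = G)
}

test_that("the penalized objective evaluates penalty terms exactly", {
  fx <- make_gene_fixture(seed = 62, n = 100, p = 2, beta = 0)
  eta <- rbind(c(0.7, 0.7, 0.7), c(3, 4, 0), c(0, 0, 0))
  G <- cbind(1, scale(fx$G))
  # kappa = 0: exactly the unpenalized log-likelihood
  expect_identical(penalized_objective(eta, fx$Y, G, c = 0.5, kappa = 0),
                   dirichlet_loglik(fx$Y, exp(G %*% eta)))
  # ridge block (3,4,0): squared group norm 25
  base <- dirichlet_loglik(fx$Y, exp(G %*% eta))
  expect_equal(penalized_objective(eta, fx$Y, G, c = 1, kappa = 1),
               base - 25, tolerance = 1e-10)
  # lasso with kappa = 2: 2 * |3|+|4| = 14
  expect_equal(penalized_objective(eta, fx$Y, G, c = 0, kappa = 2),
               base - 14, tolerance = 1e-10)
  expect_error(penalized_objective(eta, fx$Y, G, c = 0, kappa = -1),
               "nonnegative")
})

test_that("kappa = 0 refit equals the unpenalized MLE", {
  fx <- make_gene_fixture(seed = 63)
  f0 <- dirichreg_penalized(fx$Y, fx$G, c = 0.5, kappa = 0)
  fu <- dirichreg(fx$Y, cbind("(Intercept)" = 1, scale(fx$G)))
  expect_equal(f0$objective, fu$logLik, tolerance = 1e-8)
  expect_equal(unname(f0$eta), unname(fu$coef), tolerance = 1e-5)
  # kappa = 0 selects everything (generic MLE has no exact zeros)
  expect_identical(count_selected(f0), 6L * 3L)
})

test_that("the elastic-net prox matches brute-force scalar minimization", {
  # prox_t(x) = argmin_z (z - x)^2 / (2t) + c*kappa*z^2 + (1-c)*kappa*|z|
  grid <- seq(-6, 6, by = 1e-4)
  for (cc in c(0, 0.4, 1)) for (x in c(-2.3, -0.04, 0.02, 1.7)) {
    t <- 0.37; kap <- 1.9
    z_hat <- dirichscan:::.prox_en(x, t, cc, kap)
    obj <- (grid - x)^2 / (2 * t) + cc * kap * grid^2 +
      (1 - cc) * kap * abs(grid)
    expect_lt(abs(z_hat - grid[which.min(obj)]), 2e-4)
  }
})

test_that("lasso limit zeroes everything; ridge never does", {
  fx <- make_gene_fixture(seed = 64, n = 300)
  f_lasso <- dirichreg_penalized(fx$Y, fx$G, c = 0, kappa = 1e4)
  expect_identical(count_selected(f_lasso), 0L)
  f_ridge <- dirichreg_penalized(fx$Y, fx$G, c = 1, kappa = 25)
  expect_identical(count_selected(f_ridge, tolerance = 0), 6L * 3L)
  # ridge shrinks the group norms relative to the unpenalized fit (with a
  # little slack for tiny groups, whose norms can move either way when
  # predictors are correlated)
  f_free <- dirichreg_penalized(fx$Y, fx$G, c = 1, kappa = 0)
  expect_true(all(f_ridge$group_norms <= f_free$group_norms + 5e-3))
  expect_lt(sum(f_ridge$group_norms), sum(f_free$group_norms))
  expect_lt(max(f_ridge$group_norms), max(f_free$group_norms))
})

test_that("c = 0 solutions satisfy the lasso KKT conditions", {
  fx <- make_gene_fixture(seed = 65)
  for (kap in c(5, 20, 60)) {
    f <- dirichreg_penalized(fx$Y, fx$G, c = 0, kappa = kap)
    Gd <- cbind(1, sweep(sweep(fx$G, 2, f$center), 2, f$scale, "/"))
    th <- as.vector(f$eta)
    score <- -dirichscan:::.dirich_ngr(th, Gd, log(compress_simplex(fx$Y)))
    pmask <- rep(f$penalized, 3)
    zero <- pmask & abs(th) < 1e-12
    nonzero <- pmask & abs(th) >= 1e-12
    # |score| <= kappa at zeros; score = kappa * sign(eta) at actives
    if (any(zero)) expect_lt(max(abs(score[zero])) - kap, 1e-6)
    if (any(nonzero))
      expect_lt(max(abs(score[nonzero] - kap * sign(th[nonzero]))), 1e-6)
  }
})

test_that("the objective trace is monotone nondecreasing", {
  fx <- make_gene_fixture(seed = 66)
  for (cc in c(0, 0.5, 1)) {
    f <- dirichreg_penalized(fx$Y, fx$G, c = cc, kappa = 10)
    expect_true(all(diff(f$trace) >= -1e-8))
    expect_true(f$converged)
  }
})

test_that("a truly associated SNP dominates a null SNP across kappa", {
  set.seed(67)
  n <- 500
  G <- matrix(rbinom(n * 2, 2, 0.3), n, 2,
              dimnames = list(NULL, c("causal", "null")))
  L <- exp(cbind(log(2) + 0.8 * G[, 1], log(2), log(2) - 0.8 * G[, 1]))
  Y <- rdirichlet(n, L)
  for (kap in c(2, 10, 30)) {
    f <- dirichreg_penalized(Y, G, c = 0.5, kappa = kap)
    expect_gt(f$group_norms["causal"], f$group_norms["null"])
  }
})

test_that("count_selected counts coefficients above tolerance", {
  fx <- make_gene_fixture(seed = 68, n = 100, p = 3, beta = 0)
  f <- dirichreg_penalized(fx$Y, fx$G, c = 0, kappa = 1e4)
  f$eta[2, ] <- c(0.5, 0, 0.2)           # 2 entries above tolerance
  f$eta[3, 1] <- 1e-9                    # below tolerance
  expect_identical(count_selected(f), 2L)
  expect_identical(count_selected(f, groups = TRUE), 1L)
})

test_that("selection paths reproduce the c-grid report shape", {
  fx <- make_gene_fixture(seed = 69, n = 300)
  sp <- selection_path(fx$Y, fx$G, kappa = 15)
  expect_s3_class(sp, "selection_path")
  expect_identical(nrow(sp), 5L)
  expect_identical(sp$c, c(0, 0.3, 0.5, 0.7, 1))
  expect_true(all(sp$converged))
  # kappa = 0 column: counts constant across c (penalty inactive)
  sp0 <- selection_path(fx$Y, fx$G, c_grid = c(0, 0.5, 1), kappa = 0)
  expect_identical(length(unique(sp0$n_selected)), 1L)
  # selected counts nonincreasing in kappa at c = 0 and c = 1
  for (cc in c(0, 1)) {
    spk <- selection_path(fx$Y, fx$G, c_grid = cc, kappa = c(2, 10, 40, 120))
    expect_true(all(diff(spk$n_selected) <= 0))
  }
})

test_that("family contrasts are never penalized under M2-style fits", {
  set.seed(70)
  n <- 200
  fam <- rep(sprintf("F%d", 1:10), each = 20)
  G <- matrix(rbinom(n * 3, 2, 0.3), n, 3)
  Y <- rdirichlet(n, c(2, 2, 2))
  f <- dirichreg_penalized(Y, G, c = 0, kappa = 1e4, family_ids = fam)
  # all SNP blocks zeroed, but family contrasts and intercept survive
  expect_identical(count_selected(f), 0L)
  fam_rows <- grep("^fam", rownames(f$eta))
  expect_gt(length(fam_rows), 0)
  expect_gt(max(abs(f$eta[fam_rows, ])), 0)
})

test_that("monomorphic SNP columns are rejected", {
  Y <- rdirichlet(50, c(2, 2, 2))
  G <- cbind(a = rbinom(50, 2, 0.4), b = rep(1, 50))
  expect_error(dirichreg_penalized(Y, G, c = 0.5, kappa = 1), "monomorphic")
})
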