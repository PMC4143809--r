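test_that("log-likelihood matches closed-form Dirichlet densities", {
  # lambda = (1,1,1): uniform density on the simplex, logGamma(3) = log 2
  expect_equal(dirichlet_loglik(matrix(c(0.2, 0.3, 0.5), 1),
                                matrix(1, 1, 3)),
               log(2), tolerance = 1e-12)
  # lambda = (2,1,1) at y = (.5,.25,.25): Gamma(4)/Gamma(2) * y1 = 6 * 0.5
  expect_equal(dirichlet_loglik(matrix(c(0.5, 0.25, 0.25), 1),
                                matrix(c(2, 1, 1), 1)),
               log(3), tolerance = 1e-12)
  # boundary responses are rejected with advice
  expect_error(dirichlet_loglik(matrix(c(0, 0.5, 0.5), 1),
                                matrix(1, 1, 3)), "compress_simplex")
  expect_error(dirichlet_loglik(matrix(c(0.2, 0.3, 0.5), 1),
                                matrix(c(-1, 1, 1), 1)), "positive")
})

test_that("log-likelihood equals naive term-by-term summation", {
  set.seed(21)
  Y <- rdirichlet(20, c(1.5, 2, 0.8))
  Lambda <- matrix(rgamma(60, 2, 0.5), 20, 3)
  expect_equal(dirichlet_loglik(Y, Lambda),
               dirich_loglik_naive(Y, Lambda), tolerance = 1e-10)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(22)
  worst <- 0
  for (rep in 1:50) {
    n <- 30
    S <- cbind(1, rbinom(n, 2, 0.3))
    theta <- rnorm(6, 0, 0.5)
    Y <- rdirichlet(n, exp(S %*% matrix(theta, 2, 3)))
    logY <- log(Y)
    g <- -dirichscan:::.dirich_ngr(theta, S, logY)
    g_fd <- fd_grad(function(th) -dirichscan:::.dirich_nll(th, S, logY),
                    theta)
    worst <- max(worst, max(abs(g - g_fd) / pmax(abs(g_fd), 1)))
  }
  expect_lt(worst, 1e-6)
})

test_that("analytic Hessian matches finite differences of the gradient", {
  set.seed(23)
  n <- 40
  S <- cbind(1, runif(n, 0, 2))
  theta <- rnorm(6, 0, 0.3)
  Y <- rdirichlet(n, exp(S %*% matrix(theta, 2, 3)))
  logY <- log(Y)
  H <- dirichscan:::.dirich_hess(theta, S, logY)
  H_fd <- t(vapply(seq_along(theta), function(i) {
    e <- numeric(6); e[i] <- 1e-6
    (-dirichscan:::.dirich_ngr(theta + e, S, logY) +
       dirichscan:::.dirich_ngr(theta - e, S, logY)) / 2e-6
  }, numeric(6)))
  expect_equal(H, H_fd, tolerance = 1e-5)
})

test_that("compress_simplex keeps interior rows and fixes boundary rows", {
  Y <- rbind(c(0.2, 0.3, 0.5), c(0, 0.5, 0.5), c(1e-12, 1 - 2e-12, 1e-12))
  Yc <- compress_simplex(Y)
  expect_identical(Yc[1, ], Y[1, ])
  expect_true(all(Yc > 0 & Yc < 1))
  expect_equal(rowSums(Yc), rep(1, 3), tolerance = 1e-12)
})

test_that("intercept-only fit recovers the generating concentration", {
  set.seed(24)
  Y <- rdirichlet(1000, c(2, 2, 2))
  f <- dirichreg(Y)
  expect_true(f$converged)
  expect_lt(f$grad_norm, 1e-6)
  se <- sqrt(diag(f$vcov))
  z <- (as.vector(f$coef) - log(2)) / se
  expect_true(all(abs(z) < 3))
  # MLE log-likelihood is at least that of the truth
  expect_gte(f$logLik, dirichlet_loglik(f$Y, matrix(2, 1000, 3)))
})

test_that("slope recovery within 3 SE on simulated genotype effects", {
  set.seed(25)
  n <- 2000
  g <- rbinom(n, 2, 0.3)
  beta <- c(0.5, 0, -0.5)
  L <- exp(sweep(outer(g, beta), 2, log(2), "+"))
  Y <- rdirichlet(n, L)
  f <- dirichreg(Y, cbind("(Intercept)" = 1, g = g))
  se <- sqrt(diag(f$vcov))
  est <- as.vector(f$coef)          # (a1, b1, a2, b2, a3, b3)
  truth <- as.vector(rbind(log(2), beta))
  expect_true(all(abs((est - truth) / se) < 3))
})

test_that("the MLE is a local maximum against random perturbations", {
  set.seed(26)
  n <- 300
  g <- rbinom(n, 2, 0.25)
  S <- cbind(1, g)
  Y <- rdirichlet(n, exp(S %*% matrix(c(0.7, 0.2, 0.7, 0, 0.7, -0.2), 2, 3)))
  f <- dirichreg(Y, S)
  th <- as.vector(f$coef)
  logY <- log(f$Y)
  for (k in 1:100) {
    d <- rnorm(6); d <- d / sqrt(sum(d^2)) * 1e-2
    ll <- -dirichscan:::.dirich_nll(th + d, S, logY)
    expect_lte(ll, f$logLik + 1e-10)
  }
})

test_that("Wald test gives exact chi-square tails and trivial cases", {
  set.seed(27)
  Y <- rdirichlet(400, c(2, 2, 2))
  g <- rbinom(400, 2, 0.3)
  f <- dirichreg(Y, cbind("(Intercept)" = 1, g = g))
  w <- wald_test(f)
  expect_identical(w$df, 3L)
  expect_equal(w$p.value, pchisq(w$statistic, 3, lower.tail = FALSE))
  expect_gte(w$statistic, 0)
  # beta-hat = (1,1,1), V = I gives W = 3, p = P(chi2_3 > 3) ~ 0.3916
  f2 <- f
  f2$coef["g", ] <- c(1, 1, 1)
  idx <- c(2, 4, 6)
  f2$vcov[idx, idx] <- diag(3)
  w2 <- wald_test(f2)
  expect_equal(w2$statistic, 3, tolerance = 1e-12)
  expect_equal(w2$p.value, 0.3916252, tolerance = 1e-6)
  # zero coefficients give W = 0, p = 1
  f2$coef["g", ] <- c(0, 0, 0)
  expect_equal(wald_test(f2)$statistic, 0)
  expect_equal(wald_test(f2)$p.value, 1)
  expect_error(wald_test(f, "nonexistent"), "not in the fit")
})

test_that("family contrasts are treatment-coded with pooling and invariances", {
  # one family degenerates to a zero-column matrix
  expect_identical(ncol(family_contrasts(rep("A", 5))), 0L)
  # three equal families: n x 2 indicators
  fam <- rep(c("A", "B", "C"), each = 4)
  FM <- family_contrasts(fam)
  expect_identical(dim(FM), c(12L, 2L))
  expect_true(all(FM %in% c(0, 1)))
  expect_true(all(rowSums(FM) <= 1))
  # singleton families pool into the reference
  FM2 <- family_contrasts(c(rep("A", 4), "B", rep("C", 3)))
  expect_identical(ncol(FM2), 1L)        # only C survives as a level
  # relabeling families leaves the fitted SNP effect untouched
  set.seed(28)
  n <- 120
  fam1 <- rep(sprintf("f%d", 1:10), each = 12)
  fam2 <- rep(sprintf("g%d", 10:1), each = 12)   # same blocks, new labels
  g <- rbinom(n, 2, 0.4)
  Y <- rdirichlet(n, c(2, 2, 2))
  S1 <- cbind("(Intercept)" = 1, g = g, family_contrasts(fam1))
  S2 <- cbind("(Intercept)" = 1, g = g, family_contrasts(fam2))
  fA <- dirichreg(Y, S1); fB <- dirichreg(Y, S2)
  expect_equal(fA$coef["g", ], fB$coef["g", ], tolerance = 1e-6)
  expect_equal(wald_test(fA)$p.value, wald_test(fB)$p.value,
               tolerance = 1e-6)
})

test_that("M2 with zero-column family contrasts reproduces M1 exactly", {
  set.seed(29)
  Y <- rdirichlet(150, c(2, 1.5, 2.5))
  g <- rbinom(150, 2, 0.3)
  FM <- family_contrasts(rep("onefam", 150))
  m1 <- dirichscan:::.fit_marker(Y, g, NULL)
  m2 <- dirichscan:::.fit_marker(Y, g, FM)
  expect_equal(m1$coef, m2$coef, tolerance = 1e-10)
  expect_equal(m1$logLik, m2$logLik, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected with the offending columns", {
  Y <- rdirichlet(50, c(2, 2, 2))
  S <- cbind(a = rep(1, 50), b = rep(2, 50))
  expect_error(dirichreg(Y, S), "collinear")
})
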