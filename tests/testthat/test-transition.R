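test_that("transition rows pair consecutive exams with earlier-exam covariates", {
  r <- toy_records(ns = 10, ne = 4)
  s <- build_state_sequences(r)
  rows <- build_transition_rows(s)
  expect_identical(nrow(rows), 30L)               # 10 subjects x 3 pairs
  # covariates at the earlier exam: age column equals earlier exam's age
  expect_true(all(rows$age %in% (40 + 1:3)))
  expect_identical(levels(rows$time), c("1", "2", "3"))
  # a [1,2,2] state path yields rows 1->2 and 2->2
  one <- data.frame(subject_id = "A", family_id = "F", exam = 1:3,
                    sbp = c(110, 130, 130), dbp = c(70, 85, 85),
                    meds = FALSE, sex = 1, smoke = 0, age = 50:52)
  rows1 <- build_transition_rows(build_state_sequences(one))
  expect_identical(rows1$prev_state, c(1L, 2L))
  expect_identical(rows1$next_state, c(2L, 2L))
  # empty input
  expect_identical(nrow(build_transition_rows(build_state_sequences(
    toy_records(0, 0)))), 0L)
})

test_that("intercept-only fits reproduce empirical transition frequencies", {
  # closed-form MLE: fitted probabilities = (60, 30, 10) / 100
  rows <- data.frame(prev_state = 1L,
                     next_state = rep(c(1L, 2L, 3L), c(60, 30, 10)),
                     sex = 0, smoke = 0, age = 50)
  f <- fit_multinomial(rows, ~ 1, prev_state = 1L)
  eta <- f$coef[1, ]
  p_stay <- 1 / (1 + sum(exp(eta)))
  probs <- unname(c(p_stay, exp(eta) * p_stay))   # order: 1, 2, 3
  expect_equal(probs, c(0.6, 0.3, 0.1), tolerance = 1e-6)
  expect_lt(f$grad_norm, 1e-6)

  # all three previous states on random data
  set.seed(7)
  rws <- data.frame(prev_state = sample(1:3, 600, replace = TRUE),
                    next_state = sample(1:3, 600, replace = TRUE),
                    sex = 0, smoke = 0, age = 50)
  for (l in 1:3) {
    fl <- fit_multinomial(rws, ~ 1, l)
    dest <- setdiff(1:3, l)
    emp <- prop.table(table(factor(
      rws$next_state[rws$prev_state == l], levels = c(l, dest))))
    eta <- fl$coef[1, ]
    fitted <- c(1, exp(eta)) / (1 + sum(exp(eta)))
    expect_equal(unname(fitted), as.vector(emp), tolerance = 1e-6)
  }
})

test_that("degenerate categories are handled by the coefficient cap", {
  rows <- data.frame(prev_state = 2L, next_state = rep(2L, 40),
                     sex = 0, smoke = 0, age = 50)
  f <- fit_multinomial(rows, ~ 1, 2L)
  eta <- f$coef[1, ]
  # coefficients stay finite (bounded by the cap) with the staying
  # probability pinned against 1
  expect_true(all(is.finite(eta)) && all(eta >= -30))
  p_stay <- 1 / (1 + sum(exp(eta)))
  expect_gt(p_stay, 1 - 1e-9)
})

test_that("fitted coefficients agree with an independent multinomial fitter", {
  skip_if_not_installed("nnet")
  gamma <- cbind(c(-1, 0.3, 0.4, 0.01), c(-2.5, 0.2, 0.5, 0.02))
  rows <- sim_glogit_rows(1500, gamma, prev_state = 1L, seed = 11)
  f <- fit_multinomial(rows, ~ sex + smoke + age, 1L)
  ref <- nnet::multinom(factor(next_state, levels = c(1, 2, 3)) ~
                          sex + smoke + age, data = rows, trace = FALSE,
                        reltol = 1e-14)
  expect_equal(unname(t(coef(ref))), unname(f$coef), tolerance = 1e-4)
})

test_that("parameter recovery within 3 SE at n = 5000", {
  gamma <- cbind(c(-2.0, 0.15, 0.30, 0.03), c(-3.5, 0.10, 0.40, 0.04))
  rows <- sim_glogit_rows(5000, gamma, prev_state = 1L, seed = 42)
  f <- fit_multinomial(rows, ~ sex + smoke + age, 1L)
  se <- sqrt(diag(vcov(f)))
  z <- (as.vector(f$coef) - as.vector(gamma)) / se
  expect_true(all(abs(z) < 3))
})

test_that("the fit is a local maximum of the log-likelihood", {
  gamma <- cbind(c(-1, 0.3, 0, 0.01), c(-2, 0, 0.5, 0.02))
  rows <- sim_glogit_rows(800, gamma, seed = 3)
  f <- fit_multinomial(rows, ~ sex + smoke + age, 1L)
  set.seed(4)
  base_ll <- f$logLik
  X <- model.matrix(~ sex + smoke + age, rows)
  y_idx <- match(rows$next_state, c(2L, 3L), nomatch = 0L)
  for (k in 1:25) {
    pert <- as.vector(f$coef) + 1e-3 * rnorm(8) / sqrt(8)
    ll_p <- -dirichscan:::.glogit_nll(pert, X, y_idx)
    expect_lte(ll_p, base_ll + 1e-10)
  }
})

test_that("likelihood-ratio test behaves as a chi-square test", {
  rows <- sim_glogit_rows(400, cbind(c(-1, 0.2, 0.1, 0.01),
                                     c(-2, 0.1, 0.2, 0.02)), seed = 5)
  f1 <- fit_multinomial(rows, ~ sex + smoke + age, 1L)
  # identical models: statistic 0, p = 1
  same <- lrt_time_effect(f1, f1)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  # df and tail probability: 5.99 on 2 df sits at p ~ 0.05
  expect_equal(pchisq(5.99, 2, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  f0 <- fit_multinomial(rows, ~ sex + smoke, 1L)
  out <- lrt_time_effect(f1, f0)
  expect_identical(out$df, 2L)
  expect_gte(out$statistic, 0)
  expect_error(lrt_time_effect(f0, f1), "nested")
})

test_that("LRT for a null-true time effect rejects at about the nominal rate", {
  # states generated without any time effect; test sex coefficient pair
  # (also null-true) via nested fits over 200 replicates
  set.seed(6)
  rej <- 0L
  reps <- 200L
  gamma <- cbind(c(-1, 0, 0.2, 0.01), c(-2, 0, 0.1, 0.02))  # sex effect 0
  for (r in seq_len(reps)) {
    rows <- sim_glogit_rows(300, gamma, seed = 1000 + r)
    ff <- fit_multinomial(rows, ~ sex + smoke + age, 1L)
    f0 <- fit_multinomial(rows, ~ smoke + age, 1L)
    if (lrt_time_effect(ff, f0)$p.value < 0.05) rej <- rej + 1L
  }
  # 99% binomial band around 0.05 at 200 reps: [0.013, 0.093]
  expect_gt(rej / reps, 0.013)
  expect_lt(rej / reps, 0.093)
})

test_that("TPMs are proper stochastic matrices and match closed forms", {
  # gamma = 0 gives uniform rows
  rows <- data.frame(prev_state = rep(1:3, each = 30),
                     next_state = rep(rep(1:3, 10), 3),
                     sex = 0, smoke = 0, age = 50,
                     subject_id = "x", family_id = "f")
  # build a transition_models object from equal-frequency data: empirical
  # frequencies are exactly uniform, so every TPM row is (1/3, 1/3, 1/3)
  fits <- lapply(1:3, function(l) fit_multinomial(rows, ~ 1, l))
  tm <- structure(list(fits = fits, shapes = rep("base", 3),
                       lrt = NULL, n_rows = rep(30L, 3),
                       time_levels = "1"),
                  class = "transition_models")
  tpm <- build_tpm(tm, data.frame(sex = 0, smoke = 0, age = 50))
  expect_equal(unclass(tpm), matrix(1 / 3, 3, 3), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(rowSums(tpm), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  # response extraction picks the conditioning row
  y <- extract_response(tpm, 2L)
  expect_equal(unname(y), as.vector(unclass(tpm)[2, ]))
})

test_that("TPM rows sum to one for every subject of a simulated cohort", {
  cfg <- sim_config(seed = 31, n_families = 40, family_size = 4,
                    n_markers = 2, clinical_missing = 0)
  cohort <- simulate_cohort(cfg)
  seqs <- build_state_sequences(cohort$phenotypes)
  tm <- transition_models(seqs, time_effect = "none")
  last <- seqs[!duplicated(seqs$subject_id, fromLast = TRUE), ]
  dev <- vapply(seq_len(nrow(last)), function(i) {
    tpm <- build_tpm(tm, last[i, ])
    max(abs(rowSums(tpm) - 1))
  }, numeric(1))
  expect_lt(max(dev), 1e-12)
  # entries strictly inside (0, 1)
  tpm1 <- build_tpm(tm, last[1, ])
  expect_true(all(tpm1 > 0 & tpm1 < 1))
})

test_that("responses condition on the last observed state and covariates", {
  cfg <- sim_config(seed = 32, n_families = 30, family_size = 4,
                    n_markers = 2, clinical_missing = 0.15)
  cohort <- simulate_cohort(cfg)
  seqs <- build_state_sequences(cohort$phenotypes)
  tm <- transition_models(seqs, time_effect = "none")
  resp <- extract_responses(tm, seqs)
  Y <- as.matrix(resp[, c("y1", "y2", "y3")])
  expect_true(all(Y > 0 & Y < 1))
  expect_lt(max(abs(rowSums(Y) - 1)), 1e-12)
  # subjects with a single retained exam still get a response
  n_subj <- length(unique(seqs$subject_id))
  expect_identical(nrow(resp), n_subj)
  # spot-check one subject against the TPM row
  last <- seqs[!duplicated(seqs$subject_id, fromLast = TRUE), ]
  i <- 5L
  tpm <- build_tpm(tm, last[i, ])
  expect_equal(unname(as.numeric(resp[resp$subject_id == last$subject_id[i],
                                      c("y1", "y2", "y3")])),
               unname(extract_response(tpm, last$state[i])),
               tolerance = 1e-12)
})

test_that("unseen time levels error in build_tpm and are clamped in responses", {
  cfg <- sim_config(seed = 33, n_families = 40, family_size = 4,
                    n_markers = 2, clinical_missing = 0)
  cohort <- simulate_cohort(cfg)
  seqs <- build_state_sequences(cohort$phenotypes)
  tm <- transition_models(seqs, time_effect = "fixed",
                          shapes = c("time", "time", "time"))
  nd <- data.frame(sex = 0, smoke = 0, age = 50, time = "99")
  expect_error(build_tpm(tm, nd), "99")
  resp <- extract_responses(tm, seqs)   # last exam's level gets clamped
  expect_false(anyNA(resp$y1))
})
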