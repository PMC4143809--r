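# Independent oracles and small fixture builders used across test files.

# Exact HWE p-value by direct enumeration over heterozygote counts with
# log-multinomial probabilities (independent of the package's recurrence).
hwe_enum_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, 2 * n - n_A)
  if (rare == 0) return(1)
  hs <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hs, function(h) {
    r <- (rare - h) / 2
    c0 <- n - h - r
    lfactorial(n) - lfactorial(h) - lfactorial(r) - lfactorial(c0) +
      h * log(2) -
      (lfactorial(2 * n) - lfactorial(n_A) - lfactorial(2 * n - n_A))
  }, numeric(1))
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, hs)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# Naive term-by-term Dirichlet log-likelihood (scalar loop; no matrix tricks).
dirich_loglik_naive <- function(Y, Lambda) {
  tot <- 0
  for (i in seq_len(nrow(Y))) {
    Li <- sum(Lambda[i, ])
    tot <- tot + lgamma(Li)
    for (j in seq_len(ncol(Y)))
      tot <- tot - lgamma(Lambda[i, j]) +
        (Lambda[i, j] - 1) * log(Y[i, j])
  }
  tot
}

# Central finite-difference gradient of a scalar function.
fd_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# Small complete phenotype table: ns subjects x ne exams, deterministic states.
toy_records <- function(ns = 4, ne = 3) {
  if (ns == 0 || ne == 0)
    return(data.frame(subject_id = character(0), family_id = character(0),
                      exam = integer(0), sbp = numeric(0), dbp = numeric(0),
                      meds = logical(0), sex = numeric(0), smoke = numeric(0),
                      age = numeric(0)))
  expand_grid <- expand.grid(subject_id = sprintf("S%02d", seq_len(ns)),
                             exam = seq_len(ne),
                             stringsAsFactors = FALSE)
  r <- expand_grid[order(expand_grid$subject_id, expand_grid$exam), ]
  n <- nrow(r)
  data.frame(subject_id = r$subject_id, family_id = "F1", exam = r$exam,
             sbp = 110 + 10 * (seq_len(n) %% 3), dbp = 70,
             meds = FALSE, sex = 0, smoke = 0,
             age = 40 + r$exam, stringsAsFactors = FALSE)
}

# Simulate transition rows from known gamma for one previous state and
# return the design plus the generating coefficients.
sim_glogit_rows <- function(n, gamma, prev_state = 1L, seed = 1) {
  set.seed(seed)
  sex <- rbinom(n, 1, 0.5)
  smoke <- rbinom(n, 1, 0.3)
  age <- runif(n, 30, 70)
  Z <- cbind(1, sex, smoke, age)
  eta <- Z %*% gamma                      # n x 2
  dest <- setdiff(1:3, prev_state)
  nxt <- integer(n)
  for (i in seq_len(n)) {
    m <- max(0, eta[i, ])
    den <- exp(-m) + sum(exp(eta[i, ] - m))
    pr <- c(exp(-m), exp(eta[i, ] - m)) / den  # stay, dest1, dest2
    nxt[i] <- sample(c(prev_state, dest), 1, prob = pr)
  }
  data.frame(prev_state = prev_state, next_state = nxt,
             sex = sex, smoke = smoke, age = age)
}
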