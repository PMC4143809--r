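#' Build the transition design rows from state sequences
#'
#' One row per observed consecutive exam pair (t-1, t) within a subject.
#' Covariates (sex, smoke, age) are taken at the earlier exam, matching the
#' conditioning in the transition probability
#' P(S_t = j | S_{t-1} = l, x_{t-1}); the \code{time} covariate is the
#' categorical index of the earlier exam. Subjects with fewer than two
#' retained exams contribute nothing.
#'
#' @param sequences a \code{state_sequences} object from
#'   [build_state_sequences()].
#' @return data.frame with columns \code{subject_id}, \code{family_id},
#'   \code{prev_state}, \code{next_state}, \code{sex}, \code{smoke},
#'   \code{age}, \code{time} (factor).
#' @export
build_transition_rows <- function(sequences) {
  s <- as.data.frame(sequences)
  if (nrow(s) == 0L)
    return(data.frame(subject_id = character(0), family_id = character(0),
                      prev_state = integer(0), next_state = integer(0),
                      sex = numeric(0), smoke = numeric(0), age = numeric(0),
                      time = factor(integer(0))))
  s <- s[order(s$subject_id, s$exam), , drop = FALSE]
  same <- s$subject_id[-1L] == s$subject_id[-nrow(s)]
  from <- which(same)           # earlier exam of each within-subject pair
  out <- data.frame(
    subject_id = s$subject_id[from],
    family_id  = s$family_id[from],
    prev_state = s$state[from],
    next_state = s$state[from + 1L],
    sex   = s$sex[from],
    smoke = s$smoke[from],
    age   = s$age[from],
    stringsAsFactors = FALSE)
  out$time <- factor(s$exam[from], levels = sort(unique(s$exam[from])))
  rownames(out) <- NULL
  out
}

## Negative log-likelihood and gradient of the generalized-logit
## (baseline-category multinomial) model for transitions out of one state.
## theta is the stacked coefficient vector c(gamma_j1, gamma_j2) for the two
## non-baseline destinations.
.glogit_nll <- function(theta, X, y_idx) {
  q <- ncol(X)
  eta <- X %*% matrix(theta, nrow = q)            # n x 2, linear predictors
  m <- pmax(eta[, 1L], pmax(eta[, 2L], 0))        # log-sum-exp guard
  lse <- m + log(exp(-m) + exp(eta[, 1L] - m) + exp(eta[, 2L] - m))
  pick <- numeric(nrow(X))                        # eta of observed category
  pick[y_idx == 1L] <- eta[y_idx == 1L, 1L]
  pick[y_idx == 2L] <- eta[y_idx == 2L, 2L]
  -sum(pick - lse)
}

.glogit_ngr <- function(theta, X, y_idx) {
  q <- ncol(X)
  eta <- X %*% matrix(theta, nrow = q)
  m <- pmax(eta[, 1L], pmax(eta[, 2L], 0))
  denom <- exp(-m) + exp(eta[, 1L] - m) + exp(eta[, 2L] - m)
  p1 <- exp(eta[, 1L] - m) / denom
  p2 <- exp(eta[, 2L] - m) / denom
  r1 <- (y_idx == 1L) - p1
  r2 <- (y_idx == 2L) - p2
  -c(crossprod(X, r1), crossprod(X, r2))
}

## Hessian of the negative log-likelihood: the usual multinomial information,
## blocks X' diag(p_j (1{j=k} - p_k)) X.
.glogit_nhess <- function(theta, X, y_idx) {
  q <- ncol(X)
  eta <- X %*% matrix(theta, nrow = q)
  m <- pmax(eta[, 1L], pmax(eta[, 2L], 0))
  denom <- exp(-m) + exp(eta[, 1L] - m) + exp(eta[, 2L] - m)
  p1 <- exp(eta[, 1L] - m) / denom
  p2 <- exp(eta[, 2L] - m) / denom
  H11 <- crossprod(X * (p1 * (1 - p1)), X)
  H22 <- crossprod(X * (p2 * (1 - p2)), X)
  H12 <- crossprod(X * (-p1 * p2), X)
  rbind(cbind(H11, H12), cbind(t(H12), H22))
}

#' Fit a generalized-logit transition model for one previous state
#'
#' Maximum likelihood for the baseline-category multinomial model
#' \eqn{\log(y_{lj} / y_{ll}) = z \gamma_{lj}}, \eqn{j \ne l}, where the
#' baseline category is the previous state \eqn{l} itself. Coefficients are
#' box-constrained to \eqn{|\gamma| \le} \code{cap} so that empty destination
#' categories yield finite fits with transition probabilities pinned near 0.
#'
#' @param rows transition design rows (see [build_transition_rows()]),
#'   already restricted to \code{prev_state == prev_state}.
#' @param formula right-hand-side formula for the covariates, e.g.
#'   \code{~ sex + smoke + age}.
#' @param prev_state the previous state l in 1:3 (baseline category).
#' @param cap coefficient bound used during optimization (default 30).
#' @return object of class \code{glogit_fit} with elements \code{coef}
#'   (q x 2 matrix, columns = destination states), \code{logLik}, \code{n},
#'   \code{formula}, \code{prev_state}, \code{terms}, \code{xlevels},
#'   \code{converged}, \code{grad_norm}.
#' @export
fit_multinomial <- function(rows, formula, prev_state, cap = 30) {
  stopifnot(prev_state %in% 1:3)
  rows <- rows[rows$prev_state == prev_state, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("no observed transitions out of state ", prev_state)
  mf <- stats::model.frame(formula, data = rows)
  X <- stats::model.matrix(formula, mf)
  if (qr(X)$rank < ncol(X))
    stop("design matrix for previous state ", prev_state, " is rank deficient")
  dest <- setdiff(1:3, prev_state)
  y_idx <- match(rows$next_state, dest, nomatch = 0L)   # 0 = stayed (baseline)
  q <- ncol(X)
  fit <- stats::optim(rep(0, 2L * q), .glogit_nll, .glogit_ngr,
                      X = X, y_idx = y_idx, method = "L-BFGS-B",
                      lower = -cap, upper = cap,
                      control = list(maxit = 1000L, pgtol = 1e-10))
  theta <- fit$par
  ## Newton polish on interior coordinates to reach gradient norm < 1e-8
  for (it in seq_len(50L)) {
    g <- .glogit_ngr(theta, X, y_idx)
    free <- abs(theta) < cap - 1e-8
    if (sqrt(sum(g[free]^2)) < 1e-9) break
    H <- .glogit_nhess(theta, X, y_idx)
    step <- numeric(length(theta))
    st <- tryCatch(solve(H[free, free, drop = FALSE] +
                           diag(1e-10, sum(free)), -g[free]),
                   error = function(e) NULL)
    if (is.null(st)) break
    step[free] <- st
    f0 <- .glogit_nll(theta, X, y_idx)
    damp <- 1
    repeat {
      cand <- pmin(pmax(theta + damp * step, -cap), cap)
      f1 <- .glogit_nll(cand, X, y_idx)
      if (is.finite(f1) && f1 <= f0 + 1e-12) break
      damp <- damp / 2
      if (damp < 1e-10) break
    }
    if (damp < 1e-10) break
    theta <- cand
  }
  g <- .glogit_ngr(theta, X, y_idx)
  at_bound <- abs(abs(theta) - cap) < 1e-8
  grad_norm <- sqrt(sum(g[!at_bound]^2))
  if (grad_norm > 1e-6)
    stop("multinomial fit for previous state ", prev_state,
         " did not converge (gradient norm ", format(grad_norm),
         "); possible separation or singular design")
  cf <- matrix(theta, nrow = q,
               dimnames = list(colnames(X), paste0("to", dest)))
  ll <- -.glogit_nll(theta, X, y_idx)
  lab <- as.vector(outer(colnames(X), paste0("to", dest),
                         function(a, b) paste(b, a, sep = ":")))
  V <- tryCatch(solve(.glogit_nhess(theta, X, y_idx)),
                error = function(e) matrix(NA_real_, 2L * q, 2L * q))
  dimnames(V) <- list(lab, lab)
  structure(list(coef = cf, vcov = V, logLik = ll, df = 2L * q, n = nrow(rows),
                 formula = formula, prev_state = prev_state,
                 terms = attr(mf, "terms"),
                 xlevels = stats::.getXlevels(attr(mf, "terms"), mf),
                 converged = TRUE, grad_norm = grad_norm, cap = cap),
            class = "glogit_fit")
}

#' @export
coef.glogit_fit <- function(object, ...) object$coef

#' @export
vcov.glogit_fit <- function(object, ...) object$vcov

#' @export
logLik.glogit_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
print.glogit_fit <- function(x, ...) {
  cat("Generalized-logit transition model, previous state ", x$prev_state,
      " (baseline)\n", sep = "")
  cat("  ", deparse(x$formula), ";  n = ", x$n,
      ",  logLik = ", format(x$logLik, digits = 6), "\n", sep = "")
  print(x$coef)
  invisible(x)
}

#' Likelihood-ratio test between nested transition models
#'
#' @param fit_full,fit_null \code{glogit_fit} objects for the same previous
#'   state on identical rows, \code{fit_null} nested in \code{fit_full}.
#' @return list with \code{statistic}, \code{df}, \code{p.value}.
#' @export
lrt_time_effect <- function(fit_full, fit_null) {
  if (fit_full$n != fit_null$n || fit_full$prev_state != fit_null$prev_state)
    stop("models are not fitted to the same rows")
  df <- fit_full$df - fit_null$df
  if (df < 0L) stop("fit_full has fewer parameters than fit_null; not nested")
  stat <- max(0, 2 * (fit_full$logLik - fit_null$logLik))
  p <- if (df == 0L) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p.value = p)
}

.shape_formula <- function(shape) {
  switch(shape,
         base    = ~ sex + smoke + age,
         time    = ~ sex + smoke + age + time,
         agetime = ~ sex + smoke + age + age:time,
         stop("unknown model shape '", shape, "'"))
}

#' Fit the three per-previous-state transition models
#'
#' Fits a generalized-logit model for transitions out of each state on sex,
#' smoking status and age, with an examination-time effect chosen per
#' previous state. Candidate shapes are \code{"base"} (no time effect),
#' \code{"time"} (categorical main effect of the earlier exam index) and
#' \code{"agetime"} (age slope varying with exam, i.e. age + age:time).
#' With \code{time_effect = "select"} the shape is chosen per previous state
#' by likelihood-ratio tests against the base model at level \code{alpha};
#' \code{"fixed"} uses \code{shapes} as given (default: age-by-time
#' interaction out of state 1, time main effect out of state 2, no time
#' effect out of state 3); \code{"none"} uses the base shape everywhere.
#'
#' @param sequences a \code{state_sequences} object.
#' @param time_effect one of \code{"select"}, \code{"fixed"}, \code{"none"}.
#' @param shapes character vector of length 3 used when
#'   \code{time_effect = "fixed"}.
#' @param alpha LRT significance level for shape selection (default 0.05).
#' @param cap coefficient bound, see [fit_multinomial()].
#' @return object of class \code{transition_models}: list with \code{fits}
#'   (list of 3 \code{glogit_fit}), \code{shapes}, \code{lrt} (selection
#'   table or NULL), \code{rows} counts.
#' @export
transition_models <- function(sequences,
                              time_effect = c("select", "fixed", "none"),
                              shapes = c("agetime", "time", "base"),
                              alpha = 0.05, cap = 30) {
  time_effect <- match.arg(time_effect)
  rows <- build_transition_rows(sequences)
  if (nrow(rows) == 0L) stop("no transitions: need subjects with >= 2 exams")
  fits <- vector("list", 3L)
  used <- character(3L)
  lrt_tab <- NULL
  for (l in 1:3) {
    rl <- rows[rows$prev_state == l, , drop = FALSE]
    if (nrow(rl) == 0L)
      stop("no observed transitions out of state ", l)
    single_time <- nlevels(droplevels(rl$time)) < 2L
    if (time_effect == "none" || single_time) {
      shape <- "base"
    } else if (time_effect == "fixed") {
      shape <- shapes[l]
    } else {
      rl$time <- droplevels(rl$time)
      f0 <- fit_multinomial(rl, .shape_formula("base"), l, cap)
      cand <- c("time", "agetime")
      ps <- stats <- numeric(2L)
      cf <- list()
      for (k in seq_along(cand)) {
        cf[[k]] <- fit_multinomial(rl, .shape_formula(cand[k]), l, cap)
        tst <- lrt_time_effect(cf[[k]], f0)
        ps[k] <- tst$p.value; stats[k] <- tst$statistic
      }
      shape <- if (min(ps) < alpha) cand[which.min(ps)] else "base"
      lrt_tab <- rbind(lrt_tab, data.frame(
        prev_state = l, candidate = cand, statistic = stats, p.value = ps,
        chosen = cand == shape))
    }
    rl$time <- droplevels(rl$time)
    fits[[l]] <- fit_multinomial(rl, .shape_formula(shape), l, cap)
    used[l] <- shape
  }
  structure(list(fits = fits, shapes = used, lrt = lrt_tab,
                 n_rows = as.integer(table(factor(rows$prev_state, 1:3))),
                 time_levels = levels(rows$time)),
            class = "transition_models")
}

#' @export
print.transition_models <- function(x, ...) {
  cat("Transition models (generalized logit, baseline = previous state)\n")
  for (l in 1:3)
    cat("  out of state ", l, ": shape '", x$shapes[l], "', n = ",
        x$n_rows[l], ", logLik = ", format(x$fits[[l]]$logLik, digits = 6),
        "\n", sep = "")
  if (!is.null(x$lrt)) {
    cat("Time-effect LRT selection:\n")
    print(x$lrt, row.names = FALSE)
  }
  invisible(x)
}

#' @export
logLik.transition_models <- function(object, ...) {
  ll <- sum(vapply(object$fits, `[[`, numeric(1), "logLik"))
  structure(ll, df = sum(vapply(object$fits, `[[`, integer(1), "df")),
            class = "logLik")
}

## Linear predictors -> one TPM row for previous state l at covariates `newdata`
.tpm_row <- function(fit, newdata) {
  tt <- stats::delete.response(fit$terms)
  if (!is.null(fit$xlevels) && length(fit$xlevels)) {
    for (v in names(fit$xlevels)) {
      val <- as.character(newdata[[v]])
      bad <- !val %in% fit$xlevels[[v]]
      if (any(bad))
        stop("covariate '", v, "' level '", val[bad][1L],
             "' was not present when the transition model for state ",
             fit$prev_state, " was fitted")
      newdata[[v]] <- factor(val, levels = fit$xlevels[[v]])
    }
  }
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels)
  X <- stats::model.matrix(tt, mf)
  eta <- drop(X %*% fit$coef)                     # length 2: destinations
  dest <- setdiff(1:3, fit$prev_state)
  m <- max(0, eta)
  denom <- exp(-m) + sum(exp(eta - m))
  row <- numeric(3L)
  row[fit$prev_state] <- exp(-m) / denom
  row[dest] <- exp(eta - m) / denom
  row
}

#' Build a subject's transition probability matrix
#'
#' Evaluates all three fitted per-previous-state models at one covariate
#' vector, giving a 3x3 matrix whose (l, j) entry is the probability of
#' moving from state l to state j for this subject. Every row uses the same
#' covariates; rows sum to 1 by construction.
#'
#' @param models a \code{transition_models} object.
#' @param newdata one-row data.frame with the covariates (sex, smoke, age,
#'   and time if any fitted shape uses it).
#' @return 3x3 matrix of class \code{tpm}.
#' @export
build_tpm <- function(models, newdata) {
  stopifnot(inherits(models, "transition_models"), nrow(newdata) == 1L)
  tpm <- t(vapply(models$fits, .tpm_row, numeric(3L), newdata = newdata))
  dimnames(tpm) <- list(from = paste0("s", 1:3), to = paste0("s", 1:3))
  class(tpm) <- c("tpm", class(tpm))
  tpm
}

#' @export
print.tpm <- function(x, digits = 4, ...) {
  cat("Transition probability matrix\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Extract the simplex responses for all subjects
#'
#' For each subject, evaluates the transition probability matrix at the
#' covariates of the last retained exam and returns the row indexed by the
#' last observed state: the probability vector of the next transition
#' conditional on where the subject was last seen. Subjects with a single
#' retained exam still receive a response (they have a last observed state
#' and covariates even though they contributed no transition).
#'
#' The exam-time factor levels seen in fitting run over earlier exams only;
#' a subject last observed at the final exam has a time level the model never
#' saw. With \code{clamp_time = TRUE} (default) such levels are mapped to the
#' highest fitted level; with \code{FALSE} the evaluation errors.
#'
#' @param models a \code{transition_models} object.
#' @param sequences the \code{state_sequences} the models were fitted to (or
#'   compatible new sequences).
#' @param clamp_time logical, see above.
#' @return object of class \code{response_set}: data.frame with
#'   \code{subject_id}, \code{family_id}, \code{conditioning_state},
#'   \code{y1}, \code{y2}, \code{y3}.
#' @export
extract_responses <- function(models, sequences, clamp_time = TRUE) {
  s <- as.data.frame(sequences)
  if (nrow(s) == 0L) stop("no retained exams")
  s <- s[order(s$subject_id, s$exam), , drop = FALSE]
  last <- s[!duplicated(s$subject_id, fromLast = TRUE), , drop = FALSE]
  Y <- matrix(NA_real_, nrow(last), 3L)
  for (i in seq_len(nrow(last))) {
    nd <- last[i, , drop = FALSE]
    fit <- models$fits[[last$state[i]]]
    tv <- as.character(nd$exam)
    fl <- fit$xlevels[["time"]]
    if (!is.null(fl) && clamp_time && !tv %in% fl)
      tv <- fl[length(fl)]
    nd$time <- tv
    Y[i, ] <- .tpm_row(fit, nd)
  }
  out <- data.frame(subject_id = last$subject_id, family_id = last$family_id,
                    conditioning_state = last$state,
                    y1 = Y[, 1L], y2 = Y[, 2L], y3 = Y[, 3L],
                    stringsAsFactors = FALSE)
  structure(out, class = c("response_set", "data.frame"))
}

#' Extract one subject's response vector from a TPM
#'
#' @param tpm a \code{tpm} matrix from [build_tpm()].
#' @param conditioning_state the subject's last observed state in 1:3.
#' @return numeric length-3 simplex vector.
#' @export
extract_response <- function(tpm, conditioning_state) {
  stopifnot(conditioning_state %in% 1:3)
  y <- unclass(tpm)[conditioning_state, ]
  names(y) <- paste0("y", 1:3)
  y
}

#' @export
print.response_set <- function(x, ...) {
  cat("Simplex responses for", nrow(x), "subjects\n")
  print(utils::head(as.data.frame(x)))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
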