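## Elementwise elastic-net prox for step t: soft-threshold at t*(1-c)*kappa,
## then shrink by 1/(1 + 2*t*c*kappa). Applied only to penalized rows.
.prox_en <- function(x, t, c, kappa) {
  thr <- t * (1 - c) * kappa
  sign(x) * pmax(abs(x) - thr, 0) / (1 + 2 * t * c * kappa)
}

.pen_value <- function(eta_pen, c, kappa) {
  c * kappa * sum(eta_pen^2) + (1 - c) * kappa * sum(abs(eta_pen))
}

#' Penalized Dirichlet log-likelihood objective
#'
#' \deqn{pl(\eta) = \ell(\eta; Y, G) - c\kappa \sum_l \|\eta_{\cdot l}\|_2^2
#'   - (1-c)\kappa \sum_l \|\eta_{\cdot l}\|_1}
#' where the sums run over penalized predictors l (SNPs; never the intercept
#' or pedigree-contrast rows). With c = 1 the penalty is ridge on each SNP's
#' coefficient block; with c = 0 it is the lasso. Both terms separate over
#' individual coefficients, since the group-L2 norm enters squared.
#'
#' @param eta M x k coefficient matrix (rows = design columns).
#' @param Y n x k simplex response matrix.
#' @param G n x M design matrix (intercept column included).
#' @param c mixing weight in \[0, 1\].
#' @param kappa overall penalty weight, >= 0.
#' @param penalized logical vector of length M marking penalized rows;
#'   default all but the first (intercept) row.
#' @return scalar penalized log-likelihood.
#' @export
penalized_objective <- function(eta, Y, G, c, kappa,
                                penalized = c(FALSE, rep(TRUE, nrow(eta) - 1L))) {
  stopifnot(c >= 0, c <= 1)
  if (kappa < 0) stop("kappa must be nonnegative")
  L <- exp(as.matrix(G) %*% eta)
  dirichlet_loglik(Y, L) - .pen_value(eta[penalized, , drop = FALSE], c, kappa)
}

#' Penalized Dirichlet regression for gene-level SNP selection
#'
#' Maximizes the penalized Dirichlet log-likelihood over all SNPs of a gene
#' simultaneously, blending a squared group-L2 (ridge, c = 1) and an L1
#' (lasso, c = 0) penalty on the SNP coefficient blocks. Optimization is
#' proximal-gradient ascent with backtracking line search (soft-thresholding
#' for the L1 part, closed-form shrinkage for the quadratic part), followed
#' by a damped Newton polish on the active set. Intercepts and, under M2,
#' pedigree contrasts are never penalized. SNP dosage columns are centered
#' and scaled before penalization; coefficients are reported on both scales.
#'
#' @param Y n x 3 simplex response matrix.
#' @param snps n x p SNP dosage matrix (one gene's markers).
#' @param c penalty mixing weight in \[0, 1\].
#' @param kappa penalty weight; \code{NULL} picks 0.1 * kappa_max, where
#'   kappa_max is the smallest lasso weight that zeroes every SNP
#'   coefficient at c = 0.
#' @param family_ids optional vector of pedigree ids; when given, M2-style
#'   unpenalized family contrasts are added.
#' @param standardize center/scale SNP columns before penalizing
#'   (default TRUE).
#' @param tol convergence tolerance on the relative objective change
#'   (default 1e-8).
#' @param max_iter maximum proximal-gradient iterations (default 5000).
#' @return object of class \code{dirich_penfit}: list with \code{eta}
#'   (standardized-scale coefficients, M x 3), \code{coef} (original-scale),
#'   \code{objective}, \code{logLik}, \code{iterations}, \code{converged},
#'   \code{group_norms} (per-SNP L2 norms, standardized scale), \code{c},
#'   \code{kappa}, \code{penalized} (row mask), \code{trace} (objective per
#'   iteration), \code{kkt} (max KKT violation at zero coefficients).
#' @export
dirichreg_penalized <- function(Y, snps, c = 0.5, kappa = NULL,
                                family_ids = NULL, standardize = TRUE,
                                tol = 1e-8, max_iter = 5000L) {
  stopifnot(c >= 0, c <= 1)
  Y <- compress_simplex(as.matrix(Y))
  snps <- as.matrix(snps)
  if (anyNA(snps))
    stop("missing dosages in the SNP matrix; impute (e.g. column means) ",
         "or drop incomplete markers before penalized fitting")
  n <- nrow(Y); p <- ncol(snps); k <- ncol(Y)
  if (is.null(colnames(snps))) colnames(snps) <- paste0("snp", seq_len(p))
  ctr <- if (standardize) colMeans(snps) else rep(0, p)
  scl <- if (standardize) {
    s <- apply(snps, 2L, stats::sd)
    if (any(s == 0)) stop("monomorphic SNP column(s): ",
                          paste(colnames(snps)[s == 0], collapse = ", "))
    s
  } else rep(1, p)
  Z <- sweep(sweep(snps, 2L, ctr), 2L, scl, "/")
  FM <- if (!is.null(family_ids)) family_contrasts(family_ids) else
    matrix(0, n, 0L)
  G <- cbind("(Intercept)" = 1, Z, FM)
  M <- ncol(G)
  penalized <- c(FALSE, rep(TRUE, p), rep(FALSE, ncol(FM)))
  logY <- log(Y)

  nll  <- function(th) .dirich_nll(th, G, logY, k)
  ngr  <- function(th) .dirich_ngr(th, G, logY, k)
  pmask <- rep(penalized, k)            # component-major stacking

  ## start: intercept-only fit, slopes 0
  theta <- .dirich_start(Y, M, k)
  f0 <- dirichreg(Y, matrix(1, n, 1L))
  th0 <- matrix(0, M, k); th0[1L, ] <- f0$coef[1L, ]
  theta <- as.vector(th0)

  if (is.null(kappa)) {
    score0 <- -ngr(theta)
    kappa <- 0.1 * max(abs(score0[pmask]))
  }
  if (kappa < 0) stop("kappa must be nonnegative")

  obj <- function(th)
    -nll(th) - .pen_value(matrix(th, M, k)[penalized, , drop = FALSE], c, kappa)

  t_step <- 1 / n
  cur <- obj(theta)
  trace <- cur
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    gr <- -ngr(theta)                   # gradient of log-likelihood
    ll_old <- -nll(theta)
    repeat {
      cand <- theta + t_step * gr
      cand[pmask] <- .prox_en(cand[pmask], t_step, c, kappa)
      delta <- cand - theta
      ll_new <- -nll(cand)
      ## majorization condition for proximal gradient ascent
      if (is.finite(ll_new) &&
          ll_new >= ll_old + sum(gr * delta) - sum(delta^2) / (2 * t_step) - 1e-12)
        break
      t_step <- t_step / 2
      if (t_step < 1e-14) break
    }
    theta <- cand
    new <- obj(theta)
    trace <- c(trace, new)
    if (abs(new - cur) <= tol * (abs(cur) + 1)) { converged <- TRUE; cur <- new; break }
    cur <- new
    t_step <- t_step * 1.5              # adaptive step growth
  }

  ## Newton polish on the active set: smooth objective once signs are fixed.
  theta <- .pen_polish(theta, obj, ngr, M, k, penalized, c, kappa,
                       G, logY)
  cur <- obj(theta)
  trace <- c(trace, cur)

  eta <- matrix(theta, M, k,
                dimnames = list(colnames(G), paste0("comp", seq_len(k))))
  score <- -ngr(theta)
  zero <- pmask & abs(theta) < 1e-12
  kkt <- if (any(zero)) max(abs(score[zero])) - (1 - c) * kappa else -Inf

  ## back-transform to the original dosage scale
  beta <- eta
  snp_rows <- 1L + seq_len(p)
  beta[snp_rows, ] <- eta[snp_rows, , drop = FALSE] / scl
  beta[1L, ] <- eta[1L, ] - colSums(eta[snp_rows, , drop = FALSE] * ctr / scl)

  gn <- sqrt(rowSums(eta[snp_rows, , drop = FALSE]^2))
  names(gn) <- colnames(snps)
  structure(list(eta = eta, coef = beta, objective = cur,
                 logLik = -nll(theta), iterations = it,
                 converged = converged, group_norms = gn,
                 c = c, kappa = kappa, penalized = penalized,
                 trace = trace, kkt = kkt, n = n, p = p,
                 center = ctr, scale = scl),
            class = "dirich_penfit")
}

## Damped Newton on nonzero + unpenalized coordinates; steps are shrunk so no
## active penalized coordinate crosses zero (sign pattern stays valid).
.pen_polish <- function(theta, obj, ngr, M, k, penalized, c, kappa,
                        G, logY, max_steps = 50L) {
  pmask <- rep(penalized, k)
  for (s in seq_len(max_steps)) {
    act <- !pmask | abs(theta) > 1e-12
    if (!any(act)) return(theta)
    sg <- sign(theta)
    gr_full <- -ngr(theta) - 2 * c * kappa * theta * pmask -
      (1 - c) * kappa * sg * pmask
    gr <- gr_full[act]
    if (sqrt(sum(gr^2)) < 1e-10) return(theta)
    H <- .dirich_hess(theta, G, logY, k)
    diag(H) <- diag(H) - 2 * c * kappa * pmask
    Ha <- H[act, act, drop = FALSE]
    step_a <- tryCatch(-solve(Ha, gr), error = function(e) NULL)
    if (is.null(step_a)) return(theta)
    step <- numeric(length(theta)); step[act] <- step_a
    ## keep active penalized coordinates on their side of zero
    cross <- pmask & act & sg != 0 & sign(theta + step) == -sg
    damp <- 1
    if (any(cross))
      damp <- min(1, 0.99 * min(-theta[cross] / step[cross]))
    f0 <- obj(theta)
    repeat {
      cand <- theta + damp * step
      cand[pmask & abs(cand) < 1e-14] <- 0
      f1 <- obj(cand)
      if (is.finite(f1) && f1 >= f0 - 1e-12) break
      damp <- damp / 2
      if (damp < 1e-10) return(theta)
    }
    if (f1 <= f0 + 1e-14 && damp == 1) { theta <- cand; return(theta) }
    theta <- cand
  }
  theta
}

#' @export
print.dirich_penfit <- function(x, ...) {
  cat("Penalized Dirichlet regression: p = ", x$p, " SNPs, c = ", x$c,
      ", kappa = ", format(x$kappa, digits = 4), "\n", sep = "")
  cat("  objective = ", format(x$objective, digits = 8),
      ", iterations = ", x$iterations,
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  cat("  selected coefficients: ", count_selected(x),
      " of ", x$p * ncol(x$eta), " (",
      sum(x$group_norms > 1e-6), " SNP groups)\n", sep = "")
  invisible(x)
}

#' @export
coef.dirich_penfit <- function(object, scale = c("original", "standardized"),
                               ...) {
  scale <- match.arg(scale)
  if (scale == "original") object$coef else object$eta
}

#' @export
logLik.dirich_penfit <- function(object, ...) {
  structure(object$logLik, class = "logLik")
}

#' Count selected (nonzero) penalized coefficients
#'
#' @param fit a \code{dirich_penfit}.
#' @param tolerance absolute threshold on the standardized-predictor scale
#'   (default 1e-6).
#' @param groups if TRUE, count SNP groups with nonzero L2 norm instead of
#'   individual coefficients.
#' @return integer count (intercepts and family contrasts excluded).
#' @export
count_selected <- function(fit, tolerance = 1e-6, groups = FALSE) {
  eta_pen <- fit$eta[fit$penalized, , drop = FALSE]
  if (groups) sum(sqrt(rowSums(eta_pen^2)) > tolerance)
  else sum(abs(eta_pen) > tolerance)
}

#' Selection path across the penalty-mixing grid
#'
#' Refits the penalized Dirichlet regression for each value of c (and kappa)
#' and tabulates the number of parameters selected together with the
#' iterations to convergence, the reporting format of gene-level selection
#' tables.
#'
#' @param Y n x 3 simplex response matrix.
#' @param snps n x p dosage matrix.
#' @param c_grid mixing weights (default \code{c(0, 0.3, 0.5, 0.7, 1)}).
#' @param kappa single value or vector; \code{NULL} picks the default of
#'   [dirichreg_penalized()] once (at c = 0) and reuses it across the grid.
#' @param family_ids optional pedigree ids for M2-style adjustment.
#' @param tolerance selection tolerance, see [count_selected()].
#' @param ... passed to [dirichreg_penalized()].
#' @return object of class \code{selection_path}: data.frame with columns
#'   n_snps, c, kappa, n_selected, n_groups, iterations, converged.
#' @export
selection_path <- function(Y, snps, c_grid = c(0, 0.3, 0.5, 0.7, 1),
                           kappa = NULL, family_ids = NULL,
                           tolerance = 1e-6, ...) {
  if (is.null(kappa)) {
    f0 <- dirichreg_penalized(Y, snps, c = 0, kappa = NULL,
                              family_ids = family_ids, max_iter = 1L)
    kappa <- f0$kappa
  }
  grid <- expand.grid(c = c_grid, kappa = kappa)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fit <- tryCatch(
      dirichreg_penalized(Y, snps, c = grid$c[i], kappa = grid$kappa[i],
                          family_ids = family_ids, ...),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(n_snps = ncol(snps), c = grid$c[i],
                        kappa = grid$kappa[i], n_selected = NA_integer_,
                        n_groups = NA_integer_, iterations = NA_integer_,
                        converged = FALSE))
    data.frame(n_snps = ncol(snps), c = grid$c[i], kappa = grid$kappa[i],
               n_selected = count_selected(fit, tolerance),
               n_groups = count_selected(fit, tolerance, groups = TRUE),
               iterations = fit$iterations, converged = fit$converged)
  })
  structure(do.call(rbind, rows),
            class = c("selection_path", "data.frame"))
}

#' @export
print.selection_path <- function(x, ...) {
  cat("Gene-level selection path (",
      x$n_snps[1L], " SNPs)\n", sep = "")
  print(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}
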