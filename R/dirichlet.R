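#' Dirichlet log-likelihood of a simplex response matrix
#'
#' \deqn{\ell = \sum_i [\log\Gamma(\Lambda_i) - \sum_j \log\Gamma(\lambda_{ij})
#'   + \sum_j (\lambda_{ij} - 1)\log y_{ij}]}
#' with \eqn{\Lambda_i = \sum_j \lambda_{ij}}.
#'
#' @param Y n x 3 matrix; every row strictly inside the simplex (entries in
#'   (0,1), summing to 1). Boundary rows raise an error: apply
#'   [compress_simplex()] first.
#' @param Lambda n x 3 matrix of positive Dirichlet concentration parameters.
#' @return scalar log-likelihood.
#' @export
dirichlet_loglik <- function(Y, Lambda) {
  Y <- as.matrix(Y); Lambda <- as.matrix(Lambda)
  stopifnot(ncol(Y) == ncol(Lambda), nrow(Y) == nrow(Lambda))
  if (any(Y <= 0) || any(Y >= 1))
    stop("response rows must lie strictly inside the simplex; ",
         "apply compress_simplex() to boundary observations")
  if (any(Lambda <= 0)) stop("all Dirichlet parameters must be positive")
  Li <- rowSums(Lambda)
  sum(lgamma(Li)) - sum(lgamma(Lambda)) + sum((Lambda - 1) * log(Y))
}

#' Compress simplex observations away from the boundary
#'
#' Applies the standard shrink-toward-centroid transform
#' \eqn{y' = (y (n - 1) + 1/k) / n} to rows with any component within
#' \code{eps} of 0 or 1 (k = number of components, n = number of rows).
#' Interior rows are returned unchanged.
#'
#' @param Y n x k simplex matrix.
#' @param eps boundary tolerance (default 1e-10).
#' @return matrix of the same shape with all rows strictly interior.
#' @export
compress_simplex <- function(Y, eps = 1e-10) {
  Y <- as.matrix(Y)
  n <- nrow(Y); k <- ncol(Y)
  bad <- rowSums(Y <= eps | Y >= 1 - eps) > 0L
  if (any(bad)) Y[bad, ] <- (Y[bad, , drop = FALSE] * (n - 1) + 1 / k) / n
  Y
}

## theta: stacked coefficient vector, one block of length M per component j.
## S: n x M design.  Returns Lambda = exp(S %*% B).
.dirich_lambda <- function(theta, S, k = 3L) {
  B <- matrix(theta, ncol = k)
  ex <- exp(S %*% B)
  pmin(ex, 1e290)   # guard overflow; fits never live out here
}

.dirich_nll <- function(theta, S, logY, k = 3L) {
  L <- .dirich_lambda(theta, S, k)
  Li <- rowSums(L)
  -(sum(lgamma(Li)) - sum(lgamma(L)) + sum((L - 1) * logY))
}

## dl/dtheta_jm = sum_i lambda_ij s_im [digamma(Lambda_i) - digamma(lambda_ij)
##                                      + log y_ij]
.dirich_ngr <- function(theta, S, logY, k = 3L) {
  L <- .dirich_lambda(theta, S, k)
  Li <- rowSums(L)
  Gm <- L * (digamma(Li) - digamma(L) + logY)     # n x k
  -as.vector(crossprod(S, Gm))
}

## Analytic Hessian of the log-likelihood (not negated). Block (j,k'):
##  sum_i s s' [ lam_ij lam_ik tri(Li) + 1{j=k'} lam_ij (g_ij - lam_ij tri(lam_ij)) ]
## with g_ij = digamma(Li) - digamma(lam_ij) + log y_ij.
.dirich_hess <- function(theta, S, logY, k = 3L) {
  L <- .dirich_lambda(theta, S, k)
  Li <- rowSums(L)
  g <- digamma(Li) - digamma(L) + logY
  tri_Li <- trigamma(Li)
  M <- ncol(S)
  H <- matrix(0, k * M, k * M)
  for (j in seq_len(k)) for (j2 in j:k) {
    w <- L[, j] * L[, j2] * tri_Li
    if (j2 == j) w <- w + L[, j] * g[, j] - L[, j]^2 * trigamma(L[, j])
    blk <- crossprod(S * w, S)
    ri <- (j - 1L) * M + seq_len(M); ci <- (j2 - 1L) * M + seq_len(M)
    H[ri, ci] <- blk
    if (j2 != j) H[ci, ri] <- t(blk)
  }
  H
}

## Moment-based starting values for the intercepts; slopes start at zero.
.dirich_start <- function(Y, M, k = 3L) {
  m <- colMeans(Y)
  v <- stats::var(Y[, 1L])
  prec <- max(m[1L] * (1 - m[1L]) / max(v, 1e-8) - 1, 0.5)
  theta0 <- matrix(0, M, k)
  theta0[1L, ] <- log(pmax(m, 1e-6) * prec)
  as.vector(theta0)
}

#' Dirichlet regression with log link
#'
#' Fits the common-parametrization Dirichlet regression: each concentration
#' parameter has its own linear predictor,
#' \eqn{\log \lambda_{ij} = s_i^\top \theta_j}, j = 1..k, with no reference
#' component. Maximization is quasi-Newton (BFGS with analytic gradient)
#' followed by Newton polishing with the analytic Hessian; the coefficient
#' covariance is the inverse observed information.
#'
#' @param Y n x k simplex response matrix (k = 3 for the blood-pressure
#'   application); boundary rows are compressed via [compress_simplex()].
#' @param S n x M design matrix including the intercept column. If missing, an
#'   intercept-only design is used.
#' @param tol gradient-norm convergence target (default 1e-6).
#' @param max_newton maximum Newton polishing steps.
#' @return object of class \code{dirich_fit}: list with \code{coef}
#'   (M x k matrix, rows = design columns, columns = components),
#'   \code{vcov} (kM x kM, component-major order matching
#'   \code{as.vector(coef)}), \code{logLik}, \code{fitted.lambda},
#'   \code{converged}, \code{grad_norm}, \code{n}, \code{df}.
#' @examples
#' set.seed(1)
#' Y <- rdirichlet(200, c(2, 2, 2))
#' f <- dirichreg(Y)
#' coef(f)          # intercepts approx log(2)
#' @export
dirichreg <- function(Y, S = NULL, tol = 1e-6, max_newton = 25L) {
  Y <- compress_simplex(as.matrix(Y))
  n <- nrow(Y); k <- ncol(Y)
  if (is.null(S)) S <- matrix(1, n, 1L, dimnames = list(NULL, "(Intercept)"))
  S <- as.matrix(S)
  if (is.null(colnames(S))) colnames(S) <- paste0("s", seq_len(ncol(S)))
  stopifnot(nrow(S) == n)
  qrS <- qr(S)
  if (qrS$rank < ncol(S)) {
    drop_cols <- colnames(S)[qrS$pivot[-seq_len(qrS$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(drop_cols, collapse = ", "))
  }
  logY <- log(Y)
  M <- ncol(S)
  theta <- .dirich_start(Y, M, k)
  opt <- stats::optim(theta, .dirich_nll, .dirich_ngr, S = S, logY = logY,
                      k = k, method = "BFGS",
                      control = list(maxit = 500L, reltol = 1e-12))
  theta <- opt$par
  ## Newton polish to drive the gradient norm below tol
  conv <- FALSE
  for (it in seq_len(max_newton)) {
    gr <- -.dirich_ngr(theta, S, logY, k)
    if (sqrt(sum(gr^2)) < tol) { conv <- TRUE; break }
    H <- .dirich_hess(theta, S, logY, k)
    step <- tryCatch(solve(H, gr), error = function(e) NULL)
    if (is.null(step)) break
    step <- -step                       # ascend: H is negative definite at max
    f0 <- .dirich_nll(theta, S, logY, k)
    damp <- 1
    repeat {
      cand <- theta + damp * step
      f1 <- .dirich_nll(cand, S, logY, k)
      if (is.finite(f1) && f1 <= f0 + 1e-12) { theta <- cand; break }
      damp <- damp / 2
      if (damp < 1e-10) break
    }
    if (damp < 1e-10) break
  }
  gr <- -.dirich_ngr(theta, S, logY, k)
  grad_norm <- sqrt(sum(gr^2))
  conv <- grad_norm < max(tol, 1e-4)    # polished fits report the true norm
  H <- .dirich_hess(theta, S, logY, k)
  V <- tryCatch(solve(-H), error = function(e) matrix(NA_real_, k * M, k * M))
  V <- (V + t(V)) / 2
  cf <- matrix(theta, M, k,
               dimnames = list(colnames(S), paste0("comp", seq_len(k))))
  lab <- as.vector(outer(colnames(S), paste0("comp", seq_len(k)),
                         function(a, b) paste(b, a, sep = ":")))
  dimnames(V) <- list(lab, lab)
  structure(list(coef = cf, vcov = V,
                 logLik = -.dirich_nll(theta, S, logY, k),
                 fitted.lambda = .dirich_lambda(theta, S, k),
                 converged = conv, grad_norm = grad_norm,
                 n = n, k = k, df = k * M, S = S, Y = Y),
            class = "dirich_fit")
}

#' @export
coef.dirich_fit <- function(object, ...) object$coef

#' @export
vcov.dirich_fit <- function(object, ...) object$vcov

#' @export
logLik.dirich_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n, class = "logLik")
}

#' @export
fitted.dirich_fit <- function(object, ...) {
  object$fitted.lambda / rowSums(object$fitted.lambda)
}

#' @export
predict.dirich_fit <- function(object, newdata = NULL,
                               type = c("mean", "lambda"), ...) {
  type <- match.arg(type)
  S <- if (is.null(newdata)) object$S else as.matrix(newdata)
  L <- exp(S %*% object$coef)
  if (type == "lambda") L else L / rowSums(L)
}

#' @export
print.dirich_fit <- function(x, ...) {
  cat("Dirichlet regression (log link), n = ", x$n,
      ", logLik = ", format(x$logLik, digits = 7),
      if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(x$coef)
  invisible(x)
}

#' @export
summary.dirich_fit <- function(object, ...) {
  se <- matrix(sqrt(pmax(diag(object$vcov), 0)),
               nrow(object$coef), object$k)
  z <- object$coef / se
  out <- list(coef = object$coef, se = se, z = z,
              p = 2 * stats::pnorm(-abs(z)),
              logLik = object$logLik, n = object$n,
              converged = object$converged)
  class(out) <- "summary.dirich_fit"
  out
}

#' @export
print.summary.dirich_fit <- function(x, ...) {
  cat("Dirichlet regression summary (n = ", x$n, ", logLik = ",
      format(x$logLik, digits = 7), ")\n", sep = "")
  for (j in seq_len(ncol(x$coef))) {
    cat("\nComponent", j, "\n")
    tab <- cbind(Estimate = x$coef[, j], `Std. Error` = x$se[, j],
                 `z value` = x$z[, j], `Pr(>|z|)` = x$p[, j])
    stats::printCoefmat(tab, digits = 4)
  }
  invisible(x)
}

#' Draw from a Dirichlet distribution
#'
#' @param n number of draws.
#' @param alpha concentration vector, or n x k matrix of per-row parameters.
#' @return n x k matrix of simplex rows.
#' @export
rdirichlet <- function(n, alpha) {
  if (is.matrix(alpha)) {
    stopifnot(nrow(alpha) == n)
    g <- matrix(stats::rgamma(length(alpha), shape = alpha), n, ncol(alpha))
  } else {
    k <- length(alpha)
    g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), n, k)
  }
  g / rowSums(g)
}
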