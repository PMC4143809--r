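#' Treatment-coded pedigree contrasts
#'
#' Builds the n x (F-1) indicator matrix for pedigree membership used by the
#' family-adjusted model M2, with the largest family as the reference level.
#' Families smaller than \code{min_size} are pooled into the reference to
#' avoid rank problems from near-empty categories.
#'
#' @param family_ids vector of family identifiers, one per subject.
#' @param min_size smallest family kept as its own level (default 2).
#' @return n x (F-1) numeric matrix (zero columns when one family remains).
#' @export
family_contrasts <- function(family_ids, min_size = 2L) {
  f <- as.character(family_ids)
  if (length(f) == 0L) stop("need at least one subject")
  sizes <- table(f)
  ref <- names(sizes)[which.max(sizes)]
  pooled <- names(sizes)[sizes < min_size]
  f[f %in% c(ref, pooled)] <- ref
  lev <- c(ref, sort(setdiff(unique(f), ref)))
  ff <- factor(f, levels = lev)
  if (nlevels(ff) == 1L)
    return(matrix(0, length(f), 0L))
  FM <- stats::model.matrix(~ ff)[, -1L, drop = FALSE]
  colnames(FM) <- paste0("fam", lev[-1L])
  rownames(FM) <- NULL
  FM
}

#' Joint Wald test of the per-component SNP coefficients
#'
#' Tests H0: beta = (beta_1, ..., beta_k) = 0, where beta_j is the SNP dosage
#' coefficient in the linear predictor of component j. The statistic is
#' \eqn{W = \hat\beta^\top \hat V^{-1} \hat\beta}, chi-square with k degrees
#' of freedom under H0.
#'
#' @param fit a \code{dirich_fit}.
#' @param coef_name name of the design column to test (default \code{"g"},
#'   the dosage column used by [snp_scan()]).
#' @return list with \code{statistic}, \code{df}, \code{p.value},
#'   \code{labels}.
#' @export
wald_test <- function(fit, coef_name = "g") {
  stopifnot(inherits(fit, "dirich_fit"))
  if (!fit$converged) stop("fit did not converge; Wald test unavailable")
  M <- nrow(fit$coef)
  r <- match(coef_name, rownames(fit$coef))
  if (is.na(r)) stop("coefficient '", coef_name, "' not in the fit")
  idx <- (seq_len(fit$k) - 1L) * M + r
  b <- fit$coef[r, ]
  V <- fit$vcov[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular covariance sub-matrix for the tested coefficients"))
  W <- max(0, drop(t(b) %*% Vi %*% b))
  list(statistic = W, df = fit$k,
       p.value = stats::pchisq(W, fit$k, lower.tail = FALSE),
       labels = colnames(fit$vcov)[idx])
}

## Fit one marker under M1 (intercept + dosage) or M2 (+ family contrasts).
.fit_marker <- function(y, g, FM = NULL) {
  S <- cbind("(Intercept)" = 1, g = g)
  if (!is.null(FM) && ncol(FM)) S <- cbind(S, FM)
  dirichreg(y, S)
}

#' Per-SNP Dirichlet regression association scan
#'
#' Fits, for every marker, the base model M1
#' (\eqn{\log\lambda_{ij} = \alpha_j + \beta_j g_{ik}}) and/or the
#' family-adjusted model M2 (adding fixed pedigree contrasts), and reports
#' the joint k-df Wald p-value for the SNP effect. Subjects with missing
#' dosage at a marker are dropped for that marker only. Markers whose fit
#' fails to converge are flagged and given NA p-values.
#'
#' @param responses a \code{response_set} from [extract_responses()], or any
#'   data.frame with columns subject_id, family_id, y1..y3.
#' @param genotypes a \code{genotype_matrix} (see [read_genotypes()]) or a
#'   plain n x p dosage matrix with subject ids as rownames.
#' @param models character subset of \code{c("M1", "M2")}.
#' @param min_family_size passed to [family_contrasts()].
#' @param sig_threshold genome-wide significance flag threshold
#'   (default 5e-8).
#' @return object of class \code{dirich_scan}: data.frame with one row per
#'   marker (id, chrom, pos, minor allele, maf, p / convergence flag per
#'   model, significance flag).
#' @export
snp_scan <- function(responses, genotypes, models = c("M1", "M2"),
                     min_family_size = 2L, sig_threshold = 5e-8) {
  models <- match.arg(models, c("M1", "M2"), several.ok = TRUE)
  resp <- as.data.frame(responses)
  G <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
       else as.matrix(genotypes)
  map <- if (inherits(genotypes, "genotype_matrix")) genotypes$map else NULL
  if (is.null(rownames(G))) stop("genotype matrix needs subject ids as rownames")
  orphans_p <- setdiff(resp$subject_id, rownames(G))
  orphans_g <- setdiff(rownames(G), resp$subject_id)
  if (length(orphans_p))
    stop("subjects with responses but no genotypes: ",
         paste(utils::head(orphans_p, 5L), collapse = ", "),
         if (length(orphans_p) > 5L) " ...")
  G <- G[match(resp$subject_id, rownames(G)), , drop = FALSE]
  if (length(orphans_g))
    message(length(orphans_g), " genotyped subjects without responses ignored")
  Y <- as.matrix(resp[, c("y1", "y2", "y3")])
  FM <- if ("M2" %in% models)
    family_contrasts(resp$family_id, min_family_size) else NULL
  p <- ncol(G)
  out <- data.frame(marker = colnames(G), stringsAsFactors = FALSE)
  if (!is.null(map)) {
    mi <- match(out$marker, map$id)
    out$chrom <- map$chrom[mi]; out$pos <- map$pos[mi]
    out$minor_allele <- map$minor_allele[mi]
  }
  out$maf <- apply(G, 2L, function(d) {
    m <- mean(d, na.rm = TRUE) / 2; min(m, 1 - m)
  })
  for (mod in models) {
    pv <- rep(NA_real_, p); ok <- logical(p)
    for (j in seq_len(p)) {
      g <- G[, j]
      keep <- !is.na(g)
      res <- tryCatch({
        fit <- .fit_marker(Y[keep, , drop = FALSE], g[keep],
                           if (mod == "M2") FM[keep, , drop = FALSE])
        if (!fit$converged) stop("no convergence")
        wald_test(fit)$p.value
      }, error = function(e) NA_real_)
      pv[j] <- res; ok[j] <- !is.na(res)
    }
    out[[paste0("p_", mod)]] <- pv
    out[[paste0("converged_", mod)]] <- ok
  }
  pmin_col <- do.call(pmin, c(out[paste0("p_", models)], na.rm = TRUE))
  out$significant <- !is.na(pmin_col) & pmin_col < sig_threshold
  structure(out, class = c("dirich_scan", "data.frame"),
            models = models, sig_threshold = sig_threshold)
}

#' @export
print.dirich_scan <- function(x, ...) {
  cat("Dirichlet regression scan: ", nrow(x), " markers, models ",
      paste(attr(x, "models"), collapse = "+"), "\n", sep = "")
  for (m in attr(x, "models")) {
    pc <- x[[paste0("p_", m)]]
    cat("  ", m, ": min p = ", format(min(pc, na.rm = TRUE), digits = 3),
        " (", sum(!is.na(pc)), " converged)\n", sep = "")
  }
  if (any(x$significant))
    cat("  significant at ", format(attr(x, "sig_threshold")), ": ",
        paste(x$marker[x$significant], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Manhattan plot of a scan
#'
#' Plots -log10(p) against position (or marker index when no map is
#' attached), one panel series per model, with the genome-wide threshold as
#' a horizontal line.
#'
#' @param x a \code{dirich_scan}.
#' @param model which model's p-values to plot (default the first fitted).
#' @param ... passed to [graphics::plot()].
#' @export
plot.dirich_scan <- function(x, model = attr(x, "models")[1L], ...) {
  pv <- x[[paste0("p_", model)]]
  pos <- if ("pos" %in% names(x) && !anyNA(x$pos)) x$pos else seq_len(nrow(x))
  graphics::plot(pos, -log10(pv), pch = 20,
                 xlab = if ("pos" %in% names(x)) "position (bp)" else "marker index",
                 ylab = expression(-log[10](p)),
                 main = paste("Dirichlet scan,", model), ...)
  graphics::abline(h = -log10(attr(x, "sig_threshold")), lty = 2, col = "red")
  invisible(x)
}
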