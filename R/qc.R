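#' Construct a genotype matrix object
#'
#' Container for additive-coded genotypes: an n x p dosage matrix (0-2 minor
#' allele copies, possibly fractional for imputed data, NA for missing) with
#' subject ids as rownames and marker ids as colnames, plus optional marker
#' metadata.
#'
#' @param dosage numeric matrix, entries in \[0, 2\] or NA.
#' @param map optional data.frame with columns \code{id}, \code{chrom},
#'   \code{pos} and optionally \code{ref}, \code{alt}, \code{minor_allele},
#'   aligned to \code{colnames(dosage)}.
#' @param hard_calls logical; if missing, detected as all non-missing entries
#'   being in {0, 1, 2}.
#' @return object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosage, map = NULL, hard_calls = NULL) {
  dosage <- as.matrix(dosage)
  if (is.null(rownames(dosage))) stop("dosage needs subject ids as rownames")
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("m", seq_len(ncol(dosage)))
  if (anyDuplicated(colnames(dosage))) stop("marker ids must be unique")
  rng <- range(dosage, na.rm = TRUE)
  if (is.finite(rng[1L]) && (rng[1L] < 0 || rng[2L] > 2))
    stop("dosages must lie in [0, 2]")
  if (is.null(hard_calls)) {
    v <- dosage[!is.na(dosage)]
    hard_calls <- length(v) == 0L || all(v %in% c(0, 1, 2))
  }
  if (!is.null(map)) {
    if (!all(c("id", "chrom", "pos") %in% names(map)))
      stop("map needs columns id, chrom, pos")
    map <- map[match(colnames(dosage), map$id), , drop = FALSE]
  }
  structure(list(dosage = dosage, map = map, hard_calls = hard_calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix: ", nrow(x$dosage), " subjects x ", ncol(x$dosage),
      " markers (", if (x$hard_calls) "hard calls" else "dosages", ", ",
      format(100 * mean(is.na(x$dosage)), digits = 3), "% missing)\n",
      sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Minor allele frequency per marker
#'
#' MAF is computed from non-missing dosages as min(m, 1 - m) with
#' m = mean(dosage) / 2, and is invariant to allele-label swap.
#'
#' @param G a \code{genotype_matrix} or dosage matrix.
#' @return named numeric vector of MAFs.
#' @export
maf <- function(G) {
  d <- if (inherits(G, "genotype_matrix")) G$dosage else as.matrix(G)
  m <- colMeans(d, na.rm = TRUE) / 2
  pmin(m, 1 - m)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of HWE: given the observed allele counts, the
#' p-value is the sum of probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count. The
#' probabilities are computed by the standard stable recurrence over
#' heterozygote counts. Monomorphic markers return p = 1.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (nonnegative, not all zero).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be nonnegative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0L) stop("all genotype counts are zero")
  n_A <- 2L * n_AA + n_Aa
  rare <- min(n_A, 2L * n - n_A)
  if (rare == 0L) return(1)
  ## heterozygote counts share the parity of the rare-allele count
  hs <- seq(rare %% 2L, rare, by = 2L)
  probs <- numeric(length(hs))
  ## start from the modal region for numerical stability: begin at largest h
  ## and recurse downward; P(h-2)/P(h) = h(h-1) / (4 (r(h)+1)(c(h)+1))
  probs[length(hs)] <- 1
  for (i in rev(seq_len(length(hs) - 1L))) {
    h <- hs[i + 1L]
    r_hom <- (rare - h) / 2
    c_hom <- n - h - r_hom
    probs[i] <- probs[i + 1L] * h * (h - 1) /
      (4 * (r_hom + 1) * (c_hom + 1))
  }
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, hs)]
  if (is.na(obs)) stop("inconsistent genotype counts")
  min(1, sum(probs[probs <= obs * (1 + 1e-12)]))
}

#' Remove samples with low genotyping call rate
#'
#' @param G a \code{genotype_matrix}.
#' @param threshold minimum fraction of non-missing markers per sample
#'   (default 0.95).
#' @return list with \code{genotypes} (filtered \code{genotype_matrix}) and
#'   \code{removed} (character vector of dropped subject ids).
#' @export
sample_call_rate_filter <- function(G, threshold = 0.95) {
  stopifnot(inherits(G, "genotype_matrix"))
  cr <- rowMeans(!is.na(G$dosage))
  drop <- cr < threshold
  out <- genotype_matrix(G$dosage[!drop, , drop = FALSE], G$map,
                         G$hard_calls)
  list(genotypes = out, removed = rownames(G$dosage)[drop])
}

#' Marker quality-control cascade
#'
#' Applies, in order: marker call rate (missingness at most
#' 1 - \code{call_rate}), exact Hardy-Weinberg test (hard-call data only;
#' skipped with a notice for imputed dosages), and minor allele frequency.
#' Each marker is removed at the first stage it fails, so the stage counts
#' partition the input marker set.
#'
#' @param G a \code{genotype_matrix}.
#' @param call_rate minimum fraction of non-missing genotypes per marker
#'   (default 0.95).
#' @param hwe_alpha HWE exact-test significance level (default 1e-6).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @return list with \code{genotypes} (filtered) and \code{report}
#'   (a \code{qc_report}).
#' @export
marker_filters <- function(G, call_rate = 0.95, hwe_alpha = 1e-6,
                           maf_min = 0.05) {
  stopifnot(inherits(G, "genotype_matrix"))
  d <- G$dosage
  p0 <- ncol(d)
  status <- rep("retained", p0)

  cr <- colMeans(!is.na(d))
  status[cr < call_rate] <- "call_rate"

  hwe_applied <- G$hard_calls
  if (hwe_applied) {
    idx <- which(status == "retained")
    for (j in idx) {
      v <- d[, j]; v <- v[!is.na(v)]
      p <- hwe_exact_test(sum(v == 0), sum(v == 1), sum(v == 2))
      if (p < hwe_alpha) status[j] <- "hwe"
    }
  } else {
    message("dosage (non-hard-call) genotypes: HWE filter skipped")
  }

  idx <- which(status == "retained")
  mafs <- maf(d[, idx, drop = FALSE])
  status[idx[mafs < maf_min]] <- "maf"

  keep <- status == "retained"
  report <- structure(list(
    n_input = p0,
    removed_call_rate = sum(status == "call_rate"),
    removed_hwe = sum(status == "hwe"),
    removed_maf = sum(status == "maf"),
    retained = sum(keep),
    hwe_applied = hwe_applied,
    thresholds = list(call_rate = call_rate, hwe_alpha = hwe_alpha,
                      maf_min = maf_min),
    marker_status = stats::setNames(status, colnames(d))),
    class = "qc_report")
  list(genotypes = genotype_matrix(d[, keep, drop = FALSE],
                                   if (!is.null(G$map))
                                     G$map[keep, , drop = FALSE],
                                   G$hard_calls),
       report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Marker QC report\n")
  cat("  input markers:          ", x$n_input, "\n")
  cat("  removed by call rate:   ", x$removed_call_rate,
      " (< ", x$thresholds$call_rate, ")\n", sep = "")
  cat("  removed by HWE:         ", x$removed_hwe,
      if (!x$hwe_applied) " (skipped: dosage data)",
      " (p < ", format(x$thresholds$hwe_alpha), ")\n", sep = "")
  cat("  removed by MAF:         ", x$removed_maf,
      " (< ", x$thresholds$maf_min, ")\n", sep = "")
  cat("  retained:               ", x$retained, "\n")
  invisible(x)
}
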