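#' Read genotypes from VCF, PLINK text, or dosage CSV
#'
#' Supported formats:
#' \describe{
#'   \item{vcf}{VCF 4.x via the vcfR package. Per site, the GT field is
#'     converted to alternate-allele counts (DS is used when GT is absent);
#'     hard calls are then oriented to the minor allele. Multi-allelic sites
#'     are skipped with a warning; missing calls ("./.") become NA.}
#'   \item{plink}{A .ped/.map text pair (give either file). Allele pairs are
#'     counted toward the minor allele; "0" denotes missing.}
#'   \item{dosage_csv}{CSV with a subject-id first column and one marker per
#'     remaining column; values are kept exactly as read (imputed dosages
#'     stay fractional, orientation untouched). Marker metadata may be
#'     supplied via \code{map_path} (CSV with columns id, chrom, pos, ...).}
#' }
#'
#' @param path input file.
#' @param format one of \code{"auto"}, \code{"vcf"}, \code{"plink"},
#'   \code{"dosage_csv"}; \code{"auto"} keys on the file extension.
#' @param map_path optional marker map CSV for \code{dosage_csv} input.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink",
                                            "dosage_csv"),
                           map_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
    format <- switch(ext,
                     vcf = "vcf",
                     ped = , map = "plink",
                     csv = "dosage_csv",
                     stop("cannot infer genotype format from '", path, "'"))
  }
  switch(format,
         vcf = .read_vcf(path),
         plink = .read_plink_text(path),
         dosage_csv = .read_dosage_csv(path, map_path))
}

.read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- matrix(fix, ncol = ncol(fix), dimnames = dimnames(fix))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic site(s) skipped")
  }
  keep <- which(!multi)
  if (!length(keep)) stop("no biallelic sites in ", path)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"), error = function(e) NULL)
  if (!is.null(gt) && !all(is.na(gt))) {
    gt <- gt[keep, , drop = FALSE]
    cnt <- function(x) {
      a <- strsplit(gsub("\\|", "/", x), "/", fixed = FALSE)
      vapply(a, function(al) {
        if (length(al) == 0L || anyNA(al) || any(al == "." | al == ""))
          return(NA_real_)
        sum(al == "1")
      }, numeric(1))
    }
    dos <- t(apply(gt, 1L, cnt))
    if (ncol(gt) == 1L) dos <- matrix(dos, ncol = 1L)
    hard <- TRUE
  } else {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    if (is.null(ds)) stop("VCF has neither GT nor DS fields")
    dos <- ds[keep, , drop = FALSE]
    hard <- FALSE
  }
  ids <- fix[keep, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[is.na(ids) | ids == "."]
  rownames(dos) <- ids
  dos <- t(dos)                          # subjects x markers
  minor <- fix[keep, "ALT"]
  if (hard) {
    ## orient hard calls to the minor allele
    afreq <- colMeans(dos, na.rm = TRUE) / 2
    flip <- !is.na(afreq) & afreq > 0.5
    dos[, flip] <- 2 - dos[, flip, drop = FALSE]
    minor[flip] <- fix[keep, "REF"][flip]
  }
  map <- data.frame(id = ids, chrom = fix[keep, "CHROM"],
                    pos = as.numeric(fix[keep, "POS"]),
                    ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                    minor_allele = minor, stringsAsFactors = FALSE)
  genotype_matrix(dos, map, hard_calls = hard)
}

.read_plink_text <- function(path) {
  base <- sub("\\.(ped|map)$", "", path)
  ped_path <- paste0(base, ".ped"); map_path <- paste0(base, ".map")
  if (!file.exists(ped_path)) stop("missing PLINK file: ", ped_path)
  if (!file.exists(map_path)) stop("missing PLINK file: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(mp) < 4L) stop("malformed .map: expected 4 columns")
  names(mp)[c(1L, 2L, 4L)] <- c("chrom", "id", "pos")
  ped <- utils::read.table(ped_path, header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  p <- nrow(mp)
  if (ncol(ped) != 6L + 2L * p)
    stop("malformed .ped: ", ncol(ped), " columns for ", p, " markers")
  ids <- ped[[2L]]
  dos <- matrix(NA_real_, nrow(ped), p,
                dimnames = list(ids, mp$id))
  minor <- character(p)
  for (j in seq_len(p)) {
    a1 <- ped[[6L + 2L * j - 1L]]; a2 <- ped[[6L + 2L * j]]
    miss <- a1 == "0" | a2 == "0"
    alleles <- sort(unique(c(a1[!miss], a2[!miss])))
    if (length(alleles) == 0L) { minor[j] <- NA_character_; next }
    counts <- vapply(alleles, function(a)
      sum(a1[!miss] == a) + sum(a2[!miss] == a), numeric(1))
    minor[j] <- alleles[which.min(counts)]
    dos[, j] <- (a1 == minor[j]) + (a2 == minor[j])
    dos[miss, j] <- NA_real_
  }
  mp$minor_allele <- minor
  genotype_matrix(dos, mp[, c("id", "chrom", "pos", "minor_allele")],
                  hard_calls = TRUE)
}

.read_dosage_csv <- function(path, map_path = NULL) {
  d <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE,
                       check.names = FALSE)
  if (ncol(d) < 2L) stop("dosage CSV needs an id column plus markers")
  ids <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  map <- if (!is.null(map_path))
    utils::read.csv(map_path, stringsAsFactors = FALSE) else NULL
  genotype_matrix(m, map)
}

#' Write the simplex responses to CSV
#'
#' @param responses a \code{response_set}.
#' @param path output CSV path.
#' @export
write_responses <- function(responses, path) {
  utils::write.csv(as.data.frame(responses), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read simplex responses written by [write_responses()]
#' @param path CSV path.
#' @return a \code{response_set}.
#' @export
read_responses <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "family_id", "conditioning_state",
            "y1", "y2", "y3")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("response CSV lacks columns: ",
                         paste(miss, collapse = ", "))
  structure(d, class = c("response_set", "data.frame"))
}

#' Serialize fitted transition models to JSON
#'
#' Stores, per previous state: the model shape, coefficient matrix,
#' log-likelihood and factor levels — enough to rebuild TPMs.
#'
#' @param models a \code{transition_models}.
#' @param path output JSON path.
#' @export
write_transition_json <- function(models, path) {
  obj <- list(
    shapes = models$shapes,
    time_levels = models$time_levels,
    fits = lapply(models$fits, function(f) list(
      prev_state = f$prev_state,
      formula = deparse(f$formula),
      coef = as.list(as.data.frame(f$coef)),
      coef_rows = rownames(f$coef),
      logLik = f$logLik, n = f$n,
      xlevels = f$xlevels)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a scan table as TSV
#' @param scan a \code{dirich_scan}.
#' @param path output TSV path.
#' @export
write_scan <- function(scan, path) {
  utils::write.table(as.data.frame(scan), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a selection path as TSV
#' @param path_obj a \code{selection_path}.
#' @param path output TSV path.
#' @export
write_selection <- function(path_obj, path) {
  utils::write.table(as.data.frame(path_obj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
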