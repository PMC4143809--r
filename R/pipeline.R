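#' Read a long-format phenotype CSV
#'
#' One row per (subject, exam); empty fields and "NA" are read as missing.
#'
#' @param path CSV path.
#' @param col_map optional named character vector mapping canonical column
#'   names (subject_id, family_id, exam, sbp, dbp, meds, sex, smoke, age)
#'   to the file's column names.
#' @return data.frame of exam records.
#' @export
read_phenotypes <- function(path, col_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("", "NA"))
  if (!is.null(col_map))
    for (canon in names(col_map))
      names(d)[names(d) == col_map[[canon]]] <- canon
  if ("meds" %in% names(d)) d$meds <- as.logical(d$meds)
  d
}

.default_config <- function() {
  list(phenotypes = NULL, genotypes = NULL, genotype_format = "auto",
       col_map = NULL, out_dir = "dirichscan_out",
       qc = list(sample_call_rate = 0.95, marker_call_rate = 0.95,
                 hwe_alpha = 1e-6, maf_min = 0.05),
       models = c("M1", "M2"), time_effect = "select",
       sig_threshold = 5e-8,
       genes = NULL,              # named list of marker-id vectors
       penalty = list(c_grid = c(0, 0.3, 0.5, 0.7, 1), kappa = NULL),
       min_family_size = 2L,
       seed = 1L)
}

#' Validate and normalize a pipeline run configuration
#'
#' @param config a list (see [run_pipeline()]) or path to a YAML/JSON file.
#' @return validated config list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML config requires the yaml package; use JSON instead")
      yaml::read_yaml(config)
    } else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(.default_config(), config)
  for (f in c("phenotypes", "genotypes")) {
    if (is.null(cfg[[f]])) stop("config field '", f, "' is required")
    if (!file.exists(cfg[[f]])) stop(f, " file not found: ", cfg[[f]])
  }
  stopifnot(cfg$qc$sample_call_rate >= 0, cfg$qc$sample_call_rate <= 1,
            cfg$qc$marker_call_rate >= 0, cfg$qc$marker_call_rate <= 1,
            cfg$qc$hwe_alpha > 0, cfg$qc$hwe_alpha < 1,
            cfg$qc$maf_min >= 0, cfg$qc$maf_min < 0.5,
            cfg$sig_threshold > 0, cfg$sig_threshold < 1)
  cfg$models <- match.arg(cfg$models, c("M1", "M2"), several.ok = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' Run the full association pipeline
#'
#' Executes QC, state assignment, transition-model fitting, response
#' extraction, the per-SNP Dirichlet scan, and (when gene definitions are
#' supplied) gene-level penalized selection, writing all artifacts to
#' \code{config$out_dir}: \code{qc_report.json}, \code{transition_models.json},
#' \code{responses.csv}, \code{scan.tsv}, \code{manhattan.png},
#' \code{selection_<gene>.tsv} and \code{manifest.json}. Outputs are a pure
#' function of (inputs, config, seed); a rerun with the same config yields
#' byte-identical numeric artifacts.
#'
#' @param config list or YAML/JSON path; see [validate_config()]. Required
#'   fields: \code{phenotypes}, \code{genotypes}. Optional: \code{out_dir},
#'   \code{qc} thresholds, \code{models}, \code{time_effect},
#'   \code{sig_threshold}, \code{genes} (named list of marker-id vectors for
#'   penalized selection), \code{penalty} (c_grid, kappa), \code{seed}.
#' @return (invisibly) list with all stage objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  art <- list()
  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e)
      stop("pipeline failed at stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }

  G <- stage("read-genotypes",
             read_genotypes(cfg$genotypes, cfg$genotype_format))
  sf <- stage("qc-samples",
              sample_call_rate_filter(G, cfg$qc$sample_call_rate))
  mf <- stage("qc-markers",
              marker_filters(sf$genotypes, cfg$qc$marker_call_rate,
                             cfg$qc$hwe_alpha, cfg$qc$maf_min))
  qc_json <- file.path(cfg$out_dir, "qc_report.json")
  rep <- mf$report
  jsonlite::write_json(list(
    samples_removed = sf$removed,
    markers = rep[c("n_input", "removed_call_rate", "removed_hwe",
                    "removed_maf", "retained", "hwe_applied")],
    thresholds = rep$thresholds), qc_json, auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  art$qc_report <- qc_json

  records <- stage("read-phenotypes",
                   read_phenotypes(cfg$phenotypes, cfg$col_map))
  seqs <- stage("states", build_state_sequences(records))
  tm <- stage("transition",
              transition_models(seqs, time_effect = cfg$time_effect))
  tm_json <- file.path(cfg$out_dir, "transition_models.json")
  write_transition_json(tm, tm_json)
  art$transition_models <- tm_json

  resp <- stage("response", extract_responses(tm, seqs))
  ## keep only subjects passing genotype QC
  resp <- resp[resp$subject_id %in% rownames(mf$genotypes$dosage), ,
               drop = FALSE]
  if (nrow(resp) == 0L)
    stop("pipeline failed at stage 'response': no subjects with both ",
         "responses and QC-passed genotypes", call. = FALSE)
  resp_csv <- file.path(cfg$out_dir, "responses.csv")
  write_responses(resp, resp_csv)
  art$responses <- resp_csv

  Gq <- mf$genotypes
  Gq$dosage <- Gq$dosage[match(resp$subject_id, rownames(Gq$dosage)), ,
                         drop = FALSE]
  scan <- stage("scan",
                snp_scan(resp, Gq, models = cfg$models,
                         min_family_size = cfg$min_family_size,
                         sig_threshold = cfg$sig_threshold))
  scan_tsv <- file.path(cfg$out_dir, "scan.tsv")
  write_scan(scan, scan_tsv)
  art$scan <- scan_tsv
  mh <- file.path(cfg$out_dir, "manhattan.png")
  ok <- tryCatch({
    grDevices::png(mh, width = 900, height = 420)
    plot(scan)
    grDevices::dev.off()
    TRUE
  }, error = function(e) FALSE)
  if (ok) art$manhattan <- mh

  sel <- NULL
  if (!is.null(cfg$genes)) {
    sel <- list()
    Y <- as.matrix(resp[, c("y1", "y2", "y3")])
    for (gene in names(cfg$genes)) {
      ids <- intersect(cfg$genes[[gene]], colnames(Gq$dosage))
      if (!length(ids)) next
      snps <- Gq$dosage[, ids, drop = FALSE]
      snps[is.na(snps)] <- matrix(rep(colMeans(snps, na.rm = TRUE),
                                      each = nrow(snps)),
                                  nrow(snps))[is.na(snps)]
      fam <- if ("M2" %in% cfg$models) resp$family_id else NULL
      sp <- stage(paste0("gene-select:", gene),
                  selection_path(Y, snps, c_grid = cfg$penalty$c_grid,
                                 kappa = cfg$penalty$kappa,
                                 family_ids = fam))
      f <- file.path(cfg$out_dir, paste0("selection_", gene, ".tsv"))
      write_selection(sp, f)
      sel[[gene]] <- sp
      art[[paste0("selection_", gene)]] <- f
    }
  }

  cfg_for_hash <- cfg
  manifest <- list(
    package = "dirichscan",
    version = as.character(utils::packageVersion("dirichscan")),
    seed = cfg$seed,
    config_hash = .config_hash(cfg_for_hash),
    n_subjects = nrow(resp),
    n_markers = ncol(Gq$dosage),
    artifacts = unlist(lapply(art, basename), use.names = TRUE))
  mf_json <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  art$manifest <- mf_json

  invisible(list(config = cfg, qc = rep, sequences = seqs,
                 transition = tm, responses = resp, scan = scan,
                 selection = sel, artifacts = art))
}

## md5 of the canonicalized config (written through a temp file; no
## timestamps so identical configs hash identically)
.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
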