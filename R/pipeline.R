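# End-to-end orchestration: load a cohort directory, run the molecular
# arm (clonality + burden + signatures + cohort statistics) and the
# pathology arm (tile features + inter-focus correlation), and write the
# result bundle as TSV/JSON.

#' Run configuration for the pipeline
#'
#' Collects input paths and every tunable threshold in one place so a run
#' can be replayed exactly.
#'
#' @param maf_dir directory of per-lesion MAF files (`<lesion>.maf`).
#' @param seg_dir directory of per-lesion segment files
#'   (`<lesion>.seg.tsv`).
#' @param sample_info path to the ploidy/purity/MSI sidecar TSV.
#' @param clinical path to the clinical CSV.
#' @param reference optional reference FASTA (enables signature fitting).
#' @param signature_tsv signature matrix TSV (default: bundled synthetic
#'   30-signature matrix).
#' @param tiles_dir optional directory of per-focus tile PNGs laid out as
#'   `<lesion_id>/<tile>.png`.
#' @param out_dir output directory.
#' @param jaccard_threshold MO/IM decision threshold (default 0.01).
#' @param cds_mb TMB denominator in megabases (default 36).
#' @param msi_threshold MSI-H cutoff (default 20).
#' @param min_exposure minimum retained signature exposure (default 0.06).
#' @param signature_groups named signature groups for reduction.
#' @param nonsilent_only compute sharing on non-silent variants only.
#' @param correlation_standardize standardize image features against
#'   cohort statistics before correlating (default TRUE).
#' @param mpp microns per pixel for tiles.
#' @param seed integer seed (only stages with randomness use it).
#' @return list of class `run_config`.
#' @export
run_config <- function(maf_dir = NULL, seg_dir = NULL, sample_info = NULL,
                       clinical = NULL, reference = NULL,
                       signature_tsv = NULL, tiles_dir = NULL,
                       out_dir = tempfile("mfclone_run_"),
                       jaccard_threshold = 0.01, cds_mb = 36.0,
                       msi_threshold = 20.0, min_exposure = 0.06,
                       signature_groups = c(1, 3, 6, 10),
                       nonsilent_only = FALSE,
                       correlation_standardize = TRUE, mpp = 0.5,
                       seed = 1L) {
  stopifnot(jaccard_threshold > 0, jaccard_threshold < 1, cds_mb > 0,
            msi_threshold >= 0, min_exposure >= 0, min_exposure < 1)
  structure(as.list(environment()), class = "run_config")
}

load_cohort <- function(config) {
  clin <- read_clinical(config$clinical)
  info <- read_sample_info(config$sample_info)
  if (!"msi_score" %in% names(info)) info$msi_score <- 0
  pairs <- list()
  for (i in seq_len(nrow(clin))) {
    pid <- clin$patient_id[i]
    les <- lapply(c(clin$lesion_a_id[i], clin$lesion_b_id[i]), function(lid) {
      maf_path <- file.path(config$maf_dir, paste0(lid, ".maf"))
      if (!file.exists(maf_path)) {
        stop("stage load, sample ", lid, ": MAF not found: ", maf_path)
      }
      groups <- read_maf(maf_path)
      variants <- if (length(groups) == 0) empty_variants() else groups[[1]]
      seg_path <- file.path(config$seg_dir, paste0(lid, ".seg.tsv"))
      segments <- if (!is.null(config$seg_dir) && file.exists(seg_path)) {
        read_segments(seg_path)
      } else {
        empty_segments()
      }
      row <- info[info$sample == lid, , drop = FALSE]
      if (nrow(row) == 0) {
        stop("stage load, sample ", lid, ": missing sample-info row")
      }
      lesion_profile(pid, lid, variants, segments, ploidy = row$ploidy[1],
                     msi_score = row$msi_score[1])
    })
    pairs[[pid]] <- patient_pair(pid, les[[1]], les[[2]],
                                 pfs_months = clin$pfs_months[i],
                                 event = clin$event[i],
                                 pathology_call = clin$pathology_call[i])
  }
  list(pairs = pairs, clinical = clin)
}

#' Run the molecular arm of the pipeline
#'
#' Reads the cohort from `config`, classifies every pair (Jaccard + MO/IM
#' call + pair tree), computes per-lesion burden summaries and (when a
#' reference is available) signature exposures, then runs the cohort-level
#' group comparisons (TMB, CNV score, MSI, ploidy; driver-gene 2x2 tests),
#' Kaplan-Meier/log-rank survival by molecular call, and the concordance
#' with the pathology calls. Deterministic given the config.
#'
#' @param config a [run_config()].
#' @param write logical; write the TSV/JSON bundle to `config$out_dir`.
#' @return list with `calls`, `trees`, `burden`, `exposures` (or NULL),
#'   `comparisons`, `gene_tests`, `survival`, `concordance`.
#' @export
run_molecular <- function(config, write = TRUE) {
  cohort <- load_cohort(config)
  if (length(cohort$pairs) == 0) stop("empty cohort: no patients loaded")
  cl <- classify_cohort(cohort$pairs, threshold = config$jaccard_threshold,
                        nonsilent_only = config$nonsilent_only)
  burden <- do.call(rbind, lapply(cohort$pairs, function(pr) {
    rbind(burden_summary(pr$lesion_a, config$cds_mb, config$msi_threshold),
          burden_summary(pr$lesion_b, config$cds_mb, config$msi_threshold))
  }))
  rownames(burden) <- NULL
  exposures <- NULL
  if (!is.null(config$reference)) {
    S <- if (is.null(config$signature_tsv)) load_signature_matrix() else
      load_signature_matrix(config$signature_tsv)
    ref <- resolve_reference(config$reference)
    exp_rows <- list()
    for (pr in cohort$pairs) {
      for (les in list(pr$lesion_a, pr$lesion_b)) {
        le <- tryCatch(
          lesion_exposures(les, ref, S, config$min_exposure,
                           config$signature_groups),
          error = function(e) NULL)
        if (is.null(le)) next
        exp_rows[[les$lesion_id]] <- data.frame(
          lesion_id = les$lesion_id, t(le$fit$exposures), t(le$reduced),
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
    exposures <- do.call(rbind, exp_rows)
    rownames(exposures) <- NULL
  }
  # lesion-level group label = the patient's molecular call
  call_of <- setNames(cl$calls$call, cl$calls$patient_id)
  patient_of <- do.call(c, unname(lapply(cohort$pairs, function(pr)
    setNames(rep(pr$patient_id, 2),
             c(pr$lesion_a$lesion_id, pr$lesion_b$lesion_id)))))
  lesion_group <- call_of[patient_of[burden$lesion_id]]
  comparisons <- do.call(rbind, lapply(
    c("tmb", "cnv_score", "ploidy"), function(v)
      group_comparison(burden[[v]], lesion_group, variable = v)))
  msi_num <- vapply(cohort$pairs, function(pr)
    c(pr$lesion_a$msi_score, pr$lesion_b$msi_score), numeric(2))
  comparisons <- rbind(comparisons,
                       group_comparison(as.numeric(msi_num),
                                        rep(call_of[names(cohort$pairs)],
                                            each = 2),
                                        variable = "msi_score"))
  gene_tests <- driver_gene_tests(cohort$pairs, lesion_group, burden)
  surv <- km_logrank(cohort$clinical$pfs_months, cohort$clinical$event,
                     call_of[cohort$clinical$patient_id])
  conc <- tryCatch(
    concordance(call_of[cohort$clinical$patient_id],
                cohort$clinical$pathology_call),
    error = function(e) NULL)
  out <- list(calls = cl$calls, trees = cl$trees, burden = burden,
              exposures = exposures, comparisons = comparisons,
              gene_tests = gene_tests, survival = surv, concordance = conc)
  if (write) write_molecular_bundle(out, config)
  out
}

# Fisher tests of per-lesion driver-gene mutation frequency between calls.
driver_gene_tests <- function(pairs, lesion_group, burden,
                              genes = c("TP53", "ARID1A")) {
  lesions <- list()
  for (pr in pairs) {
    lesions[[pr$lesion_a$lesion_id]] <- pr$lesion_a
    lesions[[pr$lesion_b$lesion_id]] <- pr$lesion_b
  }
  rows <- list()
  for (g in genes) {
    flags <- vapply(burden$lesion_id, function(lid)
      g %in% lesions[[lid]]$variants$gene, logical(1))
    tab <- gene_frequency_table(unname(lesion_group), unname(flags))
    ft <- fisher_exact(tab)
    rows[[g]] <- data.frame(
      gene = g, mut_im = tab["mutated", "IM"], n_im = sum(tab[, "IM"]),
      mut_mo = tab["mutated", "MO"], n_mo = sum(tab[, "MO"]),
      odds_ratio = ft$odds_ratio, p_value = ft$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

write_molecular_bundle <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) write.table(
    df, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)
  tsv(res$calls, "clonality_calls.tsv")
  tsv(res$burden, "burden.tsv")
  if (!is.null(res$exposures)) tsv(res$exposures, "exposures.tsv")
  tsv(res$comparisons, "group_comparisons.tsv")
  tsv(res$gene_tests, "gene_tests.tsv")
  tsv(res$survival$curves, "survival_curves.tsv")
  for (id in names(res$trees)) {
    writeLines(res$trees[[id]]$newick,
               file.path(config$out_dir, paste0(id, ".nwk")))
  }
  if (!is.null(res$concordance)) {
    jsonlite::write_json(
      list(n_total = res$concordance$n_total,
           n_agree = res$concordance$n_agree,
           percent_agreement = round(res$concordance$percent_agreement, 1)),
      file.path(config$out_dir, "concordance.json"),
      auto_unbox = TRUE, digits = NA)
  }
  invisible(config$out_dir)
}

#' Run the pathology arm of the pipeline
#'
#' For every focus directory under `config$tiles_dir`, reads its PNG
#' tiles, pools all segmented nuclei across tiles, and computes one
#' image-level feature vector per focus. Feature vectors are standardized
#' against cohort statistics (unless disabled) and the Pearson correlation
#' between the two foci of each patient is reported; a focus with no valid
#' tiles is recorded as missing rather than aborting the run.
#'
#' @param config a [run_config()] with `tiles_dir` and `clinical` set.
#' @param reference_tile optional RGB array used as the Macenko
#'   normalization reference (default: first tile encountered).
#' @param write write the TSV bundle to `config$out_dir`.
#' @return list with `features` (matrix, foci in rows), `correlations`
#'   (data frame per patient), `missing` (character).
#' @export
run_histo <- function(config, reference_tile = NULL, write = TRUE) {
  clin <- read_clinical(config$clinical)
  focus_ids <- c(rbind(clin$lesion_a_id, clin$lesion_b_id))
  feats <- list()
  missing <- character(0)
  for (fid in focus_ids) {
    fdir <- file.path(config$tiles_dir, fid)
    paths <- if (dir.exists(fdir)) {
      list.files(fdir, pattern = "\\.png$", full.names = TRUE)
    } else {
      character(0)
    }
    records <- list()
    for (p in sort(paths)) {
      tile <- read_tile_png(p)
      if (is.null(reference_tile)) reference_tile <- tile
      norm <- macenko_normalize(tile, reference_tile)
      labels <- segment_nuclei(norm, mpp = config$mpp)
      if (max(labels) == 0) next
      records[[p]] <- nucleus_features(labels, norm, mpp = config$mpp,
                                       tile_id = basename(p))
    }
    pooled <- do.call(rbind, records)
    if (is.null(pooled) || nrow(pooled) == 0) {
      missing <- c(missing, fid)
      next
    }
    feats[[fid]] <- image_level_features(pooled)
  }
  if (length(feats) == 0) stop("no focus produced any features")
  fmat <- do.call(rbind, feats)
  stats <- if (config$correlation_standardize) {
    cohort_feature_stats(fmat)
  } else {
    NULL
  }
  cors <- list()
  for (i in seq_len(nrow(clin))) {
    a <- clin$lesion_a_id[i]
    b <- clin$lesion_b_id[i]
    if (!a %in% rownames(fmat) || !b %in% rownames(fmat)) next
    r <- focus_pair_correlation(fmat[a, ], fmat[b, ],
                                center = stats$center, scale = stats$scale)
    cors[[clin$patient_id[i]]] <- data.frame(
      patient_id = clin$patient_id[i], correlation = r,
      stringsAsFactors = FALSE)
  }
  correlations <- do.call(rbind, cors)
  rownames(correlations) <- NULL
  out <- list(features = fmat, correlations = correlations,
              missing = missing)
  if (write) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(focus = rownames(fmat), fmat,
                           check.names = FALSE),
                file.path(config$out_dir, "focus_features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(correlations,
                file.path(config$out_dir, "focus_correlations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
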