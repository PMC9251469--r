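# Variant tables, segment tables, clinical tables and the non-silent
# classification rule. Coordinates are 1-based inclusive throughout (MAF
# convention); chromosome labels are compared after stripping any leading
# "chr" prefix.

#' The nine non-silent variant classifications
#'
#' Closed vocabulary of consequence labels counted as non-silent for tumour
#' mutational burden and related summaries, in the vcf2maf dialect.
#'
#' @format Character vector of nine `Variant_Classification` labels.
#' @export
NONSILENT_CLASSES <- c(
  "Splice_Site", "Splice_Region", "Missense_Mutation", "Nonstop_Mutation",
  "Nonsense_Mutation", "Frame_Shift_Ins", "Frame_Shift_Del",
  "In_Frame_Ins", "In_Frame_Del"
)

# Recognised silent-class labels (everything a MAF commonly carries that is
# not one of the nine non-silent classes).
SILENT_CLASSES <- c(
  "Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA",
  "Translation_Start_Site", "Targeted_Region"
)

#' Canonicalise a Variant_Classification label
#'
#' Trims whitespace and converts internal spaces/dots to underscores so that
#' e.g. `"Missense Mutation"` and `"Missense_Mutation"` compare equal.
#'
#' @param x character vector of labels.
#' @return character vector of canonical labels.
#' @export
normalize_classification <- function(x) {
  gsub("[ .]+", "_", trimws(as.character(x)))
}

#' Is a variant classification non-silent?
#'
#' TRUE iff the (canonicalised) label is one of the nine non-silent classes
#' ([NONSILENT_CLASSES]). Labels outside the recognised vocabulary return
#' FALSE with a warning rather than an error, so a stray annotation never
#' aborts a burden computation.
#'
#' @param classification character vector of labels.
#' @return logical vector.
#' @examples
#' is_nonsilent(c("Missense_Mutation", "Silent", "Frame_Shift_Del"))
#' @export
is_nonsilent <- function(classification) {
  if (length(classification) == 0) return(logical(0))
  if (any(!nzchar(classification) | is.na(classification))) {
    stop("classification must be a non-empty string")
  }
  cls <- normalize_classification(classification)
  known <- c(NONSILENT_CLASSES, normalize_classification(SILENT_CLASSES))
  unknown <- setdiff(unique(cls), known)
  if (length(unknown) > 0) {
    warning("unknown Variant_Classification label(s): ",
            paste(unknown, collapse = ", "))
  }
  cls %in% NONSILENT_CLASSES
}

#' Normalise a chromosome label
#'
#' Strips a leading "chr" (any case) so "chr17" and "17" compare equal.
#'
#' @param x character vector of chromosome labels.
#' @return character vector.
#' @export
normalize_chrom <- function(x) {
  sub("^[Cc][Hh][Rr]", "", as.character(x))
}

#' Genomic identity key of a variant
#'
#' Two variants count as the same somatic event for sharing/Jaccard purposes
#' iff their keys are equal. The key is (chromosome, position, ref, alt);
#' gene symbol and consequence class are deliberately excluded so that
#' identity does not depend on the annotator version.
#'
#' @param chromosome,position,ref_allele,alt_allele vectors of equal length,
#'   or `chromosome` may be a variant data frame with those columns.
#' @return character vector of keys `"chrom:pos:ref:alt"`.
#' @export
variant_key <- function(chromosome, position = NULL, ref_allele = NULL,
                        alt_allele = NULL) {
  if (is.data.frame(chromosome)) {
    df <- chromosome
    return(variant_key(df$chromosome, df$position, df$ref_allele,
                       df$alt_allele))
  }
  paste(normalize_chrom(chromosome), position, ref_allele, alt_allele,
        sep = ":")
}

maf_required_cols <- c(
  "Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
  "Tumor_Seq_Allele2", "Variant_Classification", "Tumor_Sample_Barcode"
)

#' Read a MAF-style somatic variant table
#'
#' Reads a tab-separated variant table in the vcf2maf column dialect and
#' returns one data frame of variants per tumour sample. No row filtering is
#' applied; every data row becomes one variant. When `t_depth` and
#' `t_alt_count` are present a `vaf` column is derived.
#'
#' @param path path to a tab-separated MAF file (lines starting `#` are
#'   skipped).
#' @return named list of data frames (one per `Tumor_Sample_Barcode`), each
#'   with columns `chromosome`, `position`, `ref_allele`, `alt_allele`,
#'   `gene`, `classification` and optionally `vaf`.
#' @export
read_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, comment.char = "#", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
  missing <- setdiff(maf_required_cols, names(raw))
  if (length(missing) > 0) {
    stop("MAF format error: missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) return(structure(list(), names = character(0)))
  pos <- suppressWarnings(as.numeric(raw$Start_Position))
  bad <- which(is.na(pos))
  if (length(bad) > 0) {
    stop(sprintf("MAF row error at line %d: unparseable Start_Position '%s'",
                 bad[1] + 1L, raw$Start_Position[bad[1]]))
  }
  df <- data.frame(
    chromosome = raw$Chromosome,
    position = as.integer(pos),
    ref_allele = raw$Reference_Allele,
    alt_allele = raw$Tumor_Seq_Allele2,
    gene = raw$Hugo_Symbol,
    classification = normalize_classification(raw$Variant_Classification),
    stringsAsFactors = FALSE
  )
  if (all(c("t_depth", "t_alt_count") %in% names(raw))) {
    dp <- suppressWarnings(as.numeric(raw$t_depth))
    ac <- suppressWarnings(as.numeric(raw$t_alt_count))
    df$vaf <- ifelse(!is.na(dp) & dp > 0, ac / dp, NA_real_)
  }
  split(df, factor(raw$Tumor_Sample_Barcode,
                   levels = unique(raw$Tumor_Sample_Barcode)))
}

#' Write variants back to a MAF-style table
#'
#' Inverse of [read_maf()]: serialises a named list of per-sample variant
#' data frames to a single tab-separated table with the vcf2maf column
#' names, preserving the key columns verbatim.
#'
#' @param groups named list of variant data frames as returned by
#'   [read_maf()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(groups, path) {
  rows <- lapply(names(groups), function(s) {
    df <- groups[[s]]
    data.frame(
      Hugo_Symbol = df$gene,
      Chromosome = df$chromosome,
      Start_Position = df$position,
      Reference_Allele = df$ref_allele,
      Tumor_Seq_Allele2 = df$alt_allele,
      Variant_Classification = df$classification,
      Tumor_Sample_Barcode = s,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- setNames(
      data.frame(matrix(character(0), nrow = 0, ncol = 7)),
      c("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
        "Tumor_Seq_Allele2", "Variant_Classification",
        "Tumor_Sample_Barcode"))
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a copy-number segment table
#'
#' Tab-separated FACETS-like segment table with columns `chrom`, `start`,
#' `end`, `tcn` (total copy number) and `lcn` (minor copy number).
#'
#' @param path path to the segment file.
#' @return data frame with columns `chromosome`, `start`, `end`, `total_cn`,
#'   `minor_cn`.
#' @export
read_segments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "tcn", "lcn")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("segment format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  seg <- data.frame(
    chromosome = as.character(raw$chrom),
    start = as.integer(raw$start),
    end = as.integer(raw$end),
    total_cn = as.integer(raw$tcn),
    minor_cn = as.integer(raw$lcn),
    stringsAsFactors = FALSE
  )
  validate_segments(seg)
  seg
}

validate_segments <- function(seg) {
  if (nrow(seg) == 0) return(invisible(seg))
  if (any(seg$start > seg$end)) stop("segment with start > end")
  if (any(seg$total_cn < 0) || any(seg$minor_cn < 0)) {
    stop("negative copy number in segment table")
  }
  if (any(seg$minor_cn > seg$total_cn)) {
    stop("segment with minor_cn > total_cn")
  }
  invisible(seg)
}

#' Read the per-sample ploidy/purity/MSI sidecar table
#'
#' Tab-separated table with columns `sample`, `ploidy`, `purity` and
#' optionally `msi_score`.
#'
#' @param path path to the sidecar file.
#' @return data frame keyed by `sample`.
#' @export
read_sample_info <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "ploidy", "purity")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("sample-info format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(raw$ploidy <= 0)) stop("ploidy must be positive")
  raw
}

#' Read the clinical table
#'
#' CSV with one row per patient: `patient_id`, `lesion_a_id`, `lesion_b_id`,
#' `pfs_months`, `event` (0/1 or logical) and `pathology_call`
#' (`MO`/`IM`/`unknown`).
#'
#' @param path path to the clinical CSV.
#' @return data frame with `event` coerced to logical.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "lesion_a_id", "lesion_b_id", "pfs_months",
            "event", "pathology_call")
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("clinical format error: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  raw$event <- as.logical(as.integer(raw$event))
  if (any(raw$pfs_months < 0)) stop("negative pfs_months")
  bad <- setdiff(unique(raw$pathology_call), c("MO", "IM", "unknown"))
  if (length(bad) > 0) {
    stop("pathology_call must be MO/IM/unknown; saw: ",
         paste(bad, collapse = ", "))
  }
  raw
}

#' Construct a per-lesion analysis profile
#'
#' Bundles one lesion's somatic variants, copy-number segments, ploidy and
#' MSI score. Duplicate variant keys within the lesion are collapsed with a
#' warning (a lesion carries each somatic event at most once).
#'
#' @param patient_id,lesion_id identifiers.
#' @param variants variant data frame ([read_maf()] element); may be empty.
#' @param segments segment data frame ([read_segments()]); may be empty.
#' @param ploidy positive real; sample-average DNA ploidy.
#' @param msi_score non-negative instability score.
#' @return object of class `lesion_profile`.
#' @export
lesion_profile <- function(patient_id, lesion_id, variants,
                           segments = empty_segments(), ploidy = 2,
                           msi_score = 0) {
  stopifnot(is.data.frame(variants))
  if (!(ploidy > 0)) stop("ploidy must be positive")
  if (msi_score < 0) stop("msi_score must be non-negative")
  validate_segments(segments)
  if (nrow(variants) > 0) {
    keys <- variant_key(variants)
    if (anyDuplicated(keys)) {
      warning(sprintf("%s: %d duplicate variant key(s) collapsed",
                      lesion_id, sum(duplicated(keys))))
      variants <- variants[!duplicated(keys), , drop = FALSE]
    }
  }
  structure(
    list(patient_id = patient_id, lesion_id = lesion_id,
         variants = variants, segments = segments, ploidy = ploidy,
         msi_score = msi_score),
    class = "lesion_profile"
  )
}

empty_segments <- function() {
  data.frame(chromosome = character(0), start = integer(0),
             end = integer(0), total_cn = integer(0), minor_cn = integer(0),
             stringsAsFactors = FALSE)
}

empty_variants <- function() {
  data.frame(chromosome = character(0), position = integer(0),
             ref_allele = character(0), alt_allele = character(0),
             gene = character(0), classification = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a two-lesion patient record
#'
#' @param patient_id identifier; must match both lesions' `patient_id`.
#' @param lesion_a,lesion_b [lesion_profile()] objects.
#' @param pfs_months non-negative time to progression (months).
#' @param event logical; TRUE if progression observed, FALSE if censored.
#' @param pathology_call `"MO"`, `"IM"` or `"unknown"` (the pathologist's
#'   independent read of the two lesions).
#' @return object of class `patient_pair`.
#' @export
patient_pair <- function(patient_id, lesion_a, lesion_b, pfs_months = NA,
                         event = NA, pathology_call = "unknown") {
  stopifnot(inherits(lesion_a, "lesion_profile"),
            inherits(lesion_b, "lesion_profile"))
  if (!identical(lesion_a$patient_id, patient_id) ||
      !identical(lesion_b$patient_id, patient_id)) {
    stop("lesion patient_id mismatch for ", patient_id)
  }
  if (!pathology_call %in% c("MO", "IM", "unknown")) {
    stop("pathology_call must be MO/IM/unknown")
  }
  structure(
    list(patient_id = patient_id, lesion_a = lesion_a, lesion_b = lesion_b,
         pfs_months = pfs_months, event = event,
         pathology_call = pathology_call),
    class = "patient_pair"
  )
}

#' @export
print.lesion_profile <- function(x, ...) {
  cat(sprintf("<lesion_profile> %s / %s: %d variants, %d segments, ploidy %.2f, MSI %.2f\n",
              x$patient_id, x$lesion_id, nrow(x$variants), nrow(x$segments),
              x$ploidy, x$msi_score))
  invisible(x)
}

#' @export
print.patient_pair <- function(x, ...) {
  cat(sprintf("<patient_pair> %s: lesions %s + %s, pathology %s\n",
              x$patient_id, x$lesion_a$lesion_id, x$lesion_b$lesion_id,
              x$pathology_call))
  invisible(x)
}
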