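# Per-lesion burden metrics: tumour mutational burden, AMP/DEL segment
# calls, the exome-wide copy-number burden score, and MSI status.

#' Tumour mutational burden
#'
#' Count of non-silent variants (the nine classes of [is_nonsilent()])
#' divided by the captured coding length in megabases. The default 36 Mb is
#' the coding footprint of the Agilent V6 whole-exome design.
#'
#' @param variants variant data frame with a `classification` column.
#' @param cds_mb captured CDS length in megabases (default 36).
#' @return mutations per megabase (0 for an empty table).
#' @export
compute_tmb <- function(variants, cds_mb = 36.0) {
  if (!(cds_mb > 0)) stop("cds_mb must be positive")
  if (nrow(variants) == 0) return(0.0)
  sum(is_nonsilent(variants$classification)) / cds_mb
}

#' AMP/DEL/NEUTRAL call for one segment
#'
#' A segment is an amplification when its total copy number exceeds twice
#' the sample ploidy, a deletion when the total copy number is zero, and
#' neutral otherwise (vectorised over `total_cn`).
#'
#' @param total_cn non-negative integer total copy number(s).
#' @param ploidy positive sample-average ploidy.
#' @return character vector in `{"AMP", "DEL", "NEUTRAL"}`.
#' @export
call_segment_state <- function(total_cn, ploidy) {
  if (any(total_cn < 0)) stop("negative copy number")
  if (!(ploidy > 0)) stop("ploidy must be positive")
  ifelse(total_cn == 0, "DEL",
         ifelse(total_cn > 2 * ploidy, "AMP", "NEUTRAL"))
}

#' Exome-wide copy-number burden score
#'
#' Sums, over every segment whose total copy number differs from the
#' rounded sample ploidy, the segment length in megabases times a relative
#' alteration weight. The default weight is the relative deviation from
#' ploidy, `|total_cn - ploidy| / ploidy`, which is unitless and zero for
#' ploidy-neutral segments; pass a different `weight_fn(total_cn, ploidy)`
#' to change it. The score is additive over segments, so splitting a
#' segment into same-copy-number pieces leaves it unchanged.
#'
#' @param segments segment data frame (`start`, `end`, `total_cn`).
#' @param ploidy positive sample-average ploidy.
#' @param weight_fn function of `(total_cn, ploidy)` returning the per-copy
#'   alteration weight.
#' @return non-negative score (Mb-weighted).
#' @export
cnv_score <- function(segments, ploidy,
                      weight_fn = function(total_cn, ploidy)
                        abs(total_cn - ploidy) / ploidy) {
  if (!(ploidy > 0)) stop("ploidy must be positive")
  if (nrow(segments) == 0) return(0.0)
  validate_segments(segments)
  altered <- segments$total_cn != round(ploidy)
  if (!any(altered)) return(0.0)
  seg <- segments[altered, , drop = FALSE]
  len_mb <- (seg$end - seg$start + 1) / 1e6
  sum(len_mb * weight_fn(seg$total_cn, ploidy))
}

#' MSI status from an instability score
#'
#' MSI-high is called when the score strictly exceeds the threshold
#' (default 20); otherwise microsatellite-stable.
#'
#' @param score non-negative instability score(s).
#' @param threshold MSI-H cutoff (default 20).
#' @return `"MSI-H"` or `"MSS"` (vectorised).
#' @export
msi_status <- function(score, threshold = 20.0) {
  if (any(score < 0)) stop("MSI score must be non-negative")
  ifelse(score > threshold, "MSI-H", "MSS")
}

#' Gene-level copy-number state
#'
#' Assigns each gene the AMP/DEL/NEUTRAL state of the segment covering its
#' midpoint; genes covered by no segment are NEUTRAL. The midpoint rule
#' gives every gene a single unambiguous call even when it straddles a
#' segment boundary.
#'
#' @param segments segment data frame.
#' @param ploidy sample ploidy.
#' @param gene_intervals data frame with columns `gene`, `chromosome`,
#'   `start`, `end` (1-based inclusive).
#' @return data frame `gene`, `state`.
#' @export
gene_level_cnv <- function(segments, ploidy, gene_intervals) {
  stopifnot(all(c("gene", "chromosome", "start", "end") %in%
                  names(gene_intervals)))
  mid <- (gene_intervals$start + gene_intervals$end) %/% 2
  gchrom <- normalize_chrom(gene_intervals$chromosome)
  schrom <- normalize_chrom(segments$chromosome)
  state <- rep("NEUTRAL", nrow(gene_intervals))
  for (i in seq_len(nrow(gene_intervals))) {
    hit <- which(schrom == gchrom[i] & segments$start <= mid[i] &
                   segments$end >= mid[i])
    if (length(hit) > 0) {
      state[i] <- call_segment_state(segments$total_cn[hit[1]], ploidy)
    }
  }
  data.frame(gene = gene_intervals$gene, state = state,
             stringsAsFactors = FALSE)
}

#' Burden summary for one lesion
#'
#' @param profile a [lesion_profile()].
#' @param cds_mb CDS megabases for TMB (default 36).
#' @param msi_threshold MSI-H cutoff (default 20).
#' @return one-row data frame `lesion_id`, `tmb`, `cnv_score`,
#'   `msi_status`, `ploidy`.
#' @export
burden_summary <- function(profile, cds_mb = 36.0, msi_threshold = 20.0) {
  stopifnot(inherits(profile, "lesion_profile"))
  data.frame(
    lesion_id = profile$lesion_id,
    tmb = compute_tmb(profile$variants, cds_mb),
    cnv_score = cnv_score(profile$segments, profile$ploidy),
    msi_status = msi_status(profile$msi_score, msi_threshold),
    ploidy = profile$ploidy,
    stringsAsFactors = FALSE
  )
}
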