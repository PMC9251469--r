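# 96-trinucleotide-context spectra and signature-exposure fitting.
#
# Context ordering is fixed as substitution-major (C>A, C>G, C>T, T>A,
# T>C, T>G), then 5' base, then 3' base, both in A,C,G,T order, so that
# context vectors are comparable across runs and with the bundled
# signature matrix.

SUBSTITUTIONS_6 <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide context labels, in canonical order
#'
#' Labels of the form `"A[C>T]G"`: substitution-major, then 5' base, then
#' 3' base (A, C, G, T order for both flanks).
#'
#' @return character vector of length 96.
#' @export
context_labels <- function() {
  bases <- c("A", "C", "G", "T")
  unlist(lapply(SUBSTITUTIONS_6, function(s)
    unlist(lapply(bases, function(p5)
      paste0(p5, "[", s, "]", bases)))))
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_chr <- function(x) {
  vapply(strsplit(x, ""), function(b)
    paste(rev(unname(COMPLEMENT[b])), collapse = ""), character(1))
}

resolve_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (inherits(reference, "DNAStringSet")) {
    seqs <- as.character(reference)
  } else if (is.character(reference)) {
    seqs <- reference
  } else {
    stop("reference must be a FASTA path, DNAStringSet or named character vector")
  }
  names(seqs) <- normalize_chrom(names(seqs))
  seqs
}

#' Trinucleotide context of a single-nucleotide variant
#'
#' Looks up the 5' and 3' flanking bases in the reference and reports the
#' substitution in the pyrimidine convention: when the reference allele is
#' a purine (A/G) the variant and both flanks are reverse-complemented so
#' the reported reference base is C or T.
#'
#' @param v one-row variant data frame (or list) with `chromosome`,
#'   `position`, `ref_allele`, `alt_allele`.
#' @param reference FASTA path, `DNAStringSet`, or named character vector of
#'   contig sequences; contig names tolerant of a "chr" prefix.
#' @return one of the 96 labels of [context_labels()].
#' @export
trinucleotide_context <- function(v, reference) {
  seqs <- resolve_reference(reference)
  ref <- toupper(v$ref_allele)
  alt <- toupper(v$alt_allele)
  if (nchar(ref) != 1 || nchar(alt) != 1 ||
      !ref %in% names(COMPLEMENT) || !alt %in% names(COMPLEMENT)) {
    stop("not an SNV: ", ref, ">", alt)
  }
  chrom <- normalize_chrom(v$chromosome)
  if (!chrom %in% names(seqs)) stop("contig not in reference: ", chrom)
  seq <- seqs[[chrom]]
  pos <- as.integer(v$position)
  if (pos < 2 || pos > nchar(seq) - 1) {
    stop("position ", pos, " too close to contig edge for a trinucleotide")
  }
  tri <- toupper(substr(seq, pos - 1, pos + 1))
  if (substr(tri, 2, 2) != ref) {
    stop(sprintf("reference mismatch at %s:%d: MAF says %s, reference has %s",
                 chrom, pos, ref, substr(tri, 2, 2)))
  }
  if (ref %in% c("A", "G")) {
    tri <- revcomp_chr(tri)
    ref <- unname(COMPLEMENT[ref])
    alt <- unname(COMPLEMENT[alt])
  }
  paste0(substr(tri, 1, 1), "[", ref, ">", alt, "]", substr(tri, 3, 3))
}

#' 96-context mutation spectrum of a set of SNVs
#'
#' Counts each SNV's trinucleotide context; the vector total equals the
#' number of input SNVs. Non-SNV rows must be removed by the caller (see
#' [is_snv()]).
#'
#' @param snvs variant data frame of single-nucleotide substitutions.
#' @param reference as in [trinucleotide_context()].
#' @return named integer vector of length 96 in [context_labels()] order.
#' @export
build_context_vector <- function(snvs, reference) {
  labels <- context_labels()
  counts <- setNames(integer(96), labels)
  if (nrow(snvs) == 0) return(counts)
  seqs <- resolve_reference(reference)
  for (i in seq_len(nrow(snvs))) {
    ctx <- trinucleotide_context(snvs[i, , drop = FALSE], seqs)
    counts[ctx] <- counts[ctx] + 1L
  }
  counts
}

#' Is a variant a single-nucleotide substitution?
#'
#' @param variants variant data frame.
#' @return logical vector: TRUE where both alleles are single A/C/G/T bases
#'   and differ.
#' @export
is_snv <- function(variants) {
  ref <- toupper(variants$ref_allele)
  alt <- toupper(variants$alt_allele)
  ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    ref != alt
}

#' Load a 96 x N signature matrix from TSV
#'
#' Expects a tab-separated file whose first column holds the 96 context
#' labels and whose remaining columns are signature probability vectors.
#' Rows are reordered to canonical [context_labels()] order and columns are
#' renormalised to sum exactly to 1 (they must already sum to 1 within
#' 1e-6).
#'
#' @param path TSV path; default is the synthetic 30-signature matrix
#'   bundled with the package (see [synthetic_signature_matrix()]).
#' @return 96 x N numeric matrix with context rownames and signature
#'   colnames.
#' @export
load_signature_matrix <- function(path = system.file(
    "extdata", "signatures_96x30_synthetic.tsv", package = "mfclone")) {
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ctx <- raw[[1]]
  S <- as.matrix(raw[, -1, drop = FALSE])
  rownames(S) <- ctx
  labels <- context_labels()
  if (!setequal(ctx, labels)) stop("signature matrix rows are not the 96 contexts")
  S <- S[labels, , drop = FALSE]
  if (any(S < 0)) stop("negative signature probability")
  sums <- colSums(S)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("signature column(s) do not sum to 1 within 1e-6")
  }
  sweep(S, 2, sums, "/")
}

#' Deterministic synthetic 30-signature reference matrix
#'
#' Builds the 96 x 30 probability matrix that ships with the package as
#' `inst/extdata/signatures_96x30_synthetic.tsv`. It is a synthetic
#' stand-in for a curated 30-signature catalogue, generated from a fixed
#' seed: each signature is a sparse random spectrum, and signatures 1, 3,
#' 6, 10 and 22 additionally carry strong characteristic peaks loosely
#' modelled on their well-known biology (deamination C>T at CpG for 1,
#' flat homologous-recombination-deficiency spectrum for 3, mismatch-repair
#' C>T for 6, polymerase-epsilon `T[C>A]T` for 10, T>A for 22) so that
#' mixtures of the named signatures are well identifiable.
#'
#' @param seed integer seed (the bundled file uses the default).
#' @return 96 x 30 column-stochastic matrix.
#' @export
synthetic_signature_matrix <- function(seed = 20260924) {
  labels <- context_labels()
  withr::with_seed(seed, {
    S <- matrix(0, 96, 30, dimnames = list(labels, paste0("Signature.", 1:30)))
    for (k in 1:30) {
      S[, k] <- rgamma(96, shape = 0.25, rate = 1)
    }
    peak <- function(k, pattern, w) {
      idx <- grep(pattern, labels, fixed = FALSE)
      S[idx, k] <<- S[idx, k] + w / length(idx)
    }
    # the named signatures carry concentrated characteristic peaks whose
    # share of total mass mirrors the corresponding curated spectra
    peak(1, "\\[C>T\\]G$", 20)          # CpG deamination, ~45% of mass
    S[, 3] <- S[, 3] + 0.06 + rgamma(96, shape = 4, rate = 1) / 20  # near-flat
    peak(6, "^G\\[C>T\\]", 14)          # mismatch-repair C>T
    peak(10, "^T\\[C>A\\]T$", 10)       # POLE hotspot, ~30% on one context
    peak(10, "^T\\[C>T\\]G$", 4)
    peak(22, "\\[T>A\\]", 12)           # aristolochic-acid-like T>A
    sweep(S, 2, colSums(S), "/")
  })
}

#' Fit signature exposures by non-negative least squares
#'
#' Normalises the context counts to a probability spectrum `p` and solves
#' `min ||p - S e||_2` subject to `e >= 0`. Exposures are expressed as
#' proportions; any proportion below `min_exposure` is set to zero and the
#' fit is re-run on the surviving signatures (so the reported residual is
#' the residual of the final support), then proportions are renormalised to
#' sum to 1. Deterministic for fixed input.
#'
#' @param cv named 96-vector of context counts ([build_context_vector()]).
#' @param S signature matrix ([load_signature_matrix()]).
#' @param min_exposure minimum retained proportion (default 0.06, the
#'   conventional default of reference exposure-fitting tools).
#' @return object of class `exposure_fit`: list with `exposures` (named
#'   proportions over all signatures, zeros included), `residual`
#'   (L2 norm of `p - S e` on the final support) and `min_exposure`.
#' @export
fit_signatures <- function(cv, S = load_signature_matrix(),
                           min_exposure = 0.06) {
  if (sum(cv) <= 0) stop("empty context vector: no SNVs to fit")
  labels <- context_labels()
  if (!is.null(names(cv))) cv <- cv[labels]
  p <- as.numeric(cv) / sum(cv)
  fit <- pracma::lsqnonneg(S, p)
  e <- fit$x
  if (sum(e) == 0) stop("degenerate fit: all exposures zero")
  keep <- rep(TRUE, ncol(S))
  # drop sub-threshold exposures and refit on the surviving support until
  # every retained proportion clears min_exposure
  repeat {
    prop <- e / sum(e)
    drop <- keep & prop < min_exposure
    if (!any(drop)) break
    keep <- keep & !drop
    if (!any(keep)) {
      keep <- prop == max(prop)
    }
    fit <- pracma::lsqnonneg(S[, keep, drop = FALSE], p)
    e <- numeric(ncol(S))
    e[keep] <- fit$x
    if (sum(e) == 0) {
      e[keep] <- 1 / sum(keep)
      break
    }
    if (sum(keep) == 1) break
  }
  prop <- setNames(e / sum(e), colnames(S))
  residual <- sqrt(sum((p - as.numeric(S %*% e))^2))
  structure(list(exposures = prop, residual = residual,
                 min_exposure = min_exposure),
            class = "exposure_fit")
}

#' Reduce exposures to named signature groups
#'
#' The named signatures pass through; all remaining exposure is summed into
#' `"others"`. The default groups are signatures 1, 3, 6 and 10, the ones
#' recurrently active in hepatocellular carcinoma.
#'
#' @param e an `exposure_fit` or a named exposure vector
#'   (`Signature.1` ... style names).
#' @param groups integer vector of signature numbers kept as named groups.
#' @return named vector `sig1, sig3, ..., others` summing to the input
#'   total.
#' @export
reduce_exposures <- function(e, groups = c(1, 3, 6, 10)) {
  if (inherits(e, "exposure_fit")) e <- e$exposures
  keep <- paste0("Signature.", groups)
  named <- setNames(numeric(length(groups)), paste0("sig", groups))
  for (i in seq_along(groups)) {
    if (keep[i] %in% names(e)) named[i] <- e[[keep[i]]]
  }
  c(named, others = sum(e[setdiff(names(e), keep)]))
}

#' @export
print.exposure_fit <- function(x, ...) {
  nz <- x$exposures[x$exposures > 0]
  cat("<exposure_fit> residual", format(x$residual, digits = 4), "\n")
  for (n in names(sort(nz, decreasing = TRUE))) {
    cat(sprintf("  %-14s %.3f\n", n, nz[[n]]))
  }
  invisible(x)
}

#' Per-lesion signature exposures
#'
#' Filters a lesion's variants to SNVs, builds the 96-context spectrum and
#' fits exposures.
#'
#' @param profile a [lesion_profile()].
#' @param reference reference sequence source.
#' @param S signature matrix.
#' @param min_exposure see [fit_signatures()].
#' @param groups see [reduce_exposures()].
#' @return list with `context_vector`, `fit`, `reduced`.
#' @export
lesion_exposures <- function(profile, reference, S = load_signature_matrix(),
                             min_exposure = 0.06, groups = c(1, 3, 6, 10)) {
  snvs <- profile$variants[is_snv(profile$variants), , drop = FALSE]
  cv <- build_context_vector(snvs, reference)
  fit <- fit_signatures(cv, S, min_exposure)
  list(context_vector = cv, fit = fit,
       reduced = reduce_exposures(fit, groups))
}
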