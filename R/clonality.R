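# The core clonality classifier: Jaccard index of shared somatic mutations
# between the two lesions of one patient, the MO/IM decision rule, the
# trunk/private partition, and the two-lesion phylogeny.

#' Jaccard index of two variant-key sets
#'
#' `|A intersect B| / |A union B|`, computed over genomic identity keys
#' ([variant_key()]). Duplicate keys within one set are ignored.
#'
#' @param set_a,set_b character vectors of variant keys (treated as sets).
#' @return exact ratio in `[0, 1]`.
#' @examples
#' jaccard_index(c("1:10:A:T", "1:20:C:G"), c("1:10:A:T", "2:5:G:A"))
#' @export
jaccard_index <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  n_union <- length(union(a, b))
  if (n_union == 0) {
    stop("both variant sets are empty; Jaccard index undefined")
  }
  length(intersect(a, b)) / n_union
}

#' MO/IM call from a Jaccard index
#'
#' Pairs sharing less than `threshold` of their somatic mutations are called
#' multicentric occurrence (MO, independent primaries); pairs at or above it
#' are called intrahepatic metastasis (IM). The tie at exactly `threshold`
#' goes to IM, so the better-prognosis MO call requires strictly
#' sub-threshold sharing.
#'
#' @param j Jaccard index in `[0, 1]`.
#' @param threshold decision threshold in `(0, 1)`; default 0.01.
#' @return `"MO"` or `"IM"` (vectorised over `j`).
#' @export
classify_pair <- function(j, threshold = 0.01) {
  if (any(is.na(j)) || any(j < 0) || any(j > 1)) {
    stop("Jaccard index must lie in [0, 1]")
  }
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0, 1)")
  ifelse(j < threshold, "MO", "IM")
}

#' Trunk/private partition of two variant sets
#'
#' Splits the union of two lesions' variant keys into the shared (trunk)
#' set and the two private sets. The three parts are disjoint and their
#' union is `A union B`.
#'
#' @param set_a,set_b character vectors of variant keys.
#' @return list with elements `shared`, `private_a`, `private_b`.
#' @export
shared_private_partition <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  list(shared = intersect(a, b),
       private_a = setdiff(a, b),
       private_b = setdiff(b, a))
}

#' Clonality result for one patient pair
#'
#' Computes the trunk/private counts, the Jaccard index and the MO/IM call
#' for a pair of lesions. Accepts either two key vectors or a
#' [patient_pair()] (keys are then taken over all variants by default; set
#' `nonsilent_only = TRUE` to restrict to the nine non-silent classes).
#'
#' @param pair a [patient_pair()], or a character vector of keys for lesion
#'   A (then `set_b` must be given).
#' @param set_b character vector of keys for lesion B when `pair` is a key
#'   vector.
#' @param threshold MO/IM decision threshold (default 0.01).
#' @param nonsilent_only logical; restrict to non-silent variants before
#'   computing sharing (default FALSE: all somatic variants).
#' @return object of class `clonality_result`: a one-row data frame with
#'   `patient_id`, `n_shared`, `n_private_a`, `n_private_b`, `n_union`,
#'   `jaccard`, `call`.
#' @export
clonality_result <- function(pair, set_b = NULL, threshold = 0.01,
                             nonsilent_only = FALSE) {
  if (inherits(pair, "patient_pair")) {
    va <- pair$lesion_a$variants
    vb <- pair$lesion_b$variants
    if (nonsilent_only) {
      va <- va[is_nonsilent(va$classification), , drop = FALSE]
      vb <- vb[is_nonsilent(vb$classification), , drop = FALSE]
    }
    set_a <- variant_key(va)
    set_b <- variant_key(vb)
    patient_id <- pair$patient_id
  } else {
    set_a <- pair
    patient_id <- NA_character_
  }
  part <- shared_private_partition(set_a, set_b)
  n_shared <- length(part$shared)
  n_pa <- length(part$private_a)
  n_pb <- length(part$private_b)
  n_union <- n_shared + n_pa + n_pb
  j <- jaccard_index(set_a, set_b)
  out <- data.frame(
    patient_id = patient_id, n_shared = n_shared, n_private_a = n_pa,
    n_private_b = n_pb, n_union = n_union, jaccard = j,
    call = classify_pair(j, threshold), stringsAsFactors = FALSE
  )
  class(out) <- c("clonality_result", "data.frame")
  attr(out, "partition") <- part
  out
}

#' Two-lesion phylogeny from a clonality result
#'
#' The two-leaf case is combinatorially determined: a rooted three-taxon
#' topology `(Normal, (A, B))` whose trunk branch carries the shared
#' mutations and whose leaf branches carry the private mutations. Branch
#' lengths are mutation counts. The shared (trunk) gene symbols are the
#' candidate early drivers.
#'
#' @param result a `clonality_result` (one row).
#' @param label_a,label_b leaf labels (default `"A"`, `"B"`).
#' @param trunk_genes character vector of gene symbols mutated on the trunk.
#' @return object of class `pair_tree`: list with `trunk_length`,
#'   `branch_a_length`, `branch_b_length`, `trunk_genes`, `newick`.
#' @export
build_pair_tree <- function(result, label_a = "A", label_b = "B",
                            trunk_genes = character(0)) {
  stopifnot(inherits(result, "clonality_result"), nrow(result) == 1)
  s <- result$n_shared
  pa <- result$n_private_a
  pb <- result$n_private_b
  newick <- sprintf("(Normal:0,(%s:%d,%s:%d):%d);",
                    label_a, pa, label_b, pb, s)
  structure(
    list(trunk_length = s, branch_a_length = pa, branch_b_length = pb,
         trunk_genes = sort(unique(trunk_genes)), newick = newick),
    class = "pair_tree"
  )
}

#' @export
print.pair_tree <- function(x, ...) {
  cat(sprintf("<pair_tree> trunk %d, branches %d + %d\n  %s\n",
              x$trunk_length, x$branch_a_length, x$branch_b_length,
              x$newick))
  if (length(x$trunk_genes) > 0) {
    cat("  trunk genes:", paste(x$trunk_genes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify every pair of a cohort
#'
#' Runs [clonality_result()] and [build_pair_tree()] for a list of
#' [patient_pair()]s. Trunk genes are the gene symbols of the shared
#' variants of each pair.
#'
#' @param pairs list of [patient_pair()] objects.
#' @param threshold MO/IM decision threshold.
#' @param nonsilent_only restrict sharing to non-silent variants.
#' @return list with `calls` (data frame, one row per patient) and `trees`
#'   (named list of `pair_tree`s).
#' @export
classify_cohort <- function(pairs, threshold = 0.01,
                            nonsilent_only = FALSE) {
  rows <- list()
  trees <- list()
  for (pair in pairs) {
    res <- clonality_result(pair, threshold = threshold,
                            nonsilent_only = nonsilent_only)
    part <- attr(res, "partition")
    va <- pair$lesion_a$variants
    tg <- unique(va$gene[variant_key(va) %in% part$shared])
    trees[[pair$patient_id]] <- build_pair_tree(
      res, label_a = pair$lesion_a$lesion_id,
      label_b = pair$lesion_b$lesion_id, trunk_genes = tg)
    rows[[pair$patient_id]] <- as.data.frame(res)
  }
  calls <- do.call(rbind, rows)
  rownames(calls) <- NULL
  list(calls = calls, trees = trees)
}

#' Write per-patient clonality calls to TSV, trees to newick
#'
#' @param cohort result of [classify_cohort()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_clonality <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$calls, file.path(dir, "clonality_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (id in names(cohort$trees)) {
    writeLines(cohort$trees[[id]]$newick,
               file.path(dir, paste0(id, ".nwk")))
  }
  invisible(dir)
}
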