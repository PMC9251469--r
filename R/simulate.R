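# Seeded generator of synthetic multifocal cohorts: paired lesion mutation
# sets with controlled trunk/private structure, copy-number segments,
# survival times, MSI scores, pathology calls, and rendered H&E-like
# nucleus tiles. All randomness flows through the R RNG, so a single
# set.seed() (or the config seed) makes every output reproducible.

#' Simulation configuration for a synthetic multifocal cohort
#'
#' Defaults encode the cohort structure the classifier assumes: 17
#' two-lesion patients of whom 7/17 are intrahepatic metastases; IM pairs
#' share a Poisson(82) mutation trunk with Poisson(12.5) private mutations
#' per lesion, while MO lesions are independent with only a small
#' coincidental overlap; TP53 and ARID1A are enriched in IM lesions
#' (per-lesion probabilities 8/14 vs 1/20 and 4/14 vs 2/20); IM carries a
#' heavier copy-number burden and a worse exponential progression hazard.
#'
#' @param n_patients number of two-lesion patients.
#' @param prop_im probability a patient is an IM pair.
#' @param trunk_rate_im Poisson mean of shared (trunk) mutations, IM pairs.
#' @param private_rate Poisson mean of private mutations per IM lesion.
#' @param mo_lesion_rate Poisson mean of mutations per MO lesion. The
#'   default (172) reflects that two independent primaries carry
#'   essentially disjoint burdens (~345-mutation unions), whereas clonally
#'   related lesions overlap heavily.
#' @param chance_overlap_rate_mo Poisson mean of coincidentally shared
#'   mutations in MO pairs (sequencing artefacts / recurrent passengers).
#' @param driver_gene_probs data frame `gene`, `p_im`, `p_mo`: per-lesion
#'   mutation probabilities by group.
#' @param cnv_params per-group list: `n_seg` (Poisson mean segments),
#'   `p_alt` (probability a segment is non-diploid), `mean_len_mb`
#'   (exponential mean segment length).
#' @param survival_params per-group exponential hazards (per month) plus
#'   `censor_max` months of uniform censoring.
#' @param image_params nucleus-rendering parameters, see
#'   [simulate_focus_pair_images()].
#' @param path_concordance probability the simulated pathologist agrees
#'   with the generating label.
#' @param seed integer RNG seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_patients = 17,
    prop_im = 7 / 17,
    trunk_rate_im = 82,
    private_rate = 12.5,
    mo_lesion_rate = 172,
    chance_overlap_rate_mo = 0.2,
    driver_gene_probs = data.frame(
      gene = c("TP53", "ARID1A"),
      p_im = c(8 / 14, 4 / 14),
      p_mo = c(1 / 20, 2 / 20),
      stringsAsFactors = FALSE),
    cnv_params = list(
      IM = list(n_seg = 65, p_alt = 0.8, mean_len_mb = 5),
      MO = list(n_seg = 55, p_alt = 0.6, mean_len_mb = 5)),
    survival_params = list(
      hazard = c(IM = log(2) / 18, MO = log(2) / 42), censor_max = 60),
    image_params = default_image_params(),
    path_concordance = 12 / 17,
    seed = 1L) {
  stopifnot(prop_im >= 0, prop_im <= 1, trunk_rate_im >= 0,
            private_rate >= 0, chance_overlap_rate_mo >= 0)
  structure(as.list(environment()), class = "simulation_config")
}

# Synthetic genome: 10 named contigs of random sequence; cached per
# (seed, n, len) so repeated draws in one session are cheap.
.genome_cache <- new.env(parent = emptyenv())

#' Synthetic reference genome
#'
#' Deterministic random genome of `n_contigs` contigs (`sc1`..) of
#' `contig_len` bases each, used so trinucleotide contexts are computable
#' offline. Positions 1-1000 of `sc1` are reserved for fixed driver-gene
#' loci and never receive background mutations.
#'
#' @param seed integer seed.
#' @param n_contigs,contig_len genome shape (default 10 x 200 kb).
#' @return named character vector of contig sequences.
#' @export
synthetic_genome <- function(seed = 1L, n_contigs = 10, contig_len = 2e5) {
  key <- paste(seed, n_contigs, contig_len, sep = "_")
  if (!is.null(.genome_cache[[key]])) return(.genome_cache[[key]])
  g <- withr::with_seed(seed, {
    setNames(
      vapply(seq_len(n_contigs), function(i)
        paste(sample(c("A", "C", "G", "T"), contig_len, replace = TRUE),
              collapse = ""),
        character(1)),
      paste0("sc", seq_len(n_contigs)))
  })
  .genome_cache[[key]] <- g
  g
}

#' Write a genome to FASTA
#'
#' @param genome named character vector ([synthetic_genome()]).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

DRIVER_RESERVE <- 1000L  # leading bases of sc1 reserved for driver loci

# Sample n distinct genomic positions (outside contig edges and the driver
# reserve) and build variant rows for them.
draw_variants <- function(n, genome) {
  if (n == 0) return(empty_variants())
  lens <- nchar(genome)
  usable <- lens - 2L
  usable[1] <- usable[1] - DRIVER_RESERVE
  offsets <- cumsum(c(0, usable[-length(usable)]))
  idx <- sample.int(sum(usable), n)
  contig_i <- findInterval(idx - 1, cumsum(usable), left.open = FALSE) + 1L
  contig_i <- pmin(contig_i, length(genome))
  within <- idx - offsets[contig_i]
  pos <- within + 1L
  pos[contig_i == 1] <- pos[contig_i == 1] + DRIVER_RESERVE
  chrom <- names(genome)[contig_i]
  ref <- toupper(substr(genome[contig_i], pos, pos))
  bases <- c("A", "C", "G", "T")
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1),
                USE.NAMES = FALSE)
  cls_pool <- c("Missense_Mutation", "Silent", "Nonsense_Mutation",
                "Splice_Site", "Splice_Region", "Frame_Shift_Del",
                "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
                "Intron", "3'UTR")
  cls_prob <- c(0.50, 0.16, 0.04, 0.03, 0.02, 0.05, 0.04, 0.02, 0.01,
                0.07, 0.06)
  cls <- sample(cls_pool, n, replace = TRUE, prob = cls_prob)
  # indel classes get indel-style alleles (still keyed genomically)
  del <- cls %in% c("Frame_Shift_Del", "In_Frame_Del")
  ins <- cls %in% c("Frame_Shift_Ins", "In_Frame_Ins")
  alt[del] <- "-"
  ref[ins] <- "-"
  alt[ins] <- vapply(seq_len(sum(ins)), function(i) sample(bases, 1),
                     character(1))
  data.frame(
    chromosome = chrom, position = pos, ref_allele = ref, alt_allele = alt,
    gene = sprintf("G_%s_%03d", chrom, pos %/% 2000L),
    classification = normalize_classification(cls),
    stringsAsFactors = FALSE
  )
}

driver_variant <- function(gene, gene_index, genome) {
  pos <- 100L + 50L * gene_index
  ref <- toupper(substr(genome[["sc1"]], pos, pos))
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  data.frame(chromosome = "sc1", position = pos, ref_allele = ref,
             alt_allele = alt, gene = gene,
             classification = "Missense_Mutation", stringsAsFactors = FALSE)
}

#' Simulate the mutation sets of one lesion pair
#'
#' IM pairs draw a Poisson trunk of shared mutations plus independent
#' Poisson private sets per lesion; MO pairs draw two independent
#' Poisson(`mo_lesion_rate`) sets plus a Poisson number of coincidentally
#' shared mutations. Positions never collide within a pair, so the truth
#' counts are exact set cardinalities.
#'
#' @param pattern `"IM"` or `"MO"`.
#' @param config a [simulation_config()].
#' @param genome a [synthetic_genome()] (defaults to the config seed's).
#' @return list with `variants_a`, `variants_b` (variant data frames) and
#'   `truth` (`pattern`, `n_trunk`, `n_private_a`, `n_private_b`).
#' @export
simulate_pair_mutations <- function(pattern, config = simulation_config(),
                                    genome = synthetic_genome(config$seed)) {
  stopifnot(pattern %in% c("IM", "MO"))
  if (pattern == "IM") {
    n_shared <- rpois(1, config$trunk_rate_im)
    n_a <- rpois(1, config$private_rate)
    n_b <- rpois(1, config$private_rate)
  } else {
    n_shared <- rpois(1, config$chance_overlap_rate_mo)
    n_a <- rpois(1, config$mo_lesion_rate)
    n_b <- rpois(1, config$mo_lesion_rate)
  }
  all_v <- draw_variants(n_shared + n_a + n_b, genome)
  shared <- all_v[seq_len(n_shared), , drop = FALSE]
  priv_a <- all_v[n_shared + seq_len(n_a), , drop = FALSE]
  priv_b <- all_v[n_shared + n_a + seq_len(n_b), , drop = FALSE]
  list(
    variants_a = rbind(shared, priv_a),
    variants_b = rbind(shared, priv_b),
    truth = list(pattern = pattern, n_trunk = n_shared,
                 n_private_a = n_a, n_private_b = n_b)
  )
}

# Copy-number segments never touch reference sequence, so they live on a
# virtual human-scale karyotype (22 autosomes, approximate megabase
# lengths) rather than the small mutation genome; this keeps segment
# lengths, and hence CNV-score magnitudes, on the scale of real exomes.
VIRTUAL_KARYOTYPE <- local({
  mb <- c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134,
          115, 107, 103, 90, 81, 78, 59, 63, 48, 51)
  setNames(as.integer(mb * 1e6), as.character(1:22))
})

simulate_segments <- function(params) {
  n <- rpois(1, params$n_seg)
  if (n == 0) return(empty_segments())
  lens <- VIRTUAL_KARYOTYPE
  ci <- sample.int(length(lens), n, replace = TRUE,
                   prob = lens / sum(lens))
  start <- vapply(ci, function(i) sample.int(lens[i] - 10L, 1), integer(1))
  len <- pmax(1000, round(rexp(n, 1 / (params$mean_len_mb * 1e6))))
  end <- pmin(start + len - 1L, lens[ci])
  altered <- runif(n) < params$p_alt
  cn <- ifelse(altered,
               sample(c(0L, 1L, 3L, 4L, 5L, 6L), n, replace = TRUE,
                      prob = c(0.15, 0.15, 0.2, 0.25, 0.15, 0.1)),
               2L)
  data.frame(chromosome = names(lens)[ci], start = start,
             end = as.integer(end), total_cn = cn,
             minor_cn = pmin(1L, cn), stringsAsFactors = FALSE)
}

#' Simulate a full multifocal cohort and write its file bundle
#'
#' Draws `n_patients` pairs (group labels Bernoulli(`prop_im`)), assigns
#' driver-gene mutations by group, simulates per-lesion segments, ploidy
#' and MSI scores, exponential progression times with uniform censoring,
#' and a pathologist call that agrees with the truth with probability
#' `path_concordance`. When `out_dir` is given, writes per-lesion MAF and
#' segment files, a sample-info sidecar, clinical and truth CSVs, the
#' reference FASTA and a manifest JSON, all in the dialects of the package
#' readers.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional output directory.
#' @return list with `pairs` (list of [patient_pair()]), `truth` (data
#'   frame), `clinical` (data frame), `genome`, and `paths` when files
#'   were written.
#' @export
simulate_cohort <- function(config = simulation_config(), out_dir = NULL) {
  set.seed(config$seed)
  genome <- synthetic_genome(config$seed)
  pairs <- list()
  truth_rows <- list()
  clin_rows <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("Pt%02d", i)
    pattern <- if (runif(1) < config$prop_im) "IM" else "MO"
    sim <- simulate_pair_mutations(pattern, config, genome)
    va <- sim$variants_a
    vb <- sim$variants_b
    dg <- config$driver_gene_probs
    for (k in seq_len(nrow(dg))) {
      p <- if (pattern == "IM") dg$p_im[k] else dg$p_mo[k]
      dv <- driver_variant(dg$gene[k], k, genome)
      if (runif(1) < p) va <- rbind(va, dv)
      if (runif(1) < p) vb <- rbind(vb, dv)
    }
    cp <- config$cnv_params[[pattern]]
    prof <- lapply(c(a = "a", b = "b"), function(side) {
      lid <- paste0(pid, "_", toupper(side))
      ploidy <- max(1.5, rnorm(1, 2, 0.15))
      lesion_profile(
        patient_id = pid, lesion_id = lid,
        variants = if (side == "a") va else vb,
        segments = simulate_segments(cp),
        ploidy = ploidy, msi_score = rexp(1, 1 / 3))
    })
    haz <- config$survival_params$hazard[[pattern]]
    t_event <- rexp(1, haz)
    t_cens <- runif(1, 0, config$survival_params$censor_max)
    pfs <- min(t_event, t_cens)
    event <- t_event <= t_cens
    path_call <- if (runif(1) < config$path_concordance) pattern else
      setdiff(c("IM", "MO"), pattern)
    pairs[[pid]] <- patient_pair(pid, prof$a, prof$b, pfs_months = pfs,
                                 event = event, pathology_call = path_call)
    # truth counts from the final sets (driver variants included)
    part <- shared_private_partition(variant_key(prof$a$variants),
                                     variant_key(prof$b$variants))
    truth_rows[[pid]] <- data.frame(
      patient_id = pid, pattern = pattern,
      n_trunk = length(part$shared),
      n_private_a = length(part$private_a),
      n_private_b = length(part$private_b), stringsAsFactors = FALSE)
    clin_rows[[pid]] <- data.frame(
      patient_id = pid, lesion_a_id = prof$a$lesion_id,
      lesion_b_id = prof$b$lesion_id, pfs_months = pfs,
      event = as.integer(event), pathology_call = path_call,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)
  clinical <- do.call(rbind, clin_rows)
  rownames(truth) <- rownames(clinical) <- NULL
  out <- list(pairs = pairs, truth = truth, clinical = clinical,
              genome = genome)
  if (!is.null(out_dir)) {
    out$paths <- write_cohort_bundle(out, config, out_dir)
  }
  out
}

write_cohort_bundle <- function(cohort, config, out_dir) {
  maf_dir <- file.path(out_dir, "maf")
  seg_dir <- file.path(out_dir, "seg")
  dir.create(maf_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(seg_dir, showWarnings = FALSE, recursive = TRUE)
  info_rows <- list()
  for (pair in cohort$pairs) {
    for (les in list(pair$lesion_a, pair$lesion_b)) {
      lid <- les$lesion_id
      write_maf(setNames(list(les$variants), lid),
                file.path(maf_dir, paste0(lid, ".maf")))
      seg <- les$segments
      write.table(
        data.frame(chrom = seg$chromosome, start = seg$start, end = seg$end,
                   tcn = seg$total_cn, lcn = seg$minor_cn),
        file.path(seg_dir, paste0(lid, ".seg.tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      info_rows[[lid]] <- data.frame(sample = lid, ploidy = les$ploidy,
                                     purity = 0.8,
                                     msi_score = les$msi_score,
                                     stringsAsFactors = FALSE)
    }
  }
  info_path <- file.path(out_dir, "samples.tsv")
  write.table(do.call(rbind, info_rows), info_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  clin_path <- file.path(out_dir, "clinical.csv")
  write.csv(cohort$clinical, clin_path, row.names = FALSE)
  truth_path <- file.path(out_dir, "truth.csv")
  write.csv(cohort$truth, truth_path, row.names = FALSE)
  fasta_path <- file.path(out_dir, "reference.fa")
  write_genome_fasta(cohort$genome, fasta_path)
  manifest_path <- file.path(out_dir, "manifest.json")
  cfg <- unclass(config)
  cfg$image_params <- NULL
  jsonlite::write_json(cfg, manifest_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  list(maf_dir = maf_dir, seg_dir = seg_dir, sample_info = info_path,
       clinical = clin_path, truth = truth_path, reference = fasta_path,
       manifest = manifest_path)
}

#' Default nucleus-rendering parameters
#'
#' @return list: tile side (pixels), microns per pixel, nucleus count
#'   range, mean/sd of nucleus radius (microns), colour/intensity levels
#'   and the between-focus `divergence` scale used for MO pairs.
#' @export
default_image_params <- function() {
  list(side = 512, mpp = 0.5, n_range = c(15, 40),
       radius_mean = 4, radius_sd = 0.6,
       nucleus_rgb = c(0.36, 0.28, 0.55), background_rgb = c(0.91, 0.72, 0.80),
       intensity_jitter = 0.05, pixel_noise = 0.015, divergence = 1)
}

#' Render a synthetic H&E-like nucleus tile
#'
#' Places `n_nuclei` non-overlapping ellipses (dark blue-purple) on a pink
#' stroma-like background with light pixel noise, and reports exact ground
#' truth (per-nucleus pixel area, centroid, mean colour) alongside the
#' label mask. Errors if the requested count cannot be placed without
#' overlap after bounded retries.
#'
#' @param n_nuclei number of nuclei to render.
#' @param params rendering parameters ([default_image_params()]).
#' @param radius_mean_um,radius_sd_um override the radius distribution.
#' @return list with `img` (`[side, side, 3]` array in `[0, 1]`), `mask`
#'   (integer label matrix) and `truth` (data frame).
#' @export
render_nucleus_tile <- function(n_nuclei, params = default_image_params(),
                                radius_mean_um = params$radius_mean,
                                radius_sd_um = params$radius_sd) {
  side <- params$side
  mpp <- params$mpp
  centers <- matrix(numeric(0), 0, 2)
  ax <- numeric(0)
  bx <- numeric(0)
  th <- numeric(0)
  tries <- 0
  while (nrow(centers) < n_nuclei) {
    tries <- tries + 1
    if (tries > 200 * n_nuclei + 200) {
      stop("could not place ", n_nuclei, " non-overlapping nuclei")
    }
    a_um <- max(1.8, rnorm(1, radius_mean_um, radius_sd_um))
    a_px <- a_um / mpp
    b_px <- a_px * runif(1, 0.65, 1)
    margin <- a_px + 2
    cx <- runif(1, margin, side - margin)
    cy <- runif(1, margin, side - margin)
    if (nrow(centers) > 0) {
      d <- sqrt((centers[, 1] - cx)^2 + (centers[, 2] - cy)^2)
      if (any(d < ax + a_px + 3)) next
    }
    centers <- rbind(centers, c(cx, cy))
    ax <- c(ax, a_px)
    bx <- c(bx, b_px)
    th <- c(th, runif(1, 0, pi))
  }
  img <- array(rep(params$background_rgb, each = side * side),
               dim = c(side, side, 3))
  img <- img + array(rnorm(side * side * 3, 0, params$pixel_noise),
                     dim = c(side, side, 3))
  mask <- matrix(0L, side, side)
  truth <- list()
  for (k in seq_len(n_nuclei)) {
    cx <- centers[k, 1]
    cy <- centers[k, 2]
    a <- ax[k]
    b <- bx[k]
    rr <- max(a, b)
    xs <- max(1, floor(cx - rr)):min(side, ceiling(cx + rr))
    ys <- max(1, floor(cy - rr)):min(side, ceiling(cy + rr))
    gx <- outer(xs - cx, rep(1, length(ys)))
    gy <- outer(rep(1, length(xs)), ys - cy)
    xr <- gx * cos(th[k]) + gy * sin(th[k])
    yr <- -gx * sin(th[k]) + gy * cos(th[k])
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    col <- pmin(1, pmax(0, params$nucleus_rgb +
                          rnorm(3, 0, params$intensity_jitter)))
    sel <- which(inside, arr.ind = TRUE)
    px <- cbind(xs[sel[, 1]], ys[sel[, 2]])
    for (ch in 1:3) img[cbind(px, ch)] <- col[ch]
    mask[px] <- k
    truth[[k]] <- data.frame(
      label = k, cx = mean(px[, 1]), cy = mean(px[, 2]),
      area_px = nrow(px), area_um2 = nrow(px) * mpp^2,
      rmean = col[1] * 255, gmean = col[2] * 255, bmean = col[3] * 255,
      stringsAsFactors = FALSE)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  list(img = img,
       mask = mask,
       truth = if (n_nuclei > 0) do.call(rbind, truth) else
         data.frame(label = integer(0)))
}

#' Simulate the tile pair of one patient's two foci
#'
#' IM pairs render both foci from one shared morphology parameter draw;
#' MO pairs draw the two foci's parameters independently. The
#' `divergence` entry of `params` scales how far an independent draw can
#' wander from the cohort-average morphology, so at `divergence = 0` the
#' two regimes are indistinguishable in expectation.
#'
#' @param pattern `"IM"` or `"MO"`.
#' @param params image parameters ([default_image_params()]).
#' @return list with `tile_a`, `tile_b` (each a [render_nucleus_tile()]
#'   result) and the drawn per-focus parameters.
#' @export
simulate_focus_pair_images <- function(pattern,
                                       params = default_image_params()) {
  stopifnot(pattern %in% c("IM", "MO"))
  draw_theta <- function() {
    list(
      n = round(runif(1, params$n_range[1], params$n_range[2])),
      radius_mean = max(2.2, params$radius_mean +
                          params$divergence * rnorm(1, 0, 1.0)),
      radius_sd = params$radius_sd,
      rgb_shift = params$divergence * rnorm(3, 0, 0.06)
    )
  }
  th_a <- draw_theta()
  th_b <- if (pattern == "IM") th_a else draw_theta()
  render <- function(th) {
    p <- params
    p$nucleus_rgb <- pmin(0.95, pmax(0.05, p$nucleus_rgb + th$rgb_shift))
    render_nucleus_tile(th$n, p, radius_mean_um = th$radius_mean,
                        radius_sd_um = th$radius_sd)
  }
  list(tile_a = render(th_a), tile_b = render(th_b),
       theta_a = th_a, theta_b = th_b)
}

#' Write a tile to PNG
#'
#' @param tile RGB array in `[0, 1]` (or a [render_nucleus_tile()] result).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_tile_png <- function(tile, path) {
  if (is.list(tile)) tile <- tile$img
  png::writePNG(tile, path)
  invisible(path)
}

#' Read a tile from PNG
#'
#' @param path PNG path.
#' @return RGB array in `[0, 1]`.
#' @export
read_tile_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
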