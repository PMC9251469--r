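test_that("pair simulation matches its Poisson design", {
  cfg <- simulation_config(seed = 2)
  genome <- synthetic_genome(2)
  # IM unions concentrate near trunk + 2 x private = 107
  set.seed(2)
  unions <- replicate(400, {
    sim <- simulate_pair_mutations("IM", cfg, genome)
    length(union(variant_key(sim$variants_a), variant_key(sim$variants_b)))
  })
  expected <- cfg$trunk_rate_im + 2 * cfg$private_rate
  se <- sqrt(expected / 400)
  expect_lt(abs(mean(unions) - expected), 3 * se)
  # zero chance-overlap makes MO pairs fully disjoint
  cfg0 <- simulation_config(seed = 2, chance_overlap_rate_mo = 0)
  set.seed(5)
  for (i in 1:20) {
    sim <- simulate_pair_mutations("MO", cfg0, genome)
    expect_equal(jaccard_index(variant_key(sim$variants_a),
                               variant_key(sim$variants_b)), 0)
  }
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 9, n_patients = 4)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$pairs$Pt01$lesion_a$variants,
                   c2$pairs$Pt01$lesion_a$variants)
  set.seed(31)
  t1 <- render_nucleus_tile(8, small_image_params())
  set.seed(31)
  t2 <- render_nucleus_tile(8, small_image_params())
  expect_identical(t1$img, t2$img)
  expect_identical(t1$mask, t2$mask)
})

test_that("cohort truth matches set cardinalities and label proportions", {
  cfg <- simulation_config(seed = 13, n_patients = 10)
  cohort <- simulate_cohort(cfg)
  for (i in seq_len(10)) {
    pid <- cohort$truth$patient_id[i]
    pr <- cohort$pairs[[pid]]
    part <- shared_private_partition(variant_key(pr$lesion_a$variants),
                                     variant_key(pr$lesion_b$variants))
    expect_equal(cohort$truth$n_trunk[i], length(part$shared))
    expect_equal(cohort$truth$n_private_a[i], length(part$private_a))
    expect_equal(cohort$truth$n_private_b[i], length(part$private_b))
  }
  all_mo <- simulate_cohort(simulation_config(seed = 3, n_patients = 6,
                                              prop_im = 0))
  expect_true(all(all_mo$truth$pattern == "MO"))
})

test_that("emitted cohort files re-parse cleanly through the readers", {
  out_dir <- withr::local_tempdir()
  cfg <- simulation_config(seed = 8, n_patients = 3)
  cohort <- simulate_cohort(cfg, out_dir = out_dir)
  expect_no_warning({
    clin <- read_clinical(cohort$paths$clinical)
    info <- read_sample_info(cohort$paths$sample_info)
    for (lid in info$sample) {
      groups <- read_maf(file.path(cohort$paths$maf_dir, paste0(lid, ".maf")))
      seg <- read_segments(file.path(cohort$paths$seg_dir,
                                     paste0(lid, ".seg.tsv")))
    }
  })
  expect_equal(nrow(clin), 3)
  expect_equal(nrow(info), 6)
  # MAF contents survive the round trip
  lid <- clin$lesion_a_id[1]
  back <- read_maf(file.path(cohort$paths$maf_dir, paste0(lid, ".maf")))[[lid]]
  orig <- cohort$pairs[[clin$patient_id[1]]]$lesion_a$variants
  expect_equal(back$position, orig$position)
  expect_equal(back$ref_allele, orig$ref_allele)
  # the reference FASTA matches the in-memory genome
  ref <- Biostrings::readDNAStringSet(cohort$paths$reference)
  expect_equal(as.character(ref[["sc1"]]), cohort$genome[["sc1"]])
  # variants are reference-consistent (contexts computable)
  snv <- orig[is_snv(orig), ][1:5, ]
  for (k in seq_len(nrow(snv))) {
    expect_no_error(trinucleotide_context(snv[k, ], cohort$genome))
  }
})

test_that("IM pairs have shorter survival than MO pairs by design", {
  cfg <- simulation_config(seed = 77, n_patients = 150, prop_im = 0.5)
  cohort <- simulate_cohort(cfg)
  # compare observed event times by truth label on a large draw
  im <- cohort$clinical$pfs_months[cohort$truth$pattern == "IM"]
  mo <- cohort$clinical$pfs_months[cohort$truth$pattern == "MO"]
  expect_lt(median(im), median(mo))
  # consistent with exponential medians ln(2)/lambda before censoring
  expect_lt(log(2) / cfg$survival_params$hazard[["IM"]],
            log(2) / cfg$survival_params$hazard[["MO"]])
})

test_that("render_nucleus_tile reports exact ground truth", {
  set.seed(41)
  tile <- render_nucleus_tile(10, small_image_params())
  expect_equal(max(tile$mask), 10)
  expect_equal(nrow(tile$truth), 10)
  # mask component sizes equal the reported pixel areas
  sizes <- tabulate(tile$mask[tile$mask > 0], 10)
  expect_equal(sizes, tile$truth$area_px)
  # circular nuclei: pi r^2 within rasterization tolerance
  p <- small_image_params()
  p$radius_sd <- 0
  set.seed(42)
  circ <- render_nucleus_tile(5, p)   # radius 4 um = 8 px (b varies)
  expect_true(all(circ$truth$area_px <= pi * 8.5^2 + 40))
  expect_error(render_nucleus_tile(10000, small_image_params(side = 64)),
               "could not place")
})

test_that("divergence zero makes IM and MO image regimes indistinguishable", {
  p <- small_image_params()
  p$divergence <- 0
  set.seed(50)
  im <- simulate_focus_pair_images("IM", p)
  mo <- simulate_focus_pair_images("MO", p)
  expect_equal(mo$theta_a$radius_mean, mo$theta_b$radius_mean)
  expect_equal(mo$theta_a$rgb_shift, mo$theta_b$rgb_shift)
  expect_identical(im$theta_a, im$theta_b)
})
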