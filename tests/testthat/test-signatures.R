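test_that("context labels are substitution-major and complete", {
  labels <- context_labels()
  expect_length(labels, 96)
  expect_equal(labels[1], "A[C>A]A")
  expect_equal(labels[96], "T[T>G]T")
  expect_false(anyDuplicated(labels) > 0)
  # first 16 all C>A with 5' base A,C,G,T in blocks of 4
  expect_true(all(grepl("\\[C>A\\]", labels[1:16])))
})

test_that("trinucleotide_context reads off and reverse-complements", {
  ref <- tiny_reference()   # sc1 = AACGTACGTTACGGAT
  v <- data.frame(chromosome = "sc1", position = 3, ref_allele = "C",
                  alt_allele = "T")
  expect_equal(trinucleotide_context(v, ref), "A[C>T]G")
  # purine reference: C_G>A_T must become A[C>T]G via reverse complement
  v2 <- data.frame(chromosome = "sc1", position = 8, ref_allele = "G",
                   alt_allele = "A")
  got <- trinucleotide_context(v2, ref)
  # independent oracle: Biostrings reverse complement of the plus-strand triplet
  tri <- substr(ref[["sc1"]], 7, 9)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tri)))
  alt_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString("A")))
  expect_equal(got, paste0(substr(rc, 1, 1), "[", substr(rc, 2, 2), ">",
                           alt_rc, "]", substr(rc, 3, 3)))
  expect_equal(got, "A[C>T]G")
})

test_that("trinucleotide_context error contracts hold", {
  ref <- tiny_reference()
  # reference mismatch
  v <- data.frame(chromosome = "sc1", position = 3, ref_allele = "A",
                  alt_allele = "T")
  expect_error(trinucleotide_context(v, ref), "mismatch")
  # indel input
  v <- data.frame(chromosome = "sc1", position = 3, ref_allele = "-",
                  alt_allele = "T")
  expect_error(trinucleotide_context(v, ref), "not an SNV")
  # contig edge
  v <- data.frame(chromosome = "sc1", position = 1, ref_allele = "A",
                  alt_allele = "T")
  expect_error(trinucleotide_context(v, ref), "edge")
})

test_that("build_context_vector conserves counts and canonicalises strand", {
  ref <- tiny_reference()
  empty <- build_context_vector(empty_snvs <- data.frame(
    chromosome = character(0), position = integer(0),
    ref_allele = character(0), alt_allele = character(0)), ref)
  expect_equal(sum(empty), 0)
  v <- data.frame(chromosome = rep("sc1", 10), position = 3,
                  ref_allele = "C", alt_allele = "T")
  cv <- build_context_vector(v, ref)
  expect_equal(unname(cv["A[C>T]G"]), 10L)
  expect_equal(sum(cv), 10)
  # the same biological change seen from either strand lands in one cell:
  # sc1:3 C>T (plus) and its purine mirror at a G site with mirrored flanks
  genome <- synthetic_genome(99, n_contigs = 2, contig_len = 5000)
  set.seed(5)
  snvs <- draw_many_snvs(genome, 200)
  cv_all <- build_context_vector(snvs, genome)
  expect_equal(sum(cv_all), nrow(snvs))
  # canonical: every counted context has a pyrimidine reference base
  expect_true(all(grepl("\\[(C|T)>", names(cv_all)[cv_all > 0])))
})

test_that("pure and mixed signature spectra are recovered by the fit", {
  S <- load_signature_matrix()
  # pure signature column
  cv <- round(S[, 7] * 1000)
  fit <- fit_signatures(cv, S)
  expect_gte(fit$exposures[["Signature.7"]], 0.99)
  # exact 0.6/0.4 two-signature mixture
  cv <- round(1e5 * (0.6 * S[, 1] + 0.4 * S[, 6]))
  fit <- fit_signatures(cv, S)
  expect_equal(unname(fit$exposures[["Signature.1"]]), 0.6, tolerance = 0.02 / 0.6)
  expect_equal(unname(fit$exposures[["Signature.6"]]), 0.4, tolerance = 0.02 / 0.4)
  expect_error(fit_signatures(setNames(rep(0, 96), context_labels()), S),
               "empty")
})

test_that("finite-sample draws from one signature stay dominant", {
  S <- load_signature_matrix()
  set.seed(77)
  res <- replicate(100, {
    cv <- as.numeric(rmultinom(1, 50, S[, 1]))
    fit <- fit_signatures(setNames(cv, context_labels()), S)
    c(l1 = sum(abs(fit$exposures - c(1, rep(0, 29)))),
      dominant = unname(fit$exposures[1]) == max(fit$exposures))
  })
  # 50 mutations are few: the fit must still put most mass on the true
  # signature in every run, with a bounded distributional L1 error
  expect_equal(sum(res["dominant", ]), 100)
  expect_lt(mean(res["l1", ]), 0.3)
})

test_that("residual never increases when min_exposure is lowered", {
  S <- load_signature_matrix()
  set.seed(12)
  for (i in 1:5) {
    w <- as.numeric(rmultinom(1, 3, rep(1 / 30, 30))) / 3
    cv <- as.numeric(rmultinom(1, 2000, as.numeric(S %*% w)))
    cv <- setNames(cv, context_labels())
    res <- vapply(c(0.2, 0.1, 0.06, 0.01, 0),
                  function(m) fit_signatures(cv, S, m)$residual, numeric(1))
    expect_true(all(diff(res) <= 1e-12))
  }
})

test_that("reduce_exposures groups named signatures and conserves mass", {
  e <- setNames(numeric(30), paste0("Signature.", 1:30))
  e["Signature.1"] <- 1
  r <- reduce_exposures(e)
  expect_equal(unname(r["sig1"]), 1.0)
  expect_equal(unname(r["others"]), 0.0)
  e[] <- 0
  e[c("Signature.22", "Signature.3")] <- 0.5
  r <- reduce_exposures(e)
  expect_equal(unname(r["sig3"]), 0.5)
  expect_equal(unname(r["others"]), 0.5)
  set.seed(8)
  for (i in 1:100) {
    e[] <- rgamma(30, 1)
    e <- e / sum(e)
    expect_equal(sum(reduce_exposures(e)), sum(e))
  }
  # configurable group set
  r22 <- reduce_exposures(e, groups = c(1, 3, 6, 22))
  expect_true("sig22" %in% names(r22))
})

test_that("the bundled signature TSV equals its generator and is stochastic", {
  S_file <- load_signature_matrix()
  S_gen <- synthetic_signature_matrix()
  expect_equal(S_file, S_gen, tolerance = 1e-6)
  expect_true(all(abs(colSums(S_file) - 1) < 1e-9))
  expect_true(all(S_file >= 0))
})
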