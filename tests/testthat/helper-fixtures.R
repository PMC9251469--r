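# Shared fixtures built in code at test time.

toy_maf_lines <- function() {
  c(
    paste("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
          "Tumor_Seq_Allele2", "Variant_Classification",
          "Tumor_Sample_Barcode", sep = "\t"),
    paste("TP53", "chr17", "7578406", "C", "T", "Missense_Mutation", "S1",
          sep = "\t"),
    paste("TTN", "2", "179400000", "G", "A", "Silent", "S1", sep = "\t"),
    paste("ARID1A", "1", "27100000", "A", "G", "Nonsense_Mutation", "S2",
          sep = "\t")
  )
}

write_toy_maf <- function(lines = toy_maf_lines()) {
  path <- withr::local_tempfile(fileext = ".maf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# random variant-key sets for property tests
random_key_set <- function(n, universe = 500) {
  paste0("1:", sample.int(universe, n), ":A:T")
}

# brute-force Jaccard by double loop (independent of set operations)
jaccard_bruteforce <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  n_int <- 0
  for (x in a) {
    for (y in b) {
      if (identical(x, y)) n_int <- n_int + 1
    }
  }
  n_int / (length(a) + length(b) - n_int)
}

# independent two-sided Fisher p by explicit choose()-based enumeration
fisher_p_oracle <- function(a, b, cc, d) {
  n <- a + b + cc + d
  m1 <- a + b
  k1 <- a + cc
  prob_of <- function(x) {
    choose(m1, x) * choose(n - m1, k1 - x) / choose(n, k1)
  }
  xs <- max(0, k1 - (n - m1)):min(m1, k1)
  probs <- vapply(xs, prob_of, numeric(1))
  p_obs <- prob_of(a)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# small deterministic reference sequence for context tests
tiny_reference <- function() {
  c(sc1 = "AACGTACGTTACGGAT", sc2 = "TTTCAGGCATCA")
}

# draw n reference-consistent SNVs from a synthetic genome
draw_many_snvs <- function(genome, n) {
  contigs <- sample(names(genome), n, replace = TRUE)
  pos <- vapply(contigs, function(cn)
    sample(2:(nchar(genome[[cn]]) - 1), 1), integer(1))
  ref <- toupper(substr(genome[contigs], pos, pos))
  alt <- vapply(ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
  data.frame(chromosome = contigs, position = pos, ref_allele = ref,
             alt_allele = unname(alt), row.names = NULL,
             stringsAsFactors = FALSE)
}

small_image_params <- function(side = 256, n_range = c(8, 20)) {
  p <- mfclone::default_image_params()
  p$side <- side
  p$n_range <- n_range
  p
}
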