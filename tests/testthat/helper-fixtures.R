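# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk.

# minimal hand-built bundle
tiny_bundle <- function(geno, chrom = NULL, pos = NULL) {
  geno <- as.matrix(geno)
  n <- nrow(geno); m <- ncol(geno)
  cohort_bundle(
    geno,
    data.frame(sample_id = sprintf("s%03d", seq_len(n))),
    data.frame(variant_id = sprintf("v%03d", seq_len(m)),
               chrom = chrom %||% rep("1", m),
               pos = pos %||% seq_len(m) * 1000L,
               allele1 = "A", allele2 = "G",
               stringsAsFactors = FALSE)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one-population cohort without the LD region
plain_spec <- function(n_samples, n_variants, seed, missing_rate = 0.002,
                       maf_dist = list(type = "beta", shape1 = 2, shape2 = 2,
                                       min = 0.05, max = 0.5)) {
  cohort_spec(n_samples = n_samples, n_variants = n_variants,
              maf_dist = maf_dist, region = list(n_variants = 0L),
              ancestry = list(k = 1L, fst = 0, proportions = 1),
              missing_rate = missing_rate, seed = seed)
}

# the region-test study fixture: 200 samples, 300-SNP dense-LD region
region_fixture_spec <- function(seed) {
  cohort_spec(
    n_samples = 200L, n_variants = 300L,
    region = list(n_variants = 300L, block_length = 10L, pool_size = 8L,
                  maf_dist = list(type = "beta", shape1 = 2, shape2 = 2,
                                  min = 0.05, max = 0.5),
                  chrom = "6", start = 29600000L, end = 33100000L),
    ancestry = list(k = 1L, fst = 0, proportions = 1),
    missing_rate = 0.002, seed = seed)
}

# planted region effect at the calibrated size: 10 causal SNPs, +0.5 per
# (centred) minor allele on each DMN constituent symptom
planted_region_effects <- function() {
  effect_spec(region_effect = list(
    symptom = c("diarrhoea", "mucositis", "neutropenia"),
    n_causal = 10L, beta = 0.5))
}

# small grade table for phenotype tests
toy_grades <- function() {
  grade_table(data.frame(
    sample_id = paste0("p", 1:6),
    diarrhoea   = c(2L, 3L, 0L, 0L, 1L, NA),
    mucositis   = c(0L, 1L, 0L, 2L, 1L, 0L),
    neutropenia = c(3L, 0L, 0L, 1L, 2L, 0L),
    hfs         = c(2L, 3L, 0L, 1L, 2L, 0L),
    treatment   = c("Capecitabine", "Capecitabine", "5FU", "Capecitabine",
                    "5FU", "Capecitabine"),
    stringsAsFactors = FALSE
  ))
}
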