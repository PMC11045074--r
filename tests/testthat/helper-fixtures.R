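# shared fixture builders (all generated in code, no stored data)

# a tiny kin_samples table built directly from a genotype matrix
tiny_samples <- function(geno, ids = NULL, ...) {
  n <- nrow(geno)
  meta <- data.frame(sample_id = if (is.null(ids)) sprintf("S%02d", 1:n) else ids,
                     ...)
  kin_samples(geno, meta)
}

# the survey-shaped 183-record fixture used across tests
study_fixture <- function(seed = 1, ...) sim_srw_study(seed = seed, ...)

# reorder rows of a kin_samples via the public constructor
.subset_samples_for_test <- function(s, idx) {
  kin_samples(s$geno[idx, , drop = FALSE], s$meta[idx, , drop = FALSE],
              loci = s$loci)
}

# n HWE draws from a single locus with given freqs, as a kin_samples
hwe_locus_samples <- function(n, alleles, freqs, seed = 1) {
  set.seed(seed)
  a1 <- sample(alleles, n, replace = TRUE, prob = freqs)
  a2 <- sample(alleles, n, replace = TRUE, prob = freqs)
  tiny_samples(cbind(L1_1 = a1, L1_2 = a2))
}
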