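# Small builders shared across the suite. All fixtures are generated in
# code; nothing is read from disk except files the tests write themselves.

tiny_genome <- function(n_chrom = 2, length_bp = 1e7, map_length = 1) {
  genome_model(paste0("chr", seq_len(n_chrom)), length_bp, map_length)
}

# Allele-depth tibble from an alt-count matrix and a depth matrix
# (sites x samples), at consecutive positions on one chromosome.
ad_from_matrices <- function(alt_mat, depth_mat, chrom = "chr1",
                             pos = seq_len(nrow(alt_mat)) * 1000L) {
  samples <- paste0("s", seq_len(ncol(alt_mat)))
  purrr::map_dfr(seq_along(samples), function(j) {
    tibble::tibble(chrom = chrom, pos = as.integer(pos),
                   ref = "A", alt = "G", sample = samples[j],
                   alt_count = as.integer(alt_mat[, j]),
                   total_depth = as.integer(depth_mat[, j]))
  })
}

# Independent brute-force coding of the ranked-VAF triage rule, kept
# deliberately naive (explicit sort, if/else chain).
oracle_classify <- function(vafs, vaf_min = 0.05, ratio = 0.40) {
  v <- sort(vafs, decreasing = TRUE)
  if (v[1] <= vaf_min) {
    "EXCLUDED"
  } else if (v[2] > ratio * v[1]) {
    "GERMLINE_OR_FALSE"
  } else {
    "SOMATIC"
  }
}

# Exact binomial expectation of |VAF - 0.5| at depth d for a balanced het
# site: direct summation over all outcomes.
expected_abs_dev <- function(d) {
  k <- 0:d
  sum(abs(k / d - 0.5) * dbinom(k, d, 0.5))
}
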