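# Shared fixture builders.

make_snp_dataset <- function(ref, alt, group,
                             subject = sprintf("S%02d", seq_along(ref)),
                             snp_id = "rs_test", region = "BLA") {
  structure(list(
    site = list(chrom = "chr1", pos = 1000L, snp_id = snp_id,
                ref = "A", alt = "G"),
    region = region,
    data = data.frame(subject_id = subject, group = group,
                      ref_count = ref, alt_count = alt,
                      stringsAsFactors = FALSE)),
    class = "snp_dataset")
}

# A small random GLMM dataset with both groups represented.
random_glmm_dataset <- function(n_min = 3, n_max = 6, depth = 100,
                                theta = 10, sigma_b = 0.3,
                                beta12 = log(2)) {
  n <- sample(n_min:n_max, 1)
  g <- c(0L, 1L, rbinom(max(0, n - 2), 1, 0.5))[seq_len(max(n, 2))]
  b <- rnorm(length(g), 0, sigma_b)
  m0 <- log(depth) - log1p(exp(beta12 * g)) - sigma_b^2 / 2
  ref <- rnbinom(length(g), mu = exp(m0 + b), size = theta)
  alt <- rnbinom(length(g), mu = exp(m0 + beta12 * g + b), size = theta)
  ase_design(ref, alt, ifelse(g == 1, "AUD", "control"),
             sprintf("S%02d", seq_along(g)))
}

# Minimal result-table row for classification/consistency fixtures.
result_row <- function(snp_id, beta12, p, q, region = "BLA") {
  data.frame(snp_id = snp_id, chrom = "chr1",
             pos = as.integer(1000 * seq_along(snp_id)), region = region,
             beta12 = beta12, adj_log2_fc = beta12 / log(2),
             std_error = 0.1, p_value = p, q_value = q,
             direction = ifelse(beta12 > 0, "up", "down"),
             n_het_aud = 5L, n_het_ctl = 5L, sigma_b = 0.3, theta = 10,
             fit_status = "converged", stringsAsFactors = FALSE)
}
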