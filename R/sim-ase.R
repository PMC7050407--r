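#' Configuration for the ASE cohort simulator
#'
#' Defines the study design and generative parameters of the synthetic
#' allelic-count data: a two-group cohort measured in one or more brain
#' regions, with negative binomial allelic counts at heterozygous SNPs, a
#' per-subject random intercept, and a planted allele-by-group interaction
#' in a chosen fraction of SNPs.  Defaults mirror the design the package
#' targets: 30 AUD and 30 control subjects across four brain regions,
#' read depth around 100 per heterozygous sample and SNP.
#'
#' The intercept is calibrated per group so that the expected total
#' (ref + alt) per heterozygous sample equals `depth_mean` exactly,
#' including the lognormal inflation from the random intercept:
#' `beta0_g = log(depth_mean) - log(1 + exp(beta1 + beta12 * g)) - sigma_b^2 / 2`.
#'
#' @param n_aud,n_ctl Subjects per group.
#' @param regions Character vector of region labels.
#' @param n_snps Number of simulated SNPs.
#' @param frac_differential Fraction of SNPs with a planted non-zero
#'   interaction.
#' @param beta12_true Planted allele-by-group interaction, natural-log
#'   scale (`log(2)` corresponds to an adjusted log2 fold change of 1,
#'   the significance threshold used downstream).
#' @param beta1_base Baseline allelic bias (log alt/ref in controls).
#' @param theta NB dispersion (variance `mu + mu^2/theta`).
#' @param sigma_b SD of the per-subject random intercept (log scale).
#' @param depth_mean Expected total reads per heterozygous sample per SNP.
#' @param het_prob Probability that a subject is heterozygous at a SNP.
#' @param seed Integer seed; all outputs are deterministic given it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_aud = 30, n_ctl = 30,
                       regions = c("BLA", "CE", "NAC", "SFC"),
                       n_snps = 100, frac_differential = 0.1,
                       beta12_true = log(2), beta1_base = 0,
                       theta = 10, sigma_b = 0.3, depth_mean = 100,
                       het_prob = 0.3, seed = 1L) {
  stopifnot(n_aud >= 0, n_ctl >= 0, length(regions) >= 1, n_snps >= 1,
            frac_differential >= 0, frac_differential <= 1,
            het_prob >= 0, het_prob <= 1, theta > 0, sigma_b >= 0,
            depth_mean > 0)
  structure(list(n_aud = as.integer(n_aud), n_ctl = as.integer(n_ctl),
                 regions = as.character(regions),
                 n_snps = as.integer(n_snps),
                 frac_differential = frac_differential,
                 beta12_true = beta12_true, beta1_base = beta1_base,
                 theta = theta, sigma_b = sigma_b,
                 depth_mean = depth_mean, het_prob = het_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# NB draw that degrades gracefully to Poisson at very large theta.
.rnb <- function(n, mu, theta) {
  if (theta >= 1e7) rpois(n, mu) else rnbinom(n, mu = mu, size = theta)
}

# Deterministic synthetic SNP sites: chr1..chr22 round-robin, positions
# spaced 1 kb, alternating ref/alt alleles.
.sim_sites <- function(n_snps) {
  base <- c("A", "C", "G", "T")
  ref <- base[(seq_len(n_snps) - 1L) %% 4L + 1L]
  alt <- base[seq_len(n_snps) %% 4L + 1L]
  data.frame(contig = paste0("chr", (seq_len(n_snps) - 1L) %% 22L + 1L),
             position = 1000L * seq_len(n_snps),
             snp_id = sprintf("snp%04d", seq_len(n_snps)),
             ref = ref, alt = alt, stringsAsFactors = FALSE)
}

#' Generate a two-group cohort with genotypes
#'
#' Creates subject/sample metadata (one sample per subject per region) and
#' a genotype call matrix.  Each (subject, SNP) is heterozygous with
#' probability `het_prob`, independently; the remaining probability is
#' split equally between the two homozygous states.
#'
#' @param config A [sim_config()].
#' @return List with `samples` (data frame: sample_id, subject_id, group,
#'   region), `sites` (data frame of SNP coordinates and alleles) and
#'   `genotypes` (character matrix, SNPs x subjects, values `hom_ref`,
#'   `het`, `hom_alt`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_aud == 0L || config$n_ctl == 0L)
    stop("both groups must have at least one subject")
  withr::with_seed(config$seed, {
    subjects <- c(sprintf("AUD%02d", seq_len(config$n_aud)),
                  sprintf("CTL%02d", seq_len(config$n_ctl)))
    group <- rep(c("AUD", "control"), c(config$n_aud, config$n_ctl))
    samples <- data.frame(
      sample_id = as.vector(outer(subjects, config$regions, paste, sep = "_")),
      subject_id = rep(subjects, times = length(config$regions)),
      group = rep(group, times = length(config$regions)),
      region = rep(config$regions, each = length(subjects)),
      stringsAsFactors = FALSE)
    sites <- .sim_sites(config$n_snps)
    n <- config$n_snps * length(subjects)
    u <- runif(n)
    call <- ifelse(u < config$het_prob, "het",
                   ifelse(u < config$het_prob + (1 - config$het_prob) / 2,
                          "hom_ref", "hom_alt"))
    genotypes <- matrix(call, nrow = config$n_snps,
                        dimnames = list(sites$snp_id, subjects))
    list(samples = samples, sites = sites, genotypes = genotypes)
  })
}

#' Generate allelic count tables with planted differential ASE
#'
#' For every heterozygous (subject, SNP) pair in every region, draws a
#' per-subject-and-region random intercept `b ~ N(0, sigma_b^2)` and NB
#' counts for the two alleles:
#' `ref ~ NB(exp(beta0_g + b), theta)`,
#' `alt ~ NB(exp(beta0_g + beta1 + beta12 * g + b), theta)`,
#' where `g = 1` for AUD subjects and `beta0_g` is calibrated so the
#' expected total equals `depth_mean` in both groups.  A fraction
#' `frac_differential` of SNPs (the first ones, recorded in the truth
#' table) carries `beta12 = beta12_true`; the rest have `beta12 = 0`.
#' Homozygous subjects receive all reads on the carried allele.
#'
#' @param config A [sim_config()].
#' @param cohort Output of [generate_cohort()].
#' @return List with `counts` (named list, one ASEReadCounter-style data
#'   frame per region with a trailing `sample` column) and `truth`
#'   (data frame: snp_id, is_differential, beta12_true, beta1_true).
#' @export
generate_ase_counts <- function(config, cohort) {
  stopifnot(inherits(config, "sim_config"))
  n_diff <- round(config$frac_differential * config$n_snps)
  truth <- data.frame(
    snp_id = cohort$sites$snp_id,
    is_differential = seq_len(config$n_snps) <= n_diff,
    beta12_true = ifelse(seq_len(config$n_snps) <= n_diff,
                         config$beta12_true, 0),
    beta1_true = config$beta1_base, stringsAsFactors = FALSE)
  subjects <- colnames(cohort$genotypes)
  subj_group <- unique(cohort$samples[, c("subject_id", "group")])
  g <- as.integer(subj_group$group[match(subjects,
                                         subj_group$subject_id)] == "AUD")
  counts <- withr::with_seed(config$seed + 1L, {
    lapply(setNames(config$regions, config$regions), function(region) {
      rows <- lapply(seq_len(config$n_snps), function(i) {
        b12 <- truth$beta12_true[i]
        b1 <- config$beta1_base
        call <- cohort$genotypes[i, ]
        b <- rnorm(length(subjects), 0, config$sigma_b)
        beta0 <- log(config$depth_mean) - log1p(exp(b1 + b12 * g)) -
          config$sigma_b^2 / 2
        mu_ref <- exp(beta0 + b)
        mu_alt <- exp(beta0 + b1 + b12 * g + b)
        ref <- .rnb(length(subjects), mu_ref, config$theta)
        alt <- .rnb(length(subjects), mu_alt, config$theta)
        # homozygotes express only the carried allele; total stays at depth
        mu_hom <- exp(log(config$depth_mean) - config$sigma_b^2 / 2 + b)
        hom <- .rnb(length(subjects), mu_hom, config$theta)
        ref <- ifelse(call == "het", ref, ifelse(call == "hom_ref", hom, 0L))
        alt <- ifelse(call == "het", alt, ifelse(call == "hom_alt", hom, 0L))
        data.frame(contig = cohort$sites$contig[i],
                   position = cohort$sites$position[i],
                   variantID = cohort$sites$snp_id[i],
                   refAllele = cohort$sites$ref[i],
                   altAllele = cohort$sites$alt[i],
                   refCount = as.integer(ref), altCount = as.integer(alt),
                   totalCount = as.integer(ref + alt),
                   sample = paste(subjects, region, sep = "_"),
                   stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows)
      out[order(out$position), , drop = FALSE]
    })
  })
  list(counts = counts, truth = truth)
}

#' Simulate one SNP's per-subject allelic counts
#'
#' Low-level generator used by the power simulation and calibration
#' studies: `n_aud + n_ctl` heterozygous subjects, NB allelic counts with
#' a per-subject random intercept and an allele-by-group interaction
#' `beta12` (natural-log scale).  Draws from the current RNG stream; seed
#' control belongs to the caller.
#'
#' @param n_aud,n_ctl Heterozygous subjects per group.
#' @param depth_mean Expected total reads per subject.
#' @param theta NB dispersion.
#' @param sigma_b Random-intercept SD.
#' @param beta1 Baseline log alt/ref bias.
#' @param beta12 Planted interaction (natural-log scale).
#' @return Data frame: subject_id, group, ref_count, alt_count.
#' @export
simulate_snp_dataset <- function(n_aud, n_ctl, depth_mean = 100,
                                 theta = 10, sigma_b = 0.3,
                                 beta1 = 0, beta12 = 0) {
  n <- n_aud + n_ctl
  g <- rep(c(1L, 0L), c(n_aud, n_ctl))
  b <- rnorm(n, 0, sigma_b)
  beta0 <- log(depth_mean) - log1p(exp(beta1 + beta12 * g)) - sigma_b^2 / 2
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = ifelse(g == 1L, "AUD", "control"),
    ref_count = .rnb(n, exp(beta0 + b), theta),
    alt_count = .rnb(n, exp(beta0 + beta1 + beta12 * g + b), theta),
    stringsAsFactors = FALSE)
}

#' Write an allelic count table in ASEReadCounter-style TSV
#'
#' @param counts Data frame as produced by [generate_ase_counts()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ase_counts <- function(counts, path) {
  write.table(counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cohort genotypes as a GT-only VCF v4.2
#'
#' @param cohort Output of [generate_cohort()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(cohort, path) {
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
               missing = "./.")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       colnames(cohort$genotypes)), collapse = "\t")), con)
  body <- vapply(seq_len(nrow(cohort$sites)), function(i) {
    paste(c(cohort$sites$contig[i], cohort$sites$position[i],
            cohort$sites$snp_id[i], cohort$sites$ref[i],
            cohort$sites$alt[i], ".", "PASS", ".", "GT",
            gt_code[cohort$genotypes[i, ]]), collapse = "\t")
  }, "")
  writeLines(body, con)
  invisible(path)
}

#' Write sample metadata TSV
#'
#' @param samples Data frame with sample_id, subject_id, group, region.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sample_meta <- function(samples, path) {
  write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
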