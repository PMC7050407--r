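write_counts_fixture <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

base_counts <- function() {
  data.frame(contig = "chr1", position = 1000L, variantID = "rs1",
             refAllele = "A", altAllele = "G", refCount = 12L,
             altCount = 8L, stringsAsFactors = FALSE)
}

test_that("ASE count tables parse, validate, and report bad lines", {
  p <- write_counts_fixture(base_counts())
  rec <- read_ase_counts(p, sample_id = "s1")
  expect_equal(rec$totalCount, 20L)
  expect_equal(rec$sample, "s1")
  # header-only file gives an empty collection
  p0 <- write_counts_fixture(base_counts()[0, ])
  expect_equal(nrow(read_ase_counts(p0, sample_id = "s1")), 0L)
  # negative counts are rejected with the offending line
  bad <- base_counts()
  bad$refCount <- -1L
  expect_error(read_ase_counts(write_counts_fixture(bad), "s1"),
               "refCount at line 2")
  # multi-allelic sites are rejected
  ma <- rbind(base_counts(), base_counts())
  ma$altAllele[2] <- "T"
  ma$sample <- "s1"
  expect_error(read_ase_counts(write_counts_fixture(ma)), "multi-allelic")
  # identical ref/alt is invalid
  same <- base_counts()
  same$altAllele <- "A"
  expect_error(read_ase_counts(write_counts_fixture(same), "s1"),
               "alleles")
})

test_that("genotype readers map GT codes and dosages, ignoring phase", {
  cfg <- sim_config(n_aud = 3, n_ctl = 3, regions = "BLA", n_snps = 5,
                    seed = 7)
  cohort <- generate_cohort(cfg)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes_vcf(cohort, vcf)
  gt <- read_genotypes(vcf)
  expect_equal(dim(gt$calls), dim(cohort$genotypes))
  expect_equal(unname(gt$calls), unname(cohort$genotypes))
  # GT string mapping incl. phased and missing
  expect_equal(aseglmm:::.gt_to_call(c("0/1", "1|0", "./.", "0|0", "1/1")),
               c("het", "het", "missing", "hom_ref", "hom_alt"))
  # TSV dosage variant
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(snp_id = c("a", "b"), S1 = c(0, 1),
                         S2 = c(2, NA)),
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  gt2 <- read_genotypes(tsv)
  expect_equal(gt2$calls["a", "S2"], "hom_alt")
  expect_equal(gt2$calls["b", "S2"], "missing")
  expect_equal(gt2$calls["b", "S1"], "het")
})

make_filter_fixture <- function(n_aud_het, n_ctl_het, total = 30,
                                n_aud = 8, n_ctl = 8, snp = "rs1") {
  subj <- c(sprintf("A%02d", seq_len(n_aud)), sprintf("C%02d", seq_len(n_ctl)))
  grp <- rep(c("AUD", "control"), c(n_aud, n_ctl))
  samples <- data.frame(sample_id = paste0(subj, "_BLA"), subject_id = subj,
                        group = grp, region = "BLA",
                        stringsAsFactors = FALSE)
  het <- c(rep("het", n_aud_het), rep("hom_ref", n_aud - n_aud_het),
           rep("het", n_ctl_het), rep("hom_alt", n_ctl - n_ctl_het))
  calls <- matrix(het, nrow = 1, dimnames = list(snp, subj))
  counts <- data.frame(contig = "chr1", position = 1000L, variantID = snp,
                       refAllele = "A", altAllele = "G",
                       refCount = as.integer(ceiling(total / 2)),
                       altCount = as.integer(floor(total / 2)),
                       totalCount = as.integer(total),
                       sample = samples$sample_id,
                       stringsAsFactors = FALSE)
  list(counts = counts, genotypes = list(calls = calls), samples = samples)
}

test_that("testability filter applies the het and read-depth rules", {
  # 5 + 5 qualifying hets at total >= 11: retained
  fx <- make_filter_fixture(5, 5, total = 11)
  fl <- filter_testable_snps(fx$counts, fx$genotypes, fx$samples)
  expect_length(fl$datasets, 1)
  expect_equal(nrow(fl$datasets[[1]]$data), 10)
  # a subject at exactly the threshold total is excluded (strict >)
  fx10 <- make_filter_fixture(5, 5, total = 10)
  fl10 <- filter_testable_snps(fx10$counts, fx10$genotypes, fx10$samples)
  expect_length(fl10$datasets, 0)
  expect_true(all(fl10$audit$reason[fl10$audit$reason == "low_reads"] ==
                    "low_reads"))
  # 6 AUD but only 4 control hets: dropped
  fx64 <- make_filter_fixture(6, 4, total = 30)
  fl64 <- filter_testable_snps(fx64$counts, fx64$genotypes, fx64$samples)
  expect_length(fl64$datasets, 0)
  expect_true("insufficient_het_subjects" %in% fl64$audit$reason)
})

test_that("every input record lands in a dataset or the audit log", {
  cfg <- sim_config(n_aud = 8, n_ctl = 8, regions = "BLA", n_snps = 15,
                    depth_mean = 30, het_prob = 0.5, seed = 13)
  cohort <- generate_cohort(cfg)
  sim <- generate_ase_counts(cfg, cohort)
  counts <- sim$counts$BLA
  fl <- filter_testable_snps(counts, list(calls = cohort$genotypes),
                             cohort$samples)
  n_in_datasets <- sum(vapply(fl$datasets, function(d) nrow(d$data), 0L))
  n_subject_audit <- sum(!is.na(fl$audit$subject_id))
  expect_equal(n_in_datasets + n_subject_audit, nrow(counts))
})

test_that("filter matches a brute-force re-scan on random fixtures", {
  set.seed(17)
  for (rep in 1:25) {
    cfg <- sim_config(n_aud = sample(5:9, 1), n_ctl = sample(5:9, 1),
                      regions = "BLA", n_snps = 8,
                      depth_mean = sample(c(8, 15, 40), 1),
                      het_prob = runif(1, 0.3, 0.9),
                      seed = sample.int(1e6, 1))
    cohort <- generate_cohort(cfg)
    sim <- generate_ase_counts(cfg, cohort)
    fl <- filter_testable_snps(sim$counts$BLA,
                               list(calls = cohort$genotypes),
                               cohort$samples)
    got <- sort(vapply(fl$datasets, function(d) d$site$snp_id, ""))
    want <- filter_brute(sim$counts$BLA, cohort$genotypes, cohort$samples)
    expect_equal(got, want)
  }
})

test_that("filtering is idempotent", {
  cfg <- sim_config(n_aud = 8, n_ctl = 8, regions = "BLA", n_snps = 12,
                    het_prob = 0.7, seed = 19)
  cohort <- generate_cohort(cfg)
  sim <- generate_ase_counts(cfg, cohort)
  fl1 <- filter_testable_snps(sim$counts$BLA,
                              list(calls = cohort$genotypes),
                              cohort$samples)
  counts2 <- datasets_to_counts(fl1$datasets, cohort$samples)
  fl2 <- filter_testable_snps(counts2, list(calls = cohort$genotypes),
                              cohort$samples)
  expect_equal(length(fl2$datasets), length(fl1$datasets))
  expect_equal(lapply(fl2$datasets, function(d) d$data),
               lapply(fl1$datasets, function(d) d$data))
  expect_equal(nrow(fl2$audit), 0L)
})

test_that("subjects missing from the genotype table are warned and dropped", {
  fx <- make_filter_fixture(5, 5, total = 30)
  calls <- fx$genotypes$calls[, -1, drop = FALSE]  # drop one subject
  expect_warning(
    fl <- filter_testable_snps(fx$counts, list(calls = calls), fx$samples),
    "absent from genotypes")
  expect_true("genotype_missing" %in% fl$audit$reason)
})
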