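small_library <- function(n = 3, flank_len = 10, seed = 101) {
  design_library(simulate_snp_manifest(n, flank_len = flank_len,
                                       seed = seed),
                 flank_len = flank_len)
}

test_that("library design yields two constructs per SNP differing at the center", {
  man <- simulate_snp_manifest(25, flank_len = 12, seed = 3)
  lib <- design_library(man, flank_len = 12)
  expect_equal(nrow(lib), 50L)
  expect_equal(as.integer(table(lib$snp_id)), rep(2L, 25))
  pair <- lib[lib$snp_id == "snp0001", ]
  a <- strsplit(pair$sequence[1], "")[[1]]
  b <- strsplit(pair$sequence[2], "")[[1]]
  expect_equal(which(a != b), 13L)   # flank_len + 1: the variant base
  expect_equal(length(a), 2L * 12L + 1L)
  # insufficient flank names the SNP
  man$flank5[3] <- "ACGT"
  expect_error(design_library(man, flank_len = 12), "snp0003")
  # identical inserts across SNPs are an ambiguity error
  man2 <- simulate_snp_manifest(2, flank_len = 8, seed = 4)
  man2[2, c("ref", "alt", "flank5", "flank3")] <-
    man2[1, c("ref", "alt", "flank5", "flank3")]
  expect_error(design_library(man2, flank_len = 8), "duplicate insert")
})

test_that("the replicate layout yields one barcode per condition", {
  bm <- make_barcode_map(n_replicates = 6, seed = 5)
  expect_equal(nrow(bm), 24L)  # 2 cell lines x 6 replicates x 2 sources
  expect_equal(anyDuplicated(bm$barcode), 0L)
  expect_true(all(nchar(bm$barcode) == 8L))
  # duplicated barcodes are rejected downstream
  bm$barcode[2] <- bm$barcode[1]
  expect_error(demultiplex("ACGTACGTAAA", bm), "duplicate barcodes")
})

test_that("demultiplexing assigns exact matches and refuses ties", {
  bm <- data.frame(barcode = c("AAAAAAAA", "CCCCCCCC", "AAAAAATT"),
                   cell_line = "SH", replicate = c(1, 1, 2),
                   source = c("DNA", "RNA", "DNA"),
                   stringsAsFactors = FALSE)
  reads <- c("AAAAAAAAGGG",   # exact
             "AAAAAAGGGGG",   # 2 mismatches from barcode 1
             "AAAAAAATGGG",   # 1 mismatch from barcodes 1 and 3: tie
             "CCCCCCCAGGG")   # 1 mismatch from barcode 2
  d0 <- demultiplex(reads, bm, max_mismatch = 0)
  expect_equal(d0$assignment$barcode[1], "AAAAAAAA")
  expect_equal(d0$n_unassigned, 3L)
  d1 <- demultiplex(reads, bm, max_mismatch = 1)
  expect_true(is.na(d1$assignment$barcode[2]))   # beyond tolerance
  expect_true(is.na(d1$assignment$barcode[3]))   # equidistant tie
  expect_equal(d1$assignment$barcode[4], "CCCCCCCC")
  expect_equal(d1$n_unassigned, 2L)
})

test_that("UMI extraction trims, discards short reads, flags Ns", {
  r <- c(paste0(strrep("A", 10), strrep("G", 65)),  # 75 nt
         strrep("A", 10),                           # exactly umi_len
         paste0("ACGTNACGTN", "TTTT"))
  um <- extract_umi(r, umi_len = 10)
  expect_equal(nchar(um$insert[1]), 65L)
  expect_equal(nchar(um$umi[1]), 10L)
  expect_true(is.na(um$umi[2]))
  expect_equal(um$n_discarded, 1L)
  expect_true(um$flag_n[3])
})

test_that("allele assignment is by exact sequence content", {
  lib <- small_library(2, flank_len = 10)
  full <- lib$sequence[1]
  pair <- lib[lib$snp_id == lib$snp_id[1], ]
  # a read equal to a construct insert maps to it
  a1 <- assign_allele(full, lib)
  expect_equal(a1$status, "assigned")
  expect_equal(a1$allele, lib$allele[1])
  # flank-only read (variant base not covered) is ambiguous
  flank <- substr(full, 1, 10)
  expect_equal(assign_allele(flank, lib)$status, "ambiguous")
  # substituting the variant base reassigns to the other allele
  other <- pair$sequence[2]
  expect_equal(assign_allele(other, lib)$allele, pair$allele[2])
  # foreign sequence is unmapped
  expect_equal(assign_allele(strrep("A", 21), lib)$status, "unmapped")
})

test_that("UMI deduplication matches brute force in both modes", {
  grp <- data.frame(snp_id = "s", allele = "ref", cell_line = "SH",
                    replicate = 1L, source = "DNA",
                    umi = c("AAA", "AAA", "AAT"),
                    stringsAsFactors = FALSE)
  expect_equal(dedup_count(grp, "unique")$umi_count, 2L)
  expect_equal(dedup_count(grp, "directional")$umi_count, 1L)
  expect_equal(dedup_count(grp[0, ], "unique")$umi_count, integer(0))
  set.seed(23)
  alphabet <- c("A", "C", "G", "T")
  for (rep in 1:60) {
    k <- sample(1:50, 1)
    umis <- vapply(seq_len(k), function(i)
      paste(sample(alphabet, 4, replace = TRUE), collapse = ""), "")
    umis <- sample(umis, k + sample(0:30, 1), replace = TRUE)
    g <- grp[rep(1, length(umis)), ]
    g$umi <- umis
    expect_equal(dedup_count(g, "unique")$umi_count,
                 dedup_unique_brute(umis))
    expect_equal(dedup_count(g, "directional")$umi_count,
                 dedup_directional_brute(umis))
  }
})

test_that("noise-free 2x activity ratio gives an exact interaction of log 2", {
  # deterministic counts across 6 replicates: DNA 100/100, RNA 100/200
  rows <- expand.grid(allele = c("ref", "alt"), source = c("DNA", "RNA"),
                      replicate = 1:6, stringsAsFactors = FALSE)
  rows$snp_id <- "s1"
  rows$cell_line <- "SH"
  rows$umi_count <- ifelse(rows$source == "RNA" & rows$allele == "alt",
                           200L, 100L)
  res <- test_snp_activity(rows)
  expect_true(res$detected)
  expect_lt(abs(res$beta12 - log(2)), 1e-4)
  # identical ratios in RNA and DNA: no effect
  rows$umi_count <- ifelse(rows$allele == "alt", 150L, 100L)
  res0 <- test_snp_activity(rows)
  expect_lt(abs(res0$beta12), 1e-6)
  expect_gt(res0$p_value, 0.9)
  # an undetected SNP is not tested
  rows$umi_count[rows$allele == "alt" & rows$source == "RNA"] <- 0L
  resna <- test_snp_activity(rows)
  expect_false(resna$detected)
  expect_true(is.na(resna$p_value))
})

test_that("consistent-hit calling counts both-significant and same-sign SNPs", {
  mk <- function(snp, line, b, q)
    data.frame(snp_id = snp, cell_line = line, beta12 = b,
               adj_log2_fc = b / log(2), std_error = 0.1, p_value = q / 2,
               q_value = q, detected = TRUE, fit_status = "converged",
               stringsAsFactors = FALSE)
  res <- rbind(
    mk("s1", "SH", 1.0, 0.01), mk("s1", "SK", 0.8, 0.01),    # hit, same
    mk("s2", "SH", -1.0, 0.01), mk("s2", "SK", 0.9, 0.01),   # hit, opposite
    mk("s3", "SH", 0.5, 0.01), mk("s3", "SK", 0.6, 0.01),    # hit, same
    mk("s4", "SH", 1.0, 0.01), mk("s4", "SK", 1.0, 0.3),     # one line only
    mk("s5", "SH", -0.7, 0.02), mk("s5", "SK", -0.2, 0.04),  # hit, same
    mk("s6", "SH", 0.9, 0.5), mk("s6", "SK", 0.9, 0.6))      # no hit
  hits <- call_consistent_hits(res, fdr = 0.05)
  expect_equal(hits$n_hits, 4L)
  expect_equal(hits$n_consistent, 3L)
  expect_false(hits$hits$consistent[hits$hits$snp_id == "s2"])
})

test_that("detection summary reports the both-allele both-line rate", {
  tmpl <- expand.grid(allele = c("ref", "alt"), cell_line = c("SH", "SK"),
                      replicate = 1L, source = c("DNA", "RNA"),
                      stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(sprintf("s%02d", 1:10), function(s) {
    d <- tmpl
    d$snp_id <- s
    d$umi_count <- 50L
    d$read_count <- 60L
    d
  }))
  # knock out one allele in one line for 3 SNPs
  ko <- counts$snp_id %in% c("s01", "s02", "s03") &
    counts$allele == "alt" & counts$cell_line == "SK"
  counts$umi_count[ko] <- 0L
  det <- detection_summary(counts)
  expect_equal(det$n_detected, 7L)
  expect_equal(det$rate_pct, 70.0)
  expect_equal(detection_summary(counts[counts$umi_count > 0 &
                                          counts$allele == "ref", ])$rate_pct,
               0.0)
})

test_that("synthetic reads round-trip exactly through the count pipeline", {
  lib <- small_library(4, flank_len = 12, seed = 31)
  bm <- make_barcode_map(cell_lines = c("SH", "SK"), n_replicates = 3,
                         seed = 32)
  pr <- generate_passport_reads(lib, bm, effects = c(snp0001 = log(2)),
                                mean_molecules = 40,
                                duplication_rate = 0.5, seed = 33)
  # duplication_rate 0.5 creates real duplicates
  expect_gt(sum(pr$truth$n_reads), sum(pr$truth$n_molecules))
  # truth conservation: molecule counts bounded by reads
  expect_true(all(pr$truth$n_umi_unique <= pr$truth$n_molecules))
  expect_true(all(pr$truth$n_molecules <= pr$truth$n_reads))
  pp <- passport_count_pipeline(pr$reads, bm, lib)
  # read conservation across the stages
  expect_equal(unname(pp$tally["assigned"] + pp$tally["unassigned_barcode"] +
                 pp$tally["too_short"] + pp$tally["ambiguous"] +
                 pp$tally["unmapped"]),
               unname(pp$tally["total"]))
  # recovered UMI counts equal the generator's truth exactly
  key <- function(d, cols = c("snp_id", "allele", "cell_line",
                              "replicate", "source"))
    do.call(paste, d[cols])
  tr <- pr$truth[pr$truth$n_molecules > 0, ]
  i <- match(key(pp$counts), key(tr))
  expect_false(anyNA(i))
  expect_equal(pp$counts$umi_count, tr$n_umi_unique[i])
  expect_equal(pp$counts$read_count, tr$n_reads[i])
  # with no duplication, read counts equal molecule counts
  pr0 <- generate_passport_reads(lib, bm, mean_molecules = 20,
                                 duplication_rate = 0, seed = 34)
  expect_equal(pr0$truth$n_reads, pr0$truth$n_molecules)
  # byte-identical regeneration under the same seed
  pr_again <- generate_passport_reads(lib, bm,
                                      effects = c(snp0001 = log(2)),
                                      mean_molecules = 40,
                                      duplication_rate = 0.5, seed = 33)
  expect_identical(pr$reads, pr_again$reads)
})

test_that("FASTQ writing and re-reading preserves the reads", {
  lib <- small_library(2, flank_len = 8, seed = 41)
  bm <- make_barcode_map(cell_lines = "SH", n_replicates = 1, seed = 42)
  pr <- generate_passport_reads(lib, bm, mean_molecules = 10,
                                duplication_rate = 0, seed = 43)
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(pr$reads, fq, pr$read_ids)
  back <- as.character(Biostrings::readDNAStringSet(fq, format = "fastq"))
  expect_equal(unname(back), pr$reads)
  # the pipeline accepts the FASTQ path directly
  pp <- passport_count_pipeline(fq, bm, lib)
  expect_equal(unname(pp$tally["total"]), length(pr$reads))
})
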