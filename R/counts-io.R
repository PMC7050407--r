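#' Read an ASEReadCounter-style allelic count table
#'
#' Expects a TSV with at least the columns `contig`, `position`,
#' `refAllele`, `altAllele`, `refCount`, `altCount`.  A `variantID` column
#' is used as the SNP identifier when present (else `contig:position`);
#' a `sample` column carries the sample identifier for multi-sample
#' tables, otherwise supply `sample_id` (ASEReadCounter emits one file
#' per sample).  Unknown extra columns are preserved.
#'
#' @param path TSV file.
#' @param sample_id Sample identifier to attach when the file has no
#'   `sample` column.
#' @return Data frame of validated records with columns contig, position,
#'   variantID, refAllele, altAllele, refCount, altCount, totalCount,
#'   sample (plus any extras).
#' @export
read_ase_counts <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("contig", "position", "refAllele", "altAllele",
            "refCount", "altCount")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) {
    x$variantID <- character(0)
    x$totalCount <- integer(0)
    x$sample <- character(0)
    return(x)
  }
  line <- seq_len(nrow(x)) + 1L  # 1-based file line, after the header
  bad <- which(!is.finite(x$position) | x$position < 1)
  if (length(bad)) stop("malformed position at line ", bad[1] + 1L)
  for (col in c("refCount", "altCount")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad))
      stop("invalid ", col, " at line ", line[bad[1]],
           " (must be a non-negative integer)")
    x[[col]] <- as.integer(v)
  }
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  bad <- which(!ok_allele(x$refAllele) | !ok_allele(x$altAllele) |
                 x$refAllele == x$altAllele)
  if (length(bad))
    stop("invalid alleles at line ", line[bad[1]],
         " (biallelic SNPs over A/C/G/T required)")
  if (is.null(x$variantID))
    x$variantID <- paste0(x$contig, ":", x$position)
  # multi-allelic sites (same position, different alt) are not supported
  key <- paste(x$contig, x$position)
  amb <- tapply(paste(x$refAllele, x$altAllele), key,
                function(z) length(unique(z)))
  if (any(amb > 1))
    stop("multi-allelic site at ", names(amb)[which(amb > 1)[1]])
  x$totalCount <- x$refCount + x$altCount
  if (is.null(x$sample)) {
    if (is.null(sample_id))
      stop("table has no 'sample' column; supply sample_id")
    x$sample <- sample_id
  }
  x
}

#' Read a genotype table (VCF or TSV)
#'
#' VCF input is parsed with `vcfR` and the GT field mapped to calls
#' (`0/0` -> hom_ref, `0/1`, `1/0` and phased equivalents -> het,
#' `1/1` -> hom_alt, missing -> missing; phase is ignored).  TSV input is
#' a wide table with a `snp_id` column and one column per subject holding
#' either those call strings or allele dosages 0/1/2.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return List with `sites` (data frame contig, position, snp_id, ref,
#'   alt when available) and `calls` (character matrix SNPs x subjects).
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v, element = "GT")
    fx <- vcfR::getFIX(v)
    fx <- if (is.null(nrow(fx))) t(fx) else fx
    sites <- data.frame(contig = fx[, "CHROM"],
                        position = as.integer(fx[, "POS"]),
                        snp_id = fx[, "ID"], ref = fx[, "REF"],
                        alt = fx[, "ALT"], stringsAsFactors = FALSE)
    calls <- matrix(.gt_to_call(gt), nrow = nrow(gt),
                    dimnames = list(sites$snp_id, colnames(gt)))
  } else {
    x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"snp_id" %in% names(x)) stop("TSV genotypes need a snp_id column")
    subj <- setdiff(names(x), c("snp_id", "contig", "position",
                                "ref", "alt"))
    calls <- as.matrix(x[, subj, drop = FALSE])
    calls <- matrix(.dosage_to_call(calls), nrow = nrow(x),
                    dimnames = list(x$snp_id, subj))
    sites <- x[, intersect(c("contig", "position", "snp_id", "ref", "alt"),
                           names(x)), drop = FALSE]
  }
  list(sites = sites, calls = calls)
}

.gt_to_call <- function(gt) {
  g <- gsub("\\|", "/", as.character(gt))
  out <- rep("missing", length(g))
  out[g %in% "0/0"] <- "hom_ref"
  out[g %in% c("0/1", "1/0")] <- "het"
  out[g %in% "1/1"] <- "hom_alt"
  out
}

.dosage_to_call <- function(x) {
  v <- as.character(x)
  out <- rep("missing", length(v))
  out[v %in% c("0", "hom_ref")] <- "hom_ref"
  out[v %in% c("1", "het")] <- "het"
  out[v %in% c("2", "hom_alt")] <- "hom_alt"
  out
}

#' Read sample metadata
#'
#' @param path TSV with columns sample_id, subject_id, group, region.
#' @return Validated data frame.
#' @export
read_sample_meta <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "group", "region")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("sample metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id in metadata")
  one_group <- tapply(x$group, x$subject_id,
                      function(g) length(unique(g)))
  if (any(one_group > 1)) stop("a subject maps to more than one group")
  x
}

#' Filter SNPs to the testable set for differential ASE
#'
#' Applies the two testability rules for one region's count table: a
#' subject contributes to a SNP only if it is genotyped heterozygous there
#' and its total read count at the SNP is strictly greater than
#' `min_reads`; a SNP is retained only if at least `min_het_per_group`
#' qualifying subjects remain in *both* groups.  Every excluded subject
#' row and SNP is accounted for in the audit table.
#'
#' @param counts Count records for one region ([read_ase_counts()] form).
#' @param genotypes Output of [read_genotypes()] (or a compatible list
#'   with a `calls` matrix).
#' @param samples Sample metadata ([read_sample_meta()] form).
#' @param min_het_per_group Minimum qualifying heterozygotes per group.
#' @param min_reads Per-sample total read threshold (strict `>`).
#' @param het_from_counts If `TRUE`, heterozygosity is inferred from the
#'   counts (both alleles with at least one read) instead of the genotype
#'   table; off by default and flagged in the result.
#' @return List with `datasets` (list of `snp_dataset`: `site`, `region`,
#'   `data` with one row per qualifying subject), `audit` (data frame of
#'   exclusions with reasons) and `het_from_counts` flag.
#' @export
filter_testable_snps <- function(counts, genotypes, samples,
                                 min_het_per_group = 5, min_reads = 10,
                                 het_from_counts = FALSE) {
  idx <- match(counts$sample, samples$sample_id)
  if (anyNA(idx))
    stop("samples missing from metadata: ",
         paste(unique(counts$sample[is.na(idx)]), collapse = ", "))
  counts$subject_id <- samples$subject_id[idx]
  counts$group <- samples$group[idx]
  region <- unique(samples$region[idx])
  if (length(region) != 1L)
    stop("counts table spans multiple regions; filter one region at a time")
  dup <- duplicated(counts[, c("variantID", "subject_id")])
  if (any(dup))
    stop("multiple samples per subject within a region are not supported")

  calls <- genotypes$calls
  known_subj <- counts$subject_id %in% colnames(calls)
  if (!all(known_subj))
    warning("subjects absent from genotypes treated as missing: ",
            paste(unique(counts$subject_id[!known_subj]), collapse = ", "))
  call <- rep("missing", nrow(counts))
  ok <- known_subj & counts$variantID %in% rownames(calls)
  call[ok] <- calls[cbind(counts$variantID[ok], counts$subject_id[ok])]
  if (het_from_counts)
    call <- ifelse(counts$refCount >= 1 & counts$altCount >= 1,
                   "het", "not_het_by_counts")

  total <- counts$refCount + counts$altCount
  reason <- rep(NA_character_, nrow(counts))
  reason[call == "missing"] <- "genotype_missing"
  reason[is.na(reason) & call != "het"] <- "not_heterozygous"
  reason[is.na(reason) & total <= min_reads] <- "low_reads"
  qual <- is.na(reason)

  audit <- data.frame(snp_id = counts$variantID[!qual],
                      subject_id = counts$subject_id[!qual],
                      reason = reason[!qual], stringsAsFactors = FALSE)

  keep <- counts[qual, , drop = FALSE]
  n_aud <- tapply(keep$group == "AUD", keep$variantID, sum)
  n_ctl <- tapply(keep$group != "AUD", keep$variantID, sum)
  snp_ok <- names(n_aud)[n_aud >= min_het_per_group &
                           n_ctl >= min_het_per_group]
  # rows of SNPs failing the per-group het minimum are audited per
  # subject, so every input record is conserved between datasets and audit
  lost <- keep[!keep$variantID %in% snp_ok, , drop = FALSE]
  if (nrow(lost))
    audit <- rbind(audit, data.frame(
      snp_id = lost$variantID, subject_id = lost$subject_id,
      reason = "insufficient_het_subjects", stringsAsFactors = FALSE))

  keep <- keep[keep$variantID %in% snp_ok, , drop = FALSE]
  keep <- keep[order(keep$contig, keep$position, keep$subject_id), ,
               drop = FALSE]
  datasets <- lapply(split(keep, factor(keep$variantID,
                                        levels = unique(keep$variantID))),
                     function(d) {
    structure(list(
      site = list(chrom = d$contig[1], pos = d$position[1],
                  snp_id = d$variantID[1], ref = d$refAllele[1],
                  alt = d$altAllele[1]),
      region = region,
      data = data.frame(subject_id = d$subject_id, group = d$group,
                        ref_count = d$refCount, alt_count = d$altCount,
                        stringsAsFactors = FALSE)),
      class = "snp_dataset")
  })
  list(datasets = unname(datasets), audit = audit,
       het_from_counts = het_from_counts)
}

#' Rebuild a count table from filtered per-SNP datasets
#'
#' Inverse convenience of [filter_testable_snps()] (used e.g. to verify
#' filter idempotence).
#'
#' @param datasets List of `snp_dataset` objects.
#' @param samples Sample metadata to recover sample ids.
#' @return Count records in [read_ase_counts()] form.
#' @export
datasets_to_counts <- function(datasets, samples) {
  do.call(rbind, lapply(datasets, function(ds) {
    m <- samples[samples$subject_id %in% ds$data$subject_id &
                   samples$region == ds$region, ]
    data.frame(contig = ds$site$chrom, position = ds$site$pos,
               variantID = ds$site$snp_id, refAllele = ds$site$ref,
               altAllele = ds$site$alt,
               refCount = ds$data$ref_count, altCount = ds$data$alt_count,
               totalCount = ds$data$ref_count + ds$data$alt_count,
               sample = m$sample_id[match(ds$data$subject_id,
                                          m$subject_id)],
               stringsAsFactors = FALSE)
  }))
}

#' Write a filter audit table
#'
#' @param audit Audit data frame from [filter_testable_snps()].
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_filter_audit <- function(audit, path) {
  write.table(audit, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
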