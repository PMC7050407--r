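#' Design the two-allele oligo library for a SNP manifest
#'
#' Builds one reporter insert per allele per SNP: `flank_len` bases of
#' 5' flank, the allele base, `flank_len` bases of 3' flank.  The two
#' constructs of a SNP differ at exactly the central position.
#'
#' @param manifest Data frame with columns `snp_id`, `ref`, `alt`,
#'   `flank5`, `flank3` (flanking sequence, at least `flank_len` nt each).
#' @param flank_len Flank length per side (nt).
#' @param fasta Optional path; when given, the construct sequences are
#'   written as a FASTA reference (`<snp_id>_<allele>` headers).
#' @return Data frame of constructs: snp_id, allele (`ref`/`alt`),
#'   sequence.
#' @export
design_library <- function(manifest, flank_len = 30, fasta = NULL) {
  need <- c("snp_id", "ref", "alt", "flank5", "flank3")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("manifest missing columns: ", paste(miss, collapse = ", "))
  short <- nchar(manifest$flank5) < flank_len |
    nchar(manifest$flank3) < flank_len
  if (any(short))
    stop("insufficient flanking sequence for SNP ",
         manifest$snp_id[which(short)[1]])
  up <- substr(manifest$flank5, nchar(manifest$flank5) - flank_len + 1L,
               nchar(manifest$flank5))
  down <- substr(manifest$flank3, 1L, flank_len)
  lib <- data.frame(
    snp_id = rep(manifest$snp_id, each = 2L),
    allele = rep(c("ref", "alt"), nrow(manifest)),
    sequence = as.vector(rbind(paste0(up, manifest$ref, down),
                               paste0(up, manifest$alt, down))),
    stringsAsFactors = FALSE)
  if (anyDuplicated(lib$sequence)) {
    d <- lib$sequence[duplicated(lib$sequence)][1]
    stop("duplicate insert sequence (ambiguous assignment): shared by ",
         paste(lib$snp_id[lib$sequence == d], collapse = ", "))
  }
  if (!is.null(fasta)) {
    ss <- Biostrings::DNAStringSet(setNames(lib$sequence,
                                            paste(lib$snp_id, lib$allele,
                                                  sep = "_")))
    Biostrings::writeXStringSet(ss, fasta)
  }
  lib
}

#' Demultiplex reads by their barcode prefix
#'
#' Assigns each read to the unique barcode within `max_mismatch`
#' substitutions of its first `nchar(barcode)` bases.  Reads matching no
#' barcode, or equidistant from two barcodes, are unassigned.
#'
#' @param reads Character vector of read sequences.
#' @param barcode_map Data frame: barcode, cell_line, replicate, source.
#' @param max_mismatch Maximum substitutions allowed (default 0).
#' @return List: `assignment` (data frame read, barcode, cell_line,
#'   replicate, source, with NA rows for unassigned reads) and
#'   `n_unassigned`.
#' @export
demultiplex <- function(reads, barcode_map, max_mismatch = 0) {
  .check_barcode_map(barcode_map)
  bl <- nchar(barcode_map$barcode[1])
  too_short <- nchar(reads) < bl
  prefix <- substr(reads, 1L, bl)
  if (max_mismatch == 0) {
    hit <- match(prefix, barcode_map$barcode)
  } else {
    pm <- matrix(unlist(strsplit(prefix, "")), ncol = bl, byrow = TRUE)
    dist <- vapply(barcode_map$barcode, function(b) {
      bb <- strsplit(b, "")[[1]]
      rowSums(pm != matrix(bb, nrow(pm), bl, byrow = TRUE))
    }, numeric(length(reads)))
    dist <- matrix(dist, nrow = length(reads))
    best <- apply(dist, 1L, min)
    n_best <- rowSums(dist == best)
    hit <- apply(dist, 1L, which.min)
    hit[best > max_mismatch | n_best > 1L] <- NA_integer_
  }
  hit[too_short] <- NA_integer_
  assignment <- data.frame(
    read = seq_along(reads), barcode = barcode_map$barcode[hit],
    cell_line = barcode_map$cell_line[hit],
    replicate = barcode_map$replicate[hit],
    source = barcode_map$source[hit], stringsAsFactors = FALSE)
  list(assignment = assignment, n_unassigned = sum(is.na(hit)))
}

.check_barcode_map <- function(barcode_map) {
  stopifnot(all(c("barcode", "cell_line", "replicate", "source") %in%
                  names(barcode_map)))
  if (anyDuplicated(barcode_map$barcode))
    stop("duplicate barcodes across conditions")
  if (length(unique(nchar(barcode_map$barcode))) != 1L)
    stop("barcodes must all have the same length")
  if (!all(barcode_map$source %in% c("DNA", "RNA")))
    stop("source must be DNA or RNA")
  invisible(TRUE)
}

#' Extract UMIs from barcode-trimmed reads
#'
#' The first `umi_len` bases after the barcode are the UMI; the rest is
#' the insert.  Reads of length `umi_len` or shorter are discarded and
#' tallied.  UMIs containing N are kept but flagged.
#'
#' @param trimmed Character vector of reads with the barcode removed.
#' @param umi_len UMI length (nt, default 10).
#' @return List: `umi`, `insert` (NA for discarded reads), `flag_n`
#'   (logical, UMI contains N), `n_discarded`.
#' @export
extract_umi <- function(trimmed, umi_len = 10) {
  ok <- nchar(trimmed) > umi_len
  umi <- ifelse(ok, substr(trimmed, 1L, umi_len), NA_character_)
  insert <- ifelse(ok, substr(trimmed, umi_len + 1L, nchar(trimmed)),
                   NA_character_)
  list(umi = umi, insert = insert,
       flag_n = !is.na(umi) & grepl("N", umi, fixed = TRUE),
       n_discarded = sum(!ok))
}

#' Assign reads to library constructs by exact sequence content
#'
#' Matches each insert against the designed construct sequences by exact
#' substring containment (constructs are short designed inserts, so exact
#' matching takes the place of read alignment).  A read whose sequence is
#' consistent with more than one construct — e.g. it covers only flank
#' shared by both alleles — is `ambiguous`; a read matching nothing is
#' `unmapped`.
#'
#' @param inserts Character vector of insert sequences.
#' @param library Construct table from [design_library()].
#' @return Data frame: snp_id, allele, status
#'   (`assigned`/`ambiguous`/`unmapped`).
#' @export
assign_allele <- function(inserts, library) {
  uq <- unique(inserts[!is.na(inserts)])
  snp <- setNames(rep(NA_character_, length(uq)), uq)
  allele <- snp
  status <- setNames(rep("unmapped", length(uq)), uq)
  exact <- match(uq, library$sequence)
  done <- !is.na(exact)
  snp[done] <- library$snp_id[exact[done]]
  allele[done] <- library$allele[exact[done]]
  status[done] <- "assigned"
  for (s in uq[!done]) {
    hit <- which(vapply(library$sequence, grepl, NA, pattern = s,
                        fixed = TRUE))
    if (length(hit) == 1L) {
      snp[s] <- library$snp_id[hit]
      allele[s] <- library$allele[hit]
      status[s] <- "assigned"
    } else if (length(hit) > 1L) {
      status[s] <- "ambiguous"
    }
  }
  i <- match(inserts, uq)
  data.frame(snp_id = snp[i], allele = allele[i],
             status = ifelse(is.na(inserts), "unmapped", status[i]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Hamming distance between equal-length strings.
.hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Directional UMI collapse within one group: sort by count (ties broken
# lexicographically), then breadth-first absorb any UMI at Hamming
# distance 1 whose count satisfies count(parent) >= 2*count(child) - 1;
# the number of roots is the molecule count.
.dedup_directional <- function(umis) {
  tab <- table(umis)
  u <- names(tab)
  cnt <- as.integer(tab)
  o <- order(-cnt, u)
  u <- u[o]
  cnt <- cnt[o]
  k <- length(u)
  assigned <- logical(k)
  roots <- 0L
  for (i in seq_len(k)) {
    if (assigned[i]) next
    roots <- roots + 1L
    assigned[i] <- TRUE
    queue <- i
    while (length(queue)) {
      x <- queue[1L]
      queue <- queue[-1L]
      for (j in seq_len(k)) {
        if (assigned[j]) next
        if (cnt[x] >= 2L * cnt[j] - 1L && .hamming(u[x], u[j]) == 1L) {
          assigned[j] <- TRUE
          queue <- c(queue, j)
        }
      }
    }
  }
  roots
}

#' UMI-deduplicated molecule counts per construct and condition
#'
#' Collapses PCR duplicates within each (SNP, allele, cell line,
#' replicate, source) group.  `method = "unique"` counts distinct UMI
#' strings; `method = "directional"` additionally absorbs likely
#' sequencing-error UMIs by the count-adjacency rule (Hamming distance 1,
#' parent count at least `2 * child - 1`).
#'
#' @param assigned Data frame with columns snp_id, allele, cell_line,
#'   replicate, source, umi (one row per read).
#' @param method `"unique"` (default) or `"directional"`.
#' @return Data frame: snp_id, allele, cell_line, replicate, source,
#'   umi_count, read_count.
#' @export
dedup_count <- function(assigned, method = c("unique", "directional")) {
  method <- match.arg(method)
  need <- c("snp_id", "allele", "cell_line", "replicate", "source", "umi")
  stopifnot(all(need %in% names(assigned)))
  if (nrow(assigned) == 0L)
    return(data.frame(snp_id = character(0), allele = character(0),
                      cell_line = character(0), replicate = integer(0),
                      source = character(0), umi_count = integer(0),
                      read_count = integer(0)))
  key <- interaction(assigned$snp_id, assigned$allele, assigned$cell_line,
                     assigned$replicate, assigned$source, drop = TRUE)
  parts <- split(assigned, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    n_umi <- if (method == "unique") length(unique(d$umi))
             else .dedup_directional(d$umi)
    data.frame(snp_id = d$snp_id[1], allele = d$allele[1],
               cell_line = d$cell_line[1], replicate = d$replicate[1],
               source = d$source[1], umi_count = n_umi,
               read_count = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$snp_id, out$allele, out$cell_line, out$replicate,
            out$source), , drop = FALSE]
}

#' Run the full PASSPORT-seq counting pipeline on reads
#'
#' Demultiplex by barcode, trim, extract UMIs, assign alleles, and
#' UMI-deduplicate.  Reads are conserved: every input read ends up
#' assigned or in one of the loss tallies.
#'
#' @param reads Character vector of read sequences, or a FASTQ path.
#' @param barcode_map Data frame: barcode, cell_line, replicate, source.
#' @param library Construct table from [design_library()].
#' @param umi_len UMI length.
#' @param max_mismatch Barcode mismatch tolerance.
#' @param method UMI dedup method, see [dedup_count()].
#' @return List: `counts` (see [dedup_count()]), `tally` (named vector:
#'   total, assigned, unassigned_barcode, too_short, ambiguous, unmapped),
#'   `n_umi_with_n`.
#' @export
passport_count_pipeline <- function(reads, barcode_map, library,
                                    umi_len = 10, max_mismatch = 0,
                                    method = "unique") {
  if (length(reads) == 1L && file.exists(reads))
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  dm <- demultiplex(reads, barcode_map, max_mismatch)
  ok <- !is.na(dm$assignment$barcode)
  bl <- nchar(barcode_map$barcode[1])
  trimmed <- substr(reads[ok], bl + 1L, nchar(reads[ok]))
  um <- extract_umi(trimmed, umi_len)
  keep <- !is.na(um$umi)
  al <- assign_allele(um$insert[keep], library)
  asg <- cbind(dm$assignment[ok, ][keep, c("cell_line", "replicate",
                                           "source")],
               umi = um$umi[keep], al)
  assigned <- asg[asg$status == "assigned", , drop = FALSE]
  counts <- dedup_count(assigned, method)
  tally <- c(total = length(reads),
             assigned = nrow(assigned),
             unassigned_barcode = dm$n_unassigned,
             too_short = um$n_discarded,
             ambiguous = sum(asg$status == "ambiguous"),
             unmapped = sum(asg$status == "unmapped"))
  list(counts = counts, tally = tally,
       n_umi_with_n = sum(um$flag_n[keep]))
}

#' Test one SNP for differential allelic activity (RNA vs DNA)
#'
#' Fits a fixed-effects NB GLM to the UMI counts of one SNP in one cell
#' line — observations are (allele, source, replicate) — with a log
#' library-size offset per (replicate, source), fixed effects for allele,
#' source and their interaction, and Wald-tests the allele-by-source
#' interaction: a non-zero value means the alt/ref ratio differs between
#' expressed RNA and input plasmid DNA, i.e. the variant changes RNA
#' levels.
#'
#' @param counts UMI count rows for one (snp_id, cell_line): columns
#'   allele, source, replicate, umi_count.
#' @param lib_sizes Data frame replicate, source, lib_size giving total
#'   UMIs of each library (for the offset); NULL for no offset.
#' @param control Fitting control.
#' @return One-row data frame: beta12, adj_log2_fc, std_error, p_value,
#'   detected, fit_status.
#' @export
test_snp_activity <- function(counts, lib_sizes = NULL,
                              control = nb_fit_control()) {
  detected <- all(c("ref", "alt") %in% counts$allele[counts$source == "DNA" &
                                                       counts$umi_count > 0]) &&
    all(c("ref", "alt") %in% counts$allele[counts$source == "RNA" &
                                             counts$umi_count > 0])
  out <- data.frame(beta12 = NA_real_, adj_log2_fc = NA_real_,
                    std_error = NA_real_, p_value = NA_real_,
                    detected = detected, fit_status = "not_detected",
                    stringsAsFactors = FALSE)
  if (!detected) return(out)
  off <- NULL
  if (!is.null(lib_sizes)) {
    i <- match(paste(counts$replicate, counts$source),
               paste(lib_sizes$replicate, lib_sizes$source))
    if (anyNA(i)) stop("lib_sizes missing a (replicate, source) library")
    off <- log(lib_sizes$lib_size[i])
  }
  alt <- as.integer(counts$allele == "alt")
  rna <- as.integer(counts$source == "RNA")
  X <- cbind("(Intercept)" = 1, alt = alt, rna = rna,
             "alt:rna" = alt * rna)
  fit <- tryCatch(fit_nb_glm(counts$umi_count, X, offset = off,
                             control = control), error = function(e) NULL)
  if (is.null(fit)) {
    out$fit_status <- "failed"
    return(out)
  }
  out$fit_status <- fit$status
  if (fit$status %in% c("converged", "boundary")) {
    w <- wald_test(fit, "alt:rna")
    out$beta12 <- w$estimate
    out$adj_log2_fc <- w$estimate / log(2)
    out$std_error <- w$std_error
    out$p_value <- w$p_value
  }
  out
}

#' Run the allelic-activity test over all SNPs and cell lines
#'
#' Computes per-library total-UMI offsets, tests every detected SNP in
#' every cell line ([test_snp_activity()]) and applies Benjamini-Hochberg
#' within each cell line.
#'
#' @param counts Full UMI count table ([dedup_count()] form).
#' @param control Fitting control.
#' @return Data frame: snp_id, cell_line, beta12, adj_log2_fc, std_error,
#'   p_value, q_value, detected, fit_status.
#' @export
run_passport_tests <- function(counts, control = nb_fit_control()) {
  out <- do.call(rbind, lapply(split(counts, counts$cell_line), function(cc) {
    ls <- aggregate(umi_count ~ replicate + source, cc, sum)
    names(ls)[names(ls) == "umi_count"] <- "lib_size"
    res <- do.call(rbind, lapply(split(cc, cc$snp_id), function(d) {
      cbind(data.frame(snp_id = d$snp_id[1], cell_line = d$cell_line[1],
                       stringsAsFactors = FALSE),
            test_snp_activity(d, ls, control))
    }))
    res$q_value <- bh_fdr(res$p_value)
    res
  }))
  rownames(out) <- NULL
  out[order(out$cell_line, out$snp_id), , drop = FALSE]
}

#' SNPs with significant, direction-consistent activity in both cell lines
#'
#' @param results Output of [run_passport_tests()] covering >= 2 cell
#'   lines.
#' @param fdr FDR threshold within each cell line.
#' @return List: `hits` (SNPs with q < fdr in both lines; columns snp_id,
#'   beta12 per line, consistent flag), `n_hits`, `n_consistent`.
#' @export
call_consistent_hits <- function(results, fdr = 0.05) {
  lines <- unique(results$cell_line)
  if (length(lines) < 2L) stop("need results from at least 2 cell lines")
  sig <- results[!is.na(results$q_value) & results$q_value < fdr, ]
  by_snp <- split(sig, sig$snp_id)
  rows <- lapply(by_snp, function(d) {
    if (!all(lines %in% d$cell_line)) return(NULL)
    data.frame(snp_id = d$snp_id[1],
               consistent = length(unique(sign(d$beta12))) == 1L,
               stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows[!vapply(rows, is.null, NA)])
  if (is.null(hits))
    hits <- data.frame(snp_id = character(0), consistent = logical(0))
  rownames(hits) <- NULL
  list(hits = hits, n_hits = nrow(hits),
       n_consistent = sum(hits$consistent))
}

#' Detection summary for the reporter screen
#'
#' A SNP counts as detected when both of its alleles have non-zero UMI
#' counts in every cell line screened.
#'
#' @param counts UMI count table ([dedup_count()] form).
#' @param screened Total number of SNPs screened (defaults to the number
#'   of distinct snp_ids in `counts`).
#' @return List: `per_snp` (data frame snp_id, detected),
#'   `n_detected`, `n_screened`, `rate_pct` (one decimal).
#' @export
detection_summary <- function(counts, screened = NULL) {
  lines <- unique(counts$cell_line)
  pos <- counts[counts$umi_count > 0, ]
  det <- vapply(split(pos, pos$snp_id), function(d) {
    all(vapply(lines, function(cl) {
      all(c("ref", "alt") %in% d$allele[d$cell_line == cl])
    }, NA))
  }, NA)
  per_snp <- data.frame(snp_id = names(det), detected = unname(det),
                        stringsAsFactors = FALSE)
  n_screened <- if (is.null(screened)) length(unique(counts$snp_id))
                else screened
  n_detected <- sum(det)
  list(per_snp = per_snp, n_detected = n_detected,
       n_screened = n_screened,
       rate_pct = round(100 * n_detected / n_screened, 1))
}
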