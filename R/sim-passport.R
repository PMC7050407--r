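#' Synthetic SNP manifest with random flanking sequence
#'
#' Generates a manifest suitable for [design_library()]: random flanks and
#' a random ref/alt pair per SNP.  Useful for pipeline validation at the
#' scale of the real screen (437 SNPs).
#'
#' @param n_snps Number of SNPs.
#' @param flank_len Flank length provided on each side.
#' @param seed Seed.
#' @return Data frame: snp_id, ref, alt, flank5, flank3.
#' @export
simulate_snp_manifest <- function(n_snps, flank_len = 30, seed = 1L) {
  withr::with_seed(seed, {
    rand_seq <- function(n, len) {
      vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
              collapse = ""), "")
    }
    ref <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
    data.frame(snp_id = sprintf("snp%04d", seq_len(n_snps)),
               ref = ref, alt = unname(alt),
               flank5 = rand_seq(n_snps, flank_len),
               flank3 = rand_seq(n_snps, flank_len),
               stringsAsFactors = FALSE)
  })
}

#' Barcode layout for a reporter-assay sequencing design
#'
#' One unique barcode per (cell line, replicate, source) condition, with
#' pairwise Hamming distance of at least 3 so single mismatches cannot
#' cross conditions.
#'
#' @param cell_lines Cell-line labels (default the two neuroblastoma
#'   lines of the screen).
#' @param n_replicates Biological replicates per condition (default 6).
#' @param sources `c("DNA", "RNA")`.
#' @param barcode_len Barcode length (nt, default 8).
#' @param seed Seed.
#' @return Data frame: barcode, cell_line, replicate, source.
#' @export
make_barcode_map <- function(cell_lines = c("SH-SY5Y", "SK-N-BE2"),
                             n_replicates = 6, sources = c("DNA", "RNA"),
                             barcode_len = 8, seed = 1L) {
  conds <- expand.grid(cell_line = cell_lines,
                       replicate = seq_len(n_replicates),
                       source = sources, stringsAsFactors = FALSE)
  n <- nrow(conds)
  withr::with_seed(seed, {
    codes <- character(0)
    while (length(codes) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), barcode_len,
                           replace = TRUE), collapse = "")
      if (all(vapply(codes, function(b) .hamming(b, cand) >= 3L, NA)))
        codes <- c(codes, cand)
    }
    cbind(barcode = codes, conds, stringsAsFactors = FALSE)
  })
}

# Random UMI strings of fixed length.
.rand_umis <- function(n, umi_len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(c("A", "C", "G", "T"), n * umi_len, replace = TRUE),
              nrow = n)
  apply(m, 1L, paste, collapse = "")
}

#' Generate synthetic reporter-assay reads with UMIs and PCR duplicates
#'
#' Emulates the sequencing output of the pooled reporter assay: for every
#' (construct, condition) the number of true molecules is NB-distributed
#' around `mean_molecules`; in RNA libraries the alternative-allele
#' construct's mean is scaled by `exp(effect)` (the planted allelic
#' activity difference), while plasmid DNA is effect-free.  Each molecule
#' receives a random UMI and is re-sampled `Geometric(1 -
#' duplication_rate)` times (support >= 1), so `duplication_rate = 0`
#' means one read per molecule.  Reads are `barcode + UMI + insert`.
#'
#' @param library Construct table from [design_library()].
#' @param barcode_map Layout from [make_barcode_map()].
#' @param effects Named numeric vector of planted RNA activity effects
#'   per snp_id (natural-log scale); missing SNPs get 0.
#' @param mean_molecules Mean true molecules per construct per library.
#' @param theta NB dispersion of molecule counts across libraries.
#' @param duplication_rate PCR duplication probability in [0, 1).
#' @param umi_len UMI length (nt, default 10).
#' @param seed Seed; identical inputs and seed give byte-identical reads.
#' @return List: `reads` (character vector), `read_ids`, `truth` (data
#'   frame snp_id, allele, cell_line, replicate, source, n_molecules,
#'   n_umi_unique, n_reads).
#' @export
generate_passport_reads <- function(library, barcode_map, effects = NULL,
                                    mean_molecules = 300, theta = 10,
                                    duplication_rate = 0.5, umi_len = 10,
                                    seed = 1L) {
  stopifnot(nrow(library) >= 1, duplication_rate >= 0,
            duplication_rate < 1)
  .check_barcode_map(barcode_map)
  eff <- setNames(rep(0, length(unique(library$snp_id))),
                  unique(library$snp_id))
  if (!is.null(effects)) eff[names(effects)] <- effects
  withr::with_seed(seed, {
    truth <- list()
    reads <- list()
    for (k in seq_len(nrow(barcode_map))) {
      bc <- barcode_map$barcode[k]
      is_rna <- barcode_map$source[k] == "RNA"
      mu <- mean_molecules *
        exp(ifelse(is_rna & library$allele == "alt",
                   eff[library$snp_id], 0))
      n_mol <- .rnb(nrow(library), mu, theta)
      for (i in seq_len(nrow(library))) {
        if (n_mol[i] == 0L) {
          truth[[length(truth) + 1L]] <- data.frame(
            snp_id = library$snp_id[i], allele = library$allele[i],
            cell_line = barcode_map$cell_line[k],
            replicate = barcode_map$replicate[k],
            source = barcode_map$source[k], n_molecules = 0L,
            n_umi_unique = 0L, n_reads = 0L, stringsAsFactors = FALSE)
          next
        }
        umis <- .rand_umis(n_mol[i], umi_len)
        copies <- rgeom(n_mol[i], 1 - duplication_rate) + 1L
        reads[[length(reads) + 1L]] <-
          paste0(bc, rep(umis, copies), library$sequence[i])
        truth[[length(truth) + 1L]] <- data.frame(
          snp_id = library$snp_id[i], allele = library$allele[i],
          cell_line = barcode_map$cell_line[k],
          replicate = barcode_map$replicate[k],
          source = barcode_map$source[k], n_molecules = n_mol[i],
          n_umi_unique = length(unique(umis)),
          n_reads = sum(copies), stringsAsFactors = FALSE)
      }
    }
    reads <- unlist(reads) %||% character(0)
    list(reads = reads,
         read_ids = sprintf("read%07d", seq_along(reads)),
         truth = do.call(rbind, truth))
  })
}

#' Write reads as FASTQ (Phred+33, constant Q30)
#'
#' @param reads Character vector of sequences.
#' @param path Output FASTQ.
#' @param ids Read names (defaults to read0000001, ...).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("read%07d", seq_along(reads))
  ss <- Biostrings::DNAStringSet(setNames(reads, ids))
  qual <- Biostrings::BStringSet(vapply(nchar(reads), function(n)
    strrep("?", n), ""))
  Biostrings::writeXStringSet(ss, path, format = "fastq", qualities = qual)
  invisible(path)
}
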