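#' Test one SNP for differential allelic imbalance between groups
#'
#' Expands the per-subject (ref, alt) counts into the two-row-per-subject
#' allelic design ([ase_design()]), fits the random-intercept NB GLMM
#' ([fit_nb_glmm()]) and Wald-tests the allele-by-group interaction.  The
#' interaction is reported both on the natural-log scale (`beta12`) and as
#' the adjusted log2 fold change `adj_log2_fc = beta12 / log(2)`, the
#' group difference in log2 alt/ref odds.
#'
#' @param dataset A `snp_dataset` (see [filter_testable_snps()]).
#' @param control Fitting control, see [nb_fit_control()].
#' @return One-row data frame: snp_id, chrom, pos, region, beta12,
#'   adj_log2_fc, std_error, p_value, q_value (NA until
#'   [run_region()]), direction (`up` = higher alternative-allele
#'   fraction in AUD), n_het_aud, n_het_ctl, sigma_b, theta, fit_status.
#' @export
test_snp <- function(dataset, control = nb_fit_control()) {
  stopifnot(inherits(dataset, "snp_dataset"))
  d <- dataset$data
  des <- ase_design(d$ref_count, d$alt_count, d$group, d$subject_id)
  fit <- tryCatch(fit_nb_glmm(des$y, des$X, des$subject, control = control),
                  error = function(e) NULL)
  res <- data.frame(
    snp_id = dataset$site$snp_id, chrom = dataset$site$chrom,
    pos = dataset$site$pos, region = dataset$region,
    beta12 = NA_real_, adj_log2_fc = NA_real_, std_error = NA_real_,
    p_value = NA_real_, q_value = NA_real_, direction = NA_character_,
    n_het_aud = sum(d$group == "AUD"), n_het_ctl = sum(d$group != "AUD"),
    sigma_b = NA_real_, theta = NA_real_,
    fit_status = "failed", stringsAsFactors = FALSE)
  if (is.null(fit)) return(res)
  res$fit_status <- fit$status
  res$sigma_b <- fit$sigma_b
  res$theta <- fit$theta
  if (fit$status %in% c("converged", "boundary")) {
    w <- wald_test(fit, "allele:group")
    res$beta12 <- w$estimate
    res$adj_log2_fc <- w$estimate / log(2)
    res$std_error <- w$std_error
    res$p_value <- w$p_value
    res$direction <- if (w$estimate > 0) "up" else "down"
  }
  res
}

#' Run the differential-ASE test over one region
#'
#' Tests every dataset, adjusts p-values by Benjamini-Hochberg across the
#' region's converged SNPs, and returns the table sorted by position.
#'
#' @param datasets List of `snp_dataset` from one region.
#' @param control Fitting control.
#' @return Data frame of per-SNP results with q-values.
#' @export
run_region <- function(datasets, control = nb_fit_control()) {
  stopifnot(length(datasets) >= 1)
  regions <- unique(vapply(datasets, function(d) d$region, ""))
  if (length(regions) != 1L) stop("datasets must share one region")
  res <- do.call(rbind, lapply(datasets, test_snp, control = control))
  res$q_value <- bh_fdr(res$p_value)
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Classify significant differential-ASE SNPs
#'
#' Retains results with `q_value < fdr_cut` and an absolute effect above
#' `min_abs_effect`.  The effect-size filter is applied to the adjusted
#' log2 fold change by default (`scale = "log2"`); `scale = "ln"` applies
#' it to the raw natural-log interaction instead (the two readings of the
#' `|interaction| > 1` rule).
#'
#' @param results Result table from [run_region()].
#' @param fdr_cut FDR threshold (default 0.05).
#' @param min_abs_effect Minimum absolute effect size (default 1).
#' @param scale `"log2"` (default) or `"ln"`.
#' @return List: `significant` (subset of rows), `n_up`, `n_down`.
#' @export
classify_significant <- function(results, fdr_cut = 0.05,
                                 min_abs_effect = 1,
                                 scale = c("log2", "ln")) {
  scale <- match.arg(scale)
  eff <- if (scale == "log2") results$adj_log2_fc else results$beta12
  keep <- !is.na(results$q_value) & results$q_value < fdr_cut &
    !is.na(eff) & abs(eff) > min_abs_effect
  sig <- results[keep, , drop = FALSE]
  list(significant = sig,
       n_up = sum(sig$beta12 > 0), n_down = sum(sig$beta12 < 0))
}

#' Cross-region consistency of differential-ASE calls
#'
#' For every SNP passing the FDR cut in the primary region (FDR only, no
#' effect-size filter), collects each other region where the SNP was
#' tested with `p < p_secondary` and scores direction concordance by the
#' sign of the interaction.  SNPs absent from a secondary region are
#' skipped, not counted as discordant.
#'
#' @param results_by_region Named list of [run_region()] tables.
#' @param primary_region Name of the discovery region.
#' @param fdr_primary FDR threshold in the primary region.
#' @param p_secondary Nominal p threshold in the other regions.
#' @return List: `rows` (per-(SNP, other region) data frame with
#'   concordance flags), `n_overlap` (primary hits with at least one
#'   qualifying other region), `n_concordant` (those concordant in at
#'   least one qualifying region), `primary_region`.
#' @export
cross_region_consistency <- function(results_by_region, primary_region,
                                     fdr_primary = 0.05,
                                     p_secondary = 0.05) {
  stopifnot(length(results_by_region) >= 2,
            primary_region %in% names(results_by_region))
  prim <- results_by_region[[primary_region]]
  hits <- prim[!is.na(prim$q_value) & prim$q_value < fdr_primary, ,
               drop = FALSE]
  others <- results_by_region[setdiff(names(results_by_region),
                                      primary_region)]
  rows <- list()
  for (i in seq_len(nrow(hits))) {
    for (rg in names(others)) {
      o <- others[[rg]]
      j <- match(hits$snp_id[i], o$snp_id)
      if (is.na(j) || is.na(o$p_value[j]) || o$p_value[j] >= p_secondary)
        next
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = hits$snp_id[i], primary_q = hits$q_value[i],
        other_region = rg, other_p = o$p_value[j],
        beta12_primary = hits$beta12[i], beta12_other = o$beta12[j],
        concordant = sign(hits$beta12[i]) == sign(o$beta12[j]),
        stringsAsFactors = FALSE)
    }
  }
  rows <- if (length(rows)) do.call(rbind, rows) else
    data.frame(snp_id = character(0), primary_q = numeric(0),
               other_region = character(0), other_p = numeric(0),
               beta12_primary = numeric(0), beta12_other = numeric(0),
               concordant = logical(0))
  by_snp <- if (nrow(rows)) tapply(rows$concordant, rows$snp_id, any)
            else logical(0)
  list(rows = rows, n_overlap = length(by_snp),
       n_concordant = sum(by_snp), primary_region = primary_region)
}

#' Power of the differential-ASE test by simulation
#'
#' Simulates SNP datasets at a given design point (read depth, number of
#' heterozygotes per group, interaction effect) with
#' [simulate_snp_dataset()], runs [test_snp()] on each, and reports the
#' fraction rejected at `alpha`.  With `beta12_true = 0` this estimates
#' the type-I error.
#'
#' @param depth Expected total reads per heterozygous sample.
#' @param n_het_per_group Heterozygous subjects in each group.
#' @param beta12_true Planted interaction (natural-log scale).
#' @param theta NB dispersion.
#' @param sigma_b Random-intercept SD.
#' @param alpha Rejection level on the per-SNP p-value.
#' @param n_sims Number of simulated SNPs (>= 100).
#' @param seed Seed for the whole simulation.
#' @return One-row data frame: depth, n_het_per_group, beta12_true,
#'   alpha, n_sims, n_converged, power, mc_se
#'   (`sqrt(power * (1 - power) / n_sims)`).
#' @export
estimate_power <- function(depth, n_het_per_group, beta12_true,
                           theta = 10, sigma_b = 0.3, alpha = 0.05,
                           n_sims = 200, seed = 1L) {
  stopifnot(n_sims >= 100)
  p <- withr::with_seed(seed, replicate(n_sims, {
    ds <- structure(list(
      site = list(chrom = "chr1", pos = 1L, snp_id = "sim",
                  ref = "A", alt = "G"),
      region = "sim",
      data = simulate_snp_dataset(n_het_per_group, n_het_per_group,
                                  depth_mean = depth, theta = theta,
                                  sigma_b = sigma_b,
                                  beta12 = beta12_true)),
      class = "snp_dataset")
    test_snp(ds)$p_value
  }))
  pw <- mean(p < alpha, na.rm = TRUE)
  data.frame(depth = depth, n_het_per_group = n_het_per_group,
             beta12_true = beta12_true, alpha = alpha, n_sims = n_sims,
             n_converged = sum(!is.na(p)), power = pw,
             mc_se = sqrt(pw * (1 - pw) / n_sims))
}

#' Power grid over read depth and sample size
#'
#' @param depths Vector of read depths.
#' @param n_hets Vector of per-group heterozygote counts.
#' @param beta12_true Planted interaction (natural-log scale).
#' @param ... Passed to [estimate_power()].
#' @param seed Base seed; each grid cell uses a distinct derived seed.
#' @return Data frame with one row per (depth, n) cell.
#' @export
power_grid <- function(depths, n_hets, beta12_true, ..., seed = 1L) {
  grid <- expand.grid(depth = depths, n_het = n_hets)
  do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    estimate_power(grid$depth[i], grid$n_het[i], beta12_true, ...,
                   seed = seed + i)
  }))
}
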