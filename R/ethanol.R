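#' Generate synthetic ethanol dose-response allelic counts
#'
#' Emulates the in-vitro dose experiment: untreated and ethanol-treated
#' libraries (doses in mM), several biological replicates per condition,
#' NB allelic counts per SNP and library.  The log alt/ref ratio of a SNP
#' is `beta1 + slope * dose`; a fraction of SNPs carries a non-zero
#' planted slope.  Each library has a lognormal depth effect of SD
#' `sigma_rep` applied to both alleles (the replicate intercept of the
#' fitted model); `sigma_ratio` optionally adds allele-asymmetric
#' replicate noise on the ratio (default 0).
#'
#' @param n_snps Number of SNPs.
#' @param doses Ethanol doses in mM (default `c(0, 10, 20)`).
#' @param n_reps Biological replicates per dose (>= 2, default 4).
#' @param slope Planted dose slope, per mM on the natural-log ratio.
#' @param frac_responsive Fraction of SNPs with the planted slope.
#' @param depth_mean Expected total reads per SNP per library.
#' @param theta NB dispersion.
#' @param beta1 Baseline log alt/ref ratio.
#' @param sigma_rep SD of the per-library depth intercept (log scale).
#' @param sigma_ratio SD of per-(SNP, library) ratio noise (default 0).
#' @param timepoint Timepoint label attached to all records.
#' @param seed Seed.
#' @return List: `records` (data frame snp_id, dose_mM, replicate,
#'   timepoint, refCount, altCount) and `truth` (snp_id, is_responsive,
#'   slope_true).
#' @export
generate_ethanol_counts <- function(n_snps = 20, doses = c(0, 10, 20),
                                    n_reps = 4, slope = 0.05,
                                    frac_responsive = 0.25,
                                    depth_mean = 500, theta = 10,
                                    beta1 = 0, sigma_rep = 0.3,
                                    sigma_ratio = 0, timepoint = "42h",
                                    seed = 1L) {
  stopifnot(length(doses) >= 1, n_reps >= 2, depth_mean > 0, theta > 0)
  n_resp <- round(frac_responsive * n_snps)
  truth <- data.frame(snp_id = sprintf("snp%04d", seq_len(n_snps)),
                      is_responsive = seq_len(n_snps) <= n_resp,
                      slope_true = ifelse(seq_len(n_snps) <= n_resp,
                                          slope, 0),
                      stringsAsFactors = FALSE)
  libs <- expand.grid(dose_mM = doses, replicate = seq_len(n_reps))
  withr::with_seed(seed, {
    u_lib <- rnorm(nrow(libs), 0, sigma_rep)
    rows <- lapply(seq_len(n_snps), function(i) {
      r <- beta1 + truth$slope_true[i] * libs$dose_mM +
        (if (sigma_ratio > 0) rnorm(nrow(libs), 0, sigma_ratio) else 0)
      m <- depth_mean * exp(u_lib - sigma_rep^2 / 2)
      mu_ref <- m / (1 + exp(r))
      mu_alt <- m * exp(r) / (1 + exp(r))
      data.frame(snp_id = truth$snp_id[i], dose_mM = libs$dose_mM,
                 replicate = libs$replicate, timepoint = timepoint,
                 refCount = .rnb(nrow(libs), mu_ref, theta),
                 altCount = .rnb(nrow(libs), mu_alt, theta),
                 stringsAsFactors = FALSE)
    })
    list(records = do.call(rbind, rows), truth = truth)
  })
}

#' Filter SNPs testable for an ethanol dose response
#'
#' Retains SNPs whose mean total read count per library is strictly
#' greater than `min_avg_depth` and whose pooled minor-allele fraction is
#' at least `min_minor_frac` in the treated pool (dose > 0) or the
#' untreated pool.
#'
#' @param records Dose count table (see [generate_ethanol_counts()]).
#' @param min_avg_depth Average per-library depth threshold (strict `>`).
#' @param min_minor_frac Pooled minor-allele fraction threshold (`>=`).
#' @return List: `records` (rows of retained SNPs), `audit` (data frame
#'   snp_id, reason for dropped SNPs).
#' @export
filter_dose_snps <- function(records, min_avg_depth = 15,
                             min_minor_frac = 0.10) {
  parts <- split(records, records$snp_id)
  keep <- character(0)
  audit <- list()
  for (s in names(parts)) {
    d <- parts[[s]]
    avg_depth <- mean(d$refCount + d$altCount)
    pool_frac <- function(sub) {
      tot <- sum(sub$refCount + sub$altCount)
      if (tot == 0) return(0)
      min(sum(sub$refCount), sum(sub$altCount)) / tot
    }
    frac_ok <- pool_frac(d[d$dose_mM > 0, ]) >= min_minor_frac ||
      pool_frac(d[d$dose_mM == 0, ]) >= min_minor_frac
    if (avg_depth <= min_avg_depth) {
      audit[[s]] <- "low_average_depth"
    } else if (!frac_ok) {
      audit[[s]] <- "low_minor_allele_fraction"
    } else {
      keep <- c(keep, s)
    }
  }
  list(records = records[records$snp_id %in% keep, , drop = FALSE],
       audit = data.frame(snp_id = names(audit),
                          reason = unlist(audit) %||% character(0),
                          stringsAsFactors = FALSE, row.names = NULL))
}

#' Test one SNP for a dose-responsive allelic ratio
#'
#' Fits the random-intercept NB GLMM with two rows per library (ref and
#' alt counts), fixed effects allele, dose (continuous, mM) and the
#' allele-by-dose interaction, and a random intercept per library
#' (dose x replicate), then Wald-tests the interaction: its estimate is
#' the per-mM change in the log alt/ref ratio.
#'
#' @param records Dose count rows for one SNP.
#' @param control Fitting control.
#' @return One-row data frame: snp_id, dose_slope (per mM, natural-log
#'   scale), std_error, p_value, fit_status.
#' @export
test_dose_response <- function(records, control = nb_fit_control()) {
  stopifnot(length(unique(records$snp_id)) == 1L)
  if (length(unique(records$dose_mM)) < 2L)
    stop("need at least 2 doses to fit a dose response")
  lib <- paste(records$dose_mM, records$replicate, records$timepoint,
               sep = "_")
  n <- nrow(records)
  alt <- rep(c(0L, 1L), each = n)
  dose <- rep(records$dose_mM, 2L)
  X <- cbind("(Intercept)" = 1, alt = alt, dose = dose,
             "alt:dose" = alt * dose)
  y <- c(records$refCount, records$altCount)
  fit <- tryCatch(fit_nb_glmm(y, X, rep(lib, 2L), control = control),
                  error = function(e) NULL)
  out <- data.frame(snp_id = records$snp_id[1], dose_slope = NA_real_,
                    std_error = NA_real_, p_value = NA_real_,
                    fit_status = "failed", stringsAsFactors = FALSE)
  if (is.null(fit)) return(out)
  out$fit_status <- fit$status
  if (fit$status %in% c("converged", "boundary")) {
    w <- wald_test(fit, "alt:dose")
    out$dose_slope <- w$estimate
    out$std_error <- w$std_error
    out$p_value <- w$p_value
  }
  out
}

#' Run the ethanol dose-response analysis
#'
#' Applies [filter_dose_snps()] then [test_dose_response()] per retained
#' SNP.
#'
#' @param records Dose count table.
#' @param min_avg_depth,min_minor_frac Filter thresholds.
#' @param control Fitting control.
#' @return List: `results` (per-SNP data frame with `passed_filters`
#'   flag; p-values only for SNPs that passed), `audit`.
#' @export
run_ethanol <- function(records, min_avg_depth = 15,
                        min_minor_frac = 0.10,
                        control = nb_fit_control()) {
  fl <- filter_dose_snps(records, min_avg_depth, min_minor_frac)
  res <- if (nrow(fl$records))
    do.call(rbind, lapply(split(fl$records, fl$records$snp_id),
                          test_dose_response, control = control))
  else data.frame(snp_id = character(0), dose_slope = numeric(0),
                  std_error = numeric(0), p_value = numeric(0),
                  fit_status = character(0))
  res$passed_filters <- TRUE
  if (nrow(fl$audit))
    res <- rbind(res, data.frame(snp_id = fl$audit$snp_id,
                                 dose_slope = NA_real_,
                                 std_error = NA_real_, p_value = NA_real_,
                                 fit_status = "filtered",
                                 passed_filters = FALSE))
  rownames(res) <- NULL
  list(results = res[order(res$snp_id), , drop = FALSE], audit = fl$audit)
}

#' Compare effect directions across the three analyses
#'
#' Tabulates, per SNP, the sign of the brain differential-ASE
#' interaction, the reporter-assay activity interaction, and the ethanol
#' dose slope, and flags SNPs whose ethanol response opposes the brain
#' direction.
#'
#' @param brain Differential-ASE results (snp_id, beta12).
#' @param passport Reporter results (snp_id, beta12).
#' @param dose Ethanol results (snp_id, dose_slope).
#' @return Data frame: snp_id, sign_brain, sign_passport, sign_ethanol
#'   (each `+`, `-` or `n/a`), opposite_flag (NA when either sign is
#'   undefined).
#' @export
compare_directions <- function(brain, passport, dose) {
  ids <- unique(c(brain$snp_id, passport$snp_id, dose$snp_id))
  sgn <- function(x) if (is.na(x)) "n/a" else if (x > 0) "+" else "-"
  look <- function(df, col, id) {
    i <- match(id, df$snp_id)
    if (is.na(i)) NA_real_ else df[[col]][i]
  }
  out <- do.call(rbind, lapply(ids, function(id) {
    b <- look(brain, "beta12", id)
    p <- look(passport, "beta12", id)
    e <- look(dose, "dose_slope", id)
    data.frame(snp_id = id, sign_brain = sgn(b), sign_passport = sgn(p),
               sign_ethanol = sgn(e),
               opposite_flag = if (is.na(b) || is.na(e)) NA
                               else sign(b) != sign(e),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
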