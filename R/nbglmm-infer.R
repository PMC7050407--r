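#' Wald test for one fixed-effect coefficient
#'
#' Two-sided normal test of `H0: coefficient = 0` from the estimate and
#' its standard error (square root of the corresponding diagonal element
#' of the fixed-effect covariance).
#'
#' @param fit An `nb_glmm_fit` with status `converged` or `boundary`.
#' @param coefficient Name of the coefficient to test (e.g.
#'   `"allele:group"`).
#' @return A one-row data frame with `estimate`, `std_error`, `z`,
#'   `p_value`.
#' @export
wald_test <- function(fit, coefficient) {
  stopifnot(inherits(fit, "nb_glmm_fit"))
  if (!fit$status %in% c("converged", "boundary"))
    stop("cannot run a Wald test on a ", fit$status, " fit")
  if (!coefficient %in% names(fit$coefficients))
    stop("no coefficient named '", coefficient, "'")
  if (is.null(fit$vcov)) stop("fit has no covariance matrix")
  est <- unname(fit$coefficients[coefficient])
  se <- sqrt(fit$vcov[coefficient, coefficient])
  z <- est / se
  data.frame(estimate = est, std_error = se, z = z,
             p_value = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg adjusted p-values (q-values)
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} p_(j) * m / j` over the
#' ranked p-values, with the original order restored.  `NA` p-values
#' (e.g. non-converged fits) propagate as `NA` without entering `m`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

# Independent pure-R evaluation of one subject's marginal likelihood
# contribution by adaptive Gauss-Hermite quadrature.
.agh_subject <- function(y, eta, theta, sigma_b, nodes) {
  h <- function(b) sum(dnbinom(y, mu = exp(eta + b), size = theta,
                               log = TRUE)) + dnorm(b, 0, sigma_b, log = TRUE)
  opt <- optimize(function(b) -h(b), interval = c(-60, 60), tol = 1e-10)
  bhat <- opt$minimum
  eps <- 1e-4 * max(1, abs(bhat))
  h2 <- (h(bhat + eps) - 2 * h(bhat) + h(bhat - eps)) / eps^2
  if (!is.finite(h2) || h2 >= 0) h2 <- -1 / sigma_b^2
  s <- 1 / sqrt(-h2)
  b_k <- bhat + sqrt(2) * s * nodes$x
  lg <- log(nodes$w) + nodes$x^2 + vapply(b_k, h, 0) + log(sqrt(2) * s)
  m <- max(lg)
  m + log(sum(exp(lg - m)))
}

#' Adaptive Gauss-Hermite oracle for the GLMM marginal log-likelihood
#'
#' Evaluates the marginal log-likelihood of the random-intercept NB GLMM
#' at given parameters by adaptive Gauss-Hermite quadrature, centered and
#' scaled at each subject's conditional mode.  This is an independent
#' check on the Laplace approximation used by [fit_nb_glmm()]: it shares
#' no code with the fitting path (NB density via [stats::dnbinom()],
#' mode by golden-section search, nodes from [pracma::gaussHermite()]).
#'
#' @param beta Fixed-effect vector matching the columns of `X`.
#' @param theta NB dispersion.
#' @param sigma_b Random-intercept SD; `0` gives the exact fixed-effects
#'   log-likelihood.
#' @param y,X,subject,offset Data as in [fit_nb_glmm()].
#' @param n_nodes Number of quadrature nodes (>= 8).
#' @return The marginal log-likelihood (a scalar).
#' @export
loglik_oracle <- function(beta, theta, sigma_b, y, X, subject,
                          offset = NULL, n_nodes = 32) {
  stopifnot(n_nodes >= 8, theta > 0, sigma_b >= 0)
  X <- as.matrix(X)
  if (is.null(offset)) offset <- numeric(length(y))
  eta <- drop(X %*% beta) + offset
  if (sigma_b == 0)
    return(sum(dnbinom(y, mu = exp(eta), size = theta, log = TRUE)))
  nodes <- pracma::gaussHermite(n_nodes)
  sum(vapply(split(seq_along(y), subject), function(idx) {
    .agh_subject(y[idx], eta[idx], theta, sigma_b, nodes)
  }, 0))
}

#' Build the per-SNP ASE design (two rows per heterozygous subject)
#'
#' Expands per-subject (ref, alt) counts into the long format of the
#' allelic GLMM: for each subject a reference-allele row (`allele = 0`)
#' and an alternative-allele row (`allele = 1`), with `group = 1` for the
#' case group (AUD) and an `allele:group` interaction column.  The
#' interaction coefficient is the group difference in log alt/ref odds.
#'
#' @param ref_count,alt_count Per-subject allele counts.
#' @param group Per-subject group labels; `case_level` codes 1.
#' @param subject Per-subject identifiers.
#' @param case_level Label coding `group = 1` (default `"AUD"`).
#' @return List with `y`, `X`, `subject` ready for [fit_nb_glmm()].
#' @export
ase_design <- function(ref_count, alt_count, group, subject,
                       case_level = "AUD") {
  n <- length(ref_count)
  stopifnot(length(alt_count) == n, length(group) == n,
            length(subject) == n)
  g <- as.integer(group == case_level)
  allele <- rep(c(0L, 1L), each = n)
  grp <- rep(g, 2L)
  X <- cbind("(Intercept)" = 1, allele = allele, group = grp,
             "allele:group" = allele * grp)
  list(y = c(ref_count, alt_count), X = X, subject = rep(subject, 2L))
}
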