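#' Control parameters for negative binomial (mixed) model fitting
#'
#' @param max_beta Cap on the absolute value of any fixed-effect
#'   coefficient (natural-log scale).  Estimates pinned at this cap signal
#'   separation (e.g. an all-zero design cell) and the fit is flagged
#'   `degenerate`.
#' @param theta_min,theta_max Box for the NB dispersion `theta`
#'   (variance `mu + mu^2/theta`).  `theta_max` is the effective Poisson
#'   limit.
#' @param sigma_min Boundary-detection threshold for the random-intercept
#'   SD: a fitted `sigma_b` below it is treated as the `sigma_b = 0`
#'   boundary and the model collapses to the fixed-effects NB GLM.  On the
#'   log scale the likelihood is flat as `sigma_b` approaches 0, so
#'   optimizers stop anywhere in the numerically-zero plateau (empirically
#'   below ~1e-4 when the true variance is zero); the default 1e-3
#'   separates that plateau from genuinely small variance components.
#' @param sigma_max Upper box for `sigma_b`.
#' @param rel_tol Relative convergence tolerance of the outer
#'   quasi-Newton optimizer.
#' @param max_iter Maximum outer iterations.
#' @return A list of class `nb_fit_control`.
#' @export
nb_fit_control <- function(max_beta = 30, theta_min = 1e-4, theta_max = 1e8,
                           sigma_min = 1e-3, sigma_max = 20,
                           rel_tol = 1e-12, max_iter = 200) {
  stopifnot(max_beta > 0, theta_min > 0, theta_max > theta_min,
            sigma_min > 0, sigma_max > sigma_min, rel_tol > 0, max_iter >= 1)
  structure(list(max_beta = max_beta, theta_min = theta_min,
                 theta_max = theta_max, sigma_min = sigma_min,
                 sigma_max = sigma_max, rel_tol = rel_tol,
                 max_iter = max_iter),
            class = "nb_fit_control")
}

# Validate and normalise the (y, X, subject, offset) bundle shared by the
# GLM and GLMM fitters.  Returns a list with subject recoded to 0-based
# integer indices for the compiled objective.
.check_nb_data <- function(y, X, subject = NULL, offset = NULL) {
  y <- as.numeric(y)
  if (length(y) == 0L) stop("no observations")
  if (any(!is.finite(y)) || any(y < 0) || any(y != floor(y)))
    stop("counts must be finite non-negative integers")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  if (is.null(offset)) offset <- numeric(length(y))
  if (length(offset) != length(y)) stop("offset length mismatch")
  # max-abs scaling of the design columns: indicator columns are left
  # untouched (scale 1), continuous covariates (e.g. dose in arbitrary
  # units) are brought to O(1), which conditions the optimizer and makes
  # the fit exactly invariant to covariate unit changes.  Coefficients
  # and covariance are transformed back on output.
  scales <- apply(abs(X), 2, max)
  scales[scales == 0] <- 1
  Xs <- sweep(X, 2, scales, "/")
  if (!is.null(subject)) {
    if (length(subject) != length(y)) stop("subject length mismatch")
    f <- factor(subject)
    idx <- as.integer(f) - 1L
    list(y = y, X = Xs, scales = scales, offset = as.numeric(offset),
         subj = idx, nsub = nlevels(f), subjects = levels(f))
  } else {
    list(y = y, X = Xs, scales = scales, offset = as.numeric(offset),
         subj = integer(length(y)), nsub = 1L, subjects = NULL)
  }
}

# Least-squares starting values for beta on log(y + 0.5) - offset.
.beta_start <- function(d, cap) {
  b <- tryCatch(qr.solve(d$X, log(d$y + 0.5) - d$offset),
                error = function(e) numeric(ncol(d$X)))
  pmin(pmax(b, -cap + 1), cap - 1)
}

# Fisher-scoring (IRLS) solve for beta at fixed theta; log link, NB2
# weights mu*theta/(theta+mu).  Coefficients are clamped at +/- cap so
# separated cells stall at the cap instead of diverging.
.nb_irls <- function(d, theta, beta, cap) {
  for (it in seq_len(200L)) {
    eta <- drop(d$X %*% beta) + d$offset
    eta <- pmin(pmax(eta, -cap - 5), cap + 5)
    mu <- exp(eta)
    w <- mu * theta / (theta + mu)
    z <- (eta - d$offset) + (d$y - mu) / mu
    A <- crossprod(d$X, w * d$X) + diag(1e-12, ncol(d$X))
    beta_new <- tryCatch(drop(solve(A, crossprod(d$X, w * z))),
                         error = function(e) beta)
    beta_new <- pmin(pmax(beta_new, -cap), cap)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-11) break
  }
  beta
}

# nlminb reports several distinct convergence messages; these indicate a
# genuine optimum.  "false/singular convergence" is accepted only after
# an explicit numeric gradient check in the caller.
.nlminb_ok <- function(opt) {
  opt$convergence == 0 ||
    grepl("relative convergence|X-convergence|absolute function",
          opt$message %||% "")
}


# Parameters away from their box bounds (the betas always count as free).
.free_params <- function(par, lower, upper, p) {
  free <- which(par > lower + 1e-6 & par < upper - 1e-6)
  sort(union(seq_len(p), free))
}

# Numeric Hessian of the objective over the free parameters.
.hess_free <- function(par, free, fn, gr) {
  wrap <- function(th) { full <- par; full[free] <- th; fn(full) }
  wrap_gr <- if (!is.null(gr))
    function(th) { full <- par; full[free] <- th; gr(full)[free] }
  tryCatch(stats::optimHess(par[free], wrap, wrap_gr),
           error = function(e) NULL)
}

# A few damped Newton steps from the optimizer's end point, reusing a
# fixed Hessian: quasi-Newton stops on a relative-objective rule, which
# can leave ~1e-4 slop in flat directions; polishing restores exact
# invariances (e.g. sign flips under label swaps) to ~1e-8.
.newton_polish <- function(par, free, H, fn, gr, lower, upper,
                           max_steps = 5L) {
  if (is.null(H)) return(par)
  f <- fn(par)
  Hr <- H + diag(1e-10, nrow(H))
  for (s in seq_len(max_steps)) {
    g <- gr(par)[free]
    if (max(abs(g)) < 1e-9 * max(1, abs(f))) break
    step <- tryCatch(drop(solve(Hr, g)), error = function(e) NULL)
    if (is.null(step)) break
    if (max(abs(step)) > 0.5) step <- step * 0.5 / max(abs(step))
    cand <- par
    cand[free] <- par[free] - step
    cand <- pmin(pmax(cand, lower), upper)
    fc <- fn(cand)
    if (fc <= f) {
      par <- cand
      f <- fc
    } else break
  }
  par
}

# Covariance of the fixed effects from the (already computed) Hessian over
# the free parameters: invert, extract the beta block.  NULL if the
# Hessian is not invertible or not positive on the betas.
.nb_vcov <- function(H, free, p) {
  if (is.null(H)) return(NULL)
  V <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(V)) return(NULL)
  keep <- match(seq_len(p), free)
  Vb <- V[keep, keep, drop = FALSE]
  Vb <- (Vb + t(Vb)) / 2
  if (any(!is.finite(Vb)) || any(diag(Vb) <= 0)) return(NULL)
  Vb
}

.finish_fit <- function(opt, d, control, random, lower, upper, fn,
                        gr = NULL, hess = NULL, free = NULL) {
  p <- ncol(d$X)
  beta_std <- unname(opt$par[seq_len(p)])
  beta <- beta_std / unname(d$scales)
  names(beta) <- colnames(d$X)
  theta <- unname(exp(opt$par[p + 1]))
  sigma_b <- if (random) unname(exp(opt$par[p + 2])) else 0
  status <- if (isTRUE(opt$converged)) "converged" else "failed"
  # separation is detected on the standardized scale, where the box
  # bound lives
  if (any(abs(beta_std) >= control$max_beta - 1e-2)) status <- "degenerate"
  vcov <- NULL
  if (status != "failed") {
    if (is.null(free)) free <- .free_params(opt$par, lower, upper, p)
    if (is.null(hess)) hess <- .hess_free(opt$par, free, fn, gr)
    vcov <- .nb_vcov(hess, free, p)
    if (is.null(vcov) && status == "converged") status <- "degenerate"
  }
  if (!is.null(vcov)) {
    vcov <- vcov / tcrossprod(d$scales)
    dimnames(vcov) <- list(names(beta), names(beta))
  }
  structure(list(coefficients = beta, theta = theta, sigma_b = sigma_b,
                 vcov = vcov, loglik = -opt$objective, status = status,
                 n_obs = length(d$y), n_subjects = d$nsub,
                 subjects = d$subjects, random = random,
                 iterations = opt$iterations, par = opt$par,
                 data = d, control = control),
            class = "nb_glmm_fit")
}

#' Fit a negative binomial GLM (fixed effects only) by maximum likelihood
#'
#' Joint maximum likelihood over the fixed effects and the NB dispersion
#' `theta` (NB2 parameterization, variance `mu + mu^2/theta`), log link.
#' This is the `sigma_b = 0` special case of [fit_nb_glmm()] and is used
#' for the reporter-assay RNA-vs-DNA tests, where replicates are
#' independent libraries.
#'
#' @param y Non-negative integer counts.
#' @param X Model matrix with named columns (include the intercept).
#' @param offset Optional per-observation offset on the natural-log scale
#'   (e.g. log library size).
#' @param control See [nb_fit_control()].
#' @return An object of class `nb_glmm_fit` with elements `coefficients`
#'   (natural-log scale), `theta`, `sigma_b` (0 here), `vcov`, `loglik`,
#'   `status` (`converged`, `boundary`, `degenerate` or `failed`),
#'   `n_obs`, `n_subjects`.
#' @examples
#' X <- cbind(1, c(0, 1, 0, 1), c(0, 0, 1, 1), c(0, 0, 0, 1))
#' colnames(X) <- c("(Intercept)", "allele", "group", "allele:group")
#' fit <- fit_nb_glm(c(100, 50, 100, 100), X)
#' coef(fit)[["allele:group"]]   # log((100/100)/(50/100)) = log 2
#' @export
fit_nb_glm <- function(y, X, offset = NULL, control = nb_fit_control()) {
  d <- .check_nb_data(y, X, NULL, offset)
  p <- ncol(d$X)
  fn <- function(par) nbglmm_nll_cpp(par, d$y, d$X, d$offset, d$subj,
                                     d$nsub, FALSE)
  cap <- control$max_beta
  beta0 <- .beta_start(d, cap)
  # Profile likelihood: beta solved exactly by IRLS at each theta, then a
  # 1-D bounded search over log(theta).  This keeps beta at its exact MLE
  # even when the profile in theta is flat (e.g. saturated designs, where
  # the dispersion is unidentified but the means are).
  prof <- function(lt) {
    b <- .nb_irls(d, exp(lt), beta0, cap)
    nbglmm_nll_cpp(c(b, lt), d$y, d$X, d$offset, d$subj, d$nsub, FALSE)
  }
  os <- optimize(prof, c(log(control$theta_min), log(control$theta_max)),
                 tol = 1e-9)
  # snap to the Poisson-limit cap if the profile is still decreasing there
  lt_cap <- log(control$theta_max)
  lt <- if (prof(lt_cap) <= os$objective + 1e-10) lt_cap else os$minimum
  beta <- .nb_irls(d, exp(lt), beta0, cap)
  opt <- list(par = c(beta, lt), objective = fn(c(beta, lt)),
              converged = TRUE, iterations = NA_integer_)
  lower <- c(rep(-cap, p), log(control$theta_min))
  upper <- c(rep(cap, p), log(control$theta_max))
  gr <- function(par) nbglmm_nll_grad_cpp(par, d$y, d$X, d$offset, d$subj,
                                          d$nsub, FALSE)
  .finish_fit(opt, d, control, random = FALSE, lower, upper, fn, gr)
}

#' Fit a negative binomial GLMM with a per-subject random intercept
#'
#' Laplace-approximate marginal maximum likelihood over the fixed effects,
#' `log theta` and `log sigma_b`.  For each evaluation of the marginal
#' likelihood, the mode of every subject's random intercept is found by an
#' inner Newton solve (the joint is strictly concave in the intercept) and
#' the integral is replaced by its Laplace approximation; the outer
#' problem is solved by bounded quasi-Newton.  If the variance component
#' converges to the zero boundary the model is refitted as a plain NB GLM
#' and flagged `status = "boundary"`.
#'
#' This is the model used for differential allele-specific expression:
#' two rows per heterozygous subject (reference and alternative counts),
#' the random intercept absorbing subject-level expression, and the
#' allele-by-group interaction measuring the group difference in allelic
#' imbalance.
#'
#' @inheritParams fit_nb_glm
#' @param subject Grouping factor for the random intercept (one level per
#'   subject/library); at least 2 levels.
#' @return See [fit_nb_glm()]; additionally `sigma_b` is the fitted
#'   random-intercept SD and `loglik` the Laplace marginal log-likelihood.
#' @seealso [loglik_oracle()] for an independent adaptive Gauss-Hermite
#'   evaluation of the same marginal likelihood.
#' @export
fit_nb_glmm <- function(y, X, subject, offset = NULL,
                        control = nb_fit_control()) {
  d <- .check_nb_data(y, X, subject, offset)
  if (d$nsub < 2L) stop("need at least 2 subjects for a random intercept")
  p <- ncol(d$X)
  fn <- function(par) nbglmm_nll_cpp(par, d$y, d$X, d$offset, d$subj,
                                     d$nsub, TRUE)
  gr <- function(par) nbglmm_nll_grad_cpp(par, d$y, d$X, d$offset, d$subj,
                                          d$nsub, TRUE)
  lower <- c(rep(-control$max_beta, p), log(control$theta_min), log(1e-8))
  upper <- c(rep(control$max_beta, p), log(control$theta_max),
             log(control$sigma_max))
  start <- c(.beta_start(d, control$max_beta), log(10), log(0.25))
  ctl <- list(iter.max = control$max_iter,
              eval.max = 10 * control$max_iter,
              rel.tol = control$rel_tol)
  opt <- nlminb(start, fn, gradient = gr, lower = lower, upper = upper,
                control = ctl)
  if (!.nlminb_ok(opt))   # one restart from the stalled point
    opt <- nlminb(opt$par, fn, gradient = gr, lower = lower, upper = upper,
                  control = ctl)
  if (!.nlminb_ok(opt)) {
    # still stalled: retry from fresh variance-component starts and keep
    # the best end point
    for (ls in log(c(0.5, 0.02))) {
      alt_start <- c(opt$par[seq_len(p + 1)], ls)
      cand <- nlminb(alt_start, fn, gradient = gr, lower = lower,
                     upper = upper, control = ctl)
      if (cand$objective <= opt$objective) opt <- cand
      if (.nlminb_ok(opt)) break
    }
  }
  # Newton polish with the Hessian (reused below for the covariance)
  free <- .free_params(opt$par, lower, upper, p)
  hess <- .hess_free(opt$par, free, fn, gr)
  par2 <- .newton_polish(opt$par, free, hess, fn, gr, lower, upper)
  if (max(abs(par2 - opt$par)) > 1e-5)   # moved: refresh the curvature
    hess <- .hess_free(par2, free, fn, gr)
  opt$par <- par2
  opt$objective <- fn(par2)
  opt$converged <- .nlminb_ok(opt) ||
    max(abs(gr(opt$par)[free])) < 1e-5 * max(1, abs(opt$objective))
  opt$iterations <- opt$iterations %||% NA_integer_
  sigma_hat <- exp(opt$par[p + 2])
  as_boundary <- function() {
    # refit on the original (unstandardized) design; fit_nb_glm applies
    # its own scaling
    fit <- fit_nb_glm(d$y, sweep(d$X, 2, d$scales, "*"), d$offset, control)
    fit$status <- if (fit$status == "converged") "boundary" else fit$status
    fit$sigma_b <- 0
    fit$n_subjects <- d$nsub
    fit$subjects <- d$subjects
    fit$random <- TRUE
    fit
  }
  # a numerically-zero variance component is a boundary case whether or
  # not the joint optimizer reported clean convergence on the plateau:
  # the profile GLM refit decides the final status
  if (sigma_hat < control$sigma_min) return(as_boundary())
  if (!opt$converged) {
    # typical stall: a joint ridge towards theta -> Inf, sigma_b -> 0
    # (deterministic or underdispersed counts).  If the sigma_b = 0
    # profile fit attains at least the stalled objective, the boundary
    # model is the maximum and is returned instead of a failure.
    glm_fit <- as_boundary()
    if (glm_fit$status == "boundary" &&
        glm_fit$loglik >= -opt$objective - 1e-6)
      return(glm_fit)
  }
  .finish_fit(opt, d, control, random = TRUE, lower, upper, fn, gr,
              hess = hess, free = free)
}

#' @export
print.nb_glmm_fit <- function(x, ...) {
  kind <- if (x$random) "NB GLMM (random intercept)" else "NB GLM"
  cat(kind, "fit —", x$status, "\n")
  cat("  observations:", x$n_obs, " subjects:", x$n_subjects, "\n")
  cat("  theta:", format(x$theta, digits = 4),
      " sigma_b:", format(x$sigma_b, digits = 4),
      " logLik:", format(x$loglik, digits = 8), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
coef.nb_glmm_fit <- function(object, ...) object$coefficients

#' @export
vcov.nb_glmm_fit <- function(object, ...) object$vcov

#' @export
logLik.nb_glmm_fit <- function(object, ...) object$loglik

#' Conditional modes of the random intercepts
#'
#' @param fit A converged [fit_nb_glmm()] fit.
#' @return Data frame of per-subject modes and curvatures of the joint
#'   log-density at the fitted parameters.
#' @export
ranef_modes <- function(fit) {
  stopifnot(inherits(fit, "nb_glmm_fit"), fit$random)
  d <- fit$data
  par <- fit$par
  if (length(par) == ncol(d$X) + 1L) par <- c(par, log(1e-8))
  r <- nbglmm_ranef_cpp(par, d$y, d$X, d$offset, d$subj, d$nsub)
  data.frame(subject = d$subjects, mode = r$mode, curvature = r$curvature)
}

#' Serialize fit diagnostics to JSON
#'
#' @param fit An `nb_glmm_fit`.
#' @return A JSON string with coefficients, vcov, dispersion, variance
#'   component, status, log-likelihood and sizes.
#' @export
fit_to_json <- function(fit) {
  stopifnot(inherits(fit, "nb_glmm_fit"))
  jsonlite::toJSON(list(
    coefficients = as.list(fit$coefficients),
    vcov = fit$vcov, theta = fit$theta, sigma_b = fit$sigma_b,
    loglik = fit$loglik, status = fit$status,
    n_obs = fit$n_obs, n_subjects = fit$n_subjects,
    iterations = fit$iterations), auto_unbox = TRUE, digits = NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
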