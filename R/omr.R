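#' Omnigenic MR: block composite-likelihood estimator
#'
#' The estimator uses every harmonized SNP as an instrument. Under the
#' structural model (standardized genotypes, unit-variance phenotypes,
#' disjoint cohorts), the block of exposure and outcome z-scores over an LD
#' block with correlation matrix `R` is zero-mean multivariate normal with
#' covariance
#' \deqn{\Sigma = \begin{pmatrix} a R^2 + R & c R^2 \\ c R^2 & b R^2 + R
#'   \end{pmatrix}}
#' where `a = n_x sigma2_beta / p`,
#' `b = n_y (alpha^2 sigma2_beta + sigma2_gamma) / p`, and
#' `c = sqrt(n_x n_y) alpha sigma2_beta / p`. The pleiotropy variance
#' `sigma2_gamma` enters only the outcome margin while the causal effect
#' `alpha` also drives the cross-covariance: that asymmetry is what
#' separates causation from correlated pleiotropy here. A weighted sum of
#' block log-densities (the composite log-likelihood) is maximized over
#' `(alpha, log sigma2_beta, log sigma2_gamma)`; standard errors come from a
#' delete-one-block jackknife, since composite likelihoods misstate
#' curvature-based variances.
#'
#' @name omr
NULL

#' Model parameters
#'
#' @param alpha scalar causal effect.
#' @param sigma2_beta exposure-genetic variance fraction (>= 0).
#' @param sigma2_gamma pleiotropy variance fraction (>= 0).
#' @return list of class `"omr_params"`.
#' @export
omr_params <- function(alpha = 0, sigma2_beta = 0.1, sigma2_gamma = 0.01) {
  stopifnot(is.finite(alpha), is.finite(sigma2_beta),
            is.finite(sigma2_gamma),
            sigma2_beta >= 0, sigma2_gamma >= 0)
  structure(list(alpha = alpha, sigma2_beta = sigma2_beta,
                 sigma2_gamma = sigma2_gamma), class = "omr_params")
}

# Variance-scale coefficients shared by every covariance formula.
.abc <- function(params, n_x, n_y, p_total) {
  list(
    a = n_x * params$sigma2_beta / p_total,
    b = n_y * (params$alpha^2 * params$sigma2_beta +
                 params$sigma2_gamma) / p_total,
    c = sqrt(n_x * n_y) * params$alpha * params$sigma2_beta / p_total
  )
}

#' Joint covariance of one block's stacked z-vector
#'
#' Returns the dense `2m x 2m` matrix `[[a R^2 + R, c R^2], [c R^2,
#' b R^2 + R]]` (see [omr]). Mostly used for oracle checks and small
#' instances; the fitting path never forms it.
#'
#' @param block one element of [build_blocks()]'s result (needs `R`).
#' @param params an [omr_params()].
#' @param n_x,n_y GWAS sample sizes.
#' @param p_total total number of SNPs entering the analysis.
#' @return numeric matrix of dimension `2m x 2m`.
#' @export
block_covariance <- function(block, params, n_x, n_y, p_total) {
  stopifnot(inherits(params, "omr_params"))
  R <- block$R
  R2 <- R %*% R
  k <- .abc(params, n_x, n_y, p_total)
  rbind(cbind(k$a * R2 + R, k$c * R2),
        cbind(k$c * R2, k$b * R2 + R))
}

# Rotate the pair's z-scores into each block's eigenbasis once; the
# likelihood kernel then works on these fixed quantities.
.prep_loglik <- function(pair, blocks) {
  d <- unlist(lapply(blocks, function(b) b$eig$values))
  wx <- unlist(lapply(blocks, function(b)
    as.numeric(crossprod(b$eig$vectors, pair$z_x[b$idx]))))
  wy <- unlist(lapply(blocks, function(b)
    as.numeric(crossprod(b$eig$vectors, pair$z_y[b$idx]))))
  blk <- rep(seq_along(blocks) - 1L,
             vapply(blocks, function(b) b$m, 1L))
  list(d = d, wx = wx, wy = wy, blk = as.integer(blk),
       nblocks = length(blocks),
       n_x = pair$n_x, n_y = pair$n_y, p_total = length(pair$z_x))
}

.block_logliks <- function(prep, params) {
  k <- .abc(params, prep$n_x, prep$n_y, prep$p_total)
  .cl_block_loglik(prep$d, prep$wx, prep$wy, prep$blk, prep$nblocks,
                   k$a, k$b, k$c)
}

.block_weights <- function(blocks, weights) {
  m <- vapply(blocks, function(b) b$m, 1L)
  switch(weights,
         equal = rep(1, length(blocks)),
         invsize = 1 / m,
         stop("unknown weighting scheme: ", weights, call. = FALSE))
}

#' Composite log-likelihood
#'
#' Weighted sum of block log marginal densities of the stacked
#' `(z_x, z_y)` vectors under the model covariance, evaluated through each
#' block's eigendecomposition (a factorization; no explicit inverse is ever
#' formed). Equal weights (the default) make the composite likelihood equal
#' the exact joint likelihood whenever the blocks are truly independent.
#'
#' @param pair a `harmonized_pair`.
#' @param blocks an `ld_blocks` list covering the pair.
#' @param params an [omr_params()].
#' @param weights `"equal"` (w_b = 1) or `"invsize"` (w_b = 1/m_b).
#' @return scalar composite log-likelihood.
#' @export
composite_loglik <- function(pair, blocks, params, weights = "equal") {
  prep <- .prep_loglik(pair, blocks)
  w <- .block_weights(blocks, weights)
  ll <- .block_logliks(prep, params)
  if (any(!is.finite(ll))) {
    stop("covariance factorization failed in block(s) ",
         paste(which(!is.finite(ll)), collapse = ", "), call. = FALSE)
  }
  sum(w * ll)
}

#' Method-of-moments initializer
#'
#' Ignoring LD (`R ~ I`), the marginal and cross moments of the z-scores
#' identify the parameters:
#' `E[z_x^2] = 1 + n_x sigma2_beta / p` and
#' `E[z_x z_y] = sqrt(n_x n_y) alpha sigma2_beta / p`. Solving gives quick,
#' consistent-under-independence starting values (and an LD-free
#' cross-check estimator for the MLE). With essentially no exposure signal
#' (`mean(z_x^2) <= 1.05`) the moment system is ill-posed and a neutral
#' fallback is returned with a warning.
#'
#' @param pair a `harmonized_pair`.
#' @return an [omr_params()].
#' @export
moment_init <- function(pair) {
  p <- length(pair$z_x)
  stopifnot(p > 0L)
  mzx2 <- mean(pair$z_x^2)
  if (mzx2 <= 1 + 0.05) {
    warning("weak exposure signal (mean z_x^2 <= 1.05); ",
            "falling back to neutral starting values", call. = FALSE)
    return(omr_params(0, 0.01, 0.01))
  }
  s2b <- p * (mzx2 - 1) / pair$n_x
  denom <- mzx2 - 1
  a0 <- if (denom > 0.05) {
    sqrt(pair$n_x / pair$n_y) * mean(pair$z_x * pair$z_y) / denom
  } else 0
  s2g <- p * (mean(pair$z_y^2) - 1) / pair$n_y - a0^2 * s2b
  omr_params(a0, max(s2b, 0), max(s2g, 0))
}

.VAR_FLOOR <- 1e-8

.theta_to_params <- function(theta) {
  omr_params(theta[1L], exp(theta[2L]), exp(theta[3L]))
}

.params_to_theta <- function(params) {
  c(params$alpha,
    log(max(params$sigma2_beta, 1e-4)),
    log(max(params$sigma2_gamma, 1e-4)))
}

# Maximize the weighted composite loglik, optionally excluding one block.
# The objective avoids all validation/allocation on the hot path: the
# jackknife calls this hundreds of times.
.optimize_cl <- function(prep, w, theta0, maxit = 500L, exclude = 0L,
                         restarts = 8L) {
  n_x <- prep$n_x
  n_y <- prep$n_y
  p <- prep$p_total
  sn <- sqrt(n_x * n_y)
  negll <- function(theta) {
    if (any(!is.finite(theta)) || abs(theta[1L]) > 50 ||
        any(theta[2:3] > 10)) return(1e12)
    s2b <- exp(theta[2L])
    s2g <- exp(theta[3L])
    ll <- .cl_block_loglik(prep$d, prep$wx, prep$wy, prep$blk, prep$nblocks,
                           n_x * s2b / p,
                           n_y * (theta[1L]^2 * s2b + s2g) / p,
                           sn * theta[1L] * s2b / p)
    v <- sum(w * ll)
    if (exclude >= 1L) v <- v - w[exclude] * ll[exclude]
    if (!is.finite(v)) 1e12 else -v
  }
  # restart Nelder-Mead from each solution until it stops moving: a single
  # run can stall on a collapsed simplex. Convergence is declared when a
  # restart moves neither the parameters (> 1e-6) nor the objective
  # (> 1e-8).
  fit <- stats::optim(theta0, negll, method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-12))
  converged <- FALSE
  for (r in seq_len(restarts)) {
    nxt <- stats::optim(fit$par, negll, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-12))
    converged <- max(abs(nxt$par - fit$par)) < 1e-6 &&
      abs(nxt$value - fit$value) < 1e-8
    fit <- nxt
    if (converged) break
  }
  list(theta = fit$par, value = -fit$value, converged = converged)
}

#' Fit the omnigenic MR model
#'
#' Maximizes the composite log-likelihood over
#' `(alpha, log sigma2_beta, log sigma2_gamma)` (log scale enforces
#' positivity of the variance components) starting from [moment_init()],
#' then runs a delete-one-block jackknife: each block is removed in turn,
#' the model re-maximized from the full-data optimum, and
#' \deqn{se(\hat\alpha) = \sqrt{\frac{B-1}{B}
#'   \sum_b (\hat\alpha_{(-b)} - \bar\alpha)^2}.}
#' The two-sided Wald p-value is computed in log space, so magnitudes far
#' below double underflow are representable through `log10_p`.
#'
#' @param pair a `harmonized_pair`.
#' @param blocks an `ld_blocks` list (>= 2 blocks for the jackknife).
#' @param weights block weighting scheme, `"equal"` or `"invsize"`.
#' @param init optional [omr_params()] overriding the moment initializer.
#' @param maxit Nelder-Mead iteration cap per optimization (default 500).
#' @return an object of class `"omr_fit"`: `alpha_hat`, `se_alpha`,
#'   `p_value`, `log10_p`, `sigma2_beta_hat`, `sigma2_gamma_hat`,
#'   `pve_pleiotropy` (identical to `sigma2_gamma_hat`: the fraction of
#'   outcome variance attributable to direct SNP effects), `loglik`,
#'   `n_snps`, `n_blocks`, `converged`, `boundary`, and the per-block
#'   jackknife estimates `jackknife`.
#' @export
fit_omr <- function(pair, blocks, weights = "equal", init = NULL,
                    maxit = 500L) {
  stopifnot(inherits(pair, "harmonized_pair"), inherits(blocks, "ld_blocks"))
  B <- length(blocks)
  if (B < 2L) stop("need >= 2 blocks for jackknife inference", call. = FALSE)
  prep <- .prep_loglik(pair, blocks)
  w <- .block_weights(blocks, weights)
  theta0 <- .params_to_theta(init %||% suppressWarnings(moment_init(pair)))
  full <- .optimize_cl(prep, w, theta0, maxit = maxit)
  if (!full$converged) {
    warning("composite-likelihood optimization did not converge within ",
            maxit, " iterations", call. = FALSE)
  }
  est <- .theta_to_params(full$theta)
  boundary <- est$sigma2_beta < .VAR_FLOOR || est$sigma2_gamma < .VAR_FLOOR
  if (boundary) {
    warning("variance component at its lower boundary", call. = FALSE)
  }
  # delete-one-block re-fits warm-started at the full optimum; a single
  # restart suffices there (the optimum moves by O(1/B))
  jack <- vapply(seq_len(B), function(b) {
    .optimize_cl(prep, w, full$theta, maxit = maxit, exclude = b,
                 restarts = 1L)$theta[1L]
  }, numeric(1L))
  se_alpha <- sqrt((B - 1) / B * sum((jack - mean(jack))^2))
  zstat <- est$alpha / se_alpha
  log_p <- log_p_from_z(zstat)
  structure(list(
    alpha_hat = est$alpha,
    se_alpha = se_alpha,
    p_value = max(exp(log_p), .Machine$double.xmin),
    log10_p = log_p / log(10),
    sigma2_beta_hat = est$sigma2_beta,
    sigma2_gamma_hat = est$sigma2_gamma,
    pve_pleiotropy = est$sigma2_gamma,
    loglik = full$value,
    n_snps = prep$p_total,
    n_blocks = B,
    converged = full$converged,
    boundary = boundary,
    weights = weights,
    jackknife = jack
  ), class = "omr_fit")
}

#' @export
print.omr_fit <- function(x, ...) {
  ci <- x$alpha_hat + c(-1, 1) * stats::qnorm(0.975) * x$se_alpha
  cat("Omnigenic MR fit (block composite likelihood)\n")
  cat(sprintf("  alpha = %.4g (se %.3g), 95%% CI [%.4g, %.4g]\n",
              x$alpha_hat, x$se_alpha, ci[1L], ci[2L]))
  cat(sprintf("  p = %.3g (log10 p = %.2f)\n", x$p_value, x$log10_p))
  cat(sprintf("  sigma2_beta = %.4g, sigma2_gamma (pleiotropy PVE) = %.4g\n",
              x$sigma2_beta_hat, x$sigma2_gamma_hat))
  cat(sprintf("  %d SNPs in %d blocks; converged: %s%s\n", x$n_snps,
              x$n_blocks, x$converged,
              if (x$boundary) " (variance at boundary)" else ""))
  invisible(x)
}

#' Flatten one or more fits into the results-table dialect
#'
#' @param fits a single `omr_fit` or a named list of them.
#' @param exposure,outcome labels for the table.
#' @return data.frame with columns `exposure`, `outcome`, `n_snps`,
#'   `n_blocks`, `alpha`, `se`, `ci_low`, `ci_high`, `p`, `log10_p`,
#'   `sigma2_beta`, `sigma2_gamma`, `pve_pleiotropy`, `converged`.
#' @export
omr_fit_table <- function(fits, exposure = "exposure", outcome = NULL) {
  if (inherits(fits, "omr_fit")) fits <- list(fits)
  if (length(fits) == 0L) {
    return(data.frame(
      exposure = character(0L), outcome = character(0L),
      n_snps = integer(0L), n_blocks = integer(0L),
      alpha = numeric(0L), se = numeric(0L),
      ci_low = numeric(0L), ci_high = numeric(0L),
      p = numeric(0L), log10_p = numeric(0L),
      sigma2_beta = numeric(0L), sigma2_gamma = numeric(0L),
      pve_pleiotropy = numeric(0L), converged = logical(0L),
      stringsAsFactors = FALSE
    ))
  }
  if (is.null(outcome)) {
    outcome <- names(fits) %||% paste0("outcome_", seq_along(fits))
  }
  q <- stats::qnorm(0.975)
  do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(
      exposure = exposure, outcome = outcome[i],
      n_snps = f$n_snps, n_blocks = f$n_blocks,
      alpha = f$alpha_hat, se = f$se_alpha,
      ci_low = f$alpha_hat - q * f$se_alpha,
      ci_high = f$alpha_hat + q * f$se_alpha,
      p = f$p_value, log10_p = f$log10_p,
      sigma2_beta = f$sigma2_beta_hat,
      sigma2_gamma = f$sigma2_gamma_hat,
      pve_pleiotropy = f$pve_pleiotropy,
      converged = f$converged,
      stringsAsFactors = FALSE
    )
  }))
}
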