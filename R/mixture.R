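#' Mixture-model grid-search replication estimator
#'
#' An independent, instrument-based check on the composite-likelihood
#' estimate. Genome-wide-significant, approximately independent instruments
#' are selected by greedy LD clumping; for each candidate causal effect
#' `theta` on a grid, the residuals `t_j = beta_y,j - theta * beta_x,j`
#' (known variance `s_j^2 = se_y,j^2 + theta^2 se_x,j^2`) are fitted with a
#' two-component normal mixture
#' `pi0 * N(0, s_j^2) + (1 - pi0) * N(0, s_j^2 + tau^2)`: the null
#' component holds instruments whose outcome effect is fully explained by
#' the causal path, the inflated component absorbs pleiotropic ones. The
#' causal estimate is the `theta` maximizing the null-component mass
#' `pi0` — the peak of the probability-mass profile.
#'
#' @name mixture_grid
NULL

#' Select approximately independent significant instruments
#'
#' Keeps SNPs passing the exposure p-value threshold, then clumps greedily
#' by ascending exposure p: a SNP is retained only if its panel r-squared
#' with every already-kept SNP in the same LD block stays below `r2_max`
#' (SNPs in different blocks are independent by construction).
#'
#' @param pair a `harmonized_pair`.
#' @param blocks an `ld_blocks` list covering the pair.
#' @param p_threshold exposure significance threshold (default 5e-8).
#' @param r2_max clumping r-squared ceiling (default 0.1).
#' @return list of class `"instrument_set"`: `index` (into the pair),
#'   `beta_x`, `se_x`, `beta_y`, `se_y`, `p_x`, and the selection settings.
#' @export
select_instruments <- function(pair, blocks, p_threshold = 5e-8,
                               r2_max = 0.1) {
  stopifnot(inherits(pair, "harmonized_pair"))
  log_px <- log_p_from_z(pair$z_x)
  cand <- which(log_px < log(p_threshold))
  if (length(cand) == 0L) {
    stop("no instrument passes the exposure p-value threshold ",
         format(p_threshold), call. = FALSE)
  }
  # map pair index -> (block number, position within block)
  blk_of <- integer(length(pair$z_x))
  pos_of <- integer(length(pair$z_x))
  for (k in seq_along(blocks)) {
    blk_of[blocks[[k]]$idx] <- k
    pos_of[blocks[[k]]$idx] <- seq_len(blocks[[k]]$m)
  }
  cand <- cand[order(log_px[cand])]
  kept <- integer(0L)
  for (j in cand) {
    ok <- TRUE
    same_blk <- kept[blk_of[kept] == blk_of[j]]
    if (length(same_blk) > 0L) {
      r <- blocks[[blk_of[j]]]$R[pos_of[j], pos_of[same_blk]]
      ok <- all(r^2 < r2_max)
    }
    if (ok) kept <- c(kept, j)
  }
  kept <- sort(kept)
  sx <- rep(1 / sqrt(pair$n_x), length(kept))
  sy <- rep(1 / sqrt(pair$n_y), length(kept))
  structure(list(
    index = kept,
    beta_x = pair$z_x[kept] * sx, se_x = sx,
    beta_y = pair$z_y[kept] * sy, se_y = sy,
    p_x = exp(log_px[kept]),
    settings = list(p_threshold = p_threshold, r2_max = r2_max)
  ), class = "instrument_set")
}

#' Construct an instrument set from raw effect estimates
#'
#' For use when instruments come from an external source rather than a
#' harmonized pair (the replication estimator only needs the four effect
#' columns).
#'
#' @param beta_x,se_x,beta_y,se_y aligned per-instrument effect estimates
#'   and standard errors.
#' @return an `instrument_set`.
#' @export
instrument_set <- function(beta_x, se_x, beta_y, se_y) {
  stopifnot(length(beta_x) == length(se_x),
            length(beta_x) == length(beta_y),
            length(beta_x) == length(se_y),
            all(se_x > 0), all(se_y > 0))
  structure(list(index = seq_along(beta_x),
                 beta_x = beta_x, se_x = se_x,
                 beta_y = beta_y, se_y = se_y,
                 p_x = p_from_z(beta_x / se_x),
                 settings = list()), class = "instrument_set")
}

.TAU2_FLOOR <- 1e-6

#' Fit the two-component residual mixture at a fixed theta
#'
#' EM with responsibilities for the null component; the M-step for `pi0` is
#' closed-form and the M-step for `tau2` maximizes the expected complete
#' log-likelihood by a one-dimensional search (exact, so every iteration
#' increases the observed likelihood). Initialization: `pi0 = 0.5`,
#' `tau2 = max(var(t) - mean(s^2), 1e-6)`.
#'
#' @param instr an `instrument_set`.
#' @param theta candidate causal effect.
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-8).
#' @param max_iter EM iteration cap (default 500).
#' @return list with `pi0`, `tau2`, `loglik`, `n_iter`.
#' @export
fit_mixture_at_theta <- function(instr, theta, tol = 1e-8, max_iter = 500L) {
  stopifnot(inherits(instr, "instrument_set"))
  t <- instr$beta_y - theta * instr$beta_x
  s2 <- instr$se_y^2 + theta^2 * instr$se_x^2
  n <- length(t)
  if (n < 2L) stop("need >= 2 instruments", call. = FALSE)
  pi0 <- 0.5
  tau2 <- max(stats::var(t) - mean(s2), .TAU2_FLOOR)
  if (all(t == t[1L])) {
    # degenerate: no spread at all; the null component absorbs everything
    warning("degenerate residuals (all equal); pi0 at boundary",
            call. = FALSE)
    ll <- sum(stats::dnorm(t, 0, sqrt(s2), log = TRUE))
    return(list(pi0 = 1, tau2 = .TAU2_FLOOR, loglik = ll, n_iter = 0L))
  }
  obs_ll <- function(pi0, tau2) {
    l0 <- stats::dnorm(t, 0, sqrt(s2), log = TRUE) + log(pi0)
    l1 <- stats::dnorm(t, 0, sqrt(s2 + tau2), log = TRUE) + log1p(-pi0)
    m <- pmax(l0, l1)
    sum(m + log(exp(l0 - m) + exp(l1 - m)))
  }
  ll <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    # E-step
    l0 <- stats::dnorm(t, 0, sqrt(s2), log = TRUE) + log(pi0)
    l1 <- stats::dnorm(t, 0, sqrt(s2 + tau2), log = TRUE) + log1p(-pi0)
    m <- pmax(l0, l1)
    r0 <- exp(l0 - m) / (exp(l0 - m) + exp(l1 - m))
    # M-step
    pi0 <- min(max(mean(r0), 1e-6), 1 - 1e-6)
    w1 <- 1 - r0
    if (sum(w1) > 1e-10) {
      q <- function(tau2) {
        -0.5 * sum(w1 * (log(s2 + tau2) + t^2 / (s2 + tau2)))
      }
      hi <- max(stats::var(t) * 4, mean(s2) * 4, 1)
      opt <- stats::optimize(q, c(.TAU2_FLOOR, hi), maximum = TRUE,
                             tol = 1e-10)
      tau2 <- opt$maximum
    }
    ll_new <- obs_ll(pi0, tau2)
    if (ll_new - ll < tol || it >= max_iter) {
      ll <- max(ll, ll_new)
      break
    }
    ll <- ll_new
  }
  list(pi0 = pi0, tau2 = tau2, loglik = ll, n_iter = it)
}

#' Grid search over candidate causal effects
#'
#' Runs [fit_mixture_at_theta()] at every grid point and selects the theta
#' maximizing the null-component mass, breaking exact ties toward the
#' smallest |theta| (the conservative choice). The full pi0/tau2/loglik
#' curves are retained.
#'
#' @param instr an `instrument_set`.
#' @param theta_grid ordered candidate values (default `seq(-1, 1, 0.005)`,
#'   wide enough to bracket any plausible standardized effect).
#' @return object of class `"mixture_grid_fit"`: `theta_grid`, `pi0_curve`,
#'   `tau2_curve`, `loglik_curve`, `theta_hat`, `pi0_hat`, `n_instruments`.
#' @export
grid_search_theta <- function(instr, theta_grid = seq(-1, 1, by = 0.005)) {
  stopifnot(inherits(instr, "instrument_set"), length(theta_grid) >= 1L)
  fits <- lapply(theta_grid, function(th) fit_mixture_at_theta(instr, th))
  pi0 <- vapply(fits, `[[`, numeric(1L), "pi0")
  best <- which(pi0 == max(pi0))
  if (length(best) > 1L) best <- best[which.min(abs(theta_grid[best]))]
  structure(list(
    theta_grid = theta_grid,
    pi0_curve = pi0,
    tau2_curve = vapply(fits, `[[`, numeric(1L), "tau2"),
    loglik_curve = vapply(fits, `[[`, numeric(1L), "loglik"),
    theta_hat = theta_grid[best],
    pi0_hat = pi0[best],
    n_instruments = length(instr$beta_x)
  ), class = "mixture_grid_fit")
}

#' @export
print.mixture_grid_fit <- function(x, ...) {
  cat("Mixture-model grid search\n")
  cat(sprintf("  theta_hat = %g (pi0 peak %.3f) over %d instruments\n",
              x$theta_hat, x$pi0_hat, x$n_instruments))
  cat(sprintf("  grid [%g, %g], %d points\n", min(x$theta_grid),
              max(x$theta_grid), length(x$theta_grid)))
  invisible(x)
}

#' Write a grid-search result as TSV
#'
#' Columns `theta`, `pi0`, `tau2`, `loglik`, plus a trailing summary row
#' flagged in the `is_peak` column.
#'
#' @param fit a `mixture_grid_fit`.
#' @param path output path.
#' @export
write_grid_fit <- function(fit, path) {
  df <- data.frame(theta = fit$theta_grid, pi0 = fit$pi0_curve,
                   tau2 = fit$tau2_curve, loglik = fit$loglik_curve,
                   is_peak = fit$theta_grid == fit$theta_hat)
  write_table(df, path)
}
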