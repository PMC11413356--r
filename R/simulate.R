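#' Simulation configuration for synthetic GWAS
#'
#' Defines the structural model under which panels and paired
#' exposure/outcome GWAS are generated: `p_snps` standardized SNP genotypes
#' in `n_blocks` LD blocks with AR(1) within-block correlation `rho`;
#' per-SNP effects on the exposure `beta_j ~ N(0, sigma2_beta / p_snps)` and
#' direct (horizontally pleiotropic) effects on the outcome
#' `gamma_j ~ N(0, sigma2_gamma / p_snps)`; a scalar causal effect `alpha`
#' carrying the exposure into the outcome; and two disjoint GWAS cohorts of
#' sizes `n_x` and `n_y`. Residual variances are set to `1 - sigma2_beta`
#' (exposure) and `1 - alpha^2 sigma2_beta - sigma2_gamma` (outcome) so both
#' phenotypes have unit variance, which is the scale the z-score algebra of
#' the estimator assumes.
#'
#' The defaults are the conditions used throughout this package's own
#' simulation studies: a polygenic exposure (`sigma2_beta = 0.3`) read in a
#' large cohort, a modest causal effect, and a small but non-zero
#' pleiotropy component.
#'
#' @param p_snps total SNP count.
#' @param n_blocks LD block count (`p_snps %% n_blocks` SNPs join the last
#'   block).
#' @param rho AR(1) within-block LD parameter in \[0, 1).
#' @param n_ref reference-panel sample count.
#' @param n_x,n_y exposure / outcome GWAS sample counts.
#' @param alpha scalar causal effect of exposure on outcome.
#' @param sigma2_beta fraction of exposure variance that is genetic.
#' @param sigma2_gamma fraction of outcome variance from direct SNP effects.
#' @param maf_range allele-frequency bounds, within (0, 0.5].
#' @param seed RNG seed.
#' @return a validated list of class `"sim_config"`.
#' @export
sim_config <- function(p_snps = 20000L, n_blocks = 400L, rho = 0.5,
                       n_ref = 503L, n_x = 50000L, n_y = 30000L,
                       alpha = 0.2, sigma2_beta = 0.3, sigma2_gamma = 0.05,
                       maf_range = c(0.05, 0.5), seed = 1L) {
  cfg <- list(p_snps = as.integer(p_snps), n_blocks = as.integer(n_blocks),
              rho = rho, n_ref = as.integer(n_ref), n_x = as.integer(n_x),
              n_y = as.integer(n_y), alpha = alpha,
              sigma2_beta = sigma2_beta, sigma2_gamma = sigma2_gamma,
              maf_range = maf_range, seed = as.integer(seed))
  if (!is.numeric(rho) || rho < 0 || rho >= 1) {
    stop("rho must lie in [0, 1)", call. = FALSE)
  }
  if (cfg$sigma2_beta < 0 || cfg$sigma2_gamma < 0) {
    stop("variance components must be non-negative", call. = FALSE)
  }
  if (cfg$alpha^2 * cfg$sigma2_beta + cfg$sigma2_gamma >= 1) {
    stop("outcome residual variance non-positive: require ",
         "alpha^2 * sigma2_beta + sigma2_gamma < 1", call. = FALSE)
  }
  if (cfg$sigma2_beta >= 1) {
    stop("exposure residual variance non-positive: require sigma2_beta < 1",
         call. = FALSE)
  }
  if (length(maf_range) != 2L || maf_range[1L] <= 0 ||
      maf_range[1L] > maf_range[2L] || maf_range[2L] > 0.5) {
    stop("maf_range must satisfy 0 < lower <= upper <= 0.5", call. = FALSE)
  }
  if (cfg$p_snps < cfg$n_blocks || cfg$n_blocks < 1L) {
    stop("need 1 <= n_blocks <= p_snps", call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# block boundaries implied by a config: equal windows, remainder to the last
.config_blocks <- function(cfg) {
  size <- cfg$p_snps %/% cfg$n_blocks
  start <- (seq_len(cfg$n_blocks) - 1L) * size + 1L
  end <- start + size - 1L
  end[cfg$n_blocks] <- cfg$p_snps
  data.frame(block_id = seq_len(cfg$n_blocks), chr = "1",
             start_index = start, end_index = end,
             stringsAsFactors = FALSE)
}

# Draw a haplotype/latent matrix (n x p) with AR(1) correlation rho within
# each block and independence across blocks, then threshold column j at
# qnorm(freq_j) so allele 1 has frequency freq_j.
.draw_alleles <- function(n, blocks, rho, freq) {
  p <- max(blocks$end_index)
  x <- matrix(stats::rnorm(n * p), n, p)
  if (rho > 0) {
    w <- sqrt(1 - rho^2)
    for (b in seq_len(nrow(blocks))) {
      if (blocks$end_index[b] > blocks$start_index[b]) {
        for (j in seq.int(blocks$start_index[b] + 1L, blocks$end_index[b])) {
          x[, j] <- rho * x[, j - 1L] + w * x[, j]
        }
      }
    }
  }
  thr <- stats::qnorm(freq)
  # allele indicator: latent below the frequency threshold
  x < matrix(thr, n, p, byrow = TRUE)
}

# Draw an n x p diploid dosage matrix under the config's generative process.
.draw_genotypes <- function(n, cfg, blocks, freq) {
  h1 <- .draw_alleles(n, blocks, cfg$rho, freq)
  h2 <- .draw_alleles(n, blocks, cfg$rho, freq)
  matrix(as.numeric(h1 + h2), n, cfg$p_snps)
}

#' Simulate a reference panel
#'
#' Draws `n_ref` diploid genotypes over `p_snps` SNPs. Within each block the
#' two haplotypes follow a latent AR(1) Gaussian threshold model with
#' parameter `rho`, so adjacent SNPs are in LD with tunable decay; blocks
#' are mutually independent. Allele frequencies are drawn uniformly within
#' `maf_range`. The SNP map records the drawn (generative) frequencies.
#'
#' @param config a [sim_config()].
#' @return a [ref_panel] with block boundaries attached.
#' @export
simulate_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  blocks <- .config_blocks(config)
  freq <- stats::runif(config$p_snps, config$maf_range[1L],
                       config$maf_range[2L])
  dos <- .draw_genotypes(config$n_ref, config, blocks, freq)
  alleles <- c("A", "C", "G", "T")
  a2 <- sample(alleles, config$p_snps, replace = TRUE)
  a1 <- vapply(a2, function(r) sample(setdiff(alleles, r), 1L), character(1L))
  map <- data.frame(
    snp_id = sprintf("snp_%06d", seq_len(config$p_snps)),
    chr = "1",
    pos = seq_len(config$p_snps) * 1000L,
    a1 = unname(a1), a2 = a2,
    freq = freq,
    stringsAsFactors = FALSE
  )
  new_ref_panel(dos, map, blocks)
}

#' Draw per-SNP effect vectors
#'
#' `beta` (effect on the exposure) and `gamma` (direct, horizontally
#' pleiotropic effect on the outcome) are drawn iid
#' `N(0, sigma2/p_snps)` and are independent of each other, so that the
#' total variance contributed genome-wide is `sigma2_beta` and
#' `sigma2_gamma` respectively on the standardized-genotype scale.
#'
#' @param config a [sim_config()].
#' @return list with numeric vectors `beta` and `gamma` of length `p_snps`.
#' @export
draw_effects <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  list(
    beta = stats::rnorm(config$p_snps, 0,
                        sqrt(config$sigma2_beta / config$p_snps)),
    gamma = stats::rnorm(config$p_snps, 0,
                         sqrt(config$sigma2_gamma / config$p_snps))
  )
}

# Standardize dosage columns to mean 0, variance 1 using 2f(1-f) from the
# supplied frequencies (the scale on which beta is defined).
.standardize_dosage <- function(dos, freq) {
  sweep(sweep(dos, 2L, 2 * freq, "-"), 2L, sqrt(2 * freq * (1 - freq)), "/")
}

# Per-SNP marginal OLS of centered phenotype y on each standardized SNP.
.marginal_gwas <- function(g_std, y) {
  n <- length(y)
  y <- y - mean(y)
  g_std <- sweep(g_std, 2L, colMeans(g_std), "-")
  ssg <- colSums(g_std^2)
  beta <- as.numeric(crossprod(g_std, y)) / ssg
  rss <- sum(y^2) - beta^2 * ssg
  se <- sqrt(pmax(rss, 0) / ((n - 2L) * ssg))
  list(beta = beta, se = se)
}

.sumstats_from_map <- function(map, beta, se, n, trait_label) {
  as_sumstats(data.frame(
    snp_id = map$snp_id, chr = map$chr, pos = map$pos,
    a1 = map$a1, a2 = map$a2, freq = map$freq,
    beta = beta, se = se, n = n,
    stringsAsFactors = FALSE
  ), trait_label = trait_label)
}

#' Simulate paired GWAS at the individual level
#'
#' The oracle sampler: draws two disjoint cohorts of genotypes by the same
#' generative process as the panel, builds phenotypes
#' `x = G_x beta + e_x` and `y = G_y (alpha * beta + gamma) + e_y` on
#' standardized genotypes with unit-variance phenotypes, centers them (so
#' intercepts never reach the summary statistics), and runs a per-SNP
#' marginal regression in each cohort. Intended for modest sizes (the
#' per-cohort genotype matrix is held in memory).
#'
#' @param config a [sim_config()].
#' @param panel the panel from [simulate_reference_panel()] (supplies the
#'   SNP map and frequencies).
#' @param effects vectors from [draw_effects()].
#' @return list with `sumstats` tables `exposure` and `outcome`.
#' @export
simulate_individual_gwas <- function(config, panel, effects) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "ref_panel"))
  var_ex <- 1 - config$sigma2_beta
  var_ey <- 1 - config$alpha^2 * config$sigma2_beta - config$sigma2_gamma
  if (var_ex <= 0 || var_ey <= 0) {
    stop("non-positive residual variance under this config", call. = FALSE)
  }
  set.seed(config$seed + 2L)
  blocks <- panel$blocks %||% .config_blocks(config)
  freq <- panel$map$freq
  bvec <- effects$beta
  gvec <- config$alpha * effects$beta + effects$gamma

  gx <- .standardize_dosage(.draw_genotypes(config$n_x, config, blocks, freq),
                            freq)
  x <- as.numeric(gx %*% bvec) +
    stats::rnorm(config$n_x, 0, sqrt(var_ex))
  fx <- .marginal_gwas(gx, x)
  rm(gx)

  gy <- .standardize_dosage(.draw_genotypes(config$n_y, config, blocks, freq),
                            freq)
  y <- as.numeric(gy %*% gvec) +
    stats::rnorm(config$n_y, 0, sqrt(var_ey))
  fy <- .marginal_gwas(gy, y)
  rm(gy)

  list(
    exposure = .sumstats_from_map(panel$map, fx$beta, fx$se, config$n_x,
                                  "sim_exposure"),
    outcome = .sumstats_from_map(panel$map, fy$beta, fy$se, config$n_y,
                                 "sim_outcome")
  )
}

#' Simulate paired GWAS at the summary level
#'
#' The fast sampler: works block by block directly on z-scores. With `R_b`
#' the block LD matrix (estimated from the panel's standardized dosages and
#' shrunk exactly as the estimator shrinks it),
#' \deqn{z_{x,b} = \sqrt{n_x} R_b \beta_b + e_x, \quad e_x \sim N(0, R_b)}
#' \deqn{z_{y,b} = \sqrt{n_y} R_b (\alpha \beta_b + \gamma_b) + e_y, \quad
#'       e_y \sim N(0, R_b)}
#' with `e_x` independent of `e_y` (disjoint cohorts, no sample overlap).
#' z-scores are converted to `beta = z/sqrt(n)`, `se = 1/sqrt(n)` on the
#' standardized scale.
#'
#' @inheritParams simulate_individual_gwas
#' @param ld optional list of per-block Cholesky-factored LD matrices from a
#'   previous call (component `ld` of the returned attribute), to avoid
#'   re-estimating LD in replicate loops.
#' @return list with `sumstats` tables `exposure` and `outcome`; the
#'   attribute `ld` carries the per-block factorizations for reuse.
#' @export
simulate_summary_gwas <- function(config, panel, effects, ld = NULL) {
  stopifnot(inherits(config, "sim_config"), inherits(panel, "ref_panel"))
  blocks <- panel$blocks %||% .config_blocks(config)
  if (is.null(ld)) {
    ld <- lapply(seq_len(nrow(blocks)), function(b) {
      idx <- seq.int(blocks$start_index[b], blocks$end_index[b])
      R <- .estimate_block_R(panel, idx, lambda_min = 0.05)$R
      ch <- tryCatch(chol(R), error = function(e) NULL)
      if (is.null(ch)) {
        stop("block ", b, " LD matrix not positive definite even after ",
             "shrinkage", call. = FALSE)
      }
      list(idx = idx, R = R, chol = ch)
    })
  }
  set.seed(config$seed + 3L)
  p <- config$p_snps
  zx <- numeric(p)
  zy <- numeric(p)
  for (blk in ld) {
    m <- length(blk$idx)
    mu_x <- sqrt(config$n_x) * as.numeric(blk$R %*% effects$beta[blk$idx])
    mu_y <- sqrt(config$n_y) *
      as.numeric(blk$R %*% (config$alpha * effects$beta[blk$idx] +
                              effects$gamma[blk$idx]))
    zx[blk$idx] <- mu_x + as.numeric(crossprod(blk$chol, stats::rnorm(m)))
    zy[blk$idx] <- mu_y + as.numeric(crossprod(blk$chol, stats::rnorm(m)))
  }
  out <- list(
    exposure = .sumstats_from_map(panel$map, zx / sqrt(config$n_x),
                                  rep(1 / sqrt(config$n_x), p), config$n_x,
                                  "sim_exposure"),
    outcome = .sumstats_from_map(panel$map, zy / sqrt(config$n_y),
                                 rep(1 / sqrt(config$n_y), p), config$n_y,
                                 "sim_outcome")
  )
  attr(out, "ld") <- ld
  out
}
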