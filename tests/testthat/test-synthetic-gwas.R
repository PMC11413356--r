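test_that("config invariants are enforced", {
  expect_error(sim_config(rho = 1), "rho")
  expect_error(sim_config(rho = -0.1), "rho")
  expect_error(sim_config(alpha = 1, sigma2_beta = 0.9, sigma2_gamma = 0.2),
               "residual variance")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_s3_class(sim_config(p_snps = 100, n_blocks = 7), "sim_config")
})

test_that("rho = 0 panels have near-independent SNPs, rho = 0.9 strong local LD", {
  cfg0 <- sim_config(p_snps = 60, n_blocks = 3, rho = 0, n_ref = 800,
                     seed = 5)
  pan0 <- simulate_reference_panel(cfg0)
  r <- cor(pan0$dosage)
  off <- abs(r[upper.tri(r)])
  expect_gt(mean(off < 4 / sqrt(cfg0$n_ref)), 0.95)

  cfg9 <- sim_config(p_snps = 60, n_blocks = 3, rho = 0.9, n_ref = 800,
                     seed = 5)
  pan9 <- simulate_reference_panel(cfg9)
  r9 <- cor(pan9$dosage)
  adjacent <- mean(abs(r9[cbind(1:19, 2:20)]))        # within block 1
  across <- mean(abs(r9[cbind(18:20, 21:23)]))        # straddling boundary
  expect_gt(adjacent, 0.5)
  expect_gt(adjacent, across + 0.3)
})

test_that("fixed seed reproduces panels and summary tables exactly", {
  cfg <- sim_config(p_snps = 100, n_blocks = 5, n_ref = 100, seed = 1)
  p1 <- simulate_reference_panel(cfg)
  p2 <- simulate_reference_panel(cfg)
  expect_identical(p1$dosage, p2$dosage)
  expect_identical(p1$map, p2$map)
  e1 <- draw_effects(cfg)
  expect_identical(e1, draw_effects(cfg))
  s1 <- simulate_summary_gwas(cfg, p1, e1)
  s2 <- simulate_summary_gwas(cfg, p2, e1)
  expect_identical(as.data.frame(s1$exposure), as.data.frame(s2$exposure))
  expect_identical(as.data.frame(s1$outcome), as.data.frame(s2$outcome))
})

test_that("effect vectors have the stated scale", {
  cfg0 <- sim_config(p_snps = 500, n_blocks = 10, sigma2_beta = 0,
                     seed = 2)
  expect_equal(draw_effects(cfg0)$beta, rep(0, 500))
  # chi-square concentration: mean(beta^2) ~ s2b/p with relative sd
  # sqrt(2/p) ~ 0.8% at p = 30000, so 5% is a > 6-sigma band
  cfgb <- sim_config(p_snps = 30000, n_blocks = 600, sigma2_beta = 0.3,
                     seed = 3)
  b <- draw_effects(cfgb)$beta
  expect_equal(mean(b^2), 0.3 / 30000, tolerance = 0.05)
})

test_that("individual-level null GWAS gives mean z^2 near 1", {
  cfg <- sim_config(p_snps = 400, n_blocks = 8, rho = 0.4, n_ref = 300,
                    n_x = 1500, n_y = 1200, alpha = 0, sigma2_beta = 0,
                    sigma2_gamma = 0, seed = 8)
  pan <- simulate_reference_panel(cfg)
  eff <- draw_effects(cfg)
  g <- simulate_individual_gwas(cfg, pan, eff)
  # null marginal chi-square has mean 1, sd sqrt(2/p_eff); LD reduces the
  # effective count, keep a wide band
  expect_equal(mean(g$exposure$z^2), 1, tolerance = 0.15)
  expect_equal(mean(g$outcome$z^2), 1, tolerance = 0.15)
})

test_that("individual-level polygenic GWAS matches the expected chi-square inflation", {
  # E[z_x^2] = 1 + n_x * s2b / p = 1.3 under independence
  cfg <- sim_config(p_snps = 2000, n_blocks = 40, rho = 0, n_ref = 400,
                    n_x = 2000, n_y = 1000, alpha = 0, sigma2_beta = 0.3,
                    sigma2_gamma = 0, seed = 9)
  pan <- simulate_reference_panel(cfg)
  eff <- draw_effects(cfg)
  g <- simulate_individual_gwas(cfg, pan, eff)
  expect_equal(mean(g$exposure$z^2), 1.3, tolerance = 0.05)
})

test_that("summary-level cross moment matches the moment identity", {
  # per-SNP E[z_x z_y] = sqrt(n_x n_y) alpha s2b diag(R^2) / p, which is
  # 0.1 under exact independence (R = I); the LD matrices estimated from a
  # finite panel carry sampling noise that inflates diag(R^2) slightly, so
  # the oracle uses the matrices the sampler actually used
  ld <- NULL
  reps <- vapply(1:5, function(r) {
    cfg <- sim_config(p_snps = 10000, n_blocks = 200, rho = 0,
                      n_ref = 600, n_x = 10000, n_y = 10000, alpha = 0.5,
                      sigma2_beta = 0.2, sigma2_gamma = 0, seed = 20 + r)
    pan <- simulate_reference_panel(cfg)
    eff <- draw_effects(cfg)
    s <- simulate_summary_gwas(cfg, pan, eff)
    if (r == 1L) ld <<- attr(s, "ld")
    mean(s$exposure$z * s$outcome$z)
  }, numeric(1L))
  r2d <- mean(unlist(lapply(ld, function(b) diag(b$R %*% b$R))))
  expect_equal(r2d, 1, tolerance = 0.15)  # near-identity panel LD
  expect_equal(mean(reps), 0.1 * r2d,
               tolerance = (3 * sd(reps) / sqrt(5) + 0.01) / 0.1)
})

test_that("null summary GWAS has uncorrelated exposure/outcome z-scores", {
  reps <- vapply(1:5, function(r) {
    cfg <- sim_config(p_snps = 4000, n_blocks = 80, rho = 0.5, n_ref = 400,
                      alpha = 0, sigma2_beta = 0.2, sigma2_gamma = 0,
                      n_x = 20000, n_y = 20000, seed = 30 + r)
    pan <- simulate_reference_panel(cfg)
    eff <- draw_effects(cfg)
    s <- simulate_summary_gwas(cfg, pan, eff)
    mean(s$exposure$z * s$outcome$z)
  }, numeric(1L))
  expect_lt(abs(mean(reps)), 3 * sd(reps) / sqrt(5) + 0.02)
})

test_that("individual- and summary-level samplers share one law (block z covariance)", {
  cfg <- sim_config(p_snps = 40, n_blocks = 2, rho = 0.5, n_ref = 2000,
                    n_x = 1500, n_y = 1200, alpha = 0.4, sigma2_beta = 0.3,
                    sigma2_gamma = 0.05, seed = 40)
  pan <- simulate_reference_panel(cfg)
  nrep <- 150L
  collect <- function(simulator) {
    zx <- matrix(0, nrep, 20L)  # block 1 only
    zy <- matrix(0, nrep, 20L)
    ld <- NULL
    for (r in seq_len(nrep)) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + 100L * r
      eff <- draw_effects(cfg_r)
      s <- simulator(cfg_r, eff, ld)
      ld <- attr(s, "ld") %||% NULL
      zx[r, ] <- s$exposure$z[1:20]
      zy[r, ] <- s$outcome$z[1:20]
    }
    stats::cov(cbind(zx, zy))
  }
  cov_ind <- collect(function(cfg_r, eff, ld)
    simulate_individual_gwas(cfg_r, pan, eff))
  cov_sum <- collect(function(cfg_r, eff, ld)
    simulate_summary_gwas(cfg_r, pan, eff, ld = ld))
  # entrywise agreement within Monte-Carlo error: covariance entries have
  # sampling sd of order max variance / sqrt(nrep); both matrices carry it
  scale_ <- max(diag(cov_ind))
  tol <- 8 * scale_ / sqrt(nrep)
  expect_lt(max(abs(cov_ind - cov_sum)), tol)
})

test_that("moment conservation: mean(z_x^2) - 1 tracks n_x s2b tr(R^2)/p per block", {
  cfg <- sim_config(p_snps = 100, n_blocks = 2, rho = 0.6, n_ref = 800,
                    n_x = 30000, n_y = 10000, alpha = 0, sigma2_beta = 0.25,
                    sigma2_gamma = 0, seed = 55)
  pan <- simulate_reference_panel(cfg)
  nrep <- 60L
  ld <- NULL
  vals <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    eff <- draw_effects(cfg_r)
    s <- simulate_summary_gwas(cfg_r, pan, eff, ld = ld)
    ld <- attr(s, "ld")
    vals[r] <- mean(s$exposure$z^2) - 1
  }
  R2diag <- unlist(lapply(ld, function(b) diag(b$R %*% b$R)))
  expected <- cfg$n_x * cfg$sigma2_beta * mean(R2diag) / cfg$p_snps
  expect_equal(mean(vals), expected,
               tolerance = 3 * sd(vals) / sqrt(nrep) / expected)
})

test_that("cross-block z-scores are uncorrelated", {
  cfg <- sim_config(p_snps = 60, n_blocks = 3, rho = 0.8, n_ref = 500,
                    n_x = 5000, n_y = 5000, alpha = 0, sigma2_beta = 0,
                    sigma2_gamma = 0, seed = 66)
  pan <- simulate_reference_panel(cfg)
  nrep <- 200L
  ld <- NULL
  z1 <- numeric(nrep)
  z2 <- numeric(nrep)
  for (r in seq_len(nrep)) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r
    s <- simulate_summary_gwas(cfg_r, pan, draw_effects(cfg_r), ld = ld)
    ld <- attr(s, "ld")
    z1[r] <- s$exposure$z[20]   # last SNP of block 1
    z2[r] <- s$exposure$z[21]   # first SNP of block 2
  }
  expect_lt(abs(cor(z1, z2)), 4 / sqrt(nrep))
})
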