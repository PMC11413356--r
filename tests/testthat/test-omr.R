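test_that("block covariance has the stated closed forms and symmetries", {
  R <- matrix(c(1, 0.5, 0.5, 1), 2L)
  blk <- list(R = R, m = 2L)
  # null genetics: plain LD on both margins, no cross term
  S0 <- block_covariance(blk, omr_params(0.3, 0, 0), 1000, 2000, 100)
  expect_equal(S0, rbind(cbind(R, 0 * R), cbind(0 * R, R)))
  # scalar reduction
  blk1 <- list(R = matrix(1, 1L, 1L), m = 1L)
  S1 <- block_covariance(blk1, omr_params(0.4, 0.3, 0.05),
                         n_x = 1000, n_y = 4000, p_total = 100)
  expect_equal(S1[1, 1], 1 + 1000 * 0.3 / 100)
  expect_equal(S1[2, 2], 1 + 4000 * (0.4^2 * 0.3 + 0.05) / 100)
  expect_equal(S1[1, 2], sqrt(1000 * 4000) * 0.4 * 0.3 / 100)
  # alpha -> -alpha: margins fixed, cross-covariance negated
  Sp <- block_covariance(blk, omr_params(0.4, 0.3, 0.05), 1000, 4000, 100)
  Sm <- block_covariance(blk, omr_params(-0.4, 0.3, 0.05), 1000, 4000, 100)
  expect_equal(Sp[1:2, 1:2], Sm[1:2, 1:2])
  expect_equal(Sp[3:4, 3:4], Sm[3:4, 3:4])
  expect_equal(Sp[1:2, 3:4], -Sm[1:2, 3:4])
})

test_that("single-SNP composite loglik reduces to the standard bivariate normal", {
  pair <- make_pair(z_x = 1.3, z_y = -0.7, n_x = 1000, n_y = 1000)
  blocks <- structure(list(list(idx = 1L, panel_index = 1L,
                                R = matrix(1, 1, 1), lambda = 0.05, m = 1L,
                                eig = eigen(matrix(1, 1, 1),
                                            symmetric = TRUE))),
                      class = "ld_blocks")
  ll <- composite_loglik(pair, blocks, omr_params(0, 0, 0))
  expect_equal(ll, -log(2 * pi) - (1.3^2 + (-0.7)^2) / 2, tolerance = 1e-12)
})

test_that("at alpha = 0 the loglik separates into the two marginal logliks", {
  s <- make_sim(p_snps = 60, n_blocks = 3, n_ref = 300, n_x = 3000,
                n_y = 2000, seed = 21)
  params <- omr_params(0, 0.2, 0.04)
  ll_joint <- composite_loglik(s$pair, s$blocks, params)
  # marginal oracle: dense normal per block and per trait
  k <- list(a = s$pair$n_x * 0.2 / length(s$pair$z_x),
            b = s$pair$n_y * 0.04 / length(s$pair$z_x))
  ll_marg <- sum(vapply(s$blocks, function(b) {
    R2 <- b$R %*% b$R
    dense_mvn_loglik(s$pair$z_x[b$idx], k$a * R2 + b$R) +
      dense_mvn_loglik(s$pair$z_y[b$idx], k$b * R2 + b$R)
  }, numeric(1L)))
  expect_equal(ll_joint, ll_marg, tolerance = 1e-10)
})

test_that("composite loglik with one all-SNPs block matches the dense joint density", {
  for (seed in c(31, 32)) {
    s <- make_sim(p_snps = 50, n_blocks = 1, rho = 0.6, n_ref = 400,
                  n_x = 3000, n_y = 2500, seed = seed)
    params <- omr_params(0.3, 0.25, 0.03)
    ll <- composite_loglik(s$pair, s$blocks, params)
    S <- block_covariance(s$blocks[[1L]], params, s$pair$n_x, s$pair$n_y,
                          length(s$pair$z_x))
    oracle <- dense_mvn_loglik(c(s$pair$z_x, s$pair$z_y), S)
    expect_equal(ll, oracle, tolerance = 1e-8)
  }
})

test_that("independent blocks: composite equals one dense evaluation over all SNPs", {
  s <- make_sim(p_snps = 40, n_blocks = 2, rho = 0.5, n_ref = 400,
                n_x = 3000, n_y = 2500, seed = 33)
  params <- omr_params(0.2, 0.3, 0.05)
  ll <- composite_loglik(s$pair, s$blocks, params)
  p <- length(s$pair$z_x)
  m1 <- s$blocks[[1L]]$m
  # assemble the joint covariance of (z_x, z_y) over both blocks
  S <- matrix(0, 2L * p, 2L * p)
  off <- 0L
  for (b in s$blocks) {
    Sb <- block_covariance(b, params, s$pair$n_x, s$pair$n_y, p)
    m <- b$m
    ix <- off + seq_len(m)
    S[ix, ix] <- Sb[seq_len(m), seq_len(m)]
    S[p + ix, p + ix] <- Sb[m + seq_len(m), m + seq_len(m)]
    S[ix, p + ix] <- Sb[seq_len(m), m + seq_len(m)]
    S[p + ix, ix] <- Sb[m + seq_len(m), seq_len(m)]
    off <- off + m
  }
  oracle <- dense_mvn_loglik(c(s$pair$z_x, s$pair$z_y), S)
  expect_equal(ll, oracle, tolerance = 1e-8)
})

test_that("blocks partition the SNPs and shrinkage bounds the spectrum", {
  s <- make_sim(p_snps = 100, n_blocks = 2, rho = 0.7, n_ref = 120,
                n_x = 3000, n_y = 3000, seed = 34)
  expect_equal(length(s$blocks), 2L)
  expect_equal(vapply(s$blocks, function(b) b$m, 1L),
               vapply(s$blocks, function(b) length(b$idx), 1L))
  expect_equal(sort(unlist(lapply(s$blocks, function(b) b$idx))),
               seq_along(s$pair$z_x))
  for (b in s$blocks) {
    expect_equal(unname(diag(b$R)), rep(1, b$m))
    expect_gte(min(b$eig$values), b$lambda - 1e-12)
    expect_gte(b$lambda, 0.05)
  }
})

test_that("moment initializer recovers alpha on LD-free data and is sign-equivariant", {
  a0 <- vapply(1:6, function(r) {
    s <- make_sim(p_snps = 4000, n_blocks = 80, rho = 0, n_ref = 500,
                  n_x = 30000, n_y = 20000, alpha = 0.2, seed = 40 + r)
    moment_init(s$pair)$alpha
  }, numeric(1L))
  expect_lt(abs(mean(a0) - 0.2), 0.05)
  s <- make_sim(p_snps = 1000, n_blocks = 20, rho = 0, n_ref = 300,
                n_x = 30000, n_y = 20000, alpha = 0.2, seed = 50)
  init <- moment_init(s$pair)
  flipped <- s$pair
  flipped$z_y <- -flipped$z_y
  init_f <- moment_init(flipped)
  expect_equal(init_f$alpha, -init$alpha)
  expect_equal(init_f$sigma2_beta, init$sigma2_beta)
})

test_that("moment initializer falls back with a warning when exposure signal is absent", {
  pair <- make_pair(z_x = rep(0, 200), z_y = rnorm(200), n_x = 1e4,
                    n_y = 1e4)
  expect_warning(init <- moment_init(pair), "weak exposure")
  expect_equal(init$alpha, 0)
})

test_that("negating the outcome z-scores exactly negates the fitted alpha", {
  s <- make_sim(p_snps = 600, n_blocks = 12, rho = 0.5, n_ref = 300,
                n_x = 20000, n_y = 15000, alpha = 0.25, seed = 60)
  fit <- fit_omr(s$pair, s$blocks)
  flipped <- s$pair
  flipped$z_y <- -flipped$z_y
  fit_f <- fit_omr(flipped, s$blocks)
  # agreement is bounded by the optimizer's 1e-6 parameter tolerance (the
  # likelihood itself is exactly symmetric; the simplex search is not)
  expect_lt(abs(fit_f$alpha_hat + fit$alpha_hat), 2e-6)
  expect_lt(abs(fit_f$se_alpha - fit$se_alpha), 2e-6)
  expect_lt(abs(fit_f$sigma2_beta_hat - fit$sigma2_beta_hat), 2e-6)
  expect_lt(abs(fit_f$sigma2_gamma_hat - fit$sigma2_gamma_hat), 2e-6)
})

test_that("jackknife standard error shrinks as the SNP count grows", {
  se_at <- function(p_snps, seed) {
    s <- make_sim(p_snps = p_snps, n_blocks = p_snps / 50, rho = 0.5,
                  n_ref = 300, n_x = 30000, n_y = 20000, alpha = 0.2,
                  seed = seed)
    fit_omr(s$pair, s$blocks)$se_alpha
  }
  se_small <- vapply(1:4, function(r) se_at(800, 70 + r), numeric(1L))
  se_large <- vapply(1:4, function(r) se_at(6400, 80 + r), numeric(1L))
  expect_lt(median(se_large), median(se_small))
})

test_that("maximum-likelihood and method-of-moments agree on LD-free data", {
  s <- make_sim(p_snps = 6000, n_blocks = 120, rho = 0, n_ref = 500,
                n_x = 30000, n_y = 20000, alpha = 0.2, seed = 90)
  mom <- moment_init(s$pair)
  mle <- fit_omr(s$pair, s$blocks)
  expect_lt(abs(mle$alpha_hat - mom$alpha), 0.05)
})

test_that("pleiotropy variance is estimated near zero when absent", {
  g <- vapply(1:3, function(r) {
    s <- make_sim(p_snps = 2000, n_blocks = 40, rho = 0.5, n_ref = 300,
                  n_x = 30000, n_y = 20000, alpha = 0.2, sigma2_gamma = 0,
                  seed = 100 + r)
    # the true value sits on the parameter boundary, so the fit may
    # legitimately flag a boundary solution
    suppressWarnings(fit_omr(s$pair, s$blocks)$sigma2_gamma_hat)
  }, numeric(1L))
  expect_lt(max(abs(g)), 0.02)
})

test_that("fit_omr requires at least two blocks", {
  s <- make_sim(p_snps = 50, n_blocks = 1, n_ref = 300, n_x = 3000,
                n_y = 2000, seed = 110)
  expect_error(fit_omr(s$pair, s$blocks), "2 blocks")
})
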