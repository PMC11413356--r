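# Shared fixtures, built in code at test time.

# Independent oracle: dense zero-mean multivariate-normal log-density via
# Cholesky. Used to check the composite-likelihood kernel, so it must stay
# free of any package internals.
dense_mvn_loglik <- function(z, S) {
  ch <- chol(S)
  q <- backsolve(ch, z, transpose = TRUE)
  -length(z) / 2 * log(2 * pi) - sum(log(diag(ch))) - 0.5 * sum(q^2)
}

# A tiny deterministic panel with known dosages for IO / harmonization
# tests: n_samples x n_snps, all-distinct non-palindromic alleles unless
# overridden.
make_toy_panel <- function(n_samples = 6L, n_snps = 8L,
                           a1 = NULL, a2 = NULL, freq_target = NULL,
                           blocks = NULL) {
  set.seed(99L)
  freq_target <- freq_target %||% rep(0.3, n_snps)
  dos <- sapply(freq_target, function(f) {
    d <- stats::rbinom(n_samples, 2L, f)
    # keep frequencies strictly inside (0,1)
    if (sum(d) == 0L) d[1L] <- 1L
    if (sum(d) == 2L * n_samples) d[1L] <- 1L
    d
  })
  dos <- matrix(as.numeric(dos), n_samples, n_snps)
  a1 <- a1 %||% rep(c("A", "C"), length.out = n_snps)
  a2 <- a2 %||% rep(c("G", "T"), length.out = n_snps)
  map <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n_snps)),
    chr = "1", pos = seq_len(n_snps) * 100L,
    a1 = a1, a2 = a2,
    freq = colMeans(dos) / 2,
    stringsAsFactors = FALSE
  )
  omnimr:::new_ref_panel(dos, map, blocks)
}

# Sumstats rows matching a panel map, with chosen betas.
toy_sumstats <- function(panel, beta = NULL, n = 10000L, label = "toy",
                         a1 = NULL, a2 = NULL, freq = NULL) {
  p <- nrow(panel$map)
  beta <- beta %||% seq(0.01, by = 0.01, length.out = p)
  as_sumstats(data.frame(
    snp_id = panel$map$snp_id, chr = panel$map$chr, pos = panel$map$pos,
    a1 = a1 %||% panel$map$a1, a2 = a2 %||% panel$map$a2,
    freq = freq %||% panel$map$freq,
    beta = beta, se = rep(1 / sqrt(n), p), n = n,
    stringsAsFactors = FALSE
  ), trait_label = label)
}

# Full synthetic pipeline at a given config: panel, effects, summary GWAS,
# harmonized pair and blocks. qc floor lowered so small fixtures pass.
make_sim <- function(..., qc = qc_settings(min_snps = 10L)) {
  cfg <- sim_config(...)
  panel <- simulate_reference_panel(cfg)
  eff <- draw_effects(cfg)
  sim <- simulate_summary_gwas(cfg, panel, eff)
  pair <- merge_pair(sim$exposure, sim$outcome, panel, qc = qc)
  blocks <- build_blocks(pair, panel)
  list(cfg = cfg, panel = panel, eff = eff, sim = sim, pair = pair,
       blocks = blocks)
}

# Build a harmonized_pair directly from z-vectors (bypassing file I/O) for
# estimator-level tests that need exact control of the data.
make_pair <- function(z_x, z_y, n_x, n_y, block_id = NULL,
                      panel_index = NULL) {
  structure(list(
    snp_id = sprintf("s%05d", seq_along(z_x)),
    panel_index = panel_index %||% seq_along(z_x),
    z_x = z_x, z_y = z_y, n_x = n_x, n_y = n_y,
    block_id = block_id %||% rep(NA_integer_, length(z_x)),
    freq = rep(0.3, length(z_x)),
    qc_log = c(),
    qc_settings = qc_settings()
  ), class = "harmonized_pair")
}

# Instruments from the two-component residual model directly: beta_x
# strong and fixed, beta_y = theta_true * beta_x plus, for a (1 - pi0)
# fraction, a pleiotropic N(0, tau2) shift, plus sampling noise.
# se sets the identification width of the pi0 profile (~ se / sd(beta_x));
# 0.005 puts it at the scale of one default grid step, i.e. strong
# instruments from a well-powered GWAS.
make_mixture_instruments <- function(n, theta_true, pi0, tau2, se = 0.005,
                                     seed = 1L) {
  set.seed(seed)
  bx_true <- rnorm(n, 0, 0.15) + 0.3 * sign(rnorm(n))
  is_null <- runif(n) < pi0
  shift <- ifelse(is_null, 0, rnorm(n, 0, sqrt(tau2)))
  bx <- bx_true + rnorm(n, 0, se)
  by <- theta_true * bx_true + shift + rnorm(n, 0, se)
  instrument_set(bx, rep(se, n), by, rep(se, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
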