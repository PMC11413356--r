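#!/usr/bin/env Rscript
# Build the synthetic study: one reference panel, one exposure GWAS, five
# candidate mediator GWAS (two with a real causal link from the exposure)
# and two downstream outcome GWAS (one causally driven by mediator_1).
# Everything is written as plain text (TSV summary statistics, VCF panel)
# under results/data/ so the later steps run purely from files, the way a
# real two-sample MR analysis would.

suppressPackageStartupMessages(library(omnimr))

out_dir <- "results/data"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# Desk-scale study conditions: 2 000 SNPs in 40 LD blocks keeps every later
# stage (including delete-one-block jackknives) in seconds while preserving
# the genome-wide character of the method.
base <- sim_config(p_snps = 2000L, n_blocks = 40L, rho = 0.5, n_ref = 503L,
                   n_x = 50000L, n_y = 30000L, alpha = 0, seed = 101L)
panel <- simulate_reference_panel(base)
write_panel_vcf(panel, file.path(out_dir, "panel.vcf"),
                file.path(out_dir, "panel_blocks.tsv"))

# One polygenic effect vector beta defines the exposure's genetics; every
# mediator GWAS shares it (that is what carries the causal signal) but has
# its own pleiotropy draw.
eff_base <- draw_effects(base)

mediator_alpha <- c(mediator_1 = 0.30, mediator_2 = 0.00,
                    mediator_3 = -0.20, mediator_4 = 0.00,
                    mediator_5 = 0.00)
exposure <- NULL
med_gamma <- list()
for (i in seq_along(mediator_alpha)) {
  cfg <- base
  cfg$alpha <- mediator_alpha[[i]]
  cfg$seed <- base$seed + i
  eff <- list(beta = eff_base$beta, gamma = draw_effects(cfg)$gamma)
  med_gamma[[i]] <- eff$gamma
  sim <- simulate_summary_gwas(cfg, panel, eff)
  if (is.null(exposure)) {
    exposure <- sim$exposure  # one exposure GWAS shared by all tests
    write_sumstats(exposure, file.path(out_dir, "exposure.tsv"))
  }
  write_sumstats(sim$outcome,
                 file.path(out_dir, paste0(names(mediator_alpha)[i], ".tsv")))
}

# Outcomes in the second round are caused by mediator_1 (or by nothing):
# mediator_1's total genetic effect is 0.30 * beta + gamma_1, and the
# outcome inherits theta times that, plus its own pleiotropy.
b_med1 <- mediator_alpha[["mediator_1"]] * eff_base$beta + med_gamma[[1L]]
for (spec in list(list(label = "outcome_1", theta = 0.25, seed = 301L),
                  list(label = "outcome_2", theta = 0.00, seed = 302L))) {
  cfg <- base
  cfg$alpha <- spec$theta
  cfg$seed <- spec$seed
  eff <- list(beta = b_med1, gamma = draw_effects(cfg)$gamma)
  sim <- simulate_summary_gwas(cfg, panel, eff)
  write_sumstats(sim$outcome, file.path(out_dir, paste0(spec$label, ".tsv")))
}

cat("Synthetic study written to", out_dir, "\n")
cat("  panel: 503 samples x", base$p_snps, "SNPs in", base$n_blocks,
    "blocks\n")
cat("  mediators with true effects:",
    paste(names(mediator_alpha)[mediator_alpha != 0],
          mediator_alpha[mediator_alpha != 0], collapse = ", "), "\n")
cat("  outcome_1 caused by mediator_1 (theta = 0.25); outcome_2 null\n")
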