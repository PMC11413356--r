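#' Two-round screening cascade with layered Bonferroni correction
#'
#' The study design this package automates: one exposure is tested against
#' K candidate mediators (round 1); mediators surviving the Bonferroni
#' threshold `alpha_level / K` become exposures in round 2 against M
#' outcomes, corrected at `alpha_level / (M * k)` with `k` the number of
#' survivors. With K = 42 mediators the round-1 threshold is
#' 0.05/42 = 0.00119; with k = 7 survivors and M = 15 outcomes the round-2
#' threshold is 0.05/105 = 0.000477. A nominal tier (p < alpha_level but
#' above the Bonferroni threshold) is flagged separately, never promoted.
#'
#' @name cascade
NULL

#' Bonferroni threshold
#'
#' @param alpha_level family-wise error rate, in (0, 1).
#' @param m number of tests (>= 1).
#' @return `alpha_level / m` at full precision (tables round to 3
#'   significant digits at serialization only).
#' @export
bonferroni_threshold <- function(alpha_level, m) {
  if (length(m) != 1L || is.na(m) || m < 1) {
    stop("number of tests m must be >= 1", call. = FALSE)
  }
  if (alpha_level <= 0 || alpha_level >= 1) {
    stop("alpha_level must lie in (0, 1)", call. = FALSE)
  }
  alpha_level / m
}

#' Reconstruct a Wald standard error and 95% CI from (estimate, p)
#'
#' Published MR tables typically print the estimate, its two-sided p-value
#' and a 95% interval. Given the first two, the implied standard error is
#' `|estimate| / z*` with `z*` the two-sided normal quantile of `p`, and the
#' interval is `estimate +/- qnorm(0.975) * se`. All tail arithmetic runs in
#' log space, so p-values like 1.71e-32 (or far smaller, via `log_p`) are
#' handled exactly.
#'
#' @param estimate point estimate (non-zero).
#' @param p two-sided p-value in (0, 1); ignored when `log_p` is supplied.
#' @param log_p optional natural log of the p-value.
#' @return list with `se`, `ci_low`, `ci_high`.
#' @export
wald_interval <- function(estimate, p = NULL, log_p = NULL) {
  if (!is.finite(estimate) || estimate == 0) {
    stop("standard error undefined for a zero estimate", call. = FALSE)
  }
  if (is.null(log_p)) {
    if (is.null(p) || p <= 0 || p >= 1) {
      stop("p must lie strictly in (0, 1)", call. = FALSE)
    }
    log_p <- log(p)
  }
  zstar <- z_from_p(log_p = log_p)
  se <- abs(estimate) / zstar
  q <- stats::qnorm(0.975)
  list(se = se, ci_low = estimate - q * se, ci_high = estimate + q * se)
}

#' Run one round of MR fits against a list of target datasets
#'
#' For each target: harmonize against the panel, build LD blocks, fit the
#' composite-likelihood model. A failure for one target (unreadable file,
#' insufficient overlap, ...) is recorded as a row with `status` set to the
#' error message; it never silently disappears and never aborts the other
#' targets.
#'
#' @param exposure a `sumstats` table or a path readable by
#'   [read_sumstats()].
#' @param targets named list of `sumstats` tables and/or paths.
#' @param panel a [ref_panel].
#' @param settings list of estimator settings: `block_size`, `lambda_min`,
#'   `weights`, `maxit`, and `qc` (a [qc_settings()]).
#' @return data.frame in the results dialect with one row per target and a
#'   `status` column (`"ok"` or the error message).
#' @export
run_round <- function(exposure, targets, panel, settings = list()) {
  if (is.character(exposure)) exposure <- read_sumstats(exposure)
  if (length(targets) == 0L) {
    return(cbind(omr_fit_table(list()), status = character(0L)))
  }
  labels <- names(targets) %||% paste0("target_", seq_along(targets))
  exp_label <- attr(exposure, "trait_label") %||% "exposure"
  s <- utils::modifyList(
    list(block_size = 50L, lambda_min = 0.05, weights = "equal",
         maxit = 500L, qc = qc_settings()),
    settings)
  rows <- lapply(seq_along(targets), function(i) {
    res <- tryCatch({
      tgt <- targets[[i]]
      if (is.character(tgt)) tgt <- read_sumstats(tgt, trait_label = labels[i])
      pair <- merge_pair(exposure, tgt, panel, qc = s$qc)
      blocks <- build_blocks(pair, panel, block_size = s$block_size,
                             lambda_min = s$lambda_min)
      fit <- fit_omr(pair, blocks, weights = s$weights, maxit = s$maxit)
      cbind(omr_fit_table(fit, exposure = exp_label, outcome = labels[i]),
            status = "ok", stringsAsFactors = FALSE)
    }, error = function(e) {
      out <- omr_fit_table(list())
      out[1L, "exposure"] <- exp_label
      out[1L, "outcome"] <- labels[i]
      cbind(out, status = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (all(out$status != "ok")) {
    stop("every target in this round failed; first error: ",
         out$status[1L], call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Cascade configuration
#'
#' @param exposure `sumstats` table or path.
#' @param mediators named list of K mediator tables/paths (K >= 1).
#' @param outcomes named list of M outcome tables/paths (M >= 0).
#' @param panel a [ref_panel] or a VCF path.
#' @param blocks_path optional block sidecar when `panel` is a path.
#' @param alpha_level family-wise error rate per round (default 0.05).
#' @param settings estimator settings passed to [run_round()].
#' @param replication list: `enabled`, `p_threshold`, `r2_max`,
#'   `theta_grid` — when enabled, every Bonferroni-significant round-2 pair
#'   is re-estimated with [grid_search_theta()].
#' @return list of class `"cascade_config"`.
#' @export
cascade_config <- function(exposure, mediators, outcomes = list(),
                           panel, blocks_path = NULL, alpha_level = 0.05,
                           settings = list(),
                           replication = list(enabled = FALSE)) {
  stopifnot(length(mediators) >= 1L)
  labs <- c(names(mediators), names(outcomes))
  if (anyDuplicated(stats::na.omit(labs))) {
    stop("mediator/outcome labels must be unique", call. = FALSE)
  }
  rep_defaults <- list(enabled = FALSE, p_threshold = 5e-8, r2_max = 0.1,
                       theta_grid = seq(-1, 1, by = 0.005))
  structure(list(
    exposure = exposure, mediators = mediators, outcomes = outcomes,
    panel = panel, blocks_path = blocks_path, alpha_level = alpha_level,
    settings = settings,
    replication = utils::modifyList(rep_defaults, replication)
  ), class = "cascade_config")
}

#' Run the full two-round cascade
#'
#' Round 1 tests exposure -> each of the K mediators at threshold
#' `alpha_level / K`. Survivors (p below threshold, fit converged) become
#' round-2 exposures against the M outcomes at `alpha_level / (M * k)`.
#' With no survivors, round 2 is empty and its threshold is reported as NA
#' (not an error). When replication is enabled, each Bonferroni-significant
#' round-2 pair is re-estimated by the mixture grid search.
#'
#' @param config a [cascade_config()].
#' @return object of class `"cascade_report"`: `round1`, `survivors`,
#'   `round2`, `thresholds` (`t1`, `t2`), `alpha_level`, `replication`
#'   (named list of `mixture_grid_fit`s or NULL).
#' @export
run_cascade <- function(config) {
  stopifnot(inherits(config, "cascade_config"))
  panel <- config$panel
  if (is.character(panel)) {
    panel <- read_panel_vcf(panel, blocks_path = config$blocks_path)
  }
  exposure <- config$exposure
  if (is.character(exposure)) exposure <- read_sumstats(exposure)

  K <- length(config$mediators)
  t1 <- bonferroni_threshold(config$alpha_level, K)
  round1 <- run_round(exposure, config$mediators, panel, config$settings)
  round1$threshold <- t1
  round1$pass <- !is.na(round1$p) & round1$p < t1
  round1$nominal <- !is.na(round1$p) & round1$p < config$alpha_level &
    !round1$pass
  survivors <- round1$outcome[round1$pass]

  M <- length(config$outcomes)
  k <- length(survivors)
  t2 <- if (M > 0L && k > 0L) {
    bonferroni_threshold(config$alpha_level, M * k)
  } else NA_real_
  round2 <- NULL
  replication <- NULL
  if (M > 0L && k > 0L) {
    parts <- lapply(survivors, function(lab) {
      med <- config$mediators[[lab]]
      if (is.character(med)) med <- read_sumstats(med, trait_label = lab)
      run_round(med, config$outcomes, panel, config$settings)
    })
    round2 <- do.call(rbind, parts)
    round2$threshold <- t2
    round2$pass <- !is.na(round2$p) & round2$p < t2
    round2$nominal <- !is.na(round2$p) & round2$p < config$alpha_level &
      !round2$pass
    if (isTRUE(config$replication$enabled) && any(round2$pass)) {
      sig <- which(round2$pass)
      replication <- lapply(sig, function(i) {
        med <- config$mediators[[round2$exposure[i]]]
        if (is.character(med)) med <- read_sumstats(med)
        out <- config$outcomes[[round2$outcome[i]]]
        if (is.character(out)) out <- read_sumstats(out)
        tryCatch({
          pair <- merge_pair(med, out, panel,
                             qc = config$settings$qc %||% qc_settings())
          blocks <- build_blocks(pair, panel)
          instr <- select_instruments(
            pair, blocks,
            p_threshold = config$replication$p_threshold,
            r2_max = config$replication$r2_max)
          grid_search_theta(instr, config$replication$theta_grid)
        }, error = function(e) conditionMessage(e))
      })
      names(replication) <- paste(round2$exposure[sig], round2$outcome[sig],
                                  sep = "->")
    }
  }
  structure(list(
    round1 = round1, survivors = survivors, round2 = round2,
    thresholds = c(t1 = t1, t2 = t2), alpha_level = config$alpha_level,
    replication = replication
  ), class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("Two-round MR cascade\n")
  cat(sprintf("  Round 1: %d mediator(s), threshold %.3g; %d survivor(s)\n",
              nrow(x$round1), x$thresholds["t1"], length(x$survivors)))
  if (length(x$survivors) > 0L) {
    cat("   ", paste(x$survivors, collapse = ", "), "\n")
  }
  if (!is.null(x$round2)) {
    cat(sprintf("  Round 2: %d test(s), threshold %.3g; %d significant\n",
                nrow(x$round2), x$thresholds["t2"], sum(x$round2$pass)))
  } else {
    cat("  Round 2: not run (no survivors or no outcomes)\n")
  }
  invisible(x)
}

#' Write a cascade report to a directory
#'
#' Emits `round1.tsv`, `round2.tsv` (when round 2 ran), `survivors.txt`,
#' `thresholds.txt`, and per-pair `replication/<pair>.tsv` grid curves when
#' replication ran.
#'
#' @param report a `cascade_report`.
#' @param dir output directory (created if absent).
#' @export
write_cascade_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(report$round1, file.path(dir, "round1.tsv"))
  if (!is.null(report$round2)) {
    write_table(report$round2, file.path(dir, "round2.tsv"))
  }
  writeLines(report$survivors, file.path(dir, "survivors.txt"))
  thr <- report$thresholds
  writeLines(sprintf("%s\t%s", names(thr), signif(thr, 3L)),
             file.path(dir, "thresholds.txt"))
  if (!is.null(report$replication)) {
    rd <- file.path(dir, "replication")
    dir.create(rd, showWarnings = FALSE)
    for (nm in names(report$replication)) {
      f <- report$replication[[nm]]
      if (inherits(f, "mixture_grid_fit")) {
        write_grid_fit(f, file.path(rd, paste0(gsub("[^A-Za-z0-9_.-]", "_",
                                                    nm), ".tsv")))
      }
    }
  }
  invisible(dir)
}
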