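#' Harmonization: align summary statistics to a panel and merge a pair
#'
#' Before any two-sample MR, the exposure GWAS, the outcome GWAS and the LD
#' reference panel must agree SNP-for-SNP on which allele the effect is
#' reported for. [align_to_panel()] resolves allele orientation against the
#' panel; [merge_pair()] intersects the three sources and applies the QC
#' filters, producing the analysis-ready `harmonized_pair`.
#'
#' @name harmonize
NULL

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.complement <- function(x) unname(.COMPLEMENT[x])

.is_palindromic <- function(a1, a2) a1 == .complement(a2)

#' Align a sumstats table to the reference panel
#'
#' Joins on `snp_id` (falling back to `chr:pos:sortedalleles` where ids are
#' missing) and resolves allele orientation per SNP:
#' \itemize{
#'   \item same orientation as the panel: kept as-is;
#'   \item swapped alleles: `beta`/`z` negated, `freq := 1 - freq`;
#'   \item strand complement of either orientation: complemented first, then
#'     the same rule;
#'   \item palindromic SNPs (A/T, C/G), where strand cannot disambiguate:
#'     oriented by frequency agreement
#'     (`|freq_ss - freq_panel| < |freq_ss - (1 - freq_panel)|` keeps the
#'     sign); ambiguous ones are dropped later by [merge_pair()]'s
#'     frequency-band filter;
#'   \item anything else: dropped as an allele mismatch.
#' }
#' Unmatched SNPs are dropped. Every drop is counted in the `qc_log`
#' attribute (`unmatched`, `mismatch`).
#'
#' @param ss a `sumstats` table.
#' @param panel a [ref_panel].
#' @return the aligned `sumstats` table, rows ordered as in the panel map,
#'   with attributes `qc_log` (named counts) and `panel_index` (row index of
#'   each retained SNP in the panel map).
#' @export
align_to_panel <- function(ss, panel) {
  stopifnot(inherits(ss, "sumstats"), inherits(panel, "ref_panel"))
  key <- function(id, chr, pos, a1, a2) {
    miss <- is.na(id) | id == "" | id == "."
    out <- as.character(id)
    out[miss] <- paste(chr, pos, pmin(a1, a2), pmax(a1, a2),
                       sep = ":")[miss]
    out
  }
  ss_key <- key(ss$snp_id, ss$chr, ss$pos, ss$a1, ss$a2)
  pn_key <- key(panel$map$snp_id, panel$map$chr, panel$map$pos,
                panel$map$a1, panel$map$a2)
  hit <- match(ss_key, pn_key)
  qc <- c(unmatched = sum(is.na(hit)), mismatch = 0L)
  keep <- !is.na(hit)
  df <- as.data.frame(ss)[keep, , drop = FALSE]
  pidx <- hit[keep]
  pa1 <- panel$map$a1[pidx]
  pa2 <- panel$map$a2[pidx]
  pfreq <- panel$map$freq[pidx]

  pal <- .is_palindromic(df$a1, df$a2)
  same <- df$a1 == pa1 & df$a2 == pa2
  swap <- df$a1 == pa2 & df$a2 == pa1
  c_same <- .complement(df$a1) == pa1 & .complement(df$a2) == pa2
  c_swap <- .complement(df$a1) == pa2 & .complement(df$a2) == pa1

  flip <- logical(nrow(df))
  ok <- same | swap | c_same | c_swap
  # non-palindromic: orientation fully determined by the allele pair
  flip[!pal & (swap | c_swap)] <- TRUE
  # palindromic: A/T vs T/A etc. satisfies all four tests; use frequencies
  if (any(pal & ok)) {
    i <- which(pal & ok)
    flip[i] <- abs(df$freq[i] - pfreq[i]) >=
      abs(df$freq[i] - (1 - pfreq[i]))
  }
  qc["mismatch"] <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  pidx <- pidx[ok]
  fl <- flip[ok]
  df$beta[fl] <- -df$beta[fl]
  df$z[fl] <- -df$z[fl]
  df$freq[fl] <- 1 - df$freq[fl]
  df$a1 <- panel$map$a1[pidx]
  df$a2 <- panel$map$a2[pidx]
  ord <- order(pidx)
  df <- df[ord, , drop = FALSE]
  pidx <- pidx[ord]
  if (nrow(df) == 0L) {
    stop("no SNPs overlap between summary statistics and panel",
         call. = FALSE)
  }
  out <- as_sumstats(df, trait_label = attr(ss, "trait_label"))
  attr(out, "qc_log") <- qc
  attr(out, "panel_index") <- pidx
  out
}

#' Default QC filter settings for [merge_pair()]
#'
#' @param drop_palindromic drop palindromic SNPs whose panel frequency lies
#'   in `ambiguous_freq` (frequency cannot orient them reliably there).
#' @param ambiguous_freq frequency band treated as ambiguous.
#' @param maf_min minimum panel minor-allele frequency; LD estimated from a
#'   small panel is unstable below ~1\%.
#' @param z_cap optional |z| ceiling applied to both traits (off by
#'   default).
#' @param min_snps error if fewer SNPs survive (genome-wide methods are
#'   meaningless on a handful of SNPs).
#' @return a named list of settings.
#' @export
qc_settings <- function(drop_palindromic = TRUE,
                        ambiguous_freq = c(0.4, 0.6),
                        maf_min = 0.01, z_cap = NULL, min_snps = 100L) {
  list(drop_palindromic = drop_palindromic, ambiguous_freq = ambiguous_freq,
       maf_min = maf_min, z_cap = z_cap, min_snps = as.integer(min_snps))
}

#' Merge an exposure/outcome pair with the panel
#'
#' Aligns both tables to the panel, intersects the SNP sets, and applies QC
#' filters in a fixed order: (1) ambiguous palindromic SNPs (panel frequency
#' inside `ambiguous_freq`), (2) panel MAF below `maf_min`, (3) optional
#' |z| cap. The filters are non-interacting set predicates, so the final
#' SNP set does not depend on their order. Per-filter removal counts and the
#' settings used are recorded in `qc_log`.
#'
#' Sample sizes are collapsed to per-trait scalars (medians when per-SNP `n`
#' varies), the form the estimator's covariance algebra uses.
#'
#' @param ss_x,ss_y exposure and outcome `sumstats` tables.
#' @param panel a [ref_panel].
#' @param qc settings from [qc_settings()].
#' @return a list of class `"harmonized_pair"`: `snp_id`, `panel_index`,
#'   `z_x`, `z_y`, `n_x`, `n_y`, `block_id` (NA when the panel has no block
#'   boundaries), `freq`, `qc_log`.
#' @export
merge_pair <- function(ss_x, ss_y, panel, qc = qc_settings()) {
  ax <- align_to_panel(ss_x, panel)
  ay <- align_to_panel(ss_y, panel)
  qc_log <- c(
    unmatched_x = unname(attr(ax, "qc_log")["unmatched"]),
    mismatch_x = unname(attr(ax, "qc_log")["mismatch"]),
    unmatched_y = unname(attr(ay, "qc_log")["unmatched"]),
    mismatch_y = unname(attr(ay, "qc_log")["mismatch"])
  )
  ix <- attr(ax, "panel_index")
  iy <- attr(ay, "panel_index")
  common <- intersect(ix, iy)
  mx <- match(common, ix)
  my <- match(common, iy)
  pfreq <- panel$map$freq[common]
  pa1 <- panel$map$a1[common]
  pa2 <- panel$map$a2[common]

  keep <- rep(TRUE, length(common))
  pal <- .is_palindromic(pa1, pa2)
  drop_pal <- if (isTRUE(qc$drop_palindromic)) {
    pal & pfreq >= qc$ambiguous_freq[1L] & pfreq <= qc$ambiguous_freq[2L]
  } else rep(FALSE, length(common))
  maf <- pmin(pfreq, 1 - pfreq)
  drop_maf <- maf < qc$maf_min & !drop_pal
  drop_z <- rep(FALSE, length(common))
  if (!is.null(qc$z_cap)) {
    drop_z <- (abs(ax$z[mx]) > qc$z_cap | abs(ay$z[my]) > qc$z_cap) &
      !drop_pal & !drop_maf
  }
  keep <- !(drop_pal | drop_maf | drop_z)
  qc_log <- c(qc_log, palindrome = sum(drop_pal), maf = sum(drop_maf),
              z_cap = sum(drop_z))

  if (sum(keep) < qc$min_snps) {
    stop(sprintf(
      "insufficient overlap: %d SNP(s) retained, floor is %d",
      sum(keep), qc$min_snps), call. = FALSE)
  }
  common <- common[keep]
  mx <- mx[keep]
  my <- my[keep]
  block_id <- rep(NA_integer_, length(common))
  if (!is.null(panel$blocks)) {
    b <- panel$blocks[order(panel$blocks$start_index), ]
    idx <- findInterval(common, b$start_index)
    inside <- idx >= 1L & common <= b$end_index[pmax(idx, 1L)]
    block_id[inside] <- b$block_id[idx[inside]]
  }
  structure(list(
    snp_id = panel$map$snp_id[common],
    panel_index = common,
    z_x = ax$z[mx],
    z_y = ay$z[my],
    n_x = stats::median(ax$n[mx]),
    n_y = stats::median(ay$n[my]),
    block_id = block_id,
    freq = pfreq[keep],
    qc_log = qc_log,
    qc_settings = qc
  ), class = "harmonized_pair")
}

#' @export
print.harmonized_pair <- function(x, ...) {
  cat(sprintf(
    "Harmonized pair: %d SNPs, n_x = %g, n_y = %g\n",
    length(x$z_x), x$n_x, x$n_y))
  ql <- x$qc_log
  cat("  QC removals:", paste(names(ql), ql, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Write a harmonization QC log as TSV
#'
#' One row per filter with the count removed and the running count
#' remaining.
#'
#' @param pair a `harmonized_pair`.
#' @param path output path.
#' @param n_input optional count of SNPs before harmonization (for the
#'   first "remaining" entry); defaults to retained + total removed.
#' @export
write_qc_log <- function(pair, path, n_input = NULL) {
  ql <- pair$qc_log
  retained <- length(pair$z_x)
  n0 <- n_input %||% (retained + sum(ql))
  remaining <- n0 - cumsum(as.numeric(ql))
  utils::write.table(
    data.frame(filter = names(ql), removed = as.integer(ql),
               remaining = as.integer(remaining)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
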