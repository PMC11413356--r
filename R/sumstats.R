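#' GWAS summary-statistics tables
#'
#' The canonical in-memory representation of one GWAS is a `data.frame` of
#' class `"sumstats"` with columns `snp_id`, `chr`, `pos` (1-based), `a1`
#' (effect allele), `a2` (other allele), `freq` (frequency of `a1`), `beta`,
#' `se`, `p`, `n` and the derived `z = beta / se`, plus a `trait_label`
#' attribute and a `qc_log` attribute counting rows removed at ingestion.
#'
#' @name sumstats
NULL

.SUMSTATS_DEFAULT_DIALECT <- c(
  snp_id = "SNP", chr = "CHR", pos = "BP", a1 = "A1", a2 = "A2",
  freq = "FREQ", beta = "BETA", se = "SE", p = "P", n = "N", z = "Z"
)

.SUMSTATS_COLS <- c("snp_id", "chr", "pos", "a1", "a2", "freq",
                    "beta", "se", "p", "n", "z")

#' Construct a sumstats table from columns
#'
#' Validates, normalises (uppercase alleles, derived `z`), and classes a
#' summary-statistics table. Mostly used by the synthetic generator and by
#' [read_sumstats()]; analysts start from files.
#'
#' @param df data.frame carrying the canonical columns (`z` optional when
#'   `beta`/`se` present, and vice versa given `n`).
#' @param trait_label label naming the trait.
#' @return a `sumstats` data.frame.
#' @export
as_sumstats <- function(df, trait_label = "trait") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("snp_id", "chr", "pos", "a1", "a2", "freq", "n")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0L) {
    stop("sumstats table is missing required columns: ",
         paste(missing_cols, collapse = ","), call. = FALSE)
  }
  if (!all(c("beta", "se") %in% names(df))) {
    if (!"z" %in% names(df)) {
      stop("sumstats table needs either beta+se or z columns", call. = FALSE)
    }
    # z-only input: place effects on the standardized scale, se = 1/sqrt(n)
    df$se <- 1 / sqrt(df$n)
    df$beta <- df$z * df$se
  }
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  df$chr <- as.character(df$chr)
  df$z <- df$beta / df$se
  if (!"p" %in% names(df)) df$p <- p_from_z(df$z)
  df <- df[, .SUMSTATS_COLS]
  attr(df, "trait_label") <- trait_label
  class(df) <- c("sumstats", "data.frame")
  df
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a (possibly gzipped) tab- or whitespace-delimited file into the
#' canonical table. Column names are mapped through `dialect`; the default
#' dialect is `SNP CHR BP A1 A2 FREQ BETA SE P N`. Rows failing basic QC are
#' dropped and counted in the `qc_log` attribute:
#' \itemize{
#'   \item missing required fields or non-positive `se`;
#'   \item indels (multi-base alleles; this is a SNP-only pipeline);
#'   \item duplicate `snp_id` (the record with the largest `n` is kept);
#' }
#' Rows whose stored `p` disagrees with `2*pnorm(-|z|)` by more than 1e-3
#' relative error are retained but flagged in the `p_flagged` attribute (a
#' logical vector aligned with the returned rows); the stored `p` is
#' replaced by the z-implied value so downstream log-space arithmetic stays
#' self-consistent.
#'
#' If `beta`/`se` are absent but `z` and `n` are present, effects are placed
#' on the standardized scale with `se = 1/sqrt(n)`.
#'
#' @param path file path.
#' @param dialect named character vector mapping canonical names
#'   (`snp_id`, `chr`, ...) to the file's column names; merged over the
#'   default dialect.
#' @param trait_label label for the trait; defaults to the file name.
#' @return a `sumstats` data.frame (see [sumstats]).
#' @export
read_sumstats <- function(path, dialect = NULL, trait_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  map <- .SUMSTATS_DEFAULT_DIALECT
  if (!is.null(dialect)) map[names(dialect)] <- dialect
  raw <- data.table::fread(path, header = TRUE, data.table = FALSE,
                           showProgress = FALSE)
  # map file columns -> canonical names
  hit <- map[map %in% names(raw)]
  df <- raw[, hit, drop = FALSE]
  names(df) <- names(hit)

  required <- c("snp_id", "chr", "pos", "a1", "a2", "freq", "n")
  has_effect <- all(c("beta", "se") %in% names(df)) || "z" %in% names(df)
  missing_cols <- setdiff(required, names(df))
  if (!has_effect) missing_cols <- c(missing_cols, "beta", "se")
  if (length(missing_cols) > 0L) {
    stop("input lacks required columns (after dialect mapping): ",
         paste(sort(unique(missing_cols)), collapse = ","), call. = FALSE)
  }

  qc <- c(missing = 0L, bad_se = 0L, indel = 0L, duplicate = 0L)
  eff_cols <- if (all(c("beta", "se") %in% names(df))) c("beta", "se") else "z"
  check_cols <- c(required, eff_cols)
  ok <- stats::complete.cases(df[, check_cols])
  qc["missing"] <- sum(!ok)
  df <- df[ok, , drop = FALSE]
  if ("se" %in% names(df)) {
    bad <- df$se <= 0
    qc["bad_se"] <- sum(bad)
    df <- df[!bad, , drop = FALSE]
  }
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  snp_only <- nchar(df$a1) == 1L & nchar(df$a2) == 1L &
    df$a1 %in% c("A", "C", "G", "T") & df$a2 %in% c("A", "C", "G", "T")
  qc["indel"] <- sum(!snp_only)
  df <- df[snp_only, , drop = FALSE]
  # duplicates: keep largest n, deterministic
  if (anyDuplicated(df$snp_id)) {
    ord <- order(df$snp_id, -df$n)
    df <- df[ord, , drop = FALSE]
    dup <- duplicated(df$snp_id)
    qc["duplicate"] <- sum(dup)
    df <- df[!dup, , drop = FALSE]
    df <- df[order(df$chr, df$pos), , drop = FALSE]
  }
  if (nrow(df) == 0L) {
    stop("no rows retained after quality control in ", path, call. = FALSE)
  }
  dropped <- sum(qc)
  if (dropped > 0L) {
    message(sprintf("read_sumstats: dropped %d row(s) [%s]", dropped,
                    paste(names(qc)[qc > 0], qc[qc > 0],
                          sep = "=", collapse = ", ")))
  }
  out <- as_sumstats(df, trait_label = trait_label %||% basename(path))
  # consistency of stored p with |z|
  if ("p" %in% names(df)) {
    p_implied <- p_from_z(out$z)
    stored <- df$p
    flagged <- is.finite(stored) &
      abs(stored - p_implied) > 1e-3 * pmax(p_implied, .Machine$double.xmin)
    out$p[flagged] <- p_implied[flagged]
    attr(out, "p_flagged") <- flagged
    if (any(flagged)) {
      message(sprintf(
        "read_sumstats: %d row(s) with p inconsistent with |z| flagged",
        sum(flagged)))
    }
  }
  attr(out, "qc_log") <- qc
  out
}

#' Write a results table to TSV
#'
#' Serialises homogeneous result records (for example one [fit_omr()] row per
#' trait) with a fixed column order, floats at 6 significant digits and
#' p-values in scientific notation. Magnitudes like 1e-32 round-trip without
#' underflow. An empty record set produces a header-only file.
#'
#' @param rows data.frame of results.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  fmt <- function(col, nm) {
    if (!is.numeric(col)) return(as.character(col))
    if (grepl("^p($|_)|_p$|pval", nm)) {
      sprintf("%.6e", col)
    } else if (all(col == round(col), na.rm = TRUE) && !anyNA(col) &&
               all(abs(col) < 2^31)) {
      format(as.integer(round(col)))
    } else {
      sprintf("%.6g", col)
    }
  }
  out <- rows
  for (nm in names(out)) out[[nm]] <- fmt(out[[nm]], nm)
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Write a sumstats table in the default TSV dialect
#'
#' @param ss a `sumstats` table.
#' @param path output path (plain TSV; add `.gz` for gzip).
#' @export
write_sumstats <- function(ss, path) {
  df <- as.data.frame(ss)[, c("snp_id", "chr", "pos", "a1", "a2",
                              "freq", "beta", "se", "p", "n")]
  names(df) <- c("SNP", "CHR", "BP", "A1", "A2", "FREQ", "BETA", "SE",
                 "P", "N")
  df$P <- sprintf("%.6e", df$P)
  for (nm in c("FREQ", "BETA", "SE")) df[[nm]] <- sprintf("%.6g", df[[nm]])
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s\n", attr(x, "trait_label")))
  cat(sprintf("  %d SNPs, median n = %g\n", nrow(x),
              stats::median(x$n)))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat(sprintf("  ... %d more rows\n", nrow(x) - 5L))
  invisible(x)
}
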