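#' Reference panels
#'
#' A reference panel is a list of class `"ref_panel"` with components:
#' \describe{
#'   \item{dosage}{numeric matrix, samples x SNPs, ALT-allele counts 0/1/2
#'     (fractional dosages permitted).}
#'   \item{map}{data.frame with `snp_id`, `chr`, `pos`, `a1` (ALT/effect),
#'     `a2` (REF/other), `freq` (frequency of `a1`).}
#'   \item{blocks}{optional data.frame of LD-block boundaries with
#'     `block_id`, `chr`, `start_index`, `end_index` (1-based SNP indices
#'     into the map), or `NULL`.}
#' }
#' It stands in for the LD structure of the genotyped cohorts, the role a
#' 1000 Genomes panel plays in real analyses.
#'
#' @name ref_panel
NULL

new_ref_panel <- function(dosage, map, blocks = NULL) {
  stopifnot(is.matrix(dosage), nrow(map) == ncol(dosage))
  stopifnot(all(map$freq > 0 & map$freq < 1))
  for (ch in unique(map$chr)) {
    pos <- map$pos[map$chr == ch]
    if (is.unsorted(pos)) {
      stop("panel map positions must be non-decreasing within chromosome ",
           ch, call. = FALSE)
    }
  }
  if (!is.null(blocks)) .validate_blocks(blocks, nrow(map))
  structure(list(dosage = dosage, map = map, blocks = blocks),
            class = "ref_panel")
}

.validate_blocks <- function(blocks, p) {
  need <- c("block_id", "chr", "start_index", "end_index")
  if (!all(need %in% names(blocks))) {
    stop("block sidecar must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(blocks$start_index > blocks$end_index) ||
      any(blocks$start_index < 1L) || any(blocks$end_index > p)) {
    stop("block sidecar has out-of-range indices", call. = FALSE)
  }
  ord <- order(blocks$start_index)
  b <- blocks[ord, ]
  if (nrow(b) > 1L &&
      any(b$start_index[-1L] <= b$end_index[-nrow(b)])) {
    stop("block sidecar has overlapping block ranges", call. = FALSE)
  }
  invisible(blocks)
}

#' Read a reference panel from VCF
#'
#' Loads diploid GT genotypes from a VCF 4.x file into a dosage matrix
#' (count of ALT alleles; `a1` := ALT, `a2` := REF, `freq` computed from the
#' dosages). Non-biallelic-SNP records are skipped with a message. Block
#' boundaries are read from an optional tab-delimited sidecar with columns
#' `block_id`, `chr`, `start_index`, `end_index`.
#'
#' @param path VCF path (plain or gzipped).
#' @param blocks_path optional block-sidecar TSV path.
#' @return a [ref_panel] object.
#' @export
read_panel_vcf <- function(path, blocks_path = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  bases <- c("A", "C", "G", "T")
  keep <- ref %in% bases & alt %in% bases
  if (sum(!keep) > 0L) {
    message(sprintf("read_panel_vcf: skipped %d non-biallelic-SNP record(s)",
                    sum(!keep)))
  }
  if (sum(keep) == 0L) {
    stop("no biallelic SNP records in ", path, call. = FALSE)
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  # count ALT alleles per genotype string ("0/1", "1|1", ...)
  dos <- apply(gt, 2L, function(col) {
    a <- substr(col, 1L, 1L)
    b <- substr(col, 3L, 3L)
    suppressWarnings(as.numeric(a) + as.numeric(b))
  })
  dos <- t(matrix(dos, nrow = sum(keep)))  # samples x SNPs
  ids <- fix[keep, "ID"]
  no_id <- is.na(ids) | ids == "." | ids == ""
  if (any(no_id)) {
    # fallback join key: chr:pos:sorted alleles
    al <- cbind(ref[keep], alt[keep])
    sorted <- paste(pmin(al[, 1L], al[, 2L]), pmax(al[, 1L], al[, 2L]),
                    sep = ":")
    ids[no_id] <- paste(fix[keep, "CHROM"], fix[keep, "POS"],
                        sorted, sep = ":")[no_id]
  }
  map <- data.frame(
    snp_id = ids,
    chr = as.character(fix[keep, "CHROM"]),
    pos = as.integer(fix[keep, "POS"]),
    a1 = alt[keep],
    a2 = ref[keep],
    freq = colMeans(dos) / 2,
    stringsAsFactors = FALSE
  )
  blocks <- NULL
  if (!is.null(blocks_path)) {
    blocks <- utils::read.delim(blocks_path, stringsAsFactors = FALSE)
    .validate_blocks(blocks, nrow(map))
  }
  new_ref_panel(dos, map, blocks)
}

#' Write a reference panel as VCF plus block sidecar
#'
#' Emits a minimal VCF 4.2 with a single GT FORMAT field (unphased diploid
#' genotypes reconstructed from the integer dosages) and, when the panel
#' carries block boundaries, a tab-delimited sidecar. The dialect is the
#' fixed, SNP-only one this pipeline consumes; it reads back through
#' [read_panel_vcf()].
#'
#' @param panel a [ref_panel].
#' @param path output VCF path.
#' @param blocks_path optional sidecar path (required if the panel has
#'   blocks and you want them persisted).
#' @export
write_panel_vcf <- function(panel, path, blocks_path = NULL) {
  stopifnot(inherits(panel, "ref_panel"))
  dos <- round(panel$dosage)
  n <- nrow(dos)
  gt_codes <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("S%04d", seq_len(n))), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(dos)), function(j) {
    m <- panel$map[j, ]
    paste(c(m$chr, m$pos, m$snp_id, m$a2, m$a1, ".", "PASS", ".", "GT",
            gt_codes[dos[, j] + 1L]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  if (!is.null(panel$blocks) && !is.null(blocks_path)) {
    utils::write.table(panel$blocks, blocks_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("Reference panel: %d samples x %d SNPs on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chr))))
  if (!is.null(x$blocks)) {
    cat(sprintf("  %d LD block(s) defined\n", nrow(x$blocks)))
  }
  invisible(x)
}
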