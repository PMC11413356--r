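#' LD blocks
#'
#' The composite likelihood treats the genome as a sequence of LD blocks,
#' within which SNP correlations matter and across which z-scores are taken
#' as independent. Each block carries the correlation matrix `R` estimated
#' from the reference panel's standardized dosages, shrunk toward the
#' identity, `R <- (1 - lambda) R + lambda I`, with
#' `lambda = max(lambda_min, m / n_ref)`. The shrinkage identity bounds the
#' smallest eigenvalue below by `lambda`, so every block is positive
#' definite even when the block size approaches the panel size.
#'
#' @name ld_blocks
NULL

# Estimate (and shrink) the correlation matrix of panel SNPs `idx`.
.estimate_block_R <- function(panel, idx, lambda_min = 0.05) {
  m <- length(idx)
  n_ref <- nrow(panel$dosage)
  lambda <- max(lambda_min, m / n_ref)
  if (lambda >= 1) {
    stop("block of size ", m, " cannot be regularized against a panel of ",
         n_ref, " samples", call. = FALSE)
  }
  if (m == 1L) return(list(R = matrix(1, 1L, 1L), lambda = lambda))
  R <- stats::cor(panel$dosage[, idx, drop = FALSE])
  R <- (1 - lambda) * R + lambda * diag(m)
  list(R = R, lambda = lambda)
}

#' Partition a harmonized pair into LD blocks
#'
#' Uses the panel's block boundaries when present (each boundary block
#' restricted to the retained SNPs), otherwise contiguous windows of
#' `block_size` SNPs that never straddle a chromosome boundary. Every block
#' stores its shrunk correlation matrix and its eigendecomposition, which
#' the likelihood kernel consumes.
#'
#' @param pair a `harmonized_pair` from [merge_pair()].
#' @param panel the [ref_panel] used for harmonization.
#' @param block_size window size when boundaries are absent (default 50).
#' @param lambda_min shrinkage floor (default 0.05).
#' @return a list of class `"ld_blocks"`; each element has `idx` (positions
#'   into the pair's vectors), `panel_index`, `R`, `lambda`, `m`, and the
#'   eigendecomposition `eig`.
#' @export
build_blocks <- function(pair, panel, block_size = 50L, lambda_min = 0.05) {
  stopifnot(inherits(pair, "harmonized_pair"), inherits(panel, "ref_panel"))
  p <- length(pair$z_x)
  if (p == 0L) stop("empty harmonized pair", call. = FALSE)
  if (!is.null(panel$blocks) && !all(is.na(pair$block_id))) {
    groups <- split(seq_len(p), pair$block_id)
  } else {
    chr <- panel$map$chr[pair$panel_index]
    groups <- unlist(lapply(split(seq_len(p), chr), function(i) {
      split(i, (seq_along(i) - 1L) %/% block_size)
    }), recursive = FALSE)
    groups <- groups[order(vapply(groups, min, 1L))]
  }
  groups <- groups[vapply(groups, length, 1L) > 0L]
  blocks <- lapply(seq_along(groups), function(k) {
    i <- groups[[k]]
    pidx <- pair$panel_index[i]
    est <- .estimate_block_R(panel, pidx, lambda_min)
    list(idx = i, panel_index = pidx, R = est$R, lambda = est$lambda,
         m = length(i), eig = eigen(est$R, symmetric = TRUE))
  })
  structure(blocks, class = "ld_blocks")
}

#' @export
print.ld_blocks <- function(x, ...) {
  m <- vapply(x, function(b) b$m, 1L)
  cat(sprintf("%d LD block(s), sizes %d-%d (median %g), shrinkage %.3g-%.3g\n",
              length(x), min(m), max(m), stats::median(m),
              min(vapply(x, function(b) b$lambda, 1)),
              max(vapply(x, function(b) b$lambda, 1))))
  invisible(x)
}
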