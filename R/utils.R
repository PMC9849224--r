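# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize chromosome labels
#'
#' Strips a leading "chr" prefix so "chr1" and "1" compare equal.
#'
#' @param chrom character vector of chromosome labels.
#' @return character vector of normalized labels.
#' @keywords internal
.norm_chrom <- function(chrom) {
  sub("^chr", "", as.character(chrom), ignore.case = TRUE)
}

# Reverse-complement an allele string (supports multi-base alleles).
.complement_allele <- function(allele) {
  vapply(allele, function(a) {
    bases <- rev(strsplit(a, "", fixed = TRUE)[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A")[bases]
    if (anyNA(comp)) return(NA_character_)
    paste(comp, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Palindromic (strand-ambiguous) variant: alleles are reverse complements
# of each other, e.g. A/T or C/G.
.is_palindromic <- function(ref, alt) {
  comp <- .complement_allele(alt)
  !is.na(comp) & ref == comp
}

#' Canonical variant identifier
#'
#' chrom:pos:ref:alt string used as the key for joins, LD lookups and
#' credible-set intersection.
#'
#' @param chrom,pos,ref,alt variant coordinates and alleles.
#' @return character vector of identifiers.
#' @export
variant_id <- function(chrom, pos, ref, alt) {
  paste(.norm_chrom(chrom), as.integer(pos), ref, alt, sep = ":")
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.assert <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) .stopf(fmt, ...)
  invisible(TRUE)
}

# Derive a per-stage 32-bit seed from a global seed and a stage counter.
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + 7919L * as.integer(stage)) %% .Machine$integer.max
}

# Project a symmetric matrix to the nearest positive semi-definite matrix
# by eigenvalue clipping, preserving the unit diagonal.
.nearest_psd_corr <- function(m, eps = 1e-10) {
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= -eps)) return(m)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% diag(vals, nrow = length(vals)) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / tcrossprod(d)
  diag(out) <- 1
  (out + t(out)) / 2
}
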