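#' Approximate-Bayes-factor fine-mapping configuration
#'
#' @param prior_var_w prior variance W of the causal log-odds effect
#'   (default 0.04, i.e. prior SD 0.2).
#' @return object of class `abf_config`.
#' @export
abf_config <- function(prior_var_w = 0.04) {
  .assert(prior_var_w > 0, "prior_var_w must be positive")
  structure(list(prior_var_w = prior_var_w), class = "abf_config")
}

#' Single-causal-variant posterior inclusion probabilities
#'
#' Wakefield-style approximate Bayes factor per variant,
#' ABF_i = sqrt(se_i^2 / (se_i^2 + W)) * exp(z_i^2 W / (2 (se_i^2 + W))),
#' normalized across the locus under the assumption of exactly one
#' causal variant with a flat prior over variants:
#' PIP_i = ABF_i / sum_j ABF_j. Computed in log space, so arbitrarily
#' large |z| cannot overflow.
#'
#' @param beta,se per-variant log-odds estimates and standard errors of
#'   one locus.
#' @param config an [abf_config].
#' @return PIP vector summing to 1.
#' @export
abf_pips <- function(beta, se, config = abf_config()) {
  .assert(length(beta) >= 1L, "empty locus")
  .assert(length(beta) == length(se), "beta and se must have equal length")
  .assert(all(se > 0), "all se must be positive")
  w <- config$prior_var_w
  z2 <- (beta / se)^2
  log_abf <- 0.5 * log(se^2 / (se^2 + w)) + z2 * w / (2 * (se^2 + w))
  log_abf <- log_abf - max(log_abf)
  exp(log_abf) / sum(exp(log_abf))
}

#' Low-level credible-set constructor
#'
#' Builds a `credible_set` object from variants and PIPs without
#' applying the coverage-prefix rule; used by file IO and fixture
#' generators. Variants are sorted by descending PIP.
#'
#' @param variants data.frame with chrom, pos, ref, alt (rsid optional).
#' @param pip PIPs aligned to `variants`, each in (0, 1], summing to at
#'   most 1 (within tolerance).
#' @param locus_id,cs_id identifiers.
#' @param coverage nominal coverage the set was built for.
#' @param contains_gws whether any member is genome-wide significant.
#' @return object of class `credible_set`.
#' @export
new_credible_set <- function(variants, pip, locus_id = "locus",
                             cs_id = "cs1", coverage = NA_real_,
                             contains_gws = NA) {
  .assert(nrow(variants) == length(pip), "variants and pip must align")
  .assert(all(pip > 0 & pip <= 1), "PIPs must be in (0, 1]")
  .assert(sum(pip) <= 1 + 1e-9, "PIPs must sum to at most 1")
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  variants$chrom <- .norm_chrom(variants$chrom)
  variants$id <- variant_id(variants$chrom, variants$pos,
                            variants$ref, variants$alt)
  ord <- order(-pip, variants$chrom, variants$pos)
  structure(list(locus_id = locus_id, cs_id = cs_id,
                 variants = variants[ord, , drop = FALSE],
                 pip = pip[ord], coverage = coverage,
                 contains_gws = contains_gws),
            class = "credible_set")
}

#' 95% credible set from locus PIPs
#'
#' The credible set is the smallest descending-PIP prefix of the locus
#' whose cumulative PIP reaches the target coverage. A set without any
#' genome-wide-significant member is marked `excluded` (such sets are
#' dropped from downstream reporting).
#'
#' @param pips full-locus PIP vector (summing to 1).
#' @param coverage target cumulative PIP in (0, 1] (default 0.95).
#' @param gws_flags logical per variant: genome-wide significant?
#' @param variants optional data.frame (chrom, pos, ref, alt, rsid)
#'   aligned with `pips`; synthesized if absent.
#' @param locus_id,cs_id identifiers.
#' @return a `credible_set` with members, their PIPs, the achieved
#'   coverage, `contains_gws`, and `excluded = !contains_gws`.
#' @export
credible_set <- function(pips, coverage = 0.95, gws_flags = NULL,
                         variants = NULL, locus_id = "locus", cs_id = "cs1") {
  .assert(coverage > 0 && coverage <= 1, "coverage must be in (0, 1]")
  .assert(abs(sum(pips) - 1) < 1e-6, "locus PIPs must sum to 1")
  n <- length(pips)
  if (is.null(variants)) {
    variants <- data.frame(stringsAsFactors = FALSE,
                           chrom = "1", pos = 10000L * seq_len(n),
                           ref = "A", alt = "G")
  }
  gws_flags <- gws_flags %||% rep(NA, n)
  ord <- order(-pips, seq_len(n))
  cum <- cumsum(pips[ord])
  size <- which(cum >= coverage - 1e-12)[1L]
  members <- ord[seq_len(size)]
  cs <- new_credible_set(variants[members, , drop = FALSE], pips[members],
                         locus_id = locus_id, cs_id = cs_id,
                         coverage = coverage,
                         contains_gws = any(gws_flags[members]))
  cs$achieved_coverage <- cum[size]
  cs$excluded <- isFALSE(cs$contains_gws)
  cs
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("Credible set %s/%s: %d variant(s), cumulative PIP %.3f%s\n",
              x$locus_id, x$cs_id, length(x$pip), sum(x$pip),
              if (isTRUE(x$excluded)) " [excluded: no GWS member]" else ""))
  invisible(x)
}

#' Fine-map one locus from association records
#'
#' Convenience wrapper: computes single-causal ABF PIPs over a locus's
#' records and extracts the credible set, flagging genome-wide
#' significant members.
#'
#' @param locus_records data.frame/[sumstats] rows for one locus (needs
#'   chrom, pos, ref, alt, beta, se, pval; rsid optional).
#' @param config an [abf_config].
#' @param coverage target coverage.
#' @param thresholds a [significance_thresholds] for the GWS flags.
#' @param locus_id,cs_id identifiers.
#' @return a `credible_set`.
#' @export
finemap_locus <- function(locus_records, config = abf_config(),
                          coverage = 0.95,
                          thresholds = significance_thresholds(),
                          locus_id = "locus", cs_id = "cs1") {
  pips <- abf_pips(locus_records$beta, locus_records$se, config)
  credible_set(pips, coverage = coverage,
               gws_flags = locus_records$pval <= thresholds$gws,
               variants = locus_records[, intersect(
                 c("chrom", "pos", "ref", "alt", "rsid"), names(locus_records))],
               locus_id = locus_id, cs_id = cs_id)
}
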