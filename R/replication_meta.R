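#' Two-cohort heterogeneity test
#'
#' Test statistic z = (beta1 - beta2)^2 / (SE1^2 + SE2^2), referred to a
#' 1-df chi-square upper tail. Pairs with p below 0.05 are conventionally
#' considered heterogeneous between the cohorts.
#'
#' @param beta1,se1 effect and SE in cohort 1 (vectorized).
#' @param beta2,se2 effect and SE in cohort 2.
#' @return data.frame with `het_stat` and `het_pval`.
#' @export
heterogeneity_test <- function(beta1, se1, beta2, se2) {
  .assert(all(se1 > 0) && all(se2 > 0), "standard errors must be positive")
  stat <- (beta1 - beta2)^2 / (se1^2 + se2^2)
  data.frame(het_stat = stat,
             het_pval = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Recover (beta, se) from a printed odds ratio and 95% CI
#'
#' Inverts the normal-approximation confidence interval:
#' beta = ln(OR), se = (ln(CI_high) - ln(CI_low)) / (2 * 1.959964).
#' The two-sided Wald p-value follows as 2 * pnorm(-|beta/se|).
#'
#' @param or_point odds ratio point estimate.
#' @param ci_low,ci_high 95% confidence bounds, 0 < low <= OR <= high.
#' @return data.frame with `beta`, `se` and `pval` (NA when the CI is
#'   degenerate).
#' @export
from_or_ci <- function(or_point, ci_low, ci_high) {
  .assert(all(or_point > 0) && all(ci_low > 0) && all(ci_high > 0),
          "odds ratios and CI bounds must be positive")
  .assert(all(ci_low <= or_point + 1e-12) && all(or_point <= ci_high + 1e-12),
          "need ci_low <= OR <= ci_high")
  beta <- log(or_point)
  se <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  pval <- ifelse(se > 0, 2 * stats::pnorm(-abs(beta / se)), NA_real_)
  data.frame(beta = beta, se = se, pval = pval)
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Weights w_i = 1/se_i^2; beta_meta = sum(w beta)/sum(w);
#' se_meta = 1/sqrt(sum(w)). The heterogeneity statistic is Cochran's Q
#' (which for two studies equals the two-cohort statistic of
#' [heterogeneity_test()]) with k-1 degrees of freedom. Effects are
#' co-directional when all nonzero estimates share a sign; an exactly
#' zero effect is co-directional with anything.
#'
#' @param betas,ses effect estimates and SEs of k >= 2 studies.
#' @return object of class `meta_result`: list with `beta_meta`,
#'   `se_meta`, `pval_meta`, `het_stat`, `het_pval`, `codirectional`.
#' @export
ivw_meta <- function(betas, ses) {
  .assert(length(betas) >= 2L, "meta-analysis needs at least two studies")
  .assert(length(ses) == length(betas) && all(ses > 0),
          "ses must match betas and be positive")
  w <- 1 / ses^2
  beta_meta <- sum(w * betas) / sum(w)
  se_meta <- 1 / sqrt(sum(w))
  q <- sum(w * (betas - beta_meta)^2)
  structure(list(
    beta_meta = beta_meta, se_meta = se_meta,
    pval_meta = 2 * stats::pnorm(-abs(beta_meta / se_meta)),
    het_stat = q,
    het_pval = stats::pchisq(q, df = length(betas) - 1L, lower.tail = FALSE),
    codirectional = all(sign(betas) >= 0) || all(sign(betas) <= 0)),
    class = "meta_result")
}

#' Replication classification of a discovery variant
#'
#' Applies the tiered significance rule for a variant discovered in one
#' cohort and looked up in a replication cohort:
#' \describe{
#'   \item{meta_significant}{effects co-directional and the IVW
#'     meta-analysis p reaches genome-wide significance;}
#'   \item{replicated}{discovery p is GWS, effects co-directional, and
#'     the replication p is below `rep_alpha`;}
#'   \item{discovery_only_mts}{discovery p reaches the stricter
#'     multiple-testing threshold on its own;}
#'   \item{not_supported}{anything else.}
#' }
#' Only co-directional pairs are meta-analyzed; for counter-directional
#' pairs the meta rule cannot fire.
#'
#' @param disc,rep lists / one-row data.frames with `beta`, `se`,
#'   `pval` for the discovery and replication cohorts.
#' @param meta optional precomputed [ivw_meta()] result; computed from
#'   `disc` and `rep` when NULL and the pair is co-directional.
#' @param thresholds a [significance_thresholds].
#' @param rep_alpha replication significance level (default 0.05,
#'   two-sided).
#' @return object of class `replication_call`: list with `category`,
#'   `codirectional` and the `meta` result used (NULL if none).
#' @export
classify_replication <- function(disc, rep, meta = NULL,
                                 thresholds = significance_thresholds(),
                                 rep_alpha = 0.05) {
  codir <- sign(disc$beta) * sign(rep$beta) >= 0
  if (codir && is.null(meta)) {
    meta <- ivw_meta(c(disc$beta, rep$beta), c(disc$se, rep$se))
  }
  category <- if (codir && !is.null(meta) && meta$pval_meta < thresholds$gws) {
    "meta_significant"
  } else if (disc$pval < thresholds$gws && codir && rep$pval < rep_alpha) {
    "replicated"
  } else if (disc$pval < thresholds$mts) {
    "discovery_only_mts"
  } else {
    "not_supported"
  }
  structure(list(category = category, codirectional = codir,
                 meta = if (codir) meta else NULL),
            class = "replication_call")
}
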