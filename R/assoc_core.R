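#' Significance thresholds
#'
#' Genome-wide significance (GWS) and the stricter multiple-testing
#' significance (MTS) used when several phenotypes are analyzed at once.
#' MTS defaults to `gws / n_phenotypes` (5e-8 / 10 = 5e-9 for ten
#' phenotypes).
#'
#' @param gws genome-wide significance p threshold (default 5e-8).
#' @param n_phenotypes number of phenotypes the MTS correction covers.
#' @param mts multiple-testing threshold; derived from `gws` and
#'   `n_phenotypes` unless given explicitly.
#' @return object of class `significance_thresholds`.
#' @export
significance_thresholds <- function(gws = 5e-8, n_phenotypes = 10L,
                                    mts = gws / n_phenotypes) {
  .assert(mts > 0 && mts <= gws && gws < 1, "need 0 < mts <= gws < 1")
  structure(list(gws = gws, mts = mts, n_phenotypes = as.integer(n_phenotypes)),
            class = "significance_thresholds")
}

#' Single-variant logistic-regression GWAS
#'
#' Plain logistic regression of a binary phenotype on each variant's
#' dosage plus optional covariates, reporting the Wald log-odds
#' estimate, its standard error and the two-sided normal-approximation
#' p-value `2 * pnorm(-|beta/se|)`. Monomorphic variants are skipped
#' with a flag; variants where the fit fails to converge (e.g. perfect
#' separation) are flagged, not fatal.
#'
#' @param genotypes individuals x variants dosage matrix; column names
#'   (if any) are used as rsids.
#' @param phenotype binary 0/1 outcome vector.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param variants optional data.frame (chrom, pos, ref, alt, rsid, af)
#'   describing the columns of `genotypes`; synthesized when absent.
#' @param phenotype_name label stored on the output table.
#' @return a [sumstats] object for the variants that could be tested,
#'   with attribute `flags`: character vector per input variant in
#'   "ok", "monomorphic", "unstable".
#' @export
run_gwas_logistic <- function(genotypes, phenotype, covariates = NULL,
                              variants = NULL, phenotype_name = "pheno") {
  y <- as.integer(phenotype)
  .assert(all(y %in% c(0L, 1L)), "phenotype must be binary 0/1")
  .assert(sum(y) > 0L && sum(1L - y) > 0L,
          "need at least one case and one control")
  .assert(!anyNA(genotypes), "missing genotypes are not supported")
  m <- ncol(genotypes)
  if (is.null(variants)) {
    variants <- data.frame(stringsAsFactors = FALSE,
                           chrom = "1", pos = 10000L * seq_len(m),
                           ref = "A", alt = "G",
                           rsid = colnames(genotypes) %||%
                             sprintf("snp_%d", seq_len(m)))
  }
  X0 <- cbind(`(Intercept)` = rep(1, length(y)), g = 0)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    .assert(nrow(covariates) == length(y), "covariate rows must match phenotype")
    X0 <- cbind(X0, covariates)
  }
  flags <- rep("ok", m)
  beta <- se <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    if (stats::var(g) == 0) {
      flags[j] <- "monomorphic"
      next
    }
    X0[, 2L] <- g
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X0, y, family = stats::binomial())),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      flags[j] <- "unstable"
      next
    }
    # Wald SE from the inverse Fisher information at the fit
    w <- fit$weights
    XtWX <- crossprod(X0 * sqrt(w))
    cov <- tryCatch(solve(XtWX), error = function(e) NULL)
    if (is.null(cov) || cov[2L, 2L] <= 0 || !is.finite(cov[2L, 2L])) {
      flags[j] <- "unstable"
      next
    }
    b <- fit$coefficients[2L]
    s <- sqrt(cov[2L, 2L])
    if (!is.finite(b) || abs(b) > 15) {   # separation-scale estimates
      flags[j] <- "unstable"
      next
    }
    beta[j] <- b
    se[j] <- s
  }
  keep <- flags == "ok"
  af <- colMeans(genotypes[, keep, drop = FALSE]) / 2
  df <- data.frame(stringsAsFactors = FALSE,
                   chrom = variants$chrom[keep], pos = variants$pos[keep],
                   ref = variants$ref[keep], alt = variants$alt[keep],
                   rsid = variants$rsid[keep],
                   af = pmin(pmax(af, 1e-6), 1 - 1e-6),
                   beta = beta[keep], se = se[keep],
                   pval = 2 * stats::pnorm(-abs(beta[keep] / se[keep])))
  out <- sumstats(df, phenotype = phenotype_name,
                  n_cases = sum(y), n_controls = sum(1L - y))
  attr(out, "flags") <- flags
  out
}

#' Genomic inflation factor
#'
#' lambda_GC = median(z^2) / 0.4549364, the median of a 1-df chi-square.
#'
#' @param table a [sumstats] object with at least 100 records.
#' @return the inflation factor.
#' @export
genomic_inflation <- function(table) {
  .assert(nrow(table) >= 100L, "need at least 100 records for lambda_GC")
  z2 <- (table$beta / table$se)^2
  stats::median(z2) / stats::qchisq(0.5, df = 1)
}

#' Per-variant significance flags
#'
#' Classifies each variant as "mts" (p at or below the multiple-testing
#' threshold), "gws" (at or below genome-wide significance but not MTS),
#' or "none". Boundary p-values count as significant.
#'
#' @param table a [sumstats] object.
#' @param thresholds a [significance_thresholds].
#' @return character vector, one flag per record.
#' @export
significance_flags <- function(table, thresholds = significance_thresholds()) {
  ifelse(table$pval <= thresholds$mts, "mts",
         ifelse(table$pval <= thresholds$gws, "gws", "none"))
}

#' Effective sample size of a case-control study
#'
#' Neff = 4 / (1/n_cases + 1/n_controls); equals the total n for a
#' balanced design and shrinks as the design becomes unbalanced.
#'
#' @param n_cases,n_controls positive subject counts.
#' @return effective sample size.
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  .assert(all(n_cases > 0) && all(n_controls > 0), "counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Effective-sample-size ratio of two designs
#'
#' @param design_a,design_b each a length-2 vector `c(n_cases,
#'   n_controls)` or an [overlap_design] with one phenotype.
#' @return `100 * Neff_b / Neff_a`, in percent.
#' @export
ess_ratio <- function(design_a, design_b) {
  counts <- function(d) {
    if (inherits(d, "overlap_design")) c(d$n_cases[1L], d$n_shared_controls) else d
  }
  a <- counts(design_a); b <- counts(design_b)
  100 * effective_sample_size(b[1L], b[2L]) / effective_sample_size(a[1L], a[2L])
}

#' Power of a two-sided Wald replication test
#'
#' power = Phi(|beta|/se - z_{alpha/2}) + Phi(-|beta|/se - z_{alpha/2}).
#'
#' @param beta_true assumed true log-odds effect.
#' @param se_replication standard error in the replication cohort.
#' @param alpha two-sided significance level (default 0.05).
#' @return power in [0, 1].
#' @export
replication_power <- function(beta_true, se_replication, alpha = 0.05) {
  .assert(all(se_replication > 0), "se must be positive")
  zcrit <- stats::qnorm(1 - alpha / 2)
  zeff <- abs(beta_true) / se_replication
  stats::pnorm(zeff - zcrit) + stats::pnorm(-zeff - zcrit)
}

#' Replication SE implied by effective-sample-size scaling
#'
#' When no replication-cohort SE is available, the discovery SE is
#' scaled by sqrt(Neff_discovery / Neff_replication) — the standard
#' summary-level approximation (SE is inversely proportional to the
#' square root of the effective sample size).
#'
#' @param se_discovery discovery standard error.
#' @param neff_discovery,neff_replication effective sample sizes.
#' @return projected replication standard error.
#' @export
replication_se <- function(se_discovery, neff_discovery, neff_replication) {
  .assert(all(neff_discovery > 0) && all(neff_replication > 0),
          "effective sample sizes must be positive")
  se_discovery * sqrt(neff_discovery / neff_replication)
}
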