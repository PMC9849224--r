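#' Simulation configuration for LD-blocked genotypes
#'
#' Genotypes are simulated as independent LD blocks. Within a block,
#' haplotypes come from a latent Gaussian AR(1) process with adjacent
#' correlation `rho`, thresholded at each variant's allele-frequency
#' quantile; two haplotypes are summed per individual, giving 0/1/2
#' dosages with a controllable r2 decay along the block.
#'
#' @param n_individuals number of individuals.
#' @param n_blocks number of independent LD blocks.
#' @param block_size variants per block.
#' @param rho latent adjacent-variant correlation in [0, 1).
#' @param maf_range (low, high) range of simulated allele frequencies,
#'   within (0, 0.5].
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_blocks = 1L, block_size = 10L,
                       rho = 0.5, maf_range = c(0.05, 0.5), seed = 1L) {
  .assert(n_individuals >= 1 && n_blocks >= 1 && block_size >= 1,
          "counts must be >= 1")
  .assert(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  .assert(length(maf_range) == 2L && maf_range[1] > 0 &&
            maf_range[1] <= maf_range[2] && maf_range[2] <= 0.5,
          "maf_range must satisfy 0 < low <= high <= 0.5")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 rho = rho, maf_range = maf_range, seed = as.integer(seed)),
            class = "sim_config")
}

#' Cross-phenotype causal-effect configuration
#'
#' Describes the true effect structure of a set of causal variants
#' across K phenotypes: `null` (no effect anywhere), `fixed` (one
#' identical log-odds effect for every active phenotype), `correlated`
#' (similar but not identical effects, drawn per variant from a
#' multivariate normal centred at `beta_mean` with correlation `corr`
#' and standard deviation `beta_sd`), `single` (effect on exactly one
#' phenotype), or `subset` (a fixed effect restricted to a declared
#' subset of phenotypes).
#'
#' @param model one of "null", "fixed", "correlated", "single", "subset".
#' @param active_set integer indices of phenotypes with a nonzero effect.
#' @param beta_mean log-odds effect magnitude.
#' @param corr effect correlation for the correlated model, in (-1, 1).
#' @param beta_sd effect SD around `beta_mean` for the correlated model;
#'   defaults to `beta_mean / 4` (similar, not identical, effects).
#' @param causal_variants integer variant indices carrying the effect.
#' @return object of class `effect_config`.
#' @export
effect_config <- function(model = c("null", "fixed", "correlated", "single", "subset"),
                          active_set = integer(0), beta_mean = 0.25,
                          corr = 0.9, beta_sd = beta_mean / 4,
                          causal_variants = integer(0)) {
  model <- match.arg(model)
  active_set <- as.integer(active_set)
  if (model == "null") {
    .assert(length(active_set) == 0L, "null model must have an empty active_set")
  } else {
    .assert(length(active_set) >= 1L, "%s model needs a non-empty active_set", model)
  }
  if (model == "single") {
    .assert(length(active_set) == 1L, "single model needs exactly one active phenotype")
  }
  if (model == "correlated") {
    .assert(corr > -1 && corr < 1, "corr must be in (-1, 1)")
  }
  structure(list(model = model, active_set = active_set,
                 beta_mean = beta_mean, corr = corr, beta_sd = beta_sd,
                 causal_variants = as.integer(causal_variants)),
            class = "effect_config")
}

# True per-variant x per-phenotype effect matrix implied by a list of
# effect configurations. Correlated draws consume the current RNG stream.
.effects_to_beta <- function(effects, n_variants, n_phenotypes) {
  if (inherits(effects, "effect_config")) effects <- list(effects)
  B <- matrix(0, n_variants, n_phenotypes)
  for (cfg in effects) {
    if (cfg$model == "null" || length(cfg$causal_variants) == 0L) next
    .assert(all(cfg$causal_variants >= 1L & cfg$causal_variants <= n_variants),
            "causal_variants out of range")
    .assert(all(cfg$active_set <= n_phenotypes), "active_set out of range")
    for (v in cfg$causal_variants) {
      if (cfg$model == "correlated") {
        k <- length(cfg$active_set)
        R <- matrix(cfg$corr, k, k); diag(R) <- 1
        L <- chol(R)
        draw <- cfg$beta_mean + cfg$beta_sd * drop(stats::rnorm(k) %*% L)
        B[v, cfg$active_set] <- draw
      } else {
        B[v, cfg$active_set] <- cfg$beta_mean
      }
    }
  }
  B
}

#' Overlapping-control study design
#'
#' Case counts per phenotype together with the size of the single
#' control pool shared by every phenotype's GWAS, mirroring a biobank
#' design in which all case sets are compared against the same controls.
#' Optionally carries the K x K correlation matrix of effect estimates
#' under the null induced by the overlap.
#'
#' @param phenotypes character phenotype identifiers.
#' @param n_cases integer case counts, one per phenotype.
#' @param n_shared_controls size of the shared control pool.
#' @param est_corr optional K x K estimate-correlation matrix (symmetric,
#'   unit diagonal, positive semi-definite).
#' @return object of class `overlap_design`.
#' @export
overlap_design <- function(phenotypes, n_cases, n_shared_controls,
                           est_corr = NULL) {
  K <- length(phenotypes)
  .assert(length(n_cases) == K, "n_cases must match phenotypes")
  .assert(all(n_cases >= 1) && n_shared_controls >= 1, "counts must be >= 1")
  if (!is.null(est_corr)) {
    .assert(is.matrix(est_corr) && nrow(est_corr) == K && ncol(est_corr) == K,
            "est_corr must be K x K")
    .assert(max(abs(est_corr - t(est_corr))) < 1e-8, "est_corr must be symmetric")
    .assert(max(abs(diag(est_corr) - 1)) < 1e-8, "est_corr must have unit diagonal")
    .assert(min(eigen(est_corr, symmetric = TRUE, only.values = TRUE)$values) > -1e-8,
            "est_corr must be positive semi-definite")
  }
  structure(list(phenotypes = as.character(phenotypes),
                 n_cases = as.integer(n_cases),
                 n_shared_controls = as.integer(n_shared_controls),
                 est_corr = est_corr),
            class = "overlap_design")
}

#' Analytic estimate correlation for a shared-control design
#'
#' Large-sample approximation to the correlation between two phenotypes'
#' log-odds estimates at a null variant when the case sets are disjoint
#' but every analysis uses the same control pool of size n0: the shared
#' controls contribute the 1/n0 term to both scores, giving
#' corr = (1/n0) / sqrt((1/nc_k + 1/n0)(1/nc_l + 1/n0)).
#'
#' @param design an [overlap_design].
#' @return K x K correlation matrix.
#' @export
overlap_correlation_design <- function(design) {
  .assert(inherits(design, "overlap_design"), "design must be an overlap_design")
  nc <- design$n_cases
  n0 <- design$n_shared_controls
  v <- 1 / nc + 1 / n0
  R <- (1 / n0) / sqrt(outer(v, v))
  diag(R) <- 1
  dimnames(R) <- list(design$phenotypes, design$phenotypes)
  R
}

#' Simulate LD-blocked genotypes
#'
#' @param config a [sim_config].
#' @return list with `genotypes` (individuals x variants dosage matrix)
#'   and `variants` (data.frame: chrom, pos, ref, alt, rsid, maf, block).
#'   Blocks are placed on separate chromosome labels; variants are 10 kb
#'   apart within a block. Fully reproducible from `config$seed`.
#' @export
simulate_genotypes <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  n <- config$n_individuals
  m <- config$block_size
  rho <- config$rho
  blocks <- vector("list", config$n_blocks)
  meta <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    thr <- stats::qnorm(maf)
    # two latent AR(1) haplotypes per individual
    haps <- matrix(0L, 2L * n, m)
    z <- stats::rnorm(2L * n)
    haps[, 1L] <- (z < thr[1L])
    for (j in seq_len(m)[-1L]) {
      z <- rho * z + sqrt(1 - rho^2) * stats::rnorm(2L * n)
      haps[, j] <- (z < thr[j])
    }
    blocks[[b]] <- haps[seq_len(n), , drop = FALSE] +
      haps[n + seq_len(n), , drop = FALSE]
    meta[[b]] <- data.frame(stringsAsFactors = FALSE,
                            chrom = as.character(b),
                            pos = 10000L * seq_len(m),
                            ref = "A", alt = "G",
                            rsid = sprintf("var_%d_%d", b, seq_len(m)),
                            maf = maf, block = b)
  }
  G <- do.call(cbind, blocks)
  variants <- do.call(rbind, meta)
  colnames(G) <- variants$rsid
  list(genotypes = G, variants = variants)
}

#' Simulate multi-phenotype binary outcomes with shared controls
#'
#' Each phenotype is drawn from its own logistic model on the genotype
#' dosages; the shared control pool is the set of individuals with no
#' phenotype at all, mirroring a design where every case set is analyzed
#' against the same controls.
#'
#' @param genotypes individuals x variants dosage matrix.
#' @param effects an [effect_config] or list of them (per-variant truth).
#' @param intercepts per-phenotype baseline log-odds (length K).
#' @param seed integer RNG seed.
#' @param phenotypes optional phenotype names (default P1..PK).
#' @return list with `outcomes` (individuals x K 0/1 matrix), `design`
#'   (an [overlap_design] with realized counts), and `beta` (the true
#'   variants x K effect matrix actually used).
#' @export
simulate_phenotypes <- function(genotypes, effects, intercepts, seed = 1L,
                                phenotypes = NULL) {
  K <- length(intercepts)
  phenotypes <- phenotypes %||% paste0("P", seq_len(K))
  set.seed(seed)
  B <- .effects_to_beta(effects, ncol(genotypes), K)
  eta <- sweep(genotypes %*% B, 2L, intercepts, "+")
  p <- 1 / (1 + exp(-eta))
  Y <- matrix(stats::rbinom(length(p), 1L, p), nrow(p), K,
              dimnames = list(NULL, phenotypes))
  n_cases <- colSums(Y)
  n_shared <- sum(rowSums(Y) == 0L)
  if (any(n_cases == 0L) || any(n_cases == nrow(Y)) || n_shared == 0L) {
    .stopf("degenerate design: a phenotype has zero cases or zero controls")
  }
  list(outcomes = Y,
       design = overlap_design(phenotypes, n_cases, n_shared),
       beta = B)
}

#' Simulate summary statistics directly from an overlap design
#'
#' Fast path that skips individual-level data: per variant, the K-vector
#' of effect estimates is drawn from a multivariate normal centred at
#' the true effect vector with covariance D R D, where R is the design's
#' null estimate-correlation matrix and D = diag(se). Used for
#' classifier calibration and anywhere LD is irrelevant.
#'
#' @param design an [overlap_design]; `est_corr` is used if supplied,
#'   otherwise derived with [overlap_correlation_design()].
#' @param effects an [effect_config] or list of them.
#' @param n_variants number of variants to simulate.
#' @param se_scale standard error, a scalar or length-K vector.
#' @param seed integer RNG seed.
#' @return named list of [sumstats] tables, one per phenotype. Variants
#'   are placed on chromosome 1, 10 kb apart, alleles A/G.
#' @export
simulate_sumstats_direct <- function(design, effects, n_variants,
                                     se_scale = 0.02, seed = 1L) {
  .assert(inherits(design, "overlap_design"), "design must be an overlap_design")
  K <- length(design$phenotypes)
  R <- design$est_corr %||% overlap_correlation_design(design)
  .assert(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) > -1e-8,
          "est_corr must be positive semi-definite")
  se <- rep_len(se_scale, K)
  set.seed(seed)
  B <- .effects_to_beta(effects, n_variants, K)
  L <- chol(R + diag(1e-12, K))
  Z <- matrix(stats::rnorm(n_variants * K), n_variants, K) %*% L
  est <- B + sweep(Z, 2L, se, "*")
  af <- stats::runif(n_variants, 0.05, 0.5)
  out <- vector("list", K)
  names(out) <- design$phenotypes
  for (k in seq_len(K)) {
    df <- data.frame(stringsAsFactors = FALSE,
                     chrom = "1", pos = 10000L * seq_len(n_variants),
                     ref = "A", alt = "G",
                     rsid = sprintf("snp_%d", seq_len(n_variants)),
                     af = af, beta = est[, k], se = se[k],
                     pval = 2 * stats::pnorm(-abs(est[, k] / se[k])))
    out[[k]] <- sumstats(df, phenotype = design$phenotypes[k],
                         n_cases = design$n_cases[k],
                         n_controls = design$n_shared_controls)
  }
  out
}

#' Build a pair of credible sets with prescribed shared / unique PIPs
#'
#' Fixture generator for colocalization metrics: constructs two credible
#' sets that overlap on `length(shared_pips_a)` variants with the given
#' posterior inclusion probabilities, plus optional variants unique to
#' each set.
#'
#' @param shared_pips_a,shared_pips_b PIPs of the shared variants in set
#'   A and B respectively (same length, pairing by position).
#' @param unique_pips_a,unique_pips_b PIPs of the variants unique to A / B.
#' @param locus_id locus identifier used for both sets.
#' @return list of two [credible_set] objects (`a`, `b`).
#' @export
make_credible_set_pair <- function(shared_pips_a, shared_pips_b,
                                   unique_pips_a = numeric(0),
                                   unique_pips_b = numeric(0),
                                   locus_id = "locus1") {
  .assert(length(shared_pips_a) == length(shared_pips_b),
          "shared PIP vectors must have equal length")
  all_pips <- c(shared_pips_a, shared_pips_b, unique_pips_a, unique_pips_b)
  .assert(all(all_pips >= 0), "negative PIP")
  .assert(sum(shared_pips_a) + sum(unique_pips_a) <= 1 + 1e-9 &&
            sum(shared_pips_b) + sum(unique_pips_b) <= 1 + 1e-9,
          "PIPs of a credible set must sum to at most 1")
  ns <- length(shared_pips_a)
  mk_vars <- function(pos) data.frame(stringsAsFactors = FALSE,
                                      chrom = rep("1", length(pos)), pos = pos,
                                      ref = rep("A", length(pos)),
                                      alt = rep("G", length(pos)))
  shared <- mk_vars(1000L * seq_len(ns))
  ua <- mk_vars(100000L + 1000L * seq_along(unique_pips_a))
  ub <- mk_vars(200000L + 1000L * seq_along(unique_pips_b))
  a <- new_credible_set(rbind(shared, ua), c(shared_pips_a, unique_pips_a),
                        locus_id = locus_id, cs_id = "a")
  b <- new_credible_set(rbind(shared, ub), c(shared_pips_b, unique_pips_b),
                        locus_id = locus_id, cs_id = "b")
  list(a = a, b = b)
}

#' Simulate summary statistics under the LD score regression model
#'
#' Draws per-variant z-scores for one or two traits directly from the
#' polygenic model underlying LD score regression:
#' E\[chi2_j\] = 1 + N h2 l_j / M and, for two traits,
#' E\[z_aj z_bj\] = sqrt(Na Nb) rg sqrt(h2_a h2_b) l_j / M plus a
#' constant `overlap_intercept` absorbing sample overlap.
#'
#' @param n_variants number of variants M' actually simulated.
#' @param h2_a,h2_b SNP heritabilities (observed scale).
#' @param rg genetic correlation between the traits (ignored if `h2_b`
#'   is NULL, in which case only one table is returned).
#' @param n_eff_a,n_eff_b effective sample sizes.
#' @param ld_scores optional per-variant LD scores; by default drawn as
#'   1 + Gamma(shape 2, scale 1), giving realistic spread.
#' @param m_total total variant count M for scaling (default
#'   `n_variants`).
#' @param overlap_intercept constant added to the cross-trait z product
#'   expectation (0 for independent cohorts).
#' @param seed integer RNG seed.
#' @return list with `table_a`, `table_b` (NULL for one trait), and
#'   `scores` (an [ld_score_set]).
#' @export
simulate_ldsc_sumstats <- function(n_variants, h2_a, n_eff_a, h2_b = NULL,
                                   rg = NULL, n_eff_b = NULL,
                                   ld_scores = NULL, m_total = n_variants,
                                   overlap_intercept = 0, seed = 1L) {
  set.seed(seed)
  l <- ld_scores %||% (1 + stats::rgamma(n_variants, shape = 2, scale = 1))
  .assert(length(l) == n_variants, "ld_scores must have length n_variants")
  v_a <- 1 + n_eff_a * h2_a * l / m_total
  mk_table <- function(z, pheno) {
    df <- data.frame(stringsAsFactors = FALSE,
                     chrom = "1", pos = 10000L * seq_len(n_variants),
                     ref = "A", alt = "G",
                     rsid = sprintf("snp_%d", seq_len(n_variants)),
                     af = stats::runif(n_variants, 0.05, 0.5),
                     beta = z, se = 1,
                     pval = 2 * stats::pnorm(-abs(z)))
    sumstats(df, phenotype = pheno)
  }
  if (is.null(h2_b)) {
    z_a <- stats::rnorm(n_variants, sd = sqrt(v_a))
    return(list(table_a = mk_table(z_a, "trait_a"), table_b = NULL,
                scores = ld_score_set(l, m_total)))
  }
  v_b <- 1 + n_eff_b * h2_b * l / m_total
  cv <- sqrt(n_eff_a * n_eff_b) * rg * sqrt(h2_a * h2_b) * l / m_total +
    overlap_intercept
  .assert(all(cv^2 < v_a * v_b), "cross-trait covariance exceeds trait variances")
  e1 <- stats::rnorm(n_variants)
  e2 <- stats::rnorm(n_variants)
  z_a <- sqrt(v_a) * e1
  z_b <- (cv / sqrt(v_a)) * e1 + sqrt(v_b - cv^2 / v_a) * e2
  list(table_a = mk_table(z_a, "trait_a"), table_b = mk_table(z_b, "trait_b"),
       scores = ld_score_set(l, m_total))
}
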