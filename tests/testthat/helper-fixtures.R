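# Shared fixture builders and independent oracles used across test files.

# Summary-statistics table with Wald-consistent p-values (se defaults to 1
# so beta doubles as the z-score).
make_table <- function(chrom = "1", pos, ref = "A", alt = "G", beta, se = 1,
                       af = 0.3, phenotype = "pheno", rsid = NULL,
                       n_cases = NA, n_controls = NA) {
  n <- length(pos)
  df <- data.frame(stringsAsFactors = FALSE,
                   chrom = rep_len(chrom, n), pos = pos,
                   ref = rep_len(ref, n), alt = rep_len(alt, n),
                   af = rep_len(af, n), beta = rep_len(beta, n),
                   se = rep_len(se, n))
  df$pval <- 2 * pnorm(-abs(df$beta / df$se))
  if (!is.null(rsid)) df$rsid <- rsid
  sumstats(df, phenotype = phenotype, n_cases = n_cases,
           n_controls = n_controls)
}

# Random valid summary-statistics table for round-trip properties.
rand_table <- function(n, seed) {
  set.seed(seed)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), character(1))
  beta <- rnorm(n, sd = 0.3)
  se <- runif(n, 0.01, 0.2)
  df <- data.frame(stringsAsFactors = FALSE,
                   chrom = sample(c("1", "2", "X"), n, replace = TRUE),
                   pos = sample.int(1e8, n), ref = ref, alt = alt,
                   rsid = sprintf("rs%d", seq_len(n)),
                   af = runif(n, 0.01, 0.99), beta = beta, se = se,
                   pval = 2 * pnorm(-abs(beta / se)))
  df <- df[!duplicated(variant_id(df$chrom, df$pos, df$ref, df$alt)), ]
  sumstats(df, phenotype = "rand")
}

# Independent brute-force clumping oracle: literal transcription of the
# grouping rule with plain loops, no shared code with clump_loci().
oracle_clump <- function(df, r2m, gws = 5e-8, dist = 2e6, r2min = 0.1) {
  un <- df$pval <= gws
  groups <- list()
  while (any(un)) {
    idx <- which(un)
    lead <- idx[order(df$pval[idx], df$chrom[idx], df$pos[idx])][1L]
    mem <- lead
    for (j in idx) {
      if (j != lead && df$chrom[j] == df$chrom[lead] &&
          abs(df$pos[j] - df$pos[lead]) < dist &&
          r2m[lead, j] > r2min) {
        mem <- c(mem, j)
      }
    }
    un[mem] <- FALSE
    groups[[length(groups) + 1L]] <- sort(mem)
  }
  groups
}

# Random clumping instance: GWS variants on 1-2 chromosomes with a random
# sparse symmetric r2 matrix.
rand_clump_instance <- function(seed, max_n = 50L) {
  set.seed(seed)
  n <- sample(2:max_n, 1L)
  df <- data.frame(stringsAsFactors = FALSE,
                   chrom = as.character(sample(1:2, n, replace = TRUE)),
                   pos = sample.int(6e6, n),
                   ref = "A", alt = "G",
                   beta = -qnorm(10^-runif(n, 7.5, 12) / 2), se = 1)
  df$pval <- 2 * pnorm(-abs(df$beta / df$se))
  df <- df[!duplicated(paste(df$chrom, df$pos)), ]
  n <- nrow(df)
  r2m <- matrix(0, n, n)
  r2m[upper.tri(r2m)] <- runif(n * (n - 1) / 2) *
    rbinom(n * (n - 1) / 2, 1L, 0.4)
  r2m <- r2m + t(r2m)
  diag(r2m) <- 1
  ids <- variant_id(df$chrom, df$pos, df$ref, df$alt)
  dimnames(r2m) <- list(ids, ids)
  list(df = df, r2m = r2m, ids = ids)
}

# Canonical partition representation: member-id sets sorted internally and
# the list ordered by each set's first id, so partitions compare as sets.
canonical_partition <- function(sets) {
  parts <- lapply(sets, sort)
  parts[order(vapply(parts, `[`, character(1), 1L))]
}

partition_of <- function(loci) {
  canonical_partition(lapply(loci, function(l) l$members$id))
}

# Random credible-set pair for colocalization properties.
rand_cs_pair <- function(seed) {
  set.seed(seed)
  n_shared <- sample(0:6, 1L)
  n_ua <- sample(0:4, 1L)
  n_ub <- sample(0:4, 1L)
  raw <- function(k, total) {
    if (k == 0L) return(numeric(0))
    p <- runif(k)
    p / sum(p) * total
  }
  ta <- runif(1, 0.2, 1); tb <- runif(1, 0.2, 1)
  wa <- raw(n_shared + n_ua, ta)
  wb <- raw(n_shared + n_ub, tb)
  make_credible_set_pair(
    shared_pips_a = utils::head(wa, n_shared),
    shared_pips_b = utils::head(wb, n_shared),
    unique_pips_a = wa[n_shared + seq_len(n_ua)],
    unique_pips_b = wb[n_shared + seq_len(n_ub)])
}

# Hand-rolled multivariate-normal log density (Cholesky), independent of
# the implementation's density routine.
oracle_dmvnorm_log <- function(x, sigma) {
  L <- chol(sigma)
  q <- backsolve(L, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(q^2)
}

# Posterior over a model space computed from first principles with the
# oracle density.
oracle_posteriors <- function(betas, ses, overlap_corr, space, tau, r_corr) {
  K <- length(betas)
  V <- diag(ses, K) %*% overlap_corr %*% diag(ses, K)
  ll <- vapply(seq_len(nrow(space)), function(m) {
    act <- space$active[[m]]
    S <- matrix(0, K, K)
    if (length(act)) {
      r <- switch(space$kind[m], fixed = 1, subset_fixed = 1,
                  correlated = r_corr, single = 1)
      blk <- matrix(r * tau^2, length(act), length(act))
      diag(blk) <- tau^2
      S[act, act] <- blk
    }
    oracle_dmvnorm_log(betas, V + S)
  }, numeric(1))
  w <- log(space$prior_weight) + ll
  w <- w - max(w)
  setNames(exp(w) / sum(exp(w)), space$name)
}
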