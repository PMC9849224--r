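z_of_p <- function(p) -qnorm(p / 2)

test_that("clumping applies the distance AND r2 rule around the best lead", {
  tab <- make_table(pos = c(1.0e6, 1.5e6, 4.0e6),
                    beta = z_of_p(c(1e-10, 1e-9, 1e-8)))
  ids <- variant_id(tab$chrom, tab$pos, tab$ref, tab$alt)
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.5
  dimnames(r2) <- list(ids, ids)
  loci <- clump_loci(tab, r2)
  expect_length(loci, 2L)
  expect_equal(nrow(loci[[1]]$members), 2L)
  expect_equal(loci[[1]]$lead$pos, 1.0e6)
  expect_equal(loci[[2]]$lead$pos, 4.0e6)
  expect_equal(loci[[1]]$lead_pval, min(tab$pval))

  # single GWS variant: one singleton locus
  one <- clump_loci(make_table(pos = 5e6, beta = z_of_p(1e-9)), NULL)
  expect_length(one, 1L)
  expect_equal(nrow(one[[1]]$members), 1L)

  # strong LD but 3 Mb apart: the conjunction keeps them separate
  far <- make_table(pos = c(1e6, 4e6), beta = z_of_p(c(1e-10, 1e-9)))
  fids <- variant_id(far$chrom, far$pos, far$ref, far$alt)
  fr2 <- matrix(0.9, 2, 2); diag(fr2) <- 1; dimnames(fr2) <- list(fids, fids)
  expect_length(clump_loci(far, fr2), 2L)

  # sub-threshold variants never enter a locus
  mix <- make_table(pos = c(1e6, 1.1e6), beta = z_of_p(c(1e-10, 1e-6)))
  expect_length(clump_loci(mix, NULL), 1L)
  expect_equal(nrow(clump_loci(mix, NULL)[[1]]$members), 1L)
})

test_that("clumping agrees with the brute-force oracle on random instances", {
  for (seed in 1:25) {
    inst <- rand_clump_instance(seed)
    tab <- sumstats(inst$df)
    loci <- clump_loci(tab, inst$r2m)
    expect_identical(partition_of(loci),
                     canonical_partition(
                       lapply(oracle_clump(inst$df, inst$r2m), function(m)
                         inst$ids[m])),
                     info = sprintf("instance seed %d", seed))
    # every GWS variant in exactly one locus
    all_members <- unlist(lapply(loci, function(l) l$members$id))
    expect_setequal(all_members, inst$ids)
    expect_false(anyDuplicated(all_members) > 0)
    # a later (higher-p) lead is never assignable to an earlier lead,
    # else the greedy pass would have absorbed it
    leads <- do.call(rbind, lapply(loci, `[[`, "lead"))
    if (nrow(leads) > 1L) {
      for (i in seq_len(nrow(leads) - 1L)) {
        for (j in (i + 1L):nrow(leads)) {
          expect_false(leads$chrom[i] == leads$chrom[j] &&
                         abs(leads$pos[i] - leads$pos[j]) < 2e6 &&
                         inst$r2m[leads$id[i], leads$id[j]] > 0.1)
        }
      }
    }
  }
})

test_that("missing LD entries follow the configured policy", {
  tab <- make_table(pos = c(1e6, 1.2e6), beta = z_of_p(c(1e-10, 1e-9)))
  expect_length(clump_loci(tab, NULL, missing_ld = "zero"), 2L)
  expect_error(clump_loci(tab, NULL, missing_ld = "error"), "LD")
})

test_that("the effect matrix merges same-locus leads and fills every cell", {
  mk <- function(beta, pheno) {
    make_table(pos = c(1.0e6, 1.001e6, 8.0e6), beta = beta, se = 0.05,
               phenotype = pheno,
               rsid = c("rs_a", "rs_b", "rs_c"))
  }
  # P1's lead at 1.0 Mb (stronger), P2's at 1.001 Mb; r2 0.95 between them
  t1 <- mk(c(0.40, 0.30, 0.35), "P1")
  t2 <- mk(c(0.30, 0.38, 0.34), "P2")
  ids <- variant_id(t1$chrom, t1$pos, t1$ref, t1$alt)
  r2 <- diag(3); r2[1, 2] <- r2[2, 1] <- 0.95
  dimnames(r2) <- list(ids, ids)
  loci <- list(P1 = clump_loci(t1, r2), P2 = clump_loci(t2, r2))
  em <- build_effect_matrix(loci, list(P1 = t1, P2 = t2), ld = r2)
  # leads rs_a (P1) and rs_b (P2) merge into one row; rs_c rows merge too
  expect_equal(nrow(em$beta), 2L)
  expect_equal(ncol(em$beta), 2L)
  expect_false(any(em$missing))
  merged <- em$leads$rsid
  expect_true("rs_a" %in% merged)       # lower-p representative wins
  expect_false("rs_b" %in% merged)
  # cells are the per-phenotype estimates of the representative lead
  expect_equal(em$beta["rs_a", "P1"], 0.40)
  expect_equal(em$beta["rs_a", "P2"], 0.30)

  # a lead absent from one phenotype's table is flagged and imputed
  t2_short <- sumstats(as.data.frame(t2)[-1, ], phenotype = "P2")
  em2 <- build_effect_matrix(list(P1 = clump_loci(t1, r2)),
                             list(P1 = t1, P2 = t2_short))
  expect_true(em2$missing["rs_a", "P2"])
  expect_equal(em2$beta["rs_a", "P2"], 0)
  expect_equal(em2$pval["rs_a", "P2"], 1)
})

test_that("effect-matrix clustering is deterministic and permutation-invariant", {
  set.seed(81L)
  # two obvious blocks: rows 1-3 load on P1/P2, rows 4-6 on P3/P4
  B <- rbind(matrix(c(0.4, 0.4, 0.02, 0.02), 3, 4, byrow = TRUE),
             matrix(c(0.02, 0.02, 0.4, 0.4), 3, 4, byrow = TRUE)) +
    matrix(rnorm(24, sd = 0.01), 6, 4)
  em <- list(beta = B, se = matrix(0.05, 6, 4),
             pval = matrix(0.5, 6, 4), missing = matrix(FALSE, 6, 4),
             phenotypes = paste0("P", 1:4))
  rownames(em$beta) <- rownames(em$se) <- paste0("L", 1:6)
  cl <- cluster_effect_matrix(em)
  top_split <- cutree(cl$row_hclust, k = 2)
  expect_length(unique(top_split[1:3]), 1L)
  expect_length(unique(top_split[4:6]), 1L)
  expect_false(top_split[1] == top_split[4])
  col_split <- cutree(cl$col_hclust, k = 2)
  expect_false(col_split[1] == col_split[3])

  # identical rows merge first (zero distance)
  em2 <- em
  em2$beta[2, ] <- em2$beta[1, ]
  cl2 <- cluster_effect_matrix(em2)
  first_merge <- cl2$row_hclust$merge[1, ]
  expect_setequal(abs(first_merge), c(1, 2))

  # permuting the rows permutes, but does not change, the partition
  perm <- c(4, 1, 6, 2, 5, 3)
  em3 <- em
  em3$beta <- em$beta[perm, ]; em3$se <- em$se[perm, ]
  cl3 <- cluster_effect_matrix(em3)
  for (k in 2:4) {
    p_orig <- cutree(cl$row_hclust, k = k)
    p_perm <- cutree(cl3$row_hclust, k = k)[order(perm)]
    # same partition up to label renaming
    expect_equal(length(unique(paste(p_orig, p_perm))),
                 length(unique(p_orig)))
  }

  # degenerate matrices fall back to identity ordering
  em1 <- lapply(em, function(x) if (is.matrix(x)) x[1, , drop = FALSE] else x)
  cl1 <- cluster_effect_matrix(em1)
  expect_equal(cl1$row_order, 1L)
})

test_that("co-directionality counting applies the Bonferroni sign rule", {
  # default threshold for a 24 x 8 matrix is 0.05/192
  em <- list(beta = matrix(0.1, 24, 8), se = matrix(0.02, 24, 8),
             pval = matrix(1, 24, 8), missing = matrix(FALSE, 24, 8),
             phenotypes = paste0("P", 1:8),
             leads = data.frame(home = rep("P1", 24)))
  cc <- count_codirectional(em)
  expect_equal(cc$alpha_bonf, 0.05 / 192)
  expect_equal(round(cc$alpha_bonf, 5), 0.00026)
  expect_equal(cc$count, 0L)    # all off-home p = 1

  # a significant co-directional cell counts the locus once
  em$pval[3, 4] <- 1e-9
  expect_equal(count_codirectional(em)$count, 1L)

  # opposite signs never count, however significant
  em2 <- list(beta = matrix(c(0.3, -0.3, 0.2, 0.2), 2, 2),
              se = matrix(0.02, 2, 2),
              pval = matrix(1e-9, 2, 2), missing = matrix(FALSE, 2, 2),
              phenotypes = c("P1", "P2"),
              leads = data.frame(home = c("P1", "P1")))
  cc2 <- count_codirectional(em2, alpha_bonf = 0.05)
  expect_equal(cc2$codirectional, c(TRUE, FALSE))
})
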