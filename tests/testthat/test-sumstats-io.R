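test_that("summary-statistics tables round-trip through TSV files", {
  tab <- make_table(pos = c(100L, 200L, 300L), beta = c(0.1, -0.2, 0.05),
                    se = c(0.02, 0.05, 0.01), af = c(0.1, 0.5, 0.9))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path)
  back <- read_sumstats(path, phenotype = "pheno")
  expect_equal(nrow(back), 3L)
  expect_equal(back$pos, tab$pos)
  expect_equal(back$beta, tab$beta, tolerance = 1e-6)
  expect_equal(back$pval, tab$pval, tolerance = 1e-6)

  # identical writes are byte-identical
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, path2)
  expect_identical(readLines(path), readLines(path2))

  # arbitrary valid tables round-trip at the declared precision
  for (seed in 1:5) {
    t0 <- rand_table(40L, seed)
    p <- withr::local_tempfile(fileext = ".tsv")
    write_sumstats(t0, p)
    t1 <- read_sumstats(p)
    expect_equal(t1$beta, t0$beta, tolerance = 1e-5)
    expect_equal(t1$se, t0$se, tolerance = 1e-5)
    expect_equal(variant_id(t1$chrom, t1$pos, t1$ref, t1$alt),
                 variant_id(t0$chrom, t0$pos, t0$ref, t0$alt))
  }

  # empty table gives a header-only file
  empty <- make_table(pos = integer(0), beta = numeric(0), se = numeric(0))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(empty, p)
  expect_length(readLines(p), 1L)
})

test_that("validation rejects malformed records with informative errors", {
  base <- data.frame(chrom = "1", pos = 100L, ref = "A", alt = "G",
                     beta = 0.1, se = 0.05, pval = 0.0455)
  expect_error(sumstats(transform(base, se = 0)), "se")
  expect_error(sumstats(transform(base, pval = 0)), "pval")
  expect_error(sumstats(transform(base, alt = "A")), "allele")
  expect_error(sumstats(transform(base, pos = 0L)), "position")
  expect_error(sumstats(rbind(base, base)), "duplicate")
  expect_error(sumstats(base[, setdiff(names(base), "beta")]), "beta")
  # p-value flatly inconsistent with |beta/se|
  expect_error(sumstats(transform(base, pval = 1e-8)), "pval")
})

test_that("the FinnGen header dialect parses and errors name missing columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#chrom\tpos\tref\talt\taf_alt\tbeta\tsebeta\tpval\trsids",
               "1\t100\tA\tG\t0.3\t0.1\t0.05\t0.0455\trs1",
               "chr2\t200\tC\tT\t0.2\t-0.2\t0.1\t0.0455\trs2"),
             path)
  tab <- read_sumstats(path, dialect = "finngen")
  expect_equal(tab$chrom, c("1", "2"))  # "chr" prefix stripped
  expect_equal(tab$rsid, c("rs1", "rs2"))
  expect_equal(tab$af, c(0.3, 0.2))

  # same file under the generic dialect lacks its columns
  expect_error(read_sumstats(path, dialect = "generic"), "beta|se")
  # non-numeric effect reported with its line number
  writeLines(c("#chrom\tpos\tref\talt\taf_alt\tbeta\tsebeta\tpval",
               "1\t100\tA\tG\t0.3\tnot_a_number\t0.05\t0.05"), path)
  expect_error(read_sumstats(path), "line")
})

test_that("allele harmonization finds matches in all orientations", {
  a <- make_table(pos = c(100L, 200L, 300L, 400L, 500L),
                  ref = c("A", "A", "A", "A", "A"),
                  alt = c("G", "G", "G", "T", "G"),
                  beta = c(0.1, 0.1, 0.1, 0.1, 0.1), se = 0.05,
                  af = c(0.3, 0.3, 0.3, 0.3, 0.3))
  b <- make_table(pos = c(100L, 200L, 300L, 400L, 900L),
                  ref = c("A", "T", "G", "T", "A"),
                  alt = c("G", "C", "A", "A", "G"),
                  beta = c(0.2, 0.3, 0.2, 0.4, 0.5), se = 0.05,
                  af = c(0.3, 0.3, 0.7, 0.3, 0.3))
  h <- harmonize_variants(a, b)
  expect_equal(h$match_type,
               c("exact", "strand_flip", "allele_swap", "ambiguous",
                 "unmatched"))
  expect_equal(h$beta_b[1], 0.2)
  expect_equal(h$beta_b[2], 0.3)          # strand flip: no sign change
  expect_equal(h$beta_b[3], -0.2)         # swap flips the sign exactly
  expect_equal(h$af_b[3], 0.3)            # and maps af to 1 - af
  expect_true(is.na(h$beta_b[4]))         # palindromic stays flagged
  # with the flag, the palindromic pair's statistics pass through
  # unmodified (orientation undefined, no flip applied)
  h_amb <- harmonize_variants(a, b, include_ambiguous = TRUE)
  expect_equal(h_amb$beta_b[4], 0.4)
})

test_that("harmonization is an involution on the matched set", {
  a <- make_table(pos = c(100L, 200L, 300L),
                  ref = c("A", "C", "G"), alt = c("G", "T", "C"),
                  beta = c(0.1, -0.2, 0.3), se = 0.05,
                  af = c(0.2, 0.4, 0.6))
  b <- make_table(pos = c(100L, 200L, 300L),
                  ref = c("G", "C", "C"), alt = c("A", "T", "G"),
                  beta = c(0.15, -0.25, 0.35), se = 0.05,
                  af = c(0.8, 0.4, 0.5))
  ab <- harmonize_variants(a, b, include_ambiguous = TRUE)
  ba <- harmonize_variants(b, a, include_ambiguous = TRUE)
  matched <- !ab$match_type %in% "unmatched"
  expect_equal(sum(matched), sum(!ba$match_type %in% "unmatched"))
  # orientation ops invert: A's beta seen from B equals B's beta seen from A
  # after undoing the flip
  swap_ab <- ab$match_type %in% c("allele_swap", "strand_flip_swap", "ambiguous")
  swap_ba <- ba$match_type %in% c("allele_swap", "strand_flip_swap", "ambiguous")
  expect_equal(sum(swap_ab), sum(swap_ba))
  expect_equal(sort(abs(ab$beta_b[matched])), sort(abs(b$beta)))
})

test_that("credible-set tables round-trip through TSV", {
  pair <- make_credible_set_pair(c(0.5, 0.3), c(0.4, 0.2),
                                 unique_pips_a = 0.1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_credible_sets(pair, path)
  back <- read_credible_sets(path)
  expect_length(back, 2L)
  expect_equal(sort(back[["locus1/a"]]$pip), sort(c(0.5, 0.3, 0.1)),
               tolerance = 1e-6)
  expect_equal(back[["locus1/b"]]$variants$id[order(back[["locus1/b"]]$pip)],
               pair$b$variants$id[order(pair$b$pip)])
})
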