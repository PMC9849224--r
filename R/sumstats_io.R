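#' Column dialects for summary-statistic tables
#'
#' A dialect maps the canonical column names used internally (`chrom`,
#' `pos`, `ref`, `alt`, `af`, `beta`, `se`, `pval`, optionally `rsid`)
#' to the column headers found in a file. Two dialects are built in:
#' `"finngen"` (`#chrom pos ref alt af_alt beta sebeta pval`) and
#' `"generic"` (canonical names used verbatim). A custom mapping can be
#' supplied as a named character vector, names being canonical fields.
#'
#' @param name `"finngen"`, `"generic"`, or a named character vector.
#' @return named character vector mapping canonical -> file column names.
#' @export
sumstats_dialect <- function(name = "finngen") {
  if (is.character(name) && length(name) > 1L) {
    .assert(!is.null(names(name)), "a custom dialect must be a named character vector")
    return(name)
  }
  switch(name,
    finngen = c(chrom = "#chrom", pos = "pos", ref = "ref", alt = "alt",
                af = "af_alt", beta = "beta", se = "sebeta", pval = "pval",
                rsid = "rsids"),
    generic = c(chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
                af = "af", beta = "beta", se = "se", pval = "pval",
                rsid = "rsid"),
    .stopf("unknown dialect '%s'", name)
  )
}

.SUMSTATS_REQUIRED <- c("chrom", "pos", "ref", "alt", "beta", "se", "pval")

#' Construct a validated summary-statistics table
#'
#' The central container of the package: one row per variant with the
#' effect-allele log-odds estimate `beta`, its standard error `se`, the
#' two-sided p-value `pval`, and optionally the effect-allele frequency
#' `af` and an `rsid`. Case/control counts and the phenotype label travel
#' as attributes so downstream design-based computations (effective
#' sample size, overlap correlation) can reach them.
#'
#' Validation enforces: positions >= 1, `ref != alt`, alleles drawn from
#' A/C/G/T (multi-base allowed), `se > 0`, `pval` in (0, 1], unique
#' variant keys, and (when both are present) consistency of `pval` with
#' `2*pnorm(-|beta/se|)` to one significant figure.
#'
#' @param df data.frame with the canonical columns.
#' @param phenotype phenotype identifier.
#' @param n_cases,n_controls subject counts (optional, NA if unknown).
#' @param check_pval check Wald consistency of p-values (default TRUE).
#' @return object of class `sumstats` (a data.frame).
#' @export
sumstats <- function(df, phenotype = NA_character_, n_cases = NA_integer_,
                     n_controls = NA_integer_, check_pval = TRUE) {
  .assert(is.data.frame(df), "df must be a data.frame")
  missing_cols <- setdiff(.SUMSTATS_REQUIRED, names(df))
  .assert(length(missing_cols) == 0L,
          "missing required column(s): %s", paste(missing_cols, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$chrom <- .norm_chrom(df$chrom)
  df$pos <- as.integer(df$pos)
  if (is.null(df$af)) df$af <- rep(NA_real_, nrow(df))
  if (is.null(df$rsid)) df$rsid <- rep(NA_character_, nrow(df))
  df <- df[, c("chrom", "pos", "ref", "alt", "rsid", "af", "beta", "se", "pval")]

  for (col in c("beta", "se", "pval", "af")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      rows <- which(cond)
      .stopf("invalid %s in row(s): %s", what,
             paste(utils::head(rows, 10L), collapse = ", "))
    }
  }
  bad(is.na(df$pos) | df$pos < 1L, "position (must be >= 1)")
  bad(!grepl("^[ACGT]+$", df$ref) | !grepl("^[ACGT]+$", df$alt),
      "allele (must be A/C/G/T strings)")
  bad(df$ref == df$alt, "alleles (ref == alt)")
  bad(is.na(df$beta), "beta (non-numeric)")
  bad(is.na(df$se) | df$se <= 0, "se (must be > 0)")
  bad(is.na(df$pval) | df$pval <= 0 | df$pval > 1, "pval (must be in (0,1])")
  bad(!is.na(df$af) & (df$af <= 0 | df$af >= 1), "af (must be in (0,1))")

  ids <- variant_id(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(ids)) {
    dups <- unique(ids[duplicated(ids)])
    .stopf("duplicate variant key(s): %s", paste(utils::head(dups, 10L), collapse = ", "))
  }

  if (isTRUE(check_pval)) {
    expected <- 2 * stats::pnorm(-abs(df$beta / df$se))
    ratio_ok <- abs(df$pval - expected) / pmax(expected, .Machine$double.xmin) < 0.5
    ok <- is.na(expected) | expected == 0 |
      signif(df$pval, 1) == signif(expected, 1) | ratio_ok
    bad(!ok, "pval (inconsistent with |beta/se| at 1 significant figure)")
  }

  rownames(df) <- NULL
  structure(df,
            phenotype = phenotype,
            n_cases = if (is.na(n_cases)) NA_integer_ else as.integer(n_cases),
            n_controls = if (is.na(n_controls)) NA_integer_ else as.integer(n_controls),
            class = c("sumstats", "data.frame"))
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s cases / %s controls), %d variants\n",
              attr(x, "phenotype"), attr(x, "n_cases"), attr(x, "n_controls"),
              nrow(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

#' Read a summary-statistics table from a TSV file
#'
#' @param path file path.
#' @param dialect dialect name or named mapping, see [sumstats_dialect()].
#' @param phenotype,n_cases,n_controls metadata attached to the table.
#' @param ... passed to [sumstats()] (e.g. `check_pval`).
#' @return a [sumstats] object; row order of the file is preserved.
#' @export
read_sumstats <- function(path, dialect = "finngen", phenotype = NA_character_,
                          n_cases = NA_integer_, n_controls = NA_integer_, ...) {
  .assert(file.exists(path), "file not found: %s", path)
  map <- sumstats_dialect(dialect)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "",
                           colClasses = "character")
  required <- map[.SUMSTATS_REQUIRED]
  absent <- required[!required %in% names(raw)]
  .assert(length(absent) == 0L, "file %s lacks required column(s): %s",
          path, paste(absent, collapse = ", "))
  out <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                    chrom = raw[[map[["chrom"]]]],
                    pos = raw[[map[["pos"]]]],
                    ref = raw[[map[["ref"]]]],
                    alt = raw[[map[["alt"]]]])
  for (fld in c("af", "beta", "se", "pval")) {
    col <- map[fld]
    if (!is.na(col) && col %in% names(raw)) {
      v <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(is.na(v) & !is.na(raw[[col]]) & raw[[col]] != "" &
                     toupper(raw[[col]]) != "NA")
      if (length(bad) && fld != "af") {
        .stopf("non-numeric %s at line(s): %s of %s", fld,
               paste(utils::head(bad + 1L, 10L), collapse = ", "), path)
      }
      out[[fld]] <- v
    }
  }
  if (!is.na(map["rsid"]) && map[["rsid"]] %in% names(raw)) {
    out$rsid <- raw[[map[["rsid"]]]]
  }
  sumstats(out, phenotype = phenotype, n_cases = n_cases,
           n_controls = n_controls, ...)
}

#' Write a summary-statistics table to a TSV file
#'
#' Output is deterministic: fixed column order, effect estimates and
#' frequencies at 6 significant digits, p-values in scientific notation.
#' `read_sumstats(write_sumstats(x))` is the identity up to the output
#' precision.
#'
#' @param table a [sumstats] object.
#' @param path output path.
#' @param dialect column-name dialect for the header.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path, dialect = "finngen") {
  .assert(inherits(table, "sumstats"), "table must be a sumstats object")
  map <- sumstats_dialect(dialect)
  fmt_num <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
  fmt_p <- function(x) ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "e"))
  out <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
                    a = table$chrom, b = table$pos, c = table$ref, d = table$alt,
                    e = fmt_num(table$af), f = fmt_num(table$beta),
                    g = fmt_num(table$se), h = fmt_p(table$pval),
                    i = ifelse(is.na(table$rsid), "NA", table$rsid))
  names(out) <- unname(map[c("chrom", "pos", "ref", "alt", "af", "beta",
                             "se", "pval", "rsid")])
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) .stopf("cannot write %s: %s", path, conditionMessage(ok))
  invisible(path)
}

#' Harmonize variants of one cohort against another
#'
#' For each variant of `table_a`, finds the matching record of `table_b`
#' trying, in order: exact (chrom, pos, ref, alt) match; strand
#' complement; ref/alt swap (effect sign flipped, allele frequency
#' mapped to 1 - af); strand complement plus swap. Palindromic variants
#' (A/T, C/G) whose only match involves a strand operation cannot be
#' oriented and are flagged `ambiguous`. Unmatched variants are returned
#' with `match_type = "unmatched"`. Each B record is consumed at most
#' once, in A's row order.
#'
#' @param table_a,table_b [sumstats] objects; output keys carry A's
#'   orientation.
#' @param include_ambiguous keep palindromic-ambiguous pairs' B statistics
#'   (default FALSE: their B columns are set to NA but the row is kept
#'   with its flag, so callers can count them).
#' @return data.frame with A's key columns, `*_a` and `*_b` statistic
#'   columns, and `match_type` in exact / strand_flip / allele_swap /
#'   strand_flip_swap / ambiguous / unmatched.
#' @export
harmonize_variants <- function(table_a, table_b, include_ambiguous = FALSE) {
  .assert(inherits(table_a, "sumstats") && inherits(table_b, "sumstats"),
          "both inputs must be sumstats objects")
  b_key <- function(ref, alt) paste(table_b$chrom, table_b$pos, ref, alt, sep = ":")
  b_exact <- b_key(table_b$ref, table_b$alt)
  b_used <- rep(FALSE, nrow(table_b))
  b_index <- split(seq_len(nrow(table_b)), b_exact)

  comp_ref_b <- .complement_allele(table_b$ref)
  comp_alt_b <- .complement_allele(table_b$alt)

  n <- nrow(table_a)
  match_type <- character(n)
  b_row <- rep(NA_integer_, n)
  flip <- logical(n)

  a_id_of <- function(i, ref, alt) {
    paste(table_a$chrom[i], table_a$pos[i], ref, alt, sep = ":")
  }
  lookup <- function(key) {
    idx <- b_index[[key]]
    idx <- idx[!b_used[idx]]
    if (length(idx)) idx[1L] else NA_integer_
  }
  # candidate generators in priority order: b-row matcher + orientation op
  pal_a <- .is_palindromic(table_a$ref, table_a$alt)

  for (i in seq_len(n)) {
    ref_a <- table_a$ref[i]; alt_a <- table_a$alt[i]
    cands <- list(
      exact = a_id_of(i, ref_a, alt_a),
      strand_flip = a_id_of(i, .complement_allele(ref_a), .complement_allele(alt_a)),
      allele_swap = a_id_of(i, alt_a, ref_a),
      strand_flip_swap = a_id_of(i, .complement_allele(alt_a), .complement_allele(ref_a))
    )
    hit <- NA_integer_; type <- "unmatched"
    for (tp in names(cands)) {
      hit <- lookup(cands[[tp]])
      if (!is.na(hit)) { type <- tp; break }
    }
    if (!is.na(hit)) {
      if (pal_a[i] && type != "exact") type <- "ambiguous"
      b_used[hit] <- TRUE
      b_row[i] <- hit
      flip[i] <- type %in% c("allele_swap", "strand_flip_swap")
    }
    match_type[i] <- type
  }

  beta_b <- table_b$beta[b_row]
  af_b <- table_b$af[b_row]
  beta_b[flip] <- -beta_b[flip]
  af_b[flip] <- 1 - af_b[flip]
  out <- data.frame(stringsAsFactors = FALSE,
                    chrom = table_a$chrom, pos = table_a$pos,
                    ref = table_a$ref, alt = table_a$alt,
                    rsid = table_a$rsid,
                    af_a = table_a$af, beta_a = table_a$beta,
                    se_a = table_a$se, pval_a = table_a$pval,
                    af_b = af_b, beta_b = beta_b,
                    se_b = table_b$se[b_row], pval_b = table_b$pval[b_row],
                    match_type = match_type)
  if (!include_ambiguous) {
    amb <- out$match_type == "ambiguous"
    out[amb, c("af_b", "beta_b", "se_b", "pval_b")] <- NA_real_
  }
  out
}

#' Read / write credible-set tables
#'
#' Credible sets are exchanged as TSVs with columns `locus_id, cs_id,
#' chrom, pos, ref, alt, pip`. Reading returns a list of [credible_set]
#' objects, one per (locus_id, cs_id).
#'
#' @param path file path.
#' @return list of credible sets (`read_credible_sets`); the path,
#'   invisibly (`write_credible_sets`).
#' @export
read_credible_sets <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("locus_id", "cs_id", "chrom", "pos", "ref", "alt", "pip")
  missing_cols <- setdiff(need, names(df))
  .assert(length(missing_cols) == 0L, "credible-set file lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  parts <- split(df, paste(df$locus_id, df$cs_id, sep = "\r"))
  out <- lapply(parts, function(p) {
    new_credible_set(variants = p[, c("chrom", "pos", "ref", "alt")],
                     pip = as.numeric(p$pip), locus_id = p$locus_id[1L],
                     cs_id = p$cs_id[1L])
  })
  names(out) <- vapply(out, function(cs) paste(cs$locus_id, cs$cs_id, sep = "/"),
                       character(1))
  out[order(names(out))]
}

#' @param sets list of [credible_set] objects.
#' @rdname read_credible_sets
#' @export
write_credible_sets <- function(sets, path) {
  if (inherits(sets, "credible_set")) sets <- list(sets)
  rows <- lapply(sets, function(cs) {
    data.frame(stringsAsFactors = FALSE,
               locus_id = cs$locus_id, cs_id = cs$cs_id,
               chrom = cs$variants$chrom, pos = cs$variants$pos,
               ref = cs$variants$ref, alt = cs$variants$alt,
               pip = formatC(cs$pip, digits = 6, format = "g"))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
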