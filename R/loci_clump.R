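#' Greedy lead-variant locus clumping
#'
#' Iteratively takes the unassigned genome-wide-significant variant with
#' the smallest p-value as a locus lead, and assigns to its locus every
#' unassigned GWS variant on the same chromosome within `dist_bp` of the
#' lead AND with r2 above `r2_min` with the lead (conjunction of the
#' distance and LD conditions). Repeats until every GWS variant belongs
#' to exactly one locus. Ties on p-value are broken by (chrom, pos).
#'
#' @param table a [sumstats] object.
#' @param ld LD lookup: a square r2 matrix whose dimnames are canonical
#'   variant ids (see [variant_id()]), or NULL for no LD information.
#' @param thresholds a [significance_thresholds]; variants with
#'   p <= gws enter clumping.
#' @param dist_bp maximum distance from the lead (default 2 Mb, strict).
#' @param r2_min minimum r2 with the lead (default 0.1, strict).
#' @param missing_ld what to do when a same-chromosome candidate pair
#'   has no LD entry: "zero" treats it as r2 = 0, "error" aborts.
#' @return list of `locus_group` objects, each with `lead` (1-row
#'   data.frame), `members` (data.frame of assigned records),
#'   `lead_pval` and `phenotype`; ordered by lead p-value.
#' @export
clump_loci <- function(table, ld = NULL,
                       thresholds = significance_thresholds(),
                       dist_bp = 2e6, r2_min = 0.1,
                       missing_ld = c("zero", "error")) {
  missing_ld <- match.arg(missing_ld)
  gws <- which(table$pval <= thresholds$gws)
  if (length(gws) == 0L) return(list())
  cand <- as.data.frame(table)[gws, , drop = FALSE]
  cand$id <- variant_id(cand$chrom, cand$pos, cand$ref, cand$alt)

  r2_with <- function(lead_id, other_ids) {
    if (length(other_ids) == 0L) return(numeric(0))
    if (is.null(ld)) {
      if (missing_ld == "error") .stopf("no LD information for %s", lead_id)
      return(rep(0, length(other_ids)))
    }
    out <- rep(NA_real_, length(other_ids))
    have <- lead_id %in% rownames(ld)
    if (have) {
      hit <- match(other_ids, colnames(ld))
      out[!is.na(hit)] <- ld[lead_id, hit[!is.na(hit)]]
    }
    if (anyNA(out) && missing_ld == "error") {
      .stopf("missing LD entry for pair involving %s", lead_id)
    }
    out[is.na(out)] <- 0
    out
  }

  ord <- order(cand$pval, cand$chrom, cand$pos)
  cand <- cand[ord, , drop = FALSE]
  unassigned <- rep(TRUE, nrow(cand))
  loci <- list()
  while (any(unassigned)) {
    lead_i <- which(unassigned)[1L]   # smallest p among unassigned
    open <- which(unassigned & cand$chrom == cand$chrom[lead_i] &
                    abs(cand$pos - cand$pos[lead_i]) < dist_bp)
    open <- setdiff(open, lead_i)
    r2 <- r2_with(cand$id[lead_i], cand$id[open])
    members_i <- c(lead_i, open[r2 > r2_min])
    unassigned[members_i] <- FALSE
    members <- cand[sort(members_i), , drop = FALSE]
    loci[[length(loci) + 1L]] <- structure(
      list(lead = cand[lead_i, , drop = FALSE],
           members = members,
           lead_pval = cand$pval[lead_i],
           phenotype = attr(table, "phenotype")),
      class = "locus_group")
  }
  loci
}

#' @export
print.locus_group <- function(x, ...) {
  cat(sprintf("Locus led by %s (%s:%d, p = %.3g), %d member(s), phenotype %s\n",
              x$lead$rsid, x$lead$chrom, x$lead$pos, x$lead_pval,
              nrow(x$members), x$phenotype))
  invisible(x)
}

#' Cross-phenotype effect matrix of locus leads
#'
#' Collects the lead variants of per-phenotype locus lists, merges leads
#' that belong to the same locus across phenotypes (within `dist_bp` and
#' r2 > `r2_min` of each other, keeping the lowest-p representative —
#' the same rule as clumping), and fills one row per merged lead with
#' each phenotype's effect estimate and p-value, whether significant
#' there or not. Cells whose variant is absent from a phenotype's table
#' are flagged missing and displayed as beta = 0, p = 1.
#'
#' @param loci_by_phenotype named list (phenotype -> list of
#'   `locus_group`s from [clump_loci()]).
#' @param tables named list of [sumstats] objects covering the same
#'   phenotypes (keys must match `loci_by_phenotype`).
#' @param ld optional LD matrix as in [clump_loci()].
#' @param dist_bp,r2_min lead-merging radius, defaulting to the clumping
#'   radius.
#' @return object of class `effect_matrix`: list with matrices `beta`,
#'   `se`, `pval`, logical `missing`, data.frame `leads`, and the
#'   phenotype vector. Row names are lead rsids (or variant ids).
#' @export
build_effect_matrix <- function(loci_by_phenotype, tables, ld = NULL,
                                dist_bp = 2e6, r2_min = 0.1) {
  .assert(all(names(loci_by_phenotype) %in% names(tables)),
          "every phenotype with loci needs a summary-statistics table")
  leads <- do.call(rbind, lapply(names(loci_by_phenotype), function(ph) {
    locs <- loci_by_phenotype[[ph]]
    if (length(locs) == 0L) return(NULL)
    do.call(rbind, lapply(locs, function(l) {
      cbind(l$lead[, c("chrom", "pos", "ref", "alt", "rsid", "pval", "id")],
            home = ph)
    }))
  }))
  if (is.null(leads) || nrow(leads) == 0L) {
    return(structure(list(beta = matrix(0, 0, length(tables)),
                          se = matrix(0, 0, length(tables)),
                          pval = matrix(1, 0, length(tables)),
                          missing = matrix(FALSE, 0, length(tables)),
                          leads = data.frame(), phenotypes = names(tables)),
                     class = "effect_matrix"))
  }
  leads <- leads[order(leads$pval, leads$chrom, leads$pos), , drop = FALSE]

  same_locus <- function(i, j) {
    if (leads$chrom[i] != leads$chrom[j]) return(FALSE)
    if (abs(leads$pos[i] - leads$pos[j]) >= dist_bp) return(FALSE)
    if (leads$id[i] == leads$id[j]) return(TRUE)
    if (is.null(ld)) return(FALSE)
    r2 <- if (leads$id[i] %in% rownames(ld) && leads$id[j] %in% colnames(ld)) {
      ld[leads$id[i], leads$id[j]]
    } else 0
    r2 > r2_min
  }
  rep_of <- rep(NA_integer_, nrow(leads))
  for (i in seq_len(nrow(leads))) {
    if (!is.na(rep_of[i])) next
    rep_of[i] <- i
    for (j in seq_len(nrow(leads))) {
      if (is.na(rep_of[j]) && same_locus(i, j)) rep_of[j] <- i
    }
  }
  reps <- unique(rep_of)
  merged <- leads[reps, , drop = FALSE]
  merged$home <- vapply(reps, function(r) {
    grp <- leads[rep_of == r, , drop = FALSE]
    grp$home[which.min(grp$pval)]
  }, character(1))

  phenos <- names(tables)
  n <- nrow(merged)
  beta <- se <- matrix(NA_real_, n, length(phenos),
                       dimnames = list(merged$rsid, phenos))
  pval <- matrix(NA_real_, n, length(phenos), dimnames = dimnames(beta))
  miss <- matrix(FALSE, n, length(phenos), dimnames = dimnames(beta))
  for (k in seq_along(phenos)) {
    tab <- tables[[phenos[k]]]
    ids <- variant_id(tab$chrom, tab$pos, tab$ref, tab$alt)
    hit <- match(merged$id, ids)
    miss[, k] <- is.na(hit)
    beta[, k] <- ifelse(is.na(hit), 0, tab$beta[hit])
    se[, k] <- ifelse(is.na(hit), NA_real_, tab$se[hit])
    pval[, k] <- ifelse(is.na(hit), 1, tab$pval[hit])
  }
  structure(list(beta = beta, se = se, pval = pval, missing = miss,
                 leads = merged[, c("chrom", "pos", "ref", "alt", "rsid",
                                    "pval", "id", "home")],
                 phenotypes = phenos),
            class = "effect_matrix")
}

#' Hierarchical clustering of an effect matrix
#'
#' Orders loci (rows) and phenotypes (columns) by agglomerative
#' hierarchical clustering of per-cell z-scores (beta/se; missing cells
#' contribute 0), average linkage on Euclidean distance by default.
#' Deterministic for a fixed input; with fewer than two rows or columns
#' the identity ordering is returned for that dimension.
#'
#' @param em an [build_effect_matrix()] result.
#' @param method linkage passed to [stats::hclust()].
#' @return list with `row_order`, `col_order`, and the `row_hclust` /
#'   `col_hclust` dendrograms (NULL where not computed).
#' @export
cluster_effect_matrix <- function(em, method = "average") {
  z <- em$beta / em$se
  z[!is.finite(z)] <- 0
  row_order <- seq_len(nrow(z)); col_order <- seq_len(ncol(z))
  rh <- ch <- NULL
  if (nrow(z) >= 2L) {
    rh <- stats::hclust(stats::dist(z), method = method)
    row_order <- rh$order
  }
  if (ncol(z) >= 2L) {
    ch <- stats::hclust(stats::dist(t(z)), method = method)
    col_order <- ch$order
  }
  list(row_order = row_order, col_order = col_order,
       row_hclust = rh, col_hclust = ch)
}

#' Count loci co-directionally associated with another phenotype
#'
#' A locus counts if, in any phenotype other than its home phenotype,
#' the effect has the same sign as the home effect and the p-value is
#' below the Bonferroni threshold `alpha_bonf` (default 0.05 divided by
#' the number of cells of the matrix).
#'
#' @param em an [build_effect_matrix()] result.
#' @param home per-row home phenotype; defaults to the `home` column
#'   recorded by [build_effect_matrix()].
#' @param alpha_bonf co-directionality significance threshold.
#' @return list with `count`, `alpha_bonf` and the per-row logical
#'   `codirectional`.
#' @export
count_codirectional <- function(em, home = NULL, alpha_bonf = NULL) {
  home <- home %||% em$leads$home
  n_cells <- nrow(em$beta) * ncol(em$beta)
  alpha_bonf <- alpha_bonf %||% (0.05 / n_cells)
  hit <- logical(nrow(em$beta))
  for (i in seq_len(nrow(em$beta))) {
    h <- match(home[i], em$phenotypes)
    s0 <- sign(em$beta[i, h])
    others <- setdiff(seq_along(em$phenotypes), h)
    ok <- !em$missing[i, others] &
      sign(em$beta[i, others]) == s0 & s0 != 0 &
      em$pval[i, others] < alpha_bonf
    hit[i] <- any(ok)
  }
  list(count = sum(hit), alpha_bonf = alpha_bonf, codirectional = hit)
}
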