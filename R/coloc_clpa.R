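#' Colocalization posterior probability (CLPP)
#'
#' CLPP = sum over variants present in both credible sets of the
#' product of their posterior inclusion probabilities, x_i * y_i.
#' Significant above 0.20 by convention. Variant identity uses the
#' canonical chrom:pos:ref:alt key, so harmonize orientations first if
#' the sets come from differently oriented cohorts (PIPs themselves are
#' orientation-free).
#'
#' @param cs_a,cs_b `credible_set` objects.
#' @return CLPP in [0, 1]; 0 for disjoint sets.
#' @export
clpp <- function(cs_a, cs_b) {
  hit <- match(cs_a$variants$id, cs_b$variants$id)
  sum(cs_a$pip[!is.na(hit)] * cs_b$pip[hit[!is.na(hit)]])
}

#' Causal posterior agreement (CLPA)
#'
#' CLPA = sum over shared variants of min(x_i, y_i) — a credible-set-
#' size-independent agreement measure between the two fine-mapping
#' results. Significant above 0.50 by convention. Always at least CLPP,
#' since x*y <= min(x, y) for probabilities.
#'
#' @param cs_a,cs_b `credible_set` objects.
#' @return CLPA in [0, 1].
#' @export
clpa <- function(cs_a, cs_b) {
  hit <- match(cs_a$variants$id, cs_b$variants$id)
  sum(pmin(cs_a$pip[!is.na(hit)], cs_b$pip[hit[!is.na(hit)]]))
}

#' Colocalization of one credible-set pair
#'
#' @param cs_a,cs_b `credible_set` objects.
#' @param clpp_threshold,clpa_threshold significance cutoffs (defaults
#'   0.20 and 0.50).
#' @return one-row data.frame: set identifiers, `n_shared`, `clpp`,
#'   `clpa`, and the two significance flags.
#' @export
coloc_pair <- function(cs_a, cs_b, clpp_threshold = 0.20,
                       clpa_threshold = 0.50) {
  n_shared <- length(intersect(cs_a$variants$id, cs_b$variants$id))
  p <- clpp(cs_a, cs_b)
  a <- clpa(cs_a, cs_b)
  data.frame(stringsAsFactors = FALSE,
             cs_a = paste(cs_a$locus_id, cs_a$cs_id, sep = "/"),
             cs_b = paste(cs_b$locus_id, cs_b$cs_id, sep = "/"),
             n_shared = n_shared, clpp = p, clpa = a,
             clpp_significant = p > clpp_threshold,
             clpa_significant = a > clpa_threshold)
}

#' Pairwise colocalization scan of two credible-set collections
#'
#' Evaluates every cross-collection pair whose variant spans (same
#' chromosome, interval from the lowest to the highest member position)
#' lie within `same_locus_window_bp` of each other. Output rows are
#' deterministically ordered by the identifiers of the pair.
#'
#' @param sets_a,sets_b lists of `credible_set` objects.
#' @param same_locus_window_bp maximum gap between the two variant
#'   spans (default 1 Mb).
#' @param clpp_threshold,clpa_threshold significance cutoffs.
#' @return data.frame, one row per evaluated pair (possibly empty).
#' @export
coloc_scan <- function(sets_a, sets_b, same_locus_window_bp = 1e6,
                       clpp_threshold = 0.20, clpa_threshold = 0.50) {
  if (inherits(sets_a, "credible_set")) sets_a <- list(sets_a)
  if (inherits(sets_b, "credible_set")) sets_b <- list(sets_b)
  span <- function(cs) list(chrom = cs$variants$chrom[1L],
                            lo = min(cs$variants$pos),
                            hi = max(cs$variants$pos))
  rows <- list()
  for (a in sets_a) {
    sa <- span(a)
    for (b in sets_b) {
      sb <- span(b)
      if (sa$chrom != sb$chrom) next
      gap <- max(0, max(sa$lo, sb$lo) - min(sa$hi, sb$hi))
      if (gap > same_locus_window_bp) next
      rows[[length(rows) + 1L]] <- coloc_pair(a, b, clpp_threshold,
                                              clpa_threshold)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(cs_a = character(0), cs_b = character(0),
                      n_shared = integer(0), clpp = numeric(0),
                      clpa = numeric(0), clpp_significant = logical(0),
                      clpa_significant = logical(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$cs_a, out$cs_b), , drop = FALSE]
}
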