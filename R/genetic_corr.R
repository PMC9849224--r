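#' LD score set
#'
#' Per-variant LD scores l_j = sum over the window of r^2 with every
#' variant (including the variant itself, so l_j >= 1), plus the total
#' variant count M used for scaling the polygenic regressor N l / M.
#'
#' @param scores numeric LD scores.
#' @param m_total total variant count M (>= number of scores).
#' @param variants optional variant identifiers.
#' @return object of class `ld_score_set`.
#' @export
ld_score_set <- function(scores, m_total = length(scores), variants = NULL) {
  .assert(all(scores >= 1 - 1e-8), "LD scores must be >= 1 (self r^2 included)")
  .assert(m_total >= length(scores), "m_total must be >= number of variants")
  structure(list(scores = as.numeric(scores), m_total = m_total,
                 variants = variants),
            class = "ld_score_set")
}

#' LD scores from a variant-correlation matrix
#'
#' l_j = sum_k r^2_jk over the supplied window, including j itself.
#'
#' @param ld square matrix of signed correlations r (or dosage
#'   correlations); squared internally.
#' @param m_total total variant count for scaling (default `ncol(ld)`).
#' @return an [ld_score_set].
#' @export
compute_ld_scores <- function(ld, m_total = ncol(ld)) {
  .assert(is.matrix(ld) && nrow(ld) == ncol(ld), "ld must be a square matrix")
  ld_score_set(rowSums(ld^2), m_total = m_total,
               variants = rownames(ld))
}

# Weighted chi2-on-LD-score regression shared by the h2 and rg paths.
# Returns intercept/slope plus delete-one-block jackknife replicates.
.ldsc_regress <- function(y, x, w, n_blocks) {
  X <- cbind(1, x)
  fit <- stats::lm.wfit(X, y, w)
  n <- length(y)
  blocks <- split(seq_len(n), cut(seq_len(n), breaks = n_blocks, labels = FALSE))
  jack <- t(vapply(blocks, function(idx) {
    stats::lm.wfit(X[-idx, , drop = FALSE], y[-idx], w[-idx])$coefficients
  }, numeric(2)))
  list(intercept = fit$coefficients[1L], slope = fit$coefficients[2L],
       jack = jack)
}

.jack_se <- function(est) {
  b <- length(est)
  sqrt((b - 1) / b * sum((est - mean(est))^2))
}

#' Observed-scale SNP heritability by LD score regression
#'
#' Regresses the per-variant association chi-square on N l_j / M with
#' the standard two-pass weights (first pass 1/l_j, second pass
#' 1/(l_j (1 + N h2 l_j / M)^2)). The slope estimates the observed-scale
#' SNP heritability; the intercept captures confounding or overlap
#' inflation and is about 1 for a well-calibrated GWAS. Standard errors
#' come from a delete-one block jackknife over contiguous blocks.
#'
#' @param table a [sumstats] object, aligned with `scores`.
#' @param scores an [ld_score_set] with one score per record of `table`.
#' @param n_eff (effective) sample size N of the GWAS.
#' @param n_blocks jackknife blocks (default 20).
#' @return list with `h2`, `h2_se`, `intercept`, `intercept_se`.
#' @export
ldsc_h2 <- function(table, scores, n_eff, n_blocks = 20L) {
  l <- scores$scores
  .assert(nrow(table) == length(l), "table and scores must align on variants")
  .assert(nrow(table) >= 200L, "need at least 200 variants")
  .assert(stats::var(l) > 0, "degenerate regressor: constant LD scores")
  chi2 <- (table$beta / table$se)^2
  x <- n_eff * l / scores$m_total
  w0 <- 1 / l
  h2_1 <- max(stats::lm.wfit(cbind(1, x), chi2, w0)$coefficients[2L], 0)
  w <- 1 / (l * (1 + n_eff * h2_1 * l / scores$m_total)^2)
  reg <- .ldsc_regress(chi2, x, w, n_blocks)
  list(h2 = unname(reg$slope), h2_se = .jack_se(reg$jack[, 2L]),
       intercept = unname(reg$intercept),
       intercept_se = .jack_se(reg$jack[, 1L]))
}

#' Genetic correlation by cross-trait LD score regression
#'
#' Regresses the per-variant product z_a z_b on sqrt(Na Nb) l_j / M; the
#' slope estimates the genetic covariance rg * sqrt(h2_a h2_b) and the
#' intercept absorbs sample overlap between the two GWASs, so shared
#' controls bias the intercept, not the slope. rg is the slope divided
#' by sqrt of the two traits' LD-score-regression heritabilities; its
#' standard error comes from a delete-one block jackknife of the full
#' ratio, and the p-value from a normal approximation on rg/se.
#'
#' @param table_a,table_b aligned [sumstats] objects (same variants in
#'   the same order).
#' @param scores an [ld_score_set].
#' @param n_eff_a,n_eff_b (effective) sample sizes.
#' @param n_blocks jackknife blocks (default 20).
#' @return list with `rg`, `se`, `pval`, `gencov`, `intercept`, the two
#'   `h2` fits, and `defined` (FALSE when either h2 estimate is <= 0,
#'   in which case rg is NA).
#' @export
ldsc_rg <- function(table_a, table_b, scores, n_eff_a, n_eff_b,
                    n_blocks = 20L) {
  l <- scores$scores
  .assert(nrow(table_a) == length(l) && nrow(table_b) == length(l),
          "tables and scores must align on variants")
  h2a <- ldsc_h2(table_a, scores, n_eff_a, n_blocks)
  h2b <- ldsc_h2(table_b, scores, n_eff_b, n_blocks)
  za <- table_a$beta / table_a$se
  zb <- table_b$beta / table_b$se
  y <- za * zb
  m <- scores$m_total
  x <- sqrt(n_eff_a * n_eff_b) * l / m
  w <- 1 / (l * (1 + n_eff_a * max(h2a$h2, 0) * l / m) *
              (1 + n_eff_b * max(h2b$h2, 0) * l / m))
  reg <- .ldsc_regress(y, x, w, n_blocks)
  if (h2a$h2 <= 0 || h2b$h2 <= 0) {
    return(list(rg = NA_real_, se = NA_real_, pval = NA_real_,
                gencov = unname(reg$slope), intercept = unname(reg$intercept),
                h2_a = h2a, h2_b = h2b, defined = FALSE))
  }
  rg <- unname(reg$slope) / sqrt(h2a$h2 * h2b$h2)

  # jackknife the full ratio: redo the h2 slopes on the same blocks
  chi2a <- za^2; chi2b <- zb^2
  xa <- n_eff_a * l / m; xb <- n_eff_b * l / m
  wa <- 1 / (l * (1 + n_eff_a * max(h2a$h2, 0) * l / m)^2)
  wb <- 1 / (l * (1 + n_eff_b * max(h2b$h2, 0) * l / m)^2)
  n <- length(y)
  blocks <- split(seq_len(n), cut(seq_len(n), breaks = n_blocks, labels = FALSE))
  rg_jack <- vapply(blocks, function(idx) {
    sl <- function(yy, xx, ww) {
      stats::lm.wfit(cbind(1, xx[-idx]), yy[-idx], ww[-idx])$coefficients[2L]
    }
    h2aj <- sl(chi2a, xa, wa); h2bj <- sl(chi2b, xb, wb)
    if (h2aj <= 0 || h2bj <= 0) return(NA_real_)
    sl(y, x, w) / sqrt(h2aj * h2bj)
  }, numeric(1))
  rg_jack <- rg_jack[is.finite(rg_jack)]
  se <- if (length(rg_jack) >= 2L) .jack_se(rg_jack) else NA_real_
  pval <- if (is.na(se) || se == 0) NA_real_ else 2 * stats::pnorm(-abs(rg / se))
  list(rg = rg, se = se, pval = pval, gencov = unname(reg$slope),
       intercept = unname(reg$intercept), h2_a = h2a, h2_b = h2b,
       defined = TRUE)
}

#' Threshold-based phenotype grouping from a genetic-correlation matrix
#'
#' For each threshold t, phenotypes are grouped as the connected
#' components of the graph with an edge wherever rg > t. Because edge
#' sets shrink as t grows, the grouping at a higher threshold is always
#' a refinement of the grouping at a lower one, yielding the nested
#' cluster structure used to define disease groups (e.g. rg > 0.75 and
#' rg > 0.90 tiers).
#'
#' @param rg_matrix symmetric K x K genetic-correlation matrix with
#'   phenotype dimnames.
#' @param thresholds numeric thresholds (default c(0.75, 0.90)).
#' @return named list (one element per threshold, in the given order);
#'   each element is a list of character vectors of phenotype names.
#' @export
rg_cluster <- function(rg_matrix, thresholds = c(0.75, 0.90)) {
  .assert(is.matrix(rg_matrix) && nrow(rg_matrix) == ncol(rg_matrix),
          "rg_matrix must be square")
  phen <- rownames(rg_matrix) %||% paste0("P", seq_len(nrow(rg_matrix)))
  out <- lapply(thresholds, function(t) {
    adj <- (rg_matrix > t)
    diag(adj) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    memb <- igraph::components(g)$membership
    grps <- split(phen, memb)
    names(grps) <- NULL
    grps[order(vapply(grps, `[`, character(1), 1L))]
  })
  names(out) <- format(thresholds)
  out
}
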