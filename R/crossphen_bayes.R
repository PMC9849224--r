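#' Prior configuration for the cross-phenotype Bayesian classifier
#'
#' @param tau prior SD of a nonzero log-odds effect (default 0.2, the
#'   standard approximate-Bayes-factor scale for binary traits).
#' @param r_corr effect correlation under the correlated model, in
#'   (0, 1); strictly below 1 so that "correlated" remains
#'   distinguishable from "fixed" (default 0.9).
#' @param decision_threshold posterior probability a compared model
#'   needs to be called "most probable" (default 0.70; a stricter 0.75
#'   is sometimes used for shared calls and is available via this
#'   parameter).
#' @return object of class `prior_config`.
#' @export
prior_config <- function(tau = 0.2, r_corr = 0.9, decision_threshold = 0.70) {
  .assert(tau > 0, "tau must be positive")
  .assert(r_corr > 0 && r_corr < 1, "r_corr must be in (0, 1)")
  .assert(decision_threshold > 0.5 && decision_threshold <= 1,
          "decision_threshold must be in (0.5, 1]")
  structure(list(tau = tau, r_corr = r_corr,
                 decision_threshold = decision_threshold),
            class = "prior_config")
}

#' Model space for cross-phenotype effect classification
#'
#' The compared models are: the null model (no effect anywhere), the
#' shared model, one single-phenotype model per phenotype, and any
#' declared subset models (a fixed effect on a named subset of
#' phenotypes). Each compared model receives equal prior probability
#' 1/C. The shared model is the union of the "fixed" model (identical
#' effect on all phenotypes) and the "correlated" model (similar
#' effects, correlation < 1); its prior mass is split equally between
#' the two, so fixed and correlated each get 1/(2C) — half the prior of
#' the null and single-phenotype models.
#'
#' With a single phenotype the space degenerates to two models, null
#' and effect, each with prior 1/2.
#'
#' @param phenotypes character vector of phenotype names (length K).
#' @param subset_models optional named list of integer index vectors (or
#'   character vectors of phenotype names), each declaring a subset
#'   model; duplicates are rejected.
#' @return data.frame of class `model_space` with columns `name`,
#'   `kind` (null / fixed / correlated / single / subset_fixed),
#'   `prior_weight`, and the list-column `active` of phenotype indices.
#' @export
build_model_space <- function(phenotypes, subset_models = NULL) {
  K <- length(phenotypes)
  .assert(K >= 1L, "need at least one phenotype")
  subsets <- lapply(subset_models, function(s) {
    if (is.character(s)) s <- match(s, phenotypes)
    s <- sort(as.integer(s))
    .assert(!anyNA(s) && all(s >= 1L & s <= K), "subset references unknown phenotype")
    .assert(length(s) >= 2L && length(s) < K,
            "a subset model must cover 2..K-1 phenotypes")
    s
  })
  if (length(subsets)) {
    keys <- vapply(subsets, paste, character(1), collapse = ",")
    .assert(!anyDuplicated(keys), "duplicate subset definitions")
    if (is.null(names(subsets)) || any(names(subsets) == "")) {
      names(subsets) <- vapply(subsets, function(s)
        paste(phenotypes[s], collapse = "&"), character(1))
    }
  }
  rows <- list()
  add <- function(name, kind, weight, active) {
    rows[[length(rows) + 1L]] <<- data.frame(stringsAsFactors = FALSE,
                                             name = name, kind = kind,
                                             prior_weight = weight)
    attr(rows[[length(rows)]], "active") <<- active
  }
  if (K == 1L) {
    add("null", "null", 0.5, integer(0))
    add(phenotypes[1L], "single", 0.5, 1L)
  } else {
    C <- 2L + K + length(subsets)
    add("null", "null", 1 / C, integer(0))
    add("fixed", "fixed", 1 / (2 * C), seq_len(K))
    add("correlated", "correlated", 1 / (2 * C), seq_len(K))
    for (k in seq_len(K)) add(phenotypes[k], "single", 1 / C, k)
    for (nm in names(subsets)) add(nm, "subset_fixed", 1 / C, subsets[[nm]])
  }
  space <- do.call(rbind, rows)
  space$active <- lapply(rows, attr, "active")
  structure(space, phenotypes = phenotypes, class = c("model_space", "data.frame"))
}

# Prior effect covariance of one model on the K-dimensional effect scale.
.model_prior_cov <- function(kind, active, K, tau, r_corr) {
  S <- matrix(0, K, K)
  if (length(active) == 0L) return(S)
  r <- switch(kind,
              fixed = 1, subset_fixed = 1, correlated = r_corr, single = 1,
              .stopf("unknown model kind '%s'", kind))
  block <- matrix(r * tau^2, length(active), length(active))
  diag(block) <- tau^2
  S[active, active] <- block
  S
}

#' Estimate the between-phenotype estimate-correlation matrix
#'
#' Two routes. The empirical route takes a matrix of per-variant
#' z-scores (variants x phenotypes), restricts to variants that look
#' null in every phenotype (|z| below `z_max`), and returns their
#' correlation matrix — this directly measures the correlation induced
#' by overlapping subjects, whatever its mechanism. The design route
#' computes the analytic shared-controls approximation from case/control
#' counts via [overlap_correlation_design()].
#'
#' @param null_zscores variants x phenotypes z-score matrix (empirical
#'   route); needs >= `min_null` retained null variants.
#' @param design an [overlap_design] (design route; used when
#'   `null_zscores` is NULL).
#' @param z_max |z| cutoff defining "null" variants (default 2).
#' @param min_null minimum retained variants for the empirical route
#'   (default 1000).
#' @return symmetric, unit-diagonal, positive semi-definite K x K
#'   correlation matrix (projected to the nearest PSD matrix with a
#'   warning if sampling noise breaks PSD-ness).
#' @export
estimate_overlap_correlation <- function(null_zscores = NULL, design = NULL,
                                         z_max = 2, min_null = 1000L) {
  if (!is.null(null_zscores)) {
    Z <- as.matrix(null_zscores)
    keep <- rowSums(abs(Z) < z_max) == ncol(Z)
    if (sum(keep) < min_null) {
      .stopf(paste("only %d null variants (|z| < %g in all phenotypes);",
                   "need >= %d — supply the design route instead"),
             sum(keep), z_max, min_null)
    }
    R <- stats::cor(Z[keep, , drop = FALSE])
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-10) {
      warning("empirical correlation not PSD; projecting to nearest PSD matrix")
      R <- .nearest_psd_corr(R)
    }
    diag(R) <- 1
    return((R + t(R)) / 2)
  }
  .assert(!is.null(design), "supply null_zscores or a design")
  overlap_correlation_design(design)
}

#' Posterior probabilities of cross-phenotype effect models
#'
#' For one variant with effect estimates `betas` and standard errors
#' `ses` across K phenotypes, the marginal likelihood of each model m is
#' the multivariate normal density of the estimate vector at mean zero
#' with covariance V + S_m, where V = D R D is the sampling covariance
#' (R the overlapping-sample estimate correlation, D = diag(ses)) and
#' S_m the model's prior effect covariance: zero for the null model,
#' tau^2 with correlation 1 over the active set for fixed/subset models,
#' tau^2 with correlation `r_corr` for the correlated model, tau^2 on
#' the single active entry for single-phenotype models. Posteriors are
#' prior_weight x likelihood, normalized; everything is computed in log
#' space. The shared posterior is P(fixed) + P(correlated).
#'
#' @param betas,ses numeric length-K effect estimates and SEs.
#' @param overlap_corr K x K estimate-correlation matrix (identity for
#'   independent cohorts; NULL means identity).
#' @param model_space a [build_model_space()] result.
#' @param prior a [prior_config].
#' @return object of class `model_posterior`: list with `posteriors`
#'   (named, one per model, summing to 1), `compared` (posteriors with
#'   fixed+correlated aggregated to "shared"), `shared_posterior`, and
#'   `call` (see [classify_variant()]).
#' @export
model_posteriors <- function(betas, ses, overlap_corr = NULL,
                             model_space = NULL, prior = prior_config()) {
  K <- length(betas)
  .assert(length(ses) == K && all(ses > 0), "ses must match betas and be positive")
  if (is.null(model_space)) model_space <- build_model_space(paste0("P", seq_len(K)))
  .assert(length(attr(model_space, "phenotypes")) == K,
          "model space was built for a different number of phenotypes")
  R <- overlap_corr %||% diag(K)
  V <- diag(ses, K) %*% R %*% diag(ses, K)
  logliks <- vapply(seq_len(nrow(model_space)), function(m) {
    S <- .model_prior_cov(model_space$kind[m], model_space$active[[m]], K,
                          prior$tau, prior$r_corr)
    sigma <- V + S
    ll <- tryCatch(
      mvtnorm::dmvnorm(betas, sigma = sigma, log = TRUE, checkSymmetry = FALSE),
      error = function(e) .stopf("non-PSD covariance for model '%s': %s",
                                 model_space$name[m], conditionMessage(e)))
    ll
  }, numeric(1))
  lp <- log(model_space$prior_weight) + logliks
  lp <- lp - max(lp)
  post <- exp(lp) / sum(exp(lp))
  names(post) <- model_space$name
  .finalize_posterior(post, model_space, prior)
}

.finalize_posterior <- function(post, model_space, prior) {
  kinds <- model_space$kind
  shared <- sum(post[kinds %in% c("fixed", "correlated")])
  compared <- c(post[kinds == "null"],
                if (any(kinds %in% c("fixed", "correlated"))) c(shared = shared),
                post[kinds %in% c("single", "subset_fixed")])
  mp <- structure(list(posteriors = post, compared = compared,
                       shared_posterior = shared, call = NA_character_),
                  class = "model_posterior")
  mp$call <- classify_variant(mp, prior$decision_threshold)
  mp
}

#' Call the most probable compared model
#'
#' Returns the label of the compared model (null / shared / each single
#' phenotype / each subset) whose posterior reaches the threshold, or
#' "uncertain" when none does.
#'
#' @param posterior a [model_posteriors()] result.
#' @param threshold posterior probability required (default 0.70).
#' @return character label.
#' @export
classify_variant <- function(posterior, threshold = 0.70) {
  cmp <- posterior$compared
  top <- which.max(cmp)
  if (cmp[top] >= threshold) names(cmp)[top] else "uncertain"
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("Compared-model posteriors:\n")
  print(round(x$compared, 4))
  cat(sprintf("call: %s (shared posterior %.3f)\n", x$call, x$shared_posterior))
  invisible(x)
}

#' Classify many variants at once
#'
#' Vectorized driver for [model_posteriors()] over a matrix of effect
#' estimates. When every variant shares the same SE vector (the common
#' case in calibration studies) the per-model densities are evaluated
#' for all variants in one pass.
#'
#' @param beta_matrix variants x K effect estimates.
#' @param se_matrix variants x K standard errors, or a length-K vector
#'   shared by all variants.
#' @param overlap_corr K x K estimate-correlation matrix or NULL.
#' @param model_space a [build_model_space()] result (default: no
#'   subsets).
#' @param prior a [prior_config].
#' @return data.frame with one row per variant: the call, the shared
#'   posterior, and one posterior column per compared model.
#' @export
classify_effects <- function(beta_matrix, se_matrix, overlap_corr = NULL,
                             model_space = NULL, prior = prior_config()) {
  B <- as.matrix(beta_matrix)
  K <- ncol(B)
  if (is.null(model_space)) model_space <- build_model_space(paste0("P", seq_len(K)))
  if (is.vector(se_matrix)) {
    se_matrix <- matrix(se_matrix, nrow(B), K, byrow = TRUE)
  }
  common_se <- nrow(B) > 1L &&
    all(abs(sweep(se_matrix, 2L, se_matrix[1L, ])) < 1e-12)
  R <- overlap_corr %||% diag(K)
  if (common_se) {
    ses <- se_matrix[1L, ]
    V <- diag(ses, K) %*% R %*% diag(ses, K)
    ll <- vapply(seq_len(nrow(model_space)), function(m) {
      S <- .model_prior_cov(model_space$kind[m], model_space$active[[m]], K,
                            prior$tau, prior$r_corr)
      mvtnorm::dmvnorm(B, sigma = V + S, log = TRUE, checkSymmetry = FALSE)
    }, numeric(nrow(B)))
    lp <- sweep(ll, 2L, log(model_space$prior_weight), "+")
    lp <- lp - apply(lp, 1L, max)
    post <- exp(lp) / rowSums(exp(lp))
    colnames(post) <- model_space$name
    res <- lapply(seq_len(nrow(B)), function(i)
      .finalize_posterior(stats::setNames(post[i, ], model_space$name),
                          model_space, prior))
  } else {
    res <- lapply(seq_len(nrow(B)), function(i)
      model_posteriors(B[i, ], se_matrix[i, ], overlap_corr = R,
                       model_space = model_space, prior = prior))
  }
  cmp <- do.call(rbind, lapply(res, function(r) r$compared))
  out <- data.frame(stringsAsFactors = FALSE,
                    call = vapply(res, function(r) r$call, character(1)),
                    shared_posterior = vapply(res, function(r) r$shared_posterior,
                                              numeric(1)))
  cbind(out, as.data.frame(cmp))
}
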