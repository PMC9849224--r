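#' End-to-end pipeline configuration
#'
#' Bundles the sub-configurations of a full synthetic study: simulate
#' LD-blocked genotypes and multi-phenotype outcomes over a shared
#' control pool, run per-phenotype logistic GWAS, clump loci, fine-map
#' credible sets, classify cross-phenotype effects, replicate against a
#' second simulated cohort with meta-analysis, colocalize credible sets
#' and group phenotypes by genetic correlation.
#'
#' @param sim a [sim_config] (its seed is overridden by the pipeline's
#'   stage-seed scheme).
#' @param effects an [effect_config] or list of them.
#' @param intercepts per-phenotype baseline log-odds.
#' @param phenotypes optional phenotype names.
#' @param thresholds a [significance_thresholds].
#' @param prior a [prior_config] for the Bayesian classifier.
#' @param abf an [abf_config] for fine-mapping.
#' @param coverage credible-set coverage (default 0.95).
#' @param rg_thresholds genetic-correlation grouping thresholds.
#' @param replication_fraction replication-cohort size relative to the
#'   discovery cohort (default 0.5).
#' @param output_dir directory for intermediate files (default: a fresh
#'   subdirectory of `tempdir()`).
#' @param seed global integer seed; per-stage seeds are derived from it
#'   by a fixed counter scheme so stages can be re-run in isolation.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(sim, effects, intercepts, phenotypes = NULL,
                            thresholds = significance_thresholds(),
                            prior = prior_config(), abf = abf_config(),
                            coverage = 0.95, rg_thresholds = c(0.75, 0.90),
                            replication_fraction = 0.5, output_dir = NULL,
                            seed = 1L) {
  .assert(inherits(sim, "sim_config"), "sim must be a sim_config")
  if (inherits(effects, "effect_config")) effects <- list(effects)
  .assert(all(vapply(effects, inherits, logical(1), "effect_config")),
          "effects must be effect_config objects")
  .assert(replication_fraction > 0 && replication_fraction <= 1,
          "replication_fraction must be in (0, 1]")
  structure(list(sim = sim, effects = effects, intercepts = intercepts,
                 phenotypes = phenotypes %||%
                   paste0("P", seq_along(intercepts)),
                 thresholds = thresholds, prior = prior, abf = abf,
                 coverage = coverage, rg_thresholds = rg_thresholds,
                 replication_fraction = replication_fraction,
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full synthetic cross-phenotype study
#'
#' Executes every stage on simulated data and writes the intermediate
#' tables (per-phenotype summary statistics, loci, credible sets,
#' colocalization results) plus a machine-readable JSON report to the
#' configured output directory. Fully deterministic for a fixed
#' configuration and seed.
#'
#' @param config a [pipeline_config].
#' @param quiet suppress progress messages (default TRUE).
#' @return the report: a list of per-stage counts and the file
#'   manifest.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  out_dir <- config$output_dir %||%
    file.path(tempdir(), sprintf("crossgwas_run_%d", config$seed))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  thr <- config$thresholds
  K <- length(config$intercepts)
  phen <- config$phenotypes

  # 1-2: genotypes and outcomes
  sim <- config$sim
  sim$seed <- .stage_seed(config$seed, 1L)
  gt <- .stage("simulate_genotypes", simulate_genotypes(sim))
  ph <- .stage("simulate_phenotypes",
               simulate_phenotypes(gt$genotypes, config$effects,
                                   config$intercepts,
                                   seed = .stage_seed(config$seed, 2L),
                                   phenotypes = phen))
  say("simulated %d individuals x %d variants, %d phenotypes",
      nrow(gt$genotypes), ncol(gt$genotypes), K)

  # 3: per-phenotype logistic GWAS of cases vs the shared controls
  shared_ctrl <- rowSums(ph$outcomes) == 0L
  tables <- .stage("gwas", {
    lapply(stats::setNames(seq_len(K), phen), function(k) {
      use <- ph$outcomes[, k] == 1L | shared_ctrl
      run_gwas_logistic(gt$genotypes[use, , drop = FALSE],
                        ph$outcomes[use, k], variants = gt$variants,
                        phenotype_name = phen[k])
    })
  })
  for (k in seq_len(K)) {
    write_sumstats(tables[[k]], file.path(out_dir, paste0(phen[k], ".tsv")))
  }
  lambda <- vapply(tables, function(t)
    if (nrow(t) >= 100L) genomic_inflation(t) else NA_real_, numeric(1))
  sig_counts <- lapply(tables, function(t) table(significance_flags(t, thr)))

  # 4: LD (r^2) from the realized genotypes
  ld <- .stage("ld", {
    r <- stats::cor(gt$genotypes)
    ids <- variant_id(gt$variants$chrom, gt$variants$pos,
                      gt$variants$ref, gt$variants$alt)
    dimnames(r) <- list(ids, ids)
    r^2
  })

  # 5: clumping
  loci <- .stage("clump", lapply(tables, clump_loci, ld = ld,
                                 thresholds = thr))
  loci_rows <- do.call(rbind, lapply(names(loci), function(p) {
    if (length(loci[[p]]) == 0L) return(NULL)
    do.call(rbind, lapply(seq_along(loci[[p]]), function(i) {
      l <- loci[[p]][[i]]
      data.frame(stringsAsFactors = FALSE,
                 locus_id = sprintf("%s_L%d", p, i), phenotype = p,
                 rsid = l$lead$rsid, chrom = l$lead$chrom, pos = l$lead$pos,
                 ref = l$lead$ref, alt = l$lead$alt,
                 n_members = nrow(l$members), lead_pval = l$lead_pval)
    }))
  }))
  if (!is.null(loci_rows)) {
    utils::write.table(loci_rows, file.path(out_dir, "loci.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # 6: fine-mapping per locus (records of the lead's chromosome block)
  credsets <- .stage("finemap", {
    sets <- list()
    for (p in names(loci)) {
      for (i in seq_along(loci[[p]])) {
        l <- loci[[p]][[i]]
        tab <- tables[[p]]
        in_window <- tab$chrom == l$lead$chrom &
          abs(tab$pos - l$lead$pos) < 2e6
        cs <- finemap_locus(as.data.frame(tab)[in_window, , drop = FALSE],
                            config = config$abf, coverage = config$coverage,
                            thresholds = thr,
                            locus_id = sprintf("%s_L%d", p, i),
                            cs_id = "cs1")
        if (isTRUE(cs$contains_gws)) sets[[length(sets) + 1L]] <- cs
      }
    }
    sets
  })
  if (length(credsets)) {
    write_credible_sets(credsets, file.path(out_dir, "credible_sets.tsv"))
  }

  # 7: overlap correlation, empirical with design fallback
  overlap <- .stage("overlap", {
    ids <- lapply(tables, function(t) variant_id(t$chrom, t$pos, t$ref, t$alt))
    common <- Reduce(intersect, ids)
    Z <- vapply(seq_len(K), function(k) {
      t <- tables[[k]]
      (t$beta / t$se)[match(common, ids[[k]])]
    }, numeric(length(common)))
    tryCatch(estimate_overlap_correlation(Z),
             error = function(e) overlap_correlation_design(ph$design))
  })

  # 8-9: cross-phenotype effect matrix + Bayesian classification
  em <- .stage("effect_matrix",
               build_effect_matrix(loci, tables, ld = ld))
  codir <- if (nrow(em$beta) > 0L) count_codirectional(em) else
    list(count = 0L, alpha_bonf = NA_real_, codirectional = logical(0))
  space <- build_model_space(phen)
  calls <- .stage("crossphen", {
    if (nrow(em$beta) == 0L) character(0) else
      vapply(seq_len(nrow(em$beta)), function(i) {
        ok <- !em$missing[i, ]
        if (sum(ok) < 2L) return(NA_character_)
        mp <- model_posteriors(em$beta[i, ok], em$se[i, ok],
                               overlap_corr = overlap[ok, ok, drop = FALSE],
                               model_space = build_model_space(phen[ok]),
                               prior = config$prior)
        mp$call
      }, character(1))
  })

  # 10: replication cohort + meta-analysis of locus leads
  replication <- .stage("replication", {
    if (is.null(loci_rows)) {
      list(categories = character(0))
    } else {
      rep_sim <- config$sim
      rep_sim$n_individuals <-
        max(200L, as.integer(config$sim$n_individuals *
                               config$replication_fraction))
      rep_sim$seed <- .stage_seed(config$seed, 10L)
      rgt <- simulate_genotypes(rep_sim)
      rph <- simulate_phenotypes(rgt$genotypes, config$effects,
                                 config$intercepts,
                                 seed = .stage_seed(config$seed, 11L),
                                 phenotypes = phen)
      rep_ctrl <- rowSums(rph$outcomes) == 0L
      cats <- vapply(seq_len(nrow(loci_rows)), function(i) {
        p <- loci_rows$phenotype[i]
        k <- match(p, phen)
        use <- rph$outcomes[, k] == 1L | rep_ctrl
        j <- match(loci_rows$rsid[i], rgt$variants$rsid)
        rt <- run_gwas_logistic(rgt$genotypes[use, j, drop = FALSE],
                                rph$outcomes[use, k],
                                variants = rgt$variants[j, , drop = FALSE],
                                phenotype_name = p)
        if (nrow(rt) == 0L) return("not_genotyped")
        disc_tab <- tables[[p]]
        di <- match(loci_rows$rsid[i], disc_tab$rsid)
        classify_replication(
          disc = list(beta = disc_tab$beta[di], se = disc_tab$se[di],
                      pval = disc_tab$pval[di]),
          rep = list(beta = rt$beta[1L], se = rt$se[1L], pval = rt$pval[1L]),
          thresholds = thr)$category
      }, character(1))
      list(categories = cats)
    }
  })

  # 11: colocalization across phenotypes' credible sets
  coloc <- .stage("coloc", {
    if (length(credsets) < 2L) {
      coloc_scan(list(), list())
    } else {
      pheno_of <- vapply(credsets, function(cs)
        sub("_L\\d+$", "", cs$locus_id), character(1))
      rows <- list()
      for (a in seq_along(credsets)) {
        for (b in seq_along(credsets)) {
          if (a < b && pheno_of[a] != pheno_of[b]) {
            rows[[length(rows) + 1L]] <-
              coloc_scan(credsets[[a]], credsets[[b]])
          }
        }
      }
      if (length(rows)) do.call(rbind, rows) else coloc_scan(list(), list())
    }
  })
  if (nrow(coloc)) {
    utils::write.table(coloc, file.path(out_dir, "coloc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  # 12: genetic correlation + grouping (needs enough variants)
  rg <- .stage("rg", {
    m <- ncol(gt$genotypes)
    if (m < 200L || K < 2L) {
      list(matrix = NULL, groups = NULL)
    } else {
      scores <- compute_ld_scores(stats::cor(gt$genotypes))
      ids <- lapply(tables, function(t) t$rsid)
      common <- Reduce(intersect, ids)
      keep <- match(common, gt$variants$rsid)
      sc <- ld_score_set(scores$scores[keep], m_total = scores$m_total)
      M <- diag(1, K); dimnames(M) <- list(phen, phen)
      for (a in seq_len(K - 1L)) {
        for (b in (a + 1L):K) {
          ta <- tables[[a]]; tb <- tables[[b]]
          ia <- match(common, ta$rsid); ib <- match(common, tb$rsid)
          fit <- ldsc_rg(
            sumstats(as.data.frame(ta)[ia, ], check_pval = FALSE),
            sumstats(as.data.frame(tb)[ib, ], check_pval = FALSE),
            sc,
            effective_sample_size(attr(ta, "n_cases"), attr(ta, "n_controls")),
            effective_sample_size(attr(tb, "n_cases"), attr(tb, "n_controls")))
          M[a, b] <- M[b, a] <- if (isTRUE(fit$defined)) fit$rg else NA_real_
        }
      }
      Mg <- M; Mg[is.na(Mg)] <- 0
      list(matrix = M, groups = rg_cluster(Mg, config$rg_thresholds))
    }
  })

  report <- list(
    seed = config$seed,
    n_individuals = nrow(gt$genotypes),
    n_variants = ncol(gt$genotypes),
    phenotypes = phen,
    n_cases = as.list(stats::setNames(ph$design$n_cases, phen)),
    n_shared_controls = ph$design$n_shared_controls,
    lambda_gc = as.list(lambda),
    n_gws = as.list(vapply(sig_counts, function(s)
      sum(s[names(s) %in% c("gws", "mts")]), numeric(1))),
    n_mts = as.list(vapply(sig_counts, function(s)
      sum(s[names(s) == "mts"]), numeric(1))),
    n_loci = as.list(vapply(loci, length, integer(1))),
    n_credible_sets_gws = length(credsets),
    crossphen_calls = as.list(table(calls[!is.na(calls)])),
    codirectional_loci = codir$count,
    replication_categories = as.list(table(replication$categories)),
    n_coloc_pairs = nrow(coloc),
    n_coloc_clpp_significant = sum(coloc$clpp_significant),
    n_coloc_clpa_significant = sum(coloc$clpa_significant),
    rg_groups = rg$groups,
    files = list.files(out_dir)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  report$output_dir <- out_dir
  invisible(report)
}
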