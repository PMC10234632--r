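# Experiment driver: replicate simulations, r-sweeps of both association
# models, metric aggregation, and paired model comparison with Bonferroni
# correction -- the full evaluation design at configurable (desk) scale.

#' Build an experiment configuration
#'
#' @param scenario One of "admixture", "family", "tree".
#' @param n Individuals per replicate (per generation for "family").
#' @param m Loci per replicate.
#' @param K Subpopulations ("admixture"/"family") or leaves ("tree").
#' @param fst,kinship_ratio Admixture-model calibration targets.
#' @param n_generations Pedigree depth for the "family" scenario.
#' @param tree A `subpop_tree` for the "tree" scenario (NULL = admixture).
#' @param trait_model "fes" or "rc".
#' @param h2 Narrow-sense heritability.
#' @param env_vars,env_k Environment variance proportions and group counts.
#' @param r_grid Numbers of PCs to sweep.
#' @param n_reps Number of replicates (>= 2).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return List of class `experiment_config`.
#' @export
experiment_config <- function(scenario = c("admixture", "family", "tree"),
                              n = 500, m = 20000, K = 10,
                              fst = 0.1, kinship_ratio = 0.5,
                              n_generations = 20, tree = NULL,
                              trait_model = c("fes", "rc"), h2 = 0.8,
                              env_vars = NULL, env_k = NULL,
                              r_grid = c(0:5, 10, 20), n_reps = 10,
                              seed = 1) {
  scenario <- match.arg(scenario)
  trait_model <- match.arg(trait_model)
  if (n_reps < 2) stop("need at least 2 replicates")
  if (any(r_grid >= n)) stop("all r values must be below n")
  if (1 - h2 - sum(env_vars %||% 0) < 0) stop("infeasible variance partition")
  structure(list(scenario = scenario, n = n, m = m, K = K, fst = fst,
                 kinship_ratio = kinship_ratio, n_generations = n_generations,
                 tree = tree, trait_model = trait_model, h2 = h2,
                 env_vars = env_vars, env_k = env_k, r_grid = sort(r_grid),
                 n_reps = n_reps, seed = seed),
            class = "experiment_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# one replicate's genotypes + true ancestral frequencies (if known);
# loci that end up monomorphic (possible after genotype dropping) are removed
# before analysis, as the standard pipelines do
.draw_scenario <- function(cfg, model) {
  out <- if (cfg$scenario == "admixture") {
    g <- draw_admixture_genotypes(model, cfg$m, want_p_ind = FALSE)
    list(X = g$X, p_anc = g$p_anc)
  } else if (cfg$scenario == "family") {
    g <- draw_admixture_genotypes(model, cfg$m, want_p_ind = FALSE)
    ped <- draw_pedigree(model$coords, cfg$n_generations)
    list(X = drop_genotypes(ped, g$X), p_anc = g$p_anc)
  } else {
    g <- draw_tree_genotypes(cfg$tree, ceiling(cfg$n / length(cfg$tree$leaves)),
                             cfg$m)
    keep <- seq_len(min(cfg$n, ncol(g$X)))
    list(X = g$X[, keep, drop = FALSE], p_anc = g$p_anc)
  }
  rs <- rowSums(out$X)
  poly <- rs > 0L & rs < 2L * ncol(out$X)
  out$X <- out$X[poly, , drop = FALSE]
  out$p_anc <- out$p_anc[poly]
  out
}

#' Run replicated simulations and r-sweeps of both association models
#'
#' For each replicate: fresh genotypes from the configured scenario, a fresh
#' causal set and trait, the standard kinship estimate, PCs from the
#' MAF-filtered standard kinship, then a PCA and an LMM scan at every r in
#' the grid.  Each scan is scored with SRMSDp (on null loci), AUCPR (scores =
#' -log10 p over all loci) and the inflation factor.  Failed fits are
#' recorded as NA rows rather than aborting the run.
#'
#' @param cfg An `experiment_config`.
#' @param methods Subset of `c("pca", "lmm")`.
#' @param verbose Print per-replicate progress.
#' @return Data frame of evaluation records: `rep`, `method`, `r`, `srmsd_p`,
#'   `auc_pr`, `lambda_gc`, `error` (NA or message).
#' @export
run_replicates <- function(cfg, methods = c("pca", "lmm"), verbose = FALSE) {
  model <- if (cfg$scenario %in% c("admixture", "family"))
    fit_admixture_model(cfg$n, cfg$K, cfg$fst, cfg$kinship_ratio) else NULL
  records <- list()
  for (rep_i in seq_len(cfg$n_reps)) {
    set.seed(cfg$seed + rep_i)
    sim <- .draw_scenario(cfg, model)
    X <- sim$X
    trait <- simulate_trait_replicate(X, cfg$h2, cfg$trait_model,
                                      p_anc = sim$p_anc,
                                      env_vars = cfg$env_vars, env_k = cfg$env_k)
    covar <- NULL
    if (!is.null(cfg$env_vars)) {
      # environment groups are modeled as fixed covariates (drop one level
      # per environment to keep the design full rank next to the intercept)
      covar <- do.call(cbind, lapply(cfg$env_k, function(k) {
        Z <- t(make_env_groups(ncol(X), k)$Z)
        Z[, -1, drop = FALSE]
      }))
    }
    null_mask <- !(seq_len(nrow(X)) %in% trait$causal)
    kin <- standard_kinship(X)
    eigen_K <- eigen(2 * kin, symmetric = TRUE)
    U_all <- compute_pcs(X, max(cfg$r_grid), maf_min = 0.1)
    for (r in cfg$r_grid) {
      U <- U_all[, seq_len(r), drop = FALSE]
      for (method in methods) {
        rec <- data.frame(rep = rep_i, method = method, r = r,
                          srmsd_p = NA_real_, auc_pr = NA_real_,
                          lambda_gc = NA_real_, error = NA_character_)
        res <- tryCatch({
          a <- if (method == "pca") pca_assoc(X, trait$y, U, covar)
               else lmm_assoc(X, trait$y, kin, U, covar,
                              null_fit = lmm_null_reml(trait$y, kin, U, covar,
                                                       eigen_K = eigen_K))
          rec$srmsd_p <- srmsd_p(a$p[null_mask])
          rec$auc_pr <- auc_pr(-log10(pmax(a$p, 1e-300)),
                               !null_mask)
          rec$lambda_gc <- inflation_lambda(a$p[null_mask])
          rec
        }, error = function(e) {
          rec$error <- conditionMessage(e)
          rec
        })
        records[[length(records) + 1L]] <- res
      }
    }
    if (verbose)
      message("replicate ", rep_i, "/", cfg$n_reps, " done")
  }
  do.call(rbind, records)
}

#' Compare PCA and LMM over replicated evaluation records
#'
#' For each metric (|SRMSDp| minimized, AUCPR maximized) and each method,
#' picks the best r by the mean over replicates, flags calibration
#' (mean |SRMSDp| < 0.01 at the best r), and runs a paired one-tailed
#' Wilcoxon signed-rank test between the two methods' per-replicate values at
#' their respective best r.  The winner is the better-mean method if the
#' p-value clears the Bonferroni threshold `alpha / n_tests`, otherwise Tie.
#' The exact test is used for 25 or fewer pairs, the normal approximation
#' above that.  Replicates missing for either method are dropped pairwise.
#'
#' @param records Output of [run_replicates()].
#' @param alpha Family-wise significance level (default 0.01).
#' @param n_tests Number of tests for the Bonferroni correction (default 1).
#' @return Data frame with one row per metric: best r and mean per method,
#'   calibration flags, Wilcoxon p-value, winner.
#' @export
compare_models <- function(records, alpha = 0.01, n_tests = 1) {
  stopifnot(all(c("pca", "lmm") %in% records$method))
  out <- list()
  for (metric in c("srmsd", "aucpr")) {
    val <- if (metric == "srmsd") abs(records$srmsd_p) else records$auc_pr
    best <- list()
    for (method in c("pca", "lmm")) {
      sel <- records$method == method
      means <- tapply(val[sel], records$r[sel], mean, na.rm = TRUE)
      best_r <- as.numeric(names(means))[
        if (metric == "srmsd") which.min(means) else which.max(means)]
      rows <- sel & records$r == best_r
      best[[method]] <- list(
        r = best_r, mean = means[[as.character(best_r)]],
        values = records[rows, ][order(records$rep[rows]), , drop = FALSE],
        calibrated = mean(abs(records$srmsd_p[rows]), na.rm = TRUE) < 0.01)
    }
    v_pca <- if (metric == "srmsd") abs(best$pca$values$srmsd_p)
             else best$pca$values$auc_pr
    v_lmm <- if (metric == "srmsd") abs(best$lmm$values$srmsd_p)
             else best$lmm$values$auc_pr
    ok <- !is.na(v_pca) & !is.na(v_lmm)
    v_pca <- v_pca[ok]; v_lmm <- v_lmm[ok]
    lmm_better_mean <- if (metric == "srmsd") mean(v_lmm) < mean(v_pca)
                       else mean(v_lmm) > mean(v_pca)
    pw <- if (all(v_pca == v_lmm)) NA_real_ else
      suppressWarnings(stats::wilcox.test(
        if (lmm_better_mean) v_lmm else v_pca,
        if (lmm_better_mean) v_pca else v_lmm,
        paired = TRUE,
        alternative = if (metric == "srmsd") "less" else "greater",
        exact = sum(ok) <= 25))$p.value
    winner <- if (is.na(pw) || pw >= alpha / n_tests) "Tie"
              else if (lmm_better_mean) "LMM" else "PCA"
    out[[metric]] <- data.frame(
      metric = if (metric == "srmsd") "|SRMSDp|" else "AUCPR",
      best_r_pca = best$pca$r, mean_pca = best$pca$mean,
      best_r_lmm = best$lmm$r, mean_lmm = best$lmm$mean,
      calibrated_pca = best$pca$calibrated, calibrated_lmm = best$lmm$calibrated,
      p_wilcoxon = pw, winner = winner)
  }
  do.call(rbind, out)
}
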