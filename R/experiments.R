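# Scripted Monte-Carlo design experiments: the irrelevance of a
# high-sensitivity symptom, bias-detection performance grids, and the
# efficiency (sample-size / question-count) grid with the direct-sampling
# baseline.

#' Mean absolute error between two cause distributions
#'
#' `(1/J) * sum_j |est_j - truth_j|`.  Values are proportions: 0.0128
#' corresponds to a 1.28 percentage-point average deviation per cause.
#'
#' @param est,truth [csmf] vectors (or numerics) of equal length.
#' @return A nonnegative scalar.
#' @export
mean_absolute_error <- function(est, truth) {
  e <- as.numeric(est); t <- as.numeric(truth)
  if (length(e) != length(t)) stop_va("CSMF dimension mismatch")
  mean(abs(e - t))
}

#' Mean squared error between two cause distributions
#'
#' `(1/J) * sum_j (est_j - truth_j)^2`.
#'
#' @inheritParams mean_absolute_error
#' @return A nonnegative scalar; zero iff the vectors are equal.
#' @export
mean_squared_error <- function(est, truth) {
  e <- as.numeric(est); t <- as.numeric(truth)
  if (length(e) != length(t)) stop_va("CSMF dimension mismatch")
  mean((e - t)^2)
}

mc_se <- function(x) stats::sd(x) / sqrt(length(x))

new_experiment <- function(design, per_replicate, summary, seed) {
  structure(list(design = design, per_replicate = per_replicate,
                 summary = summary, seed = seed),
            class = "va_experiment")
}

#' @export
print.va_experiment <- function(x, ...) {
  cat("<va_experiment> seed", x$seed, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' High-sensitivity symptom experiment
#'
#' For each questionnaire size K, generates paired hospital/community
#' replicates with and without a symptom having 100% sensitivity for the
#' first cause (and 0% for all others) and estimates the CSMF in each.
#' Replicate estimates are averaged first and the average compared with
#' the truth — setting aside sampling variability and isolating the
#' systematic error — giving the absolute error for cause 1 and the mean
#' absolute error over all causes.  Per-replicate error vectors are kept
#' in `per_replicate` for variance-aware comparisons.  The with-arm uses
#' K-1 ordinary symptoms plus the perfect symptom (K total); the
#' without-arm uses K ordinary symptoms from the same model.  Arms share
#' replicate seeds (common random numbers), so the arm difference is
#' estimated with reduced variance.
#'
#' @param K_list questionnaire sizes (default 20, 30, 50).
#' @param replicates paired datasets per cell (the full design uses 80).
#' @param seed master seed.
#' @param config an [estimator_config] (its seed is re-derived per run).
#' @param J,n causes and deaths per sample.
#' @return A `va_experiment`; `summary` has one row per (K, arm, metric)
#'   with the Monte-Carlo mean and standard error.
#' @export
run_sensitivity_experiment <- function(K_list = c(20L, 30L, 50L),
                                       replicates = 80L, seed = 1L,
                                       config = estimator_config(),
                                       J = 10L, n = 3000L) {
  truth <- default_community_csmf(J)
  hosp_csmf <- csmf(rep(1 / J, J))
  per_rep <- list()
  rows <- list()
  for (K in K_list) {
    base <- make_symptom_model(J, K, seed = derive_seed(seed, K),
                               high_sens = TRUE)   # K ordinary + perfect
    arms <- list(
      with    = restrict_model(base, c(seq_len(K - 1L), K + 1L)),
      without = restrict_model(base, seq_len(K)))
    for (arm in names(arms)) {
      err1 <- mae <- numeric(replicates)
      ests <- matrix(NA_real_, replicates, J)
      for (r in seq_len(replicates)) {
        sd_r <- derive_seed(seed, K * 1000L + r)  # shared across arms
        hosp <- simulate_deaths(arms[[arm]], hosp_csmf, n,
                                case_control = TRUE, seed = sd_r)
        comm <- simulate_deaths(arms[[arm]], truth, n,
                                case_control = FALSE,
                                seed = derive_seed(sd_r, 1L))
        comm <- va_data(comm$symptoms, symptom_names = comm$symptom_names)
        cfg <- config
        cfg$seed <- derive_seed(sd_r, 2L)
        est <- estimate_csmf(hosp, comm, cfg)$point
        ests[r, ] <- as.numeric(est)
        err1[r] <- abs(est[1] - truth[1])
        mae[r] <- mean_absolute_error(est, truth)
      }
      per_rep[[paste0("K", K, "_", arm)]] <-
        list(estimates = ests, cause1_abs_error = err1, mae = mae)
      avg <- colMeans(ests)
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, arm = arm,
        metric = c("cause1_abs_error", "mae"),
        value = c(abs(avg[1] - as.numeric(truth)[1]),
                  mean(abs(avg - as.numeric(truth)))),
        mc_se = c(stats::sd(ests[, 1]) / sqrt(replicates),
                  mean(apply(ests, 2, stats::sd)) / sqrt(replicates)))
    }
  }
  new_experiment(list(K_list = K_list, replicates = replicates, J = J,
                      n = n, truth = truth),
                 per_rep, do.call(rbind, rows), seed)
}

#' Bias-detection performance experiment
#'
#' For each grid row `(K, n_biased, n)` and each significance level,
#' simulates the misreporting design (uniform case-control hospital,
#' front-loaded community CSMF, the first `n_biased` columns of
#' [misreport_pattern] applied to the community side), runs the iterative
#' selection, and records how many symptoms were flagged and how many of
#' those were truly biased.
#'
#' @param grid data frame with columns `K`, `n_biased`, `n`.
#' @param alpha_list significance levels to evaluate.
#' @param seed master seed.
#' @param config an [estimator_config].
#' @param replicates runs per cell (1 = single seeded run).
#' @param trace also record the forced removal-order MSE trace?  When
#'   TRUE, each run removes `max_removals` symptoms regardless of
#'   significance and stores the per-step MSE against the true community
#'   CSMF.
#' @param max_removals removal budget for `trace` mode (default
#'   `2 * n_biased`).
#' @param multiple_testing Bonferroni counting rule passed to
#'   [select_biased_symptoms]; use `"removals"` to reproduce the
#'   sequential-count benchmark runs.
#' @return A `va_experiment`; `summary` has one row per
#'   (K, n_biased, n, alpha, replicate) with `flagged` and `correct`
#'   counts; traces, when requested, sit in `per_replicate`.
#' @export
run_bias_detection_experiment <- function(grid, alpha_list = 0.05,
                                          seed = 1L,
                                          config = estimator_config(),
                                          replicates = 1L, trace = FALSE,
                                          max_removals = NULL,
                                          multiple_testing = c("candidates",
                                                               "removals")) {
  multiple_testing <- match.arg(multiple_testing)
  stopifnot(all(c("K", "n_biased", "n") %in% names(grid)))
  rows <- list()
  per_rep <- list()
  for (g in seq_len(nrow(grid))) {
    K <- grid$K[g]; nb <- grid$n_biased[g]; n <- grid$n[g]
    mis <- if (nb > 0) misreport_pattern(nb) else NULL
    if (!is.null(mis) && any(mis$symptom > K))
      stop_va("misreporting pattern names symptom ",
              max(mis$symptom), " but the design has only ", K)
    des <- sim_design(K = K, n_hospital = n, n_community = n,
                      misreports = mis, seed = derive_seed(seed, g))
    for (r in seq_len(replicates)) {
      study <- simulate_study(des, replicate = r)
      for (alpha in alpha_list) {
        cfg <- config
        cfg$seed <- derive_seed(seed, g * 10000L + r * 10L)
        key <- paste0("K", K, "_b", nb, "_n", n, "_a", alpha, "_r", r)
        if (trace) {
          res <- symptom_removal_trace(
            study$hospital, study$community, alpha = alpha, config = cfg,
            max_removals = max_removals %||% (2L * max(nb, 1L)),
            truth = study$truth, multiple_testing = multiple_testing)
          flagged <- sum(res$removed$exceeds_threshold)
          correct_set <- res$removed$index[res$removed$exceeds_threshold]
        } else {
          res <- select_biased_symptoms(study$hospital, study$community,
                                        alpha = alpha, config = cfg,
                                        multiple_testing = multiple_testing)
          flagged <- nrow(res$removed)
          correct_set <- res$removed$index
        }
        biased_idx <- if (nb > 0) misreport_pattern(nb)$symptom else integer()
        rows[[length(rows) + 1L]] <- data.frame(
          K = K, n_biased = nb, n = n, alpha = alpha, replicate = r,
          flagged = flagged,
          correct = sum(correct_set %in% biased_idx))
        per_rep[[key]] <- res
      }
    }
  }
  new_experiment(list(grid = grid, alpha_list = alpha_list,
                      replicates = replicates),
                 per_rep, do.call(rbind, rows), seed)
}

#' Efficiency experiment: error versus design choices
#'
#' Full factorial grid over causes J, questionnaire size K, and hospital
#' and community sample sizes.  For every cell, replicate studies are
#' generated (case-control uniform hospital, front-loaded community CSMF,
#' no misreporting), the CSMF estimated, and the mean absolute error per
#' cause averaged over replicates.  For each (J, community size) the
#' direct-sampling baseline — tabulating directly ascertained causes of
#' the same number of community deaths — is reported alongside as the
#' sampling-variability lower bound.
#'
#' @param J_list,K_list,n_hospital_list,n_community_list grid axes.
#' @param replicates replicate studies per cell (the full design uses 80).
#' @param seed master seed.
#' @param config an [estimator_config].
#' @return A `va_experiment`; `summary` rows carry `method`
#'   (`"subset_ls"` or `"direct_sampling"`), the grid cell, `mae`, and
#'   `mc_se`.
#' @export
run_efficiency_experiment <- function(J_list = 10L,
                                      K_list = c(10L, 20L, 30L, 50L),
                                      n_hospital_list = c(500L, 1000L, 3000L),
                                      n_community_list = c(1000L, 3000L),
                                      replicates = 80L, seed = 1L,
                                      config = estimator_config()) {
  rows <- list()
  per_rep <- list()
  cell <- 0L
  for (J in J_list) {
    truth <- default_community_csmf(J)
    for (K in K_list) for (nh in n_hospital_list) for (nc in n_community_list) {
      cell <- cell + 1L
      des <- sim_design(J = J, K = K, n_hospital = nh, n_community = nc,
                        seed = derive_seed(seed, cell))
      maes <- numeric(replicates)
      for (r in seq_len(replicates)) {
        study <- simulate_study(des, replicate = r)
        cfg <- config
        cfg$seed <- derive_seed(seed, cell * 1000L + r)
        est <- estimate_csmf(study$hospital, study$community, cfg)$point
        maes[r] <- mean_absolute_error(est, truth)
      }
      per_rep[[paste0("J", J, "_K", K, "_nh", nh, "_nc", nc)]] <- maes
      rows[[length(rows) + 1L]] <- data.frame(
        method = "subset_ls", J = J, K = K, n_hospital = nh,
        n_community = nc, mae = mean(maes), mc_se = mc_se(maes))
    }
    for (nc in n_community_list) {
      maes <- vapply(seq_len(replicates), function(r)
        mean_absolute_error(
          direct_sampling_estimate(truth, nc,
                                   seed = derive_seed(seed, 900000L + nc + r)),
          truth), numeric(1))
      per_rep[[paste0("J", J, "_direct_nc", nc)]] <- maes
      rows[[length(rows) + 1L]] <- data.frame(
        method = "direct_sampling", J = J, K = NA_integer_,
        n_hospital = NA_integer_, n_community = nc,
        mae = mean(maes), mc_se = mc_se(maes))
    }
  }
  new_experiment(list(J_list = J_list, K_list = K_list,
                      n_hospital_list = n_hospital_list,
                      n_community_list = n_community_list,
                      replicates = replicates),
                 per_rep, do.call(rbind, rows), seed)
}
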