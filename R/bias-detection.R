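# Detection of biased ("misreported") symptom questions.  A symptom whose
# reporting given cause differs between hospital and community violates
# the key assumption and shows up as an outlying residual when the
# community marginal prevalence of each symptom is compared with the
# prevalence predicted from the estimated CSMF and the hospital
# conditionals.  Symptoms are removed one at a time by the largest
# standardised residual, with a Bonferroni-adjusted critical value.

#' Predicted community symptom prevalence under the key assumption
#'
#' For each active symptom k, computes
#' `sum_j P^h(S_k = 1 | D = j) * P(D = j)`: the community marginal
#' prevalence implied by the hospital conditionals and an estimated CSMF.
#'
#' @param csmf_est a [csmf] (or `csmf_estimate`) for P(D).
#' @param hospital a [va_data] with cause labels.
#' @param active integer indices of the symptoms to predict (default all).
#' @return A named numeric vector of predicted prevalences in `[0, 1]`.
#' @export
predicted_symptom_prevalence <- function(csmf_est, hospital,
                                         active = seq_len(ncol(hospital$symptoms))) {
  if (inherits(csmf_est, "csmf_estimate")) csmf_est <- csmf_est$point
  stopifnot(inherits(hospital, "va_data"))
  p_d <- as.numeric(csmf_est)
  J <- n_causes(hospital)
  if (length(p_d) != J) stop_va("CSMF dimension does not match causes")
  n_j <- tabulate(hospital$cause, nbins = J)
  if (any(n_j == 0L))
    stop_va("no hospital records for cause(s): ",
            paste(hospital$cause_names[n_j == 0L], collapse = ", "))
  q <- rowsum(hospital$symptoms[, active, drop = FALSE], hospital$cause) / n_j
  setNames(as.numeric(crossprod(q, p_d)), hospital$symptom_names[active])
}

#' Residual t statistics for symptom prevalences
#'
#' Treats each active symptom's observed community prevalence as a data
#' point and the model-predicted prevalence as its fit; the residuals
#' `e_k = observed - predicted` are standardised by the residual standard
#' deviation `sigma_hat = sqrt(sum(e_k^2) / (K0 - 1))`, giving statistics
#' approximately t-distributed with `K0 - 1` degrees of freedom under the
#' key assumption.
#'
#' @param community a [va_data].
#' @param predicted vector of predicted prevalences for `active`.
#' @param active integer indices of active symptoms (K0 of them, K0 >= 2).
#' @param sigma optional length-K0 vector of per-symptom standard errors
#'   (the analytic variance rule, see [select_biased_symptoms]); when
#'   `NULL` the pooled residual standard deviation
#'   `sqrt(sum(e^2) / (K0 - 1))` is used for every symptom.
#' @return A list of class `symptom_test_stats` with `observed`,
#'   `predicted`, `residuals`, `sigma_hat` (length 1 for the pooled rule,
#'   length K0 otherwise), `t_stats`, `df`, and `degenerate` (TRUE when
#'   all residuals are zero, in which case the t statistics are defined
#'   as zero).
#' @export
residual_t_statistics <- function(community, predicted,
                                  active = seq_len(ncol(community$symptoms)),
                                  sigma = NULL) {
  stopifnot(inherits(community, "va_data"))
  active <- as.integer(active)
  K0 <- length(active)
  if (K0 < 2L) stop_va("need at least 2 active symptoms")
  if (length(predicted) != K0)
    stop_va("predicted prevalence length does not match active symptoms")
  observed <- colMeans(community$symptoms[, active, drop = FALSE])
  e <- as.numeric(observed) - as.numeric(predicted)
  if (is.null(sigma)) sigma <- sqrt(sum(e^2) / (K0 - 1))
  degenerate <- all(sigma == 0) || all(e == 0)
  t_stats <- if (degenerate) rep(0, K0) else e / sigma
  nm <- community$symptom_names[active]
  structure(list(observed = setNames(as.numeric(observed), nm),
                 predicted = setNames(as.numeric(predicted), nm),
                 residuals = setNames(e, nm),
                 sigma_hat = sigma,
                 t_stats = setNames(t_stats, nm),
                 df = K0 - 1L, degenerate = degenerate),
            class = "symptom_test_stats")
}

# Per-symptom standard error of the prevalence residual from the two
# binomial sampling layers: the community tabulation of the observed
# marginal and the hospital estimates of the per-cause prevalences
# weighted by the estimated CSMF.
analytic_residual_sd <- function(obs, q, pd, n_j, L) {
  sqrt(pmax(obs * (1 - obs), 0.25 / L) / L +
         as.numeric(crossprod(q * (1 - q), pd^2 / n_j)))
}

# One selection sweep shared by select_biased_symptoms() and
# symptom_removal_trace().  Removal is always by largest |t|; `forced`
# bypasses the significance stopping rule.
run_selection <- function(hospital, community, config, alpha,
                          min_symptoms, max_removals, forced,
                          truth = NULL, variance_rule = "analytic",
                          multiple_testing = "candidates") {
  K <- n_symptoms(hospital)
  active <- seq_len(K)
  removed <- data.frame(symptom = character(), index = integer(),
                        iteration = integer(), t_value = numeric(),
                        critical_value = numeric(),
                        stringsAsFactors = FALSE)
  per_iter_csmf <- list()
  per_iter_mse <- numeric()
  stopped <- NULL
  iter <- 0L
  repeat {
    iter <- iter + 1L
    K0 <- length(active)
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, iter)
    cfg_i$subset_size <- min(config$subset_size, K0)
    h_i <- restrict_symptoms(hospital, active)
    c_i <- restrict_symptoms(community, active)
    est <- estimate_csmf(h_i, c_i, cfg_i)
    per_iter_csmf[[iter]] <- est$point
    if (!is.null(truth))
      per_iter_mse[iter] <- mean_squared_error(est$point, truth)

    if (K0 <= min_symptoms) { stopped <- "floor reached"; break }
    pred <- predicted_symptom_prevalence(est$point, h_i)
    sigma <- NULL
    if (variance_rule == "analytic") {
      pd <- as.numeric(est$point)
      n_j <- tabulate(h_i$cause, nbins = n_causes(h_i))
      q <- rowsum(h_i$symptoms + 0, h_i$cause) / n_j
      obs <- colMeans(c_i$symptoms)
      sigma <- analytic_residual_sd(obs, q, pd, n_j, n_records(c_i))
    }
    stats <- residual_t_statistics(c_i, pred, sigma = sigma)
    if (stats$degenerate) { stopped <- "all residuals zero"; break }
    m <- if (multiple_testing == "candidates") K  # every symptom scanned
         else nrow(removed) + 1L                  # removals so far + 1
    crit <- qt(1 - alpha / (2 * m), df = stats$df)
    k_star <- which.max(abs(stats$t_stats))
    t_star <- stats$t_stats[k_star]
    exceeds <- abs(t_star) > crit
    if (!forced && !exceeds) { stopped <- "no symptom exceeds threshold"; break }
    removed <- rbind(removed, data.frame(
      symptom = names(stats$t_stats)[k_star],
      index = active[k_star], iteration = iter, t_value = as.numeric(t_star),
      critical_value = crit, exceeds_threshold = exceeds,
      stringsAsFactors = FALSE))
    active <- active[-k_star]
    if (!is.null(max_removals) && nrow(removed) >= max_removals) {
      stopped <- "removal budget reached"; break
    }
  }
  structure(list(removed = removed, final_symptoms = hospital$symptom_names[active],
                 final_indices = active, per_iteration_csmf = per_iter_csmf,
                 per_iteration_mse = if (!is.null(truth)) per_iter_mse,
                 alpha = alpha, stopped_reason = stopped,
                 config = config),
            class = "bias_selection")
}

# Restrict a dataset to a subset of symptom columns.
restrict_symptoms <- function(x, idx) {
  va_data(x$symptoms[, idx, drop = FALSE],
          cause = if (!is.null(x$cause)) x$cause_names[x$cause],
          stratum = x$stratum,
          symptom_names = x$symptom_names[idx],
          cause_names = x$cause_names)
}

#' Iteratively select biased symptom questions
#'
#' Implements the iterative screening procedure: estimate the CSMF on the
#' active symptoms, standardise the prevalence residuals, and move the
#' symptom with the largest absolute t statistic to the removed set when
#' it exceeds a Bonferroni-adjusted two-sided critical value at
#' `K0 - 1` degrees of freedom.  Stops when no symptom exceeds the
#' threshold, or when the retained set reaches `min_symptoms`.
#' Each iteration re-estimates the CSMF with a fresh subset-draw stream
#' derived from the master seed and the iteration index, so a full run is
#' reproducible.
#'
#' @param hospital,community [va_data] objects sharing symptom columns.
#' @param alpha familywise significance level in `(0, 0.5]`.
#' @param config an [estimator_config].
#' @param min_symptoms smallest retained symptom set (floor preventing
#'   degenerate estimation; default 3).
#' @param truth optional [csmf] of true community fractions; when given,
#'   the per-iteration mean squared error is recorded (validation mode).
#' @param variance_rule how residuals are standardised: `"analytic"`
#'   (default) uses the per-symptom binomial standard error of the
#'   residual (community tabulation noise plus CSMF-weighted hospital
#'   prevalence noise), which keeps power for symptoms with small
#'   marginals and is not inflated by the biased symptoms themselves;
#'   `"pooled"` uses the residual standard deviation over the active
#'   symptoms with `K0 - 1` degrees of freedom.
#' @param multiple_testing how the Bonferroni denominator m in the
#'   per-iteration test level `alpha / m` is counted.  `"candidates"`
#'   (default) counts every symptom scanned, `m = K`, which controls the
#'   familywise error of the whole screen at `alpha` under the null.
#'   `"removals"` counts only the symptoms already removed plus the one
#'   under test, `m = |B| + 1`; this sequential count gives the screen
#'   more power but lets the familywise error under the null grow with
#'   the questionnaire length (the first iteration tests the maximum of
#'   K0 statistics at an unadjusted level).
#' @return A `bias_selection` object: `removed` (data frame: symptom,
#'   index, iteration, t value, critical value), `final_symptoms`,
#'   `per_iteration_csmf`, optional `per_iteration_mse`, `alpha`, and
#'   `stopped_reason`.
#' @export
select_biased_symptoms <- function(hospital, community, alpha = 0.05,
                                   config = estimator_config(),
                                   min_symptoms = 3L, truth = NULL,
                                   variance_rule = c("analytic", "pooled"),
                                   multiple_testing = c("candidates",
                                                        "removals")) {
  stopifnot(alpha > 0, alpha <= 0.5)
  variance_rule <- match.arg(variance_rule)
  multiple_testing <- match.arg(multiple_testing)
  if (n_symptoms(hospital) < 3L) stop_va("need at least 3 symptoms")
  run_selection(hospital, community, config, alpha, min_symptoms,
                max_removals = NULL, forced = FALSE, truth = truth,
                variance_rule = variance_rule,
                multiple_testing = multiple_testing)
}

#' Forced symptom-removal trace
#'
#' Repeats the removal step of [select_biased_symptoms] without the
#' significance stopping rule: at every iteration the symptom with the
#' largest absolute t statistic is removed, down to `min_symptoms` or a
#' removal budget.  With `truth` supplied this reproduces the
#' mean-squared-error-versus-removals trace used to visualise the
#' bias-efficiency trade-off (MSE falls while biased symptoms are removed,
#' then rises as informative unbiased symptoms are discarded).
#'
#' @inheritParams select_biased_symptoms
#' @param max_removals maximum number of symptoms to remove.
#' @return A `bias_selection` object; `removed$exceeds_threshold` records
#'   which removals would also have passed the `alpha`-level rule.
#' @export
symptom_removal_trace <- function(hospital, community, alpha = 0.05,
                                  config = estimator_config(),
                                  max_removals = NULL, min_symptoms = 3L,
                                  truth = NULL,
                                  variance_rule = c("analytic", "pooled"),
                                  multiple_testing = c("candidates",
                                                       "removals")) {
  variance_rule <- match.arg(variance_rule)
  multiple_testing <- match.arg(multiple_testing)
  run_selection(hospital, community, config, alpha, min_symptoms,
                max_removals = max_removals, forced = TRUE, truth = truth,
                variance_rule = variance_rule,
                multiple_testing = multiple_testing)
}

#' @export
print.bias_selection <- function(x, ...) {
  cat("<bias_selection> alpha =", x$alpha, "|", nrow(x$removed),
      "symptom(s) removed |", x$stopped_reason, "\n")
  if (nrow(x$removed))
    print(x$removed[, c("symptom", "iteration", "t_value", "critical_value")],
          row.names = FALSE)
  invisible(x)
}
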