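# CSMF estimation by back-calculation.  The decomposition
#   P(S) = P(S|D) P(D)
# holds exactly for any symptom subset; P(S) is tabulated from the
# community, P(S|D) from the hospital (the key assumption being that the
# conditional distribution of symptom profiles given cause is the same in
# both samples), and P(D) is recovered by least squares constrained to the
# probability simplex.  Because 2^K is huge for a full questionnaire, the
# system is solved on many random symptom subsets and the solutions are
# averaged.

#' Estimator configuration
#'
#' @param subset_size number of symptoms per random subset draw (B).  The
#'   default 8 keeps the 2^B = 256 profile cells estimable from samples of
#'   a few hundred to a few thousand deaths while retaining joint-profile
#'   information.
#' @param n_subsets number of random subset draws to average over.
#' @param seed integer seed controlling the subset draws (recorded in the
#'   estimate for reproducibility).
#' @param solver_tolerance numerical tolerance of the constrained solver.
#' @param bootstrap_reps nonparametric bootstrap replicates (resampling
#'   records of both samples) for standard errors; 0 = point estimate only.
#' @param smoothing empirical-Bayes shrinkage of each per-cause profile
#'   distribution toward the product of its within-cause symptom
#'   marginals.  The shrinkage weight is chosen per cause from the data
#'   (estimated sampling variance over estimated distance to the product
#'   form), so it vanishes as the hospital sample grows and the estimator
#'   remains assumption-free asymptotically; at realistic sample sizes it
#'   removes most of the multinomial noise in the sparse 2^B-cell
#'   tabulations.
#' @param variance_correction subtract the (delta-method) estimate of the
#'   remaining sampling-noise variance of the conditional profile matrix
#'   from the least-squares Gram matrix before solving.  Noise in the
#'   design matrix otherwise acts as a ridge penalty that shrinks the
#'   estimated fractions toward uniform (errors-in-variables
#'   attenuation); the corrected quadratic programme is unbiased for the
#'   population objective.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(subset_size = 8L, n_subsets = 300L, seed = 1L,
                             solver_tolerance = 1e-9, bootstrap_reps = 0L,
                             smoothing = TRUE, variance_correction = TRUE) {
  stopifnot(subset_size >= 1, n_subsets >= 1, bootstrap_reps >= 0,
            solver_tolerance >= 0)
  structure(list(subset_size = as.integer(subset_size),
                 n_subsets = as.integer(n_subsets),
                 seed = as.integer(seed),
                 solver_tolerance = solver_tolerance,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 smoothing = isTRUE(smoothing),
                 variance_correction = isTRUE(variance_correction)),
            class = "estimator_config")
}

# Empirical-Bayes smoothing of a conditional profile matrix.  For each
# cause the raw 2^B-cell tabulation p-hat is shrunk toward the product of
# the within-cause symptom marginals q:
#   p-tilde = (1 - w) p-hat + w prod_k q_k^{s_k} (1 - q_k)^{1 - s_k},
# with w = V / (V + D), V the estimated total sampling variance of p-hat
# and D the estimated squared distance between the true cell vector and
# the product form (observed distance minus V, floored at 0).  Under
# within-cause dependence D stays positive and w shrinks; as n_j grows
# w -> 0 and the raw tabulation is recovered.  Attribute "omega" carries
# the delta-method estimate of the residual noise trace per cause, used
# by the errors-in-variables correction.
smooth_profile_cond <- function(m, q_sub) {
  B <- length(m$subset)
  J <- ncol(m$matrix)
  pat <- profile_patterns(B)
  eps <- 1e-12
  lq <- log(pmax(q_sub, eps))
  l1q <- log(pmax(1 - q_sub, eps))
  tgt <- exp(pat %*% t(lq) + (1 - pat) %*% t(l1q))  # 2^B x J product form
  omega <- numeric(J)
  for (j in seq_len(J)) {
    n_j <- m$n_per_cause[j]
    p <- m$matrix[, j]
    q <- q_sub[j, ]
    V <- sum(p * (1 - p)) / max(n_j - 1L, 1L)
    D <- max(sum((p - tgt[, j])^2) - V, 0)
    w <- V / (V + D + eps)
    m$matrix[, j] <- (1 - w) * p + w * tgt[, j]
    s2 <- q^2 + (1 - q)^2
    Vt <- 2 * prod(s2) * sum(q * (1 - q) / n_j / s2)  # var of product form
    omega[j] <- (1 - w)^2 * V + w^2 * Vt + 2 * w * (1 - w) * Vt
  }
  attr(m, "omega") <- omega
  m
}

# Simplex-constrained quadratic programme min b'Gb - 2c'b, used for the
# errors-in-variables-corrected per-subset solves.  The corrected Gram
# can lose positive definiteness to sampling noise; eigenvalues are
# floored at 1e-6 before the problem is rewritten as an augmented
# nonnegative least-squares system.
solve_simplex_qp <- function(G, cc, cause_names, tolerance = 1e-9) {
  J <- ncol(G)
  ee <- eigen(G, symmetric = TRUE)
  lam <- pmax(ee$values, 1e-6)
  C <- sqrt(lam) * t(ee$vectors)
  d <- as.numeric(t(ee$vectors) %*% cc) / sqrt(lam)
  w <- 1e2
  A <- rbind(C, rep(w, J), 1e-4 * diag(J))
  x <- pracma::lsqnonneg(A, c(d, w, rep(0, J)))$x
  x[x < tolerance] <- 0
  if (sum(x) <= 0) x <- rep(1 / J, J)
  csmf(x / sum(x), cause_names)
}

#' Solve one simplex-constrained least-squares system
#'
#' Finds the cause distribution `beta` minimising
#' `|| p_s - M beta ||^2` subject to `beta >= 0` and `sum(beta) = 1`,
#' i.e. the exact back-calculation of P(D) from a tabulated P(S) and an
#' estimated P(S|D) on one symptom subset.  Implemented as nonnegative
#' least squares on an augmented system carrying a heavily weighted
#' sum-to-one row, followed by renormalisation.
#'
#' @param p_s a [tabulate_profiles] result (community P(S)).
#' @param m an [estimate_conditional_profiles] result (hospital P(S|D)).
#' @param tolerance nonnegative solver tolerance; solutions are
#'   renormalised onto the simplex.
#' @return A [csmf] with attributes `residual_norm` (achieved
#'   `||p_s - M beta||`) and `rank_deficient` (TRUE when M has column rank
#'   < J, in which case the minimiser need not be unique; one feasible
#'   minimiser is returned).
#' @export
solve_simplex_ls <- function(p_s, m, tolerance = 1e-9) {
  stopifnot(inherits(p_s, "profile_dist"), inherits(m, "profile_cond"))
  if (!identical(p_s$subset, m$subset))
    stop_va("profile distribution and conditional matrix use different ",
            "symptom subsets")
  M <- m$matrix
  b <- p_s$probabilities
  if (length(b) != nrow(M)) stop_va("profile dimension mismatch")
  J <- ncol(M)
  if (J == 1L) {
    out <- csmf(1, m$cause_names)
    attr(out, "residual_norm") <- sqrt(sum((b - M[, 1])^2))
    attr(out, "rank_deficient") <- FALSE
    return(out)
  }
  w <- 1e2  # sum-to-one row weight; residuals are O(1) so violation ~ 1/w^2
  ridge <- 1e-4  # keeps the augmented system full column rank when J > 2^B
  C <- rbind(M, rep(w, J), ridge * diag(J))
  d <- c(b, w, rep(0, J))
  x <- pracma::lsqnonneg(C, d)$x
  x[x < tolerance] <- 0
  if (sum(x) <= 0) x <- rep(1 / J, J)  # degenerate all-zero guard
  beta <- x / sum(x)
  out <- csmf(beta, m$cause_names)
  attr(out, "residual_norm") <- sqrt(sum((b - M %*% beta)^2))
  attr(out, "rank_deficient") <- qr(M)$rank < J
  out
}

# J x K within-cause symptom prevalences from hospital data.
cause_marginals <- function(hospital) {
  n_j <- tabulate(hospital$cause, nbins = n_causes(hospital))
  rowsum(hospital$symptoms + 0, hospital$cause) / n_j
}

# Draw the list of random symptom subsets for one estimation run.
draw_subsets <- function(K, B, n_subsets, seed) {
  if (B > K) stop_va("subset_size ", B, " exceeds number of symptoms ", K)
  with_seed(seed, lapply(seq_len(n_subsets), function(i) sort(sample.int(K, B))))
}

# Shared core: estimate the CSMF given a function building the conditional
# matrix for a subset (plain or stratum-weighted).
estimate_csmf_core <- function(community, cond_fun, cause_names, config) {
  K <- n_symptoms(community)
  subsets <- draw_subsets(K, min(config$subset_size, K), config$n_subsets,
                          config$seed)
  J <- length(cause_names)
  per_subset <- matrix(NA_real_, nrow = config$n_subsets, ncol = J,
                       dimnames = list(NULL, cause_names))
  resid <- numeric(config$n_subsets)
  rankdef <- logical(config$n_subsets)
  for (s in seq_along(subsets)) {
    ps <- tabulate_profiles(community, subsets[[s]])
    m <- cond_fun(subsets[[s]])
    omega <- attr(m, "omega")
    if (config$variance_correction && !is.null(omega)) {
      b <- ps$probabilities
      sol <- solve_simplex_qp(crossprod(m$matrix) - diag(omega),
                              crossprod(m$matrix, b), cause_names,
                              config$solver_tolerance)
      per_subset[s, ] <- as.numeric(sol)
      resid[s] <- sqrt(sum((b - m$matrix %*% as.numeric(sol))^2))
      rankdef[s] <- FALSE
    } else {
      sol <- solve_simplex_ls(ps, m, config$solver_tolerance)
      per_subset[s, ] <- as.numeric(sol)
      resid[s] <- attr(sol, "residual_norm")
      rankdef[s] <- attr(sol, "rank_deficient")
    }
  }
  point <- colMeans(per_subset)
  point <- pmax(point, 0)
  point <- point / sum(point)  # guards float drift; mean is already on simplex
  structure(
    list(point = csmf(point, cause_names), per_subset = per_subset,
         standard_errors = NULL, config = config,
         diagnostics = list(residual_norms = resid,
                            rank_deficient_draws = sum(rankdef),
                            seed = config$seed)),
    class = "csmf_estimate")
}

#' Estimate the community cause-specific mortality fractions
#'
#' Runs the subset-averaged back-calculation: for each of `n_subsets`
#' seeded random subsets of `subset_size` symptoms, tabulates the
#' community profile distribution and the per-cause hospital profile
#' distributions, solves the simplex-constrained least-squares system, and
#' averages the per-subset solutions.
#'
#' @param hospital a [va_data] with cause labels (training sample).
#' @param community a [va_data] with the same symptoms, no labels needed.
#' @param config an [estimator_config].
#' @return A `csmf_estimate`: list with `point` ([csmf]), `per_subset`
#'   (n_subsets-by-J matrix), `standard_errors` (when
#'   `bootstrap_reps > 0`), `config`, and solver `diagnostics`.
#' @export
estimate_csmf <- function(hospital, community, config = estimator_config()) {
  stopifnot(inherits(hospital, "va_data"), inherits(community, "va_data"))
  if (!identical(hospital$symptom_names, community$symptom_names))
    stop_va("hospital and community datasets must share the same symptom ",
            "columns in the same order")
  q_full <- if (config$smoothing) cause_marginals(hospital)
  cond_fun <- function(ss) {
    m <- estimate_conditional_profiles(hospital, ss)
    if (config$smoothing)
      m <- smooth_profile_cond(m, q_full[, ss, drop = FALSE])
    m
  }
  est <- estimate_csmf_core(community, cond_fun, hospital$cause_names,
                            config)
  if (config$bootstrap_reps > 0L)
    est$standard_errors <- bootstrap_se(hospital, community, config)
  est
}

# Nonparametric bootstrap over records of both samples.  Not part of the
# original estimator; provided as uncertainty plumbing.
bootstrap_se <- function(hospital, community, config) {
  J <- n_causes(hospital)
  reps <- matrix(NA_real_, nrow = config$bootstrap_reps, ncol = J)
  for (r in seq_len(config$bootstrap_reps)) {
    sd_r <- derive_seed(config$seed, r)
    idx <- with_seed(sd_r, list(
      h = sample.int(n_records(hospital), replace = TRUE),
      c = sample.int(n_records(community), replace = TRUE)))
    h_r <- va_data_rows(hospital, idx$h)
    c_r <- va_data_rows(community, idx$c)
    cfg_r <- config
    cfg_r$seed <- derive_seed(config$seed, r + config$bootstrap_reps)
    cfg_r$bootstrap_reps <- 0L
    reps[r, ] <- tryCatch(as.numeric(estimate_csmf(h_r, c_r, cfg_r)$point),
                          error = function(e) rep(NA_real_, J))
  }
  apply(reps, 2, sd, na.rm = TRUE)
}

#' @export
print.csmf_estimate <- function(x, digits = 4, ...) {
  cat("<csmf_estimate> ", nrow(x$per_subset), " subset draws of size ",
      x$config$subset_size, ", seed ", x$config$seed, "\n", sep = "")
  tab <- data.frame(cause = names(x$point),
                    fraction = round(as.numeric(x$point), digits))
  if (!is.null(x$standard_errors))
    tab$se <- round(x$standard_errors, digits)
  print(tab, row.names = FALSE)
  if (x$diagnostics$rank_deficient_draws > 0)
    cat("note:", x$diagnostics$rank_deficient_draws,
        "draw(s) had a rank-deficient conditional matrix\n")
  invisible(x)
}

#' Stratified CSMF estimation
#'
#' Adjusts for a known compositional difference between hospital and
#' community (e.g. age group): the hospital conditional profile
#' distribution is estimated within each stratum and combined as a
#' weighted average with the community stratum distribution as weights,
#' before solving the same constrained least-squares systems.
#'
#' @param hospital,community [va_data] objects carrying stratum labels.
#' @param stratum_weights named numeric vector: the community distribution
#'   of the stratifying variable (must sum to 1 within 1e-6; every named
#'   stratum must appear in the hospital data).
#' @param config an [estimator_config].
#' @return A `csmf_estimate`, as for [estimate_csmf].
#' @export
stratified_estimate_csmf <- function(hospital, community, stratum_weights,
                                     config = estimator_config()) {
  stopifnot(inherits(hospital, "va_data"), inherits(community, "va_data"))
  if (is.null(hospital$stratum) || is.null(community$stratum))
    stop_va("both datasets must carry stratum labels")
  if (!identical(hospital$symptom_names, community$symptom_names))
    stop_va("hospital and community datasets must share the same symptom ",
            "columns in the same order")
  w <- stratum_weights
  if (is.null(names(w)) || any(!nzchar(names(w))))
    stop_va("stratum_weights must be a named vector")
  if (abs(sum(w) - 1) > 1e-6)
    stop_va("stratum weights must sum to 1 (got ", format(sum(w)), ")")
  hosp_strata <- levels(hospital$stratum)
  missing_strata <- setdiff(names(w), hosp_strata)
  if (length(missing_strata))
    stop_va("stratum/strata absent from hospital data: ",
            paste(missing_strata, collapse = ", "))

  hosp_by_stratum <- lapply(names(w), function(a)
    va_data_rows(hospital, which(hospital$stratum == a)))
  names(hosp_by_stratum) <- names(w)
  q_by_stratum <- if (config$smoothing)
    lapply(hosp_by_stratum, cause_marginals)

  cond_fun <- function(ss) {
    parts <- lapply(names(w), function(a) {
      p <- estimate_conditional_profiles(hosp_by_stratum[[a]], ss)
      if (config$smoothing)
        p <- smooth_profile_cond(p, q_by_stratum[[a]][, ss, drop = FALSE])
      p
    })
    mat <- Reduce(`+`, Map(function(p, wa) p$matrix * wa, parts, w))
    out <- structure(
      list(subset = parts[[1]]$subset, matrix = mat,
           cause_names = hospital$cause_names,
           n_per_cause = Reduce(`+`, lapply(parts, `[[`, "n_per_cause"))),
      class = "profile_cond")
    if (config$smoothing)
      attr(out, "omega") <- Reduce(`+`, Map(function(p, wa)
        attr(p, "omega") * wa^2, parts, w))
    out
  }
  estimate_csmf_core(community, cond_fun, hospital$cause_names, config)
}

#' Classify an individual death by Bayes rule
#'
#' Computes the posterior probability of each cause for one symptom
#' profile:
#' `P(D=j | S=s) \propto P(D=j) * prod_k q_jk^{s_k} (1-q_jk)^{1-s_k}`,
#' where the prior `P(D=j)` is the estimated community CSMF and `q_jk` is
#' the hospital-estimated prevalence of symptom k given cause j, under a
#' conditional-independence assumption (needed for individual
#' classification but not for CSMF estimation).  The marginal P(S=s)
#' cancels under normalisation; when `community` is supplied its direct
#' tabulation is attached as a diagnostic.
#'
#' @param profile length-K 0/1 vector of symptom responses.
#' @param hospital a [va_data] with cause labels.
#' @param csmf_est a [csmf] (or `csmf_estimate`) used as the prior P(D).
#' @param community optional [va_data]; adds attribute
#'   `profile_prob_community`, the empirical frequency of exactly this
#'   profile in the community sample.
#' @return A named posterior probability vector over causes (sums to 1),
#'   with attribute `log_likelihood` per cause.  Hospital prevalences are
#'   clipped to `[1/(2 n_j), 1 - 1/(2 n_j)]` (continuity correction) so no
#'   observed profile gets zero likelihood.
#' @export
classify_individual <- function(profile, hospital, csmf_est,
                                community = NULL) {
  if (inherits(csmf_est, "csmf_estimate")) csmf_est <- csmf_est$point
  stopifnot(inherits(hospital, "va_data"))
  prior <- as.numeric(csmf_est)
  J <- n_causes(hospital)
  if (length(prior) != J) stop_va("CSMF dimension does not match causes")
  profile <- as.numeric(profile)
  if (length(profile) != n_symptoms(hospital) ||
      !all(profile %in% c(0, 1)))
    stop_va("profile must be a length-K 0/1 vector")
  n_j <- tabulate(hospital$cause, nbins = J)
  if (any(n_j == 0L))
    stop_va("no hospital records for cause(s): ",
            paste(hospital$cause_names[n_j == 0L], collapse = ", "))
  q <- rowsum(hospital$symptoms, hospital$cause) / n_j  # J x K prevalence
  lo <- 1 / (2 * n_j)
  q <- pmin(pmax(q, lo), 1 - lo)
  loglik <- as.numeric(log(q) %*% profile + log(1 - q) %*% (1 - profile))
  lp <- log(pmax(prior, .Machine$double.xmin)) + loglik
  lp[prior == 0] <- -Inf
  post <- exp(lp - max(lp))
  post <- post / sum(post)
  names(post) <- hospital$cause_names
  attr(post, "log_likelihood") <- setNames(loglik, hospital$cause_names)
  if (!is.null(community)) {
    hits <- colSums(t(community$symptoms) == profile) == length(profile)
    attr(post, "profile_prob_community") <- mean(hits)
  }
  post
}
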