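# Synthetic verbal-autopsy data: cause-conditional Bernoulli symptom
# models (symptoms independent given cause), case-control or random
# hospital sampling, an optional perfectly sensitive/specific symptom, and
# community-side misreporting shifts that break the key assumption by a
# controlled number of percentage points of marginal prevalence.

#' Build a cause-conditional symptom model
#'
#' Draws a J-by-K matrix of symptom sensitivities
#' `p_jk = P(S_k = 1 | D = j)` i.i.d. Uniform(`p_min`, `s_max`).  The
#' floor `p_min` keeps every symptom weakly informative (specificity below
#' one but above zero); the cap `s_max` bounds the sensitivity of every
#' ordinary symptom.  With `high_sens = TRUE` an extra symptom is appended
#' with sensitivity 1 for the first cause and 0 elsewhere — a perfectly
#' sensitive and specific marker of cause 1.
#'
#' @param J number of causes (>= 2 when `high_sens`).
#' @param K number of ordinary symptoms.
#' @param seed integer seed (same seed, same matrix).
#' @param s_max maximum sensitivity of ordinary symptoms (default 0.3).
#' @param high_sens append the perfect symptom for cause 1?
#' @param p_min minimum sensitivity (default 0.02).
#' @param sens_ranges optional K-by-2 matrix of per-symptom sensitivity
#'   ranges overriding `(p_min, s_max)`; used by designs that need
#'   particular marginal prevalences (e.g. room for large misreporting
#'   shifts).
#' @return A list of class `symptom_model`: `sensitivities` (J-by-K or
#'   J-by-(K+1)), `cause_names`, `symptom_names`, `high_sens_index`
#'   (or `NA`), `seed`.
#' @export
make_symptom_model <- function(J, K, seed = 1L, s_max = 0.3,
                               high_sens = FALSE, p_min = 0.02,
                               sens_ranges = NULL) {
  stopifnot(J >= 1, K >= 1, s_max > 0, s_max <= 1, p_min >= 0,
            p_min < s_max)
  if (high_sens && J < 2) stop_va("high-sensitivity symptom needs J >= 2")
  p <- with_seed(seed, {
    u <- matrix(runif(J * K), nrow = J)
    if (is.null(sens_ranges)) {
      p_min + u * (s_max - p_min)
    } else {
      stopifnot(nrow(sens_ranges) == K, ncol(sens_ranges) == 2)
      lo <- matrix(sens_ranges[, 1], nrow = J, ncol = K, byrow = TRUE)
      hi <- matrix(sens_ranges[, 2], nrow = J, ncol = K, byrow = TRUE)
      lo + u * (hi - lo)
    }
  })
  hs_index <- NA_integer_
  if (high_sens) {
    p <- cbind(p, c(1, rep(0, J - 1)))
    hs_index <- as.integer(K) + 1L
  }
  rownames(p) <- paste0("cause", seq_len(J))
  colnames(p) <- paste0("s", seq_len(ncol(p)))
  structure(list(sensitivities = p, cause_names = rownames(p),
                 symptom_names = colnames(p), high_sens_index = hs_index,
                 seed = as.integer(seed)),
            class = "symptom_model")
}

#' @export
print.symptom_model <- function(x, ...) {
  cat("<symptom_model> ", nrow(x$sensitivities), " causes x ",
      ncol(x$sensitivities), " symptoms",
      if (!is.na(x$high_sens_index))
        paste0(" (incl. perfect symptom at column ", x$high_sens_index, ")"),
      "\n", sep = "")
  invisible(x)
}

# Keep a subset of model symptoms (used to build paired experiment arms).
restrict_model <- function(model, idx) {
  m <- model
  m$sensitivities <- model$sensitivities[, idx, drop = FALSE]
  m$symptom_names <- model$symptom_names[idx]
  m$high_sens_index <- if (!is.na(model$high_sens_index) &&
                           model$high_sens_index %in% idx)
    match(model$high_sens_index, idx) else NA_integer_
  m
}

#' Simulate deaths from a symptom model
#'
#' Draws `n` deaths: causes either i.i.d. from `true_csmf` (random
#' sampling, the community design) or with fixed per-cause counts of
#' `n/J` each (case-control sampling, the usual hospital design; any
#' remainder goes to the first causes).  Given its cause, each symptom is
#' an independent Bernoulli draw with the model sensitivity.  An optional
#' block-dependence hook induces positive within-block correlation for
#' robustness experiments.
#'
#' @param model a [make_symptom_model] result.
#' @param true_csmf a [csmf] (or numeric summing to 1) of length J.
#' @param n number of deaths.
#' @param case_control fixed equal cause counts instead of random draws?
#' @param seed integer seed.
#' @param dependence optional list `(blocks, rho)`: `blocks` assigns each
#'   symptom to a block; within a record, all symptoms of a block share
#'   one uniform variate with probability `rho`, correlating their
#'   responses.  `NULL` (default) keeps symptoms independent given cause.
#' @return A [va_data] with cause labels.
#' @export
simulate_deaths <- function(model, true_csmf, n, case_control = FALSE,
                            seed = 1L, dependence = NULL) {
  stopifnot(inherits(model, "symptom_model"), n >= 1)
  p <- model$sensitivities
  J <- nrow(p); K <- ncol(p)
  f <- as.numeric(true_csmf)
  if (length(f) != J) stop_va("CSMF length does not match model causes")
  if (abs(sum(f) - 1) > 1e-8) stop_va("true_csmf must sum to 1")
  if (case_control && n < J)
    stop_va("case-control sampling needs n >= J")
  with_seed(seed, {
    if (case_control) {
      base <- n %/% J
      counts <- rep(base, J)
      extra <- n - base * J
      if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
      causes <- rep(seq_len(J), counts)
    } else {
      causes <- sample.int(J, n, replace = TRUE, prob = f)
    }
    probs <- p[causes, , drop = FALSE]
    if (is.null(dependence)) {
      u <- matrix(runif(n * K), nrow = n)
    } else {
      u <- matrix(runif(n * K), nrow = n)
      blocks <- dependence$blocks
      rho <- dependence$rho
      stopifnot(length(blocks) == K, rho >= 0, rho <= 1)
      for (b in unique(blocks)) {
        cols <- which(blocks == b)
        if (length(cols) < 2) next
        share <- runif(n) < rho
        u[share, cols] <- u[share, cols[1]]
      }
    }
    sm <- (u < probs) + 0L
    colnames(sm) <- model$symptom_names
    va_data(sm, cause = model$cause_names[causes],
            cause_names = model$cause_names)
  })
}

#' The canonical misreporting pattern
#'
#' The fixed pattern used throughout the bias-detection simulations: up to
#' ten designated symptoms with community-side marginal prevalence shifts
#' (percent change of the symptom's reporting frequency), applied in
#' column order (a design with `b` biased symptoms uses the first `b`
#' columns).
#'
#' @param n_biased how many columns of the pattern to use (1..10).
#' @return A data frame with columns `symptom` (index) and `shift`
#'   (percent).
#' @export
misreport_pattern <- function(n_biased = 10L) {
  symptoms <- c(1L, 5L, 10L, 11L, 15L, 20L, 21L, 25L, 30L, 31L)
  shifts <- c(30, -30, -50, 30, -30, 30, -30, -50, 30, -30)
  if (n_biased < 0L || n_biased > length(symptoms))
    stop_va("n_biased must be between 0 and ", length(symptoms))
  data.frame(symptom = symptoms, shift = shifts)[seq_len(n_biased), ,
                                                 drop = FALSE]
}

#' Apply community-side misreporting to a symptom model
#'
#' Produces the community version of a symptom model in which designated
#' symptoms are reported with different frequencies than in the hospital,
#' violating the assumption that symptom reporting given cause is the
#' same in both samples.  For each `(symptom k, shift d)` pair the
#' community marginal prevalence `sum_j csmf_j p_jk` is moved to a target
#' value and every cause-conditional sensitivity `p_jk` is shifted by a
#' common additive constant, solved numerically so the target is hit
#' exactly inside the `[0.01, 0.99]` clipping bounds.  With
#' `shift_type = "relative"` (default) a shift of `d` means the symptom
#' is reported `d` percent more (or less) often in the community than the
#' unbiased model would imply — e.g. -50 halves its frequency; with
#' `"absolute"` the marginal moves by `d/100` in absolute terms.  Because
#' only marginal shifts are specified, the same shift applies to all
#' causes; `target_causes` restricts the shift to chosen causes instead
#' (the marginal shift is still matched).
#'
#' @param model a [make_symptom_model] result (the hospital-side model).
#' @param misreports a data frame with columns `symptom` and `shift`
#'   (percent), e.g. from [misreport_pattern].
#' @param community_csmf the community [csmf], defining the marginals.
#' @param shift_type `"relative"` (percent of the unbiased marginal) or
#'   `"absolute"` (percentage points).
#' @param target_causes optional integer vector: shift only these causes'
#'   conditionals.
#' @return A `symptom_model` with attribute `achieved_shifts`: the
#'   realised marginal change per listed symptom, on the `shift_type`
#'   scale.
#' @export
apply_misreporting <- function(model, misreports, community_csmf,
                               shift_type = c("relative", "absolute"),
                               target_causes = NULL) {
  shift_type <- match.arg(shift_type)
  stopifnot(inherits(model, "symptom_model"))
  if (is.null(misreports) || nrow(misreports) == 0L) {
    attr(model, "achieved_shifts") <- numeric(0)
    return(model)
  }
  f <- as.numeric(community_csmf)
  p <- model$sensitivities
  if (length(f) != nrow(p)) stop_va("CSMF length does not match model")
  lo <- 0.01; hi <- 0.99
  tc <- target_causes %||% seq_len(nrow(p))
  achieved <- numeric(nrow(misreports))
  for (r in seq_len(nrow(misreports))) {
    k <- misreports$symptom[r]
    d <- misreports$shift[r] / 100
    if (k < 1 || k > ncol(p))
      stop_va("misreported symptom index ", k, " outside 1..", ncol(p))
    base <- sum(f * p[, k])
    target <- if (shift_type == "relative") base * (1 + d) else base + d
    marg <- function(cc) {
      col <- p[, k]
      col[tc] <- pmin(pmax(col[tc] + cc, lo), hi)
      sum(f * col)
    }
    if (target < marg(-1) - 1e-12 || target > marg(1) + 1e-12)
      stop_va("requested shift of ", misreports$shift[r],
              " points for symptom ", k, " is unattainable within the [",
              lo, ", ", hi, "] sensitivity bounds")
    cc <- uniroot(function(x) marg(x) - target, c(-1, 1),
                  tol = 1e-12)$root
    p[tc, k] <- pmin(pmax(p[tc, k] + cc, lo), hi)
    achieved[r] <- if (shift_type == "relative")
      (sum(f * p[, k]) / base - 1) * 100 else (sum(f * p[, k]) - base) * 100
  }
  model$sensitivities <- p
  attr(model, "achieved_shifts") <-
    setNames(achieved, model$symptom_names[misreports$symptom])
  model
}

#' Direct-sampling baseline estimate
#'
#' The infeasible lower-bound estimator: the cause of each of `n` randomly
#' sampled community deaths is directly ascertained and the counts
#' tabulated.  Its error is pure sampling variability, so it bounds from
#' below the error of any method using the same number of community
#' deaths.
#'
#' @param true_csmf the true community [csmf].
#' @param n number of sampled deaths.
#' @param seed integer seed.
#' @return A [csmf] of normalised multinomial counts.
#' @export
direct_sampling_estimate <- function(true_csmf, n, seed = 1L) {
  f <- as.numeric(true_csmf)
  counts <- with_seed(seed, rmultinom(1, n, f)[, 1])
  csmf(counts / n, names(true_csmf) %||% paste0("cause", seq_along(f)))
}

#' Default community cause distribution
#'
#' Front-loaded cause distributions used by the design experiments: a few
#' prevalent causes and several rarer ones.  For 10 causes this is
#' `(0.2, 0.2, 0.2, 0.1, 0.05 x 6)`; for 5 and 15 causes analogous
#' front-loaded vectors; for any other J a normalised vector giving the
#' first 30% of causes four times the weight of the rest.
#'
#' @param J number of causes.
#' @return A [csmf].
#' @export
default_community_csmf <- function(J) {
  f <- switch(as.character(J),
    "5"  = c(0.30, 0.25, 0.20, 0.15, 0.10),
    "10" = c(0.2, 0.2, 0.2, 0.1, rep(0.05, 6)),
    "15" = c(0.15, 0.15, 0.10, 0.10, 0.10, rep(0.04, 10)),
    {
      n_big <- max(1L, ceiling(0.3 * J))
      w <- c(rep(4, n_big), rep(1, J - n_big))
      w / sum(w)
    })
  csmf(f)
}

#' Simulation design for a paired hospital/community study
#'
#' Bundles everything needed to generate one synthetic study: the symptom
#' model dimensions, the two cause distributions, sample sizes, sampling
#' scheme, the optional perfect symptom, and community-side misreporting.
#' Defaults follow the bias-detection study conditions: 10 causes, uniform
#' hospital CSMF with case-control sampling, front-loaded community CSMF,
#' 3,000 deaths per sample, ordinary sensitivities capped at 0.3.
#'
#' @param J,K causes and ordinary symptoms.
#' @param hospital_csmf,community_csmf cause distributions (defaults:
#'   uniform; [default_community_csmf]).
#' @param n_hospital,n_community sample sizes.
#' @param case_control case-control hospital sampling?
#' @param high_sens include the perfect cause-1 symptom?
#' @param misreports data frame of community-side shifts (see
#'   [misreport_pattern]), or `NULL`.
#' @param s_max,p_min sensitivity bounds for ordinary symptoms.  Designs
#'   without misreporting default to Uniform(0.02, 0.3) draws (weakly
#'   informative symptoms capped at 30% sensitivity); designs with
#'   misreporting default to Uniform(0.1, 0.5), giving marginal
#'   prevalences around 0.3 so that the relative reporting shifts
#'   translate into absolute marginal differences that are large against
#'   sampling noise at thousands of deaths but comparable to it at
#'   hundreds.  Explicit `s_max`/`p_min` values override either default.
#' @param seed master seed.
#' @return A list of class `sim_design`.
#' @export
sim_design <- function(J = 10L, K = 20L,
                       hospital_csmf = csmf(rep(1 / J, J)),
                       community_csmf = default_community_csmf(J),
                       n_hospital = 3000L, n_community = 3000L,
                       case_control = TRUE, high_sens = FALSE,
                       misreports = NULL, s_max = NULL, p_min = NULL,
                       seed = 1L) {
  has_misreports <- !is.null(misreports) && nrow(misreports) > 0L
  if (has_misreports && any(misreports$symptom > K))
    stop_va("misreporting pattern names symptom ",
            max(misreports$symptom), " but the design has only ", K)
  s_max <- s_max %||% if (has_misreports) 0.5 else 0.3
  p_min <- p_min %||% if (has_misreports) 0.1 else 0.02
  structure(list(J = as.integer(J), K = as.integer(K),
                 hospital_csmf = hospital_csmf,
                 community_csmf = community_csmf,
                 n_hospital = as.integer(n_hospital),
                 n_community = as.integer(n_community),
                 case_control = case_control, high_sens = high_sens,
                 misreports = misreports, s_max = s_max, p_min = p_min,
                 seed = as.integer(seed)),
            class = "sim_design")
}

#' Generate one replicate of a simulated study
#'
#' Builds the symptom model from the design seed, applies any misreporting
#' to a community-side copy of the model, and draws the hospital and
#' community samples with replicate-specific derived seeds.  The same
#' design and replicate index always reproduce identical datasets.
#'
#' @param design a [sim_design].
#' @param replicate replicate index (>= 1); varies the data draws but not
#'   the symptom model.
#' @return A list: `hospital` ([va_data] with causes), `community`
#'   ([va_data], causes hidden), `community_causes` (the held-out truth
#'   labels), `truth` (the community [csmf]), `model`, `community_model`.
#' @export
simulate_study <- function(design, replicate = 1L) {
  stopifnot(inherits(design, "sim_design"), replicate >= 1)
  model <- make_symptom_model(design$J, design$K,
                              seed = derive_seed(design$seed, 0L),
                              s_max = design$s_max,
                              high_sens = design$high_sens,
                              p_min = design$p_min)
  cmodel <- apply_misreporting(model, design$misreports,
                               design$community_csmf)
  hosp <- simulate_deaths(model, design$hospital_csmf, design$n_hospital,
                          case_control = design$case_control,
                          seed = derive_seed(design$seed, 2L * replicate))
  comm_full <- simulate_deaths(cmodel, design$community_csmf,
                               design$n_community, case_control = FALSE,
                               seed = derive_seed(design$seed,
                                                  2L * replicate + 1L))
  community <- va_data(comm_full$symptoms,
                       symptom_names = comm_full$symptom_names)
  list(hospital = hosp, community = community,
       community_causes = comm_full$cause_names[comm_full$cause],
       truth = design$community_csmf, model = model,
       community_model = cmodel)
}
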