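# Symptom-profile tabulation: the nonparametric building blocks P(S) and
# P(S|D).  A profile over a subset of B symptoms is one of the 2^B joint
# response patterns; profiles are indexed in lexicographic bit order with
# pattern 00..0 first and the first subset symptom as the lowest bit.

MAX_SUBSET_SIZE <- 16L  # 2^16 cells; larger subsets are never estimable

profile_index <- function(symptoms, subset) {
  # 1-based index of each record's profile over `subset`
  bits <- symptoms[, subset, drop = FALSE]
  as.integer(bits %*% 2^(seq_along(subset) - 1L)) + 1L
}

#' Enumerate symptom profiles in canonical order
#'
#' @param B number of symptoms in the subset.
#' @return A `2^B`-by-`B` 0/1 matrix; row `p` is the bit pattern of profile
#'   `p` (lexicographic order, `00..0` first, first symptom = lowest bit).
#' @export
profile_patterns <- function(B) {
  stopifnot(B >= 1, B <= MAX_SUBSET_SIZE)
  idx <- 0:(2^B - 1)
  sapply(seq_len(B), function(k) bitwAnd(idx %/% 2^(k - 1L), 1L))
}

#' Tabulate the empirical symptom-profile distribution P(S)
#'
#' Counts, without any modelling assumptions, how often each of the `2^B`
#' joint response patterns over a chosen symptom subset occurs in a
#' dataset.
#'
#' @param data a [va_data] object.
#' @param subset integer indices of the symptoms to use (size B).
#' @return An object of class `profile_dist`: list with `subset` (sorted
#'   ascending), `probabilities` (length `2^B`, sums to 1), `n` records
#'   tabulated.
#' @export
tabulate_profiles <- function(data, subset) {
  stopifnot(inherits(data, "va_data"))
  subset <- sort(as.integer(subset))
  if (length(subset) == 0L) stop_va("symptom subset must be nonempty")
  if (anyDuplicated(subset)) stop_va("symptom subset has duplicate indices")
  if (min(subset) < 1L || max(subset) > n_symptoms(data))
    stop_va("symptom subset indices out of range 1..", n_symptoms(data))
  if (length(subset) > MAX_SUBSET_SIZE)
    stop_va("subset larger than the maximum of ", MAX_SUBSET_SIZE,
            " symptoms (2^B profile cells must remain enumerable)")
  n <- n_records(data)
  if (n == 0L) stop_va("empty dataset")
  counts <- tabulate(profile_index(data$symptoms, subset),
                     nbins = 2^length(subset))
  structure(list(subset = subset, probabilities = counts / n, n = n),
            class = "profile_dist")
}

#' Estimate per-cause profile distributions P(S|D) from hospital data
#'
#' Tabulates the symptom-profile distribution separately within each cause
#' of death in the training (hospital) sample.  Column `j` of the result is
#' the profile distribution among deaths from cause `j`.
#'
#' @param hospital a [va_data] with cause labels.
#' @param subset integer indices of the symptoms to use (size B).
#' @return An object of class `profile_cond`: list with `subset`, `matrix`
#'   (`2^B`-by-J, columns sum to 1), `cause_names`, and `n_per_cause`.
#' @export
estimate_conditional_profiles <- function(hospital, subset) {
  stopifnot(inherits(hospital, "va_data"))
  if (is.null(hospital$cause))
    stop_va("hospital data must carry cause-of-death labels")
  subset <- sort(as.integer(subset))
  J <- n_causes(hospital)
  n_j <- tabulate(hospital$cause, nbins = J)
  if (any(n_j == 0L))
    stop_va("no hospital records for cause(s): ",
            paste(hospital$cause_names[n_j == 0L], collapse = ", "),
            " -- the fraction for an unobserved cause is not identifiable")
  if (length(subset) == 0L || min(subset) < 1L ||
      max(subset) > n_symptoms(hospital) || anyDuplicated(subset))
    stop_va("invalid symptom subset")
  idx <- profile_index(hospital$symptoms, subset)
  ncell <- 2^length(subset)
  m <- matrix(0, nrow = ncell, ncol = J)
  for (j in seq_len(J))
    m[, j] <- tabulate(idx[hospital$cause == j], nbins = ncell) / n_j[j]
  structure(list(subset = subset, matrix = m,
                 cause_names = hospital$cause_names, n_per_cause = n_j),
            class = "profile_cond")
}
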