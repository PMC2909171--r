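# Independent oracles used by the solver tests: brute-force profile
# counting and simplex grid search, kept free of the package's solve path.

# Naive double loop over records and patterns.
brute_force_profiles <- function(symptoms, subset) {
  B <- length(subset)
  pat <- profile_patterns(B)
  counts <- numeric(2^B)
  for (i in seq_len(nrow(symptoms))) {
    for (p in seq_len(2^B)) {
      if (all(symptoms[i, subset] == pat[p, ])) {
        counts[p] <- counts[p] + 1
        break
      }
    }
  }
  counts / nrow(symptoms)
}

# Minimum of ||b - M beta||^2 over the simplex on a regular grid.
grid_search_objective <- function(M, b, step = 0.001) {
  J <- ncol(M)
  stopifnot(J <= 3)
  if (J == 1) return(sum((b - M[, 1])^2))
  if (J == 2) {
    b1 <- seq(0, 1, by = step)
    G <- rbind(b1, 1 - b1)
  } else {
    b1 <- seq(0, 1, by = step)
    G <- do.call(cbind, lapply(b1, function(x) {
      b2 <- seq(0, 1 - x, by = step)
      rbind(x, b2, 1 - x - b2)
    }))
  }
  fits <- M %*% G
  min(colSums((b - fits)^2))
}

# Random column-stochastic conditional matrix wrapped as a profile_cond.
random_cond <- function(B, J, seed) {
  m <- with_seed_test(seed, {
    raw <- matrix(rexp(2^B * J), nrow = 2^B)
    sweep(raw, 2, colSums(raw), "/")
  })
  structure(list(subset = seq_len(B), matrix = m,
                 cause_names = paste0("c", seq_len(J)),
                 n_per_cause = rep(1000L, J)),
            class = "profile_cond")
}

as_profile_dist <- function(probabilities, B) {
  structure(list(subset = seq_len(B), probabilities = probabilities,
                 n = NA_integer_),
            class = "profile_dist")
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
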