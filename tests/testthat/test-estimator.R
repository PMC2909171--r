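test_that("solver recovers exactly solvable systems", {
  m <- random_cond(2, 2, seed = 1)
  m$matrix <- cbind(c(1, 0, 0, 0), c(0, 0, 0, 1))
  sol <- solve_simplex_ls(as_profile_dist(c(0.3, 0, 0, 0.7), 2), m)
  expect_equal(as.numeric(sol), c(0.3, 0.7), tolerance = 1e-8)
  expect_lt(attr(sol, "residual_norm"), 1e-8)

  # J = 1: the simplex is a point
  m1 <- random_cond(2, 1, seed = 2)
  expect_equal(as.numeric(solve_simplex_ls(
    as_profile_dist(c(0.1, 0.2, 0.3, 0.4), 2), m1)), 1)
})

test_that("solver recovers mixture weights of a consistent system", {
  m <- random_cond(3, 3, seed = 3)
  beta <- c(0.2, 0.3, 0.5)
  b <- as.numeric(m$matrix %*% beta)
  sol <- solve_simplex_ls(as_profile_dist(b, 3), m)
  expect_equal(as.numeric(sol), beta, tolerance = 1e-6)
})

test_that("solver objective matches brute-force simplex grid search", {
  for (seed in 1:10) {
    B <- sample(2:4, 1)
    J <- sample(2:3, 1)
    m <- random_cond(B, J, seed = 100 + seed)
    b <- with_seed_test(200 + seed, {
      raw <- rexp(2^B)
      raw / sum(raw)
    })
    sol <- solve_simplex_ls(as_profile_dist(b, B), m)
    obj_ls <- sum((b - m$matrix %*% as.numeric(sol))^2)
    obj_grid <- grid_search_objective(m$matrix, b, step = 0.002)
    expect_lte(obj_ls, obj_grid + 1e-9)
    expect_lte(obj_grid - obj_ls, 5e-4)
  }
})

test_that("solver flags dimension mismatch and rank deficiency", {
  m <- random_cond(2, 2, seed = 4)
  expect_error(solve_simplex_ls(as_profile_dist(rep(0.125, 8), 3), m),
               "different|mismatch")
  m$matrix[, 2] <- m$matrix[, 1]
  sol <- solve_simplex_ls(as_profile_dist(m$matrix[, 1], 2), m)
  expect_true(attr(sol, "rank_deficient"))
  expect_equal(sum(as.numeric(sol)), 1, tolerance = 1e-8)
})

test_that("estimate equals empirical cause shares when community mirrors hospital", {
  st <- small_study(n = 600, J = 3, K = 10, seed = 9)
  hosp <- st$hospital
  mirror <- va_data(hosp$symptoms, symptom_names = hosp$symptom_names)
  cfg <- fast_config(smoothing = FALSE, variance_correction = FALSE)
  est <- estimate_csmf(hosp, mirror, cfg)
  emp <- tabulate(hosp$cause, 3) / n_records(hosp)
  expect_equal(as.numeric(est$point), emp, tolerance = 1e-6)
})

test_that("estimate tracks the community CSMF, not the hospital CSMF", {
  J <- 4
  model <- make_symptom_model(J, 16, seed = 41, s_max = 0.5)
  truth <- csmf(c(0.45, 0.3, 0.15, 0.1))
  hosp <- simulate_deaths(model, csmf(rep(1 / J, J)), 1500,
                          case_control = TRUE, seed = 42)
  comm_full <- simulate_deaths(model, truth, 1500, seed = 43)
  comm <- va_data(comm_full$symptoms, symptom_names = comm_full$symptom_names)
  est <- estimate_csmf(hosp, comm, estimator_config(n_subsets = 100, seed = 7))
  expect_lt(max(abs(as.numeric(est$point) - as.numeric(truth))), 0.06)
  # far from the uniform hospital distribution
  expect_gt(max(abs(as.numeric(est$point) - 1 / J)), 0.1)
})

test_that("estimates live on the simplex and average the subset draws", {
  st <- small_study(n = 400, J = 3, K = 8, seed = 77)
  est <- estimate_csmf(st$hospital, st$community, fast_config())
  expect_equal(sum(est$point), 1, tolerance = 1e-8)
  expect_true(all(est$point >= 0))
  renorm <- colMeans(est$per_subset)
  renorm <- renorm / sum(renorm)
  expect_equal(as.numeric(est$point), as.numeric(renorm), tolerance = 1e-12)
  expect_identical(nrow(est$per_subset), 30L)

  # same config, same result
  est2 <- estimate_csmf(st$hospital, st$community, fast_config())
  expect_identical(est$per_subset, est2$per_subset)
})

test_that("estimator rejects mismatched inputs", {
  st <- small_study(n = 200, J = 3, K = 6)
  comm <- st$community
  comm$symptom_names <- rev(comm$symptom_names)
  expect_error(estimate_csmf(st$hospital, comm, fast_config()),
               "share the same symptom")
})

test_that("bootstrap standard errors are nonnegative and plausibly scaled", {
  st <- small_study(n = 400, J = 3, K = 8, seed = 15)
  est <- estimate_csmf(st$hospital, st$community,
                       fast_config(bootstrap_reps = 8L))
  expect_length(est$standard_errors, 3)
  expect_true(all(est$standard_errors >= 0))
  expect_true(all(is.finite(est$standard_errors)))
  expect_true(all(est$standard_errors < 0.4))
})

test_that("stratified estimation reduces to the plain estimator when strata agree", {
  st <- small_study(n = 500, J = 3, K = 10, seed = 19)
  hosp <- st$hospital
  comm <- st$community
  strat_h <- rep(c("u", "v"), length.out = n_records(hosp))
  strat_c <- rep(c("u", "v"), length.out = n_records(comm))
  h2 <- va_data(hosp$symptoms, cause = hosp$cause_names[hosp$cause],
                stratum = strat_h, cause_names = hosp$cause_names)
  c2 <- va_data(comm$symptoms, stratum = strat_c)

  # single stratum with weight 1 equals the unstratified estimate exactly
  h1 <- va_data(hosp$symptoms, cause = hosp$cause_names[hosp$cause],
                stratum = rep("all", n_records(hosp)),
                cause_names = hosp$cause_names)
  c1 <- va_data(comm$symptoms, stratum = rep("all", n_records(comm)))
  cfg <- fast_config()
  expect_equal(as.numeric(stratified_estimate_csmf(h1, c1,
                                                   c(all = 1), cfg)$point),
               as.numeric(estimate_csmf(hosp, comm, cfg)$point),
               tolerance = 1e-12)

  # equal weights over interchangeable strata stay close to unstratified
  est_s <- stratified_estimate_csmf(h2, c2, c(u = 0.5, v = 0.5), cfg)
  est_p <- estimate_csmf(hosp, comm, cfg)
  expect_lt(max(abs(as.numeric(est_s$point) - as.numeric(est_p$point))),
            0.05)
})

test_that("stratified estimation validates weights and strata", {
  st <- small_study(n = 200, J = 3, K = 6)
  h <- va_data(st$hospital$symptoms,
               cause = st$hospital$cause_names[st$hospital$cause],
               stratum = rep("u", 200),
               cause_names = st$hospital$cause_names)
  cm <- va_data(st$community$symptoms, stratum = rep("u", 200))
  expect_error(stratified_estimate_csmf(h, cm, c(u = 0.5, v = 0.5),
                                        fast_config()),
               "absent from hospital")
  expect_error(stratified_estimate_csmf(h, cm, c(u = 0.9), fast_config()),
               "sum to 1")
  expect_error(stratified_estimate_csmf(st$hospital, st$community,
                                        c(u = 1), fast_config()),
               "stratum labels")
})

test_that("stratified adjustment removes composition bias on simulated data", {
  J <- 3; K <- 10
  m_child <- make_symptom_model(J, K, seed = 61, s_max = 0.6)
  m_adult <- make_symptom_model(J, K, seed = 62, s_max = 0.6, p_min = 0.3)
  truth <- csmf(c(0.5, 0.3, 0.2))
  gen <- function(model, f, n, seed, label, cc = FALSE) {
    d <- simulate_deaths(model, f, n, case_control = cc, seed = seed)
    va_data(d$symptoms, cause = d$cause_names[d$cause],
            stratum = rep(label, n), cause_names = d$cause_names)
  }
  err_strat <- err_plain <- numeric(3)
  for (r in 1:3) {
    # hospital oversamples children (80%); community is half and half
    h <- do.call(rbind, list())
    hc <- gen(m_child, csmf(rep(1/3, 3)), 1200, 70 + r, "child", cc = TRUE)
    ha <- gen(m_adult, csmf(rep(1/3, 3)), 300, 80 + r, "adult", cc = TRUE)
    hosp <- va_data(rbind(hc$symptoms, ha$symptoms),
                    cause = c(hc$cause_names[hc$cause],
                              ha$cause_names[ha$cause]),
                    stratum = c(as.character(hc$stratum),
                                as.character(ha$stratum)),
                    cause_names = hc$cause_names)
    cc_ <- gen(m_child, truth, 750, 90 + r, "child")
    ca <- gen(m_adult, truth, 750, 95 + r, "adult")
    comm <- va_data(rbind(cc_$symptoms, ca$symptoms),
                    stratum = c(as.character(cc_$stratum),
                                as.character(ca$stratum)))
    cfg <- estimator_config(n_subsets = 60, seed = 5)
    est_s <- stratified_estimate_csmf(hosp, comm,
                                      c(child = 0.5, adult = 0.5), cfg)
    plain_h <- va_data(hosp$symptoms, cause = hosp$cause_names[hosp$cause],
                       cause_names = hosp$cause_names)
    est_p <- estimate_csmf(plain_h, va_data(comm$symptoms), cfg)
    err_strat[r] <- mean_absolute_error(est_s$point, truth)
    err_plain[r] <- mean_absolute_error(est_p$point, truth)
  }
  expect_lt(mean(err_strat), mean(err_plain))
})

test_that("individual classification follows Bayes rule", {
  # hospital with empirical prevalences 0.9/0.9 (cause a) and 0.1/0.1 (b)
  mk <- function(p, n) sapply(1:2, function(k) rep(c(1, 0), c(p * n, n - p * n)))
  h <- va_data(rbind(mk(0.9, 10), mk(0.1, 10)),
               cause = rep(c("a", "b"), each = 10))
  post <- classify_individual(c(1, 1), h, csmf(c(0.5, 0.5), c("a", "b")))
  expect_equal(as.numeric(post), c(0.81, 0.01) / 0.82, tolerance = 1e-10)

  # point-mass prior dominates any profile with nonzero likelihood
  post_b <- classify_individual(c(1, 1), h, csmf(c(0, 1), c("a", "b")))
  expect_equal(as.numeric(post_b), c(0, 1))

  # community tabulation diagnostic
  cm <- va_data(rbind(c(1, 1), c(1, 1), c(0, 0), c(1, 0)))
  post_c <- classify_individual(c(1, 1), h, csmf(c(0.5, 0.5), c("a", "b")),
                                community = cm)
  expect_equal(attr(post_c, "profile_prob_community"), 0.5)
})

test_that("classification beats chance on simulated deaths", {
  st <- small_study(n = 700, J = 4, K = 12, seed = 55)
  est <- estimate_csmf(st$hospital, st$community, fast_config())
  idx <- seq_len(60)
  hit <- vapply(idx, function(i) {
    post <- classify_individual(st$community$symptoms[i, ], st$hospital,
                                est$point)
    post[match(st$community_causes[i], st$hospital$cause_names)]
  }, numeric(1))
  expect_gt(mean(hit), 1 / 4)
})
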