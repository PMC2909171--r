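test_that("symptom models are reproducible and bounded", {
  m1 <- make_symptom_model(5, 12, seed = 3)
  m2 <- make_symptom_model(5, 12, seed = 3)
  expect_identical(m1$sensitivities, m2$sensitivities)
  expect_true(all(m1$sensitivities >= 0.02 & m1$sensitivities <= 0.3))

  hs <- make_symptom_model(5, 12, seed = 3, high_sens = TRUE)
  expect_identical(hs$high_sens_index, 13L)
  expect_equal(unname(hs$sensitivities[, 13]), c(1, 0, 0, 0, 0))
  expect_true(all(hs$sensitivities[, 1:12] <= 0.3))

  rng <- matrix(rep(c(0.4, 0.6), each = 4), ncol = 2)
  mr <- make_symptom_model(3, 4, seed = 5, sens_ranges = rng)
  expect_true(all(mr$sensitivities >= 0.4 & mr$sensitivities <= 0.6))
})

test_that("death simulation honours cause distribution and sampling design", {
  model <- make_symptom_model(3, 4, seed = 11)
  model$sensitivities[1, ] <- 1
  all1 <- simulate_deaths(model, csmf(c(1, 0, 0)), 50, seed = 12)
  expect_true(all(all1$symptoms == 1L))
  expect_true(all(all1$cause == 1L))

  cc <- simulate_deaths(make_symptom_model(10, 5, seed = 13),
                        csmf(rep(0.1, 10)), 3000, case_control = TRUE,
                        seed = 14)
  expect_identical(tabulate(cc$cause, 10), rep(300L, 10))
  expect_error(simulate_deaths(make_symptom_model(10, 5, seed = 13),
                               csmf(rep(0.1, 10)), 5, case_control = TRUE,
                               seed = 1),
               "n >= J")
})

test_that("empirical prevalences converge to the model sensitivities", {
  model <- make_symptom_model(3, 6, seed = 21, s_max = 0.8)
  dat <- simulate_deaths(model, csmf(c(0.4, 0.35, 0.25)), 20000, seed = 22)
  emp <- rowsum(dat$symptoms + 0, dat$cause) / tabulate(dat$cause, 3)
  expect_lt(max(abs(emp - model$sensitivities)), 0.02)
})

test_that("block dependence hook correlates symptoms within a block", {
  model <- make_symptom_model(2, 4, seed = 31, p_min = 0.45, s_max = 0.55)
  dep <- list(blocks = c(1, 1, 2, 2), rho = 0.9)
  dat <- simulate_deaths(model, csmf(c(0.5, 0.5)), 4000, seed = 32,
                         dependence = dep)
  r_in <- cor(dat$symptoms[, 1], dat$symptoms[, 2])
  r_out <- cor(dat$symptoms[, 1], dat$symptoms[, 3])
  expect_gt(r_in, 0.5)
  expect_lt(abs(r_out), 0.1)
})

test_that("misreporting shifts the community marginal by the stated amount", {
  model <- make_symptom_model(4, 6, seed = 41, s_max = 0.6)
  f <- default_community_csmf(4)
  base <- as.numeric(model$sensitivities["cause2", , drop = FALSE])
  marg <- as.numeric(crossprod(model$sensitivities, as.numeric(f)))

  shifted <- apply_misreporting(model, data.frame(symptom = 1, shift = 30),
                                f)
  new_marg <- sum(as.numeric(f) * shifted$sensitivities[, 1])
  expect_equal(new_marg, marg[1] * 1.3, tolerance = 1e-9)
  expect_equal(attr(shifted, "achieved_shifts")[["s1"]], 30,
               tolerance = 1e-6)

  # absolute mode: 0.40 -> 0.70 for a flat-sensitivity symptom
  flat <- model
  flat$sensitivities[, 2] <- 0.4
  abs_shift <- apply_misreporting(flat, data.frame(symptom = 2, shift = 30),
                                  f, shift_type = "absolute")
  expect_equal(sum(as.numeric(f) * abs_shift$sensitivities[, 2]), 0.7,
               tolerance = 1e-9)

  # untouched symptoms and empty specs are identities
  expect_equal(shifted$sensitivities[, -1], model$sensitivities[, -1])
  expect_identical(apply_misreporting(model, NULL, f)$sensitivities,
                   model$sensitivities)

  expect_error(apply_misreporting(flat, data.frame(symptom = 2, shift = 90),
                                  f, shift_type = "absolute"),
               "unattainable")
})

test_that("the canonical misreporting pattern matches its published layout", {
  pat <- misreport_pattern(10)
  expect_identical(pat$symptom, c(1L, 5L, 10L, 11L, 15L, 20L, 21L, 25L,
                                  30L, 31L))
  expect_identical(pat$shift, c(30, -30, -50, 30, -30, 30, -30, -50, 30,
                                -30))
  expect_identical(nrow(misreport_pattern(3)), 3L)
  expect_error(misreport_pattern(11), "between 0 and 10")
})

test_that("direct sampling baseline is consistent and degenerate-safe", {
  f <- default_community_csmf(10)
  big <- direct_sampling_estimate(f, 1e6, seed = 51)
  expect_lt(max(abs(as.numeric(big) - as.numeric(f))), 0.002)

  point <- direct_sampling_estimate(csmf(c(1, 0)), 40, seed = 52)
  expect_equal(as.numeric(point), c(1, 0))
})

test_that("direct sampling MAE matches the folded-normal approximation", {
  f <- as.numeric(default_community_csmf(10))
  n <- 1000
  maes <- vapply(1:500, function(r)
    mean_absolute_error(direct_sampling_estimate(f, n, seed = 600 + r), f),
    numeric(1))
  approx <- mean(sqrt(2 * f * (1 - f) / (pi * n)))
  expect_lt(abs(mean(maes) - approx) / approx, 0.1)
})

test_that("studies are reproducible and respect the design", {
  des <- sim_design(J = 4, K = 8, n_hospital = 300, n_community = 400,
                    misreports = misreport_pattern(1), seed = 61)
  s1 <- simulate_study(des, replicate = 2)
  s2 <- simulate_study(des, replicate = 2)
  expect_identical(s1$hospital$symptoms, s2$hospital$symptoms)
  expect_identical(s1$community$symptoms, s2$community$symptoms)
  expect_null(s1$community$cause)
  expect_length(s1$community_causes, 400)
  expect_identical(tabulate(s1$hospital$cause, 4), rep(75L, 4))

  s3 <- simulate_study(des, replicate = 3)
  expect_false(identical(s1$community$symptoms, s3$community$symptoms))

  expect_error(sim_design(J = 10, K = 10, misreports = misreport_pattern(4)),
               "only 10")
})
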