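# a tiny converged fit object assembled by hand for the delta-method tests
stub_fit <- function(model, se) {
  v <- diag(se^2, length(model$params))
  dimnames(v) <- list(names(model$params), names(model$params))
  out <- list(model = model, estimates = model$params,
              se = stats::setNames(rep(se, length(model$params)),
                                   names(model$params)),
              vcov = v, loglik = 0, converged = TRUE)
  class(out) <- "panelmsm_fit"
  out
}

test_that("hazard ratios are exp(beta) with delta-method CIs", {
  spec <- covariate_spec(covariates = list(x = c("no", "yes")),
                         design = list(x = "1-2"))
  m <- intensity_model(structure = transition_structure(), spec = spec,
                       beta = list(x = list(yes = c("1-2" = 0))))
  fit <- stub_fit(m, se = 0.1)
  hr <- hazard_ratios(fit)
  expect_equal(hr$hr, 1)
  expect_equal(hr$lower, exp(-1.96 * 0.1), tolerance = 1e-3)
  expect_equal(hr$upper, exp(1.96 * 0.1), tolerance = 1e-3)
  expect_equal(round(hr$lower, 2), 0.82)
  expect_equal(round(hr$upper, 2), 1.22)

  # degenerate SE = 0 pins the CI to the point estimate
  m2 <- intensity_model(structure = transition_structure(), spec = spec,
                        beta = list(x = list(yes = c("1-2" = log(2)))))
  hr2 <- hazard_ratios(stub_fit(m2, se = 0))
  expect_equal(hr2$hr, 2)
  expect_equal(hr2$lower, 2)
  expect_equal(hr2$upper, 2)

  # without vcov the CI is marked unavailable, HR still exact
  fit_nv <- stub_fit(m2, se = 0.1)
  fit_nv$vcov <- NULL
  hr3 <- hazard_ratios(fit_nv)
  expect_equal(hr3$hr, 2)
  expect_true(is.na(hr3$lower) && is.na(hr3$upper))
  # HR cells are exactly exp(beta) -- no re-estimation
  expect_identical(hr3$hr, unname(exp(fit_nv$estimates["beta(x=yes,1-2)"])))
})

test_that("hazard-ratio table lays transitions out as columns", {
  gen <- elsa_like_model("wealth")
  tabl <- format_hr_table(hazard_ratios(stub_fit(gen, se = 0.05)))
  expect_equal(names(tabl), c("covariate", "level",
                              "1-2", "2-1", "2-3", "1-3", "3-4"))
  expect_true(all(c("wealth", "sex", "marital") %in% tabl$covariate))
  w <- tabl[tabl$covariate == "wealth" & tabl$level == "highest", ]
  expect_match(w[["2-1"]], "^1.56")
})

test_that("occupancy curves: unit mass at t=0, constant under zero rates", {
  m <- plain_model()
  oc <- occupancy_curves(m, start_state = 2L, times = c(0, 1, 2))
  expect_equal(oc$probability[oc$time == 0],
               c(0, 1, 0, 0))
  z <- intensity_model(structure = transition_structure(), log_q0 = log(0.1),
                       rate_zero = c("1-2", "1-3", "1-4", "2-1", "2-3",
                                     "2-4", "3-4"))
  ocz <- occupancy_curves(z, start_state = 2L, times = c(0, 3, 7))
  expect_equal(ocz$probability[ocz$state == 2], rep(1, 3))
  # rows sum to one across states at every grid point
  tot <- tapply(oc$probability, oc$time, sum)
  expect_lt(max(abs(tot - 1)), 1e-8)
})

test_that("occupancy absorption is higher from age 80 than age 60", {
  m <- elsa_like_model("wealth")
  cov <- list(wealth = "middle", sex = "female", marital = "married")
  oc60 <- occupancy_curves(m, cov, start_age = 60, times = c(0, 10))
  oc80 <- occupancy_curves(m, cov, start_age = 80, times = c(0, 10))
  d60 <- oc60$probability[oc60$time == 10 & oc60$state == 4]
  d80 <- oc80$probability[oc80$time == 10 & oc80$state == 4]
  expect_gt(d80, d60)
})

test_that("total length of stay matches the analytic two-state value", {
  m <- two_state_model(0.5)
  expect_equal(unname(total_length_of_stay(m, horizon = 0)), c(0, 0))
  expect_error(total_length_of_stay(m, horizon = -1), ">= 0")
  tl <- total_length_of_stay(m, horizon = 10)
  expect_equal(unname(tl["well"]), (1 - exp(-5)) / 0.5, tolerance = 1e-9)
  expect_equal(unname(sum(tl)), 10, tolerance = 1e-6)
})

test_that("totlos conserves the horizon and is non-decreasing in T", {
  m <- elsa_like_model("wealth")
  cov <- list(wealth = "highest", sex = "male", marital = "single")
  prev <- rep(0, 4)
  for (T in c(2, 5, 10)) {
    tl <- total_length_of_stay(m, cov, start_age = 67, horizon = T)
    expect_equal(unname(sum(tl)), T, tolerance = 1e-6)
    expect_true(all(tl - prev >= -1e-9))
    prev <- tl
  }
})

test_that("totlos agrees with Simpson's rule at step 0.01", {
  m <- elsa_like_model("wealth")
  cov <- list(wealth = "lowest", sex = "female", marital = "married")
  tl <- total_length_of_stay(m, cov, start_age = 66, horizon = 6)
  simp <- simpson_totlos(m, cov, age_start = 66, horizon = 6)
  expect_lt(max(abs(tl - simp)), 1e-6)
})

test_that("sojourn times are the reciprocal total outflow", {
  m <- plain_model()
  sj <- sojourn_times(m)
  # state 1 outflow: 0.25 + 0.002 + 0.02
  expect_equal(sj$sojourn[sj$state == 1], 1 / 0.272, tolerance = 1e-12)
  expect_equal(sj$sojourn[sj$state == 3], 1 / 0.30, tolerance = 1e-12)
  expect_error(sojourn_times(m, states = 4L), "absorbing")

  # halving every outflow rate doubles the sojourn time
  m2 <- update_params_for_test(m, m$params + log(0.5))
  sj2 <- sojourn_times(m2)
  expect_equal(sj2$sojourn, 2 * sj$sojourn, tolerance = 1e-12)
})

test_that("sojourn time matches Monte-Carlo holding times within 3 SEs", {
  m <- plain_model()
  n <- 10000
  coh <- data.frame(id = seq_len(n), state = 1L)
  paths <- simulate_paths(m, coh, horizon = 200, seed = 31)
  first_jump <- tapply(paths$jumps$time, paths$jumps$id, function(t)
    if (length(t) > 1L) t[2L] else NA_real_)
  hold <- first_jump[!is.na(first_jump)]
  expected <- sojourn_times(m)$sojourn[1]
  expect_lt(abs(mean(hold) - expected),
            3 * stats::sd(hold) / sqrt(length(hold)))
})

test_that("sojourn delta-method CI behaves and covers the point estimate", {
  gen <- group_model()
  pd <- simulate_panel(gen, group_cohort_config(800, seed = 32),
                       death_exact = FALSE)
  fit <- suppressWarnings(fit_panel_msm(pd, gen))
  sj <- sojourn_times(fit, covariates = list(group = "a"))
  expect_true(all(sj$lower <= sj$sojourn & sj$sojourn <= sj$upper,
                  na.rm = TRUE))
  expect_true(all(sj$sojourn > 0))
})

test_that("prevalence gof: baseline exact, self-consistent, detects misfit", {
  gen <- plain_model()
  # dropout-free so the grid-time risk sets are unbiased (see vignette on
  # the dead-stay-in / dropped-leave prevalence artifact)
  pd <- simulate_panel(gen, cohort_config(n_subjects = 2000, seed = 33),
                       dropout = 0)
  gof <- prevalence_gof(gen, pd, times = seq(0, 10, 2))
  # baseline: expected equals observed initial distribution exactly
  b <- gof[gof$time == 0, ]
  expect_equal(b$observed, b$expected, tolerance = 1e-12)
  # self-consistency: simulated-from model matches within 3 MC SDs
  dev <- abs(gof$observed - gof$expected)
  mc_sd <- sqrt(pmax(gof$expected * (1 - gof$expected), 1e-6) / gof$n)
  expect_true(all(dev <= 3 * mc_sd + 1e-9))
  # both rows sum to one over states
  expect_lt(max(abs(tapply(gof$observed, gof$time, sum) - 1)), 1e-9)
  expect_lt(max(abs(tapply(gof$expected, gof$time, sum) - 1)), 1e-9)

  # misspecified model: doubled dementia onset inflates expected prevalence
  bad <- update_params_for_test(gen, gen$params +
    (names(gen$params) %in% c("logq(1-3)", "logq(2-3)")) * log(6))
  gof_bad <- prevalence_gof(bad, pd, times = c(10))
  g3 <- gof_bad[gof_bad$state == 3, ]
  expect_gt(g3$expected, g3$observed)
})
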