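test_that("default transition structure matches the four-state cognitive model", {
  st <- transition_structure()
  expect_equal(st$n_states, 4L)
  expect_equal(st$labels, c("1-2", "1-3", "1-4", "2-1", "2-3", "2-4", "3-4"))
  expect_equal(st$absorbing, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(st$state_names, c("NOCI", "CIND", "Dementia", "Death"))
  # absorbing state has no outgoing pairs; transients all have at least one
  expect_false(any(st$allowed[, 1L] == 4L))
  expect_true(all(1:3 %in% st$allowed[, 1L]))
})

test_that("structure validation rejects malformed inputs", {
  expect_error(transition_structure(allowed = cbind(1L, 1L)), "self-transitions")
  expect_error(transition_structure(allowed = rbind(c(1L, 2L), c(1L, 2L))),
               "duplicate")
  expect_error(transition_structure(n_states = 3L, allowed = cbind(1L, 4L)),
               "outside")
})

test_that("reachability closes over indirect paths", {
  reach <- reachable_states(transition_structure())
  expect_true(reach["NOCI", "Death"])
  expect_true(reach["CIND", "Dementia"])
  expect_false(reach["Dementia", "NOCI"])
  expect_false(reach["Death", "NOCI"])
})

test_that("generator: zero-rate flags give the zero matrix", {
  m <- intensity_model(structure = transition_structure(),
                       log_q0 = log(0.1),
                       rate_zero = c("1-2", "1-3", "1-4", "2-1", "2-3",
                                     "2-4", "3-4"))
  Q <- build_generator(m)
  expect_equal(Q, matrix(0, 4, 4, dimnames = dimnames(Q)))
})

test_that("generator follows q0 * exp(beta z)", {
  spec <- covariate_spec(covariates = list(x = c("no", "yes")),
                         design = list(x = "1-2"))
  m <- intensity_model(structure = two_state_model(0.2)$structure,
                       spec = spec, log_q0 = c("1-2" = log(0.2)),
                       beta = list(x = list(yes = c("1-2" = log(0.5)))))
  expect_equal(build_generator(m, list(x = "yes"))[1, 2], 0.1)
  expect_equal(build_generator(m, list(x = "no"))[1, 2], 0.2)
})

test_that("calibrated model generator matches hand assembly entry by entry", {
  m <- elsa_like_model("wealth")
  cov <- list(wealth = "highest", sex = "female", marital = "single")
  Q <- build_generator(m, cov, age = 72)  # band [70,80): two decades offset
  # hand-assembled from q0 * HR_wealth * HR_sex * HR_marital * age^2
  expect_equal(Q[1, 2], 0.25 * 0.68 * 1.05 * 1.10 * 1.20^2, tolerance = 1e-12)
  expect_equal(Q[2, 1], 0.15 * 1.56 * 0.95 * 0.90 * 0.90^2, tolerance = 1e-12)
  expect_equal(Q[1, 3], 0.002 * 0.87, tolerance = 1e-12)  # no demographic adj
  expect_equal(Q[2, 3], 0.05 * 0.74, tolerance = 1e-12)
  expect_equal(Q[1, 4], 0.02 * 0.75 * 1.25 * 1.50^2, tolerance = 1e-12)
  expect_equal(Q[2, 4], 0.06 * 0.75 * 1.25 * 1.50^2, tolerance = 1e-12)
  expect_equal(Q[3, 4], 0.30 * 0.98 * 0.75 * 1.10 * 1.20^2, tolerance = 1e-12)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_equal(unname(Q[4, ]), rep(0, 4))
})

test_that("generator errors name the offending covariate / level", {
  m <- elsa_like_model("wealth")
  expect_error(build_generator(m, list(sex = "female", marital = "married"),
                               age = 60), "wealth")
  expect_error(build_generator(m, list(wealth = "top", sex = "female",
                                       marital = "married"), age = 60),
               "unknown level 'top'")
  expect_error(build_generator(m, list(wealth = "lowest", sex = "female",
                                       marital = "married")), "age")
})

test_that("row-sum conservation holds across covariate patterns and bands", {
  m <- elsa_like_model("all")
  lv <- m$spec$covariates
  set.seed(42)
  for (i in 1:20) {
    cov <- lapply(lv, function(l) sample(l, 1))
    Q <- build_generator(m, cov, age = runif(1, 45, 95))
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    off <- Q[m$structure$allowed]
    expect_true(all(off >= 0))
  }
})

test_that("P(0) is the identity and t < 0 errors", {
  m <- plain_model()
  expect_equal(unname(transition_probability(m, t = 0)), diag(4))
  expect_error(transition_probability(m, t = -1), ">= 0")
})

test_that("two-state chain matches the analytic closed form", {
  m <- two_state_model(0.5)
  P <- transition_probability(m, t = 2)
  expect_equal(P[1, 2], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(P[1, 1], exp(-1), tolerance = 1e-12)
  expect_equal(unname(P[2, ]), c(0, 1))
})

test_that("matrix exponential agrees with the RK4 ODE oracle", {
  m <- plain_model()
  P <- transition_probability(m, t = 2)
  P_ode <- rk4_transition_probability(m, t = 2)
  expect_lt(max(abs(P - P_ode)), 1e-8)

  # age-banded model: product of segment exponentials vs piecewise ODE
  ma <- elsa_like_model("wealth")
  cov <- list(wealth = "middle", sex = "male", marital = "married")
  P2 <- transition_probability(ma, cov, age_start = 68.4, t = 3)
  P2_ode <- rk4_transition_probability(ma, cov, age_start = 68.4, t = 3)
  expect_lt(max(abs(P2 - P2_ode)), 1e-8)
  expect_lt(max(abs(rowSums(P2) - 1)), 1e-10)
})

test_that("matrix exponential matches Matrix::expm on random generators", {
  skip_if_not_installed("Matrix")
  set.seed(99)
  for (i in 1:10) {
    Q <- matrix(runif(16, 0, 0.8), 4)
    diag(Q) <- 0
    diag(Q) <- -rowSums(Q)
    t <- runif(1, 0.1, 20)
    expect_lt(max(abs(panelmsm:::mat_exp(Q * t) -
                        as.matrix(Matrix::expm(Q * t)))), 1e-12)
  }
})

test_that("Chapman-Kolmogorov holds within homogeneous segments", {
  set.seed(7)
  for (i in 1:10) {
    m <- plain_model(log_q0 = stats::setNames(log(runif(7, 0.01, 0.5)),
                                              c("1-2", "1-3", "1-4", "2-1",
                                                "2-3", "2-4", "3-4")))
    t1 <- runif(1, 0.1, 3)
    t2 <- runif(1, 0.1, 3)
    P12 <- transition_probability(m, t = t1 + t2)
    P1 <- transition_probability(m, t = t1)
    P2 <- transition_probability(m, t = t2)
    expect_lt(max(abs(P12 - P1 %*% P2)), 1e-8)
    expect_lt(max(abs(rowSums(P12) - 1)), 1e-10)
    expect_true(all(P12 >= -1e-12 & P12 <= 1 + 1e-12))
  }
})

test_that("absorption probability is non-decreasing in t", {
  m <- elsa_like_model("wealth")
  cov <- list(wealth = "lowest", sex = "female", marital = "married")
  ts <- seq(0, 12, by = 0.5)
  p4 <- vapply(ts, function(t)
    transition_probability(m, cov, age_start = 63, t = t)[, 4], numeric(4))
  for (r in 1:3) expect_true(all(diff(p4[r, ]) >= -1e-12))
})

test_that("zeroing a rate with no indirect path zeroes the flow", {
  m <- intensity_model(structure = transition_structure(),
                       log_q0 = log(c("1-2" = 0.25, "1-3" = 0.002,
                                      "1-4" = 0.02, "2-1" = 0.15,
                                      "2-3" = 0.05, "2-4" = 0.06,
                                      "3-4" = 0.30)),
                       rate_zero = c("1-3", "2-3"))
  P <- transition_probability(m, t = 5)
  expect_equal(P[1, 3], 0)
  expect_equal(P[2, 3], 0)
})

test_that("age interval splitting composes across band boundaries", {
  m <- elsa_like_model("wealth")
  cov <- list(wealth = "middle", sex = "female", marital = "married")
  # crossing 70 at t = 1.5: P(0,3) = P(0,1.5) %*% P(1.5,3)
  P <- transition_probability(m, cov, age_start = 68.5, t = 3)
  Pa <- transition_probability(m, cov, age_start = 68.5, t = 1.5)
  Pb <- transition_probability(m, cov, age_start = 70, t = 1.5)
  expect_lt(max(abs(P - Pa %*% Pb)), 1e-12)
})
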