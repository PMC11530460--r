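# Small model builders and independent numerical oracles used across tests.

# two-state chain 1 -> 2 (state 2 absorbing), constant rate q, no covariates
two_state_model <- function(q) {
  st <- transition_structure(n_states = 2L,
                             allowed = cbind(from = 1L, to = 2L),
                             state_names = c("well", "gone"))
  intensity_model(structure = st, log_q0 = c("1-2" = log(q)))
}

# four-state baseline-only model (no covariates, no age bands)
plain_model <- function(log_q0 = log(c(
    "1-2" = 0.25, "1-3" = 0.002, "1-4" = 0.02,
    "2-1" = 0.15, "2-3" = 0.05, "2-4" = 0.06, "3-4" = 0.30))) {
  intensity_model(structure = transition_structure(), log_q0 = log_q0)
}

# four-state model with one binary covariate on selected transitions only;
# used by the coverage and SE-scaling suites (kept deliberately small)
group_model <- function(beta12 = 0) {
  spec <- covariate_spec(covariates = list(group = c("a", "b")),
                         design = list(group = "1-2"))
  intensity_model(structure = transition_structure(), spec = spec,
                  log_q0 = log(c("1-2" = 0.25, "1-3" = 0.002, "1-4" = 0.02,
                                 "2-1" = 0.15, "2-3" = 0.05, "2-4" = 0.06,
                                 "3-4" = 0.30)),
                  beta = list(group = list(b = c("1-2" = beta12))))
}

group_cohort_config <- function(n, seed) {
  cohort_config(n_subjects = n,
                covariate_distribution = list(group = c(a = 0.5, b = 0.5)),
                seed = seed)
}

simulate_panel <- function(model, cfg, horizon = 10, death_exact = TRUE,
                           dropout = cfg$dropout_hazard) {
  coh <- generate_cohort(cfg)
  paths <- simulate_paths(model, coh, horizon = horizon, seed = cfg$seed + 1L)
  observe_panel(paths, wave_times = cfg$wave_times, dropout_hazard = dropout,
                death_exact = death_exact, seed = cfg$seed + 2L)
}

# Independent ODE oracle: RK4 integration of the Kolmogorov forward
# equations dP/du = P Q(age_start + u), integrated piecewise between
# age-band cut-points so the right-hand side is smooth on each segment.
rk4_transition_probability <- function(model, covariates = list(),
                                       age_start = NULL, t, h = 1e-3) {
  n <- model$structure$n_states
  P <- diag(n)
  if (t == 0) return(P)
  cuts <- model$spec$age_bands
  brk <- if (is.null(cuts) || is.null(age_start)) c(0, t)
         else unique(c(0, pmin(pmax(cuts - age_start, 0), t), t))
  brk <- sort(brk[brk >= 0 & brk <= t])
  for (i in seq_len(length(brk) - 1L)) {
    a <- brk[i]; b <- brk[i + 1L]
    if (b <= a) next
    Q <- build_generator(model, covariates,
                         age = if (is.null(cuts)) NULL else age_start + a)
    nstep <- max(1L, ceiling((b - a) / h))
    hh <- (b - a) / nstep
    for (s in seq_len(nstep)) {
      k1 <- P %*% Q
      k2 <- (P + hh / 2 * k1) %*% Q
      k3 <- (P + hh / 2 * k2) %*% Q
      k4 <- (P + hh * k3) %*% Q
      P <- P + hh / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
  }
  P
}

# Simpson's rule for the total-length-of-stay integral oracle
simpson_totlos <- function(model, covariates = list(), age_start = NULL,
                           start_state = 1L, horizon, step = 0.01) {
  m <- ceiling(horizon / step / 2) * 2
  u <- seq(0, horizon, length.out = m + 1L)
  w <- c(1, rep(c(4, 2), length.out = m - 1L), 1)
  vals <- vapply(u, function(ui)
    transition_probability(model, covariates, age_start, ui)[start_state, ],
    numeric(model$structure$n_states))
  as.numeric(vals %*% w) * (u[2L] - u[1L]) / 3
}

update_params_for_test <- function(model, theta)
  panelmsm:::update_params(model, theta)

ref_pattern <- function(sep = "wealth") {
  pats <- list(wealth = list(wealth = "lowest"),
               education = list(education = "low"),
               occupation = list(occupation = "routine"))
  c(pats[[sep]], list(sex = "male", marital = "married"))
}
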