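#' Configuration of a synthetic ELSA-like cohort
#'
#' Default marginal distributions mirror the baseline table of an English
#' ageing panel with n = 8442: age mean 67 (SD 9.5, truncated at 50, whole
#' years), 55.74% female, 65.30% married/partnered, education
#' low/middle/high 27.81/54.11/18.07%, occupation
#' routine/intermediate/managerial 31.02/35.24/33.73%, and wealth tertiles
#' roughly a third each (32.80/33.74/33.45%).  Six roughly biennial waves at
#' 0, 2, ..., 10 years.  Probability vectors are normalised to sum exactly
#' to 1; vectors off by more than 0.02 are rejected.
#'
#' @param n_subjects Cohort size.
#' @param wave_times Strictly increasing observation schedule starting at 0.
#' @param covariate_distribution Named list of named probability vectors.
#' @param age_mean,age_sd,age_min Baseline age distribution (years); sampled
#'   from a truncated normal and rounded to whole years.
#' @param initial_state_probs Probabilities over transient states 1..3.
#' @param dropout_hazard Per-wave probability of dropping out before each
#'   wave after baseline.
#' @param seed Integer seed; every stochastic stage derives from it.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8442L,
                          wave_times = seq(0, 10, by = 2),
                          covariate_distribution = list(
                            sex        = c(male = 44.26, female = 55.74) / 100,
                            marital    = c(married = 65.30, single = 34.70) / 100,
                            education  = c(low = 27.81, middle = 54.11,
                                           high = 18.07) / 100,
                            occupation = c(routine = 31.02, intermediate = 35.24,
                                           managerial = 33.73) / 100,
                            wealth     = c(lowest = 32.80, middle = 33.74,
                                           highest = 33.45) / 100),
                          age_mean = 67, age_sd = 9.5, age_min = 50,
                          initial_state_probs = c(0.65, 0.33, 0.02),
                          dropout_hazard = 0.08,
                          seed = 1L) {
  if (length(wave_times) < 2L || wave_times[1L] != 0 ||
      is.unsorted(wave_times, strictly = TRUE))
    stop("wave_times must be strictly increasing and start at 0")
  for (nm in names(covariate_distribution)) {
    p <- covariate_distribution[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 0.02 || is.null(names(p)))
      stop("invalid probability vector for covariate '", nm, "'")
    covariate_distribution[[nm]] <- p / sum(p)
  }
  if (any(initial_state_probs < 0) || abs(sum(initial_state_probs) - 1) > 1e-8)
    stop("initial_state_probs must be a probability vector")
  if (dropout_hazard < 0 || dropout_hazard >= 1)
    stop("dropout_hazard must be in [0, 1)")
  structure(list(n_subjects = as.integer(n_subjects), wave_times = wave_times,
                 covariate_distribution = covariate_distribution,
                 age_mean = age_mean, age_sd = age_sd, age_min = age_min,
                 initial_state_probs = initial_state_probs /
                   sum(initial_state_probs),
                 dropout_hazard = dropout_hazard, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Draw a baseline cohort table
#'
#' Samples baseline covariates (independently from the configured marginals),
#' integer ages and initial states.  Covariate dependence can be injected by
#' post-processing the returned table (documented hook: every downstream
#' stage only reads the table, never the config marginals).
#'
#' @param config A [cohort_config()].
#' @return data.frame with columns `id`, `age`, one column per covariate and
#'   `state`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  out <- data.frame(id = seq_len(n))
  # truncated normal by rejection, rounded to whole years
  age <- numeric(n)
  todo <- seq_len(n)
  while (length(todo)) {
    age[todo] <- stats::rnorm(length(todo), config$age_mean, config$age_sd)
    todo <- todo[age[todo] < config$age_min]
  }
  out$age <- round(age)
  for (nm in names(config$covariate_distribution)) {
    p <- config$covariate_distribution[[nm]]
    out[[nm]] <- if (n) sample(names(p), n, replace = TRUE, prob = p)
                 else character(0)
  }
  out$state <- if (n) sample(seq_along(config$initial_state_probs), n,
                             replace = TRUE, prob = config$initial_state_probs)
               else integer(0)
  out
}

## Per-year outflow rates for every (pattern, band) combo of a cohort.
## Returns list(pat_id = per-subject combo row, rates = matrix
## (npattern*nbands) x K, band of each row, nb).
combo_rates <- function(model, cohort) {
  spec <- model$spec
  covs <- names(spec$covariates)
  nb <- n_bands(spec)
  pat_key <- if (length(covs))
    do.call(paste, c(lapply(covs, function(cv) cohort[[cv]]), sep = "\r"))
  else rep("", nrow(cohort))
  upat <- !duplicated(pat_key)
  pat_id <- match(pat_key, pat_key[upat])
  patterns <- cohort[upat, covs, drop = FALSE]
  if (length(covs)) patterns <- validate_pattern_df(spec, patterns)
  G <- nrow(patterns)
  pat_rep <- patterns[rep(seq_len(G), each = nb), , drop = FALSE]
  band_rep <- rep(seq_len(nb), times = G)
  A <- design_matrix_combos(model$map, model$structure, pat_rep, band_rep)
  K <- length(model$structure$labels)
  logq <- matrix(A %*% model$params, ncol = K, byrow = TRUE)
  q <- exp(logq)
  q[, model$rate_zero] <- 0
  list(pat_id = pat_id, rates = q, nb = nb)
}

## validate_pattern for a multi-row data.frame
validate_pattern_df <- function(spec, df) {
  for (cv in names(spec$covariates)) {
    if (is.null(df[[cv]])) stop("missing value for covariate '", cv, "'")
    lv <- spec$covariates[[cv]]
    if (is.null(lv)) {
      df[[cv]] <- as.numeric(df[[cv]])
    } else {
      bad <- setdiff(unique(as.character(df[[cv]])), lv)
      if (length(bad))
        stop("unknown level '", bad[1L], "' for covariate '", cv, "'")
      df[[cv]] <- as.character(df[[cv]])
    }
  }
  df[names(spec$covariates)]
}

#' Simulate exact continuous-time trajectories (Gillespie scheme)
#'
#' Holding time in state r is exponential with rate \eqn{-q_{rr}} under the
#' current age band; at age-band boundaries the clock is re-drawn (valid by
#' memorylessness of the exponential), so intensities are piecewise constant
#' in age exactly as in the fitted model.  The next state is s with
#' probability \eqn{q_{rs}/(-q_{rr})}.  Paths stop at the horizon or on
#' absorption.  Zero total outflow is valid: the subject stays put.
#'
#' @param model An [intensity_model()].
#' @param cohort Baseline table from [generate_cohort()].
#' @param horizon Follow-up length in years.
#' @param seed Integer seed.
#' @return Object of class `exact_paths`: list with `jumps` (data.frame
#'   `id`, `time`, `state`; the first row of each subject is the initial
#'   state at time 0), `cohort`, `horizon`.
#' @export
simulate_paths <- function(model, cohort, horizon = 10, seed = 1L) {
  stopifnot(nrow(cohort) == 0 || all(c("id", "state") %in% names(cohort)))
  set.seed(seed)
  spec <- model$spec
  cuts <- spec$age_bands
  cr <- combo_rates(model, cohort)
  K <- length(model$structure$labels)
  from <- model$structure$allowed[, 1L]
  to <- model$structure$allowed[, 2L]
  absorbing <- model$structure$absorbing
  ids <- times <- states <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    s <- cohort$state[i]
    t <- 0
    tt <- 0
    ss <- s
    base_age <- if (is.null(cuts)) NA_real_ else cohort$age[i]
    repeat {
      if (absorbing[s] || t >= horizon) break
      b <- if (is.null(cuts)) 1L else band_index(spec, base_age + t)
      rates <- cr$rates[(cr$pat_id[i] - 1L) * cr$nb + b, ]
      rates[from != s] <- 0
      tot <- sum(rates)
      if (tot == 0) break
      # time at which the band (hence Q) next changes
      t_change <- if (is.null(cuts) || b >= length(cuts)) Inf
                  else cuts[b + 1L] - base_age
      tau <- stats::rexp(1L, tot)
      if (t + tau >= min(horizon, t_change)) {
        t <- min(horizon, t_change)    # re-draw after the boundary
        next
      }
      t <- t + tau
      s <- to[sample.int(K, 1L, prob = rates)]
      tt <- c(tt, t)
      ss <- c(ss, s)
    }
    ids[[i]] <- rep(cohort$id[i], length(tt))
    times[[i]] <- tt
    states[[i]] <- ss
  }
  structure(list(jumps = data.frame(id = unlist(ids), time = unlist(times),
                                    state = unlist(states)),
                 cohort = cohort, horizon = horizon),
            class = "exact_paths")
}

path_state_at <- function(times, states, t) {
  states[findInterval(t, times)]
}

#' Degrade exact paths to panel observations
#'
#' Records the state at each attended interview wave.  Dropout removes all
#' records from the (geometrically distributed) dropout wave onwards; the
#' baseline wave is always attended.  A death is discovered at the first
#' scheduled wave after it occurs (a proxy report at the next interview),
#' and only if that wave would still have been attended; with
#' `death_exact = TRUE` the discovered death is recorded at its exact
#' event time, otherwise as state 4 at the discovery wave.  Discovery-based
#' ascertainment keeps dropout non-informative: the interval between a
#' subject's last attended wave and their dropout wave yields no record
#' whether they survived it or not, so the panel likelihood (which ignores
#' that tail) is exactly the density of the generated records.
#'
#' @param paths An `exact_paths` object from [simulate_paths()].
#' @param wave_times Interview schedule (years), within the path horizon.
#' @param dropout_hazard Per-wave dropout probability.
#' @param death_exact Record exact death times (default TRUE).
#' @param seed Integer seed (dropout randomness).
#' @return A [panel_dataset()].
#' @export
observe_panel <- function(paths, wave_times = seq(0, 10, by = 2),
                          dropout_hazard = 0.08, death_exact = TRUE,
                          seed = 1L) {
  stopifnot(inherits(paths, "exact_paths"))
  if (max(wave_times) > paths$horizon + 1e-9)
    stop("wave_times must lie within the simulated horizon")
  set.seed(seed)
  cohort <- paths$cohort
  jumps <- split(paths$jumps[c("time", "state")], paths$jumps$id)
  W <- length(wave_times)
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    j <- jumps[[as.character(cohort$id[i])]]
    # wave attendance: drop with prob h before each wave after baseline
    drop_at <- if (dropout_hazard > 0) {
      u <- stats::runif(W - 1L) < dropout_hazard
      if (any(u)) which(u)[1L] + 1L else W + 1L
    } else W + 1L
    attended <- wave_times[seq_len(min(drop_at - 1L, W))]
    died <- j$state[nrow(j)] == 4L
    dtime <- if (died) j$time[nrow(j)] else Inf
    # death is discovered at the first scheduled wave after the event,
    # provided that wave precedes dropout
    discovery <- if (died) which(wave_times > dtime)[1L] else NA_integer_
    discovered <- !is.na(discovery) && discovery < drop_at
    if (death_exact) {
      tt <- attended[attended < dtime]
      st <- path_state_at(j$time, j$state, tt)
      if (discovered) {
        tt <- c(tt, dtime)
        st <- c(st, 4L)
      }
    } else {
      tt <- attended[attended < dtime]
      st <- path_state_at(j$time, j$state, tt)
      if (discovered) {
        tt <- c(tt, wave_times[discovery])
        st <- c(st, 4L)
      }
    }
    base_age <- if (!is.null(cohort$age)) cohort$age[i] else NA_real_
    rows[[i]] <- if (length(tt))
      data.frame(id = cohort$id[i], time = tt, age = base_age + tt,
                 state = st)
  }
  long <- do.call(rbind, rows)
  covs <- setdiff(names(cohort), c("id", "age", "state"))
  long <- merge(long, cohort[c("id", covs)], by = "id", sort = TRUE)
  long <- long[order(long$id, long$time), ]
  rownames(long) <- NULL
  panel_dataset(long, spec = NULL, death_exact = death_exact)
}
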