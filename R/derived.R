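#' Hazard-ratio table from a fitted model
#'
#' One row per (covariate, non-reference level, transition): hazard ratio
#' `exp(beta)` with delta-method confidence interval
#' `exp(beta +/- z * SE)` on the log scale.  No re-estimation is performed:
#' the HR is exactly the exponential of the fitted coefficient.  When the
#' covariance matrix is unavailable the point estimates are returned with
#' CI columns set to `NA`.
#'
#' @param fit A `panelmsm_fit`.
#' @param include_age Include the age-band offsets as rows (default FALSE).
#' @param conf_level Confidence level (default 0.95).
#' @return data.frame with columns `covariate`, `level`, `transition`,
#'   `hr`, `lower`, `upper`, `se_log`.
#' @export
hazard_ratios <- function(fit, include_age = FALSE, conf_level = 0.95) {
  stopifnot(inherits(fit, "panelmsm_fit"))
  map <- fit$model$map
  keep <- map$kind == "beta" | (include_age & map$kind == "age")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  est <- fit$estimates[keep]
  se <- if (is.null(fit$vcov)) rep(NA_real_, sum(keep)) else fit$se[keep]
  out <- data.frame(covariate = map$covariate[keep],
                    level = map$level[keep],
                    transition = map$transition[keep],
                    hr = exp(est),
                    lower = exp(est - z * se),
                    upper = exp(est + z * se),
                    se_log = se,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Lay a hazard-ratio table out with transitions as columns
#'
#' The conventional reporting layout for the cognitive model: columns
#' 1-2 (NOCI to CIND), 2-1, 2-3, 1-3, 3-4, cells "HR (lower, upper)".
#'
#' @param hrt Output of [hazard_ratios()].
#' @param transitions Column order.
#' @return data.frame, one row per (covariate, level).
#' @export
format_hr_table <- function(hrt, transitions = c("1-2", "2-1", "2-3",
                                                 "1-3", "3-4")) {
  transitions <- intersect(transitions, unique(hrt$transition))
  keys <- unique(hrt[c("covariate", "level")])
  out <- keys
  num <- function(x) {
    # boundary/non-identified cells can be astronomically large or tiny
    ifelse(is.finite(x) & x >= 0.01 & x < 100, sprintf("%.2f", x),
           sprintf("%.2g", x))
  }
  for (tr in transitions) {
    cell <- character(nrow(keys))
    for (i in seq_len(nrow(keys))) {
      row <- hrt[hrt$covariate == keys$covariate[i] &
                 hrt$level == keys$level[i] & hrt$transition == tr, ]
      cell[i] <- if (!nrow(row)) "-"
      else if (is.na(row$lower)) sprintf("%s (CI unavailable)", num(row$hr))
      else sprintf("%s (%s, %s)", num(row$hr), num(row$lower), num(row$upper))
    }
    out[[tr]] <- cell
  }
  out
}

#' State-occupancy (stacked transition-probability) curves
#'
#' Rows of \eqn{P(t)} from a starting state over a time grid, with
#' piecewise-constant age bands applied along the way; suitable for stacked
#' occupancy plotting and for predicted prevalence.
#'
#' @param model An [intensity_model()] or `panelmsm_fit`.
#' @param covariates Covariate values (all covariates in the spec).
#' @param start_age Age in years at time 0.
#' @param start_state Starting state (default 1).
#' @param times Non-negative increasing time grid (years).
#' @return Tidy data.frame: `time`, `state`, `state_name`, `probability`.
#' @export
occupancy_curves <- function(model, covariates = list(), start_age = NULL,
                             start_state = 1L, times = seq(0, 10, by = 0.5)) {
  if (inherits(model, "panelmsm_fit")) model <- model$model
  if (any(times < 0) || is.unsorted(times))
    stop("times must be non-negative and increasing")
  st <- model$structure
  pattern <- validate_pattern(model$spec, covariates)
  n <- st$n_states
  P <- diag(n)
  out <- matrix(NA_real_, length(times), n)
  prev_t <- 0
  for (i in seq_along(times)) {
    segs <- age_segments(model$spec,
                         if (is.null(start_age)) NULL else start_age + prev_t,
                         times[i] - prev_t)
    for (j in seq_len(nrow(segs)))
      P <- P %*% mat_exp(generator_combo(model, pattern, segs$band[j]) *
                           segs$dur[j])
    out[i, ] <- P[start_state, ]
    prev_t <- times[i]
  }
  data.frame(time = rep(times, n),
             state = rep(seq_len(n), each = length(times)),
             state_name = rep(st$state_names, each = length(times)),
             probability = as.numeric(out))
}

## integral of expm(Q u) du over [0, dur] (Van Loan augmented-matrix form):
## expm([[Q, I], [0, 0]] dur) has the integral as its upper-right block.
expm_integral <- function(Q, dur) {
  n <- nrow(Q)
  Aug <- matrix(0, 2L * n, 2L * n)
  Aug[seq_len(n), seq_len(n)] <- Q
  Aug[seq_len(n), n + seq_len(n)] <- diag(n)
  E <- mat_exp(Aug * dur)
  list(P = E[seq_len(n), seq_len(n), drop = FALSE],
       I = E[seq_len(n), n + seq_len(n), drop = FALSE])
}

#' Expected total length of stay per state over a horizon
#'
#' \eqn{\mathrm{totlos}(r, s, T) = \int_0^T P_{rs}(u)\,du}: the expected
#' number of years spent in state s within T years, starting from state r.
#' The integral is evaluated in closed form segment-by-segment across
#' age-band boundaries via the augmented-matrix-exponential identity (no
#' quadrature error); the entries sum to T over states.
#'
#' @inheritParams occupancy_curves
#' @param horizon Horizon T in years (>= 0).
#' @return Named numeric vector of expected years by state.
#' @export
total_length_of_stay <- function(model, covariates = list(), start_age = NULL,
                                 start_state = 1L, horizon = 10) {
  if (inherits(model, "panelmsm_fit")) model <- model$model
  if (horizon < 0) stop("horizon must be >= 0")
  st <- model$structure
  pattern <- validate_pattern(model$spec, covariates)
  n <- st$n_states
  tot <- stats::setNames(numeric(n), st$state_names)
  if (horizon == 0) return(tot)
  P <- diag(n)
  segs <- age_segments(model$spec, start_age, horizon)
  for (j in seq_len(nrow(segs))) {
    Q <- generator_combo(model, pattern, segs$band[j])
    E <- expm_integral(Q, segs$dur[j])
    tot <- tot + as.numeric((P %*% E$I)[start_state, ])
    P <- P %*% E$P
  }
  tot
}

#' Mean sojourn times in transient states
#'
#' The mean duration of a single stay in transient state r is
#' \eqn{-1/q_{rr}(z, \mathrm{age})}, the reciprocal of the total outflow
#' rate.  For fitted models a delta-method confidence interval on the log
#' scale is returned.
#'
#' @param model An [intensity_model()] or `panelmsm_fit`.
#' @param covariates Covariate values.
#' @param age Age in years (selects the age band).
#' @param states States to report (default: all transient states);
#'   requesting an absorbing state is an error.
#' @param conf_level Confidence level.
#' @return data.frame `state`, `state_name`, `sojourn` (years), `lower`,
#'   `upper`.
#' @export
sojourn_times <- function(model, covariates = list(), age = NULL,
                          states = NULL, conf_level = 0.95) {
  fit <- NULL
  if (inherits(model, "panelmsm_fit")) {
    fit <- model
    model <- model$model
  }
  st <- model$structure
  if (is.null(states)) states <- which(!st$absorbing)
  if (any(st$absorbing[states]))
    stop("sojourn time is undefined for absorbing state(s) ",
         paste(states[st$absorbing[states]], collapse = ", "))
  pattern <- validate_pattern(model$spec, covariates)
  b <- if (is.null(model$spec$age_bands)) 1L else {
    if (is.null(age)) stop("age is required: the model has age bands")
    band_index(model$spec, age)
  }
  A <- design_matrix_combos(model$map, st, pattern, b)
  q <- exp(as.numeric(A %*% model$params))
  q[model$rate_zero] <- 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(state = states, state_name = st$state_names[states],
                    sojourn = NA_real_, lower = NA_real_, upper = NA_real_)
  for (ii in seq_along(states)) {
    r <- states[ii]
    kk <- which(st$allowed[, 1L] == r)
    tot <- sum(q[kk])
    out$sojourn[ii] <- 1 / tot
    if (!is.null(fit) && !is.null(fit$vcov) && tot > 0) {
      # d(log sum q)/d theta = sum_k q_k A_k / sum q
      g <- colSums(q[kk] * A[kk, , drop = FALSE]) / tot
      se_log <- sqrt(max(0, as.numeric(g %*% fit$vcov %*% g)))
      out$lower[ii] <- 1 / tot * exp(-z * se_log)
      out$upper[ii] <- 1 / tot * exp(z * se_log)
    }
  }
  out
}

#' Observed versus model-predicted prevalence over time
#'
#' Goodness-of-fit summary: at each grid time, the observed prevalence is
#' the distribution of states among subjects assignable to that time
#' (nearest observation within a window, defaulting to half the median
#' inter-observation gap; subjects with an exactly observed death before
#' the grid time count as dead), and the expected prevalence is the
#' average of model occupancy probabilities from each such subject's
#' baseline state, covariates and age.
#'
#' @param fit A `panelmsm_fit` (or [intensity_model()]).
#' @param dataset The fitted [panel_dataset()].
#' @param times Grid times in years.
#' @param window Assignment half-window in years (default: half the median
#'   gap between consecutive observations).
#' @return data.frame `time`, `state`, `state_name`, `observed`,
#'   `expected`, `n` (risk-set size); cells with an empty risk set are
#'   `NA`.
#' @export
prevalence_gof <- function(fit, dataset, times = seq(0, 10, by = 2),
                           window = NULL) {
  model <- if (inherits(fit, "panelmsm_fit")) fit$model else fit
  st <- model$structure
  n <- st$n_states
  d <- dataset$data
  if (is.null(window)) {
    gaps <- unlist(tapply(d$time, d$id, diff))
    window <- stats::median(gaps) / 2
  }
  subj <- split(d, d$id)
  base_state <- vapply(subj, function(x) x$state[1L], integer(1))
  base_age <- if (!is.null(d$age))
    vapply(subj, function(x) x$age[1L] - x$time[1L], numeric(1))
  else rep(NA_real_, length(subj))
  covs <- names(model$spec$covariates)
  base_cov <- if (length(covs))
    do.call(rbind, lapply(subj, function(x) x[1L, covs, drop = FALSE]))
  else data.frame(row.names = seq_along(subj))
  death_state <- which(st$absorbing)[1L]
  death_time <- vapply(subj, function(x)
    if (x$state[nrow(x)] %in% which(st$absorbing)) x$time[nrow(x)] else Inf,
    numeric(1))

  # occupancy curves per unique (pattern, baseline age, baseline state)
  key <- paste(do.call(paste, c(base_cov, sep = "\r")), base_age, base_state)
  ukey <- !duplicated(key)
  gid <- match(key, key[ukey])
  occ <- vector("list", sum(ukey))
  idx <- which(ukey)
  for (g in seq_along(idx)) {
    i <- idx[g]
    oc <- occupancy_curves(model,
                           covariates = as.list(base_cov[i, , drop = FALSE]),
                           start_age = if (is.na(base_age[i])) NULL
                                       else base_age[i],
                           start_state = base_state[i], times = times)
    occ[[g]] <- matrix(oc$probability, nrow = length(times))
  }

  out <- NULL
  for (ti in seq_along(times)) {
    t0 <- times[ti]
    obs_state <- rep(NA_integer_, length(subj))
    for (si in seq_along(subj)) {
      if (dataset$death_exact && death_time[si] <= t0) {
        obs_state[si] <- death_state
      } else {
        dts <- abs(subj[[si]]$time - t0)
        jmin <- which.min(dts)
        if (dts[jmin] <= window + 1e-9) obs_state[si] <- subj[[si]]$state[jmin]
      }
    }
    risk <- which(!is.na(obs_state))
    if (!length(risk)) {
      out <- rbind(out, data.frame(time = t0, state = seq_len(n),
                                   state_name = st$state_names,
                                   observed = NA_real_, expected = NA_real_,
                                   n = 0L))
      next
    }
    obs <- tabulate(obs_state[risk], n) / length(risk)
    exp_mat <- vapply(risk, function(si) occ[[gid[si]]][ti, ], numeric(n))
    expd <- rowMeans(exp_mat)
    out <- rbind(out, data.frame(time = t0, state = seq_len(n),
                                 state_name = st$state_names,
                                 observed = obs, expected = expd,
                                 n = length(risk)))
  }
  rownames(out) <- NULL
  out
}
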