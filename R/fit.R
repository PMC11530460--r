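#' Crude initial intensities from observed transition counts
#'
#' Baseline rate for transition r->s is initialised as (number of observed
#' successive r->s pairs) / (total observed person-time with left state r),
#' with zero counts replaced by a small floor; all covariate effects start
#' at 0.  This mirrors the standard crude-rate initialisation for panel
#' multistate models.
#'
#' @param dataset A [panel_dataset()].
#' @param structure A [transition_structure()].
#' @param spec A [covariate_spec()] for the returned model (default: none).
#' @param floor Minimum initial rate (per year) for unobserved transitions.
#' @return An [intensity_model()] with `log_q0` set and all betas 0.
#' @export
crude_initial_values <- function(dataset, structure = dataset$structure,
                                 spec = covariate_spec(), floor = 1e-4) {
  d <- dataset$data
  if (!nrow(d)) stop("empty dataset")
  n <- nrow(d)
  same <- if (n > 1L) d$id[-1L] == d$id[-n] else logical(0)
  i <- which(same)
  tab <- statetable(dataset)
  ptime <- vapply(seq_len(structure$n_states), function(r)
    sum((d$time[i + 1L] - d$time[i])[d$state[i] == r]), numeric(1))
  q0 <- numeric(length(structure$labels))
  for (k in seq_along(structure$labels)) {
    r <- structure$allowed[k, 1L]
    s <- structure$allowed[k, 2L]
    if (ptime[r] <= 0) {
      warning("no observed person-time in state ", r,
              "; using floor rate for ", structure$labels[k])
      q0[k] <- floor
    } else {
      q0[k] <- max(tab[r, s] / ptime[r], floor)
    }
  }
  intensity_model(structure = structure, spec = spec,
                  log_q0 = stats::setNames(log(q0), structure$labels))
}

central_gradient <- function(fn, theta, rel_step = 1e-5) {
  p <- length(theta)
  g <- numeric(p)
  for (j in seq_len(p)) {
    h <- rel_step * max(1, abs(theta[j]))
    up <- dn <- theta
    up[j] <- theta[j] + h
    dn[j] <- theta[j] - h
    g[j] <- (fn(up) - fn(dn)) / (2 * h)
  }
  g
}

central_hessian <- function(fn, theta, rel_step = 1e-4) {
  p <- length(theta)
  h <- rel_step * pmax(1, abs(theta))
  H <- matrix(0, p, p)
  f0 <- fn(theta)
  for (j in seq_len(p)) {
    ej <- numeric(p)
    ej[j] <- h[j]
    H[j, j] <- (fn(theta + ej) - 2 * f0 + fn(theta - ej)) / h[j]^2
    for (k in seq_len(j - 1L)) {
      ek <- numeric(p)
      ek[k] <- h[k]
      H[j, k] <- H[k, j] <-
        (fn(theta + ej + ek) - fn(theta + ej - ek) -
         fn(theta - ej + ek) + fn(theta - ej - ek)) / (4 * h[j] * h[k])
    }
  }
  H
}

#' Maximum-likelihood fit of a multistate intensity model to panel data
#'
#' Quasi-Newton (BFGS) maximisation of the interval-censored panel
#' likelihood on the unconstrained scale (log baseline intensities, raw
#' covariate/age coefficients), with central finite-difference gradients.
#' Standard errors come from the inverse of the central finite-difference
#' Hessian at the optimum; a near-singular Hessian (condition number >
#' 1e10) falls back to an eigenvalue pseudo-inverse with a warning.
#' Subjects with a single observation are dropped (counted in
#' `$n_dropped`).  Per-coefficient identifiability diagnostics (observed
#' direct transition pairs informing each effect) are in `$diagnostics`.
#'
#' @param dataset A [panel_dataset()].
#' @param model An [intensity_model()] defining structure, covariate design
#'   and (optionally) initial values.
#' @param init `"crude"` (default: crude rates, betas 0) or `"model"` (use
#'   `model$params` as given).
#' @param death_exact Exact-death likelihood contribution for final
#'   absorbing observations (defaults to the dataset's flag).
#' @param hessian Compute the Hessian / covariance matrix (default TRUE).
#' @param engine Likelihood engine, `"C"` (default) or `"R"`.
#' @param control Passed to [stats::optim()]; defaults
#'   `list(maxit = 500, reltol = 1e-10)`.
#' @return Object of class `panelmsm_fit`: fitted model, `estimates`,
#'   `se`, `vcov`, `loglik`, `converged`, `statetable`, counts and
#'   diagnostics.
#' @export
fit_panel_msm <- function(dataset, model, init = c("crude", "model"),
                          death_exact = dataset$death_exact,
                          hessian = TRUE, engine = c("C", "R"),
                          control = list()) {
  init <- match.arg(init)
  engine <- match.arg(engine)
  stopifnot(inherits(dataset, "panel_dataset"), inherits(model, "intensity_model"))
  if (any(model$rate_zero))
    stop("cannot fit a model with rate_zero flags; drop those transitions ",
         "from the structure instead")
  L <- build_likelihood_data(dataset, model, death_exact)
  if (!is.null(L$impossible))
    stop("dataset contains transition(s) impossible under the structure; ",
         "first offender: subject ", L$impossible$id[1L], " at time ",
         L$impossible$time[1L], " (", L$impossible$from[1L], "->",
         L$impossible$to[1L], ")")
  theta0 <- if (init == "crude") {
    m0 <- crude_initial_values(dataset, model$structure, model$spec)
    m0$params
  } else model$params
  if (any(!is.finite(theta0))) stop("non-finite initial values")
  negll <- function(th) -panel_loglik(th, L, engine)
  grad <- function(th) -central_gradient(function(x) panel_loglik(x, L, engine), th)
  control <- utils::modifyList(list(maxit = 500, reltol = 1e-10), control)
  opt <- stats::optim(theta0, fn = negll, gr = grad, method = "BFGS",
                      control = control)
  theta <- stats::setNames(opt$par, model$map$name)
  fitted <- update_params(model, theta)

  K <- length(model$structure$labels)
  if (any(theta[seq_len(K)] < log(1e-6)))
    warning("fitted rate(s) at the zero boundary: ",
            paste(model$map$name[seq_len(K)][theta[seq_len(K)] < log(1e-6)],
                  collapse = ", "))

  vcov <- NULL
  se <- rep(NA_real_, length(theta))
  if (hessian) {
    H <- central_hessian(negll, opt$par)
    ev <- eigen(H, symmetric = TRUE)
    if (min(ev$values) <= 0 ||
        max(ev$values) / max(min(ev$values), .Machine$double.xmin) > 1e10) {
      warning("Hessian is singular or near-singular (condition number > 1e10); ",
              "using pseudo-inverse standard errors")
      pos <- ev$values > max(ev$values) * 1e-12
      vcov <- ev$vectors[, pos, drop = FALSE] %*%
        diag(1 / ev$values[pos], sum(pos)) %*% t(ev$vectors[, pos, drop = FALSE])
    } else {
      vcov <- ev$vectors %*% diag(1 / ev$values, length(ev$values)) %*%
        t(ev$vectors)
    }
    vcov <- (vcov + t(vcov)) / 2
    dimnames(vcov) <- list(names(theta), names(theta))
    se <- sqrt(pmax(diag(vcov), 0))
  }

  # identifiability: observed direct pairs informing each coefficient
  tab <- statetable_from_L(L, model$structure)
  diag_df <- model$map
  diag_df$events <- tab[cbind(as.integer(sub("-.*", "", diag_df$transition)),
                              as.integer(sub(".*-", "", diag_df$transition)))]

  out <- list(model = fitted,
              estimates = theta,
              se = stats::setNames(se, names(theta)),
              vcov = vcov,
              loglik = -opt$value,
              converged = opt$convergence == 0L,
              optim_code = opt$convergence,
              optim_counts = opt$counts,
              message = opt$message,
              n_subjects = L$n_subjects,
              n_observations = L$n_observations,
              n_dropped = L$n_dropped,
              statetable = tab,
              diagnostics = diag_df,
              death_exact = death_exact,
              engine = engine)
  class(out) <- "panelmsm_fit"
  out
}

statetable_from_L <- function(L, structure) {
  n <- structure$n_states
  tab <- matrix(0, n, n, dimnames = list(from = structure$state_names,
                                         to = structure$state_names))
  for (i in seq_along(L$term_r))
    tab[L$term_r[i], L$term_s[i]] <- tab[L$term_r[i], L$term_s[i]] + L$term_w[i]
  tab
}

#' @export
print.panelmsm_fit <- function(x, ...) {
  cat("Multistate Markov model fit (", if (x$converged) "converged"
      else "NOT converged", ")\n", sep = "")
  cat("  -2 log-likelihood:", format(-2 * x$loglik, digits = 8), "\n")
  cat("  subjects:", x$n_subjects, " observations:", x$n_observations,
      if (x$n_dropped) paste0(" (", x$n_dropped, " single-observation subjects dropped)"),
      "\n")
  est <- data.frame(estimate = round(x$estimates, 4))
  if (!is.null(x$vcov)) {
    est$se <- round(x$se, 4)
    est$`exp(est)` <- round(exp(x$estimates), 4)
  }
  print(utils::head(est, 30))
  if (nrow(est) > 30) cat("  ...", nrow(est) - 30, "more parameters\n")
  invisible(x)
}

#' @export
logLik.panelmsm_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$estimates), class = "logLik")
}

#' @export
vcov.panelmsm_fit <- function(object, ...) object$vcov

#' @export
coef.panelmsm_fit <- function(object, ...) object$estimates
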