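## Parameterisation: for allowed transition r->s with covariate vector z and
## age band b,   q_rs(z, b) = exp( log_q0_rs + beta_rs' z + alpha_rs[b] ),
## i.e. proportional intensities on the log scale with piecewise-constant
## additive age-band offsets.  The full parameter vector theta concatenates
## log_q0 (one per allowed transition), the beta blocks (per covariate, per
## non-reference level, per designed transition) and the age offsets (bands
## 2..B, per designed transition).

param_template <- function(structure, spec) {
  K <- length(structure$labels)
  rows <- data.frame(name = sprintf("logq(%s)", structure$labels),
                     kind = "logq", covariate = NA_character_,
                     level = NA_character_, band = NA_integer_,
                     transition = structure$labels, k = seq_len(K),
                     stringsAsFactors = FALSE)
  for (cv in names(spec$covariates)) {
    lv <- spec$covariates[[cv]]
    tr <- spec$design[[cv]]
    k <- trans_index(structure, sub("-.*", "", tr), sub(".*-", "", tr))
    if (is.null(lv)) {
      rows <- rbind(rows, data.frame(
        name = sprintf("beta(%s,%s)", cv, tr), kind = "beta",
        covariate = cv, level = NA_character_, band = NA_integer_,
        transition = tr, k = k, stringsAsFactors = FALSE))
    } else {
      for (l in lv[-1L]) {
        rows <- rbind(rows, data.frame(
          name = sprintf("beta(%s=%s,%s)", cv, l, tr), kind = "beta",
          covariate = cv, level = l, band = NA_integer_,
          transition = tr, k = k, stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(spec$age_bands) && length(spec$age_bands) > 1L &&
      length(spec$age_design)) {
    lab <- band_labels(spec$age_bands)
    tr <- spec$age_design
    k <- trans_index(structure, sub("-.*", "", tr), sub(".*-", "", tr))
    for (b in 2L:length(spec$age_bands)) {
      rows <- rbind(rows, data.frame(
        name = sprintf("beta(age=%s,%s)", lab[b], tr), kind = "age",
        covariate = "age", level = lab[b], band = b,
        transition = tr, k = k, stringsAsFactors = FALSE))
    }
  }
  rownames(rows) <- NULL
  rows
}

## Design matrix mapping theta to the stacked log-intensities of a set of
## covariate-pattern x age-band combos; rows are combo-major blocks of K
## transitions: row (g-1)*K + k = log q for transition k under combo g.
design_matrix_combos <- function(map, structure, patterns, bands) {
  G <- nrow(patterns)
  K <- length(structure$labels)
  A <- matrix(0, G * K, nrow(map))
  for (j in seq_len(nrow(map))) {
    k <- map$k[j]
    rows <- (seq_len(G) - 1L) * K + k
    val <- switch(map$kind[j],
      logq = rep(1, G),
      beta = if (is.na(map$level[j])) as.numeric(patterns[[map$covariate[j]]])
             else as.numeric(patterns[[map$covariate[j]]] == map$level[j]),
      age  = as.numeric(bands == map$band[j]))
    A[rows, j] <- val
  }
  colnames(A) <- map$name
  A
}

#' Transition-intensity regression model
#'
#' Combines a [transition_structure()], a [covariate_spec()] and parameter
#' values into the model \eqn{q_{rs}(z) = q^0_{rs} \exp(\beta_{rs}' z +
#' \alpha_{rs}[band(age)])}.  `exp(beta)` is the hazard ratio of a covariate
#' level versus its reference.
#'
#' @param structure A [transition_structure()].
#' @param spec A [covariate_spec()].
#' @param log_q0 Named numeric of baseline log intensities per allowed
#'   transition (per-year rates); a scalar is recycled.
#' @param beta Nested list: `beta[[covariate]][[level]]` is a named numeric of
#'   log hazard ratios by transition label (numeric covariates use
#'   `beta[[covariate]]` directly).  Unspecified entries are 0.
#' @param age_offsets Named list by age-band label (bands 2 onwards), each a
#'   named numeric of additive log-intensity offsets by transition label.
#' @param rate_zero Character vector of transition labels whose baseline rate
#'   is structurally zero (a flag, so that `-Inf` log intensities are never
#'   stored).
#' @return Object of class `intensity_model`; the canonical parameter vector
#'   is in `$params` with the layout described by `$map`.
#' @export
intensity_model <- function(structure = transition_structure(),
                            spec = covariate_spec(),
                            log_q0 = log(0.1), beta = list(),
                            age_offsets = list(), rate_zero = character()) {
  map <- param_template(structure, spec)
  theta <- stats::setNames(numeric(nrow(map)), map$name)
  K <- length(structure$labels)
  if (length(log_q0) == 1L && is.null(names(log_q0)))
    log_q0 <- stats::setNames(rep(log_q0, K), structure$labels)
  if (!all(structure$labels %in% names(log_q0)))
    stop("log_q0 must name every allowed transition")
  if (any(!is.finite(unlist(log_q0))))
    stop("log_q0 must be finite; use rate_zero to switch a transition off")
  theta[seq_len(K)] <- log_q0[structure$labels]
  for (cv in names(beta)) {
    if (!cv %in% names(spec$covariates)) stop("unknown covariate '", cv, "' in beta")
    bl <- beta[[cv]]
    if (is.null(spec$covariates[[cv]])) bl <- list(. = bl)  # numeric covariate
    for (l in names(bl)) {
      v <- bl[[l]]
      for (tr in names(v)) {
        nm <- if (is.null(spec$covariates[[cv]]))
          sprintf("beta(%s,%s)", cv, tr)
        else sprintf("beta(%s=%s,%s)", cv, l, tr)
        if (!nm %in% map$name)
          stop("no parameter ", nm, " in the model design")
        theta[nm] <- v[[tr]]
      }
    }
  }
  if (length(age_offsets)) {
    lab <- band_labels(spec$age_bands)
    for (l in names(age_offsets)) {
      v <- age_offsets[[l]]
      for (tr in names(v)) {
        nm <- sprintf("beta(age=%s,%s)", l, tr)
        if (!nm %in% map$name) stop("no parameter ", nm, " in the model design")
        theta[nm] <- v[[tr]]
      }
    }
  }
  if (length(rate_zero) && !all(rate_zero %in% structure$labels))
    stop("rate_zero entries must be allowed transition labels")
  out <- list(structure = structure, spec = spec, params = theta,
              map = map, rate_zero = structure$labels %in% rate_zero)
  class(out) <- "intensity_model"
  out
}

#' @export
print.intensity_model <- function(x, ...) {
  cat("Transition-intensity model:", length(x$structure$labels),
      "transitions,", nrow(x$map), "parameters\n")
  print(round(x$params, 4))
  invisible(x)
}

update_params <- function(model, theta) {
  stopifnot(length(theta) == nrow(model$map))
  model$params <- stats::setNames(as.numeric(theta), model$map$name)
  model
}

## Validates a covariate value set against the spec; returns a one-row
## data.frame pattern.  Errors name the offending covariate/level.
validate_pattern <- function(spec, covariates) {
  covariates <- as.list(covariates)
  out <- list()
  for (cv in names(spec$covariates)) {
    if (is.null(covariates[[cv]]))
      stop("missing value for covariate '", cv, "'")
    v <- covariates[[cv]]
    lv <- spec$covariates[[cv]]
    if (is.null(lv)) {
      out[[cv]] <- as.numeric(v)
    } else {
      v <- as.character(v)
      bad <- setdiff(unique(v), lv)
      if (length(bad))
        stop("unknown level '", bad[1L], "' for covariate '", cv,
             "' (levels: ", paste(lv, collapse = ", "), ")")
      out[[cv]] <- v
    }
  }
  if (!length(out)) return(data.frame(row.names = 1L))
  as.data.frame(out, stringsAsFactors = FALSE)
}

assemble_Q <- function(structure, q) {
  n <- structure$n_states
  Q <- matrix(0, n, n, dimnames = list(structure$state_names,
                                       structure$state_names))
  Q[structure$allowed] <- q
  diag(Q) <- -rowSums(Q)
  Q
}

#' Build the generator (intensity) matrix Q
#'
#' Evaluates every allowed transition intensity at the given covariate values
#' and age, returning the n x n generator: non-negative off-diagonal entries
#' on allowed transitions, zero elsewhere, rows summing to zero, absorbing
#' rows identically zero.
#'
#' @param model An [intensity_model()].
#' @param covariates Named list/row of covariate values (every covariate in
#'   the spec must be supplied).
#' @param age Age in years (required when the spec has age bands; clamped to
#'   the outer bands).
#' @return n x n numeric generator matrix (per-year rates).
#' @export
build_generator <- function(model, covariates = list(), age = NULL) {
  spec <- model$spec
  pattern <- validate_pattern(spec, covariates)
  if (!is.null(spec$age_bands) && is.null(age))
    stop("age is required: the model has age bands")
  b <- if (is.null(spec$age_bands)) 1L else band_index(spec, age)
  generator_combo(model, pattern, b)
}

## Generator for an already-validated pattern and band index.
generator_combo <- function(model, pattern, band) {
  A <- design_matrix_combos(model$map, model$structure, pattern, band)
  q <- exp(as.numeric(A %*% model$params))
  q[model$rate_zero] <- 0
  assemble_Q(model$structure, q)
}

## Matrix exponential: scaling-and-squaring with a [6/6] Pade approximant.
## Accurate to ~1e-14 for the small (<= 6x6) generators used here.
mat_exp <- function(A) {
  n <- nrow(A)
  nrm <- max(rowSums(abs(A)))
  j <- if (nrm > 0.5) ceiling(log2(nrm / 0.5)) else 0
  As <- A / 2^j
  X <- diag(n)
  N <- diag(n)
  D <- diag(n)
  cf <- 1
  for (k in 1:6) {
    cf <- cf * (6 - k + 1) / (k * (12 - k + 1))
    X <- As %*% X
    N <- N + cf * X
    D <- D + (-1)^k * cf * X
  }
  P <- solve(D, N)
  for (i in seq_len(j)) P <- P %*% P
  P
}

## Splits the age interval [age_start, age_start + t] at age-band cut-points;
## returns a data.frame of (band, dur) segments in time order.
age_segments <- function(spec, age_start, t) {
  if (t <= 0) return(data.frame(band = integer(), dur = numeric()))
  if (is.null(spec$age_bands) || is.null(age_start))
    return(data.frame(band = 1L, dur = t))
  cuts <- spec$age_bands
  inner <- cuts[cuts > age_start & cuts < age_start + t]
  pts <- c(age_start, inner, age_start + t)
  data.frame(band = band_index(spec, pts[-length(pts)]), dur = diff(pts))
}

#' Transition probability matrix P(t)
#'
#' Computes \eqn{P(t) = \exp(Qt)} by matrix exponential; when the age
#' interval `[age_start, age_start + t]` crosses age-band cut-points the
#' result is the ordered product of per-segment exponentials (the standard
#' time-inhomogeneous piecewise-constant construction).
#'
#' @inheritParams build_generator
#' @param age_start Age in years at the start of the interval.
#' @param t Interval length in years (>= 0).
#' @return n x n stochastic matrix; rows sum to 1.
#' @export
transition_probability <- function(model, covariates = list(),
                                   age_start = NULL, t) {
  if (t < 0) stop("t must be >= 0")
  n <- model$structure$n_states
  P <- diag(n)
  dimnames(P) <- list(model$structure$state_names, model$structure$state_names)
  segs <- age_segments(model$spec, age_start, t)
  if (!nrow(segs)) return(P)
  pattern <- validate_pattern(model$spec, covariates)
  if (!is.null(model$spec$age_bands) && is.null(age_start))
    stop("age_start is required: the model has age bands")
  for (i in seq_len(nrow(segs))) {
    Q <- generator_combo(model, pattern, segs$band[i])
    P <- P %*% mat_exp(Q * segs$dur[i])
  }
  dimnames(P) <- list(model$structure$state_names, model$structure$state_names)
  P
}
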