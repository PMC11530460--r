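## Preprocessing of a panel dataset into the grouped term representation
## consumed by the likelihood engines.  Subjects with a single observation
## cannot contribute and are dropped (with a count).  Interval covariates are
## taken at the left endpoint; the age interval of each observation pair is
## split at age-band cut-points.

build_likelihood_data <- function(dataset, model,
                                  death_exact = dataset$death_exact) {
  st <- model$structure
  spec <- model$spec
  d <- dataset$data
  K <- length(st$labels)
  nobs_per <- table(d$id)
  singles <- names(nobs_per)[nobs_per < 2L]
  n_dropped <- length(singles)
  if (n_dropped) d <- d[!(d$id %in% singles), , drop = FALSE]
  n <- nrow(d)
  if (n < 2L) stop("no subject has two or more observations")
  same <- d$id[-1L] == d$id[-n]
  i <- which(same)
  r <- d$state[i]
  s <- d$state[i + 1L]
  dt <- d$time[i + 1L] - d$time[i]
  covs <- names(spec$covariates)
  if (length(covs) && !all(covs %in% names(d)))
    stop("dataset is missing covariate column(s): ",
         paste(setdiff(covs, names(d)), collapse = ", "))
  has_bands <- !is.null(spec$age_bands)
  if (has_bands && is.null(d$age))
    stop("the model has age bands but the dataset has no 'age' column")
  age_l <- if (has_bands) d$age[i] else rep(NA_real_, length(i))

  # structurally impossible observed pairs
  reach <- reachable_states(st)
  bad <- !reach[cbind(r, s)]
  impossible <- if (any(bad))
    data.frame(id = d$id[i][bad], time = d$time[i][bad],
               from = r[bad], to = s[bad])
  else NULL

  # covariate patterns at interval left endpoints
  if (length(covs)) {
    pat_df <- validate_pattern_df(spec, d[i, covs, drop = FALSE])
    pat_key <- do.call(paste, c(pat_df, sep = "\r"))
  } else {
    pat_df <- data.frame(row.names = seq_along(i))
    pat_key <- rep("", length(i))
  }
  upat <- !duplicated(pat_key)
  patterns <- pat_df[upat, , drop = FALSE]
  pat_id <- match(pat_key, pat_key[upat])

  # final pair of each subject -> candidate exact-death term
  same2 <- c(same, FALSE)
  final <- !same2[i + 1L]
  death <- death_exact & final & st$absorbing[s]

  # age-band segmentation per pair, plus the band at the death instant
  nseg <- integer(length(i))
  seg_band <- seg_dur <- vector("list", length(i))
  for (p in seq_along(i)) {
    sg <- age_segments(spec, age_l[p], dt[p])
    nseg[p] <- nrow(sg)
    seg_band[[p]] <- sg$band
    seg_dur[[p]] <- sg$dur
  }
  death_band <- ifelse(death & has_bands,
                       band_index(spec, age_l + dt), 1L)

  # combos = unique (pattern, band) pairs appearing in segments or at death
  combo_key <- c(paste(rep(pat_id, nseg), unlist(seg_band)),
                 paste(pat_id[death], death_band[death]))
  ucombo <- unique(combo_key)
  combo_pat <- as.integer(sub(" .*", "", ucombo))
  combo_band <- as.integer(sub(".* ", "", ucombo))
  G <- length(ucombo)

  # jobs = unique (combo, duration) pairs
  pair_combo <- split(match(paste(rep(pat_id, nseg), unlist(seg_band)), ucombo),
                      rep(seq_along(i), nseg))
  durs <- unlist(seg_dur)
  all_combo <- unlist(pair_combo)
  job_key <- paste(all_combo, signif(durs, 12))
  ujob <- !duplicated(job_key)
  job_id_per_seg <- match(job_key, job_key[ujob])
  job_combo <- all_combo[ujob]
  job_dur <- durs[ujob]

  # group identical likelihood terms
  seg_sig <- vapply(split(job_id_per_seg, rep(seq_along(i), nseg)),
                    paste, character(1L), collapse = ";")
  death_combo <- ifelse(death, match(paste(pat_id, death_band), ucombo), 0L)
  gkey <- paste(seg_sig, r, s, death, death_combo)
  ug <- !duplicated(gkey)
  gid <- match(gkey, gkey[ug])
  w <- as.numeric(tabulate(gid, max(gid)))
  first <- which(ug)
  jobs_by_term <- split(job_id_per_seg, rep(seq_along(i), nseg))[first]

  A <- design_matrix_combos(model$map,
                            st,
                            patterns[combo_pat, , drop = FALSE],
                            combo_band)
  list(A = A,
       from = st$allowed[, 1L], to = st$allowed[, 2L],
       rate_zero = as.integer(model$rate_zero),
       n_states = st$n_states,
       job_combo = as.integer(job_combo), job_dur = as.numeric(job_dur),
       term_off = c(0L, cumsum(lengths(jobs_by_term)))[seq_along(first)],
       term_nseg = lengths(jobs_by_term, use.names = FALSE),
       term_jobs = as.integer(unlist(jobs_by_term)),
       term_r = r[first], term_s = s[first], term_w = w,
       term_death = as.integer(death[first]),
       term_death_combo = as.integer(death_combo[first]),
       impossible = impossible,
       n_dropped = n_dropped,
       n_subjects = length(unique(d$id)),
       n_observations = n,
       n_pairs = length(i))
}

## Pure-R evaluation of the same grouped terms; used as a slow cross-check
## of the compiled engine and as a fallback.
panel_loglik_r <- function(theta, L) {
  K <- length(L$from)
  q <- exp(as.numeric(L$A %*% theta))
  q[rep(L$rate_zero == 1L, length.out = length(q))] <- 0
  G <- length(q) / K
  n <- L$n_states
  Qs <- lapply(seq_len(G), function(g) {
    qq <- q[(g - 1L) * K + seq_len(K)]
    Q <- matrix(0, n, n)
    for (k in seq_len(K)) Q[L$from[k], L$to[k]] <- qq[k]
    diag(Q) <- -rowSums(Q)
    Q
  })
  Ps <- lapply(seq_along(L$job_combo), function(j) {
    P <- mat_exp(Qs[[L$job_combo[j]]] * L$job_dur[j])
    if (any(!is.finite(P))) return(NULL)
    pmin(pmax(P, 0), 1)
  })
  if (any(vapply(Ps, is.null, logical(1)))) return(-Inf)
  ll <- 0
  for (i in seq_along(L$term_r)) {
    jobs <- L$term_jobs[L$term_off[i] + seq_len(L$term_nseg[i])]
    M <- Reduce(`%*%`, Ps[jobs])
    if (L$term_death[i] == 1L) {
      gc <- L$term_death_combo[i]
      contrib <- 0
      for (k in seq_len(K))
        if (L$to[k] == L$term_s[i] && L$rate_zero[k] == 0L)
          contrib <- contrib + M[L$term_r[i], L$from[k]] * q[(gc - 1L) * K + k]
    } else {
      contrib <- M[L$term_r[i], L$term_s[i]]
    }
    if (!(contrib > 0)) return(-Inf)
    ll <- ll + L$term_w[i] * log(contrib)
  }
  ll
}

panel_loglik <- function(theta, L, engine = c("C", "R")) {
  engine <- match.arg(engine)
  if (!is.null(L$impossible)) return(-Inf)
  if (engine == "C")
    panel_loglik_cpp(theta, L$A, L$from, L$to, L$rate_zero, L$n_states,
                     L$job_combo, L$job_dur, L$term_off, L$term_nseg,
                     L$term_jobs, L$term_r, L$term_s, L$term_w,
                     L$term_death, L$term_death_combo)
  else panel_loglik_r(theta, L)
}

#' Panel-data log-likelihood
#'
#' Sum over subjects and consecutive observation intervals of
#' \eqn{\log P_{rs}(\Delta t)}; a final interval ending in an exactly
#' observed death at \eqn{\Delta t} contributes
#' \eqn{\log \sum_{s'} P_{r,s'}(\Delta t^-)\, q_{s',death}} over transient
#' states s' with an allowed transition to death.  Observation pairs that
#' are impossible under the transition structure give `-Inf` with a
#' diagnostic (attribute `"impossible"`) listing the offending records.
#'
#' @param dataset A [panel_dataset()].
#' @param model An [intensity_model()] sharing the dataset's covariates.
#' @param death_exact Treat final absorbing observations as exact event
#'   times (defaults to the dataset's flag).
#' @param engine `"C"` (compiled, default) or `"R"` (reference
#'   implementation).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, model, death_exact = dataset$death_exact,
                           engine = c("C", "R")) {
  L <- build_likelihood_data(dataset, model, death_exact)
  if (!is.null(L$impossible)) {
    warning("observed transition(s) impossible under the structure; ",
            "first offender: subject ", L$impossible$id[1L], " (",
            L$impossible$from[1L], "->", L$impossible$to[1L], ")")
    out <- -Inf
    attr(out, "impossible") <- L$impossible
    return(out)
  }
  panel_loglik(model$params, L, match.arg(engine))
}
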