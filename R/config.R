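## Model and cohort configuration as plain lists, so the same structure can
## live in YAML (human-edited configs) or JSON (machine-written truth/fit
## files) and round-trip exactly.

#' Serialise / restore an intensity model as a configuration list
#'
#' @param model An [intensity_model()].
#' @return `model_to_config`: a plain list (states, transitions, covariates,
#'   age bands, parameter values) that [config_to_model()] restores exactly.
#' @export
model_to_config <- function(model) {
  st <- model$structure
  spec <- model$spec
  theta <- model$params
  map <- model$map
  covs <- lapply(names(spec$covariates), function(cv) {
    list(levels = spec$covariates[[cv]],
         transitions = spec$design[[cv]])
  })
  names(covs) <- names(spec$covariates)
  beta <- list()
  for (cv in names(spec$covariates)) {
    rows <- map$kind == "beta" & map$covariate == cv
    if (!any(rows)) next
    if (is.null(spec$covariates[[cv]])) {
      beta[[cv]] <- as.list(stats::setNames(theta[map$name[rows]],
                                            map$transition[rows]))
    } else {
      beta[[cv]] <- lapply(spec$covariates[[cv]][-1L], function(l) {
        r <- rows & map$level == l
        as.list(stats::setNames(theta[map$name[r]], map$transition[r]))
      })
      names(beta[[cv]]) <- spec$covariates[[cv]][-1L]
    }
  }
  age_offsets <- list()
  if (any(map$kind == "age")) {
    for (l in unique(map$level[map$kind == "age"])) {
      r <- map$kind == "age" & map$level == l
      age_offsets[[l]] <- as.list(stats::setNames(theta[map$name[r]],
                                                  map$transition[r]))
    }
  }
  list(states = st$state_names,
       transitions = st$labels,
       covariates = covs,
       age_bands = spec$age_bands,
       age_transitions = spec$age_design,
       log_q0 = as.list(stats::setNames(theta[seq_along(st$labels)],
                                        st$labels)),
       beta = beta,
       age_offsets = age_offsets,
       rate_zero = st$labels[model$rate_zero])
}

#' @rdname model_to_config
#' @param config A list as produced by [model_to_config()] (or read from a
#'   YAML/JSON model configuration file).
#' @export
config_to_model <- function(config) {
  labels <- unlist(config$transitions)
  allowed <- cbind(as.integer(sub("-.*", "", labels)),
                   as.integer(sub(".*-", "", labels)))
  st <- transition_structure(n_states = length(unlist(config$states)),
                             allowed = allowed,
                             state_names = unlist(config$states))
  covs <- lapply(config$covariates, function(cv)
    if (is.null(cv$levels)) NULL else unlist(cv$levels))
  design <- lapply(config$covariates, function(cv) unlist(cv$transitions))
  spec <- covariate_spec(covariates = covs, design = design,
                         age_bands = unlist(config$age_bands),
                         age_design = unlist(config$age_transitions))
  beta <- lapply(config$beta, function(b)
    if (!is.list(b[[1L]])) unlist(b) else lapply(b, unlist))
  intensity_model(structure = st, spec = spec,
                  log_q0 = unlist(config$log_q0),
                  beta = beta,
                  age_offsets = lapply(config$age_offsets, unlist),
                  rate_zero = unlist(config$rate_zero))
}

#' Read / write model and run configuration files
#'
#' YAML on disk for hand-edited configuration, JSON for machine-written
#' truth and fit files; both hold the same list structure.  A run
#' configuration may have top-level sections `model` and `cohort`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
}

#' @rdname read_config
#' @param config List to write.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  else yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname model_to_config
#' @param config_cohort List with fields matching [cohort_config()]
#'   arguments.
#' @export
config_to_cohort <- function(config_cohort) {
  cc <- config_cohort
  args <- list()
  if (!is.null(cc$n_subjects)) args$n_subjects <- cc$n_subjects
  if (!is.null(cc$wave_times)) args$wave_times <- unlist(cc$wave_times)
  if (!is.null(cc$covariates))
    args$covariate_distribution <- lapply(cc$covariates, unlist)
  if (!is.null(cc$age)) {
    args$age_mean <- cc$age$mean
    args$age_sd <- cc$age$sd
    if (!is.null(cc$age$min)) args$age_min <- cc$age$min
  }
  if (!is.null(cc$initial_state_probs))
    args$initial_state_probs <- unlist(cc$initial_state_probs)
  if (!is.null(cc$dropout_hazard)) args$dropout_hazard <- cc$dropout_hazard
  if (!is.null(cc$seed)) args$seed <- cc$seed
  do.call(cohort_config, args)
}

#' @rdname model_to_config
#' @param cohort A [cohort_config()].
#' @export
cohort_to_config <- function(cohort) {
  list(n_subjects = cohort$n_subjects,
       wave_times = cohort$wave_times,
       covariates = lapply(cohort$covariate_distribution, as.list),
       age = list(mean = cohort$age_mean, sd = cohort$age_sd,
                  min = cohort$age_min),
       initial_state_probs = cohort$initial_state_probs,
       dropout_hazard = cohort$dropout_hazard,
       seed = cohort$seed)
}
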