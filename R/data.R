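#' Panel dataset of interval-censored state observations
#'
#' One row per subject per observation: subject id, observation time in
#' years since baseline, age at observation, observed state (1..n) and
#' baseline covariate columns.  Observation times must be strictly
#' increasing within subject and an absorbing state may only appear as a
#' subject's final observation.
#'
#' @param data data.frame with columns `id`, `time`, `state`, optionally
#'   `age`, plus covariate columns.  The aliases `subject_id` and
#'   `time_years` are accepted.
#' @param structure A [transition_structure()] (defaults to the 4-state
#'   cognitive model; used for validation only).
#' @param death_exact Whether final observations in the absorbing state are
#'   exactly observed event times (`TRUE`, the default, emulating linked
#'   mortality records) or just the first wave at which death was known.
#' @param spec Optional [covariate_spec()] describing the covariate columns;
#'   carried along for downstream fitting.
#' @return Object of class `panel_dataset`.
#' @export
panel_dataset <- function(data, structure = transition_structure(),
                          death_exact = TRUE, spec = NULL) {
  if (is.null(structure)) structure <- transition_structure()
  nm <- names(data)
  nm[nm == "subject_id"] <- "id"
  nm[nm == "time_years"] <- "time"
  names(data) <- nm
  req <- c("id", "time", "state")
  if (!all(req %in% names(data)))
    stop("data must have columns ", paste(req, collapse = ", "))
  data <- data[order(data$id, data$time), , drop = FALSE]
  rownames(data) <- NULL
  data$state <- as.integer(data$state)
  if (nrow(data)) {
    if (any(data$state < 1L | data$state > structure$n_states, na.rm = TRUE))
      stop("states must be integers in 1..", structure$n_states)
    same <- c(FALSE, data$id[-1L] == data$id[-nrow(data)])
    dt <- c(NA, diff(data$time))
    if (any(same & dt <= 0))
      stop("duplicate or non-increasing (subject, time) pairs, e.g. subject ",
           data$id[which(same & dt <= 0)[1L]])
    nxt <- c(data$id[-1L] == data$id[-nrow(data)], FALSE)
    bad <- data$state %in% which(structure$absorbing) & nxt
    if (any(bad))
      stop("absorbing state before a later observation for subject ",
           data$id[which(bad)[1L]])
  }
  out <- list(data = data, structure = structure, spec = spec,
              death_exact = isTRUE(death_exact))
  class(out) <- "panel_dataset"
  out
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("Panel dataset:", length(unique(x$data$id)), "subjects,",
      nrow(x$data), "observations",
      if (x$death_exact) "(exact death times)\n" else "(panel death)\n")
  invisible(x)
}

#' @export
as.data.frame.panel_dataset <- function(x, ...) x$data

n_subjects <- function(dataset) length(unique(dataset$data$id))

#' Table of successive observed state pairs
#'
#' Entry (r, s) counts consecutive observation pairs within subject with
#' state r followed by state s (including r = s).  The counts sum to
#' (number of observations) - (number of subjects).
#'
#' @param dataset A [panel_dataset()].
#' @return n x n integer matrix with state names as dimnames.
#' @export
statetable <- function(dataset) {
  st <- dataset$structure
  n <- st$n_states
  tab <- matrix(0L, n, n, dimnames = list(from = st$state_names,
                                          to = st$state_names))
  d <- dataset$data
  if (nrow(d) > 1L) {
    same <- d$id[-1L] == d$id[-nrow(d)]
    from <- d$state[-nrow(d)][same]
    to <- d$state[-1L][same]
    for (i in seq_along(from)) tab[from[i], to[i]] <- tab[from[i], to[i]] + 1L
  }
  tab
}

#' Read / write panel data as long-format CSV
#'
#' The on-disk schema is `subject_id, time_years, age, state` plus one
#' column per covariate (comma-separated, header row, UTF-8).
#'
#' @param path File path.
#' @param ... Passed to [panel_dataset()].
#' @return `read_panel_csv`: a [panel_dataset()].
#' @export
read_panel_csv <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "time_years", "state")
  alias <- c("id", "time", "state")
  miss <- req[!(req %in% names(df) | alias %in% names(df))]
  if (length(miss))
    stop("CSV ", path, " is missing required column(s): ",
         paste(miss, collapse = ", "))
  panel_dataset(df, ...)
}

#' @rdname read_panel_csv
#' @param dataset A [panel_dataset()].
#' @export
write_panel_csv <- function(dataset, path) {
  d <- dataset$data
  nm <- names(d)
  nm[nm == "id"] <- "subject_id"
  nm[nm == "time"] <- "time_years"
  names(d) <- nm
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
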