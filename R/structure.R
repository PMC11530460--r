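#' Allowed-transition structure of a multistate model
#'
#' Defines the state space and the set of instantaneous transitions that the
#' intensity matrix may populate.  States with no outgoing transitions are
#' absorbing.  The default is the four-state cognitive-ageing structure:
#' 1 = NOCI (no cognitive impairment), 2 = CIND (cognitive impairment, no
#' dementia), 3 = dementia, 4 = death, with seven allowed transitions
#' 1-2, 2-1, 1-3, 2-3, 1-4, 2-4, 3-4 and death absorbing.
#'
#' @param n_states Number of states.
#' @param allowed Two-column integer matrix of allowed (from, to) pairs.
#' @param state_names Optional character vector of state names.
#' @return An object of class `transition_structure` with fields `n_states`,
#'   `allowed` (ordered two-column matrix), `labels` (e.g. `"1-2"`),
#'   `absorbing` (logical per state) and `state_names`.
#' @examples
#' s <- transition_structure()
#' s$absorbing   # only death
#' @export
transition_structure <- function(n_states = 4L,
                                 allowed = cbind(
                                   from = c(1L, 2L, 1L, 2L, 1L, 2L, 3L),
                                   to   = c(2L, 1L, 3L, 3L, 4L, 4L, 4L)),
                                 state_names = NULL) {
  n_states <- as.integer(n_states)
  allowed <- matrix(as.integer(as.matrix(allowed)), ncol = 2L,
                    dimnames = list(NULL, c("from", "to")))
  if (n_states < 2L) stop("need at least 2 states")
  if (any(allowed < 1L | allowed > n_states))
    stop("allowed transitions reference states outside 1..n_states")
  if (any(allowed[, 1L] == allowed[, 2L]))
    stop("self-transitions (r,r) are not allowed pairs")
  if (anyDuplicated(paste(allowed[, 1L], allowed[, 2L])))
    stop("duplicate allowed transition pairs")
  ord <- order(allowed[, 1L], allowed[, 2L])
  allowed <- allowed[ord, , drop = FALSE]
  absorbing <- !(seq_len(n_states) %in% allowed[, 1L])
  if (is.null(state_names)) {
    state_names <- if (n_states == 4L &&
                       nrow(allowed) == 7L &&
                       all(absorbing == c(FALSE, FALSE, FALSE, TRUE)))
      c("NOCI", "CIND", "Dementia", "Death")
    else paste0("state", seq_len(n_states))
  }
  stopifnot(length(state_names) == n_states)
  structure(list(
    n_states = n_states,
    allowed = allowed,
    labels = paste0(allowed[, 1L], "-", allowed[, 2L]),
    absorbing = absorbing,
    state_names = state_names
  ), class = "transition_structure")
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Multistate transition structure:", x$n_states, "states\n")
  for (i in seq_len(x$n_states)) {
    out <- x$allowed[x$allowed[, 1L] == i, 2L]
    cat(sprintf("  %d %-10s -> %s\n", i, x$state_names[i],
                if (length(out)) paste(out, collapse = ", ") else "(absorbing)"))
  }
  invisible(x)
}

#' States reachable from each state (including indirectly)
#'
#' Transitive closure of the allowed-transition graph; used to diagnose
#' observed state pairs that are impossible under the structure (for example
#' dementia back to NOCI in the default model).
#'
#' @param structure A [transition_structure()].
#' @return Logical n x n matrix; entry (r, s) is `TRUE` if s is reachable
#'   from r in zero or more allowed jumps.
#' @export
reachable_states <- function(structure) {
  n <- structure$n_states
  reach <- diag(n) > 0
  reach[structure$allowed] <- TRUE
  for (i in seq_len(n)) reach <- reach | (reach %*% reach > 0)
  dimnames(reach) <- list(structure$state_names, structure$state_names)
  reach
}

trans_index <- function(structure, from, to) {
  i <- match(paste0(from, "-", to), structure$labels)
  if (anyNA(i)) stop("transition ", paste0(from, "-", to)[which(is.na(i))[1L]],
                     " is not in the allowed structure")
  i
}
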