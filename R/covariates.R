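#' Covariate specification for transition-intensity regression
#'
#' Declares the covariates acting multiplicatively on the transition
#' intensities, which transitions each covariate acts on, and the
#' piecewise-constant age bands.  Categorical covariates are given as a
#' character vector of levels whose FIRST element is the reference level;
#' by convention the reference is the most socioeconomically disadvantaged
#' group.  A covariate declared as `NULL` is treated as numeric (one
#' coefficient per transition).
#'
#' Age enters the model as additive log-intensity offsets that are constant
#' within bands defined by `age_bands` cut-points; the first band is the
#' reference.  Ages outside the supported range are clamped to the outer
#' bands.
#'
#' @param covariates Named list of level vectors (reference first) or `NULL`
#'   for numeric covariates.
#' @param design Named list mapping each covariate name to the character
#'   vector of transition labels (`"1-2"` style) it acts on.
#' @param age_bands Strictly increasing numeric cut-points in years, e.g.
#'   `c(50, 60, 70, 80)` giving bands `[50,60) [60,70) [70,80) [80,Inf)`;
#'   `NULL` disables age dependency.
#' @param age_design Transition labels receiving age-band offsets; defaults
#'   to all transitions when `age_bands` is given.
#' @return Object of class `covariate_spec`.
#' @export
covariate_spec <- function(covariates = list(), design = list(),
                           age_bands = NULL, age_design = NULL) {
  stopifnot(is.list(covariates), is.list(design))
  if (length(covariates) && is.null(names(covariates)))
    stop("covariates must be a named list")
  for (nm in names(covariates)) {
    lv <- covariates[[nm]]
    if (!is.null(lv) && (!is.character(lv) || length(lv) < 2L ||
                         anyDuplicated(lv)))
      stop("covariate '", nm, "' needs >= 2 distinct character levels ",
           "(reference first) or NULL for numeric")
    if (is.null(design[[nm]]))
      stop("no per-transition design given for covariate '", nm, "'")
  }
  if (!all(names(design) %in% names(covariates)))
    stop("design names must match covariate names")
  if (!is.null(age_bands)) {
    age_bands <- as.numeric(age_bands)
    if (length(age_bands) < 1L || is.unsorted(age_bands, strictly = TRUE))
      stop("age_bands cut-points must be strictly increasing")
  }
  structure(list(covariates = covariates, design = design,
                 age_bands = age_bands, age_design = age_design),
            class = "covariate_spec")
}

#' @export
print.covariate_spec <- function(x, ...) {
  cat("Covariate specification:\n")
  for (nm in names(x$covariates)) {
    lv <- x$covariates[[nm]]
    cat(sprintf("  %-12s %s  on %s\n", nm,
                if (is.null(lv)) "<numeric>"
                else paste0(lv[1L], " (ref) | ", paste(lv[-1L], collapse = ", ")),
                paste(x$design[[nm]], collapse = ", ")))
  }
  if (!is.null(x$age_bands))
    cat("  age bands:", paste(band_labels(x$age_bands), collapse = " "),
        " on", paste(x$age_design, collapse = ", "), "\n")
  invisible(x)
}

band_labels <- function(cuts) {
  nb <- length(cuts)
  c(sprintf("[%g,%g)", cuts[-nb], cuts[-1L]), sprintf("[%g,Inf)", cuts[nb]))
}

n_bands <- function(spec) {
  if (is.null(spec$age_bands)) 1L else length(spec$age_bands)
}

#' Age band index for a vector of ages (clamped to the outer bands)
#' @noRd
band_index <- function(spec, age) {
  if (is.null(spec$age_bands)) return(rep(1L, length(age)))
  pmax(1L, findInterval(age, spec$age_bands))
}

#' Default covariate specification for the cognitive-ageing model
#'
#' Mirrors the modelling strategy of socioeconomic multistate analyses of
#' ELSA-style cohorts: one socioeconomic indicator at a time (education,
#' occupation or non-pension wealth tertile, reference = most disadvantaged
#' group), acting on the five transitions 1-2, 2-1, 2-3, 1-3, 3-4;
#' demographic adjustment by sex (ref male), marital status (ref married)
#' and piecewise-constant age bands [50,60) [60,70) [70,80) [80,Inf) on all
#' transitions EXCEPT the two dementia-onset transitions 1-3 and 2-3.
#'
#' @param sep Which socioeconomic indicator(s) to include: one of
#'   `"wealth"`, `"education"`, `"occupation"`, `"all"`, `"none"`.
#' @param demographics Include sex/marital/age adjustment (default TRUE).
#' @return A [covariate_spec()].
#' @export
elsa_covariate_spec <- function(sep = c("wealth", "education", "occupation",
                                        "all", "none"),
                                demographics = TRUE) {
  sep <- match.arg(sep)
  sep_trans <- c("1-2", "2-1", "2-3", "1-3", "3-4")
  demo_trans <- c("1-2", "2-1", "1-4", "2-4", "3-4")  # not the 1-3/2-3 onsets
  sep_levels <- list(
    education  = c("low", "middle", "high"),
    occupation = c("routine", "intermediate", "managerial"),
    wealth     = c("lowest", "middle", "highest"))
  covs <- list(); design <- list()
  if (sep != "none") {
    keep <- if (sep == "all") names(sep_levels) else sep
    covs <- sep_levels[keep]
    design <- stats::setNames(rep(list(sep_trans), length(keep)), keep)
  }
  if (demographics) {
    covs$sex <- c("male", "female")
    covs$marital <- c("married", "single")
    design$sex <- demo_trans
    design$marital <- demo_trans
  }
  covariate_spec(covariates = covs, design = design,
                 age_bands = if (demographics) c(50, 60, 70, 80) else NULL,
                 age_design = if (demographics) demo_trans else NULL)
}
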