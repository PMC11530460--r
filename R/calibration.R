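#' Reference hazard ratios for the synthetic-cohort fixture
#'
#' The package ships a calibrated set of socioeconomic hazard ratios used as
#' generating truth by the synthetic cohort: for each indicator (education,
#' occupation, wealth tertile), the multiplicative effect of each
#' non-reference level on the five transitions NOCI->CIND (1-2), CIND->NOCI
#' (2-1), CIND->dementia (2-3), NOCI->dementia (1-3) and dementia->death
#' (3-4).  The values encode the qualitative pattern reported for English
#' cohorts: socioeconomic advantage slows impairment onset and dementia
#' progression, raises the chance of reverting from CIND to NOCI (e.g.
#' highest vs lowest wealth tertile HR 1.56 on 2-1), and (for education)
#' lowers mortality after dementia onset.
#'
#' @return A data.frame with columns `covariate`, `level`, `transition`, `hr`.
#' @export
reference_hazard_ratios <- function() {
  tr <- c("1-2", "2-1", "2-3", "1-3", "3-4")
  tab <- list(
    education  = list(middle       = c(0.73, 1.37, 0.38, 0.81, 0.69),
                      high         = c(0.57, 1.81, 0.31, 0.91, 0.61)),
    occupation = list(intermediate = c(0.82, 1.46, 0.80, 0.91, 1.03),
                      managerial   = c(0.67, 1.81, 0.63, 0.88, 0.96)),
    wealth     = list(middle       = c(0.86, 1.29, 0.98, 0.90, 1.18),
                      highest      = c(0.68, 1.56, 0.74, 0.87, 0.98)))
  out <- do.call(rbind, lapply(names(tab), function(cv) {
    do.call(rbind, lapply(names(tab[[cv]]), function(l) {
      data.frame(covariate = cv, level = l, transition = tr,
                 hr = tab[[cv]][[l]], stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

## Baseline per-year intensities for the synthetic fixture, ordered to
## reproduce the qualitative transition abundance of cognitive ageing panels:
## NOCI<->CIND common, CIND->dementia moderate, NOCI->dementia rare,
## dementia->death high.
default_baseline_rates <- function() {
  c("1-2" = 0.25, "2-1" = 0.15, "1-3" = 0.002, "2-3" = 0.05,
    "1-4" = 0.02, "2-4" = 0.06, "3-4" = 0.30)
}

#' Calibrated four-state cognitive-ageing intensity model
#'
#' The generating model behind the synthetic cohort: default baseline rates
#' (see source), socioeconomic log hazard ratios from
#' [reference_hazard_ratios()], plausible demographic effects (female
#' mortality advantage ~0.70-0.75, living single raising mortality ~1.25) and
#' positive age-band offsets on progression and mortality (mortality roughly
#' doubling per decade of age; CIND->NOCI recovery declining with age).
#' Transitions 1-3 and 2-3 carry no demographic/age adjustment.
#'
#' @param sep Socioeconomic indicator(s) whose effects are active:
#'   `"wealth"`, `"education"`, `"occupation"`, `"all"` or `"none"`.
#' @param demographics Include sex/marital/age effects (default TRUE).
#' @return An [intensity_model()].
#' @export
elsa_like_model <- function(sep = "all", demographics = TRUE) {
  spec <- elsa_covariate_spec(sep, demographics)
  hrs <- reference_hazard_ratios()
  beta <- list()
  for (cv in intersect(names(spec$covariates),
                       c("education", "occupation", "wealth"))) {
    sub <- hrs[hrs$covariate == cv, ]
    beta[[cv]] <- lapply(split(sub, sub$level), function(d)
      stats::setNames(log(d$hr), d$transition))
  }
  demo_tr <- c("1-2", "2-1", "1-4", "2-4", "3-4")
  age_offsets <- NULL
  if (demographics) {
    beta$sex <- list(female = stats::setNames(
      log(c(1.05, 0.95, 0.75, 0.75, 0.75)), demo_tr))
    beta$marital <- list(single = stats::setNames(
      log(c(1.10, 0.90, 1.25, 1.25, 1.10)), demo_tr))
    per_decade <- stats::setNames(log(c(1.20, 0.90, 1.50, 1.50, 1.20)), demo_tr)
    lab <- band_labels(spec$age_bands)
    age_offsets <- stats::setNames(
      lapply(1:3, function(d) per_decade * d), lab[2:4])
  }
  intensity_model(structure = transition_structure(), spec = spec,
                  log_q0 = log(default_baseline_rates()),
                  beta = beta, age_offsets = age_offsets)
}
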