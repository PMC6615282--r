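#' Population pharmacokinetic model
#'
#' Bundles everything needed to predict and simulate: structural fixed
#' effects, active covariate relations, diagonal inter-individual variability
#' (IIV) on CL and V2, and the proportional residual error variance.
#'
#' @param fixed A [fixed_effects()] object (its `th_temp`/`th_prot` fields
#'   are ignored when `relations` is supplied explicitly).
#' @param relations List of [cov_relation()] objects; `NULL` means the
#'   default final-model pair derived from `fixed` and `references`.
#' @param omega2_cl,omega2_v2 IIV variances (log scale) on CL and V2; `>= 0`,
#'   zero switches the random effect off.
#' @param sigma2_prop Proportional residual error variance; `> 0`.
#' @param references A [reference_values()] object (centering medians).
#' @return Object of class `pop_model`.
#' @seealso [ecmo_reference_model()] for ready-made typical values.
#' @export
pop_model <- function(fixed, relations = NULL,
                      omega2_cl = 0, omega2_v2 = 0,
                      sigma2_prop = 1e-8,
                      references = reference_values()) {
  stopifnot(inherits(fixed, "fixed_effects"))
  if (omega2_cl < 0 || omega2_v2 < 0) stop("omega2 must be >= 0")
  if (sigma2_prop <= 0) stop("sigma2_prop must be > 0")
  if (is.null(relations)) relations <- default_relations(fixed, references)
  stopifnot(all(vapply(relations, inherits, TRUE, "cov_relation")))
  structure(list(fixed = fixed, relations = relations,
                 omega2 = c(cl = omega2_cl, v2 = omega2_v2),
                 sigma2 = sigma2_prop, references = references),
            class = "pop_model")
}

#' Reference sufentanil VA-ECMO population model
#'
#' The typical adult VA-ECMO parameter set used throughout the package as
#' simulation truth and as a starting model: CL 37.8 L/h at 36.9 degC with an
#' exponential temperature coefficient of 0.207 per degC, V1 229 L, V2 1640 L
#' at a total plasma protein of 4.5 g/dL with a power exponent of 2.46,
#' Q 41 L/h, IIV variances 0.167 (CL) and 1.13 (V2), proportional residual
#' error variance 0.0841.
#'
#' @param iiv Logical; include the inter-individual variability terms.
#' @return A [pop_model()].
#' @export
ecmo_reference_model <- function(iiv = TRUE) {
  pop_model(fixed_effects(37.8, 229, 1640, 41,
                          th_temp = 0.207, th_prot = 2.46),
            omega2_cl = if (iiv) 0.167 else 0,
            omega2_v2 = if (iiv) 1.13 else 0,
            sigma2_prop = 0.0841,
            references = reference_values(36.9, 4.5))
}

#' @export
print.pop_model <- function(x, ...) {
  fx <- x$fixed
  cat("Population PK model (two-compartment IV infusion)\n")
  cat(sprintf("  CL %.4g L/h | V1 %.4g L | V2 %.4g L | Q %.4g L/h\n",
              fx$th_cl, fx$th_v1, fx$th_v2, fx$th_q))
  for (r in x$relations)
    cat(sprintf("  %s ~ %s [%s] theta=%.4g center=%.4g\n",
                r$parameter, r$covariate, r$form, r$theta, r$center))
  cat(sprintf("  omega2: CL %.4g, V2 %.4g | sigma2(prop) %.4g\n",
              x$omega2[["cl"]], x$omega2[["v2"]], x$sigma2))
  invisible(x)
}

#' One subject's data
#'
#' @param id Unique subject identifier.
#' @param regimen An [infusion_regimen()].
#' @param times Observation times (h), sorted, `>= 0`.
#' @param dv Observed concentrations (ug/L), same length as `times`;
#'   strictly positive (below-LLOQ records are excluded upstream).
#' @param covariates A [covariate_set()].
#' @return Object of class `individual_data`.
#' @export
individual_data <- function(id, regimen, times = numeric(),
                            dv = numeric(),
                            covariates = covariate_set()) {
  stopifnot(length(times) == length(dv))
  if (length(times)) {
    if (any(times < 0)) stop("observation times must be >= 0")
    if (is.unsorted(times)) stop("observation times must be sorted")
    if (any(!is.finite(dv)) || any(dv <= 0))
      stop("dv must be finite and > 0 (below-LLOQ records are excluded)")
  }
  structure(list(id = id, regimen = regimen, times = as.numeric(times),
                 dv = as.numeric(dv), covariates = covariates),
            class = "individual_data")
}

#' Cohort of subjects
#'
#' @param individuals List of [individual_data()] objects with unique ids.
#' @return Object of class `population_dataset`.
#' @export
population_dataset <- function(individuals) {
  stopifnot(length(individuals) >= 1,
            all(vapply(individuals, inherits, TRUE, "individual_data")))
  ids <- vapply(individuals, function(x) as.character(x$id), "")
  if (anyDuplicated(ids)) stop("subject ids must be unique")
  structure(list(individuals = individuals), class = "population_dataset")
}

#' @export
print.population_dataset <- function(x, ...) {
  n_obs <- sum(vapply(x$individuals, function(i) length(i$times), 0L))
  cat(sprintf("population_dataset: %d subjects, %d observations\n",
              length(x$individuals), n_obs))
  invisible(x)
}

#' @export
length.population_dataset <- function(x) length(x$individuals)

## Individual structural parameters for one subject at given etas.
individual_params <- function(model, ind, eta = c(0, 0)) {
  typ <- apply_covariates(model$fixed, ind$covariates,
                          model$references, model$relations)
  list(cl = typ$cl * exp(eta[1]), v1 = typ$v1,
       v2 = typ$v2 * exp(eta[2]), q = typ$q)
}

#' Model-predicted concentrations for one subject
#'
#' @param model A [pop_model()].
#' @param ind An [individual_data()].
#' @param eta Length-2 vector `(eta_cl, eta_v2)`; zero gives the population
#'   prediction (PRED).
#' @param times Times at which to predict; defaults to the subject's
#'   observation times.
#' @return Numeric concentrations (ug/L).
#' @export
predict_individual <- function(model, ind, eta = c(0, 0),
                               times = ind$times) {
  p <- individual_params(model, ind, eta)
  conc_fast(p$cl, p$v1, p$v2, p$q,
            ind$regimen$start_h, ind$regimen$end_h, ind$regimen$rate,
            times)
}
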