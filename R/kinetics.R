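#' Typical (population) fixed effects of the two-compartment infusion model
#'
#' Container for the structural parameters of a mammillary two-compartment
#' model parameterised by clearances and volumes, together with the two
#' covariate coefficients of the final sufentanil-ECMO model: an exponential
#' effect of body temperature on systemic clearance and a power effect of
#' total plasma protein on the peripheral volume of distribution.
#'
#' @param th_cl Typical systemic clearance CL (L/h).
#' @param th_v1 Typical central volume V1 (L).
#' @param th_v2 Typical peripheral volume V2 (L).
#' @param th_q Typical intercompartmental clearance Q (L/h). `0` gives the
#'   degenerate one-compartment model.
#' @param th_temp Exponential temperature coefficient on CL (1/degC).
#' @param th_prot Power exponent of total plasma protein on V2 (unitless).
#' @return An object of class `fixed_effects` (named list).
#' @examples
#' fixed_effects(37.8, 229, 1640, 41, th_temp = 0.207, th_prot = 2.46)
#' @export
fixed_effects <- function(th_cl, th_v1, th_v2, th_q,
                          th_temp = 0, th_prot = 0) {
  for (nm in c("th_cl", "th_v1", "th_v2")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) stop(nm, " must be strictly positive")
  }
  if (!is.finite(th_q) || th_q < 0) stop("th_q must be non-negative")
  if (!is.finite(th_temp) || !is.finite(th_prot))
    stop("covariate coefficients must be finite")
  structure(list(th_cl = th_cl, th_v1 = th_v1, th_v2 = th_v2, th_q = th_q,
                 th_temp = th_temp, th_prot = th_prot),
            class = "fixed_effects")
}

#' Covariate centering values
#'
#' Continuous covariates enter the model centred on population medians; the
#' defaults are the medians of the ECMO study population (tympanic temperature
#' 36.9 degC, total plasma protein 4.5 g/dL). When fitting fresh data the
#' centering values should be recomputed as the dataset medians.
#'
#' @param temp_ref Centering body temperature (degC).
#' @param prot_ref Centering total plasma protein (g/dL).
#' @return Object of class `reference_values`.
#' @export
reference_values <- function(temp_ref = 36.9, prot_ref = 4.5) {
  stopifnot(is.finite(temp_ref), temp_ref > 0,
            is.finite(prot_ref), prot_ref > 0)
  structure(list(temp_ref = temp_ref, prot_ref = prot_ref),
            class = "reference_values")
}

#' Individual covariate values
#'
#' Holds the two covariates of the final model plus any screening covariates
#' (age, weight, bilirubin, ...) passed through `...` as named scalars.
#'
#' @param temperature Tympanic body temperature (degC), in (25, 45).
#' @param total_protein Total plasma protein (g/dL), > 0.
#' @param ... Additional named scalar covariates kept for screening.
#' @return Object of class `covariate_set` (named list).
#' @export
covariate_set <- function(temperature = 36.9, total_protein = 4.5, ...) {
  if (!is.finite(temperature) || temperature <= 25 || temperature >= 45)
    stop("temperature must lie in (25, 45) degC")
  if (!is.finite(total_protein) || total_protein <= 0)
    stop("total_protein must be > 0")
  extra <- list(...)
  if (length(extra) && is.null(names(extra)))
    stop("extra covariates must be named")
  structure(c(list(temperature = temperature, total_protein = total_protein),
              extra),
            class = "covariate_set")
}

#' Piecewise-constant infusion regimen
#'
#' @param start_h,end_h,rate Numeric vectors of equal length: segment start
#'   and end times (h) and infusion rates (ug/h). Segments must be
#'   non-overlapping with `start_h < end_h` and `rate >= 0`.
#' @return Object of class `infusion_regimen`: a data.frame with columns
#'   `start_h`, `end_h`, `rate`.
#' @examples
#' infusion_regimen(0, 120, 17.5)
#' @export
infusion_regimen <- function(start_h = numeric(), end_h = numeric(),
                             rate = numeric()) {
  stopifnot(length(start_h) == length(end_h),
            length(start_h) == length(rate))
  if (length(start_h)) {
    if (any(!is.finite(start_h)) || any(!is.finite(end_h)) ||
        any(!is.finite(rate)))
      stop("regimen entries must be finite")
    if (any(start_h < 0)) stop("segment start times must be >= 0")
    if (any(start_h >= end_h)) stop("segment start must precede end")
    if (any(rate < 0)) stop("rates must be >= 0")
    o <- order(start_h)
    start_h <- start_h[o]; end_h <- end_h[o]; rate <- rate[o]
    if (length(start_h) > 1 &&
        any(start_h[-1] < end_h[-length(end_h)] - 1e-12))
      stop("segments must not overlap")
  }
  structure(data.frame(start_h = start_h, end_h = end_h, rate = rate),
            class = c("infusion_regimen", "data.frame"))
}

#' Apply covariate relations to the typical parameters
#'
#' Evaluates the covariate model at one subject's covariates. With the default
#' final-model relations this is
#' \deqn{CL = \theta_{CL} e^{\theta_{Temp} (T - T_{ref})}, \quad
#'       V2 = \theta_{V2} (TP / TP_{ref})^{\theta_{T.Prot}},}
#' with V1 and Q unaffected. Arbitrary extra relations (power, linear,
#' exponential) built with [cov_relation()] are supported for covariate
#' screening.
#'
#' @param fx A [fixed_effects()] object.
#' @param cov A [covariate_set()] object.
#' @param ref A [reference_values()] object.
#' @param relations Optional list of [cov_relation()] objects replacing the
#'   default pair (temperature on CL, protein on V2). Use `list()` for a
#'   covariate-free model.
#' @return Named list with elements `cl`, `v1`, `v2`, `q` (typical values for
#'   this covariate vector, before inter-individual random effects).
#' @examples
#' fx <- fixed_effects(37.8, 229, 1640, 41, 0.207, 2.46)
#' apply_covariates(fx, covariate_set(36.9, 4.5), reference_values())
#' @export
apply_covariates <- function(fx, cov, ref = reference_values(),
                             relations = NULL) {
  p <- list(cl = fx$th_cl, v1 = fx$th_v1, v2 = fx$th_v2, q = fx$th_q)
  if (is.null(relations)) {
    relations <- default_relations(fx, ref)
  }
  for (rel in relations) {
    x <- cov[[rel$covariate]]
    if (is.null(x) || !is.finite(x))
      stop("covariate '", rel$covariate, "' missing from covariate_set")
    key <- tolower(rel$parameter)
    p[[key]] <- eval_relation(rel, p[[key]], x)
  }
  if (any(unlist(p[c("cl", "v1", "v2")]) <= 0))
    stop("covariate model produced non-positive parameter")
  p
}

default_relations <- function(fx, ref) {
  rels <- list()
  if (fx$th_temp != 0)
    rels <- c(rels, list(cov_relation("CL", "temperature", "exp_centered",
                                      fx$th_temp, ref$temp_ref)))
  if (fx$th_prot != 0)
    rels <- c(rels, list(cov_relation("V2", "total_protein", "power",
                                      fx$th_prot, ref$prot_ref)))
  rels
}

#' Build one covariate-parameter relation
#'
#' Functional forms for continuous covariates, centred on the population
#' median `center`:
#' \describe{
#'   \item{`power`}{\eqn{\theta_{TV} (x/c)^{\theta}}; requires `x > 0`.}
#'   \item{`linear`}{\eqn{\theta_{TV} + \theta (x - c)}.}
#'   \item{`exponential`}{\eqn{\theta_{TV} e^{\theta x / c}} (as-printed
#'     screening form; ratio-scaled, not centred at 1).}
#'   \item{`exp_centered`}{\eqn{\theta_{TV} e^{\theta (x - c)}} (the form of
#'     the final temperature-on-CL model).}
#' }
#' Dichotomous covariates (0/1 flags) should use `power`, which reduces to a
#' proportional shift \eqn{\theta_{TV} \theta^{x}} via
#' `cov_relation(..., form = "indicator")`.
#'
#' @param parameter One of `"CL"`, `"V1"`, `"V2"`, `"Q"`.
#' @param covariate Covariate name (must be present in the covariate set).
#' @param form Functional form, see Details.
#' @param theta Covariate coefficient.
#' @param center Centering value (dataset median for continuous covariates).
#' @return Object of class `cov_relation`.
#' @export
cov_relation <- function(parameter, covariate, form, theta, center = 1) {
  parameter <- match.arg(parameter, c("CL", "V1", "V2", "Q"))
  form <- match.arg(form, c("power", "linear", "exponential",
                            "exp_centered", "indicator"))
  stopifnot(is.finite(theta), is.finite(center))
  structure(list(parameter = parameter, covariate = covariate, form = form,
                 theta = theta, center = center),
            class = "cov_relation")
}

eval_relation <- function(rel, tv, x) {
  switch(rel$form,
    power = {
      if (x <= 0) stop("power form needs positive covariate '",
                       rel$covariate, "'")
      tv * (x / rel$center)^rel$theta
    },
    linear = tv + rel$theta * (x - rel$center),
    exponential = tv * exp(rel$theta * x / rel$center),
    exp_centered = tv * exp(rel$theta * (x - rel$center)),
    indicator = tv * exp(rel$theta * (x > 0))
  )
}

#' Individualise typical parameters with log-normal random effects
#'
#' \eqn{\theta_i = \theta_{pop} e^{\eta_i}} applied to CL and V2 (the two
#' parameters carrying inter-individual variability in the final model).
#'
#' @param typ Named list with `cl`, `v1`, `v2`, `q` (from
#'   [apply_covariates()]).
#' @param eta_cl,eta_v2 Subject-level random effects (any finite real).
#' @return Object of class `individual_parameters`.
#' @export
individualize <- function(typ, eta_cl = 0, eta_v2 = 0) {
  stopifnot(is.finite(eta_cl), is.finite(eta_v2))
  structure(list(cl = typ$cl * exp(eta_cl), v1 = typ$v1,
                 v2 = typ$v2 * exp(eta_v2), q = typ$q),
            class = "individual_parameters")
}

#' Micro rate constants and disposition exponents
#'
#' Reparameterises (CL, V1, V2, Q) as first-order micro constants and the two
#' disposition eigenvalues: `k10 = CL/V1`, `k12 = Q/V1`, `k21 = Q/V2`, and
#' `lambda1 >= lambda2 > 0` the roots of
#' \eqn{\lambda^2 - (k10+k12+k21)\lambda + k10\,k21 = 0}.
#' With `q = 0` the one-compartment limit is returned (`lambda1 = k10`,
#' `lambda2 = NA`, `one_compartment = TRUE`). A (measure-zero) repeated root
#' is split by perturbing `lambda2` down by `1e-9 * lambda1` with a warning.
#'
#' @param p An [individualize()] result or any list with `cl`, `v1`, `v2`,
#'   `q`.
#' @return Named list `k10`, `k12`, `k21`, `lambda1`, `lambda2`,
#'   `one_compartment`.
#' @export
micro_constants <- function(p) {
  stopifnot(p$cl > 0, p$v1 > 0, p$v2 > 0, p$q >= 0)
  k10 <- p$cl / p$v1
  if (p$q == 0)
    return(list(k10 = k10, k12 = 0, k21 = 0,
                lambda1 = k10, lambda2 = NA_real_, one_compartment = TRUE))
  k12 <- p$q / p$v1
  k21 <- p$q / p$v2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  if (disc <= 1e-12 * s^2) {
    warning("near-repeated disposition eigenvalues; perturbing lambda2")
    l1 <- s / 2
    l2 <- l1 * (1 - 1e-9)
  } else {
    r <- sqrt(disc)
    l1 <- (s + r) / 2
    l2 <- (s - r) / 2
  }
  list(k10 = k10, k12 = k12, k21 = k21, lambda1 = l1, lambda2 = l2,
       one_compartment = FALSE)
}

## Step response of the central concentration to a unit-rate infusion
## switched on at time 0: bi-exponential closed form (superposition basis).
step_response <- function(mk, v1, t) {
  t <- pmax(t, 0)
  if (mk$one_compartment) {
    k10 <- mk$k10
    return((1 - exp(-k10 * t)) / (v1 * k10))
  }
  l1 <- mk$lambda1; l2 <- mk$lambda2; k21 <- mk$k21
  A <- (l1 - k21) / (v1 * (l1 - l2))
  B <- (k21 - l2) / (v1 * (l1 - l2))
  A / l1 * (1 - exp(-l1 * t)) + B / l2 * (1 - exp(-l2 * t))
}

#' Central concentration under a piecewise-constant infusion
#'
#' Exact closed-form solution of the linear two-compartment (or degenerate
#' one-compartment) model: each segment contributes a unit step response at
#' its start minus one at its end, scaled by the rate (superposition). No ODE
#' solver is involved.
#'
#' @param p Individual parameters (list with `cl`, `v1`, `v2`, `q`).
#' @param regimen An [infusion_regimen()].
#' @param times Sorted non-negative times (h).
#' @return Numeric vector of central concentrations (ug/L), one per time.
#' @examples
#' p <- list(cl = 37.8, v1 = 229, v2 = 1640, q = 41)
#' conc_profile(p, infusion_regimen(0, 120, 17.5), c(0, 24, 120))
#' @export
conc_profile <- function(p, regimen, times) {
  if (any(times < 0)) stop("times must be >= 0")
  if (is.unsorted(times)) stop("times must be sorted")
  mk <- micro_constants(p)
  out <- numeric(length(times))
  if (!nrow(regimen)) return(out)
  for (i in seq_len(nrow(regimen))) {
    R <- regimen$rate[i]
    if (R == 0) next
    out <- out + R * (step_response(mk, p$v1, times - regimen$start_h[i]) -
                        step_response(mk, p$v1, times - regimen$end_h[i]))
  }
  pmax(out, 0)
}

## Fast path used inside estimation loops: plain numeric parameters,
## precomputed regimen columns, no validation.
conc_fast <- function(cl, v1, v2, q, seg_start, seg_end, seg_rate, times) {
  k10 <- cl / v1
  if (q == 0) {
    f <- function(t) {
      t[t < 0] <- 0
      (1 - exp(-k10 * t)) / (v1 * k10)
    }
  } else {
    k12 <- q / v1
    k21 <- q / v2
    s <- k10 + k12 + k21
    disc <- s * s - 4 * k10 * k21
    if (disc <= 1e-12 * s * s) {
      l1 <- s / 2; l2 <- l1 * (1 - 1e-9)
    } else {
      r <- sqrt(disc)
      l1 <- (s + r) / 2; l2 <- (s - r) / 2
    }
    A <- (l1 - k21) / (v1 * (l1 - l2))
    B <- (k21 - l2) / (v1 * (l1 - l2))
    a1 <- A / l1; a2 <- B / l2
    f <- function(t) {
      t[t < 0] <- 0
      a1 * (1 - exp(-l1 * t)) + a2 * (1 - exp(-l2 * t))
    }
  }
  out <- numeric(length(times))
  for (i in seq_along(seg_rate)) {
    R <- seg_rate[i]
    if (R == 0) next
    out <- out + R * (f(times - seg_start[i]) - f(times - seg_end[i]))
  }
  out[out < 0] <- 0
  out
}

## Batched variant over m (cl, v2) parameter pairs (v1, q scalars): returns
## an m x length(times) matrix. Used by the inner eta solver, where the
## centre and the four finite-difference perturbations are evaluated in one
## vectorised pass.
conc_batch <- function(cl, v1, v2, q, seg_start, seg_end, seg_rate, times) {
  if (!all(is.finite(cl)) || !all(is.finite(v2)) || !is.finite(v1) ||
      !is.finite(q))
    stop("non-finite kinetic parameters")
  m <- length(cl)
  nt <- length(times)
  out <- matrix(0, m, nt)
  k10 <- cl / v1
  if (q == 0) {
    for (i in seq_along(seg_rate)) {
      R <- seg_rate[i]
      if (R == 0) next
      t1 <- times - seg_start[i]; t1[t1 < 0] <- 0
      t2 <- times - seg_end[i]; t2[t2 < 0] <- 0
      out <- out + (R / v1) *
        (exp(tcrossprod(-k10, t2)) - exp(tcrossprod(-k10, t1))) / k10
    }
    out[out < 0] <- 0
    return(out)
  }
  k12 <- q / v1
  k21 <- q / v2
  s <- k10 + k12 + k21
  disc <- s * s - 4 * k10 * k21
  deg <- disc <= 1e-12 * s * s
  r <- sqrt(pmax(disc, 0))
  l1 <- (s + r) / 2
  l2 <- (s - r) / 2
  if (any(deg)) {
    l1[deg] <- s[deg] / 2
    l2[deg] <- l1[deg] * (1 - 1e-9)
  }
  den <- v1 * (l1 - l2)
  a1 <- (l1 - k21) / (den * l1)
  a2 <- (k21 - l2) / (den * l2)
  for (i in seq_along(seg_rate)) {
    R <- seg_rate[i]
    if (R == 0) next
    t1 <- times - seg_start[i]; t1[t1 < 0] <- 0
    t2 <- times - seg_end[i]; t2[t2 < 0] <- 0
    step <- a1 * (exp(tcrossprod(-l1, t2)) - exp(tcrossprod(-l1, t1))) +
      a2 * (exp(tcrossprod(-l2, t2)) - exp(tcrossprod(-l2, t1)))
    out <- out + R * step
  }
  out[out < 0] <- 0
  out
}

#' General linear mammillary profile via eigendecomposition
#'
#' Concentration of the central compartment for a mammillary model with an
#' arbitrary number of peripheral compartments, solved exactly through the
#' eigendecomposition of the rate matrix. Used for the three-compartment
#' candidate during structural model comparison; the one/two-compartment
#' production path uses the bi-exponential closed form in [conc_profile()].
#'
#' @param cl Systemic clearance (L/h).
#' @param v Vector of volumes, central first (L).
#' @param q Vector of intercompartmental clearances, one per peripheral
#'   compartment (L/h).
#' @param regimen An [infusion_regimen()].
#' @param times Sorted non-negative times (h).
#' @return Central concentrations (ug/L).
#' @export
conc_profile_mammillary <- function(cl, v, q, regimen, times) {
  stopifnot(length(v) == length(q) + 1, cl > 0, all(v > 0), all(q > 0))
  n <- length(v)
  A <- matrix(0, n, n)
  A[1, 1] <- -(cl + sum(q)) / v[1]
  for (j in seq_along(q)) {
    A[1, j + 1] <- q[j] / v[j + 1]
    A[j + 1, 1] <- q[j] / v[1]
    A[j + 1, j + 1] <- -q[j] / v[j + 1]
  }
  eg <- eigen(A)
  P <- eg$vectors
  lam <- eg$values
  Pinv <- solve(P)
  ## unit-rate step response of compartment amounts: P diag((e^{lam t}-1)/lam) Pinv e1
  w <- Pinv[, 1]
  step1 <- function(t) {
    t <- pmax(t, 0)
    M <- outer(lam, t, function(l, tt) (exp(l * tt) - 1) / l)
    drop(Re((P %*% (M * w))[1, ]))
  }
  out <- numeric(length(times))
  for (i in seq_len(nrow(regimen))) {
    R <- regimen$rate[i]
    if (R == 0) next
    out <- out + R * (step1(times - regimen$start_h[i]) -
                        step1(times - regimen$end_h[i]))
  }
  pmax(out, 0) / v[1]
}
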