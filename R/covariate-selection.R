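#' Likelihood-ratio critical OFV drop
#'
#' Upper-`alpha` quantile of the chi-squared distribution with `df` degrees
#' of freedom: the OFV drop a nested model extension must exceed to be
#' significant at level `alpha`. The conventional one-parameter values are
#' 3.84 (`alpha = 0.05`) and 6.64 (`alpha = 0.01`).
#'
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom (>= 1).
#' @return Critical delta-OFV.
#' @examples
#' lrt_threshold(0.05, 1)  # 3.84
#' lrt_threshold(0.01, 1)  # 6.63
#' @export
lrt_threshold <- function(alpha, df = 1) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.finite(df) || df < 1) stop("df must be >= 1")
  stats::qchisq(1 - alpha, df)
}

#' Candidate covariate relation for screening
#'
#' A candidate names a structural parameter, a covariate, and the functional
#' forms to try. At screening each form is fitted and the best (largest OFV
#' drop) represents the covariate. Dichotomous covariates should use
#' `forms = "indicator"`.
#'
#' @param parameter One of `"CL"`, `"V1"`, `"V2"`, `"Q"`.
#' @param covariate Covariate name.
#' @param forms Character vector of forms (see [cov_relation()]); default
#'   tries power, linear, and the two exponential variants.
#' @return Object of class `cov_candidate`.
#' @export
cov_candidate <- function(parameter, covariate,
                          forms = c("power", "linear", "exp_centered")) {
  structure(list(parameter = parameter, covariate = covariate, forms = forms),
            class = "cov_candidate")
}

cohort_covariate_median <- function(data, covariate) {
  v <- vapply(data$individuals, function(i) {
    x <- i$covariates[[covariate]]
    if (is.null(x)) NA_real_ else x
  }, 0)
  if (anyNA(v)) stop("covariate '", covariate, "' missing for some subjects")
  stats::median(v)
}

## Fit base model plus one extra relation (theta started at a small value).
fit_with_relation <- function(data, base_fit, rel, fix, control) {
  m <- base_fit$model
  m$relations <- c(m$relations, list(rel))
  fit_foce(data, m, fix = fix, control = control)
}

## Extensions start at exactly zero effect: the extended model then starts
## at the base optimum, so the fitted delta-OFV is non-negative by
## construction (up to refresh wobble) and the LRT null calibration is not
## polluted by optimiser noise from a displaced start.
start_theta <- function(form) 0

#' Univariate covariate screening
#'
#' Refits the base model with each candidate relation added singly and
#' tabulates the OFV drop. For every candidate all requested functional
#' forms are tried; the best form represents the covariate. Candidates whose
#' extended fit fails are marked not evaluable.
#'
#' @param data A [population_dataset()].
#' @param base_fit A converged [fit_foce()] of the base model.
#' @param candidates List of [cov_candidate()] objects.
#' @param fix,control Passed to the extension fits (defaults inherit the
#'   base fit's fixed parameters).
#' @return data.frame: `parameter`, `covariate`, `form`, `theta`,
#'   `ofv_base`, `ofv_extended`, `delta_ofv`, `evaluable`; sorted by
#'   decreasing `delta_ofv`. Attribute `fits` keeps the winning extended fit
#'   per candidate.
#' @export
univariate_screen <- function(data, base_fit, candidates,
                              fix = base_fit$fix,
                              control = list(presearch = 0, cycle_nm = 250,
                                             restarts = 3, maxit = 100)) {
  stopifnot(inherits(base_fit, "foce_fit"))
  rows <- list()
  fits <- list()
  for (ci in seq_along(candidates)) {
    cand <- candidates[[ci]]
    center <- if (identical(cand$forms, "indicator")) 1
              else cohort_covariate_median(data, cand$covariate)
    best <- NULL
    for (form in cand$forms) {
      rel <- cov_relation(cand$parameter, cand$covariate, form,
                          start_theta(form), center)
      fit <- tryCatch(
        fit_with_relation(data, base_fit, rel, fix, control),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$ofv < best$fit$ofv)
        best <- list(form = form, fit = fit)
    }
    if (is.null(best)) {
      rows[[ci]] <- data.frame(parameter = cand$parameter,
                               covariate = cand$covariate,
                               form = NA_character_, theta = NA_real_,
                               ofv_base = base_fit$ofv,
                               ofv_extended = NA_real_,
                               delta_ofv = NA_real_, evaluable = FALSE,
                               stringsAsFactors = FALSE)
    } else {
      last_rel <- best$fit$model$relations[[length(best$fit$model$relations)]]
      rows[[ci]] <- data.frame(parameter = cand$parameter,
                               covariate = cand$covariate,
                               form = best$form, theta = last_rel$theta,
                               ofv_base = base_fit$ofv,
                               ofv_extended = best$fit$ofv,
                               delta_ofv = base_fit$ofv - best$fit$ofv,
                               evaluable = TRUE, stringsAsFactors = FALSE)
      fits[[paste(cand$parameter, cand$covariate, sep = ":")]] <- best$fit
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(-ifelse(is.na(out$delta_ofv), -Inf, out$delta_ofv)), ]
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  out
}

#' Stepwise covariate model building
#'
#' Forward selection followed by backward elimination on OFV drops.
#' Forward: repeatedly add the evaluable candidate with the largest OFV drop
#' `>= lrt_threshold(forward_alpha, 1)` (ties broken by declaration order).
#' Backward: from the full forward model, repeatedly remove the selected
#' relation whose removal raises the OFV the least, while that rise is
#' `< lrt_threshold(backward_alpha, 1)`.
#'
#' @param data A [population_dataset()].
#' @param base_fit A converged [fit_foce()] of the covariate-free model.
#' @param candidates List of [cov_candidate()] objects.
#' @param forward_alpha,backward_alpha Significance levels (defaults 0.05 /
#'   0.01, i.e. critical drops 3.84 and 6.64 for one parameter).
#' @param fix,control Passed to every refit.
#' @return List: `fit` (final model fit), `trace` (data.frame log with one
#'   row per tested step: step, action, relation, OFVs, delta, decision).
#' @export
stepwise <- function(data, base_fit, candidates,
                     forward_alpha = 0.05, backward_alpha = 0.01,
                     fix = base_fit$fix,
                     control = list(presearch = 0, cycle_nm = 250,
                                    restarts = 3, maxit = 100)) {
  fwd_crit <- lrt_threshold(forward_alpha, 1)
  bwd_crit <- lrt_threshold(backward_alpha, 1)
  trace <- list()
  step <- 0L
  log_row <- function(action, label, before, after, decision) {
    step <<- step + 1L
    trace[[step]] <<- data.frame(step = step, action = action,
                                 relation = label, ofv_before = before,
                                 ofv_after = after,
                                 delta_ofv = before - after,
                                 decision = decision,
                                 stringsAsFactors = FALSE)
  }
  current <- base_fit
  remaining <- candidates
  ## ---- forward ----
  repeat {
    if (!length(remaining)) break
    scr <- univariate_screen(data, current, remaining, fix = fix,
                             control = control)
    scr_ok <- scr[scr$evaluable & is.finite(scr$delta_ofv), , drop = FALSE]
    if (!nrow(scr_ok)) break
    ## largest drop; exact ties -> candidate declaration order
    ord <- order(-scr_ok$delta_ofv,
                 match(paste(scr_ok$parameter, scr_ok$covariate),
                       vapply(remaining, function(c)
                         paste(c$parameter, c$covariate), "")))
    top <- scr_ok[ord[1], ]
    label <- sprintf("%s~%s(%s)", top$parameter, top$covariate, top$form)
    if (top$delta_ofv < fwd_crit) {
      log_row("forward", label, current$ofv, top$ofv_extended, "stop")
      break
    }
    log_row("forward", label, current$ofv, top$ofv_extended, "add")
    current <- attr(scr, "fits")[[paste(top$parameter, top$covariate,
                                        sep = ":")]]
    keep <- vapply(remaining, function(c)
      !(c$parameter == top$parameter && c$covariate == top$covariate), TRUE)
    remaining <- remaining[keep]
  }
  ## ---- backward ----
  repeat {
    rels <- current$model$relations
    if (!length(rels)) break
    drops <- vector("list", length(rels))
    for (j in seq_along(rels)) {
      m <- current$model
      m$relations <- rels[-j]
      drops[[j]] <- tryCatch(fit_foce(data, m, fix = fix, control = control),
                             error = function(e) NULL)
    }
    rises <- vapply(drops, function(f)
      if (is.null(f)) Inf else f$ofv - current$ofv, 0)
    j <- which.min(rises)
    rel <- rels[[j]]
    label <- sprintf("%s~%s(%s)", rel$parameter, rel$covariate, rel$form)
    if (rises[j] < bwd_crit) {
      log_row("backward", label, current$ofv, drops[[j]]$ofv, "remove")
      current <- drops[[j]]
    } else {
      log_row("backward", label, current$ofv,
              current$ofv + rises[j], "keep")
      break
    }
  }
  trace_df <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(),
               relation = character(), ofv_before = numeric(),
               ofv_after = numeric(), delta_ofv = numeric(),
               decision = character(), stringsAsFactors = FALSE)
  list(fit = current, trace = trace_df)
}
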