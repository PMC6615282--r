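#' Standard errors and relative standard errors of a fit
#'
#' Observed-information standard errors: the Hessian of OFV/2 with respect to
#' the estimation-scale parameters is computed by central finite differences
#' and inverted. The default relative step of 1e-3 keeps the second
#' differences well above the numerical noise floor of the inner
#' empirical-Bayes solves (a 1e-4 step places them at comparable magnitude
#' and yields indefinite Hessians). Standard errors are mapped back to the
#' natural reporting scale by the delta method (`se_nat = estimate * se_log`
#' for log-coded parameters); `rse_percent = 100 * se / |estimate|`.
#'
#' @param fit A [fit_foce()] result.
#' @param rel_step Relative finite-difference step.
#' @return data.frame with columns `parameter`, `estimate`, `se`,
#'   `rse_percent`; attribute `ok` is `FALSE` when the Hessian was not
#'   positive definite (all `se` then `NA`).
#' @export
standard_errors <- function(fit, rel_step = 1e-3) {
  stopifnot(inherits(fit, "foce_fit"))
  par <- fit$par
  tab <- fit$par_table
  n_ind <- length(fit$data$individuals)
  etas <- fit$etas
  ## each subject's empirical-Bayes solve is refined from the fitted etas
  ## WITHOUT the multi-start basin scan: the observed information is the
  ## curvature of the smooth likelihood branch the MLE sits on, and letting
  ## subjects swap conditional modes inside a second difference would
  ## corrupt it with the kinks of the min-over-modes surface
  objective <- function(p) {
    m <- decode_model(p, tab, fit$start)
    tot <- 0
    for (i in seq_len(n_ind)) {
      part <- individual_ofv(fit$data$individuals[[i]], m, etas[i, ],
                             scan = FALSE)
      tot <- tot + part$ofv
    }
    tot / 2
  }
  k <- length(par)
  h <- pmax(abs(par), 1) * rel_step
  H <- matrix(0, k, k)
  f0 <- objective(par)
  for (i in seq_len(k)) {
    for (j in i:k) {
      if (i == j) {
        pp <- pm <- par
        pp[i] <- par[i] + h[i]; pm[i] <- par[i] - h[i]
        H[i, i] <- (objective(pp) - 2 * f0 + objective(pm)) / h[i]^2
      } else {
        ppp <- ppm <- pmp <- pmm <- par
        ppp[c(i, j)] <- par[c(i, j)] + h[c(i, j)]
        pmm[c(i, j)] <- par[c(i, j)] - h[c(i, j)]
        ppm[i] <- par[i] + h[i]; ppm[j] <- par[j] - h[j]
        pmp[i] <- par[i] - h[i]; pmp[j] <- par[j] + h[j]
        H[i, j] <- H[j, i] <-
          (objective(ppp) - objective(ppm) - objective(pmp) +
             objective(pmm)) / (4 * h[i] * h[j])
      }
    }
  }
  est_rows <- which(tab$estimated)
  natural <- tab$value[est_rows]
  ok <- TRUE
  se_code <- rep(NA_real_, k)
  cv <- tryCatch(chol2inv(chol(H)), error = function(e) NULL)
  if (is.null(cv)) {
    ok <- FALSE
  } else {
    d <- diag(cv)
    if (any(d < 0)) ok <- FALSE else se_code <- sqrt(d)
  }
  ## delta method back to natural scale; estimates on the natural scale come
  ## from the refreshed table so log-coding cancels exactly
  est_nat <- fit$estimates[tab$name[est_rows]]
  se_nat <- ifelse(tab$log_scale[est_rows], abs(est_nat) * se_code, se_code)
  out <- data.frame(parameter = tab$name[est_rows],
                    estimate = as.numeric(est_nat),
                    se = as.numeric(se_nat),
                    rse_percent = 100 * as.numeric(se_nat) /
                      abs(as.numeric(est_nat)),
                    stringsAsFactors = FALSE)
  attr(out, "ok") <- ok
  out
}

#' Eta- and epsilon-shrinkage of a fit
#'
#' Eta-shrinkage per random effect: `100 * (1 - SD(eta_hat) / omega)`.
#' Epsilon-shrinkage: `100 * (1 - SD(IWRES))` where
#' `IWRES = (y - f_hat) / (sigma * f_hat)` at the conditional prediction.
#' Random effects with zero variance are reported as `NA`.
#'
#' @param fit A [fit_foce()] result with at least two subjects.
#' @return Named numeric: `eta_cl`, `eta_v2`, `epsilon` (percent).
#' @export
shrinkage <- function(fit) {
  stopifnot(inherits(fit, "foce_fit"))
  if (nrow(fit$etas) < 2) stop("shrinkage needs >= 2 subjects")
  om <- fit$model$omega2
  sh <- c(eta_cl = NA_real_, eta_v2 = NA_real_, epsilon = NA_real_)
  if (om[["cl"]] > 0)
    sh[["eta_cl"]] <- 100 * (1 - stats::sd(fit$etas[, "eta_cl"]) /
                               sqrt(om[["cl"]]))
  if (om[["v2"]] > 0)
    sh[["eta_v2"]] <- 100 * (1 - stats::sd(fit$etas[, "eta_v2"]) /
                               sqrt(om[["v2"]]))
  if (length(fit$iwres) >= 2)
    sh[["epsilon"]] <- 100 * (1 - stats::sd(fit$iwres))
  sh
}

#' Conditional weighted residuals
#'
#' FOCE-linearised residuals \eqn{V^{-1/2}(y - E)} per subject, where
#' \eqn{E = f(\hat\eta) - G\hat\eta} and
#' \eqn{V = G \Omega G' + diag(\sigma^2 f(\hat\eta)^2)} are the first-order
#' conditional mean and covariance expanded about the MAP etas. Approximately
#' standard normal under a correctly specified model.
#'
#' @param data A [population_dataset()]; defaults to the fit's own data.
#' @param fit A [fit_foce()] result.
#' @return data.frame with columns `id`, `time_h`, `dv`, `pred`, `ipred`,
#'   `cwres`, `iwres`.
#' @export
cwres_table <- function(fit, data = fit$data) {
  stopifnot(inherits(fit, "foce_fit"))
  det <- foce_ofv(data, fit$model, detail = TRUE)
  ids <- unlist(lapply(data$individuals,
                       function(i) rep(as.character(i$id), length(i$times))))
  data.frame(id = ids,
             time_h = unlist(lapply(data$individuals, `[[`, "times")),
             dv = unlist(lapply(data$individuals, `[[`, "dv")),
             pred = attr(det, "pred"),
             ipred = attr(det, "ipred"),
             cwres = attr(det, "cwres"),
             iwres = attr(det, "iwres"),
             stringsAsFactors = FALSE)
}

#' Parameter report of a fitted model
#'
#' Estimate / RSE% / shrinkage% table in the conventional population-PK
#' reporting layout (fixed effects, then IIV variances, then residual
#' variance).
#'
#' @param object A [fit_foce()] result.
#' @param se Logical; compute standard errors (slower).
#' @param ... Unused.
#' @return data.frame with one row per reported parameter.
#' @export
summary.foce_fit <- function(object, se = TRUE, ...) {
  est <- object$estimates[object$estimated]
  out <- data.frame(parameter = names(est), estimate = as.numeric(est),
                    rse_percent = NA_real_, shrinkage_percent = NA_real_,
                    stringsAsFactors = FALSE)
  if (se) {
    s <- standard_errors(object)
    out$rse_percent <- s$rse_percent[match(out$parameter, s$parameter)]
  }
  sh <- shrinkage(object)
  out$shrinkage_percent[out$parameter == "omega2_cl"] <- sh[["eta_cl"]]
  out$shrinkage_percent[out$parameter == "omega2_v2"] <- sh[["eta_v2"]]
  out$shrinkage_percent[out$parameter == "sigma2"] <- sh[["epsilon"]]
  class(out) <- c("foce_fit_summary", "data.frame")
  out
}

#' Write a fit report to a JSON file
#'
#' @param fit A [fit_foce()] result.
#' @param path Output file.
#' @param se Logical; include RSE% (requires a Hessian pass).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, se = FALSE) {
  s <- summary(fit, se = se)
  jsonlite::write_json(list(ofv = fit$ofv, converged = fit$converged,
                            parameters = s),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
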