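#' Non-stratified bootstrap of a population fit
#'
#' Resamples subjects (not observations) with replacement to the original
#' cohort size, refits each replicate, and summarises the replicate
#' estimates by their median and 2.5/97.5 percentile bounds. Replicates are
#' warm-started from the supplied model's estimates to keep many replicates
#' tractable; failed or non-converged replicates are excluded and counted.
#'
#' @param data A [population_dataset()].
#' @param start_model A [pop_model()] (typically the final fitted model).
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param fix,control Passed to each replicate [fit_foce()].
#' @return Object of class `bootstrap_result`: `replicates` (matrix, one row
#'   per successful replicate), `median`, `ci_lower`, `ci_upper` (2.5% /
#'   97.5%), `n_success`, `n_failed`.
#' @export
bootstrap_model <- function(data, start_model, n_reps = 200, seed = 1,
                            fix = character(),
                            control = list(presearch = 0, maxit = 60,
                                           restarts = 0)) {
  stopifnot(n_reps >= 1)
  n <- length(data$individuals)
  set.seed(seed)
  reps <- list()
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    idx <- sample.int(n, n, replace = TRUE)
    ## a subject drawn k times enters once with likelihood weight k
    counts <- tabulate(idx, nbins = n)
    keep <- which(counts > 0)
    inds <- data$individuals[keep]
    for (j in seq_along(inds)) inds[[j]]$id <- paste0("B", r, "_", j)
    bd <- population_dataset(inds)
    fit <- tryCatch(
      suppressWarnings(fit_foce(bd, start_model, fix = fix,
                                control = control,
                                weights = counts[keep])),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      n_failed <- n_failed + 1L
      next
    }
    reps[[length(reps) + 1L]] <- fit$estimates[fit$estimated]
  }
  if (!length(reps)) stop("all bootstrap replicates failed")
  mat <- do.call(rbind, reps)
  structure(list(replicates = mat,
                 median = apply(mat, 2, stats::median),
                 ci_lower = apply(mat, 2, stats::quantile, 0.025),
                 ci_upper = apply(mat, 2, stats::quantile, 0.975),
                 n_success = nrow(mat), n_failed = n_failed,
                 seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap: %d successful, %d failed replicates\n",
              x$n_success, x$n_failed))
  print(data.frame(median = x$median, ci_2.5 = x$ci_lower,
                   ci_97.5 = x$ci_upper))
  invisible(x)
}

## Simulate one replicate dataset from the model on the design of `data`
## (same subjects, regimens, times, covariates; new etas and residuals).
simulate_observations <- function(data, model) {
  lapply(data$individuals, function(ind) {
    n <- length(ind$times)
    eta <- c(stats::rnorm(1, 0, sqrt(model$omega2[["cl"]])),
             stats::rnorm(1, 0, sqrt(model$omega2[["v2"]])))
    f <- predict_individual(model, ind, eta)
    f * (1 + stats::rnorm(n, 0, sqrt(model$sigma2)))
  })
}

#' Prediction-corrected visual predictive check
#'
#' Observations and simulated replicates are normalised by
#' `pcY = Y * median(PRED in bin) / PRED`, where PRED is the population
#' (eta = 0) prediction; the observed 5th/50th/95th percentiles per time bin
#' are then compared with confidence bands of the same percentiles across
#' `n_sims` datasets simulated from the model on the observed design.
#'
#' @param data A [population_dataset()].
#' @param model A fitted [pop_model()].
#' @param n_sims Number of simulated replicate datasets.
#' @param bins Number of quantile-based time bins (default 8), or a numeric
#'   vector of explicit bin edges.
#' @param seed Integer seed.
#' @param conf Width of the simulated confidence band (default 0.95; the
#'   narrower 0.90 plotting convention is also supported).
#' @param probs Percentiles summarised per bin.
#' @return Object of class `vpc_result`: a long-format data.frame `table`
#'   with columns `bin`, `t_mid`, `t_lo`, `t_hi`, `n_obs`, `statistic`
#'   (`p5`/`p50`/`p95`), `observed`, `sim_lo`, `sim_median`, `sim_hi`.
#' @export
pc_vpc <- function(data, model, n_sims = 200, bins = 8, seed = 1,
                   conf = 0.95, probs = c(0.05, 0.5, 0.95)) {
  times <- unlist(lapply(data$individuals, `[[`, "times"))
  obs <- unlist(lapply(data$individuals, `[[`, "dv"))
  pred <- unlist(lapply(data$individuals, function(ind)
    predict_individual(model, ind, c(0, 0))))
  if (any(pred <= 0))
    stop("population prediction must be > 0 for every observation")
  if (length(bins) == 1) {
    edges <- unique(stats::quantile(times, seq(0, 1, length.out = bins + 1)))
  } else {
    edges <- sort(unique(bins))
  }
  edges[1] <- min(edges[1], min(times))
  edges[length(edges)] <- max(edges[length(edges)], max(times))
  bin_id <- cut(times, edges, include.lowest = TRUE, labels = FALSE)
  if (anyNA(bin_id)) stop("observations fall outside the bin edges")
  counts <- tabulate(bin_id, nbins = length(edges) - 1)
  if (any(counts == 0))
    stop("empty time bin; use fewer or explicit bins")
  pred_med <- stats::ave(pred, bin_id, FUN = stats::median)
  pc_obs <- obs * pred_med / pred
  n_bins <- length(edges) - 1
  obs_pct <- vapply(seq_len(n_bins), function(b)
    stats::quantile(pc_obs[bin_id == b], probs, names = FALSE),
    numeric(length(probs)))
  set.seed(seed)
  sim_pct <- array(NA_real_, c(n_sims, length(probs), n_bins))
  for (s in seq_len(n_sims)) {
    ysim <- unlist(simulate_observations(data, model))
    pc_sim <- ysim * pred_med / pred
    sim_pct[s, , ] <- vapply(seq_len(n_bins), function(b)
      stats::quantile(pc_sim[bin_id == b], probs, names = FALSE),
      numeric(length(probs)))
  }
  a <- (1 - conf) / 2
  rows <- list()
  t_mid <- vapply(seq_len(n_bins), function(b)
    stats::median(times[bin_id == b]), 0)
  for (b in seq_len(n_bins)) {
    for (p in seq_along(probs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        bin = b, t_mid = t_mid[b], t_lo = edges[b], t_hi = edges[b + 1],
        n_obs = counts[b],
        statistic = paste0("p", round(100 * probs[p])),
        observed = obs_pct[p, b],
        sim_lo = stats::quantile(sim_pct[, p, b], a, names = FALSE),
        sim_median = stats::median(sim_pct[, p, b]),
        sim_hi = stats::quantile(sim_pct[, p, b], 1 - a, names = FALSE),
        stringsAsFactors = FALSE)
    }
  }
  structure(list(table = do.call(rbind, rows), conf = conf,
                 n_sims = n_sims, seed = seed),
            class = "vpc_result")
}

#' Fraction of observed VPC percentile points outside the simulated bands
#'
#' @param vpc A [pc_vpc()] result.
#' @return Fraction in `[0, 1]`.
#' @export
vpc_coverage_gap <- function(vpc) {
  t <- vpc$table
  mean(t$observed < t$sim_lo | t$observed > t$sim_hi)
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("pc-VPC: %d simulations, %.0f%% bands, %d bins\n",
              x$n_sims, 100 * x$conf, max(x$table$bin)))
  cat(sprintf("  observed percentile points outside bands: %.1f%%\n",
              100 * vpc_coverage_gap(x)))
  invisible(x)
}
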