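test_that("map_etas sits at the prior mode in degenerate cases", {
  model <- ecmo_reference_model()
  empty <- individual_data("E1", infusion_regimen(0, 120, 17.5))
  expect_equal(as.numeric(map_etas(empty, model)), c(0, 0))

  # zero IIV forces eta = 0 even with data
  m0 <- ecmo_reference_model(iiv = FALSE)
  set.seed(4)
  ind <- rich_individual(model = m0, sigma = 0.2)
  expect_equal(as.numeric(map_etas(ind, m0)), c(0, 0))

  # shrinking omega2 pulls the MAP towards 0
  set.seed(5)
  ind <- rich_individual(model = model, eta = c(0.5, 0.5), sigma = 0.1)
  m_small <- model; m_small$omega2 <- c(cl = 1e-6, v2 = 1e-6)
  expect_lt(max(abs(map_etas(ind, m_small))), 1e-3)
})

test_that("map_etas matches a dense grid-search oracle", {
  model <- ecmo_reference_model()
  # single-observation subject: MAP is prior-dominated but nontrivial
  reg <- infusion_regimen(0, 120, 17.5)
  cov <- covariate_set(36.9, 4.5)
  ind <- individual_data("G1", reg, times = 48, dv = 0.62, covariates = cov)
  eta_hat <- map_etas(ind, model)
  g <- function(e1, e2) {
    f <- predict_individual(model, ind, c(e1, e2))
    v <- model$sigma2 * f^2
    log(v) + (ind$dv - f)^2 / v +
      e1^2 / model$omega2[["cl"]] + e2^2 / model$omega2[["v2"]]
  }
  # three-stage nested grid refinement down to 1e-5 spacing
  ctr <- c(0, 0); half <- c(2, 3)
  for (stage in 1:4) {
    e1s <- seq(ctr[1] - half[1], ctr[1] + half[1], length.out = 41)
    e2s <- seq(ctr[2] - half[2], ctr[2] + half[2], length.out = 41)
    vals <- outer(e1s, e2s, Vectorize(g))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    ctr <- c(e1s[ix[1]], e2s[ix[2]])
    half <- half * 0.06
  }
  expect_lt(max(abs(eta_hat - ctr)), 1e-4)
})

test_that("FOCE OFV is additive over independent individuals", {
  model <- ecmo_reference_model()
  d <- toy_cohort(4, model, seed = 10)
  ofv1 <- foce_ofv(d, model)
  dup <- d$individuals
  for (i in seq_along(dup)) dup[[i]]$id <- paste0("dup", i)
  d2 <- population_dataset(c(d$individuals, dup))
  expect_equal(foce_ofv(d2, model), 2 * ofv1, tolerance = 1e-12)
})

test_that("with zero IIV the OFV is the fixed-effect weighted -2LL", {
  m0 <- ecmo_reference_model(iiv = FALSE)
  set.seed(3)
  d <- toy_cohort(3, m0, seed = 3)
  expected <- 0
  for (ind in d$individuals) {
    f <- predict_individual(m0, ind, c(0, 0))
    v <- m0$sigma2 * f^2
    expected <- expected + sum(log(v) + (ind$dv - f)^2 / v) +
      length(f) * log(2 * pi)
  }
  expect_equal(foce_ofv(d, m0), expected, tolerance = 1e-10)
})

test_that("FOCE+I OFV tracks adaptive Gauss-Hermite quadrature", {
  # moderate IIV, informative designs: linearisation error should be far
  # below 1 OFV unit per 5-subject instance (acceptance re-runs this at the
  # full 10-instance, 64-node setting)
  model <- ecmo_reference_model()
  model$omega2 <- c(cl = 0.1, v2 = 0.2)
  model$sigma2 <- 0.04
  for (seed in 1:3) {
    d <- toy_cohort(5, model, seed = 100 + seed)
    ofv <- foce_ofv(d, model)
    ofv_oracle <- agq_ofv_oracle(d, model, n_nodes = 32)
    expect_lt(abs(ofv - ofv_oracle), 1)
  }
})

test_that("noise-free self-consistency: fit started at truth stays there", {
  truth <- ecmo_reference_model(iiv = FALSE)
  truth$sigma2 <- 1e-8
  set.seed(9)
  d <- toy_cohort(4, truth, seed = 9)
  fit <- fit_foce(d, truth, fix = c("sigma2"),
                  control = list(presearch = 0, maxit = 40))
  est <- fit$estimates
  expect_lt(abs(est[["th_cl"]] / 37.8 - 1), 1e-3)
  expect_lt(abs(est[["th_v1"]] / 229 - 1), 1e-3)
  expect_lt(abs(est[["th_v2"]] / 1640 - 1), 1e-3)
  expect_lt(abs(est[["th_q"]] / 41 - 1), 1e-3)
  expect_lt(abs(est[["th_cl_temperature"]] - 0.207), 1e-3)
  expect_lt(abs(est[["th_v2_total_protein"]] - 2.46), 5e-3)
})

test_that("standard errors: definition, scale invariance and 1/sqrt(n)", {
  # the clearance-side parameters are cleanly identified and keep the
  # observed information positive definite; the volume/protein directions
  # sit on a flat ridge at this cohort size and are exercised elsewhere.
  # The SE machinery (definition, inversion, scaling) is what is under
  # test here
  truth <- ecmo_reference_model()
  truth$omega2 <- c(cl = 0.1, v2 = 0.2)
  d <- toy_cohort(8, truth, seed = 21)
  fit <- fit_foce(d, truth, fix = c("th_v1", "th_v2", "th_q",
                                    "th_v2_total_protein", "omega2_cl",
                                    "omega2_v2", "sigma2"),
                  control = list(presearch = 0, maxit = 60))
  se <- standard_errors(fit)
  expect_true(attr(se, "ok"))
  expect_equal(se$rse_percent, 100 * se$se / abs(se$estimate))
  # quadrupling the cohort shrinks SEs roughly by half
  rep4 <- d$individuals
  inds <- d$individuals
  for (k in 1:3) {
    more <- lapply(rep4, function(x) { x$id <- paste0(x$id, "_", k); x })
    inds <- c(inds, more)
  }
  d4 <- population_dataset(inds)
  fit4 <- fit_foce(d4, fit$model, fix = fit$fix,
                   control = list(presearch = 0, maxit = 60))
  se4 <- standard_errors(fit4)
  ratio <- se4$se / se$se
  expect_true(all(ratio > 0.3 & ratio < 0.75))
})

test_that("shrinkage behaves at its limits", {
  model <- ecmo_reference_model()
  # subjects with no observations: EBEs are 0, shrinkage 100%
  inds <- lapply(1:4, function(i)
    individual_data(paste0("N", i), infusion_regimen(0, 120, 17.5)))
  # add two informative subjects so the fit object is well-formed
  set.seed(30)
  rich <- lapply(5:6, function(i)
    rich_individual(paste0("N", i), model,
                    eta = c(rnorm(1, 0, 0.4), rnorm(1, 0, 0.4)),
                    sigma = sqrt(model$sigma2)))
  d <- population_dataset(c(inds, rich))
  det <- foce_ofv(d, model, detail = TRUE)
  etas <- attr(det, "etas")
  expect_true(all(etas[1:4, ] == 0))
  # rich data, many subjects, correct model: shrinkage well below sparse
  # levels
  d_rich <- toy_cohort(30, model, seed = 31,
                       times = c(1, 3, 6, 12, 24, 48, 72, 96, 120, 121,
                                 123, 126, 132, 144, 168, 192))
  fit <- structure(list(etas = attr(foce_ofv(d_rich, model, detail = TRUE),
                                    "etas"),
                        iwres = attr(foce_ofv(d_rich, model, detail = TRUE),
                                     "iwres"),
                        model = model),
                   class = "foce_fit")
  sh <- shrinkage(fit)
  expect_lt(sh[["eta_cl"]], 35)
  expect_lt(sh[["epsilon"]], 20)
  # omega = 0 is undefined
  m0 <- ecmo_reference_model(iiv = FALSE)
  fit0 <- fit
  fit0$model <- m0
  expect_true(is.na(shrinkage(fit0)[["eta_cl"]]))
})

test_that("CWRES reduces to the weighted residual without IIV", {
  m0 <- ecmo_reference_model(iiv = FALSE)
  reg <- infusion_regimen(0, 120, 17.5)
  ind <- individual_data("C1", reg, times = 48, dv = 0.5,
                         covariates = covariate_set())
  d <- population_dataset(list(ind))
  det <- foce_ofv(d, m0, detail = TRUE)
  f <- predict_individual(m0, ind, c(0, 0))
  expect_equal(attr(det, "cwres"),
               (0.5 - f) / (sqrt(m0$sigma2) * f), tolerance = 1e-12)
})

test_that("CWRES is approximately standard normal under the true model", {
  model <- ecmo_reference_model()
  d <- toy_cohort(60, model, seed = 77,
                  times = c(3, 12, 24, 48, 72, 96, 120, 126, 144, 168))
  det <- foce_ofv(d, model, detail = TRUE)
  cw <- attr(det, "cwres")
  expect_gte(length(cw), 500)
  expect_lt(abs(mean(cw)), 0.1)
  expect_lt(abs(sd(cw) - 1), 0.15)
  # inflating residual noise in the data only pushes SD(CWRES) above 1
  infl <- model
  infl$sigma2 <- model$sigma2 * 4
  d_noisy <- toy_cohort(60, infl, seed = 78,
                        times = c(3, 12, 24, 48, 72, 96, 120, 126, 144,
                                  168))
  cw_noisy <- attr(foce_ofv(d_noisy, model, detail = TRUE), "cwres")
  expect_gt(sd(cw_noisy), 1.2)
})
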