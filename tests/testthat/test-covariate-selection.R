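test_that("LRT thresholds reproduce the chi-squared quantiles", {
  expect_equal(lrt_threshold(0.05, 1), 3.84, tolerance = 5e-3)
  expect_equal(lrt_threshold(0.01, 1), 6.64, tolerance = 5e-3)
  expect_equal(lrt_threshold(0.5, 1), 0.455, tolerance = 5e-3)
  # independent numerical inversion of the chi2(1) CDF:
  # P(X <= x) = 2 Phi(sqrt(x)) - 1
  inv <- uniroot(function(x) 2 * pnorm(sqrt(x)) - 1 - 0.95, c(0, 20),
                 tol = 1e-12)$root
  expect_equal(lrt_threshold(0.05, 1), inv, tolerance = 1e-9)
  expect_equal(lrt_threshold(0.05, 2), qchisq(0.95, 2))
  expect_error(lrt_threshold(0), "alpha")
  expect_error(lrt_threshold(0.05, 0), "df")
})

test_that("a relation with zero coefficient leaves the OFV unchanged", {
  model <- ecmo_reference_model()
  d <- toy_cohort(4, model, seed = 14)
  extended <- model
  extended$relations <- c(extended$relations,
                          list(cov_relation("CL", "total_protein", "power",
                                            0, 4.5)))
  expect_identical(foce_ofv(d, extended), foce_ofv(d, model))
})

test_that("screening respects nesting and stepwise mirrors the study", {
  truth <- ecmo_reference_model()
  design <- cohort_design()
  d <- generate_cohort(design, covariate_distributions(), truth, seed = 101)
  # covariate-free base model; variances and the two weakly identified
  # structural parameters (V1, Q) are held at plausible values so each
  # refit estimates CL, V2 and the covariate coefficient under test --
  # the selection logic, not full-model identifiability, is the target
  base_model <- pop_model(fixed_effects(37.8, 229, 1640, 41),
                          omega2_cl = truth$omega2[["cl"]],
                          omega2_v2 = truth$omega2[["v2"]],
                          sigma2_prop = truth$sigma2)
  fixpar <- c("th_v1", "th_q", "omega2_cl", "omega2_v2", "sigma2")
  ctl <- list(presearch = 0, cycle_nm = 150, restarts = 2, maxit = 100)
  base <- fit_foce(d, base_model, fix = fixpar, control = ctl)
  cands <- list(
    cov_candidate("CL", "temperature", forms = "exp_centered"),
    cov_candidate("CL", "bilirubin", forms = "power"),
    cov_candidate("V2", "total_protein", forms = "power"),
    cov_candidate("V2", "lean_body_weight", forms = "power"))
  scr <- univariate_screen(d, base, cands, fix = fixpar, control = ctl)
  # nesting: an extra parameter can only lower the OFV (optimiser slack)
  expect_true(all(scr$delta_ofv[scr$evaluable] > -1e-3))
  # the true temperature effect dominates the pure-noise candidates
  expect_equal(scr$covariate[1], "temperature")
  sel <- stepwise(d, base, cands, fix = fixpar, control = ctl)
  final_rels <- vapply(sel$fit$model$relations, function(r)
    paste(r$parameter, r$covariate), "")
  # the noise covariates must not survive; the true temperature effect must
  expect_true("CL temperature" %in% final_rels)
  expect_false(any(grepl("bilirubin|lean_body_weight", final_rels)))
  # trace is internally consistent
  expect_equal(sel$trace$delta_ofv,
               sel$trace$ofv_before - sel$trace$ofv_after)
  # rerun is identical (deterministic given data)
  sel2 <- stepwise(d, base, cands, fix = fixpar, control = ctl)
  expect_identical(sel$trace, sel2$trace)
})

test_that("vacuous selection returns the base model", {
  truth <- ecmo_reference_model()
  d <- generate_cohort(cohort_design(n_subjects = 12),
                       covariate_distributions(), truth, seed = 55)
  base_model <- pop_model(fixed_effects(37.8, 229, 1640, 41),
                          omega2_cl = truth$omega2[["cl"]],
                          omega2_v2 = truth$omega2[["v2"]],
                          sigma2_prop = truth$sigma2)
  fixpar <- c("omega2_cl", "omega2_v2", "sigma2")
  base <- fit_foce(d, base_model, fix = fixpar,
                   control = list(presearch = 0, maxit = 50))
  # an absurdly strict forward level lets nothing in
  sel <- stepwise(d, base,
                  list(cov_candidate("CL", "bilirubin", forms = "power")),
                  forward_alpha = 1e-12,
                  control = list(presearch = 0, maxit = 50))
  expect_length(sel$fit$model$relations, 0)
  expect_false(any(sel$trace$decision == "add"))
})
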