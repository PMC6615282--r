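test_that("covariate model reproduces the reference typical values", {
  fx <- ref_fixed()
  ref <- reference_values()

  at_ref <- apply_covariates(fx, covariate_set(36.9, 4.5), ref)
  expect_equal(at_ref$cl, 37.8)
  expect_equal(at_ref$v2, 1640)
  expect_equal(at_ref$v1, 229)
  expect_equal(at_ref$q, 41)

  # hypothermia: CL = 37.8 exp(0.207 (33 - 36.9)) (frozen scalar evaluation)
  cold <- apply_covariates(fx, covariate_set(33, 4.5), ref)
  expect_equal(cold$cl, 16.8611, tolerance = 1e-5)

  # power form on V2 responds and CL ignores protein
  hi_prot <- apply_covariates(fx, covariate_set(36.9, 6), ref)
  expect_equal(hi_prot$v2, 1640 * (6 / 4.5)^2.46, tolerance = 1e-12)
  expect_equal(hi_prot$cl, 37.8)
})

test_that("covariate relations validate inputs and forms", {
  fx <- ref_fixed()
  expect_error(covariate_set(temperature = 50), "temperature")
  expect_error(covariate_set(total_protein = -1), "total_protein")
  # power form with non-positive covariate is a domain error
  rel <- cov_relation("V2", "x", "power", 2, 4.5)
  expect_error(
    apply_covariates(fx, covariate_set(36.9, 4.5, x = -1),
                     relations = list(rel)),
    "positive")
  # linear and indicator forms evaluate as documented
  lin <- cov_relation("CL", "age", "linear", -0.1, 55)
  p <- apply_covariates(fx, covariate_set(36.9, 4.5, age = 65),
                        relations = list(lin))
  expect_equal(p$cl, 37.8 - 0.1 * 10)
  flag <- cov_relation("CL", "crrt", "indicator", 0.3, 1)
  p1 <- apply_covariates(fx, covariate_set(36.9, 4.5, crrt = 1),
                         relations = list(flag))
  expect_equal(p1$cl, 37.8 * exp(0.3))
})

test_that("individualize applies log-normal random effects", {
  typ <- ref_params()
  expect_equal(unclass(individualize(typ, 0, 0))[c("cl", "v1", "v2", "q")],
               typ)
  expect_equal(individualize(typ, log(2), 0)$cl, 2 * typ$cl)
  expect_equal(individualize(typ, 0.3, 0)$cl, 51.0247, tolerance = 1e-5)
  expect_equal(individualize(typ, 0, -0.5)$v2, 1640 * exp(-0.5))
  expect_equal(individualize(typ, 1, 1)$v1, typ$v1)  # no IIV on V1
})

test_that("micro constants satisfy Vieta identities and match eigenvalues", {
  p <- ref_params()
  mk <- micro_constants(p)
  expect_equal(mk$lambda1 * mk$lambda2, mk$k10 * mk$k21, tolerance = 1e-12)
  expect_equal(mk$lambda1 + mk$lambda2, mk$k10 + mk$k12 + mk$k21,
               tolerance = 1e-12)
  # independent eigen-decomposition of the 2x2 rate matrix
  A <- matrix(c(-(mk$k10 + mk$k12), mk$k21, mk$k12, -mk$k21), 2, 2,
              byrow = TRUE)
  ev <- sort(-Re(eigen(A)$values))
  expect_equal(sort(c(mk$lambda1, mk$lambda2)), ev, tolerance = 1e-10)
  expect_equal(mk$lambda2, 0.01154098, tolerance = 1e-6)
  # one-compartment degenerate limit
  mk1 <- micro_constants(list(cl = 37.8, v1 = 229, v2 = 1640, q = 0))
  expect_true(mk1$one_compartment)
  expect_equal(mk1$lambda1, 37.8 / 229)
  expect_true(is.na(mk1$lambda2))
})

test_that("closed-form concentration has the right limits", {
  p <- ref_params()
  reg <- infusion_regimen(0, 120, 17.5)
  expect_equal(conc_profile(p, reg, 0), 0)
  expect_equal(conc_profile(p, infusion_regimen(), c(0, 10, 50)),
               c(0, 0, 0))
  expect_error(conc_profile(p, reg, c(-1, 5)), ">= 0")
  # steady state R/CL to 0.1% beyond 10 terminal half-lives
  mk <- micro_constants(p)
  t_ss <- 10 * log(2) / mk$lambda2
  reg_long <- infusion_regimen(0, t_ss * 2, 17.5)
  expect_equal(conc_profile(p, reg_long, t_ss), 17.5 / p$cl,
               tolerance = 1e-3)
  # reference 120-h value, cross-checked against the exact linear-system
  # oracle
  c120 <- conc_profile(p, reg, 120)
  expect_equal(c120, 0.398486, tolerance = 1e-5)
  expect_equal(c120, conc_expm_oracle(p, reg, 120), tolerance = 1e-9)
})

test_that("closed form agrees with the linear-system oracle on random draws", {
  set.seed(42)
  for (rep in 1:200) {
    p <- list(cl = runif(1, 5, 80), v1 = runif(1, 20, 400),
              v2 = runif(1, 100, 3000), q = runif(1, 5, 80))
    t_stop <- runif(1, 20, 200)
    reg <- infusion_regimen(c(0, t_stop + runif(1, 1, 20)),
                            c(t_stop, t_stop + runif(1, 25, 60)),
                            runif(2, 5, 30))
    times <- sort(runif(4, 0.5, t_stop + 80))
    a <- conc_profile(p, reg, times)
    b <- conc_expm_oracle(p, reg, times)
    expect_equal(a, b, tolerance = 1e-6)
  }
})

test_that("superposition and covariate monotonicity hold", {
  p <- ref_params()
  times <- c(6, 24, 60, 130, 150)
  r1 <- infusion_regimen(0, 120, 17.5)
  r2 <- infusion_regimen(120, 150, 10)
  both <- infusion_regimen(c(0, 120), c(120, 150), c(17.5, 10))
  expect_equal(conc_profile(p, both, times),
               conc_profile(p, r1, times) + conc_profile(p, r2, times),
               tolerance = 1e-12)
  # concentration strictly decreasing in temperature (th_temp > 0)
  fx <- ref_fixed()
  temps <- c(33, 35, 36.9, 38, 39)
  c48 <- vapply(temps, function(tt) {
    typ <- apply_covariates(fx, covariate_set(tt, 4.5))
    conc_profile(typ, r1, 48)
  }, 0)
  expect_true(all(diff(c48) < 0))
  # V2 strictly increasing in protein (th_prot > 0)
  v2s <- vapply(c(2, 4, 6, 8), function(pp)
    apply_covariates(fx, covariate_set(36.9, pp))$v2, 0)
  expect_true(all(diff(v2s) > 0))
})

test_that("two-compartment profile converges to the one-compartment form", {
  times <- c(3, 12, 48, 96, 130)
  reg <- infusion_regimen(0, 120, 17.5)
  one <- conc_profile(list(cl = 37.8, v1 = 229, v2 = 1, q = 0), reg, times)
  # with q -> 0 the peripheral compartment decouples
  two <- conc_profile(list(cl = 37.8, v1 = 229, v2 = 1640, q = 1e-8),
                      reg, times)
  expect_equal(two, one, tolerance = 1e-5)
})

test_that("eigendecomposition path matches the bi-exponential closed form", {
  p <- ref_params()
  reg <- infusion_regimen(0, 120, 17.5)
  times <- c(3, 24, 96, 121, 160)
  expect_equal(conc_profile_mammillary(p$cl, c(p$v1, p$v2), p$q, reg, times),
               conc_profile(p, reg, times), tolerance = 1e-9)
  # three-compartment candidate reduces to two-compartment when the second
  # peripheral compartment is negligibly connected
  expect_equal(conc_profile_mammillary(p$cl, c(p$v1, p$v2, 1), c(p$q, 1e-9),
                                       reg, times),
               conc_profile(p, reg, times), tolerance = 1e-6)
})
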