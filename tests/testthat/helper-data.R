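# Small in-code fixtures shared across test files.

ref_fixed <- function() fixed_effects(37.8, 229, 1640, 41,
                                      th_temp = 0.207, th_prot = 2.46)

ref_params <- function() list(cl = 37.8, v1 = 229, v2 = 1640, q = 41)

# One subject with a rich design: 120-h infusion at 17.5 ug/h, observations
# through infusion and washout, noise-free data unless dv supplied.
rich_individual <- function(id = "R1", model = ecmo_reference_model(),
                            eta = c(0, 0), sigma = 0,
                            temperature = 36.9, total_protein = 4.5,
                            times = c(3, 12, 24, 48, 72, 96, 120, 121,
                                      126, 144, 168)) {
  reg <- infusion_regimen(0, 120, 17.5)
  cov <- covariate_set(temperature = temperature,
                       total_protein = total_protein)
  ind <- individual_data(id, reg, covariates = cov)
  f <- predict_individual(model, ind, eta, times)
  dv <- f * (1 + rnorm(length(times), 0, sigma))
  individual_data(id, reg, times, pmax(dv, 1e-6), cov)
}

# A toy cohort: n subjects with random etas/noise under `model`.
toy_cohort <- function(n = 5, model = ecmo_reference_model(), seed = 1,
                       times = c(3, 12, 24, 48, 72, 96, 120, 126, 144),
                       temp_range = c(34, 38.5), prot_range = c(2.5, 6)) {
  set.seed(seed)
  inds <- lapply(seq_len(n), function(i) {
    rich_individual(
      id = paste0("T", i), model = model,
      eta = c(rnorm(1, 0, sqrt(model$omega2[["cl"]])),
              rnorm(1, 0, sqrt(model$omega2[["v2"]]))),
      sigma = sqrt(model$sigma2),
      temperature = runif(1, temp_range[1], temp_range[2]),
      total_protein = runif(1, prot_range[1], prot_range[2]),
      times = times)
  })
  population_dataset(inds)
}
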