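test_that("predict_tbars matches the closed-form models", {
  cr <- control_rates()
  arr <- fit_arrhenius(cr$temperature_k, cr$k_mean, treatment = "control")
  ll <- fit_log_logistic(cr$temperature_k - 273, cr$k_mean,
                         treatment = "control")

  # day 0 is 100 % by definition, for either model
  expect_equal(predict_tbars(arr, 12, 0), 100)
  expect_equal(predict_tbars(ll, 12, 0), 100)

  # one-line oracle for the integrated Arrhenius model at 12 C, day 5
  k12 <- arr$k0 * exp(-arr$ea / (8.314 * (12 + 273.15)))
  expect_equal(predict_tbars(arr, 12, 5), 100 * exp(5 * k12),
               tolerance = 1e-12)

  # one-line oracle for the integrated log-logistic model at 8 C, day 1;
  # the exponent is the model's k(8 C), close to the measured rate there
  k8 <- log(1 + exp(ll$c * (8 - ll$tc)))
  expect_equal(predict_tbars(ll, 8, 1), 100 * exp(k8), tolerance = 1e-12)
  expect_lt(abs(k8 - cr$k_mean[cr$temperature_k == 281]) /
              cr$k_mean[cr$temperature_k == 281], 0.01)

  expect_error(predict_tbars(arr, 12, -1), "domain")

  # strictly increasing in day and in temperature
  expect_true(all(diff(predict_tbars(arr, 12, 0:10)) > 0))
  expect_true(all(diff(sapply(seq(0, 30, 2), function(tt)
    predict_tbars(arr, tt, 5))) > 0))
  expect_true(all(diff(sapply(seq(0, 30, 2), function(tt)
    predict_tbars(ll, tt, 5))) > 0))

  # both well-fitting models agree within 15% at the fitted temperatures
  expect_gt(arr$r2, 0.99)
  expect_gt(ll$r2, 0.99)
  for (tt in cr$temperature_k - 273) {
    a <- predict_tbars(arr, tt, 3, kelvin_offset = 273)
    b <- predict_tbars(ll, tt, 3)
    expect_lt(abs(a - b) / a, 0.15)
  }
})

test_that("shelf_life_days inverts the integrated model", {
  cr <- control_rates()
  arr <- fit_arrhenius(cr$temperature_k, cr$k_mean)
  d <- shelf_life_days(arr, 8, 300)
  expect_equal(predict_tbars(arr, 8, d), 300, tolerance = 1e-9)
})

test_that("validate_external computes the contracted metrics", {
  obs <- c(110, 150, 190, 260, 320)
  perfect <- validate_external(obs, obs)
  expect_equal(perfect$r2_adj, 1)
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$slope, 1)

  biased <- validate_external(obs, obs + 10)
  expect_equal(biased$rmse, 10)
  expect_equal(biased$r2_adj, 1)

  # 6-point hand-computed oracle (explicit formulas, no lm)
  pred <- c(100, 140, 200, 260, 330, 400)
  ob <- c(112, 130, 214, 250, 340, 390)
  n <- 6
  sxx <- sum((pred - mean(pred))^2)
  sxy <- sum((pred - mean(pred)) * (ob - mean(ob)))
  syy <- sum((ob - mean(ob))^2)
  slope <- sxy / sxx
  r2 <- sxy^2 / (sxx * syy)
  v <- validate_external(pred, ob)
  expect_equal(v$slope, slope, tolerance = 1e-12)
  expect_equal(v$intercept, mean(ob) - slope * mean(pred),
               tolerance = 1e-12)
  expect_equal(v$r2_adj, 1 - (1 - r2) * (n - 1) / (n - 2),
               tolerance = 1e-12)
  expect_equal(v$rmse, sqrt(mean((ob - pred)^2)), tolerance = 1e-12)

  expect_error(validate_external(1:4, 1:5), "contract")
  expect_error(validate_external(rep(1, 5), 1:5), "degenerate")
})

test_that("noiseless holdout validation is essentially perfect", {
  truth <- paper_like_truth(noise_sigma = 0, replicates = 1, seed = 3)
  ds <- simulate_dataset(truth)
  v <- holdout_pipeline(ds, 12, "arrhenius", kelvin_offset = 273)
  expect_gte(v$r2_adj, 1 - 1e-9)
  expect_lt(v$rmse, 1e-8)
  expect_equal(v$n, nrow(ds[ds$temperature_c == 12 & ds$day > 0, ]))
})

test_that("noisy holdout validation degrades but stays strong", {
  truth <- paper_like_truth(noise_sigma = 0.05, replicates = 3, seed = 9)
  ds <- simulate_dataset(truth)
  v <- holdout_pipeline(ds, 12, "arrhenius", kelvin_offset = 273)
  expect_gt(v$rmse, 0)
  expect_gt(v$r2_adj, 0.9)
  expect_lt(v$r2_adj, 1)
  expect_true(is.data.frame(v$pairs))
  expect_false(is.null(v$per_treatment))
})

test_that("holdout on an absent temperature is a configuration error", {
  ds <- simulate_dataset(paper_like_truth(noise_sigma = 0, replicates = 1,
                                          seed = 1))
  expect_error(holdout_pipeline(ds, 14, "arrhenius"), "configuration")
})

test_that("the pipeline recovers Arrhenius truths across the Ea range", {
  # Ea spanning the plausible activation-energy range; k0 anchored so
  # k(12 C) = 0.2/day, a mid-range oxidation rate
  for (case in list(c(ea = 30000, seed = 1), c(ea = 80000, seed = 2),
                    c(ea = 130000, seed = 3))) {
    ea <- case[["ea"]]
    k0 <- 0.2 / exp(-ea / (R_GAS * (12 + 273.15)))
    truth <- synthetic_truth(
      data.frame(treatment = "control", model = "arrhenius", ea = ea,
                 k0 = k0, c = NA, tc = NA),
      noise_sigma = 0.05, replicates = 3L, seed = case[["seed"]])
    ds <- simulate_dataset(truth)
    rt <- rate_table(ds[ds$temperature_c != 12, ])
    arr <- fit_arrhenius(celsius_to_kelvin(rt$aggregated$temperature_c),
                         rt$aggregated$k_mean)
    expect_lt(abs(arr$ea - ea) / ea, 0.05)
    v <- holdout_pipeline(ds, 12, "arrhenius")
    expect_gte(v$r2_adj, 0.95)
  }
})
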