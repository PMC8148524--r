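# noiseless generator for the dummy-coded regression: log-linear truth in
# day, temperature and treatment offsets (control = 0)
mlr_dataset <- function(beta0 = 4.4, beta_time = 0.14, beta_temp = 0.06,
                        effects = c(control = 0, garlic = -0.8),
                        sigma = 0, seed = 1, replicates = 1L) {
  set.seed(seed)
  rows <- expand.grid(treatment = names(effects),
                      temperature_c = c(4, 8, 12, 16, 20),
                      replicate = seq_len(replicates), day = 0:5,
                      stringsAsFactors = FALSE)
  mu <- beta0 + beta_time * rows$day + beta_temp * rows$temperature_c +
    effects[rows$treatment]
  rows$tbars <- exp(mu + rnorm(nrow(rows), 0, sigma))
  rows$scale <- "percent"
  kinetic_dataset(rows)
}

test_that("noiseless generative coefficients are recovered exactly", {
  # summary.lm warns about the (intentionally) perfect fit
  fit <- suppressWarnings(fit_mlr_dummy(mlr_dataset()))
  expect_equal(fit$intercept, 4.4, tolerance = 1e-10)
  expect_equal(fit$coef_time, 0.14, tolerance = 1e-10)
  expect_equal(fit$coef_temperature, 0.06, tolerance = 1e-10)
  garlic <- fit$coefficients[fit$coefficients$term == "garlic", ]
  expect_equal(garlic$estimate, -0.8, tolerance = 1e-10)
  expect_lt(sum(residuals(fit$fit)^2), 1e-20)
})

test_that("the design has one dummy per non-control treatment", {
  effects <- setNames(c(0, seq(-0.9, -0.1, length.out = 13)),
                      c("control", paste0("ext", 1:13)))
  ds <- mlr_dataset(effects = effects)
  fit <- suppressWarnings(fit_mlr_dummy(ds))  # perfect-fit warning
  # intercept + day + temperature + 13 dummies = 16 columns
  expect_equal(nrow(fit$coefficients), 16L)
  expect_equal(ncol(model.matrix(fit$fit)), 16L)
  expect_false("control" %in% fit$coefficients$term)
})

test_that("fit_mlr_dummy equals the normal-equations solution", {
  ds <- mlr_dataset(effects = c(control = 0, a = -0.5, b = -0.2),
                    sigma = 0.3, seed = 8)
  fit <- fit_mlr_dummy(ds)
  X <- model.matrix(fit$fit)
  beta <- solve(crossprod(X), crossprod(X, log(ds$tbars)))
  expect_equal(unname(coef(fit$fit)), unname(drop(beta)),
               tolerance = 1e-10)
})

test_that("noisy estimates stay within 3 SE of the generative truth", {
  effects <- setNames(c(0, -0.87, -0.5, -0.1), c("control", "bay", "mid",
                                                 "weak"))
  ds <- mlr_dataset(effects = effects, sigma = 0.3, seed = 42,
                    replicates = 3L)
  fit <- fit_mlr_dummy(ds)
  for (tr in c("bay", "mid", "weak")) {
    row <- fit$coefficients[fit$coefficients$term == tr, ]
    expect_lt(abs(row$estimate - effects[[tr]]), 3 * row$std_error)
  }
  # the strongest true inhibitor ranks first
  rk <- rank_treatment_effects(fit)
  expect_equal(rk$treatment[1], "bay")
  expect_true(all(c("coefficient", "p_value", "significant") %in% names(rk)))
})

test_that("response shifts move only the intercept", {
  ds <- mlr_dataset(effects = c(control = 0, a = -0.4), sigma = 0.2,
                    seed = 3)
  f1 <- fit_mlr_dummy(ds)
  ds2 <- ds
  ds2$tbars <- ds2$tbars * exp(1.5)  # adds 1.5 to log response
  f2 <- fit_mlr_dummy(ds2)
  expect_equal(f2$intercept, f1$intercept + 1.5, tolerance = 1e-10)
  expect_equal(f2$coef_time, f1$coef_time, tolerance = 1e-10)
  expect_equal(f2$coefficients$estimate[-1], f1$coefficients$estimate[-1],
               tolerance = 1e-10)
})

test_that("ranking is deterministic and null effects are flagged", {
  ds <- mlr_dataset(effects = c(control = 0, a = 0, b = 0), sigma = 0.5,
                    seed = 12, replicates = 2L)
  fit <- fit_mlr_dummy(ds)
  rk1 <- rank_treatment_effects(fit)
  # shuffling record order leaves the ranking unchanged
  set.seed(99)
  shuffled <- kinetic_dataset(as.data.frame(ds)[sample(nrow(ds)), ],
                              treatments = treatments(ds))
  rk2 <- rank_treatment_effects(fit_mlr_dummy(shuffled))
  expect_equal(rk1, rk2, tolerance = 1e-12)

  expect_error(fit_mlr_dummy(mlr_dataset(effects = c(x = 0, y = -1))),
               "control")
})

test_that("DPPH activity and phenolic content are near-perfectly correlated", {
  res <- dpph_tpc_correlation()
  expect_equal(res$n, 13L)
  expect_equal(round(res$r, 2), 0.98)
  expect_lt(res$p_value, 1e-6)

  # exactly proportional columns give r = 1
  prop <- data.frame(dpph_umol_te_g = c(1, 2, 3, 4),
                     tpc_mg_gae_g = c(2, 4, 6, 8))
  expect_equal(dpph_tpc_correlation(prop)$r, 1)

  # 4-row closed-form oracle
  tab <- data.frame(dpph_umol_te_g = c(10, 40, 25, 90),
                    tpc_mg_gae_g = c(2, 5, 4, 11))
  dx <- tab$dpph_umol_te_g - mean(tab$dpph_umol_te_g)
  dy <- tab$tpc_mg_gae_g - mean(tab$tpc_mg_gae_g)
  expect_equal(dpph_tpc_correlation(tab)$r,
               sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)),
               tolerance = 1e-12)

  expect_error(dpph_tpc_correlation(
    data.frame(dpph_umol_te_g = c(1, 1, 1), tpc_mg_gae_g = c(1, 2, 3))),
    "variance")
})
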