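test_that("feature encoding produces the canonical design", {
  ds <- simulate_dataset(paper_like_truth(noise_sigma = 0, replicates = 1,
                                          seed = 1))
  ft <- encode_features(ds)
  # 2 numeric inputs + 14 treatment indicators = 16 input columns
  expect_equal(ncol(ft$x), 16L)
  expect_equal(ft$treatments[1], "control")
  ind <- ft$x[, -(1:2)]
  expect_true(all(rowSums(ind) == 1))
  expect_true(all(ind %in% c(0, 1)))
  # a control record has its 1 in the first indicator position
  i <- which(ds$treatment == "control")[1]
  expect_equal(unname(ind[i, 1]), 1)
  # numeric inputs are z-scored
  expect_equal(mean(ft$x[, "day"]), 0, tolerance = 1e-12)
  expect_equal(sd(ft$x[, "day"]), 1, tolerance = 1e-12)
  # identical records (replicate sisters of a noiseless run) encode identically
  ds2 <- simulate_dataset(paper_like_truth(noise_sigma = 0, replicates = 2,
                                           seed = 1),
                          storage_design(temperatures_c = c(4, 20)))
  ft2 <- encode_features(ds2)
  j <- which(ds2$treatment == "control" & ds2$day == 3 &
               ds2$temperature_c == 4)
  expect_length(j, 2L)
  expect_equal(ft2$x[j[1], ], ft2$x[j[2], ])
})

test_that("the 2:1:1 split holds to one record and is reproducible", {
  for (n in c(40, 101, 2268)) {
    s <- split_221(n, seed = 4)
    tab <- table(factor(s, levels = c("train", "valid", "test")))
    expect_lte(abs(tab[["train"]] - n / 2), 1)
    expect_lte(abs(tab[["valid"]] - n / 4), 1)
    expect_lte(abs(tab[["test"]] - n / 4), 1)
  }
  expect_identical(split_221(100, seed = 4), split_221(100, seed = 4))
  expect_false(identical(split_221(100, seed = 4), split_221(100, seed = 5)))

  strata <- rep(c("a", "b"), each = 40)
  s <- split_221(80, seed = 1, strata = strata)
  for (g in c("a", "b")) {
    tab <- table(s[strata == g])
    expect_lte(abs(tab[["train"]] - 20), 1)
  }
})

test_that("a single network learns the noiseless kinetic surface", {
  ds <- simulate_dataset(paper_like_truth(noise_sigma = 0, replicates = 1,
                                          seed = 1))
  ft <- encode_features(ds)
  f <- train_mlp(ann_spec(7, "tanh", "exponential", seed = 1), ft)
  expect_gte(f$r2, 0.99)
  expect_true(all(f$performance >= -1 & f$performance <= 1))

  # deterministic retraining
  f2 <- train_mlp(ann_spec(7, "tanh", "exponential", seed = 1), ft)
  expect_identical(f$weights, f2$weights)
  expect_identical(f$r2, f2$r2)

  # constant target is reproduced to numerical precision
  dc <- ds
  dc$tbars <- 100
  fc <- train_mlp(ann_spec(5, "tanh", "exponential", seed = 1),
                  encode_features(dc))
  expect_lt(max(abs(predict(fc) - 100)), 1e-3)
})

test_that("network selection ranks by validation error", {
  ds <- simulate_dataset(paper_like_truth(noise_sigma = 0, replicates = 1,
                                          seed = 1),
                         storage_design(temperatures_c = c(4, 12, 20)))
  ft <- encode_features(ds)
  specs <- list(ann_spec(3, seed = 2), ann_spec(5, seed = 3),
                ann_spec(7, seed = 4), ann_spec(4, "exponential", seed = 5))
  sel <- select_best_networks(specs, ft, n_keep = 3, split_seed = 1)
  val <- sapply(sel$fits, function(f) f$error[["valid"]])
  expect_equal(length(sel$fits), 3L)
  expect_true(all(diff(val) >= 0))

  # n_keep = 1 with a single spec returns that fit
  one <- select_best_networks(specs[1], ft, n_keep = 1, split_seed = 1)
  expect_equal(length(one$fits), 1L)
  expect_equal(one$fits[[1]]$spec$n_hidden, 3L)

  # ranking is invariant to the order the specs are supplied in
  sel_shuffled <- select_best_networks(specs[c(3, 1, 4, 2)], ft,
                                       n_keep = 3, split_seed = 1)
  expect_equal(sapply(sel_shuffled$fits, function(f) f$error[["valid"]]),
               val, tolerance = 1e-12)

  # validation-ranked best has test error within 3x the minimum test error
  all4 <- select_best_networks(specs, ft, n_keep = 4, split_seed = 1)
  test_err <- sapply(all4$fits, function(f) f$error[["test"]])
  expect_lte(test_err[1], 3 * min(test_err))
})

test_that("ann_spec and ann_table enforce their schemas", {
  expect_error(ann_spec(2), "n_hidden")
  expect_error(ann_spec(11), "n_hidden")
  expect_error(ann_spec(5, error_function = "cross_entropy"))
  grid <- default_ann_grid(seed = 1)
  expect_length(grid, 20L)
  expect_true(all(sapply(grid, function(s) s$n_hidden) %in% 3:10))

  ds <- simulate_dataset(paper_like_truth(noise_sigma = 0, replicates = 1,
                                          seed = 1),
                         storage_design(temperatures_c = c(4, 20)))
  ft <- encode_features(ds)
  sel <- select_best_networks(grid[1:3], ft, n_keep = 2, split_seed = 1)
  tab <- ann_table(sel)
  expect_equal(nrow(tab), 2L)
  expect_match(tab$structure, "^MLP 16-\\d+-1$")
  expect_equal(tab$error_function, rep("SOS", 2))
})
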