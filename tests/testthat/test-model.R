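test_that("the 80/20 split is seeded, disjoint and exhaustive", {
  rec <- make_records(500, seed = 1L)
  sp <- split_dataset(rec, 0.8, seed = 1L)
  expect_equal(nrow(sp$train), 400)
  expect_equal(nrow(sp$test), 100)
  expect_length(intersect(sp$train$sample_id, sp$test$sample_id), 0)
  expect_setequal(c(sp$train$sample_id, sp$test$sample_id), rec$sample_id)

  again <- split_dataset(rec, 0.8, seed = 1L)
  expect_identical(sp$train$sample_id, again$train$sample_id)

  small <- make_records(10, seed = 2L)
  sp10 <- split_dataset(small, 0.8, seed = 1L)
  expect_equal(nrow(sp10$train), 8)
  expect_equal(nrow(sp10$test), 2)
  expect_setequal(c(sp10$train$sample_id, sp10$test$sample_id),
                  small$sample_id)

  expect_error(split_dataset(rec, 1.2, 1L), "train_frac")
  expect_error(split_dataset(small[1:5, ], 0.8, 1L), "at least 10")
})

test_that("accuracy metrics match hand and brute-force computation", {
  ev <- evaluate_predictions(c(1, 2, 3), c(2, 2, 2))
  expect_equal(ev$mae, 2 / 3)
  expect_equal(ev$mse, 2 / 3)
  expect_equal(ev$rmse, sqrt(2 / 3))
  expect_equal(ev$r2, 0)
  expect_equal(ev$residuals, c(-1, 0, 1))

  perfect <- evaluate_predictions(c(0.2, 0.4, 0.9), c(0.2, 0.4, 0.9))
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$rmse, 0)

  y <- with_seed(5L, runif(200)); p <- with_seed(6L, runif(200))
  ev <- evaluate_predictions(y, p)
  bf <- brute_metrics(y, p)
  expect_equal(ev$r2, bf$r2, tolerance = 1e-10)
  expect_equal(ev$mae, bf$mae, tolerance = 1e-10)
  expect_equal(ev$mse, bf$mse, tolerance = 1e-10)
  expect_equal(ev$rmse, bf$rmse, tolerance = 1e-10)
  expect_equal(ev$rmse^2, ev$mse, tolerance = 1e-12)
  expect_lte(ev$mae, ev$rmse)

  expect_warning(ev0 <- evaluate_predictions(c(1, 1, 1), c(1, 2, 1)),
                 "zero variance")
  expect_true(is.na(ev0$r2))
  expect_error(evaluate_predictions(1:3, 1:2), "length")
})

test_that("a constant-label chain predicts the constant everywhere", {
  rec <- make_constant_records(120, seed = 3L, value = 0.5)
  spec <- chain_spec(search_budget = 3L, rng_seed = 1L)
  ch <- fit_chain(rec, spec)
  probe <- make_records(50, seed = 4L)
  expect_true(all(abs(predict_vnqi(ch, probe) - 0.5) < 0.01))

  mo <- fit_baseline(rec, "multi_output", spec)
  p <- predict(mo, probe)
  expect_true(all(abs(p - 0.5) < 0.01))
})

test_that("a linear ground truth is recovered almost perfectly", {
  rec <- make_records(400, seed = 7L, noise = 0)   # oxy_t linear in coverage
  sp <- split_dataset(rec, 0.8, 1L)
  ch <- fit_chain(sp$train, chain_spec(rng_seed = 2L))
  r2 <- evaluate_predictions(sp$test$oxy_t, predict_vnqi(ch, sp$test))$r2
  # least-squares oracle on the same split attains R2 = 1 by construction
  ols <- lm(oxy_t ~ vessel_coverage, data = sp$train)
  expect_gte(suppressWarnings(summary(ols)$r.squared), 0.999)
  expect_gte(r2, 0.99)
})

test_that("the OXY_V-augmented baseline learns an identity relation", {
  rec <- make_records(300, seed = 8L, noise = 0.05)
  rec$oxy_t <- rec$oxy_v                     # exact identity
  sp <- split_dataset(rec, 0.8, 1L)
  m <- fit_baseline(sp$train, "oxy_t_with_true_oxy_v", chain_spec(rng_seed = 3L))
  r2 <- evaluate_predictions(sp$test$oxy_t, predict(m, sp$test))$r2
  expect_gte(r2, 0.999)
  expect_error(fit_baseline(sp$train, "bogus"), "unknown variant")
})

test_that("training is deterministic under a fixed seed", {
  rec <- make_records(150, seed = 9L, noise = 0.02)
  spec <- chain_spec(search_budget = 4L, rng_seed = 11L)
  c1 <- fit_chain(rec, spec)
  c2 <- fit_chain(rec, spec)
  expect_identical(c1$manifest, c2$manifest)
  probe <- make_records(20, seed = 10L)
  expect_identical(predict_vnqi(c1, probe), predict_vnqi(c2, probe))
})

test_that("VNQI is clipped to the unit interval", {
  # labels at the top of the range push raw network output beyond 1
  rec <- make_records(150, seed = 12L)
  rec$oxy_v <- clip01(rec$oxy_v + 0.3)
  rec$oxy_t <- 1.0
  rec$oxy_t[1] <- 0.999  # keep target variance nonzero
  ch <- fit_chain(rec, chain_spec(search_budget = 3L, rng_seed = 1L))
  probe <- make_records(200, seed = 13L)
  v <- predict_vnqi(ch, probe)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("scaler statistics come from the training set only", {
  rec <- make_records(200, seed = 14L)
  sp <- split_dataset(rec, 0.8, 1L)
  ch <- fit_chain(sp$train, chain_spec(search_budget = 2L, rng_seed = 1L))
  x <- as.matrix(sp$train[, morphology_columns()])
  expect_equal(unname(ch$scaler$center), unname(colMeans(x)), tolerance = 1e-12)
  expect_equal(unname(ch$scaler$scale), unname(apply(x, 2, sd)),
               tolerance = 1e-12)
})

test_that("NN2 is teacher-forced: trained on oracle OXY_V, chained at inference", {
  # oxy_t equals oxy_v exactly, but oxy_v is pure noise w.r.t. morphology:
  # a teacher-forced NN2 learns the identity (tiny inner validation error)
  # while the chained prediction, forced through NN1's morphology-only
  # OXY_V estimate, cannot recover it
  rec <- make_records(300, seed = 15L)
  rec$oxy_v <- with_seed(16L, runif(300))
  rec$oxy_t <- rec$oxy_v
  sp <- split_dataset(rec, 0.8, 1L)
  ch <- fit_chain(sp$train, chain_spec(rng_seed = 4L))
  expect_lt(ch$manifest$nn2_val_mse, 0.005)
  ev_chain <- evaluate_predictions(sp$test$oxy_t, predict_vnqi(ch, sp$test))
  expect_lt(ev_chain$r2, 0.5)
})
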