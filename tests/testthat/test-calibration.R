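# small noiseless dataset used across the calibration tests
calib_dataset <- noiseless_dataset(design = pulse_series_design(), dt_min = 15)

test_that("the objective is zero when the model generated the data", {
  w <- wss_objective(ref_params, ref_hxt4, calib_dataset)
  expect_lt(as.numeric(w), 1e-6)
  expect_false(attr(w, "failed"))
})

test_that("doubling all SEMs divides the objective by four", {
  p <- update_params(ref_params, aM = ref_params$aM * 1.5)
  ds1 <- calib_dataset
  ds1$sem_au <- 0.5 # well above any floor
  ds2 <- ds1
  ds2$sem_au <- 1
  w1 <- as.numeric(wss_objective(p, ref_hxt4, ds1, weight_floor_frac = 0))
  w2 <- as.numeric(wss_objective(p, ref_hxt4, ds2, weight_floor_frac = 0))
  expect_equal(w1 / w2, 4, tolerance = 1e-12)
})

test_that("the objective is invariant to record and row order", {
  ds <- dplyr::bind_rows(
    calib_dataset,
    noiseless_dataset(design = deletion_panel_design()[1, ], dt_min = 15)
  )
  ds <- as_hxt_dataset(ds, attr(calib_dataset, "profiles"))
  p <- update_params(ref_params, kinG1 = 5)
  shuffled <- as_hxt_dataset(
    ds[sample.int(nrow(ds)), ],
    attr(calib_dataset, "profiles")
  )
  expect_equal(
    as.numeric(wss_objective(p, ref_hxt4, ds)),
    as.numeric(wss_objective(p, ref_hxt4, shuffled))
  )
})

test_that("perturbing a generating parameter increases the objective", {
  for (fac in c(0.7, 1.3)) {
    p <- update_params(ref_params, aM = ref_params$aM * fac)
    expect_gt(as.numeric(wss_objective(p, ref_hxt4, calib_dataset)), 1e-2)
  }
  pr <- ref_hxt4
  pr$aH <- pr$aH * 1.2
  expect_gt(as.numeric(wss_objective(ref_params, pr, calib_dataset)), 1e-2)
})

test_that("fit_model is deterministic and honours the degenerate budget", {
  bounds <- list(aH = c(5, 80), K_Mig1 = c(0.05, 0.8))
  f1 <- fit_model(calib_dataset, bounds, seed = 4, budget = 30, pop = 10)
  f2 <- fit_model(calib_dataset, bounds, seed = 4, budget = 30, pop = 10)
  expect_equal(f1$theta, f2$theta)
  expect_equal(f1$objective, f2$objective)
  # budget 1: best of the initial population, no error
  f3 <- fit_model(calib_dataset, bounds, seed = 4, budget = 1, pop = 10)
  expect_s3_class(f3, "hxt_fit")
  expect_true(is.finite(f3$objective))
  # re-evaluating the objective at the best parameters reproduces it
  expect_equal(
    as.numeric(wss_objective(f1$params, f1$promoter, calib_dataset)),
    f1$objective,
    tolerance = 1e-9
  )
})

test_that("fit_model validates its inputs", {
  expect_error(
    fit_model(calib_dataset, list(aH = c(10, 1)), seed = 1, budget = 10),
    "lower bound"
  )
  expect_error(
    fit_model(calib_dataset, list(c(1, 2)), seed = 1, budget = 10),
    "named"
  )
  expect_error(
    fit_model(calib_dataset, list(aH = c(0, Inf)), seed = 1, budget = 10),
    "finite"
  )
  expect_error(
    fit_model(calib_dataset[0, ], list(aH = c(1, 2)), seed = 1, budget = 10),
    "empty dataset"
  )
})

test_that("a short fit recovers the generating trajectories", {
  start <- ref_hxt4
  bounds <- list(
    aH = c(ref_hxt4$aH / 5, ref_hxt4$aH * 5),
    K_Mig1 = c(ref_hxt4$K["Mig1"] / 5, ref_hxt4$K["Mig1"] * 5),
    dHmax = c(ref_hxt4$dHmax / 5, ref_hxt4$dHmax * 5)
  )
  fit <- fit_model(calib_dataset, bounds, seed = 2, budget = 400, pop = 12)
  expect_lt(prediction_nrmse(fit, calib_dataset), 0.10)
})

test_that("tidy and glance expose the fit in broom form", {
  f <- fit_model(calib_dataset, list(aH = c(5, 80)), seed = 1, budget = 1, pop = 10)
  td <- tidy(f)
  expect_named(td, c("term", "estimate"))
  gl <- glance(f)
  expect_equal(gl$n_param, 1L)
  expect_true(is.na(gl$in_class))
})

test_that("mechanism-class selection prefers Std1-activates-SNF1 fits", {
  # reference parameters are in the class by construction
  expect_true(mechanism_class(ref_params, ref_hxt4)$std1_snf1)

  # an out-of-class variant: Std1 barely stimulates SNF1 but dominates pMIG2
  out_params <- update_params(ref_params,
    beta1 = 0.001, K_G2_std1 = 0.05, K_G2_mth1 = 50
  )
  expect_false(mechanism_class(out_params, ref_hxt4)$std1_snf1)

  fit_in <- structure(
    list(params = ref_params, promoter = ref_hxt4, objective = 1.05,
         theta = c(aH = 20), in_class = NA),
    class = "hxt_fit"
  )
  fit_out <- structure(
    list(params = out_params, promoter = ref_hxt4, objective = 1.0,
         theta = c(aH = 20), in_class = NA),
    class = "hxt_fit"
  )
  # both within margin: the in-class fit wins even at higher objective
  pick <- select_mechanism_class(list(fit_out, fit_in), margin = 0.1)
  expect_true(pick$in_class)
  expect_equal(pick$objective, 1.05)
  # single fit in class returns that fit
  expect_true(select_mechanism_class(list(fit_in))$in_class)
  # no in-class fit within margin: best overall, flagged
  pick2 <- select_mechanism_class(list(fit_out), margin = 0.1)
  expect_false(pick2$in_class)
  expect_equal(pick2$objective, 1.0)
})

test_that("datasets round-trip through CSV", {
  f <- tempfile(fileext = ".csv")
  write_hxt_dataset(calib_dataset, f)
  back <- read_hxt_dataset(f, attr(calib_dataset, "profiles"))
  expect_equal(back$mean_au, calib_dataset$mean_au)
  expect_s3_class(back, "hxt_dataset")
})
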