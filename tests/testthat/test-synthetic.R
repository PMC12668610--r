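quiet_cfg <- function(...) {
  synth_config(
    design = pulse_series_design(), replicates = 2,
    autofluor_mean = 0, autofluor_sd = 0, day_sd = 0, meas_sd = 0, ...
  )
}

test_that("identity corruption reproduces the ground truth exactly", {
  raw <- generate_raw(quiet_cfg(), seed = 1)
  gt <- attr(raw, "ground_truth")
  tagged <- raw[raw$chamber == "tagged" & raw$replicate == 1, ]
  expect_equal(tagged$fluor_au, gt$H)
  # and normalisation is then exact (controls are noiseless too)
  ds <- normalise_raw(raw)
  joined <- dplyr::inner_join(
    tibble::as_tibble(ds), gt,
    by = c("genotype", "profile", "hxt", "time_h")
  )
  expect_equal(joined$mean_au, joined$H, tolerance = 1e-12)
  expect_true(all(joined$sem_au == 0)) # identical replicates
})

test_that("generation is seed-reproducible", {
  cfg <- synth_config(design = pulse_series_design(), replicates = 2)
  r1 <- generate_raw(cfg, seed = 42)
  r2 <- generate_raw(cfg, seed = 42)
  expect_equal(r1$fluor_au, r2$fluor_au)
  r3 <- generate_raw(cfg, seed = 43)
  expect_false(isTRUE(all.equal(r1$fluor_au, r3$fluor_au)))
})

test_that("rescaling a whole device (all chambers) cancels in normalisation", {
  cfg <- synth_config(
    design = pulse_series_design(), replicates = 2,
    autofluor_mean = 0, autofluor_sd = 0, day_sd = 0.1, meas_sd = 0
  )
  raw <- generate_raw(cfg, seed = 7)
  ds1 <- normalise_raw(raw)
  scaled <- raw
  scaled$fluor_au[scaled$replicate == 1] <- 2 * scaled$fluor_au[scaled$replicate == 1]
  ds2 <- normalise_raw(scaled)
  expect_equal(ds1$mean_au, ds2$mean_au, tolerance = 1e-12)
})

test_that("normalisation inverts the corruption up to measurement noise", {
  biases <- vapply(1:8, function(s) {
    cfg <- synth_config(design = pulse_series_design(), replicates = 3)
    raw <- generate_raw(cfg, seed = s)
    ds <- normalise_raw(raw)
    gt <- attr(raw, "ground_truth")
    joined <- dplyr::inner_join(
      tibble::as_tibble(ds), gt,
      by = c("genotype", "profile", "hxt", "time_h")
    )
    mean(joined$mean_au - joined$H)
  }, numeric(1))
  cfg <- synth_config(design = pulse_series_design())
  expect_lt(max(abs(biases)), cfg$meas_sd)
})

test_that("the replicate mean converges on the ground truth", {
  cfg <- synth_config(
    design = pulse_series_design(), replicates = 5,
    autofluor_sd = 0.02, day_sd = 0.03, meas_sd = 0.1
  )
  # pool replicates over 10 seeds: N = 50 effective replicates
  per_seed <- lapply(1:10, function(s) {
    ds <- normalise_raw(generate_raw(cfg, seed = s))
    ds$mean_au
  })
  pooled <- Reduce(`+`, per_seed) / length(per_seed)
  gt <- attr(generate_raw(quiet_cfg(), seed = 1), "ground_truth")
  se <- cfg$meas_sd / sqrt(50)
  # mean absolute deviation within 3 standard errors of the pooled mean,
  # allowing for the small day-effect variance contribution
  expect_lt(mean(abs(pooled - gt$H)), 3 * (se + cfg$day_sd * mean(gt$H) / sqrt(50)))
})

test_that("an empty pre-glucose window is rejected", {
  prof <- glucose_profile(
    data.frame(time_h = c(0, 5), conc_pct = c(1, 1)),
    name = "always_on"
  )
  cfg <- synth_config(
    design = tibble::tibble(genotype = "wt", profile = "always_on", hxt = "HXT4"),
    profiles = list(always_on = prof), replicates = 2
  )
  raw <- generate_raw(cfg, seed = 1)
  expect_error(normalise_raw(raw), "pre-glucose")
})

test_that("configuration bounds are enforced", {
  expect_error(synth_config(replicates = 1), "between 2 and 5")
  expect_error(synth_config(replicates = 6), "between 2 and 5")
  expect_error(synth_config(meas_sd = -1), ">= 0")
  expect_error(
    synth_config(design = tibble::tibble(
      genotype = "wt", profile = "nope", hxt = "HXT4"
    )),
    "missing"
  )
})

test_that("galactose-history initial levels only lift the tagged Hxt", {
  cfg <- quiet_cfg(H0_galactose = c(HXT4 = 3))
  raw <- generate_raw(cfg, seed = 1)
  gt <- attr(raw, "ground_truth")
  expect_equal(gt$H[gt$time_h == 0][1], 3)
})

test_that("the reference calibration passes its qualitative constraint suite", {
  # mechanism class
  expect_true(mechanism_class(ref_params, ref_hxt4)$std1_snf1)
  # low-affinity HXT1 higher in 1 % than 0.01 %; high-affinity HXT7 opposite
  h1 <- vapply(c(0.01, 1), function(g) {
    steady_state(g, ref_params, ref_cal$promoters$HXT1)$H
  }, numeric(1))
  expect_gt(h1[2], h1[1])
  h7 <- vapply(c(0.01, 1), function(g) {
    steady_state(g, ref_params, ref_cal$promoters$HXT7)$H
  }, numeric(1))
  expect_gt(h7[1], h7[2])
  # deletion-strain orderings at the 1 % steady state
  h_at <- function(g, dels = character(0)) {
    steady_state(g, ref_params, ref_hxt4, dels)$H
  }
  expect_gt(h_at(0, "MTH1"), 3 * h_at(0)) # mth1Δ: much higher without glucose
  expect_gt(h_at(1, "MIG1"), 2 * h_at(1)) # mig1Δ: much higher in glucose
  expect_lt(h_at(1, "STD1"), h_at(1)) # std1Δ: reduced expression in glucose
  expect_lt(h_at(1, "SNF3"), h_at(1)) # snf3Δ: lower in glucose
  expect_gt(h_at(1, "RGT2"), h_at(1)) # rgt2Δ: higher in glucose
})
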