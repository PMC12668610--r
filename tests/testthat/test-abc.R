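# compact observed data for ABC tests: wild-type steady levels at three
# constant glucose concentrations plus the 1 % pulse series
abc_observed <- function(promoter, sem_frac = 0.08) {
  cal <- list(params = ref_params, promoters = list(HXT4 = promoter))
  dyn <- noiseless_dataset(design = pulse_series_design(), calibration = cal, dt_min = 15)
  stat <- steady_dataset(calibration = cal, sem_frac = sem_frac)
  ds <- dplyr::bind_rows(dyn, stat)
  ds$sem_au <- pmax(sem_frac * ds$mean_au, 0.02)
  as_hxt_dataset(
    ds,
    c(attr(dyn, "profiles"), attr(stat, "profiles"))
  )
}

test_that("allowed models follow the prior restriction", {
  restr <- default_prior_restriction()
  expect_length(allowed_models(restr, "HXT1"), 8) # Std1 required
  expect_length(allowed_models(restr, "HXT4"), 15) # unrestricted
  all_four <- prior_restriction("HXT9", required = list(hxt_repressors()))
  expect_length(allowed_models(all_four, "HXT9"), 1)
  expect_error(allowed_models(restr, "HXT5"), "not regulated")
  expect_error(
    prior_restriction("HXT1", required = list("Std1"), excluded = list("Std1")),
    "both required and excluded"
  )
  excl <- prior_restriction("HXT2", excluded = list(c("Mth1", "Std1", "Mig2")))
  expect_equal(
    vapply(allowed_models(excl, "HXT2"), structure_label, character(1)),
    "Mig1"
  )
})

test_that("the ABC distance behaves like an SEM-weighted L2 norm", {
  obs <- abc_observed(ref_hxt4)
  sim_perfect <- tibble::tibble(
    profile = obs$profile, time_h = obs$time_h, H = obs$mean_au
  )
  expect_equal(abc_distance(sim_perfect, obs), 0)

  sim_off <- sim_perfect
  sim_off$H[1] <- sim_off$H[1] + 1
  d1 <- abc_distance(sim_off, obs)
  expect_gt(d1, 0)
  sim_off$H[2] <- sim_off$H[2] + 1 # one more discrepant point
  expect_gt(abc_distance(sim_off, obs), d1)

  # doubling SEMs (above the floor) halves the distance
  obs_hi <- obs
  obs_hi$sem_au <- rep(1, nrow(obs))
  obs_2x <- obs
  obs_2x$sem_au <- rep(2, nrow(obs))
  expect_equal(
    abc_distance(sim_off, obs_hi, weight_floor_frac = 0),
    2 * abc_distance(sim_off, obs_2x, weight_floor_frac = 0)
  )

  bad <- tibble::tibble(profile = obs$profile[1], time_h = 1e4, H = 1)
  expect_error(
    abc_distance(bad, obs[obs$profile == obs$profile[1], ]),
    "disjoint"
  )
})

test_that("zero generations return the prior over models", {
  obs <- abc_observed(ref_hxt4)
  post <- abc_smc(obs, "HXT4", ref_params,
    config = abc_config(n_particles = 30, max_gen = 0), seed = 5
  )
  expect_equal(post$models$probability, rep(1 / 15, 15))
  expect_equal(sum(post$particles$weight), 1, tolerance = 1e-12)
})

test_that("posteriors are normalised, reproducible, with non-increasing tolerances", {
  obs <- abc_observed(ref_hxt4)
  cfg <- abc_config(n_particles = 50, max_gen = 4)
  p1 <- abc_smc(obs, "HXT4", ref_params, config = cfg, seed = 11)
  p2 <- abc_smc(obs, "HXT4", ref_params, config = cfg, seed = 11)
  expect_equal(sum(p1$models$probability), 1, tolerance = 1e-12)
  expect_true(all(p1$models$probability >= 0))
  expect_equal(p1$models$probability, p2$models$probability)
  expect_equal(p1$eps_history, p2$eps_history)
  expect_true(all(diff(p1$eps_history) <= 1e-12))
  # particle weights per structure sum to that structure's probability
  by_struct <- tapply(p1$particles$weight, p1$particles$structure, sum)
  expect_equal(
    unname(by_struct[p1$models$structure[p1$models$probability > 0]]),
    p1$models$probability[p1$models$probability > 0],
    tolerance = 1e-12
  )
  # effective sample size stays above the configured floor
  expect_true(all(
    p1$ess_history >= cfg$ess_floor * floor(cfg$alpha * cfg$n_particles) - 1e-9
  ))
})

test_that("the generating structure is recovered on a 3-candidate problem", {
  gen_structure <- c("Mig1", "Mig2")
  gen_promoter <- promoter_params(
    gen_structure,
    aH = ref_hxt4$aH, dHmax = ref_hxt4$dHmax, dHmin = ref_hxt4$dHmin,
    K_dH = ref_hxt4$K_dH, K = ref_hxt4$K[gen_structure],
    n = ref_hxt4$n[gen_structure]
  )
  obs <- abc_observed(gen_promoter)
  candidates <- list(c("Mig1", "Mig2"), "Mth1", "Std1")
  post <- abc_smc(obs, "HXT4", ref_params,
    config = abc_config(n_particles = 150, max_gen = 25),
    seed = 21, models = candidates
  )
  expect_equal(
    post$models$structure[which.max(post$models$probability)],
    "Mig1+Mig2"
  )
})

test_that("bootstrap repression summarises the posterior deterministically", {
  obs <- abc_observed(ref_hxt4)
  post <- abc_smc(obs, "HXT4", ref_params,
    config = abc_config(n_particles = 40, max_gen = 3), seed = 9
  )
  b1 <- bootstrap_repression(post, ref_params, n_samples = 50, seed = 3)
  b2 <- bootstrap_repression(post, ref_params, n_samples = 50, seed = 3)
  expect_equal(b1, b2)
  expect_true(all(b1$lo <= b1$mean & b1$mean <= b1$hi))
  expect_setequal(unique(b1$pair), c("MthStd", "MigMig"))

  # degenerate posterior (one particle) gives zero-width intervals
  post1 <- post
  post1$particles <- post1$particles[1, ]
  post1$particles$weight <- 1
  b3 <- bootstrap_repression(post1, ref_params, n_samples = 20, seed = 1)
  expect_equal(b3$lo, b3$hi)
  expect_equal(b3$lo, b3$mean)
})

test_that("reference-promoter repression shows the push-pull trend with glucose", {
  # a posterior concentrated on the calibrated HXT4 promoter
  obs <- abc_observed(ref_hxt4)
  post <- abc_smc(obs, "HXT4", ref_params,
    config = abc_config(n_particles = 30, max_gen = 2), seed = 2
  )
  post$particles <- post$particles[1, ]
  post$particles$weight <- 1
  post$particles$promoter[[1]] <- ref_hxt4
  b <- bootstrap_repression(post, ref_params,
    glucose_levels = c(0.01, 0.1, 1), n_samples = 10, seed = 1
  )
  mth <- b$mean[b$pair == "MthStd"][order(b$glucose_pct[b$pair == "MthStd"])]
  mig <- b$mean[b$pair == "MigMig"][order(b$glucose_pct[b$pair == "MigMig"])]
  expect_true(all(diff(mth) < 0))
  expect_true(all(diff(mig) > 0))
})

test_that("posteriors serialise to a JSON model table and CSV particle store", {
  obs <- abc_observed(ref_hxt4)
  post <- abc_smc(obs, "HXT4", ref_params,
    config = abc_config(n_particles = 30, max_gen = 2), seed = 4
  )
  d <- tempfile()
  write_posterior(post, d)
  models <- jsonlite::read_json(file.path(d, "models.json"), simplifyVector = TRUE)
  expect_equal(models$hxt, "HXT4")
  expect_equal(sum(models$models$probability), 1, tolerance = 1e-12)
  parts <- utils::read.csv(file.path(d, "particles.csv"))
  expect_equal(nrow(parts), nrow(post$particles))
  expect_equal(sum(parts$weight), 1, tolerance = 1e-12)
})

test_that("affinity-class summaries average the member HXTs", {
  s <- tibble::tibble(
    hxt = c("HXT1", "HXT3"), pair = "MthStd", glucose_pct = 0.01,
    mean = c(2, 4), lo = c(1, 3), hi = c(3, 5)
  )
  a <- affinity_repression(s)
  expect_equal(a$affinity, "low")
  expect_equal(a$mean, 3)
})
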