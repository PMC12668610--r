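test_that("sensor signal is a saturating Hill response", {
  expect_equal(sensor_signal(0, 0.1, 2), 0)
  expect_equal(sensor_signal(0.1, 0.1, 2), 0.5) # half-saturation
  expect_gt(sensor_signal(1e6, 0.1, 2), 1 - 1e-9) # saturation limit
  ge <- seq(0, 2, by = 0.05)
  expect_true(all(diff(sensor_signal(ge, 0.3, 3)) > 0)) # monotone
  expect_error(sensor_signal(-0.1, 0.1, 2), ">= 0")
  expect_error(sensor_signal(1, -1, 2), "K")
})

test_that("intracellular glucose follows the logistic onset law", {
  zero <- glucose_profile(data.frame(time_h = c(0, 10), conc_pct = c(0, 0)))
  expect_true(all(intracellular_glucose(seq(0, 10), zero, r_g = 5) == 0))

  const <- glucose_profile(data.frame(time_h = c(0, 100), conc_pct = c(0.5, 0.5)))
  # logistic plateau: gi -> gmax_scale * ge
  expect_equal(intracellular_glucose(100, const, r_g = 5, gmax_scale = 2), 1,
    tolerance = 1e-6
  )
  # closed-form half-rise time log((1 - L0)/L0)/r_g for L0 = 0.01
  r_g <- 3
  t_half <- log(99) / r_g
  gi <- intracellular_glucose(t_half, const, r_g = r_g, gmax_scale = 1, L0 = 0.01)
  expect_equal(gi, 0.5 * 0.5, tolerance = 1e-9)
  # numerically locate the half-rise and compare with the closed form
  tt <- seq(0, 10, by = 1e-4)
  gg <- intracellular_glucose(tt, const, r_g = r_g)
  expect_equal(tt[which.min(abs(gg - 0.25))], t_half, tolerance = 1e-3)

  # gi returns to zero when extracellular glucose does
  pulse <- glucose_pulse(plateau_pct = 1)
  expect_equal(intracellular_glucose(max(pulse$time_h), pulse, r_g = 5), 0)
  expect_error(intracellular_glucose(1, const, r_g = -1), "r_g")
})

test_that("SNF1 activity decreases with glucose and saturates in Std1", {
  p <- ref_params
  expect_equal(snf1_activity(0, 0, p), p$beta0)
  ge <- seq(0.01, 2, by = 0.01)
  expect_true(all(diff(snf1_activity(ge, 0.5, p)) < 0))
  # at the glucose half-repression point with saturating Std1
  expect_equal(
    snf1_activity(p$K_Ag, 1e9, p),
    (p$beta0 + p$beta1) / 2,
    tolerance = 1e-6
  )
  expect_error(snf1_activity(0, -1, p), "Std1")
})

test_that("the model reports five ODEs and one algebraic relation", {
  eq <- model_equations()
  expect_equal(sum(eq$type == "differential"), 5L)
  expect_equal(sum(eq$type == "algebraic"), 1L)
  expect_setequal(eq$variable, c("M", "S", "G1", "G2", "H", "gi"))
})

test_that("deletions zero exactly the right parameters", {
  expect_equal(apply_deletion(ref_params, character(0)), ref_params)
  snf3 <- apply_deletion(ref_params, "SNF3")
  expect_equal(snf3$dSnf3M, 0)
  expect_equal(snf3$koutSnf3S, 0)
  expect_equal(snf3$dRgt2M, ref_params$dRgt2M) # Rgt2 arm untouched
  expect_equal(snf3$koutRgt2S, ref_params$koutRgt2S)
  mth1 <- apply_deletion(ref_params, "MTH1")
  expect_equal(mth1$aM, 0)
  std1 <- apply_deletion(ref_params, "STD1")
  expect_equal(std1$ST, 0)
  expect_error(as_genotype("MIG2"), "unknown deletion")
  expect_equal(parse_genotype("mig1Δ"), "MIG1")
  expect_equal(genotype_label(character(0)), "wt")
})

test_that("the right-hand side vanishes at the analytic fixed point", {
  rhs <- pushpull:::make_rhs(
    glucose_profile(data.frame(time_h = c(0, 50), conc_pct = c(0, 0))),
    ref_params, ref_hxt4
  )
  ss <- steady_state(0, ref_params, ref_hxt4)
  d <- rhs(25, c(M = ss$M, S = ss$S, G1 = ss$G1, G2 = ss$G2, H = ss$H))[[1]]
  expect_lt(max(abs(d)), 1e-10)
  # unrepressed synthesis: with G1 = G2 = 0, dM/dt at M = 0 equals aM
  d0 <- rhs(25, c(M = 0, S = ss$S, G1 = 0, G2 = 0, H = 0))[[1]]
  expect_equal(d0[[1]], ref_params$aM)
})

test_that("glucose-free steady state stays constant under simulation", {
  zero <- glucose_profile(data.frame(time_h = c(0, 30), conc_pct = c(0, 0)))
  tr <- simulate_hxt(character(0), zero, ref_params, ref_hxt4,
    t_grid = seq(0, 30, by = 0.5)
  )
  for (v in c("M", "S", "G1", "G2", "H")) {
    expect_lt(diff(range(tr[[v]])), 1e-5 * max(abs(tr[[v]])))
  }
})

test_that("mig1 deletion pins nuclear Mig1 at zero along the trajectory", {
  tr <- simulate_hxt("MIG1", pulse_1pct, ref_params, ref_hxt4)
  expect_true(all(tr$G1 == 0))
})

test_that("trajectories respect non-negativity and the box bounds", {
  for (g in list(character(0), "MTH1", "STD1", "MIG1", "SNF3", "RGT2")) {
    tr <- simulate_hxt(g, pulse_1pct, ref_params, ref_hxt4)
    expect_true(all(tr$M >= 0 & tr$S >= 0 & tr$G1 >= 0 & tr$G2 >= 0 & tr$H >= 0))
    expect_true(all(tr$S <= ref_params$ST + 1e-8))
    expect_true(all(tr$G1 <= ref_params$G1T + 1e-8))
  }
})

test_that("mth1 deletion lifts glucose-free expression above wild type", {
  h_wt <- steady_state(0, ref_params, ref_hxt4)$H
  h_mth1 <- steady_state(0, ref_params, ref_hxt4, "MTH1")$H
  expect_gt(h_mth1, h_wt)
})

test_that("wild-type Hxt4 spikes after glucose removal under a 1 % pulse", {
  tr <- simulate_hxt(character(0), pulse_1pct, ref_params, ref_hxt4)
  t_drop <- 3 + 1 / 1.5 + 8
  plateau_h <- max(tr$H[tr$time_h >= t_drop - 2 & tr$time_h <= t_drop])
  post_peak <- max(tr$H[tr$time_h > t_drop])
  expect_gt(post_peak, plateau_h)
})

test_that("push-pull monotonicity holds at steady state across glucose", {
  grid <- seq(0, 1, length.out = 20)
  sc <- steady_state_curve(grid, ref_params, ref_hxt4)
  expect_true(all(diff(sc$M + sc$S) <= 1e-9))
  expect_true(all(diff(sc$G1 + sc$G2) >= -1e-9))
})

test_that("root-finding steady state matches the long-time simulation", {
  set.seed(101)
  for (i in 1:15) {
    p <- random_signalling()
    pr <- random_promoter(sample(hxt_repressors(), sample(1:4, 1)))
    g <- runif(1, 0, 1)
    t_end <- relaxation_horizon(p, pr, g)
    const <- glucose_profile(data.frame(time_h = c(0, t_end), conc_pct = c(g, g)))
    ss <- steady_state(g, p, pr)
    tr <- simulate_hxt(character(0), const, p, pr,
      t_grid = c(0, t_end / 2, t_end), rtol = 1e-10, atol = 1e-12,
      y0 = c(
        M = ss$M * 2 + 0.1, S = min(ss$S * 1.5, p$ST),
        G1 = min(ss$G1 * 1.5, p$G1T), G2 = ss$G2 * 2 + 0.1, H = ss$H * 2 + 0.1
      )
    )
    v_ss <- unlist(ss[c("M", "S", "G1", "G2", "H")])
    v_tr <- unlist(tr[3, c("M", "S", "G1", "G2", "H")])
    expect_lt(max(abs(v_ss - v_tr) / (abs(v_ss) + 1e-9)), 1e-6)
  }
})

test_that("halving solver tolerances leaves trajectories essentially unchanged", {
  tr1 <- simulate_hxt(character(0), pulse_1pct, ref_params, ref_hxt4)
  tr2 <- simulate_hxt(character(0), pulse_1pct, ref_params, ref_hxt4,
    rtol = 5e-7, atol = 5e-10
  )
  expect_lt(max(abs(tr1$H - tr2$H)) / max(tr1$H), 1e-5)
})

test_that("response time recovers the closed form for exponential relaxation", {
  k <- 2.5
  tt <- seq(0, 5, by = 0.01)
  df <- tibble::tibble(time_h = tt, y = exp(-k * tt))
  expect_equal(response_time(df, "y", c(0, 5)), log(2) / k, tolerance = 1e-3)
  flat <- tibble::tibble(time_h = tt, y = rep(1, length(tt)))
  expect_error(
    response_time(flat, "y", c(0, 5)),
    class = "pushpull_flat_trajectory"
  )
})

test_that("Mig1/Mig2 respond over twice as fast as Mth1/Std1 at 1 %", {
  tr <- simulate_hxt(character(0), pulse_1pct, ref_params, ref_hxt4)
  rs <- pair_response_summary(tr)
  expect_equal(nrow(rs), 2L)
  expect_true(all(rs$ratio >= 2))
})

test_that("std1 deletion lowers SNF1 activity and raises nuclear Mig1 in glucose", {
  ss_wt <- steady_state(1, ref_params, ref_hxt4)
  ss_std1 <- steady_state(1, ref_params, ref_hxt4, "STD1")
  expect_lt(ss_std1$A, ss_wt$A)
  expect_gt(ss_std1$G1, ss_wt$G1)
})

test_that("r_g resolution honours the per-condition table", {
  expect_equal(resolve_rg(ref_params, character(0), 1), 7)
  expect_equal(resolve_rg(ref_params, character(0), 0.2), 5)
  expect_equal(resolve_rg(ref_params, character(0), 99), ref_params$r_g)
  p0 <- model_params()
  expect_equal(resolve_rg(p0, "MTH1", 1), p0$r_g)
})

test_that("model parameters serialise to flat JSON and back", {
  f <- tempfile(fileext = ".json")
  write_model_params(ref_params, f)
  back <- read_model_params(f)
  expect_equal(back$aM, ref_params$aM)
  expect_equal(back$snf1_glucose, ref_params$snf1_glucose)
  expect_equal(nrow(back$r_g_table), nrow(ref_params$r_g_table))
})
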