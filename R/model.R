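#' Sensor glucose response
#'
#' Saturating Hill response of a glucose sensor (Snf3 or Rgt2):
#' `ge^h / (K^h + ge^h)`, zero without glucose and approaching one in
#' saturating glucose.
#'
#' @param ge Extracellular glucose (% w/v), >= 0; vectorised.
#' @param K Half-saturation (% w/v), > 0.
#' @param h Hill number, >= 1.
#' @return Values in `[0, 1)`.
#' @export
sensor_signal <- function(ge, K, h) {
  if (K <= 0) rlang::abort("sensor half-saturation K must be > 0")
  if (h < 1) rlang::abort("sensor Hill number must be >= 1")
  if (any(ge < 0)) rlang::abort("extracellular glucose must be >= 0")
  x <- (ge / K)^h
  x / (1 + x)
}

logistic_ramp <- function(tau, r_g, L0) {
  # rises from L0 at tau = 0 to 1; half-rise at log((1 - L0)/L0)/r_g
  out <- 1 / (1 + ((1 - L0) / L0) * exp(-r_g * tau))
  out[tau < 0] <- 0
  out
}

#' Intracellular glucose (the model's algebraic relation)
#'
#' Intracellular glucose is minimal unless extracellular glucose is present;
#' once glucose appears (the most recent zero-to-positive onset of the
#' programme, at `t_on`), it follows
#' `gi(t) = gmax_scale * ge(t) * L(t - t_on)`, where `L` is a logistic ramp
#' rising from `L0` to 1 with growth rate `r_g` — the transporters themselves
#' must accumulate before import saturates. When extracellular glucose
#' returns to zero so does `gi`.
#'
#' @param t Times (h); vectorised.
#' @param profile A [glucose_profile()].
#' @param r_g Logistic growth rate (1/h), > 0.
#' @param gmax_scale Ceiling per unit extracellular glucose.
#' @param L0 Logistic seed in (0, 1).
#' @return Intracellular glucose, same units as `gmax_scale * ge`.
#' @export
intracellular_glucose <- function(t, profile, r_g, gmax_scale = 1, L0 = 0.01) {
  if (r_g <= 0) rlang::abort("r_g must be > 0")
  onsets <- glc_onsets(profile)
  ge <- glc_at(profile, t)
  if (length(onsets) == 0) return(rep(0, length(t)))
  t_on <- vapply(t, function(ti) {
    prev <- onsets[onsets <= ti]
    if (length(prev) == 0) NA_real_ else max(prev)
  }, numeric(1))
  L <- ifelse(is.na(t_on), 0, logistic_ramp(t - t_on, r_g, L0))
  gmax_scale * ge * L
}

#' SNF1 kinase activity
#'
#' `A = K_Ag^h_A / (K_Ag^h_A + g^h_A) * (beta0 + beta1 * S / (S + K_AS))`:
#' strictly decreasing in glucose `g` and strictly increasing in nuclear Std1
#' `S`. Which glucose pool `g` is (extracellular by default, or
#' intracellular) is set by `params$snf1_glucose`; callers pass the matching
#' value.
#'
#' @param g Glucose seen by SNF1 (>= 0); vectorised.
#' @param S Nuclear Std1 (>= 0); vectorised.
#' @param params A [model_params()].
#' @return Activity (dimensionless, >= 0).
#' @export
snf1_activity <- function(g, S, params) {
  if (any(S < 0)) rlang::abort("Std1 level must be >= 0")
  Kh <- params$K_Ag^params$h_A
  (Kh / (Kh + g^params$h_A)) * (params$beta0 + params$beta1 * S / (S + params$K_AS))
}

mig2_degradation <- function(g, params) {
  params$dG2min + (params$dG2max - params$dG2min) * params$K_dG2 / (params$K_dG2 + g)
}

hxt_degradation <- function(ge, promoter) {
  promoter$dHmin + (promoter$dHmax - promoter$dHmin) * promoter$K_dH / (promoter$K_dH + ge)
}

#' The model's equations
#'
#' Reports the structure of the mechanistic model: five differential state
#' equations (Mth1 `M`, nuclear Std1 `S`, nuclear Mig1 `G1`, Mig2 `G2`,
#' tagged Hxt `H`) and one algebraic relation (intracellular glucose `gi`).
#' SNF1 activity `A` is an inline algebraic expression, not a state.
#'
#' @param deletions Deletion set (kept for symmetry; deletions zero parameters
#'   but do not remove equations).
#' @return A tibble with columns `variable`, `type`, `description`.
#' @export
model_equations <- function(deletions = character(0)) {
  as_genotype(deletions)
  tibble::tibble(
    variable = c("M", "S", "G1", "G2", "H", "gi"),
    type = c(rep("differential", 5), "algebraic"),
    description = c(
      "Mth1: synthesis repressed by nuclear Mig1/Mig2; basal + sensor-mediated degradation",
      "nuclear Std1: import of cytoplasmic pool (total constant); basal + sensor-mediated export",
      "nuclear Mig1: import of cytoplasmic pool (total constant); export basal + proportional to SNF1 activity",
      "Mig2: synthesis repressed by Mth1/Std1; degradation a decreasing function of glucose",
      "tagged Hxt: promoter transcription rate aH/(1+W); degradation faster without glucose",
      "intracellular glucose: logistic rise after glucose onset, amplitude tracking extracellular glucose"
    )
  )
}

# fast closure-based right-hand side for one (genotype, profile) context
make_rhs <- function(profile, params, promoter, deletions = character(0)) {
  p <- apply_deletion(params, deletions)
  ge_fun <- if (nrow(profile) == 1) {
    function(t) rep(profile$conc_pct[[1]], length(t))
  } else {
    stats::approxfun(profile$time_h, profile$conc_pct, rule = 2)
  }
  onsets <- glc_onsets(profile)
  r_g <- resolve_rg(p, deletions, glc_plateau(profile))
  struct <- promoter$structure
  idx <- match(struct, c("Mth1", "Std1", "Mig1", "Mig2"))
  Kp <- promoter$K
  np <- promoter$n
  snf1_intra <- identical(p$snf1_glucose, "intracellular")
  mig2_extra <- identical(p$mig2_glucose, "extracellular")

  gi_at <- function(t, ge) {
    if (length(onsets) == 0) return(0)
    prev <- onsets[onsets <= t]
    if (length(prev) == 0) return(0)
    p$gmax_scale * ge * logistic_ramp(t - max(prev), r_g, p$L0)
  }

  function(t, y, ...) {
    y <- pmax(y, 0)
    M <- y[[1]]; S <- y[[2]]; G1 <- y[[3]]; G2 <- y[[4]]; H <- y[[5]]
    ge <- ge_fun(t)
    gi <- gi_at(t, ge)
    s3 <- sensor_signal(ge, p$K_snf3, p$h_snf3)
    r2 <- sensor_signal(ge, p$K_rgt2, p$h_rgt2)
    A <- snf1_activity(if (snf1_intra) gi else ge, S, p)
    dM <- p$aM / (1 + (G1 / p$K_M_mig1)^p$n_M + (G2 / p$K_M_mig2)^p$n_M) -
      (p$d0M + p$dSnf3M * s3 + p$dRgt2M * r2) * M
    dS <- p$kinS * (p$ST - S) -
      (p$kout0S + p$koutSnf3S * s3 + p$koutRgt2S * r2) * S
    dG1 <- p$kinG1 * (p$G1T - G1) - (p$e0 + p$e1 * A) * G1
    dG2 <- p$aG2 / (1 + (M / p$K_G2_mth1)^p$n_G2 + (S / p$K_G2_std1)^p$n_G2) -
      mig2_degradation(if (mig2_extra) ge else gi, p) * G2
    lev <- c(M, S, G1, G2)[idx]
    W <- sum((lev / Kp)^np)
    dH <- promoter$aH / (1 + W) - hxt_degradation(ge, promoter) * H
    list(c(dM, dS, dG1, dG2, dH), ge = ge, gi = gi, A = A)
  }
}

#' Steady state at constant glucose
#'
#' Solves the model's fixed point at a constant extracellular glucose
#' concentration. Nuclear Std1 and Mig1 have closed-form steady states; Mth1
#' and Mig2, which mutually repress, are solved by a damped fixed-point
#' iteration with a Newton fallback; the tagged Hxt then follows explicitly.
#' Intracellular glucose is taken at its plateau `gmax_scale * ge`
#' (zero when `ge = 0`).
#'
#' @param ge Constant extracellular glucose (% w/v), scalar >= 0.
#' @param params A [model_params()].
#' @param promoter A [promoter_params()].
#' @param deletions Deletion set.
#' @param tol Convergence tolerance on the (M, G2) iteration.
#' @return One-row tibble with columns `ge, M, S, G1, G2, H, gi, A`.
#' @export
steady_state <- function(ge, params, promoter, deletions = character(0),
                         tol = 1e-13) {
  stopifnot(length(ge) == 1, ge >= 0)
  p <- apply_deletion(params, deletions)
  s3 <- sensor_signal(ge, p$K_snf3, p$h_snf3)
  r2 <- sensor_signal(ge, p$K_rgt2, p$h_rgt2)
  gi <- p$gmax_scale * ge
  S <- p$kinS * p$ST /
    (p$kinS + p$kout0S + p$koutSnf3S * s3 + p$koutRgt2S * r2)
  A <- snf1_activity(if (identical(p$snf1_glucose, "intracellular")) gi else ge, S, p)
  G1 <- p$kinG1 * p$G1T / (p$kinG1 + p$e0 + p$e1 * A)
  degM <- p$d0M + p$dSnf3M * s3 + p$dRgt2M * r2
  dg2 <- mig2_degradation(if (identical(p$mig2_glucose, "extracellular")) ge else gi, p)
  f_M <- function(G2) {
    p$aM / (1 + (G1 / p$K_M_mig1)^p$n_M + (G2 / p$K_M_mig2)^p$n_M) / degM
  }
  f_G2 <- function(M) {
    p$aG2 / (1 + (M / p$K_G2_mth1)^p$n_G2 + (S / p$K_G2_std1)^p$n_G2) / dg2
  }
  M <- f_M(0)
  G2 <- f_G2(M)
  ok <- FALSE
  for (i in seq_len(1000)) {
    M_new <- 0.5 * (M + f_M(G2))
    G2_new <- 0.5 * (G2 + f_G2(M_new))
    if (max(abs(M_new - M), abs(G2_new - G2)) <
        tol * max(1, abs(M_new), abs(G2_new))) {
      M <- M_new
      G2 <- G2_new
      ok <- TRUE
      break
    }
    M <- M_new
    G2 <- G2_new
  }
  if (!ok) {
    # Newton on the 2-d residual, numerical Jacobian
    res <- function(x) c(x[1] - f_M(x[2]), x[2] - f_G2(x[1]))
    x <- c(M, G2)
    for (i in seq_len(100)) {
      r0 <- res(x)
      if (max(abs(r0)) < tol * max(1, max(abs(x)))) break
      J <- matrix(0, 2, 2)
      hstep <- pmax(abs(x), 1e-8) * 1e-7
      for (j in 1:2) {
        xj <- x
        xj[j] <- xj[j] + hstep[j]
        J[, j] <- (res(xj) - r0) / hstep[j]
      }
      x <- x - solve(J, r0)
      x <- pmax(x, 0)
    }
    M <- x[1]
    G2 <- x[2]
  }
  lev <- c(Mth1 = M, Std1 = S, Mig1 = G1, Mig2 = G2)
  H <- transcription_rate(lev, promoter) / hxt_degradation(ge, promoter)
  tibble::tibble(ge = ge, M = M, S = S, G1 = G1, G2 = G2, H = H, gi = gi, A = A)
}

#' Steady states over a glucose grid
#'
#' Convenience wrapper mapping [steady_state()] over a vector of constant
#' glucose concentrations; used for the push-pull monotonicity analysis and
#' the repression summaries.
#'
#' @param ge_grid Vector of constant glucose concentrations (% w/v).
#' @inheritParams steady_state
#' @return Tibble, one row per concentration, with the [steady_state()]
#'   columns plus pair repression weights `W_MthStd` and `W_MigMig`.
#' @export
steady_state_curve <- function(ge_grid, params, promoter,
                               deletions = character(0)) {
  purrr::map_dfr(ge_grid, function(g) {
    ss <- steady_state(g, params, promoter, deletions)
    lev <- c(Mth1 = ss$M, Std1 = ss$S, Mig1 = ss$G1, Mig2 = ss$G2)
    ss$W_MthStd <- pair_repression(lev, promoter, "MthStd")
    ss$W_MigMig <- pair_repression(lev, promoter, "MigMig")
    ss
  })
}

#' Simulate the network under a glucose programme
#'
#' Integrates the five-state ODE model from the glucose-free steady state
#' (cells pre-grown without glucose) unless `y0` overrides it, sampling on the
#' experimental 5-minute grid by default. Uses a stiff-capable solver
#' (`deSolve`, lsoda) with tight tolerances; identical inputs give identical
#' trajectories.
#'
#' @param deletions Deletion set (see [as_genotype()]).
#' @param profile A [glucose_profile()].
#' @param params A [model_params()].
#' @param promoter A [promoter_params()].
#' @param t_grid Output times (h), increasing; default 5-min grid over the
#'   profile.
#' @param y0 Optional named initial state `c(M, S, G1, G2, H)`; default the
#'   glucose-free steady state. Galactose pre-growth is emulated by
#'   overriding `H0` only.
#' @param H0 Optional initial Hxt level overriding the steady-state value.
#' @param rtol,atol Solver tolerances.
#' @return An `hxt_trajectory`: a tibble with columns
#'   `time_h, M, S, G1, G2, H, ge, gi, A` and attributes `genotype`,
#'   `profile_name`, `promoter`, `profile`.
#' @export
simulate_hxt <- function(deletions, profile, params, promoter,
                         t_grid = NULL, y0 = NULL, H0 = NULL,
                         rtol = 1e-6, atol = 1e-9) {
  deletions <- as_genotype(deletions)
  if (is.null(t_grid)) {
    t_grid <- seq(0, max(profile$time_h), by = 5 / 60)
  }
  if (is.unsorted(t_grid, strictly = TRUE)) {
    rlang::abort("t_grid must be strictly increasing")
  }
  if (is.null(y0)) {
    ss0 <- steady_state(glc_at(profile, t_grid[1]), params, promoter, deletions)
    y0 <- c(M = ss0$M, S = ss0$S, G1 = ss0$G1, G2 = ss0$G2, H = ss0$H)
  } else {
    y0 <- y0[c("M", "S", "G1", "G2", "H")]
  }
  if (!is.null(H0)) y0[["H"]] <- H0
  rhs <- make_rhs(profile, params, promoter, deletions)
  sol <- deSolve::ode(
    y = y0, times = t_grid, func = rhs, parms = NULL,
    method = "lsoda", rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1] < 0 || nrow(sol) < length(t_grid)) {
    rlang::abort(
      paste0(
        "ODE solver failed for genotype ", genotype_label(deletions),
        " under profile ", attr(profile, "name") %||% "?"
      ),
      class = "pushpull_solver_failure"
    )
  }
  out <- tibble::as_tibble(as.data.frame(sol))
  names(out)[1] <- "time_h"
  out$M <- pmax(out$M, 0)
  out$S <- pmax(out$S, 0)
  out$G1 <- pmax(out$G1, 0)
  out$G2 <- pmax(out$G2, 0)
  out$H <- pmax(out$H, 0)
  structure(
    out,
    genotype = genotype_label(deletions),
    profile_name = attr(profile, "name") %||% "profile",
    promoter = structure_label(promoter$structure),
    profile = profile,
    class = c("hxt_trajectory", class(tibble::tibble()))
  )
}

#' Half-change response time
#'
#' Time from the start of `window` until `variable` completes half of its
#' total change within the window, by linear interpolation between sampled
#' points. Intended for windows in which the variable relaxes monotonically
#' after a perturbation; for a pure exponential relaxation with rate `k` it
#' returns `log(2)/k`.
#'
#' @param trajectory An `hxt_trajectory` (or any data frame with `time_h` and
#'   the variable).
#' @param variable State column name, e.g. `"M"`.
#' @param window Length-2 numeric `c(start, end)` (h).
#' @return Duration (h).
#' @export
response_time <- function(trajectory, variable, window) {
  stopifnot(length(window) == 2, window[2] > window[1])
  df <- trajectory[trajectory$time_h >= window[1] & trajectory$time_h <= window[2], ]
  if (nrow(df) < 3) rlang::abort("window contains too few time points")
  y <- df[[variable]]
  tt <- df$time_h
  total <- y[length(y)] - y[1]
  if (abs(total) <= 1e-9 * max(abs(y), 1e-12)) {
    rlang::abort(
      paste0("variable ", variable, " is flat in the window; no response time defined"),
      class = "pushpull_flat_trajectory"
    )
  }
  target <- y[1] + 0.5 * total
  crossed <- if (total > 0) y >= target else y <= target
  i <- which(crossed)[1]
  if (is.na(i)) {
    rlang::abort("variable never reaches half of its total change",
      class = "pushpull_flat_trajectory"
    )
  }
  if (i == 1) return(0)
  # linear interpolation between the bracketing samples
  t_half <- tt[i - 1] + (target - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
  t_half - window[1]
}

#' Repressor response times over the rising and falling phases of a pulse
#'
#' Splits a pulse experiment into a rising phase (glucose onset to the start
#' of the falling ramp) and a falling phase (start of the falling ramp to the
#' end), and computes the half-change [response_time()] of each repressor
#' state in each phase. The mean over the Mth1/Std1 pair versus the
#' Mig1/Mig2 pair quantifies the timescale separation that creates the
#' expression spike in falling glucose.
#'
#' @param trajectory An `hxt_trajectory` from [simulate_hxt()] whose profile
#'   is a single pulse.
#' @return Tibble with columns `variable`, `phase`, `response_h`.
#' @export
repressor_response_times <- function(trajectory) {
  profile <- attr(trajectory, "profile")
  if (is.null(profile)) rlang::abort("trajectory carries no glucose profile")
  plateau <- glc_plateau(profile)
  if (plateau <= 0) rlang::abort("profile has no glucose pulse")
  onsets <- glc_onsets(profile)
  at_plateau <- profile$time_h[profile$conc_pct >= plateau - 1e-12]
  t_on <- onsets[1]
  t_drop <- max(at_plateau)
  t_end <- max(trajectory$time_h)
  phases <- list(rising = c(t_on, t_drop), falling = c(t_drop, t_end))
  purrr::map_dfr(c("M", "S", "G1", "G2"), function(v) {
    purrr::map_dfr(names(phases), function(ph) {
      tibble::tibble(
        variable = v, phase = ph,
        response_h = response_time(trajectory, v, phases[[ph]])
      )
    })
  })
}

#' Pair response-time summary
#'
#' Mean response time of the Mth1/Std1 pair and of the Mig1/Mig2 pair in each
#' phase of a pulse, plus their ratio (Mth/Std over Mig/Mig).
#'
#' @inheritParams repressor_response_times
#' @return Tibble with columns `phase`, `mth_std_h`, `mig_mig_h`, `ratio`.
#' @export
pair_response_summary <- function(trajectory) {
  rt <- repressor_response_times(trajectory)
  rt$pair <- ifelse(rt$variable %in% c("M", "S"), "mth_std", "mig_mig")
  out <- rt |>
    dplyr::group_by(.data$phase, .data$pair) |>
    dplyr::summarise(mean_h = mean(.data$response_h), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "mean_h")
  out$ratio <- out$mth_std / out$mig_mig
  dplyr::select(out, phase = "phase", mth_std_h = "mth_std",
                mig_mig_h = "mig_mig", ratio = "ratio")
}
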