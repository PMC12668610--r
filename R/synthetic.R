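#' Synthetic-experiment configuration
#'
#' Describes an in-silico microfluidics experiment: which strain/programme
#' combinations are run, how often chambers are imaged, how many replicate
#' devices are used, and the noise model that corrupts the ground-truth
#' fluorescence. Defaults emulate the real measurements: 5-minute sampling,
#' 2-5 replicates, an autofluorescence offset that drifts slowly (a
#' stationary AR(1) held positive), a per-replicate multiplicative day effect,
#' and i.i.d. additive measurement noise sized so replicate SEMs are roughly
#' 5-10 % of the signal range.
#'
#' @param design A data frame with columns `genotype` (strain label, see
#'   [genotype_label()]), `profile` (name into `profiles`), `hxt` (tagged
#'   gene, e.g. `"HXT4"`). Defaults to [deletion_panel_design()].
#' @param profiles Named list of [glucose_profile()]s covering
#'   `design$profile`.
#' @param replicates Replicate count per design row, between 2 and 5.
#' @param dt_min Imaging interval (minutes).
#' @param autofluor_mean,autofluor_sd Mean and stationary sd of the
#'   autofluorescence offset (a.u.).
#' @param autofluor_rho AR(1) coefficient per frame of the autofluorescence
#'   drift (close to 1 = slow drift).
#' @param day_sd Standard deviation of the log day effect (multiplicative,
#'   shared by all chambers of one replicate device).
#' @param meas_sd Additive measurement noise sd (a.u.).
#' @param H0_galactose Optional named vector of initial Hxt levels emulating
#'   galactose pre-growth (e.g. `c(HXT7 = 1)`); default none.
#' @param calibration Ground-truth calibration, default
#'   [reference_calibration()].
#' @return A `synth_config` list.
#' @export
synth_config <- function(design = deletion_panel_design(),
                         profiles = standard_profiles(),
                         replicates = 3,
                         dt_min = 5,
                         autofluor_mean = 0.3, autofluor_sd = 0.05,
                         autofluor_rho = 0.95,
                         day_sd = 0.08, meas_sd = 0.15,
                         H0_galactose = NULL,
                         calibration = reference_calibration()) {
  if (replicates < 2 || replicates > 5) {
    rlang::abort("replicate count must be between 2 and 5")
  }
  if (any(c(autofluor_sd, day_sd, meas_sd) < 0)) {
    rlang::abort("noise standard deviations must be >= 0")
  }
  miss <- setdiff(unique(design$profile), names(profiles))
  if (length(miss) > 0) {
    rlang::abort(paste0("profiles missing from `profiles`: ", paste(miss, collapse = ", ")))
  }
  structure(
    list(
      design = tibble::as_tibble(design), profiles = profiles,
      replicates = replicates, dt_min = dt_min,
      autofluor_mean = autofluor_mean, autofluor_sd = autofluor_sd,
      autofluor_rho = autofluor_rho, day_sd = day_sd, meas_sd = meas_sd,
      H0_galactose = H0_galactose, calibration = calibration
    ),
    class = "synth_config"
  )
}

#' Standard glucose programmes
#'
#' The pulse programmes used throughout: 3 h glucose-free lead-in, linear rise
#' at 1.5 %/h to a plateau of 0.2, 0.4 or 1 % held for 8 h, linear fall at
#' 2 %/h, then a glucose-free tail.
#'
#' @param plateaus Plateau concentrations (% w/v).
#' @return Named list of [glucose_profile()]s (`"pulse_0.2pct"`, ...).
#' @export
standard_profiles <- function(plateaus = c(0.2, 0.4, 1)) {
  profs <- lapply(plateaus, function(pc) glucose_pulse(plateau_pct = pc))
  stats::setNames(profs, vapply(profs, function(p) attr(p, "name"), character(1)))
}

#' Experiment designs
#'
#' `deletion_panel_design()` is the joint calibration design: the wild type and the
#' five single-deletion strains (snf3Δ, rgt2Δ, mth1Δ, std1Δ, mig1Δ), each
#' carrying tagged HXT4, under pulses to 0.2, 0.4 and 1 % glucose.
#' `pulse_series_design()` is the single-strain dynamic series: wild type with one
#' tagged HXT under the 1 % pulse.
#'
#' @param hxt Tagged gene for `pulse_series_design()`.
#' @return Tibble with columns `genotype`, `profile`, `hxt`.
#' @export
deletion_panel_design <- function() {
  tidyr::crossing(
    genotype = c("wt", "snf3Δ", "rgt2Δ", "mth1Δ", "std1Δ", "mig1Δ"),
    profile = names(standard_profiles()),
    hxt = "HXT4"
  )
}

#' @rdname deletion_panel_design
#' @export
pulse_series_design <- function(hxt = "HXT4") {
  tibble::tibble(genotype = "wt", profile = "pulse_1pct", hxt = hxt)
}

ar1_positive <- function(n, mean, sd, rho) {
  if (sd == 0) return(rep(mean, n))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, mean, sd)
  innov_sd <- sd * sqrt(1 - rho^2)
  for (i in seq_len(n - 1)) {
    x[i + 1] <- mean + rho * (x[i] - mean) + stats::rnorm(1, 0, innov_sd)
  }
  pmax(x, 0)
}

#' Generate raw synthetic fluorescence
#'
#' Simulates the ground-truth trajectory for every design row, then corrupts
#' it the way the microscope sees it: adds a slowly drifting autofluorescence
#' offset, multiplies by a per-replicate day effect, and adds i.i.d.
#' measurement noise. Two control chambers are emitted per replicate: an
#' untagged autofluorescence control (offset + noise only) and a Mig1-GFP
#' normalisation control whose underlying signal is the constant total Mig1,
#' fixed at 1 model unit, so normalised data come out on the model scale.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed; same seed, same output.
#' @return A `raw_fluorescence` tibble with columns `genotype, profile, hxt,
#'   replicate, chamber, time_h, fluor_au`; attributes carry the ground-truth
#'   trajectories and the profile list.
#' @export
generate_raw <- function(config, seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  cal <- config$calibration
  design <- config$design
  truth <- purrr::pmap(design, function(genotype, profile, hxt) {
    prof <- config$profiles[[profile]]
    H0 <- config$H0_galactose[[hxt]] %||% NULL
    tr <- simulate_hxt(
      parse_genotype(genotype), prof, cal$params, cal$promoters[[hxt]],
      t_grid = seq(0, max(prof$time_h), by = config$dt_min / 60),
      H0 = H0
    )
    tibble::tibble(
      genotype = genotype, profile = profile, hxt = hxt,
      time_h = tr$time_h, H = tr$H
    )
  })
  names(truth) <- paste(design$genotype, design$profile, design$hxt)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  rows <- purrr::map_dfr(truth, function(tr) {
    purrr::map_dfr(seq_len(config$replicates), function(rep_i) {
      n <- nrow(tr)
      day <- exp(stats::rnorm(1, 0, config$day_sd))
      a <- ar1_positive(n, config$autofluor_mean, config$autofluor_sd, config$autofluor_rho)
      noise <- function() stats::rnorm(n, 0, config$meas_sd)
      tagged <- day * tr$H + a + noise()
      autofluor <- a + noise()
      normctrl <- day * 1 + a + noise()
      tibble::tibble(
        genotype = tr$genotype[[1]], profile = tr$profile[[1]], hxt = tr$hxt[[1]],
        replicate = rep_i,
        chamber = rep(c("tagged", "autofluorescence", "normalisation"), each = n),
        time_h = rep(tr$time_h, 3),
        fluor_au = c(tagged, autofluor, normctrl)
      )
    })
  })
  structure(
    rows,
    ground_truth = dplyr::bind_rows(truth),
    profiles = config$profiles,
    class = c("raw_fluorescence", class(tibble::tibble()))
  )
}

#' Normalise raw fluorescence into an experiment dataset
#'
#' Applies the measurement-correction procedure: subtract the
#' autofluorescence-chamber signal pointwise, then divide by the scalar
#' pre-glucose mean of the (autofluorescence-corrected) normalisation-control
#' chamber, per replicate; finally average replicates and compute the SEM per
#' time point. The day effect multiplies every chamber of a device equally,
#' so it cancels exactly.
#'
#' @param raw A `raw_fluorescence` from [generate_raw()].
#' @param profiles Named list of profiles (default: carried on `raw`), used to
#'   find each programme's pre-glucose window.
#' @return An `hxt_dataset` tibble: `genotype, profile, hxt, time_h, mean_au,
#'   sem_au, n_rep`, with the profile list attached as an attribute.
#' @export
normalise_raw <- function(raw, profiles = attr(raw, "profiles")) {
  if (is.null(profiles)) rlang::abort("no glucose profiles supplied")
  wide <- tidyr::pivot_wider(
    tibble::as_tibble(raw),
    names_from = "chamber", values_from = "fluor_au"
  )
  per_rep <- wide |>
    dplyr::group_by(.data$genotype, .data$profile, .data$hxt, .data$replicate) |>
    dplyr::group_modify(function(df, key) {
      prof <- profiles[[key$profile]]
      onsets <- glc_onsets(prof)
      t_on <- if (length(onsets) > 0) onsets[1] else max(df$time_h) + 1
      pre <- df$time_h < t_on - 1e-9
      if (!any(pre)) rlang::abort("empty pre-glucose window; cannot normalise")
      ctrl <- mean(df$normalisation[pre] - df$autofluorescence[pre])
      tibble::tibble(
        time_h = df$time_h,
        norm_au = (df$tagged - df$autofluorescence) / ctrl
      )
    }) |>
    dplyr::ungroup()
  out <- per_rep |>
    dplyr::group_by(.data$genotype, .data$profile, .data$hxt, .data$time_h) |>
    dplyr::summarise(
      mean_au = mean(.data$norm_au),
      sem_au = stats::sd(.data$norm_au) / sqrt(dplyr::n()),
      n_rep = dplyr::n(),
      .groups = "drop"
    )
  as_hxt_dataset(out, profiles)
}

#' Construct or validate an experiment dataset
#'
#' An `hxt_dataset` holds population-mean fluorescence time series: one row
#' per (strain, glucose programme, tagged HXT, time point) with the replicate
#' mean and SEM. The glucose programmes are attached as an attribute keyed by
#' the `profile` column.
#'
#' @param x A data frame with columns `genotype, profile, hxt, time_h,
#'   mean_au, sem_au`.
#' @param profiles Named list of [glucose_profile()]s.
#' @return An `hxt_dataset`.
#' @export
as_hxt_dataset <- function(x, profiles) {
  need <- c("genotype", "profile", "hxt", "time_h", "mean_au", "sem_au")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    rlang::abort(paste0("dataset lacks column(s): ", paste(miss, collapse = ", ")))
  }
  bad <- setdiff(unique(x$profile), names(profiles))
  if (length(bad) > 0) {
    rlang::abort(paste0("no glucose profile supplied for: ", paste(bad, collapse = ", ")))
  }
  structure(
    tibble::as_tibble(x),
    profiles = profiles,
    class = c("hxt_dataset", class(tibble::tibble()))
  )
}

#' One-call synthetic dataset
#'
#' [generate_raw()] followed by [normalise_raw()].
#'
#' @inheritParams generate_raw
#' @return An `hxt_dataset`.
#' @export
synth_dataset <- function(config = synth_config(), seed = 1) {
  normalise_raw(generate_raw(config, seed = seed))
}

#' Noiseless dataset straight from the model
#'
#' Simulates the design's ground truth and wraps it as an `hxt_dataset` with a
#' constant nominal SEM — the self-fit and recovery harness input.
#'
#' @param design Design tibble (`genotype, profile, hxt`).
#' @param profiles Named profile list.
#' @param calibration Generating calibration (default packaged reference).
#' @param sem Nominal SEM attached to every point (> 0, used as fitting
#'   weight).
#' @param dt_min Sampling interval (minutes).
#' @return An `hxt_dataset`.
#' @export
noiseless_dataset <- function(design = deletion_panel_design(),
                              profiles = standard_profiles(),
                              calibration = reference_calibration(),
                              sem = 0.05, dt_min = 5) {
  rows <- purrr::pmap_dfr(design, function(genotype, profile, hxt) {
    prof <- profiles[[profile]]
    tr <- simulate_hxt(
      parse_genotype(genotype), prof, calibration$params,
      calibration$promoters[[hxt]],
      t_grid = seq(0, max(prof$time_h), by = dt_min / 60)
    )
    tibble::tibble(
      genotype = genotype, profile = profile, hxt = hxt,
      time_h = tr$time_h, mean_au = tr$H, sem_au = sem, n_rep = 1L
    )
  })
  as_hxt_dataset(rows, profiles)
}

#' Steady-state expression dataset at constant glucose
#'
#' Emulates the constant-glucose endpoint measurements: the wild-type
#' steady-state level of a tagged HXT at each glucose concentration, with a
#' proportional SEM. Profiles are constant programmes named
#' `"const_<level>pct"`.
#'
#' @param hxt Tagged gene.
#' @param levels Constant glucose concentrations (% w/v).
#' @param calibration Generating calibration.
#' @param sem_frac SEM as a fraction of each steady-state level.
#' @param t_obs Nominal observation time (h) recorded for each point.
#' @return An `hxt_dataset` (one row per level).
#' @export
steady_dataset <- function(hxt = "HXT4", levels = c(0.01, 0.1, 1),
                           calibration = reference_calibration(),
                           sem_frac = 0.1, t_obs = 10) {
  profs <- lapply(levels, function(g) {
    glucose_profile(
      tibble::tibble(time_h = c(0, t_obs + 2), conc_pct = c(g, g)),
      name = sprintf("const_%gpct", g)
    )
  })
  names(profs) <- vapply(profs, function(p) attr(p, "name"), character(1))
  rows <- purrr::map2_dfr(levels, names(profs), function(g, nm) {
    ss <- steady_state(g, calibration$params, calibration$promoters[[hxt]])
    tibble::tibble(
      genotype = "wt", profile = nm, hxt = hxt, time_h = t_obs,
      mean_au = ss$H, sem_au = max(sem_frac * ss$H, 1e-6), n_rep = 1L
    )
  })
  as_hxt_dataset(rows, profs)
}

#' Write / read an experiment dataset as CSV
#'
#' Columns `genotype, profile, hxt, time_h, mean_au, sem_au` (plus `n_rep` if
#' present). Profiles are not serialised with the table; supply them on read.
#'
#' @param dataset An `hxt_dataset`.
#' @param path CSV path.
#' @param profiles Named profile list for [read_hxt_dataset()].
#' @return The dataset (invisibly for write).
#' @export
write_hxt_dataset <- function(dataset, path) {
  utils::write.csv(tibble::as_tibble(dataset), path, row.names = FALSE)
  invisible(dataset)
}

#' @rdname write_hxt_dataset
#' @export
read_hxt_dataset <- function(path, profiles) {
  as_hxt_dataset(utils::read.csv(path, check.names = FALSE), profiles)
}
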