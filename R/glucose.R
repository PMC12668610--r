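#' Piecewise-linear extracellular glucose programmes
#'
#' A glucose profile describes the extracellular glucose concentration
#' delivered to the microfluidic device as a function of time: an ordered set
#' of breakpoints `(time_h, conc_pct)` interpolated linearly, and clamped to
#' the nearest endpoint outside the breakpoint range. Time is in hours and
#' concentration in % w/v (g/100 mL), matching the axes of the experiments
#' the model is fitted to.
#'
#' @param breakpoints A data frame with columns `time_h` and `conc_pct`
#'   (strictly increasing times, non-negative concentrations), or a two-column
#'   matrix/list of `[time, conc]` pairs.
#' @param name Optional profile label carried through tidy outputs.
#'
#' @return A `glucose_profile`: a tibble with columns `time_h` and `conc_pct`
#'   plus a `name` attribute.
#' @export
#' @examples
#' prof <- glucose_profile(data.frame(time_h = c(0, 1, 2), conc_pct = c(0, 1, 0)))
#' glc_at(prof, c(-1, 0.5, 3))
glucose_profile <- function(breakpoints, name = "profile") {
  if (is.matrix(breakpoints)) {
    breakpoints <- tibble::tibble(time_h = breakpoints[, 1], conc_pct = breakpoints[, 2])
  } else if (is.list(breakpoints) && !is.data.frame(breakpoints)) {
    breakpoints <- tibble::tibble(
      time_h = vapply(breakpoints, function(b) b[[1]], numeric(1)),
      conc_pct = vapply(breakpoints, function(b) b[[2]], numeric(1))
    )
  }
  bp <- tibble::as_tibble(breakpoints[, c("time_h", "conc_pct")])
  if (nrow(bp) < 1) rlang::abort("a glucose profile needs at least one breakpoint")
  if (any(!is.finite(bp$time_h)) || any(!is.finite(bp$conc_pct))) {
    rlang::abort("glucose profile breakpoints must be finite")
  }
  if (nrow(bp) > 1 && any(diff(bp$time_h) <= 0)) {
    rlang::abort("glucose profile times must be strictly increasing")
  }
  if (any(bp$conc_pct < 0)) rlang::abort("glucose concentrations must be >= 0")
  structure(bp, name = name, class = c("glucose_profile", class(tibble::tibble())))
}

#' Pulse profile: glucose-free lead-in, linear ramp up, plateau, ramp down
#'
#' Builds the canonical experimental programme: cells sit in glucose-free
#' medium for `lead_in_h`, glucose then rises linearly at
#' `rise_rate_pct_per_h` to `plateau_pct`, holds for `plateau_h`, and falls
#' linearly at `fall_rate_pct_per_h` back to zero. The default rates are the
#' measured media-switch ramps (1.5 %/h up, 2 %/h down).
#'
#' @param lead_in_h Glucose-free lead-in duration (h).
#' @param plateau_pct Plateau concentration (% w/v).
#' @param plateau_h Plateau duration (h).
#' @param rise_rate_pct_per_h,fall_rate_pct_per_h Ramp slopes (%/h), > 0.
#' @param tail_h Glucose-free tail appended after the falling ramp (h).
#' @param name Profile label; defaults to e.g. `"pulse_1pct"`.
#'
#' @return A [glucose_profile()].
#' @export
#' @examples
#' p <- glucose_pulse(3, 1, 8) # 40-min rise, 30-min fall
#' glc_at(p, 3 + 1 / 3) # mid-ramp
glucose_pulse <- function(lead_in_h = 3, plateau_pct = 1, plateau_h = 8,
                          rise_rate_pct_per_h = 1.5, fall_rate_pct_per_h = 2,
                          tail_h = 5,
                          name = sprintf("pulse_%gpct", plateau_pct)) {
  if (rise_rate_pct_per_h <= 0 || fall_rate_pct_per_h <= 0) {
    rlang::abort("ramp rates must be > 0")
  }
  if (lead_in_h < 0 || plateau_h < 0 || tail_h < 0 || plateau_pct < 0) {
    rlang::abort("durations and plateau concentration must be >= 0")
  }
  if (plateau_pct == 0) {
    total <- lead_in_h + plateau_h + tail_h
    return(glucose_profile(
      tibble::tibble(time_h = c(0, max(total, 1e-9)), conc_pct = c(0, 0)),
      name = name
    ))
  }
  rise_h <- plateau_pct / rise_rate_pct_per_h
  fall_h <- plateau_pct / fall_rate_pct_per_h
  t_on <- lead_in_h
  t_top <- t_on + rise_h
  t_drop <- t_top + plateau_h
  t_off <- t_drop + fall_h
  glucose_profile(
    tibble::tibble(
      time_h = c(0, t_on, t_top, t_drop, t_off, t_off + tail_h),
      conc_pct = c(0, 0, plateau_pct, plateau_pct, 0, 0)
    ),
    name = name
  )
}

#' Evaluate a glucose profile
#'
#' Linear interpolation between breakpoints; times outside the breakpoint
#' range clamp to the nearest endpoint concentration.
#'
#' @param profile A [glucose_profile()].
#' @param t Times (h), any numeric vector.
#' @return Concentrations (% w/v), same length as `t`.
#' @export
glc_at <- function(profile, t) {
  stopifnot(inherits(profile, "glucose_profile"))
  if (nrow(profile) == 1) return(rep(profile$conc_pct, length(t)))
  stats::approx(profile$time_h, profile$conc_pct, xout = t, rule = 2)$y
}

#' Glucose onset times of a profile
#'
#' Returns the times at which extracellular glucose switches from absent to
#' present (the zero-to-positive crossings), used to anchor the intracellular
#' glucose logistic. A profile that starts positive has an onset at its first
#' breakpoint.
#'
#' @param profile A [glucose_profile()].
#' @return Numeric vector of onset times (h); `numeric(0)` if glucose never
#'   appears.
#' @export
glc_onsets <- function(profile) {
  stopifnot(inherits(profile, "glucose_profile"))
  tt <- profile$time_h
  cc <- profile$conc_pct
  on <- numeric(0)
  if (cc[1] > 0) on <- tt[1]
  if (length(tt) > 1) {
    for (i in seq_len(length(tt) - 1)) {
      if (cc[i] == 0 && cc[i + 1] > 0) on <- c(on, tt[i])
    }
  }
  on
}

#' Plateau concentration of a profile
#'
#' The maximum concentration, used to index per-condition intracellular
#' glucose growth rates.
#' @param profile A [glucose_profile()].
#' @return Scalar concentration (% w/v).
#' @export
glc_plateau <- function(profile) max(profile$conc_pct)

#' Read a glucose profile from YAML or JSON
#'
#' Two schemas are accepted: explicit breakpoints
#' `{name, breakpoints: [[t, c], ...]}`, or the pulse shorthand
#' `{name, lead_in, plateau, duration, rise_rate, fall_rate}`.
#'
#' @param path File path; format chosen by extension (`.json` vs `.yml`/`.yaml`).
#' @return A [glucose_profile()].
#' @export
read_glucose_profile <- function(path) {
  spec <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  nm <- spec$name %||% "profile"
  if (!is.null(spec$breakpoints)) {
    bp <- spec$breakpoints
    if (is.list(bp) && !is.data.frame(bp) && !is.matrix(bp)) {
      bp <- do.call(rbind, lapply(bp, unlist))
    }
    glucose_profile(as.matrix(bp), name = nm)
  } else {
    glucose_pulse(
      lead_in_h = spec$lead_in %||% 3,
      plateau_pct = spec$plateau,
      plateau_h = spec$duration %||% 8,
      rise_rate_pct_per_h = spec$rise_rate %||% 1.5,
      fall_rate_pct_per_h = spec$fall_rate %||% 2,
      name = nm
    )
  }
}

#' Render a profile on a regular time grid
#'
#' @param profile A [glucose_profile()].
#' @param dt_min Grid spacing in minutes (default the imaging interval, 5 min).
#' @param t_end End time (h); defaults to the last breakpoint.
#' @return A tibble with columns `time_h`, `conc_pct`, `profile`.
#' @export
render_profile <- function(profile, dt_min = 5, t_end = NULL) {
  t_end <- t_end %||% max(profile$time_h)
  tt <- seq(0, t_end, by = dt_min / 60)
  tibble::tibble(
    time_h = tt,
    conc_pct = glc_at(profile, tt),
    profile = attr(profile, "name") %||% "profile"
  )
}
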