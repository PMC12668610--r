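hill_like_names <- c("n_M", "n_G2", "h_A", "h_snf3", "h_rgt2")

is_linear_scale <- function(nm) nm %in% hill_like_names | grepl("^n_", nm)

# split a mixed theta vector into model-parameter and promoter updates
apply_theta <- function(theta, params, promoter) {
  p <- unclass(params)
  pr <- promoter
  for (nm in names(theta)) {
    v <- theta[[nm]]
    if (nm %in% c("aH", "dHmax", "dHmin", "K_dH")) {
      pr[[nm]] <- v
    } else if (grepl("^K_(Mth1|Std1|Mig1|Mig2)$", nm)) {
      pr$K[[sub("^K_", "", nm)]] <- v
    } else if (grepl("^n_(Mth1|Std1|Mig1|Mig2)$", nm)) {
      pr$n[[sub("^n_", "", nm)]] <- v
    } else if (nm %in% names(p) && is.numeric(p[[nm]])) {
      p[[nm]] <- v
    } else {
      rlang::abort(paste0("unknown parameter in bounds/theta: ", nm))
    }
  }
  if (pr$dHmin > pr$dHmax) return(NULL) # infeasible corner of the box
  params2 <- tryCatch(
    {
      validate_model_params(p)
      structure(p, class = "model_params")
    },
    error = function(e) NULL
  )
  promoter2 <- tryCatch(
    promoter_params(pr$structure, pr$aH, pr$dHmax, pr$dHmin, pr$K_dH, pr$K, pr$n),
    error = function(e) NULL
  )
  if (is.null(params2) || is.null(promoter2)) return(NULL)
  list(params = params2, promoter = promoter2)
}

# model-predicted fluorescence for every dataset row, in row order;
# constant-glucose profiles use the steady state directly
dataset_predictions <- function(params, promoter, dataset,
                                profiles = attr(dataset, "profiles")) {
  if (is.null(profiles)) rlang::abort("dataset carries no glucose profiles")
  df <- tibble::as_tibble(dataset)
  df$.row <- seq_len(nrow(df))
  pred <- df |>
    dplyr::group_by(.data$genotype, .data$profile) |>
    dplyr::group_modify(function(d, key) {
      prof <- profiles[[key$profile]]
      dels <- parse_genotype(key$genotype)
      if (length(unique(prof$conc_pct)) == 1) {
        h <- steady_state(prof$conc_pct[[1]], params, promoter, dels)$H
        return(tibble::tibble(.row = d$.row, pred_au = rep(h, nrow(d))))
      }
      tt <- sort(unique(d$time_h))
      grid <- if (tt[1] > 0) c(0, tt) else tt
      tr <- simulate_hxt(dels, prof, params, promoter, t_grid = grid)
      tibble::tibble(
        .row = d$.row,
        pred_au = stats::approx(tr$time_h, tr$H, xout = d$time_h, rule = 2)$y
      )
    }) |>
    dplyr::ungroup()
  out <- df
  out$pred_au <- pred$pred_au[order(pred$.row)]
  out$.row <- NULL
  out
}

#' Weighted sum-of-squares objective
#'
#' `sum(((model - measured) / w)^2)` over every time point of every record,
#' with weights `w` equal to the measurement SEM floored at a fraction of the
#' dataset's maximum fluorescence (so near-zero-variance points cannot
#' dominate). A simulation failure yields a large finite penalty flagged via
#' the `"failed"` attribute rather than an error, so optimisers can continue.
#'
#' @param params A [model_params()].
#' @param promoter A [promoter_params()].
#' @param dataset An `hxt_dataset` (see [as_hxt_dataset()]).
#' @param profiles Named profile list; defaults to the dataset attribute.
#' @param weight_floor_frac SEM floor as a fraction of `max(mean_au)`.
#' @return Non-negative scalar; attribute `failed` is `TRUE` after a penalty.
#' @export
wss_objective <- function(params, promoter, dataset,
                          profiles = attr(dataset, "profiles"),
                          weight_floor_frac = 0.05) {
  if (nrow(dataset) == 0) rlang::abort("empty dataset")
  floor_w <- weight_floor_frac * max(dataset$mean_au)
  pred <- tryCatch(
    dataset_predictions(params, promoter, dataset, profiles),
    error = function(e) NULL
  )
  if (is.null(pred) || any(!is.finite(pred$pred_au))) {
    return(structure(1e8, failed = TRUE))
  }
  w <- pmax(dataset$sem_au, floor_w)
  structure(sum(((pred$pred_au - dataset$mean_au) / w)^2), failed = FALSE)
}

sample_init_population <- function(lo, hi, n) {
  d <- length(lo)
  # stratified (latin-hypercube style) start so small populations still cover the box
  cols <- lapply(seq_len(d), function(j) {
    strata <- (sample.int(n) - stats::runif(n)) / n
    lo[j] + strata * (hi[j] - lo[j])
  })
  matrix(unlist(cols), nrow = n, ncol = d)
}

#' Fit the model by global box-constrained search
#'
#' Differential-evolution global search over a box of parameters (log scale
#' for rates and constants, linear for Hill numbers), followed by a local
#' quasi-Newton polish of the best member. Parameters not named in `bounds`
#' stay fixed at the supplied baseline. Identical `seed` and `budget` give
#' identical results; `budget` counts objective evaluations of the
#' evolutionary phase, and a budget no larger than the population size returns
#' the best of the initial population.
#'
#' @param dataset An `hxt_dataset` to fit.
#' @param bounds Named list of `c(lower, upper)` boxes. Names may be
#'   signalling parameters (e.g. `"aM"`, `"kinG1"`, `"r_g"`), promoter scalars
#'   (`"aH"`, `"dHmax"`, `"dHmin"`, `"K_dH"`), or per-repressor promoter
#'   entries (`"K_Mig1"`, `"n_Mth1"`, ...).
#' @param seed Integer seed.
#' @param budget Objective evaluations for the global phase, > 0.
#' @param params,promoter Baseline [model_params()] and [promoter_params()]
#'   (defaults: the packaged reference calibration's signalling set and HXT4
#'   promoter).
#' @param profiles Profile list; defaults to the dataset attribute.
#' @param pop Population size (default `max(10, 4 * n_par)`).
#' @param F,CR Differential weight and crossover probability.
#' @param weight_floor_frac Passed to [wss_objective()].
#' @param polish Run the local polish after the global phase?
#' @return An `hxt_fit`: best parameters, promoter, objective, trace, seed.
#' @export
fit_model <- function(dataset, bounds, seed = 1, budget = 2000,
                      params = reference_calibration()$params,
                      promoter = reference_calibration()$promoters$HXT4,
                      profiles = attr(dataset, "profiles"),
                      pop = NULL, F = 0.8, CR = 0.9,
                      weight_floor_frac = 0.05, polish = TRUE) {
  if (nrow(dataset) == 0) rlang::abort("empty dataset")
  if (budget < 1) rlang::abort("budget must be >= 1")
  nm <- names(bounds)
  if (is.null(nm) || any(!nzchar(nm))) rlang::abort("bounds must be named")
  lo_nat <- vapply(bounds, function(b) b[[1]], numeric(1))
  hi_nat <- vapply(bounds, function(b) b[[2]], numeric(1))
  if (any(!is.finite(lo_nat)) || any(!is.finite(hi_nat))) {
    rlang::abort("bounds must be finite")
  }
  if (any(lo_nat > hi_nat)) rlang::abort("lower bound exceeds upper bound")
  linear <- is_linear_scale(nm)
  if (any(lo_nat[!linear] <= 0)) {
    rlang::abort("log-scale parameters need positive lower bounds")
  }
  to_nat <- function(x) ifelse(linear, x, 10^x)
  lo <- ifelse(linear, lo_nat, log10(lo_nat))
  hi <- ifelse(linear, hi_nat, log10(hi_nat))
  d <- length(lo)
  pop <- pop %||% max(10L, 4L * d)

  obj_nat <- function(theta_nat) {
    names(theta_nat) <- nm
    upd <- apply_theta(as.list(theta_nat), params, promoter)
    if (is.null(upd)) return(1e8)
    as.numeric(wss_objective(upd$params, upd$promoter, dataset, profiles,
      weight_floor_frac = weight_floor_frac
    ))
  }
  obj <- function(x) obj_nat(to_nat(x))

  res <- with_local_seed(seed, {
    X <- sample_init_population(lo, hi, pop)
    fx <- apply(X, 1, obj)
    evals <- pop
    trace <- tibble::tibble(generation = 0L, best = min(fx), evals = evals)
    gen <- 0L
    while (evals + pop <= budget) {
      gen <- gen + 1L
      for (i in seq_len(pop)) {
        r <- sample(setdiff(seq_len(pop), i), 3)
        v <- X[r[1], ] + F * (X[r[2], ] - X[r[3], ])
        cross <- stats::runif(d) < CR
        cross[sample.int(d, 1)] <- TRUE
        u <- ifelse(cross, v, X[i, ])
        u <- pmin(pmax(u, lo), hi)
        fu <- obj(u)
        if (fu <= fx[i]) {
          X[i, ] <- u
          fx[i] <- fu
        }
      }
      evals <- evals + pop
      trace <- dplyr::bind_rows(
        trace,
        tibble::tibble(generation = gen, best = min(fx), evals = evals)
      )
    }
    best_i <- which.min(fx)
    x_best <- X[best_i, ]
    f_best <- fx[best_i]
    if (polish && budget > pop) {
      pol <- tryCatch(
        stats::optim(x_best, obj,
          method = "L-BFGS-B", lower = lo, upper = hi,
          control = list(maxit = 100)
        ),
        error = function(e) NULL
      )
      if (!is.null(pol) && is.finite(pol$value) && pol$value <= f_best) {
        x_best <- pol$par
        f_best <- pol$value
        evals <- evals + pol$counts[["function"]]
      }
    }
    list(x = x_best, f = f_best, evals = evals, trace = trace)
  })

  theta_nat <- to_nat(res$x)
  names(theta_nat) <- nm
  upd <- apply_theta(as.list(theta_nat), params, promoter)
  structure(
    list(
      params = upd$params, promoter = upd$promoter, theta = theta_nat,
      objective = res$f, trace = res$trace, seed = seed, budget = budget,
      evals = res$evals, in_class = NA
    ),
    class = "hxt_fit"
  )
}

#' @export
print.hxt_fit <- function(x, ...) {
  cat(sprintf(
    "<hxt_fit> %d parameter(s), objective %.6g after %d evaluations (seed %s)\n",
    length(x$theta), x$objective, x$evals, format(x$seed)
  ))
  print(tidy(x))
  invisible(x)
}

#' @export
tidy.hxt_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' @export
glance.hxt_fit <- function(x, ...) {
  tibble::tibble(
    objective = x$objective, n_param = length(x$theta),
    n_eval = x$evals, seed = x$seed,
    in_class = x$in_class
  )
}

#' Pick a fit in the Std1-activates-SNF1 mechanism class
#'
#' Among near-optimal fits (objective within `margin` of the best), returns
#' one whose parameters put Std1's action predominately on SNF1 rather than on
#' MIG2 repression (see [mechanism_class()]), breaking ties by objective. If
#' none qualifies, the best fit overall is returned with its `in_class` flag
#' set `FALSE`.
#'
#' @param fits A list of `hxt_fit` objects (length >= 1).
#' @param margin Relative objective margin defining "near-optimal".
#' @return One `hxt_fit`, with `in_class` set.
#' @export
select_mechanism_class <- function(fits, margin = 0.1) {
  if (inherits(fits, "hxt_fit")) fits <- list(fits)
  if (length(fits) == 0) rlang::abort("need at least one fit")
  objs <- vapply(fits, function(f) f$objective, numeric(1))
  best <- min(objs)
  near <- which(objs <= best * (1 + margin) + 1e-12)
  in_class <- vapply(fits, function(f) {
    mechanism_class(f$params, f$promoter)$std1_snf1
  }, logical(1))
  cand <- near[in_class[near]]
  if (length(cand) > 0) {
    pick <- cand[which.min(objs[cand])]
    out <- fits[[pick]]
    out$in_class <- TRUE
  } else {
    pick <- which.min(objs)
    out <- fits[[pick]]
    out$in_class <- FALSE
  }
  out
}

#' Prediction-recovery error
#'
#' Normalised RMSE between a fitted model's predictions and a dataset's
#' recorded means, per (genotype, profile) record: RMSE divided by the
#' record's dynamic range, averaged over records. The honest recovery target
#' when individual parameters are non-identifiable.
#'
#' @param fit An `hxt_fit` (or a list with `params` and `promoter`).
#' @param dataset An `hxt_dataset` of generating trajectories.
#' @return Scalar NRMSE (fraction, not percent).
#' @export
prediction_nrmse <- function(fit, dataset) {
  pred <- dataset_predictions(fit$params, fit$promoter, dataset)
  per <- pred |>
    dplyr::group_by(.data$genotype, .data$profile) |>
    dplyr::summarise(
      nrmse = sqrt(mean((.data$pred_au - .data$mean_au)^2)) /
        max(diff(range(.data$mean_au)), 1e-9),
      .groups = "drop"
    )
  mean(per$nrmse)
}
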