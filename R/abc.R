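#' Prior restrictions on promoter structures
#'
#' Earlier deletion-strain screens constrain which repressors must (or must
#' not) appear in the candidate promoter models of each HXT. A restriction
#' table has one row per HXT with `required` and `excluded` repressor sets
#' (list columns); structures must contain every required repressor and no
#' excluded one. The default table requires Std1 for HXT1 and HXT3 and leaves
#' HXT2, HXT4, HXT6 and HXT7 unrestricted. HXT5 never appears: it is not
#' regulated by this network.
#'
#' @param hxt Character vector of HXT names.
#' @param required,excluded Lists of repressor character vectors, parallel to
#'   `hxt`.
#' @return A `prior_restriction` tibble.
#' @export
prior_restriction <- function(hxt, required = NULL, excluded = NULL) {
  n <- length(hxt)
  required <- required %||% rep(list(character(0)), n)
  excluded <- excluded %||% rep(list(character(0)), n)
  stopifnot(length(required) == n, length(excluded) == n)
  required <- lapply(required, canon_repressor)
  excluded <- lapply(excluded, canon_repressor)
  for (i in seq_len(n)) {
    if (length(intersect(required[[i]], excluded[[i]])) > 0) {
      rlang::abort("a repressor cannot be both required and excluded")
    }
    if (length(required[[i]]) == 0 && length(excluded[[i]]) >= 4) {
      rlang::abort("restriction leaves no allowed promoter structure")
    }
  }
  structure(
    tibble::tibble(hxt = toupper(hxt), required = required, excluded = excluded),
    class = c("prior_restriction", class(tibble::tibble()))
  )
}

#' @rdname prior_restriction
#' @export
default_prior_restriction <- function() {
  prior_restriction(
    hxt = c("HXT1", "HXT2", "HXT3", "HXT4", "HXT6", "HXT7"),
    required = list("Std1", character(0), "Std1", character(0), character(0), character(0))
  )
}

#' Allowed promoter structures under a restriction
#'
#' Filters the canonical 15-structure enumeration to those containing every
#' required repressor and none of the excluded ones for the named HXT. An HXT
#' absent from the table is unrestricted.
#'
#' @param restriction A [prior_restriction()].
#' @param hxt Gene name, e.g. `"HXT3"`.
#' @return List of structures (character vectors), in canonical order.
#' @export
allowed_models <- function(restriction, hxt) {
  hxt <- toupper(hxt)
  if (hxt == "HXT5") {
    rlang::abort("HXT5 is not regulated by the Snf3-Rgt2 network; no models defined")
  }
  req <- character(0)
  exc <- character(0)
  i <- match(hxt, restriction$hxt)
  if (!is.na(i)) {
    req <- restriction$required[[i]]
    exc <- restriction$excluded[[i]]
  }
  keep <- Filter(
    function(s) all(req %in% s) && !any(exc %in% s),
    promoter_structures()
  )
  if (length(keep) == 0) rlang::abort("restriction admits no promoter structure")
  keep
}

#' ABC-SMC settings
#'
#' Adaptive population Monte Carlo schedule: per generation the tolerance is
#' set to the `alpha`-quantile of the current particles' distances, the
#' worst `1 - alpha` are replaced by kernel-perturbed proposals, and sampling
#' stops when the fraction of proposals beating the previous tolerance falls
#' below `p_acc_min` or after `max_gen` generations. Parameter priors are
#' log-uniform over `prior_decades` decades centred on the calibrated HXT4
#' promoter values (Hill numbers uniform on `[1, 8]`); the model prior is
#' uniform over the allowed structures. A fraction `model_refresh` of
#' proposals is drawn fresh from the prior so no structure is ever starved.
#'
#' @param n_particles Population size.
#' @param alpha Quantile kept as survivors each generation.
#' @param p_acc_min Stopping threshold on the proposal acceptance rate.
#' @param max_gen Generation cap; `0` returns the prior itself.
#' @param prior_decades Width of the log-uniform parameter priors (decades).
#' @param model_refresh Fraction of proposals drawn fresh from the prior.
#' @param ess_floor Resample survivors when their effective sample size drops
#'   below this fraction of the survivor count.
#' @param weight_floor_frac SEM floor used in the distance, as in
#'   [wss_objective()].
#' @param init_factor The calibration (first) generation draws
#'   `init_factor * n_particles` prior-predictive samples, stratified over the
#'   allowed models, so every structure starts from its best prior region.
#' @param min_gen Generations to run before the acceptance-rate stop rule may
#'   fire (the calibration generation sets a demanding starting tolerance, so
#'   early acceptance rates are uninformative).
#' @return An `abc_config` list.
#' @export
abc_config <- function(n_particles = 500, alpha = 0.3, p_acc_min = 0.005,
                       max_gen = 25, prior_decades = 4, model_refresh = 0.1,
                       ess_floor = 0.5, weight_floor_frac = 0.05,
                       init_factor = 20, min_gen = 6) {
  stopifnot(
    n_particles >= 10, alpha > 0, alpha < 1, p_acc_min >= 0,
    max_gen >= 0, prior_decades > 0, model_refresh >= 0, model_refresh < 1,
    init_factor >= 1, min_gen >= 1
  )
  structure(
    list(
      n_particles = n_particles, alpha = alpha, p_acc_min = p_acc_min,
      max_gen = max_gen, prior_decades = prior_decades,
      model_refresh = model_refresh, ess_floor = ess_floor,
      weight_floor_frac = weight_floor_frac, init_factor = init_factor,
      min_gen = min_gen
    ),
    class = "abc_config"
  )
}

# ---- prior over promoter parameters, on the sampling scale -----------------
# components: log10(aH), log10(dHmax), log10(dHmin/dHmax) in [-3, 0],
# log10(K_dH), log10(K_i) per repressor, n_i (linear) per repressor.
make_prior <- function(structure, center, decades) {
  half <- decades / 2
  nm <- c(
    "laH", "ldHmax", "lfrac", "lKdH",
    paste0("lK_", structure), paste0("n_", structure)
  )
  lo <- c(
    log10(center$aH) - half, log10(center$dHmax) - half, -3,
    log10(center$K_dH) - half,
    log10(center$K[structure]) - half, rep(1, length(structure))
  )
  hi <- c(
    log10(center$aH) + half, log10(center$dHmax) + half, 0,
    log10(center$K_dH) + half,
    log10(center$K[structure]) + half, rep(8, length(structure))
  )
  names(lo) <- names(hi) <- nm
  list(
    names = nm, lo = lo, hi = hi,
    dens = prod(1 / (hi - lo)),
    sample = function() stats::setNames(lo + stats::runif(length(lo)) * (hi - lo), nm),
    inside = function(th) all(th >= lo - 1e-12) && all(th <= hi + 1e-12)
  )
}

theta_to_promoter <- function(theta, structure) {
  k <- 10^theta[paste0("lK_", structure)]
  n <- theta[paste0("n_", structure)]
  names(k) <- names(n) <- structure
  dHmax <- 10^theta[["ldHmax"]]
  promoter_params(
    structure = structure,
    aH = 10^theta[["laH"]],
    dHmax = dHmax,
    dHmin = dHmax * 10^theta[["lfrac"]],
    K_dH = 10^theta[["lKdH"]],
    K = k, n = n
  )
}

# ---- fast wild-type predictions with fixed signalling ----------------------
# The signalling states do not depend on the promoter, so they are simulated
# once per glucose programme; each candidate promoter then only requires the
# scalar linear ODE for H, integrated in closed form between grid points.
signalling_context <- function(params, dataset,
                               profiles = attr(dataset, "profiles"),
                               deletions = character(0)) {
  probe <- reference_calibration()$promoters$HXT4
  used <- unique(dataset$profile)
  ctx <- list()
  for (nm in used) {
    prof <- profiles[[nm]]
    if (length(unique(prof$conc_pct)) == 1) {
      ss <- steady_state(prof$conc_pct[[1]], params, probe, deletions)
      ctx[[nm]] <- list(
        type = "constant", ge = prof$conc_pct[[1]],
        levels = c(Mth1 = ss$M, Std1 = ss$S, Mig1 = ss$G1, Mig2 = ss$G2)
      )
    } else {
      grid <- seq(0, max(prof$time_h), by = 5 / 60)
      tr <- simulate_hxt(deletions, prof, params, probe, t_grid = grid)
      ctx[[nm]] <- list(
        type = "dynamic", time_h = tr$time_h, ge = tr$ge,
        R = cbind(Mth1 = tr$M, Std1 = tr$S, Mig1 = tr$G1, Mig2 = tr$G2)
      )
    }
  }
  ctx
}

predict_H_ctx <- function(promoter, ctx_entry, times = NULL) {
  if (ctx_entry$type == "constant") {
    return(transcription_rate(ctx_entry$levels, promoter) /
      hxt_degradation(ctx_entry$ge, promoter))
  }
  R <- ctx_entry$R[, promoter$structure, drop = FALSE]
  W <- rowSums(
    sweep(R, 2, promoter$K, "/")^
      matrix(promoter$n, nrow(R), ncol(R), byrow = TRUE)
  )
  rate <- promoter$aH / (1 + W)
  deg <- hxt_degradation(ctx_entry$ge, promoter)
  tt <- ctx_entry$time_h
  H <- numeric(length(tt))
  H[1] <- rate[1] / deg[1]
  for (k in seq_len(length(tt) - 1)) {
    dt <- tt[k + 1] - tt[k]
    dbar <- 0.5 * (deg[k] + deg[k + 1])
    rbar <- 0.5 * (rate[k] + rate[k + 1])
    ed <- exp(-dbar * dt)
    H[k + 1] <- H[k] * ed + rbar * (1 - ed) / dbar
  }
  if (is.null(times)) H else stats::approx(tt, H, xout = times, rule = 2)$y
}

#' SEM-weighted distance between simulated and observed series
#'
#' The ABC distance: the L2 norm of SEM-weighted residuals over all series,
#' in the same weighting dialect as [wss_objective()] (SEM floored at a
#' fraction of the maximum observed fluorescence). Simulated series are
#' interpolated onto the observed time points per profile; it is an error
#' only if the time ranges are disjoint.
#'
#' @param simulated A data frame with columns `profile, time_h, H` (and
#'   optionally `genotype`).
#' @param observed An `hxt_dataset`.
#' @param weight_floor_frac SEM floor fraction.
#' @return Non-negative scalar.
#' @export
abc_distance <- function(simulated, observed, weight_floor_frac = 0.05) {
  floor_w <- weight_floor_frac * max(observed$mean_au)
  obs <- tibble::as_tibble(observed)
  sq <- 0
  for (nm in unique(obs$profile)) {
    o <- obs[obs$profile == nm, ]
    s <- simulated[simulated$profile == nm, ]
    if (nrow(s) == 0) rlang::abort(paste0("no simulated series for profile ", nm))
    if (min(s$time_h) > max(o$time_h) || max(s$time_h) < min(o$time_h)) {
      rlang::abort(paste0("simulated and observed time ranges are disjoint for ", nm))
    }
    pred <- if (nrow(s) == 1) {
      rep(s$H, nrow(o))
    } else {
      stats::approx(s$time_h, s$H, xout = o$time_h, rule = 2)$y
    }
    w <- pmax(o$sem_au, floor_w)
    sq <- sq + sum(((pred - o$mean_au) / w)^2)
  }
  sqrt(sq)
}

#' ABC-SMC promoter-model selection for one HXT
#'
#' Infers the posterior probability of each allowed promoter structure for
#' `hxt`, together with its promoter parameters, from wild-type expression
#' data (constant-glucose steady levels and/or dynamic pulse series), with
#' the signalling parameters held fixed at the calibrated values. The sampler
#' is sequential Monte Carlo with an adaptive population Monte Carlo
#' tolerance schedule (see [abc_config()]); the model index is sampled jointly
#' with the parameters and perturbed through a prior-refresh mixture kernel.
#'
#' @param dataset An `hxt_dataset` of wild-type series for `hxt`.
#' @param hxt Gene name.
#' @param signalling Calibrated [model_params()].
#' @param restriction A [prior_restriction()] (default packaged table).
#' @param config An [abc_config()].
#' @param seed Integer seed; runs are reproducible.
#' @param prior_center Promoter whose parameters centre the priors (default
#'   the packaged calibrated HXT4 promoter).
#' @param models Optional explicit list of candidate structures (character
#'   vectors), overriding the restriction-derived enumeration.
#' @return An `hxt_posterior`: model probabilities, weighted particles,
#'   tolerance/acceptance history.
#' @export
abc_smc <- function(dataset, hxt, signalling,
                    restriction = default_prior_restriction(),
                    config = abc_config(), seed = 1,
                    prior_center = reference_calibration()$promoters$HXT4,
                    models = NULL) {
  dataset <- dataset[dataset$hxt == toupper(hxt) & dataset$genotype == "wt", ]
  if (nrow(dataset) == 0) {
    rlang::abort("dataset contains no wild-type series for this HXT")
  }
  structures <- models %||% allowed_models(restriction, hxt)
  structures <- lapply(structures, canon_repressor)
  M <- length(structures)
  priors <- lapply(structures, make_prior,
    center = prior_center, decades = config$prior_decades
  )
  ctx <- signalling_context(signalling, dataset)
  floor_w <- config$weight_floor_frac * max(dataset$mean_au)
  w_obs <- pmax(dataset$sem_au, floor_w)
  obs_split <- split(
    tibble::tibble(time_h = dataset$time_h, mean = dataset$mean_au,
                   w = w_obs),
    dataset$profile
  )

  dist_fun <- function(m, theta) {
    promoter <- theta_to_promoter(theta, structures[[m]])
    sq <- 0
    for (nm in names(obs_split)) {
      o <- obs_split[[nm]]
      pred <- predict_H_ctx(promoter, ctx[[nm]], times = o$time_h)
      sq <- sq + sum(((pred - o$mean) / o$w)^2)
    }
    sqrt(sq)
  }

  N <- config$n_particles
  n_keep <- max(2L, floor(config$alpha * N))

  finalize <- function(part, eps_hist, pacc_hist, ess_hist) {
    wt <- part$weight / sum(part$weight)
    lab <- vapply(structures, structure_label, character(1))
    prob <- vapply(seq_len(M), function(m) sum(wt[part$model == m]), numeric(1))
    particles <- tibble::tibble(
      structure = lab[part$model],
      weight = wt,
      distance = part$distance,
      promoter = purrr::map2(part$model, part$theta, function(m, th) {
        theta_to_promoter(th, structures[[m]])
      })
    )
    structure(
      list(
        hxt = toupper(hxt),
        models = tibble::tibble(structure = lab, probability = prob),
        particles = particles,
        eps_history = eps_hist, p_acc_history = pacc_hist,
        ess_history = ess_hist,
        final_eps = if (length(eps_hist)) eps_hist[length(eps_hist)] else Inf,
        allowed = lab, config = config, seed = seed
      ),
      class = "hxt_posterior"
    )
  }

  with_local_seed(seed, {
    if (config$max_gen == 0) {
      # the prior itself: equal model probabilities, stratified prior particles
      per <- ceiling(N / M)
      part <- list(model = integer(0), theta = list(), distance = numeric(0), weight = numeric(0))
      for (m in seq_len(M)) {
        for (i in seq_len(per)) {
          part$model <- c(part$model, m)
          part$theta <- c(part$theta, list(priors[[m]]$sample()))
          part$distance <- c(part$distance, NA_real_)
          part$weight <- c(part$weight, 1 / (M * per))
        }
      }
      return(finalize(part, numeric(0), numeric(0), numeric(0)))
    }

    # stratified calibration generation: every allowed model gets an equal
    # share of prior-predictive draws (the model prior is uniform)
    N0 <- ceiling(config$init_factor * N)
    model0 <- rep(seq_len(M), length.out = N0)
    theta0 <- lapply(model0, function(m) priors[[m]]$sample())
    dist0 <- vapply(seq_len(N0), function(i) dist_fun(model0[i], theta0[[i]]), numeric(1))
    if (all(!is.finite(dist0))) {
      rlang::abort(
        "all prior-predictive distances are non-finite: prior incompatible with data",
        class = "pushpull_abc_prior_failure"
      )
    }
    ord <- order(dist0)[seq_len(n_keep)]
    part <- list(
      model = model0[ord], theta = theta0[ord],
      distance = dist0[ord], weight = rep(1 / n_keep, n_keep)
    )
    eps <- max(part$distance)
    eps_hist <- eps
    pacc_hist <- 1
    ess_hist <- n_keep

    # elitist archive: each model's best few particles ever seen stay
    # proposable, so a structure squeezed out of the survivor set can return
    # once the tolerance approaches its best achievable distance
    n_arch <- 8L
    archive <- lapply(seq_len(M), function(m) {
      sel <- which(model0 == m)
      sel <- sel[order(dist0[sel])][seq_len(min(n_arch, length(sel)))]
      list(theta = theta0[sel], distance = dist0[sel])
    })
    update_archive <- function(models, thetas, dists) {
      for (m in seq_len(M)) {
        sel <- which(models == m)
        if (length(sel) == 0) next
        th <- c(archive[[m]]$theta, thetas[sel])
        dd <- c(archive[[m]]$distance, dists[sel])
        o <- order(dd)[seq_len(min(n_arch, length(dd)))]
        archive[[m]] <<- list(theta = th[o], distance = dd[o])
      }
    }

    aux_frac <- 0.35 # share of kernel proposals seeded from the archive

    for (gen in seq_len(config$max_gen - 1)) {
      # proposal pool: weighted survivors plus the per-model archive
      pool_model <- part$model
      pool_theta <- part$theta
      v <- part$weight / sum(part$weight) * (1 - aux_frac)
      arch_m <- integer(0)
      arch_th <- list()
      for (m in seq_len(M)) {
        arch_m <- c(arch_m, rep(m, length(archive[[m]]$theta)))
        arch_th <- c(arch_th, archive[[m]]$theta)
      }
      pool_model <- c(pool_model, arch_m)
      pool_theta <- c(pool_theta, arch_th)
      v <- c(v, rep(aux_frac / length(arch_m), length(arch_m)))
      v <- v / sum(v)

      # per-model kernel scales from the pooled particles; models alive only
      # in the archive keep a wide kernel so they continue to explore
      sds <- lapply(seq_len(M), function(m) {
        sel <- which(pool_model == m)
        pr <- priors[[m]]
        width <- pr$hi - pr$lo
        sd_floor <- if (any(part$model == m)) width / 200 else width / 15
        if (length(sel) < 2) return(pmax(width / 20, sd_floor))
        th <- do.call(rbind, pool_theta[sel])
        wts <- v[sel] / sum(v[sel])
        mu <- colSums(th * wts)
        vv <- colSums((th - rep(mu, each = nrow(th)))^2 * wts)
        pmax(sqrt(2 * vv), sd_floor)
      })
      n_new <- N - n_keep
      new <- vector("list", n_new)
      for (i in seq_len(n_new)) {
        if (stats::runif(1) < config$model_refresh) {
          m <- sample.int(M, 1)
          th <- priors[[m]]$sample()
        } else {
          j <- sample.int(length(pool_model), 1, prob = v)
          m <- pool_model[j]
          th <- pool_theta[[j]] + stats::rnorm(length(pool_theta[[j]]), 0, sds[[m]])
          tries <- 0
          while (!priors[[m]]$inside(th) && tries < 20) {
            th <- pool_theta[[j]] + stats::rnorm(length(th), 0, sds[[m]])
            tries <- tries + 1
          }
          if (!priors[[m]]$inside(th)) th <- priors[[m]]$sample()
        }
        names(th) <- priors[[m]]$names
        new[[i]] <- list(m = m, th = th)
      }
      dist_new <- vapply(new, function(x) dist_fun(x$m, x$th), numeric(1))
      p_acc <- mean(dist_new <= eps)
      update_archive(
        vapply(new, function(x) x$m, integer(1)),
        lapply(new, function(x) x$th), dist_new
      )
      # importance weights under the actual mixture proposal
      w_new <- vapply(seq_len(n_new), function(i) {
        m <- new[[i]]$m
        th <- new[[i]]$th
        pr <- priors[[m]]
        prior_dens <- pr$dens / M
        sel <- which(pool_model == m)
        kern <- if (length(sel) > 0) {
          sum(vapply(sel, function(j) {
            v[j] * prod(stats::dnorm(th, pool_theta[[j]], sds[[m]]))
          }, numeric(1)))
        } else {
          0
        }
        q <- config$model_refresh * prior_dens + (1 - config$model_refresh) * kern
        if (q <= 0) 0 else prior_dens / q
      }, numeric(1))

      all_model <- c(part$model, vapply(new, function(x) x$m, integer(1)))
      all_theta <- c(part$theta, lapply(new, function(x) x$th))
      all_dist <- c(part$distance, dist_new)
      all_w <- c(part$weight, w_new)
      keep <- order(all_dist)[seq_len(n_keep)]
      part <- list(
        model = all_model[keep], theta = all_theta[keep],
        distance = all_dist[keep], weight = all_w[keep]
      )
      if (sum(part$weight) <= 0) part$weight <- rep(1 / n_keep, n_keep)
      part$weight <- part$weight / sum(part$weight)
      eps <- min(eps, max(part$distance))
      ess <- 1 / sum(part$weight^2)
      if (ess < config$ess_floor * n_keep) {
        idx <- sample.int(n_keep, n_keep, replace = TRUE, prob = part$weight)
        part <- list(
          model = part$model[idx], theta = part$theta[idx],
          distance = part$distance[idx], weight = rep(1 / n_keep, n_keep)
        )
        ess <- n_keep
      }
      eps_hist <- c(eps_hist, eps)
      pacc_hist <- c(pacc_hist, p_acc)
      ess_hist <- c(ess_hist, ess)
      if (gen + 1 >= config$min_gen && p_acc < config$p_acc_min) break
    }
    finalize(part, eps_hist, pacc_hist, ess_hist)
  })
}

#' @export
print.hxt_posterior <- function(x, ...) {
  cat(sprintf(
    "<hxt_posterior> %s: %d allowed structures, %d generations, final tolerance %.4g\n",
    x$hxt, length(x$allowed), length(x$eps_history), x$final_eps
  ))
  print(dplyr::arrange(x$models, dplyr::desc(.data$probability)))
  invisible(x)
}

#' @export
tidy.hxt_posterior <- function(x, ...) {
  dplyr::arrange(x$models, dplyr::desc(.data$probability))
}

#' @export
glance.hxt_posterior <- function(x, ...) {
  tibble::tibble(
    hxt = x$hxt,
    n_models = length(x$allowed),
    n_generations = length(x$eps_history),
    final_eps = x$final_eps,
    map_structure = x$models$structure[which.max(x$models$probability)],
    map_probability = max(x$models$probability),
    seed = x$seed
  )
}

#' Serialise a posterior ensemble
#'
#' Writes the model table as JSON (`models.json`) and the weighted particle
#' store as CSV (`particles.csv`: structure, weight, distance, and the
#' promoter parameters flattened to one column per entry) into `dir`.
#'
#' @param posterior An `hxt_posterior`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(posterior, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      hxt = posterior$hxt,
      models = posterior$models,
      eps_history = posterior$eps_history,
      p_acc_history = posterior$p_acc_history,
      final_eps = posterior$final_eps,
      seed = posterior$seed
    ),
    file.path(dir, "models.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  flat <- purrr::map2_dfr(
    seq_len(nrow(posterior$particles)), posterior$particles$promoter,
    function(i, pr) {
      row <- tibble::tibble(
        structure = posterior$particles$structure[i],
        weight = posterior$particles$weight[i],
        distance = posterior$particles$distance[i],
        aH = pr$aH, dHmax = pr$dHmax, dHmin = pr$dHmin, K_dH = pr$K_dH
      )
      for (r in pr$structure) {
        row[[paste0("K_", r)]] <- pr$K[[r]]
        row[[paste0("n_", r)]] <- pr$n[[r]]
      }
      row
    }
  )
  utils::write.csv(flat, file.path(dir, "particles.csv"), row.names = FALSE)
  invisible(dir)
}

#' Bootstrap steady-state repression from a posterior
#'
#' Draws `(structure, parameters)` samples from the posterior over promoter
#' models (with replacement, by particle weight), computes the wild-type
#' signalling steady state at each constant glucose level, and evaluates the
#' repression weight of both repressor pairs. Reports the mean and percentile
#' 95 % confidence interval per (pair, level).
#'
#' @param posterior An `hxt_posterior`.
#' @param signalling Calibrated [model_params()].
#' @param glucose_levels Constant glucose concentrations (% w/v).
#' @param n_samples Bootstrap draws (default 100).
#' @param seed Integer seed.
#' @return Tibble: `hxt, pair, glucose_pct, mean, lo, hi`.
#' @export
bootstrap_repression <- function(posterior, signalling,
                                 glucose_levels = c(0.01, 0.1, 1),
                                 n_samples = 100, seed = 1) {
  parts <- posterior$particles
  if (nrow(parts) == 0) rlang::abort("posterior has no particles")
  probe <- reference_calibration()$promoters$HXT4
  levels_at <- lapply(glucose_levels, function(g) {
    ss <- steady_state(g, signalling, probe)
    c(Mth1 = ss$M, Std1 = ss$S, Mig1 = ss$G1, Mig2 = ss$G2)
  })
  draws <- with_local_seed(seed, {
    idx <- sample.int(nrow(parts), n_samples, replace = TRUE, prob = parts$weight)
    purrr::map_dfr(idx, function(i) {
      pr <- parts$promoter[[i]]
      purrr::map_dfr(seq_along(glucose_levels), function(k) {
        tibble::tibble(
          glucose_pct = glucose_levels[k],
          MthStd = pair_repression(levels_at[[k]], pr, "MthStd"),
          MigMig = pair_repression(levels_at[[k]], pr, "MigMig")
        )
      })
    })
  })
  draws |>
    tidyr::pivot_longer(c("MthStd", "MigMig"),
      names_to = "pair", values_to = "repression"
    ) |>
    dplyr::group_by(.data$pair, .data$glucose_pct) |>
    dplyr::summarise(
      mean = mean(.data$repression),
      lo = stats::quantile(.data$repression, 0.025, names = FALSE),
      hi = stats::quantile(.data$repression, 0.975, names = FALSE),
      .groups = "drop"
    ) |>
    dplyr::mutate(hxt = posterior$hxt, .before = 1)
}

#' Affinity-class repression summary
#'
#' Averages per-HXT repression summaries over the transporter affinity
#' classes: low = HXT1 + HXT3, medium = HXT2 + HXT4, high = HXT6 + HXT7.
#'
#' @param summaries A tibble as returned by row-binding
#'   [bootstrap_repression()] results over HXTs.
#' @return Tibble: `affinity, pair, glucose_pct, mean`.
#' @export
affinity_repression <- function(summaries) {
  classes <- c(
    HXT1 = "low", HXT3 = "low", HXT2 = "medium",
    HXT4 = "medium", HXT6 = "high", HXT7 = "high"
  )
  summaries |>
    dplyr::mutate(affinity = unname(classes[.data$hxt])) |>
    dplyr::group_by(.data$affinity, .data$pair, .data$glucose_pct) |>
    dplyr::summarise(mean = mean(.data$mean), .groups = "drop")
}
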