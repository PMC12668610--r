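#' Signalling-network parameters
#'
#' All rates are per hour; totals and dissociation constants are in the same
#' arbitrary units as the corresponding state; glucose constants are in % w/v.
#' The parameters describe the Snf3-Rgt2/SNF1 network: Mth1 synthesis
#' (repressed by nuclear Mig1 and Mig2) and degradation (basal plus
#' sensor-mediated), nuclear Std1 shuttling at constant total, nuclear Mig1
#' shuttling at constant total with export proportional to SNF1 activity,
#' SNF1 activity (repressed by glucose, stimulated by nuclear Std1), Mig2
#' synthesis (repressed by Mth1 and Std1) and glucose-dependent degradation,
#' the two sensors' glucose responses, and the intracellular-glucose logistic.
#'
#' @param aM Maximal MTH1 synthesis rate.
#' @param K_M_mig1,K_M_mig2,n_M Mig1/Mig2 repression constants and Hill number
#'   on the MTH1 promoter.
#' @param d0M Basal Mth1 degradation rate.
#' @param dSnf3M,dRgt2M Sensor-mediated Mth1 degradation amplitudes.
#' @param ST Total Std1 (constant).
#' @param kinS Std1 nuclear import rate.
#' @param kout0S,koutSnf3S,koutRgt2S Basal and sensor-mediated Std1
#'   nuclear-export amplitudes.
#' @param G1T Total Mig1 (constant).
#' @param kinG1 Mig1 nuclear import rate.
#' @param e0,e1 Basal and SNF1-proportional Mig1 nuclear-export rates.
#' @param beta0,beta1,K_AS SNF1 activity baseline, Std1-stimulation amplitude,
#'   and Std1 half-saturation.
#' @param K_Ag,h_A Glucose half-repression constant and Hill number for SNF1
#'   inactivation.
#' @param aG2 Maximal MIG2 synthesis rate.
#' @param K_G2_mth1,K_G2_std1,n_G2 Mth1/Std1 repression constants and Hill
#'   number on the MIG2 promoter.
#' @param dG2max,dG2min,K_dG2 Mig2 degradation bounds (fast at zero glucose,
#'   slow in glucose) and glucose half-saturation.
#' @param K_snf3,h_snf3 High-affinity sensor (Snf3) glucose half-saturation
#'   and Hill number.
#' @param K_rgt2,h_rgt2 Low-affinity sensor (Rgt2) glucose half-saturation and
#'   Hill number.
#' @param gmax_scale Intracellular-glucose ceiling per unit extracellular.
#' @param r_g Default logistic growth rate of intracellular glucose (1/h).
#' @param r_g_table Optional data frame `(genotype, plateau_pct, r_g)` giving
#'   per-condition, per-genotype growth rates; rows override `r_g`.
#' @param L0 Logistic seed, the fraction of the intracellular ceiling present
#'   at glucose onset; fixed small so the half-rise time `log((1-L0)/L0)/r_g`
#'   is finite and set only by `r_g`.
#' @param snf1_glucose Which glucose pool inactivates SNF1:
#'   `"extracellular"` (default) or `"intracellular"`.
#' @param mig2_glucose Which glucose pool slows Mig2 degradation:
#'   `"intracellular"` (default) or `"extracellular"`.
#'
#' @return A `model_params` object (named list).
#' @export
model_params <- function(aM = 1,
                         K_M_mig1 = 0.5, K_M_mig2 = 0.5, n_M = 2,
                         d0M = 0.2, dSnf3M = 0.2, dRgt2M = 0.08,
                         ST = 1, kinS = 0.2,
                         kout0S = 0.05, koutSnf3S = 0.12, koutRgt2S = 0.36,
                         G1T = 1, kinG1 = 4, e0 = 0.4, e1 = 20,
                         beta0 = 0.2, beta1 = 1.5, K_AS = 0.3,
                         K_Ag = 0.1, h_A = 2,
                         aG2 = 1, K_G2_mth1 = 8, K_G2_std1 = 3, n_G2 = 2,
                         dG2max = 6, dG2min = 2.5, K_dG2 = 0.1,
                         K_snf3 = 0.05, h_snf3 = 2, K_rgt2 = 0.5, h_rgt2 = 2,
                         gmax_scale = 1, r_g = 7, r_g_table = NULL,
                         L0 = 0.01,
                         snf1_glucose = c("extracellular", "intracellular"),
                         mig2_glucose = c("intracellular", "extracellular")) {
  p <- list(
    aM = aM, K_M_mig1 = K_M_mig1, K_M_mig2 = K_M_mig2, n_M = n_M,
    d0M = d0M, dSnf3M = dSnf3M, dRgt2M = dRgt2M,
    ST = ST, kinS = kinS,
    kout0S = kout0S, koutSnf3S = koutSnf3S, koutRgt2S = koutRgt2S,
    G1T = G1T, kinG1 = kinG1, e0 = e0, e1 = e1,
    beta0 = beta0, beta1 = beta1, K_AS = K_AS, K_Ag = K_Ag, h_A = h_A,
    aG2 = aG2, K_G2_mth1 = K_G2_mth1, K_G2_std1 = K_G2_std1, n_G2 = n_G2,
    dG2max = dG2max, dG2min = dG2min, K_dG2 = K_dG2,
    K_snf3 = K_snf3, h_snf3 = h_snf3, K_rgt2 = K_rgt2, h_rgt2 = h_rgt2,
    gmax_scale = gmax_scale, r_g = r_g, L0 = L0,
    snf1_glucose = match.arg(snf1_glucose),
    mig2_glucose = match.arg(mig2_glucose)
  )
  p$r_g_table <- if (!is.null(r_g_table)) tibble::as_tibble(r_g_table) else NULL
  validate_model_params(p)
  structure(p, class = "model_params")
}

validate_model_params <- function(p) {
  pos <- c(
    "aM", "K_M_mig1", "K_M_mig2", "d0M", "kinS", "kinG1", "e0",
    "beta0", "beta1", "K_AS", "K_Ag", "aG2", "K_G2_mth1", "K_G2_std1",
    "K_dG2", "K_snf3", "K_rgt2", "gmax_scale", "r_g"
  )
  # totals and sensor amplitudes may be exactly zero after a deletion
  nonneg <- c(
    "ST", "G1T", "dSnf3M", "dRgt2M", "kout0S", "koutSnf3S", "koutRgt2S",
    "e1", "dG2max", "dG2min"
  )
  for (nm in pos) {
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0) {
      rlang::abort(paste0("model parameter ", nm, " must be > 0"))
    }
  }
  for (nm in nonneg) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 0) {
      rlang::abort(paste0("model parameter ", nm, " must be >= 0"))
    }
  }
  for (nm in c("n_M", "n_G2", "h_A", "h_snf3", "h_rgt2")) {
    if (!is.finite(p[[nm]]) || p[[nm]] < 1 || p[[nm]] > 8) {
      rlang::abort(paste0("Hill number ", nm, " must lie in [1, 8]"))
    }
  }
  if (p$dG2max < p$dG2min) rlang::abort("need dG2max >= dG2min")
  if (p$L0 <= 0 || p$L0 >= 1) rlang::abort("L0 must lie in (0, 1)")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> Snf3-Rgt2/SNF1 signalling parameters\n")
  num <- names(x)[vapply(x, is.numeric, logical(1))]
  vals <- unlist(x[num])
  cat(paste(sprintf("  %-10s %.4g", names(vals), vals), collapse = "\n"), "\n")
  cat(sprintf(
    "  SNF1 senses %s glucose; Mig2 degradation senses %s glucose\n",
    x$snf1_glucose, x$mig2_glucose
  ))
  invisible(x)
}

#' Update model parameters
#'
#' Returns a copy of `params` with the named numeric entries replaced, after
#' re-validation.
#' @param params A [model_params()].
#' @param ... Named replacements, e.g. `aM = 2`.
#' @return A [model_params()].
#' @export
update_params <- function(params, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown model parameter(s): ", paste(bad, collapse = ", ")))
  }
  p <- unclass(params)
  p[names(repl)] <- repl
  validate_model_params(p)
  structure(p, class = "model_params")
}

deletable_genes <- c("SNF3", "RGT2", "MTH1", "STD1", "MIG1")

#' Strain genotypes
#'
#' A genotype is the set of deleted regulator genes, a subset of
#' `{SNF3, RGT2, MTH1, STD1, MIG1}` (the genes deleted one at a time in the
#' experiments; MIG2 was not deleted because it acts redundantly with Mig1).
#' `genotype_label()` renders the conventional strain name; `parse_genotype()`
#' inverts it.
#'
#' @param deletions Character vector of deleted genes (case-insensitive);
#'   empty for wild type.
#' @return `as_genotype()` returns the validated uppercase deletion set.
#' @export
#' @examples
#' genotype_label(character(0)) # "wt"
#' genotype_label("MTH1") # "mth1Δ"
#' parse_genotype("std1Δ")
as_genotype <- function(deletions) {
  if (length(deletions) == 0) return(character(0))
  d <- toupper(deletions)
  bad <- setdiff(d, deletable_genes)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "unknown deletion(s): ", paste(bad, collapse = ", "),
      " (allowed: ", paste(deletable_genes, collapse = ", "), ")"
    ))
  }
  sort(unique(d))
}

#' @rdname as_genotype
#' @export
genotype_label <- function(deletions) {
  d <- as_genotype(deletions)
  if (length(d) == 0) return("wt")
  paste0(paste0(tolower(d), "Δ"), collapse = " ")
}

#' @rdname as_genotype
#' @param label A strain label such as `"wt"`, `"mth1Δ"` or `"mig1"`.
#' @export
parse_genotype <- function(label) {
  if (tolower(label) %in% c("wt", "wild-type", "wildtype", "wild type")) {
    return(character(0))
  }
  parts <- strsplit(gsub("Δ", "", label), "[ +]+")[[1]]
  as_genotype(parts[nzchar(parts)])
}

#' Apply gene deletions to the signalling parameters
#'
#' Deletions act structurally, never by refitting: `MTH1` zeroes Mth1
#' synthesis (`aM = 0`), `STD1` zeroes total Std1, `MIG1` zeroes total Mig1,
#' `SNF3` zeroes the Snf3-mediated Mth1-degradation and Std1-export
#' amplitudes, and `RGT2` likewise for Rgt2. All other parameters are
#' untouched.
#'
#' @param params A [model_params()].
#' @param deletions Deletion set, see [as_genotype()].
#' @return A `model_params` with the corresponding entries zeroed.
#' @export
apply_deletion <- function(params, deletions) {
  d <- as_genotype(deletions)
  p <- unclass(params)
  if ("MTH1" %in% d) p$aM <- 0
  if ("STD1" %in% d) p$ST <- 0
  if ("MIG1" %in% d) p$G1T <- 0
  if ("SNF3" %in% d) {
    p$dSnf3M <- 0
    p$koutSnf3S <- 0
  }
  if ("RGT2" %in% d) {
    p$dRgt2M <- 0
    p$koutRgt2S <- 0
  }
  # aM = 0 is only reachable through deletion, so skip the positivity check
  structure(p, class = "model_params")
}

#' Resolve the intracellular-glucose growth rate
#'
#' Looks up `r_g` for a (genotype, glucose plateau) pair in the parameter
#' set's `r_g_table`, falling back to the default `r_g`.
#'
#' @param params A [model_params()].
#' @param deletions Deletion set.
#' @param plateau_pct Plateau glucose concentration of the programme (% w/v).
#' @return Scalar rate (1/h).
#' @export
resolve_rg <- function(params, deletions = character(0), plateau_pct = NA) {
  tab <- params$r_g_table
  if (is.null(tab) || nrow(tab) == 0 || is.na(plateau_pct)) return(params$r_g)
  lbl <- genotype_label(deletions)
  hit <- tab[tab$genotype == lbl & abs(tab$plateau_pct - plateau_pct) < 1e-9, ]
  if (nrow(hit) == 0) {
    hit <- tab[tab$genotype == lbl & is.na(tab$plateau_pct), ]
  }
  if (nrow(hit) == 0) return(params$r_g)
  hit$r_g[[1]]
}

#' Serialise / deserialise model parameters as flat JSON
#'
#' Numeric entries are written flat; the two glucose-pool switches and the
#' optional `r_g_table` ride along. Units: rates 1/h, glucose constants
#' % w/v.
#'
#' @param params A [model_params()].
#' @param path File path.
#' @return `read_model_params()` returns a [model_params()].
#' @export
write_model_params <- function(params, path) {
  p <- unclass(params)
  if (!is.null(p$r_g_table)) p$r_g_table <- as.data.frame(p$r_g_table)
  jsonlite::write_json(p, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_params
#' @export
read_model_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(model_params, x)
}
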