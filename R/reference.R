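#' Packaged reference calibration (synthetic)
#'
#' A versioned, fully synthetic parameter set standing in for a best fit of
#' the signalling model plus per-HXT promoters. It was constructed once to
#' satisfy the qualitative behaviour the system is known to show and is the
#' ground truth for the package's synthetic data generator:
#'
#' * push-pull monotonicity — steady-state Mth1 + Std1 falls and nuclear
#'   Mig1 + Mig2 rises with constant glucose;
#' * a spike of Hxt4 after glucose removal, with low expression during a 1 %
#'   plateau;
#' * the deletion-strain orderings (e.g. much higher expression without
#'   glucose in mth1Δ, and in glucose in mig1Δ);
#' * the Std1-activates-SNF1 mechanism class (Std1's stimulation of SNF1
#'   dominates its share of MIG2-promoter repression);
#' * Mig1/Mig2 responding at least twice as fast as Mth1/Std1 in both phases
#'   of a 1 % pulse;
#' * low-affinity transporters (Hxt1, Hxt3) highest in 1 % glucose and
#'   high-affinity ones (Hxt6, Hxt7) highest in 0.01 %.
#'
#' Promoter structures are the modal inferred architectures: all four
#' repressors for HXT6 and HXT7; Std1 + Mig1 for HXT3; Mth1 + Mig1 for HXT2;
#' Std1 (alone) for HXT1; all four for HXT4. HXT5 is absent because it is not
#' regulated by this network.
#'
#' @return A list with elements `params` (a [model_params()], including a
#'   per-condition `r_g_table`) and `promoters` (named list of
#'   [promoter_params()] for HXT1-4, 6, 7).
#' @export
#' @examples
#' ref <- reference_calibration()
#' names(ref$promoters)
reference_calibration <- function() {
  conditions <- tibble::tibble(plateau_pct = c(0.2, 0.4, 1), r_g = c(5, 6, 7))
  genotypes <- c("wt", "mth1Δ", "std1Δ", "mig1Δ", "snf3Δ", "rgt2Δ")
  r_g_table <- tidyr::crossing(genotype = genotypes, conditions)
  params <- model_params(r_g_table = r_g_table)

  two <- function(x) stats::setNames(rep(2, length(x)), x)
  promoters <- list(
    HXT1 = promoter_params(
      structure = "Std1", aH = 15, dHmax = 0.8, dHmin = 0.25, K_dH = 0.1,
      K = c(Std1 = 0.3), n = two("Std1")
    ),
    HXT2 = promoter_params(
      structure = c("Mth1", "Mig1"), aH = 12, dHmax = 1, dHmin = 0.3, K_dH = 0.1,
      K = c(Mth1 = 1.2, Mig1 = 0.35), n = two(c("Mth1", "Mig1"))
    ),
    HXT3 = promoter_params(
      structure = c("Std1", "Mig1"), aH = 18, dHmax = 0.8, dHmin = 0.25, K_dH = 0.1,
      K = c(Std1 = 0.35, Mig1 = 2.5), n = two(c("Std1", "Mig1"))
    ),
    HXT4 = promoter_params(
      structure = hxt_repressors(), aH = 20, dHmax = 1.2, dHmin = 0.3, K_dH = 0.1,
      K = c(Mth1 = 1, Std1 = 1, Mig1 = 0.2, Mig2 = 0.2),
      n = two(hxt_repressors())
    ),
    HXT6 = promoter_params(
      structure = hxt_repressors(), aH = 16, dHmax = 0.9, dHmin = 0.3, K_dH = 0.1,
      K = c(Mth1 = 8, Std1 = 4, Mig1 = 0.25, Mig2 = 0.2),
      n = two(hxt_repressors())
    ),
    HXT7 = promoter_params(
      structure = hxt_repressors(), aH = 14, dHmax = 0.9, dHmin = 0.3, K_dH = 0.1,
      K = c(Mth1 = 7, Std1 = 3.5, Mig1 = 0.22, Mig2 = 0.18),
      n = two(hxt_repressors())
    )
  )
  list(params = params, promoters = promoters)
}

#' Mechanism-class read-out: how does Std1 act?
#'
#' Two degenerate mechanisms can explain the reduced expression of a tagged
#' HXT in glucose after deleting STD1: Std1 mainly stimulating SNF1 (so its
#' loss hyperactivates nuclear Mig1), or Std1 mainly repressing MIG2 (so its
#' loss de-represses Mig2). The classifier compares, at the glucose-free
#' steady state, Std1's share of SNF1 stimulation,
#' `beta1 S/(S + K_AS) / (beta0 + beta1 S/(S + K_AS))`, with Std1's share of
#' the MIG2-promoter repression weight; the parameter set is in the
#' Std1-activates-SNF1 class when the former exceeds the latter.
#'
#' @param params A [model_params()].
#' @param promoter A [promoter_params()] (any; only signalling states enter).
#' @return A list with `snf1_share`, `mig2_share`, and logical `std1_snf1`.
#' @export
mechanism_class <- function(params, promoter = reference_calibration()$promoters$HXT4) {
  ss <- steady_state(0, params, promoter)
  stim <- params$beta1 * ss$S / (ss$S + params$K_AS)
  snf1_share <- stim / (params$beta0 + stim)
  w_std <- (ss$S / params$K_G2_std1)^params$n_G2
  w_mth <- (ss$M / params$K_G2_mth1)^params$n_G2
  mig2_share <- if (w_std + w_mth > 0) w_std / (w_std + w_mth) else 0
  list(
    snf1_share = snf1_share, mig2_share = mig2_share,
    std1_snf1 = snf1_share > mig2_share
  )
}
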