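# shared fixtures: everything is generated in code, nothing is read from disk
ref_cal <- reference_calibration()
ref_params <- ref_cal$params
ref_hxt4 <- ref_cal$promoters$HXT4
pulse_1pct <- glucose_pulse(plateau_pct = 1)

# random but valid promoter parameter draws, reproducible
random_promoter <- function(structure = hxt_repressors()) {
  k <- stats::setNames(10^stats::runif(length(structure), -1.5, 1.5), structure)
  n <- stats::setNames(stats::runif(length(structure), 1, 8), structure)
  dmax <- 10^stats::runif(1, -1, 1)
  promoter_params(
    structure = structure,
    aH = 10^stats::runif(1, 0, 2),
    dHmax = dmax, dHmin = dmax * stats::runif(1, 0.05, 1),
    K_dH = 10^stats::runif(1, -2, 0),
    K = k, n = n
  )
}

# simulation horizon long enough for the slowest relaxation of a draw
relaxation_horizon <- function(params, promoter, ge) {
  dH_g <- promoter$dHmin +
    (promoter$dHmax - promoter$dHmin) * promoter$K_dH / (promoter$K_dH + ge)
  max(1500, 45 / min(dH_g, params$d0M, params$kinS, params$kinG1, params$dG2min))
}

# a jittered, valid variant of the reference signalling parameters
random_signalling <- function(spread = 0.4) {
  jit <- function(x) x * exp(stats::runif(1, -spread, spread))
  update_params(
    ref_params,
    aM = jit(ref_params$aM), d0M = jit(ref_params$d0M),
    dSnf3M = jit(ref_params$dSnf3M), dRgt2M = jit(ref_params$dRgt2M),
    kinS = jit(ref_params$kinS), kout0S = jit(ref_params$kout0S),
    kinG1 = jit(ref_params$kinG1), e0 = jit(ref_params$e0),
    e1 = jit(ref_params$e1), aG2 = jit(ref_params$aG2),
    K_G2_mth1 = jit(ref_params$K_G2_mth1), dG2max = ref_params$dG2max,
    K_M_mig1 = jit(ref_params$K_M_mig1), K_M_mig2 = jit(ref_params$K_M_mig2),
    beta0 = jit(ref_params$beta0), beta1 = jit(ref_params$beta1)
  )
}

# binding-site fixture with the expected promoter biases: low-affinity
# promoters Rgt1-heavy, high-affinity promoters Mig-heavy
bias_fixture_sites <- function() {
  tibble::tribble(
    ~promoter, ~tf, ~start, ~end, ~posterior,
    "HXT1", "Rgt1", 100, 112, 0.9,
    "HXT1", "Rgt1", 300, 312, 0.7,
    "HXT1", "Mig1", 210, 220, 0.2,
    "HXT3", "Rgt1", 150, 162, 0.8,
    "HXT3", "Rgt1", 420, 432, 0.6,
    "HXT3", "Mig2", 250, 260, 0.3,
    "HXT6", "Rgt1", 120, 132, 0.2,
    "HXT6", "Mig1", 200, 210, 0.9,
    "HXT6", "Mig2", 330, 340, 0.8,
    "HXT7", "Rgt1", 140, 152, 0.3,
    "HXT7", "Mig1", 260, 270, 0.8,
    "HXT7", "Mig2", 410, 420, 0.9
  )
}
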