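#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Defines the structural causal model exposure -> mediator -> outcome under
#' which two-sample (optionally two-cohort) summary statistics are generated:
#' a continuous exposure (BMI/WHR-like, SD units), a continuous mediator
#' (serum-calcium-like, SD units) and a binary outcome (kidney-stone-like,
#' log-odds scale). Instrument SNPs carry exposure effects
#' `gamma_j ~ N(0, sigma_gamma^2)`; a fraction of them are invalid and add a
#' direct (pleiotropic) outcome effect `alpha_j`. The mediator has its own
#' instruments `eta_j ~ N(0, sigma_eta^2)` — without them the mediator's
#' effect column is exactly proportional to the exposure's and multivariable
#' MR is unidentified. Optionally a block of reverse-causal SNPs affects the
#' outcome directly and is transmitted back to the exposure via
#' `reverse_path`, to exercise Steiger filtering.
#'
#' True marginal effects per SNP j: exposure `gamma_j (+ reverse_path * delta_j)`;
#' mediator `a_path * gamma_j + eta_j`; outcome
#' `(theta_direct + a_path * b_path) * gamma_j + b_path * eta_j +
#' sign(gamma_j) * alpha_j + delta_j`. The `sign(gamma_j)` factor expresses the
#' pleiotropic effect relative to the exposure-increasing allele, so
#' `pleiotropy_mean != 0` is directional in the orientation-invariant sense
#' that MR-Egger detects.
#' Observed effects add independent normal noise with
#' `se = 1 / sqrt(2 maf (1 - maf) n)` for continuous traits and
#' `se = 1 / sqrt(2 maf (1 - maf) n v (1 - v))`, `v` the case fraction, for the
#' binary outcome.
#'
#' @param m_snps total SNPs simulated.
#' @param m_instruments SNPs with nonzero exposure effect.
#' @param m_instruments_mediator SNPs with mediator-specific effects.
#' @param m_reverse SNPs with direct outcome effects transmitted to the
#'   exposure (reverse causal); default 0.
#' @param maf_range interval within (0, 0.5] for Uniform MAF draws.
#' @param sigma_gamma SD of instrument-exposure effects (SD units/allele).
#' @param sigma_eta SD of mediator-specific instrument effects.
#' @param sigma_delta SD of reverse-causal SNP outcome effects (log-odds).
#' @param theta_direct direct exposure->outcome effect c' (log-odds per SD).
#' @param a_path exposure->mediator effect A (mediator SD per exposure SD).
#' @param b_path mediator->outcome effect B (log-odds per mediator SD).
#' @param reverse_path outcome->exposure transmission for reverse SNPs.
#' @param pleiotropy_fraction proportion of exposure instruments with direct
#'   outcome effects (invalid instruments).
#' @param pleiotropy_mean,pleiotropy_sd distribution of direct effects alpha_j;
#'   `pleiotropy_mean != 0` gives directional pleiotropy.
#' @param n_exposure,n_mediator,n_outcome per-trait GWAS sample sizes (>= 100).
#' @param n_case_fraction proportion of cases in the outcome sample.
#' @param n_cohorts 1 or 2; with 2, the binary outcome GWAS is generated twice
#'   with independent noise (UK-Biobank/FinnGen-like two-cohort setting).
#' @param ld_block_size,ld_r2 block-diagonal LD structure for [simulate_ld()].
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(m_snps = 500,
                              m_instruments = 100,
                              m_instruments_mediator = 100,
                              m_reverse = 0,
                              maf_range = c(0.05, 0.5),
                              sigma_gamma = 0.05,
                              sigma_eta = 0.05,
                              sigma_delta = 0.05,
                              theta_direct = 0.1,
                              a_path = 0.5,
                              b_path = 0.2,
                              reverse_path = 0.3,
                              pleiotropy_fraction = 0,
                              pleiotropy_mean = 0,
                              pleiotropy_sd = 0.01,
                              n_exposure = 1e5,
                              n_mediator = 1e5,
                              n_outcome = 1e5,
                              n_case_fraction = 0.5,
                              n_cohorts = 1,
                              ld_block_size = 1,
                              ld_r2 = 0,
                              seed = 20230885) {
  cfg <- as.list(environment())
  class(cfg) <- "simulation_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  with(cfg, {
    if (m_instruments + m_instruments_mediator + m_reverse > m_snps) {
      stop("instrument + mediator + reverse SNP counts exceed m_snps")
    }
    if (length(maf_range) != 2L || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
        maf_range[1] > maf_range[2]) {
      stop("maf_range must be an interval within (0, 0.5]")
    }
    if (pleiotropy_fraction < 0 || pleiotropy_fraction > 1) {
      stop("pleiotropy_fraction must be in [0, 1]")
    }
    if (min(n_exposure, n_mediator, n_outcome) < 100) {
      stop("all sample sizes must be >= 100")
    }
    if (n_case_fraction <= 0 || n_case_fraction >= 1) {
      stop("n_case_fraction must be in (0, 1)")
    }
    if (!n_cohorts %in% c(1, 2)) stop("n_cohorts must be 1 or 2")
    if (ld_block_size < 1) stop("ld_block_size must be >= 1")
    if (ld_r2 < 0 || ld_r2 > 1) stop("ld_r2 must be in [0, 1]")
  })
  invisible(cfg)
}

# observed-association builder for one trait (one cohort draw)
sim_trait <- function(true_beta, maf, n, binary, case_fraction, ids, pos) {
  eff_n <- if (binary) n * case_fraction * (1 - case_fraction) else n
  se <- 1 / sqrt(2 * maf * (1 - maf) * eff_n)
  beta <- true_beta + stats::rnorm(length(true_beta), 0, se)
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  p[p == 0] <- .Machine$double.xmin   # keep p in (0, 1]
  df <- data.frame(
    variant_id = ids, chromosome = "1", position = pos,
    effect_allele = "A", other_allele = "G",
    eaf = maf, beta = beta, se = se, p_value = p, n = n,
    stringsAsFactors = FALSE
  )
  if (binary) {
    df$n_case <- round(n * case_fraction)
    df$n_control <- n - round(n * case_fraction)
  }
  df
}

#' Simulate GWAS summary statistics under a known causal structure
#'
#' @param config a [simulation_config()].
#' @return list with elements `exposure`, `mediator` ([summary_stats]),
#'   `outcome` (a [summary_stats] for `n_cohorts = 1`, else a list of two),
#'   and `truth` (a `ground_truth` list: `theta_total`, `theta_direct`,
#'   `a_path`, `b_path`, `proportion_mediated`, `valid_instrument_ids`,
#'   `invalid_instrument_ids`, `mediator_instrument_ids`,
#'   `reverse_instrument_ids`, per-SNP `gamma`, `maf`).
#' @export
simulate_sumstats <- function(config = simulation_config()) {
  validate_config(config)
  set.seed(config$seed)
  m <- config$m_snps
  ids <- sprintf("rs%06d", seq_len(m))
  pos <- seq_len(m) * 10000
  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])

  idx_instr <- seq_len(config$m_instruments)
  idx_med <- seq_len(config$m_instruments_mediator) + config$m_instruments
  idx_rev <- seq_len(config$m_reverse) + config$m_instruments +
    config$m_instruments_mediator
  if (config$m_reverse == 0) idx_rev <- integer(0)
  if (config$m_instruments_mediator == 0) idx_med <- integer(0)
  if (config$m_instruments == 0) idx_instr <- integer(0)

  gamma <- numeric(m)
  gamma[idx_instr] <- stats::rnorm(length(idx_instr), 0, config$sigma_gamma)
  eta <- numeric(m)
  eta[idx_med] <- stats::rnorm(length(idx_med), 0, config$sigma_eta)
  delta <- numeric(m)
  delta[idx_rev] <- stats::rnorm(length(idx_rev), 0, config$sigma_delta)

  n_invalid <- round(config$pleiotropy_fraction * length(idx_instr))
  idx_invalid <- if (n_invalid > 0) idx_instr[seq_len(n_invalid)] else integer(0)
  alpha <- numeric(m)
  if (n_invalid > 0) {
    alpha[idx_invalid] <- stats::rnorm(n_invalid, config$pleiotropy_mean,
                                       config$pleiotropy_sd)
  }

  theta_total <- config$theta_direct + config$a_path * config$b_path
  true_exp <- gamma + config$reverse_path * delta
  true_med <- config$a_path * true_exp + eta
  # pleiotropic effects are directional relative to the exposure-increasing
  # allele (allele coding is arbitrary, so a fixed-sign alpha would wash out
  # under orientation); sign(gamma) re-expresses alpha on that coding
  orient <- ifelse(gamma >= 0, 1, -1)
  true_out <- theta_total * gamma + config$b_path * eta + orient * alpha + delta

  exposure <- summary_stats(
    sim_trait(true_exp, maf, config$n_exposure, FALSE, NA, ids, pos),
    trait_name = "exposure", trait_type = "continuous", validate = FALSE)
  mediator <- summary_stats(
    sim_trait(true_med, maf, config$n_mediator, FALSE, NA, ids, pos),
    trait_name = "mediator", trait_type = "continuous", validate = FALSE)
  out1 <- summary_stats(
    sim_trait(true_out, maf, config$n_outcome, TRUE, config$n_case_fraction,
              ids, pos),
    trait_name = "outcome", trait_type = "binary", validate = FALSE)
  outcome <- if (config$n_cohorts == 2) {
    out2 <- summary_stats(
      sim_trait(true_out, maf, config$n_outcome, TRUE, config$n_case_fraction,
                ids, pos),
      trait_name = "outcome_cohort2", trait_type = "binary", validate = FALSE)
    out1$trait_name <- "outcome_cohort1"
    list(cohort1 = out1, cohort2 = out2)
  } else {
    out1
  }

  truth <- structure(list(
    theta_total = theta_total,
    theta_direct = config$theta_direct,
    a_path = config$a_path,
    b_path = config$b_path,
    proportion_mediated = if (theta_total != 0) {
      config$a_path * config$b_path / theta_total
    } else NA_real_,
    valid_instrument_ids = ids[setdiff(idx_instr, idx_invalid)],
    invalid_instrument_ids = ids[idx_invalid],
    mediator_instrument_ids = ids[idx_med],
    reverse_instrument_ids = ids[idx_rev],
    gamma = stats::setNames(gamma, ids),
    maf = stats::setNames(maf, ids)
  ), class = "ground_truth")

  list(exposure = exposure, mediator = mediator, outcome = outcome,
       truth = truth)
}

#' Simulate a block-diagonal LD matrix
#'
#' Consecutive SNPs are grouped into blocks of `ld_block_size`; within-block
#' off-diagonal r-squared is `ld_r2`, cross-block 0, diagonal 1.
#'
#' @param config a [simulation_config()].
#' @return an [ld_matrix] over the simulated variant IDs.
#' @export
simulate_ld <- function(config = simulation_config()) {
  validate_config(config)
  m <- config$m_snps
  ids <- sprintf("rs%06d", seq_len(m))
  block <- (seq_len(m) - 1L) %/% config$ld_block_size
  r2 <- outer(block, block, `==`) * config$ld_r2
  diag(r2) <- 1
  ld_matrix(r2, ids)
}
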