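#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: `adjusted_(i) = min over j >= rank(i) of p_(j) m / j`,
#' capped at 1, returned in the input order.
#'
#' @param p p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  m <- length(p)
  if (m == 0L) stop("empty p-value vector")
  if (any(is.na(p)) || any(p <= 0) || any(p > 1)) {
    stop("p-values must be in (0, 1]")
  }
  ord <- order(p, decreasing = TRUE)
  adj_sorted <- pmin(1, cummin(p[ord] * m / rank(p, ties.method = "max")[ord]))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Assemble a pipeline run configuration
#'
#' Traits may be given as [summary_stats] objects or as
#' `list(path =, schema =, trait_type =)` specs resolved at run time.
#'
#' @param exposures named list of exposure traits.
#' @param outcome the outcome trait (binary, log-odds scale).
#' @param mediators named list of candidate mediator traits (may be empty).
#' @param ld optional [ld_matrix] or file path for clumping.
#' @param p_instrument instrument significance threshold (default `5e-8`).
#' @param clump_r2,clump_window clumping parameters (defaults 0.01, 10 Mb).
#' @param i2_exclude meta-analysis heterogeneity exclusion threshold (75).
#' @param fdr_level FDR control level (0.05).
#' @param egger_alpha Egger-intercept test level for estimator selection.
#' @param palindrome_eaf_window see [harmonize()].
#' @param min_instruments minimum harmonizable instruments per pair (3).
#' @param always_sensitivity run leave-one-out and Steiger stages regardless
#'   of post-FDR significance (default FALSE: conditional).
#' @param seed root seed for all stochastic stages (weighted-median bootstrap).
#' @return a validated `mr_run_config` list.
#' @export
mr_run_config <- function(exposures, outcome, mediators = list(), ld = NULL,
                          p_instrument = 5e-8, clump_r2 = 0.01,
                          clump_window = 1e7, i2_exclude = 75,
                          fdr_level = 0.05, egger_alpha = 0.05,
                          palindrome_eaf_window = 0.08, min_instruments = 3,
                          always_sensitivity = FALSE, seed = 1L) {
  stopifnot(p_instrument > 0, p_instrument < 1,
            clump_r2 > 0, clump_r2 <= 1,
            i2_exclude >= 0, i2_exclude <= 100,
            fdr_level > 0, fdr_level < 1,
            egger_alpha > 0, egger_alpha < 1,
            min_instruments >= 1)
  cfg <- list(exposures = exposures, outcome = outcome, mediators = mediators,
              ld = ld, p_instrument = p_instrument, clump_r2 = clump_r2,
              clump_window = clump_window, i2_exclude = i2_exclude,
              fdr_level = fdr_level, egger_alpha = egger_alpha,
              palindrome_eaf_window = palindrome_eaf_window,
              min_instruments = min_instruments,
              always_sensitivity = always_sensitivity, seed = as.integer(seed))
  # every file-based trait must exist at validation time
  for (tr in c(cfg$exposures, cfg$mediators, list(cfg$outcome))) {
    if (is.list(tr) && !inherits(tr, "summary_stats") && !is.null(tr$path) &&
        !file.exists(tr$path)) {
      stop("trait file does not exist: ", tr$path)
    }
  }
  class(cfg) <- "mr_run_config"
  cfg
}

resolve_trait <- function(x, default_type = "continuous") {
  if (inherits(x, "summary_stats")) return(x)
  if (is.list(x) && !is.null(x$path)) {
    return(read_sumstats(x$path, schema = x$schema,
                         trait_name = x$trait_name %||% basename(x$path),
                         trait_type = x$trait_type %||% default_type))
  }
  stop("trait must be a summary_stats object or a list with a path")
}

resolve_ld <- function(ld) {
  if (is.null(ld) || inherits(ld, "ld_matrix")) return(ld)
  if (is.character(ld)) return(read_ld_matrix(ld))
  stop("ld must be NULL, an ld_matrix, or a file path")
}

# one exposure-outcome pair: selection, clumping, harmonization, all fits
fit_pair <- function(exposure, outcome, cfg, ld, seed) {
  instruments <- tryCatch(
    suppressWarnings(select_instruments(exposure, cfg$p_instrument)),
    error = function(e) NULL)
  if (is.null(instruments) || nrow(instruments) == 0L) {
    return(list(skipped = "no genome-wide-significant instruments"))
  }
  if (!is.null(ld)) {
    instruments <- ld_clump(instruments, ld, cfg$clump_r2, cfg$clump_window)
  }
  exposure_sel <- exposure
  exposure_sel$data <- instruments
  hset <- tryCatch(
    harmonize(exposure_sel, outcome, cfg$palindrome_eaf_window),
    error = function(e) NULL)
  if (is.null(hset) || nrow(hset) < cfg$min_instruments) {
    return(list(skipped = "insufficient instruments"))
  }
  fits <- list(ivw = mr_ivw(hset), egger = mr_egger(hset))
  fits$weighted_median <- tryCatch(
    mr_weighted_median(hset, seed = seed), error = function(e) NULL)
  fits$contamination_mixture <- tryCatch(
    mr_conmix(hset), error = function(e) NULL)
  primary <- select_primary_estimate(fits$ivw, fits$egger, cfg$egger_alpha)
  strength <- instrument_strength(hset$beta_exposure, hset$eaf_exposure,
                                  n = hset$n_outcome[1])
  list(hset = hset, fits = fits, primary = primary, strength = strength)
}

#' Univariable MR screen across exposure-outcome pairs
#'
#' For every exposure: select and clump instruments, harmonize against the
#' outcome, fit IVW, MR-Egger, weighted median and contamination mixture,
#' choose the primary estimate by the Egger-intercept rule, and apply BH-FDR
#' across the family of IVW p-values. Leave-one-out and Steiger-filtered
#' re-estimates run for pairs significant after FDR (or always with
#' `always_sensitivity`). A bidirectional (outcome -> exposure) IVW runs for
#' every pair when the outcome has instruments of its own. Failures and
#' skips are per-pair, never fatal to the screen.
#'
#' @param config an [mr_run_config()].
#' @param outcome optional override of the configured outcome (used by the
#'   full analysis to screen mediators against the outcome).
#' @param exposures optional override of the configured exposure list.
#' @return `screen_report`: `pairs` summary data.frame (exposure, outcome,
#'   n_snp, selected method, estimate, se, p_ivw, fdr_p, significant,
#'   intercept_p, Q block, skip reason) and `details`, a per-pair list with
#'   the harmonized set and all fitted results.
#' @export
run_univariable_screen <- function(config, outcome = NULL, exposures = NULL) {
  stopifnot(inherits(config, "mr_run_config"))
  outcome <- resolve_trait(outcome %||% config$outcome, "binary")
  exposures <- exposures %||% config$exposures
  exposures <- lapply(exposures, resolve_trait)
  if (is.null(names(exposures))) {
    names(exposures) <- vapply(exposures, function(e) e$trait_name, character(1))
  }
  ld <- resolve_ld(config$ld)

  details <- list()
  for (nm in names(exposures)) {
    details[[nm]] <- tryCatch(
      fit_pair(exposures[[nm]], outcome, config, ld, seed = config$seed),
      error = function(e) list(skipped = paste("error:", conditionMessage(e))))
  }

  fitted <- !vapply(details, function(d) is.null(d$fits), logical(1))
  ivw_p <- vapply(details[fitted], function(d) d$fits$ivw$p, numeric(1))
  fdr_p <- if (any(fitted)) bh_fdr(ivw_p) else numeric(0)

  rows <- list()
  i_f <- 0L
  for (nm in names(details)) {
    d <- details[[nm]]
    if (is.null(d$fits)) {
      rows[[nm]] <- data.frame(exposure = nm, outcome = outcome$trait_name,
                               n_snp = NA_integer_, method = NA_character_,
                               estimate = NA_real_, se = NA_real_,
                               p_ivw = NA_real_, fdr_p = NA_real_,
                               significant = FALSE,
                               intercept_p = NA_real_, q = NA_real_,
                               q_p = NA_real_,
                               skipped = d$skipped, stringsAsFactors = FALSE)
      next
    }
    i_f <- i_f + 1L
    d$fdr_p <- fdr_p[i_f]
    d$significant <- d$fdr_p < config$fdr_level
    run_sens <- d$significant || config$always_sensitivity
    if (run_sens) {
      d$leave_one_out <- tryCatch(
        leave_one_out(d$hset, mr_ivw), error = function(e) NULL)
      d$steiger <- tryCatch({
        st <- steiger_filter(d$hset)
        if (nrow(st$retained) >= 2L) st$refit <- mr_ivw(st$retained)
        st
      }, error = function(e) NULL)
    }
    # bidirectional: outcome as exposure, when it has instruments
    d$bidirectional <- tryCatch({
      rev <- fit_pair(outcome, exposures[[nm]], config, ld, seed = config$seed)
      if (is.null(rev$fits)) NULL else rev$fits$ivw
    }, error = function(e) NULL)
    details[[nm]] <- d
    rows[[nm]] <- data.frame(
      exposure = nm, outcome = outcome$trait_name,
      n_snp = d$primary$n_snp, method = d$primary$method,
      estimate = d$primary$estimate, se = d$primary$se,
      p_ivw = d$fits$ivw$p, fdr_p = d$fdr_p, significant = d$significant,
      intercept_p = d$fits$egger$intercept_p,
      q = d$fits$ivw$q, q_p = d$fits$ivw$q_p,
      skipped = NA_character_, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, details = details,
                 outcome = outcome$trait_name),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("MR screen against '%s' (%d pair(s))\n", x$outcome, nrow(x$pairs)))
  print(x$pairs[, c("exposure", "n_snp", "method", "estimate", "p_ivw",
                    "fdr_p", "significant", "skipped")], row.names = FALSE)
  invisible(x)
}

#' Full exposure -> mediator -> outcome analysis
#'
#' Executes the three-stage workflow: (Q2) exposures against the outcome;
#' (Q3) candidate mediators against the outcome; (Q4) for each mediator
#' passing Q3 after FDR, exposure -> mediator MR (the A path), multivariable
#' MR of exposure + mediator on the outcome (direct c' and B paths), and the
#' mediation decomposition. A provenance block records seed, thresholds and
#' package version.
#'
#' @param config an [mr_run_config()] with non-empty `mediators`.
#' @return list of class `mr_analysis_bundle`: `q2_screen`, `q3_screen`,
#'   `q4` (per exposure x passing mediator: `a_path` fit, `mvmr`,
#'   `mediation`), `provenance`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "mr_run_config"))
  outcome <- resolve_trait(config$outcome, "binary")
  exposures <- lapply(config$exposures, resolve_trait)
  mediators <- lapply(config$mediators, resolve_trait)

  q2 <- run_univariable_screen(config, outcome = outcome, exposures = exposures)
  q3 <- if (length(mediators) > 0L) {
    run_univariable_screen(config, outcome = outcome, exposures = mediators)
  } else NULL

  q4 <- list()
  passing <- if (!is.null(q3)) {
    q3$pairs$exposure[which(q3$pairs$significant)]
  } else character(0)
  if (length(passing) == 0L) {
    message("no mediator passes the outcome screen; mediation stage skipped")
  }
  for (med_nm in passing) {
    for (exp_nm in names(exposures)) {
      d2 <- q2$details[[exp_nm]]
      if (is.null(d2$fits)) next
      key <- paste(exp_nm, med_nm, sep = "->")
      q4[[key]] <- tryCatch({
        a_fit <- fit_pair(exposures[[exp_nm]], mediators[[med_nm]], config,
                          resolve_ld(config$ld), seed = config$seed)
        if (is.null(a_fit$fits)) stop("A path: ", a_fit$skipped)
        mv_set <- harmonize_mv(
          stats::setNames(list(exposures[[exp_nm]], mediators[[med_nm]]),
                          c(exp_nm, med_nm)),
          outcome, config$palindrome_eaf_window)
        # MVMR instrument set: union of per-trait instruments, restricted to
        # jointly harmonized SNPs
        instr_ids <- unique(c(
          suppressWarnings(select_instruments(exposures[[exp_nm]],
                                              config$p_instrument))$variant_id,
          suppressWarnings(select_instruments(mediators[[med_nm]],
                                              config$p_instrument))$variant_id))
        mv_sub <- mv_set[mv_set$variant_id %in% instr_ids, , drop = FALSE]
        mv <- mvmr_fit(mv_sub, exposures = c(exp_nm, med_nm))
        med <- mediate(
          total = q2$details[[exp_nm]]$fits$ivw,
          a_path = a_fit$fits$ivw,
          b_path = mv$estimates[mv$estimates$exposure == med_nm, ],
          direct = mv$estimates[mv$estimates$exposure == exp_nm, ])
        list(a_path = a_fit$fits$ivw, mvmr = mv, mediation = med)
      }, error = function(e) list(skipped = conditionMessage(e)))
    }
  }

  structure(list(
    q2_screen = q2, q3_screen = q3, q4 = q4,
    provenance = list(
      package_version = as.character(utils::packageVersion("stonemr")),
      seed = config$seed,
      thresholds = config[c("p_instrument", "clump_r2", "clump_window",
                            "i2_exclude", "fdr_level", "egger_alpha",
                            "palindrome_eaf_window", "min_instruments")],
      timestamp = NA_character_  # deliberately unset: byte-identical reruns
    )
  ), class = "mr_analysis_bundle")
}
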