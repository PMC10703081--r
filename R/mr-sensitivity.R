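#' Leave-one-out sensitivity analysis
#'
#' Refits the estimator `n_snp` times, omitting one SNP each time, and flags
#' SNPs whose omission changes the sign of the estimate or moves it by more
#' than one (full-set) standard error — the signature of a single-variant
#' driver.
#'
#' @param set a `harmonized_set` with at least 3 SNPs.
#' @param method estimator function taking the set, default [mr_ivw].
#' @return data.frame with one row per omitted SNP: `omitted`, `estimate`,
#'   `se`, `p`, `delta` (shift from the full estimate), `flagged`. The full
#'   fit is in `attr(, "full")`.
#' @export
leave_one_out <- function(set, method = mr_ivw) {
  n <- nrow(set)
  if (n < 3L) stop("leave-one-out requires at least 3 SNPs")
  full <- method(set)
  rows <- lapply(seq_len(n), function(i) {
    fit <- method(set[-i, , drop = FALSE])
    data.frame(omitted = set$variant_id[i], estimate = fit$estimate,
               se = fit$se, p = fit$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta <- out$estimate - full$estimate
  out$flagged <- sign(out$estimate) != sign(full$estimate) |
    abs(out$delta) > full$se
  attr(out, "full") <- full
  out
}

# variance explained by one SNP in a trait
snp_r2 <- function(beta, se, eaf, n, binary) {
  maf <- pmin(eaf, 1 - eaf)
  if (binary) {
    z2 <- (beta / se)^2
    z2 / (z2 + n)
  } else {
    2 * beta^2 * maf * (1 - maf)
  }
}

#' Steiger directionality test and filtering
#'
#' Per SNP, compares the variance explained in the exposure with that in the
#' outcome (continuous traits: `2 beta^2 MAF (1 - MAF)`; binary traits: the
#' `Z^2/(Z^2 + N)` approximation). A SNP supports the assumed exposure ->
#' outcome direction when it explains strictly more variance in the exposure.
#' The p-value tests the difference of the two correlations via Fisher's z
#' (the samples are independent in the two-sample setting).
#'
#' @param set a `harmonized_set`.
#' @param n_exp,n_out trait sample sizes; defaults taken from the set's
#'   `n_exposure`/`n_outcome` columns.
#' @param outcome_binary is the outcome binary (log-odds scale)? Default from
#'   the set's `outcome_type` attribute, else TRUE.
#' @return list of class `steiger_result`: per-SNP data.frame `snps`
#'   (`r2_exposure`, `r2_outcome`, `direction_correct`, `steiger_p`) and
#'   `retained`, the subset of `set` with `direction_correct = TRUE`.
#' @export
steiger_filter <- function(set, n_exp = NULL, n_out = NULL,
                           outcome_binary = NULL) {
  v <- hset_vectors(set)
  n_exp <- n_exp %||% set$n_exposure
  n_out <- n_out %||% set$n_outcome
  if (is.null(n_exp) || is.null(n_out) || anyNA(n_exp) || anyNA(n_out)) {
    stop("sample sizes required for the Steiger test")
  }
  if (is.null(outcome_binary)) {
    outcome_binary <- identical(attr(set, "outcome_type"), "binary") ||
      is.null(attr(set, "outcome_type"))
  }
  r2_exp <- snp_r2(v$bx, v$sx, set$eaf_exposure, n_exp, binary = FALSE)
  r2_out <- snp_r2(v$by, v$sy, set$eaf_outcome %||% set$eaf_exposure,
                   n_out, binary = outcome_binary)
  direction <- r2_exp > r2_out
  z1 <- atanh(pmin(sqrt(r2_exp), 1 - 1e-12))
  z2 <- atanh(pmin(sqrt(r2_out), 1 - 1e-12))
  zstat <- (z1 - z2) / sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  steiger_p <- 2 * stats::pnorm(-abs(zstat))
  snps <- data.frame(variant_id = set$variant_id,
                     r2_exposure = r2_exp, r2_outcome = r2_out,
                     direction_correct = direction, steiger_p = steiger_p,
                     stringsAsFactors = FALSE)
  retained <- set[direction, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(snps = snps, retained = retained), class = "steiger_result")
}

#' Choose the primary estimate between IVW and MR-Egger
#'
#' The selection rule: when the MR-Egger intercept is compatible with zero
#' (`intercept_p >= 0.05`), IVW is the estimate of best fit; when the
#' intercept suggests directional pleiotropy (`intercept_p < 0.05`), the
#' MR-Egger slope is used instead.
#'
#' @param ivw,egger `mr_result`s fitted on the same instrument set.
#' @param alpha intercept test level, default 0.05.
#' @return the selected `mr_result`, with a `rationale` string attached.
#' @export
select_primary_estimate <- function(ivw, egger, alpha = 0.05) {
  stopifnot(inherits(ivw, "mr_result"), inherits(egger, "mr_result"))
  if (is.null(egger$intercept_p)) stop("egger result lacks an intercept block")
  if (egger$intercept_p < alpha) {
    egger$rationale <- sprintf(
      "MR-Egger selected: intercept p = %.3g < %.2g suggests directional pleiotropy",
      egger$intercept_p, alpha)
    egger
  } else {
    ivw$rationale <- sprintf(
      "IVW selected: MR-Egger intercept compatible with zero (p = %.3g >= %.2g)",
      egger$intercept_p, alpha)
    ivw
  }
}
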