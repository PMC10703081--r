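#' Multivariable MR: direct effects of several exposures
#'
#' Weighted multivariable regression of outcome effects on the matrix of
#' exposure effects without an intercept, weights `1/se_outcome^2`. Each
#' coefficient is the direct (conditional) effect of that exposure given the
#' co-exposures. Residual Cochran's Q is reported; an `egger = TRUE` variant
#' adds an intercept after orienting SNPs to the first exposure.
#'
#' @param set an `mv_harmonized_set` from [harmonize_mv()], or a data.frame
#'   with `beta_<exposure>` columns plus `beta_outcome`, `se_outcome`.
#' @param exposures exposure names; default from the set's
#'   `exposure_names` attribute or the `beta_*` columns.
#' @param egger include an intercept (MVMR-Egger), default FALSE.
#' @return `mvmr_result`: data.frame `estimates` (per exposure:
#'   `direct_estimate`, `se`, `ci_lower`, `ci_upper`, `p`), plus `n_snp`,
#'   `q`, `q_df`, `q_p` and an intercept block when `egger = TRUE`.
#' @export
mvmr_fit <- function(set, exposures = NULL, egger = FALSE) {
  exposures <- exposures %||% attr(set, "exposure_names")
  if (is.null(exposures)) {
    bcols <- grep("^beta_", names(set), value = TRUE)
    exposures <- sub("^beta_", "", setdiff(bcols, "beta_outcome"))
  }
  if (length(exposures) < 2L) stop("multivariable MR needs >= 2 exposures")
  bcols <- paste0("beta_", exposures)
  stopifnot(all(c(bcols, "beta_outcome", "se_outcome") %in% names(set)))
  X <- as.matrix(set[, bcols, drop = FALSE])
  y <- set$beta_outcome
  n <- nrow(X)
  if (n <= length(exposures)) stop("need more SNPs than exposures")
  w <- 1 / set$se_outcome^2
  # an all-zero effect column carries no instrument strength: report NA for
  # that exposure and fit the rest (distinct from genuine collinearity)
  zero_col <- apply(X, 2, function(col) all(col == 0))
  dropped_exposures <- exposures[zero_col]
  if (any(zero_col)) {
    message("exposure(s) with all-zero effects dropped from MVMR: ",
            paste(dropped_exposures, collapse = ", "))
    X <- X[, !zero_col, drop = FALSE]
    exposures_fit <- exposures[!zero_col]
    if (ncol(X) == 0L) stop("no exposure with nonzero effects")
  } else {
    exposures_fit <- exposures
  }
  if (egger) {
    flip <- sign(X[, 1]); flip[flip == 0] <- 1
    X <- X * flip
    y <- y * flip
    X <- cbind(`(intercept)` = 1, X)
  }
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop("collinear exposure effect columns: ", paste(dep, collapse = ", "))
  }
  XtW <- t(X * w)
  vc <- solve(XtW %*% X)
  fit <- drop(vc %*% (XtW %*% y))
  resid <- y - drop(X %*% fit)
  q <- sum(w * resid^2)
  q_df <- n - ncol(X)
  q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  infl <- max(1, sqrt(q / q_df))
  ses <- sqrt(diag(vc)) * infl
  idx <- if (egger) -1L else seq_along(fit)
  est_fit <- fit[idx]; se_fit <- ses[idx]
  est <- se_fit_all <- rep(NA_real_, length(exposures))
  est[match(exposures_fit, exposures)] <- est_fit
  se_fit_all[match(exposures_fit, exposures)] <- se_fit
  se <- se_fit_all
  z <- stats::qnorm(0.975)
  estimates <- data.frame(
    exposure = exposures, direct_estimate = est, se = se,
    ci_lower = est - z * se, ci_upper = est + z * se,
    p = 2 * stats::pnorm(-abs(est / se)),
    stringsAsFactors = FALSE, row.names = NULL)
  out <- list(estimates = estimates, n_snp = n, q = q, q_df = q_df, q_p = q_p)
  if (egger) {
    out$intercept <- fit[1]
    out$intercept_se <- ses[1]
    out$intercept_p <- 2 * stats::pnorm(-abs(fit[1] / ses[1]))
  }
  structure(out, class = "mvmr_result")
}

#' @export
print.mvmr_result <- function(x, ...) {
  cat(sprintf("Multivariable MR on %d SNPs (residual Q = %.2f, df %d, p = %.3g)\n",
              x$n_snp, x$q, x$q_df, x$q_p))
  print(x$estimates, row.names = FALSE)
  invisible(x)
}

#' Mediation decomposition by the product of coefficients
#'
#' Given the total effect of the exposure on the outcome (c), the effect of
#' the exposure on the mediator (A) and the effect of the mediator on the
#' outcome adjusted for the exposure (B), the indirect effect is `A x B`
#' with delta-method variance `A^2 var(B) + B^2 var(A)`, and the proportion
#' mediated is `indirect / c` with delta-method SE. The direct effect is
#' reported both as the difference `c - A x B` and, when supplied, as the
#' multivariable-MR conditional estimate c'.
#'
#' @param total `mr_result` for exposure -> outcome (c).
#' @param a_path `mr_result` for exposure -> mediator (A).
#' @param b_path `mr_result` or one row of [mvmr_fit()] estimates for
#'   mediator -> outcome given the exposure (B).
#' @param direct optional `mr_result`-like direct effect c' from MVMR.
#' @return `mediation_result` list: `total`, `direct_product`
#'   (`c - A x B`), `direct_mvmr` (c' when supplied), `a_path`, `b_path`,
#'   `indirect`, `proportion_mediated`, each with `estimate`/`se`/CI where
#'   defined, and `proportion_defined`.
#' @export
mediate <- function(total, a_path, b_path, direct = NULL) {
  get_es <- function(x) {
    if (inherits(x, "mr_result")) {
      c(x$estimate, x$se)
    } else if (is.data.frame(x)) {
      c(x$direct_estimate[1], x$se[1])
    } else if (is.numeric(x) && length(x) == 2L) {
      x
    } else stop("cannot interpret effect input")
  }
  ct <- get_es(total); a <- get_es(a_path); b <- get_es(b_path)
  indirect <- a[1] * b[1]
  var_ind <- a[1]^2 * b[2]^2 + b[1]^2 * a[2]^2
  prop_defined <- ct[1] != 0
  if (prop_defined) {
    prop <- indirect / ct[1]
    var_prop <- var_ind / ct[1]^2 + indirect^2 * ct[2]^2 / ct[1]^4
  } else {
    prop <- NA_real_
    var_prop <- NA_real_
    warning("total effect is zero: proportion mediated undefined")
  }
  dd <- ct[1] - indirect
  var_dd <- ct[2]^2 + var_ind   # conservative: ignores cov(c, AB)
  z <- stats::qnorm(0.975)
  block <- function(est, se) {
    list(estimate = est, se = se, ci_lower = est - z * se, ci_upper = est + z * se)
  }
  structure(list(
    total = block(ct[1], ct[2]),
    a_path = block(a[1], a[2]),
    b_path = block(b[1], b[2]),
    indirect = block(indirect, sqrt(var_ind)),
    direct_product = block(dd, sqrt(var_dd)),
    direct_mvmr = if (!is.null(direct)) {
      d <- get_es(direct); block(d[1], d[2])
    },
    proportion_mediated = block(prop, sqrt(var_prop)),
    proportion_defined = prop_defined
  ), class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  fmt <- function(nm, b) {
    if (is.null(b)) return()
    cat(sprintf("  %-20s %8.4f (se %.4f)\n", nm, b$estimate, b$se))
  }
  cat("Mediation decomposition (product method primary)\n")
  fmt("total (c)", x$total)
  fmt("A (exp->med)", x$a_path)
  fmt("B (med->out|exp)", x$b_path)
  fmt("indirect (A x B)", x$indirect)
  fmt("direct (c - A x B)", x$direct_product)
  fmt("direct (MVMR c')", x$direct_mvmr)
  fmt("proportion mediated", x$proportion_mediated)
  invisible(x)
}
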