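mr_result <- function(method, estimate, se, p = NULL, n_snp, level = 0.95,
                      q = NULL, q_df = NULL, q_p = NULL,
                      intercept = NULL, intercept_se = NULL, intercept_p = NULL,
                      ci_lower = NULL, ci_upper = NULL, ci_set = NULL,
                      extra = NULL) {
  z <- stats::qnorm((1 + level) / 2)
  if (is.null(ci_lower)) ci_lower <- estimate - z * se
  if (is.null(ci_upper)) ci_upper <- estimate + z * se
  if (is.null(p)) p <- 2 * stats::pnorm(-abs(estimate / se))
  structure(
    c(list(method = method, estimate = estimate, se = se,
           ci_lower = ci_lower, ci_upper = ci_upper, p = p, n_snp = n_snp,
           q = q, q_df = q_df, q_p = q_p,
           intercept = intercept, intercept_se = intercept_se,
           intercept_p = intercept_p, ci_set = ci_set),
      extra),
    class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s: estimate %.4f (se %.4f, 95%% CI %.4f to %.4f), p = %.3g, %d SNP(s)\n",
              x$method, x$estimate, x$se, x$ci_lower, x$ci_upper, x$p, x$n_snp))
  if (!is.null(x$q)) {
    cat(sprintf("  heterogeneity Q = %.2f (df %d), p = %.3g\n", x$q, x$q_df, x$q_p))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  intercept %.4g (se %.4g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  }
  invisible(x)
}

# pull aligned effect vectors out of a harmonized_set or a plain data.frame
hset_vectors <- function(set) {
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  stopifnot(all(need %in% names(set)))
  list(bx = set$beta_exposure, sx = set$se_exposure,
       by = set$beta_outcome, sy = set$se_outcome)
}

#' Wald ratio estimate for a single SNP
#'
#' `estimate = beta_outcome / beta_exposure` with first-order delta-method
#' standard error `se_outcome / |beta_exposure|`; the `second_order` flag
#' adds the exposure-uncertainty term
#' `sqrt(se_out^2/bx^2 + by^2 se_exp^2 / bx^4)`.
#'
#' @param beta_exp,se_exp,beta_out,se_out per-SNP effects and SEs.
#' @param second_order use the second-order SE (default FALSE).
#' @return an `mr_result` with `method = "wald"`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out, second_order = FALSE) {
  if (beta_exp == 0) stop("undefined Wald ratio: beta_exp is zero")
  est <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  mr_result("wald", est, se, n_snp = 1L)
}

# Q over Wald ratios with first-order weights; used by IVW
ratio_q <- function(bx, by, sy, theta) {
  w <- bx^2 / sy^2
  r <- by / bx
  q <- sum(w * (r - theta)^2)
  list(q = q, df = length(bx) - 1L,
       q_p = stats::pchisq(q, df = length(bx) - 1L, lower.tail = FALSE))
}

#' Inverse-variance weighted MR estimate
#'
#' Weighted regression of outcome on exposure effects through the origin with
#' weights `1/se_outcome^2`; equivalently the inverse-variance weighted mean
#' of Wald ratios. The standard error uses multiplicative random-effects
#' inflation floored at 1: `se = se_fixed * max(1, sqrt(Q/(n-1)))`, with
#' Cochran's Q computed over the Wald ratios with first-order weights.
#'
#' @param set a `harmonized_set` (or data.frame with the same effect columns).
#' @return an `mr_result` with `method = "ivw"`.
#' @export
mr_ivw <- function(set) {
  v <- hset_vectors(set)
  n <- length(v$bx)
  if (n < 2L) stop("IVW requires at least 2 SNPs")
  w <- 1 / v$sy^2
  est <- sum(w * v$bx * v$by) / sum(w * v$bx^2)
  se_fixed <- 1 / sqrt(sum(w * v$bx^2))
  het <- ratio_q(v$bx, v$by, v$sy, est)
  se <- se_fixed * max(1, sqrt(het$q / (n - 1)))
  mr_result("ivw", est, se, n_snp = n,
            q = het$q, q_df = het$df, q_p = het$q_p)
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with an
#' intercept, weights `1/se_outcome^2`. SNPs are first oriented so every
#' exposure effect is non-negative (required for the intercept to be
#' interpretable). A non-zero intercept indicates directional horizontal
#' pleiotropy; the slope is the pleiotropy-adjusted causal estimate.
#' Residual-based SE inflation (floored at 1) mirrors the IVW convention.
#'
#' @param set a `harmonized_set`.
#' @return an `mr_result` with `method = "egger"` and an intercept block.
#' @export
mr_egger <- function(set) {
  v <- hset_vectors(set)
  n <- length(v$bx)
  if (n < 3L) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(v$bx)
  flip[flip == 0] <- 1
  bx <- v$bx * flip
  by <- v$by * flip
  w <- 1 / v$sy^2
  X <- cbind(1, bx)
  XtW <- t(X * w)
  fit <- solve(XtW %*% X, XtW %*% by)
  resid <- by - X %*% fit
  q <- sum(w * resid^2)
  q_df <- n - 2L
  q_p <- stats::pchisq(q, df = q_df, lower.tail = FALSE)
  vc <- solve(XtW %*% X)
  infl <- max(1, sqrt(q / q_df))
  se_int <- sqrt(vc[1, 1]) * infl
  se_slope <- sqrt(vc[2, 2]) * infl
  mr_result("egger", fit[2], se_slope, n_snp = n,
            q = q, q_df = q_df, q_p = q_p,
            intercept = fit[1], intercept_se = se_int,
            intercept_p = 2 * stats::pnorm(-abs(fit[1] / se_int)))
}

# interpolated weighted median of ratios at cumulative weight 0.5
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cs <- cumsum(w) - w / 2
  if (cs[1] >= 0.5) return(r[1])
  if (cs[length(cs)] <= 0.5) return(r[length(r)])
  below <- max(which(cs < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - cs[below]) / (cs[below + 1] - cs[below])
}

#' Weighted median MR estimate
#'
#' Inverse-variance weighted median of the per-SNP Wald ratios, interpolated
#' at cumulative weight 0.5; consistent when at least half the instrument
#' weight comes from valid instruments. The SE comes from a seeded parametric
#' bootstrap resampling the exposure and outcome effects from their
#' reported sampling distributions.
#'
#' @param set a `harmonized_set`.
#' @param n_boot bootstrap resamples, default 1000.
#' @param seed bootstrap seed.
#' @return an `mr_result` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(set, n_boot = 1000, seed = 1L) {
  v <- hset_vectors(set)
  n <- length(v$bx)
  if (n < 3L) stop("weighted median requires at least 3 SNPs")
  ratios <- v$by / v$bx
  weights <- v$bx^2 / v$sy^2   # inverse of first-order ratio variance
  est <- weighted_median_point(ratios, weights)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(n, v$bx, v$sx)
      by <- stats::rnorm(n, v$by, v$sy)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / v$sy[ok]^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  if (se == 0) se <- .Machine$double.eps
  mr_result("weighted_median", est, se, n_snp = n)
}

# evaluate-with-seed without clobbering the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Contamination-mixture MR estimate
#'
#' Profile likelihood over candidate causal effects theta on a grid spanning
#' the Wald-ratio range. Each SNP contributes the larger of two normal
#' log-densities for its ratio: valid (centred at theta with its first-order
#' SE) or invalid (centred at 0 with variance `se^2 + psi^2`). The estimate is
#' the grid argmax; the confidence set is all theta whose profile
#' log-likelihood is within 1.92 (chi-squared 95%) of the maximum, reported
#' as a union of intervals that may be disjoint.
#'
#' @param set a `harmonized_set`.
#' @param psi dispersion of invalid-SNP ratios; default 1.5 x SD of the
#'   Wald ratios.
#' @param grid_resolution grid step as a fraction of the ratio range,
#'   default 1/1000.
#' @param grid optional explicit grid of candidate theta values, overriding
#'   `grid_resolution`.
#' @return an `mr_result` with `method = "contamination_mixture"` and a
#'   `ci_set` matrix of interval bounds.
#' @export
mr_conmix <- function(set, psi = NULL, grid_resolution = 1e-3, grid = NULL) {
  v <- hset_vectors(set)
  n <- length(v$bx)
  if (n < 3L) stop("contamination mixture requires at least 3 SNPs")
  ratios <- v$by / v$bx
  ses <- v$sy / abs(v$bx)
  if (is.null(psi)) psi <- 1.5 * stats::sd(ratios)
  if (psi <= 0) stop("psi must be > 0")
  if (is.null(grid)) {
    span <- range(c(ratios, 0))
    pad <- 0.25 * diff(span) + 2 * max(ses)
    grid <- seq(span[1] - pad, span[2] + pad,
                length.out = max(10L, ceiling(1 / grid_resolution) + 1L))
  }
  if (length(grid) < 2L || !all(is.finite(grid))) stop("degenerate grid")
  invalid_ll <- stats::dnorm(ratios, 0, sqrt(ses^2 + psi^2), log = TRUE)
  ll <- vapply(grid, function(theta) {
    sum(pmax(stats::dnorm(ratios, theta, ses, log = TRUE), invalid_ll))
  }, numeric(1))
  best <- which.max(ll)
  inside <- ll >= ll[best] - 1.92
  # contiguous runs of grid points inside the likelihood set
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ci_set <- cbind(lower = grid[starts[runs$values]],
                  upper = grid[ends[runs$values]])
  band <- which(inside)
  se <- (grid[max(band)] - grid[min(band)]) / (2 * 1.96)  # rough, for reporting
  mr_result("contamination_mixture", grid[best], se, n_snp = n,
            ci_lower = min(ci_set[, "lower"]), ci_upper = max(ci_set[, "upper"]),
            ci_set = ci_set, extra = list(psi = psi))
}
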