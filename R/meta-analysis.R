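#' Fixed-effects inverse-variance meta-analysis for one variant
#'
#' Pools per-cohort log odds ratios with weights `w_i = 1/se_i^2`:
#' `pooled_beta = sum(w b) / sum(w)`, `pooled_se = 1/sqrt(sum(w))`, two-sided
#' normal p-value, plus Cochran's Q heterogeneity block via [cochran_q()].
#' A single-cohort variant passes through unchanged with `i2 = 0`.
#'
#' @param betas per-cohort log odds ratios (alleles aligned beforehand).
#' @param ses per-cohort standard errors, all > 0.
#' @param cohorts optional cohort labels.
#' @return list: `pooled_beta`, `pooled_se`, `pooled_p`, `q`, `df`, `q_p`,
#'   `i2`, `k`, `betas`, `ses`.
#' @export
fixed_effect_meta <- function(betas, ses, cohorts = NULL) {
  k <- length(betas)
  if (k == 0L) stop("no cohorts supplied")
  if (length(ses) != k) stop("betas and ses must have equal length")
  if (any(is.na(ses)) || any(ses <= 0)) stop("all standard errors must be > 0")
  w <- 1 / ses^2
  pooled_beta <- sum(w * betas) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  pooled_p <- 2 * stats::pnorm(-abs(pooled_beta / pooled_se))
  het <- cochran_q(betas, ses, pooled_beta)
  list(pooled_beta = pooled_beta, pooled_se = pooled_se, pooled_p = pooled_p,
       q = het$q, df = het$df, q_p = het$q_p, i2 = het$i2, k = k,
       betas = betas, ses = ses, cohorts = cohorts)
}

#' Cochran's Q and I-squared across cohorts
#'
#' `Q = sum w_i (b_i - pooled)^2` with `w_i = 1/se_i^2`, chi-squared p on
#' `k - 1` degrees of freedom, and `I2 = max(0, (Q - df)/Q) * 100` (0 when
#' `Q = 0` or for a single study).
#'
#' @param betas,ses per-study estimates and standard errors.
#' @param pooled_beta fixed-effects pooled estimate.
#' @return list: `q`, `df`, `q_p`, `i2` (percentage in `[0, 100]`).
#' @export
cochran_q <- function(betas, ses, pooled_beta) {
  k <- length(betas)
  if (length(ses) != k) stop("betas and ses must have equal length")
  if (k < 2L) return(list(q = 0, df = 0L, q_p = 1, i2 = 0))
  w <- 1 / ses^2
  q <- sum(w * (betas - pooled_beta)^2)
  df <- k - 1L
  q_p <- stats::pchisq(q, df = df, lower.tail = FALSE)
  i2 <- if (q > 0) max(0, (q - df) / q) * 100 else 0
  list(q = q, df = df, q_p = q_p, i2 = i2)
}

#' Meta-analyse per-variant associations across cohort summary statistics
#'
#' Harmonizes each further cohort to the first cohort's effect alleles (via
#' [harmonize()] semantics on shared variants), then pools every variant with
#' [fixed_effect_meta()]. Variants present in a single cohort pass through as
#' that cohort's estimate with `i2 = 0`. Optionally drops variants with
#' cohort-level MAF below `maf_min` before pooling.
#'
#' @param cohort_list list of [summary_stats] for the same trait (>= 1).
#' @param maf_min minimum minor-allele frequency applied per cohort
#'   (default 0.01; `0` disables).
#' @return A `meta_result` data.frame: `variant_id`, `pooled_beta`,
#'   `pooled_se`, `pooled_p`, `q`, `df`, `q_p`, `i2`, `k`, `excluded`
#'   (all FALSE here; see [filter_heterogeneous()]).
#' @export
meta_analyse <- function(cohort_list, maf_min = 0.01) {
  stopifnot(is.list(cohort_list), length(cohort_list) >= 1L)
  for (ss in cohort_list) stopifnot(inherits(ss, "summary_stats"))
  if (maf_min > 0) {
    cohort_list <- lapply(cohort_list, function(ss) {
      maf <- pmin(ss$data$eaf, 1 - ss$data$eaf)
      ss$data <- ss$data[maf >= maf_min, , drop = FALSE]
      ss
    })
  }
  ref <- cohort_list[[1]]
  aligned <- list(ref$data[, c("variant_id", "beta", "se")])
  if (length(cohort_list) > 1L) {
    for (i in seq_along(cohort_list)[-1]) {
      shared <- intersect(ref$data$variant_id, cohort_list[[i]]$data$variant_id)
      if (length(shared) > 0L) {
        h <- harmonize(ref, cohort_list[[i]])
        aligned[[i]] <- data.frame(variant_id = h$variant_id,
                                   beta = h$beta_outcome, se = h$se_outcome)
      } else {
        aligned[[i]] <- ref$data[0, c("variant_id", "beta", "se")]
      }
    }
  }
  # single-cohort-only variants (e.g. filtered out elsewhere) pass through
  extra <- lapply(seq_along(cohort_list)[-1], function(i) {
    d <- cohort_list[[i]]$data
    d <- d[!d$variant_id %in% ref$data$variant_id, c("variant_id", "beta", "se")]
    d
  })
  all_tabs <- c(aligned, extra)
  ids <- unique(unlist(lapply(all_tabs, function(d) d$variant_id)))
  rows <- lapply(ids, function(id) {
    b <- s <- numeric(0)
    for (d in all_tabs) {
      j <- match(id, d$variant_id)
      if (!is.na(j)) { b <- c(b, d$beta[j]); s <- c(s, d$se[j]) }
    }
    fm <- fixed_effect_meta(b, s)
    data.frame(variant_id = id, pooled_beta = fm$pooled_beta,
               pooled_se = fm$pooled_se, pooled_p = fm$pooled_p,
               q = fm$q, df = fm$df, q_p = fm$q_p, i2 = fm$i2, k = fm$k,
               excluded = FALSE, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  class(res) <- c("meta_result", "data.frame")
  res
}

#' Exclude variants with high between-cohort heterogeneity
#'
#' Flags and removes variants whose I-squared strictly exceeds the threshold
#' (the exclusion rule is `I2 > 75` by default, so `I2 = 75` is retained).
#' Single-cohort variants are always retained.
#'
#' @param meta a `meta_result` from [meta_analyse()].
#' @param i2_threshold percentage in `[0, 100]`, default 75.
#' @return the retained `meta_result` rows; excluded rows (with
#'   `excluded = TRUE`) in `attr(, "excluded")`.
#' @export
filter_heterogeneous <- function(meta, i2_threshold = 75) {
  if (i2_threshold < 0 || i2_threshold > 100) {
    stop("i2_threshold must be in [0, 100]")
  }
  drop <- meta$i2 > i2_threshold & meta$k > 1L
  meta$excluded <- drop
  out <- meta[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- meta[drop, , drop = FALSE]
  out
}
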