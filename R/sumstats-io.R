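REQUIRED_COLS <- c("variant_id", "chromosome", "position", "effect_allele",
                   "other_allele", "eaf", "beta", "se", "p_value", "n")

#' Construct a summary-statistics object
#'
#' A `summary_stats` object bundles one trait's per-variant GWAS association
#' records with trait metadata. Effects for binary traits are on the log-odds
#' scale; continuous traits are in SD units.
#'
#' @param data data.frame with columns `variant_id`, `chromosome`, `position`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p_value`, `n` and
#'   optionally `n_case`, `n_control`.
#' @param trait_name character scalar.
#' @param trait_type `"binary"` or `"continuous"`.
#' @param validate reject rows violating the record invariants (default TRUE).
#' @return A `summary_stats` object. Rows failing validation are dropped and
#'   counted in `attr(, "n_rejected")`.
#' @export
summary_stats <- function(data, trait_name, trait_type = c("binary", "continuous"),
                          validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(REQUIRED_COLS, names(data))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!("n_case" %in% names(data))) data$n_case <- NA_real_
  if (!("n_control" %in% names(data))) data$n_control <- NA_real_
  data <- data[, c(REQUIRED_COLS, "n_case", "n_control")]
  data$variant_id <- as.character(data$variant_id)
  data$chromosome <- as.character(data$chromosome)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("position", "eaf", "beta", "se", "p_value", "n", "n_case", "n_control")) {
    data[[col]] <- suppressWarnings(as.numeric(data[[col]]))
  }

  n_rejected <- 0L
  if (validate && nrow(data) > 0L) {
    ok <- validate_associations(data)
    n_rejected <- sum(!ok)
    data <- data[ok, , drop = FALSE]
  }
  if (anyDuplicated(data$variant_id)) {
    stop("duplicate variant_id keys in '", trait_name, "'")
  }
  rownames(data) <- NULL
  structure(
    list(
      trait_name = trait_name,
      trait_type = trait_type,
      effect_scale = if (trait_type == "binary") "log_odds" else "sd_units",
      data = data
    ),
    n_rejected = n_rejected,
    class = "summary_stats"
  )
}

# Row-level invariants for variant association records. Returns a logical
# keep-vector; NA in any mandatory numeric field rejects the row.
validate_associations <- function(data) {
  ok <- !is.na(data$variant_id) & nzchar(data$variant_id) &
    !is.na(data$effect_allele) & !is.na(data$other_allele) &
    data$effect_allele != data$other_allele &
    grepl("^[ACGT]+$", data$effect_allele) & grepl("^[ACGT]+$", data$other_allele) &
    !is.na(data$beta) & !is.na(data$se) & data$se > 0 &
    !is.na(data$eaf) & data$eaf >= 0 & data$eaf <= 1 &
    !is.na(data$p_value) & data$p_value > 0 & data$p_value <= 1 &
    !is.na(data$n) & data$n > 0
  # case/control counts, when present, must sum to n
  has_cc <- !is.na(data$n_case) & !is.na(data$n_control)
  ok[has_cc] <- ok[has_cc] &
    (data$n_case[has_cc] + data$n_control[has_cc] == data$n[has_cc])
  ok & !is.na(ok)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: %s (%s, %s)\n  %d variants (%d rejected at read)\n",
              x$trait_name, x$trait_type, x$effect_scale,
              nrow(x$data), attr(x, "n_rejected") %||% 0L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited table with a header, maps columns via
#' `schema`, validates each row, and returns a [summary_stats] object. An
#' odds-ratio column may be mapped instead of `beta`, in which case
#' `beta = log(OR)` is taken at read time so all internal effects are on the
#' additive scale.
#'
#' @param path file path.
#' @param schema named list/character vector mapping canonical field names
#'   (`variant_id`, `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta` or `or`, `se`, `p_value`, `n`, optionally `n_case`,
#'   `n_control`) to column names in the file. Defaults to identity.
#' @param trait_name,trait_type trait metadata, see [summary_stats()].
#' @param sep field separator; guessed from the file extension when `NULL`
#'   (`.csv` is comma, anything else tab).
#' @return `summary_stats`; rejected row count in `attr(, "n_rejected")`.
#' @export
read_sumstats <- function(path, schema = NULL, trait_name = basename(path),
                          trait_type = c("binary", "continuous"), sep = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0L) stop("empty summary-statistics file: ", path)

  schema <- as.list(schema %||% list())
  canonical <- c(REQUIRED_COLS, "or", "n_case", "n_control")
  for (fld in names(schema)) {
    if (!fld %in% canonical) stop("unknown schema field: ", fld)
  }
  pick <- function(fld) schema[[fld]] %||% fld
  use_or <- ("or" %in% names(schema)) || (!"beta" %in% names(raw) && "or" %in% names(raw))

  out <- data.frame(row.names = seq_len(nrow(raw)))
  fields <- setdiff(REQUIRED_COLS, if (use_or) "beta" else character())
  fields <- c(fields, if (use_or) "or",
              intersect(c("n_case", "n_control"),
                        union(names(schema), names(raw))))
  for (fld in fields) {
    col <- pick(fld)
    if (!col %in% names(raw)) {
      if (fld %in% c("n_case", "n_control")) next
      stop("schema error: column '", col, "' (field '", fld, "') not in ", path)
    }
    out[[fld]] <- raw[[col]]
  }
  if (use_or) {
    or_num <- suppressWarnings(as.numeric(out$or))
    out$beta <- ifelse(!is.na(or_num) & or_num > 0, log(or_num), NA_real_)
    out$or <- NULL
  }

  ss <- summary_stats(out, trait_name = trait_name, trait_type = trait_type)
  n_rej <- attr(ss, "n_rejected")
  if (n_rej > nrow(raw) / 2) {
    stop(sprintf("more than half of the rows (%d/%d) failed validation in %s",
                 n_rej, nrow(raw), path))
  }
  if (n_rej > 0L) {
    message(sprintf("read_sumstats: rejected %d/%d row(s) in %s",
                    n_rej, nrow(raw), path))
  }
  ss
}

#' Convert an odds ratio with confidence interval to log-odds and SE
#'
#' Recovers `beta = log(OR)` and `se = (log(upper) - log(lower)) / (2 z)` from
#' a reported odds ratio and its confidence interval, with `z` the standard
#' normal quantile at `(1 + level) / 2`. This is how printed "OR (95% CI)"
#' records are consumed on the additive scale.
#'
#' @param or_point,ci_lower,ci_upper odds ratio and CI bounds (all > 0).
#' @param level confidence level in (0, 1), default 0.95.
#' @return list with `beta` and `se`.
#' @export
se_from_or_ci <- function(or_point, ci_lower, ci_upper, level = 0.95) {
  if (any(c(or_point, ci_lower, ci_upper) <= 0)) {
    stop("odds ratios and CI bounds must be positive")
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (ci_lower > or_point || or_point > ci_upper) {
    stop("require ci_lower <= or_point <= ci_upper")
  }
  z <- stats::qnorm((1 + level) / 2)
  list(beta = log(or_point), se = (log(ci_upper) - log(ci_lower)) / (2 * z))
}

# "1.33 (1.27 to 1.4)" formatting used in the results tables
format_or_ci <- function(or, lo, hi, digits = 2) {
  sprintf("%s (%s to %s)", round(or, digits), round(lo, digits), round(hi, digits))
}

#' Write MR results to a delimited table plus a JSON run report
#'
#' Writes one row per [mr_result] with numeric columns at full precision and a
#' human-readable `or_ci` column formatted as e.g. `"1.33 (1.27 to 1.4)"`.
#' A JSON sidecar (`<path>.json`) carries the same rows machine-readably.
#'
#' @param results a single `mr_result` or a list of them.
#' @param path output TSV path.
#' @param exposure,outcome optional trait labels recycled across rows.
#' @return invisibly, the written data.frame.
#' @export
write_results <- function(results, path, exposure = NA_character_,
                          outcome = NA_character_) {
  if (inherits(results, "mr_result")) results <- list(results)
  if (length(results) == 0L) stop("no results to write")
  rows <- lapply(results, function(r) {
    stopifnot(inherits(r, "mr_result"))
    data.frame(
      exposure = exposure, outcome = outcome, method = r$method,
      n_snp = r$n_snp, estimate = r$estimate, se = r$se,
      ci_lower = r$ci_lower, ci_upper = r$ci_upper, p = r$p,
      or_ci = format_or_ci(exp(r$estimate), exp(r$ci_lower), exp(r$ci_upper)),
      q = r$q %||% NA_real_, q_df = r$q_df %||% NA_real_, q_p = r$q_p %||% NA_real_,
      intercept = r$intercept %||% NA_real_,
      intercept_se = r$intercept_se %||% NA_real_,
      intercept_p = r$intercept_p %||% NA_real_,
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  ok <- tryCatch({
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write results to ", path, ": ", conditionMessage(e)))
  jsonlite::write_json(tab, paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(tab)
}

#' Write a summary_stats object as a TSV readable by read_sumstats
#' @param ss a [summary_stats] object.
#' @param path output path.
#' @export
write_sumstats <- function(ss, path) {
  stopifnot(inherits(ss, "summary_stats"))
  utils::write.table(ss$data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
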