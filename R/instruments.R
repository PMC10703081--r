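#' Construct an LD matrix
#'
#' Pairwise r-squared between variants: square, symmetric, unit diagonal,
#' entries in `[0, 1]`.
#'
#' @param r2 square numeric matrix.
#' @param variant_ids variant identifiers, one per row/column.
#' @return an `ld_matrix` object.
#' @export
ld_matrix <- function(r2, variant_ids) {
  r2 <- as.matrix(r2)
  if (nrow(r2) != ncol(r2)) stop("r2 must be square")
  if (length(variant_ids) != nrow(r2)) stop("variant_ids length mismatch")
  if (any(r2 < 0 | r2 > 1)) stop("r2 entries must be in [0, 1]")
  if (any(abs(diag(r2) - 1) > 1e-12)) stop("r2 diagonal must be 1")
  if (any(abs(r2 - t(r2)) > 1e-8)) stop("r2 must be symmetric")
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2),
            class = "ld_matrix")
}

#' Read an LD matrix from a TSV file
#'
#' Accepts either a square matrix with variant IDs as header (and optional
#' first column of row IDs), or a triplet table with columns
#' `id_a`, `id_b`, `r2` (unlisted pairs default to r2 = 0).
#'
#' @param path file path.
#' @return an [ld_matrix].
#' @export
read_ld_matrix <- function(path) {
  head_fields <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (length(head_fields) == 3L && all(c("id_a", "id_b", "r2") %in% head_fields)) {
    trip <- utils::read.table(path, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
    ids <- unique(c(trip$id_a, trip$id_b))
    r2 <- diag(1, length(ids))
    dimnames(r2) <- list(ids, ids)
    for (i in seq_len(nrow(trip))) {
      r2[trip$id_a[i], trip$id_b[i]] <- trip$r2[i]
      r2[trip$id_b[i], trip$id_a[i]] <- trip$r2[i]
    }
    diag(r2) <- 1
    return(ld_matrix(r2, ids))
  }
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.numeric(tab[[1]])) {
    rownames(tab) <- tab[[1]]
    tab <- tab[, -1, drop = FALSE]
  }
  ld_matrix(as.matrix(tab), colnames(tab))
}

#' Select genome-wide-significant candidate instruments
#'
#' Subsets to associations with `p_value < p_threshold` (strict), sorted by
#' ascending p-value. A pipeline needs at least three independent instruments
#' per exposure; fewer triggers a warning, not an error, so the caller can
#' skip the pair with a recorded reason.
#'
#' @param ss a [summary_stats] object.
#' @param p_threshold significance threshold in (0, 1); default `5e-8`.
#' @return data.frame of selected association records sorted by p.
#' @export
select_instruments <- function(ss, p_threshold = 5e-8) {
  stopifnot(inherits(ss, "summary_stats"))
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must be in (0, 1)")
  sel <- ss$data[ss$data$p_value < p_threshold, , drop = FALSE]
  sel <- sel[order(sel$p_value, sel$chromosome, sel$position, sel$variant_id), ]
  rownames(sel) <- NULL
  if (nrow(sel) == 0L) warning("no variant passes the significance threshold")
  sel
}

#' Greedy LD clumping of candidate instruments
#'
#' Standard clumping semantics: repeatedly take the lowest-p unclaimed SNP as
#' an index and discard all unclaimed SNPs with `r2 >= r2_threshold` to it
#' that lie within `window_bp` on the same chromosome. Ties in p are broken
#' by (chromosome, position, variant_id). Candidates absent from the LD
#' matrix are treated as unlinked.
#'
#' @param candidates data.frame with `variant_id`, `chromosome`, `position`,
#'   `p_value` (e.g. from [select_instruments()]).
#' @param ld an [ld_matrix].
#' @param r2_threshold clumping r-squared threshold in (0, 1]; default 0.01.
#' @param window_bp clumping window in base pairs; default 10 Mb.
#' @return the retained (independent) subset of `candidates`, sorted by p.
#' @export
ld_clump <- function(candidates, ld, r2_threshold = 0.01, window_bp = 1e7) {
  stopifnot(is.data.frame(candidates))
  if (r2_threshold <= 0 || r2_threshold > 1) stop("r2_threshold must be in (0, 1]")
  if (nrow(candidates) == 0L) return(candidates)
  ord <- order(candidates$p_value, candidates$chromosome,
               candidates$position, candidates$variant_id)
  cand <- candidates[ord, , drop = FALSE]
  unknown <- !cand$variant_id %in% ld$variant_ids
  if (any(unknown)) {
    message(sum(unknown), " candidate(s) absent from LD matrix; treated as unlinked")
  }
  claimed <- rep(FALSE, nrow(cand))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (claimed[i]) next
    keep[i] <- TRUE
    claimed[i] <- TRUE
    if (unknown[i]) next
    rest <- which(!claimed)
    if (length(rest) == 0L) break
    same_chr <- cand$chromosome[rest] == cand$chromosome[i]
    in_window <- abs(cand$position[rest] - cand$position[i]) <= window_bp
    r2v <- rep(0, length(rest))
    known <- !unknown[rest]
    if (any(known)) {
      r2v[known] <- ld$r2[cand$variant_id[i], cand$variant_id[rest][known]]
    }
    claimed[rest[same_chr & in_window & r2v >= r2_threshold]] <- TRUE
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument-strength diagnostics R-squared and F
#'
#' Per-SNP variance explained in the exposure
#' `r2_snp = 2 a_hat^2 MAF (1 - MAF)` with `a_hat` in SD units, aggregated as
#' `r2_total = sum(r2_snp)`, and the instrument F statistic
#' `F = r2_total (N - 1 - K) / ((1 - r2_total) K)` where `N` is the sample
#' size of the instrument-outcome association and `K` the number of
#' instruments. Mean and SD of the per-SNP r-squared are also reported.
#'
#' @param beta_exposure per-instrument exposure effects in SD units.
#' @param eaf effect-allele frequencies (MAF is taken as `min(eaf, 1 - eaf)`).
#' @param n sample size; must exceed `K + 1`.
#' @return list: `r2_snp`, `r2_total`, `r2_mean`, `r2_sd`, `f_stat`, `n`, `k`.
#' @export
instrument_strength <- function(beta_exposure, eaf, n) {
  k <- length(beta_exposure)
  if (k < 1L) stop("need at least one instrument")
  if (length(eaf) != k) stop("beta_exposure and eaf must have equal length")
  if (n <= k + 1) stop("sample size must exceed K + 1")
  maf <- pmin(eaf, 1 - eaf)
  r2_snp <- 2 * beta_exposure^2 * maf * (1 - maf)
  r2_total <- sum(r2_snp)
  if (r2_total >= 1) stop("total R-squared >= 1; check effect-size units")
  f_stat <- r2_total * (n - 1 - k) / ((1 - r2_total) * k)
  list(r2_snp = r2_snp, r2_total = r2_total,
       r2_mean = mean(r2_snp), r2_sd = if (k > 1) stats::sd(r2_snp) else 0,
       f_stat = f_stat, n = n, k = k)
}
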