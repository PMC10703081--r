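PALINDROME_PAIRS <- c("AT", "TA", "CG", "GC")

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, nea) {
  paste0(ea, nea) %in% PALINDROME_PAIRS
}

#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Aligns per-SNP effects so that the exposure's effect allele is the effect
#' allele for every trait. Non-palindromic SNPs with swapped alleles get the
#' outcome beta negated and EAF complemented; strand flips (allele complements)
#' are reconciled silently. Palindromic SNPs (A/T, G/C) cannot be resolved from
#' alleles alone: the strand is inferred from allele frequencies, and SNPs whose
#' frequency in either trait is within `palindrome_eaf_window` of 0.5 are
#' dropped as ambiguous. Indels and irreconcilable allele pairs are dropped.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param palindrome_eaf_window half-width of the ambiguity zone around
#'   EAF = 0.5 inside which palindromic SNPs are dropped; in `[0, 0.5)`,
#'   default 0.08.
#' @return A `harmonized_set`: data.frame with columns `variant_id`,
#'   `chromosome`, `position`, `effect_allele`, `other_allele`,
#'   `beta_exposure`, `se_exposure`, `p_exposure`, `eaf_exposure`,
#'   `n_exposure`, `beta_outcome`, `se_outcome`, `p_outcome`, `eaf_outcome`,
#'   `n_outcome`, `action`. Dropped SNPs are recorded in
#'   `attr(, "dropped")` with their action.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  if (palindrome_eaf_window < 0 || palindrome_eaf_window >= 0.5) {
    stop("palindrome_eaf_window must be in [0, 0.5)")
  }
  ex <- exposure$data
  ou <- outcome$data
  if (nrow(ex) == 0L || nrow(ou) == 0L) stop("empty summary statistics")
  ids <- intersect(ex$variant_id, ou$variant_id)
  if (length(ids) == 0L) stop("no shared variant IDs between exposure and outcome")
  ex <- ex[match(ids, ex$variant_id), ]
  ou <- ou[match(ids, ou$variant_id), ]

  mismatch_pos <- !is.na(ex$position) & !is.na(ou$position) &
    (ex$chromosome != ou$chromosome | ex$position != ou$position)
  if (any(mismatch_pos)) {
    warning(sum(mismatch_pos), " SNP(s) disagree on chromosome/position; ",
            "matching by variant_id")
  }

  n <- length(ids)
  action <- character(n)
  beta_out <- ou$beta
  eaf_out <- ou$eaf

  indel <- nchar(ex$effect_allele) > 1L | nchar(ex$other_allele) > 1L |
    nchar(ou$effect_allele) > 1L | nchar(ou$other_allele) > 1L
  pal <- !indel & is_palindromic(ex$effect_allele, ex$other_allele)

  for (i in seq_len(n)) {
    if (indel[i]) {
      action[i] <- "dropped_mismatch"
      next
    }
    eea <- ex$effect_allele[i]; ena <- ex$other_allele[i]
    oea <- ou$effect_allele[i]; ona <- ou$other_allele[i]
    if (pal[i]) {
      if (!setequal(c(oea, ona), c(eea, ena))) {
        action[i] <- "dropped_mismatch"
        next
      }
      fx <- ex$eaf[i]; fo <- ou$eaf[i]
      if (is.na(fx) || is.na(fo) ||
          abs(fx - 0.5) <= palindrome_eaf_window ||
          abs(fo - 0.5) <= palindrome_eaf_window) {
        action[i] <- "dropped_palindrome"
        next
      }
      # step 1: align allele labels at face value
      b <- if (oea == eea) beta_out[i] else -beta_out[i]
      f <- if (oea == eea) fo else 1 - fo
      # step 2: the labels may sit on the opposite strand (undecidable from
      # alleles for a palindrome); discordant frequencies reveal this, in
      # which case the true aligned allele is the complement: undo the flip
      if ((fx < 0.5) != (f < 0.5)) {
        b <- -b
        f <- 1 - f
      }
      beta_out[i] <- b
      eaf_out[i] <- f
      action[i] <- "palindrome_inferred"
      next
    }
    if (oea == eea && ona == ena) {
      action[i] <- "kept"
    } else if (oea == ena && ona == eea) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped"
    } else if (allele_complement(oea) == eea && allele_complement(ona) == ena) {
      action[i] <- "kept"  # strand flip, orientation preserved
    } else if (allele_complement(oea) == ena && allele_complement(ona) == eea) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
      action[i] <- "flipped"
    } else {
      action[i] <- "dropped_mismatch"
    }
  }

  res <- data.frame(
    variant_id = ids,
    chromosome = ex$chromosome,
    position = ex$position,
    effect_allele = ex$effect_allele,
    other_allele = ex$other_allele,
    beta_exposure = ex$beta,
    se_exposure = ex$se,
    p_exposure = ex$p_value,
    eaf_exposure = ex$eaf,
    n_exposure = ex$n,
    beta_outcome = beta_out,
    se_outcome = ou$se,
    p_outcome = ou$p_value,
    eaf_outcome = eaf_out,
    n_outcome = ou$n,
    action = action,
    stringsAsFactors = FALSE
  )
  keep <- !startsWith(action, "dropped")
  dropped <- res[!keep, c("variant_id", "action")]
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            dropped = dropped,
            exposure_name = exposure$trait_name,
            outcome_name = outcome$trait_name,
            outcome_type = outcome$trait_type,
            class = c("harmonized_set", "data.frame"))
}

#' Jointly harmonize several exposures and one outcome
#'
#' Harmonizes each exposure against the outcome, then inner-joins the retained
#' SNPs so all exposure effects are aligned to the outcome's harmonized effect
#' allele. Used by multivariable MR.
#'
#' @param exposures named list of [summary_stats] objects (length >= 2).
#' @param outcome a [summary_stats] object.
#' @param palindrome_eaf_window see [harmonize()].
#' @return data.frame of class `mv_harmonized_set` with per-exposure columns
#'   `beta_<name>` / `se_<name>` and outcome columns as in [harmonize()].
#' @export
harmonize_mv <- function(exposures, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(is.list(exposures), length(exposures) >= 2L)
  if (is.null(names(exposures)) || any(!nzchar(names(exposures)))) {
    names(exposures) <- vapply(exposures, function(e) e$trait_name, character(1))
  }
  sets <- lapply(exposures, harmonize, outcome = outcome,
                 palindrome_eaf_window = palindrome_eaf_window)
  ids <- Reduce(intersect, lapply(sets, function(s) s$variant_id))
  if (length(ids) == 0L) stop("no SNP retained across all exposures")
  base <- sets[[1]][match(ids, sets[[1]]$variant_id),
                    c("variant_id", "chromosome", "position", "effect_allele",
                      "other_allele", "beta_outcome", "se_outcome", "p_outcome",
                      "eaf_outcome", "n_outcome")]
  for (nm in names(sets)) {
    s <- sets[[nm]][match(ids, sets[[nm]]$variant_id), ]
    base[[paste0("beta_", nm)]] <- s$beta_exposure
    base[[paste0("se_", nm)]] <- s$se_exposure
    base[[paste0("p_", nm)]] <- s$p_exposure
    base[[paste0("n_", nm)]] <- s$n_exposure
  }
  rownames(base) <- NULL
  structure(base,
            exposure_names = names(sets),
            outcome_name = outcome$trait_name,
            class = c("mv_harmonized_set", "data.frame"))
}
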