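# Builders and independent brute-force oracles shared across the suite.

make_assoc <- function(variant_id, beta, se, eaf = 0.3, p = NULL,
                       ea = "A", oa = "G", chr = "1", pos = NULL, n = 1e5) {
  k <- length(variant_id)
  data.frame(
    variant_id = variant_id,
    chromosome = rep_len(chr, k),
    position = pos %||% seq_len(k) * 1000,
    effect_allele = rep_len(ea, k),
    other_allele = rep_len(oa, k),
    eaf = rep_len(eaf, k),
    beta = beta,
    se = se,
    p_value = p %||% pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = rep_len(n, k),
    stringsAsFactors = FALSE
  )
}

make_ss <- function(..., trait_name = "trait", trait_type = "continuous") {
  summary_stats(make_assoc(...), trait_name = trait_name,
                trait_type = trait_type)
}

# aligned instrument set without going through harmonize()
make_hset <- function(bx, sx, by, sy, eaf = NULL, n_exp = 1e5, n_out = 1e5) {
  k <- length(bx)
  structure(
    data.frame(
      variant_id = sprintf("snp%03d", seq_len(k)),
      chromosome = "1", position = seq_len(k) * 1000,
      effect_allele = "A", other_allele = "G",
      beta_exposure = bx, se_exposure = sx,
      p_exposure = 2 * pnorm(-abs(bx / sx)),
      eaf_exposure = eaf %||% rep(0.3, k),
      n_exposure = n_exp,
      beta_outcome = by, se_outcome = sy,
      p_outcome = 2 * pnorm(-abs(by / sy)),
      eaf_outcome = eaf %||% rep(0.3, k),
      n_outcome = n_out,
      action = "kept", stringsAsFactors = FALSE),
    class = c("harmonized_set", "data.frame"),
    outcome_type = "binary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- oracles ---------------------------------------------------------------

oracle_ivw <- function(bx, by, sy) {
  fit <- lm(by ~ 0 + bx, weights = 1 / sy^2)
  unname(coef(fit)[1])
}

oracle_egger <- function(bx, by, sy) {
  flip <- ifelse(bx < 0, -1, 1)
  fit <- lm(I(by * flip) ~ I(bx * flip), weights = 1 / sy^2)
  unname(coef(fit))  # c(intercept, slope)
}

# weighted median by explicit cumulative-weight scan with interpolation
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cw <- cumsum(w) - w / 2
  if (cw[1] >= 0.5) return(r[1])
  for (i in seq_along(cw)[-1]) {
    if (cw[i] >= 0.5) {
      return(r[i - 1] + (r[i] - r[i - 1]) * (0.5 - cw[i - 1]) / (cw[i] - cw[i - 1]))
    }
  }
  r[length(r)]
}

# exhaustive-grid contamination-mixture scan (same model, naive loops)
oracle_conmix <- function(ratios, ses, psi, grid) {
  ll <- sapply(grid, function(theta) {
    total <- 0
    for (j in seq_along(ratios)) {
      lv <- dnorm(ratios[j], theta, ses[j], log = TRUE)
      li <- dnorm(ratios[j], 0, sqrt(ses[j]^2 + psi^2), log = TRUE)
      total <- total + max(lv, li)
    }
    total
  })
  grid[which.max(ll)]
}

# literal transcription of the greedy clumping rule
oracle_clump <- function(cand, r2, r2_threshold, window_bp) {
  cand <- cand[order(cand$p_value, cand$chromosome, cand$position,
                     cand$variant_id), ]
  kept <- character(0)
  pool <- cand
  while (nrow(pool) > 0) {
    index <- pool[1, ]
    kept <- c(kept, index$variant_id)
    drop <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      if (pool$variant_id[i] == index$variant_id) { drop[i] <- TRUE; next }
      linked <- FALSE
      if (index$variant_id %in% rownames(r2) &&
          pool$variant_id[i] %in% rownames(r2)) {
        linked <- r2[index$variant_id, pool$variant_id[i]] >= r2_threshold
      }
      near <- pool$chromosome[i] == index$chromosome &&
        abs(pool$position[i] - index$position) <= window_bp
      drop[i] <- linked && near
    }
    pool <- pool[!drop, , drop = FALSE]
  }
  kept
}

# step-up BH exactly as defined
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    adj[i] <- min(1, min(p[ord[rank_i:m]] * m / (rank_i:m)))
  }
  adj
}
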