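# Shared fixtures and small statistical helpers for the suite.

# two-category design mirroring a large obstetric trial's published shape
big_design <- function(confidence = 0.3) {
  trial_design(1355, 48, confidence, c(NW = 0.30, H = 0.20),
               rubr_target = 0.5)
}

flat_design <- function(n_target = 1000, horizon = 100) {
  trial_design(n_target, horizon, 0, c(NW = 0.3, H = 0.1))
}

# accrual posterior with given (A, B) built through the public API:
# flat prior plus an interim of A enrollments over B time-units
post_ab <- function(A, B) {
  accrual_posterior(accrual_prior(flat_design()), interim_data(A, B))
}

# chi-square goodness-of-fit p-value of integer draws against a tabulated
# pmf (data.frame count/prob); bins are pooled left-to-right until every
# expected count reaches min_expected, with the untabulated tail lumped in
gof_pvalue <- function(draws, pmf, min_expected = 5) {
  stopifnot(all(pmf$count == seq(min(pmf$count), max(pmf$count))))
  tail_prob <- max(0, 1 - sum(pmf$prob))
  probs <- c(pmf$prob, tail_prob)
  idx <- match(pmin(draws, max(pmf$count) + 1L),
               c(pmf$count, max(pmf$count) + 1L))
  obs <- tabulate(idx, nbins = length(probs))
  expd <- probs * length(draws)

  o <- numeric(0); e <- numeric(0); co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= min_expected) {
      o <- c(o, co); e <- c(e, ce); co <- 0; ce <- 0
    }
  }
  if (ce > 0 || co > 0) {
    o[length(o)] <- o[length(o)] + co
    e[length(e)] <- e[length(e)] + ce
  }
  stat <- sum((o - e)^2 / e)
  stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
}

# two-sample chi-square p-value that two integer draw vectors share a
# distribution (bins pooled so every expected cell count is >= 5)
two_sample_pvalue <- function(x, y, min_expected = 5) {
  pooled <- c(x, y)
  support <- min(pooled):max(pooled)
  ox <- tabulate(match(x, support), nbins = length(support))
  oy <- tabulate(match(y, support), nbins = length(support))
  keep_x <- numeric(0); keep_y <- numeric(0); cx <- 0; cy <- 0
  for (i in seq_along(support)) {
    cx <- cx + ox[i]; cy <- cy + oy[i]
    if (cx + cy >= 2 * min_expected) {
      keep_x <- c(keep_x, cx); keep_y <- c(keep_y, cy); cx <- 0; cy <- 0
    }
  }
  if (cx + cy > 0) {
    keep_x[length(keep_x)] <- keep_x[length(keep_x)] + cx
    keep_y[length(keep_y)] <- keep_y[length(keep_y)] + cy
  }
  suppressWarnings(
    stats::chisq.test(rbind(keep_x, keep_y))$p.value)
}
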