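# Per-category UBR model: membership flags y_i^u | p^u are Bernoulli, the
# category count S_m^u ~ Binomial(m, p^u), with a conjugate Beta(alpha, beta)
# prior on p^u.

#' Beta prior/posterior parameters for a UBR category rate
#'
#' `beta_params()` is the bare container (prior pseudo-successes `alpha`,
#' pseudo-failures `beta`; both may be 0 for a flat prior). [ubr_prior()]
#' builds the elicited prior for one design category:
#' `alpha = p0 * n_target * confidence`,
#' `beta = (1 - p0) * n_target * confidence` — the prior is worth
#' `n * P` pseudo-subjects at the prior expected rate `p0`. A boundary
#' `p0` of 0 or 1 with `P > 0` gives a one-sided improper prior; it is
#' kept as elicited and rejected at posterior time (nudge `p0` off the
#' boundary if that is not intended).
#'
#' @param alpha,beta non-negative beta parameters.
#' @return an object of class `beta_params`.
#' @export
beta_params <- function(alpha, beta) {
  check_scalar(alpha, "alpha", min = 0)
  check_scalar(beta, "beta", min = 0)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta)),
            class = "beta_params")
}

#' @rdname beta_params
#' @param design a [trial_design()].
#' @param label the category label; may be omitted for a single-category
#'   design.
#' @export
ubr_prior <- function(design, label = NULL) {
  if (!inherits(design, "trial_design"))
    stop_validation("design must be a trial_design")
  cats <- design$categories
  if (is.null(label)) {
    if (nrow(cats) != 1L)
      stop_validation("label is required for a multi-category design")
    label <- cats$label[1L]
  }
  i <- match(label, cats$label)
  if (is.na(i))
    stop_validation("unknown category label '", label, "'")
  w <- design$n_target * design$confidence
  beta_params(cats$p0[i] * w, (1 - cats$p0[i]) * w)
}

#' @export
print.beta_params <- function(x, ...) {
  cat(sprintf("Beta(%g, %g)", x$alpha, x$beta))
  if (x$alpha > 0 && x$beta > 0)
    cat(sprintf(", mean %g", mean(x)))
  cat("\n")
  invisible(x)
}

#' @export
mean.beta_params <- function(x, ...) x$alpha / (x$alpha + x$beta)

check_proper <- function(params, what) {
  if (params$alpha <= 0 || params$beta <= 0)
    stop_improper(
      what, " is improper: Beta(", params$alpha, ", ", params$beta,
      ") needs both parameters positive. With a flat prior this happens ",
      "when the observed category count is 0 or m; with confidence P > 0 ",
      "it happens for a boundary prior rate p0 of 0 or 1.")
  invisible(params)
}

#' Conjugate beta posterior for a category rate
#'
#' Adds the observed category count to the prior:
#' `Beta(alpha + successes, beta + m - successes)`. Raises a
#' `ubr_improper_posterior` error if either updated parameter is 0.
#'
#' @param prior a [beta_params()] prior.
#' @param m subjects observed.
#' @param successes observed category count `S_m` (`0 <= successes <= m`).
#' @return a `beta_params` posterior.
#' @export
ubr_posterior <- function(prior, m, successes) {
  if (!inherits(prior, "beta_params"))
    stop_validation("prior must be beta_params")
  check_scalar(m, "m", min = 0, integerish = TRUE)
  check_scalar(successes, "successes", min = 0, max = m, integerish = TRUE)
  if (prior$alpha + prior$beta > 0 &&
      (prior$alpha == 0 || prior$beta == 0))
    stop_improper(
      "elicited prior Beta(", prior$alpha, ", ", prior$beta, ") is ",
      "boundary-improper: a prior rate p0 of 0 or 1 with confidence ",
      "P > 0 places all prior mass on the boundary. Nudge p0 off the ",
      "boundary rather than relying on silent regularization.")
  post <- beta_params(prior$alpha + successes, prior$beta + m - successes)
  check_proper(post, "category posterior")
}

#' Posterior-predictive draws of future category counts
#'
#' For each element of `remaining` a fresh rate `p_j` is drawn from the
#' beta posterior and a future count from `Binomial(remaining[j], p_j)` —
#' one rate draw per accrual draw, so that rate uncertainty propagates
#' into every joint prediction. Draw order under a seed: all `p_j` first,
#' then the binomial counts.
#'
#' @param posterior a proper [beta_params()] posterior.
#' @param remaining integer vector of remaining sample sizes, one per
#'   accrual draw (`n_j^p - m >= 0`).
#' @param seed optional integer seed.
#' @return integer vector of future counts, `0 <= count <= remaining`.
#' @export
draw_future_counts <- function(posterior, remaining, seed = NULL) {
  if (!inherits(posterior, "beta_params"))
    stop_validation("posterior must be beta_params")
  check_proper(posterior, "category posterior")
  if (!is.numeric(remaining) || length(remaining) < 1L ||
      any(remaining < 0) || any(remaining != round(remaining)))
    stop_validation("remaining must be non-negative integers")
  if (!is.null(seed)) set.seed(seed)
  p <- rbeta(length(remaining), posterior$alpha, posterior$beta)
  as.integer(rbinom(length(remaining), size = remaining, prob = p))
}

#' Beta-binomial probability mass function
#'
#' `dbetabinom()` evaluates the beta-binomial pmf — the marginal of
#' `Binomial(size, p)` with `p ~ Beta(alpha, beta)` — at counts `x`.
#' [betabinom_pmf()] tabulates it for a posterior at a fixed remaining
#' sample size; this is the closed-form predictive of future category
#' counts when the final sample size is known rather than itself
#' predicted, and the oracle [draw_future_counts()] is verified against.
#'
#' @param x vector of counts.
#' @param size number of trials.
#' @param alpha,beta positive beta parameters.
#' @return `dbetabinom`: probabilities at `x`.
#' @examples
#' dbetabinom(0:2, 2, 1, 1)  # uniform on {0, 1, 2}
#' @export
dbetabinom <- function(x, size, alpha, beta) {
  check_scalar(size, "size", min = 0, integerish = TRUE)
  check_scalar(alpha, "alpha", min = .Machine$double.xmin)
  check_scalar(beta, "beta", min = .Machine$double.xmin)
  out <- numeric(length(x))
  ok <- x >= 0 & x <= size & x == round(x)
  out[ok] <- exp(lchoose(size, x[ok]) +
                 lbeta(x[ok] + alpha, size - x[ok] + beta) -
                 lbeta(alpha, beta))
  out
}

#' @rdname dbetabinom
#' @param posterior a proper [beta_params()] posterior.
#' @param remaining_n fixed remaining sample size.
#' @return `betabinom_pmf`: a data frame with columns `count`
#'   (`0:remaining_n`) and `prob`, summing to 1.
#' @export
betabinom_pmf <- function(posterior, remaining_n) {
  if (!inherits(posterior, "beta_params"))
    stop_validation("posterior must be beta_params")
  check_proper(posterior, "category posterior")
  check_scalar(remaining_n, "remaining_n", min = 0, integerish = TRUE)
  counts <- 0:remaining_n
  data.frame(count = counts,
             prob = dbetabinom(counts, remaining_n,
                               posterior$alpha, posterior$beta))
}
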