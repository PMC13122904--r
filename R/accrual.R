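# Accrual model: exponential waiting times w_i | theta ~ Exp(mean theta),
# conjugate inverse-gamma prior on theta.
#
# Parameterization contract (stated because IG conventions differ):
# theta ~ IG(shape a, scale b) has density proportional to
# theta^-(a+1) exp(-b/theta), equivalently 1/theta ~ Gamma(shape a, rate b),
# with mean b/(a - 1) for a > 1.

rinvgamma <- function(n, shape, scale) scale / rgamma(n, shape = shape)

#' Accrual prior from a trial design
#'
#' The inverse-gamma prior on the mean waiting time `theta` is worth
#' `n * P` pseudo-enrollments observed over `T * P` pseudo-time: shape
#' `k = n_target * confidence`, scale `V = horizon * confidence`. With
#' `P = 0` both are 0 (flat prior).
#'
#' @param design a [trial_design()].
#' @return an `accrual_prior` with fields `shape` (k) and `scale` (V).
#' @examples
#' accrual_prior(trial_design(1355, 48, 0.3, c(NW = 0.3)))  # k 406.5, V 14.4
#' @export
accrual_prior <- function(design) {
  if (!inherits(design, "trial_design"))
    stop_validation("design must be a trial_design")
  structure(
    list(shape = design$n_target * design$confidence,
         scale = design$horizon * design$confidence),
    class = "accrual_prior"
  )
}

#' @export
print.accrual_prior <- function(x, ...) {
  cat(sprintf("Inverse-gamma accrual prior: shape k = %g, scale V = %g\n",
              x$shape, x$scale))
  invisible(x)
}

#' Conjugate posterior of the mean waiting time
#'
#' Adds the observed enrollments to the prior pseudo-data: shape
#' `A = k + m`, scale `B = V + t_m`. The posterior is improper when no
#' information is available on either axis (e.g. a flat prior with no
#' enrollments), in which case an error of class `ubr_improper_posterior`
#' is raised.
#'
#' @param prior an [accrual_prior()].
#' @param interim an [interim_data()].
#' @return an `accrual_posterior` with fields `shape` (A) and `scale` (B).
#' @export
accrual_posterior <- function(prior, interim) {
  if (!inherits(prior, "accrual_prior"))
    stop_validation("prior must be an accrual_prior")
  if (!inherits(interim, "interim_data"))
    stop_validation("interim must be interim_data")
  A <- prior$shape + interim$m
  B <- prior$scale + interim$t_m
  if (A <= 0 || B <= 0)
    stop_improper(
      "accrual posterior is improper (shape = ", A, ", scale = ", B,
      "): a flat prior (P = 0) needs at least one observed enrollment ",
      "at a positive time")
  structure(list(shape = A, scale = B), class = "accrual_posterior")
}

#' @export
print.accrual_posterior <- function(x, ...) {
  cat(sprintf("Inverse-gamma accrual posterior: shape A = %g, scale B = %g\n",
              x$shape, x$scale))
  if (x$shape > 1)
    cat(sprintf("posterior mean waiting time: %g\n", mean(x)))
  invisible(x)
}

#' @export
mean.accrual_posterior <- function(x, ...) {
  if (x$shape <= 1) return(NA_real_)
  x$scale / (x$shape - 1)
}

#' Posterior-predictive draws of the final sample size
#'
#' For each of `s` draws, a mean waiting time `theta_j` is drawn from the
#' inverse-gamma posterior and the number of further enrollments whose
#' waiting times fit in the remaining budget `max(0, horizon - t_m)` is
#' added to the `m` already observed. Equivalently to counting sequential
#' exponential waiting times against the budget (the paper-facing
#' construction via partial sums of total waiting time), the count in a
#' fixed window of a rate-`1/theta_j` Poisson process is
#' `Poisson(budget / theta_j)`; `method` selects either route and the two
#' are distributionally identical.
#'
#' Draw order under a seed: all `theta_j` first (j ascending), then all
#' counts — runs with the same seed are bit-reproducible.
#'
#' @param posterior an [accrual_posterior()].
#' @param interim the [interim_data()] the posterior was updated with
#'   (supplies `m` and `t_m`).
#' @param horizon recruitment window `T`.
#' @param s number of posterior-predictive draws.
#' @param seed optional integer seed.
#' @param method `"poisson"` (default, closed-form count) or
#'   `"sequential"` (explicit waiting-time counting).
#' @return an `accrual_prediction`: integer `draws` (each `>= m`), the
#'   `m` at prediction, and mean/median/95\% interval summaries.
#' @export
draw_sample_sizes <- function(posterior, interim, horizon, s = 10000,
                              seed = NULL,
                              method = c("poisson", "sequential")) {
  if (!inherits(posterior, "accrual_posterior"))
    stop_validation("posterior must be an accrual_posterior")
  if (!inherits(interim, "interim_data"))
    stop_validation("interim must be interim_data")
  check_scalar(horizon, "horizon", min = .Machine$double.xmin)
  check_scalar(s, "s", min = 1, integerish = TRUE)
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)

  budget <- max(0, horizon - interim$t_m)
  theta <- rinvgamma(s, posterior$shape, posterior$scale)
  extra <- if (budget == 0) {
    integer(s)
  } else if (method == "poisson") {
    rpois(s, budget / theta)
  } else {
    vapply(theta, count_arrivals, integer(1), budget = budget)
  }
  draws <- interim$m + extra

  structure(
    list(draws = as.integer(draws), m = interim$m, horizon = horizon,
         budget = budget, s = as.integer(s), seed = seed, method = method,
         summary = summarize_draws(draws)),
    class = "accrual_prediction"
  )
}

# count exponential(theta) waiting times whose cumulative sum stays within
# budget; chunked so long horizons do not draw one variate at a time
count_arrivals <- function(theta, budget) {
  n <- 0L
  elapsed <- 0
  repeat {
    chunk <- max(16L, ceiling(1.5 * (budget - elapsed) / theta + 8))
    w <- rexp(chunk, rate = 1 / theta)
    partial <- elapsed + cumsum(w)
    k <- sum(partial <= budget)
    n <- n + as.integer(k)
    if (k < chunk) return(n)
    elapsed <- partial[chunk]
  }
}

summarize_draws <- function(draws) {
  q <- unname(quantile(draws, c(0.025, 0.5, 0.975)))
  c(mean = mean(draws), median = q[2], lower95 = q[1], upper95 = q[3])
}

#' @export
print.accrual_prediction <- function(x, ...) {
  cat(sprintf(
    "Predicted final sample size (%d draws, m = %d observed):\n", x$s, x$m))
  cat(sprintf("  median %d, mean %.1f, 95%% CrI (%d, %d)\n",
              as.integer(x$summary["median"]), x$summary["mean"],
              as.integer(x$summary["lower95"]),
              as.integer(x$summary["upper95"])))
  invisible(x)
}

#' Exact predictive distribution of the additional enrollment count
#'
#' Marginally over the inverse-gamma posterior, the Poisson count of
#' further enrollments in a remaining budget `L` is negative binomial with
#' size `A` and success probability `B / (B + L)` (mean `L * A / B`).
#' `dpredcount()` evaluates that pmf; [predictive_count_pmf()] tabulates
#' it. `L = 0` is a point mass at zero. This closed form is the oracle the
#' Monte-Carlo sampler is verified against.
#'
#' @param x vector of non-negative counts at which to evaluate the pmf.
#' @param posterior an [accrual_posterior()].
#' @param budget remaining recruitment time `L >= 0`.
#' @return `dpredcount`: probabilities at `x`.
#' @examples
#' p <- accrual_posterior(accrual_prior(trial_design(10, 5, 1, c(NW = .5))),
#'                        interim_data(0, 0))
#' dpredcount(0:3, p, budget = 5)
#' @export
dpredcount <- function(x, posterior, budget) {
  if (!inherits(posterior, "accrual_posterior"))
    stop_validation("posterior must be an accrual_posterior")
  check_scalar(budget, "budget", min = 0)
  if (budget == 0) return(as.numeric(x == 0))
  dnbinom(x, size = posterior$shape,
          prob = posterior$scale / (posterior$scale + budget))
}

#' @rdname dpredcount
#' @param max_count largest count to tabulate; defaults to covering all but
#'   `1e-9` of the mass.
#' @return `predictive_count_pmf`: a data frame with columns `count` and
#'   `prob`.
#' @export
predictive_count_pmf <- function(posterior, budget, max_count = NULL) {
  check_scalar(budget, "budget", min = 0)
  if (budget == 0)
    return(data.frame(count = 0L, prob = 1))
  if (is.null(max_count))
    max_count <- qnbinom(1e-9, size = posterior$shape,
                         prob = posterior$scale / (posterior$scale + budget),
                         lower.tail = FALSE)
  counts <- 0:max_count
  data.frame(count = counts, prob = dpredcount(counts, posterior, budget))
}
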