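#' Joint posterior-predictive forecast of sample size and rUBR
#'
#' Couples the accrual and category models at one interim look. For each
#' of `s` draws: (1) a final sample size `n_j^p` is drawn from the accrual
#' posterior predictive; (2) for every UBR category a fresh rate is drawn
#' from its beta posterior and a future count from
#' `Binomial(n_j^p - m, p_j)`, added to the observed count; (3) the
#' combined rUBR draw is the sum over categories of category total divided
#' by `n_j^p`. Under a fixed seed the draw order is: accrual rates, accrual
#' counts, then per category (design order) rates and counts — identical
#' seeds give identical predictions.
#'
#' Because aggregated counts cannot express overlap, a subject in two
#' categories is counted twice by the additive rUBR formula; draws above 1
#' are therefore possible and are reported with a warning, never clamped.
#'
#' @param design a [trial_design()]; every design category must have an
#'   observed count in `interim`.
#' @param interim an [interim_data()].
#' @param s number of paired draws (default 10,000).
#' @param seed optional integer seed.
#' @return a `joint_prediction` with elements `sample_size` (integer
#'   draws), `category_totals` (named list of integer draw vectors, each
#'   observed + future), `rubr` (numeric draws), the inputs, and
#'   mean/median/95\% interval summaries per quantity.
#' @examples
#' d <- trial_design(200, 20, 0.3, c(NW = 0.3, H = 0.1))
#' i <- interim_data(100, 10, c(NW = 32, H = 9))
#' predict_joint(d, i, s = 1000, seed = 1)
#' @export
predict_joint <- function(design, interim, s = 10000, seed = NULL) {
  if (!inherits(design, "trial_design"))
    stop_validation("design must be a trial_design")
  if (!inherits(interim, "interim_data"))
    stop_validation("interim must be interim_data")
  check_scalar(s, "s", min = 1, integerish = TRUE)
  labels <- design$categories$label
  missing_counts <- setdiff(labels, names(interim$counts))
  if (length(missing_counts))
    stop_validation("interim counts missing for categories: ",
                    paste(missing_counts, collapse = ", "))

  acc_post <- accrual_posterior(accrual_prior(design), interim)
  cat_posts <- lapply(labels, function(u)
    ubr_posterior(ubr_prior(design, u), interim$m, interim$counts[[u]]))
  names(cat_posts) <- labels

  if (!is.null(seed)) set.seed(seed)
  budget <- max(0, design$horizon - interim$t_m)
  theta <- rinvgamma(s, acc_post$shape, acc_post$scale)
  extra <- if (budget == 0) integer(s) else rpois(s, budget / theta)
  n_draws <- interim$m + as.integer(extra)

  totals <- lapply(labels, function(u) {
    post <- cat_posts[[u]]
    p <- rbeta(s, post$alpha, post$beta)
    interim$counts[[u]] + as.integer(rbinom(s, size = extra, prob = p))
  })
  names(totals) <- labels

  total_ubr <- Reduce(`+`, totals)
  rubr <- ifelse(n_draws > 0, total_ubr / n_draws, 0)
  if (any(rubr > 1))
    warning(sprintf(
      "%.1f%% of rUBR draws exceed 1: the additive combined rate double-",
      100 * mean(rubr > 1)),
      "counts subjects belonging to several categories (aggregated-data ",
      "limitation)", call. = FALSE)

  structure(
    list(sample_size = n_draws, category_totals = totals, rubr = rubr,
         design = design, interim = interim, s = as.integer(s), seed = seed,
         summary = list(sample_size = summarize_draws(n_draws),
                        rubr = summarize_draws(rubr))),
    class = "joint_prediction"
  )
}

#' @export
print.joint_prediction <- function(x, ...) {
  sn <- x$summary$sample_size
  sr <- x$summary$rubr
  cat(sprintf("Joint prediction at m = %d, t_m = %g (%d draws)\n",
              x$interim$m, x$interim$t_m, x$s))
  cat(sprintf("  sample size: median %d, mean %.1f, 95%% CrI (%d, %d)\n",
              as.integer(sn["median"]), sn["mean"],
              as.integer(sn["lower95"]), as.integer(sn["upper95"])))
  cat(sprintf("  rUBR:        median %.3f, mean %.3f, 95%% CrI (%.3f, %.3f)\n",
              sr["median"], sr["mean"], sr["lower95"], sr["upper95"]))
  invisible(x)
}

#' Final observed combined rUBR
#'
#' The combined rate of UBR at trial completion: the sum over categories
#' of the final category count divided by the final sample size, e.g.
#' `rUBR_f = n_f^NW/n_f + n_f^H/n_f + n_f^R/n_f` for race, ethnicity and
#' rurality. Returned at full precision; display convention in reports and
#' tables is 3 decimals.
#'
#' @param final a [final_counts()] object.
#' @return the combined rUBR (numeric; may exceed 1 when categories
#'   overlap).
#' @examples
#' round(final_rubr(final_counts(1100, c(NW = 302, H = 244))), 3)
#' @export
final_rubr <- function(final) {
  if (!inherits(final, "final_counts"))
    stop_validation("final must be a final_counts object")
  sum(final$counts) / final$n_f
}

#' Probability of meeting accrual and rUBR targets
#'
#' The proportion of joint draws at or above each target (ties count as
#' meeting). With the trial window exhausted the draws are degenerate at
#' the observed state and the probabilities are exact 0/1 indicators.
#'
#' @param prediction a [predict_joint()] result.
#' @param n_target sample-size target; defaults to the design's.
#' @param rubr_target combined-rUBR target; defaults to the design's (if
#'   set).
#' @return named numeric `c(p_accrual, p_rubr)`; `p_rubr` is `NA` when no
#'   rUBR target is available.
#' @export
prob_meeting <- function(prediction, n_target = NULL, rubr_target = NULL) {
  if (!inherits(prediction, "joint_prediction"))
    stop_validation("prediction must be a joint_prediction")
  if (is.null(n_target)) n_target <- prediction$design$n_target
  if (is.null(rubr_target)) rubr_target <- prediction$design$rubr_target
  c(p_accrual = mean(prediction$sample_size >= n_target),
    p_rubr = if (is.null(rubr_target)) NA_real_
             else mean(prediction$rubr >= rubr_target))
}

#' Interim monitoring report across looks
#'
#' Runs [predict_joint()] at each interim look and tabulates, per look,
#' the point estimates (median by default, with the mean alongside) and
#' equal-tailed 95% credible intervals for the predicted final sample
#' size and combined rUBR, plus the probabilities of meeting the design
#' targets. Per-look seeds are derived as `seed + look index - 1` so the
#' whole table is reproducible.
#'
#' @param design a [trial_design()].
#' @param interims list of [interim_data()], ordered by `t_m`.
#' @param s draws per look.
#' @param seed optional integer seed.
#' @return an `interim_report`: a data frame with one row per look and
#'   attributes `design`, `s`, `seed`.
#' @export
summarize_interims <- function(design, interims, s = 10000, seed = NULL) {
  if (!length(interims))
    stop_validation("interims must be a non-empty list of interim_data")
  if (inherits(interims, "interim_data")) interims <- list(interims)
  t_ms <- vapply(interims, function(x) x$t_m, numeric(1))
  if (is.unsorted(t_ms))
    stop_validation("interims must be ordered by non-decreasing t_m")

  rows <- lapply(seq_along(interims), function(i) {
    look_seed <- if (is.null(seed)) NULL else seed + i - 1L
    pred <- predict_joint(design, interims[[i]], s = s, seed = look_seed)
    pm <- prob_meeting(pred)
    sn <- pred$summary$sample_size
    sr <- pred$summary$rubr
    data.frame(
      interim = i, m = interims[[i]]$m, t_m = interims[[i]]$t_m,
      n_median = sn[["median"]], n_mean = sn[["mean"]],
      n_lower95 = sn[["lower95"]], n_upper95 = sn[["upper95"]],
      rubr_median = sr[["median"]], rubr_mean = sr[["mean"]],
      rubr_lower95 = sr[["lower95"]], rubr_upper95 = sr[["upper95"]],
      p_accrual = pm[["p_accrual"]], p_rubr = pm[["p_rubr"]])
  })
  report <- do.call(rbind, rows)
  structure(report, design = design, s = as.integer(s), seed = seed,
            class = c("interim_report", "data.frame"))
}

#' @export
print.interim_report <- function(x, ...) {
  cat(sprintf("Interim monitoring report (%d looks, s = %d draws each)\n",
              nrow(x), attr(x, "s")))
  shown <- data.frame(
    interim = x$interim, m = x$m, t_m = round(x$t_m, 2),
    `sample size (95% CrI)` = sprintf("%d (%d, %d)",
      as.integer(round(x$n_median)), as.integer(round(x$n_lower95)),
      as.integer(round(x$n_upper95))),
    `rUBR (95% CrI)` = sprintf("%.3f (%.3f, %.3f)",
      x$rubr_median, x$rubr_lower95, x$rubr_upper95),
    p_accrual = round(x$p_accrual, 3), p_rubr = round(x$p_rubr, 3),
    check.names = FALSE)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Scatter of joint predictive draws
#'
#' Plots (rUBR draw, sample-size draw) pairs with dashed reference lines
#' at the targets, the usual picture of a joint interim forecast.
#'
#' @param x a `joint_prediction`.
#' @param n_target,rubr_target reference targets; default to the design's.
#' @param ... passed to [plot()].
#' @export
plot.joint_prediction <- function(x, n_target = NULL, rubr_target = NULL,
                                  ...) {
  if (is.null(n_target)) n_target <- x$design$n_target
  if (is.null(rubr_target)) rubr_target <- x$design$rubr_target
  plot(x$rubr, x$sample_size, pch = 16, cex = 0.4,
       col = rgb(0, 0, 0, 0.25),
       xlab = "predicted rUBR", ylab = "predicted sample size", ...)
  if (!is.null(n_target)) abline(h = n_target, col = "red", lty = 2)
  if (!is.null(rubr_target)) abline(v = rubr_target, col = "red", lty = 2)
  invisible(x)
}
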