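#' Specify a trial design for accrual and rUBR monitoring
#'
#' A trial design holds the planned sample size `n_target`, the recruitment
#' horizon `horizon` (in study time-units; the package is unit-agnostic as
#' long as all times share the unit), the prior confidence `confidence`
#' (`P`, on the 0-1 scale; an elicitation on the conventional 1-10 scale is
#' divided by 10, see [read_design()]), and the UBR category specifications.
#'
#' The confidence scales every prior: the accrual prior is worth `n * P`
#' pseudo-subjects observed over `T * P` time-units, and each category prior
#' is worth `n * P` pseudo-subjects at its prior rate `p0`. `P = 0` is a
#' flat prior, `P = 1` full prior weight of the planned trial.
#'
#' @param n_target planned sample size (positive integer).
#' @param horizon recruitment window `T > 0`, in study time-units.
#' @param confidence prior confidence `P` in `[0, 1]`.
#' @param categories UBR categories: either a named numeric vector of prior
#'   rates (`c(NW = 0.3, H = 0.2)`) or a data frame with columns `label`,
#'   `p0` and optionally `target` (a per-category monitoring target rate).
#' @param rubr_target optional combined-rUBR monitoring target in `[0, 1]`.
#' @return an object of class `trial_design`.
#' @examples
#' trial_design(1355, 48, 0.3, c(NW = 0.30, H = 0.20), rubr_target = 0.5)
#' @export
trial_design <- function(n_target, horizon, confidence, categories,
                         rubr_target = NULL) {
  check_scalar(n_target, "n_target", min = 1, integerish = TRUE)
  check_scalar(horizon, "horizon", min = .Machine$double.xmin)
  check_scalar(confidence, "confidence", min = 0, max = 1)
  if (!is.null(rubr_target))
    check_scalar(rubr_target, "rubr_target", min = 0, max = 1)

  categories <- as_category_table(categories)

  structure(
    list(n_target = as.integer(n_target), horizon = as.numeric(horizon),
         confidence = as.numeric(confidence), categories = categories,
         rubr_target = rubr_target),
    class = "trial_design"
  )
}

# normalize the two accepted category forms to a data.frame(label, p0, target)
as_category_table <- function(categories) {
  if (is.numeric(categories) && !is.null(names(categories))) {
    categories <- data.frame(label = names(categories),
                             p0 = as.numeric(categories),
                             target = NA_real_,
                             stringsAsFactors = FALSE)
  }
  if (!is.data.frame(categories) ||
      !all(c("label", "p0") %in% names(categories)))
    stop_validation("categories must be a named numeric vector of prior ",
                    "rates or a data frame with columns 'label' and 'p0'")
  if (is.null(categories$target)) categories$target <- NA_real_
  categories <- categories[, c("label", "p0", "target")]
  categories$label <- as.character(categories$label)
  if (nrow(categories) < 1L)
    stop_validation("at least one UBR category is required")
  if (any(is.na(categories$label)) || any(!nzchar(categories$label)))
    stop_validation("category labels must be non-empty")
  if (anyDuplicated(categories$label))
    stop_validation("category labels must be unique")
  if (any(!is.finite(categories$p0)) ||
      any(categories$p0 < 0) || any(categories$p0 > 1))
    stop_validation("every prior rate p0 must lie in [0, 1]")
  bad_target <- !is.na(categories$target) &
    (categories$target < 0 | categories$target > 1)
  if (any(bad_target))
    stop_validation("category targets must lie in [0, 1]")
  rownames(categories) <- NULL
  categories
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf("Trial design: n = %d within T = %g (confidence P = %g)\n",
              x$n_target, x$horizon, x$confidence))
  cat("UBR categories:\n")
  print(x$categories, row.names = FALSE)
  if (!is.null(x$rubr_target))
    cat(sprintf("Combined rUBR target: %.3f\n", x$rubr_target))
  invisible(x)
}

#' Observed interim data at a monitoring look
#'
#' Aggregated interim state at (or just after) the `m`-th enrollment: the
#' number enrolled `m`, the elapsed accrual time `t_m` (the time of the
#' `m`-th enrollment, i.e. the sum of the observed waiting times), and the
#' per-category counts of UBR membership among those `m` subjects — the
#' form in which DSMB reports present enrollment.
#'
#' @param m subjects enrolled so far (non-negative integer).
#' @param t_m time of the `m`-th enrollment in study time-units; must be 0
#'   when `m = 0`.
#' @param counts named integer vector of per-category UBR counts
#'   (`0 <= counts <= m`). Names must match the design's category labels
#'   when the interim is used for prediction.
#' @return an object of class `interim_data`.
#' @examples
#' interim_data(50, 3.0, c(NW = 10, H = 10))
#' @export
interim_data <- function(m, t_m, counts = integer()) {
  check_scalar(m, "m", min = 0, integerish = TRUE)
  check_scalar(t_m, "t_m", min = 0)
  if (length(counts) && is.null(names(counts)))
    stop_validation("counts must be named by category label")
  if (length(counts)) {
    for (u in names(counts))
      check_scalar(counts[[u]], paste0("counts[", u, "]"),
                   min = 0, max = m, integerish = TRUE)
  }
  if (m == 0 && t_m != 0)
    stop_validation("t_m must be 0 when no subjects are enrolled (m = 0)")
  structure(
    list(m = as.integer(m), t_m = as.numeric(t_m),
         counts = stats::setNames(as.integer(counts), names(counts))),
    class = "interim_data"
  )
}

#' @export
print.interim_data <- function(x, ...) {
  cat(sprintf("Interim data: m = %d enrolled by t_m = %g\n", x$m, x$t_m))
  if (length(x$counts))
    cat("counts:", paste(names(x$counts), x$counts, sep = " = ",
                         collapse = ", "), "\n")
  invisible(x)
}

#' Final enrollment counts of a completed trial
#'
#' @param n_f final sample size (positive integer).
#' @param counts named integer vector of final per-category UBR counts,
#'   each at most `n_f`.
#' @return an object of class `final_counts`.
#' @seealso [final_rubr()]
#' @export
final_counts <- function(n_f, counts) {
  check_scalar(n_f, "n_f", min = 1, integerish = TRUE)
  if (!length(counts) || is.null(names(counts)))
    stop_validation("counts must be a non-empty named vector")
  for (u in names(counts))
    check_scalar(counts[[u]], paste0("counts[", u, "]"),
                 min = 0, max = n_f, integerish = TRUE)
  structure(
    list(n_f = as.integer(n_f),
         counts = stats::setNames(as.integer(counts), names(counts))),
    class = "final_counts"
  )
}
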