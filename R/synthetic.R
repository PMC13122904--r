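# Synthetic trials with exactly the generative structure the models assume:
# i.i.d. exponential inter-arrival times and per-subject Bernoulli category
# flags. Used for every test and simulation study; no external data needed.

#' Configure a synthetic trial
#'
#' @param theta true mean waiting time between enrollments (study
#'   time-units per subject).
#' @param p named vector of true category membership probabilities.
#' @param horizon recruitment window; enrollment stops at whichever of
#'   `horizon` or `n_max` binds first.
#' @param n_max cap on enrolled subjects (default unbounded).
#' @param overlap_pairs optional list of 2-element character vectors; each
#'   pair shares a single Bernoulli draw (the second label copies the
#'   first), forcing complete overlap between the two categories. The
#'   default is independent flags — the implicit assumption of the
#'   aggregated additive rUBR; the overlap mode exists to demonstrate its
#'   double-counting bias.
#' @param seed optional integer seed used by [generate_trial()].
#' @return a `synth_trial_config`.
#' @export
synth_trial_config <- function(theta, p, horizon, n_max = Inf,
                               overlap_pairs = NULL, seed = NULL) {
  check_scalar(theta, "theta", min = .Machine$double.xmin)
  check_scalar(horizon, "horizon", min = .Machine$double.xmin)
  if (!is.numeric(p) || is.null(names(p)) || any(p < 0) || any(p > 1))
    stop_validation("p must be a named vector of probabilities in [0, 1]")
  if (!identical(n_max, Inf))
    check_scalar(n_max, "n_max", min = 0, integerish = TRUE)
  for (pair in overlap_pairs) {
    if (length(pair) != 2L || !all(pair %in% names(p)))
      stop_validation("each overlap pair must name two configured categories")
  }
  structure(
    list(theta = theta, p = p, horizon = horizon, n_max = n_max,
         overlap_pairs = overlap_pairs, seed = seed),
    class = "synth_trial_config"
  )
}

#' Simulate an enrollment log
#'
#' Inter-arrival times are i.i.d. exponential with mean `theta`;
#' enrollment stops at the last arrival within `horizon` or at `n_max`
#' subjects, whichever comes first. Each subject carries one 0/1 flag per
#' category, Bernoulli with the configured probability (overlap pairs
#' share draws). Reproducible under the config seed.
#'
#' @param config a [synth_trial_config()].
#' @return an `enrollment_log`: a data frame with columns `subject`,
#'   `time` (strictly increasing enrollment times since study start) and
#'   one 0/1 column per category.
#' @export
generate_trial <- function(config) {
  if (!inherits(config, "synth_trial_config"))
    stop_validation("config must be a synth_trial_config")
  if (!is.null(config$seed)) set.seed(config$seed)

  times <- numeric(0)
  elapsed <- 0
  repeat {
    chunk <- max(32L,
                 ceiling(1.5 * (config$horizon - elapsed) / config$theta + 8))
    w <- rexp(chunk, rate = 1 / config$theta)
    arrivals <- elapsed + cumsum(w)
    keep <- arrivals <= config$horizon
    times <- c(times, arrivals[keep])
    if (length(times) >= config$n_max || !all(keep)) break
    elapsed <- arrivals[chunk]
  }
  if (length(times) > config$n_max) times <- times[seq_len(config$n_max)]

  n <- length(times)
  log <- data.frame(subject = seq_len(n), time = times)
  for (u in names(config$p)) log[[u]] <- rbinom(n, 1L, config$p[[u]])
  for (pair in config$overlap_pairs) log[[pair[2L]]] <- log[[pair[1L]]]

  enrollment_log(log, names(config$p))
}

# internal constructor: validates and classes a subject-level log
enrollment_log <- function(df, categories) {
  if (!all(c("subject", "time") %in% names(df)))
    stop_validation("an enrollment log needs 'subject' and 'time' columns")
  if (is.unsorted(df$time, strictly = FALSE))
    stop_validation("enrollment times must be non-decreasing")
  for (u in categories) {
    if (is.null(df[[u]]))
      stop_validation("missing flag column for category '", u, "'")
    bad <- which(!(df[[u]] %in% c(0L, 1L)))
    if (length(bad))
      stop_validation("flag column '", u, "' has a value outside {0, 1} ",
                      "at row ", bad[1L])
  }
  structure(df[, c("subject", "time", categories), drop = FALSE],
            categories = categories,
            class = c("enrollment_log", "data.frame"))
}

#' Aggregate an enrollment log at a monitoring time
#'
#' Counts the subjects enrolled by `at_time`; `t_m` is the time of the
#' last of them (0 for an empty interim) — in-progress waiting time after
#' the m-th enrollment does not enter the likelihood.
#'
#' @param log an `enrollment_log`.
#' @param at_time monitoring time (`>= 0`).
#' @return an [interim_data()].
#' @export
aggregate_at <- function(log, at_time) {
  if (!inherits(log, "enrollment_log"))
    stop_validation("log must be an enrollment_log")
  check_scalar(at_time, "at_time", min = 0)
  categories <- attr(log, "categories")
  enrolled <- log[log$time <= at_time, , drop = FALSE]
  m <- nrow(enrolled)
  counts <- vapply(categories, function(u) sum(enrolled[[u]]), numeric(1))
  interim_data(m, if (m > 0) max(enrolled$time) else 0, counts)
}

#' A packaged large-trial synthetic configuration
#'
#' Emulates the published *shape* of a large multi-year obstetric trial:
#' target 1355 subjects over a 48-month window at prior confidence 0.3,
#' final enrollment near 1100, two UBR categories (non-white near 27%,
#' Hispanic near 22%), and ten monitoring looks every quarter once 300
#' subjects are enrolled. Only summary shape is emulated; no subject-level
#' data from any real trial is involved.
#'
#' @param seed integer seed for the generated log.
#' @return a list with elements `design` (a [trial_design()]), `config`
#'   (a [synth_trial_config()]) and `look_spec` (`after_m`, `every`,
#'   `n_looks`).
#' @seealso [look_times()]
#' @export
adore_like_trial <- function(seed = 20260101) {
  design <- trial_design(
    n_target = 1355, horizon = 48, confidence = 0.3,
    categories = c(NW = 0.30, H = 0.20), rubr_target = 0.5)
  config <- synth_trial_config(
    theta = 48 / 1100, p = c(NW = 302 / 1100, H = 244 / 1100),
    horizon = 48, seed = seed)
  list(design = design, config = config,
       look_spec = list(after_m = 300L, every = 3, n_looks = 10L))
}

#' Monitoring look times for an enrollment log
#'
#' Returns `n_looks` equally spaced monitoring times starting when the
#' `after_m`-th subject enrolls, truncated to the horizon.
#'
#' @param log an `enrollment_log`.
#' @param after_m first look occurs at the `after_m`-th enrollment.
#' @param every spacing between looks, in study time-units.
#' @param n_looks number of looks.
#' @param horizon optional truncation time.
#' @return numeric vector of look times.
#' @export
look_times <- function(log, after_m, every, n_looks, horizon = Inf) {
  if (!inherits(log, "enrollment_log"))
    stop_validation("log must be an enrollment_log")
  if (nrow(log) < after_m)
    stop_validation("log has fewer than ", after_m, " enrollments")
  start <- log$time[after_m]
  times <- start + every * (seq_len(n_looks) - 1)
  times[times <= horizon]
}
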