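# File formats: YAML/JSON design documents, subject-level enrollment CSVs,
# aggregated interim-summary CSV/JSON, and versioned JSON reports.

REPORT_SCHEMA_VERSION <- "1.0"
DAYS_PER_MONTH <- 30.4375  # mean Gregorian month

#' Read a trial-design document
#'
#' Reads a declarative YAML or JSON design. Required fields: `n_target`,
#' `horizon`, `confidence`, `confidence_scale` (`"ten"` for the 1-10
#' elicitation scale, divided by 10; `"unit"` for an already-normalized
#' 0-1 value — exactly one scale must be declared), and `categories` (a
#' list of `label`/`p0`/optional `target`). Optional: `rubr_target`,
#' `time_unit` (label only; all times must share it), `s`, `seed`,
#' `start_date` (ISO-8601, used by [read_enrollment_csv()] for date
#' columns).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return a [trial_design()] with attributes `s`, `seed`, `time_unit`,
#'   `start_date` when present in the document.
#' @export
read_design <- function(path) {
  doc <- read_config(path)
  for (field in c("n_target", "horizon", "confidence", "confidence_scale",
                  "categories"))
    if (is.null(doc[[field]]))
      stop_validation("design document is missing required field '",
                      field, "'")
  confidence <- switch(
    as.character(doc$confidence_scale),
    ten = doc$confidence / 10,
    unit = doc$confidence,
    stop_validation("confidence_scale must be 'ten' or 'unit', got '",
                    doc$confidence_scale, "'"))
  cats <- do.call(rbind, lapply(doc$categories, function(cc) {
    if (is.null(cc$label) || is.null(cc$p0))
      stop_validation("each category needs 'label' and 'p0'")
    data.frame(label = cc$label, p0 = cc$p0,
               target = if (is.null(cc$target)) NA_real_ else cc$target)
  }))
  design <- trial_design(doc$n_target, doc$horizon, confidence, cats,
                         rubr_target = doc$rubr_target)
  for (a in c("s", "seed", "time_unit", "start_date"))
    attr(design, a) <- doc[[a]]
  design
}

read_config <- function(path) {
  if (!file.exists(path))
    stop_validation("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop_validation("unsupported config format '.", ext,
                    "' (use .yaml/.yml/.json): ", path)
  }
}

#' Read a subject-level enrollment log
#'
#' Parses a CSV with one row per enrolled subject: `subject_id`, either
#' `enroll_time` (numeric, study time-units) or `enroll_date` (ISO-8601,
#' converted using `start_date` and `unit`: days, or months at
#' 30.4375 days/month), and one 0/1 flag column per design category.
#' Rows are sorted by time; ties keep file order.
#'
#' @param path CSV path.
#' @param design a [trial_design()] declaring the expected categories.
#' @param start_date study start (ISO-8601 string or `Date`), required for
#'   date-based files; defaults to the design's `start_date` attribute.
#' @param unit `"months"` or `"days"` for date conversion.
#' @return an `enrollment_log`.
#' @export
read_enrollment_csv <- function(path, design, start_date = NULL,
                                unit = c("months", "days")) {
  unit <- match.arg(unit)
  if (!inherits(design, "trial_design"))
    stop_validation("design must be a trial_design")
  if (!file.exists(path))
    stop_validation("file not found: ", path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (is.null(raw$subject_id))
    stop_validation("enrollment CSV is missing column 'subject_id'")

  if (!is.null(raw$enroll_time)) {
    time <- as.numeric(raw$enroll_time)
    if (any(is.na(time)))
      stop_validation("non-numeric enroll_time at row ",
                      which(is.na(time))[1L])
  } else if (!is.null(raw$enroll_date)) {
    if (is.null(start_date)) start_date <- attr(design, "start_date")
    if (is.null(start_date))
      stop_validation("date-based enrollment needs a study start_date")
    start <- as.Date(start_date)
    dates <- as.Date(raw$enroll_date, format = "%Y-%m-%d")
    if (any(is.na(dates)))
      stop_validation("unparseable enroll_date at row ",
                      which(is.na(dates))[1L])
    days <- as.numeric(dates - start)
    time <- if (unit == "months") days / DAYS_PER_MONTH else days
  } else {
    stop_validation("enrollment CSV needs 'enroll_time' or 'enroll_date'")
  }
  if (any(time < 0))
    stop_validation("enrollment before study start at row ",
                    which(time < 0)[1L])

  labels <- design$categories$label
  for (u in labels) {
    if (is.null(raw[[u]]))
      stop_validation("enrollment CSV is missing flag column '", u, "'")
    bad <- which(!(raw[[u]] %in% c(0L, 1L)))
    if (length(bad))
      stop_validation("flag value outside {0, 1} at row ", bad[1L],
                      ", column '", u, "'")
  }

  ord <- order(time)  # stable: ties keep file order
  df <- data.frame(subject = raw$subject_id[ord], time = time[ord])
  for (u in labels) df[[u]] <- as.integer(raw[[u]][ord])
  enrollment_log(df, labels)
}

#' Write an enrollment log as CSV
#'
#' Inverse of [read_enrollment_csv()] for the numeric-time dialect.
#'
#' @param log an `enrollment_log`.
#' @param path output CSV path.
#' @export
write_enrollment_csv <- function(log, path) {
  if (!inherits(log, "enrollment_log"))
    stop_validation("log must be an enrollment_log")
  out <- log
  names(out)[names(out) == "subject"] <- "subject_id"
  names(out)[names(out) == "time"] <- "enroll_time"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read aggregated interim summaries
#'
#' Parses a CSV (or JSON array) with one row per monitoring look: `m`,
#' `t_m` and one count column per design category (optionally
#' `interim_index`). Looks must be in non-decreasing `t_m` order and each
#' count at most `m`. An empty file yields an empty list with a warning.
#'
#' @param path CSV or JSON path.
#' @param design a [trial_design()].
#' @return a list of [interim_data()] ordered by `t_m`.
#' @export
read_interim_summary <- function(path, design) {
  if (!inherits(design, "trial_design"))
    stop_validation("design must be a trial_design")
  if (!file.exists(path))
    stop_validation("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  rows <- if (ext == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path, stringsAsFactors = FALSE)
  }
  if (!nrow(rows)) {
    warning("interim summary '", path, "' contains no looks", call. = FALSE)
    return(list())
  }
  for (field in c("m", "t_m", design$categories$label))
    if (is.null(rows[[field]]))
      stop_validation("interim summary is missing column '", field, "'")
  if (is.unsorted(rows$t_m))
    stop_validation("interim t_m values must be non-decreasing")
  lapply(seq_len(nrow(rows)), function(i) {
    counts <- vapply(design$categories$label,
                     function(u) rows[[u]][i], numeric(1))
    interim_data(rows$m[i], rows$t_m[i], counts)
  })
}

#' Write and read a JSON monitoring report
#'
#' `write_report()` serializes an [summarize_interims()] table or a single
#' [predict_joint()] result as a versioned JSON document: model settings,
#' then one block per interim with the observed state, point estimates,
#' 95% credible intervals and meeting probabilities. Per-draw arrays are
#' included only when `include_draws = TRUE` (joint predictions only).
#' `read_report()` parses the document back into a plain list.
#'
#' @param x an `interim_report` or `joint_prediction`.
#' @param path output path.
#' @param include_draws include raw draw vectors (default off).
#' @return `write_report()` returns `path` invisibly; `read_report()` the
#'   parsed document.
#' @export
write_report <- function(x, path, include_draws = FALSE) {
  doc <- report_document(x, include_draws)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    stop_validation("file not found: ", path)
  jsonlite::read_json(path, simplifyVector = FALSE)
}

report_document <- function(x, include_draws = FALSE) {
  UseMethod("report_document")
}

#' @export
report_document.interim_report <- function(x, include_draws = FALSE) {
  design <- attr(x, "design")
  blocks <- lapply(seq_len(nrow(x)), function(i) {
    row <- x[i, ]
    list(index = row$interim, m = row$m, t_m = row$t_m,
         sample_size = list(median = row$n_median, mean = row$n_mean,
                            lower95 = row$n_lower95,
                            upper95 = row$n_upper95),
         rubr = list(median = row$rubr_median, mean = row$rubr_mean,
                     lower95 = row$rubr_lower95,
                     upper95 = row$rubr_upper95),
         prob_meeting = list(accrual = row$p_accrual, rubr = row$p_rubr))
  })
  list(schema_version = REPORT_SCHEMA_VERSION, tool = "ubrmonitor",
       settings = design_settings(design, attr(x, "s"), attr(x, "seed")),
       interims = blocks)
}

#' @export
report_document.joint_prediction <- function(x, include_draws = FALSE) {
  pm <- prob_meeting(x)
  block <- list(
    index = 1L, m = x$interim$m, t_m = x$interim$t_m,
    counts = as.list(x$interim$counts),
    sample_size = as.list(x$summary$sample_size),
    rubr = as.list(x$summary$rubr),
    prob_meeting = list(accrual = pm[["p_accrual"]], rubr = pm[["p_rubr"]]))
  if (include_draws)
    block$draws <- list(sample_size = x$sample_size, rubr = x$rubr)
  list(schema_version = REPORT_SCHEMA_VERSION, tool = "ubrmonitor",
       settings = design_settings(x$design, x$s, x$seed),
       interims = list(block))
}

design_settings <- function(design, s, seed) {
  list(
    n_target = design$n_target, horizon = design$horizon,
    confidence = design$confidence, rubr_target = design$rubr_target,
    categories = lapply(seq_len(nrow(design$categories)), function(i)
      list(label = design$categories$label[i],
           p0 = design$categories$p0[i],
           target = design$categories$target[i])),
    s = s, seed = seed)
}

#' Validate a parsed report against the shipped schema
#'
#' Structural check: schema version, settings fields, and per-interim
#' blocks with estimates, intervals and probabilities.
#'
#' @param doc a parsed report ([read_report()]).
#' @return `TRUE` invisibly; raises a validation error otherwise.
#' @export
validate_report <- function(doc) {
  if (!identical(as.character(doc$schema_version), REPORT_SCHEMA_VERSION))
    stop_validation("unknown report schema version")
  for (field in c("n_target", "horizon", "confidence", "categories"))
    if (is.null(doc$settings[[field]]))
      stop_validation("report settings missing '", field, "'")
  interims <- doc$interims
  if (!length(interims))
    stop_validation("report has no interim blocks")
  for (b in interims) {
    for (field in c("index", "m", "t_m", "sample_size", "rubr",
                    "prob_meeting"))
      if (is.null(b[[field]]))
        stop_validation("interim block missing '", field, "'")
    for (q in c("sample_size", "rubr"))
      for (field in c("median", "mean", "lower95", "upper95"))
        if (is.null(b[[q]][[field]]))
          stop_validation("interim block ", q, " missing '", field, "'")
  }
  invisible(TRUE)
}
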