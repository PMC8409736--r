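#' Analysis configuration
#'
#' Collects every tunable of the workflow with its default. Defaults follow
#' common plate-reader practice: measurements every 10 min
#' (`interval_seconds = 600`), 95% credible intervals, 100 posterior
#' samples, a 20% secondary-phase threshold for diauxie calls, a 1.2
#' normalized-AUC threshold for calling growth, 100 permutations with a 10%
#' false discovery rate for differential testing, and a 1 h Gaussian filter
#' for the empirical noise profile.
#'
#' @param interval_seconds measurement cadence used when a file has no
#'   explicit time axis.
#' @param skip_first_n leading time points to drop.
#' @param do_blank_subtraction,do_control_subtraction,do_polynomial_baseline
#'   optional preprocessing steps.
#' @param limit_of_detection positivity floor in OD units, or `"auto"`.
#' @param time_units `"auto"` (values > 100 are seconds), `"hours"`, or
#'   `"seconds"` for explicit time axes in plate files.
#' @param confidence credible level in (0, 1).
#' @param posterior_samples posterior draws for sampled summaries.
#' @param diauxie_ratio secondary/primary threshold for confirming a phase.
#' @param diauxie_criterion `"total-growth"` or `"growth-rate"`.
#' @param growth_call_threshold normalized-AUC threshold for calling growth.
#' @param n_permutations permutations for the null Bayes-factor
#'   distribution.
#' @param fdr false discovery rate in (0, 1).
#' @param seed integer seed, or `NULL`.
#' @param include_noise_in_bands add the fitted Gaussian noise to credible
#'   bands?
#' @param empirical_noise estimate a fixed time-dependent noise profile
#'   across replicates?
#' @param filter_width_hours Gaussian filter width for the noise profile.
#' @param restarts optimizer restarts per GP fit.
#' @param ... further entries stored verbatim (e.g. `step_order`).
#' @return a list of class `"growth_config"`.
#' @export
growth_config <- function(interval_seconds = 600,
                          skip_first_n = 0L,
                          do_blank_subtraction = FALSE,
                          do_control_subtraction = FALSE,
                          do_polynomial_baseline = FALSE,
                          limit_of_detection = "auto",
                          time_units = "auto",
                          confidence = 0.95,
                          posterior_samples = 100L,
                          diauxie_ratio = 0.20,
                          diauxie_criterion = "total-growth",
                          growth_call_threshold = 1.2,
                          n_permutations = 100L,
                          fdr = 0.10,
                          seed = NULL,
                          include_noise_in_bands = TRUE,
                          empirical_noise = FALSE,
                          filter_width_hours = 1.0,
                          restarts = 3L,
                          ...) {
  cfg <- c(as.list(environment()), list(...))
  stopifnot(cfg$interval_seconds > 0,
            cfg$skip_first_n >= 0,
            cfg$confidence > 0 && cfg$confidence < 1,
            cfg$posterior_samples > 0,
            cfg$diauxie_ratio > 0,
            cfg$growth_call_threshold > 0,
            cfg$n_permutations > 0,
            cfg$fdr > 0 && cfg$fdr < 1,
            cfg$filter_width_hours > 0)
  cfg$diauxie_criterion <- match.arg(cfg$diauxie_criterion,
                                     c("total-growth", "growth-rate"))
  cfg$time_units <- match.arg(cfg$time_units, c("auto", "hours", "seconds"))
  if (!identical(cfg$limit_of_detection, "auto") &&
      (!is.numeric(cfg$limit_of_detection) || cfg$limit_of_detection <= 0))
    stop("limit_of_detection must be positive or 'auto'")
  class(cfg) <- "growth_config"
  cfg
}

#' Read a key:value configuration file
#'
#' Flat text configuration: one `key: value` (or `key = value`) per line;
#' `#` starts a comment. Values are coerced to numeric or logical when they
#' parse as such. Entries override the built-in defaults of
#' [growth_config()].
#'
#' @param path configuration file path.
#' @return a [growth_config()].
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$", lines))
  bad <- lengths(kv) == 0L
  if (any(bad)) stop("unparseable config line: ", lines[bad][1L])
  args <- stats::setNames(lapply(kv, function(m) coerce_value(trimws(m[3L]))),
                          vapply(kv, `[`, "", 2L))
  do.call(growth_config, args)
}

coerce_value <- function(v) {
  if (tolower(v) %in% c("true", "yes", "on")) return(TRUE)
  if (tolower(v) %in% c("false", "no", "off")) return(FALSE)
  n <- suppressWarnings(as.numeric(v))
  if (!is.na(n)) return(n)
  v
}
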