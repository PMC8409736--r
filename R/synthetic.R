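#' Specify a synthetic growth curve with known parameters
#'
#' Ground-truth generator used to exercise and validate the whole pipeline.
#' Growth shapes are built on the log scale with a sigmoid parameterized
#' directly by its plateau, maximum slope and tangent-intercept lag,
#' \deqn{y(t) = K / (1 + \exp\{4r/K\,(\lambda - t) + 2\}),}
#' so the generated curve's maximum slope equals `r` and the tangent at the
#' inflection crosses zero exactly at `lag` \eqn{= \lambda}. Available
#' shapes: `"logistic"`; `"double-logistic"` (sum of two sigmoids, the
#' second with plateau `K2`, rate `r2` and onset `onset2`);
#' `"logistic-with-decay"` (linear ln OD decline of slope `decay_rate`
#' after `decay_onset`); `"flat"`; and `"exponential"` (linear ln OD rise
#' of slope `r` after `lag`).
#'
#' @param shape curve class, see Details.
#' @param K,r,lag plateau (ln OD), maximum specific growth rate (1/h) and
#'   lag (h) of the (primary) sigmoid.
#' @param K2,r2,onset2 secondary-phase parameters for
#'   `"double-logistic"`.
#' @param decay_rate,decay_onset decline slope (1/h, positive number) and
#'   onset (h) for `"logistic-with-decay"`.
#' @param noise_sd standard deviation of the additive Gaussian measurement
#'   noise on the ln OD scale.
#' @param n_replicates replicate curves to generate.
#' @param cadence measurement interval in hours (default 1/6, i.e. 10 min).
#' @param duration assay length in hours.
#' @param seed integer seed for the noise.
#' @return a validated list of class `"curve_spec"`.
#' @export
curve_spec <- function(shape = c("logistic", "double-logistic",
                                 "logistic-with-decay", "flat", "exponential"),
                       K = 1, r = 0.5, lag = 2,
                       K2 = 0.5, r2 = 0.25, onset2 = 12,
                       decay_rate = 0.1, decay_onset = 12,
                       noise_sd = 0.02, n_replicates = 3L,
                       cadence = 1 / 6, duration = 24, seed = NULL) {
  shape <- match.arg(shape)
  if (cadence <= 0) stop("cadence must be positive")
  if (duration < 10 * cadence) stop("duration must be at least 10 cadences")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (shape %in% c("logistic", "double-logistic", "logistic-with-decay",
                   "exponential") && (K <= 0 || r <= 0))
    stop("growth shapes require positive K and r")
  structure(as.list(environment()), class = "curve_spec")
}

log_sigmoid <- function(t, K, r, lag) {
  K / (1 + exp(4 * r / K * (lag - t) + 2))
}

#' Generate the noiseless curve and its true parameters
#'
#' @param spec a [curve_spec()].
#' @return list with `time` (hours), `y` (true ln OD), and `truth`, a
#'   one-row data.frame of the analytically known parameters (`K`, `r`,
#'   `lag`, `auc` by the package's Riemann convention on the same grid,
#'   `death`, `diauxie`).
#' @export
make_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  t <- seq(0, spec$duration, by = spec$cadence)
  y <- switch(spec$shape,
    "flat" = rep(0, length(t)),
    "logistic" = log_sigmoid(t, spec$K, spec$r, spec$lag),
    "double-logistic" = log_sigmoid(t, spec$K, spec$r, spec$lag) +
      log_sigmoid(t, spec$K2, spec$r2, spec$onset2),
    "logistic-with-decay" = log_sigmoid(t, spec$K, spec$r, spec$lag) -
      spec$decay_rate * pmax(0, t - spec$decay_onset),
    "exponential" = spec$r * pmax(0, t - spec$lag))
  h <- spec$cadence
  Kt <- max(y)
  truth <- data.frame(
    shape = spec$shape,
    K = if (spec$shape == "flat") 0 else Kt,
    r = switch(spec$shape, "flat" = 0,
               "double-logistic" = max(spec$r, spec$r2),
               spec$r),
    lag = if (spec$shape == "flat") NA_real_ else spec$lag,
    auc = h * sum(y),
    death = Kt - y[length(y)],
    diauxie = spec$shape == "double-logistic")
  list(time = t, y = y, truth = truth)
}

#' Generate noisy replicate curves
#'
#' Adds iid Gaussian noise (`noise_sd` on the ln OD scale) to the true
#' curve, once per replicate, reproducibly under the spec's seed.
#'
#' @param spec a [curve_spec()].
#' @return list with `time`, `truth` (as in [make_curve()]), and `y`, an
#'   `n_replicates` by `length(time)` matrix.
#' @export
make_replicates <- function(spec) {
  cv <- make_curve(spec)
  n <- spec$n_replicates
  noise <- with_seed(spec$seed, {
    matrix(stats::rnorm(n * length(cv$time), 0, spec$noise_sd), nrow = n)
  })
  list(time = cv$time,
       y = sweep(noise, 2L, cv$y, "+"),
       truth = cv$truth)
}

#' Write a synthetic plate file with known ground truth
#'
#' Builds a full plate from curve specs (one well per spec, assigned
#' row-major A1, A2, ...), converts the log-scale curves to the OD scale as
#' `od = 0.05 * exp(y)` (a typical inoculation density of 0.05), and
#' writes three files readable by the package's own readers: the wide plate
#' matrix, a well mapping table, and a tab-separated ground-truth parameter
#' table.
#'
#' @param specs list of [curve_spec()]s (at most 96), optionally named by
#'   well label.
#' @param out_dir output directory.
#' @param plate_id plate identifier used in the file names.
#' @param blank_wells well labels flagged `is_blank` in the mapping table.
#' @param od0 inoculation optical density.
#' @return list of the three file paths (`plate`, `mapping`, `truth`).
#' @export
make_plate <- function(specs, out_dir, plate_id = "synthetic",
                       blank_wells = character(0), od0 = 0.05) {
  if (length(specs) > 96L) stop("at most 96 wells per plate")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  wells <- names(specs) %||% well_labels_96()[seq_along(specs)]
  if (is.null(names(specs))) names(specs) <- wells

  curves <- lapply(specs, function(s) {
    r <- make_replicates(s)
    # one observed curve per well: the first replicate
    list(time = r$time, y = r$y[1L, ], truth = r$truth)
  })
  time <- curves[[1L]]$time
  if (!all(vapply(curves, function(c) identical(c$time, time), logical(1L))))
    stop("all specs on a plate must share cadence and duration")

  od <- od0 * exp(do.call(rbind, lapply(curves, `[[`, "y")))
  plate_df <- data.frame(well = wells, od, check.names = FALSE)
  colnames(plate_df) <- c("well", signif(time, 10))
  plate_path <- file.path(out_dir, paste0(plate_id, ".txt"))
  utils::write.table(plate_df, plate_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  map <- data.frame(well_id = wells,
                    substrate = vapply(specs, `[[`, "", "shape"),
                    group = "all",
                    is_blank = wells %in% blank_wells,
                    is_control = FALSE)
  map_path <- file.path(out_dir, paste0(plate_id, "_mapping.txt"))
  utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  truth <- cbind(data.frame(well_id = wells),
                 do.call(rbind, lapply(curves, `[[`, "truth")))
  rownames(truth) <- NULL
  truth_path <- file.path(out_dir, paste0(plate_id, "_truth.txt"))
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  list(plate = plate_path, mapping = map_path, truth = truth_path)
}
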