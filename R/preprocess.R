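#' Drop the first time points of a plate
#'
#' Plate readers often show abnormally high variation at the very start of
#' an assay; this removes the first `n` measurements from every well. The
#' time axis is not re-zeroed.
#'
#' @param plate a [growth_plate()].
#' @param n nonnegative number of leading time points to drop.
#' @return a [growth_plate()].
#' @export
trim_initial <- function(plate, n) {
  stopifnot(inherits(plate, "growth_plate"))
  if (n < 0 || n != round(n)) stop("n must be a nonnegative integer")
  if (n >= length(plate$time))
    stop("cannot trim ", n, " of ", length(plate$time), " time points")
  if (n == 0L) return(plate)
  keep <- -seq_len(n)
  growth_plate(plate$od[, keep, drop = FALSE], plate$time[keep],
               plate$wells, plate$plate_id)
}

#' Subtract blank (medium-only) wells
#'
#' The time-pointwise mean of the blank wells is subtracted from every
#' other well, removing background optical density due to the medium; the
#' blank wells are dropped from the result.
#'
#' @param plate a [growth_plate()].
#' @param blank_wells well labels of the medium-only wells.
#' @return a [growth_plate()] without the blank wells.
#' @export
subtract_blank <- function(plate, blank_wells) {
  stopifnot(inherits(plate, "growth_plate"))
  if (length(blank_wells) == 0L) stop("no blank wells given")
  missing <- setdiff(blank_wells, plate$wells)
  if (length(missing))
    stop("blank wells not on plate: ", paste(missing, collapse = ", "))
  bl <- colMeans(plate$od[plate$wells %in% blank_wells, , drop = FALSE])
  keep <- !plate$wells %in% blank_wells
  if (!any(keep)) stop("all wells are blanks; nothing left to analyze")
  od <- sweep(plate$od[keep, , drop = FALSE], 2L, bl, "-")
  growth_plate(od, plate$time, plate$wells[keep], plate$plate_id)
}

#' Subtract group-specific control wells
#'
#' Within each metadata group, the pointwise mean of the group's control
#' wells (e.g. the minimal-medium well of a phenotype-microarray plate) is
#' subtracted from the group's treatment wells. Control wells are retained
#' unchanged. Subtraction never crosses groups.
#'
#' @param plate a [growth_plate()].
#' @param metadata data.frame with columns `well_id`, `group`,
#'   `is_control` (see [read_well_map()]).
#' @return a [growth_plate()].
#' @export
subtract_control <- function(plate, metadata) {
  stopifnot(inherits(plate, "growth_plate"))
  md <- metadata[match(plate$wells, metadata$well_id), , drop = FALSE]
  grp <- md$group %||% rep("all", length(plate$wells))
  grp[is.na(grp)] <- "all"
  ctrl <- parse_flag(md$is_control %||% FALSE)
  ctrl[is.na(ctrl)] <- FALSE
  od <- plate$od
  for (g in unique(grp)) {
    in_g <- grp == g
    treat <- in_g & !ctrl
    if (!any(treat)) next
    if (!any(in_g & ctrl))
      stop("group '", g, "' has treatment wells but no control well")
    cm <- colMeans(od[in_g & ctrl, , drop = FALSE])
    od[treat, ] <- sweep(od[treat, , drop = FALSE], 2L, cm, "-")
  }
  growth_plate(od, plate$time, plate$wells, plate$plate_id)
}

#' Shift measurements to enforce positivity before the log transform
#'
#' If any reading falls below the positivity floor, all readings on the
#' plate are shifted up by the same offset so the minimum equals the floor;
#' pairwise differences are preserved. The floor is the user's limit of
#' detection when given; under `"auto"` it is estimated from the
#' distribution of changes in OD between consecutive measurements as the
#' median absolute consecutive difference pooled over the plate.
#'
#' @param plate a [growth_plate()].
#' @param lod positive limit of detection in OD units, or `"auto"`.
#' @return list with the shifted `plate` and the `offset` applied (0 when
#'   no shift was needed).
#' @export
enforce_positive <- function(plate, lod = "auto") {
  stopifnot(inherits(plate, "growth_plate"))
  floor_val <- if (identical(lod, "auto")) {
    d <- abs(t(apply(plate$od, 1L, diff)))
    f <- stats::median(d)
    if (!is.finite(f) || f <= 0) f <- 1e-3   # degenerate flat plate
    f
  } else {
    if (!is.numeric(lod) || lod <= 0) stop("limit of detection must be positive or 'auto'")
    lod
  }
  mn <- min(plate$od)
  offset <- if (mn >= floor_val) 0 else floor_val - mn
  plate$od <- plate$od + offset
  list(plate = plate, offset = offset)
}

#' Log-transform and baseline-anchor growth curves
#'
#' Takes the natural logarithm of the OD readings and anchors each curve at
#' zero by subtracting a baseline: by default the first log measurement
#' (so `y[1] == 0` exactly); with `use_polynomial`, the baseline is the
#' value at the first time point of a polynomial regression over the first
#' five (time, ln OD) points, which estimates the starting OD robustly to
#' noise in the very first reading.
#'
#' @param plate a [growth_plate()] with strictly positive readings.
#' @param use_polynomial use the polynomial baseline estimate?
#' @param offset_used vertical offset recorded by [enforce_positive()],
#'   carried into the provenance of each curve.
#' @param steps character vector of preprocessing steps already applied.
#' @return list of `"transformed_curve"` objects, one per well, each with
#'   `well`, `time`, `y`, `applied_steps`, `offset_used`.
#' @export
log_baseline <- function(plate, use_polynomial = FALSE, offset_used = 0,
                         steps = character(0)) {
  stopifnot(inherits(plate, "growth_plate"))
  if (min(plate$od) <= 0)
    stop("nonpositive OD values; run enforce_positive() first")
  if (use_polynomial && length(plate$time) < 6L)
    stop("polynomial baseline needs at least 6 time points")
  lapply(seq_along(plate$wells), function(i) {
    y <- log(plate$od[i, ])
    b <- if (use_polynomial) poly_baseline(plate$time, y) else y[1L]
    structure(list(well = plate$wells[i], time = plate$time,
                   y = y - b,
                   applied_steps = c(steps, "log",
                                     if (use_polynomial) "baseline-polynomial"
                                     else "baseline-first"),
                   offset_used = offset_used),
              class = "transformed_curve")
  })
}

# Baseline from a polynomial regression over the first five points,
# evaluated at the first time point. The degree is capped below the window
# size so the fit smooths rather than interpolates.
poly_baseline <- function(time, y, n_fit = 5L) {
  tt <- time[seq_len(n_fit)] - time[1L]
  yy <- y[seq_len(n_fit)]
  deg <- min(5L, n_fit - 2L)
  fit <- stats::lm(yy ~ stats::poly(tt, deg, raw = TRUE))
  unname(stats::predict(fit, newdata = data.frame(tt = 0))[1L])
}

#' @export
print.transformed_curve <- function(x, ...) {
  cat(sprintf("transformed_curve '%s': %d points, y[1] = %.3g (steps: %s)\n",
              x$well, length(x$y), x$y[1L],
              paste(x$applied_steps, collapse = " > ")))
  invisible(x)
}

#' Canonical preprocessing pipeline
#'
#' Applies the corrections in their fixed canonical order: trim initial
#' points, blank subtraction, group-control subtraction, positivity
#' enforcement, natural-log transform, baseline anchoring. Only the last
#' three are required; trimming and the two subtraction steps run only when
#' requested in the configuration. A `step_order` entry in the
#' configuration that deviates from this order is rejected.
#'
#' @param plate a [growth_plate()].
#' @param metadata optional [read_well_map()] data.frame (needed for blank
#'   or control subtraction).
#' @param config a [growth_config()].
#' @return list of `"transformed_curve"` objects.
#' @export
preprocess_plate <- function(plate, metadata = NULL, config = growth_config()) {
  canonical <- c("trim", "blank", "control", "positive", "log", "baseline")
  if (!is.null(config$step_order) &&
      !identical(config$step_order, canonical[canonical %in% config$step_order]))
    stop("preprocessing step order is canonical (",
         paste(canonical, collapse = " > "), ") and cannot be permuted")
  steps <- character(0)
  if ((config$skip_first_n %||% 0) > 0) {
    plate <- trim_initial(plate, config$skip_first_n)
    steps <- c(steps, "trim")
  }
  if (isTRUE(config$do_blank_subtraction)) {
    if (is.null(metadata)) stop("blank subtraction requires metadata")
    bw <- metadata$well_id[parse_flag(metadata$is_blank)]
    plate <- subtract_blank(plate, intersect(bw, plate$wells))
    steps <- c(steps, "blank")
  }
  if (isTRUE(config$do_control_subtraction)) {
    if (is.null(metadata)) stop("control subtraction requires metadata")
    plate <- subtract_control(plate, metadata)
    steps <- c(steps, "control")
  }
  ep <- enforce_positive(plate, config$limit_of_detection %||% "auto")
  steps <- c(steps, "positive")
  log_baseline(ep$plate,
               use_polynomial = isTRUE(config$do_polynomial_baseline),
               offset_used = ep$offset, steps = steps)
}
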