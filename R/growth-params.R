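#' Growth parameters from a latent GP prediction
#'
#' Extracts the physiological summaries of a growth curve from the posterior
#' mean of the latent log OD function and its derivatives: carrying capacity
#' `K` (maximum of the predicted mean, in ln OD units) and its time `t_K`;
#' maximum specific growth rate `r` (maximum of the first-derivative mean,
#' 1/h) and its time `t_r`; area under the ln OD curve (Riemann sum, with a
#' normal-approximation variance); lag time (time-axis intercept of the
#' tangent at maximum growth); adaptation time (earliest time at which the
#' credible interval of the growth rate excludes zero); doubling time
#' (ln 2 / r); death (total ln OD loss after carrying capacity) and maximum
#' death rate (most negative growth rate after `t_K`); plus multiphasic
#' (diauxic) growth detection.
#'
#' @param pred a [predict_latent()] prediction on an evenly spaced grid.
#' @param confidence credible level used for the adaptation time.
#' @param diauxie_ratio,diauxie_criterion passed to [detect_phases()].
#' @return an object of class `"growth_parameters"`: a list of scalars (`K`,
#'   `t_K`, `r`, `t_r`, `auc`, `auc_var`, `lag`, `adaptation`, `doubling`,
#'   `death`, `death_rate`, `t_death_rate`, `diauxie`) and a `phases`
#'   data.frame. Undefined quantities (e.g. lag when `r <= 0`) are `NA`.
#' @export
growth_parameters <- function(pred, confidence = 0.95, diauxie_ratio = 0.2,
                              diauxie_criterion = c("total-growth", "growth-rate")) {
  stopifnot(inherits(pred, "gp_prediction"))
  diauxie_criterion <- match.arg(diauxie_criterion)
  cc <- carrying_capacity(pred)
  mg <- max_growth_rate(pred)
  a <- auc_ln(pred)
  dm <- death_metrics(pred)
  ph <- detect_phases(pred, ratio = diauxie_ratio, criterion = diauxie_criterion)
  out <- list(K = cc$K, t_K = cc$t_K, r = mg$r, t_r = mg$t_r,
              auc = a$mean, auc_var = a$var,
              lag = lag_time(pred),
              adaptation = adaptation_time(pred, confidence),
              doubling = doubling_time(mg$r),
              death = dm$death, death_rate = dm$death_rate,
              t_death_rate = dm$t_death_rate,
              diauxie = ph$diauxie, phases = ph$phases)
  class(out) <- "growth_parameters"
  out
}

#' @export
print.growth_parameters <- function(x, digits = 4, ...) {
  cat("Growth parameters (ln OD scale):\n")
  v <- unlist(x[c("K", "t_K", "r", "t_r", "auc", "lag", "adaptation",
                  "doubling", "death", "death_rate")])
  print(signif(v, digits))
  cat("diauxie:", x$diauxie, "(", nrow(x$phases), "phase(s) )\n")
  invisible(x)
}

#' Carrying capacity
#'
#' Maximum of the predicted mean ln OD; ties broken by the earliest time.
#' @param pred a [predict_latent()] object.
#' @return list with `K` and `t_K`.
#' @export
carrying_capacity <- function(pred) {
  i <- which.max(pred$mean)
  list(K = pred$mean[i], t_K = pred$grid[i])
}

#' Maximum specific growth rate
#'
#' Maximum of the posterior mean growth rate (first derivative of ln OD);
#' ties broken by the earliest time.
#' @param pred a [predict_latent()] object.
#' @return list with `r` (1/h) and `t_r` (h).
#' @export
max_growth_rate <- function(pred) {
  i <- which.max(pred$d1_mean)
  list(r = pred$d1_mean[i], t_r = pred$grid[i])
}

#' Area under the log growth curve
#'
#' Riemann sum of the predicted ln OD over an evenly spaced grid. With the
#' interval vector \eqn{a = (\Delta t, \ldots, \Delta t)} (one entry per
#' grid point), the AUC is approximately normal:
#' \eqn{AUC \sim N(a\mu, a \Sigma a')}, so the reported mean is
#' \eqn{\Delta t \sum_t \mu(t)} and the variance
#' \eqn{\Delta t^2 \sum_{ij} \Sigma_{ij}}.
#'
#' @param pred a [predict_latent()] object on an evenly spaced grid.
#' @return list with `mean` (ln OD h) and `var`.
#' @export
auc_ln <- function(pred) {
  dt <- diff(pred$grid)
  if (length(dt) == 0L) stop("AUC needs at least two grid points")
  if (max(dt) - min(dt) > 1e-8 * mean(dt))
    stop("AUC requires an evenly spaced grid; re-predict on one")
  h <- dt[1L]
  list(mean = h * sum(pred$mean), var = h^2 * sum(pred$cov))
}

#' Lag time
#'
#' Classical tangent construction: the tangent to the predicted ln OD curve
#' at the point of maximum growth rate is intersected with the time axis
#' (the zero baseline of corrected curves): `lag = t_r - mu(t_r) / r`.
#' Undefined (`NA`) when the maximum growth rate is not positive.
#' @param pred a [predict_latent()] object.
#' @return lag time in hours, or `NA`.
#' @export
lag_time <- function(pred) {
  mg <- max_growth_rate(pred)
  if (!is.finite(mg$r) || mg$r <= 0) return(NA_real_)
  i <- which.max(pred$d1_mean)
  mg$t_r - pred$mean[i] / mg$r
}

#' Adaptation time
#'
#' Earliest grid time at which the lower bound of the credible interval of
#' the growth rate exceeds zero, i.e. the time needed to reach a credibly
#' positive growth rate. `NA` if the interval never excludes zero.
#' @param pred a [predict_latent()] object.
#' @param confidence credible level of the derivative interval.
#' @return time in hours, or `NA`.
#' @export
adaptation_time <- function(pred, confidence = 0.95) {
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  lo <- pred$d1_mean - z * sqrt(pmax(diag(pred$d1_cov), 0))
  i <- which(lo > 0)
  if (length(i) == 0L) NA_real_ else pred$grid[min(i)]
}

#' Death and maximum death rate
#'
#' Death is the absolute difference between the predicted ln OD at the
#' final time point and the carrying capacity. The maximum death rate is
#' the minimum of the derivative mean restricted to times at or after
#' `t_K`, reported signed (negative during decline). When the carrying
#' capacity is reached at the final time point, death is 0 and the death
#' rate is the terminal derivative value.
#' @param pred a [predict_latent()] object.
#' @return list with `death`, `death_rate`, `t_death_rate`.
#' @export
death_metrics <- function(pred) {
  cc <- carrying_capacity(pred)
  n <- length(pred$grid)
  death <- abs(pred$mean[n] - cc$K)
  win <- which(pred$grid >= cc$t_K)
  j <- win[which.min(pred$d1_mean[win])]
  list(death = death, death_rate = pred$d1_mean[j], t_death_rate = pred$grid[j])
}

#' Doubling time
#'
#' `ln(2) / r`; undefined (`NA`) when the maximum specific growth rate is
#' not positive.
#' @param r maximum specific growth rate (1/h).
#' @return doubling time in hours, or `NA`.
#' @export
doubling_time <- function(r) {
  if (!is.finite(r) || r <= 0) return(NA_real_)
  log(2) / r
}

# Scalar parameters of one drawn (or predicted) curve; f and d1 are vectors
# over an evenly spaced time grid. Used for posterior-sample summaries.
params_from_curve <- function(time, f, d1) {
  h <- time[2L] - time[1L]
  iK <- which.max(f)
  K <- f[iK]; t_K <- time[iK]
  ir <- which.max(d1)
  r <- d1[ir]; t_r <- time[ir]
  lag <- if (r > 0) t_r - f[ir] / r else NA_real_
  win <- which(time >= t_K)
  j <- win[which.min(d1[win])]
  c(K = K, t_K = t_K, r = r, t_r = t_r,
    auc = h * sum(f),
    lag = lag,
    doubling = if (r > 0) log(2) / r else NA_real_,
    death = abs(f[length(f)] - K),
    death_rate = d1[j], t_death_rate = time[j])
}

#' Posterior-sampled summaries of growth parameters
#'
#' Draws paired function/derivative samples from the GP posterior on an
#' evenly spaced grid, recomputes every growth parameter on each draw, and
#' summarizes each parameter by its mean, standard deviation and percentile
#' credible interval. Draws in which a parameter is undefined (e.g. lag when
#' the drawn maximum rate is not positive) are dropped from that parameter's
#' summary; the number of such draws is recorded.
#'
#' @param fit a [gp_fit()] object.
#' @param grid evenly spaced prediction times; defaults to an even grid with
#'   as many points as there are unique training times.
#' @param n number of posterior draws.
#' @param confidence credible level of the percentile intervals.
#' @param seed optional integer seed.
#' @return an object of class `"parameter_summary"`: a data.frame with one
#'   row per parameter and columns `mean`, `sd`, `ci_low`, `ci_high`,
#'   `n_defined`; attributes `confidence`, `n_samples` and `draws` (the raw
#'   per-draw parameter matrix).
#' @export
sample_parameters <- function(fit, grid = NULL, n = 100, confidence = 0.95,
                              seed = NULL) {
  stopifnot(inherits(fit, "gp_fit"))
  if (n < 2L) stop("need at least 2 posterior samples")
  if (is.null(grid)) grid <- even_grid(fit)
  pred <- predict_latent(fit, grid_matrix(fit, grid))
  dr <- sample_posterior(pred, n, seed = seed)
  P <- t(vapply(seq_len(n), function(i)
    params_from_curve(pred$grid, dr$f[i, ], dr$d1[i, ]),
    numeric(10L)))
  a <- (1 - confidence) / 2
  summ <- do.call(rbind, lapply(colnames(P), function(p) {
    v <- P[, p]
    v <- v[is.finite(v)]
    if (length(v) == 0L)
      return(data.frame(parameter = p, mean = NA_real_, sd = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n_defined = 0L))
    q <- unname(stats::quantile(v, c(a, 1 - a), type = 7))
    data.frame(parameter = p, mean = mean(v), sd = stats::sd(v),
               ci_low = q[1L], ci_high = q[2L], n_defined = length(v))
  }))
  rownames(summ) <- summ$parameter
  structure(summ, confidence = confidence, n_samples = n, draws = P,
            class = c("parameter_summary", "data.frame"))
}

# Evenly spaced grid spanning the training times, same count as unique times.
even_grid <- function(fit) {
  tt <- sort(unique(fit$X[, 1L]))
  seq(min(tt), max(tt), length.out = length(tt))
}

grid_matrix <- function(fit, grid) {
  D <- ncol(fit$X)
  if (D == 1L) return(matrix(grid, ncol = 1L))
  cbind(grid, matrix(rep(fit$X[1L, -1L, drop = FALSE], each = length(grid)),
                     nrow = length(grid)))
}

#' Normalize growth parameters to a control
#'
#' Fieldwise ratio treatment / control (division, as used when comparing
#' substrate wells against a minimal-medium control well). Fields whose
#' control value is zero are undefined (`NA`).
#'
#' @param params,control_params [growth_parameters()] objects (or named
#'   lists/vectors).
#' @param fields which fields to normalize.
#' @return named numeric vector of ratios.
#' @export
normalize_parameters <- function(params, control_params,
                                 fields = c("K", "r", "auc")) {
  vapply(fields, function(f) {
    a <- as.numeric(params[[f]]); b <- as.numeric(control_params[[f]])
    if (!is.finite(b) || b == 0) NA_real_ else a / b
  }, numeric(1L))
}

#' Call significant growth from a normalized AUC
#'
#' Growth is called when the control-normalized AUC is at least the
#' threshold (inclusive; default 1.2).
#' @param normalized_auc treatment AUC divided by control AUC.
#' @param threshold positive calling threshold.
#' @return logical.
#' @export
call_growth <- function(normalized_auc, threshold = 1.2) {
  if (threshold <= 0) stop("threshold must be positive")
  !is.na(normalized_auc) & normalized_auc >= threshold
}
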