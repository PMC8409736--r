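#' Fit a growth curve model
#'
#' The main modelling entry point: fits a zero-mean GP with an RBF(+noise)
#' kernel to one corrected log growth curve or to pooled replicates, then
#' derives the latent prediction, credible band and all growth parameters.
#' Input is either a `time`/`y` pair (with `y` a vector or a replicates by
#' time matrix, replicates pooled as repeated observations), or a
#' `"transformed_curve"` from [preprocess_plate()].
#'
#' @param time observation times in hours, or a `"transformed_curve"`.
#' @param y corrected ln OD: vector, or matrix with replicates in rows.
#' @param config a [growth_config()]; controls credible level, posterior
#'   samples, diauxie thresholds, empirical noise and optimizer restarts.
#' @param grid prediction grid; defaults to an evenly spaced grid spanning
#'   the observed times with as many points as unique observation times.
#' @return an object of class `"growth_fit"`: list with the underlying
#'   `gp` ([gp_fit()]), `pred` ([predict_latent()]), `band`
#'   ([credible_band()]), `params` ([growth_parameters()]) and the call.
#' @examples
#' sp <- curve_spec("logistic", K = 1, r = 0.5, lag = 2, seed = 1,
#'                  cadence = 0.5)
#' reps <- make_replicates(sp)
#' fit <- fit_growth(reps$time, reps$y, config = growth_config(seed = 1))
#' coef(fit)
#' fit$params$K
#' @export
fit_growth <- function(time, y = NULL, config = growth_config(), grid = NULL) {
  if (inherits(time, "transformed_curve")) {
    y <- time$y
    time <- time$time
  }
  if (is.matrix(y)) {
    reps <- y
    tt <- rep(time, each = nrow(y))
    yy <- as.vector(reps)
  } else {
    reps <- NULL
    tt <- time
    yy <- as.numeric(y)
  }
  emp <- NULL
  if (isTRUE(config$empirical_noise)) {
    if (is.null(reps) || nrow(reps) < 2L)
      stop("empirical noise estimation requires replicate curves")
    emp <- empirical_noise(reps, time, width = config$filter_width_hours)
  }
  gp <- gp_fit(tt, yy, emp = emp, restarts = config$restarts %||% 3L,
               seed = config$seed)
  if (is.null(grid)) grid <- even_grid(gp)
  pred <- predict_latent(gp, grid)
  band <- credible_band(pred, alpha = 1 - config$confidence,
                        include_noise = isTRUE(config$include_noise_in_bands),
                        emp = if (!is.null(emp)) emp)
  params <- growth_parameters(pred, confidence = config$confidence,
                              diauxie_ratio = config$diauxie_ratio,
                              diauxie_criterion = config$diauxie_criterion)
  structure(list(gp = gp, pred = pred, band = band, params = params,
                 time = time, y = if (is.null(reps)) yy else reps,
                 config = config, call = match.call()),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, digits = 4, ...) {
  cat("GP growth curve fit\n")
  nrep <- if (is.matrix(x$y)) nrow(x$y) else 1L
  cat(sprintf("  %d time points, %d replicate curve(s)\n",
              length(x$time), nrep))
  cat(sprintf("  K = %s ln OD at %s h;  r = %s /h at %s h\n",
              signif(x$params$K, digits), signif(x$params$t_K, digits),
              signif(x$params$r, digits), signif(x$params$t_r, digits)))
  cat(sprintf("  lag = %s h;  AUC = %s ln OD h;  diauxie: %s\n",
              signif(x$params$lag, digits), signif(x$params$auc, digits),
              x$params$diauxie))
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) {
  h <- object$gp$hyp
  c(sf2 = h$sf2, stats::setNames(h$ls, paste0("ls", seq_along(h$ls))),
    sn2 = h$sn2)
}

#' @export
logLik.growth_fit <- function(object, ...) logLik(object$gp)

#' @export
predict.growth_fit <- function(object, grid = NULL,
                               what = c("latent", "band"), ...) {
  what <- match.arg(what)
  if (is.null(grid)) return(switch(what, latent = object$pred,
                                   band = object$band))
  pred <- predict_latent(object$gp, grid)
  switch(what,
         latent = pred,
         band = credible_band(pred,
                              alpha = 1 - object$config$confidence,
                              include_noise = isTRUE(object$config$include_noise_in_bands)))
}

#' @export
fitted.growth_fit <- function(object, ...) {
  drop(predict_latent(object$gp, grid_matrix(object$gp, object$gp$X[, 1L]))$mean)
}

#' @export
residuals.growth_fit <- function(object, ...) {
  object$gp$y - fitted(object)
}

#' @importFrom stats simulate
#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  dr <- sample_posterior(object$pred, n = nsim, seed = seed)
  out <- as.data.frame(t(dr$f))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(time = object$pred$grid), out)
}

#' @export
summary.growth_fit <- function(object, n = NULL, seed = NULL, ...) {
  cfg <- object$config
  ps <- sample_parameters(object$gp,
                          n = n %||% cfg$posterior_samples,
                          confidence = cfg$confidence,
                          seed = seed %||% cfg$seed)
  structure(list(fit = object, sampled = ps), class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("\nPosterior-sampled parameter summaries (%d draws, %.0f%% CI):\n",
              attr(x$sampled, "n_samples"),
              100 * attr(x$sampled, "confidence")))
  df <- as.data.frame(x$sampled)
  df[-1L] <- lapply(df[-1L], function(v) if (is.numeric(v)) signif(v, digits) else v)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Plot a fitted growth curve
#'
#' Two stacked panels: the corrected log growth data with the predicted
#' mean and credible band, and the inferred growth rate (first-derivative
#' posterior) with its band. Detected phase boundaries are drawn as dashed
#' vertical lines when the fit is multiphasic.
#'
#' @param x a [fit_growth()] object.
#' @param show_rate draw the growth-rate panel?
#' @param ... passed to [plot()].
#' @return invisibly, `x`.
#' @export
plot.growth_fit <- function(x, show_rate = TRUE, ...) {
  op <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(op))
  if (show_rate) graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  b <- x$band
  ylim <- range(b$lower, b$upper, unlist(x$y))
  graphics::plot(b$time, b$mean, type = "n", ylim = ylim,
                 xlab = "time (h)", ylab = "ln OD (corrected)", ...)
  graphics::polygon(c(b$time, rev(b$time)), c(b$lower, rev(b$upper)),
                    col = grDevices::adjustcolor("darkgreen", 0.2), border = NA)
  ym <- if (is.matrix(x$y)) x$y else matrix(x$y, nrow = 1L)
  for (i in seq_len(nrow(ym)))
    graphics::lines(x$time, ym[i, ], col = "gray60")
  graphics::lines(b$time, b$mean, col = "darkgreen", lwd = 2)
  if (x$params$diauxie)
    graphics::abline(v = x$params$phases$t_start[-1L], lty = 2, col = "gray30")
  if (show_rate) {
    p <- x$pred
    z <- stats::qnorm(1 - (1 - x$config$confidence) / 2)
    s <- sqrt(pmax(diag(p$d1_cov), 0))
    graphics::plot(p$grid, p$d1_mean, type = "n",
                   ylim = range(p$d1_mean - z * s, p$d1_mean + z * s),
                   xlab = "time (h)", ylab = "growth rate (1/h)")
    graphics::polygon(c(p$grid, rev(p$grid)),
                      c(p$d1_mean - z * s, rev(p$d1_mean + z * s)),
                      col = grDevices::adjustcolor("darkgreen", 0.2),
                      border = NA)
    graphics::lines(p$grid, p$d1_mean, col = "darkgreen", lwd = 2)
    graphics::abline(h = 0, lty = 3)
  }
  invisible(x)
}
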