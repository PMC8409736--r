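#' Posterior of the latent growth function and its derivatives
#'
#' Given an optimized GP fit, computes the noise-free posterior of the
#' latent function over a prediction grid, together with the posteriors of
#' its first derivative (the specific growth rate over time) and the
#' posterior mean of its second derivative (growth acceleration). The
#' derivative of a GP is again a GP, so these follow from differentiating
#' the RBF kernel with respect to the time dimension. Measurement noise is
#' excluded here; [credible_band()] adds it when requested.
#'
#' @param fit a [gp_fit()] object.
#' @param grid prediction times in hours (strictly increasing), or a matrix
#'   with time in column 1 and covariate values in further columns matching
#'   the training dimensions. Defaults to the unique sorted training times
#'   (with covariates taken from the first training row when `D > 1`).
#' @return an object of class `"gp_prediction"`: list with `grid`, `mean`,
#'   `cov`, `d1_mean`, `d1_cov`, `d2_mean`, the function/derivative
#'   cross-covariance `cov_fd`, and the fitted hyperparameters.
#' @export
predict_latent <- function(fit, grid = NULL) {
  stopifnot(inherits(fit, "gp_fit"))
  D <- ncol(fit$X)
  if (is.null(grid)) {
    tg <- sort(unique(fit$X[, 1L]))
    Xs <- cbind(tg, matrix(rep(fit$X[1L, -1L, drop = FALSE], each = length(tg)),
                           nrow = length(tg)))
  } else {
    Xs <- as_input_matrix(grid)
  }
  if (nrow(Xs) == 0L) stop("prediction grid is empty")
  if (ncol(Xs) != D) stop("grid must have ", D, " column(s)")
  tg <- Xs[, 1L]
  hyp <- fit$hyp
  l1 <- hyp$ls[1L]
  K <- rbf_kernel(fit$X, fit$X, hyp, emp = fit$emp, noise = TRUE)
  L <- chol_jitter(K)
  alpha <- backsolve(L, forwardsolve(t(L), fit$y))
  Kinv <- chol2inv(L)

  Ks <- rbf_kernel(Xs, fit$X, hyp, noise = FALSE)       # m x n
  Dts <- outer(tg, fit$X[, 1L], "-")                    # t* - t
  dKs <- -(Dts / l1^2) * Ks                             # d/dt* k(t*, t)
  d2Ks <- (Dts^2 / l1^4 - 1 / l1^2) * Ks                # d2/dt*^2

  Kss <- rbf_kernel(Xs, Xs, hyp, noise = FALSE)
  Dss <- outer(tg, tg, "-")
  ddKss <- (1 / l1^2 - Dss^2 / l1^4) * Kss              # cov(f'(s), f'(s'))
  fdKss <- (Dss / l1^2) * Kss                           # cov(f(s), f'(s'))

  A <- Ks %*% Kinv                                      # m x n
  mean_f <- drop(Ks %*% alpha)
  cov_f <- symmetrize(Kss - A %*% t(Ks))
  mean_d1 <- drop(dKs %*% alpha)
  cov_d1 <- symmetrize(ddKss - dKs %*% Kinv %*% t(dKs))
  cov_fd <- fdKss - A %*% t(dKs)
  mean_d2 <- drop(d2Ks %*% alpha)

  structure(list(grid = tg, X = Xs, mean = mean_f, cov = cov_f,
                 d1_mean = mean_d1, d1_cov = cov_d1, d2_mean = mean_d2,
                 cov_fd = cov_fd, hyp = hyp),
            class = "gp_prediction")
}

symmetrize <- function(M) (M + t(M)) / 2

#' @export
print.gp_prediction <- function(x, ...) {
  cat("GP latent prediction over", length(x$grid), "points on [",
      signif(min(x$grid), 4), ",", signif(max(x$grid), 4), "] h\n")
  invisible(x)
}

#' @export
predict.gp_fit <- function(object, grid = NULL, ...) {
  predict_latent(object, grid = grid)
}

#' Draw posterior samples of the latent function and its derivative
#'
#' Samples function/derivative pairs jointly from the multivariate normal
#' posterior over the prediction grid, so that a draw's growth curve and its
#' growth-rate curve are mutually consistent.
#'
#' @param pred a [predict_latent()] object.
#' @param n number of posterior draws.
#' @param seed optional integer seed.
#' @return list with matrices `f` and `d1` (draws in rows, grid in columns).
#' @export
sample_posterior <- function(pred, n, seed = NULL) {
  stopifnot(inherits(pred, "gp_prediction"))
  if (n <= 0) stop("number of samples must be positive")
  m <- length(pred$grid)
  mu <- c(pred$mean, pred$d1_mean)
  S <- rbind(cbind(pred$cov, pred$cov_fd),
             cbind(t(pred$cov_fd), pred$d1_cov))
  Z <- with_seed(seed, rmvn(n, mu, S))
  list(f = Z[, seq_len(m), drop = FALSE],
       d1 = Z[, m + seq_len(m), drop = FALSE])
}

# Multivariate normal draws via eigendecomposition (tolerant of
# semi-definite posterior covariances); returns n x length(mu).
rmvn <- function(n, mu, S) {
  S <- symmetrize(S)
  if (all(abs(S) < .Machine$double.eps * 100)) {
    return(matrix(mu, nrow = n, ncol = length(mu), byrow = TRUE))
  }
  e <- eigen(S, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  A <- e$vectors %*% (sqrt(ev) * t(e$vectors))
  Z <- matrix(stats::rnorm(n * length(mu)), nrow = n)
  sweep(Z %*% A, 2L, mu, "+")
}

#' Credible band for the predicted growth curve
#'
#' Computes pointwise credible intervals
#' \eqn{\mu(t) \pm z_{1-\alpha/2}\,\sigma(t)}. By default the pointwise
#' variance is the posterior latent variance plus, when requested, the
#' fitted Gaussian noise variance and any empirical noise profile:
#' \eqn{\sigma^2(t) = \mathrm{diag}(\Sigma)(t) + \sigma^2_{noise} + \sigma^2_{emp}(t)}.
#' `latent = "prior"` instead uses the RBF signal variance
#' \eqn{\sigma^2_{RBF}} verbatim as the latent term, i.e. the composition
#' \eqn{\sigma(t) = \sqrt{\sigma^2_{RBF} + \sigma^2_{noise} + \sigma^2_{emp}(t)}}
#' that ignores conditioning on the data.
#'
#' @param pred a [predict_latent()] object.
#' @param alpha significance level; the band has coverage `1 - alpha`.
#' @param include_noise include the fitted Gaussian noise variance? Without
#'   it the band reflects only the uncertainty of the latent mean (typically
#'   barely visible for well-replicated data).
#' @param emp optional [empirical_noise()] profile to add (interpolated to
#'   the prediction grid).
#' @param latent `"posterior"` (default) or `"prior"`, see Details.
#' @return data.frame with `time`, `mean`, `sd`, `lower`, `upper`.
#' @export
credible_band <- function(pred, alpha = 0.05, include_noise = TRUE,
                          emp = NULL, latent = c("posterior", "prior")) {
  stopifnot(inherits(pred, "gp_prediction"))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  latent <- match.arg(latent)
  v <- switch(latent,
              posterior = pmax(diag(pred$cov), 0),
              prior = rep(pred$hyp$sf2, length(pred$grid)))
  if (include_noise) v <- v + pred$hyp$sn2
  if (!is.null(emp)) {
    ev <- if (inherits(emp, "noise_profile"))
      stats::approx(emp$time, emp$sigma2, xout = pred$grid, rule = 2)$y
    else rep_len(as.numeric(emp), length(pred$grid))
    v <- v + pmax(ev, 0)
  }
  z <- stats::qnorm(1 - alpha / 2)
  s <- sqrt(v)
  data.frame(time = pred$grid, mean = pred$mean, sd = s,
             lower = pred$mean - z * s, upper = pred$mean + z * s)
}
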