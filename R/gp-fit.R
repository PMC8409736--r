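#' Log marginal likelihood of a GP regression model
#'
#' Evaluates the closed-form log marginal likelihood of zero-mean GP
#' regression with an RBF(+noise) kernel,
#' \deqn{\log p(y \mid X, \theta) = -\tfrac12 y' K^{-1} y - \tfrac12 \log|K| - \tfrac{n}{2}\log 2\pi,}
#' where \eqn{K} is the training covariance returned by [rbf_kernel()]
#' (including the diagonal noise and any fixed empirical noise profile).
#'
#' @inheritParams rbf_kernel
#' @param X training inputs (matrix or time vector).
#' @param y observed corrected log OD values.
#' @return a single number.
#' @export
gp_lml <- function(X, y, hyp, emp = NULL) {
  X <- as_input_matrix(X)
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  K <- rbf_kernel(X, X, hyp, emp = emp, noise = TRUE)
  L <- chol_jitter(K)
  a <- backsolve(L, forwardsolve(t(L), y))
  val <- -0.5 * sum(y * a) - sum(log(diag(L))) - 0.5 * length(y) * log(2 * pi)
  if (!is.finite(val)) stop("log marginal likelihood is not finite")
  val
}

# Negative log marginal likelihood and gradient in log-parameter space.
# par = log(c(sf2, ls_1..ls_D, sn2)). Returns list(value, gradient).
nlml_grad <- function(par, X, y, emp) {
  D <- ncol(X)
  sf2 <- exp(par[1L]); ls <- exp(par[1L + seq_len(D)]); sn2 <- exp(par[D + 2L])
  n <- length(y)
  E <- exp(-0.5 * scaled_sqdist(X, X, ls))
  Kf <- sf2 * E
  d <- rep(sn2, n)
  if (!is.null(emp)) d <- d + emp
  K <- Kf + diag(d, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L))
    L <- tryCatch(chol(K + diag(1e-8 * mean(diag(K)), n)),
                  error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, gradient = rep(0, D + 2L)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nlml <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  # d(lml)/d(theta) = 0.5 * (alpha' dK alpha - tr(Kinv dK)); negate for nlml
  W <- tcrossprod(alpha) - Kinv
  g <- numeric(D + 2L)
  g[1L] <- -0.5 * sum(W * Kf)                       # d/dlog sf2
  for (dd in seq_len(D)) {
    Dd2 <- outer(X[, dd], X[, dd], "-")^2 / ls[dd]^2
    g[1L + dd] <- -0.5 * sum(W * (Kf * Dd2))        # d/dlog ls_d
  }
  g[D + 2L] <- -0.5 * sn2 * sum(diag(W))            # d/dlog sn2
  list(value = nlml, gradient = g)
}

#' Fit a GP regression model by marginal-likelihood maximization
#'
#' Optimizes the RBF signal variance, per-dimension lengthscales and the
#' Gaussian noise variance by maximizing the log marginal likelihood with
#' multi-restart L-BFGS-B on log-transformed parameters (analytic
#' gradients). Pooled replicates enter simply as repeated rows at identical
#' times. When an empirical noise profile is supplied it is held fixed in
#' the training covariance during optimization; it is not used when
#' predicting at new time points.
#'
#' @param X training inputs: a time vector (hours) or a matrix whose first
#'   column is time and whose further columns are 0/1 condition indicators.
#' @param y corrected log OD observations, one per row of `X`.
#' @param emp optional [empirical_noise()] profile, or a numeric vector of
#'   per-observation noise variances aligned with the rows of `X`.
#' @param restarts number of optimizer starts (first from the default
#'   initialization, the rest perturbed).
#' @param seed optional integer seed controlling the restart perturbations.
#' @param lower,upper box bounds applied to all hyperparameters.
#' @return an object of class `"gp_fit"`: a list with the training data,
#'   optimized hyperparameters (`hyp`), the empirical noise profile used
#'   (`emp`), and `lml`, the log marginal likelihood at the optimum.
#' @examples
#' t <- seq(0, 10, length.out = 40)
#' fit <- gp_fit(t, sin(t) + rnorm(40, 0, 0.05), seed = 1)
#' fit$hyp$sn2
#' @export
gp_fit <- function(X, y, emp = NULL, restarts = 3L, seed = NULL,
                   lower = 1e-6, upper = 1e6) {
  X <- as_input_matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("X rows must match length of y")
  if (length(y) < 5L) stop("need at least 5 observations to fit a GP")
  D <- ncol(X)
  emp_vec <- align_emp(emp, X)

  vy <- stats::var(y)
  if (!is.finite(vy) || vy < 1e-6) vy <- 1e-3
  span <- diff(range(X[, 1L]))
  if (span <= 0) span <- 1
  ls0 <- c(span / 10, rep(1, D - 1L))
  par0 <- log(pmin(pmax(c(vy, ls0, 0.1 * vy), lower), upper))

  starts <- list(par0)
  if (restarts > 1L) {
    perturb <- with_seed(seed, {
      lapply(seq_len(restarts - 1L), function(i)
        stats::rnorm(length(par0), 0, 0.7))
    })
    for (p in perturb) starts <- c(starts, list(par0 + p))
  }

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(
      stats::optim(p0,
                   fn = function(p) nlml_grad(p, X, y, emp_vec)$value,
                   gr = function(p) nlml_grad(p, X, y, emp_vec)$gradient,
                   method = "L-BFGS-B",
                   lower = log(lower), upper = log(upper),
                   control = list(maxit = 200L)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value) || res$value >= 1e10) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("GP hyperparameter optimization failed in all ", restarts, " restarts")

  p <- best$par
  hyp <- gp_hyp(sf2 = exp(p[1L]), ls = exp(p[1L + seq_len(D)]),
                sn2 = exp(p[D + 2L]))
  structure(list(X = X, y = y, hyp = hyp, emp = emp_vec,
                 emp_profile = if (inherits(emp, "noise_profile")) emp,
                 lml = -best$value, restarts = restarts, seed = seed),
            class = "gp_fit")
}

align_emp <- function(emp, X) {
  if (is.null(emp)) return(NULL)
  if (inherits(emp, "noise_profile")) {
    v <- stats::approx(emp$time, emp$sigma2, xout = X[, 1L], rule = 2)$y
    return(pmax(v, 0))
  }
  if (length(emp) != nrow(X))
    stop("empirical noise vector must have one value per observation")
  pmax(as.numeric(emp), 0)
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("Gaussian process regression fit\n")
  cat(sprintf("  observations: %d  input dimensions: %d\n",
              length(x$y), ncol(x$X)))
  cat(sprintf("  signal variance: %.4g  noise variance: %.4g\n",
              x$hyp$sf2, x$hyp$sn2))
  cat("  lengthscales:", paste(signif(x$hyp$ls, 4), collapse = ", "), "\n")
  cat(sprintf("  log marginal likelihood: %.4f\n", x$lml))
  if (!is.null(x$emp)) cat("  empirical noise profile: fixed during fit\n")
  invisible(x)
}

#' @export
logLik.gp_fit <- function(object, ...) {
  structure(object$lml, df = length(object$hyp$ls) + 2L, class = "logLik")
}

#' Empirical measurement-noise profile across replicates
#'
#' Estimates a time-dependent measurement variance as the sample variance
#' across replicate curves at each time point, smoothed along time with a
#' Gaussian filter (default width 1 h). The resulting profile can be passed
#' to [gp_fit()] where it enters the training covariance as a fixed diagonal
#' term; it is used only for model optimization, never for predicting at
#' new time points.
#'
#' @param replicate_matrix numeric matrix, replicates in rows, time points
#'   in columns.
#' @param time time vector (hours), one per column.
#' @param width Gaussian filter width (standard deviation) in hours.
#' @return an object of class `"noise_profile"`: list with `time`, `sigma2`
#'   and `filter_width`.
#' @export
empirical_noise <- function(replicate_matrix, time, width = 1) {
  replicate_matrix <- as.matrix(replicate_matrix)
  if (nrow(replicate_matrix) < 2L)
    stop("empirical noise needs >= 2 replicates; use the model-based noise term instead")
  if (ncol(replicate_matrix) != length(time))
    stop("time length must match the number of columns")
  if (width <= 0) stop("filter width must be positive")
  v <- apply(replicate_matrix, 2L, stats::var)
  dt <- stats::median(diff(time))
  structure(list(time = as.numeric(time),
                 sigma2 = gaussian_smooth(v, sigma = width / dt),
                 filter_width = width),
            class = "noise_profile")
}

# 1-d Gaussian filter with reflected boundaries, truncated at 4 sigma.
gaussian_smooth <- function(x, sigma) {
  n <- length(x)
  if (sigma <= 0 || n < 2L) return(x)
  r <- max(1L, ceiling(4 * sigma))
  w <- stats::dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  # reflected indexing (... c b a | a b c d | d c b ...), period 2n
  pos <- seq(1L - r, n + r)
  q <- (pos - 1L) %% (2L * n)
  idx <- ifelse(q < n, q + 1L, 2L * n - q)
  out <- stats::filter(x[idx], w, sides = 2L)
  as.numeric(out[(r + 1L):(r + n)])
}
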