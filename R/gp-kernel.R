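#' Radial basis function (squared exponential) kernel
#'
#' Computes the covariance matrix between two sets of inputs under an RBF
#' kernel with one lengthscale per input dimension (automatic relevance
#' determination when `D > 1`):
#' \deqn{k(x_i, x_j) = \sigma^2_{RBF} \exp\{-\tfrac12 (x_i - x_j) \Gamma (x_i - x_j)'\}}
#' with \eqn{\Gamma = diag(1/\ell_1^2, \ldots, 1/\ell_D^2)}. When `noise` is
#' `TRUE` (the default when both input sets are identical, i.e. a training
#' covariance), a Gaussian noise term \eqn{\sigma^2_{noise}} -- plus an
#' optional fixed empirical noise variance per observation -- is added on the
#' diagonal only.
#'
#' @param X1,X2 numeric matrices (rows = inputs, columns = dimensions) or
#'   vectors (treated as a single time dimension, in hours).
#' @param hyp kernel hyperparameters: a list with elements `sf2` (signal
#'   variance, > 0), `ls` (lengthscales, one per dimension, > 0) and `sn2`
#'   (noise variance, >= 0). See [gp_hyp()].
#' @param emp optional numeric vector of empirical noise variances, one per
#'   row of `X1`; only used when `noise` is `TRUE`.
#' @param noise logical; add the diagonal noise term? Defaults to `TRUE`
#'   exactly when `X1` and `X2` are the same set.
#' @return a `nrow(X1)` by `nrow(X2)` covariance matrix.
#' @seealso [gp_lml()], [gp_fit()]
#' @export
rbf_kernel <- function(X1, X2 = X1, hyp, emp = NULL,
                       noise = identical(X1, X2)) {
  X1 <- as_input_matrix(X1)
  X2 <- as_input_matrix(X2)
  check_hyp(hyp, ncol(X1))
  if (ncol(X1) != ncol(X2))
    stop("input dimension mismatch: ", ncol(X1), " vs ", ncol(X2))
  K <- hyp$sf2 * exp(-0.5 * scaled_sqdist(X1, X2, hyp$ls))
  if (noise) {
    if (nrow(X1) != nrow(X2))
      stop("diagonal noise requires square covariance (same input set)")
    d <- rep(hyp$sn2, nrow(X1))
    if (!is.null(emp)) {
      if (length(emp) != nrow(X1))
        stop("empirical noise length must equal number of rows")
      d <- d + emp
    }
    K <- K + diag(d, nrow(X1))
  }
  K
}

#' Bundle GP kernel hyperparameters
#'
#' @param sf2 RBF signal variance (> 0).
#' @param ls lengthscales, one per input dimension (> 0), in the units of the
#'   corresponding dimension (hours for time).
#' @param sn2 Gaussian noise variance (>= 0).
#' @return a list of class `"gp_hyp"`.
#' @export
gp_hyp <- function(sf2, ls, sn2) {
  h <- structure(list(sf2 = sf2, ls = ls, sn2 = sn2), class = "gp_hyp")
  check_hyp(h, length(ls))
  h
}

check_hyp <- function(hyp, D) {
  if (!is.list(hyp) || !all(c("sf2", "ls", "sn2") %in% names(hyp)))
    stop("hyperparameters must be a list with sf2, ls, sn2 (see gp_hyp())")
  if (!is.finite(hyp$sf2) || hyp$sf2 <= 0)
    stop("signal variance sf2 must be positive")
  if (any(!is.finite(hyp$ls)) || any(hyp$ls <= 0))
    stop("lengthscales must be positive")
  if (!is.finite(hyp$sn2) || hyp$sn2 < 0)
    stop("noise variance sn2 must be nonnegative")
  if (length(hyp$ls) != D)
    stop("need one lengthscale per input dimension (", D, ")")
  invisible(TRUE)
}

as_input_matrix <- function(X) {
  if (is.null(dim(X))) X <- matrix(as.numeric(X), ncol = 1L)
  storage.mode(X) <- "double"
  X
}

# Squared distances with per-dimension scaling sum_d (x1-x2)^2 / ls_d^2.
scaled_sqdist <- function(X1, X2, ls) {
  D2 <- matrix(0, nrow(X1), nrow(X2))
  for (d in seq_len(ncol(X1))) {
    D2 <- D2 + outer(X1[, d], X2[, d], "-")^2 / ls[d]^2
  }
  D2
}

# Cholesky with escalating jitter relative to the mean diagonal.
chol_jitter <- function(K, jitter = 1e-8) {
  base <- mean(diag(K))
  if (!is.finite(base) || base <= 0) base <- 1
  for (j in c(0, jitter * c(1, 1e2, 1e4, 1e6))) {
    L <- tryCatch(chol(K + diag(j * base, nrow(K))), error = function(e) NULL)
    if (!is.null(L)) return(L)
  }
  stop("covariance matrix is not positive definite even after jitter")
}
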