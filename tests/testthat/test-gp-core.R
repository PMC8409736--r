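test_that("RBF kernel matches its closed form, symmetry and PSD", {
  h <- gp_hyp(sf2 = 1, ls = 2, sn2 = 0.1)
  K <- rbf_kernel(c(0, 2), c(0, 2), h)           # same set: noise on diagonal
  expect_equal(diag(K), c(1.1, 1.1))
  expect_equal(K[1, 2], exp(-1 / 2))             # |dt| = lengthscale
  Kx <- rbf_kernel(c(0, 2), c(1, 3), h)          # different sets: no noise
  expect_equal(Kx[1, 1], exp(-1 / 8))
  # anisotropic form: time identical, covariate differs by 1 with ls2 = 1
  h2 <- gp_hyp(sf2 = 2, ls = c(1.5, 1), sn2 = 0)
  X1 <- matrix(c(5, 0), 1); X2 <- matrix(c(5, 1), 1)
  expect_equal(rbf_kernel(X1, X2, h2)[1, 1], 2 * exp(-1 / 2))
  # symmetry and near-PSD across random hyperparameters
  set.seed(3)
  for (i in 1:5) {
    hh <- gp_hyp(sf2 = runif(1, 0.1, 3), ls = runif(1, 0.2, 5),
                 sn2 = runif(1, 0, 0.5))
    X <- sort(runif(15, 0, 24))
    KK <- rbf_kernel(X, X, hh)
    expect_equal(KK, t(KK))
    expect_gt(min(eigen(KK, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8 * sum(diag(KK)))
  }
  expect_error(rbf_kernel(1:3, 1:3, gp_hyp(1, -1, 0)), "positive")
  expect_error(gp_hyp(0, 1, 0), "positive")
})

test_that("log marginal likelihood matches dense-algebra oracle", {
  # single observation, closed form: -log(2)/2 - log(2*pi)/2
  h1 <- gp_hyp(sf2 = 1, ls = 1, sn2 = 1)
  expect_equal(gp_lml(0, 0, h1), -0.5 * log(2) - 0.5 * log(2 * pi),
               tolerance = 1e-6)
  # independent oracle via solve() and determinant() on random points
  set.seed(14)
  X <- sort(runif(10, 0, 24)); y <- rnorm(10)
  h <- gp_hyp(sf2 = 1.3, ls = 3.1, sn2 = 0.2)
  K <- h$sf2 * exp(-outer(X, X, "-")^2 / (2 * h$ls^2)) + diag(h$sn2, 10)
  oracle <- -0.5 * drop(t(y) %*% solve(K, y)) -
    0.5 * as.numeric(determinant(K)$modulus) - 5 * log(2 * pi)
  expect_equal(gp_lml(X, y, h), oracle, tolerance = 1e-8)
  # duplicated inputs with zero noise exercise the jitter path
  Xd <- c(X, X[1]); yd <- c(y, y[1])
  h0 <- gp_hyp(sf2 = 1, ls = 3, sn2 = 0)
  expect_true(is.finite(gp_lml(Xd, yd, h0)))
})

test_that("hyperparameter optimization recovers noise level and signal", {
  t <- seq(0, 10, length.out = 50)
  fit <- gp_fit(t, sin(t), seed = 5)
  expect_lt(fit$hyp$sn2, 1e-4)
  pr <- predict_latent(fit, t)
  expect_lt(max(abs(pr$mean - sin(t))), 1e-2)
  # pooling identical replicates narrows the latent uncertainty
  set.seed(8)
  y1 <- sin(t) + rnorm(50, 0, 0.1)
  f1 <- gp_fit(t, y1, seed = 5)
  f2 <- gp_fit(rep(t, 2), rep(y1, 2), seed = 5)
  expect_lt(mean(diag(predict_latent(f2, t)$cov)),
            mean(diag(predict_latent(f1, t)$cov)))
  # constant data: flat mean near zero
  fc <- gp_fit(t, rep(0, 50), seed = 5)
  expect_lt(max(abs(predict_latent(fc, t)$mean)), 1e-6)
})

test_that("empirical noise profile is the smoothed replicate variance", {
  t <- seq(0, 10, by = 0.5)
  m <- rbind(sin(t), sin(t))
  expect_equal(empirical_noise(m, t)$sigma2, rep(0, length(t)))
  # two replicates offset by +/- c: pointwise variance 2 c^2, smoothing
  # preserves the constant
  c0 <- 0.3
  m2 <- rbind(sin(t) + c0, sin(t) - c0)
  expect_equal(empirical_noise(m2, t, width = 1)$sigma2,
               rep(2 * c0^2, length(t)), tolerance = 1e-10)
  # spike spreads over about the filter width; direct convolution oracle
  spike <- rep(0, 21); spike[11] <- sqrt(0.5)   # column var 2*x^2 = 1
  m3 <- rbind(spike, -spike)
  prof <- empirical_noise(m3, t, width = 1)
  pointwise <- apply(m3, 2, var)
  sigma_pts <- 1 / 0.5                           # width in samples
  r <- ceiling(4 * sigma_pts)
  w <- dnorm(seq(-r, r), sd = sigma_pts); w <- w / sum(w)
  n <- 21L
  oracle <- sapply(seq_len(n), function(i) {
    idx <- i + seq(-r, r)
    q <- (idx - 1L) %% (2L * n)                  # reflected boundary
    idx_r <- ifelse(q < n, q + 1L, 2L * n - q)
    sum(w * pointwise[idx_r])
  })
  expect_equal(prof$sigma2, oracle, tolerance = 1e-8)
  expect_gt(prof$sigma2[9], 0.01)                # mass spread to neighbors
  expect_lt(prof$sigma2[11], 1)
  expect_error(empirical_noise(matrix(1, 1, 5), 1:5), "2 replicates")
})

test_that("derivative posteriors agree with finite differences", {
  # exact line: interior derivative is 1
  t <- seq(0, 10, length.out = 40)
  fl <- gp_fit(t, t, seed = 2)
  pl <- predict_latent(fl, seq(1, 9, by = 0.2))
  expect_lt(max(abs(pl$d1_mean - 1)), 1e-2)
  # dense-grid finite differences of the posterior mean
  fit <- logistic_fit()$gp
  g <- seq(0.5, 23.5, length.out = 400)
  p <- predict_latent(fit, g)
  fd1 <- (p$mean[3:400] - p$mean[1:398]) / (g[3:400] - g[1:398])
  expect_lt(max(abs(p$d1_mean[2:399] - fd1)), 1e-3)
  fd2 <- (p$d1_mean[3:400] - p$d1_mean[1:398]) / (g[3:400] - g[1:398])
  expect_lt(max(abs(p$d2_mean[2:399] - fd2)), 1e-3)
  # near-interpolation at training points when noise is tiny
  t2 <- seq(0, 10, length.out = 30)
  f2 <- gp_fit(t2, sin(t2), seed = 2)
  expect_lt(max(abs(predict_latent(f2, t2)$mean - sin(t2))), 1e-2)
  expect_error(predict_latent(fit, numeric(0)), "empty|grid")
})

test_that("posterior sampling is seeded and respects the covariance", {
  p <- predict_latent(logistic_fit()$gp, seq(0, 24, by = 0.5))
  s1 <- sample_posterior(p, 5, seed = 31)
  s2 <- sample_posterior(p, 5, seed = 31)
  expect_identical(s1, s2)
  s3 <- sample_posterior(p, 5, seed = 32)
  expect_false(identical(s1$f, s3$f))
  expect_error(sample_posterior(p, 0), "positive")
  # degenerate covariance: all draws equal the mean
  pz <- fake_pred(0:10, (0:10) / 10)
  sz <- sample_posterior(pz, 4, seed = 1)
  for (i in 1:4) expect_equal(sz$f[i, ], pz$mean)
  # sample mean approaches the posterior mean
  sm <- sample_posterior(p, 2000, seed = 9)
  mc_se <- sqrt(diag(p$cov) / 2000)
  expect_lt(max(abs(colMeans(sm$f) - p$mean) / pmax(3 * mc_se, 1e-6)), 1.5)
})

test_that("credible bands compose variances as documented", {
  m <- 11
  pz <- fake_pred(0:10, rep(0, m), cov = diag(0.04, m), sf2 = 2, sn2 = 0.21)
  b <- credible_band(pz, alpha = 0.05, include_noise = FALSE)
  expect_equal((b$upper - b$mean) / b$sd, rep(qnorm(0.975), m))
  expect_equal(qnorm(0.975), 1.959964, tolerance = 1e-6)
  bn <- credible_band(pz, alpha = 0.05, include_noise = TRUE)
  expect_equal(bn$sd, rep(sqrt(0.04 + 0.21), m))
  # noise-inclusive band contains the latent-only band everywhere
  expect_true(all(bn$lower <= b$lower & bn$upper >= b$upper))
  # alpha = 0.32: half-width ~0.9945 sd
  b32 <- credible_band(pz, alpha = 0.32, include_noise = FALSE)
  expect_equal((b32$upper - b32$mean) / b32$sd, rep(0.99446, m),
               tolerance = 1e-4)
  # strict prior-variance composition uses sf2 verbatim
  bp <- credible_band(pz, include_noise = TRUE, latent = "prior")
  expect_equal(bp$sd, rep(sqrt(2 + 0.21), m))
  # empirical profile adds on top
  be <- credible_band(pz, include_noise = TRUE, emp = rep(0.05, m))
  expect_equal(be$sd, rep(sqrt(0.04 + 0.21 + 0.05), m))
  expect_error(credible_band(pz, alpha = 1.2), "alpha")
})
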