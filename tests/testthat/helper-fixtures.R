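# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# Pooled-replicate fit of a clean logistic curve (the canonical test curve:
# K = 1 ln OD, r = 0.5 /h, lag = 2 h, sd 0.02, 3 replicates, 24 h at 30 min).
logistic_fit <- function() memo("logistic_fit", {
  sp <- curve_spec("logistic", K = 1, r = 0.5, lag = 2, noise_sd = 0.02,
                   n_replicates = 3L, cadence = 0.5, seed = 101)
  reps <- make_replicates(sp)
  fit_growth(reps$time, reps$y, config = growth_config(seed = 11))
})

# Biphasic fit: secondary phase half the size of the primary.
double_fit <- function() memo("double_fit", {
  sp <- curve_spec("double-logistic", K = 1, r = 0.5, lag = 2,
                   K2 = 0.5, r2 = 0.25, onset2 = 14, noise_sd = 0.01,
                   n_replicates = 3L, cadence = 0.25, seed = 202)
  reps <- make_replicates(sp)
  fit_growth(reps$time, reps$y, config = growth_config(seed = 12))
})

# Hand-constructible latent prediction, for parameter/phase arithmetic
# tests that do not need a real GP fit behind them.
num_gradient <- function(y, x) {
  n <- length(y)
  g <- numeric(n)
  g[1] <- (y[2] - y[1]) / (x[2] - x[1])
  g[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) g[2:(n - 1)] <- (y[3:n] - y[1:(n - 2)]) / (x[3:n] - x[1:(n - 2)])
  g
}

fake_pred <- function(grid, mean, d1 = NULL, d2 = NULL, cov = NULL,
                      d1_cov = NULL, sf2 = 1, sn2 = 0.01) {
  m <- length(grid)
  if (is.null(d1)) d1 <- num_gradient(mean, grid)
  if (is.null(d2)) d2 <- num_gradient(d1, grid)
  structure(list(grid = grid, mean = mean, cov = cov %||% matrix(0, m, m),
                 d1_mean = d1, d1_cov = d1_cov %||% matrix(0, m, m),
                 d2_mean = d2, cov_fd = matrix(0, m, m),
                 hyp = gp_hyp(sf2 = sf2, ls = 1, sn2 = sn2)),
            class = "gp_prediction")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small two-condition design: n_rep curves per condition over `hours` at
# `cadence`; condition "b" scales the carrying capacity by k_ratio.
two_condition_design <- function(k_ratio = 1.5, n_rep = 3L, cadence = 1,
                                 hours = 24, noise_sd = 0.02, seed = 1) {
  curves <- list()
  labels <- character(0)
  i <- 0L
  for (cond in c("a", "b")) {
    K <- if (cond == "b") 1 * k_ratio else 1
    for (r in seq_len(n_rep)) {
      i <- i + 1L
      sp <- curve_spec("logistic", K = K, r = 0.5, lag = 2,
                       noise_sd = noise_sd, n_replicates = 1L,
                       cadence = cadence, duration = hours,
                       seed = seed * 1000L + i)
      reps <- make_replicates(sp)
      curves[[i]] <- list(time = reps$time, y = reps$y[1L, ])
      labels <- c(labels, cond)
    }
  }
  build_design(curves, labels)
}

# Independent re-implementation of the phase-merge heuristic, written as a
# plain boundary-list simulation, used as an oracle for detect_phases().
oracle_phases <- function(pred, ratio, criterion = "total-growth") {
  ipts <- find_inflections(pred)
  bounds <- sort(unique(ipts$time[ipts$type == "positive"]))
  mu_at <- function(t) approx(pred$grid, pred$mean, t, rule = 2)$y
  d1_at <- function(t) approx(pred$grid, pred$d1_mean, t, rule = 2)$y
  rmax_in <- function(a, b) {
    sel <- pred$grid >= a & pred$grid <= b
    max(c(d1_at(a), pred$d1_mean[sel], d1_at(b)))
  }
  measure <- function(a, b) {
    if (criterion == "growth-rate") rmax_in(a, b) else mu_at(b) - mu_at(a)
  }
  repeat {
    k <- length(bounds) - 1L
    if (k <= 1L) break
    ms <- sapply(seq_len(k), function(i) measure(bounds[i], bounds[i + 1L]))
    sm <- order(ms, bounds[-length(bounds)])[1L]
    if (ms[sm] >= ratio * max(ms)) break
    # remove one boundary of the smallest phase: the one whose growth rate
    # is nearer the phase's own maximum rate (left on ties/edges)
    if (sm == 1L) {
      drop_at <- 2L
    } else if (sm == k) {
      drop_at <- k
    } else {
      r_own <- rmax_in(bounds[sm], bounds[sm + 1L])
      drop_at <- if (abs(r_own - d1_at(bounds[sm])) <=
                     abs(r_own - d1_at(bounds[sm + 1L]))) sm else sm + 1L
    }
    bounds <- bounds[-drop_at]
  }
  bounds
}
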