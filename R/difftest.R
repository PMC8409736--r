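#' Build a design matrix for differential growth testing
#'
#' Stacks the observations of several (preprocessed) curves and encodes a
#' categorical condition alongside time: two levels become a single 0/1
#' indicator column, more levels are one-hot encoded with one column per
#' level. The condition is constant within a curve (the sample is the unit
#' of the design).
#'
#' @param curves list of `"transformed_curve"` objects (or any lists with
#'   `time` and `y`).
#' @param labels condition label per curve.
#' @return an object of class `"gp_design"`: list with `X` (time in column
#'   1, indicators after), `y`, `sample_id`, `condition`, `levels`.
#' @export
build_design <- function(curves, labels) {
  if (length(curves) != length(labels))
    stop("need one condition label per curve")
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2L)
    stop("condition is constant across samples; nothing to test")
  rows <- lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    data.frame(time = cv$time, y = cv$y, sample = i,
               condition = labels[i])
  })
  d <- do.call(rbind, rows)
  Z <- encode_condition(d$condition, lev)
  structure(list(X = cbind(time = d$time, Z), y = d$y,
                 sample_id = d$sample, condition = d$condition,
                 levels = lev),
            class = "gp_design")
}

encode_condition <- function(condition, lev) {
  if (length(lev) == 2L) {
    matrix(as.numeric(condition == lev[2L]), ncol = 1L,
           dimnames = list(NULL, lev[2L]))
  } else {
    vapply(lev, function(l) as.numeric(condition == l),
           numeric(length(condition)))
  }
}

#' @export
print.gp_design <- function(x, ...) {
  cat(sprintf("gp_design: %d observations, %d curves, %d condition level(s)\n",
              length(x$y), length(unique(x$sample_id)), length(x$levels)))
  invisible(x)
}

#' Log Bayes factor for differential growth
#'
#' Fits two nested GP models to the same observations: the null model M0
#' with time as the only input, and the alternative M1 with time plus the
#' condition indicators (each dimension with its own lengthscale). The log
#' Bayes factor is the difference of the optimized log marginal
#' likelihoods, `logL(M1) - logL(M0)`; values above zero favor the
#' alternative, i.e. condition-dependent growth.
#'
#' @param design a [build_design()] object.
#' @param restarts,seed optimizer settings passed to [gp_fit()].
#' @return an object of class `"growth_test"` with `logL_null`,
#'   `logL_alt`, `log_bf`, and the two fits (no permutation null yet; see
#'   [test_differential_growth()]).
#' @export
bayes_factor <- function(design, restarts = 3L, seed = NULL) {
  stopifnot(inherits(design, "gp_design"))
  fit0 <- gp_fit(design$X[, 1L, drop = FALSE], design$y,
                 restarts = restarts, seed = seed)
  fit1 <- gp_fit(design$X, design$y, restarts = restarts, seed = seed)
  structure(list(logL_null = fit0$lml, logL_alt = fit1$lml,
                 log_bf = fit1$lml - fit0$lml,
                 fit_null = fit0, fit_alt = fit1, design = design,
                 null_log_bfs = NULL, fdr = NULL, fdr_threshold = NULL,
                 significant = NULL),
            class = "growth_test")
}

#' Differential growth test with a permutation FDR threshold
#'
#' Computes the observed log Bayes factor, then builds its null
#' distribution by randomly reassigning condition labels to whole curves
#' (never across time points within a curve) and refitting the alternative
#' model for each permutation. The significance threshold is the empirical
#' `100 * (1 - fdr)` percentile of the null log Bayes factors; the observed
#' score is significant when it exceeds the threshold. If the design admits
#' fewer distinct label assignments than requested, all distinct
#' assignments are used with a warning.
#'
#' @param design a [build_design()] object.
#' @param n_permutations permutations for the null distribution.
#' @param fdr false discovery rate (default 0.10, i.e. the 90th
#'   percentile).
#' @param seed integer seed for label permutation and optimizer restarts.
#' @param restarts optimizer restarts for the observed fits;
#'   permutation refits use a single start.
#' @return a complete `"growth_test"` object.
#' @export
test_differential_growth <- function(design, n_permutations = 100L,
                                     fdr = 0.10, seed = NULL, restarts = 3L) {
  stopifnot(inherits(design, "gp_design"))
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  res <- bayes_factor(design, restarts = restarts, seed = seed)

  samples <- unique(design$sample_id)
  per_sample <- design$condition[match(samples, design$sample_id)]
  n_distinct <- count_label_assignments(per_sample)
  perms <- with_seed(seed, {
    if (n_distinct < n_permutations) {
      warning("only ", n_distinct, " distinct label assignments exist; ",
              "using all of them instead of ", n_permutations)
      distinct_assignments(per_sample)
    } else {
      lapply(seq_len(n_permutations), function(i) sample(per_sample))
    }
  })

  null_bf <- vapply(perms, function(lab) {
    Xp <- design$X
    Xp[, -1L] <- encode_condition(lab[match(design$sample_id, samples)],
                                  design$levels)
    fitp <- gp_fit(Xp, design$y, restarts = 1L)
    fitp$lml - res$logL_null
  }, numeric(1L))

  res$null_log_bfs <- null_bf
  res$fdr <- fdr
  res$fdr_threshold <- unname(stats::quantile(null_bf, 1 - fdr, type = 7))
  res$significant <- res$log_bf > res$fdr_threshold
  res
}

# number of distinct arrangements of a label multiset
count_label_assignments <- function(labels) {
  n <- length(labels)
  cnt <- table(labels)
  round(exp(lgamma(n + 1) - sum(lgamma(cnt + 1))))
}

distinct_assignments <- function(labels) {
  rec <- function(pool) {
    if (length(pool) == 1L) return(list(pool))
    out <- list()
    for (u in unique(pool)) {
      rest <- pool[-match(u, pool)]
      out <- c(out, lapply(rec(rest), function(p) c(u, p)))
    }
    out
  }
  rec(labels)
}

#' @export
print.growth_test <- function(x, ...) {
  cat("Differential growth test (GP model comparison)\n")
  cat(sprintf("  logL null: %.3f  logL alternative: %.3f\n",
              x$logL_null, x$logL_alt))
  cat(sprintf("  log Bayes factor: %.3f\n", x$log_bf))
  if (!is.null(x$null_log_bfs)) {
    cat(sprintf("  permutation threshold (%d perms, FDR %.0f%%): %.3f\n",
                length(x$null_log_bfs), 100 * x$fdr, x$fdr_threshold))
    cat("  significant:", x$significant, "\n")
  }
  invisible(x)
}

#' Functional difference between two conditions
#'
#' From the alternative (condition-aware) model, jointly predicts the
#' latent growth curves of both conditions on the shared time grid and
#' forms the pointwise functional difference
#' `delta(t) = ln OD_A(t) - ln OD_B(t)`, where A is the condition encoded
#' 1 and B the condition encoded 0. The summary `||delta||` is the
#' Euclidean norm `sqrt(sum_t delta(t)^2)` over the grid; its uncertainty
#' comes from posterior draws of the joint difference.
#'
#' @param test a `"growth_test"` (or [bayes_factor()]) object for a
#'   two-level design.
#' @param n_samples posterior draws for the norm summary.
#' @param confidence credible level of the norm interval.
#' @param include_noise add the fitted Gaussian noise variance to the
#'   sampled difference (off by default: the difference of latent curves).
#' @param seed integer seed.
#' @return an object of class `"functional_difference"`: list with `grid`,
#'   `delta_mean`, `delta_sd`, `delta_band` (data.frame), `norm_mean`,
#'   `norm_ci`, and the per-draw norms.
#' @export
functional_difference <- function(test, n_samples = 100L, confidence = 0.95,
                                  include_noise = FALSE, seed = NULL) {
  stopifnot(inherits(test, "growth_test"))
  design <- test$design
  if (length(design$levels) != 2L)
    stop("functional differences are defined for two-level designs")
  fit <- test$fit_alt
  tg <- sort(unique(design$X[, 1L]))
  m <- length(tg)
  Xa <- cbind(tg, 1)   # condition A: indicator 1 (second level)
  Xb <- cbind(tg, 0)   # condition B: indicator 0 (first level)
  pred <- predict_latent(fit, rbind(Xa, Xb))
  C <- pred$cov
  if (include_noise) C <- C + diag(fit$hyp$sn2, nrow(C))
  ia <- seq_len(m); ib <- m + ia
  delta_mean <- pred$mean[ia] - pred$mean[ib]
  delta_cov <- symmetrize(C[ia, ia] + C[ib, ib] - C[ia, ib] - C[ib, ia])

  draws <- with_seed(seed, rmvn(n_samples, delta_mean, delta_cov))
  norms <- sqrt(rowSums(draws^2))
  a <- (1 - confidence) / 2
  z <- stats::qnorm(1 - a)
  sd_d <- sqrt(pmax(diag(delta_cov), 0))
  structure(list(grid = tg,
                 delta_mean = delta_mean,
                 delta_sd = sd_d,
                 delta_band = data.frame(time = tg, delta = delta_mean,
                                         lower = delta_mean - z * sd_d,
                                         upper = delta_mean + z * sd_d),
                 norm_mean = mean(norms),
                 norm_ci = unname(stats::quantile(norms, c(a, 1 - a), type = 7)),
                 norms = norms,
                 conditions = c(A = design$levels[2L], B = design$levels[1L]),
                 confidence = confidence),
            class = "functional_difference")
}

#' @export
print.functional_difference <- function(x, ...) {
  cat(sprintf("Functional difference %s - %s over %d time points\n",
              x$conditions["A"], x$conditions["B"], length(x$grid)))
  cat(sprintf("  ||delta||: %.4f  %.0f%% CI [%.4f, %.4f]\n",
              x$norm_mean, 100 * x$confidence, x$norm_ci[1L], x$norm_ci[2L]))
  invisible(x)
}

#' Compare sampled parameter summaries by credible-interval overlap
#'
#' A parameter differs significantly between two conditions when its
#' credible intervals do not overlap; intervals touching at an endpoint
#' overlap (closed intervals) and are not significant. Both summaries must
#' be at the same credible level.
#'
#' @param summary_a,summary_b [sample_parameters()] objects.
#' @return named logical vector, one flag per parameter shared by both
#'   summaries (`NA` where either interval is undefined).
#' @export
compare_parameters_ci <- function(summary_a, summary_b) {
  ca <- attr(summary_a, "confidence"); cb <- attr(summary_b, "confidence")
  if (!isTRUE(all.equal(ca, cb)))
    stop("summaries are at different confidence levels (", ca, " vs ", cb, ")")
  pars <- intersect(rownames(summary_a), rownames(summary_b))
  out <- vapply(pars, function(p) {
    a <- summary_a[p, ]; b <- summary_b[p, ]
    if (anyNA(c(a$ci_low, a$ci_high, b$ci_low, b$ci_high))) return(NA)
    a$ci_high < b$ci_low || b$ci_high < a$ci_low
  }, logical(1L))
  names(out) <- pars
  out
}
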