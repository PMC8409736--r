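#' Locate and classify inflection points of the growth curve
#'
#' Inflection points are the zeros of the second derivative of the
#' predicted ln OD. They are located as sign changes of the posterior mean
#' second derivative on the grid, with linear interpolation for the
#' crossing time. A crossing is classified `"positive"` when the second
#' derivative crosses upward (growth accelerating; a valley of the growth
#' rate) and `"negative"` when it crosses downward (a peak of the growth
#' rate). The first and last grid times are always included as positive
#' inflection points so that phases tile the observed window. Interior
#' crossings in regions where the second derivative never leaves
#' `[-tol, tol]` are discarded as flat-curve chatter.
#'
#' @param pred a [predict_latent()] object with `d2_mean` on a dense grid.
#' @param tol noise guard on the second-derivative magnitude.
#' @return data.frame with columns `time` and `type` ("positive"/"negative"),
#'   sorted by time.
#' @export
find_inflections <- function(pred, tol = 1e-6) {
  stopifnot(inherits(pred, "gp_prediction"))
  tg <- pred$grid
  d2 <- pred$d2_mean
  n <- length(tg)
  s <- sign(d2)
  cross <- which(s[-n] * s[-1L] < 0)          # strict sign change in (i, i+1)
  # exact zeros: assign to the left interval boundary
  zero <- which(s == 0 & seq_len(n) > 1L & seq_len(n) < n)
  res <- data.frame(time = numeric(0), type = character(0), idx = integer(0))
  for (i in cross) {
    t0 <- tg[i] - d2[i] * (tg[i + 1L] - tg[i]) / (d2[i + 1L] - d2[i])
    type <- if (d2[i] < 0) "positive" else "negative"
    res <- rbind(res, data.frame(time = t0, type = type, idx = i))
  }
  for (i in zero) {
    if (s[i - 1L] == 0 || s[i + 1L] == 0) next
    type <- if (s[i - 1L] < 0) "positive" else "negative"
    res <- rbind(res, data.frame(time = tg[i], type = type, idx = i))
  }
  if (nrow(res) > 0L) {
    res <- res[order(res$time), , drop = FALSE]
    # noise guard: |d2| must exceed tol on both flanking segments (up to
    # the neighboring crossing or grid edge); filters flat-curve chatter
    bounds <- c(1L, res$idx, n)
    keep <- vapply(seq_len(nrow(res)), function(k) {
      i <- res$idx[k]
      max(abs(d2[bounds[k]:i])) > tol &&
        max(abs(d2[min(i + 1L, n):bounds[k + 2L]])) > tol
    }, logical(1L))
    res <- res[keep, , drop = FALSE]
  }
  out <- rbind(data.frame(time = tg[1L], type = "positive"),
               res[, c("time", "type")],
               data.frame(time = tg[n], type = "positive"))
  rownames(out) <- NULL
  out
}

#' Candidate growth phases from positive inflection points
#'
#' Each candidate phase is bounded by two consecutive positive inflection
#' points (the first and last observation times count as positive). Per
#' phase, the total growth is the change in predicted ln OD across the
#' bounds, and the phase carrying capacity and maximum rate are maxima of
#' the predicted mean and derivative mean within the bounds.
#'
#' @param pred a [predict_latent()] object.
#' @param inflections output of [find_inflections()]; computed if missing.
#' @return data.frame with one row per phase: `t_start`, `t_end`,
#'   `total_growth`, `K_phase`, `r_phase`, `t_r_phase`.
#' @export
candidate_phases <- function(pred, inflections = find_inflections(pred)) {
  pos <- inflections$time[inflections$type == "positive"]
  pos <- sort(unique(pos))
  do.call(rbind, lapply(seq_len(length(pos) - 1L), function(k)
    phase_metrics(pred, pos[k], pos[k + 1L])))
}

phase_metrics <- function(pred, t0, t1) {
  f0 <- interp_at(pred$grid, pred$mean, t0)
  f1 <- interp_at(pred$grid, pred$mean, t1)
  inside <- pred$grid >= t0 & pred$grid <= t1
  fvals <- c(f0, pred$mean[inside], f1)
  dvals <- c(interp_at(pred$grid, pred$d1_mean, t0),
             pred$d1_mean[inside],
             interp_at(pred$grid, pred$d1_mean, t1))
  tvals <- c(t0, pred$grid[inside], t1)
  ir <- which.max(dvals)
  data.frame(t_start = t0, t_end = t1, total_growth = f1 - f0,
             K_phase = max(fvals), r_phase = dvals[ir], t_r_phase = tvals[ir])
}

interp_at <- function(x, y, x0) stats::approx(x, y, xout = x0, rule = 2)$y

#' Detect multiphasic (diauxic) growth
#'
#' Iterative merge heuristic over candidate phases. Phases are ranked by
#' total growth (or, under `criterion = "growth-rate"`, by their maximum
#' growth rate). Starting with the smallest phase, it is compared against
#' the primary (largest) phase: if its measure is at least `ratio` times
#' the primary's, all current phases are confirmed and iteration stops.
#' Otherwise the smallest phase is merged into the adjacent phase with the
#' lower activation energy -- the absolute difference between the phase's
#' own maximum growth rate and the growth rate at its left or right
#' boundary -- then phases are re-ranked and the process repeats until
#' confirmation or a single phase remains. Diauxie is called when two or
#' more phases are confirmed.
#'
#' @param pred a [predict_latent()] object.
#' @param ratio confirmation threshold relative to the primary phase
#'   (default 0.2, i.e. a secondary phase must contribute at least 20% of
#'   the primary phase's change in ln OD).
#' @param criterion `"total-growth"` (default) or `"growth-rate"`.
#' @return list with `diauxie` (logical) and `phases` (confirmed phases,
#'   as in [candidate_phases()]).
#' @export
detect_phases <- function(pred, ratio = 0.2,
                          criterion = c("total-growth", "growth-rate")) {
  criterion <- match.arg(criterion)
  ph <- candidate_phases(pred)
  ph <- merge_phases(ph, pred, ratio, criterion)
  list(diauxie = nrow(ph) >= 2L, phases = ph)
}

phase_measure <- function(ph, criterion) {
  if (criterion == "growth-rate") ph$r_phase else ph$total_growth
}

merge_phases <- function(ph, pred, ratio, criterion) {
  repeat {
    if (nrow(ph) <= 1L) return(ph)
    m <- phase_measure(ph, criterion)
    # smallest phase; ties broken by earliest start
    i <- order(m, ph$t_start)[1L]
    primary <- max(m)
    if (m[i] >= ratio * primary) return(ph)
    ph <- merge_one(ph, i, pred)
  }
}

# Merge phase i into its neighbor with the lower activation energy
# (|own max rate - rate at that boundary|); ties and edges resolve left.
merge_one <- function(ph, i, pred) {
  n <- nrow(ph)
  if (n == 1L) return(ph)
  if (i == 1L) {
    j <- 2L
  } else if (i == n) {
    j <- n - 1L
  } else {
    r_i <- ph$r_phase[i]
    ae_left <- abs(r_i - interp_at(pred$grid, pred$d1_mean, ph$t_start[i]))
    ae_right <- abs(r_i - interp_at(pred$grid, pred$d1_mean, ph$t_end[i]))
    j <- if (ae_left <= ae_right) i - 1L else i + 1L
  }
  lo <- min(i, j); hi <- max(i, j)
  merged <- phase_metrics(pred, ph$t_start[lo], ph$t_end[hi])
  out <- rbind(if (lo > 1L) ph[seq_len(lo - 1L), ], merged,
               if (hi < n) ph[(hi + 1L):n, ])
  rownames(out) <- NULL
  out
}
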