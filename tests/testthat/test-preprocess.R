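mini_plate <- function(od, time = seq_len(ncol(od)) - 1,
                       wells = paste0("A", seq_len(nrow(od)))) {
  growth_plate(od, time, wells)
}

test_that("trimming drops leading points without re-zeroing time", {
  od <- matrix(runif(2 * 145, 0.1, 1), nrow = 2)
  p <- mini_plate(od, time = (0:144) / 6)
  expect_equal(trim_initial(p, 0), p)
  p1 <- trim_initial(p, 1)
  expect_equal(length(p1$time), 144L)
  expect_equal(p1$time[1], 1 / 6)
  expect_equal(unname(p1$od), unname(od[, -1]))
  expect_error(trim_initial(p, 145), "trim")
})

test_that("blank subtraction removes the mean of blank wells", {
  od <- rbind(A1 = rep(0.1, 5), A2 = rep(0.12, 5), A3 = rep(0.3, 5),
              A4 = seq(0.2, 0.6, length.out = 5))
  p <- mini_plate(od, wells = rownames(od))
  # one blank identical to a sample: that sample becomes all-zero
  out <- subtract_blank(p, "A1")
  expect_equal(unname(out$od["A3", ]), rep(0.2, 5))
  expect_false("A1" %in% out$wells)
  same <- subtract_blank(mini_plate(rbind(A1 = rep(0.3, 5), A3 = rep(0.3, 5)),
                                    wells = c("A1", "A3")), "A1")
  expect_equal(unname(same$od[1, ]), rep(0, 5))
  # two blanks: pointwise mean (0.11) subtracted
  out2 <- subtract_blank(p, c("A1", "A2"))
  expect_equal(unname(out2$od["A3", ]), rep(0.3 - 0.11, 5))
  expect_error(subtract_blank(p, character(0)), "blank")
})

test_that("control subtraction stays within groups", {
  od <- rbind(A1 = rep(0.2, 4), A2 = rep(0.5, 4),
              B1 = rep(0.1, 4), B2 = rep(0.7, 4))
  md <- data.frame(well_id = c("A1", "A2", "B1", "B2"),
                   group = c("g1", "g1", "g2", "g2"),
                   is_control = c(TRUE, FALSE, TRUE, FALSE))
  p <- mini_plate(od, wells = rownames(od))
  out <- subtract_control(p, md)
  expect_equal(unname(out$od["A2", ]), rep(0.3, 4))   # 0.5 - 0.2
  expect_equal(unname(out$od["B2", ]), rep(0.6, 4))   # 0.7 - 0.1, not 0.2
  expect_equal(unname(out$od["A1", ]), rep(0.2, 4))   # controls retained
  # treatment identical to its control becomes zero
  md2 <- md; od2 <- od; od2["A2", ] <- od2["A1", ]
  expect_equal(unname(subtract_control(mini_plate(od2, wells = rownames(od2)),
                                       md2)$od["A2", ]), rep(0, 4))
  # a group with only controls passes through unchanged
  md3 <- data.frame(well_id = rownames(od), group = "g",
                    is_control = c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(subtract_control(p, md3)$od, p$od)
  md4 <- md; md4$is_control <- FALSE
  expect_error(subtract_control(p, md4), "g1")
})

test_that("positivity enforcement shifts to the floor and preserves differences", {
  od <- rbind(A1 = c(-0.05, 0.1, 0.4), A2 = c(0.0, 0.2, 0.5))
  p <- mini_plate(od)
  out <- enforce_positive(p, lod = 0.01)
  expect_equal(out$offset, 0.06)
  expect_equal(min(out$plate$od), 0.01)
  expect_equal(diff(out$plate$od[1, ]), diff(od[1, ]))  # shifts preserve deltas
  # already positive: identity
  ok <- mini_plate(matrix(c(0.1, 0.2, 0.3, 0.4), 2))
  expect_equal(enforce_positive(ok, 0.01)$offset, 0)
  expect_equal(enforce_positive(ok, 0.01)$plate$od, ok$od)
  # all-zero curve with lod 0.01 becomes constant 0.01
  z <- enforce_positive(mini_plate(matrix(0, 1, 4)), 0.01)
  expect_equal(unname(z$plate$od[1, ]), rep(0.01, 4))
  # idempotence
  again <- enforce_positive(out$plate, lod = 0.01)
  expect_equal(again$offset, 0)
  # auto floor is the pooled median absolute consecutive change
  pa <- mini_plate(rbind(c(-0.02, 0.0, 0.03), c(0.1, 0.12, 0.15)))
  exp_floor <- median(abs(c(0.02, 0.03, 0.02, 0.03)))
  expect_equal(enforce_positive(pa, "auto")$offset, exp_floor - (-0.02))
})

test_that("log transform and baseline anchoring behave exactly", {
  tt <- seq(0, 5, by = 0.5)
  # constant curve maps to all-zero
  cp <- mini_plate(matrix(0.05, 1, length(tt)), time = tt)
  expect_equal(log_baseline(cp)[[1]]$y, rep(0, length(tt)),
               ignore_attr = TRUE)
  # od = 0.05 exp(0.5 t) maps to exactly y = 0.5 t
  ep <- mini_plate(matrix(0.05 * exp(0.5 * tt), 1), time = tt)
  tc <- log_baseline(ep)[[1]]
  expect_equal(tc$y, 0.5 * tt, ignore_attr = TRUE)
  expect_identical(tc$y[1], 0)
  expect_error(log_baseline(mini_plate(matrix(c(0, 0.1, 0.2), 1))),
               "enforce_positive")
  expect_error(log_baseline(mini_plate(matrix(0.1, 1, 5)),
                            use_polynomial = TRUE), "6 time points")
  # polynomial baseline still lands near the first point on smooth data
  pb <- log_baseline(ep, use_polynomial = TRUE)[[1]]
  expect_lt(abs(pb$y[1]), 1e-8)
})

test_that("pipeline runs required steps in canonical order", {
  set.seed(7)
  od <- matrix(runif(4 * 12, 0.05, 0.9), nrow = 4)
  p <- mini_plate(od, time = (0:11) / 6)
  out <- preprocess_plate(p, config = growth_config())
  ref <- log_baseline(enforce_positive(p, "auto")$plate,
                      offset_used = enforce_positive(p, "auto")$offset,
                      steps = "positive")
  expect_equal(lapply(out, `[[`, "y"), lapply(ref, `[[`, "y"))
  expect_equal(out[[1]]$applied_steps, c("positive", "log", "baseline-first"))
  for (cv in out) expect_identical(cv$y[1], 0)
  expect_error(preprocess_plate(p, config = growth_config(
    step_order = c("log", "positive", "baseline"))), "canonical")
  # blanks reduce the output count
  md <- data.frame(well_id = p$wells, group = "all",
                   is_blank = c(TRUE, FALSE, FALSE, FALSE),
                   is_control = FALSE)
  out2 <- preprocess_plate(p, md, growth_config(do_blank_subtraction = TRUE))
  expect_equal(length(out2), 3L)
})
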