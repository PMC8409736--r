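test_that("the fitted-model object supports the standard methods", {
  fit <- logistic_fit()
  expect_s3_class(fit, "growth_fit")
  expect_output(print(fit), "GP growth curve fit")
  co <- coef(fit)
  expect_named(co, c("sf2", "ls1", "sn2"))
  expect_true(all(co > 0))
  expect_equal(as.numeric(logLik(fit)), fit$gp$lml)
  res <- residuals(fit)
  expect_length(res, length(fit$gp$y))
  expect_lt(mean(abs(res)), 0.05)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_equal(dim(sim), c(length(fit$pred$grid), 4L))
  expect_identical(sim, simulate(fit, nsim = 3, seed = 1))
  b <- predict(fit, what = "band")
  expect_true(all(b$lower <= b$mean & b$mean <= b$upper))
  s <- summary(fit, n = 20, seed = 2)
  expect_s3_class(s, "summary.growth_fit")
  expect_output(print(s), "Posterior-sampled")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
})

test_that("empirical noise can drive the fit through the front end", {
  sp <- curve_spec("logistic", noise_sd = 0.05, n_replicates = 3,
                   cadence = 1, seed = 55)
  reps <- make_replicates(sp)
  fit <- fit_growth(reps$time, reps$y,
                    config = growth_config(empirical_noise = TRUE, seed = 1))
  expect_false(is.null(fit$gp$emp))
  expect_length(fit$gp$emp, length(fit$gp$y))
  expect_error(fit_growth(reps$time, reps$y[1, ],
                          config = growth_config(empirical_noise = TRUE)),
               "replicate")
})

test_that("configuration files parse and validate", {
  f <- tempfile()
  writeLines(c("confidence: 0.9", "n_permutations = 25", "# comment",
               "empirical_noise: true", "diauxie_criterion: growth-rate"), f)
  cfg <- read_config(f)
  expect_equal(cfg$confidence, 0.9)
  expect_equal(cfg$n_permutations, 25)
  expect_true(cfg$empirical_noise)
  expect_equal(cfg$diauxie_criterion, "growth-rate")
  expect_error(growth_config(fdr = 1.5))
  expect_error(growth_config(confidence = 0))
  writeLines("not a config line", f)
  expect_error(read_config(f), "unparseable")
})

make_demo_plate <- function(dir, n = 6L, plate_id = "demo") {
  specs <- lapply(seq_len(n), function(i)
    curve_spec("logistic", K = ifelse(i <= n / 2, 1, 0.6), r = 0.5, lag = 2,
               noise_sd = 0.02, cadence = 1, duration = 20, seed = 400 + i))
  make_plate(specs, dir, plate_id = plate_id)
}

test_that("whole-plate analysis produces per-well and pooled tables", {
  dir <- tempfile("demo")
  paths <- make_demo_plate(dir)
  plate <- read_plate(paths$plate)
  cfg <- growth_config(seed = 7)
  res <- analyze_plate(plate, config = cfg)
  expect_equal(nrow(res$params), 6L)
  expect_setequal(res$params$id, plate$wells)
  expect_true(all(c("K", "r", "auc", "lag", "diauxie") %in%
                  names(res$params)))
  expect_equal(nrow(res$predictions), 6L * length(plate$time))
  # pooling by substrate collapses replicate wells
  md <- read_well_map(paths$mapping)
  md$condition <- rep(c("high", "low"), each = 3)
  pooled <- analyze_plate(plate, md, cfg, pool_by = "condition")
  expect_equal(nrow(pooled$params), 2L)
  expect_setequal(pooled$params$id, c("high", "low"))
  expect_error(analyze_plate(plate, md, cfg, pool_by = "nope"), "nope")
  # normalization against a control well
  md$is_control <- md$well_id == "A1"
  normed <- analyze_plate(plate, md, cfg, normalize = TRUE)
  expect_true(all(c("norm_auc", "growth") %in% names(normed$params)))
  expect_equal(normed$params$norm_auc[normed$params$id == "A1"], 1)
})

test_that("the summarize workflow is reproducible byte for byte", {
  dir <- tempfile("demo")
  make_demo_plate(dir, n = 4L)
  out1 <- file.path(tempfile(), "run1")
  out2 <- file.path(tempfile(), "run2")
  cfg <- growth_config(seed = 13, posterior_samples = 10)
  run_summarize(dir, out1, config = cfg, sampled = TRUE)
  run_summarize(dir, out2, config = cfg, sampled = TRUE)
  f1 <- file.path(out1, "demo_summary.txt")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(file.path(out2, "demo_summary.txt")))
  expect_identical(readLines(file.path(out1, "demo_fitted.txt")),
                   readLines(file.path(out2, "demo_fitted.txt")))
  tab <- read.delim(f1)
  expect_equal(nrow(tab), 4L)
  expect_true(all(c("K_mean", "K_ci_low", "K_ci_high") %in% names(tab)))
  # manifest records the run
  man <- jsonlite::read_json(file.path(out1, "run_manifest.json"))
  expect_equal(man$command, "summarize")
  expect_equal(man$seed, 13)
})

test_that("the test workflow reports a significant two-condition contrast", {
  dir <- tempfile("demo")
  make_demo_plate(dir, n = 6L)   # wells 1-3: K = 1, wells 4-6: K = 0.6
  map <- file.path(dir, "cond_mapping.txt")
  writeLines(c("plate_id\twell_id\tconcentration",
               paste("demo", c("A1", "A2", "A3", "A4", "A5", "A6"),
                     rep(c("high", "low"), each = 3), sep = "\t")), map)
  out <- tempfile("testout")
  cfg <- growth_config(seed = 3, n_permutations = 15, posterior_samples = 20)
  test <- run_test(dir, out, covariate = "concentration", config = cfg,
                   mapping = map)
  expect_s3_class(test, "growth_test")
  expect_true(test$significant)
  rep_tab <- read.delim(file.path(out, "test_report.txt"))
  expect_equal(rep_tab$log_bf, test$log_bf, tolerance = 1e-9)
  expect_true(file.exists(file.path(out, "functional_difference.txt")))
  fd <- attr(test, "fdiff")
  expect_gt(fd$norm_mean, 1)
})

test_that("simulate workflow and CLI script drive the generator", {
  spec_tab <- tempfile(fileext = ".txt")
  writeLines(c("well_id\tshape\tK\tr\tlag\tnoise_sd\tcadence\tduration",
               "A1\tlogistic\t1\t0.5\t2\t0.01\t1\t20",
               "A2\tflat\t1\t0.5\t2\t0.01\t1\t20"), spec_tab)
  out <- tempfile("sim")
  run_simulate(spec_tab, out, plate_id = "mini", seed = 4)
  expect_true(file.exists(file.path(out, "mini.txt")))
  plate <- read_plate(file.path(out, "mini.txt"))
  expect_equal(plate$wells, c("A1", "A2"))
  # same seed, same fixture
  out2 <- tempfile("sim")
  run_simulate(spec_tab, out2, plate_id = "mini", seed = 4)
  expect_identical(readLines(file.path(out, "mini.txt")),
                   readLines(file.path(out2, "mini.txt")))
  # the installed command-line script runs end to end
  cli <- system.file("cli", "gpgrowth.R", package = "gpgrowth")
  expect_true(nzchar(cli))
  if (requireNamespace("optparse", quietly = TRUE)) {
    out3 <- tempfile("sim")
    status <- system2("Rscript",
                      c(cli, "simulate", "--input", spec_tab,
                        "--output", out3, "--plate-id", "mini", "--seed", "4"),
                      stdout = FALSE, stderr = FALSE,
                      env = paste0("R_LIBS=",
                                   paste(.libPaths(), collapse = ":")))
    expect_equal(status, 0L)
    expect_identical(readLines(file.path(out3, "mini.txt")),
                     readLines(file.path(out, "mini.txt")))
  }
})
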