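test_that("HCP-style task design fills the session and alternates blocks", {
  d <- generate_task_design()
  expect_s3_class(d, "task_design")
  expect_equal(nrow(d), 6)
  expect_equal(sum(d$condition == "emotion"), 3)
  expect_equal(sum(d$condition == "shape"), 3)
  expect_true(all(d$duration == 21))
  scan_s <- attr(d, "n_volumes") * attr(d, "tr")
  expect_equal(scan_s, 126.72)                      # 2.11 minutes
  expect_lte(max(d$onset + d$duration), scan_s)
  # alternating conditions
  expect_equal(d$condition, rep(c("emotion", "shape"), 3))
})

test_that("task design errors name the overrun; empty designs are flagged", {
  err <- expect_error(generate_task_design(fix_s = 8), "exceeds scan duration")
  expect_match(conditionMessage(err), "39.28 s")    # 166 s laid out vs 126.72 s
  expect_warning(d0 <- generate_task_design(blocks_per_condition = 0),
                 "empty")
  expect_equal(nrow(d0), 0)
  expect_true(isTRUE(attr(d0, "empty")))
})

test_that("condition boxcars respect cue handling", {
  d <- generate_task_design()
  b_merge <- condition_boxcar(d, cue_handling = "merge")
  b_ignore <- condition_boxcar(d, cue_handling = "ignore")
  b_sep <- condition_boxcar(d, cue_handling = "separate")
  expect_equal(colnames(b_merge), c("emotion", "shape"))
  # merging includes the 3 s cue, ignoring drops it
  expect_gt(sum(b_merge[, "emotion"]), sum(b_ignore[, "emotion"]))
  expect_equal(colnames(b_sep), c("emotion", "shape", "cue"))
  expect_equal(sum(b_sep[, "cue"] > 0 & b_sep[, "emotion"] > 0), 0)
})

test_that("synth_config validates its invariants", {
  expect_error(synth_config(module_sizes = c(30, 40)), "sum")
  expect_error(synth_config(within_module_corr = 0.2,
                            between_module_corr = 0.3), "exceed")
  expect_error(synth_config(ar_coefficient = 1.2), "ar_coefficient")
  expect_error(synth_config(ppi_edges = data.frame(
    seed = 1, target = 1, condition = "emotion", gamma = 1)), "self-loops")
  expect_error(synth_config(ppi_edges = data.frame(
    seed = 1, target = 99, condition = "emotion", gamma = 1)), "outside")
})

test_that("generators are deterministic given (config, seed)", {
  cfg <- synth_config(n_nodes = 12, n_modules = 3, module_sizes = rep(4, 3),
                      rest_volumes_per_run = 80, task_volumes_per_session = 60,
                      activation_effects = c(1, 0, 0), seed = 4)
  a <- generate_rest_timeseries(cfg, 77)
  b <- generate_rest_timeseries(cfg, 77)
  expect_identical(a, b)
  truth <- make_ground_truth(cfg)
  des <- generate_task_design(tr = cfg$tr, n_volumes = 60,
                              blocks_per_condition = 1)
  ta <- generate_task_timeseries(cfg, des, truth, 5)
  tb <- generate_task_timeseries(cfg, des, truth, 5)
  expect_identical(ta, tb)
  expect_false(identical(ta, generate_task_timeseries(cfg, des, truth, 6)))
})

test_that("generators leave the caller's RNG stream untouched", {
  cfg <- synth_config(n_nodes = 6, n_modules = 2, module_sizes = c(3, 3),
                      rest_volumes_per_run = 50, seed = 1)
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(generate_rest_timeseries(cfg, 3)); after <- runif(1)
  expect_identical(before, after)
})

test_that("planted within-module correlation is recovered in rest data", {
  # Monte-Carlo over 20 subject seeds at the default acquisition length
  cfg <- synth_config(seed = 10)
  cors <- vapply(1:20, function(i) {
    ts <- generate_rest_timeseries(cfg, 1000 + i)
    cc <- stats::cor(ts$values)
    c(within = mean(cc[1:10, 1:10][upper.tri(cc[1:10, 1:10])]),
      between = mean(cc[1:10, 11:20]))
  }, numeric(2))
  expect_lt(abs(mean(cors["within", ]) - cfg$within_module_corr), 0.05)
  expect_lt(abs(mean(cors["between", ])), 0.05)
})

test_that("non-positive-definite latent covariance is caught before sampling", {
  # strongly negative between-module correlation breaks positive
  # definiteness of the block structure
  cfg <- synth_config(n_nodes = 12, n_modules = 2, module_sizes = c(6, 6),
                      within_module_corr = 0.1,
                      between_module_corr = -0.3)
  expect_error(generate_rest_timeseries(cfg, 1), "positive definite")
})

test_that("task generator emits a nuisance table and responds to activation", {
  cfg <- synth_config(n_nodes = 12, n_modules = 3, module_sizes = rep(4, 3),
                      task_volumes_per_session = 176, n_sessions = 1,
                      activation_effects = c(3, 0, 0), seed = 8)
  truth <- make_ground_truth(cfg)
  des <- generate_task_design()
  scan <- generate_task_timeseries(cfg, des, truth, 11)
  expect_equal(dim(scan$nuisance), c(176, 6))
  box <- condition_boxcar(des, 176)
  conv <- convolve_hrf(box[, "emotion"], cfg$hrf, cfg$tr)
  # activated module tracks the convolved emotion regressor, silent one less
  act_cor <- mean(abs(cor(conv, scan$ts$values[, 1:4])))
  silent_cor <- mean(abs(cor(conv, scan$ts$values[, 5:12])))
  expect_gt(act_cor, silent_cor + 0.2)
})
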