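test_that("training config defaults carry the optimized hyperparameters", {
  cfg <- train_config()
  expect_equal(cfg$epochs, 400L)
  expect_equal(cfg$lr, 0.00164)
  expect_equal(cfg$lr_decay, 0.27291)
  expect_equal(cfg$lr_step, 75L)
  expect_equal(cfg$momentum, 0.957437)
  expect_equal(cfg$batch_size, 9L)
})

test_that("oversampling weights equalize expected region frequencies", {
  regions <- c(rep("knee", 300), rep("calcaneus", 100))
  w <- oversample_weights(regions)
  expect_equal(sum(w), 1)
  expect_equal(sum(w[regions == "knee"]), 0.5, tolerance = 1e-12)
  expect_equal(oversample_weights(c("a", "a", "b", "b")),
               rep(0.25, 4))
  set.seed(801)
  draws <- make_sampler(regions, 4000)
  expect_equal(mean(regions[draws] == "knee"), 0.5, tolerance = 0.05)
  # single region: every draw lands there
  expect_true(all(make_sampler(rep("ankle", 7), 100) %in% 1:7))
})

test_that("one training epoch with zero learning rate leaves weights unchanged", {
  set.seed(802)
  spec <- phantom_spec(shape = 16, spacing = 10, noise_sd = 0)
  ds <- generate_dataset(4, spec, rot_deg = 15, trans_mm = 5, folds = 2)
  sp <- model_spec(input_shape = c(8, 8, 8), channels = c(2, 3),
                   head_hidden = 4, codec = rotation_codec("quaternion"),
                   mode = "baseline", regions = "ankle")
  set.seed(803)
  m <- build_model(sp)
  cfg <- train_config(epochs = 1, lr = 0, batch_size = 2, augment = FALSE,
                      seed = 804)
  out <- train_model(m, ds$samples, cfg)
  expect_equal(out$model$trunk[[1]]$W, m$trunk[[1]]$W)
  expect_equal(out$model$heads[[1]][[2]]$W, m$heads[[1]][[2]]$W)
  expect_equal(nrow(out$log), 1)
})

test_that("training is deterministic under a fixed seed and logs decreasing loss", {
  set.seed(805)
  spec <- phantom_spec(shape = 16, spacing = 10, noise_sd = 0)
  ds <- generate_dataset(6, spec, rot_deg = 20, trans_mm = 5, folds = 2)
  sp <- model_spec(input_shape = c(16, 16, 16), channels = c(2, 4),
                   head_hidden = 8, codec = rotation_codec("six_d_xy"),
                   mode = "baseline", regions = "ankle")
  run <- function() {
    set.seed(806)
    m <- build_model(sp)
    train_model(m, ds$samples,
                train_config(epochs = 5, lr = 0.003, batch_size = 3,
                             augment = TRUE, seed = 807))
  }
  a <- run(); b <- run()
  expect_identical(a$log$loss, b$log$loss)
  expect_identical(a$model$trunk[[1]]$W, b$model$trunk[[1]]$W)
  expect_lt(tail(a$log$loss, 1), a$log$loss[1])
})

test_that("learning-rate schedule decays by the configured factor at the step", {
  set.seed(808)
  spec <- phantom_spec(shape = 8, spacing = 20, noise_sd = 0)
  ds <- generate_dataset(2, spec, rot_deg = 5, trans_mm = 2, folds = 2)
  sp <- model_spec(input_shape = c(8, 8, 8), channels = c(2, 2),
                   head_hidden = 4, codec = rotation_codec("quaternion"),
                   mode = "baseline", regions = "ankle")
  m <- build_model(sp)
  out <- train_model(m, ds$samples,
                     train_config(epochs = 5, lr = 0.01, lr_decay = 0.5,
                                  lr_step = 2, batch_size = 2,
                                  augment = FALSE, seed = 809))
  expect_equal(out$log$lr, 0.01 * c(1, 1, 0.5, 0.5, 0.25))
  out2 <- train_model(m, ds$samples,
                      train_config(epochs = 3, lr = 0.01, lr_decay = 0.5,
                                   lr_step = 10, batch_size = 2,
                                   augment = FALSE, warmup_epochs = 1,
                                   warmup_factor = 0.1, seed = 809))
  expect_equal(out2$log$lr, c(0.001, 0.01, 0.01))
})

test_that("resumed training follows the same schedule and restart screening selects by loss", {
  set.seed(812)
  spec <- phantom_spec(shape = 8, spacing = 20, noise_sd = 0)
  ds <- generate_dataset(4, spec, rot_deg = 10, trans_mm = 3, folds = 2)
  sp <- model_spec(input_shape = c(8, 8, 8), channels = c(2, 2),
                   head_hidden = 4, codec = rotation_codec("quaternion"),
                   mode = "baseline", regions = "ankle")
  cfg <- train_config(epochs = 4, lr = 0.01, lr_decay = 0.5, lr_step = 2,
                      batch_size = 2, augment = FALSE, seed = 813)
  set.seed(814)
  m <- build_model(sp)
  # resume: epochs 1-2 then 3-4 follows the decayed schedule
  r1 <- train_model(m, ds$samples, cfg)
  r2a <- train_model(m, ds$samples, cfg, start_epoch = 3L)
  expect_equal(r1$log$lr, 0.01 * c(1, 1, 0.5, 0.5))
  expect_equal(r2a$log$lr, 0.01 * c(0.5, 0.5))
  out <- train_with_restarts(sp, ds$samples, cfg, n_starts = 2,
                             screen_epochs = 2, screen_loss = Inf,
                             seed = 815)
  expect_equal(nrow(out$starts), 1)       # first start passes an Inf cutoff
  expect_true(out$starts$continued[1])
  expect_equal(nrow(out$log), 4)          # screened 2 + continued 2 epochs
  out2 <- train_with_restarts(sp, ds$samples, cfg, n_starts = 2,
                              screen_epochs = 2, screen_loss = 0,
                              seed = 815)
  expect_equal(nrow(out2$starts), 2)      # nobody passes a zero cutoff
  expect_false(any(out2$starts$continued))
  expect_s3_class(out2$model, "mpr_model")
})

test_that("evaluation pipeline produces scored reports with and without postprocessing", {
  set.seed(810)
  spec <- phantom_spec(shape = 16, spacing = 10, noise_sd = 0)
  ds <- generate_dataset(3, spec, rot_deg = 10, trans_mm = 5, folds = 3)
  sp <- model_spec(input_shape = c(8, 8, 8), channels = c(2, 3),
                   head_hidden = 8, codec = rotation_codec("six_d_xy"),
                   mode = "baseline", regions = "ankle")
  m <- build_model(sp)
  # brief training so the head output is away from the degenerate origin
  m <- train_model(m, ds$samples,
                   train_config(epochs = 2, lr = 0.002, batch_size = 3,
                                augment = FALSE, seed = 811))$model
  raw <- evaluate_model(m, ds$samples, postprocess = FALSE)
  pp <- evaluate_model(m, ds$samples, postprocess = TRUE)
  expect_length(raw, 3)
  for (r in c(raw, pp)) {
    expect_s3_class(r, "plane_error_report")
    expect_true(all(r$d_mm >= 0))
    expect_true(all(r$eps_n_deg >= 0 & r$eps_n_deg <= 180))
  }
  agg <- aggregate_folds(raw, vapply(ds$samples, `[[`, numeric(1), "fold"))
  expect_setequal(agg$metric, c("d_mm", "eps_n_deg", "eps_i_deg", "score"))
})
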