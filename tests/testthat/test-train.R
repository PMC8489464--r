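test_that("patient-wise splitting partitions patients 90/10 with no leakage", {
  ids <- rep(sprintf("P%03d", 1:100), each = 3)   # 3 images per patient
  sp <- split_by_patient(ids, 0.10, seed = 42)
  expect_length(sp$val_patients, 10)
  expect_length(sp$train_patients, 90)
  expect_length(intersect(sp$train_patients, sp$val_patients), 0)
  expect_length(intersect(ids[sp$train], ids[sp$val]), 0)
  expect_equal(sort(c(sp$train, sp$val)), seq_along(ids))

  sp2 <- split_by_patient(ids, 0.10, seed = 42)
  expect_identical(sp, sp2)
  expect_error(split_by_patient("P1", 0.1), "at least 2")
})

test_that("multitask batching visits every pooled sample exactly once per epoch", {
  set.seed(50)
  vd <- list(CH2 = as.list(1:100), CH3 = as.list(101:200),
             CH4 = as.list(201:300))
  mb <- multitask_batches(vd, batch_size = 10)
  expect_length(mb$batches, 30)
  expect_equal(sort(unname(unlist(mb$batches))), 1:300)
  expect_equal(as.integer(table(mb$view)), rep(100L, 3))
  expect_error(multitask_batches(vd, 0), "batch_size")

  # view mixture across many batches follows pool proportions
  frac <- mean(vapply(mb$batches, function(b)
    mean(mb$view[b] == "CH2"), numeric(1)))
  expect_lt(abs(frac - 1 / 3), 0.05)
})

test_that("a short fit reduces the validation loss and keeps the LR schedule lawful", {
  set.seed(51)
  samples <- tiny_samples(24, seed = 3)
  prepped <- prepare_samples(samples, sigma = 3)
  net <- build_unet(tiny_model())
  cfg <- train_config(n_epochs = 6, batch_size = 4, seed = 5,
                      plateau_patience = 2)
  fitted <- fit_unet(net, prepped[1:20], prepped[21:24], cfg)
  h <- fitted$history
  expect_equal(nrow(h), 6)
  expect_lt(h$val_loss[attr(h, "best_epoch")], h$val_loss[1])
  expect_equal(attr(h, "best_epoch"), which.min(h$val_loss))
  # LR never increases, and every change divides by exactly the factor
  expect_true(all(diff(h$lr) <= 0))
  changes <- h$lr[-1][diff(h$lr) != 0]
  prevs <- h$lr[-nrow(h)][diff(h$lr) != 0]
  if (length(changes)) expect_equal(prevs / changes, rep(2, length(changes)))
  expect_error(fit_unet(net, list(), prepped[21:24], cfg), "empty")
})

test_that("fitting is reproducible from the master seed", {
  samples <- tiny_samples(12, seed = 9)
  prepped <- prepare_samples(samples, sigma = 3)
  cfg <- train_config(n_epochs = 2, batch_size = 4, seed = 11)
  run <- function() {
    set.seed(cfg$seed + 1)
    net <- build_unet(tiny_model())
    fit_unet(net, prepped[1:10], prepped[11:12], cfg)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$net$weights, b$net$weights)
})

test_that("fine-tuning starts from the pretrained weights and respects a zero epoch budget", {
  samples <- tiny_samples(12, seed = 13)
  prepped <- prepare_samples(samples, sigma = 3)
  set.seed(1)
  net <- build_unet(tiny_model())
  cfg <- train_config(fine_tune_epochs = 0)
  same <- fine_tune_unet(net, prepped[1:10], prepped[11:12], cfg)
  expect_identical(same$net$weights, net$weights)
  expect_equal(nrow(same$history), 0)

  cfg2 <- train_config(fine_tune_epochs = 2, fine_tune_lr = 5e-4,
                       batch_size = 4, seed = 2)
  ft <- fine_tune_unet(net, prepped[1:10], prepped[11:12], cfg2)
  expect_equal(nrow(ft$history), 2)
  expect_equal(ft$history$lr[1], 5e-4)
})

test_that("the detector surface trains, predicts and reports", {
  samples <- tiny_samples(20, seed = 17)
  det <- landmark_detector(samples, sigma = 3, model = tiny_model(),
                           train = train_config(n_epochs = 4,
                                                batch_size = 4, seed = 19))
  expect_s3_class(det, "landmark_detector")
  expect_output(print(det), "landmark detector")
  sm <- summary(det)
  expect_equal(sm$epochs, 4)

  pred <- predict(det, samples[[1]])
  expect_s3_class(pred, "detection_result")
  probs <- predict(det, samples[[1]], type = "probs")
  expect_equal(dim(probs), c(32, 32, 4))
  expect_lt(max(abs(apply(probs, c(1, 2), sum) - 1)), 1e-5)

  sal <- saliency_map(det, samples[[1]])
  expect_equal(dim(sal), c(32, 32))
  expect_true(all(is.finite(sal)))

  ev <- evaluate_detector(det, tiny_samples(6, seed = 23))
  expect_s3_class(ev, "eval_report")
  expect_gte(ev$detection_rate, 0)
  expect_lte(ev$detection_rate, 100)
})
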