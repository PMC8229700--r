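test_that("the network spec mirrors the published architecture", {
  spec <- build_small_cnn(100)
  expect_equal(nrow(spec), 27)
  expect_equal(sum(spec$kind == "addition"), 3)
  # stem: 32 filters of 7x7, stride 1, padding 3
  stem <- spec[spec$index == 2, ]
  expect_equal(stem$n_filters, 32)
  expect_equal(stem$filter_size, 7)
  expect_equal(stem$stride, 1)
  expect_equal(stem$padding, 3)
  # classifier head width follows num_classes
  expect_equal(spec$n_filters[spec$index == 25], 100)
  expect_equal(build_small_cnn(7)$n_filters[25], 7)
  expect_error(build_small_cnn(1), ">= 2")
})

test_that("parameter count matches the layer-wise hand count", {
  # independent per-layer arithmetic: conv k^2*cin*cout + cout, bn 2c,
  # fc 128*classes + classes
  conv <- function(k, cin, cout) k^2 * cin * cout + cout
  hand <- conv(7, 3, 32) + 2 * 32 +                         # stem + bn5
    conv(3, 32, 32) * 2 + 2 * 32 +                          # stage 1 + bn8
    conv(3, 32, 64) + conv(3, 64, 64) + 2 * 64 +            # stage 2 main
    conv(1, 32, 64) + 2 * 64 +                              # projection + bn17
    conv(3, 64, 128) + conv(3, 128, 128) + 2 * 128 +        # stage 3 main
    conv(1, 64, 128) +                                      # projection
    128 * 100 + 100                                         # fc
  expect_equal(hand, 324068)
  expect_equal(count_parameters(build_small_cnn(100)), 324068)
  # 324 K to the nearest thousand
  expect_equal(round(count_parameters(build_small_cnn(100)) / 1000), 324)
  # the count is input-size invariant (no spatial parameters)
  expect_equal(count_parameters(build_small_cnn(100, input_size = 32)), 324068)
})

test_that("training rejects degenerate label sets", {
  imgs <- toy_images(n_per_class = 4, classes = 2)
  single <- imgs[imgs$subject_id == "C1", ]
  cfg <- train_config(batch_size = 4, epochs = 1, seed = 1)
  expect_error(train_small_cnn(single, cfg), "2 classes")
  expect_error(train_small_cnn(imgs, cfg, classes = c("C1", "C2", "C9")),
               "C9")
})

test_that("training is deterministic given the seed and loss decreases", {
  imgs <- toy_images(n_per_class = 10, classes = 3, seed = 2)
  cfg <- train_config(batch_size = 10, epochs = 6, learning_rate = 0.01,
                      seed = 42)
  f1 <- train_small_cnn(imgs, cfg)
  f2 <- train_small_cnn(imgs, cfg)
  expect_identical(f1$log$loss, f2$log$loss)
  # smoothed training loss trends down on this separable toy task
  expect_lt(mean(tail(f1$log$loss, 2)), mean(head(f1$log$loss, 2)))
  expect_gt(f1$log$accuracy[nrow(f1$log)], 0.9)
})

test_that("prediction returns proper probabilities and is deterministic", {
  imgs <- toy_images(n_per_class = 8, classes = 2, seed = 3)
  cfg <- train_config(batch_size = 8, epochs = 4, learning_rate = 0.01,
                      seed = 7)
  fit <- train_small_cnn(imgs, cfg)
  pr <- predict(fit, imgs)
  expect_equal(nrow(pr), nrow(imgs))
  sums <- vapply(pr$probs, sum, numeric(1))
  expect_true(all(abs(sums - 1) < 1e-6))
  # identical inputs give identical outputs
  two <- imgs[c(1, 1), ]
  pr2 <- predict(fit, two)
  expect_identical(pr2$probs[[1]], pr2$probs[[2]])
  # training-set accuracy of a converged toy fit is high
  expect_gt(mean(pr$pred == imgs$subject_id), 0.9)
  # shape mismatch is rejected
  bad <- tibble::tibble(subject_id = "C1",
                        image = list(array(0, c(16, 16, 3))))
  expect_error(predict(fit, bad), "size")
})

test_that("tidy and glance summarize a fit", {
  imgs <- toy_images(n_per_class = 4, classes = 2, seed = 5)
  fit <- train_small_cnn(imgs, train_config(batch_size = 4, epochs = 2, seed = 1))
  expect_equal(nrow(tidy(fit)), 2)
  gl <- glance(fit)
  expect_equal(gl$n_layers, 27)
  expect_equal(gl$n_parameters, count_parameters(fit$spec))
  expect_equal(gl$n_classes, 2)
})
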