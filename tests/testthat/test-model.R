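test_that("receptive-field inequality is enforced at construction", {
  # kernel 7, base 2: 4 blocks give R = 1 + 2*6*(1+2+4+8) = 181 < 350
  tc4 <- tcn_config(n_blocks = 4, channels = 8, kernel_size = 7,
                    dilation_base = 2)
  expect_equal(receptive_field(tc4), 181)
  expect_error(build_model(model_spec(tcn = tc4), input_length = 350),
               "receptive field 181")
  # 5 blocks give R = 373 >= 350
  tc5 <- tcn_config(n_blocks = 5, channels = 8, kernel_size = 7,
                    dilation_base = 2)
  expect_equal(receptive_field(tc5), 373)
  expect_s3_class(build_model(model_spec(tcn = tc5), input_length = 350),
                  "lvm_tcn")
  # the shipped default configuration covers the default beat window
  expect_gte(receptive_field(tcn_config()), 350)
})

test_that("one encoder is instantiated per lead group", {
  m2 <- build_model(tiny_spec(), input_length = 30)
  expect_length(m2$params$groups, 2)
  spec4 <- model_spec(grouping = lead_grouping("anatomical"),
                      tcn = tiny_tcn(),
                      scalar_branches = list(demographics = c(5),
                                             ecg_params = c(5)),
                      projection_dim = 8, regressor_hidden = c(8))
  m4 <- build_model(spec4, input_length = 30)
  expect_length(m4$params$groups, 4)
  expect_named(m4$params$groups, c("LAD", "LCx", "RCA", "LM"))
  # group lead order is fixed by the builder, not by input order
  expect_equal(m4$group_sizes, c(LAD = 4L, LCx = 4L, RCA = 3L, LM = 1L))
})

test_that("MAE loss matches hand arithmetic", {
  expect_equal(mae_loss(c(110, 90), c(100, 100)), 10)
  expect_equal(mae_loss(c(50, 60), c(50, 60)), 0)
  expect_equal(mae_loss(95, 100), 5)
  expect_error(mae_loss(numeric(0), numeric(0)), "non-empty")
  expect_error(mae_loss(1:3, 1:2), "equal length")
})

test_that("evaluation-mode predictions are deterministic and batch-invariant", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 2)
  b1 <- tiny_batch(W = 30, B = 1, seed = 5)
  p_once <- predict_lvm(m, b1)
  p_again <- predict_lvm(m, b1)
  expect_identical(p_once, p_again)

  b8 <- tiny_batch(W = 30, B = 8, seed = 6)
  # splice the single sample into position 3 of the batch of 8
  for (g in 1:2) b8$groups[[g]][61:90, ] <- b1$groups[[g]]
  b8$demographics[3, ] <- b1$demographics
  b8$ecg_params[3, ] <- b1$ecg_params
  p8 <- predict_lvm(m, b8)
  expect_equal(p8[3], p_once, tolerance = 1e-10)
})

test_that("a zeroed output layer forces a constant prediction", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 2)
  nl <- length(m$params$reg)
  m$params$reg[[nl]]$w[] <- 0
  m$params$reg[[nl]]$b <- 123.4
  preds <- predict_lvm(m, tiny_batch(W = 30, B = 4, seed = 8))
  expect_equal(preds, rep(123.4, 4))
})

test_that("batch shape and grouping mismatches are rejected informatively", {
  m <- build_model(tiny_spec(), input_length = 30)
  b <- tiny_batch(W = 30)
  b_bad <- b; b_bad$groups <- b$groups[1]
  expect_error(predict_lvm(m, b_bad), "expected 2 group")
  b_bad2 <- b; b_bad2$groups[[2]] <- b$groups[[2]][, 1:5]
  expect_error(predict_lvm(m, b_bad2), "expected 6 leads, got 5")
  b_bad3 <- b; b_bad3$demographics <- NULL
  expect_error(predict_lvm(m, b_bad3), "requires the demographics")
  b_bad4 <- b; b_bad4$ecg_params[1, 2] <- NA
  expect_error(predict_lvm(m, b_bad4), "impute")
})

test_that("scalar encoding standardizes with stored statistics", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 2)
  # zero weights -> zero embedding regardless of input
  mz <- m
  mz$params$branch$demographics[[1]]$w[] <- 0
  mz$params$branch$demographics[[1]]$b[] <- 0
  expect_equal(encode_scalars(mz, c(1, 2, 3, 4), "demographics"),
               rep(0, 5))

  # (12 - 10) / 2 = 1 standardized unit feeds the branch
  m$scalers <- list(demographics = list(mean = rep(10, 4), sd = rep(2, 4)))
  e12 <- encode_scalars(m, rep(12, 4), "demographics")
  m$scalers <- NULL
  e1 <- encode_scalars(m, rep(1, 4), "demographics")
  expect_equal(e12, e1)

  expect_error(encode_scalars(m, c(1, NA, 3, 4), "demographics"), "impute")
  m_ecg <- build_model(tiny_spec("ecg_only"), input_length = 30)
  expect_error(encode_scalars(m_ecg, 1:4, "demographics"), "no")
})

test_that("gradients flow from output to waveform input", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 4)
  b <- tiny_batch(W = 30, seed = 10)
  fw <- ecglvm:::model_forward(m, b, keep_cache = TRUE)
  bw <- ecglvm:::model_backward(m, b, fw$cache, dpred = 1,
                                input_grad = TRUE)
  expect_gt(sum(abs(bw$d_inputs[[1]])), 0)
  expect_gt(sum(abs(bw$d_inputs[[2]])), 0)
})

test_that("checkpoints round-trip weights, spec and scalers", {
  m <- build_model(tiny_spec(), input_length = 30, seed = 6)
  m$scalers <- list(
    demographics = list(mean = c(a = 1, b = 2, c = 3, d = 4),
                        sd = c(a = 1, b = 1, c = 2, d = 2)),
    ecg_params = list(mean = rep(0, 4), sd = rep(1, 4)))
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  b <- tiny_batch(W = 30, B = 3, seed = 11)
  expect_equal(predict_lvm(m2, b), predict_lvm(m, b), tolerance = 1e-12)
  expect_equal(m2$spec$input_set, m$spec$input_set)
})
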