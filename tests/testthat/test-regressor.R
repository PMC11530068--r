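tiny_cfg <- function(epochs = 5, seed = 1L, lr = 3e-3,
                     aug = list(rotation_degrees = 0,
                                horizontal_flip = FALSE,
                                vertical_flip = FALSE)) {
  model_config(backbone = "tiny_cnn", input_size = c(24, 24, 3),
               lr_schedule = list(list(epochs = 1:epochs, rate = lr)),
               batch_size = 4, epochs = epochs, augmentation = aug,
               seed = seed)
}

rand_record <- function(seed, label = "PARENTAL", size = 24) {
  set.seed(seed)
  image_record(array(runif(size * size * 3), c(size, size, 3)),
               assign_soft_label(label), label)
}

test_that("untrained models output valid softmax probabilities", {
  model <- build_model(tiny_cfg())
  recs <- lapply(1:4, rand_record)
  p <- predict_soft(model, recs)
  expect_equal(dim(p), c(4L, 3L))
  expect_true(all(p > 0 & p < 1))
  expect_equal(unname(rowSums(p)), rep(1, 4), tolerance = 1e-9)
})

test_that("model initialization is seeded and parameter count is bounded", {
  a <- build_model(tiny_cfg(seed = 11))
  b <- build_model(tiny_cfg(seed = 11))
  expect_identical(a$net, b$net)
  c <- build_model(tiny_cfg(seed = 12))
  expect_false(identical(a$net, c$net))
  big <- build_model(model_config(input_size = c(32, 32, 3)))
  expect_lt(n_parameters(big), 1e5)
  expect_error(build_model(model_config(backbone = "paper_backbone")),
               "EfficientNet-B3")
  expect_error(build_model(model_config(input_size = c(8, 8, 3))),
               "too small")
})

test_that("augmentation spans the dihedral group correctly", {
  img <- array(stats::runif(16 * 16 * 3), c(16, 16, 3))
  off <- list(rotation_degrees = 0, horizontal_flip = FALSE,
              vertical_flip = FALSE)
  expect_identical(augment(img, off), img)
  hf <- mixshape:::dihedral_transform(img, 0, TRUE, FALSE)
  expect_identical(mixshape:::dihedral_transform(hf, 0, TRUE, FALSE), img)
  r4 <- img
  for (i in 1:4) r4 <- mixshape:::dihedral_transform(r4, 1)
  expect_identical(r4, img)
  expect_error(augment(array(0, c(2, 3, 3)),
                       list(rotation_degrees = 90)), "square")
})

test_that("augmentation draws are uniform over the 8 dihedral outcomes", {
  # tag each of the 8 group elements by where it sends two probe pixels
  probe <- array(0, c(8, 8, 1))
  probe[1, 2, 1] <- 1; probe[3, 1, 1] <- 2
  canon <- list()
  for (k in 0:3) for (hf in 0:1) {
    out <- mixshape:::dihedral_transform(probe, k, hf == 1, FALSE)
    canon[[paste(which(out == 1), which(out == 2))]] <- TRUE
  }
  expect_length(canon, 8)
  spec <- list(rotation_degrees = 90, horizontal_flip = TRUE,
               vertical_flip = TRUE)
  set.seed(31)
  counts <- new.env()
  for (i in 1:8000) {
    out <- augment(probe, spec)
    key <- paste(which(out == 1), which(out == 2))
    counts[[key]] <- (counts[[key]] %||% 0) + 1
  }
  ks <- ls(counts)
  expect_length(ks, 8)
  n <- vapply(ks, function(k) counts[[k]], numeric(1))
  se <- sqrt(8000 * (1 / 8) * (7 / 8))
  expect_true(all(abs(n - 1000) < 3 * se + 1))
})

test_that("training drives loss down on a separable two-image fixture", {
  rec1 <- rand_record(1, "PARENTAL")
  rec2 <- rand_record(2, "RESISTANT")
  model <- build_model(tiny_cfg(epochs = 50, seed = 3, lr = 5e-3))
  fit <- train_fold(model, list(rec1, rec2))
  expect_lt(tail(fit$log$train_loss, 1), 0.01)
  p <- predict_soft(fit, list(rec1, rec2))
  expect_equal(max.col(p), c(1, 2))
  expect_true(fit$trained)
})

test_that("constant targets give monotone non-increasing training loss", {
  recs <- lapply(1:6, rand_record, label = "PARENTAL")
  model <- build_model(tiny_cfg(epochs = 15, seed = 5, lr = 1e-3))
  fit <- train_fold(model, recs)
  d <- diff(fit$log$train_loss)
  expect_true(all(d < 1e-4))
  p <- predict_soft(fit, recs)
  expect_true(all(p[, 1] > 0.8))
  # MSE on the simplex is bounded by 2
  expect_true(all(fit$log$train_loss >= 0 & fit$log$train_loss <= 2))
})

test_that("training is deterministic and logs the learning-rate schedule", {
  recs <- lapply(1:8, function(i)
    rand_record(i, c("PARENTAL", "RESISTANT")[1 + i %% 2]))
  cfg <- model_config(backbone = "tiny_cnn", input_size = c(24, 24, 3),
                      lr_schedule = list(list(epochs = 1:2, rate = 7e-5),
                                         list(epochs = 3:4, rate = 3e-5)),
                      batch_size = 4, epochs = 4, seed = 21)
  f1 <- train_fold(build_model(cfg), recs, recs[1:2], fold_id = 1)
  f2 <- train_fold(build_model(cfg), recs, recs[1:2], fold_id = 1)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$net, f2$net)
  expect_equal(f1$log$lr, c(7e-5, 7e-5, 3e-5, 3e-5))
  expect_true(all(is.finite(f1$log$val_loss)))
  expect_error(train_fold(build_model(cfg), list()), "empty")
})

test_that("prediction is order-preserving, duplicate-consistent and stable", {
  recs <- lapply(1:5, rand_record)
  model <- build_model(tiny_cfg(seed = 2))
  p <- predict_soft(model, recs)
  pdup <- predict_soft(model, c(recs, recs[1]))
  expect_equal(pdup[6, ], p[1, ])
  expect_equal(pdup[1:5, ], p)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  expect_identical(predict_soft(back, recs), p)
})

test_that("grad_cam returns a normalized input-sized heatmap", {
  model <- build_model(tiny_cfg(seed = 4))
  rec <- rand_record(9)
  cam <- grad_cam(model, rec, "PARENTAL")
  expect_identical(dim(cam), c(24L, 24L))
  expect_true(all(cam >= 0 & cam <= 1))
  # a head with zero weights makes every logit input-independent
  frozen <- model
  nl <- length(frozen$net$layers)
  frozen$net$layers[[nl]]$W[] <- 0
  frozen$net$layers[[nl]]$b[] <- 0
  cam0 <- grad_cam(frozen, rec, 1)
  expect_true(all(cam0 == 0))
})

test_that("an overfit model localizes a discriminative blob", {
  box <- list(rows = 9:24, cols = 9:24)
  blob_record <- function(seed, with_blob) {
    set.seed(seed)
    img <- array(runif(32 * 32 * 3, 0, 0.08), c(32, 32, 3))
    if (with_blob) img[box$rows, box$cols, ] <-
      img[box$rows, box$cols, ] + 0.85
    image_record(array(pmin(img, 1), dim(img)),
                 assign_soft_label(if (with_blob) "PARENTAL" else "RESISTANT"),
                 if (with_blob) "PARENTAL" else "RESISTANT")
  }
  train <- c(lapply(1:8, blob_record, with_blob = TRUE),
             lapply(9:16, blob_record, with_blob = FALSE))
  cfg <- model_config(backbone = "tiny_cnn", input_size = c(32, 32, 3),
                      lr_schedule = list(list(epochs = 1:40, rate = 5e-3)),
                      batch_size = 4, epochs = 40,
                      augmentation = list(rotation_degrees = 0,
                                          horizontal_flip = FALSE,
                                          vertical_flip = FALSE),
                      seed = 6)
  fit <- train_fold(build_model(cfg), train)
  expect_lt(tail(fit$log$train_loss, 1), 0.05)
  cam <- grad_cam(fit, train[[1]], "PARENTAL")
  peak <- which(cam == max(cam), arr.ind = TRUE)[1, ]
  expect_true(peak[1] >= min(box$rows) && peak[1] <= max(box$rows))
  expect_true(peak[2] >= min(box$cols) && peak[2] <= max(box$cols))
})
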