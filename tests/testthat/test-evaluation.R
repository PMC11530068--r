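one_hot <- function(k, n = 3) { v <- numeric(n); v[k] <- 1; v }

test_that("confusion matrices follow argmax with the class-order tie-break", {
  true <- rbind(one_hot(1), one_hot(2), one_hot(3))
  perfect <- true
  cm <- confusion(true, perfect)
  expect_equal(unname(diag(cm)), c(1L, 1L, 1L))
  expect_equal(sum(cm), 3)

  all_p <- matrix(rep(c(0.9, 0.05, 0.05), 3), 3, byrow = TRUE)
  cm2 <- confusion(true, all_p)
  expect_equal(unname(colSums(cm2)), c(3L, 0L, 0L))

  tie <- matrix(rep(1 / 3, 3), 1)
  cm3 <- confusion(matrix(one_hot(2), 1), tie)
  expect_equal(cm3["RESISTANT", "PARENTAL"], 1L)   # tie -> PARENTAL

  expect_error(confusion(true[0, , drop = FALSE],
                         perfect[0, , drop = FALSE]), "no records")
})

# independent definition-level oracle for the macro metrics; classes
# with no true instances are excluded from macro sensitivity and F1
oracle_macro <- function(cm) {
  sens <- prec <- f1 <- numeric(3)
  for (k in 1:3) {
    tp <- cm[k, k]; fn <- sum(cm[k, -k]); fp <- sum(cm[-k, k])
    sens[k] <- if (tp + fn > 0) tp / (tp + fn) else NA
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    f1[k] <- if (is.na(sens[k])) NA
      else if (sens[k] + prec[k] > 0)
        2 * sens[k] * prec[k] / (sens[k] + prec[k]) else 0
  }
  list(acc = sum(diag(cm)) / sum(cm) * 100,
       sens = mean(sens, na.rm = TRUE) * 100,
       prec = mean(prec) * 100, f1 = mean(f1, na.rm = TRUE) * 100)
}

test_that("macro metrics equal hand computation on a worked example", {
  cm <- matrix(c(5, 0, 0, 0, 4, 1, 0, 2, 3), 3, byrow = TRUE,
               dimnames = list(true = c("PARENTAL", "RESISTANT", "CONTROL"),
                               pred = c("PARENTAL", "RESISTANT", "CONTROL")))
  got <- macro_metrics(cm)
  ref <- oracle_macro(cm)
  expect_equal(got$accuracy, ref$acc)
  expect_equal(got$macro_sensitivity, ref$sens)
  expect_equal(got$macro_precision, ref$prec)
  expect_equal(got$macro_f1, ref$f1)
  # balanced truth (equal row sums): accuracy equals macro sensitivity
  expect_equal(got$accuracy, got$macro_sensitivity)
  perfect <- diag(c(5L, 5L, 5L)); dimnames(perfect) <- dimnames(cm)
  mm <- macro_metrics(perfect)
  expect_equal(mm$accuracy, 100)
  expect_equal(mm$macro_f1, 100)
})

test_that("macro metrics match the oracle on 100 random confusion matrices", {
  set.seed(99)
  for (i in 1:100) {
    cm <- matrix(rpois(9, sample(1:20, 1)), 3)
    if (sum(cm) == 0) cm[1, 1] <- 1
    dimnames(cm) <- list(true = c("PARENTAL", "RESISTANT", "CONTROL"),
                         pred = c("PARENTAL", "RESISTANT", "CONTROL"))
    got <- suppressWarnings(macro_metrics(cm))
    ref <- oracle_macro(cm)
    expect_equal(got$accuracy, ref$acc)
    expect_equal(got$macro_sensitivity, ref$sens)
    expect_equal(got$macro_precision, ref$prec)
    expect_equal(got$macro_f1, ref$f1)
  }
})

test_that("macro AUC is null-centered and cross-checks against pROC", {
  set.seed(5)
  n <- 3000
  true <- t(vapply(sample(1:3, n, TRUE), one_hot, numeric(3)))
  raw <- matrix(runif(n * 3), n)
  pred <- raw / rowSums(raw)
  cm <- confusion(true, pred)
  mm <- macro_metrics(cm, pred, true)
  se <- 100 * sqrt(1 / 12) / sqrt(n)   # rough scale for a rank statistic
  expect_lt(abs(mm$macro_auc - 50), 3 * 2.5)   # within a few points of 50

  skip_if_not_installed("pROC")
  for (k in 1:3) {
    ours <- mixshape:::auc_rank(true[, k] > 0.5, pred[, k])
    ref <- as.numeric(pROC::auc(pROC::roc(true[, k], pred[, k],
                                          quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("AUC errors when the truth contains a single class", {
  true <- t(vapply(rep(1, 5), one_hot, numeric(3)))
  pred <- matrix(1 / 3, 5, 3)
  cm <- confusion(true, pred)
  expect_error(suppressWarnings(macro_metrics(cm, pred, true)),
               "single class")
})

test_that("soft-label RMSE matches hand-evaluated values", {
  y <- rbind(c(1, 0, 0))
  expect_equal(rmse_soft(y, y), 0)
  expect_equal(rmse_soft(rbind(c(1, 0, 0)), rbind(c(0, 1, 0))), 1)
  # N = 2 with squared errors 0.02 and 0.06 -> sqrt(0.08 / 4)
  t2 <- rbind(c(0.5, 0.5, 0), c(0.5, 0.5, 0))
  p2 <- rbind(c(0.6, 0.4, 0), c(0.5 + sqrt(0.03), 0.5 - sqrt(0.03), 0))
  expect_equal(rmse_soft(t2, p2), sqrt(0.08 / 4), tolerance = 1e-12)
  expect_error(rmse_soft(t2, p2[1, , drop = FALSE]), "same number")
})

test_that("RMSE is permutation-invariant and monotone in error", {
  set.seed(2)
  true <- matrix(runif(30), 10, 3); true <- true / rowSums(true)
  pred <- matrix(runif(30), 10, 3); pred <- pred / rowSums(pred)
  o <- sample(10)
  expect_equal(rmse_soft(true, pred), rmse_soft(true[o, ], pred[o, ]))
  worse <- true + 2 * (pred - true)
  expect_gt(rmse_soft(true, worse), rmse_soft(true, pred))
})

test_that("dominant-class accuracy uses strict inequality per ratio", {
  pred <- rbind(c(0.2, 0.7, 0.1))
  expect_equal(unname(dominant_accuracy("1:2", pred)), 100)
  expect_equal(unname(dominant_accuracy("2:1", pred)), 0)
  tiepred <- rbind(c(0.5, 0.5, 0))
  expect_equal(unname(dominant_accuracy("1:3", tiepred)), 0)  # tie fails
  # truth is self-consistent on all four ratio sets
  tags <- c("1:2", "2:1", "1:3", "3:1")
  truth <- t(vapply(tags, function(t) as.numeric(assign_soft_label(t)),
                    numeric(3)))
  da <- dominant_accuracy(tags, truth)
  expect_equal(unname(da), rep(100, 4))
  expect_identical(names(da), tags)
  expect_error(dominant_accuracy("5:5", truth[1, , drop = FALSE]),
               "unknown ratio")
})

test_that("ensembles average predictions and soft-vote the argmax", {
  dd <- mini_dataset_dir()
  m <- read_manifest(dd)
  recs <- lapply(load_records(m[1:6, ], dd), preprocess_image,
                 target_size = c(32, 32, 3))
  cfg <- model_config(input_size = c(32, 32, 3), epochs = 1, seed = 1)
  m1 <- build_model(cfg)
  cfg2 <- cfg; cfg2$seed <- 2L
  m2 <- build_model(cfg2)
  ens <- ensemble_predict(list(m1, m2), recs)
  brute <- (predict_soft(m1, recs) + predict_soft(m2, recs)) / 2
  expect_equal(ens$aggregate, brute)
  expect_true(all(abs(rowSums(ens$aggregate) - 1) < 1e-9))
  expect_identical(ens$voted_class,
                   c("PARENTAL", "RESISTANT", "CONTROL")[
                     max.col(brute, ties.method = "first")])
  # ensemble of identical models is exactly the single model
  same <- ensemble_predict(list(m1, m1, m1), recs)
  expect_equal(same$aggregate, predict_soft(m1, recs))
  # single-model ensemble is the identity
  one <- ensemble_predict(list(m2), recs)
  expect_equal(one$aggregate, predict_soft(m2, recs))
})
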