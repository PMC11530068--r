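#' Confusion matrix from hard labels and soft predictions
#'
#' Predicted class is the argmax of each predicted soft label, with ties
#' broken deterministically by class order (PARENTAL < RESISTANT <
#' CONTROL). Rows are true classes, columns predicted.
#'
#' @param true matrix `(n, 3)` of one-hot labels (or list of vertex
#'   [soft_label()]s).
#' @param pred matrix `(n, 3)` of simplex predictions.
#' @return integer 3x3 matrix of class `table`-like counts.
#' @export
confusion <- function(true, pred) {
  true <- as_label_matrix(true)
  pred <- as_label_matrix(pred)
  if (nrow(true) == 0) stop("cannot build a confusion matrix from no records")
  stopifnot(nrow(true) == nrow(pred))
  tc <- max.col(true, ties.method = "first")
  pc <- max.col(pred, ties.method = "first")
  cm <- matrix(0L, 3, 3, dimnames = list(true = CLASS_NAMES,
                                         pred = CLASS_NAMES))
  for (i in seq_along(tc)) cm[tc[i], pc[i]] <- cm[tc[i], pc[i]] + 1L
  cm
}

as_label_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x))
    x <- t(vapply(x, function(r) {
      if (inherits(r, "mixshape_record")) as.numeric(r$label)
      else as.numeric(r)
    }, numeric(3)))
  if (!is.matrix(x)) stop("expected a matrix or list of labels/records")
  colnames(x) <- CLASS_NAMES
  x
}

# one-vs-rest AUC by the rank (Mann-Whitney) method with midranks for ties
auc_rank <- function(truth, score) {
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro-averaged classification metrics
#'
#' Per-class one-vs-rest sensitivity, precision and F1 are computed from
#' the confusion matrix and averaged unweighted; macro AUC is the
#' unweighted mean of the three one-vs-rest areas computed from the
#' continuous predicted probabilities (midrank method). A class that is
#' never predicted contributes precision 0 with a warning; a class with
#' no true instances has undefined sensitivity and F1 and is excluded
#' from those macro averages. All values are percentages.
#'
#' @param cm a [confusion()] matrix.
#' @param pred matrix `(n, 3)` of predicted probabilities (for AUC;
#'   omit to skip AUC).
#' @param true matching one-hot truth matrix.
#' @return list: `accuracy`, `macro_sensitivity`, `macro_precision`,
#'   `macro_f1`, `macro_auc` (NA when `pred` absent), and `per_class`.
#' @export
macro_metrics <- function(cm, pred = NULL, true = NULL) {
  stopifnot(is.matrix(cm), all(dim(cm) == c(3, 3)))
  tp <- diag(cm)
  sens <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), NA)
  predicted <- colSums(cm)
  prec <- numeric(3)
  for (k in 1:3) {
    if (predicted[k] == 0) {
      warning("class ", CLASS_NAMES[k],
              " is never predicted; its precision contributes 0")
      prec[k] <- 0
    } else prec[k] <- tp[k] / predicted[k]
  }
  f1 <- ifelse(sens + prec > 0, 2 * sens * prec / (sens + prec), 0)
  auc <- NA_real_
  if (!is.null(pred)) {
    true <- as_label_matrix(true)
    pred <- as_label_matrix(pred)
    aucs <- numeric(3)
    for (k in 1:3) {
      truth <- true[, k] > 0.5
      if (all(truth) || !any(truth))
        stop("AUC undefined: truth contains a single class (",
             CLASS_NAMES[k], " one-vs-rest is degenerate)")
      aucs[k] <- auc_rank(truth, pred[, k])
    }
    auc <- mean(aucs) * 100
  }
  list(accuracy = sum(tp) / sum(cm) * 100,
       macro_sensitivity = mean(sens, na.rm = TRUE) * 100,
       macro_precision = mean(prec) * 100,
       macro_f1 = mean(f1, na.rm = TRUE) * 100,
       macro_auc = auc,
       per_class = data.frame(class = CLASS_NAMES, sensitivity = sens,
                              precision = prec, f1 = f1))
}

#' Soft-label RMSE
#'
#' `sqrt( sum_i ||y_i - yhat_i||^2 / (2N) )` over 3-component label
#' vectors. The 1/(2N) normalization keeps the value in `[0, 1]`: the
#' squared distance between two simplex vertices is 2, so a single
#' vertex-to-vertex error gives exactly 1.
#'
#' @param true,pred matrices `(n, 3)` (or record lists) of soft labels.
#' @return nonnegative scalar.
#' @export
rmse_soft <- function(true, pred) {
  true <- as_label_matrix(true)
  pred <- as_label_matrix(pred)
  if (nrow(true) != nrow(pred))
    stop("true and pred must have the same number of rows")
  n <- nrow(true)
  stopifnot(n >= 1)
  sqrt(sum((true - pred)^2) / (2 * n))
}

#' Dominant-class accuracy per mixture ratio
#'
#' For 1:2 and 1:3 images (RESISTANT-dominant) the accuracy is the
#' fraction with predicted RESISTANT strictly above PARENTAL; for 2:1
#' and 3:1 the reverse. Ties count as failures.
#'
#' @param tags character vector of ratio tags, one per record.
#' @param pred matrix `(n, 3)` of predictions.
#' @return named numeric vector of percentages, one entry per ratio
#'   present, in the order 1:2, 2:1, 1:3, 3:1.
#' @export
dominant_accuracy <- function(tags, pred) {
  pred <- as_label_matrix(pred)
  stopifnot(length(tags) == nrow(pred))
  resistant_dom <- c("1:2", "1:3")
  parental_dom <- c("2:1", "3:1")
  unknown <- setdiff(unique(tags), c(resistant_dom, parental_dom))
  if (length(unknown))
    stop("unknown ratio tag(s): ", paste(unknown, collapse = ", "))
  present <- intersect(RATIO_TAGS, unique(tags))
  out <- stats::setNames(numeric(length(present)), present)
  for (tg in present) {
    rows <- tags == tg
    out[tg] <- if (tg %in% resistant_dom)
      mean(pred[rows, "RESISTANT"] > pred[rows, "PARENTAL"]) * 100
    else
      mean(pred[rows, "PARENTAL"] > pred[rows, "RESISTANT"]) * 100
  }
  out
}

#' Bagging-ensemble prediction with soft voting
#'
#' Each fold model predicts a 3-vector per image; the aggregate is their
#' unweighted mean (weighted averaging is supported but off by default),
#' and the voted class is the argmax of the aggregate ("soft voting").
#' For mixture images the aggregate itself is the approximated
#' composition.
#'
#' @param models nonempty list of trained `mixshape_model`s.
#' @param records preprocessed records.
#' @param weights optional per-model weights (normalized internally);
#'   `NULL` for the simple average.
#' @return list: `per_model` (array `n x 3 x J`), `aggregate` (matrix
#'   `n x 3`), `voted_class` (character).
#' @export
ensemble_predict <- function(models, records, weights = NULL) {
  stopifnot(length(models) >= 1)
  sizes <- vapply(models, function(m)
    paste(m$config$input_size, collapse = "x"), character(1))
  if (length(unique(sizes)) != 1)
    stop("ensemble models have mismatched input sizes: ",
         paste(unique(sizes), collapse = " vs "))
  J <- length(models)
  preds <- lapply(models, predict_soft, records = records)
  n <- nrow(preds[[1]])
  per_model <- array(0, c(n, 3, J),
                     dimnames = list(NULL, CLASS_NAMES, NULL))
  for (j in seq_len(J)) per_model[, , j] <- preds[[j]]
  if (is.null(weights)) weights <- rep(1, J)
  stopifnot(length(weights) == J, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  aggregate <- matrix(0, n, 3, dimnames = list(NULL, CLASS_NAMES))
  for (j in seq_len(J)) aggregate <- aggregate + w[j] * per_model[, , j]
  voted <- CLASS_NAMES[max.col(aggregate, ties.method = "first")]
  list(per_model = per_model, aggregate = aggregate, voted_class = voted)
}
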