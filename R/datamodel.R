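#' Soft label: a point on the 3-class probability simplex
#'
#' Labels are 3-vectors of nonnegative probabilities summing to 1,
#' ordered (PARENTAL, RESISTANT, CONTROL). Hard labels are the simplex
#' vertices; mixture images carry interior points.
#'
#' @param y numeric 3-vector.
#' @return numeric 3-vector of class `mixshape_soft_label` with names
#'   `PARENTAL`, `RESISTANT`, `CONTROL`.
#' @export
soft_label <- function(y) {
  y <- as.numeric(y)
  if (length(y) != 3) stop("soft label must have 3 components")
  if (any(y < -1e-12)) stop("soft label components must be nonnegative")
  if (abs(sum(y) - 1) > 1e-9) stop("soft label components must sum to 1")
  structure(stats::setNames(pmax(y, 0), CLASS_NAMES),
            class = "mixshape_soft_label")
}

#' Map a population tag to its soft label
#'
#' Class names map to one-hot vertices; a mixture tag `"a:b"` (positive
#' integers, PARENTAL:RESISTANT) maps to `(a/(a+b), b/(a+b), 0)` with the
#' division done once from integer numerator and denominator, so e.g.
#' `"1:3"` gives a PARENTAL component of exactly 0.25.
#'
#' @param tag one of `PARENTAL`, `RESISTANT`, `CONTROL` or `"a:b"`.
#' @return a [soft_label()].
#' @export
assign_soft_label <- function(tag) {
  stopifnot(is.character(tag), length(tag) == 1)
  if (tag %in% CLASS_NAMES) {
    y <- as.numeric(CLASS_NAMES == tag)
    return(soft_label(y))
  }
  m <- regmatches(tag, regexec("^([0-9]+):([0-9]+)$", tag))[[1]]
  if (length(m) == 3) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    if (a > 0 && b > 0)
      return(soft_label(c(a / (a + b), b / (a + b), 0)))
  }
  stop("unknown tag '", tag, "'; expected one of ",
       paste(CLASS_NAMES, collapse = ", "),
       " or a ratio tag 'a:b' with positive integers (e.g. ",
       paste(RATIO_TAGS, collapse = ", "), ")")
}

#' One image with its soft label and provenance
#'
#' @param image numeric array, `(H, W, C)` in gray levels (row, col,
#'   channel order, 0-based spatial semantics).
#' @param label a [soft_label()].
#' @param tag population tag (class name or ratio tag).
#' @param source file path or `"synthetic:<op>"` provenance string.
#' @param meta free-form metadata list (realized counts, parents of
#'   resampled records, interpolation weights, ...).
#' @return object of class `mixshape_record`.
#' @export
image_record <- function(image, label, tag, source = "unknown",
                         meta = list()) {
  stopifnot(inherits(label, "mixshape_soft_label"))
  structure(list(image = image, label = label, tag = tag,
                 source = source, meta = meta),
            class = "mixshape_record")
}

#' Preprocess an image record for the network
#'
#' Bilinear-resizes the image to `target_size` (default the 300x300x3
#' network input, from the native 2048x2880x3 acquisition size) and
#' rescales intensities to `[0, 1]` (values above 1 are assumed 8-bit and
#' divided by 255). The label is untouched.
#'
#' @param record an [image_record()] with a 3-channel image.
#' @param target_size integer `(H, W, C)`, `C = 3`.
#' @return the record with resized image.
#' @export
preprocess_image <- function(record, target_size = c(300, 300, 3)) {
  stopifnot(inherits(record, "mixshape_record"), length(target_size) == 3)
  img <- record$image
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3)
    stop("preprocess_image requires a 3-channel (H, W, 3) image; got dims ",
         paste(d, collapse = "x"))
  if (max(img) > 1) img <- img / 255
  img <- array(pmin(1, pmax(0, img)), d)
  record$image <- resize_bilinear(img, target_size[1], target_size[2])
  record
}

#' @export
print.mixshape_record <- function(x, ...) {
  cat("<mixshape_record> tag=", x$tag, " dims=",
      paste(dim(x$image), collapse = "x"),
      " label=(", paste(signif(as.numeric(x$label), 4), collapse = ", "),
      ") source=", x$source, "\n", sep = "")
  invisible(x)
}

# internal: shuffle ids and cut into stratum splits by largest remainder
split_counts <- function(n, fracs) largest_remainder(fracs, n)

#' Hold-out plus K-fold split of the homogeneous (hard-label) data
#'
#' Stratified by class: 20% of each class is spared as a test set never
#' used for training; the remaining 80% is partitioned into K folds
#' (K = 5 by default), each fold in turn serving as validation set while
#' the other K-1 train. Deterministic given `seed`. At the 300-per-class
#' scale this yields 60 test, 48 validation and 192 training images per
#' class per fold.
#'
#' @param manifest manifest `data.frame` (only rows whose tag is a class
#'   name are used).
#' @param test_frac held-out fraction per class.
#' @param K number of folds.
#' @param seed integer seed.
#' @return object of class `mixshape_split`: `test_ids`, `folds` (list of
#'   `list(train, val)`), `K`, `seed`. Ids are manifest `path` values.
#' @export
split_homo <- function(manifest, test_frac = 0.2, K = 5, seed = 1L) {
  stopifnot(test_frac > 0, test_frac < 1, K >= 2)
  homo <- manifest[manifest$tag %in% CLASS_NAMES, , drop = FALSE]
  with_seed_ms(seed, {
    test_ids <- character(0)
    fold_val <- replicate(K, character(0), simplify = FALSE)
    for (cl in intersect(CLASS_NAMES, unique(homo$tag))) {
      ids <- sample(homo$path[homo$tag == cl])
      n <- length(ids)
      n_test <- round(test_frac * n)
      if (n - n_test < K)
        stop("class ", cl, " has too few images (", n,
             ") for a ", test_frac * 100, "% hold-out plus ", K, " folds")
      test_ids <- c(test_ids, ids[seq_len(n_test)])
      rest <- ids[-seq_len(n_test)]
      sizes <- split_counts(length(rest), rep(1 / K, K))
      stops <- cumsum(sizes)
      starts <- c(1L, utils::head(stops, -1) + 1L)
      for (k in seq_len(K))
        fold_val[[k]] <- c(fold_val[[k]], rest[starts[k]:stops[k]])
    }
    non_test <- unlist(fold_val, use.names = FALSE)
    folds <- lapply(seq_len(K), function(k)
      list(train = setdiff(non_test, fold_val[[k]]), val = fold_val[[k]]))
    structure(list(test_ids = test_ids, folds = folds, K = K, seed = seed),
              class = "mixshape_split")
  })
}

#' Single stratified split of the heterogeneous (soft-label) data
#'
#' Splits each mixture-ratio stratum into training, validation and test
#' sets at 64:16:20 (no cross-validation; the mixture data are split
#' once). Remainders are apportioned by the largest-remainder rule, so
#' 200 images per ratio yield 128 training, 32 validation and 40 test
#' images per ratio.
#'
#' @param manifest manifest `data.frame` (only rows with ratio tags used).
#' @param fracs numeric 3-vector `(train, val, test)` summing to 1.
#' @param seed integer seed.
#' @return list `train_ids`, `val_ids`, `test_ids` of manifest paths.
#' @export
split_hetero <- function(manifest, fracs = c(0.64, 0.16, 0.20), seed = 1L) {
  if (length(fracs) != 3 || abs(sum(fracs) - 1) > 1e-9)
    stop("fracs must be a 3-vector (train, val, test) summing to 1")
  het <- manifest[vapply(manifest$tag, is_ratio_tag, logical(1)), ,
                  drop = FALSE]
  if (nrow(het) == 0) stop("manifest contains no ratio-tagged rows")
  with_seed_ms(seed, {
    out <- list(train_ids = character(0), val_ids = character(0),
                test_ids = character(0))
    for (tag in unique(het$tag)) {
      ids <- sample(het$path[het$tag == tag])
      sizes <- split_counts(length(ids), fracs)
      stops <- cumsum(sizes)
      out$train_ids <- c(out$train_ids, ids[seq_len(stops[1])])
      if (sizes[2] > 0)
        out$val_ids <- c(out$val_ids, ids[(stops[1] + 1):stops[2]])
      if (sizes[3] > 0)
        out$test_ids <- c(out$test_ids, ids[(stops[2] + 1):stops[3]])
    }
    out
  })
}

#' Serialize / restore a split plan as JSON
#' @param plan a `mixshape_split` (optionally with `$hetero` attached).
#' @param path JSON file path.
#' @return `read_split_plan` returns the restored plan.
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(unclass(plan), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  out <- list(test_ids = as.character(unlist(x$test_ids)),
              folds = lapply(x$folds, function(f)
                list(train = as.character(unlist(f$train)),
                     val = as.character(unlist(f$val)))),
              K = x$K, seed = x$seed)
  if (!is.null(x$hetero))
    out$hetero <- lapply(x$hetero, function(v) as.character(unlist(v)))
  structure(out, class = "mixshape_split")
}
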