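test_that("identity embedding returns the raw point matrix", {
  pts <- list(point_record(1, 2, "1:2"), point_record(3, 4, "1:2"),
              point_record(1, 2, "2:1"))
  M <- embed_records(pts, identity_emb)
  expect_equal(M, rbind(c(1, 2), c(3, 4), c(1, 2)))
  expect_equal(as.numeric(dist(M[c(1, 3), ])), 0)
  expect_error(embed_records(list(), identity_emb), "empty")
})

test_that("image embedding separates distinct images deterministically", {
  a <- image_record(array(0.5, c(16, 16, 3)), assign_soft_label("1:2"), "1:2")
  set.seed(1)
  b <- image_record(array(runif(16 * 16 * 3), c(16, 16, 3)),
                    assign_soft_label("1:2"), "1:2")
  M1 <- embed_records(list(a, a, b), feature_embedding(target_size = 8))
  expect_equal(M1[1, ], M1[2, ])
  expect_gt(sqrt(sum((M1[1, ] - M1[3, ])^2)), 0)
  M2 <- embed_records(list(a, a, b), feature_embedding(target_size = 8))
  expect_identical(M1, M2)
})

test_that("random oversampling adds uniform-with-replacement duplicates", {
  recs <- lapply(1:128, function(i) point_record(i, 0, "1:2"))
  expect_identical(random_oversample(recs, 0), recs)
  expect_error(random_oversample(recs, -1), ">= 0")
  out <- random_oversample(recs, 256, seed = 5)
  expect_length(out, 384)
  expect_identical(out[1:128], recs)
  added <- out[129:384]
  xs <- vapply(added, function(r) r$image[1], numeric(1))
  expect_true(all(xs %in% 1:128))
  expect_true(all(vapply(added, function(r) r$source, character(1)) ==
                  "synthetic:random_os"))
})

test_that("oversampling draw counts are consistent with a uniform law", {
  # 200 repetitions of delta draws from n sources; pooled counts should
  # pass a chi-square uniformity test at alpha = 0.01
  recs <- lapply(1:16, function(i) point_record(i, 0, "1:2"))
  counts <- integer(16)
  for (rep in 1:200) {
    out <- random_oversample(recs, 32, seed = 1000 + rep)
    xs <- vapply(out[17:48], function(r) r$image[1], numeric(1))
    counts <- counts + tabulate(xs, 16)
  }
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)
})

test_that("SMOTE interpolates image and label with one shared gamma", {
  refs <- point_cloud(10, 0, 0, 0.3, "1:2", seed = 1)
  nbrs <- point_cloud(10, 2, 2, 0.3, "1:3", seed = 2)
  syn <- smote_soft(refs, nbrs, delta = 40, k = 3, identity_emb, seed = 3)
  expect_length(syn, 40)
  for (s in syn) {
    g <- s$meta$gamma
    ref <- refs[[s$meta$parent_ref]]; nb <- nbrs[[s$meta$parent_neighbor]]
    expect_equal(s$image, ref$image + g * (nb$image - ref$image))
    expect_equal(as.numeric(s$label),
                 as.numeric(ref$label) +
                   g * (as.numeric(nb$label) - as.numeric(ref$label)))
    # label lies on the segment between the two class points
    y <- as.numeric(s$label)
    expect_equal(y[3], 0)
    expect_equal(sum(y), 1, tolerance = 1e-12)
    expect_true(y[1] <= 1 / 3 + 1e-12 && y[1] >= 0.25 - 1e-12)
  }
  # hand-evaluated midpoint: y_ref=(2/3,1/3,0), y_nb=(1,0,0), gamma=.5
  y_half <- c(2 / 3, 1 / 3, 0) + 0.5 * (c(1, 0, 0) - c(2 / 3, 1 / 3, 0))
  expect_equal(y_half, c(5 / 6, 1 / 6, 0))
  # gamma = 0 endpoint returns the reference exactly
  one <- smote_soft(refs[1], nbrs, delta = 1, k = 3, identity_emb, seed = 4)
  g0 <- one[[1]]$meta$gamma
  manual <- refs[[1]]$image + g0 * (nbrs[[one[[1]]$meta$parent_neighbor]]$image -
                                      refs[[1]]$image)
  expect_equal(one[[1]]$image, manual)
  expect_error(smote_soft(refs, nbrs[1:2], 5, k = 3, identity_emb),
               "k = 3")
})

test_that("SMOTE neighbors are the true k-nearest in embedding space", {
  set.seed(42)
  refs <- point_cloud(25, 0, 0, 1, "1:2", seed = 11)
  nbrs <- point_cloud(30, 1, 1, 1, "1:3", seed = 12)
  syn <- smote_soft(refs, nbrs, delta = 60, k = 3, identity_emb, seed = 13)
  Mr <- embed_records(refs, identity_emb)
  Mn <- embed_records(nbrs, identity_emb)
  for (s in syn) {
    d <- sqrt(colSums((t(Mn) - Mr[s$meta$parent_ref, ])^2))
    expect_true(s$meta$parent_neighbor %in% order(d)[1:3])
  }
})

test_that("borderline DANGER set obeys the Han rule at its boundaries", {
  # a reference whose k neighbors are all competitors is noise (m = k);
  # a reference deep in its own cluster is safe (m = 0); neither is DANGER
  refs <- c(list(point_record(10, 10, "1:2")),          # surrounded: noise
            lapply(1:5, function(i) point_record(i / 10, 0, "1:2")))  # safe
  comps <- lapply(1:3, function(i)
    point_record(10 + i / 100, 10 + i / 100, "1:3"))
  danger <- borderline_danger(refs, comps, k = 3, identity_emb)
  expect_false(1 %in% danger)
  expect_length(danger, 0)
  expect_warning(
    borderline_smote_soft(refs, comps, delta = 2, k = 3, identity_emb,
                          seed = 1),
    "DANGER")
})

test_that("DANGER identification matches a brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n_ref <- sample(20:100, 1); n_comp <- sample(20:100, 1)
    refs <- point_cloud(n_ref, 0, 0, 1, "1:2", seed = seed * 2)
    comps <- point_cloud(n_comp, 0.8, 0.8, 1, "1:3", seed = seed * 2 + 1)
    got <- borderline_danger(refs, comps, k = 5, identity_emb)
    M <- embed_records(c(refs, comps), identity_emb)
    is_comp <- c(rep(FALSE, n_ref), rep(TRUE, n_comp))
    expected <- integer(0)
    for (i in seq_len(n_ref)) {
      nn <- brute_knn(M, i, 5, setdiff(seq_len(nrow(M)), i))
      m <- sum(is_comp[nn])
      if (m >= 2.5 && m < 5) expected <- c(expected, i)
    }
    expect_identical(got, expected)
  }
})

test_that("ENN deletes KNN-misclassified targets and nothing else", {
  # a target surrounded by 3 competitors is deleted
  tgt <- c(list(point_record(5, 5, "1:2")),
           lapply(1:6, function(i) point_record(i / 10, 0, "1:2")))
  comp <- lapply(1:3, function(i) point_record(5 + i / 50, 5, "2:1"))
  res <- enn_undersample(tgt, comp, k = 3, identity_emb)
  expect_identical(res$deleted_ids, 1L)
  expect_length(res$kept, 6)
  expect_error(enn_undersample(tgt, comp, k = 2, identity_emb), "odd")
  expect_error(enn_undersample(tgt[1], comp[1], k = 3, identity_emb),
               "pool size")
})

test_that("ENN agrees with a brute-force oracle and is idempotent", {
  for (seed in 1:20) {
    set.seed(seed + 100)
    n_t <- sample(30:100, 1); n_c <- sample(30:100, 1)
    tgt <- point_cloud(n_t, 0, 0, 1, "1:2", seed = seed * 3)
    comp <- point_cloud(n_c, 1, 1, 1, "2:1", seed = seed * 3 + 1)
    res <- enn_undersample(tgt, comp, k = 3, identity_emb)
    M <- embed_records(c(tgt, comp), identity_emb)
    is_comp <- c(rep(FALSE, n_t), rep(TRUE, n_c))
    expected <- integer(0)
    for (i in seq_len(n_t)) {
      nn <- brute_knn(M, i, 3, setdiff(seq_len(nrow(M)), i))
      if (sum(is_comp[nn]) > 1.5) expected <- c(expected, i)
    }
    expect_identical(res$deleted_ids, expected)
    expect_true(length(res$kept) == n_t - length(expected))
  }
  # a second edit of the kept records against the same competitor set
  # changes nothing when the first pass only removes boundary points
  # (heavily overlapping clouds can cascade, since deleting a record
  # rewires its neighbors' neighborhoods)
  tgt <- point_cloud(60, 0, 0, 0.8, "1:2", seed = 7)
  comp <- point_cloud(60, 3, 3, 0.8, "2:1", seed = 8)
  once <- enn_undersample(tgt, comp, k = 3, identity_emb)
  twice <- enn_undersample(once$kept, comp, k = 3, identity_emb)
  expect_length(twice$deleted_ids, 0)
  expect_identical(twice$kept, once$kept)
})

test_that("apply_plan bookkeeping matches the tuned increments", {
  mk_ratio <- function(tag, n, cx) point_cloud(n, cx, 0, 0.2, tag,
                                               seed = match(tag, c("1:2", "2:1", "1:3", "3:1")))
  train <- c(mk_ratio("1:2", 128, 0), mk_ratio("2:1", 128, 3),
             mk_ratio("1:3", 128, 6), mk_ratio("3:1", 128, 9),
             point_cloud(50, -5, 0, 0.2, "PARENTAL", seed = 30),
             point_cloud(50, 15, 0, 0.2, "RESISTANT", seed = 31))
  plan <- resample_plan("random_os", seed = 2)      # tuned defaults
  res <- apply_plan(train, plan, embedding = identity_emb)
  tab <- table(vapply(res$records, function(r) r$tag, character(1)))
  expect_equal(unname(tab[c("1:2", "2:1", "1:3", "3:1")]),
               c(384L, 256L, 384L, 384L), ignore_attr = TRUE)
  # homogeneous records pass through untouched
  expect_equal(unname(tab[c("PARENTAL", "RESISTANT")]), c(50L, 50L),
               ignore_attr = TRUE)
  homo_in <- Filter(function(r) r$tag == "PARENTAL", train)
  homo_out <- Filter(function(r) r$tag == "PARENTAL", res$records)
  expect_identical(homo_out, homo_in)
})

test_that("apply_plan none is the identity and missing tags error", {
  train <- point_cloud(5, 0, 0, 1, "1:2", seed = 1)
  plan0 <- resample_plan("none")
  expect_identical(apply_plan(train, plan0,
                              embedding = identity_emb)$records, train)
  plan <- resample_plan("random_os", delta_os = c("1:2" = 4, "2:1" = 4,
                                                  "1:3" = 4, "3:1" = 4))
  expect_error(apply_plan(train, plan, embedding = identity_emb),
               "missing records")
})

test_that("ENN-then-oversample edits first, then duplicates kept records", {
  # overlapping 1:2 / 2:1 clouds so ENN has something to delete
  train <- c(point_cloud(40, 0, 0, 1, "1:2", seed = 21),
             point_cloud(40, 0.5, 0.5, 1, "2:1", seed = 22),
             point_cloud(40, 5, 0, 0.4, "1:3", seed = 23),
             point_cloud(40, -5, 0, 0.4, "3:1", seed = 24))
  plan <- resample_plan("enn_then_random_os",
                        delta_os = c("1:2" = 20, "2:1" = 10,
                                     "1:3" = 20, "3:1" = 20), seed = 9)
  res <- apply_plan(train, plan, embedding = identity_emb)
  aud <- res$audit
  expect_identical(aud$n_final, aud$n_input - aud$n_deleted + aud$n_added)
  expect_identical(res$plan$delta_ds[["2:1"]], 0L)    # never edited
  expect_gt(res$plan$delta_ds[["1:2"]], 0)            # overlap is edited
  # oversampled duplicates stem only from kept records
  del <- aud$n_deleted[aud$tag == "1:2"]
  kept12 <- Filter(function(r) r$tag == "1:2" &&
                     r$source != "synthetic:random_os", res$records)
  expect_length(kept12, 40 - del)
  dup12 <- Filter(function(r) r$tag == "1:2" &&
                    r$source == "synthetic:random_os", res$records)
  kept_imgs <- lapply(kept12, `[[`, "image")
  for (d in dup12)
    expect_true(any(vapply(kept_imgs, identical, logical(1), d$image)))
})
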