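# Shared fixtures, built in code at test time.

# a bare 2D "point" record: feature vector instead of an image, for
# identity-embedding oracle tests of the KNN-based resampling operators
point_record <- function(x, y, tag) {
  image_record(c(x, y), assign_soft_label(tag), tag = tag,
               source = sprintf("pt:%g,%g", x, y))
}

point_cloud <- function(n, cx, cy, sd, tag, seed) {
  withr_seed <- seed
  set.seed(withr_seed)
  lapply(seq_len(n), function(i)
    point_record(rnorm(1, cx, sd), rnorm(1, cy, sd), tag))
}

identity_emb <- feature_embedding("identity")

# brute-force O(n^2) k-nearest-neighbour indices (independent oracle)
brute_knn <- function(M, i, k, candidates) {
  d <- sqrt(colSums((t(M[candidates, , drop = FALSE]) - M[i, ])^2))
  candidates[order(d)[seq_len(k)]]
}

# tiny on-disk dataset shared across test files (generated once)
mini_dataset_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "manifest.csv"))) {
      dir <<- file.path(tempdir(), "mixshape_mini_fixture")
      if (!file.exists(file.path(dir, "manifest.csv")))
        generate_dataset(generator_preset(12, 8,
                                          canvas_size = c(32, 32, 3),
                                          cells_per_image = 8),
                         dir, seed = 424, overlap_policy = "allow",
                         overwrite = TRUE)
    }
    dir
  }
})

# synthetic manifest (no images) for split-arithmetic tests
fake_manifest <- function(per_class = 300, per_ratio = 200) {
  tags <- c(rep(c("PARENTAL", "RESISTANT", "CONTROL"), each = per_class),
            rep(c("1:2", "2:1", "1:3", "3:1"), each = per_ratio))
  data.frame(path = sprintf("img_%05d.tif", seq_along(tags)), tag = tags,
             stringsAsFactors = FALSE)
}
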