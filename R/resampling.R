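#' Feature embedding used by the KNN-based resampling operators
#'
#' SMOTE, Borderline-SMOTE and ENN all need a feature space with a
#' distance. Images are embedded by grayscale downsampling to
#' `target_size` x `target_size`, flattening, and per-feature
#' standardization (Euclidean metric); `"identity"` flattens the stored
#' array as-is, which admits plain 2D point fixtures for oracle tests.
#'
#' @param method `"downsampled_gray"` or `"identity"`.
#' @param target_size downsampled side length in pixels.
#' @return object of class `mixshape_embedding`.
#' @export
feature_embedding <- function(method = c("downsampled_gray", "identity"),
                              target_size = 32) {
  method <- match.arg(method)
  structure(list(method = method, target_size = as.integer(target_size),
                 metric = "euclidean"),
            class = "mixshape_embedding")
}

#' Embed records as a feature matrix
#'
#' @param records list of [image_record()] (uniform image size).
#' @param embedding a [feature_embedding()].
#' @return numeric matrix, one row per record.
#' @export
embed_records <- function(records, embedding = feature_embedding()) {
  if (length(records) == 0) stop("cannot embed an empty record set")
  if (embedding$method == "identity") {
    M <- do.call(rbind, lapply(records, function(r) as.numeric(r$image)))
    return(M)
  }
  ts <- embedding$target_size
  rows <- lapply(records, function(r) {
    img <- r$image
    if (length(dim(img)) == 3) img <- apply(img, c(1, 2), mean)
    as.numeric(resize_bilinear(img, ts, ts))
  })
  M <- do.call(rbind, rows)
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  sd[!is.finite(sd) | sd < 1e-12] <- Inf   # constant feature -> contributes 0
  sweep(sweep(M, 2, mu), 2, sd, "/")
}

# squared Euclidean cross-distances between rows of A and rows of B
cross_dist2 <- function(A, B) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  pmax(d2, 0)
}

#' Random oversampling
#'
#' Adds `delta` duplicates drawn uniformly with replacement from the
#' input; originals are preserved and duplicates are flagged as
#' `synthetic:random_os` with their parent index recorded.
#'
#' @param records nonempty list of [image_record()].
#' @param delta number of duplicates to add (>= 0).
#' @param seed integer seed.
#' @return list of records of length `length(records) + delta`.
#' @export
random_oversample <- function(records, delta, seed = 1L) {
  if (length(records) == 0) stop("records must be non-empty")
  if (delta < 0) stop("delta must be >= 0")
  if (delta == 0) return(records)
  with_seed_ms(seed, {
    idx <- sample.int(length(records), delta, replace = TRUE)
    dup <- lapply(idx, function(i) {
      r <- records[[i]]
      r$source <- "synthetic:random_os"
      r$meta$parent <- i
      r
    })
    c(records, dup)
  })
}

# kNN indices (into rows of `pool_emb`) of each row of `ref_emb`;
# `exclude` is an optional vector of pool indices identified with each ref.
knn_indices <- function(ref_emb, pool_emb, k, exclude = NULL) {
  d2 <- cross_dist2(ref_emb, pool_emb)
  if (!is.null(exclude))
    d2[cbind(seq_len(nrow(ref_emb)), exclude)] <- Inf
  t(apply(d2, 1, function(row) order(row)[seq_len(k)]))
}

#' SMOTE adapted to soft labels
#'
#' Synthesizes `delta` records: a reference is drawn uniformly from
#' `ref_records`, its `k` nearest neighbors within `neighbor_records`
#' are found in the embedding space, one neighbor is picked uniformly,
#' and with gamma ~ U(0, 1) both the image and the soft label are
#' linearly interpolated: `X_new = X_ref + gamma (X_nb - X_ref)`,
#' `y_new = y_ref + gamma (y_nb - y_ref)`. Labels therefore stay on the
#' simplex segment joining the two source-class label points. The
#' neighbor class follows the adjacency convention: 1:2 pairs with 1:3,
#' 2:1 with 3:1, 1:3 with homogeneous RESISTANT, and 3:1 with
#' homogeneous PARENTAL.
#'
#' @param ref_records minority (reference) records.
#' @param neighbor_records neighbor pool (>= `k` usable records).
#' @param delta number of synthetic records.
#' @param k neighborhood size (default 3).
#' @param embedding a [feature_embedding()]; computed jointly over
#'   reference and neighbor records so standardization is shared.
#' @param seed integer seed.
#' @param exclude_self when reference and neighbor sets are the same
#'   list, exclude each reference from its own neighborhood.
#' @return list of `delta` synthetic [image_record()]s (tagged like the
#'   references, flagged `synthetic:smote`, gamma and parents in meta).
#' @export
smote_soft <- function(ref_records, neighbor_records, delta, k = 3,
                       embedding = feature_embedding(), seed = 1L,
                       exclude_self = FALSE) {
  if (length(ref_records) == 0) stop("ref_records must be non-empty")
  n_pool <- length(neighbor_records) - if (exclude_self) 1L else 0L
  if (n_pool < k)
    stop("neighbor_records has too few usable records (", n_pool,
         ") for k = ", k)
  if (delta == 0) return(list())
  all_emb <- embed_records(c(ref_records, neighbor_records), embedding)
  ref_emb <- all_emb[seq_along(ref_records), , drop = FALSE]
  nb_emb <- all_emb[length(ref_records) + seq_along(neighbor_records), ,
                    drop = FALSE]
  excl <- if (exclude_self) seq_along(ref_records) else NULL
  nn <- knn_indices(ref_emb, nb_emb, k, exclude = excl)
  with_seed_ms(seed, {
    lapply(seq_len(delta), function(s) {
      i <- sample.int(length(ref_records), 1L)
      j <- nn[i, sample.int(k, 1L)]
      gamma <- stats::runif(1)
      ref <- ref_records[[i]]; nb <- neighbor_records[[j]]
      x_new <- ref$image + gamma * (nb$image - ref$image)
      y_new <- as.numeric(ref$label) + gamma *
        (as.numeric(nb$label) - as.numeric(ref$label))
      if (abs(sum(y_new) - 1) > 1e-9) y_new <- y_new / sum(y_new)
      image_record(x_new, soft_label(y_new), tag = ref$tag,
                   source = "synthetic:smote",
                   meta = list(gamma = gamma, parent_ref = i,
                               parent_neighbor = j))
    })
  })
}

#' Identify DANGER references for Borderline-SMOTE
#'
#' Among each reference's `k` nearest neighbors in the pooled reference
#' plus competitor set (self excluded), let `m` be the competitor count.
#' References with `k/2 <= m < k` are borderline (DANGER); `m = k` marks
#' noise and `m < k/2` safe points, both excluded.
#'
#' @inheritParams smote_soft
#' @param competitor_records competing-class records.
#' @return integer vector of DANGER indices into `ref_records`.
#' @export
borderline_danger <- function(ref_records, competitor_records, k = 3,
                              embedding = feature_embedding()) {
  pool <- c(ref_records, competitor_records)
  if (length(pool) - 1 < k)
    stop("pooled set too small for k = ", k)
  emb <- embed_records(pool, embedding)
  ref_emb <- emb[seq_along(ref_records), , drop = FALSE]
  nn <- knn_indices(ref_emb, emb, k, exclude = seq_along(ref_records))
  is_comp <- c(rep(FALSE, length(ref_records)),
               rep(TRUE, length(competitor_records)))
  m <- rowSums(matrix(is_comp[nn], nrow = nrow(nn)))
  which(m >= k / 2 & m < k)
}

#' Borderline-SMOTE adapted to soft labels
#'
#' Step 1 identifies DANGER references via [borderline_danger()]; step 2
#' runs [smote_soft()] with references restricted to the DANGER set and
#' neighbors drawn from the minority class itself. If no reference is
#' borderline, falls back to plain SMOTE within the minority class with
#' a warning.
#'
#' @inheritParams borderline_danger
#' @param delta number of synthetic records.
#' @param seed integer seed.
#' @return list of synthetic records (source `synthetic:borderline_smote`).
#' @export
borderline_smote_soft <- function(ref_records, competitor_records, delta,
                                  k = 3, embedding = feature_embedding(),
                                  seed = 1L) {
  danger <- borderline_danger(ref_records, competitor_records, k, embedding)
  if (length(danger) == 0) {
    warning("no DANGER references found; falling back to plain SMOTE ",
            "within the minority class")
    out <- smote_soft(ref_records, ref_records, delta, k, embedding,
                      seed, exclude_self = TRUE)
  } else {
    # references restricted to DANGER; neighbors from the full minority
    # set, each reference excluded from its own neighborhood
    out <- smote_soft_excluding(ref_records, danger, delta, k, embedding,
                                seed)
  }
  for (i in seq_along(out)) out[[i]]$source <- "synthetic:borderline_smote"
  out
}

# SMOTE with references ref_records[danger] and neighbor pool ref_records,
# excluding each reference's own index from its neighborhood.
smote_soft_excluding <- function(ref_records, danger, delta, k, embedding,
                                 seed) {
  if (length(ref_records) - 1 < k)
    stop("minority class too small (", length(ref_records),
         ") for k = ", k)
  if (delta == 0) return(list())
  emb <- embed_records(ref_records, embedding)
  nn <- knn_indices(emb[danger, , drop = FALSE], emb, k, exclude = danger)
  with_seed_ms(seed, {
    lapply(seq_len(delta), function(s) {
      di <- sample.int(length(danger), 1L)
      i <- danger[di]
      j <- nn[di, sample.int(k, 1L)]
      gamma <- stats::runif(1)
      ref <- ref_records[[i]]; nb <- ref_records[[j]]
      x_new <- ref$image + gamma * (nb$image - ref$image)
      y_new <- as.numeric(ref$label) + gamma *
        (as.numeric(nb$label) - as.numeric(ref$label))
      if (abs(sum(y_new) - 1) > 1e-9) y_new <- y_new / sum(y_new)
      image_record(x_new, soft_label(y_new), tag = ref$tag,
                   source = "synthetic:borderline_smote",
                   meta = list(gamma = gamma, parent_ref = i,
                               parent_neighbor = j))
    })
  })
}

#' Edited nearest neighbours (ENN) undersampling
#'
#' Each target record is classified by the majority tag among its `k`
#' nearest neighbors within the pooled target plus competitor set (self
#' excluded); targets whose neighborhood majority belongs to the
#' competitor are deleted. Deterministic; `k` must be odd so the
#' two-class majority is always defined.
#'
#' @param target_records records of the class being edited.
#' @param competitor_records records of the competing class.
#' @param k odd neighborhood size (default 3).
#' @param embedding a [feature_embedding()].
#' @return list with `kept` (records) and `deleted_ids` (indices into
#'   `target_records`).
#' @export
enn_undersample <- function(target_records, competitor_records, k = 3,
                            embedding = feature_embedding()) {
  if (length(target_records) == 0 || length(competitor_records) == 0)
    stop("both target and competitor sets must be non-empty")
  if (k %% 2 == 0) stop("k must be odd (majority vote undefined for even k)")
  pool <- c(target_records, competitor_records)
  if (k >= length(pool)) stop("k (", k, ") must be below pool size (",
                              length(pool), ")")
  emb <- embed_records(pool, embedding)
  tgt_emb <- emb[seq_along(target_records), , drop = FALSE]
  nn <- knn_indices(tgt_emb, emb, k, exclude = seq_along(target_records))
  is_comp <- c(rep(FALSE, length(target_records)),
               rep(TRUE, length(competitor_records)))
  votes <- rowSums(matrix(is_comp[nn], nrow = nrow(nn)))
  deleted <- which(votes > k / 2)
  list(kept = if (length(deleted)) target_records[-deleted]
              else target_records,
       deleted_ids = deleted)
}

#' Adjacency mappings between mixture ratios and their paired classes
#'
#' Fixed conventions for which class supplies SMOTE neighbors, which
#' competes in the Borderline-SMOTE DANGER test, and which class each
#' ratio is ENN-edited against (2:1 is never edited).
#'
#' @return list with `smote_neighbor`, `borderline_competitor`,
#'   `enn_competitor` named maps.
#' @export
adjacency_map <- function() {
  list(
    smote_neighbor = c("1:2" = "1:3", "2:1" = "3:1",
                       "1:3" = "RESISTANT", "3:1" = "PARENTAL"),
    borderline_competitor = c("1:2" = "1:3", "2:1" = "PARENTAL",
                              "1:3" = "RESISTANT", "3:1" = "PARENTAL"),
    enn_competitor = c("1:2" = "2:1", "1:3" = "1:2", "3:1" = "2:1")
  )
}

#' Resampling plan: per-ratio oversampling increments and method
#'
#' The default increments are the tuned values
#' `{1:2 -> 256, 2:1 -> 128, 1:3 -> 256, 3:1 -> 256}` from a random
#' search over the grid 64..384 (step 64); ENN deletion counts
#' (`delta_ds`) are determined by the data and recorded after the fact,
#' not chosen.
#'
#' @param method one of `none`, `random_os`, `smote`, `borderline_smote`,
#'   `enn_then_random_os`.
#' @param delta_os named nonnegative increments per ratio tag.
#' @param knn_k neighborhood size for SMOTE/ENN.
#' @param seed integer seed.
#' @return object of class `mixshape_plan`.
#' @export
resample_plan <- function(method = c("none", "random_os", "smote",
                                     "borderline_smote",
                                     "enn_then_random_os"),
                          delta_os = c("1:2" = 256, "2:1" = 128,
                                       "1:3" = 256, "3:1" = 256),
                          knn_k = 3, seed = 1L) {
  method <- match.arg(method)
  if (any(delta_os < 0)) stop("delta_os values must be >= 0")
  structure(list(method = method, delta_os = delta_os,
                 delta_ds = NULL, knn_k = knn_k, seed = as.integer(seed)),
            class = "mixshape_plan")
}

#' Apply a resampling plan to a training set
#'
#' Homogeneous-class records pass through untouched. For
#' `enn_then_random_os`, each mapped ratio is first ENN-edited against
#' its competitor (deletion counts recorded into `plan$delta_ds`;
#' competitor pools are the original, unedited sets), and random
#' oversampling then draws only from the kept records — editing first
#' prevents the oversampler from duplicating ambiguous borderline
#' images. Other methods run as the single named technique, with SMOTE
#' neighbors / Borderline competitors taken from the adjacency map
#' (homogeneous classes supply neighbors for 1:3 and 3:1).
#'
#' @param train_records training records (mixed homogeneous + mixture).
#' @param plan a [resample_plan()].
#' @param adjacency an [adjacency_map()].
#' @param embedding a [feature_embedding()] shared by all KNN steps.
#' @return list with `records` (augmented training set), `plan` (with
#'   `delta_ds` filled in), and `audit` (per-tag bookkeeping
#'   `data.frame`).
#' @export
apply_plan <- function(train_records, plan, adjacency = adjacency_map(),
                       embedding = feature_embedding()) {
  stopifnot(inherits(plan, "mixshape_plan"))
  tags <- vapply(train_records, function(r) r$tag, character(1))
  by_tag <- split(seq_along(train_records), tags)
  ratio_tags <- names(plan$delta_os)
  homo_idx <- which(tags %in% CLASS_NAMES)
  get_tag <- function(tg) {
    if (is.null(by_tag[[tg]]))
      stop("training set is missing records for tag '", tg, "'")
    train_records[by_tag[[tg]]]
  }
  audit <- data.frame(tag = character(0), n_input = integer(0),
                      n_deleted = integer(0), n_added = integer(0),
                      n_final = integer(0), stringsAsFactors = FALSE)
  if (plan$method == "none")
    return(list(records = train_records, plan = plan, audit = audit))

  out_hetero <- list()
  delta_ds <- stats::setNames(rep(0L, length(ratio_tags)), ratio_tags)
  for (tg in ratio_tags) {
    recs <- get_tag(tg)
    n_in <- length(recs)
    n_del <- 0L
    delta <- plan$delta_os[[tg]]
    added <- list()
    if (plan$method == "random_os") {
      res <- random_oversample(recs, delta,
                               seed = child_seed(plan$seed, match(tg, ratio_tags)))
      kept <- res[seq_len(n_in)]
      added <- res[-seq_len(n_in)]
    } else if (plan$method == "smote") {
      nbr <- get_tag(adjacency$smote_neighbor[[tg]])
      added <- smote_soft(recs, nbr, delta, k = plan$knn_k,
                          embedding = embedding,
                          seed = child_seed(plan$seed, match(tg, ratio_tags)))
      kept <- recs
    } else if (plan$method == "borderline_smote") {
      comp <- get_tag(adjacency$borderline_competitor[[tg]])
      added <- borderline_smote_soft(recs, comp, delta, k = plan$knn_k,
                                     embedding = embedding,
                                     seed = child_seed(plan$seed,
                                                       match(tg, ratio_tags)))
      kept <- recs
    } else if (plan$method == "enn_then_random_os") {
      comp_tag <- adjacency$enn_competitor[tg]
      if (!is.na(comp_tag)) {
        edit <- enn_undersample(recs, get_tag(comp_tag[[1]]),
                                k = plan$knn_k, embedding = embedding)
        kept <- edit$kept
        n_del <- length(edit$deleted_ids)
      } else kept <- recs   # "2:1" has no competitor mapping: never edited
      res <- random_oversample(kept, delta,
                               seed = child_seed(plan$seed, match(tg, ratio_tags)))
      added <- res[-seq_len(length(kept))]
      if (delta == 0) added <- list()
    }
    delta_ds[[tg]] <- n_del
    out_hetero <- c(out_hetero, kept, added)
    audit <- rbind(audit, data.frame(
      tag = tg, n_input = n_in, n_deleted = n_del,
      n_added = length(added), n_final = n_in - n_del + length(added),
      stringsAsFactors = FALSE))
  }
  plan$delta_ds <- delta_ds
  # untouched homogeneous records plus any non-ratio hetero passthrough
  other_idx <- which(!(tags %in% ratio_tags))
  list(records = c(train_records[other_idx], out_hetero),
       plan = plan, audit = audit)
}
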