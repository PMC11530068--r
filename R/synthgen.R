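#' Phenotype shape/intensity parameters for the synthetic cell generator
#'
#' Describes one cell phenotype as distributions over per-cell shape and
#' intensity: fitted-ellipse eccentricity, area (px^2), a Fourier
#' boundary-roughness amplitude, interior gray level, and a texture grain
#' scale. The three phenotypes emulated are untreated oral cancer cells
#' (PARENTAL), their chemoresistant derivatives (RESISTANT) and normal
#' keratinocytes (CONTROL).
#'
#' @param name one of `"PARENTAL"`, `"RESISTANT"`, `"CONTROL"`.
#' @param eccentricity_mean,eccentricity_sd mean in `[0, 1)`, sd >= 0.
#' @param area_mean,area_sd cell area in pixels^2; mean > 0, sd >= 0.
#' @param boundary_roughness dimensionless amplitude of the random Fourier
#'   perturbation of the cell outline (0 = smooth ellipse).
#' @param intensity_mean,intensity_sd interior gray level in `[0, 1]`.
#' @param texture_grain spatial scale (pixels) of interior texture noise.
#' @return an object of class `mixshape_phenotype`.
#' @export
phenotype_params <- function(name,
                             eccentricity_mean, eccentricity_sd,
                             area_mean, area_sd,
                             boundary_roughness,
                             intensity_mean, intensity_sd,
                             texture_grain = 2) {
  name <- match.arg(name, CLASS_NAMES)
  stopifnot(eccentricity_mean >= 0, eccentricity_mean < 1,
            eccentricity_sd >= 0, area_mean > 0, area_sd >= 0,
            boundary_roughness >= 0, intensity_sd >= 0, texture_grain > 0)
  structure(list(name = name,
                 eccentricity_mean = eccentricity_mean,
                 eccentricity_sd = eccentricity_sd,
                 area_mean = area_mean, area_sd = area_sd,
                 boundary_roughness = boundary_roughness,
                 intensity_mean = intensity_mean,
                 intensity_sd = intensity_sd,
                 texture_grain = texture_grain),
            class = "mixshape_phenotype")
}

#' Default phenotype set with tunable PARENTAL/RESISTANT separation
#'
#' CONTROL is distinguished from the cancer classes by area and intensity;
#' PARENTAL and RESISTANT differ only in eccentricity and boundary
#' roughness, and `separation` scales that difference. At `separation = 0`
#' the two cancer phenotypes are identically distributed (chance-level
#' benchmark); at the default `separation = 1` the distributions overlap
#' but a per-image mean-eccentricity readout separates them well.
#'
#' @param separation nonnegative scale on the PARENTAL-vs-RESISTANT
#'   eccentricity/roughness gap.
#' @return named list of three [phenotype_params()] objects.
#' @export
default_phenotypes <- function(separation = 1) {
  stopifnot(separation >= 0)
  gap <- 0.175 * separation
  list(
    PARENTAL = phenotype_params("PARENTAL",
      eccentricity_mean = max(0, 0.6 - gap), eccentricity_sd = 0.08,
      area_mean = 45, area_sd = 8,
      boundary_roughness = 0.05,
      intensity_mean = 0.55, intensity_sd = 0.05),
    RESISTANT = phenotype_params("RESISTANT",
      eccentricity_mean = min(0.95, 0.6 + gap), eccentricity_sd = 0.08,
      area_mean = 45, area_sd = 8,
      boundary_roughness = 0.05 + 0.08 * separation,
      intensity_mean = 0.55, intensity_sd = 0.05),
    CONTROL = phenotype_params("CONTROL",
      eccentricity_mean = 0.45, eccentricity_sd = 0.1,
      area_mean = 80, area_sd = 12,
      boundary_roughness = 0.05,
      intensity_mean = 0.75, intensity_sd = 0.05)
  )
}

#' Render a single synthetic cell
#'
#' Draws eccentricity, area, orientation, interior intensity and a random
#' Fourier boundary perturbation from the phenotype distributions and
#' rasterizes a star-shaped (hence connected) cell mask plus a shaded
#' intensity patch. Deterministic given `rng_state`.
#'
#' @param params a [phenotype_params()] object.
#' @param rng_state integer seed controlling all draws.
#' @return list with `mask` (logical matrix), `patch` (numeric matrix in
#'   `[0, 1]`), and `draws` (the sampled eccentricity and area).
#' @export
render_cell <- function(params, rng_state) {
  stopifnot(inherits(params, "mixshape_phenotype"))
  with_seed_ms(rng_state, {
    ecc <- min(0.97, max(0, stats::rnorm(1, params$eccentricity_mean,
                                         params$eccentricity_sd)))
    area <- stats::rnorm(1, params$area_mean, params$area_sd)
    tries <- 0
    while (area < 4 && tries < 100) {   # never emit a degenerate mask
      area <- stats::rnorm(1, params$area_mean, params$area_sd)
      tries <- tries + 1
    }
    area <- max(area, 4)
    theta <- stats::runif(1, 0, pi)
    # ellipse with area A and eccentricity e: a = sqrt(A / (pi sqrt(1-e^2)))
    a <- sqrt(area / (pi * sqrt(1 - ecc^2)))
    b <- a * sqrt(1 - ecc^2)
    # Fourier perturbation of the polar radius, harmonics 2..5
    mh <- 2:5
    cm <- stats::rnorm(4) * params$boundary_roughness / sqrt(mh)
    sm <- stats::rnorm(4) * params$boundary_roughness / sqrt(mh)
    half <- ceiling(a * (1 + min(0.6, 3 * params$boundary_roughness)) + 1)
    n <- 2L * half + 1L
    xs <- seq_len(n) - half - 1L
    X <- matrix(xs, n, n, byrow = TRUE)   # col offset
    Y <- matrix(xs, n, n)                 # row offset
    u <- X * cos(theta) + Y * sin(theta)
    v <- -X * sin(theta) + Y * cos(theta)
    rho <- sqrt(u^2 + v^2)
    phi <- atan2(v, u)
    r_ell <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
    pert <- 1
    for (j in seq_along(mh))
      pert <- pert + cm[j] * cos(mh[j] * phi) + sm[j] * sin(mh[j] * phi)
    r_bound <- r_ell * pmax(pert, 0.3)
    mask <- rho <= r_bound
    if (!any(mask)) mask[half + 1L, half + 1L] <- TRUE
    base <- min(1, max(0.05, stats::rnorm(1, params$intensity_mean,
                                          params$intensity_sd)))
    # interior shading (brighter center) plus grain-scale texture noise
    shade <- base * (1 - 0.25 * pmin(1, rho / pmax(r_bound, 1e-6))^2)
    g <- max(1L, as.integer(round(params$texture_grain)))
    gn <- ceiling(n / g)
    coarse <- matrix(stats::rnorm(gn * gn, 0, 0.06), gn, gn)
    idx <- pmin(gn, ((seq_len(n) - 1L) %/% g) + 1L)
    tex <- coarse[idx, idx]
    patch <- matrix(pmin(1, pmax(0, (shade + tex) * mask)), n, n)
    list(mask = mask, patch = patch,
         draws = list(eccentricity = ecc, area = area, theta = theta))
  })
}

#' Fitted-ellipse eccentricity of a binary mask
#'
#' Second-central-moment eccentricity: with covariance eigenvalues
#' `l1 >= l2`, returns `sqrt(1 - l2/l1)`.
#'
#' @param mask logical matrix.
#' @return eccentricity in `[0, 1]`.
#' @export
mask_eccentricity <- function(mask) {
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 2) return(0)
  ctr <- colMeans(pts)
  dx <- pts[, 1] - ctr[1]; dy <- pts[, 2] - ctr[2]
  mu20 <- mean(dx^2); mu02 <- mean(dy^2); mu11 <- mean(dx * dy)
  tr <- mu20 + mu02
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(0, tr^2 / 4 - det))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(0, 1 - l2 / l1))
}

#' Specification of one synthetic scene (one image)
#'
#' @param canvas_size integer `(height, width, channels)`; channels must be 3.
#' @param cell_count number of cells to place (>= 1).
#' @param composition named numeric vector of phenotype fractions summing
#'   to 1 (names among PARENTAL/RESISTANT/CONTROL).
#' @param overlap_policy `"forbid"` (rejection-sample non-overlapping
#'   placements) or `"allow"`.
#' @param noise_sd background Gaussian noise sd (gray levels in `[0,1]`).
#' @param seed integer seed for the scene.
#' @return object of class `mixshape_scene_spec`.
#' @export
scene_spec <- function(canvas_size, cell_count, composition,
                       overlap_policy = c("forbid", "allow"),
                       noise_sd = 0.02, seed = 1L) {
  overlap_policy <- match.arg(overlap_policy)
  stopifnot(length(canvas_size) == 3, canvas_size[3] == 3, cell_count >= 1,
            abs(sum(composition) - 1) < 1e-9, all(composition >= 0),
            all(names(composition) %in% CLASS_NAMES))
  structure(list(canvas_size = as.integer(canvas_size),
                 cell_count = as.integer(cell_count),
                 composition = composition,
                 overlap_policy = overlap_policy,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "mixshape_scene_spec")
}

#' Render a full synthetic microscopy scene
#'
#' Places `cell_count` cells on a noisy background; per-phenotype counts
#' follow the declared composition under largest-remainder rounding (in
#' canonical class order PARENTAL, RESISTANT, CONTROL). The returned
#' record's metadata carries the realized counts and the mean drawn
#' eccentricity of its cells.
#'
#' @param spec a [scene_spec()].
#' @param phenotypes named list of [phenotype_params()] covering every
#'   phenotype in the composition.
#' @param tag population tag stored on the record (defaults to the single
#'   composition class, or the realized-count string).
#' @return an [image_record()].
#' @export
render_scene <- function(spec, phenotypes = default_phenotypes(), tag = NULL) {
  stopifnot(inherits(spec, "mixshape_scene_spec"))
  comp <- spec$composition[intersect(CLASS_NAMES, names(spec$composition))]
  counts <- largest_remainder(comp, spec$cell_count)
  names(counts) <- names(comp)
  H <- spec$canvas_size[1]; W <- spec$canvas_size[2]
  full_counts <- stats::setNames(integer(3), CLASS_NAMES)
  full_counts[names(counts)] <- counts
  with_seed_ms(spec$seed, {
    canvas <- matrix(0.15 + stats::rnorm(H * W, 0, spec$noise_sd), H, W)
    occupied <- matrix(FALSE, H, W)
    eccs <- numeric(0)
    cell_i <- 0L
    for (ph in names(counts)) {
      for (k in seq_len(counts[[ph]])) {
        cell_i <- cell_i + 1L
        cell <- render_cell(phenotypes[[ph]],
                            child_seed(spec$seed, cell_i))
        m <- nrow(cell$mask)
        half <- (m - 1L) %/% 2L
        placed <- FALSE
        for (try in 1:500) {
          # cells may be clipped at the image border, as in real
          # micrographs: the patch center lands anywhere on the canvas
          r0 <- sample.int(H, 1L) - half - 1L   # top-left, may be < 0
          c0 <- sample.int(W, 1L) - half - 1L
          rows <- max(1L, r0 + 1L):min(H, r0 + m)
          cols <- max(1L, c0 + 1L):min(W, c0 + m)
          prow <- rows - r0; pcol <- cols - c0
          sub_mask <- cell$mask[prow, pcol, drop = FALSE]
          if (!any(sub_mask)) next
          if (spec$overlap_policy == "forbid" &&
              any(occupied[rows, cols] & sub_mask)) next
          canvas[rows, cols][sub_mask] <-
            cell$patch[prow, pcol, drop = FALSE][sub_mask]
          occupied[rows, cols] <- occupied[rows, cols] | sub_mask
          placed <- TRUE
          break
        }
        if (!placed)
          stop("canvas ", H, "x", W, " too small to place ",
               spec$cell_count, " cells under overlap_policy='forbid'")
        eccs <- c(eccs, cell$draws$eccentricity)
      }
    }
    canvas <- matrix(pmin(1, pmax(0, canvas)), H, W)
    gains <- c(0.97, 1, 1.03)
    img <- array(0, c(H, W, 3L))
    for (ch in 1:3) img[, , ch] <- pmin(1, canvas * gains[ch])
    label <- soft_label(full_counts / sum(full_counts))
    if (is.null(tag)) {
      tag <- if (sum(comp > 0) == 1) names(comp)[comp > 0][1]
             else paste(full_counts, collapse = ":")
    }
    image_record(img, label = label, tag = tag,
                 source = "synthetic:render_scene",
                 meta = list(realized_counts = full_counts,
                             mean_eccentricity = mean(eccs),
                             seed = spec$seed))
  })
}

#' Generator presets (dataset geometry)
#'
#' The `paper`-scale preset mirrors the study design this package
#' emulates: 300 images per homogeneous class (900 total), 200 images per
#' mixture ratio for PARENTAL:RESISTANT ratios 1:2, 2:1, 1:3, 3:1 (800
#' total), native canvas 2048x2880x3. The `mini` preset (5 per class, 4
#' per ratio, 32x32 canvas) exists for fast tests.
#'
#' @param homo_per_class images per homogeneous class.
#' @param hetero_per_ratio images per mixture ratio.
#' @param ratios character vector of `"a:b"` PARENTAL:RESISTANT ratios.
#' @param native_size recorded acquisition size `(H, W, C)`.
#' @param canvas_size rendering canvas `(H, W, C)`.
#' @param cells_per_image cells placed per scene.
#' @return object of class `mixshape_preset`.
#' @export
generator_preset <- function(homo_per_class, hetero_per_ratio,
                             ratios = RATIO_TAGS,
                             native_size = c(2048, 2880, 3),
                             canvas_size = c(64, 64, 3),
                             cells_per_image = 6) {
  stopifnot(homo_per_class >= 1, hetero_per_ratio >= 0,
            all(vapply(ratios, is_ratio_tag, logical(1))))
  structure(list(homo_per_class = as.integer(homo_per_class),
                 hetero_per_ratio = as.integer(hetero_per_ratio),
                 ratios = ratios,
                 native_size = as.integer(native_size),
                 canvas_size = as.integer(canvas_size),
                 cells_per_image = as.integer(cells_per_image)),
            class = "mixshape_preset")
}

#' @rdname generator_preset
#' @export
preset_paper <- function(canvas_size = c(2048, 2880, 3),
                         cells_per_image = 6) {
  generator_preset(300, 200, RATIO_TAGS,
                   native_size = c(2048, 2880, 3),
                   canvas_size = canvas_size,
                   cells_per_image = cells_per_image)
}

#' @rdname generator_preset
#' @export
preset_mini <- function() {
  generator_preset(5, 4, RATIO_TAGS,
                   native_size = c(32, 32, 3),
                   canvas_size = c(32, 32, 3),
                   cells_per_image = 4)
}

tag_to_composition <- function(tag) {
  y <- assign_soft_label(tag)
  stats::setNames(as.numeric(y), CLASS_NAMES)
}

tag_to_filename <- function(tag) gsub(":", "to", tag)

#' Generate a complete synthetic dataset on disk
#'
#' Writes `homo_per_class` images for each of PARENTAL, RESISTANT and
#' CONTROL plus `hetero_per_ratio` images per mixture ratio (mixtures
#' contain no CONTROL cells), along with a CSV manifest with soft labels.
#' Fully reproducible from `seed` (byte-identical files).
#'
#' @param preset a [generator_preset()].
#' @param out_dir output directory (created if missing; refuses to write
#'   into a non-empty directory unless `overwrite = TRUE`).
#' @param seed integer master seed.
#' @param format `"tiff"` (default) or `"png"`.
#' @param phenotypes named list of [phenotype_params()].
#' @param overlap_policy cell placement policy; `"allow"` emulates
#'   confluent cultures where cells touch and partially occlude.
#' @param overwrite allow writing into a non-empty directory.
#' @return the manifest `data.frame` (invisibly); also written to
#'   `out_dir/manifest.csv`. Columns: `path, tag, y_parental, y_resistant,
#'   y_control, seed, realized_counts`.
#' @export
generate_dataset <- function(preset, out_dir, seed,
                             format = c("tiff", "png"),
                             phenotypes = default_phenotypes(),
                             overlap_policy = c("forbid", "allow"),
                             overwrite = FALSE) {
  stopifnot(inherits(preset, "mixshape_preset"))
  format <- match.arg(format)
  overlap_policy <- match.arg(overlap_policy)
  ext <- if (format == "tiff") "tif" else "png"
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !overwrite)
    stop("out_dir '", out_dir, "' is not empty; pass overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tags <- c(rep(CLASS_NAMES, each = preset$homo_per_class),
            rep(preset$ratios, each = preset$hetero_per_ratio))
  rows <- vector("list", length(tags))
  within_idx <- stats::ave(seq_along(tags), tags, FUN = seq_along)
  for (i in seq_along(tags)) {
    tag <- tags[i]
    comp <- tag_to_composition(tag)
    sp <- scene_spec(preset$canvas_size, preset$cells_per_image,
                     comp[comp > 0], overlap_policy = overlap_policy,
                     seed = child_seed(seed, i))
    rec <- render_scene(sp, phenotypes, tag = tag)
    fname <- sprintf("%s_%04d.%s", tag_to_filename(tag), within_idx[i], ext)
    path <- file.path(out_dir, fname)
    if (format == "tiff") tiff::writeTIFF(rec$image, path,
                                          bits.per.sample = 8L)
    else png::writePNG(rec$image, path)
    y <- rec$label
    rows[[i]] <- data.frame(
      path = fname, tag = tag,
      y_parental = y[1], y_resistant = y[2], y_control = y[3],
      seed = sp$seed,
      realized_counts = paste(rec$meta$realized_counts, collapse = "/"),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a dataset manifest written by [generate_dataset()]
#' @param dir dataset directory containing `manifest.csv`.
#' @return manifest `data.frame`.
#' @export
read_manifest <- function(dir) {
  path <- if (dir.exists(dir)) file.path(dir, "manifest.csv") else dir
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(path = "character", tag = "character"))
}

#' Load image records listed in a manifest
#' @param manifest manifest `data.frame` (possibly subset).
#' @param dir directory holding the image files.
#' @return list of [image_record()] objects.
#' @export
load_records <- function(manifest, dir) {
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- file.path(dir, manifest$path[i])
    img <- if (grepl("\\.tiff?$", p)) tiff::readTIFF(p) else png::readPNG(p)
    if (length(dim(img)) == 2) img <- array(img, c(dim(img), 1L))
    image_record(img,
                 label = soft_label(c(manifest$y_parental[i],
                                      manifest$y_resistant[i],
                                      manifest$y_control[i])),
                 tag = manifest$tag[i], source = manifest$path[i])
  })
}
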