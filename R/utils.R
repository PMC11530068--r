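#' @keywords internal
"_PACKAGE"

# Largest-remainder apportionment: integer counts summing exactly to `total`,
# proportional to `weights`. Ties broken by index order (deterministic).
largest_remainder <- function(weights, total) {
  stopifnot(is.numeric(weights), length(weights) >= 1, total >= 0)
  if (any(weights < 0)) stop("weights must be nonnegative")
  s <- sum(weights)
  if (s <= 0) stop("weights must not all be zero")
  quota <- weights / s * total
  base <- floor(quota + 1e-12)
  deficit <- as.integer(round(total - sum(base)))
  if (deficit > 0) {
    rem <- quota - base
    take <- order(-rem, seq_along(rem))[seq_len(deficit)]
    base[take] <- base[take] + 1
  }
  as.integer(base)
}

# Deterministic child seed derivation, kept within 32-bit integer range.
child_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + as.double(i) * 1299709) %% 2147483647)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed_ms <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

CLASS_NAMES <- c("PARENTAL", "RESISTANT", "CONTROL")
RATIO_TAGS <- c("1:2", "2:1", "1:3", "3:1")

is_ratio_tag <- function(tag) grepl("^[0-9]+:[0-9]+$", tag)

# (H, W, C) -> (H', W', C) bilinear resize, wrapping EBImage (which stores
# images x-major, i.e. transposed relative to our row/col convention).
resize_bilinear <- function(img, out_h, out_w) {
  was_2d <- length(dim(img)) == 2
  if (was_2d) img <- array(img, c(dim(img), 1L))
  d <- dim(img)
  if (d[1] == out_h && d[2] == out_w) {
    out <- img
  } else {
    eb <- aperm(img, c(2, 1, 3))
    res <- EBImage::resize(EBImage::Image(eb, colormode = "Grayscale"),
                           w = out_w, h = out_h, filter = "bilinear")
    out <- aperm(array(as.array(res), c(out_w, out_h, d[3])), c(2, 1, 3))
  }
  if (was_2d) out <- out[, , 1]
  out
}
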