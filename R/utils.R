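#' @keywords internal
"_PACKAGE"

# Deterministic 32-bit seed derivation: one master seed fans out to per-image /
# per-run seeds without correlated streams. Kept below 2^31 - 1.
derive_seed <- function(master, index) {
  m <- 2147483647
  x <- (as.double(master) %% m) * 48271 + as.double(index) * 1013904223
  as.integer(x %% m)
}

# Run `expr` under a local RNG state seeded with `seed`; restores the caller's
# RNG so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Intersection over union of two axis-aligned boxes
#'
#' Boxes use 0-based, half-open pixel coordinates `(x_min, y_min, x_max, y_max)`,
#' so a box covering one pixel at the origin is `c(0, 0, 1, 1)` and its area is
#' `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param a,b Numeric length-4 vectors `(x_min, y_min, x_max, y_max)` with
#'   `x_min < x_max`, `y_min < y_max`.
#' @return A single number in `[0, 1]`; 1 iff the boxes are identical and 0 when
#'   they are disjoint.
#' @examples
#' iou(c(0, 0, 2, 2), c(1, 1, 3, 3)) # 1/7
#' @export
iou <- function(a, b) {
  iw <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  ih <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (union <= 0) return(0)
  inter / union
}

# Vectorised IoU of one box against a matrix of boxes (rows).
iou_one_many <- function(a, B) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 4)
  iw <- pmax(0, pmin(a[3], B[, 3]) - pmax(a[1], B[, 1]))
  ih <- pmax(0, pmin(a[4], B[, 4]) - pmax(a[2], B[, 2]))
  inter <- iw * ih
  union <- (a[3] - a[1]) * (a[4] - a[2]) +
    (B[, 3] - B[, 1]) * (B[, 4] - B[, 2]) - inter
  out <- ifelse(union <= 0, 0, inter / union)
  out
}

box_area <- function(B) {
  if (is.null(dim(B))) B <- matrix(B, ncol = 4)
  (B[, 3] - B[, 1]) * (B[, 4] - B[, 2])
}
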