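# Small image-processing primitives shared by the phantom generator,
# preprocessing and segmentation stages. Kept dependency-free: images are
# plain numeric matrices [row, col].

# Evaluate expr with a private RNG stream; the caller's .Random.seed is
# untouched, so all package randomness flows through explicit seeds.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Translate an image by a (possibly fractional) pixel offset
#'
#' Content moves by `+dy` rows / `+dx` columns; values are bilinearly
#' interpolated. `mode = "clamp"` replicates edge pixels, `mode = "wrap"`
#' treats the image as periodic (used by intensity-preservation checks).
#'
#' @param img numeric matrix.
#' @param dy,dx translation in pixels (rows, cols).
#' @param mode `"clamp"` or `"wrap"`.
#' @return translated matrix of the same size.
#' @export
translate_image <- function(img, dy, dx, mode = c("clamp", "wrap")) {
  mode <- match.arg(mode)
  nr <- nrow(img); nc <- ncol(img)
  if (dy == 0 && dx == 0) return(img)
  # sample source coordinates (content shifts by +dy/+dx)
  ry <- seq_len(nr) - dy
  rx <- seq_len(nc) - dx
  y0 <- floor(ry); x0 <- floor(rx)
  fy <- ry - y0;  fx <- rx - x0
  idx <- function(i, n) {
    if (mode == "clamp") pmin(pmax(i, 1L), n)
    else ((i - 1L) %% n) + 1L
  }
  y0i <- idx(y0, nr); y1i <- idx(y0 + 1, nr)
  x0i <- idx(x0, nc); x1i <- idx(x0 + 1, nc)
  wy <- matrix(fy, nr, nc); wx <- matrix(fx, nr, nc, byrow = TRUE)
  img[y0i, x0i] * (1 - wy) * (1 - wx) +
    img[y1i, x0i] * wy * (1 - wx) +
    img[y0i, x1i] * (1 - wy) * wx +
    img[y1i, x1i] * wy * wx
}

# Row-normalized 1-D Gaussian smoothing operator (n x n). Each output pixel
# is a weighted average of in-bounds pixels only, so edges are unbiased and
# sigma -> Inf converges to the global mean.
gauss_operator <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- outer(seq_len(n), seq_len(n), "-")
  K <- exp(-0.5 * (d / sigma)^2)
  K[abs(d) > 4 * sigma] <- 0
  K / rowSums(K)
}

# Separable Gaussian blur with edge renormalization.
gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  Kr <- gauss_operator(nrow(img), sigma)
  Kc <- gauss_operator(ncol(img), sigma)
  Kr %*% img %*% t(Kc)
}

# 4-connected component labeling for a logical matrix (BFS flood fill).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L; c <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1L && d[1] <= nr && d[2] >= 1L && d[2] <= nc) {
          q <- (d[2] - 1L) * nr + d[1]
          if (mask[q] && lab[q] == 0L) { lab[q] <- cur; queue <- c(queue, q) }
        }
      }
    }
  }
  lab
}

disk_kernel <- function(radius) {
  r <- ceiling(radius)
  d <- outer(-r:r, -r:r, function(y, x) sqrt(x^2 + y^2))
  d <= radius + 1e-9
}

# Binary dilation/erosion with a disk structuring element, via convolution.
morph <- function(mask, radius, op = c("dilate", "erode")) {
  op <- match.arg(op)
  if (radius <= 0) return(mask)
  k <- disk_kernel(radius)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- (nrow(k) - 1L) / 2L
  if (op == "erode") {
    big <- matrix(FALSE, nr + 2 * pad, nc + 2 * pad)
  } else {
    big <- matrix(FALSE, nr + 2 * pad, nc + 2 * pad)
  }
  big[pad + seq_len(nr), pad + seq_len(nc)] <- mask
  out <- matrix(op == "erode", nr, nc)
  offs <- which(k, arr.ind = TRUE) - pad - 1L
  for (i in seq_len(nrow(offs))) {
    sub <- big[pad + seq_len(nr) + offs[i, 1], pad + seq_len(nc) + offs[i, 2]]
    out <- if (op == "erode") out & sub else out | sub
  }
  out
}

morph_close <- function(mask, radius) {
  morph(morph(mask, radius, "dilate"), radius, "erode")
}

# Image angle (radians, CCW in the displayed image: +x right, +y up) of each
# pixel about a center given as (row, col).
pixel_angles <- function(nr, nc, center) {
  yy <- matrix(seq_len(nr), nr, nc) - center[1]
  xx <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2]
  atan2(-yy, xx)
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
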