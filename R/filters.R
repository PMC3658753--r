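# Separable Gaussian filtering with reflective (half-sample symmetric)
# padding, realised as banded convolution matrices so a 2-D blur is two BLAS
# products: K_M %*% X %*% t(K_N). With a symmetric kernel this boundary rule
# preserves the channel mean exactly, which the pipeline's invariants rely on.

.blur_cache <- new.env(parent = emptyenv())

gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3.5 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k / sum(k)
}

# n x n convolution matrix for kernel k with reflective boundary
conv_matrix <- function(n, sigma) {
  key <- paste0(n, "_", sigma)
  hit <- .blur_cache[[key]]
  if (!is.null(hit)) return(hit)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  i <- seq_len(n)
  for (d in -r:r) {
    j <- i + d
    # half-sample symmetric reflection, repeated for kernels wider than n
    repeat {
      bad_lo <- j < 1L
      bad_hi <- j > n
      if (!any(bad_lo) && !any(bad_hi)) break
      j[bad_lo] <- 1L - j[bad_lo]
      j[bad_hi] <- 2L * n + 1L - j[bad_hi]
    }
    idx <- cbind(i, j)
    K[idx] <- K[idx] + k[d + r + 1L]
  }
  .blur_cache[[key]] <- K
  K
}

blur_matrix <- function(m, sigma) {
  KM <- conv_matrix(nrow(m), sigma)
  KN <- conv_matrix(ncol(m), sigma)
  KM %*% m %*% t(KN)
}

#' Gaussian blur with reflective boundary
#'
#' Channel-wise 2-D Gaussian convolution with half-sample symmetric
#' (reflective) padding. Because the kernel is symmetric, this boundary rule
#' preserves the mean of each channel exactly; constants pass through
#' unchanged.
#'
#' @param image a numeric matrix, an `M x N x C` array, or a
#'   [quaternion_image] (blurred part-wise).
#' @param sigma standard deviation of the Gaussian, in pixels (> 0).
#' @return The blurred object, same type and dimensions as the input.
#' @export
gaussian_blur <- function(image, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("sigma must be a single positive number", call. = FALSE)
  if (inherits(image, "quaternion_image")) {
    return(quaternion_image(blur_matrix(image$w, sigma),
                            blur_matrix(image$x, sigma),
                            blur_matrix(image$y, sigma),
                            blur_matrix(image$z, sigma)))
  }
  if (is.matrix(image)) return(blur_matrix(image, sigma))
  if (is.array(image) && length(dim(image)) == 3L) {
    out <- image
    for (c in seq_len(dim(image)[3])) out[, , c] <- blur_matrix(image[, , c], sigma)
    return(out)
  }
  stop("image must be a matrix, a 3-D array or a quaternion_image", call. = FALSE)
}

# Bilinear resize of a matrix to new_h x new_w. EBImage's first array
# dimension corresponds to our row (height) dimension.
resize_grid <- function(m, new_h, new_w) {
  if (nrow(m) == new_h && ncol(m) == new_w) return(m)
  unclass(EBImage::resize(m, w = new_h, h = new_w, filter = "bilinear"))
}

resize_rgb <- function(rgb, new_h, new_w) {
  d <- dim(rgb)
  if (d[1] == new_h && d[2] == new_w) return(rgb)
  out <- array(0, c(new_h, new_w, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- resize_grid(rgb[, , c], new_h, new_w)
  out
}

# RGB array in [0,1] -> HSV array in [0,1]
rgb_to_hsv_array <- function(rgb) {
  d <- dim(rgb)
  hsv <- grDevices::rgb2hsv(r = as.vector(rgb[, , 1]),
                            g = as.vector(rgb[, , 2]),
                            b = as.vector(rgb[, , 3]),
                            maxColorValue = 1)
  array(c(hsv[1, ], hsv[2, ], hsv[3, ]), c(d[1], d[2], 3))
}
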