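#' Quaternion-valued image grids
#'
#' A `quaternion_image` stores one quaternion `w + x i + y j + z k` per pixel
#' as four real matrices of identical dimension. HSV-encoded images are *pure*
#' (`w = 0` everywhere); spatio-temporal images carry a motion cue in the
#' scalar part `w`.
#'
#' @param w,x,y,z numeric matrices of identical dimension: the scalar part and
#'   the coefficients of the quaternion units i, j, k.
#' @return An object of class `quaternion_image`: a list with elements
#'   `w`, `x`, `y`, `z`.
#' @examples
#' q <- quaternion_image(matrix(0, 2, 2), matrix(1, 2, 2),
#'                       matrix(0, 2, 2), matrix(0, 2, 2))
#' dim(q)
#' @export
quaternion_image <- function(w, x, y, z) {
  parts <- list(w = w, x = x, y = y, z = z)
  d <- dim(w)
  if (is.null(d) || length(d) != 2L)
    stop("quaternion_image parts must be matrices", call. = FALSE)
  for (p in parts) {
    if (!is.numeric(p) || !identical(dim(p), d))
      stop("all four quaternion parts must be numeric matrices of equal dimension",
           call. = FALSE)
  }
  structure(parts, class = "quaternion_image")
}

#' @export
dim.quaternion_image <- function(x) dim(x$w)

#' @export
print.quaternion_image <- function(x, ...) {
  d <- dim(x)
  pure <- all(x$w == 0)
  cat(sprintf("<quaternion_image> %d x %d (%s)\n", d[1], d[2],
              if (pure) "pure" else "full"))
  invisible(x)
}

#' Hamilton product of two quaternions
#'
#' Multiplies quaternions given as length-4 numeric vectors `c(w, x, y, z)`,
#' using the non-commutative rules `i^2 = j^2 = k^2 = -1`, `ij = k`,
#' `jk = i`, `ki = j` (and anti-commuting reverses).
#'
#' @param a,b length-4 numeric vectors `c(w, x, y, z)`.
#' @return A length-4 numeric vector, the product `a * b`.
#' @examples
#' quat_multiply(c(0, 1, 0, 0), c(0, 0, 1, 0))  # i * j = k
#' @export
quat_multiply <- function(a, b) {
  stopifnot(length(a) == 4L, length(b) == 4L)
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion norm
#'
#' @param a length-4 numeric vector `c(w, x, y, z)`.
#' @return `sqrt(w^2 + x^2 + y^2 + z^2)`.
#' @export
quat_norm <- function(a) sqrt(sum(a^2))

# squared pixel-wise modulus of a quaternion image
qimg_norm2 <- function(q) q$w^2 + q$x^2 + q$y^2 + q$z^2

#' Encode an HSV image as a pure quaternion grid
#'
#' Each pixel `(H, S, V)` becomes the pure quaternion `H i + S j + V k`.
#' All three channels must lie in `[0, 1]`; hue enters as a plain coordinate
#' (no wrap-around treatment).
#'
#' @param hsv an `M x N x 3` numeric array with channels H, S, V in `[0, 1]`.
#' @return A pure [quaternion_image] (`w = 0` everywhere).
#' @export
encode_hsv <- function(hsv) {
  if (!is.array(hsv) || length(dim(hsv)) != 3L || dim(hsv)[3] != 3L)
    stop("hsv must be an M x N x 3 array", call. = FALSE)
  if (anyNA(hsv) || min(hsv) < 0 || max(hsv) > 1)
    stop("HSV channel values must lie in [0, 1]", call. = FALSE)
  d <- dim(hsv)
  ch <- function(i) matrix(hsv[, , i], d[1], d[2])
  quaternion_image(matrix(0, d[1], d[2]), ch(1), ch(2), ch(3))
}

#' Encode a motion cue and HSV image as a full quaternion grid
#'
#' The spatio-temporal encoding places the motion cue in the scalar part:
#' `q_t = M_t + H_t i + S_t j + V_t k`. With a zero motion field this reduces
#' exactly to [encode_hsv()].
#'
#' @param motion an `M x N` numeric matrix (signed motion cue).
#' @param hsv an `M x N x 3` HSV array in `[0, 1]`.
#' @return A [quaternion_image] with `w = motion`.
#' @export
encode_spatiotemporal <- function(motion, hsv) {
  if (!is.matrix(motion))
    stop("motion must be a matrix", call. = FALSE)
  if (!is.array(hsv) || length(dim(hsv)) != 3L || dim(hsv)[3] != 3L)
    stop("hsv must be an M x N x 3 array", call. = FALSE)
  if (!identical(dim(motion), dim(hsv)[1:2]))
    stop("motion and hsv_image dimensions differ", call. = FALSE)
  if (anyNA(hsv) || min(hsv) < 0 || max(hsv) > 1)
    stop("HSV channel values must lie in [0, 1]", call. = FALSE)
  d <- dim(hsv)
  ch <- function(i) matrix(hsv[, , i], d[1], d[2])
  quaternion_image(motion, ch(1), ch(2), ch(3))
}

#' Symplectic decomposition of a quaternion image
#'
#' Splits `q = f1 + f2 j` into two complex grids lying in the subfield
#' spanned by `{1, i}`: `f1 = w + x i` and `f2 = y + z i`. This is the step
#' that lets the hypercomplex Fourier transform be computed as two ordinary
#' complex FFTs.
#'
#' @param q a [quaternion_image].
#' @return An object of class `symplectic_pair`: list of complex matrices
#'   `f1`, `f2`.
#' @seealso [symplectic_recompose()]
#' @export
symplectic_decompose <- function(q) {
  stopifnot(inherits(q, "quaternion_image"))
  structure(list(f1 = q$w + 1i * q$x, f2 = q$y + 1i * q$z),
            class = "symplectic_pair")
}

#' Recompose a symplectic pair into a quaternion image
#'
#' Inverse of [symplectic_decompose()]: `q = f1 + f2 j`, i.e.
#' `w = Re f1`, `x = Im f1`, `y = Re f2`, `z = Im f2`.
#'
#' @param pair a `symplectic_pair`.
#' @return A [quaternion_image].
#' @export
symplectic_recompose <- function(pair) {
  stopifnot(inherits(pair, "symplectic_pair"))
  quaternion_image(Re(pair$f1), Im(pair$f1), Re(pair$f2), Im(pair$f2))
}

new_quaternion_spectrum <- function(w, x, y, z) {
  structure(list(w = w, x = x, y = y, z = z,
                 amplitude = NULL, unit_phase = NULL, zero_flag = NULL),
            class = "quaternion_spectrum")
}

#' @export
dim.quaternion_spectrum <- function(x) dim(x$w)

#' @export
print.quaternion_spectrum <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<quaternion_spectrum> %d x %d%s\n", d[1], d[2],
              if (!is.null(x$amplitude)) " (polar-decomposed)" else ""))
  invisible(x)
}

#' Forward hypercomplex Fourier transform
#'
#' Computes the left-sided quaternion DFT with transform axis i of a
#' quaternion image, via the symplectic decomposition: the two complex grids
#' `f1`, `f2` are transformed with ordinary unitary 2-D FFTs and recombined as
#' `Q = F1 + F2 j`. The unitary normalisation `1/sqrt(MN)` is used on both the
#' forward and the inverse transform, so the pair is a true inverse pair and
#' Parseval's identity holds.
#'
#' Frequency indexing is row-major with the DC term at index (1, 1) in R's
#' 1-based convention (no fftshift).
#'
#' @param q a [quaternion_image].
#' @return A `quaternion_spectrum` (polar fields unset; see
#'   [polar_decompose()]).
#' @export
hft_forward <- function(q) {
  stopifnot(inherits(q, "quaternion_image"))
  d <- dim(q)
  s <- sqrt(prod(d))
  p <- symplectic_decompose(q)
  F1 <- stats::fft(p$f1) / s
  F2 <- stats::fft(p$f2) / s
  new_quaternion_spectrum(Re(F1), Im(F1), Re(F2), Im(F2))
}

#' Inverse hypercomplex Fourier transform
#'
#' Inverts [hft_forward()] (unitary convention). The result is a full
#' quaternion image `a + b i + c j + d k`; after spectral-contrast filtering
#' the scalar part is generally non-zero even for a pure input.
#'
#' @param Q a `quaternion_spectrum`.
#' @return A [quaternion_image].
#' @export
hft_inverse <- function(Q) {
  stopifnot(inherits(Q, "quaternion_spectrum"))
  d <- dim(Q)
  s <- sqrt(prod(d))
  f1 <- stats::fft(Q$w + 1i * Q$x, inverse = TRUE) / s
  f2 <- stats::fft(Q$y + 1i * Q$z, inverse = TRUE) / s
  quaternion_image(Re(f1), Im(f1), Re(f2), Im(f2))
}

#' Polar decomposition of a quaternion spectrum
#'
#' Writes each frequency component as amplitude times a unit quaternion,
#' `Q = ||Q|| * (Q / ||Q||)`. Two readings of the phase factor are available:
#'
#' * `axis = "eigen"` (default): the per-frequency eigenaxis form
#'   `Q/||Q||`, which preserves all structural information and satisfies
#'   `amplitude * unit_phase == Q` exactly wherever the amplitude is positive.
#' * `axis = "j"`: the literal fixed-axis form `cos(phi) + sin(phi) j` with
#'   `phi = atan2(|vector part|, w)`. This is lossy outside the `{1, j}`
#'   subfield and is provided for comparison only.
#'
#' Zero-amplitude frequencies get the identity quaternion as unit phase and
#' are flagged in `zero_flag`; downstream spectral contrast assigns them a
#' zero coefficient, avoiding 0/0.
#'
#' @param Q a `quaternion_spectrum`.
#' @param axis `"eigen"` or `"j"`.
#' @param tol amplitudes at or below this are treated as zero.
#' @return `Q` with `amplitude` (matrix), `unit_phase` (list of four
#'   matrices), `phi` (phase-angle matrix) and `zero_flag` (logical matrix)
#'   filled in.
#' @export
polar_decompose <- function(Q, axis = c("eigen", "j"), tol = 1e-12) {
  stopifnot(inherits(Q, "quaternion_spectrum"))
  axis <- match.arg(axis)
  amp <- sqrt(Q$w^2 + Q$x^2 + Q$y^2 + Q$z^2)
  zero <- amp <= tol
  safe <- ifelse(zero, 1, amp)
  vnorm <- sqrt(Q$x^2 + Q$y^2 + Q$z^2)
  phi <- atan2(vnorm, Q$w)
  if (axis == "eigen") {
    up <- list(w = Q$w / safe, x = Q$x / safe, y = Q$y / safe, z = Q$z / safe)
  } else {
    up <- list(w = cos(phi), x = 0 * phi, y = sin(phi), z = 0 * phi)
  }
  up$w[zero] <- 1
  up$x[zero] <- 0
  up$y[zero] <- 0
  up$z[zero] <- 0
  phi[zero] <- 0
  Q$amplitude <- amp
  Q$unit_phase <- up
  Q$phi <- phi
  Q$zero_flag <- zero
  Q
}

#' Brute-force quaternion DFT (test oracle)
#'
#' Direct O((MN)^2) evaluation of the left-sided, axis-i, unitary quaternion
#' DFT: `Q[u,v] = (MN)^(-1/2) sum_{x,y} e^{-i 2 pi (x u / N + y v / M)} q(x,y)`
#' with left multiplication by the complex exponential. Used as an
#' independent cross-check of [hft_forward()]; guarded to small grids.
#'
#' @param q a [quaternion_image] with at most 4096 pixels.
#' @return A `quaternion_spectrum`.
#' @export
quaternion_dft_bruteforce <- function(q) {
  stopifnot(inherits(q, "quaternion_image"))
  d <- dim(q)
  M <- d[1]; N <- d[2]
  if (M * N > 4096)
    stop("grid too large for brute-force DFT (M*N must be <= 4096)", call. = FALSE)
  yy <- matrix(0:(M - 1), M, N)         # row index (height M)
  xx <- matrix(0:(N - 1), M, N, byrow = TRUE)  # column index (width N)
  out <- lapply(1:4, function(i) matrix(0, M, N))
  names(out) <- c("w", "x", "y", "z")
  for (v in 0:(N - 1)) {
    for (u in 0:(M - 1)) {
      theta <- 2 * pi * (xx * v / N + yy * u / M)
      a <- cos(theta)
      b <- -sin(theta)
      # left product (a + b i)(w + x i + y j + z k)
      out$w[u + 1, v + 1] <- sum(a * q$w - b * q$x)
      out$x[u + 1, v + 1] <- sum(a * q$x + b * q$w)
      out$y[u + 1, v + 1] <- sum(a * q$y - b * q$z)
      out$z[u + 1, v + 1] <- sum(a * q$z + b * q$y)
    }
  }
  s <- sqrt(M * N)
  new_quaternion_spectrum(out$w / s, out$x / s, out$y / s, out$z / s)
}
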