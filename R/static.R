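#' Configuration for the spectral-contrast saliency pipeline
#'
#' Collects the tunable parameters of the static and spatio-temporal
#' pipelines. Defaults follow the model's standard operating point: scales
#' \{1, 0.5, 0.25\}, Gaussian sigma 3 px, a 320 x 240 working resolution for
#' still images and 128 x 128 for video.
#'
#' @param scales numeric vector of scale factors in (0, 1]; the multi-scale
#'   map is the plain average over these scales.
#' @param blur_sigma Gaussian standard deviation (pixels) used both for the
#'   energy-averaging blur that defines the spectral contrast and for the
#'   final map smoothing.
#' @param base_resolution `c(width, height)` working resolution for still
#'   images; the saliency map is computed here and resized back to the input
#'   size at the end.
#' @param video_resolution `c(width, height)` working resolution for video
#'   frames.
#' @param log_epsilon small positive stabiliser added to both squared
#'   amplitudes inside the log ratio.
#' @param center_bias logical; divide the multi-scale map by the logarithmic
#'   centre-distance weight `1 + log(1 + r / r_half_diag)`.
#' @param polar_axis `"eigen"` or `"j"`; see [polar_decompose()].
#' @param motion_variant `"as_printed"` (five-tap weights (1, -4, -1, 4, -1)/8)
#'   or `"zero_sum"` (the central tap dropped so a static scene gives exactly
#'   zero motion); see [motion_cue()].
#' @return A list of class `hsc_config`.
#' @export
hsc_config <- function(scales = c(1, 0.5, 0.25),
                       blur_sigma = 3,
                       base_resolution = c(320, 240),
                       video_resolution = c(128, 128),
                       log_epsilon = 1e-12,
                       center_bias = TRUE,
                       polar_axis = c("eigen", "j"),
                       motion_variant = c("as_printed", "zero_sum")) {
  polar_axis <- match.arg(polar_axis)
  motion_variant <- match.arg(motion_variant)
  if (length(scales) < 1L || any(scales <= 0) || any(scales > 1))
    stop("scales must be a non-empty vector with values in (0, 1]", call. = FALSE)
  if (blur_sigma <= 0) stop("blur_sigma must be > 0", call. = FALSE)
  if (log_epsilon <= 0) stop("log_epsilon must be > 0", call. = FALSE)
  if (length(base_resolution) != 2L || any(base_resolution < 1))
    stop("base_resolution must be c(width, height), both >= 1", call. = FALSE)
  if (length(video_resolution) != 2L || any(video_resolution < 1))
    stop("video_resolution must be c(width, height), both >= 1", call. = FALSE)
  structure(list(scales = scales,
                 blur_sigma = blur_sigma,
                 base_resolution = as.integer(base_resolution),
                 video_resolution = as.integer(video_resolution),
                 log_epsilon = log_epsilon,
                 center_bias = isTRUE(center_bias),
                 polar_axis = polar_axis,
                 motion_variant = motion_variant),
            class = "hsc_config")
}

new_saliency_map <- function(values, normalized = FALSE) {
  structure(values, class = c("saliency_map", class(matrix())),
            normalized = normalized)
}

#' @export
print.saliency_map <- function(x, ...) {
  cat(sprintf("<saliency_map> %d x %d, range [%.4g, %.4g]%s\n",
              nrow(x), ncol(x), min(x), max(x),
              if (isTRUE(attr(x, "normalized"))) " (normalized to [0,255])" else ""))
  invisible(x)
}

as_matrix_map <- function(S) {
  m <- unclass(S)
  attr(m, "normalized") <- NULL
  m
}

#' Hypercomplex spectral contrast
#'
#' Per-frequency contrast between a raw and a blurred spectrum: the log ratio
#' of squared amplitudes, carried on the raw spectrum's unit phase,
#' `CQ(u,v) = ln((|Q_raw|^2 + eps) / (|Q_blur|^2 + eps)) * unit_phase_raw(u,v)`.
#' Frequencies whose raw amplitude is at or below 1e-12 contribute a zero
#' coefficient.
#'
#' @param Q_raw,Q_blur polar-decomposed `quaternion_spectrum` objects of equal
#'   dimension (see [polar_decompose()]).
#' @param eps positive stabiliser added to both squared amplitudes.
#' @return A `quaternion_spectrum` holding the contrast-weighted phase.
#' @export
spectral_contrast <- function(Q_raw, Q_blur, eps = 1e-12) {
  stopifnot(inherits(Q_raw, "quaternion_spectrum"),
            inherits(Q_blur, "quaternion_spectrum"))
  if (!identical(dim(Q_raw), dim(Q_blur)))
    stop("spectra have different dimensions", call. = FALSE)
  if (is.null(Q_raw$amplitude) || is.null(Q_blur$amplitude))
    stop("both spectra must be polar-decomposed first", call. = FALSE)
  coef <- log((Q_raw$amplitude^2 + eps) / (Q_blur$amplitude^2 + eps))
  coef[Q_raw$amplitude <= 1e-12] <- 0
  up <- Q_raw$unit_phase
  new_quaternion_spectrum(coef * up$w, coef * up$x, coef * up$y, coef * up$z)
}

# Core single-resolution pass: quaternion image -> raw (unnormalised)
# saliency matrix at the same resolution. Shared by the static and the
# spatio-temporal pipelines.
hsc_core <- function(q, config) {
  qb <- gaussian_blur(q, config$blur_sigma)
  Qr <- polar_decompose(hft_forward(q), axis = config$polar_axis)
  Qb <- polar_decompose(hft_forward(qb), axis = config$polar_axis)
  cq <- hft_inverse(spectral_contrast(Qr, Qb, config$log_epsilon))
  blur_matrix(qimg_norm2(cq), config$blur_sigma)
}

scale_dims <- function(config, scale, base = config$base_resolution) {
  list(w = max(1L, as.integer(round(scale * base[1]))),
       h = max(1L, as.integer(round(scale * base[2]))))
}

#' Single-scale spectral-contrast saliency
#'
#' Runs the full single-scale pipeline on an RGB image: resize to
#' `scale * base_resolution`, convert to HSV, encode as a pure quaternion
#' grid, take the hypercomplex Fourier transform of the image and of its
#' Gaussian-blurred version, form the spectral contrast, reconstruct by the
#' inverse transform, square the pixel-wise quaternion modulus, smooth, and
#' resize to `base_resolution`.
#'
#' @param rgb_image `M x N x 3` RGB array in `[0, 1]`.
#' @param config an [hsc_config()].
#' @param scale scale factor in (0, 1].
#' @return A non-negative `saliency_map` at `base_resolution`
#'   (height x width).
#' @export
single_scale_saliency <- function(rgb_image, config = hsc_config(), scale = 1) {
  if (!is.array(rgb_image) || length(dim(rgb_image)) != 3L ||
      any(dim(rgb_image)[1:2] < 1))
    stop("rgb_image must be a non-empty M x N x 3 array", call. = FALSE)
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]", call. = FALSE)
  d <- scale_dims(config, scale)
  rgb_s <- resize_rgb(rgb_image, d$h, d$w)
  rgb_s[rgb_s < 0] <- 0   # bilinear resampling can leave tiny excursions
  rgb_s[rgb_s > 1] <- 1
  q <- encode_hsv(rgb_to_hsv_array(rgb_s))
  s <- hsc_core(q, config)
  s <- resize_grid(s, config$base_resolution[2], config$base_resolution[1])
  s[s < 0] <- 0
  new_saliency_map(s)
}

#' Multi-scale spectral-contrast saliency
#'
#' The plain average of [single_scale_saliency()] over `config$scales`, all
#' maps living at `base_resolution`.
#'
#' @inheritParams single_scale_saliency
#' @return A `saliency_map` equal to the pixel-wise mean of the per-scale
#'   maps.
#' @export
multi_scale_saliency <- function(rgb_image, config = hsc_config()) {
  maps <- lapply(config$scales,
                 function(l) as_matrix_map(single_scale_saliency(rgb_image, config, l)))
  new_saliency_map(Reduce(`+`, maps) / length(maps))
}

#' Logarithmic centre-bias weighting
#'
#' Divides a saliency map by `1 + D_log(x, y)` where
#' `D_log = ln(1 + r / r_half_diag)`, `r` the Euclidean distance of a pixel
#' to the grid centre and `r_half_diag` half the diagonal of the pixel-centre
#' extent. The centre pixel is unchanged; a corner pixel is divided by
#' `1 + ln 2`. This emulates the human tendency to attend near the image
#' centre.
#'
#' @param S a `saliency_map` or numeric matrix.
#' @return The weighted map, same class as the input; never exceeds the
#'   input anywhere.
#' @export
center_bias <- function(S) {
  m <- if (inherits(S, "saliency_map")) as_matrix_map(S) else S
  M <- nrow(m); N <- ncol(m)
  cy <- (M + 1) / 2; cx <- (N + 1) / 2
  rhd <- sqrt((M - 1)^2 + (N - 1)^2) / 2
  if (rhd == 0) return(S)  # 1 x 1 grid: r = 0 everywhere
  ry <- (seq_len(M) - cy)^2
  rx <- (seq_len(N) - cx)^2
  r <- sqrt(outer(ry, rx, `+`))
  out <- m / (1 + log(1 + r / rhd))
  if (inherits(S, "saliency_map"))
    new_saliency_map(out, normalized = FALSE)
  else out
}

#' Normalise a saliency map to [0, 255]
#'
#' Optional Gaussian smoothing followed by an affine min-max mapping onto
#' `[0, 255]`. A constant map (no range) maps to all zeros.
#'
#' @param S a `saliency_map` or numeric matrix.
#' @param smooth_sigma optional Gaussian sigma (pixels) applied before
#'   rescaling; `NULL` for none.
#' @return A `saliency_map` with the `normalized` flag set.
#' @export
normalize_map <- function(S, smooth_sigma = NULL) {
  m <- if (inherits(S, "saliency_map")) as_matrix_map(S) else S
  if (!is.null(smooth_sigma)) m <- blur_matrix(m, smooth_sigma)
  lo <- min(m); hi <- max(m)
  m <- if (hi > lo) (m - lo) / (hi - lo) * 255 else m * 0
  new_saliency_map(m, normalized = TRUE)
}

#' Static saliency map of a colour image
#'
#' The end-to-end still-image pipeline: multi-scale hypercomplex spectral
#' contrast at `base_resolution`, optional logarithmic centre bias, resize to
#' the input size, optional normalisation to `[0, 255]`.
#'
#' @param rgb_image `M x N x 3` RGB array in `[0, 1]`.
#' @param config an [hsc_config()]; `config$center_bias` controls the centre
#'   weighting.
#' @param normalize map the result to `[0, 255]`.
#' @param smooth_sigma optional extra smoothing applied by [normalize_map()]
#'   (display convention); ignored when `normalize = FALSE`.
#' @return A `saliency_map` at the input image's resolution.
#' @examples
#' pat <- make_popout_pattern("color", image_size = c(160, 120), seed = 1)
#' cfg <- hsc_config(base_resolution = c(160, 120), center_bias = FALSE)
#' sm <- hsc_saliency(pat$image, cfg)
#' which(sm == max(sm), arr.ind = TRUE)
#' @export
hsc_saliency <- function(rgb_image, config = hsc_config(), normalize = TRUE,
                         smooth_sigma = NULL) {
  S <- multi_scale_saliency(rgb_image, config)
  if (config$center_bias) S <- center_bias(S)
  m <- resize_grid(as_matrix_map(S), dim(rgb_image)[1], dim(rgb_image)[2])
  m[m < 0] <- 0
  if (normalize) normalize_map(m, smooth_sigma) else new_saliency_map(m)
}
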