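#' Frame sequences
#'
#' A `frame_sequence` is an ordered list of same-size RGB arrays in `[0, 1]`.
#'
#' @param frames list of `M x N x 3` numeric arrays, all with identical
#'   dimensions.
#' @return An object of class `frame_sequence`.
#' @export
as_frame_sequence <- function(frames) {
  if (!is.list(frames) || length(frames) < 1L)
    stop("frames must be a non-empty list of RGB arrays", call. = FALSE)
  d <- dim(frames[[1]])
  if (is.null(d) || length(d) != 3L || d[3] != 3L)
    stop("each frame must be an M x N x 3 array", call. = FALSE)
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame %d has different dimensions", i), call. = FALSE)
  }
  structure(frames, class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  d <- dim(x[[1]])
  cat(sprintf("<frame_sequence> %d frames of %d x %d\n", length(x), d[1], d[2]))
  invisible(x)
}

# V channel (HSV value = max of R,G,B) of one frame
frame_value <- function(frame) pmax(frame[, , 1], frame[, , 2], frame[, , 3])

#' Five-frame motion cue
#'
#' A temporal derivative of the video intensity (the HSV value channel)
#' estimated from five consecutive frames centred on `t`:
#' `M_t = (I_{t-2} - 4 I_{t-1} - I_t + 4 I_{t+1} - I_{t+2}) / 8`
#' (variant `"as_printed"`). Those tap weights sum to -1/8, so a perfectly
#' static scene of intensity `c` yields the constant field `-c/8`; the
#' `"zero_sum"` variant drops the central `-I_t` tap so that any temporally
#' constant sequence gives exactly zero motion. Frames beyond either end of
#' the sequence are edge-replicated.
#'
#' @param seq a [as_frame_sequence()] object.
#' @param t frame index, 1-based, in `1..T`.
#' @param variant `"as_printed"` or `"zero_sum"`.
#' @return A signed numeric matrix (same grid as the frames) with attribute
#'   `variant`.
#' @export
motion_cue <- function(seq, t, variant = c("as_printed", "zero_sum")) {
  stopifnot(inherits(seq, "frame_sequence"))
  variant <- match.arg(variant)
  T <- length(seq)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > T)
    stop(sprintf("frame index t = %s outside 1..%d", format(t), T), call. = FALSE)
  at <- function(i) frame_value(seq[[min(max(i, 1L), T)]])
  m <- if (variant == "as_printed") {
    (at(t - 2) - 4 * at(t - 1) - at(t) + 4 * at(t + 1) - at(t + 2)) / 8
  } else {
    (at(t - 2) - 4 * at(t - 1) + 4 * at(t + 1) - at(t + 2)) / 8
  }
  attr(m, "variant") <- variant
  m
}

#' Spatio-temporal saliency of one video frame
#'
#' Extends the static pipeline with the five-frame motion cue: the frames are
#' resized to `config$video_resolution`, the motion field is computed there,
#' and each pixel is encoded as the full quaternion
#' `q_t = M_t + H_t i + S_t j + V_t k` (symplectic split
#' `f1 = M + H i`, `f2 = S + V i`). The multi-scale spectral-contrast
#' pipeline then runs unchanged, and the map is resized back to the original
#' frame size. With zero motion this reduces exactly to the static pipeline
#' run at `video_resolution`.
#'
#' @param seq a [as_frame_sequence()] object.
#' @param t frame index, 1-based.
#' @param config an [hsc_config()]; `video_resolution` and `motion_variant`
#'   are taken from it.
#' @param normalize map the result to `[0, 255]` (per frame). For thresholds
#'   comparable across frames see [hsc_video_saliency()].
#' @return A `saliency_map` at the original frame resolution.
#' @export
video_saliency <- function(seq, t, config = hsc_config(), normalize = FALSE) {
  stopifnot(inherits(seq, "frame_sequence"))
  T <- length(seq)
  if (!is.numeric(t) || length(t) != 1L || t < 1 || t > T)
    stop(sprintf("frame index t = %s outside 1..%d", format(t), T), call. = FALSE)
  vres <- config$video_resolution  # (width, height)
  vh <- vres[2]; vw <- vres[1]
  # five-frame window, edge-replicated, at video resolution
  idx <- pmin(pmax((t - 2):(t + 2), 1L), T)
  window <- lapply(idx, function(i) {
    f <- resize_rgb(seq[[i]], vh, vw)
    f[f < 0] <- 0; f[f > 1] <- 1
    f
  })
  mseq <- as_frame_sequence(window)
  motion <- motion_cue(mseq, 3L, config$motion_variant)
  rgb_c <- window[[3]]
  maps <- lapply(config$scales, function(l) {
    d <- scale_dims(config, l, base = vres)
    rgb_l <- resize_rgb(rgb_c, d$h, d$w)
    rgb_l[rgb_l < 0] <- 0; rgb_l[rgb_l > 1] <- 1
    mot_l <- resize_grid(motion, d$h, d$w)
    q <- encode_spatiotemporal(mot_l, rgb_to_hsv_array(rgb_l))
    s <- hsc_core(q, config)
    s <- resize_grid(s, vh, vw)
    s[s < 0] <- 0
    s
  })
  S <- Reduce(`+`, maps) / length(maps)
  if (config$center_bias) S <- center_bias(S)
  m <- resize_grid(S, dim(seq[[1]])[1], dim(seq[[1]])[2])
  m[m < 0] <- 0
  if (normalize) normalize_map(m) else new_saliency_map(m)
}

#' Spatio-temporal saliency of every frame
#'
#' Runs [video_saliency()] for each frame and optionally normalises all maps
#' with one global affine map to `[0, 255]`, so a single threshold means the
#' same thing in every frame (required by the moving-object extraction
#' protocol).
#'
#' @param seq a [as_frame_sequence()] object.
#' @param config an [hsc_config()].
#' @param normalize `"global"` (one min-max over the whole sequence),
#'   `"frame"` (per frame) or `"none"`.
#' @return A list of `saliency_map` objects, one per frame.
#' @export
hsc_video_saliency <- function(seq, config = hsc_config(),
                               normalize = c("global", "frame", "none")) {
  normalize <- match.arg(normalize)
  maps <- lapply(seq_along(seq), function(t)
    as_matrix_map(video_saliency(seq, t, config, normalize = FALSE)))
  if (normalize == "frame") return(lapply(maps, normalize_map))
  if (normalize == "global") {
    lo <- min(vapply(maps, min, 0))
    hi <- max(vapply(maps, max, 0))
    return(lapply(maps, function(m) {
      v <- if (hi > lo) (m - lo) / (hi - lo) * 255 else m * 0
      new_saliency_map(v, normalized = TRUE)
    }))
  }
  lapply(maps, new_saliency_map)
}
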