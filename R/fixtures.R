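# Deterministic stimulus generators. Everything is rendered without
# anti-aliasing so ground-truth boxes are pixel-exact, and all randomness is
# drawn from a locally seeded RNG that is restored on exit.

with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

# Paint a rotated bar into an rgb array; returns the updated array plus the
# exact bounding box of painted pixels (0-based x, y, width, height).
paint_bar <- function(img, cy, cx, half_len, half_wid, angle_deg, color) {
  M <- dim(img)[1]; N <- dim(img)[2]
  th <- angle_deg * pi / 180
  margin <- ceiling(half_len + half_wid) + 1L
  ys <- max(1L, floor(cy - margin)):min(M, ceiling(cy + margin))
  xs <- max(1L, floor(cx - margin)):min(N, ceiling(cx + margin))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  # axis of the bar at angle th from vertical
  u <- dy * cos(th) + dx * sin(th)
  v <- -dy * sin(th) + dx * cos(th)
  hit <- abs(u) <= half_len & abs(v) <= half_wid
  paint_mask(img, ys, xs, hit, color)
}

paint_arc <- function(img, cy, cx, radius, half_wid, color) {
  # upper semicircular arc band
  M <- dim(img)[1]; N <- dim(img)[2]
  margin <- ceiling(radius + half_wid) + 1L
  ys <- max(1L, floor(cy - margin)):min(M, ceiling(cy + margin))
  xs <- max(1L, floor(cx - margin)):min(N, ceiling(cx + margin))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  r <- sqrt(dy^2 + dx^2)
  hit <- abs(r - radius) <= half_wid & dy <= 0
  paint_mask(img, ys, xs, hit, color)
}

paint_disc <- function(img, cy, cx, radius, color) {
  M <- dim(img)[1]; N <- dim(img)[2]
  margin <- ceiling(radius) + 1L
  ys <- max(1L, floor(cy - margin)):min(M, ceiling(cy + margin))
  xs <- max(1L, floor(cx - margin)):min(N, ceiling(cx + margin))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  hit <- dy^2 + dx^2 <= radius^2
  paint_mask(img, ys, xs, hit, color)
}

paint_mask <- function(img, ys, xs, hit, color) {
  if (!any(hit)) return(list(img = img, box = NULL))
  idx <- which(hit, arr.ind = TRUE)
  rows <- ys[idx[, 1]]; cols <- xs[idx[, 2]]
  for (c in 1:3) {
    ch <- img[, , c]
    ch[cbind(rows, cols)] <- color[c]
    img[, , c] <- ch
  }
  box <- tibble::tibble(x = min(cols) - 1L, y = min(rows) - 1L,
                        w = max(cols) - min(cols) + 1L,
                        h = max(rows) - min(rows) + 1L)
  list(img = img, box = box)
}

#' Generate a psychological pop-out pattern
#'
#' Renders a regular grid of identical distractor items with one deviant
#' ("odd") item, the standard stimulus classes of pre-attentive search
#' experiments: a colour singleton, an orientation singleton, a curvature
#' singleton (an arc among straight bars), an intersection singleton (a cross
#' among bars), or a mixed pattern with both a colour and an orientation
#' deviant. Rendering is aliasing-free so the returned bounding boxes are
#' pixel-exact, and the generator is a pure function of its arguments and
#' `seed`.
#'
#' @param kind one of `"color"`, `"orientation"`, `"curvature"`,
#'   `"intersection"`, `"mixed"`.
#' @param grid_dim `c(rows, cols)` of item slots.
#' @param image_size `c(width, height)` in pixels.
#' @param odd_slot 1-based slot index of the deviant (row-major), or `NULL`
#'   to draw it at random from the seeded RNG. For `"mixed"`, a length-2
#'   vector (colour deviant, orientation deviant) or `NULL`.
#' @param distractor_color,deviant_color RGB triples in `[0, 1]`.
#' @param background RGB triple for the background.
#' @param seed integer seed; same spec + same seed gives bit-identical
#'   output.
#' @return A list with `image` (`height x width x 3` array) and `boxes`
#'   (tibble with 0-based `x`, `y` and `w`, `h`, one row per deviant, plus an
#'   `attribute` column naming the deviant feature).
#' @examples
#' pat <- make_popout_pattern("color", image_size = c(160, 120), seed = 7)
#' pat$boxes
#' @export
make_popout_pattern <- function(kind = c("color", "orientation", "curvature",
                                         "intersection", "mixed"),
                                grid_dim = c(5, 5),
                                image_size = c(320, 240),
                                odd_slot = NULL,
                                distractor_color = c(0.1, 0.9, 0.1),
                                deviant_color = c(0.95, 0.1, 0.1),
                                background = c(0, 0, 0),
                                seed = 1) {
  kind <- match.arg(kind)
  rows <- grid_dim[1]; cols <- grid_dim[2]
  n_slots <- rows * cols
  W <- image_size[1]; H <- image_size[2]
  with_local_seed(seed, {
    n_odd <- if (kind == "mixed") 2L else 1L
    if (is.null(odd_slot)) odd_slot <- sample.int(n_slots, n_odd)
    odd_slot <- as.integer(odd_slot)
    if (length(odd_slot) != n_odd || any(odd_slot < 1L) || any(odd_slot > n_slots) ||
        anyDuplicated(odd_slot))
      stop(sprintf("odd_slot must be %d distinct index(es) in 1..%d", n_odd, n_slots),
           call. = FALSE)
    img <- array(rep(background, each = H * W), c(H, W, 3))
    cell_h <- H / rows; cell_w <- W / cols
    item <- min(cell_h, cell_w)
    half_len <- 0.30 * item; half_wid <- 0.07 * item
    boxes <- NULL
    for (s in seq_len(n_slots)) {
      r <- (s - 1L) %/% cols + 1L
      c <- (s - 1L) %% cols + 1L
      cy <- (r - 0.5) * cell_h
      cx <- (c - 0.5) * cell_w
      role <- match(s, odd_slot)  # NA for distractors
      if (is.na(role)) {
        res <- switch(kind,
          curvature = paint_bar(img, cy, cx, half_len, half_wid, 0, distractor_color),
          paint_bar(img, cy, cx, half_len, half_wid, 0, distractor_color))
        img <- res$img
      } else {
        res <- switch(kind,
          color = paint_bar(img, cy, cx, half_len, half_wid, 0, deviant_color),
          orientation = paint_bar(img, cy, cx, half_len, half_wid, 45, distractor_color),
          curvature = paint_arc(img, cy + 0.4 * half_len, cx, 0.8 * half_len,
                                half_wid, distractor_color),
          intersection = {
            tmp <- paint_bar(img, cy, cx, half_len, half_wid, 0, distractor_color)
            res2 <- paint_bar(tmp$img, cy, cx, half_len, half_wid, 90, distractor_color)
            b <- rbind(tmp$box, res2$box)
            box <- tibble::tibble(x = min(b$x), y = min(b$y),
                                  w = max(b$x + b$w) - min(b$x),
                                  h = max(b$y + b$h) - min(b$y))
            list(img = res2$img, box = box)
          },
          mixed = if (role == 1L)
            paint_bar(img, cy, cx, half_len, half_wid, 0, deviant_color)
          else
            paint_bar(img, cy, cx, half_len, half_wid, 45, distractor_color))
        img <- res$img
        attribute <- switch(kind,
                            color = "color", orientation = "orientation",
                            curvature = "curvature", intersection = "intersection",
                            mixed = if (role == 1L) "color" else "orientation")
        boxes <- rbind(boxes, cbind(res$box, tibble::tibble(attribute = attribute)))
      }
    }
    list(image = img, boxes = tibble::as_tibble(boxes))
  })
}

#' Generate a synthetic moving-object video
#'
#' A small bright square translating at constant velocity over either a
#' static smoothed-noise texture or a dynamic background built from two
#' drifting sinusoidal gratings (enough non-stationarity to defeat naive
#' frame differencing). Per-frame ground-truth boxes track the object
#' exactly; the generator is a pure function of its arguments and `seed`.
#'
#' @param background `"static_texture"` or `"dynamic_waves"`.
#' @param n_frames number of frames.
#' @param image_size `c(width, height)`.
#' @param object logical; render the moving square.
#' @param object_size side of the square, pixels.
#' @param object_color RGB triple.
#' @param start `c(x, y)` 0-based top-left position of the square in frame 1.
#' @param velocity `c(vx, vy)` pixels per frame.
#' @param seed integer seed.
#' @return A list with `frames` (a [as_frame_sequence()] object) and `boxes`
#'   (tibble `frame` (1-based), 0-based `x`, `y`, `w`, `h`; zero rows when
#'   `object = FALSE`).
#' @export
make_synthetic_video <- function(background = c("static_texture", "dynamic_waves"),
                                 n_frames = 30,
                                 image_size = c(128, 128),
                                 object = TRUE,
                                 object_size = 16,
                                 object_color = c(1, 0.85, 0.2),
                                 start = c(20, 56),
                                 velocity = c(2, 0),
                                 seed = 1) {
  background <- match.arg(background)
  W <- image_size[1]; H <- image_size[2]
  with_local_seed(seed, {
    base <- if (background == "static_texture") {
      # fixed-tint luminance texture: static scenes vary in brightness, not hue
      tint <- c(0.45, 0.42, 0.38)
      lum <- resize_grid(matrix(stats::runif(16 * 16, 0.55, 0.95), 16, 16), H, W)
      array(c(tint[1] * lum, tint[2] * lum, tint[3] * lum), c(H, W, 3))
    } else NULL
    # grating parameters for the dynamic background
    yy <- matrix(seq_len(H), H, W)
    xx <- matrix(seq_len(W), H, W, byrow = TRUE)
    ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
    frames <- vector("list", n_frames)
    boxes <- NULL
    for (t in seq_len(n_frames)) {
      if (background == "static_texture") {
        fr <- base
      } else {
        g <- 0.5 +
          0.18 * sin(2 * pi * (xx / 14 + yy / 55) + 0.45 * t + ph1) +
          0.12 * sin(2 * pi * (xx / 33 - yy / 21) - 0.3 * t + ph2)
        fr <- array(c(0.35 * g, 0.55 * g, 0.75 * g), c(H, W, 3))
      }
      fr[fr < 0] <- 0; fr[fr > 1] <- 1
      if (object) {
        x0 <- start[1] + (t - 1) * velocity[1]
        y0 <- start[2] + (t - 1) * velocity[2]
        if (x0 < 0 || y0 < 0 || x0 + object_size > W || y0 + object_size > H)
          stop(sprintf("object leaves the frame at frame %d", t), call. = FALSE)
        rows <- (y0 + 1):(y0 + object_size)
        cols <- (x0 + 1):(x0 + object_size)
        for (c in 1:3) fr[rows, cols, c] <- object_color[c]
        boxes <- rbind(boxes, tibble::tibble(frame = t, x = x0, y = y0,
                                             w = object_size, h = object_size))
      }
      frames[[t]] <- fr
    }
    if (is.null(boxes))
      boxes <- tibble::tibble(frame = integer(), x = integer(), y = integer(),
                              w = integer(), h = integer())
    list(frames = as_frame_sequence(frames), boxes = tibble::as_tibble(boxes))
  })
}

#' Rasterise boxes into a binary mask
#'
#' @param boxes tibble/data.frame with 0-based `x`, `y` and `w`, `h`.
#' @param dim `c(height, width)` of the mask.
#' @return A logical matrix, `TRUE` inside any box.
#' @export
boxes_to_mask <- function(boxes, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (i in seq_len(nrow(boxes))) {
    b <- boxes[i, ]
    m[(b$y + 1):(b$y + b$h), (b$x + 1):(b$x + b$w)] <- TRUE
  }
  m
}
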