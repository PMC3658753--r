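# Image, sequence, box-file, curve-CSV and run-config I/O. PNG and JPEG go
# through the png/jpeg packages; PPM (P3/P6, maxval <= 65535) is parsed here
# since no installed package reads it.

img_ext <- function(path) tolower(tools::file_ext(path))

#' Read an image as an RGB array in [0, 1]
#'
#' Supports PNG, JPEG and PPM (both ASCII `P3` and binary `P6`). Grayscale
#' images are expanded to three identical channels; an alpha channel is
#' dropped. 16-bit data are scaled to `[0, 1]` without clipping.
#'
#' @param path file path.
#' @return An `M x N x 3` numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read image: no such file '%s'", path), call. = FALSE)
  ext <- img_ext(path)
  img <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    ppm = read_ppm(path),
    stop(sprintf("unsupported image format '%s' for '%s'", ext, path),
         call. = FALSE))
  if (is.matrix(img)) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] >= 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write a saliency map as an 8-bit grayscale PNG
#'
#' Maps not yet normalised are passed through [normalize_map()] first.
#'
#' @param map a `saliency_map` or numeric matrix.
#' @param path output path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write map: no such directory '%s'", dirname(path)),
         call. = FALSE)
  if (!inherits(map, "saliency_map") || !isTRUE(attr(map, "normalized")))
    map <- normalize_map(map)
  png::writePNG(as_matrix_map(map) / 255, path)
  invisible(path)
}

#' Write an RGB array as a PNG or PPM image
#'
#' @param rgb `M x N x 3` array in `[0, 1]`.
#' @param path output path; extension selects the format.
#' @return `path`, invisibly.
#' @export
write_image <- function(rgb, path) {
  ext <- img_ext(path)
  switch(ext,
    png = png::writePNG(rgb, path),
    ppm = write_ppm(rgb, path),
    stop(sprintf("unsupported output format '%s' for '%s'", ext, path),
         call. = FALSE))
  invisible(path)
}

read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  tok <- function() {
    # next whitespace-delimited token, skipping '#' comments
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0) stop(sprintf("truncated PPM header in '%s'", path),
                                call. = FALSE)
      if (ch == "#") { repeat { c2 <- readChar(con, 1L, useBytes = TRUE)
                                if (length(c2) == 0 || c2 == "\n") break } }
      else if (!grepl("[ \t\r\n]", ch)) break
    }
    out <- ch
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0 || grepl("[ \t\r\n]", ch)) break
      out <- paste0(out, ch)
    }
    out
  }
  magic <- tok()
  if (!magic %in% c("P3", "P6"))
    stop(sprintf("'%s' is not a P3/P6 PPM file", path), call. = FALSE)
  W <- as.integer(tok()); H <- as.integer(tok()); maxval <- as.integer(tok())
  n <- W * H * 3L
  vals <- if (magic == "P6") {
    if (maxval < 256) as.numeric(readBin(con, "integer", n, size = 1, signed = FALSE))
    else as.numeric(readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big"))
  } else {
    as.numeric(scan(con, what = integer(), n = n, quiet = TRUE))
  }
  if (length(vals) < n)
    stop(sprintf("truncated pixel data in '%s'", path), call. = FALSE)
  # PPM stores pixels row by row, channels interleaved
  arr <- array(0, c(H, W, 3))
  for (c in 1:3) arr[, , c] <- matrix(vals[seq(c, n, by = 3)], H, W, byrow = TRUE)
  arr / maxval
}

write_ppm <- function(rgb, path, maxval = 255L) {
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  v <- array(as.integer(round(pmin(pmax(rgb, 0), 1) * maxval)), c(H, W, 3))
  inter <- as.vector(aperm(v, c(3, 2, 1)))  # row-major pixels, RGB interleaved
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n%d\n", W, H, maxval), con, eos = NULL)
  writeBin(inter, con, size = 1)
  invisible(path)
}

#' Read a directory of frames as a sequence
#'
#' Frames are taken in lexicographic filename order; all must share the same
#' dimensions.
#'
#' @param dir directory containing PNG/JPEG/PPM frames.
#' @return A [as_frame_sequence()] object.
#' @export
read_sequence <- function(dir) {
  if (!dir.exists(dir))
    stop(sprintf("no such directory '%s'", dir), call. = FALSE)
  files <- sort(list.files(dir, pattern = "\\.(png|jpe?g|ppm)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no image frames found in '%s'", dir), call. = FALSE)
  frames <- lapply(files, read_image)
  d <- dim(frames[[1]])
  for (i in seq_along(frames)) {
    if (!identical(dim(frames[[i]]), d))
      stop(sprintf("frame '%s' has dimensions %s, expected %s",
                   basename(files[i]),
                   paste(dim(frames[[i]])[1:2], collapse = "x"),
                   paste(d[1:2], collapse = "x")), call. = FALSE)
  }
  as_frame_sequence(frames)
}

#' Write / read per-frame bounding boxes
#'
#' Plain-text format, one line per box: `frame_index x y w h`, all 0-based
#' (the in-memory tibble keeps 1-based `frame`, matching R indexing).
#'
#' @param boxes tibble with `frame` (1-based), `x`, `y`, `w`, `h`.
#' @param path file path.
#' @return `path` invisibly (write); a tibble (read).
#' @export
write_boxes <- function(boxes, path) {
  lines <- sprintf("%d %d %d %d %d", boxes$frame - 1L, boxes$x, boxes$y,
                   boxes$w, boxes$h)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_boxes
#' @export
read_boxes <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such box file '%s'", path), call. = FALSE)
  if (length(readLines(path, n = 1)) == 0)
    return(tibble::tibble(frame = integer(), x = integer(), y = integer(),
                          w = integer(), h = integer()))
  df <- utils::read.table(path, col.names = c("frame", "x", "y", "w", "h"))
  tibble::tibble(frame = as.integer(df$frame) + 1L, x = as.integer(df$x),
                 y = as.integer(df$y), w = as.integer(df$w),
                 h = as.integer(df$h))
}

#' Export evaluation curves as CSV
#'
#' @param curves an `eval_curves` tibble from [pr_curve()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  readr::write_csv(tibble::as_tibble(unclass(curves)[names(curves) != "roc_area"]),
                   path)
  invisible(path)
}

run_config_keys <- c("mode", "scales", "blur_sigma", "base_width", "base_height",
                     "video_width", "video_height", "log_epsilon", "center_bias",
                     "polar_axis", "motion_variant", "input", "output",
                     "threshold", "morph_radius", "seed", "log_level")

#' Read a flat key = value run configuration
#'
#' Blank lines and `#` comments are ignored; unknown keys are rejected.
#' Returns the parsed values merged over the pipeline defaults, plus an
#' [hsc_config()] built from them in `$config`.
#'
#' @param path config file path.
#' @return A named list with an `hsc_config` in `$config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("no such config file '%s'", path), call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2)
      stop(sprintf("malformed config line: '%s'", ln), call. = FALSE)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% run_config_keys)
      stop(sprintf("unknown config key: '%s'", key), call. = FALSE)
    kv[[key]] <- val
  }
  num <- function(k, d) if (is.null(kv[[k]])) d else as.numeric(kv[[k]])
  chr <- function(k, d) if (is.null(kv[[k]])) d else kv[[k]]
  lgl <- function(k, d) if (is.null(kv[[k]])) d else tolower(kv[[k]]) %in% c("true", "1", "yes", "on")
  scales <- if (is.null(kv$scales)) c(1, 0.5, 0.25)
            else as.numeric(strsplit(kv$scales, ",")[[1]])
  cfg <- hsc_config(scales = scales,
                    blur_sigma = num("blur_sigma", 3),
                    base_resolution = c(num("base_width", 320), num("base_height", 240)),
                    video_resolution = c(num("video_width", 128), num("video_height", 128)),
                    log_epsilon = num("log_epsilon", 1e-12),
                    center_bias = lgl("center_bias", TRUE),
                    polar_axis = chr("polar_axis", "eigen"),
                    motion_variant = chr("motion_variant", "as_printed"))
  list(mode = chr("mode", "static"),
       input = chr("input", NULL),
       output = chr("output", NULL),
       threshold = if (is.null(kv$threshold)) NULL else as.numeric(kv$threshold),
       morph_radius = num("morph_radius", 1),
       seed = as.integer(num("seed", 1)),
       log_level = chr("log_level", "info"),
       config = cfg)
}
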