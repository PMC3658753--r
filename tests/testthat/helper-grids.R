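# Shared fixtures: random quaternion grids and small geometry helpers.

random_qimage <- function(M, N, pure = FALSE) {
  m <- function() matrix(stats::rnorm(M * N), M, N)
  quaternion_image(if (pure) matrix(0, M, N) else m(), m(), m(), m())
}

qspec_parts_max_diff <- function(a, b) {
  max(abs(a$w - b$w), abs(a$x - b$x), abs(a$y - b$y), abs(a$z - b$z))
}

# is the (row, col) argmax of a map inside a 0-based box?
argmax_in_box <- function(map, box) {
  m <- unclass(map)
  am <- which(m == max(m), arr.ind = TRUE)[1, ]
  am[2] >= box$x + 1 && am[2] <= box$x + box$w &&
    am[1] >= box$y + 1 && am[1] <= box$y + box$h
}

mean_in_out <- function(map, mask) {
  m <- unclass(map)
  c(inside = mean(m[mask]), outside = mean(m[!mask]))
}

constant_rgb <- function(h, w, col = c(0.3, 0.6, 0.8)) {
  array(rep(col, each = h * w), c(h, w, 3))
}
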