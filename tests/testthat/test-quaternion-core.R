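test_that("quaternion multiplication satisfies the unit rules and norm multiplicativity", {
  i <- c(0, 1, 0, 0); j <- c(0, 0, 1, 0); k <- c(0, 0, 0, 1)
  minus1 <- c(-1, 0, 0, 0)
  expect_equal(quat_multiply(i, i), minus1)
  expect_equal(quat_multiply(j, j), minus1)
  expect_equal(quat_multiply(k, k), minus1)
  expect_equal(quat_multiply(i, j), k)
  expect_equal(quat_multiply(j, i), -k)
  expect_equal(quat_multiply(j, k), i)
  expect_equal(quat_multiply(k, j), -i)
  expect_equal(quat_multiply(k, i), j)
  expect_equal(quat_multiply(i, k), -j)

  set.seed(11)
  for (rep in 1:25) {
    a <- rnorm(4); b <- rnorm(4)
    expect_equal(quat_norm(quat_multiply(a, b)), quat_norm(a) * quat_norm(b),
                 tolerance = 1e-12)
  }
})

test_that("HSV encoding produces pure quaternions and rejects bad ranges", {
  hsv <- array(0, c(2, 2, 3))
  hsv[1, 1, ] <- c(0.5, 0.25, 1)
  q <- encode_hsv(hsv)
  expect_equal(q$w[1, 1], 0)
  expect_equal(q$x[1, 1], 0.5)
  expect_equal(q$y[1, 1], 0.25)
  expect_equal(q$z[1, 1], 1)

  zero <- encode_hsv(array(0, c(3, 4, 3)))
  expect_true(all(zero$w == 0 & zero$x == 0 & zero$y == 0 & zero$z == 0))

  basis <- encode_hsv(array(rep(c(1, 0, 0), each = 1), c(1, 1, 3)))
  expect_equal(c(basis$w, basis$x, basis$y, basis$z), c(0, 1, 0, 0))

  bad <- array(0, c(2, 2, 3)); bad[1, 1, 1] <- 1.2
  expect_error(encode_hsv(bad), "\\[0, 1\\]")
})

test_that("spatio-temporal encoding places the motion cue in the scalar part", {
  hsv <- array(0, c(2, 2, 3))
  q0 <- encode_spatiotemporal(matrix(0, 2, 2), hsv)
  expect_equal(qspec_parts_max_diff(q0, encode_hsv(hsv)), 0)

  m <- matrix(0, 2, 2); m[1, 1] <- 0.3
  q <- encode_spatiotemporal(m, hsv)
  expect_equal(q$w[1, 1], 0.3)
  expect_equal(q$x[1, 1] + q$y[1, 1] + q$z[1, 1], 0)

  ones <- array(1, c(1, 1, 3))
  qn <- encode_spatiotemporal(matrix(-1, 1, 1), ones)
  expect_equal(sqrt(qn$w^2 + qn$x^2 + qn$y^2 + qn$z^2)[1, 1], 2)

  expect_error(encode_spatiotemporal(matrix(0, 3, 2), hsv), "dimensions differ")
})

test_that("symplectic decomposition splits into {1,i} parts and recomposes exactly", {
  # single-channel case: q = 2i
  q1 <- quaternion_image(matrix(0, 1, 1), matrix(2, 1, 1),
                         matrix(0, 1, 1), matrix(0, 1, 1))
  p1 <- symplectic_decompose(q1)
  expect_equal(p1$f1[1, 1], 2i)
  expect_equal(p1$f2[1, 1], 0 + 0i)

  # H = 0.5, S = 0.25, V = 1
  hsv <- array(c(0.5, 0.25, 1), c(1, 1, 3))
  p2 <- symplectic_decompose(encode_hsv(hsv))
  expect_equal(p2$f1[1, 1], 0.5i)
  expect_equal(p2$f2[1, 1], 0.25 + 1i)

  set.seed(21)
  q <- random_qimage(4, 4)
  expect_equal(qspec_parts_max_diff(symplectic_recompose(symplectic_decompose(q)), q), 0)
})

test_that("hypercomplex FFT matches the DC prediction and the 1x2 closed form", {
  q0 <- c(0.2, -0.4, 0.7, 1.1)
  M <- 4; N <- 6
  q <- quaternion_image(matrix(q0[1], M, N), matrix(q0[2], M, N),
                        matrix(q0[3], M, N), matrix(q0[4], M, N))
  Q <- hft_forward(q)
  expect_equal(c(Q$w[1, 1], Q$x[1, 1], Q$y[1, 1], Q$z[1, 1]),
               sqrt(M * N) * q0, tolerance = 1e-12)
  off_dc <- sum(Q$w^2 + Q$x^2 + Q$y^2 + Q$z^2) -
    (Q$w[1, 1]^2 + Q$x[1, 1]^2 + Q$y[1, 1]^2 + Q$z[1, 1]^2)
  expect_lt(off_dc, 1e-20)

  a <- c(1, 2, 3, 4); b <- c(-1, 0.5, 2, -3)
  q12 <- quaternion_image(matrix(c(a[1], b[1]), 1, 2), matrix(c(a[2], b[2]), 1, 2),
                          matrix(c(a[3], b[3]), 1, 2), matrix(c(a[4], b[4]), 1, 2))
  Q12 <- hft_forward(q12)
  expect_equal(c(Q12$w[1, 1], Q12$x[1, 1], Q12$y[1, 1], Q12$z[1, 1]),
               (a + b) / sqrt(2), tolerance = 1e-12)
  expect_equal(c(Q12$w[1, 2], Q12$x[1, 2], Q12$y[1, 2], Q12$z[1, 2]),
               (a - b) / sqrt(2), tolerance = 1e-12)
})

test_that("hft_forward agrees with the brute-force left-sided axis-i DFT", {
  set.seed(31)
  for (M in c(2, 3, 5, 8)) {
    for (N in c(2, 4, 7)) {
      q <- random_qimage(M, N)
      expect_lt(qspec_parts_max_diff(hft_forward(q), quaternion_dft_bruteforce(q)),
                1e-9)
    }
  }
  # pure images too (the HSV case)
  q <- random_qimage(8, 8, pure = TRUE)
  expect_lt(qspec_parts_max_diff(hft_forward(q), quaternion_dft_bruteforce(q)), 1e-10)
  expect_error(quaternion_dft_bruteforce(random_qimage(70, 70)), "4096")
})

test_that("forward/inverse transform round-trips and satisfies Parseval", {
  set.seed(41)
  for (rep in 1:10) {
    q <- random_qimage(16, 16)
    Q <- hft_forward(q)
    expect_lt(qspec_parts_max_diff(hft_inverse(Q), q), 1e-10)
    e_img <- sum(q$w^2 + q$x^2 + q$y^2 + q$z^2)
    e_spec <- sum(Q$w^2 + Q$x^2 + Q$y^2 + Q$z^2)
    expect_equal(e_spec, e_img, tolerance = 1e-10)
  }
  # DC-only spectrum inverts to a constant image; zero inverts to zero
  Z <- hft_forward(random_qimage(3, 3))
  Z$w[] <- 0; Z$x[] <- 0; Z$y[] <- 0; Z$z[] <- 0
  Z$w[1, 1] <- 3 * 0.7
  back <- hft_inverse(Z)
  expect_equal(back$w, matrix(0.7, 3, 3), tolerance = 1e-12)
  expect_equal(max(abs(back$x), abs(back$y), abs(back$z)), 0, tolerance = 1e-12)
  Z$w[1, 1] <- 0
  zero <- hft_inverse(Z)
  expect_equal(sum(zero$w^2 + zero$x^2 + zero$y^2 + zero$z^2), 0)
})

test_that("polar decomposition splits amplitude and unit phase, handling zeros", {
  mk <- function(w, x, y, z) {
    s <- hft_forward(random_qimage(1, 1))
    s$w[] <- w; s$x[] <- x; s$y[] <- y; s$z[] <- z
    s
  }
  # Q = 3j
  p <- polar_decompose(mk(0, 0, 3, 0))
  expect_equal(p$amplitude[1, 1], 3)
  expect_equal(c(p$unit_phase$w, p$unit_phase$x, p$unit_phase$y, p$unit_phase$z),
               c(0, 0, 1, 0))
  expect_equal(p$phi[1, 1], pi / 2)
  # Q = 1 + i
  p2 <- polar_decompose(mk(1, 1, 0, 0))
  expect_equal(p2$amplitude[1, 1], sqrt(2))
  expect_equal(c(p2$unit_phase$w, p2$unit_phase$x), c(1, 1) / sqrt(2))
  expect_equal(p2$phi[1, 1], pi / 4)
  # Q = 0: identity phase, flagged
  p3 <- polar_decompose(mk(0, 0, 0, 0))
  expect_equal(p3$amplitude[1, 1], 0)
  expect_true(p3$zero_flag[1, 1])
  expect_equal(c(p3$unit_phase$w, p3$unit_phase$x, p3$unit_phase$y, p3$unit_phase$z),
               c(1, 0, 0, 0))

  # reconstruction wherever amplitude > 0
  set.seed(51)
  Q <- hft_forward(random_qimage(6, 5))
  pp <- polar_decompose(Q)
  keep <- pp$amplitude > 1e-12
  expect_lt(max(abs((pp$amplitude * pp$unit_phase$w - Q$w)[keep]),
                abs((pp$amplitude * pp$unit_phase$x - Q$x)[keep]),
                abs((pp$amplitude * pp$unit_phase$y - Q$y)[keep]),
                abs((pp$amplitude * pp$unit_phase$z - Q$z)[keep])), 1e-10)
  expect_equal(max(abs(pp$unit_phase$w^2 + pp$unit_phase$x^2 +
                         pp$unit_phase$y^2 + pp$unit_phase$z^2 - 1)), 0,
               tolerance = 1e-12)
})

test_that("fixed-axis-j polar reading reduces to the eigenaxis form in the {1,j} subfield", {
  s <- hft_forward(random_qimage(1, 1))
  s$w[] <- 0.6; s$x[] <- 0; s$y[] <- 0.8; s$z[] <- 0
  pj <- polar_decompose(s, axis = "j")
  pe <- polar_decompose(s, axis = "eigen")
  expect_equal(c(pj$unit_phase$w, pj$unit_phase$y),
               c(pe$unit_phase$w, pe$unit_phase$y), tolerance = 1e-12)
})
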