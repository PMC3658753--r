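test_that("a perfect saliency map gives perfect precision/recall and ROC area 1", {
  gt <- matrix(FALSE, 10, 10); gt[3:6, 4:8] <- TRUE
  curves <- pr_curve(255 * gt, gt)
  sub <- curves[curves$threshold <= 254, ]
  expect_true(all(sub$precision == 1))
  expect_true(all(sub$recall == 1))
  expect_equal(attr(curves, "roc_area"), 1)
  expect_equal(roc_area(255 * gt, gt), 1)
})

test_that("a constant map splits into the two analytic threshold regimes", {
  gt <- matrix(c(TRUE, FALSE), 10, 10)  # half the pixels
  curves <- pr_curve(matrix(128, 10, 10), gt)
  low <- curves[curves$threshold < 128, ]
  high <- curves[curves$threshold >= 128, ]
  expect_true(all(low$precision == 0.5))
  expect_true(all(low$recall == 1))
  expect_true(all(high$precision == 1))   # nothing predicted
  expect_true(all(high$recall == 0))
  expect_equal(attr(curves, "roc_area"), 0.5)

  # null predictor: zero recall at every threshold
  zero <- pr_curve(matrix(0, 10, 10), gt)
  expect_true(all(zero$recall == 0))
})

test_that("the four-pixel toy sweep enumerates to ROC area 1", {
  sal <- matrix(c(10, 20, 30, 40), 1, 4)
  gt <- matrix(c(FALSE, FALSE, TRUE, TRUE), 1, 4)
  expect_equal(roc_area(sal, gt), 1)
  # reversing the ranking destroys it
  expect_equal(roc_area(sal, !gt), 0)
  expect_error(pr_curve(sal, matrix(TRUE, 2, 2)), "dimensions")
})

test_that("recall and false-positive rate are non-increasing in the threshold", {
  set.seed(23)
  for (rep in 1:5) {
    sal <- matrix(runif(400, 0, 255), 20, 20)
    gt <- matrix(runif(400) < 0.3, 20, 20)
    curves <- pr_curve(sal, gt)
    expect_true(all(diff(curves$recall) <= 0))
    expect_true(all(diff(curves$fpr) <= 0))
    expect_true(attr(curves, "roc_area") >= 0 && attr(curves, "roc_area") <= 1)
  }
})

test_that("extraction recovers component boxes and removes salt noise", {
  sal <- matrix(0, 40, 40)
  sal[10:19, 5:14] <- 200
  res <- extract_moving_objects(sal, 100, morph_radius = 1)
  expect_equal(nrow(res$boxes), 1)
  expect_equal(unname(unlist(res$boxes[1, c("x", "y", "w", "h")])),
               c(4L, 9L, 10L, 10L))

  sal[25:32, 25:32] <- 220
  res2 <- extract_moving_objects(sal, 100, morph_radius = 1)
  expect_equal(nrow(res2$boxes), 2)

  set.seed(5)
  salt <- matrix(0, 40, 40)
  salt[cbind(seq(2, 38, by = 4), seq(2, 38, by = 4))] <- 255  # isolated pixels
  res3 <- extract_moving_objects(salt, 100, morph_radius = 1)
  expect_equal(nrow(res3$boxes), 0)
})

test_that("components are 8-connected and morphology is idempotent", {
  sal <- matrix(0, 10, 10)
  sal[2:3, 2:3] <- 255
  sal[4:5, 4:5] <- 255  # touches only diagonally
  res <- extract_moving_objects(sal, 100, morph_radius = 0)
  expect_equal(nrow(res$boxes), 1)

  vid <- matrix(0, 30, 30)
  vid[5:14, 5:14] <- 255; vid[20:24, 18:26] <- 255
  once <- extract_moving_objects(vid, 100, morph_radius = 2)
  twice <- extract_moving_objects(255 * once$mask, 100, morph_radius = 2)
  expect_identical(once$mask, twice$mask)
})

test_that("the 30%-in-box rule has 'at least' boundary semantics", {
  mask_map <- matrix(0, 20, 20)
  gt <- tibble::tibble(x = 0L, y = 0L, w = 10L, h = 10L)
  # exactly 30 of 100 box pixels foreground
  mask_map[1:3, 1:10] <- 255
  res <- extract_moving_objects(mask_map, 100, morph_radius = 0)
  m <- detection_metrics(res, gt)
  expect_equal(m$recall, 1)
  # 20% is below the rule
  mask_map[] <- 0; mask_map[1:2, 1:10] <- 255
  res2 <- extract_moving_objects(mask_map, 100, morph_radius = 0)
  expect_equal(detection_metrics(res2, gt)$recall, 0)
})

test_that("detection metrics reward exact extraction and penalise false boxes", {
  gt <- tibble::tibble(x = c(2L, 20L), y = c(2L, 10L), w = c(6L, 8L), h = c(6L, 5L))
  sal <- matrix(0, 30, 30)
  sal[3:8, 3:8] <- 255; sal[11:15, 21:28] <- 255  # union of the GT boxes
  res <- extract_moving_objects(sal, 100, morph_radius = 0)
  m <- detection_metrics(res, gt)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  empty <- extract_moving_objects(matrix(0, 30, 30), 100, morph_radius = 0)
  m0 <- detection_metrics(empty, gt)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 1)  # nothing predicted

  bad <- tibble::tibble(x = 28L, y = 0L, w = 10L, h = 4L)  # exceeds the grid
  expect_error(detection_metrics(res, bad), "out-of-bounds")
})

test_that("curve objects expose tidy/glance summaries", {
  gt <- matrix(FALSE, 8, 8); gt[2:4, 2:4] <- TRUE
  curves <- pr_curve(255 * gt, gt)
  expect_equal(nrow(tidy(curves)), 256)
  g <- glance(curves)
  expect_equal(g$roc_area, 1)
  res <- extract_moving_objects(255 * gt, 100, morph_radius = 0)
  expect_equal(glance(res)$n_boxes, 1)
  expect_equal(nrow(tidy(res)), 1)
})
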