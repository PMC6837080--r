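test_that("vertical polyline stroke covers the expected columns", {
  g <- semantic_graphic(polylines = list(rbind(c(0, 10), c(99, 10))),
                        image_shape = c(100, 100))
  mask <- rasterize_lines(g, 5)
  for (r in 1:100) {
    expect_identical(which(mask[r, ] == 1L), 9:13)  # 0-based cols 8..12
  }
})

test_that("stroke rasterization matches the brute-force distance oracle", {
  set.seed(42)
  for (trial in 1:5) {
    polys <- lapply(1:2, function(i)
      cbind(sort(runif(3, 0, 29)), runif(3, 0, 29)))
    g <- semantic_graphic(polylines = polys, image_shape = c(30, 30))
    expect_identical(rasterize_lines(g, 5),
                     oracle_rasterize_lines(polys, 30, 30, 5))
  }
})

test_that("empty and crossing polylines behave as specified", {
  g0 <- semantic_graphic(polylines = list(), image_shape = c(20, 20))
  expect_identical(rasterize_lines(g0, 5), matrix(0L, 20, 20))
  gx <- semantic_graphic(polylines = list(rbind(c(0, 0), c(19, 19)),
                                          rbind(c(0, 19), c(19, 0))),
                         image_shape = c(20, 20))
  mask <- rasterize_lines(gx, 3)
  expect_setequal(unique(as.vector(mask)), c(0L, 1L))
  # single-point polyline -> a thickness-sized disc
  g1 <- semantic_graphic(polylines = list(matrix(c(10, 10), 1)),
                         image_shape = c(20, 20))
  m1 <- rasterize_lines(g1, 5)
  expect_identical(sum(m1), sum(outer(0:19, 0:19, function(r, c)
    (r - 10)^2 + (c - 10)^2 <= 2.5^2)))
})

test_that("rasterization is invariant to polyline direction", {
  set.seed(9)
  for (trial in 1:10) {
    p <- cbind(sort(runif(4, 0, 49)), runif(4, 0, 49))
    g1 <- semantic_graphic(polylines = list(p), image_shape = c(50, 50))
    g2 <- semantic_graphic(polylines = list(p[4:1, ]), image_shape = c(50, 50))
    expect_identical(rasterize_lines(g1, 5), rasterize_lines(g2, 5))
  }
})

test_that("keypoint discs have the exact lattice pixel count and overwrite in order", {
  kp <- data.frame(class = "paddy", row = 50, col = 50, radius = 6)
  g <- semantic_graphic(keypoints = kp, image_shape = c(100, 100))
  mask <- rasterize_keypoints(g)
  # brute-force count of lattice points within Euclidean distance 6
  expected <- sum(outer(0:99, 0:99, function(r, c) (r - 50)^2 + (c - 50)^2 <= 36))
  expect_identical(sum(mask == 1L), expected)
  expect_identical(expected, 113L)

  # zero keypoints -> all background
  g0 <- semantic_graphic(image_shape = c(10, 10))
  expect_identical(rasterize_keypoints(g0), matrix(0L, 10, 10))

  # overlapping discs: later class wins on the overlap
  kp2 <- data.frame(class = c("paddy", "millet"), row = c(20, 20),
                    col = c(20, 26), radius = c(5, 5))
  g2 <- semantic_graphic(keypoints = kp2, image_shape = c(40, 40))
  m2 <- rasterize_keypoints(g2)
  expect_identical(m2[21, 24], 2L)  # pixel (20, 23): inside both, millet drawn later
  expect_identical(m2[21, 17], 1L)  # only inside the paddy disc
})

test_that("radius_from_depth interpolates linearly with clamping", {
  expect_equal(radius_from_depth(100, 100, 20, 12, 4), 12)
  expect_equal(radius_from_depth(20, 100, 20, 12, 4), 4)
  expect_equal(radius_from_depth(60, 100, 20, 12, 4), 8)
  expect_equal(radius_from_depth(500, 100, 20, 12, 4), 12)   # clamp near
  expect_equal(radius_from_depth(0, 100, 20, 12, 4), 4)      # clamp far
  expect_equal(radius_from_depth(7, 50, 50, 9, 3), 9)        # degenerate depth
})

test_that("class weights follow inverse frequency normalized by class count", {
  m5050 <- matrix(c(rep(0L, 50), rep(1L, 50)), 10, 10)
  expect_equal(unname(compute_class_weights(m5050)), c(1, 1))

  m991 <- matrix(0L, 10, 10); m991[1] <- 1L
  expect_equal(unname(compute_class_weights(m991)), c(100 / (2 * 99), 50),
               tolerance = 1e-12)

  m3 <- matrix(c(rep(0L, 80), rep(1L, 15), rep(2L, 5)), 10, 10)
  expect_equal(unname(compute_class_weights(m3)),
               c(1 / 0.80, 1 / 0.15, 1 / 0.05) / 3, tolerance = 1e-12)

  expect_error(compute_class_weights(m5050, n_classes = 3,
                                     class_names = c("bg", "paddy", "millet")),
               "millet")
})

test_that("weights satisfy the normalization identity on random masks", {
  set.seed(4)
  for (trial in 1:20) {
    masks <- lapply(1:3, function(i) matrix(sample(0:2, 64, TRUE), 8, 8))
    counts <- Reduce(`+`, lapply(masks, function(m) tabulate(m + 1, 3)))
    if (any(counts == 0)) next
    w <- compute_class_weights(masks, n_classes = 3)
    freq <- counts / sum(counts)
    expect_equal(sum(w * freq), 1, tolerance = 1e-12)
  }
})

test_that("annotation JSON round-trips and validates its schema", {
  kp <- data.frame(class = c("paddy", "millet"), row = c(10.5, 20),
                   col = c(30, 40.25), radius = c(6, 3.5))
  g <- semantic_graphic(polylines = list(rbind(c(0, 5), c(63, 9.5))),
                        keypoints = kp, image_shape = c(64, 64))
  f <- withr::local_tempfile(fileext = ".json")
  write_annotation(g, f)
  g2 <- read_annotation(f)
  expect_equal(g2$polylines, g$polylines, tolerance = 1e-7)
  expect_equal(g2$keypoints, g$keypoints, tolerance = 1e-7)
  expect_identical(g2$image_shape, g$image_shape)

  # missing keypoints key -> empty keypoint table
  writeLines('{"image_shape": [32, 32], "polylines": [[[0,1],[31,2]]]}', f)
  g3 <- read_annotation(f)
  expect_identical(nrow(g3$keypoints), 0L)
  expect_length(g3$polylines, 1)

  # invariant violations are rejected, naming the offending field
  writeLines(paste0('{"image_shape": [32, 32], "keypoints": ',
                    '[{"class": "paddy", "center": [5, 5], "radius": -1}]}'), f)
  expect_error(read_annotation(f), "radius")
  writeLines(paste0('{"image_shape": [32, 32], "keypoints": ',
                    '[{"class": "dandelion", "center": [5, 5], "radius": 2}]}'), f)
  expect_error(read_annotation(f), "dandelion")
})
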