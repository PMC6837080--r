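test_that("iou handles identity, disjoint and empty-class cases", {
  a <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  b <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  expect_identical(iou(a, a, 1), 1.0)
  expect_identical(iou(a, b, 1), 0.0)
  expect_identical(iou(a, a, 2), 1.0)  # class absent from both
  expect_error(iou(a, matrix(0L, 3, 3), 1), "shapes differ")
})

test_that("iou equals the counting-loop oracle on random masks", {
  set.seed(17)
  for (trial in 1:1000) {
    p <- matrix(sample(0:2, 256, TRUE), 16, 16)
    t <- matrix(sample(0:2, 256, TRUE), 16, 16)
    cls <- sample(0:2, 1)
    expect_identical(iou(p, t, cls), oracle_iou(p, t, cls))
    expect_identical(iou(p, t, cls), iou(t, p, cls))  # symmetry
  }
})

test_that("keypoint matching: exact hits, threshold boundary, empty conventions", {
  truth <- data.frame(class = "paddy", row = c(20, 60), col = c(20, 60))
  pred <- matrix(0L, 96, 96)
  pred[21, 21] <- 1L; pred[61, 61] <- 1L  # single-pixel components at truths
  prf <- keypoint_prf(pred, truth, d_thresh = 15)
  p_row <- prf[prf$class == "paddy", ]
  expect_equal(p_row$precision, 1)
  expect_equal(p_row$recall, 1)
  # millet: no predictions, no truths -> precision = recall = 1 by convention
  m_row <- prf[prf$class == "millet", ]
  expect_equal(m_row$precision, 1)
  expect_equal(m_row$recall, 1)

  # one truth, one prediction at distance 16 with d_thresh 15
  pred2 <- matrix(0L, 96, 96)
  pred2[21, 37] <- 1L  # (20, 36): 16 px right of truth (20, 20)
  prf2 <- keypoint_prf(pred2, data.frame(class = "paddy", row = 20, col = 20),
                       d_thresh = 15)
  p2 <- prf2[prf2$class == "paddy", ]
  expect_identical(c(p2$tp, p2$fp, p2$fn), c(0, 1, 1))
  # distance exactly 15 is a hit
  pred3 <- matrix(0L, 96, 96)
  pred3[21, 36] <- 1L
  prf3 <- keypoint_prf(pred3, data.frame(class = "paddy", row = 20, col = 20),
                       d_thresh = 15)
  expect_identical(prf3[prf3$class == "paddy", "tp"], 1)
})

test_that("greedy matching attains the exhaustive-assignment TP count", {
  set.seed(23)
  for (trial in 1:200) {
    nt <- sample(3:5, 1); np <- sample(3:7, 1)
    # keep points on a coarse lattice so single-pixel components stay separate
    truth_pts <- cbind(sample(seq(2, 250, 4), nt), sample(seq(2, 250, 4), nt))
    pred_pts <- cbind(sample(seq(0, 252, 4), np), sample(seq(0, 252, 4), np))
    pred <- matrix(0L, 256, 256)
    pred[pred_pts + 1L] <- 1L
    truth <- data.frame(class = "paddy", row = truth_pts[, 1],
                        col = truth_pts[, 2])
    prf <- keypoint_prf(pred, truth, d_thresh = 15, classes = "paddy")
    expect_identical(prf$tp[1],
                     as.numeric(oracle_max_tp(pred_pts, truth_pts, 15)))
  }
})

test_that("mean pixel deviation follows its definition", {
  gt <- list(list(a = 0.1, b = 40, y_min = 0, y_max = 99))
  pred_same <- list(list(a = 0.1, b = 40, y_min = 0, y_max = 99))
  mp <- mean_pixel_deviation(pred_same, gt)
  expect_equal(mp$mpd, 0)
  expect_equal(mp$deviation_range, c(0, 0))

  pred_shift <- list(list(a = 0.1, b = 43, y_min = 0, y_max = 99))
  mp3 <- mean_pixel_deviation(pred_shift, gt)
  expect_equal(mp3$mpd, 3)
  expect_equal(mp3$deviation_range, c(3, 3))

  # two lines over equal row counts, shifted +2 and -4 -> mpd 3
  gt2 <- list(list(a = 0, b = 30, y_min = 0, y_max = 49),
              list(a = 0, b = 80, y_min = 0, y_max = 49))
  pr2 <- list(list(a = 0, b = 32, y_min = 0, y_max = 49),
              list(a = 0, b = 76, y_min = 0, y_max = 49))
  mp2 <- mean_pixel_deviation(pr2, gt2)
  expect_equal(mp2$mpd, 3)
  expect_equal(mp2$deviation_range, c(-4, 2))

  # no predictions: NaN mpd, all ground truths missed
  mp0 <- mean_pixel_deviation(list(), gt2)
  expect_true(is.nan(mp0$mpd))
  expect_identical(mp0$missed, 2L)
})

test_that("mpd is invariant under a common x-translation", {
  set.seed(3)
  for (trial in 1:20) {
    gt <- lapply(1:3, function(i)
      list(a = runif(1, -0.3, 0.3), b = runif(1, 20, 200), y_min = 0, y_max = 63))
    pr <- lapply(gt, function(l) {
      l$a <- l$a + runif(1, -0.05, 0.05); l$b <- l$b + runif(1, -5, 5); l
    })
    off <- runif(1, -50, 50)
    shift <- function(ls) lapply(ls, function(l) { l$b <- l$b + off; l })
    m1 <- mean_pixel_deviation(pr, gt)
    m2 <- mean_pixel_deviation(shift(pr), shift(gt))
    expect_equal(m1$mpd, m2$mpd, tolerance = 1e-10)
  }
})

test_that("a ground-truth oracle model evaluates to mIoU 1.0", {
  dataset <- tiny_line_dataset(n = 3, seed = 33)
  om <- make_oracle_model(lapply(dataset, `[[`, "mask"))
  rep <- evaluate_model(om, dataset, task = "lines", extract_lines = FALSE)
  expect_equal(rep$miou, 1.0)
  expect_equal(rep$per_class_iou$line, 1.0)
})

test_that("dataset-level metrics equal image-by-image pooling", {
  dataset <- tiny_line_dataset(n = 4, seed = 44)
  model <- build_model(micro_net_config(in_channels = 3), seed = 2)
  rep <- evaluate_model(model, dataset, task = "lines", extract_lines = FALSE)
  inter <- c(0, 0); uni <- c(0, 0)
  for (d in dataset) {
    pred <- model_predict(model, d$image)
    for (cls in 0:1) {
      inter[cls + 1] <- inter[cls + 1] + sum(pred == cls & d$mask == cls)
      uni[cls + 1] <- uni[cls + 1] + sum(pred == cls | d$mask == cls)
    }
  }
  expect_equal(rep$miou, mean(inter / uni), tolerance = 1e-12)
})

test_that("evaluation reports round-trip through JSON", {
  dataset <- tiny_line_dataset(n = 2, seed = 55)
  om <- make_oracle_model(lapply(dataset, `[[`, "mask"))
  rep <- evaluate_model(om, dataset, task = "lines", extract_lines = TRUE)
  f <- withr::local_tempfile(fileext = ".json")
  write_report(rep, f)
  back <- read_report(f)
  expect_equal(back$miou, rep$miou, tolerance = 1e-9)
  expect_equal(back$mpd, rep$mpd, tolerance = 1e-9)
  expect_equal(back$n_images, rep$n_images)
})
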