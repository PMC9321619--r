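test_that("ROI boxes follow the landmark geometry on a template face", {
  lm <- face_landmark_template()
  rois <- select_rois(lm, c(480, 640))
  p <- lm$points
  nose_tip_y <- p[31, 2]
  chin_y <- p[9, 2]
  eyebrow_y <- min(p[18:27, 2])
  expect_equal(rois$cheek[2], nose_tip_y)          # top edge at nose tip
  expect_equal(rois$cheek[4], chin_y)              # bottom edge at chin
  expect_equal(rois$cheek[c(1, 3)],
               c(min(p[1:17, 1]), max(p[1:17, 1])))
  expect_equal(rois$forehead[4], eyebrow_y)
  expect_equal(rois$forehead[2],
               floor(eyebrow_y - 0.4 * (chin_y - eyebrow_y)))
  expect_equal(rois$forehead[c(1, 3)],
               c(min(p[18:27, 1]), max(p[18:27, 1])))
})

test_that("boxes are equivariant under integer translation", {
  lm <- face_landmark_template()
  lm10 <- landmark_frame(lm$points + cbind(rep(10, 68), rep(0, 68)))
  a <- select_rois(lm, c(480, 640))
  b <- select_rois(lm10, c(480, 640))
  for (rg in c("forehead", "cheek")) {
    expect_equal(b[[rg]][c(1, 3)], a[[rg]][c(1, 3)] + 10)
    expect_equal(b[[rg]][c(2, 4)], a[[rg]][c(2, 4)])
  }
})

test_that("a face at the image border yields clipped, in-bounds boxes", {
  # landmarks in bounds, but the forehead extension would leave the frame
  lm <- face_landmark_template(cx = 105, cy = 70)
  rois <- select_rois(lm, c(300, 300))
  expect_equal(rois$forehead[2], 0)   # clipped at the top edge
  for (b in rois) {
    expect_gte(b[1], 0); expect_gte(b[2], 0)
    expect_lte(b[3], 300); expect_lte(b[4], 300)
    expect_gt(b[3], b[1]); expect_gt(b[4], b[2])
  }
  # out-of-frame landmarks are rejected outright
  lm_out <- face_landmark_template(cx = 5, cy = 5)
  expect_error(select_rois(lm_out, c(300, 300)), "outside")
})

test_that("degenerate boxes are reported with the region name", {
  lm <- face_landmark_template()
  pts <- lm$points
  pts[31, 2] <- pts[9, 2] + 5   # nose tip below the chin line
  expect_error(select_rois(landmark_frame(pts), c(480, 640)), "cheek")
})

test_that("extract_stream picks the centred window and fixed box", {
  # encode the frame index in the pixel value; values stay in [0, 1]
  n <- 1200L
  video <- array(rep((0:(n - 1)) / n, times = 20 * 30 * 3),
                 dim = c(n, 20, 30, 3))
  st <- extract_stream(video, box = c(4, 2, 20, 14), region_label = "cheek",
                       target = c(6L, 10L), n_frames = 600L, fps = 20)
  expect_equal(dim(st$pixels), c(600, 6, 10, 3))
  # centred window: frames 300..899 (0-based)
  expect_equal(st$pixels[1, 1, 1, 1], 300 / n)
  expect_equal(st$pixels[600, 1, 1, 1], 899 / n)
  expect_equal(st$source_box, c(4L, 2L, 20L, 14L))
})

test_that("whole-video selection and constant colour survive standardising", {
  video <- array(0.25, dim = c(600, 16, 20, 3))
  video[, , , 2] <- 0.5
  st <- extract_stream(video, box = c(0, 0, 20, 16), target = c(8L, 10L),
                       n_frames = 600L)
  expect_equal(max(abs(st$pixels[, , , 1] - 0.25)), 0)
  expect_equal(max(abs(st$pixels[, , , 2] - 0.5)), 0)
  # 8-bit input is rescaled by 255
  v8 <- array(51, dim = c(600, 16, 20, 3))
  st8 <- extract_stream(v8, box = c(0, 0, 20, 16), target = c(8L, 10L),
                        n_frames = 600L)
  expect_equal(st8$pixels[1, 1, 1, 1], 0.2)
})

test_that("too-short videos report the required length", {
  video <- array(0.5, dim = c(100, 8, 8, 3))
  expect_error(extract_stream(video, c(0, 0, 8, 8), target = c(4L, 4L),
                              n_frames = 600L), "600")
})

test_that("extraction reproduces generator ROI pixels at identity size", {
  cfg <- small_sim(seed = 8)
  clip <- generate_clip(cfg)
  # embed the cheek ROI in a larger frame and extract it back
  big <- array(0, dim = c(cfg$n_frames, 30, 40, 3))
  big[, 5 + seq_len(cfg$roi_height), 7 + seq_len(cfg$roi_width), ] <-
    clip$cheek$pixels
  st <- extract_stream(big, box = c(7, 5, 7 + cfg$roi_width,
                                    5 + cfg$roi_height),
                       target = c(cfg$roi_height, cfg$roi_width),
                       n_frames = cfg$n_frames, fps = cfg$fps)
  expect_equal(st$pixels, clip$cheek$pixels, tolerance = 1e-12)
})

test_that("align_reference slices an already-matching trace unchanged", {
  x <- sin((0:799) / 10)
  out <- align_reference(x, source_rate = 20, fps = 20, n_frames = 600L)
  expect_length(out$samples, 600)
  expect_equal(out$samples, x[101:700], tolerance = 1e-12)
})

test_that("align_reference linearly interpolates a high-rate trace", {
  src_rate <- 256
  dur <- 40
  src_t <- seq(0, dur, by = 1 / src_rate)
  x <- sin(2 * pi * 0.7 * src_t) + 0.1 * src_t
  out <- align_reference(x, src_rate, fps = 20, n_frames = 600L)
  expect_length(out$samples, 600)
  offset <- (dur - 599 / 20) / 2
  for (k in c(1, 77, 300, 600)) {
    tk <- offset + (k - 1) / 20
    i <- floor(tk * src_rate)
    w <- tk * src_rate - i
    oracle <- (1 - w) * x[i + 1] + w * x[i + 2]
    expect_equal(out$samples[k], oracle, tolerance = 1e-10)
  }
  cst <- align_reference(rep(3.3, 2000), 256, fps = 20, n_frames = 60L)
  expect_equal(cst$samples, rep(3.3, 60))
})

test_that("align_reference rejects traces shorter than the window", {
  expect_error(align_reference(rnorm(100), 20, fps = 20, n_frames = 600L),
               "window")
})

test_that("landmark CSV round trip preserves the 68 points", {
  lm <- face_landmark_template()
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  df <- data.frame(frame_index = 0L, point_index = 0:67,
                   x = lm$points[, 1], y = lm$points[, 2])
  write.csv(df, path, row.names = FALSE)
  back <- read_landmarks(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$points, lm$points, ignore_attr = TRUE)
  bad <- df[-5, ]
  write.csv(bad, path, row.names = FALSE)
  expect_error(read_landmarks(path), "0..67")
})

test_that("video frames load from PNG directories and rds arrays", {
  skip_if_not_installed("png")
  dir <- file.path(tempdir(), "frames")
  dir.create(dir, showWarnings = FALSE)
  on.exit(unlink(dir, recursive = TRUE))
  set.seed(14)
  arr <- array(runif(4 * 6 * 5 * 3), c(4, 6, 5, 3))
  for (t in 1:4) {
    png::writePNG(arr[t, , , ], file.path(dir, sprintf("frame_%03d.png", t)))
  }
  got <- read_video_frames(dir)
  expect_equal(dim(got), dim(arr))
  expect_equal(got, arr, tolerance = 1 / 255)   # 8-bit quantisation
  rds <- file.path(tempdir(), "vid.rds")
  saveRDS(arr, rds)
  on.exit(unlink(rds), add = TRUE)
  expect_equal(read_video_frames(rds), arr)
  expect_error(read_video_frames(file.path(tempdir(), "nope.txt")),
               "unsupported")
})
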