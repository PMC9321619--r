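# Video -> fixed-size ROI streams. Coordinates are 0-based; boxes are
# half-open `(x0, y0, x1, y1)`; tensors are frames x height x width x
# channels. Landmark detection itself is external: landmarks arrive as a
# 68-point frame (iBUG ordering) from a file or any pluggable detector.

#' A 68-point facial landmark frame
#'
#' Standard iBUG ordering: 1--17 jaw, 18--27 eyebrows, 28--36 nose (31 = nose
#' tip), 37--48 eyes, 49--68 mouth. Coordinates are 0-based pixels.
#'
#' @param points 68 x 2 numeric matrix of (x, y).
#' @param frame_index 0-based frame the landmarks belong to.
#' @return List of class `landmark_frame`.
#' @export
landmark_frame <- function(points, frame_index = 0L) {
  points <- as.matrix(points)
  if (!all(dim(points) == c(68L, 2L))) {
    stop("landmark_frame needs exactly 68 (x, y) points")
  }
  structure(list(points = points, frame_index = as.integer(frame_index)),
            class = "landmark_frame")
}

#' Synthetic frontal-face landmark template
#'
#' A constructed, geometrically plausible 68-point frontal face used in
#' examples and tests (it is not derived from any detector or subject).
#'
#' @param cx,cy Face centre in pixels.
#' @param scale Size multiplier (1 = about a 200 x 260 px face).
#' @return A [landmark_frame()].
#' @export
face_landmark_template <- function(cx = 320, cy = 240, scale = 1) {
  pt <- matrix(NA_real_, 68L, 2L)
  th <- pi - (0:16) * pi / 16                      # jaw: ear-to-ear arc
  pt[1:17, ] <- cbind(cx + 100 * cos(th), cy - 40 + 130 * sin(th))
  pt[18:22, ] <- cbind(cx - 80 + (0:4) * 15, cy - 60)   # right eyebrow
  pt[23:27, ] <- cbind(cx + 20 + (0:4) * 15, cy - 60)   # left eyebrow
  pt[28:31, ] <- cbind(rep(cx, 4), cy - 50 + (0:3) * 15)  # nose bridge/tip
  pt[32:36, ] <- cbind(cx - 20 + (0:4) * 10, cy + 5)    # nostril base
  ang <- (0:5) * 2 * pi / 6
  pt[37:42, ] <- cbind(cx - 50 + 18 * cos(ang), cy - 45 + 7 * sin(ang))
  pt[43:48, ] <- cbind(cx + 50 + 18 * cos(ang), cy - 45 + 7 * sin(ang))
  ang2 <- (0:19) * 2 * pi / 20
  pt[49:68, ] <- cbind(cx + 30 * cos(ang2), cy + 45 + 12 * sin(ang2))
  pt[, 1] <- cx + (pt[, 1] - cx) * scale
  pt[, 2] <- cy + (pt[, 2] - cy) * scale
  landmark_frame(round(pt))
}

clip_box <- function(box, frame_shape, region) {
  b <- c(max(0, floor(box[1])), max(0, floor(box[2])),
         min(frame_shape[2], ceiling(box[3])),
         min(frame_shape[1], ceiling(box[4])))
  if (b[3] <= b[1] || b[4] <= b[2]) {
    stop(sprintf("degenerate %s box after clipping to %dx%d frame",
                 region, frame_shape[1], frame_shape[2]))
  }
  b
}

#' Select forehead and cheek boxes from first-frame landmarks
#'
#' The forehead box spans the eyebrow extent horizontally and runs from the
#' eyebrow line upward by `forehead_extend` times the eyebrow-to-chin
#' distance (68-point sets carry no hairline point, so "top of the head" is
#' this configurable extension). The cheek box spans the jaw extent
#' horizontally and runs from the nose-tip line to the chin line. Both boxes
#' are clipped to the frame; the boxes are then held fixed for every frame
#' of the clip.
#'
#' @param landmarks A [landmark_frame()] for the first frame.
#' @param frame_shape `(height, width)` of the video frames.
#' @param forehead_extend Upward extension factor (default 0.4).
#' @return List with `forehead` and `cheek`, each a 0-based half-open
#'   `(x0, y0, x1, y1)` box.
#' @export
select_rois <- function(landmarks, frame_shape, forehead_extend = 0.4) {
  stopifnot(inherits(landmarks, "landmark_frame"), length(frame_shape) == 2L)
  p <- landmarks$points
  if (any(p[, 1] < 0 | p[, 1] >= frame_shape[2] |
          p[, 2] < 0 | p[, 2] >= frame_shape[1])) {
    stop("landmark coordinates fall outside the frame bounds")
  }
  brows <- p[18:27, , drop = FALSE]
  eyebrow_y <- min(brows[, 2])
  chin_y <- p[9, 2]
  nose_tip_y <- p[31, 2]
  jaw <- p[1:17, , drop = FALSE]
  top_y <- eyebrow_y - forehead_extend * (chin_y - eyebrow_y)
  forehead <- clip_box(c(min(brows[, 1]), top_y, max(brows[, 1]), eyebrow_y),
                       frame_shape, "forehead")
  cheek <- clip_box(c(min(jaw[, 1]), nose_tip_y, max(jaw[, 1]), chin_y),
                    frame_shape, "cheek")
  list(forehead = forehead, cheek = cheek)
}

# bilinear resampling matrix mapping n_in samples to n_out (half-pixel
# centre convention, edges clamped)
resize_matrix <- function(n_out, n_in) {
  R <- matrix(0, n_out, n_in)
  pos <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  pos <- pmin(pmax(pos, 0), n_in - 1)
  lo <- floor(pos)
  w <- pos - lo
  for (i in seq_len(n_out)) {
    l <- lo[i] + 1L
    if (w[i] == 0) R[i, l] <- 1 else {
      R[i, l] <- 1 - w[i]
      R[i, l + 1L] <- w[i]
    }
  }
  R
}

#' Crop a fixed box from every frame and standardise the stream
#'
#' Selects the centred contiguous `n_frames` window (start index
#' `floor((T - n_frames) / 2)`, 0-based), crops the same box in every
#' selected frame (no tracking), bilinearly resizes each crop to
#' `target` and scales intensities to \[0, 1\] by dividing by 255 when the
#' input looks 8-bit (maximum value above 1).
#'
#' @param video_frames `(T, H, W, C)` array, or a list of `(H, W, C)` frame
#'   arrays.
#' @param box 0-based half-open `(x0, y0, x1, y1)` crop box.
#' @param region_label `"forehead"` or `"cheek"`.
#' @param target `(height, width)` of the standardised ROI (default 40, 140).
#' @param n_frames Frames to keep (default 600).
#' @param fps Frames per second of the source video.
#' @return An [roi_stream()] with `source_box = box`.
#' @export
extract_stream <- function(video_frames, box, region_label = "cheek",
                           target = c(40L, 140L), n_frames = 600L,
                           fps = 20) {
  if (is.list(video_frames)) {
    video_frames <- simplify2array(video_frames)      # (H, W, C, T)
    video_frames <- aperm(video_frames, c(4, 1, 2, 3))
  }
  d <- dim(video_frames)
  stopifnot(length(d) == 4L)
  if (d[1] < n_frames) {
    stop(sprintf("video has %d frames; %d are required", d[1], n_frames))
  }
  start <- (d[1] - n_frames) %/% 2L
  sel <- start + seq_len(n_frames)
  box <- as.integer(box)
  if (box[1] < 0 || box[2] < 0 || box[3] > d[3] || box[4] > d[2] ||
      box[3] <= box[1] || box[4] <= box[2]) {
    stop("crop box out of frame bounds or degenerate")
  }
  crop <- video_frames[sel, (box[2] + 1L):box[4], (box[1] + 1L):box[3], ,
                       drop = FALSE]
  if (max(crop) > 1) crop <- crop / 255
  Rh <- resize_matrix(target[1], dim(crop)[2])
  Rw <- resize_matrix(target[2], dim(crop)[3])
  out <- array(0, c(n_frames, target[1], target[2], d[4]))
  for (t in seq_len(n_frames)) {
    for (ch in seq_len(d[4])) {
      out[t, , , ch] <- Rh %*% crop[t, , , ch] %*% t(Rw)
    }
  }
  out <- pmin(pmax(out, 0), 1)
  roi_stream(out, fps, region_label, source_box = box)
}

#' Resample a reference trace to one sample per selected video frame
#'
#' The reference (recorded at `source_rate`) is linearly interpolated at the
#' frame times of the centred `n_frames` window, matching the frame
#' selection of [extract_stream()].
#'
#' @param samples Numeric reference signal.
#' @param source_rate Sampling rate of `samples` in Hz.
#' @param fps Video frame rate.
#' @param n_frames Frames in the selected window.
#' @param kind Trace kind for the result.
#' @return A [vital_trace()] of length `n_frames` at rate `fps`.
#' @export
align_reference <- function(samples, source_rate, fps = 20,
                            n_frames = 600L, kind = "ppg") {
  samples <- as.numeric(samples)
  m <- length(samples)
  duration <- (m - 1) / source_rate
  window <- (n_frames - 1) / fps
  if (window > duration + 1e-9) {
    stop(sprintf(
      "reference covers %.2f s but the selected window needs %.2f s",
      duration, window))
  }
  offset <- (duration - window) / 2
  tq <- offset + (seq_len(n_frames) - 1L) / fps
  src_t <- (seq_len(m) - 1L) / source_rate
  vals <- stats::approx(src_t, samples, xout = tq)$y
  vital_trace(vals, fps, kind)
}

#' Read a landmark stream from CSV
#'
#' Expected columns: `frame_index`, `point_index` (0-based, 0..67), `x`, `y`.
#'
#' @param path CSV file path.
#' @return Named list of [landmark_frame()]s keyed by frame index.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frame_index", "point_index", "x", "y")
  if (!all(need %in% names(df))) {
    stop("landmark CSV needs columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$frame_index), function(g) {
    g <- g[order(g$point_index), ]
    if (!identical(as.integer(g$point_index), 0:67)) {
      stop("frame ", g$frame_index[1], " does not contain points 0..67")
    }
    landmark_frame(cbind(g$x, g$y), g$frame_index[1])
  })
  out
}

#' Load video frames from an array file or a directory of frame images
#'
#' Real-mode input: either an `.rds` file holding a `(T, H, W, C)` array, or
#' a directory of equally sized PNG frames (lexicographic order = frame
#' order; requires the `png` package).
#'
#' @param path `.rds` file or directory of `.png` frames.
#' @return `(T, H, W, C)` numeric array.
#' @export
read_video_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0L) stop("no .png frames found in ", path)
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG frame directories requires the png package")
    }
    frames <- lapply(files, png::readPNG)
    d <- dim(frames[[1]])
    if (length(d) == 2L) d <- c(d, 1L)
    out <- array(0, c(length(frames), d))
    for (t in seq_along(frames)) out[t, , , ] <- frames[[t]]
    return(out)
  }
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    arr <- readRDS(path)
    if (length(dim(arr)) != 4L) stop("expected a (T, H, W, C) array in ", path)
    return(arr)
  }
  stop("unsupported video input: ", path,
       " (use an .rds array or a directory of PNG frames)")
}
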