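test_that("leaky ReLU follows its definition at and around zero", {
  expect_equal(leaky_relu(5), 5)
  expect_equal(leaky_relu(-100), -1)
  expect_equal(leaky_relu(0), 0)
  x <- matrix(c(-2, -0.5, 0, 0.5, 2, -1e6), 2)
  expect_equal(leaky_relu(x), ifelse(x >= 0, x, 0.01 * x))
  expect_equal(leaky_relu(-4, alpha = 0.2), -0.8)
})

test_that("zero-initialised attention gates are exactly one half", {
  set.seed(2)
  feat <- array(rnorm(6 * 6 * 8), c(6, 6, 8))
  expect_equal(channel_attention(feat), rep(0.5, 8))
  expect_equal(spatial_attention(feat), matrix(0.5, 6, 6))
})

test_that("channel gates ignore spatial permutations and stay in (0,1)", {
  set.seed(4)
  feat <- array(rnorm(5 * 7 * 6), c(5, 7, 6))
  C <- 6; hid <- 1L
  params <- list(W1 = matrix(rnorm(C * hid), C, hid), b1 = rnorm(hid),
                 W2 = matrix(rnorm(hid * C), hid, C), b2 = rnorm(C))
  g <- channel_attention(feat, params)
  expect_true(all(g > 0 & g < 1))
  perm <- sample(35)
  fmat <- matrix(feat, 35, 6)[perm, ]
  feat_p <- array(fmat, c(5, 7, 6))
  expect_equal(channel_attention(feat_p, params), g, tolerance = 1e-12)
})

test_that("channel attention matches a loop-based reimplementation", {
  set.seed(6)
  C <- 8; hid <- 1L
  feat <- array(rnorm(6 * 6 * C), c(6, 6, C))
  params <- list(W1 = matrix(rnorm(C * hid), C, hid), b1 = rnorm(hid),
                 W2 = matrix(rnorm(hid * C), hid, C), b2 = rnorm(C))
  # brute force: explicit loops over channels, shared MLP on avg and max
  avg <- numeric(C); mx <- numeric(C)
  for (c in seq_len(C)) {
    avg[c] <- mean(feat[, , c])
    mx[c] <- max(feat[, , c])
  }
  mlp <- function(v) {
    h <- pmax(as.numeric(v %*% params$W1) + params$b1, 0)
    as.numeric(h %*% params$W2) + params$b2
  }
  oracle <- 1 / (1 + exp(-(mlp(avg) + mlp(mx))))
  expect_equal(channel_attention(feat, params), oracle, tolerance = 1e-12)
})

test_that("spatial attention matches a loop-based reimplementation", {
  set.seed(7)
  h <- 6; w <- 6; C <- 8; k <- 7L; p <- 3L
  feat <- array(rnorm(h * w * C), c(h, w, C))
  params <- list(W = matrix(rnorm(2 * k * k), 2 * k * k, 1), b = rnorm(1))
  meanmap <- apply(feat, c(1, 2), mean)
  maxmap <- apply(feat, c(1, 2), max)
  oracle <- matrix(0, h, w)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      acc <- params$b
      for (dj in 0:(k - 1)) {
        for (di in 0:(k - 1)) {
          ii <- i + di - p; jj <- j + dj - p
          if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
            tap <- dj * k + di
            acc <- acc + params$W[tap * 2 + 1, 1] * meanmap[ii, jj] +
              params$W[tap * 2 + 2, 1] * maxmap[ii, jj]
          }
        }
      }
      oracle[i, j] <- 1 / (1 + exp(-acc))
    }
  }
  got <- spatial_attention(feat, params, kernel_size = k)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_true(all(got > 0 & got < 1))
  # channel-constant input: mean map equals max map
  feat_c <- array(rep(rnorm(h * w), C), c(h, w, C))
  expect_equal(apply(feat_c, c(1, 2), mean), apply(feat_c, c(1, 2), max))
})

test_that("multitask and single-task builds expose the right arity", {
  m_multi <- build_model(tiny_spec(multitask = TRUE), seed = 1)
  m_single <- build_model(tiny_spec(multitask = FALSE), seed = 1)
  Xf <- tiny_input(seed = 1); Xc <- tiny_input(seed = 2)
  out_m <- siamvitals:::mts_forward(m_multi, Xf, Xc)
  out_s <- siamvitals:::mts_forward(m_single, Xf, Xc)
  expect_length(out_m$ppg, 8)
  expect_length(out_m$resp, 8)
  expect_null(out_s$resp)
  # with the respiration head removed, the PPG path is identical
  expect_equal(out_s$ppg, out_m$ppg)
  expect_equal(count_parameters(m_multi) - count_parameters(m_single),
               length(m_multi$params$resp.W) + 1L)
})

test_that("swapping the two input streams leaves the PPG trace unchanged", {
  m <- build_model(tiny_spec(), seed = 3)
  Xf <- tiny_input(seed = 5); Xc <- tiny_input(seed = 6)
  a <- siamvitals:::mts_forward(m, Xf, Xc)
  b <- siamvitals:::mts_forward(m, Xc, Xf)
  expect_identical(a$ppg, b$ppg)
})

test_that("output length tracks the input frame count", {
  for (T in c(4L, 10L, 16L)) {
    spec <- tiny_spec(n_frames = T)
    m <- build_model(spec, seed = 1)
    Xf <- tiny_input(n_frames = T, seed = 1)
    Xc <- tiny_input(n_frames = T, seed = 2)
    out <- siamvitals:::mts_forward(m, Xf, Xc)
    expect_length(out$ppg, T)
    expect_length(out$resp, T)
    expect_true(all(is.finite(out$ppg)), all(is.finite(out$resp)))
  }
})

test_that("count_parameters agrees with hand-counted layer algebra", {
  # dense n -> m with bias contributes n*m + m
  spec <- tiny_spec()
  m <- build_model(spec, seed = 1)
  d <- length(m$params$ppg.W)
  expect_equal(d, 2L * 4L * 3L)   # pooled 2x4 map, 3 channels, flattened
  counted <- count_parameters(m)
  by_hand <- sum(
    9 * 2 * 3 + 3,          # stage-1 3x3 conv (2 -> 3 channels)
    3 * 2 + 2,              # stage-1 1x1 reduce
    2 * 1 + 1 + 1 * 2 + 2,  # stage-1 channel-attention MLP
    2 * 49 + 1,             # stage-1 spatial-attention conv
    9 * 2 * 4 + 4,          # stage-2 conv (2 -> 4)
    4 * 3 + 3,              # stage-2 reduce
    3 * 1 + 1 + 1 * 3 + 3,  # stage-2 channel-attention MLP
    2 * 49 + 1,             # stage-2 spatial-attention conv
    d + 1,                  # PPG readout
    d + 1                   # respiration head
  )
  expect_equal(counted, by_hand)
})

test_that("the default specs land on their published parameter budgets", {
  expect_silent(m <- build_model(model_spec(), seed = 1))
  expect_equal(round(count_parameters(m) / 1e6, 2), 0.72)
  expect_silent(m1 <- build_model(model_spec(multitask = FALSE), seed = 1))
  expect_equal(round(count_parameters(m1) / 1e6, 2), 0.69)
  # a spec far off its declared budget warns but still builds
  bad <- model_spec(conv_filters = c(8L, 8L, 8L),
                    reduce_filters = c(4L, 4L, 4L))
  expect_warning(build_model(bad, seed = 1), "budget")
})

test_that("model gradients match finite differences end to end", {
  set.seed(42)
  spec <- tiny_spec(n_frames = 6L)
  m <- build_model(spec, seed = 7)
  Xf <- matrix(rnorm(4 * 8 * 6 * 2), 4 * 8 * 6, 2)
  Xc <- matrix(rnorm(4 * 8 * 6 * 2), 4 * 8 * 6, 2)
  xppg <- rnorm(6); xresp <- rnorm(6)
  lossfun <- function(mm) {
    fw <- siamvitals:::mts_forward(mm, Xf, Xc)
    as.numeric(pearson_loss(xppg, fw$ppg)) +
      as.numeric(pearson_loss(xresp, fw$resp))
  }
  fw <- siamvitals:::mts_forward(m, Xf, Xc, keep_cache = TRUE)
  gr <- siamvitals:::mts_backward(
    m, fw$cache,
    siamvitals:::pearson_loss_grad(xppg, fw$ppg),
    siamvitals:::pearson_loss_grad(xresp, fw$resp))
  eps <- 1e-6
  for (nm in names(m$params)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(3, length(p)))) {
      mp <- m; mp$params[[nm]][i] <- p[i] + eps
      mm2 <- m; mm2$params[[nm]][i] <- p[i] - eps
      num <- (lossfun(mp) - lossfun(mm2)) / (2 * eps)
      if (abs(num) < 1e-7) next
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})
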