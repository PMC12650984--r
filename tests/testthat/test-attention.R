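# Channel and spatial attention operators and their cross-layer fusion

rand_state_channel <- function(C, Cprev = NULL, reduction = 2) {
  channel_attention_state(C, n_prev = Cprev, reduction = reduction,
                          init = function(n) rnorm(n, 0, 0.5))
}

test_that("pooling operators match explicit loop oracles", {
  set.seed(1)
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  cp <- channel_pool(f)
  sp <- spatial_pool(f)
  for (c in 1:3) {
    acc <- 0; mx <- -Inf
    for (h in 1:4) for (w in 1:4) {
      acc <- acc + f[h, w, c]; mx <- max(mx, f[h, w, c])
    }
    expect_equal(cp$avg[c], acc / 16, tolerance = 1e-12)
    expect_equal(cp$max[c], mx, tolerance = 1e-12)
  }
  for (h in 1:4) for (w in 1:4) {
    expect_equal(sp$avg[h, w], mean(f[h, w, ]), tolerance = 1e-12)
    expect_equal(sp$max[h, w], max(f[h, w, ]), tolerance = 1e-12)
  }

  const <- array(3, c(2, 5, 4))
  expect_equal(channel_pool(const)$avg, rep(3, 4))
  expect_equal(channel_pool(const)$max, rep(3, 4))
  one_px <- array(rnorm(6), c(1, 1, 6))
  expect_equal(channel_pool(one_px)$avg, as.vector(one_px))
  expect_equal(channel_pool(one_px)$max, as.vector(one_px))
  single_chan <- array(rnorm(9), c(3, 3, 1))
  expect_equal(spatial_pool(single_chan)$avg, single_chan[, , 1])
  expect_equal(spatial_pool(single_chan)$max, single_chan[, , 1])
})

test_that("zero parameters give uniform 0.5 attention (sigmoid at zero)", {
  f <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  cst <- channel_attention_state(4, init = "zeros")
  cst$lambda <- c(1, 1)
  expect_equal(channel_attention(f, NULL, cst), rep(0.5, 4))

  sst <- spatial_attention_state(first_layer = TRUE, init = "zeros")
  expect_equal(spatial_attention(f, NULL, sst), matrix(0.5, 3, 3))
})

test_that("channel attention matches the hand-unrolled fusion equation", {
  set.seed(11)
  for (rep in 1:3) {
    C <- 3; Cprev <- 2
    f <- array(rnorm(2 * 2 * C), c(2, 2, C))
    st <- rand_state_channel(C, Cprev)
    st$lambda <- c(0.7, 1.3, 0.4)
    st$w0$mean <- rnorm(C, 0, 0.1); st$w0$var <- runif(C, 0.5, 2)
    st$w0$gamma <- runif(C, 0.5, 2); st$w0$beta <- rnorm(C, 0, 0.2)
    prev <- runif(Cprev)

    # hand-unrolled: pooled vectors, shared MLP, W0+BN+ReLU pathway, sigmoid
    m_avg <- apply(f, 3, mean)
    m_max <- apply(f, 3, max)
    mlp <- function(v) {
      h <- pmax(st$mlp$w1 %*% v + st$mlp$b1, 0)
      drop(st$mlp$w2 %*% h + st$mlp$b2)
    }
    u <- drop(st$w0$w %*% prev + st$w0$b)
    u <- st$w0$gamma * (u - st$w0$mean) / sqrt(st$w0$var + 1e-5) + st$w0$beta
    z <- st$lambda[1] * mlp(m_avg) + st$lambda[2] * mlp(m_max) +
      st$lambda[3] * mlp(pmax(u, 0))
    oracle <- 1 / (1 + exp(-z))

    expect_equal(channel_attention(f, prev, st), oracle, tolerance = 1e-10)
    expect_true(all(channel_attention(f, prev, st) > 0 &
                    channel_attention(f, prev, st) < 1))
  }
})

test_that("channel attention is invariant to spatial permutations", {
  set.seed(12)
  f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  st <- rand_state_channel(3)
  w1 <- channel_attention(f, NULL, st)
  perm <- sample(16)
  fp <- f
  for (c in 1:3) fp[, , c] <- matrix(as.vector(f[, , c])[perm], 4, 4)
  expect_identical(w1, channel_attention(fp, NULL, st))
})

test_that("spatial attention matches the hand-unrolled fusion equation", {
  set.seed(13)
  for (rep in 1:3) {
    f <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
    st <- spatial_attention_state(first_layer = FALSE, ws_kernel = 3,
                                  init = function(n) rnorm(n, 0, 0.5))
    prev <- matrix(rnorm(16), 4, 4)

    conv3_same <- function(x, w, b) { # x: H x W x Cin, w: 3 x 3 x Cin x 1
      H <- dim(x)[1]; W <- dim(x)[2]
      out <- matrix(b, H, W)
      for (h in 1:H) for (wd in 1:W) {
        acc <- 0
        for (dr in -1:1) for (dc in -1:1) for (ic in seq_len(dim(x)[3])) {
          hh <- h + dr; ww <- wd + dc
          if (hh >= 1 && hh <= H && ww >= 1 && ww <= W) {
            acc <- acc + x[hh, ww, ic] * w[dr + 2, dc + 2, ic, 1]
          }
        }
        out[h, wd] <- out[h, wd] + acc
      }
      out
    }
    m_avg <- apply(f, c(1, 2), mean)
    m_max <- apply(f, c(1, 2), max)
    transferred <- conv3_same(array(prev, c(4, 4, 1)), st$wl$w, st$wl$b)
    stacked <- array(c(m_avg, m_max, transferred), c(4, 4, 3))
    oracle <- 1 / (1 + exp(-conv3_same(stacked, st$ws$w, st$ws$b)))

    got <- spatial_attention(f, prev, st)
    expect_equal(got, oracle, tolerance = 1e-10)
    expect_true(all(got > 0 & got < 1))
  }
})

test_that("spatial attention is invariant to channel permutations", {
  set.seed(14)
  f <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  st <- spatial_attention_state(first_layer = TRUE,
                                init = function(n) rnorm(n, 0.1, 0.3))
  m1 <- spatial_attention(f, NULL, st)
  expect_identical(m1, spatial_attention(f[, , sample(5)], NULL, st))
})

test_that("attention application broadcasts as element-wise products", {
  set.seed(15)
  f <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  w <- runif(2)
  out <- apply_channel_attention(f, w)
  for (h in 1:3) for (wd in 1:4) for (c in 1:2) {
    expect_equal(out[h, wd, c], f[h, wd, c] * w[c], tolerance = 1e-14)
  }
  expect_identical(apply_channel_attention(f, c(1, 1)), f)
  expect_equal(apply_channel_attention(f, c(0, 0)), array(0, dim(f)))

  map <- matrix(runif(12), 3, 4)
  out2 <- apply_spatial_attention(f, map)
  for (h in 1:3) for (wd in 1:4) for (c in 1:2) {
    expect_equal(out2[h, wd, c], f[h, wd, c] * map[h, wd], tolerance = 1e-14)
  }
  expect_identical(apply_spatial_attention(f, matrix(1, 3, 4)), f)
  ind <- matrix(0, 3, 4); ind[2, 3] <- 1
  masked <- apply_spatial_attention(f, ind)
  expect_equal(masked[2, 3, ], f[2, 3, ])
  expect_equal(sum(abs(masked)) , sum(abs(f[2, 3, ])))

  expect_error(apply_channel_attention(f, c(1, 1, 1)), "channels")
  expect_error(apply_spatial_attention(f, matrix(1, 2, 2)), "dims")
})

test_that("cross-layer map pooling brings resolutions into line", {
  m <- matrix(rnorm(31 * 31), 31, 31)
  p <- max_pool_map(m, 3, 2)
  expect_identical(dim(p), c(15L, 15L))
  expect_equal(p[1, 1], max(m[1:3, 1:3]))
  expect_equal(p[15, 15], max(m[29:31, 29:31]))
})

test_that("compiled attention blocks agree with the R reference", {
  set.seed(16)
  C <- 4; Cprev <- 3
  st <- rand_state_channel(C, Cprev)
  st$w0$mean <- rnorm(C, 0, 0.1); st$w0$var <- runif(C, 0.5, 2)
  f <- array(rnorm(3 * 3 * C), c(3, 3, C))
  prev <- runif(Cprev)
  params <- list(
    c_att2_mlp_w1 = st$mlp$w1, c_att2_mlp_b1 = st$mlp$b1,
    c_att2_mlp_w2 = st$mlp$w2, c_att2_mlp_b2 = st$mlp$b2,
    c_att2_lambda = st$lambda,
    c_att2_w0_w = st$w0$w, c_att2_w0_b = st$w0$b,
    c_att2_w0bn_gamma = st$w0$gamma, c_att2_w0bn_beta = st$w0$beta,
    c_att2_w0bn_mean = st$w0$mean, c_att2_w0bn_var = st$w0$var
  )
  got <- hyperbrix:::cpp_channel_attention(params, f, prev, "c_att2")
  expect_equal(got, channel_attention(f, prev, st), tolerance = 1e-12)

  sst <- spatial_attention_state(first_layer = FALSE,
                                 init = function(n) rnorm(n, 0, 0.4))
  fs <- array(rnorm(7 * 7 * 3), c(7, 7, 3))
  prev_map <- matrix(rnorm(15 * 15), 15, 15)
  sparams <- list(
    s_att2_ws_w = sst$ws$w, s_att2_ws_b = sst$ws$b,
    s_att2_wl_w = sst$wl$w, s_att2_wl_b = sst$wl$b
  )
  got_s <- hyperbrix:::cpp_spatial_attention(sparams, fs, prev_map,
                                             "s_att2", 3L, 2L)
  expect_equal(got_s, spatial_attention(fs, prev_map, sst),
               tolerance = 1e-12)
})
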