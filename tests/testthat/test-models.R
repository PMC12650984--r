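# Model assembly, training mechanics and the compiled network core

tiny_ma_spec <- function(epochs = 2L, attention = "on", act = "ReLU") {
  model_spec("ma_cnn",
             spectral_branch = branch_config(c(3, 4, 5)),
             spatial_branch = branch_config(c(3, 4, 5),
                                            kernel_sizes = c(3, 5, 7),
                                            pool_size = 3L, pool_stride = 2L),
             fc_neurons = c(6, 4), learning_rate = 2e-3, batch_size = 4L,
             optimizer = "Adam", activation = act, epochs = epochs,
             attention = attention, reduction = 2L)
}

random_patch_set <- function(n, B, label = NULL, id = "f1",
                             spatial = 31L, seed = 1) {
  set.seed(seed)
  structure(lapply(seq_len(n), function(i) {
    structure(list(
      spectral_patch = array(rnorm(3 * 3 * B), c(3, 3, B)),
      spatial_patch = array(rnorm(spatial * spatial * B),
                            c(spatial, spatial, B)),
      center = c(1L, 1L), sample_id = id,
      label = if (is.null(label)) rnorm(1, 12, 2) else label
    ), class = "patch_pair")
  }), class = "patch_set")
}

test_that("model_spec enforces branch presence by kind", {
  expect_error(model_spec("ma_cnn",
                          spectral_branch = branch_config(c(4, 4, 4))),
               "spatial branch")
  expect_error(model_spec("ca_cnn"), "spectral branch")
  sp <- model_spec("ca_cnn", spectral_branch = branch_config(c(4, 4, 4)),
                   spatial_branch = branch_config(c(4, 4, 4)))
  expect_null(sp$spatial_branch) # dropped: not part of a ca_cnn
})

test_that("parameter count equals an independent layer-by-layer count", {
  B <- 16L
  model <- build_model(ca_cnn_spec(), n_bands = B, seed = 1)
  # independent closed-form arithmetic, layer by layer
  filters <- c(32, 64, 128); r <- 8
  cin <- B; total <- 0
  for (l in 1:3) {
    cout <- filters[l]
    total <- total + 3 * 3 * cin * cout + cout  # conv W + b
    total <- total + 2 * cout                   # BN gamma + beta
    h <- max(1, cout %/% r)                     # shared attention MLP
    total <- total + h * cout + h + cout * h + cout
    total <- total + if (l == 1) 2 else 3       # lambda fusion scalars
    if (l > 1) {
      total <- total + cout * cin + cout        # W0
      total <- total + 2 * cout                 # W0 batch norm
    }
    cin <- cout
  }
  total <- total + 83 * 128 + 83 + 51 * 83 + 51 + 1 * 51 + 1
  expect_identical(count_trainable_parameters(model), as.integer(total))
})

test_that("adding an FC neuron grows the count by its in/out links", {
  spec1 <- tiny_ma_spec()
  spec2 <- tiny_ma_spec()
  spec2$fc_neurons <- c(7, 4)
  m1 <- build_model(spec1, n_bands = 4, seed = 1)
  m2 <- build_model(spec2, n_bands = 4, seed = 1)
  n_in <- 5 + 5 # concatenated branch features
  expect_identical(count_trainable_parameters(m2) -
                     count_trainable_parameters(m1),
                   as.integer(n_in + 1 + 4)) # weights in + bias + links out
})

test_that("frozen attention drops the attention parameters", {
  m_on <- build_model(tiny_ma_spec(attention = "on"), n_bands = 4, seed = 1)
  m_frozen <- build_model(tiny_ma_spec(attention = "frozen"), n_bands = 4,
                          seed = 1)
  expect_lt(count_trainable_parameters(m_frozen),
            count_trainable_parameters(m_on))
  expect_true(all(names(m_frozen$params) %in% names(m_on$params)))
})

test_that("attention frozen at one reproduces the plain CNN bitwise", {
  B <- 4
  m_frozen <- build_model(tiny_ma_spec(attention = "frozen"), B, seed = 7)
  m_off <- build_model(tiny_ma_spec(attention = "off"), B, seed = 7)
  expect_identical(m_frozen$params, m_off$params)
  ps <- random_patch_set(3, B, seed = 2)
  arr <- hyperbrix:::stack_patch_pairs(ps)
  cfg_frozen <- hyperbrix:::net_config(m_frozen$spec, B)
  cfg_off <- hyperbrix:::net_config(m_off$spec, B)
  y_frozen <- hyperbrix:::cpp_predict(m_frozen$params, cfg_frozen,
                                      arr$spectral, arr$spatial)
  y_off <- hyperbrix:::cpp_predict(m_off$params, cfg_off,
                                   arr$spectral, arr$spatial)
  expect_identical(y_frozen, y_off)
})

test_that("analytic gradients match finite differences", {
  set.seed(5)
  B <- 4
  model <- build_model(tiny_ma_spec(act = "ELU"), B, seed = 3)
  # jitter all parameters so no ReLU/max sits exactly at a kink
  for (nm in names(model$params)) {
    if (grepl("_mean$|_var$", nm)) next
    model$params[[nm]] <- model$params[[nm]] +
      rnorm(length(model$params[[nm]]), 0, 0.3)
  }
  n <- 3
  xs <- array(rnorm(3 * 3 * B * n), c(3, 3, B, n))
  xp <- array(rnorm(31 * 31 * B * n), c(31, 31, B, n))
  y <- rnorm(n)
  cfg <- hyperbrix:::net_config(model$spec, B)
  g <- hyperbrix:::cpp_gradients(model$params, cfg, xs, xp, y)
  eps <- 1e-6
  checked <- 0
  for (nm in names(model$params)) {
    if (grepl("_mean$|_var$", nm)) next
    gr <- g$gradients[[nm]]
    for (i in sample(seq_along(gr), min(2, length(gr)))) {
      p2 <- model$params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      l1 <- hyperbrix:::cpp_loss(p2, cfg, xs, xp, y)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      l0 <- hyperbrix:::cpp_loss(p2, cfg, xs, xp, y)
      num <- (l1 - l0) / (2 * eps)
      scale <- abs(num) + abs(gr[i])
      if (scale < 1e-6) next # gradient numerically zero: nothing to compare
      expect_lt(abs(num - gr[i]) / scale, 1e-4)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 40)
})

test_that("training history has one row per epoch and scales labels", {
  B <- 4
  ps <- random_patch_set(12, B, seed = 3)
  spec <- model_spec("ca_cnn", spectral_branch = branch_config(c(3, 3, 3)),
                     fc_neurons = c(4, 3), learning_rate = 1e-3,
                     batch_size = 6L, optimizer = "Adam",
                     activation = "ReLU", epochs = 30L, reduction = 2L)
  m <- train_model(build_model(spec, B, seed = 1), ps, seed = 2)
  expect_equal(nrow(m$history), 30)
  labs <- vapply(ps, function(p) p$label, numeric(1))
  expect_equal(m$label_scaler, range(labs))
})

test_that("training overfits a single repeated sample", {
  B <- 4
  one <- random_patch_set(1, B, label = 12, seed = 4)
  ps <- do.call(c, rep(list(one), 8))
  spec <- model_spec("ca_cnn", spectral_branch = branch_config(c(4, 4, 4)),
                     fc_neurons = c(6, 4), learning_rate = 1e-2,
                     batch_size = 8L, optimizer = "Adam",
                     activation = "ReLU", epochs = 200L, reduction = 2L)
  # constant labels are degenerate for min-max scaling; give the scaler a span
  m <- train_model(build_model(spec, B, seed = 2), ps, seed = 3,
                   label_scaler = c(7.2, 18.1))
  expect_lt(tail(m$history$loss, 1), 1e-3)
})

test_that("training is deterministic under a fixed seed", {
  B <- 4
  ps <- random_patch_set(10, B, seed = 6)
  val <- random_patch_set(4, B, seed = 7)
  spec <- tiny_ma_spec(epochs = 3L)
  m1 <- train_model(build_model(spec, B, seed = 5), ps, val_patches = val,
                    seed = 11)
  m2 <- train_model(build_model(spec, B, seed = 5), ps, val_patches = val,
                    seed = 11)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$history$val_r2[3], m2$history$val_r2[3], tolerance = 1e-6)
})

test_that("divergent learning rates raise a named training error", {
  B <- 4
  ps <- random_patch_set(8, B, seed = 8)
  spec <- tiny_ma_spec(epochs = 60L)
  spec$learning_rate <- 1e6
  spec$optimizer <- "SGD"
  expect_error(train_model(build_model(spec, B, seed = 1), ps, seed = 1),
               "diverged|learning rate")
})

test_that("predict_sample averages per-patch predictions", {
  B <- 4
  ps <- random_patch_set(6, B, label = 11, seed = 9)
  m <- train_model(build_model(tiny_ma_spec(epochs = 2L), B, seed = 1),
                   ps, seed = 1, label_scaler = c(7, 18))
  per_patch <- predict(m, ps)
  expect_equal(predict_sample(m, ps), mean(per_patch), tolerance = 1e-12)

  one <- structure(ps[1], class = "patch_set")
  expect_equal(predict_sample(m, one), predict(m, one)[1])
  dup <- do.call(c, rep(list(one), 10))
  expect_equal(predict_sample(m, dup), predict_sample(m, one),
               tolerance = 1e-12)
  expect_error(predict_sample(m, structure(list(), class = "patch_set")),
               "at least one")
})

test_that("every optimizer and activation runs a training step", {
  B <- 4
  ps <- random_patch_set(6, B, seed = 10)
  for (opt in c("SGD", "Adam", "AdaBound", "RMSProp")) {
    for (act in c("ReLU", "Sigmoid", "ELU", "SoftMax")) {
      spec <- tiny_ma_spec(epochs = 1L, act = act)
      spec$optimizer <- opt
      spec$learning_rate <- 1e-3
      m <- train_model(build_model(spec, B, seed = 1), ps, seed = 1)
      expect_true(is.finite(m$history$loss[1]))
    }
  }
})

test_that("broom methods expose history and summary", {
  B <- 4
  ps <- random_patch_set(8, B, seed = 12)
  m <- train_model(build_model(tiny_ma_spec(epochs = 2L), B, seed = 1),
                   ps, seed = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 2)
  gl <- glance(m)
  expect_equal(gl$epochs, 2L)
  expect_equal(gl$kind, "ma_cnn")
  expect_identical(gl$n_parameters, count_trainable_parameters(m))
  expect_s3_class(autoplot(m), "ggplot")
})
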