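# Bayesian hyperparameter optimisation: encoding, GP surrogate, PI, loop

test_that("encode/decode round-trips and hits range endpoints", {
  space <- ca_search_space()
  cfg <- list(filters1 = 32L, filters2 = 64L, filters3 = 128L,
              fc1 = 83L, fc2 = 51L, learning_rate = 1e-4,
              batch_size = 32L, activation = "ReLU", optimizer = "AdaBound")
  enc <- encode_config(cfg, space)
  expect_true(all(enc >= 0 & enc <= 1))
  # learning rate at the lower bound encodes to exactly 0
  lr_pos <- 6L # after 5 scalar dims
  expect_equal(enc[lr_pos], 0)
  expect_identical(decode_config(enc, space)[names(cfg)], cfg)

  # one-hot block of the 4 activations sums to 1
  act_block <- enc[8:11]
  expect_equal(sum(act_block), 1)

  set.seed(1)
  for (i in 1:100) {
    x <- runif(hyperbrix:::encoded_length(space))
    cfg_i <- decode_config(x, space)
    expect_identical(decode_config(encode_config(cfg_i, space), space),
                     cfg_i)
  }
  expect_error(encode_config(modifyList(cfg, list(batch_size = 500L)), space),
               "outside")
  expect_error(encode_config(modifyList(cfg, list(activation = "tanh")),
                             space), "not among")
})

test_that("GP posterior interpolates noise-free observations", {
  set.seed(2)
  x <- matrix(runif(14), ncol = 2)
  y <- sin(3 * x[, 1]) + x[, 2]^2
  gp <- fit_gp(x, y)
  pred <- gp$predict(x)
  expect_equal(pred$mu, y, tolerance = 1e-5)
  expect_true(all(pred$sd < 1e-2))
  # posterior mean at the observations is within 1e-6 after normalising by
  # the objective scale
  expect_lt(max(abs(pred$mu - y)) / diff(range(y)), 1e-6)
})

test_that("PI lies in [0, 1] and vanishes at evaluated points", {
  set.seed(3)
  x <- matrix(runif(10), ncol = 1)
  y <- as.numeric(-(x - 0.3)^2)
  gp <- fit_gp(x, y)
  grid <- matrix(seq(0, 1, length.out = 101), ncol = 1)
  pred <- gp$predict(grid)
  pi_vals <- prob_improvement(pred$mu, pred$sd, max(y), xi = 0.01)
  expect_true(all(pi_vals >= 0 & pi_vals <= 1))
  # at an already-evaluated point the posterior is certain and PI ~ 0
  at_x <- gp$predict(x)
  expect_true(all(prob_improvement(at_x$mu, at_x$sd, max(y), 0.01) < 1e-6))
})

test_that("suggest_next returns in-domain points from an empty history", {
  space <- ma_search_space()
  cfg <- suggest_next(NULL, space, seed = 4)
  expect_true(cfg$fc1 >= 64 && cfg$fc1 <= 256)
  expect_true(cfg$learning_rate >= 1e-5 && cfg$learning_rate <= 1e-1)
  expect_true(cfg$activation %in% c("ReLU", "SoftMax", "Sigmoid", "ELU"))
  # deterministic under the seed
  expect_identical(cfg, suggest_next(NULL, space, seed = 4))
})

test_that("degenerate histories fall back to random sampling with a notice", {
  space <- ma_search_space()
  trace <- tibble::tibble(
    iteration = 1:6,
    config = lapply(1:6, function(i) suggest_next(NULL, space, seed = i)),
    objective = rep(0.5, 6),
    best_so_far = rep(0.5, 6)
  )
  expect_message(cfg <- suggest_next(trace, space, seed = 1), "degenerate")
  expect_true(cfg$batch_size >= 4 && cfg$batch_size <= 128)
})

test_that("the BOA locates a 1-D optimum and beats random search", {
  space <- search_space(dim_log("x", 1e-2, 1)) # log grid still brackets 0.3
  toy <- function(cfg) -(cfg$x - 0.3)^2
  wins <- 0
  errs <- numeric(0)
  for (seed in 1:5) {
    res <- run_boa(space, toy, n_iter = 15, seed = seed)
    errs <- c(errs, abs(res$best_config$x - 0.3))
    rand_best <- withr::with_seed(seed + 100, {
      max(vapply(1:15, function(i)
        toy(decode_config(runif(1), space)), numeric(1)))
    })
    if (res$best_objective >= rand_best) wins <- wins + 1
    expect_true(all(diff(res$trace$best_so_far) >= -1e-15))
  }
  expect_lt(median(errs), 0.05)
  expect_gte(wins, 3)
})

test_that("single-iteration runs and failing objectives are handled", {
  space <- search_space(dim_int("k", 1, 10))
  res <- run_boa(space, function(cfg) cfg$k, n_iter = 1, seed = 1)
  expect_equal(nrow(res$trace), 1)
  expect_identical(res$best_config, res$trace$config[[1]])

  flaky <- function(cfg) if (cfg$k %% 2 == 0) stop("boom") else cfg$k
  warns <- testthat::capture_warnings(
    res2 <- run_boa(space, flaky, n_iter = 6, seed = 2)
  )
  expect_true(any(grepl("objective failed", warns)))
  expect_true(any(res2$trace$objective == -Inf))
  expect_true(is.finite(res2$best_objective))
  expect_equal(res2$best_objective %% 2, 1)
})

test_that("reproducibility: identical seeds give identical traces", {
  space <- search_space(dim_log("x", 1e-2, 1), dim_int("k", 1, 5))
  f <- function(cfg) -(cfg$x - 0.2)^2 - 0.01 * cfg$k
  r1 <- run_boa(space, f, n_iter = 10, seed = 9)
  r2 <- run_boa(space, f, n_iter = 10, seed = 9)
  expect_identical(r1$trace$objective, r2$trace$objective)
  expect_identical(r1$best_config, r2$best_config)
})

test_that("tie-breaking prefers the most stable, earliest iteration", {
  space <- search_space(dim_int("k", 1, 10))
  vals <- c(0.5, 0.9, 0.9, 0.7)
  folds <- list(c(0.4, 0.6), c(0.7, 1.1), c(0.88, 0.92), c(0.7, 0.7))
  i <- 0
  obj <- function(cfg) {
    i <<- i + 1
    structure(vals[i], fold_r2 = folds[[i]])
  }
  res <- run_boa(space, obj, n_iter = 4, seed = 1, n_init = 4)
  # iterations 2 and 3 tie at 0.9; 3 has the lower fold variance
  expect_equal(res$best_iteration, 3)
})

test_that("cross-validation folds partition the calibration fruit", {
  ids <- paste0("f", 1:23)
  fold <- make_folds(ids, folds = 5, seed = 3)
  expect_length(fold, 23)
  expect_setequal(unique(fold), 1:5)
  expect_true(max(table(fold)) - min(table(fold)) <= 1)
  expect_error(make_folds(ids[1:3], folds = 5), "fewer")
})

test_that("cv_objective returns a mean of per-fold R-squared values", {
  p <- scene_params(n_rows = 36, n_cols = 36, n_bands = 8,
                    informative_bands = c(680, 880), seed = 1)
  ds <- generate_dataset(p, 14, seed = 3)
  spec <- model_spec("ca_cnn", spectral_branch = branch_config(c(3, 3, 3)),
                     fc_neurons = c(4, 3), learning_rate = 2e-3,
                     batch_size = 8L, optimizer = "Adam",
                     activation = "ReLU", epochs = 2L, reduction = 2L)
  val <- cv_objective(ds, spec, folds = 3, seed = 2, k_centers = 2)
  fr <- attr(val, "fold_r2")
  expect_length(fr, 3)
  expect_equal(as.numeric(val), mean(fr), tolerance = 1e-12)
  expect_true(all(fr <= 1))
})
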