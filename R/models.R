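#' Branch configuration
#'
#' Describes one convolutional branch: three conv layers (each followed by
#' batch normalisation, the activation, the branch's attention operator and
#' max pooling), with per-layer filter counts and kernel sizes.
#'
#' @param n_filters Integer vector of 3 filter counts.
#' @param kernel_sizes Integer vector of 3 odd kernel sizes.
#' @param pool_size,pool_stride Max-pooling window and stride.
#' @return An object of class `branch_config`.
#' @export
branch_config <- function(n_filters, kernel_sizes = c(3, 3, 3),
                          pool_size = 2L, pool_stride = 2L) {
  stopifnot(length(n_filters) == 3, length(kernel_sizes) == 3,
            all(n_filters >= 1), all(kernel_sizes %% 2 == 1))
  structure(
    list(n_filters = as.integer(n_filters),
         kernel_sizes = as.integer(kernel_sizes),
         pool_size = as.integer(pool_size),
         pool_stride = as.integer(pool_stride)),
    class = "branch_config"
  )
}

ACTIVATIONS <- c(ReLU = 0L, Sigmoid = 1L, ELU = 2L, SoftMax = 3L)
OPTIMIZERS <- c(SGD = 0L, Adam = 1L, AdaBound = 2L, RMSProp = 3L)

#' Model specification
#'
#' Describes one of the three network kinds: `"ca_cnn"` (spectral branch
#' with channel attention, consuming 3 x 3 patches), `"sa_cnn"` (spatial
#' branch with spatial attention, consuming 31 x 31 patches), or
#' `"ma_cnn"` (both branches, their global-average-pooled feature vectors
#' concatenated). The head is two fully connected layers on the (fused)
#' feature vector with a linear output neuron.
#'
#' @param kind One of "ca_cnn", "sa_cnn", "ma_cnn".
#' @param spectral_branch,spatial_branch [branch_config()]s (presence must
#'   match `kind`).
#' @param fc_neurons Integer vector of 2 fully-connected layer sizes.
#' @param learning_rate Positive learning rate.
#' @param batch_size Mini-batch size.
#' @param optimizer One of "SGD", "Adam", "AdaBound", "RMSProp".
#' @param activation One of "ReLU", "SoftMax", "Sigmoid", "ELU".
#' @param epochs Training epochs (default 30).
#' @param weight_decay L2 penalty coefficient added to every weight
#'   gradient (0 disables it).
#' @param attention `"on"` (learned attention), `"frozen"` (maps fixed at
#'   1, for degenerate-equivalence checks) or `"off"` (plain CNN).
#' @param reduction Channel-attention MLP bottleneck ratio.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("ma_cnn", "ca_cnn", "sa_cnn"),
                       spectral_branch = NULL, spatial_branch = NULL,
                       fc_neurons = c(64, 32), learning_rate = 1e-3,
                       batch_size = 32L,
                       optimizer = c("Adam", "SGD", "AdaBound", "RMSProp"),
                       activation = c("ReLU", "SoftMax", "Sigmoid", "ELU"),
                       epochs = 30L,
                       attention = c("on", "frozen", "off"),
                       reduction = 8L, weight_decay = 0) {
  kind <- match.arg(kind)
  optimizer <- match.arg(optimizer)
  activation <- match.arg(activation)
  attention <- match.arg(attention)
  needs_spectral <- kind %in% c("ca_cnn", "ma_cnn")
  needs_spatial <- kind %in% c("sa_cnn", "ma_cnn")
  if (needs_spectral && is.null(spectral_branch)) {
    stop(kind, " requires a spectral branch", call. = FALSE)
  }
  if (needs_spatial && is.null(spatial_branch)) {
    stop(kind, " requires a spatial branch", call. = FALSE)
  }
  if (!needs_spectral) spectral_branch <- NULL
  if (!needs_spatial) spatial_branch <- NULL
  stopifnot(length(fc_neurons) == 2, learning_rate > 0, batch_size >= 1)
  structure(
    list(kind = kind, spectral_branch = spectral_branch,
         spatial_branch = spatial_branch,
         fc_neurons = as.integer(fc_neurons),
         learning_rate = learning_rate, batch_size = as.integer(batch_size),
         optimizer = optimizer, activation = activation,
         epochs = as.integer(epochs), attention = attention,
         reduction = as.integer(reduction), weight_decay = weight_decay),
    class = "model_spec"
  )
}

#' Reference model specifications
#'
#' `ca_cnn_spec()`, `sa_cnn_spec()` and `ma_cnn_spec()` reproduce the
#' tuned configurations of the three networks (spectral-branch filters
#' 32/64/128 with kernel 3 and pool 2/2; spatial-branch filters 64/128/56
#' with kernels 3/5/7 and pool 3 stride 2; the fused model reuses both
#' tuned branches with its own head). `desk_spec()` is a down-scaled
#' configuration of the same architecture for desk-scale synthetic
#' experiments: fewer filters and epochs, chosen so a full
#' train/evaluate cycle runs in seconds-to-minutes on one CPU while
#' exercising every code path.
#'
#' @param kind For `desk_spec()`: which network kind to scale down.
#' @param epochs Training epochs.
#' @name reference_specs
NULL

#' @rdname reference_specs
#' @export
ca_cnn_spec <- function(epochs = 30L) {
  model_spec("ca_cnn",
             spectral_branch = branch_config(c(32, 64, 128)),
             fc_neurons = c(83, 51), learning_rate = 9e-4, batch_size = 32L,
             optimizer = "AdaBound", activation = "ReLU", epochs = epochs)
}

#' @rdname reference_specs
#' @export
sa_cnn_spec <- function(epochs = 30L) {
  model_spec("sa_cnn",
             spatial_branch = branch_config(c(64, 128, 56),
                                            kernel_sizes = c(3, 5, 7),
                                            pool_size = 3L, pool_stride = 2L),
             fc_neurons = c(125, 93), learning_rate = 7e-4, batch_size = 53L,
             optimizer = "RMSProp", activation = "ELU", epochs = epochs)
}

#' @rdname reference_specs
#' @export
ma_cnn_spec <- function(epochs = 30L) {
  model_spec("ma_cnn",
             spectral_branch = branch_config(c(32, 64, 128)),
             spatial_branch = branch_config(c(64, 128, 56),
                                            kernel_sizes = c(3, 5, 7),
                                            pool_size = 3L, pool_stride = 2L),
             fc_neurons = c(86, 86), learning_rate = 1e-4, batch_size = 69L,
             optimizer = "AdaBound", activation = "ReLU", epochs = epochs)
}

#' @rdname reference_specs
#' @export
desk_spec <- function(kind = c("ma_cnn", "ca_cnn", "sa_cnn"), epochs = 10L,
                      attention = "on") {
  kind <- match.arg(kind)
  model_spec(
    kind,
    spectral_branch = if (kind != "sa_cnn") branch_config(c(8, 16, 24)),
    spatial_branch = if (kind != "ca_cnn")
      branch_config(c(6, 12, 16), kernel_sizes = c(3, 5, 7),
                    pool_size = 3L, pool_stride = 2L),
    fc_neurons = c(32, 16), learning_rate = 3e-3, batch_size = 64L,
    optimizer = "Adam", activation = "ReLU", epochs = as.integer(epochs),
    attention = attention, reduction = 4L, weight_decay = 1e-4
  )
}

# internal: translate a model_spec into the compiled core's config list
net_config <- function(spec, n_bands) {
  sb <- spec$spectral_branch
  pb <- spec$spatial_branch
  list(
    has_spectral = !is.null(sb),
    has_spatial = !is.null(pb),
    spec_filters = if (is.null(sb)) c(1L, 1L, 1L) else sb$n_filters,
    spat_filters = if (is.null(pb)) c(1L, 1L, 1L) else pb$n_filters,
    spec_kernels = if (is.null(sb)) c(3L, 3L, 3L) else sb$kernel_sizes,
    spat_kernels = if (is.null(pb)) c(3L, 5L, 7L) else pb$kernel_sizes,
    spec_pool_size = if (is.null(sb)) 2L else sb$pool_size,
    spec_pool_stride = if (is.null(sb)) 2L else sb$pool_stride,
    spat_pool_size = if (is.null(pb)) 3L else pb$pool_size,
    spat_pool_stride = if (is.null(pb)) 2L else pb$pool_stride,
    fc = spec$fc_neurons,
    activation = ACTIVATIONS[[spec$activation]],
    attention = c(off = 0L, frozen = 1L, on = 2L)[[spec$attention]],
    bands = as.integer(n_bands)
  )
}

he_init <- function(n, fan_in) stats::rnorm(n, 0, sqrt(2 / fan_in))

init_branch_params <- function(prefix, filters, kernels, n_bands,
                               attention_on, reduction, spatial) {
  p <- list()
  cin <- n_bands
  for (l in 1:3) {
    k <- kernels[l]; cout <- filters[l]
    p[[paste0(prefix, "_conv", l, "_w")]] <-
      array(he_init(k * k * cin * cout, k * k * cin), c(k, k, cin, cout))
    p[[paste0(prefix, "_conv", l, "_b")]] <- numeric(cout)
    p[[paste0(prefix, "_bn", l, "_gamma")]] <- rep(1, cout)
    p[[paste0(prefix, "_bn", l, "_beta")]] <- numeric(cout)
    p[[paste0(prefix, "_bn", l, "_mean")]] <- numeric(cout)
    p[[paste0(prefix, "_bn", l, "_var")]] <- rep(1, cout)
    if (attention_on) {
      ap <- paste0(prefix, "_att", l)
      if (!spatial) {
        h <- max(1L, cout %/% reduction)
        p[[paste0(ap, "_mlp_w1")]] <- matrix(he_init(h * cout, cout), h, cout)
        p[[paste0(ap, "_mlp_b1")]] <- numeric(h)
        p[[paste0(ap, "_mlp_w2")]] <- matrix(he_init(cout * h, h), cout, h)
        p[[paste0(ap, "_mlp_b2")]] <- numeric(cout)
        p[[paste0(ap, "_lambda")]] <- rep(1, if (l == 1) 2 else 3)
        if (l > 1) {
          cprev <- filters[l - 1]
          p[[paste0(ap, "_w0_w")]] <-
            matrix(he_init(cout * cprev, cprev), cout, cprev)
          p[[paste0(ap, "_w0_b")]] <- numeric(cout)
          p[[paste0(ap, "_w0bn_gamma")]] <- rep(1, cout)
          p[[paste0(ap, "_w0bn_beta")]] <- numeric(cout)
          p[[paste0(ap, "_w0bn_mean")]] <- numeric(cout)
          p[[paste0(ap, "_w0bn_var")]] <- rep(1, cout)
        }
      } else {
        n_in <- if (l == 1) 2L else 3L
        p[[paste0(ap, "_ws_w")]] <-
          array(he_init(49 * n_in, 49 * n_in), c(7, 7, n_in, 1))
        p[[paste0(ap, "_ws_b")]] <- 0
        if (l > 1) {
          p[[paste0(ap, "_wl_w")]] <- array(he_init(9, 9), c(3, 3, 1, 1))
          p[[paste0(ap, "_wl_b")]] <- 0
        }
      }
    }
    cin <- cout
  }
  p
}

#' Build an untrained model
#'
#' Initialises all network parameters (He-normal weights, unit batch-norm
#' gamma, attention fusion scalars at 1) for the given specification and
#' number of spectral bands. The trainable parameter count is available
#' immediately via [count_trainable_parameters()].
#'
#' @param spec A [model_spec()].
#' @param n_bands Number of spectral bands of the input patches.
#' @param seed Integer seed for weight initialisation.
#' @param spectral_size,spatial_size Input patch sides (defaults 3 and 31).
#' @return An object of class `ssc_model`.
#' @export
build_model <- function(spec, n_bands, seed = 1L,
                        spectral_size = 3L, spatial_size = 31L) {
  stopifnot(inherits(spec, "model_spec"))
  att_on <- spec$attention == "on"
  if (!is.null(spec$spatial_branch)) {
    k_max <- max(spec$spatial_branch$kernel_sizes)
    if (spatial_size < k_max) {
      stop("spatial patch side ", spatial_size,
           " smaller than the largest kernel (", k_max, ")", call. = FALSE)
    }
  }
  params <- withr::with_seed(seed, {
    p <- list()
    if (!is.null(spec$spectral_branch)) {
      p <- c(p, init_branch_params("c", spec$spectral_branch$n_filters,
                                   spec$spectral_branch$kernel_sizes,
                                   n_bands, att_on, spec$reduction,
                                   spatial = FALSE))
    }
    if (!is.null(spec$spatial_branch)) {
      p <- c(p, init_branch_params("s", spec$spatial_branch$n_filters,
                                   spec$spatial_branch$kernel_sizes,
                                   n_bands, att_on, spec$reduction,
                                   spatial = TRUE))
    }
    n_in <- sum(c(spec$spectral_branch$n_filters[3],
                  spec$spatial_branch$n_filters[3]))
    n1 <- spec$fc_neurons[1]; n2 <- spec$fc_neurons[2]
    p$fc1_w <- matrix(he_init(n1 * n_in, n_in), n1, n_in)
    p$fc1_b <- numeric(n1)
    p$fc2_w <- matrix(he_init(n2 * n1, n1), n2, n1)
    p$fc2_b <- numeric(n2)
    p$out_w <- matrix(he_init(n2, n2), 1, n2)
    p$out_b <- 0
    p
  })
  structure(
    list(spec = spec, params = params, n_bands = as.integer(n_bands),
         spectral_size = as.integer(spectral_size),
         spatial_size = as.integer(spatial_size),
         label_scaler = NULL, history = NULL),
    class = "ssc_model"
  )
}

#' @export
print.ssc_model <- function(x, ...) {
  cat("<ssc_model> ", x$spec$kind, ", ", x$n_bands, " bands, ",
      count_trainable_parameters(x), " trainable parameters",
      if (is.null(x$history)) " (untrained)" else " (trained)", "\n",
      sep = "")
  invisible(x)
}

#' Count trainable parameters
#'
#' Sums the element counts of every learnable tensor: convolution and
#' fully-connected weights and biases, batch-norm affine parameters, the
#' attention MLPs and convolutions, and the lambda fusion scalars.
#' Batch-norm running statistics are buffers, not parameters, and are
#' excluded.
#'
#' @param model An `ssc_model`.
#' @return Integer parameter count.
#' @export
count_trainable_parameters <- function(model) {
  stopifnot(inherits(model, "ssc_model"))
  nm <- names(model$params)
  buffers <- grepl("_mean$|_var$", nm)
  sum(vapply(model$params[!buffers], length, integer(1)))
}

# stack a patch_set and check sizes against the model
prepare_arrays <- function(model, patches) {
  stacked <- stack_patch_pairs(patches)
  if (dim(stacked$spectral)[3] != model$n_bands) {
    stop("patches have ", dim(stacked$spectral)[3], " bands, model expects ",
         model$n_bands, call. = FALSE)
  }
  stacked
}

#' Train a model on patch pairs
#'
#' Minimises mean squared error on min-max-scaled labels with the
#' specification's optimizer. Labels are scaled to \[0, 1\] using the
#' training-set range (stored in the model as `label_scaler` and inverted
#' at prediction time). Training is deterministic given the seed.
#'
#' @param model An `ssc_model` from [build_model()].
#' @param patches A `patch_set` with per-pair labels in degrees Brix.
#' @param val_patches Optional held-out `patch_set`; if given, validation
#'   R-squared is recorded per epoch.
#' @param seed Integer seed for mini-batch shuffling.
#' @param label_scaler Optional `c(min, max)` to reuse a previously fitted
#'   scaling (e.g. the calibration-set range when fine-tuning).
#' @return The trained `ssc_model`, with a `history` tibble (columns
#'   `epoch`, `loss`, and `val_r2` when validation patches were given).
#' @export
train_model <- function(model, patches, val_patches = NULL, seed = 1L,
                        label_scaler = NULL) {
  stopifnot(inherits(model, "ssc_model"), inherits(patches, "patch_set"))
  if (length(patches) == 0) stop("empty training set", call. = FALSE)
  tr <- prepare_arrays(model, patches)
  if (anyNA(tr$labels)) stop("training patches must carry labels", call. = FALSE)
  if (is.null(label_scaler)) {
    label_scaler <- range(tr$labels)
    if (diff(label_scaler) == 0) {
      label_scaler <- label_scaler + c(-0.5, 0.5)
    }
  }
  scale_y <- function(y) (y - label_scaler[1]) / diff(label_scaler)
  cfg <- net_config(model$spec, model$n_bands)

  has_val <- !is.null(val_patches) && length(val_patches) > 0
  if (has_val) {
    va <- prepare_arrays(model, val_patches)
    xs_val <- va$spectral; xp_val <- va$spatial
    y_val <- scale_y(va$labels)
  } else {
    xs_val <- numeric(0); xp_val <- numeric(0); y_val <- numeric(0)
  }

  wd <- model$spec$weight_decay
  if (is.null(wd)) wd <- 0
  fit <- cpp_train(model$params, cfg, tr$spectral, tr$spatial,
                   scale_y(tr$labels), model$spec$epochs,
                   model$spec$batch_size, model$spec$learning_rate,
                   OPTIMIZERS[[model$spec$optimizer]], wd, as.integer(seed),
                   xs_val, xp_val, y_val)
  model$params <- fit$params
  model$label_scaler <- label_scaler
  model$history <- tibble::tibble(
    epoch = seq_along(fit$loss),
    loss = fit$loss,
    val_r2 = if (has_val) fit$val_r2 else NA_real_
  )
  model
}

#' Per-patch predictions in degrees Brix
#'
#' @param object A trained `ssc_model`.
#' @param patches A `patch_set`.
#' @param ... Unused.
#' @return Numeric vector of per-patch SSC predictions, degrees Brix.
#' @export
predict.ssc_model <- function(object, patches, ...) {
  stopifnot(inherits(patches, "patch_set"))
  if (is.null(object$label_scaler)) {
    stop("model has not been trained (no label scaler)", call. = FALSE)
  }
  arr <- prepare_arrays(object, patches)
  cfg <- net_config(object$spec, object$n_bands)
  yhat <- cpp_predict(object$params, cfg, arr$spectral, arr$spatial)
  object$label_scaler[1] + yhat * diff(object$label_scaler)
}

#' Aggregate one fruit's patch predictions
#'
#' Labels are per fruit but predictions are per patch pair; the fruit's
#' SSC estimate is the mean of its per-patch predictions, inverse-scaled
#' to degrees Brix.
#'
#' @param model A trained `ssc_model`.
#' @param patches A `patch_set` whose pairs all come from one fruit.
#' @return A single SSC prediction in degrees Brix.
#' @export
predict_sample <- function(model, patches) {
  if (!inherits(patches, "patch_set") || length(patches) == 0) {
    stop("need at least one patch pair", call. = FALSE)
  }
  ids <- unique(vapply(patches, function(p) p$sample_id, character(1)))
  if (length(ids) > 1) {
    stop("patches come from ", length(ids),
         " different fruit; use predict_dataset()", call. = FALSE)
  }
  mean(predict(model, patches))
}

#' Per-fruit predictions for a mixed patch set
#'
#' @param model A trained `ssc_model`.
#' @param patches A `patch_set` possibly spanning several fruit.
#' @return A tibble with columns `sample_id`, `ssc_pred` (degrees Brix)
#'   and `n_patches`.
#' @export
predict_dataset <- function(model, patches) {
  stopifnot(inherits(patches, "patch_set"))
  yhat <- predict(model, patches)
  ids <- vapply(patches, function(p) p$sample_id, character(1))
  tibble::tibble(sample_id = ids, yhat = yhat) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(ssc_pred = mean(.data$yhat),
                     n_patches = dplyr::n(), .groups = "drop")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ssc_model <- function(x, ...) {
  if (is.null(x$history)) {
    stop("model has no training history yet", call. = FALSE)
  }
  x$history
}

#' @export
glance.ssc_model <- function(x, ...) {
  tibble::tibble(
    kind = x$spec$kind,
    n_parameters = count_trainable_parameters(x),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)],
    final_val_r2 = if (is.null(x$history)) NA_real_ else
      x$history$val_r2[nrow(x$history)]
  )
}

#' Plot training history
#'
#' @param object A trained `ssc_model`.
#' @param ... Unused.
#' @return A ggplot of loss (and validation R-squared, if recorded) by
#'   epoch.
#' @export
autoplot.ssc_model <- function(object, ...) {
  h <- tidy(object)
  df <- tidyr::pivot_longer(h, -"epoch", names_to = "metric",
                            values_to = "value")
  df <- df[!is.na(df$value), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
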