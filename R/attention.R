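#' Attention operators with cross-layer propagation
#'
#' These functions are the reference implementation of the two attention
#' operators at the heart of the dual-branch network:
#'
#' * **Channel attention** squeezes a feature tensor over its spatial
#'   dimensions (global average and max pooling), passes both pooled
#'   vectors through a shared two-layer perceptron, fuses them with the
#'   previous layer's attention weights through a learnable linear map
#'   `W0` (with batch normalisation and ReLU), weighs the three terms by
#'   learnable scalars `lambda1..3` (initialised at 1), and squashes with
#'   a sigmoid: `M_c = sigma(l1 MLP(avg) + l2 MLP(max) + l3 MLP(W0(M_prev)))`.
#' * **Spatial attention** squeezes over the channel dimension (per-pixel
#'   mean and max maps), transfers the previous layer's attention map
#'   through a convolution `W_l`, concatenates the three maps and fuses
#'   them with a convolution `W_s` followed by a sigmoid:
#'   `M_s = sigma(W_s[avg, max, W_l(M_prev)])`.
#'
#' At the first layer no previous attention exists and the cross-layer
#' term is dropped. Feature tensors are plain `H x W x C` arrays. These R
#' implementations favour clarity over speed; the training core uses a
#' compiled path that is tested to agree with them.
#'
#' @name attention
NULL

#' Global pooling along the spatial dimensions
#'
#' @param f `H x W x C` feature array.
#' @return List with `avg` and `max`, numeric vectors of length C holding
#'   the per-channel spatial mean and maximum.
#' @rdname attention
#' @export
channel_pool <- function(f) {
  check_feature(f)
  list(avg = apply(f, 3, mean), max = apply(f, 3, max))
}

#' Global pooling along the channel dimension
#'
#' @return For `spatial_pool()`: list with `avg` and `max`, `H x W`
#'   matrices holding the per-pixel channel mean and maximum.
#' @rdname attention
#' @export
spatial_pool <- function(f) {
  check_feature(f)
  list(avg = apply(f, c(1, 2), mean), max = apply(f, c(1, 2), max))
}

check_feature <- function(f) {
  if (length(dim(f)) != 3 || any(dim(f) < 1)) {
    stop("feature tensor must be a non-empty H x W x C array", call. = FALSE)
  }
  invisible(TRUE)
}

#' Channel-attention state
#'
#' Parameter container for one channel-attention block: the shared
#' two-layer perceptron (`C -> max(1, C/reduction) -> C`, ReLU inside),
#' the fusion scalars `lambda` (initialised at 1), and, from the second
#' layer on, the `W0` linear map from the previous layer's `C_prev`
#' weights with its batch-normalisation parameters (applied here with the
#' stored running statistics).
#'
#' @param n_channels Number of channels C of the feature tensor.
#' @param n_prev Channels of the previous layer's attention weights, or
#'   `NULL` for the first layer (cross-layer pathway disabled).
#' @param reduction Bottleneck reduction ratio r of the shared MLP.
#' @param init Either "zeros" or a function `function(n)` returning `n`
#'   random weights (biases always start at zero).
#' @return An object of class `channel_attention_state`.
#' @export
channel_attention_state <- function(n_channels, n_prev = NULL, reduction = 8,
                                    init = "zeros") {
  h <- max(1L, as.integer(floor(n_channels / reduction)))
  draw <- make_init(init)
  st <- list(
    mlp = list(
      w1 = matrix(draw(h * n_channels), h, n_channels),
      b1 = numeric(h),
      w2 = matrix(draw(n_channels * h), n_channels, h),
      b2 = numeric(n_channels)
    ),
    lambda = if (is.null(n_prev)) c(1, 1) else c(1, 1, 1),
    w0 = NULL
  )
  if (!is.null(n_prev)) {
    st$w0 <- list(
      w = matrix(draw(n_channels * n_prev), n_channels, n_prev),
      b = numeric(n_channels),
      gamma = rep(1, n_channels), beta = numeric(n_channels),
      mean = numeric(n_channels), var = rep(1, n_channels)
    )
  }
  structure(st, class = "channel_attention_state")
}

make_init <- function(init) {
  if (is.function(init)) return(init)
  if (identical(init, "zeros")) return(function(n) numeric(n))
  stop("init must be 'zeros' or a function", call. = FALSE)
}

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

mlp_forward <- function(mlp, v) {
  drop(mlp$w2 %*% relu(mlp$w1 %*% v + mlp$b1) + mlp$b2)
}

#' Channel-attention weights for one layer
#'
#' @param f `H x W x C` feature array of the current layer.
#' @param shallow_weights Previous layer's attention weight vector
#'   (length `n_prev`), or `NULL` at the first layer.
#' @param state A [channel_attention_state()].
#' @return Numeric vector of length C, strictly inside (0, 1).
#' @rdname attention
#' @export
channel_attention <- function(f, shallow_weights, state) {
  check_feature(f)
  stopifnot(inherits(state, "channel_attention_state"))
  n_c <- dim(f)[3]
  if (ncol(state$mlp$w1) != n_c) {
    stop("state sized for ", ncol(state$mlp$w1), " channels, feature has ",
         n_c, call. = FALSE)
  }
  pooled <- channel_pool(f)
  z <- state$lambda[1] * mlp_forward(state$mlp, pooled$avg) +
    state$lambda[2] * mlp_forward(state$mlp, pooled$max)
  if (!is.null(shallow_weights)) {
    if (is.null(state$w0)) {
      stop("state has no W0 pathway but shallow weights were supplied",
           call. = FALSE)
    }
    if (length(shallow_weights) != ncol(state$w0$w)) {
      stop("shallow weights length ", length(shallow_weights),
           " incompatible with W0 input ", ncol(state$w0$w), call. = FALSE)
    }
    v <- drop(state$w0$w %*% shallow_weights + state$w0$b)
    v <- state$w0$gamma * (v - state$w0$mean) / sqrt(state$w0$var + 1e-5) +
      state$w0$beta
    z <- z + state$lambda[3] * mlp_forward(state$mlp, relu(v))
  }
  sigmoid(z)
}

#' Rescale channels by attention weights
#'
#' @param weights Length-C attention weight vector.
#' @return For the `apply_*` functions: the rescaled `H x W x C` array.
#' @rdname attention
#' @export
apply_channel_attention <- function(f, weights) {
  check_feature(f)
  if (length(weights) != dim(f)[3]) {
    stop("weights length ", length(weights), " != channels ", dim(f)[3],
         call. = FALSE)
  }
  f * rep(weights, each = dim(f)[1] * dim(f)[2])
}

#' Spatial-attention state
#'
#' Parameter container for one spatial-attention block: the fusion
#' convolution `W_s` (`ws_kernel x ws_kernel`, over 2 concatenated maps at
#' the first layer or 3 afterwards) and, from the second layer on, the
#' cross-layer transfer convolution `W_l` (`wl_kernel x wl_kernel`, 1
#' channel to 1).
#'
#' @param first_layer `TRUE` if no previous attention map exists.
#' @param ws_kernel,wl_kernel Odd kernel sizes (defaults 7 and 3).
#' @param init As in [channel_attention_state()].
#' @return An object of class `spatial_attention_state`.
#' @export
spatial_attention_state <- function(first_layer = FALSE, ws_kernel = 7,
                                    wl_kernel = 3, init = "zeros") {
  draw <- make_init(init)
  n_in <- if (first_layer) 2L else 3L
  st <- list(
    ws = list(w = array(draw(ws_kernel^2 * n_in),
                        c(ws_kernel, ws_kernel, n_in, 1)),
              b = 0),
    wl = NULL
  )
  if (!first_layer) {
    st$wl <- list(w = array(draw(wl_kernel^2), c(wl_kernel, wl_kernel, 1, 1)),
                  b = 0)
  }
  structure(st, class = "spatial_attention_state")
}

# Reference 2-D convolution (cross-correlation), stride 1, zero 'same'
# padding: x is H x W x Cin, w is k x k x Cin x Cout.
conv2d_ref <- function(x, w, b = numeric(dim(w)[4])) {
  k <- dim(w)[1]; half <- (k - 1) %/% 2
  h <- dim(x)[1]; wd <- dim(x)[2]
  cin <- dim(x)[3]; cout <- dim(w)[4]
  out <- array(0, c(h, wd, cout))
  for (oc in seq_len(cout)) {
    acc <- matrix(b[oc], h, wd)
    for (ic in seq_len(cin)) {
      for (dr in -half:half) {
        for (dc in -half:half) {
          wgt <- w[dr + half + 1, dc + half + 1, ic, oc]
          if (wgt == 0) next
          rs <- seq_len(h) + dr; cs <- seq_len(wd) + dc
          rok <- rs >= 1 & rs <= h; cok <- cs >= 1 & cs <= wd
          acc[rok, cok] <- acc[rok, cok] +
            wgt * x[rs[rok], cs[cok], ic]
        }
      }
    }
    out[, , oc] <- acc
  }
  out
}

#' Max-pool a 2-D attention map
#'
#' Used to bring the previous layer's spatial attention map down to the
#' current layer's resolution when pooling has shrunk the feature maps.
#'
#' @param map `H x W` matrix.
#' @param size,stride Pooling window and stride.
#' @return The pooled matrix.
#' @export
max_pool_map <- function(map, size = 3L, stride = 2L) {
  h_out <- (nrow(map) - size) %/% stride + 1L
  w_out <- (ncol(map) - size) %/% stride + 1L
  out <- matrix(0, h_out, w_out)
  for (i in seq_len(h_out)) {
    for (j in seq_len(w_out)) {
      out[i, j] <- max(map[(i - 1) * stride + seq_len(size),
                           (j - 1) * stride + seq_len(size)])
    }
  }
  out
}

#' Spatial-attention map for one layer
#'
#' @param shallow_map Previous layer's `H_prev x W_prev` attention map, or
#'   `NULL` at the first layer. If its resolution differs from `f`'s it is
#'   max-pooled (window 3, stride 2, the branch's own pooling) until it
#'   matches.
#' @return For `spatial_attention()`: `H x W` matrix strictly inside (0, 1).
#' @rdname attention
#' @export
spatial_attention <- function(f, shallow_map, state) {
  check_feature(f)
  stopifnot(inherits(state, "spatial_attention_state"))
  h <- dim(f)[1]; w <- dim(f)[2]
  pooled <- spatial_pool(f)
  if (is.null(shallow_map)) {
    if (dim(state$ws$w)[3] != 2) {
      stop("state expects a previous attention map but none was supplied",
           call. = FALSE)
    }
    stacked <- array(c(pooled$avg, pooled$max), c(h, w, 2))
  } else {
    if (is.null(state$wl)) {
      stop("state has no W_l pathway but a shallow map was supplied",
           call. = FALSE)
    }
    guard <- 0L
    while (!identical(dim(shallow_map), c(h, w)) && guard < 8L) {
      shallow_map <- max_pool_map(shallow_map)
      guard <- guard + 1L
    }
    if (!identical(dim(shallow_map), c(h, w))) {
      stop("cannot pool the shallow map to ", h, " x ", w, call. = FALSE)
    }
    transferred <- conv2d_ref(array(shallow_map, c(h, w, 1)),
                              state$wl$w, state$wl$b)[, , 1]
    stacked <- array(c(pooled$avg, pooled$max, transferred), c(h, w, 3))
  }
  sigmoid(conv2d_ref(stacked, state$ws$w, state$ws$b)[, , 1])
}

#' Rescale pixels by an attention map
#'
#' @param map `H x W` attention map matching `f`'s spatial dims.
#' @rdname attention
#' @export
apply_spatial_attention <- function(f, map) {
  check_feature(f)
  if (!identical(dim(map), dim(f)[1:2])) {
    stop("map dims ", paste(dim(map), collapse = "x"),
         " != feature spatial dims ", paste(dim(f)[1:2], collapse = "x"),
         call. = FALSE)
  }
  f * as.vector(map)
}
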