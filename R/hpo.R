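#' Hyperparameter search-space construction
#'
#' A search space is an ordered set of dimensions, each an integer range,
#' a log-uniform continuous range, or a categorical set. Configurations
#' are encoded to `[0, 1]` coordinates for the Gaussian-process surrogate:
#' integer ranges are scaled linearly, log-uniform ranges are scaled in
#' log10, and categoricals are one-hot blocks (treated as continuous
#' coordinates inside the surrogate, the standard relaxation).
#'
#' @param ... Dimensions built with [dim_int()], [dim_log()], [dim_cat()].
#' @return An object of class `search_space`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  stopifnot(length(dims) >= 1)
  nm <- vapply(dims, function(d) d$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate dimension names", call. = FALSE)
  names(dims) <- nm
  structure(dims, class = "search_space")
}

#' @rdname search_space
#' @param name Dimension name.
#' @param lo,hi Range bounds (inclusive).
#' @export
dim_int <- function(name, lo, hi) {
  stopifnot(lo < hi)
  list(name = name, type = "integer", lo = as.integer(lo), hi = as.integer(hi))
}

#' @rdname search_space
#' @export
dim_unif <- function(name, lo, hi) {
  stopifnot(lo < hi)
  list(name = name, type = "uniform", lo = lo, hi = hi)
}

#' @rdname search_space
#' @export
dim_log <- function(name, lo, hi) {
  stopifnot(lo > 0, lo < hi)
  list(name = name, type = "loguniform", lo = lo, hi = hi)
}

#' @rdname search_space
#' @param levels Character vector of category labels.
#' @export
dim_cat <- function(name, levels) {
  stopifnot(length(levels) >= 1)
  list(name = name, type = "categorical", levels = levels)
}

#' Search spaces of the three tuned networks
#'
#' The spectral-branch network searches its three conv filter counts over
#' (4, 64), (8, 128), (16, 256), two FC sizes over (32, 128), learning
#' rate log-uniform on (1e-4, 1e-1) and batch size (2, 128); the
#' spatial-branch network uses filter ranges (4, 64), (16, 256), (8, 128),
#' FC (64, 256), learning rate (1e-4, 1e-2); the fused network searches
#' only its head: FC (64, 256), learning rate (1e-5, 1e-1), batch
#' (4, 128). All three choose the activation among ReLU, SoftMax, Sigmoid
#' and ELU and the optimizer among SGD, Adam, AdaBound and RMSProp.
#'
#' @name model_search_spaces
NULL

#' @rdname model_search_spaces
#' @export
ca_search_space <- function() {
  search_space(
    dim_int("filters1", 4, 64), dim_int("filters2", 8, 128),
    dim_int("filters3", 16, 256),
    dim_int("fc1", 32, 128), dim_int("fc2", 32, 128),
    dim_log("learning_rate", 1e-4, 1e-1),
    dim_int("batch_size", 2, 128),
    dim_cat("activation", c("ReLU", "SoftMax", "Sigmoid", "ELU")),
    dim_cat("optimizer", c("SGD", "Adam", "AdaBound", "RMSProp"))
  )
}

#' @rdname model_search_spaces
#' @export
sa_search_space <- function() {
  search_space(
    dim_int("filters1", 4, 64), dim_int("filters2", 16, 256),
    dim_int("filters3", 8, 128),
    dim_int("fc1", 64, 256), dim_int("fc2", 64, 256),
    dim_log("learning_rate", 1e-4, 1e-2),
    dim_int("batch_size", 2, 128),
    dim_cat("activation", c("ReLU", "SoftMax", "Sigmoid", "ELU")),
    dim_cat("optimizer", c("SGD", "Adam", "AdaBound", "RMSProp"))
  )
}

#' @rdname model_search_spaces
#' @export
ma_search_space <- function() {
  search_space(
    dim_int("fc1", 64, 256), dim_int("fc2", 64, 256),
    dim_log("learning_rate", 1e-5, 1e-1),
    dim_int("batch_size", 4, 128),
    dim_cat("activation", c("ReLU", "SoftMax", "Sigmoid", "ELU")),
    dim_cat("optimizer", c("SGD", "Adam", "AdaBound", "RMSProp"))
  )
}

#' Encode a configuration to surrogate coordinates
#'
#' @param config Named list, one value per dimension.
#' @param space A [search_space()].
#' @return Numeric vector in `[0, 1]^k` (categoricals one-hot).
#' @export
encode_config <- function(config, space) {
  stopifnot(inherits(space, "search_space"))
  unlist(lapply(space, function(d) {
    v <- config[[d$name]]
    if (is.null(v)) stop("config misses dimension '", d$name, "'",
                         call. = FALSE)
    switch(d$type,
      integer = {
        if (v < d$lo || v > d$hi) {
          stop(d$name, " = ", v, " outside [", d$lo, ", ", d$hi, "]",
               call. = FALSE)
        }
        (v - d$lo) / (d$hi - d$lo)
      },
      uniform = {
        if (v < d$lo || v > d$hi) {
          stop(d$name, " = ", v, " outside [", d$lo, ", ", d$hi, "]",
               call. = FALSE)
        }
        (v - d$lo) / (d$hi - d$lo)
      },
      loguniform = {
        if (v < d$lo || v > d$hi) {
          stop(d$name, " = ", v, " outside [", d$lo, ", ", d$hi, "]",
               call. = FALSE)
        }
        (log10(v) - log10(d$lo)) / (log10(d$hi) - log10(d$lo))
      },
      categorical = {
        i <- match(v, d$levels)
        if (is.na(i)) {
          stop(d$name, " = '", v, "' not among {",
               paste(d$levels, collapse = ", "), "}", call. = FALSE)
        }
        as.numeric(seq_along(d$levels) == i)
      }
    )
  }), use.names = FALSE)
}

#' Decode surrogate coordinates to a configuration
#'
#' Inverse of [encode_config()]; integer dimensions round to the nearest
#' admissible value, categoricals take the largest one-hot coordinate.
#'
#' @param x Numeric vector of encoded coordinates.
#' @param space A [search_space()].
#' @return Named list, one value per dimension.
#' @export
decode_config <- function(x, space) {
  stopifnot(inherits(space, "search_space"))
  out <- list()
  i <- 1L
  for (d in space) {
    if (d$type == "categorical") {
      k <- length(d$levels)
      out[[d$name]] <- d$levels[which.max(x[i:(i + k - 1)])]
      i <- i + k
    } else if (d$type == "integer") {
      out[[d$name]] <- as.integer(round(d$lo + x[i] * (d$hi - d$lo)))
      i <- i + 1L
    } else if (d$type == "uniform") {
      out[[d$name]] <- d$lo + x[i] * (d$hi - d$lo)
      i <- i + 1L
    } else {
      l0 <- log10(d$lo); l1 <- log10(d$hi)
      out[[d$name]] <- 10^(l0 + x[i] * (l1 - l0))
      i <- i + 1L
    }
  }
  out
}

encoded_length <- function(space) {
  sum(vapply(space, function(d)
    if (d$type == "categorical") length(d$levels) else 1L, integer(1)))
}

# uniform random point in the encoded cube, snapped through decode/encode
# so integer and categorical dims sit on admissible values
random_encoded <- function(space, n) {
  k <- encoded_length(space)
  pts <- matrix(stats::runif(n * k), n, k)
  enc <- apply(pts, 1, function(p)
    encode_config(decode_config(p, space), space))
  if (is.matrix(enc)) t(enc) else matrix(enc, ncol = 1)
}

# Matern 5/2 correlation for scaled distance r = |x - x'| / lengthscale
matern52 <- function(r) (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)

#' Fit a Gaussian-process surrogate
#'
#' Zero-mean GP on standardised objectives with a Matern 5/2 kernel, unit
#' signal variance and jitter 1e-6; the isotropic lengthscale is chosen
#' from a small grid by marginal likelihood. Used as the probabilistic
#' surrogate of the Bayesian optimiser.
#'
#' @param x Matrix of encoded configurations (rows).
#' @param y Objective values.
#' @return An object of class `gp_fit` with a `$predict(xnew)` method
#'   returning `mu` and `sd` on the original objective scale.
#' @export
fit_gp <- function(x, y) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  mu_y <- mean(y)
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  ys <- (y - mu_y) / sd_y
  d <- as.matrix(stats::dist(x))
  best <- NULL
  for (ell in c(0.1, 0.2, 0.3, 0.5, 1.0)) {
    kmat <- matern52(d / ell) + diag(1e-6, nrow(x))
    ch <- tryCatch(chol(kmat), error = function(e) NULL)
    if (is.null(ch)) next
    alpha <- backsolve(ch, forwardsolve(t(ch), ys))
    ll <- -0.5 * sum(ys * alpha) - sum(log(diag(ch)))
    if (is.null(best) || ll > best$ll) {
      best <- list(ll = ll, ell = ell, chol = ch, alpha = alpha)
    }
  }
  if (is.null(best)) stop("GP fit failed (singular kernel)", call. = FALSE)
  structure(
    list(
      x = x, ell = best$ell, chol = best$chol, alpha = best$alpha,
      mu_y = mu_y, sd_y = sd_y,
      predict = function(xnew) {
        xnew <- matrix(xnew, ncol = ncol(x))
        kx <- matern52(cross_dist(xnew, x) / best$ell)
        mu <- drop(kx %*% best$alpha)
        v <- forwardsolve(t(best$chol), t(kx))
        var_ <- pmax(1 + 1e-6 - colSums(v^2), 0)
        list(mu = mu_y + sd_y * mu, sd = sd_y * sqrt(var_))
      }
    ),
    class = "gp_fit"
  )
}

cross_dist <- function(a, b) {
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  sqrt(pmax(outer(aa, bb, "+") - 2 * tcrossprod(a, b), 0))
}

#' Probability of improvement
#'
#' `PI(x) = Phi((mu(x) - f_best - xi) / sd(x))`, the acquisition function
#' of the Bayesian optimiser (maximisation convention). Where the
#' posterior is certain (`sd = 0`), PI is 1 if the mean beats the
#' incumbent by more than `xi`, else 0.
#'
#' @param mu,sd Posterior mean and SD at the candidate points.
#' @param f_best Incumbent best objective.
#' @param xi Exploration margin (default 0.01).
#' @return PI values in `[0, 1]`.
#' @export
prob_improvement <- function(mu, sd, f_best, xi = 0.01) {
  out <- ifelse(sd > 0,
                stats::pnorm((mu - f_best - xi) / sd),
                as.numeric(mu > f_best + xi))
  pmin(pmax(out, 0), 1)
}

#' Suggest the next configuration
#'
#' With fewer than `n_init` evaluated points, returns the next point of a
#' Latin-hypercube design (quasi-random space filling). Afterwards, fits
#' the GP surrogate to the encoded history and returns the candidate with
#' the highest probability of improvement over a pool of random candidate
#' configurations. With a degenerate history (all objectives identical)
#' the surrogate carries no signal and a random configuration is returned
#' with a notice.
#'
#' @param trace A `boa_trace` tibble (or `NULL`/empty before the first
#'   evaluation) with list-column `config` and column `objective`.
#' @param space A [search_space()].
#' @param seed Integer seed (drives both the LHS design and the pool).
#' @param n_init Number of initial design points.
#' @param pool_size Random candidate pool size per iteration.
#' @param xi PI exploration margin.
#' @return A configuration (named list).
#' @export
suggest_next <- function(trace, space, seed = 1L, n_init = 5L,
                         pool_size = 512L, xi = 0.01) {
  stopifnot(inherits(space, "search_space"))
  n_done <- if (is.null(trace)) 0L else nrow(trace)
  if (n_done < n_init) {
    design <- withr::with_seed(seed,
      lhs::randomLHS(n_init, encoded_length(space)))
    pt <- encode_config(decode_config(design[n_done + 1L, ], space), space)
    return(decode_config(pt, space))
  }
  enc <- vapply(trace$config, encode_config, space = space,
                numeric(encoded_length(space)))
  xmat <- if (is.matrix(enc)) t(enc) else matrix(enc, ncol = 1)
  y <- trace$objective
  finite <- is.finite(y)
  if (sum(finite) < 2 || stats::sd(y[finite]) == 0) {
    message("degenerate optimisation history; falling back to random ",
            "sampling")
    return(withr::with_seed(seed + n_done,
      decode_config(stats::runif(encoded_length(space)), space)))
  }
  gp <- fit_gp(xmat[finite, , drop = FALSE], y[finite])
  withr::with_seed(seed + n_done, {
    cand <- random_encoded(space, pool_size)
    pred <- gp$predict(cand)
    pi_vals <- prob_improvement(pred$mu, pred$sd, max(y[finite]), xi)
    decode_config(cand[which.max(pi_vals), ], space)
  })
}

#' Run the Bayesian optimisation loop
#'
#' Sequentially evaluates `n_iter` configurations chosen by
#' [suggest_next()]. A configuration whose objective evaluation raises an
#' error is recorded as failed with objective `-Inf` and optimisation
#' continues. The best configuration is the earliest iteration attaining
#' the maximum objective, preferring (on objective ties) the one with the
#' lowest variance of fold-level R-squared when the objective supplies it
#' (attribute `fold_r2`) — i.e. the most stable of equally good
#' configurations.
#'
#' @param space A [search_space()].
#' @param objective Function mapping a configuration (named list) to a
#'   scalar to maximise (conventionally mean five-fold validation
#'   R-squared). May attach a `fold_r2` attribute.
#' @param n_iter Number of iterations (default 30).
#' @param seed Integer seed.
#' @param n_init,pool_size,xi Passed to [suggest_next()].
#' @return An object of class `boa_result`: list with `trace` (a
#'   `boa_trace` tibble: iteration, config list-column, objective,
#'   best_so_far, duration, fold_r2 list-column) and `best_config`.
#' @export
run_boa <- function(space, objective, n_iter = 30L, seed = 1L,
                    n_init = 5L, pool_size = 512L, xi = 0.01) {
  stopifnot(is.function(objective), n_iter >= 1)
  trace <- NULL
  for (it in seq_len(n_iter)) {
    config <- suggest_next(trace, space, seed = seed, n_init = n_init,
                           pool_size = pool_size, xi = xi)
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(objective(config), error = function(e) {
      warning("objective failed at iteration ", it, ": ",
              conditionMessage(e), call. = FALSE)
      -Inf
    })
    dur <- proc.time()[["elapsed"]] - t0
    fold_r2 <- attr(val, "fold_r2")
    row <- tibble::tibble(
      iteration = it,
      config = list(config),
      objective = as.numeric(val),
      best_so_far = max(as.numeric(val),
                        if (is.null(trace)) -Inf else
                          trace$best_so_far[nrow(trace)]),
      duration = dur,
      fold_r2 = list(fold_r2)
    )
    trace <- if (is.null(trace)) row else dplyr::bind_rows(trace, row)
  }
  class(trace) <- c("boa_trace", class(trace))
  best_obj <- max(trace$objective)
  at_best <- which(trace$objective == best_obj)
  if (length(at_best) > 1) {
    stab <- vapply(trace$fold_r2[at_best], function(f) {
      if (is.null(f) || length(f) < 2) Inf else stats::var(f)
    }, numeric(1))
    if (any(is.finite(stab))) at_best <- at_best[order(stab)][1]
    else at_best <- at_best[1]
  }
  structure(
    list(trace = trace, best_config = trace$config[[at_best[1]]],
         best_iteration = at_best[1], best_objective = best_obj),
    class = "boa_result"
  )
}

#' @export
print.boa_result <- function(x, ...) {
  cat("<boa_result> ", nrow(x$trace), " iterations, best objective ",
      signif(x$best_objective, 4), " at iteration ", x$best_iteration,
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.boa_result <- function(x, ...) x$trace

#' @export
glance.boa_result <- function(x, ...) {
  tibble::tibble(
    n_iterations = nrow(x$trace),
    best_objective = x$best_objective,
    best_iteration = x$best_iteration
  )
}

#' Plot a Bayesian-optimisation trace
#'
#' @param object A `boa_result`.
#' @param ... Unused.
#' @return A ggplot of per-iteration objective and the running best.
#' @export
autoplot.boa_result <- function(object, ...) {
  tr <- object$trace
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$objective)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$best_so_far),
                       colour = "steelblue") +
    ggplot2::labs(x = "iteration", y = "objective (validation R²)")
}

#' Five-fold cross-validation objective
#'
#' Evaluates one model specification by fruit-level five-fold
#' cross-validation on the calibration samples of a synthetic dataset:
#' folds partition fruit ids (never patches), the model is trained on four
#' folds and scored by per-fruit R-squared on the held-out fold, and the
#' mean across folds is returned (fold values in the `fold_r2` attribute).
#' When `augment = TRUE`, rotation/mirroring augmentation is applied to
#' the training folds only, so validation identities never change.
#'
#' @param dataset A [generate_dataset()] result.
#' @param spec A [model_spec()].
#' @param folds Number of folds (default 5).
#' @param seed Integer seed (fold assignment, patch sampling, training).
#' @param k_centers Patch pairs per fruit.
#' @param augment Augment training-fold cubes five-fold before patch
#'   extraction.
#' @return Mean validation R-squared (scalar) with attribute `fold_r2`.
#' @export
cv_objective <- function(dataset, spec, folds = 5L, seed = 1L,
                         k_centers = 8L, augment = FALSE) {
  labels <- dataset$labels
  cal <- labels[labels$split == "calibration", ]
  fold_id <- make_folds(cal$sample_id, folds = folds, seed = seed)
  prepped <- prepare_cubes(dataset, cal$sample_id)
  fold_r2 <- numeric(folds)
  for (f in seq_len(folds)) {
    tr_ids <- cal$sample_id[fold_id != f]
    va_ids <- cal$sample_id[fold_id == f]
    if (length(tr_ids) == 0 || length(va_ids) == 0) {
      stop("empty fold; reduce the number of folds", call. = FALSE)
    }
    tr_patches <- collect_patches(prepped, tr_ids, labels, k_centers, seed,
                                  augment = augment)
    va_patches <- collect_patches(prepped, va_ids, labels, k_centers, seed,
                                  augment = FALSE)
    model <- build_model(spec, n_bands = dim(tr_patches[[1]]$spectral_patch)[3],
                         seed = seed)
    model <- train_model(model, tr_patches, seed = seed + f)
    preds <- predict_dataset(model, va_patches)
    truth <- labels$ssc_brix[match(preds$sample_id, labels$sample_id)]
    fold_r2[f] <- r_squared(truth, preds$ssc_pred)
  }
  out <- mean(fold_r2)
  attr(out, "fold_r2") <- fold_r2
  out
}

#' Assign fruit ids to cross-validation folds
#'
#' Random balanced partition at the fruit level: every id lands in exactly
#' one fold and fold sizes differ by at most one.
#'
#' @param ids Vector of fruit ids.
#' @param folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold assignments aligned with `ids`.
#' @export
make_folds <- function(ids, folds = 5L, seed = 1L) {
  n <- length(ids)
  if (n < folds) stop("fewer fruit than folds", call. = FALSE)
  withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

# calibrate + mask + normalise + crop each requested cube once; the ratio
# mask is computed on the calibrated (pre-normalisation) reflectance
prepare_cubes <- function(dataset, ids, crop_size = NULL,
                          mask_threshold = 1.6) {
  out <- list()
  for (id in ids) {
    lc <- dataset$cubes[[id]]
    cube <- calibrate_reflectance(lc)
    mask <- compute_ratio_mask(cube, threshold = mask_threshold)
    cube <- normalize_cube(cube)
    size <- if (is.null(crop_size)) {
      d <- dim(cube$data)
      as.integer(min(d[1], d[2]))
    } else crop_size
    out[[id]] <- crop_to(cube, mask, size = size)
  }
  out
}

# patch extraction (with optional training-fold augmentation); augmented
# copies get a geometrically matching mask (rotated / mirrored)
collect_patches <- function(prepped, ids, labels, k_centers, seed,
                            augment = FALSE) {
  sets <- list()
  for (id in ids) {
    pc <- prepped[[id]]
    lab <- labels$ssc_brix[labels$sample_id == id]
    cube_list <- if (augment) {
      augment_cube(pc$cube, seed = seed + which(ids == id), mask = pc$mask)
    } else {
      list(pc$cube)
    }
    angles <- attr(cube_list, "angles")
    for (j in seq_along(cube_list)) {
      m <- pc$mask
      if (augment && j > 1) {
        m <- if (is.na(angles[j])) mirror_mask(m) else
          rotate_band(m * 1, angles[j], 0) > 0.5
        if (!any(m)) m <- pc$mask
      }
      sets[[length(sets) + 1]] <- extract_patch_pairs(
        cube_list[[j]], m, k_centers = k_centers,
        seed = seed + 1000L * j + which(ids == id),
        sample_id = id, label = lab
      )
    }
  }
  do.call(c, sets)
}

mirror_mask <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
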