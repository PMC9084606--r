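# Training protocol: minibatch gradient descent with momentum, MSE at every
# output node, step learning-rate decay, online augmentation, optional
# minority-class oversampling, and per-region gradient masking in multihead
# mode (only the active sample's head receives gradient; the shared trunk
# accumulates gradients from all samples).

#' Training configuration
#'
#' Defaults are the optimized hyperparameters of the plane-regression task:
#' learning rate 0.00164, decay factor 0.27291 applied every 75 epochs,
#' momentum 0.957437, batch size 9, 400 epochs, He weight initialization.
#'
#' @param epochs total training epochs.
#' @param lr initial learning rate.
#' @param lr_decay multiplicative decay factor.
#' @param lr_step epochs between decays.
#' @param momentum heavy-ball momentum coefficient.
#' @param batch_size minibatch size.
#' @param warmup_epochs number of initial epochs run at
#'   \code{warmup_factor * lr} before switching to the full learning rate;
#'   guards against collapsing the ReLU units while the output scale is
#'   still far from the targets.
#' @param warmup_factor learning-rate multiplier during warmup.
#' @param augment apply the online spatial/intensity augmentation.
#' @param aug_config an \code{\link{augmentation_config}}.
#' @param oversample weight minority regions so per-region draw frequencies
#'   are uniform.
#' @param seed RNG seed for data order, augmentation and initialization.
#' @return an object of class \code{train_config}.
#' @export
train_config <- function(epochs = 400L, lr = 0.00164, lr_decay = 0.27291,
                         lr_step = 75L, momentum = 0.957437, batch_size = 9L,
                         augment = TRUE, aug_config = augmentation_config(),
                         oversample = FALSE, warmup_epochs = 0L,
                         warmup_factor = 0.1, seed = NULL) {
  structure(list(epochs = as.integer(epochs), lr = lr, lr_decay = lr_decay,
                 lr_step = as.integer(lr_step), momentum = momentum,
                 batch_size = as.integer(batch_size), augment = augment,
                 aug_config = aug_config, oversample = oversample,
                 warmup_epochs = as.integer(warmup_epochs),
                 warmup_factor = warmup_factor, seed = seed),
            class = "train_config")
}

#' Oversampling weights for imbalanced regions
#'
#' Per-sample draw weight proportional to the reciprocal of its region's
#' volume count, so the expected per-region draw frequency is uniform.
#'
#' @param regions character vector, one region label per sample.
#' @return normalized numeric weights summing to 1.
#' @export
oversample_weights <- function(regions) {
  counts <- table(regions)
  if (any(counts == 0L)) stop("empty region")
  w <- 1 / as.numeric(counts[regions])
  w / sum(w)
}

#' Draw a weighted sampling stream
#'
#' @param regions character vector of per-sample region labels.
#' @param n_draws number of indices to draw (with replacement).
#' @return integer indices into the dataset.
#' @export
make_sampler <- function(regions, n_draws) {
  sample.int(length(regions), n_draws, replace = TRUE,
             prob = oversample_weights(regions))
}

# ---- optimizer --------------------------------------------------------------

zero_like_model <- function(model) {
  list(trunk = lapply(model$trunk, function(blk)
    list(W = blk$W * 0, b = blk$b * 0,
         gamma = blk$bn$gamma * 0, beta = blk$bn$beta * 0)),
    heads = lapply(model$heads, function(h)
      lapply(h, function(l) list(W = l$W * 0, b = l$b * 0))))
}

sgd_step <- function(model, vel, grads, lr, momentum) {
  for (i in seq_along(model$trunk)) {
    g <- grads$trunk[[i]]
    vel$trunk[[i]]$W <- momentum * vel$trunk[[i]]$W - lr * g$W
    vel$trunk[[i]]$b <- momentum * vel$trunk[[i]]$b - lr * g$b
    vel$trunk[[i]]$gamma <- momentum * vel$trunk[[i]]$gamma - lr * g$gamma
    vel$trunk[[i]]$beta <- momentum * vel$trunk[[i]]$beta - lr * g$beta
    model$trunk[[i]]$W <- model$trunk[[i]]$W + vel$trunk[[i]]$W
    model$trunk[[i]]$b <- model$trunk[[i]]$b + vel$trunk[[i]]$b
    model$trunk[[i]]$bn$gamma <- model$trunk[[i]]$bn$gamma +
      vel$trunk[[i]]$gamma
    model$trunk[[i]]$bn$beta <- model$trunk[[i]]$bn$beta +
      vel$trunk[[i]]$beta
  }
  for (r in names(model$heads)) {
    if (is.null(grads$heads[[r]])) next
    for (j in seq_along(model$heads[[r]])) {
      g <- grads$heads[[r]][[j]]
      vel$heads[[r]][[j]]$W <- momentum * vel$heads[[r]][[j]]$W - lr * g$W
      vel$heads[[r]][[j]]$b <- momentum * vel$heads[[r]][[j]]$b - lr * g$b
      model$heads[[r]][[j]]$W <- model$heads[[r]][[j]]$W +
        vel$heads[[r]][[j]]$W
      model$heads[[r]][[j]]$b <- model$heads[[r]][[j]]$b +
        vel$heads[[r]][[j]]$b
    }
  }
  list(model = model, vel = vel)
}

# ---- one training step ------------------------------------------------------

#' One minibatch gradient step
#'
#' Forward pass, MSE loss, backward pass with per-region head routing
#' (multihead gradient masking: heads of regions absent from the batch get
#' no gradient and are bit-identical after the step), and an SGD-momentum
#' parameter update.
#'
#' @param model an \code{mpr_model}.
#' @param x 5D array (X, Y, Z, 1, N), normalized network inputs.
#' @param targets n_outputs x N matrix of parameter vectors.
#' @param regions length-N character, region label per sample.
#' @param vel velocity state (from \code{\link{zero_velocity}}).
#' @param lr,momentum optimizer parameters.
#' @return list with updated \code{model}, \code{vel} and the batch
#'   \code{loss}.
#' @export
train_step <- function(model, x, targets, regions, vel, lr, momentum) {
  fw <- model_forward(model, x, regions, training = TRUE)
  model <- fw$trunk$model    # batch-norm running stats were updated
  N <- ncol(targets)
  loss <- mse_loss(fw$out, targets)
  dout <- 2 * (fw$out - targets) / length(targets)
  grads <- zero_like_model(model)
  grads$heads <- list()
  dfeat <- matrix(0, nrow(fw$trunk$features), N)
  for (r in names(fw$heads)) {
    hc <- fw$heads[[r]]
    hb <- head_backward(model$heads[[r]], hc$caches,
                        dout[, hc$cols, drop = FALSE])
    grads$heads[[r]] <- hb$grads
    dfeat[, hc$cols] <- hb$dx
  }
  tb <- trunk_backward(model, fw$trunk$caches, dfeat, fw$trunk$feat_dim)
  grads$trunk <- tb$grads
  st <- sgd_step(model, vel, grads, lr, momentum)
  list(model = st$model, vel = st$vel, loss = loss)
}

#' Zero-initialized optimizer velocity for a model
#' @param model an \code{mpr_model}.
#' @return nested list matching the parameter structure.
#' @export
zero_velocity <- function(model) zero_like_model(model)

# ---- dataset plumbing -------------------------------------------------------

prepare_sample <- function(sample, spec, config, net_geom, window_cfg) {
  if (config$augment) {
    aug <- sample_augmentation(config$aug_config)
    vol <- resample_volume(sample$volume, sample$geom, aug$transform,
                           spec$input_shape, mirror = aug$mirror)
    trip <- transform_labels(sample$triplet, aug$transform, aug$mirror)
    f <- aug$intensity_factor
  } else {
    vol <- resample_volume(sample$volume, sample$geom,
                           composed_transform(), spec$input_shape)
    trip <- sample$triplet
    f <- 1
  }
  x <- intensity_normalize(vol, window_cfg, f)
  target <- suppressWarnings(
    build_parameter_vector(trip, spec$codec, net_geom))
  list(x = x, target = target)
}

#' Train a plane-regression model
#'
#' Runs the full loop: per epoch, iterate minibatches (optionally drawn with
#' minority-region oversampling), augment each volume online (one composed
#' interpolation), window the intensities, forward, MSE, backward, SGD with
#' momentum; the learning rate is multiplied by \code{lr_decay} every
#' \code{lr_step} epochs. Deterministic given \code{config$seed}.
#'
#' @param model an \code{mpr_model} (from \code{\link{build_model}}).
#' @param dataset list of samples, each a list with fields \code{volume}
#'   (3D HU array), \code{geom} (\code{\link{volume_geometry}}),
#'   \code{triplet} (\code{\link{plane_triplet}}) and \code{region}.
#' @param config a \code{\link{train_config}}.
#' @param window_cfg an \code{\link{intensity_window_config}}.
#' @param verbose print per-epoch loss.
#' @param start_epoch first epoch to run (default 1). Together with
#'   \code{vel} this resumes an interrupted run: the learning-rate schedule
#'   is a function of the absolute epoch number, so a model trained to epoch
#'   k and resumed at k+1 follows the same schedule as an uninterrupted run.
#' @param vel optimizer velocity to resume from (default: zeros).
#' @return list with the trained \code{model}, a data.frame \code{log}
#'   (epoch, lr, mean training loss) and the final \code{vel}.
#' @export
train_model <- function(model, dataset, config = train_config(),
                        window_cfg = intensity_window_config(),
                        verbose = FALSE, start_epoch = 1L, vel = NULL) {
  if (!is.null(config$seed))
    set.seed(config$seed + (start_epoch - 1L))
  spec <- model$spec
  net_geom <- volume_geometry(spec$input_shape,
                              dataset[[1]]$geom$extent / spec$input_shape)
  regions <- vapply(dataset, `[[`, character(1), "region")
  if (is.null(vel)) vel <- zero_velocity(model)
  n <- length(dataset)
  log_rows <- list()
  warmup <- if (is.null(config$warmup_epochs)) 0L else config$warmup_epochs
  for (epoch in seq.int(start_epoch, config$epochs)) {
    lr <- config$lr * config$lr_decay^((epoch - 1L) %/% config$lr_step)
    lr_eff <- if (epoch <= warmup) lr * config$warmup_factor else lr
    order_ <- if (config$oversample) make_sampler(regions, n)
              else sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- order_[start:min(start + config$batch_size - 1L, n)]
      prepped <- lapply(dataset[idx], prepare_sample, spec = spec,
                        config = config, net_geom = net_geom,
                        window_cfg = window_cfg)
      nb <- length(prepped)
      x <- array(0, c(spec$input_shape, 1L, nb))
      targets <- matrix(0, spec$n_outputs, nb)
      for (j in seq_len(nb)) {
        x[, , , 1L, j] <- prepped[[j]]$x
        targets[, j] <- prepped[[j]]$target
      }
      if (any(!is.finite(targets))) stop("non-finite training target")
      st <- train_step(model, x, targets, regions[idx], vel, lr_eff,
                       config$momentum)
      model <- st$model; vel <- st$vel
      if (!is.finite(st$loss)) stop("NaN loss at epoch ", epoch)
      losses <- c(losses, st$loss)
    }
    log_rows[[length(log_rows) + 1L]] <- data.frame(epoch = epoch,
                                                    lr = lr_eff,
                                                    loss = mean(losses))
    if (verbose)
      message(sprintf("epoch %3d  lr %.3g  loss %.6f", epoch, lr,
                      mean(losses)))
  }
  list(model = model, log = do.call(rbind, log_rows), vel = vel)
}

#' Train with random restarts screened by training loss
#'
#' Training the small pose regressors from scratch is bimodal: depending on
#' the initialization, a run either keeps grinding the loss down or settles
#' early on a plateau where the hardest pose component is never learned.
#' The two modes separate on the training loss well before the epoch budget
#' is spent, so this wrapper trains up to \code{n_starts} He-initialized
#' models for \code{screen_epochs} epochs each, continues the first one
#' whose training loss is at or below \code{screen_loss} to the full
#' \code{config$epochs} (resuming schedule and velocity), and otherwise
#' falls back to continuing the best start. Selection uses the training
#' loss only; no validation or test data is consulted.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param dataset as in \code{\link{train_model}}.
#' @param config a \code{\link{train_config}}; \code{config$epochs} is the
#'   full budget per continued run.
#' @param n_starts maximum number of random initializations.
#' @param screen_epochs epochs per screening run.
#' @param screen_loss training-loss cutoff that triggers continuation.
#' @param seed base seed; every start derives its own init and data-order
#'   seeds from it.
#' @param window_cfg an \code{\link{intensity_window_config}}.
#' @param verbose print per-epoch losses.
#' @return list with the trained \code{model}, its full \code{log}, and a
#'   data.frame \code{starts} (one row per screened start).
#' @export
train_with_restarts <- function(spec, dataset, config, n_starts = 5L,
                                screen_epochs = 15L, screen_loss = 0.025,
                                seed = 1L,
                                window_cfg = intensity_window_config(),
                                verbose = FALSE) {
  stopifnot(screen_epochs < config$epochs)
  screen_cfg <- config
  screen_cfg$epochs <- as.integer(screen_epochs)
  best <- NULL; best_loss <- Inf; rows <- list()
  for (s in seq_len(n_starts)) {
    set.seed(seed + 1000L * s)
    model <- build_model(spec)
    screen_cfg$seed <- seed + 1000L * s + 1L
    r <- train_model(model, dataset, screen_cfg, window_cfg,
                     verbose = verbose)
    sl <- tail(r$log$loss, 1L)
    hit <- sl <= screen_loss
    rows[[s]] <- data.frame(start = s, screen_loss = sl, continued = hit)
    if (verbose)
      message(sprintf("start %d: loss %.5f after %d epochs%s", s, sl,
                      screen_epochs, if (hit) " (continuing)" else ""))
    if (is.null(best) || sl < best_loss) {
      best_loss <- sl
      best <- list(r = r, seed = screen_cfg$seed)
    }
    if (hit) { best <- list(r = r, seed = screen_cfg$seed); break }
  }
  cont_cfg <- config
  cont_cfg$seed <- best$seed
  fin <- train_model(best$r$model, dataset, cont_cfg, window_cfg,
                     verbose = verbose,
                     start_epoch = as.integer(screen_epochs) + 1L,
                     vel = best$r$vel)
  list(model = fin$model, log = rbind(best$r$log, fin$log),
       starts = do.call(rbind, rows))
}

#' Evaluate a model on a dataset
#'
#' Deterministic inference-time path: resample to the network input
#' resolution (no augmentation), window, predict, optionally postprocess,
#' and score against the stored ground-truth triplet.
#'
#' @param model a trained \code{mpr_model}.
#' @param dataset as in \code{\link{train_model}}.
#' @param postprocess apply \code{\link{postprocess_triplet}}.
#' @param window_cfg an \code{\link{intensity_window_config}}.
#' @return list of \code{plane_error_report}s.
#' @export
evaluate_model <- function(model, dataset, postprocess = TRUE,
                           window_cfg = intensity_window_config()) {
  spec <- model$spec
  lapply(dataset, function(s) {
    net_geom <- volume_geometry(spec$input_shape,
                                s$geom$extent / spec$input_shape)
    vol <- resample_volume(s$volume, s$geom, composed_transform(),
                           spec$input_shape)
    x <- intensity_normalize(vol, window_cfg)
    pred <- predict_planes(model, x, net_geom, region = s$region,
                           postprocess = postprocess)
    plane_score(pred, s$triplet)
  })
}
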