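# Convolutional pose regressor. The trunk is a stack of blocks
# (3x3x3 same-padding convolution -> ReLU -> batch normalization -> 2x2x2
# ceil-mode max pool; the final block may pool adaptively to a fixed grid so
# the flatten width is architecture-exact). One or more fully connected
# heads regress the parameter vector. Forward and backward passes are
# orchestrated here on top of the compiled kernels; parameters are plain R
# arrays so the optimizer and the gradient-masking contract stay inspectable.

#' Model specification
#'
#' The default corresponds to the baseline pose-regression network: 72^3
#' single-channel input, five convolutional blocks with channel progression
#' 1-8-16-32-64-128, an adaptive final pool to 4x5x4 (flatten width
#' 4*5*4*128 = 10240) and a fully connected head 10240-1300-50-n, where n =
#' 3*(3 + n_params) of the rotation codec.
#'
#' @param input_shape integer length-3 network input resolution.
#' @param channels output channels of the successive conv blocks.
#' @param head_hidden widths of the hidden fully connected layers.
#' @param codec a \code{\link{rotation_codec}}.
#' @param mode \code{"baseline"} (one region, one head),
#'   \code{"single_head"} (all regions through one head) or
#'   \code{"multi_head"} (shared trunk, one head per region).
#' @param regions body regions served by the model.
#' @param adaptive_pool integer length-3 target grid of the final pool, or
#'   NULL for a regular 2x2x2 pool. Defaults to \code{c(4, 5, 4)} for the
#'   five-block 72^3 layout and NULL otherwise.
#' @return an object of class \code{model_spec}.
#' @export
model_spec <- function(input_shape = c(72, 72, 72),
                       channels = c(8, 16, 32, 64, 128),
                       head_hidden = c(1300, 50),
                       codec = rotation_codec("six_d_xy"),
                       mode = c("baseline", "single_head", "multi_head"),
                       regions = "ankle",
                       adaptive_pool = if (length(channels) == 5 &&
                                           all(input_shape == 72)) c(4, 5, 4)
                                       else NULL) {
  mode <- match.arg(mode)
  if (mode == "baseline" && length(regions) != 1L)
    stop("baseline mode serves exactly one region")
  # simulate the spatial dims through the blocks
  sp <- as.integer(input_shape)
  for (i in seq_along(channels)) {
    if (i == length(channels) && !is.null(adaptive_pool))
      sp <- as.integer(adaptive_pool)
    else
      sp <- as.integer(ceiling(sp / 2))
  }
  n_flat <- prod(sp) * channels[length(channels)]
  structure(list(input_shape = as.integer(input_shape),
                 channels = as.integer(channels),
                 head_hidden = as.integer(head_hidden),
                 codec = codec, mode = mode, regions = regions,
                 adaptive_pool = if (is.null(adaptive_pool)) NULL
                                 else as.integer(adaptive_pool),
                 n_flat = as.integer(n_flat),
                 n_outputs = 3L * (3L + codec$n_params),
                 final_spatial = sp),
            class = "model_spec")
}

he_matrix <- function(nout, nin, fan_in) {
  matrix(rnorm(nout * nin, sd = sqrt(2 / fan_in)), nout, nin)
}

#' Build a pose-regression model
#'
#' Allocates He-initialized weights for the trunk and head(s) described by a
#' \code{\link{model_spec}}. Uses R's RNG stream (seed with
#' \code{set.seed} for reproducible initialization).
#'
#' @param spec a \code{\link{model_spec}}.
#' @return an object of class \code{mpr_model}.
#' @export
build_model <- function(spec) {
  cin <- c(1L, spec$channels[-length(spec$channels)])
  trunk <- lapply(seq_along(spec$channels), function(i) {
    cout <- spec$channels[i]
    list(W = he_matrix(cout, 27L * cin[i], 27L * cin[i]),
         b = numeric(cout),
         bn = list(gamma = rep(1, cout), beta = numeric(cout),
                   run_mean = numeric(cout), run_var = rep(1, cout)))
  })
  head_regions <- if (spec$mode == "multi_head") spec$regions else "__shared__"
  widths <- c(spec$n_flat, spec$head_hidden, spec$n_outputs)
  make_head <- function() {
    lapply(seq_len(length(widths) - 1L), function(i) {
      list(W = he_matrix(widths[i + 1L], widths[i], widths[i]),
           b = numeric(widths[i + 1L]))
    })
  }
  heads <- setNames(lapply(head_regions, function(r) make_head()),
                    head_regions)
  structure(list(spec = spec, trunk = trunk, heads = heads),
            class = "mpr_model")
}

#' @export
print.mpr_model <- function(x, ...) {
  cat(sprintf(
    "<mpr_model %s, input %s, channels %s, flatten %d, head %s -> %d, %d parameters>\n",
    x$spec$mode, paste(x$spec$input_shape, collapse = "x"),
    paste(x$spec$channels, collapse = "-"), x$spec$n_flat,
    paste(x$spec$head_hidden, collapse = "-"), x$spec$n_outputs,
    count_parameters(x)))
  invisible(x)
}

#' Total number of trainable parameters
#' @param model an \code{mpr_model}.
#' @return integer count (conv + batch-norm + fully connected).
#' @export
count_parameters <- function(model) {
  n <- 0
  for (blk in model$trunk)
    n <- n + length(blk$W) + length(blk$b) +
      length(blk$bn$gamma) + length(blk$bn$beta)
  for (h in model$heads)
    for (l in h) n <- n + length(l$W) + length(l$b)
  n
}

# ---- batch normalization ----------------------------------------------------

bn_forward <- function(bn, a, training, momentum = 0.1, eps = 1e-5) {
  d <- dim(a); V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  dim(a) <- c(V, C, N)
  out <- a; xhat <- a
  mean_c <- numeric(C); var_c <- numeric(C)
  for (ch in seq_len(C)) {
    xc <- a[, ch, , drop = TRUE]
    if (training) {
      m <- mean(xc); v <- mean((xc - m)^2)
    } else {
      m <- bn$run_mean[ch]; v <- bn$run_var[ch]
    }
    xh <- (xc - m) / sqrt(v + eps)
    xhat[, ch, ] <- xh
    out[, ch, ] <- bn$gamma[ch] * xh + bn$beta[ch]
    mean_c[ch] <- m; var_c[ch] <- v
  }
  if (training) {
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mean_c
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * var_c
  }
  dim(out) <- d
  list(out = out, state = bn,
       cache = list(xhat = xhat, var = var_c, eps = eps, dims = d))
}

bn_backward <- function(bn, cache, dout) {
  d <- cache$dims; V <- prod(d[1:3]); C <- d[4]; N <- d[5]
  dim(dout) <- c(V, C, N)
  dx <- dout
  dgamma <- numeric(C); dbeta <- numeric(C)
  m_tot <- V * N
  for (ch in seq_len(C)) {
    dc <- dout[, ch, , drop = TRUE]
    xh <- cache$xhat[, ch, , drop = TRUE]
    dgamma[ch] <- sum(dc * xh)
    dbeta[ch] <- sum(dc)
    inv_std <- 1 / sqrt(cache$var[ch] + cache$eps)
    dx[, ch, ] <- (bn$gamma[ch] * inv_std / m_tot) *
      (m_tot * dc - dbeta[ch] - xh * dgamma[ch])
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- trunk ------------------------------------------------------------------

trunk_forward <- function(model, x, training = TRUE) {
  nb <- length(model$trunk)
  caches <- vector("list", nb)
  cur <- x
  for (i in seq_len(nb)) {
    blk <- model$trunk[[i]]
    z <- conv3d_forward_cpp(cur, blk$W, blk$b)
    a <- pmax(z, 0); dim(a) <- dim(z)
    bnf <- bn_forward(blk$bn, a, training)
    model$trunk[[i]]$bn <- bnf$state
    adaptive <- if (i == nb) model$spec$adaptive_pool else NULL
    pl <- if (is.null(adaptive)) maxpool3d_forward_cpp(bnf$out)
          else adaptive_maxpool3d_forward_cpp(bnf$out, adaptive)
    caches[[i]] <- list(x = cur, z = z, bn = bnf$cache, idx = pl$idx,
                        pool_in_dim = dim(bnf$out))
    cur <- pl$y
  }
  d <- dim(cur)
  feats <- cur
  dim(feats) <- c(prod(d[1:4]), d[5])   # n_flat x N
  list(features = feats, caches = caches, model = model,
       feat_dim = d)
}

trunk_backward <- function(model, caches, dfeat, feat_dim) {
  nb <- length(model$trunk)
  grads <- vector("list", nb)
  cur <- dfeat
  dim(cur) <- feat_dim
  for (i in rev(seq_len(nb))) {
    blk <- model$trunk[[i]]; cc <- caches[[i]]
    dpool <- maxpool3d_backward_cpp(cur, cc$idx, cc$pool_in_dim)
    bnb <- bn_backward(blk$bn, cc$bn, dpool)
    dz <- bnb$dx * (cc$z > 0); dim(dz) <- dim(cc$z)
    cb <- conv3d_backward_cpp(cc$x, blk$W, dz)
    grads[[i]] <- list(W = cb$dW, b = cb$db,
                       gamma = bnb$dgamma, beta = bnb$dbeta)
    cur <- cb$dx
  }
  list(grads = grads, dx = cur)
}

# ---- head -------------------------------------------------------------------

head_forward <- function(head, f) {
  nl <- length(head)
  caches <- vector("list", nl)
  cur <- f
  for (i in seq_len(nl)) {
    z <- head[[i]]$W %*% cur + head[[i]]$b
    caches[[i]] <- list(x = cur, z = z)
    cur <- if (i < nl) pmax(z, 0) else z
    if (i < nl) dim(cur) <- dim(z)
  }
  list(out = cur, caches = caches)
}

head_backward <- function(head, caches, dout) {
  nl <- length(head)
  grads <- vector("list", nl)
  cur <- dout
  for (i in rev(seq_len(nl))) {
    if (i < nl) cur <- cur * (caches[[i]]$z > 0)
    grads[[i]] <- list(W = cur %*% t(caches[[i]]$x),
                       b = rowSums(cur))
    cur <- t(head[[i]]$W) %*% cur
  }
  list(grads = grads, dx = cur)
}

# ---- loss -------------------------------------------------------------------

#' Mean-squared-error loss over the output nodes
#'
#' The planes are regressed decoupled: no orthogonality penalty is added,
#' the loss is simply the mean of squared differences over all output nodes
#' (and over samples when matrices are passed).
#'
#' @param pred,target numeric vectors (or node-by-sample matrices) of equal
#'   length.
#' @return scalar loss.
#' @export
mse_loss <- function(pred, target) {
  if (length(pred) != length(target)) stop("length mismatch")
  mean((pred - target)^2)
}

# ---- full forward / predict -------------------------------------------------

model_forward <- function(model, x, regions, training = TRUE) {
  tf <- trunk_forward(model, x, training)
  N <- ncol(tf$features)
  out <- matrix(0, model$spec$n_outputs, N)
  if (model$spec$mode == "multi_head") {
    hcaches <- list()
    for (r in unique(regions)) {
      if (!r %in% names(model$heads)) stop("unknown region: ", r)
      cols <- which(regions == r)
      hf <- head_forward(model$heads[[r]], tf$features[, cols, drop = FALSE])
      out[, cols] <- hf$out
      hcaches[[r]] <- list(cols = cols, caches = hf$caches)
    }
  } else {
    hf <- head_forward(model$heads[["__shared__"]], tf$features)
    out[, ] <- hf$out
    hcaches <- list("__shared__" = list(cols = seq_len(N),
                                        caches = hf$caches))
  }
  list(out = out, trunk = tf, heads = hcaches)
}

#' Predict the standard-plane triplet for one preprocessed volume
#'
#' Runs the forward pass in evaluation mode (batch-norm running statistics),
#' parses the parameter vector, decodes the rotation codec (which always
#' yields proper rotations, whatever the raw network output), and optionally
#' applies \code{\link{postprocess_triplet}}.
#'
#' @param model a trained \code{mpr_model}.
#' @param x 3D array, the intensity-normalized network input.
#' @param geom \code{\link{volume_geometry}} of the network input (used to
#'   denormalize the translation).
#' @param region body region (selects the head in multihead mode).
#' @param postprocess apply the orthogonality postprocessing.
#' @return a \code{\link{plane_triplet}}.
#' @export
predict_planes <- function(model, x, geom, region = model$spec$regions[1],
                           postprocess = TRUE) {
  if (model$spec$mode == "multi_head" && !region %in% names(model$heads))
    stop("unknown region for multihead model: ", region)
  dim(x) <- c(dim(x)[1:3], 1L, 1L)
  fw <- model_forward(model, x, regions = region, training = FALSE)
  trip <- parse_parameter_vector(as.numeric(fw$out[, 1]), model$spec$codec,
                                 geom, region = region)
  if (postprocess) postprocess_triplet(trip) else trip
}
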