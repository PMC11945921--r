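# Deep sparse capsule network regressor and convolutional baselines.
#
# The capsule trunk is a 1-D adaptation: conv (kernel 9) + ReLU, a primary
# capsule convolution (kernel 9, stride 2) whose channels are reshaped into
# 8-dimensional capsules and squashed, then digit capsules obtained through
# learned transformation matrices and routing-by-agreement. Digit-capsule
# transforms are shared across positions within each primary map (a
# convolutional capsule layer), which keeps CPU training tractable without
# changing the routing or sparse-filtering math. The regression head is
# dense(128) + ReLU + dropout + dense(1, linear), optionally consuming the
# 36-element feature vector alongside the flattened digit capsules.

#' Model configuration
#'
#' Defaults mirror the full-size network (256 kernel-9 convolution
#' channels, 32 primary maps of 8-dimensional capsules at stride 2, three
#' 16-dimensional digit capsules — one per glucose band — with 3 routing
#' iterations); tests and desk-scale runs use reduced channel counts.
#'
#' @param conv_channels Channels of the first convolution.
#' @param conv_kernel Kernel length of both convolutions (samples).
#' @param primary_maps Number of primary capsule maps.
#' @param primary_capsule_dim Primary capsule dimension.
#' @param primary_stride Stride of the primary capsule convolution.
#' @param digit_capsules Number of digit capsules.
#' @param digit_capsule_dim Digit capsule dimension.
#' @param routing_iters Routing iterations (>= 1).
#' @param use_attention Insert a self-attention layer (over primary-map
#'   positions for the capsule net; after every block for the CNN).
#' @param use_feature_vector Concatenate the standardized feature vector
#'   before the dense head (capsule net only).
#' @param cnn_num_layers,cnn_kernel,num_filters CNN baseline stack shape.
#' @param dense_width,dropout_rate Regression head width and dropout.
#' @return An object of class `model_config`.
#' @export
model_config <- function(conv_channels = 256, conv_kernel = 9,
                         primary_maps = 32, primary_capsule_dim = 8,
                         primary_stride = 2, digit_capsules = 3,
                         digit_capsule_dim = 16, routing_iters = 3,
                         use_attention = FALSE, use_feature_vector = TRUE,
                         cnn_num_layers = 4, cnn_kernel = 3,
                         num_filters = c(32, 64, 128, 256),
                         dense_width = 128, dropout_rate = 0.5) {
  for (v in c(conv_channels, conv_kernel, primary_maps, primary_capsule_dim,
              primary_stride, digit_capsules, digit_capsule_dim,
              routing_iters, cnn_num_layers, cnn_kernel, dense_width)) {
    if (!is_count(v)) stop_input("all model counts must be positive integers")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_input("`dropout_rate` must lie in [0, 1)")
  }
  if (length(num_filters) < cnn_num_layers) {
    stop_input("`num_filters` must supply one width per CNN layer")
  }
  structure(list(conv_channels = conv_channels, conv_kernel = conv_kernel,
                 primary_maps = primary_maps,
                 primary_capsule_dim = primary_capsule_dim,
                 primary_stride = primary_stride,
                 digit_capsules = digit_capsules,
                 digit_capsule_dim = digit_capsule_dim,
                 routing_iters = routing_iters,
                 use_attention = isTRUE(use_attention),
                 use_feature_vector = isTRUE(use_feature_vector),
                 cnn_num_layers = cnn_num_layers, cnn_kernel = cnn_kernel,
                 num_filters = num_filters, dense_width = dense_width,
                 dropout_rate = dropout_rate),
            class = "model_config")
}

#' Training configuration
#'
#' @param epochs Maximum epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param seed Seed for every source of training randomness
#'   (initialisation happens at build time; shuffling, dropout and the
#'   validation carve-out happen here).
#' @param sf_weight Weight lambda (>= 0) of the sparse-filtering term.
#' @param sf_mode `"joint"` adds the term to every supervised step;
#'   `"alternating"` performs one unsupervised transform-weight update per
#'   `sf_every` supervised steps.
#' @param sf_every Supervised steps per unsupervised step (alternating
#'   mode).
#' @param split_fraction Train fraction used by callers when splitting
#'   cohorts (default 0.8).
#' @param val_fraction Fraction of the training set held out for early
#'   stopping.
#' @param patience Early-stopping patience in epochs.
#' @param loss Regression loss identifier (only `"mse"` implemented).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200, batch_size = 16,
                         learning_rate = 1e-3, seed = 0, sf_weight = 1e-3,
                         sf_mode = c("joint", "alternating"), sf_every = 5,
                         split_fraction = 0.8, val_fraction = 0.15,
                         patience = 20, loss = "mse") {
  sf_mode <- match.arg(sf_mode)
  if (sf_weight < 0) stop_input("`sf_weight` must be >= 0")
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_input("`split_fraction` must lie in (0, 1)")
  }
  if (loss != "mse") stop_input("only the MSE loss is implemented")
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = seed,
                 sf_weight = sf_weight, sf_mode = sf_mode,
                 sf_every = sf_every, split_fraction = split_fraction,
                 val_fraction = val_fraction, patience = patience,
                 loss = loss),
            class = "train_config")
}

#' Rectified linear unit
#'
#' Elementwise `max(x, 0)`.
#'
#' @param x Numeric vector/array.
#' @return Same shape as `x`.
#' @export
relu <- function(x) pmax(x, 0)

#' Capsule squash nonlinearity
#'
#' `v = (||s||^2 / (1 + ||s||^2)) * s / ||s||`: direction preserved, norm
#' mapped monotonically into \[0, 1). The zero vector maps to itself.
#'
#' @param s Numeric capsule vector, or a matrix whose columns are capsules.
#' @return Squashed vector/matrix.
#' @export
squash <- function(s) {
  if (is.matrix(s)) {
    n2 <- colSums(s^2)
    s * rep(sqrt(n2) / (1 + n2), each = nrow(s))
  } else {
    n2 <- sum(s^2)
    s * sqrt(n2) / (1 + n2)
  }
}

#' Dynamic routing by agreement
#'
#' Coupling logits start at zero; each iteration applies a softmax over the
#' output capsules, forms the weighted vote sums `s_r = sum_q C_qr
#' uhat_rq`, squashes them, and adds the prediction/output agreement to the
#' logits. Deterministic given the predictions.
#'
#' @param u_hat Prediction array of dimension `(D, Q, R)` (capsule dim,
#'   input capsules, output capsules) or `(D, Q, R, B)` with a batch axis.
#' @param iters Number of routing iterations (>= 1).
#' @return List with `v` (output capsules, `(D, R)` or `(D, R, B)`) and
#'   `coupling` (`(Q, R)` or `(Q, R, B)`; rows sum to 1 over R).
#' @export
dynamic_routing <- function(u_hat, iters = 3) {
  if (!is_count(iters)) stop_input("`iters` must be a positive integer")
  d <- dim(u_hat)
  if (is.null(d) || !length(d) %in% c(3L, 4L)) {
    stop_input("`u_hat` must be a (D, Q, R[, B]) array")
  }
  squeeze <- length(d) == 3L
  if (squeeze) dim(u_hat) <- c(d, 1L)
  r <- routing_fwd(u_hat, iters)
  if (squeeze) {
    list(v = array(r$v, dim(r$v)[1:2]), coupling = array(r$C, dim(r$C)[1:2]))
  } else {
    list(v = r$v, coupling = r$C)
  }
}

#' Row / column L2 normalisation and the sparse-filtering objective
#'
#' `row_normalize()` divides each row (one feature across samples) by its
#' Euclidean norm plus a small guard; `column_normalize()` does the same to
#' columns (per-sample feature vectors), placing them on the unit sphere.
#' `sparse_filtering_loss()` is the L1 norm of the doubly normalised
#' matrix, minimised when each sample activates a single feature (value M,
#' the number of columns) and maximal for uniform activations
#' (`M * sqrt(N)`). `sparse_filtering_grad()` is its analytic gradient.
#'
#' @param m Numeric feature matrix (features x samples).
#' @param eps Normalisation guard (default 1e-8); all-zero rows or columns
#'   pass through unchanged.
#' @return The normalised matrix, the scalar loss, or the gradient matrix.
#' @export
row_normalize <- function(m, eps = 1e-8) {
  m / (sqrt(rowSums(m^2)) + eps)
}

#' @rdname row_normalize
#' @export
column_normalize <- function(m, eps = 1e-8) {
  sweep(m, 2, sqrt(colSums(m^2)) + eps, "/")
}

#' @rdname row_normalize
#' @export
sparse_filtering_loss <- function(m, eps = 1e-8) {
  sum(abs(column_normalize(row_normalize(m, eps), eps)))
}

#' @rdname row_normalize
#' @export
sparse_filtering_grad <- function(m, eps = 1e-8) {
  nr <- sqrt(rowSums(m^2))
  R <- m / (nr + eps)
  nc <- sqrt(colSums(R^2))
  O <- sweep(R, 2, nc + eps, "/")
  G <- sign(O)
  coldot <- colSums(R * G)
  dR <- sweep(G, 2, nc + eps, "/") -
    sweep(R, 2, coldot / (pmax(nc, 1e-300) * (nc + eps)^2), "*")
  rowdot <- rowSums(m * dR)
  dR / (nr + eps) - m * (rowdot / (pmax(nr, 1e-300) * (nr + eps)^2))
}

#' Scaled dot-product self-attention over positions
#'
#' `Q = X Wq`, `K = X Wk`, `V = X Wv`; attention weights
#' `softmax(Q K^T / sqrt(d))` act over positions and the value mix is added
#' to the input (residual connection). With the default identity maps this
#' is a parameter-free attention useful for testing; inside models the maps
#' are learned.
#'
#' @param feature_map Matrix of positions x channels.
#' @param Wq,Wk,Wv Channel-mixing matrices (d x d); default identity.
#' @return Matrix of the same shape, with the position-by-position
#'   attention weights in attribute `"weights"`.
#' @export
self_attention <- function(feature_map, Wq = NULL, Wk = NULL, Wv = NULL) {
  if (!is.matrix(feature_map) || length(feature_map) == 0L) {
    stop_input("`feature_map` must be a non-empty matrix")
  }
  d <- ncol(feature_map)
  if (is.null(Wq)) Wq <- diag(d)
  if (is.null(Wk)) Wk <- diag(d)
  if (is.null(Wv)) Wv <- diag(d)
  Q <- feature_map %*% Wq
  K <- feature_map %*% Wk
  V <- feature_map %*% Wv
  Aw <- softmax_rows(Q %*% t(K) / sqrt(d))
  out <- Aw %*% V + feature_map
  attr(out, "weights") <- Aw
  out
}

#' Build the capsule network regressor
#'
#' Layer stack on a 1-D preprocessed segment: conv(kernel 9, stride 1) +
#' ReLU, primary capsule conv (kernel 9, stride `primary_stride`, channels
#' `primary_maps * primary_capsule_dim`, reshaped to capsules and
#' squashed), optional self-attention over the primary map, digit capsules
#' via shared transformation matrices and dynamic routing, then the dense
#' regression head (optionally concatenating the feature vector). The
#' parameter count is reported at build time.
#'
#' @param config A [model_config()].
#' @param input_len Segment length in samples (default 1700).
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `bgl_model` (type `"dscnet"`).
#' @export
build_dscnet <- function(config = model_config(), input_len = 1700,
                         seed = NULL) {
  k <- config$conv_kernel
  p1 <- input_len - k + 1L
  if (p1 < k) {
    stop_input("input length too short for two kernel-", k, " convolutions")
  }
  p2 <- (p1 - k) %/% config$primary_stride + 1L
  cdim <- config$primary_capsule_dim
  c2 <- config$primary_maps * cdim
  init <- function() {
    params <- list(
      conv1 = conv1d_init(1L, config$conv_channels, k),
      conv2 = conv1d_init(config$conv_channels, c2, k),
      digit = list(W = array(
        stats::rnorm(config$digit_capsule_dim * cdim *
                       config$primary_maps * config$digit_capsules, 0, 0.1),
        c(config$digit_capsule_dim, cdim, config$primary_maps,
          config$digit_capsules))),
      dense1 = dense_init(config$digit_capsules * config$digit_capsule_dim +
                            if (config$use_feature_vector) 36L else 0L,
                          config$dense_width),
      dense2 = dense_init(config$dense_width, 1L))
    if (config$use_attention) params$attn <- attention_init(c2)
    params
  }
  params <- if (is.null(seed)) init() else with_local_seed(seed, init())
  model <- structure(
    list(type = "dscnet", config = config, params = params,
         input_len = input_len, p1 = p1, p2 = p2,
         fv_dim = if (config$use_feature_vector) 36L else 0L,
         norms = NULL, trained = FALSE,
         n_params = count_params(params)),
    class = "bgl_model")
  message(sprintf("built dscnet: %d parameters, %d primary capsules",
                  model$n_params, p2 * config$primary_maps))
  model
}

#' Build the convolutional baseline
#'
#' The four-block stack: conv(kernel 3, 'same') + ReLU + maxpool(2) +
#' dropout (+ self-attention when `attention`), repeated
#' `cnn_num_layers` times with `num_filters` channels, then flatten +
#' dense(128) + ReLU + dropout + dense(1, linear).
#'
#' @param config A [model_config()].
#' @param attention Insert a self-attention layer after every block.
#' @param input_len Segment length in samples.
#' @param seed Optional seed for weight initialisation.
#' @return An object of class `bgl_model` (type `"cnn"`).
#' @export
build_cnn_baseline <- function(config = model_config(), attention = FALSE,
                               input_len = 1700, seed = NULL) {
  nl <- config$cnn_num_layers
  filters <- config$num_filters[seq_len(nl)]
  lens <- integer(nl)
  L <- input_len
  for (i in seq_len(nl)) {
    L <- L %/% 2L
    lens[i] <- L
    if (L < 1L) stop_input("input length too short for ", nl, " pool layers")
  }
  init <- function() {
    params <- list()
    cin <- 1L
    for (i in seq_len(nl)) {
      blk <- list(conv = conv1d_init(cin, filters[i], config$cnn_kernel))
      if (attention) blk$attn <- attention_init(filters[i])
      params[[paste0("block", i)]] <- blk
      cin <- filters[i]
    }
    params$dense1 <- dense_init(filters[nl] * lens[nl], config$dense_width)
    params$dense2 <- dense_init(config$dense_width, 1L)
    params
  }
  params <- if (is.null(seed)) init() else with_local_seed(seed, init())
  model <- structure(
    list(type = "cnn", config = config, params = params,
         input_len = input_len, attention = isTRUE(attention),
         filters = filters, lens = lens, fv_dim = 0L,
         norms = NULL, trained = FALSE, n_params = count_params(params)),
    class = "bgl_model")
  message(sprintf("built cnn baseline%s: %d parameters",
                  if (attention) " + self-attention" else "",
                  model$n_params))
  model
}

#' @export
print.bgl_model <- function(x, ...) {
  cat(sprintf("<bgl_model> type=%s params=%d input_len=%d %s\n", x$type,
              x$n_params, x$input_len,
              if (x$trained) "(trained)" else "(untrained)"))
  invisible(x)
}

# ---- forward / backward passes ------------------------------------------

forward_dscnet <- function(model, X, FV, train = FALSE) {
  cfg <- model$config
  p <- model$params
  cdim <- cfg$primary_capsule_dim
  maps <- cfg$primary_maps
  B <- dim(X)[3]
  c1 <- conv1d_fwd(X, p$conv1$W, p$conv1$b, cfg$conv_kernel)
  r1 <- relu_fwd(c1$out)
  c2 <- conv1d_fwd(r1$out, p$conv2$W, p$conv2$b, cfg$conv_kernel,
                   stride = cfg$primary_stride)
  feat <- c2$out
  att <- NULL
  if (cfg$use_attention) {
    att <- attention_fwd(feat, p$attn)
    feat <- att$out
  }
  P2 <- dim(feat)[2]
  # channels are ordered capsule-dim fastest: reshape to capsules
  Z <- array(feat, c(cdim, maps, P2, B))
  Zp <- aperm(Z, c(1, 3, 2, 4))                  # (cdim, P2, maps, B)
  sq1 <- squash_fwd(Zp)
  u <- sq1$out
  Dh <- cfg$digit_capsule_dim
  R <- cfg$digit_capsules
  caps <- caps_digit_fwd_cpp(u, p$digit$W, cdim, P2, maps, B, Dh, R,
                             cfg$routing_iters)
  rt <- list(C = caps$C, squash_cache = squash_fwd(caps$s))
  v <- rt$squash_cache$out                       # (Dh, R, B)
  h0 <- matrix(v, Dh * R, B)
  if (model$fv_dim > 0L) h0 <- rbind(h0, FV)
  z1 <- dense_fwd(h0, p$dense1$W, p$dense1$b)
  a1 <- relu_fwd(z1)
  dp <- dropout_fwd(a1$out, cfg$dropout_rate, train)
  yhat <- dense_fwd(dp$out, p$dense2$W, p$dense2$b)
  list(yhat = as.numeric(yhat), v = v,
       cache = list(c1 = c1, r1 = r1, c2 = c2, att = att, sq1 = sq1,
                    u = u, rt = rt, h0 = h0, a1 = a1, dp = dp,
                    P2 = P2, B = B))
}

backward_dscnet <- function(model, fw, dy, sf_weight = 0,
                            supervised = TRUE) {
  cfg <- model$config
  p <- model$params
  cdim <- cfg$primary_capsule_dim
  maps <- cfg$primary_maps
  Dh <- cfg$digit_capsule_dim
  R <- cfg$digit_capsules
  cc <- fw$cache
  P2 <- cc$P2
  B <- cc$B
  grads <- zero_like(p)
  sf_loss <- NA_real_
  dv_task <- array(0, c(Dh, R, B))
  if (supervised) {
    d2 <- dense_bwd(matrix(dy, 1L, B), cc$dp$out, p$dense2$W)
    grads$dense2$W <- d2$dW
    grads$dense2$b <- d2$db
    da1 <- dropout_bwd(d2$dX, cc$dp$mask)
    dz1 <- relu_bwd(da1, cc$a1$mask)
    d1 <- dense_bwd(dz1, cc$h0, p$dense1$W)
    grads$dense1$W <- d1$dW
    grads$dense1$b <- d1$db
    dh0 <- d1$dX
    dv_task <- array(dh0[seq_len(Dh * R), , drop = FALSE], c(Dh, R, B))
  }
  ds_task <- squash_bwd(dv_task, cc$rt$squash_cache)
  ds_sf <- NULL
  if (sf_weight > 0) {
    Fmat <- matrix(fw$v, Dh * R, B)
    sf_loss <- sparse_filtering_loss(Fmat)
    dv_sf <- array(sf_weight * sparse_filtering_grad(Fmat), c(Dh, R, B))
    ds_sf <- squash_bwd(dv_sf, cc$rt$squash_cache)
  }
  ds_w <- if (is.null(ds_sf)) ds_task else ds_task + ds_sf
  cb <- caps_digit_bwd_cpp(cc$u, p$digit$W, cc$rt$C, ds_task, ds_w,
                           cdim, P2, maps, B, Dh, R)
  grads$digit$W <- cb$dW
  dZp <- squash_bwd(cb$du, cc$sq1)
  dfeat <- aperm(dZp, c(1, 3, 2, 4))             # (cdim, maps, P2, B)
  dim(dfeat) <- c(cdim * maps, P2, B)
  if (cfg$use_attention) {
    ab <- attention_bwd(dfeat, cc$att$caches, p$attn)
    grads$attn$Wq <- ab$dWq
    grads$attn$Wk <- ab$dWk
    grads$attn$Wv <- ab$dWv
    dfeat <- ab$dA
  }
  b2 <- conv1d_bwd(dfeat, cc$c2$cache, p$conv2$W)
  grads$conv2$W <- b2$dW
  grads$conv2$b <- b2$db
  dr1 <- relu_bwd(b2$dA, cc$r1$mask)
  b1 <- conv1d_bwd(dr1, cc$c1$cache, p$conv1$W)
  grads$conv1$W <- b1$dW
  grads$conv1$b <- b1$db
  list(grads = grads, sf_loss = sf_loss)
}

forward_cnn <- function(model, X, FV = NULL, train = FALSE) {
  cfg <- model$config
  p <- model$params
  nl <- cfg$cnn_num_layers
  pad <- (cfg$cnn_kernel - 1L) %/% 2L
  a <- X
  blocks <- vector("list", nl)
  for (i in seq_len(nl)) {
    blk <- p[[paste0("block", i)]]
    cv <- conv1d_fwd(a, blk$conv$W, blk$conv$b, cfg$cnn_kernel, pad = pad)
    rl <- relu_fwd(cv$out)
    mp <- maxpool2_fwd(rl$out)
    dp <- dropout_fwd(mp$out, cfg$dropout_rate, train)
    a <- dp$out
    at <- NULL
    if (model$attention) {
      at <- attention_fwd(a, blk$attn)
      a <- at$out
    }
    blocks[[i]] <- list(cv = cv, rl = rl, mp = mp, dp = dp, at = at)
  }
  B <- dim(a)[3]
  h0 <- matrix(a, prod(dim(a)[1:2]), B)
  z1 <- dense_fwd(h0, p$dense1$W, p$dense1$b)
  a1 <- relu_fwd(z1)
  dph <- dropout_fwd(a1$out, cfg$dropout_rate, train)
  yhat <- dense_fwd(dph$out, p$dense2$W, p$dense2$b)
  list(yhat = as.numeric(yhat),
       cache = list(blocks = blocks, h0 = h0, a1 = a1, dph = dph,
                    top_dim = dim(a), B = B))
}

backward_cnn <- function(model, fw, dy) {
  cfg <- model$config
  p <- model$params
  cc <- fw$cache
  B <- cc$B
  grads <- zero_like(p)
  d2 <- dense_bwd(matrix(dy, 1L, B), cc$dph$out, p$dense2$W)
  grads$dense2$W <- d2$dW
  grads$dense2$b <- d2$db
  da1 <- dropout_bwd(d2$dX, cc$dph$mask)
  dz1 <- relu_bwd(da1, cc$a1$mask)
  d1 <- dense_bwd(dz1, cc$h0, p$dense1$W)
  grads$dense1$W <- d1$dW
  grads$dense1$b <- d1$db
  da <- array(d1$dX, cc$top_dim)
  for (i in rev(seq_len(cfg$cnn_num_layers))) {
    blk <- p[[paste0("block", i)]]
    bc <- cc$blocks[[i]]
    if (model$attention) {
      ab <- attention_bwd(da, bc$at$caches, blk$attn)
      grads[[paste0("block", i)]]$attn$Wq <- ab$dWq
      grads[[paste0("block", i)]]$attn$Wk <- ab$dWk
      grads[[paste0("block", i)]]$attn$Wv <- ab$dWv
      da <- ab$dA
    }
    da <- dropout_bwd(da, bc$dp$mask)
    da <- maxpool2_bwd(da, bc$mp)
    da <- relu_bwd(da, bc$rl$mask)
    cb <- conv1d_bwd(da, bc$cv$cache, blk$conv$W)
    grads[[paste0("block", i)]]$conv$W <- cb$dW
    grads[[paste0("block", i)]]$conv$b <- cb$db
    da <- cb$dA
  }
  list(grads = grads, sf_loss = NA_real_)
}

model_forward <- function(model, X, FV, train = FALSE) {
  if (model$type == "dscnet") forward_dscnet(model, X, FV, train)
  else forward_cnn(model, X, FV, train)
}

# ---- training ------------------------------------------------------------

#' Coerce segments to the model input array
#'
#' Stacks preprocessed segments into the `(1, length, n)` array consumed by
#' the models.
#'
#' @param segments List of equal-length [ppg_segment()]s.
#' @return Numeric array of dimension `(1, segment length, n)`.
#' @export
segments_to_array <- function(segments) {
  lens <- vapply(segments, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) != 1L) {
    stop_input("all segments must share one length")
  }
  array(unlist(lapply(segments, `[[`, "samples")),
        c(1L, lens[1], length(segments)))
}

#' Train a glucose regression model
#'
#' Minimises `MSE(yhat, y) + lambda * SF(v)` where SF is the
#' sparse-filtering objective over the digit-capsule activations (capsule
#' model only), with Adam updates, seeded shuffling/dropout, and early
#' stopping on the RMSE of an internal validation carve-out. In
#' `alternating` mode the sparse-filtering gradient is applied to the
#' capsule transform weights in separate unsupervised steps. Inputs are
#' standardized internally (feature columns and targets); predictions are
#' returned on the mmol/L scale by [predict_bgl()].
#'
#' @param model An untrained `bgl_model` from [build_dscnet()] or
#'   [build_cnn_baseline()].
#' @param x Segment array `(1, input_len, n)` (see [segments_to_array()]).
#' @param y Reference BGL vector (mmol/L), length n.
#' @param fv Optional feature matrix (36 x n) when the model consumes the
#'   feature vector.
#' @param tc A [train_config()].
#' @return List with `model` (trained, best-validation weights restored)
#'   and `history` (per-epoch data.frame: `train_rmse`, `val_rmse`,
#'   `sf_loss`, all RMSE in mmol/L).
#' @export
train_model <- function(model, x, y, fv = NULL, tc = train_config()) {
  stopifnot(inherits(model, "bgl_model"))
  if (length(dim(x)) != 3L) stop_input("`x` must be a (1, len, n) array")
  n <- dim(x)[3]
  if (n != length(y) || n < 2L) stop_input("need matching x / y with n >= 2")
  if (!all(is.finite(y))) stop_input("targets must be finite")
  if (model$fv_dim > 0L) {
    if (is.null(fv) || nrow(fv) != model$fv_dim || ncol(fv) != n) {
      stop_input("model expects a ", model$fv_dim, " x n feature matrix")
    }
  } else {
    fv <- NULL
  }
  set.seed(as.integer(tc$seed %% .Machine$integer.max))
  # standardisation fitted on the training inputs only
  norms <- list(y_center = mean(y), y_scale = max(stats::sd(y), 1e-8))
  yz <- (y - norms$y_center) / norms$y_scale
  if (!is.null(fv)) {
    norms$fv_center <- rowMeans(fv)
    norms$fv_scale <- pmax(apply(fv, 1, stats::sd), 1e-8)
    fv <- (fv - norms$fv_center) / norms$fv_scale
  }
  model$norms <- norms
  # validation carve-out for early stopping
  n_val <- floor(tc$val_fraction * n)
  if (n_val >= 1L && n - n_val >= 2L) {
    vi <- sample.int(n, n_val)
    ti <- setdiff(seq_len(n), vi)
  } else {
    ti <- seq_len(n)
    vi <- ti
  }
  state <- adam_init(model$params)
  best <- list(val = Inf, params = model$params)
  wait <- 0L
  t_adam <- 0L
  hist <- vector("list", tc$epochs)
  rmse_on <- function(idx) {
    preds <- numeric(0)
    for (chunk in split(idx, ceiling(seq_along(idx) / 32))) {
      fwc <- model_forward(model, x[, , chunk, drop = FALSE],
                           if (is.null(fv)) NULL else
                             fv[, chunk, drop = FALSE], train = FALSE)
      preds <- c(preds, fwc$yhat)
    }
    sqrt(mean((preds - yz[idx])^2)) * norms$y_scale
  }
  sf_counter <- 0L
  for (ep in seq_len(tc$epochs)) {
    perm <- sample(ti)
    sf_vals <- numeric(0)
    sse <- 0
    for (batch in split(perm, ceiling(seq_along(perm) / tc$batch_size))) {
      Xb <- x[, , batch, drop = FALSE]
      Fb <- if (is.null(fv)) NULL else fv[, batch, drop = FALSE]
      fw <- model_forward(model, Xb, Fb, train = TRUE)
      err <- fw$yhat - yz[batch]
      sse <- sse + sum(err^2)
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop("training diverged: non-finite loss at epoch ", ep,
             call. = FALSE)
      }
      dy <- 2 * err / length(batch)
      joint_sf <- model$type == "dscnet" && tc$sf_weight > 0 &&
        tc$sf_mode == "joint"
      bw <- if (model$type == "dscnet") {
        backward_dscnet(model, fw, dy,
                        sf_weight = if (joint_sf) tc$sf_weight else 0)
      } else {
        backward_cnn(model, fw, dy)
      }
      if (!is.na(bw$sf_loss)) sf_vals <- c(sf_vals, bw$sf_loss)
      t_adam <- t_adam + 1L
      up <- adam_step(model$params, bw$grads, state, tc$learning_rate,
                      t_adam)
      model$params <- up$p
      state <- up$s
      # alternating mode: a periodic unsupervised sparse-filtering step
      # that updates only the capsule transform weights
      if (model$type == "dscnet" && tc$sf_weight > 0 &&
          tc$sf_mode == "alternating") {
        sf_counter <- sf_counter + 1L
        if (sf_counter %% tc$sf_every == 0L) {
          fw2 <- model_forward(model, Xb, Fb, train = FALSE)
          bw2 <- backward_dscnet(model, fw2, numeric(length(batch)),
                                 sf_weight = tc$sf_weight,
                                 supervised = FALSE)
          sf_vals <- c(sf_vals, bw2$sf_loss)
          t_adam <- t_adam + 1L
          up2 <- adam_step(model$params["digit"], bw2$grads["digit"],
                           state["digit"], tc$learning_rate, t_adam)
          model$params$digit <- up2$p$digit
          state$digit <- up2$s$digit
        }
      }
    }
    # running training RMSE over the epoch's minibatches (pre-update)
    tr_rmse <- sqrt(sse / length(ti)) * norms$y_scale
    val_rmse <- rmse_on(vi)
    hist[[ep]] <- data.frame(epoch = ep, train_rmse = tr_rmse,
                             val_rmse = val_rmse,
                             sf_loss = if (length(sf_vals)) mean(sf_vals)
                             else NA_real_)
    if (val_rmse < best$val - 1e-8) {
      best <- list(val = val_rmse, params = model$params)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) break
    }
  }
  model$params <- best$params
  model$trained <- TRUE
  list(model = model, history = do.call(rbind, hist))
}

#' Predict blood glucose
#'
#' Forward pass in evaluation mode (no dropout), de-standardized to mmol/L
#' and clamped to the physiological range \[1, 30\] (with a warning when
#' clamping activates). Stateless: predictions are invariant to batch
#' ordering.
#'
#' @param model A trained `bgl_model`.
#' @param x Segment array `(1, input_len, n)`.
#' @param fv Optional feature matrix (36 x n) for feature-consuming models.
#' @return Numeric vector of n predictions (mmol/L).
#' @export
predict_bgl <- function(model, x, fv = NULL) {
  stopifnot(inherits(model, "bgl_model"))
  if (!isTRUE(model$trained)) stop_input("model has not been trained")
  if (length(dim(x)) != 3L || dim(x)[2] != model$input_len) {
    stop_input("`x` must be a (1, ", model$input_len, ", n) array")
  }
  n <- dim(x)[3]
  if (model$fv_dim > 0L) {
    if (is.null(fv) || nrow(fv) != model$fv_dim || ncol(fv) != n) {
      stop_input("model expects a ", model$fv_dim, " x n feature matrix")
    }
    fv <- (fv - model$norms$fv_center) / model$norms$fv_scale
  } else {
    fv <- NULL
  }
  preds <- numeric(0)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / 32))) {
    fw <- model_forward(model, x[, , chunk, drop = FALSE],
                        if (is.null(fv)) NULL else
                          fv[, chunk, drop = FALSE], train = FALSE)
    preds <- c(preds, fw$yhat)
  }
  out <- preds * model$norms$y_scale + model$norms$y_center
  if (any(out < 1 | out > 30)) {
    warning("predictions clamped to the [1, 30] mmol/L range")
    out <- clamp(out, 1, 30)
  }
  out
}

#' Save / load a trained model
#'
#' `save_model()` writes the weights to a single serialized file and a
#' human-readable JSON sidecar (`<path>.json`) carrying the model type,
#' configuration, standardization parameters and parameter count;
#' `load_model()` restores the model.
#'
#' @param model A `bgl_model`.
#' @param path Checkpoint path (e.g. `model.ckpt`).
#' @return `save_model()` returns `path` invisibly; `load_model()` the
#'   restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "bgl_model"))
  saveRDS(model, path)
  sidecar <- list(type = model$type, n_params = model$n_params,
                  input_len = model$input_len, trained = model$trained,
                  config = unclass(model$config),
                  norms = lapply(model$norms, unname))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "bgl_model"))
  model
}
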