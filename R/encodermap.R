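#' Configuration of the autoencoder embedder
#'
#' Defaults follow the reference hyperparameters for this class of embedder:
#' three hidden layers of 128 tanh units in both encoder and decoder, a linear
#' 2-unit bottleneck, Adam optimization with learning rate 1e-5, L2 weight
#' penalty 1e-5, mini-batches of 256 frames and cost weights
#' `(w_auto, w_dist, w_center) = (1, 500, 1e-4)`. Features are treated as
#' non-periodic reals (`periodicity = Inf`); a periodic-feature pathway is
#' deliberately not implemented, as closeness fingerprints are non-periodic.
#'
#' @param learning_rate Adam learning rate (> 0)
#' @param regularization_const L2 penalty weight on all layer weights
#' @param periodicity must be `Inf`: features are plain reals
#' @param n_steps number of stochastic gradient steps (>= 1)
#' @param batch_size frames per mini-batch (>= 2; the pairwise cost needs
#'   pairs). Pair distances are computed over all in-batch pairs, so the
#'   per-step pair sample is `batch_size * (batch_size - 1) / 2`.
#' @param hidden_widths integer vector of hidden layer widths (encoder order;
#'   mirrored in the decoder)
#' @param latent_dim bottleneck width (>= 1, default 2)
#' @param w_auto,w_dist,w_center cost weights: reconstruction, sigmoid
#'   pairwise-distance, and a small centering penalty keeping the latent
#'   cloud near the origin
#' @param seed integer seed controlling weight initialization and batch
#'   sampling; fixed seed + fixed hardware gives a reproducible run
#' @return object of class `encodermap_config`
#' @export
encodermap_config <- function(learning_rate = 1e-5,
                              regularization_const = 1e-5,
                              periodicity = Inf,
                              n_steps = 2000L,
                              batch_size = 256L,
                              hidden_widths = c(128L, 128L, 128L),
                              latent_dim = 2L,
                              w_auto = 1, w_dist = 500, w_center = 1e-4,
                              seed = 1L) {
  if (learning_rate <= 0) stop("input error: learning_rate must be > 0")
  if (n_steps < 1L) stop("input error: n_steps must be >= 1")
  if (batch_size < 2L) stop("input error: batch_size must be >= 2")
  if (latent_dim < 1L) stop("input error: latent_dim must be >= 1")
  if (!is.infinite(periodicity)) {
    stop("input error: only periodicity = Inf is supported (non-periodic features)")
  }
  structure(list(
    learning_rate = learning_rate,
    regularization_const = regularization_const,
    periodicity = Inf,
    n_steps = as.integer(n_steps),
    batch_size = as.integer(batch_size),
    hidden_widths = as.integer(hidden_widths),
    latent_dim = as.integer(latent_dim),
    w_auto = w_auto, w_dist = w_dist, w_center = w_center,
    seed = as.integer(seed)
  ), class = "encodermap_config")
}

#' Mean squared reconstruction cost
#'
#' @param X input feature matrix
#' @param X_hat decoded feature matrix of identical shape
#' @return mean of squared elementwise differences; 0 iff `X == X_hat`
#' @export
reconstruction_cost <- function(X, X_hat) {
  X <- as.matrix(X); X_hat <- as.matrix(X_hat)
  if (!all(dim(X) == dim(X_hat))) stop("input error: shape mismatch")
  mean((X - X_hat)^2)
}

# pairwise Euclidean distance matrix of the rows of X (zero diagonal)
pairwise_distances <- function(X) {
  s <- rowSums(X^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(X)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  sqrt(d2)
}

#' Sigmoid pairwise-distance (sketch) cost
#'
#' Mean over unordered in-batch pairs (i < j) of
#' `(s_h(R_ij) - s_l(r_ij))^2`, where `R_ij` and `r_ij` are Euclidean
#' distances between frames i and j in the high-dimensional fingerprint space
#' and the low-dimensional map, and `s_h`, `s_l` are the two sigmoids of
#' `params`. Zero iff the transformed distance matrices coincide. The mean
#' (rather than sum) makes the cost batch-size independent.
#'
#' @param X high-dimensional batch (rows = frames)
#' @param Z matching low-dimensional coordinates (same row count)
#' @param params a [sigmoid_params()]
#' @return non-negative scalar
#' @export
sketch_distance_cost <- function(X, Z, params) {
  X <- as.matrix(X); Z <- as.matrix(Z)
  if (nrow(X) != nrow(Z)) stop("input error: X and Z row counts differ")
  if (nrow(X) < 2L) stop("input error: pairwise cost needs at least 2 rows")
  sh <- sigmoid_transform(pairwise_distances(X), params$sigma_h, params$a_h, params$b_h)
  sl <- sigmoid_transform(pairwise_distances(Z), params$sigma_l, params$a_l, params$b_l)
  dif2 <- (sh - sl)^2
  sum(dif2[upper.tri(dif2)]) / (nrow(X) * (nrow(X) - 1) / 2)
}

## ---- network internals -----------------------------------------------------

# Glorot-uniform initialization of the full layer stack.
# Widths: n_in, hidden..., latent, rev(hidden)..., n_in.
# tanh on hidden layers, linear bottleneck and linear output.
init_network <- function(n_in, hidden_widths, latent_dim) {
  widths <- c(n_in, hidden_widths, latent_dim, rev(hidden_widths), n_in)
  n_layers <- length(widths) - 1L
  latent_layer <- length(hidden_widths) + 1L
  layers <- vector("list", n_layers)
  for (l in seq_len(n_layers)) {
    fan_in <- widths[l]; fan_out <- widths[l + 1L]
    lim <- sqrt(6 / (fan_in + fan_out))
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out),
      b = rep(0, fan_out),
      act = if (l == latent_layer || l == n_layers) "linear" else "tanh"
    )
  }
  list(layers = layers, latent_layer = latent_layer, widths = widths)
}

# forward pass caching all activations; A[[1]] = input, A[[l+1]] = layer l output
net_forward <- function(net, X) {
  A <- vector("list", length(net$layers) + 1L)
  A[[1L]] <- X
  for (l in seq_along(net$layers)) {
    lay <- net$layers[[l]]
    Zl <- sweep(A[[l]] %*% lay$W, 2L, lay$b, "+")
    A[[l + 1L]] <- if (lay$act == "tanh") tanh(Zl) else Zl
  }
  A
}

encode_forward <- function(net, X) {
  A <- X
  for (l in seq_len(net$latent_layer)) {
    lay <- net$layers[[l]]
    Zl <- sweep(A %*% lay$W, 2L, lay$b, "+")
    A <- if (lay$act == "tanh") tanh(Zl) else Zl
  }
  A
}

decode_forward <- function(net, Z) {
  A <- Z
  for (l in (net$latent_layer + 1L):length(net$layers)) {
    lay <- net$layers[[l]]
    Zl <- sweep(A %*% lay$W, 2L, lay$b, "+")
    A <- if (lay$act == "tanh") tanh(Zl) else Zl
  }
  A
}

# total cost and analytic gradients on one batch.
# Returns cost components and per-layer gradients (dW, db).
encodermap_cost_grad <- function(net, X, config, sparams) {
  m <- nrow(X)
  A <- net_forward(net, X)
  L <- length(net$layers)
  Lz <- net$latent_layer
  Z <- A[[Lz + 1L]]
  X_hat <- A[[L + 1L]]

  c_auto <- mean((X - X_hat)^2)

  DH <- pairwise_distances(X)
  DL <- pairwise_distances(Z)
  sh <- sigmoid_transform(DH, sparams$sigma_h, sparams$a_h, sparams$b_h)
  sl <- sigmoid_transform(DL, sparams$sigma_l, sparams$a_l, sparams$b_l)
  npairs <- m * (m - 1) / 2
  dif <- sl - sh
  c_dist <- sum(dif[upper.tri(dif)]^2) / npairs
  c_center <- mean(Z^2)

  reg <- 0
  for (l in seq_len(L)) reg <- reg + sum(net$layers[[l]]$W^2)
  c_reg <- config$regularization_const * reg
  total <- config$w_auto * c_auto + config$w_dist * c_dist +
    config$w_center * c_center + c_reg

  ## gradient wrt Z from the pairwise cost:
  ## dC/dZ_i = (1/P) sum_j f'(DL_ij) (Z_i - Z_j)/DL_ij, f' = 2 dif * sl'(DL)
  slp <- sigmoid_transform_deriv(DL, sparams$sigma_l, sparams$a_l, sparams$b_l)
  Wmat <- 2 * dif * slp
  Wmat <- ifelse(DL > 0, Wmat / DL, 0)
  diag(Wmat) <- 0
  gZ_dist <- (rowSums(Wmat) * Z - Wmat %*% Z) / npairs
  gZ_extra <- config$w_dist * gZ_dist +
    config$w_center * 2 * Z / length(Z)

  ## backprop: delta = dC/d(layer output)
  grads <- vector("list", L)
  delta <- config$w_auto * 2 * (X_hat - X) / length(X)
  for (l in L:1) {
    out <- A[[l + 1L]]
    lay <- net$layers[[l]]
    dpre <- if (lay$act == "tanh") delta * (1 - out^2) else delta
    grads[[l]] <- list(
      dW = crossprod(A[[l]], dpre) + 2 * config$regularization_const * lay$W,
      db = colSums(dpre)
    )
    delta <- dpre %*% t(lay$W)
    if (l == Lz + 1L) delta <- delta + gZ_extra  # inject latent-cost gradient
  }

  list(total = total, auto = c_auto, dist = c_dist, center = c_center,
       reg = c_reg, grads = grads, Z = Z, X_hat = X_hat)
}

# Adam update; state holds first/second moments and step counter
adam_init <- function(net) {
  list(t = 0L, m = lapply(net$layers, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  }), v = lapply(net$layers, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  }))
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[paste0("d", p)]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / bc1
      vhat <- state$v[[l]][[p]] / bc2
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

## ---- public training / projection API -------------------------------------

#' Train the autoencoder embedder on a fingerprint matrix
#'
#' Minimizes `w_auto * C_auto + w_dist * C_sketch + w_center * C_center + L2`
#' by mini-batch Adam for `n_steps` steps, where `C_auto` is the mean squared
#' reconstruction error, `C_sketch` the sigmoid-transformed pairwise-distance
#' cost ([sketch_distance_cost()]) and `C_center` a small penalty on squared
#' latent coordinates. Pair distances are evaluated over all pairs inside
#' each mini-batch (a subsample of all frame pairs); with
#' `batch_size >= nrow(features)` every batch is the full dataset and the
#' cost is exact.
#'
#' A fixed `config$seed` makes weight initialization and batch sampling
#' reproducible; identical hardware then reproduces the run (floating-point
#' reductions may differ across platforms in the last bits).
#'
#' @param features a normalized `fingerprint_matrix` (or plain numeric
#'   matrix, rows = frames)
#' @param config an [encodermap_config()]
#' @param params a [sigmoid_params()]
#' @return an `encodermap_model`: layer weights, config and sigmoid-parameter
#'   snapshots, a per-step training `trace` (total / reconstruction /
#'   distance cost) and `final_projection`, the latent coordinates of the
#'   full training set at the final weights
#' @export
train_encodermap <- function(features, config = encodermap_config(),
                             params = sigmoid_params()) {
  X <- feature_values(features, require_normalized = TRUE)
  if (anyNA(X) || !all(is.finite(X))) stop("input error: NaN in features")
  m <- nrow(X)
  if (m < config$batch_size) {
    stop("input error: need at least batch_size (", config$batch_size,
         ") frames, got ", m)
  }
  set.seed(config$seed)
  net <- init_network(ncol(X), config$hidden_widths, config$latent_dim)
  state <- adam_init(net)
  trace <- matrix(NA_real_, config$n_steps, 3L,
                  dimnames = list(NULL, c("total", "auto", "dist")))
  for (step in seq_len(config$n_steps)) {
    idx <- if (m == config$batch_size) seq_len(m) else
      sample.int(m, config$batch_size)
    cg <- encodermap_cost_grad(net, X[idx, , drop = FALSE], config, params)
    if (!is.finite(cg$total)) {
      stop("training error: non-finite cost at step ", step)
    }
    upd <- adam_step(net, cg$grads, state, config$learning_rate)
    net <- upd$net; state <- upd$state
    trace[step, ] <- c(cg$total, cg$auto, cg$dist)
  }
  model <- structure(list(
    net = net, config = config, params = params,
    n_features = ncol(X),
    feature_names = colnames(X),
    trace = as.data.frame(trace)
  ), class = "encodermap_model")
  model$final_projection <- encode_forward(net, X)
  model
}

#' @export
print.encodermap_model <- function(x, ...) {
  cat(sprintf(
    "encodermap_model: %d -> %d -> %d, %d training steps, final cost %.4g\n",
    x$n_features, x$config$latent_dim, x$n_features,
    nrow(x$trace), x$trace$total[nrow(x$trace)]))
  invisible(x)
}

feature_values <- function(features, require_normalized = FALSE) {
  if (inherits(features, "fingerprint_matrix")) {
    if (require_normalized && !features$normalized) {
      warning("features are not max-normalized; call normalize_fingerprints() first")
    }
    return(features$values)
  }
  as.matrix(features)
}

#' Project features into the low-dimensional map
#'
#' Deterministic encoder forward pass: identical inputs give identical
#' coordinates.
#'
#' @param model an `encodermap_model`
#' @param features matrix or `fingerprint_matrix` with the model's feature
#'   dimension
#' @return a `projected_map`: list with `coords` (m x latent_dim),
#'   `frame_ids` and an (initially empty) `cv` data frame for coloring
#' @export
project_map <- function(model, features) {
  X <- feature_values(features)
  if (ncol(X) != model$n_features) {
    stop("input error: feature dimension ", ncol(X),
         " does not match model input width ", model$n_features)
  }
  coords <- encode_forward(model$net, X)
  structure(list(coords = coords, frame_ids = seq_len(nrow(coords)),
                 cv = data.frame(row.names = seq_len(nrow(coords)))),
            class = "projected_map")
}

#' @export
print.projected_map <- function(x, ...) {
  cat(sprintf("projected_map: %d frames x %d dims; CV columns: %s\n",
              nrow(x$coords), ncol(x$coords),
              if (ncol(x$cv)) paste(names(x$cv), collapse = ", ") else "none"))
  invisible(x)
}

#' Attach a collective-variable series to a projected map for coloring
#'
#' @param pmap a `projected_map`
#' @param name column name
#' @param values numeric vector, one value per frame
#' @return the map with the CV column added
#' @export
add_cv <- function(pmap, name, values) {
  if (length(values) != nrow(pmap$coords)) {
    stop("input error: CV length ", length(values), " != ", nrow(pmap$coords),
         " frames")
  }
  pmap$cv[[name]] <- as.numeric(values)
  pmap
}

#' Decode features through the trained autoencoder
#'
#' Encoder followed by decoder; output has the shape of the input.
#'
#' @inheritParams project_map
#' @return decoded feature matrix
#' @export
reconstruct <- function(model, features) {
  X <- feature_values(features)
  if (ncol(X) != model$n_features) {
    stop("input error: feature dimension ", ncol(X),
         " does not match model input width ", model$n_features)
  }
  decode_forward(model$net, encode_forward(model$net, X))
}

#' Save / load a trained model as a self-describing JSON checkpoint
#'
#' The checkpoint stores all layer weights at full precision together with
#' the configuration and sigmoid parameters, so a reloaded model projects
#' identically.
#'
#' @param model an `encodermap_model`
#' @param path checkpoint file (JSON)
#' @return `path` / the reloaded model
#' @export
save_model <- function(model, path) {
  obj <- list(
    format = "rinmap-encodermap-checkpoint",
    version = 1L,
    n_features = model$n_features,
    feature_names = model$feature_names,
    latent_layer = model$net$latent_layer,
    widths = model$net$widths,
    config = unclass(model$config),
    params = unclass(model$params),
    layers = lapply(model$net$layers, function(l) {
      list(dim = dim(l$W), W = as.numeric(l$W), b = l$b, act = l$act)
    }),
    trace = as.list(model$trace)  # column-wise arrays
  )
  # Inf is not a JSON number; periodicity is stored as the string "Inf"
  obj$config$periodicity <- "Inf"
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such checkpoint: ", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "rinmap-encodermap-checkpoint")) {
    stop("I/O error: not a rinmap model checkpoint: ", path)
  }
  cfg <- lapply(obj$config, function(v) if (length(v) > 1L) unlist(v) else v)
  cfg$periodicity <- Inf
  config <- do.call(encodermap_config,
                    cfg[intersect(names(cfg), names(formals(encodermap_config)))])
  params <- do.call(sigmoid_params, lapply(obj$params, as.numeric))
  layers <- lapply(obj$layers, function(l) {
    list(W = matrix(as.numeric(unlist(l$W)), unlist(l$dim)[1], unlist(l$dim)[2]),
         b = as.numeric(unlist(l$b)), act = l$act[[1]])
  })
  net <- list(layers = layers, latent_layer = as.integer(obj$latent_layer),
              widths = as.integer(unlist(obj$widths)))
  trace <- as.data.frame(lapply(obj$trace, function(v) as.numeric(unlist(v))))
  structure(list(net = net, config = config, params = params,
                 n_features = as.integer(obj$n_features),
                 feature_names = as.character(unlist(obj$feature_names)),
                 trace = trace),
            class = "encodermap_model")
}
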